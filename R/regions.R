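#' Read target regions from BED or GFF/GTF
#'
#' Loads the annotated regions (typically protein-coding genes) over which
#' editing windows are tiled. Regions are returned coordinate-sorted with
#' overlapping records merged per chromosome, so that no genomic base is
#' tiled twice; when merged records disagree on strand the merged region's
#' strand is set to \code{"*"} (unknown).
#'
#' Coordinates are 0-based half-open throughout the package; GFF/GTF input
#' (1-based closed) is converted on load, which is the only place a
#' coordinate conversion happens.
#'
#' @param path Path to a BED (3+ columns) or GFF3/GTF file.
#' @param format \code{"auto"} (by file extension), \code{"bed"}, or
#'   \code{"gff"}.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), \code{strand} (\code{"+"}, \code{"-"} or
#'   \code{"*"}) and \code{name}, sorted by chromosome then start.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t251\tgeneA", "chr1\t150\t300\tgeneB"), bed)
#' read_regions(bed)   # one merged region [100, 300)
#' @export
read_regions <- function(path, format = c("auto", "bed", "gff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("region file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("gff", "gff3", "gtf")) "gff" else "bed"
  }
  raw <- if (format == "bed") parse_bed(path) else parse_gff(path)
  merge_regions(raw)
}

# BED is parsed directly so malformed lines can be reported by line number
parse_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      name = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 3L))
    stop("malformed BED line ", idx[which(nfield < 3L)[1]],
         ": fewer than 3 tab-separated fields", call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad))
    stop("malformed BED line ", idx[bad[1]],
         ": start/end must be integers with 0 <= start < end",
         call. = FALSE)
  name <- vapply(seq_along(fields), function(i)
    if (nfield[i] >= 4L) fields[[i]][4L] else ".", "")
  strand <- vapply(seq_along(fields), function(i)
    if (nfield[i] >= 6L && fields[[i]][6L] %in% c("+", "-"))
      fields[[i]][6L] else "*", "")
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             name = name, stringsAsFactors = FALSE)
}

parse_gff <- function(path) {
  gr <- rtracklayer::import(path)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "?"] <- "*"
  nm <- if (!is.null(gr$Name)) as.character(gr$Name)
        else if (!is.null(gr$gene_id)) as.character(gr$gene_id)
        else if (!is.null(gr$ID)) as.character(gr$ID)
        else rep(".", length(gr))
  nm[is.na(nm)] <- "."
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,   # 1-based closed -> 0-based half-open
             end = BiocGenerics::end(gr),
             strand = strand, name = nm, stringsAsFactors = FALSE)
}

merge_regions <- function(df) {
  if (!nrow(df)) return(df)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = df$strand)
  red <- GenomicRanges::reduce(gr, ignore.strand = TRUE, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  strand <- vapply(seq_along(red), function(i) {
    s <- unique(df$strand[revmap[[i]]])
    if (length(s) == 1L) s else "*"
  }, "")
  name <- vapply(seq_along(red), function(i) {
    nms <- unique(df$name[revmap[[i]]])
    nms <- nms[nms != "."]
    if (length(nms)) paste(nms, collapse = ",") else "."
  }, "")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = BiocGenerics::start(red) - 1L,
                    end = BiocGenerics::end(red),
                    strand = strand, name = name, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start + 1L, regions$end),
                         strand = regions$strand)
}

#' Tile regions into non-overlapping windows
#'
#' Each region is tiled left to right into consecutive windows of exactly
#' \code{window_size} nucleotides, anchored at the region start; a final
#' shorter remainder window is kept when the region length is not a multiple
#' of the window size. Windows never span region boundaries.
#'
#' @param regions Data.frame of merged regions as returned by
#'   \code{\link{read_regions}}.
#' @param window_size Positive integer window width in nucleotides.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), \code{strand} and \code{window_id}
#'   (\code{"chrom:start-end"}).
#' @examples
#' reg <- data.frame(chrom = "chr1", start = 0L, end = 120L,
#'                   strand = "+", name = "g")
#' tile_windows(reg, 51)   # [0,51), [51,102), [102,120)
#' @export
tile_windows <- function(regions, window_size) {
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1L)
    stop("window_size must be a positive integer", call. = FALSE)
  if (!nrow(regions)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      window_id = character(), stringsAsFactors = FALSE))
  }
  pieces <- lapply(seq_len(nrow(regions)), function(i) {
    s <- regions$start[i]; e <- regions$end[i]
    starts <- seq.int(s, e - 1L, by = window_size)
    ends <- pmin(starts + window_size, e)
    data.frame(chrom = regions$chrom[i], start = starts, end = ends,
               strand = regions$strand[i], stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, pieces)
  win <- win[order(win$chrom, win$start), , drop = FALSE]
  win$window_id <- sprintf("%s:%d-%d", win$chrom, win$start, win$end)
  rownames(win) <- NULL
  win
}
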