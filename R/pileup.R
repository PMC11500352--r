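#' Per-position base counts for two sample sets
#'
#' The central count container: for every position inside the target regions
#' it holds the reference base and, for every sample of both sets, the
#' number of reads observing A, C, G and T after quality filtering. Coverage
#' at a position is the sum of the four base counts (all matches plus all
#' mismatches). Positions whose reference base is N are dropped at
#' construction.
#'
#' @param sites Data.frame with columns \code{chrom}, \code{pos} (0-based)
#'   and \code{ref} (one of A/C/G/T).
#' @param counts Integer array of dimension (sites, 4 bases A/C/G/T,
#'   samples) with sample names on the third dimension.
#' @param set1,set2 Character vectors of sample identifiers forming the two
#'   sets; together they must equal the array's sample names, be disjoint
#'   and non-empty.
#' @return An object of class \code{"site_counts"}.
#' @export
site_counts <- function(sites, counts, set1, set2) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref") %in% names(sites)),
            length(dim(counts)) == 3L, dim(counts)[2] == 4L,
            dim(counts)[1] == nrow(sites))
  samples <- dimnames(counts)[[3]]
  if (is.null(samples)) stop("counts array must carry sample names")
  if (!length(set1) || !length(set2))
    stop("each sample set needs at least one sample", call. = FALSE)
  if (anyDuplicated(c(set1, set2)))
    stop("sample identifiers must be unique across both sets", call. = FALSE)
  if (!setequal(c(set1, set2), samples))
    stop("set1/set2 must jointly name every sample in the counts array",
         call. = FALSE)
  keep <- sites$ref %in% BASES
  sites <- sites[keep, , drop = FALSE]
  counts <- counts[keep, , , drop = FALSE]
  if (any(counts < 0)) stop("negative base counts", call. = FALSE)
  dimnames(counts)[[2]] <- BASES
  rownames(sites) <- NULL
  structure(list(sites = sites,
                 counts = counts,
                 samples = samples,
                 set1 = as.character(set1),
                 set2 = as.character(set2)),
            class = "site_counts")
}

#' @export
print.site_counts <- function(x, ...) {
  cat(sprintf("site_counts: %d positions x %d samples (%d + %d)\n",
              nrow(x$sites), length(x$samples),
              length(x$set1), length(x$set2)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$sites$chrom), collapse = ", ")))
  invisible(x)
}

#' Per-sample, per-position coverage
#'
#' Coverage is the sum of the four observed-base counts at a position.
#'
#' @param x A \code{"site_counts"} object.
#' @return Numeric matrix (positions x samples).
#' @export
site_coverage <- function(x) {
  cov <- colSums(aperm(x$counts, c(2L, 1L, 3L)), dims = 1L)
  dimnames(cov) <- list(NULL, x$samples)
  cov
}

# enumerate all region positions with their reference base; ref-N dropped
site_universe <- function(regions, ref_fasta) {
  fa <- Rsamtools::FaFile(ref_fasta)
  if (!file.exists(paste0(ref_fasta, ".fai"))) Rsamtools::indexFa(ref_fasta)
  fa_seqs <- GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(fa))
  missing <- setdiff(unique(regions$chrom), fa_seqs)
  if (length(missing))
    stop("region chromosomes absent from reference: ",
         paste(missing, collapse = ", "), call. = FALSE)
  gr <- regions_to_granges(regions)
  seqs <- Rsamtools::getSeq(fa, gr)
  pieces <- lapply(seq_len(nrow(regions)), function(i) {
    data.frame(chrom = regions$chrom[i],
               pos = seq.int(regions$start[i], regions$end[i] - 1L),
               ref = strsplit(as.character(seqs[[i]]), "")[[1]],
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, pieces)
  sites[sites$ref %in% BASES, , drop = FALSE]
}

#' Pile up one sample's alignments over the target regions
#'
#' Counts, for every position inside the regions, the read bases A/C/G/T
#' from alignments passing the mapping- and base-quality thresholds.
#' Deletions, reference skips (introns), insertions and N bases contribute
#' nothing; each read contributes at most one base per position.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param regions Merged region data.frame (see \code{\link{read_regions}}).
#' @param ref_fasta Path to the indexed reference FASTA.
#' @param cfg A \code{\link{run_config}} object.
#' @return A list with \code{sites} (chrom, pos, ref; ref-N positions
#'   dropped) and \code{counts}, an integer matrix (positions x 4 bases).
#'   Positions without qualifying reads carry zero counts.
#' @export
pileup_counts <- function(bam, regions, ref_fasta, cfg = run_config()) {
  if (!file.exists(bam)) stop("BAM file not found: ", bam, call. = FALSE)
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index (.bai) not found for: ", bam, call. = FALSE)
  sites <- site_universe(regions, ref_fasta)
  bf <- Rsamtools::BamFile(bam)
  hdr_seqs <- GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(bf))
  missing <- setdiff(unique(regions$chrom), hdr_seqs)
  if (length(missing))
    stop("region chromosomes absent from BAM header of ", bam, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  flag <- if (cfg$exclude_duplicates) {
    Rsamtools::scanBamFlag(isDuplicate = FALSE, isUnmappedQuery = FALSE)
  } else {
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  }
  sbp <- Rsamtools::ScanBamParam(which = regions_to_granges(regions),
                                 flag = flag,
                                 mapqFilter = cfg$min_mapping_quality)
  pp <- Rsamtools::PileupParam(
    max_depth = cfg$max_depth,
    min_base_quality = cfg$min_base_quality,
    min_mapq = cfg$min_mapping_quality,
    min_nucleotide_depth = 1L,
    distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE,
    include_deletions = FALSE,
    include_insertions = FALSE)
  pu <- Rsamtools::pileup(bf, scanBamParam = sbp, pileupParam = pp)
  counts <- matrix(0L, nrow(sites), 4L, dimnames = list(NULL, BASES))
  if (nrow(pu)) {
    pu <- pu[as.character(pu$nucleotide) %in% BASES, , drop = FALSE]
    key <- paste(pu$seqnames, pu$pos - 1L)        # pileup positions are 1-based
    site_key <- paste(sites$chrom, sites$pos)
    row <- match(key, site_key)
    ok <- !is.na(row)
    col <- match(as.character(pu$nucleotide), BASES)
    # merged regions are disjoint, so (row, col) pairs are unique per query
    counts[cbind(row[ok], col[ok])] <-
      counts[cbind(row[ok], col[ok])] + pu$count[ok]
  }
  list(sites = sites, counts = counts)
}

#' Merge per-sample pileups into one count container
#'
#' All samples must have been piled up over the same regions and reference,
#' so their site tables agree. Positions absent from a sample's alignments
#' are present with zero counts, never missing.
#'
#' @param per_sample Named list of per-sample results from
#'   \code{\link{pileup_counts}}; names are the sample identifiers.
#' @param set1,set2 Character vectors assigning the sample names to the two
#'   sets.
#' @return A \code{\link{site_counts}} object.
#' @export
merge_site_counts <- function(per_sample, set1, set2) {
  stopifnot(length(per_sample) >= 2L, !is.null(names(per_sample)))
  ref_sites <- per_sample[[1]]$sites
  for (nm in names(per_sample)) {
    s <- per_sample[[nm]]$sites
    if (!identical(s$chrom, ref_sites$chrom) ||
        !identical(s$pos, ref_sites$pos))
      stop("sample ", nm, " was piled up over different positions",
           call. = FALSE)
    if (!identical(s$ref, ref_sites$ref))
      stop("inconsistent reference bases across samples (sample ", nm, ")",
           call. = FALSE)
  }
  arr <- array(0L, dim = c(nrow(ref_sites), 4L, length(per_sample)),
               dimnames = list(NULL, BASES, names(per_sample)))
  for (i in seq_along(per_sample)) arr[, , i] <- per_sample[[i]]$counts
  site_counts(ref_sites, arr, set1, set2)
}

#' Observed mismatch count at eligible sites
#'
#' For mismatch class x->y, returns for each position the count of reads
#' observing base y in the given sample when the reference base is x.
#' Positions whose reference base is not x are ineligible for the class and
#' returned as \code{NA} (absent), not zero.
#'
#' @param x A \code{"site_counts"} object.
#' @param sample Sample identifier.
#' @param class Two-letter mismatch class, e.g. \code{"AG"}.
#' @return Integer vector over positions; \code{NA} where ineligible.
#' @examples
#' # ref A with observed counts A=7, G=3 yields m = 3 for class "AG"
#' @export
mismatch_count <- function(x, sample, class) {
  check_class(class)
  stopifnot(sample %in% x$samples)
  m <- x$counts[, class_obs(class), sample]
  m[x$sites$ref != class_ref(class)] <- NA_integer_
  m
}
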