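#' Simulate per-position base counts with known ground truth
#'
#' Generates a seeded synthetic dataset emulating the data model the
#' detector assumes: A-to-G mismatches carry editing signal plus background
#' noise, while the remaining mismatch classes carry background noise only,
#' so the decoy classes form a valid null for the focal class. The reference
#' is drawn uniformly over A/C/G/T, per-site per-sample coverage follows a
#' negative binomial, and observed bases are multinomial with mass
#' (1 - error - editing) on the reference base, editing level (plus
#' error/3) on the editing target, and error/3 on each remaining base.
#'
#' Editing sites are placed on reference-A positions at
#' \code{editing_site_density}, with per-site levels drawn from a beta
#' distribution shared by both sets. In planted windows every reference-A
#' position becomes an editing site (dense, repeat-like editing) and the
#' set2 level is shifted by the planted amount, clipped to [0, 1]; planted
#' windows are therefore the only source of expected between-set
#' differences. SNP sites move a fixed fraction of the reference mass to an
#' alternative base in the designated scope.
#'
#' @param n_set1,n_set2 Samples per set.
#' @param n_regions Number of simulated regions (one chromosome each).
#' @param region_length Length of each region in nucleotides.
#' @param window_size Window width used for planting and ground truth.
#' @param coverage_mean,coverage_dispersion Negative-binomial mean and size
#'   of the per-site per-sample coverage draw.
#' @param error_rate Per-base background mismatch probability, applied
#'   symmetrically to all mismatch classes.
#' @param editing_site_density Fraction of reference-A positions that are
#'   editing sites outside planted windows.
#' @param editing_level_shape Length-2 beta shape parameters of the per-site
#'   editing level.
#' @param planted_windows \code{NULL}, or a data.frame with columns
#'   \code{window} (row index into the tiled window table) and
#'   \code{delta_level} (additive set2 - set1 editing-level difference).
#' @param snp_sites \code{NULL}, or a data.frame with columns \code{chrom},
#'   \code{pos} (0-based), \code{alt} (base), \code{frac} (alt-allele
#'   fraction) and \code{scope} (\code{"both"}, \code{"set1"} or
#'   \code{"set2"}).
#' @param error_skew Optional named numeric vector of per-class multipliers
#'   of the background error (names are mismatch classes); used to probe
#'   robustness when the symmetric-noise assumption is violated.
#' @param antisense_density Fraction of reference-T positions carrying a
#'   T-to-C channel (editing on the opposite strand of an unstranded
#'   library); levels equal in both sets. Default 0.
#' @param seed Integer seed; identical parameters and seed give identical
#'   counts.
#' @return A list with \code{counts} (a \code{\link{site_counts}} object),
#'   \code{regions}, \code{windows}, and \code{truth} — per-site true
#'   levels per set and per-window expected delta plus planted labels.
#' @export
simulate_editing_counts <- function(n_set1 = 3L, n_set2 = 3L,
                                    n_regions = 20L, region_length = 510L,
                                    window_size = 51L,
                                    coverage_mean = 50, coverage_dispersion = 10,
                                    error_rate = 0.001,
                                    editing_site_density = 0.1,
                                    editing_level_shape = c(2, 8),
                                    planted_windows = NULL,
                                    snp_sites = NULL,
                                    error_skew = NULL,
                                    antisense_density = 0,
                                    seed = 1L) {
  stopifnot(n_set1 >= 1L, n_set2 >= 1L, n_regions >= 1L,
            region_length >= 1L, coverage_mean > 0,
            error_rate >= 0, error_rate <= 1,
            editing_site_density >= 0, editing_site_density <= 1,
            length(editing_level_shape) == 2L)
  local_seed(seed)

  regions <- data.frame(chrom = sprintf("sim%03d", seq_len(n_regions)),
                        start = 0L, end = as.integer(region_length),
                        strand = "+", name = sprintf("sim%03d", seq_len(n_regions)),
                        stringsAsFactors = FALSE)
  windows <- tile_windows(regions, window_size)
  n_sites <- n_regions * region_length
  sites <- data.frame(chrom = rep(regions$chrom, each = region_length),
                      pos = rep.int(seq_len(region_length) - 1L, n_regions),
                      ref = sample(BASES, n_sites, replace = TRUE),
                      stringsAsFactors = FALSE)
  widx <- assign_windows(sites, windows)

  # per-site editing levels, identical in both sets unless planted
  lvl1 <- numeric(n_sites)
  is_a <- sites$ref == "A"
  edited <- is_a & runif(n_sites) < editing_site_density
  lvl1[edited] <- rbeta(sum(edited), editing_level_shape[1],
                        editing_level_shape[2])
  lvl2 <- lvl1
  planted_flag <- rep(FALSE, nrow(windows))
  planted_level <- rep(0, nrow(windows))
  if (!is.null(planted_windows) && nrow(planted_windows)) {
    stopifnot(all(c("window", "delta_level") %in% names(planted_windows)),
              all(planted_windows$window >= 1L),
              all(planted_windows$window <= nrow(windows)))
    for (i in seq_len(nrow(planted_windows))) {
      w <- planted_windows$window[i]
      dl <- planted_windows$delta_level[i]
      in_w <- which(widx == w & is_a)
      newly <- in_w[!edited[in_w]]
      if (length(newly)) {
        lvl1[newly] <- rbeta(length(newly), editing_level_shape[1],
                             editing_level_shape[2])
        lvl2[newly] <- lvl1[newly]
        edited[newly] <- TRUE
      }
      lvl2[in_w] <- pmin(pmax(lvl1[in_w] + dl, 0), 1)
      planted_flag[w] <- TRUE
      planted_level[w] <- dl
    }
  }
  tc_lvl <- numeric(n_sites)
  if (antisense_density > 0) {
    is_t <- sites$ref == "T"
    tc <- is_t & runif(n_sites) < antisense_density
    tc_lvl[tc] <- rbeta(sum(tc), editing_level_shape[1],
                        editing_level_shape[2])
  }

  skew <- setNames(rep(1, 12), mismatch_classes())
  if (!is.null(error_skew)) {
    unknown <- setdiff(names(error_skew), mismatch_classes())
    if (length(unknown)) stop("unknown classes in error_skew: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    skew[names(error_skew)] <- error_skew
  }

  # per-set base-probability matrices (sites x ACGT)
  base_probs <- function(lvl) {
    p <- matrix(0, n_sites, 4L, dimnames = list(NULL, BASES))
    for (x in BASES) {
      rows <- sites$ref == x
      if (!any(rows)) next
      for (y in setdiff(BASES, x))
        p[rows, y] <- error_rate / 3 * skew[paste0(x, y)]
      p[rows, x] <- 1 - rowSums(p[rows, setdiff(BASES, x), drop = FALSE])
    }
    p[, "G"] <- p[, "G"] + ifelse(sites$ref == "A", lvl, 0)
    p[, "A"] <- p[, "A"] - ifelse(sites$ref == "A", lvl, 0)
    p[, "C"] <- p[, "C"] + ifelse(sites$ref == "T", tc_lvl, 0)
    p[, "T"] <- p[, "T"] - ifelse(sites$ref == "T", tc_lvl, 0)
    p
  }
  p_set <- list(set1 = base_probs(lvl1), set2 = base_probs(lvl2))

  if (!is.null(snp_sites) && nrow(snp_sites)) {
    stopifnot(all(c("chrom", "pos", "alt", "frac") %in% names(snp_sites)))
    scope <- if ("scope" %in% names(snp_sites)) snp_sites$scope
             else rep("both", nrow(snp_sites))
    key <- paste(sites$chrom, sites$pos)
    rows <- match(paste(snp_sites$chrom, snp_sites$pos), key)
    if (anyNA(rows)) stop("SNP site outside simulated regions", call. = FALSE)
    for (i in seq_len(nrow(snp_sites))) {
      r <- rows[i]; alt <- snp_sites$alt[i]; fr <- snp_sites$frac[i]
      ref <- sites$ref[r]
      if (alt == ref) stop("SNP alt base equals reference", call. = FALSE)
      for (s in c("set1", "set2")) {
        if (scope[i] != "both" && scope[i] != s) next
        p_set[[s]][r, alt] <- p_set[[s]][r, alt] + fr
        p_set[[s]][r, ref] <- p_set[[s]][r, ref] - fr
        if (p_set[[s]][r, ref] < -1e-9)
          stop("SNP fraction plus editing/error exceeds 1 at ",
               snp_sites$chrom[i], ":", snp_sites$pos[i], call. = FALSE)
        p_set[[s]][r, ref] <- max(p_set[[s]][r, ref], 0)
      }
    }
  }

  samples <- c(sprintf("s1_%d", seq_len(n_set1)),
               sprintf("s2_%d", seq_len(n_set2)))
  set1 <- samples[seq_len(n_set1)]
  set2 <- samples[n_set1 + seq_len(n_set2)]
  arr <- array(0L, dim = c(n_sites, 4L, length(samples)),
               dimnames = list(NULL, BASES, samples))
  for (s in seq_along(samples)) {
    p <- if (s <= n_set1) p_set$set1 else p_set$set2
    cov <- rnbinom(n_sites, mu = coverage_mean, size = coverage_dispersion)
    arr[, , s] <- rmultinom_rows(cov, p)
  }
  counts <- site_counts(sites, arr, set1, set2)

  expected_delta <- rep(0, nrow(windows))
  contrib <- (lvl2 - lvl1)
  has <- !is.na(widx)
  if (any(has)) {
    agg <- rowsum(contrib[has], group = widx[has])
    expected_delta[as.integer(rownames(agg))] <- agg[, 1]
  }
  truth <- list(
    sites = data.frame(sites, edited = edited, level_set1 = lvl1,
                       level_set2 = lvl2, stringsAsFactors = FALSE),
    windows = data.frame(window_id = windows$window_id,
                         planted = planted_flag,
                         delta_level = planted_level,
                         expected_delta = expected_delta,
                         stringsAsFactors = FALSE))
  list(counts = counts, regions = regions, windows = windows, truth = truth)
}

# vectorized multinomial draw, one row per site, via sequential binomials
rmultinom_rows <- function(cov, p) {
  n <- length(cov)
  out <- matrix(0L, n, 4L)
  rem <- as.integer(cov)
  pleft <- rep(1, n)
  for (b in 1:3) {
    pr <- ifelse(pleft > 1e-12, pmin(pmax(p[, b] / pleft, 0), 1), 0)
    out[, b] <- rbinom(n, rem, pr)
    rem <- rem - out[, b]
    pleft <- pleft - p[, b]
  }
  out[, 4L] <- rem
  out
}

#' Materialize a count table as micro FASTA + BAM fixtures
#'
#' Writes a reference FASTA (with .fai index) and, per sample, a
#' coordinate-sorted indexed BAM in which every counted base becomes one
#' single-base aligned read at the counted position. Piling these files
#' back up with a base-quality threshold at or below \code{base_quality}
#' reproduces the input counts exactly. Additional reads (e.g. below a
#' quality threshold, to exercise filtering) can be injected via
#' \code{extra_reads}; they are not part of the counts.
#'
#' @param x A \code{\link{site_counts}} object (small; one read is emitted
#'   per counted base).
#' @param dir Output directory (created if needed).
#' @param base_quality Phred quality assigned to every counted read base.
#' @param extra_reads \code{NULL}, or a data.frame with columns
#'   \code{sample}, \code{chrom}, \code{pos} (0-based), \code{base},
#'   \code{qual} and \code{n} (copies), injected on top of the counts.
#' @return List with \code{fasta}, named \code{bams}, \code{set1},
#'   \code{set2}.
#' @export
emit_micro_bam <- function(x, dir, base_quality = 30L, extra_reads = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chroms <- unique(x$sites$chrom)
  # chromosome sequences: reference base at known sites, A elsewhere
  seqs <- lapply(chroms, function(ch) {
    rows <- x$sites$chrom == ch
    len <- max(x$sites$pos[rows]) + 1L
    s <- rep("A", len)
    s[x$sites$pos[rows] + 1L] <- x$sites$ref[rows]
    paste(s, collapse = "")
  })
  names(seqs) <- chroms
  fasta <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(seqs)), fasta)
  Rsamtools::indexFa(fasta)
  sq <- sprintf("@SQ\tSN:%s\tLN:%d", chroms, nchar(unlist(seqs)))

  bams <- setNames(character(length(x$samples)), x$samples)
  for (s in x$samples) {
    cnt <- x$counts[, , s, drop = FALSE]
    cnt <- array(cnt, dim = dim(cnt)[1:2])
    nz <- which(cnt > 0L, arr.ind = TRUE)
    n <- cnt[nz]
    chrom <- rep(x$sites$chrom[nz[, 1]], n)
    pos1 <- rep(x$sites$pos[nz[, 1]], n) + 1L
    base <- rep(BASES[nz[, 2]], n)
    qual <- rep.int(base_quality, length(base))
    if (!is.null(extra_reads)) {
      ex <- extra_reads[extra_reads$sample == s, , drop = FALSE]
      if (nrow(ex)) {
        chrom <- c(chrom, rep(ex$chrom, ex$n))
        pos1 <- c(pos1, rep(ex$pos, ex$n) + 1L)
        base <- c(base, rep(ex$base, ex$n))
        qual <- c(qual, rep(ex$qual, ex$n))
      }
    }
    ord <- order(match(chrom, chroms), pos1)
    chrom <- chrom[ord]; pos1 <- pos1[ord]; base <- base[ord]
    qual <- qual[ord]
    lines <- c("@HD\tVN:1.6\tSO:coordinate", sq,
               if (length(chrom)) sprintf(
                 "%s_r%06d\t0\t%s\t%d\t60\t1M\t*\t0\t0\t%s\t%s",
                 s, seq_along(chrom), chrom, pos1, base,
                 vapply(qual + 33L, intToUtf8, "")))
    sam <- file.path(dir, paste0(s, ".sam"))
    writeLines(lines, sam)
    bam <- Rsamtools::asBam(sam, file.path(dir, s), overwrite = TRUE,
                            indexDestination = TRUE)
    unlink(sam)
    bams[s] <- bam
  }
  list(fasta = fasta, bams = bams, set1 = x$set1, set2 = x$set2)
}
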