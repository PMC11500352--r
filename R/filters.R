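#' Allele-frequency SNP filter
#'
#' Heuristic exclusion of positions that look like genomic variants rather
#' than RNA editing: a position is excluded from mismatch class x->y for all
#' samples of both sets if, in any single sample of either set whose
#' coverage reaches \code{min_coverage}, the class mismatch frequency
#' m/c is at or above \code{snp_freq_threshold} (default 0.80, inclusive).
#' Low-coverage samples are not consulted, so an isolated 1/1 observation
#' cannot trigger the exclusion.
#'
#' @param x A \code{\link{site_counts}} object.
#' @param class Two-letter mismatch class.
#' @param cfg A \code{\link{run_config}} object; only positions with
#'   \code{ref == class_ref} can be excluded, others return \code{FALSE}.
#' @param coverage Optional precomputed coverage matrix from
#'   \code{\link{site_coverage}}.
#' @return Data.frame with one row per position: \code{chrom}, \code{pos},
#'   \code{excluded}, \code{triggering_sample} (\code{NA} when retained) and
#'   \code{observed_freq}, the maximum class frequency over the consulted
#'   samples.
#' @export
snp_filter <- function(x, class, cfg = run_config(), coverage = NULL) {
  check_class(class)
  if (is.null(coverage)) coverage <- site_coverage(x)
  n_sites <- nrow(x$sites)
  obs <- x$counts[, class_obs(class), , drop = FALSE]
  obs <- array(obs, dim = dim(obs)[c(1L, 3L)])       # positions x samples
  freq <- obs / coverage
  freq[coverage < cfg$min_coverage | coverage == 0] <- -Inf
  max_freq <- if (n_sites) apply(freq, 1L, max) else numeric(0)
  hit <- if (n_sites) max.col(freq, ties.method = "first") else integer(0)
  is_ref <- x$sites$ref == class_ref(class)
  excluded <- is_ref & is.finite(max_freq) &
    max_freq >= cfg$snp_freq_threshold
  data.frame(
    chrom = x$sites$chrom,
    pos = x$sites$pos,
    excluded = excluded,
    triggering_sample = ifelse(excluded, x$samples[hit], NA_character_),
    observed_freq = ifelse(is.finite(max_freq), max_freq, NA_real_),
    stringsAsFactors = FALSE)
}

# logical vector of positions the SNP filter removes for one class;
# identity (all FALSE) when the filter is disabled
snp_excluded_sites <- function(x, class, cfg, coverage = NULL) {
  if (!cfg$snp_filter) return(rep(FALSE, nrow(x$sites)))
  snp_filter(x, class, cfg, coverage)$excluded
}
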