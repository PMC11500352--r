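#' Per-position editing ratio
#'
#' The fraction of reads carrying the mismatch base at one position in one
#' sample: r = m / c, with m the class mismatch count and c the position's
#' coverage (all matches plus all mismatches).
#'
#' @param m Mismatch count(s), 0 <= m <= c.
#' @param c Coverage value(s), c > 0.
#' @return Numeric vector of ratios in [0, 1].
#' @examples
#' editing_ratio(3, 10)   # 0.3
#' @export
editing_ratio <- function(m, c) {
  if (any(c <= 0)) stop("coverage must be positive", call. = FALSE)
  if (any(m < 0) || any(m > c))
    stop("mismatch count must satisfy 0 <= m <= c", call. = FALSE)
  m / c
}

#' Site eligibility for a mismatch class
#'
#' A position enters the window signal of class x->y only if (i) its
#' reference base is x, (ii) its coverage reaches \code{min_coverage} in
#' every sample of both sets, and (iii) it survives the SNP filter when
#' enabled. The all-sample coverage rule guarantees that every sample's
#' editing signal sums over the identical position set, so set means stay
#' comparable and coverage differences alone cannot create a delta.
#'
#' @param x A \code{\link{site_counts}} object.
#' @param class Two-letter mismatch class.
#' @param cfg A \code{\link{run_config}} object.
#' @param coverage Optional precomputed coverage matrix.
#' @return Logical vector over positions.
#' @export
site_eligibility <- function(x, class, cfg = run_config(), coverage = NULL) {
  check_class(class)
  if (is.null(coverage)) coverage <- site_coverage(x)
  cov_ok <- rowSums(coverage >= cfg$min_coverage) == length(x$samples)
  elig <- x$sites$ref == class_ref(class) & cov_ok
  if (cfg$snp_filter)
    elig <- elig & !snp_excluded_sites(x, class, cfg, coverage)
  elig
}

# map each position to its tiling window; NA for positions outside every
# window (cannot happen when windows tile the same regions as the pileup)
assign_windows <- function(sites, windows) {
  idx <- rep(NA_integer_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    w <- which(windows$chrom == ch)
    if (!length(w)) next
    s <- which(sites$chrom == ch)
    ord <- w[order(windows$start[w])]
    j <- findInterval(sites$pos[s], windows$start[ord])
    ok <- j >= 1L & sites$pos[s] < windows$end[ord[pmax(j, 1L)]]
    idx[s[ok]] <- ord[j[ok]]
  }
  idx
}

#' Window editing signals, set means and deltas for every mismatch class
#'
#' For each of the 12 mismatch classes this computes, per window and sample,
#' the editing signal e (the sum of per-position mismatch ratios over the
#' window's eligible positions), the per-set means z1 and z2, and the
#' between-set difference delta = z2 - z1. Windows with fewer than
#' \code{min_sites_per_window} eligible positions are absent from that
#' class's table. The focal class's delta collection carries the editing
#' signal of interest; the other eleven serve as decoy null distributions.
#'
#' @param x A \code{\link{site_counts}} object.
#' @param windows Window table from \code{\link{tile_windows}}.
#' @param cfg A \code{\link{run_config}} object.
#' @param classes Mismatch classes to compute; default all 12.
#' @return Named list of class \code{"delta_sets"}: per mismatch class a
#'   data.frame with columns \code{window_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{n_sites}, \code{z1}, \code{z2},
#'   \code{delta}, plus a \code{"signals"} attribute holding the per-sample
#'   e matrix.
#' @export
build_delta_sets <- function(x, windows, cfg = run_config(),
                             classes = mismatch_classes()) {
  coverage <- site_coverage(x)
  widx <- assign_windows(x$sites, windows)
  i1 <- match(x$set1, x$samples)
  i2 <- match(x$set2, x$samples)
  out <- setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    elig <- site_eligibility(x, cl, cfg, coverage) & !is.na(widx)
    sel <- which(elig)
    if (!length(sel)) {
      out[[cl]] <- empty_delta_frame()
      next
    }
    obs <- x$counts[sel, class_obs(cl), , drop = FALSE]
    obs <- array(obs, dim = dim(obs)[c(1L, 3L)])
    r <- obs / coverage[sel, , drop = FALSE]
    grp <- widx[sel]
    e <- rowsum(r, group = grp, reorder = TRUE)           # windows x samples
    wrow <- as.integer(rownames(e))
    n_sites <- as.vector(rowsum(rep(1L, length(sel)), group = grp,
                                reorder = TRUE))
    keep <- n_sites >= cfg$min_sites_per_window
    e <- e[keep, , drop = FALSE]
    wrow <- wrow[keep]
    n_sites <- n_sites[keep]
    z1 <- rowMeans(e[, i1, drop = FALSE])
    z2 <- rowMeans(e[, i2, drop = FALSE])
    df <- data.frame(window_id = windows$window_id[wrow],
                     chrom = windows$chrom[wrow],
                     start = windows$start[wrow],
                     end = windows$end[wrow],
                     strand = windows$strand[wrow],
                     n_sites = n_sites,
                     z1 = z1, z2 = z2,
                     delta = z2 - z1,
                     stringsAsFactors = FALSE)
    rownames(df) <- NULL
    colnames(e) <- x$samples
    attr(df, "signals") <- e
    out[[cl]] <- df
  }
  structure(out, class = "delta_sets",
            set1 = x$set1, set2 = x$set2)
}

empty_delta_frame <- function() {
  data.frame(window_id = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             n_sites = integer(), z1 = numeric(), z2 = numeric(),
             delta = numeric(), stringsAsFactors = FALSE)
}

#' @export
print.delta_sets <- function(x, ...) {
  n <- vapply(x, nrow, 0L)
  cat("delta_sets: windows per mismatch class\n")
  print(n)
  invisible(x)
}
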