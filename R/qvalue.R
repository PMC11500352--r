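#' Tail count of a delta collection at a threshold
#'
#' The number of values in \code{values} at least as extreme as
#' \code{delta0}, on delta0's side: for delta0 < 0 the count of values
#' <= delta0, for delta0 > 0 the count of values >= delta0. A threshold of
#' exactly zero is maximally non-extreme and returns the full length.
#'
#' @param values Numeric vector of window deltas.
#' @param delta0 Single threshold delta.
#' @return Non-negative integer count.
#' @examples
#' tail_count(c(-3, -2, -1, 1, 2), -2)    # 2
#' tail_count(c(-3, -2, -1, 1, 2), 1.5)   # 1
#' @export
tail_count <- function(values, delta0) {
  stopifnot(length(delta0) == 1L, !is.na(delta0))
  if (delta0 < 0) sum(values <= delta0)
  else if (delta0 > 0) sum(values >= delta0)
  else length(values)
}

# tail counts for many thresholds against one sorted value set
tail_count_vec <- function(sorted_values, delta0) {
  n <- length(sorted_values)
  out <- integer(length(delta0))
  neg <- delta0 < 0
  pos <- delta0 > 0
  if (any(neg)) out[neg] <- findInterval(delta0[neg], sorted_values)
  if (any(pos)) out[pos] <- n - findInterval(delta0[pos], sorted_values,
                                             left.open = TRUE)
  out[!neg & !pos] <- n
  out
}

#' Empirical q estimate from one decoy class
#'
#' Estimates, for a focal-class delta, the expected proportion of false
#' positives among all focal deltas as or more extreme, using one decoy
#' mismatch class as the null: the ratio of the decoy tail count to the
#' focal tail count, capped at 1. The threshold delta belongs to the focal
#' collection, so the denominator is at least 1.
#'
#' @param delta0 The focal window's delta.
#' @param focal Numeric vector of focal-class deltas (containing delta0).
#' @param decoy Numeric vector of one decoy class's deltas.
#' @param size_normalize When \code{TRUE}, the decoy tail count is rescaled
#'   by length(focal)/length(decoy) before the ratio is formed.
#' @return q estimate in [0, 1]; \code{NA} when the decoy set is empty.
#' @examples
#' empirical_q(-2, focal = c(-3, -2, -1, 1, 2), decoy = c(-1, -0.5, 0.5)) # 0
#' empirical_q(-1, focal = c(-3, -2, -1, 1, 2), decoy = c(-1, -0.5, 0.5)) # 1/3
#' @export
empirical_q <- function(delta0, focal, decoy, size_normalize = FALSE) {
  if (!length(decoy)) return(NA_real_)
  num <- tail_count(decoy, delta0)
  den <- tail_count(focal, delta0)
  if (den < 1L) stop("delta0 must be a member of the focal set",
                     call. = FALSE)
  if (size_normalize) num <- num * length(focal) / length(decoy)
  min(num / den, 1.0)
}

#' Aggregate per-decoy q estimates
#'
#' The final raw q of a window is the median of its available per-decoy
#' estimates (eleven when every decoy class has windows; empty decoy classes
#' contribute nothing). For an even count the midpoint of the two central
#' values is used.
#'
#' @param estimates Numeric vector of per-decoy q estimates, possibly with
#'   \code{NA} for unavailable decoys.
#' @return The median of the available estimates.
#' @export
aggregate_decoys <- function(estimates) {
  est <- estimates[!is.na(estimates)]
  if (!length(est))
    stop("no decoy class has any windows; no null distribution can be formed",
         call. = FALSE)
  stats::median(est)
}

#' Monotonize q values within each sign tail
#'
#' Within each tail (negative and positive deltas separately), q is forced
#' to be non-increasing as |delta| grows, by a running minimum over raw q in
#' order of increasing |delta|: q_final(i) = min{ q_raw(j) : |delta_j| <=
#' |delta_i| }. Windows with identical |delta| receive identical q_final.
#' Zero-delta windows sit in neither tail and keep q_final = min(1, q_raw).
#'
#' @param delta Numeric vector of window deltas.
#' @param q_raw Numeric vector of raw (median-aggregated) q values.
#' @return Numeric vector of monotonized q values in [0, 1].
#' @examples
#' monotonize_q(c(-1, -2, -3, -4), c(0.5, 0.3, 0.4, 0.1))
#' # 0.5 0.3 0.3 0.1
#' @export
monotonize_q <- function(delta, q_raw) {
  stopifnot(length(delta) == length(q_raw))
  q_final <- pmin(q_raw, 1.0)
  for (side in c(-1, 1)) {
    tail <- which(sign(delta) == side)
    if (!length(tail)) next
    a <- abs(delta[tail])
    ord <- order(a)
    v <- q_final[tail[ord]]
    a_sorted <- a[ord]
    # ties on |delta| all take the running minimum at the tie group's end
    gid <- match(a_sorted, unique(a_sorted))
    grp_end <- cumsum(tabulate(gid))
    q_final[tail[ord]] <- cummin(v)[grp_end][gid]
  }
  q_final
}

#' Empirical q values for the focal mismatch class
#'
#' For every focal-class window this computes one q estimate per non-focal
#' mismatch class with at least one window, takes their median, caps at 1,
#' and monotonizes within each sign tail.
#'
#' @param delta_sets A \code{"delta_sets"} list from
#'   \code{\link{build_delta_sets}}.
#' @param cfg A \code{\link{run_config}} object; \code{cfg$focal} selects
#'   the focal class and \code{cfg$normalize_decoy_size} the decoy scaling.
#' @return The focal class's data.frame extended with one \code{qhat.<class>}
#'   column per decoy, \code{q_raw} and \code{q} (final, monotonized).
#'   Empty focal class gives an empty frame with a warning.
#' @export
qvalues_for_focal <- function(delta_sets, cfg = run_config()) {
  focal_cl <- cfg$focal
  if (is.null(delta_sets[[focal_cl]]))
    stop("focal class ", focal_cl, " missing from delta sets", call. = FALSE)
  focal <- delta_sets[[focal_cl]]
  decoy_cls <- setdiff(names(delta_sets), focal_cl)
  if (!nrow(focal)) {
    warning("focal class ", focal_cl, " has no windows")
    out <- focal
    out$q_raw <- numeric(0)
    out$q <- numeric(0)
    return(out)
  }
  d0 <- focal$delta
  qhat <- matrix(NA_real_, nrow(focal), length(decoy_cls),
                 dimnames = list(NULL, paste0("qhat.", decoy_cls)))
  for (k in seq_along(decoy_cls)) {
    dec <- delta_sets[[decoy_cls[k]]]$delta
    if (!length(dec)) next
    num <- tail_count_vec(sort(dec), d0)
    den <- tail_count_vec(sort(d0), d0)
    if (cfg$normalize_decoy_size) num <- num * length(d0) / length(dec)
    qhat[, k] <- pmin(num / den, 1.0)
  }
  if (all(is.na(qhat)))
    stop("no decoy class has any windows; no null distribution can be formed",
         call. = FALSE)
  q_raw <- apply(qhat, 1L, function(v) stats::median(v[!is.na(v)]))
  out <- cbind(focal, as.data.frame(qhat))
  out$q_raw <- q_raw
  out$q <- monotonize_q(d0, q_raw)
  attr(out, "signals") <- attr(focal, "signals")
  out
}
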