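#' Differential editing analysis from a count container
#'
#' The core fitting step: tiles the target regions into non-overlapping
#' windows, computes per-window editing signals, set means and deltas for
#' all 12 mismatch classes, and estimates empirical q values for the focal
#' class from the 11 decoy classes.
#'
#' @param x A \code{\link{site_counts}} object.
#' @param regions Merged region data.frame (see \code{\link{read_regions}});
#'   ignored when \code{windows} is supplied.
#' @param cfg A \code{\link{run_config}} object.
#' @param windows Optional precomputed window table from
#'   \code{\link{tile_windows}}.
#' @return An object of class \code{"widee"}: a list with \code{results}
#'   (the focal class's per-window table including \code{delta},
#'   per-decoy \code{qhat.*}, \code{q_raw} and final \code{q}),
#'   \code{delta_sets} for all classes, \code{config}, \code{windows} and
#'   the sample-set assignment.
#' @seealso \code{\link{widee}} for the BAM front end,
#'   \code{\link{write_result_table}} for the BED-like output.
#' @export
widee_counts <- function(x, regions = NULL, cfg = run_config(),
                         windows = NULL) {
  stopifnot(inherits(x, "site_counts"), inherits(cfg, "widee_config"))
  if (is.null(windows)) {
    if (is.null(regions))
      stop("either regions or windows must be supplied", call. = FALSE)
    windows <- tile_windows(regions, cfg$window_size)
  }
  if (!nrow(windows))
    stop_widee("no windows to analyze (empty region set)",
               "widee_empty_regions")
  ds <- build_delta_sets(x, windows, cfg)
  if (!nrow(ds[[cfg$focal]]))
    stop_widee(paste0("zero eligible windows for focal class ", cfg$focal),
               "widee_no_windows")
  res <- qvalues_for_focal(ds, cfg)
  ord <- order(res$chrom, res$start)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  structure(list(results = res,
                 delta_sets = ds,
                 config = cfg,
                 windows = windows,
                 set1 = x$set1,
                 set2 = x$set2,
                 call = match.call()),
            class = "widee")
}

#' Differential A-to-I editing between two sets of BAM files
#'
#' End-to-end analysis: piles up every sample's alignments over the target
#' regions, merges the counts, and runs the window/delta/q computation (see
#' \code{\link{widee_counts}}). Positive deltas mean higher editing in
#' \code{set2} (the condition set).
#'
#' @param set1,set2 Character vectors of BAM paths (coordinate-sorted,
#'   indexed) for the control and condition sets. Single-sample sets are
#'   supported.
#' @param ref_fasta Path to the indexed reference FASTA.
#' @param regions Region data.frame, or path to a BED/GFF file.
#' @param cfg A \code{\link{run_config}} object.
#' @param sample_names Optional names for the samples; defaults to BAM base
#'   names (made unique).
#' @return A \code{"widee"} object.
#' @export
widee <- function(set1, set2, ref_fasta, regions, cfg = run_config(),
                  sample_names = NULL) {
  bams <- c(set1, set2)
  if (is.null(sample_names))
    sample_names <- make.unique(sub("\\.bam$", "", basename(bams)))
  stopifnot(length(sample_names) == length(bams))
  if (is.character(regions) && length(regions) == 1L)
    regions <- read_regions(regions)
  if (!nrow(regions))
    stop_widee("empty region set", "widee_empty_regions")
  per_sample <- setNames(vector("list", length(bams)), sample_names)
  for (i in seq_along(bams))
    per_sample[[i]] <- pileup_counts(bams[i], regions, ref_fasta, cfg)
  sc <- merge_site_counts(per_sample,
                          set1 = sample_names[seq_along(set1)],
                          set2 = sample_names[length(set1) + seq_along(set2)])
  fit <- widee_counts(sc, regions = regions, cfg = cfg)
  fit$call <- match.call()
  fit
}

stop_widee <- function(msg, class) {
  stop(structure(class = c(class, "widee_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Map a run failure to a shell exit status
#'
#' Distinct non-zero codes for the distinct validation failures of a run:
#' 2 missing index/input files, 3 empty region set, 4 zero eligible
#' windows, 1 anything else.
#'
#' @param cond A condition object.
#' @return Integer exit status.
#' @export
widee_exit_code <- function(cond) {
  if (inherits(cond, "widee_empty_regions")) return(3L)
  if (inherits(cond, "widee_no_windows")) return(4L)
  if (grepl("index|not found", conditionMessage(cond))) return(2L)
  1L
}

#' @export
print.widee <- function(x, ...) {
  cat("Differential editing analysis (focal class ",
      class_ref(x$config$focal), "->", class_obs(x$config$focal), ")\n",
      sep = "")
  cat(sprintf("  samples: %d (set1) vs %d (set2)\n",
              length(x$set1), length(x$set2)))
  cat(sprintf("  windows analyzed (focal): %d of %d tiled\n",
              nrow(x$results), nrow(x$windows)))
  sig <- x$results$q <= 0.1
  cat(sprintf("  q <= 0.1: %d windows (%d with delta > 0, %d with delta < 0)\n",
              sum(sig), sum(sig & x$results$delta > 0),
              sum(sig & x$results$delta < 0)))
  invisible(x)
}

#' @export
summary.widee <- function(object, q_threshold = 0.1, ...) {
  res <- object$results
  sig <- res$q <= q_threshold
  per_class <- vapply(object$delta_sets, nrow, 0L)
  out <- list(
    focal = object$config$focal,
    n_set1 = length(object$set1), n_set2 = length(object$set2),
    q_threshold = q_threshold,
    windows_per_class = per_class,
    n_focal = nrow(res),
    n_significant = sum(sig),
    n_sig_pos = sum(sig & res$delta > 0),
    n_sig_neg = sum(sig & res$delta < 0),
    delta_range = if (nrow(res)) range(res$delta) else c(NA, NA),
    top = utils::head(res[order(res$q, -abs(res$delta)),
                          c("window_id", "delta", "n_sites", "q")], 10L))
  class(out) <- "summary.widee"
  out
}

#' @export
print.summary.widee <- function(x, ...) {
  cat(sprintf("Focal class %s: %d windows, %d at q <= %g (#+ %d, #- %d)\n",
              x$focal, x$n_focal, x$n_significant, x$q_threshold,
              x$n_sig_pos, x$n_sig_neg))
  cat("Windows per mismatch class:\n")
  print(x$windows_per_class)
  cat("Top windows by q:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.widee <- function(x, ...) x$results

#' Bland-Altman-style view of window deltas
#'
#' Plots each focal-class window's delta against its mean set signal
#' (z1 + z2)/2, marking windows at or below the q threshold, optionally
#' alongside the same view of one decoy class (which should show noise
#' only).
#'
#' @param x A \code{"widee"} object.
#' @param q_threshold Highlight threshold. Default 0.1.
#' @param decoy \code{NULL}, or a decoy class name to show in a second
#'   panel.
#' @param ... Passed to \code{plot}.
#' @export
plot.widee <- function(x, q_threshold = 0.1, decoy = NULL, ...) {
  res <- x$results
  panels <- if (is.null(decoy)) 1L else 2L
  if (panels == 2L) {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  sig <- res$q <= q_threshold
  plot((res$z1 + res$z2) / 2, res$delta,
       col = ifelse(sig, "darkorange", "grey40"),
       pch = 20, xlab = "mean window signal (z1 + z2)/2",
       ylab = expression(delta), main = paste("focal", x$config$focal), ...)
  graphics::abline(h = 0, lty = 2)
  if (!is.null(decoy)) {
    d <- x$delta_sets[[check_class(decoy)]]
    plot((d$z1 + d$z2) / 2, d$delta, col = "grey40", pch = 20,
         xlab = "mean window signal (z1 + z2)/2",
         ylab = expression(delta), main = paste("decoy", decoy), ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}
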