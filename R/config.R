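#' Analysis configuration
#'
#' Collects and validates every threshold and convention of a differential
#' editing run in one object.
#'
#' @param window_size Window width in nucleotides used to tile the annotated
#'   regions into non-overlapping windows. Default 51.
#' @param min_coverage Minimum read coverage a position must reach in
#'   \emph{every} sample of both sets to enter any window signal. Default 10.
#' @param snp_filter Logical; when \code{TRUE}, positions whose mismatch
#'   frequency reaches \code{snp_freq_threshold} in any adequately covered
#'   sample are excluded as likely genomic variants. Default \code{FALSE}.
#' @param snp_freq_threshold Inclusive mismatch-frequency threshold of the
#'   SNP filter, a fraction in (0, 1]. Default 0.80.
#' @param focal Focal mismatch class, one of the 12 ordered base pairs
#'   (e.g. \code{"AG"} for A-to-I editing, the default). The remaining 11
#'   classes are used as decoy null distributions.
#' @param min_base_quality Minimum phred base quality for a read base to be
#'   counted in the pileup. Default 20.
#' @param min_mapping_quality Minimum mapping quality for a read to be
#'   counted. Default 0.
#' @param min_sites_per_window Minimum number of eligible positions a window
#'   must contain to be emitted for a class. Default 1.
#' @param normalize_decoy_size Logical; when \code{TRUE} each decoy tail
#'   count is rescaled by the ratio of focal to decoy set sizes before the
#'   q estimate is formed. Default \code{FALSE} (raw count ratio).
#' @param exclude_duplicates Logical; drop duplicate-flagged reads from the
#'   pileup. Default \code{FALSE} (duplicates are counted).
#' @param max_depth Pileup depth cap per position. Default 100000.
#' @param seed Optional integer seed recorded in the configuration and used
#'   by any stochastic step of a run.
#'
#' @return An object of class \code{"widee_config"} (a validated list).
#' @examples
#' cfg <- run_config(window_size = 51, min_coverage = 10)
#' cfg$focal
#' @export
run_config <- function(window_size = 51L,
                       min_coverage = 10L,
                       snp_filter = FALSE,
                       snp_freq_threshold = 0.80,
                       focal = "AG",
                       min_base_quality = 20L,
                       min_mapping_quality = 0L,
                       min_sites_per_window = 1L,
                       normalize_decoy_size = FALSE,
                       exclude_duplicates = FALSE,
                       max_depth = 100000L,
                       seed = NULL) {
  window_size <- as.integer(window_size)
  min_coverage <- as.integer(min_coverage)
  if (length(window_size) != 1L || is.na(window_size) || window_size < 1L)
    stop("window_size must be a single integer >= 1", call. = FALSE)
  if (length(min_coverage) != 1L || is.na(min_coverage) || min_coverage < 0L)
    stop("min_coverage must be a single integer >= 0", call. = FALSE)
  if (!is.logical(snp_filter) || length(snp_filter) != 1L || is.na(snp_filter))
    stop("snp_filter must be TRUE or FALSE", call. = FALSE)
  if (!is.numeric(snp_freq_threshold) || length(snp_freq_threshold) != 1L ||
      is.na(snp_freq_threshold) ||
      snp_freq_threshold <= 0 || snp_freq_threshold > 1)
    stop("snp_freq_threshold must lie in (0, 1]", call. = FALSE)
  check_class(focal)
  min_base_quality <- as.integer(min_base_quality)
  min_mapping_quality <- as.integer(min_mapping_quality)
  min_sites_per_window <- as.integer(min_sites_per_window)
  if (is.na(min_base_quality) || min_base_quality < 0L)
    stop("min_base_quality must be a non-negative integer", call. = FALSE)
  if (is.na(min_mapping_quality) || min_mapping_quality < 0L)
    stop("min_mapping_quality must be a non-negative integer", call. = FALSE)
  if (is.na(min_sites_per_window) || min_sites_per_window < 1L)
    stop("min_sites_per_window must be a positive integer", call. = FALSE)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (length(seed) != 1L || is.na(seed))
      stop("seed must be a single integer or NULL", call. = FALSE)
  }
  structure(list(
    window_size = window_size,
    min_coverage = min_coverage,
    snp_filter = isTRUE(snp_filter),
    snp_freq_threshold = snp_freq_threshold,
    focal = focal,
    q_cap = 1.0,
    min_base_quality = min_base_quality,
    min_mapping_quality = min_mapping_quality,
    min_sites_per_window = min_sites_per_window,
    normalize_decoy_size = isTRUE(normalize_decoy_size),
    exclude_duplicates = isTRUE(exclude_duplicates),
    max_depth = as.integer(max_depth),
    seed = seed
  ), class = "widee_config")
}

#' @export
print.widee_config <- function(x, ...) {
  cat("Differential editing configuration\n")
  cat(sprintf("  window size          : %d nt\n", x$window_size))
  cat(sprintf("  min coverage         : %d (all samples)\n", x$min_coverage))
  cat(sprintf("  focal mismatch class : %s->%s\n",
              class_ref(x$focal), class_obs(x$focal)))
  cat(sprintf("  SNP filter           : %s (threshold %.2f)\n",
              if (x$snp_filter) "on" else "off", x$snp_freq_threshold))
  cat(sprintf("  base/mapping quality : >=%d / >=%d\n",
              x$min_base_quality, x$min_mapping_quality))
  cat(sprintf("  min sites per window : %d\n", x$min_sites_per_window))
  if (x$normalize_decoy_size)
    cat("  decoy counts rescaled by focal/decoy set-size ratio\n")
  invisible(x)
}

#' Read a key=value configuration file
#'
#' Mirrors the command-line flags: each non-empty, non-comment line holds
#' \code{key = value}, keys matching the arguments of \code{\link{run_config}}.
#'
#' @param path Path to the configuration file.
#' @return A \code{"widee_config"} object.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(parts[1]); val <- trimws(parts[2])
    args[[key]] <- if (val %in% c("TRUE", "FALSE", "true", "false")) {
      toupper(val) == "TRUE"
    } else if (grepl("^-?[0-9.]+$", val)) {
      as.numeric(val)
    } else val
  }
  unknown <- setdiff(names(args), names(formals(run_config)))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, args)
}
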