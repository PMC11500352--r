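RESULT_COLUMNS <- c("chrom", "start", "end", "window_id", "delta", "strand",
                    "q_value", "n_sites", "mean_signal_set1",
                    "mean_signal_set2")

#' Write the BED-like result table
#'
#' Serializes per-window records as a tab-delimited table with columns
#' chrom, start (0-based), end (half-open), window_id, delta, strand,
#' q_value, n_sites, mean_signal_set1, mean_signal_set2, sorted by
#' chromosome then start. Classes without q values (decoy tables) carry NA
#' in the q_value column. Writing then re-reading is the identity on all
#' fields.
#'
#' @param records Data.frame as produced by \code{\link{widee_counts}}
#'   (\code{$results}) or one element of \code{\link{build_delta_sets}}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_result_table <- function(records, path) {
  df <- data.frame(
    chrom = records$chrom,
    start = records$start,
    end = records$end,
    window_id = records$window_id,
    delta = records$delta,
    strand = ifelse(records$strand %in% c("+", "-"), records$strand, "."),
    q_value = if ("q" %in% names(records)) records$q
              else rep(NA_real_, nrow(records)),
    n_sites = records$n_sites,
    mean_signal_set1 = records$z1,
    mean_signal_set2 = records$z2,
    stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(RESULT_COLUMNS, collapse = "\t"), con)
  if (nrow(df)) {
    fmt <- function(v) {
      if (is.double(v)) {
        out <- vapply(v, function(x)
          if (is.na(x)) "NA" else format(x, digits = 15, scientific = FALSE,
                                         trim = TRUE), "")
        out
      } else as.character(v)
    }
    cols <- lapply(df, fmt)
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Read a result table written by \code{\link{write_result_table}}
#'
#' @param path Path to the tab-delimited result file.
#' @return Data.frame with the documented columns.
#' @export
read_result_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t",
             colClasses = c(chrom = "character", start = "integer",
                            end = "integer", window_id = "character",
                            delta = "numeric", strand = "character",
                            q_value = "numeric", n_sites = "integer",
                            mean_signal_set1 = "numeric",
                            mean_signal_set2 = "numeric"),
             stringsAsFactors = FALSE)
}

#' Run the full analysis and write its result files
#'
#' Drives the complete pipeline on alignment files: pileup, window signals
#' and deltas for all 12 mismatch classes, q values for the focal class,
#' then one result table per class (named \code{<class>.tsv}; q values only
#' in the focal class's file), a JSON run manifest and a log. The manifest
#' records the configuration, input checksums, package version, per-class
#' window counts and the focal windows at q <= 0.1 split by delta sign.
#'
#' @param set1,set2 Character vectors of BAM paths for the two sets.
#' @param ref_fasta Indexed reference FASTA path.
#' @param regions Region data.frame or BED/GFF path.
#' @param out_dir Output directory (created if needed).
#' @param cfg A \code{\link{run_config}} object.
#' @param sample_names Optional sample names.
#' @param quiet Suppress progress messages. Default \code{FALSE}.
#' @return The \code{"widee"} fit, invisibly.
#' @export
widee_run <- function(set1, set2, ref_fasta, regions, out_dir,
                      cfg = run_config(), sample_names = NULL,
                      quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  logmsg <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   paste0(...))
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }
  logmsg("analysis start: ", length(set1), " vs ", length(set2), " samples")
  region_path <- if (is.character(regions)) regions else NULL
  if (!is.null(region_path)) regions <- read_regions(region_path)
  logmsg("regions: ", nrow(regions), " merged intervals on ",
         length(unique(regions$chrom)), " chromosomes")
  fit <- widee(set1, set2, ref_fasta, regions, cfg,
               sample_names = sample_names)
  for (cl in names(fit$delta_sets)) {
    tab <- if (cl == cfg$focal) fit$results else fit$delta_sets[[cl]]
    write_result_table(tab, file.path(out_dir, paste0(cl, ".tsv")))
    logmsg("class ", cl, ": ", nrow(tab), " windows written")
  }
  res <- fit$results
  sig <- res$q <= 0.1
  inputs <- c(set1, set2, ref_fasta, region_path)
  manifest <- list(
    tool = "widee",
    version = as.character(utils::packageVersion("widee")),
    config = unclass(cfg),
    inputs = data.frame(path = inputs, md5 = tools::md5sum(inputs),
                        row.names = NULL, stringsAsFactors = FALSE),
    set1 = if (is.null(sample_names)) basename(set1)
           else sample_names[seq_along(set1)],
    set2 = if (is.null(sample_names)) basename(set2)
           else sample_names[length(set1) + seq_along(set2)],
    windows_per_class = as.list(vapply(fit$delta_sets, nrow, 0L)),
    significant_q10 = list(positive = sum(sig & res$delta > 0),
                           negative = sum(sig & res$delta < 0)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  logmsg("focal ", cfg$focal, ": ", nrow(res), " windows, ",
         sum(sig), " at q <= 0.1 (", manifest$significant_q10$positive,
         " positive, ", manifest$significant_q10$negative, " negative)")
  invisible(fit)
}
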