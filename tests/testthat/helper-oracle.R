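# Independent brute-force reference implementation of the whole statistic:
# per-position ratios summed to window signals, set means, deltas, decoy
# tail-count q estimates, median aggregation and running-minimum
# monotonization. Written as plain nested loops straight from the
# definitions; deliberately shares no code with the package internals.

oracle_all_classes <- function() {
  out <- character(0)
  for (x in c("A", "C", "G", "T"))
    for (y in c("A", "C", "G", "T"))
      if (x != y) out <- c(out, paste0(x, y))
  out
}

oracle_coverage <- function(sc, i, s) {
  sum(sc$counts[i, , s])
}

oracle_delta_sets <- function(sc, windows, cfg) {
  classes <- oracle_all_classes()
  samples <- sc$samples
  res <- list()
  for (cl in classes) {
    xb <- substr(cl, 1, 1); yb <- substr(cl, 2, 2)
    rows <- list()
    for (w in seq_len(nrow(windows))) {
      in_w <- which(sc$sites$chrom == windows$chrom[w] &
                    sc$sites$pos >= windows$start[w] &
                    sc$sites$pos < windows$end[w])
      elig <- integer(0)
      for (i in in_w) {
        if (sc$sites$ref[i] != xb) next
        ok <- TRUE
        for (s in samples)
          if (oracle_coverage(sc, i, s) < cfg$min_coverage) ok <- FALSE
        if (ok && cfg$snp_filter) {
          for (s in samples) {
            cv <- oracle_coverage(sc, i, s)
            if (cv >= cfg$min_coverage && cv > 0 &&
                sc$counts[i, yb, s] / cv >= cfg$snp_freq_threshold)
              ok <- FALSE
          }
        }
        if (ok) elig <- c(elig, i)
      }
      if (length(elig) < cfg$min_sites_per_window) next
      e <- numeric(length(samples))
      names(e) <- samples
      for (s in samples)
        for (i in elig)
          e[s] <- e[s] + sc$counts[i, yb, s] / oracle_coverage(sc, i, s)
      z1 <- mean(e[sc$set1]); z2 <- mean(e[sc$set2])
      rows[[length(rows) + 1L]] <- data.frame(
        window_id = windows$window_id[w], n_sites = length(elig),
        z1 = z1, z2 = z2, delta = z2 - z1, stringsAsFactors = FALSE)
    }
    res[[cl]] <- if (length(rows)) do.call(rbind, rows)
                 else data.frame(window_id = character(), n_sites = integer(),
                                 z1 = numeric(), z2 = numeric(),
                                 delta = numeric())
  }
  res
}

oracle_tail <- function(values, d0) {
  n <- 0L
  if (d0 < 0) { for (v in values) if (v <= d0) n <- n + 1L }
  else if (d0 > 0) { for (v in values) if (v >= d0) n <- n + 1L }
  else n <- length(values)
  n
}

oracle_qvalues <- function(delta_sets, focal, size_normalize = FALSE) {
  dfoc <- delta_sets[[focal]]$delta
  decoys <- setdiff(names(delta_sets), focal)
  nq <- length(dfoc)
  qhat <- matrix(NA_real_, nq, length(decoys), dimnames = list(NULL, decoys))
  for (k in seq_along(decoys)) {
    dd <- delta_sets[[decoys[k]]]$delta
    if (!length(dd)) next
    for (i in seq_len(nq)) {
      num <- oracle_tail(dd, dfoc[i])
      den <- oracle_tail(dfoc, dfoc[i])
      if (size_normalize) num <- num * length(dfoc) / length(dd)
      qhat[i, k] <- min(num / den, 1)
    }
  }
  q_raw <- numeric(nq)
  for (i in seq_len(nq)) {
    est <- qhat[i, ][!is.na(qhat[i, ])]
    q_raw[i] <- median(est)
  }
  # direct O(n^2) reading of the running-minimum definition
  q_final <- pmin(q_raw, 1)
  for (i in seq_len(nq)) {
    if (dfoc[i] == 0) next
    for (j in seq_len(nq)) {
      if (sign(dfoc[j]) == sign(dfoc[i]) && abs(dfoc[j]) <= abs(dfoc[i]))
        q_final[i] <- min(q_final[i], min(q_raw[j], 1))
    }
  }
  list(qhat = qhat, q_raw = q_raw, q_final = q_final)
}
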