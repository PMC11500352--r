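# Fixture builders used across the suite; everything is generated in code.

# random small count table over one chromosome tiled into n_windows windows
random_site_counts <- function(n_windows = 3L, window_size = 10L,
                               n1 = 2L, n2 = 2L, max_count = 12L) {
  len <- n_windows * window_size
  samples <- c(paste0("a", seq_len(n1)), paste0("b", seq_len(n2)))
  sites <- data.frame(chrom = "chrT",
                      pos = seq_len(len) - 1L,
                      ref = sample(c("A", "C", "G", "T"), len, replace = TRUE),
                      stringsAsFactors = FALSE)
  arr <- array(sample(0:max_count, len * 4L * length(samples), replace = TRUE),
               dim = c(len, 4L, length(samples)),
               dimnames = list(NULL, c("A", "C", "G", "T"), samples))
  site_counts(sites, arr, set1 = samples[seq_len(n1)],
              set2 = samples[n1 + seq_len(n2)])
}

fixture_regions <- function(chrom = "chrT", len = 30L) {
  data.frame(chrom = chrom, start = 0L, end = as.integer(len),
             strand = "+", name = "r", stringsAsFactors = FALSE)
}

# hand-buildable count table: one chromosome, explicit per-sample coverage
# and A->G mismatch counts at ref-A positions, clean coverage elsewhere
manual_counts <- function(n_pos, cov, ag, n1 = 2L, n2 = 2L, ref = NULL) {
  samples <- c(paste0("a", seq_len(n1)), paste0("b", seq_len(n2)))
  if (is.null(ref)) ref <- rep("A", n_pos)
  if (is.matrix(cov)) covm <- cov else covm <- matrix(cov, n_pos, n1 + n2)
  if (is.matrix(ag)) agm <- ag else agm <- matrix(ag, n_pos, n1 + n2)
  arr <- array(0L, dim = c(n_pos, 4L, n1 + n2),
               dimnames = list(NULL, c("A", "C", "G", "T"), samples))
  for (s in seq_len(n1 + n2)) {
    for (i in seq_len(n_pos)) {
      arr[i, ref[i], s] <- covm[i, s] - agm[i, s]
      tgt <- if (ref[i] == "A") "G" else setdiff(c("A", "C", "G", "T"),
                                                 ref[i])[1]
      arr[i, tgt, s] <- arr[i, tgt, s] + agm[i, s]
    }
  }
  sites <- data.frame(chrom = "chrT", pos = seq_len(n_pos) - 1L, ref = ref,
                      stringsAsFactors = FALSE)
  site_counts(sites, arr, set1 = samples[seq_len(n1)],
              set2 = samples[n1 + seq_len(n2)])
}
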