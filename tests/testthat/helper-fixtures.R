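# Small in-code fixtures shared across test files.

# Uniform single-chromosome map: n windows of equal cM width.
uniform_map <- function(n = 10, total_cm = 1, chrom = "1", bp_per_win = 1000,
                        x_chrom = NA) {
  cm_end <- seq_len(n) * total_cm / n
  genome_map(data.frame(
    chrom = chrom,
    phys_start = (seq_len(n) - 1) * bp_per_win,
    phys_end = seq_len(n) * bp_per_win,
    cm_start = c(0, cm_end[-n]),
    cm_end = cm_end), x_chrom = x_chrom)
}

# Small Drosophila-like synthetic map for simulation tests.
small_map <- function(n = 40, seed = 42) {
  make_synthetic_map(n_windows = n, seed = seed)
}

# A quick breeding design small enough for many replicates.
small_config <- function(...) {
  args <- list(mode = "bsa", N = 200, G = 6, q = 0.2, depth = 200,
               n_pheno = 200)
  args[names(list(...))] <- list(...)
  do.call(experiment_config, args)
}

# Hand-made null peak height distribution.
fake_null <- function(heights, n_reps) {
  structure(list(heights = heights, per_rep = NULL, n_reps = n_reps,
                 thresholds = thresholds()),
            class = "null_peak_distribution")
}

# Hand-made single-QTL prior records.
fake_records <- function(s, max_ad, peak_cm = 0, max_v = 0, pos_id = 1) {
  data.frame(rep = seq_along(s), pos_id = pos_id, s = s, max_ad = max_ad,
             peak_window = 1L, peak_cm = peak_cm, max_v = max_v)
}

# Independent triangular-weight smoother used as an oracle (plain loops,
# no shared code with smooth_profile).
smooth_oracle <- function(x, chrom_index, m) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    den <- 0
    for (d in -m:m) {
      j <- i + d
      if (j >= 1 && j <= n && chrom_index[j] == chrom_index[i]) {
        w <- m + 1 - abs(d)
        num <- num + w * x[j]
        den <- den + w
      }
    }
    out[i] <- num / den
  }
  out
}
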