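# Shared fixture builders and independent oracles.

# random non-negative profile with a controllable share of zero pixels
random_profile <- function(n, zero_frac = 0.3) {
  x <- stats::runif(n, 0, 100)
  x[stats::runif(n) < zero_frac] <- 0
  if (sum(x) == 0) x[sample.int(n, 1)] <- 1
  x
}

# brute-force prefix-DI curve: cumulative share minus the equality diagonal
prefix_di <- function(x, k) {
  if (k == 0) return(0)
  n <- length(x)
  sum(x[seq_len(k)]) / sum(x) - k / n
}

# literal transcription oracle for DI: average the doubled deviations
brute_di <- function(x) {
  n <- length(x)
  total <- sum(x)
  if (total == 0) return(0)
  acc <- 0
  for (k in seq_len(n)) {
    acc <- acc + 2 * (sum(x[1:k]) / total - k / n)
  }
  acc / n
}

# pixel-replication upsampling of a profile (resolution doubling)
duplicate_pixels <- function(x) rep(x, each = 2)

# pixel-replication upsampling of a map by an integer factor
upsample_map <- function(m, f = 2L) {
  m[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f)]
}

# closed-form two-sided p-value of a Pearson correlation
pearson_p_oracle <- function(r, n) {
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

# write a signal series (or matrix) to a temporary stacked text file
write_temp_series <- function(m, sep = " ") {
  path <- tempfile(fileext = ".txt")
  lines <- apply(m, 1, paste, collapse = sep)
  writeLines(lines, path)
  path
}
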