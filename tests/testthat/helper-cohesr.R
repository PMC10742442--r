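# Calibrated estimator parameters shared across the suite (one calibration)
acc_params <- dv_calibrate(dv_params())

# Independent oracles: plain-loop summations, kept deliberately free of the
# package's vectorised code paths.

oracle_entropy <- function(p, base = exp(1)) {
  h <- 0
  for (x in p) if (x > 0) h <- h - x * log(x, base = base)
  h
}

oracle_jsd <- function(p, q, wa, wb) {
  mix <- numeric(length(p))
  for (i in seq_along(p)) mix[i] <- wa * p[i] + wb * q[i]
  wa * (oracle_entropy(mix) - oracle_entropy(p)) +
    wb * (oracle_entropy(mix) - oracle_entropy(q))
}

oracle_incoherence <- function(prob_rows, weights, base = exp(1)) {
  n_cat <- length(prob_rows[[1L]])
  pooled <- numeric(n_cat)
  for (k in seq_along(prob_rows)) {
    for (i in seq_len(n_cat)) {
      pooled[i] <- pooled[i] + weights[k] * prob_rows[[k]][i]
    }
  }
  h_pool <- oracle_entropy(pooled, base)
  acc <- 0
  for (k in seq_along(prob_rows)) {
    acc <- acc + weights[k] * (h_pool - oracle_entropy(prob_rows[[k]], base))^2
  }
  sqrt(acc / h_pool)
}

# random categorical replicate samples over shared category labels
random_categorical_samples <- function(k, n_cat, min_count = 1L,
                                       max_count = 20L) {
  cats <- paste0("c", seq_len(n_cat))
  lapply(seq_len(k), function(i) {
    counts <- sample(min_count:max_count, n_cat, replace = TRUE)
    replicate_sample(paste0("s", i), counts = stats::setNames(counts, cats))
  })
}
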