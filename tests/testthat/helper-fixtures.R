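# small parameter sets and tracks reused across tests

toy_params <- function(window_size = 4L, eps = NULL, w = NULL, alpha = 0) {
  if (is.null(eps)) eps <- uniform_stacking_energy(window_size)
  if (is.null(w)) w <- rep(1 / (window_size - 1), window_size - 1L)
  stacking_params(eps, w, alpha = alpha, window_size = window_size)
}

# named energy table with selected overrides, zero elsewhere
energy_table <- function(...) {
  e <- stats::setNames(rep(0, 16), DINUCLEOTIDES)
  ov <- c(...)
  e[names(ov)] <- ov
  e
}

random_params <- function(window_size = 6L) {
  stacking_params(stats::setNames(stats::runif(16, 0.1, 2), DINUCLEOTIDES),
                  stats::runif(window_size - 1L, 0.1, 1),
                  alpha = stats::rnorm(1, 0, 0.3),
                  window_size = window_size)
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent slow oracle: energy by explicit loop over dinucleotides
free_energy_loop <- function(bases, params) {
  chars <- strsplit(bases, "")[[1]]
  total <- 0
  for (k in seq_len(nchar(bases) - 1L)) {
    dn <- paste0(chars[k], chars[k + 1L])
    total <- total + params$positional_weights[k] * params$stacking_energy[[dn]]
  }
  total
}

# independent slow oracle: Poisson deviance position by position
poisson_deviance_loop <- function(n, mu) {
  total <- 0
  for (i in seq_along(n)) {
    t1 <- if (n[i] > 0) n[i] * log(n[i] / mu[i]) else 0
    total <- total + 2 * (t1 - (n[i] - mu[i]))
  }
  total
}

# a tiny deterministic dataset with hand-set counts
toy_track <- function(id = "t1", seq = "ACGTACGTACGT", counts = NULL) {
  if (is.null(counts)) counts <- rep(1, nchar(seq))
  transcript_track(id, seq, counts)
}
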