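# Shared fixtures, all generated in code at test time.

options(mastertime.log_level = "quiet")

# Minimal independent generator for GPLVM unit tests: smooth (logistic)
# curves of a hidden 1-D latent plus Gaussian noise.  Deliberately written
# without the package's simulator so the two can cross-check each other.
make_smooth_data <- function(n = 60, d = 30, sigma = 0.5, seed = 1,
                             range = 16, latent = NULL) {
  set.seed(seed)
  t_true <- if (is.null(latent)) runif(n) else latent
  Y <- sapply(seq_len(d), function(j) {
    c0 <- runif(1, 0.1, 0.9)
    k <- runif(1, 4, 12)
    s <- sample(c(-1, 1), 1)
    s * range * plogis(k * (t_true - c0)) + rnorm(n, 0, sigma)
  })
  rownames(Y) <- sprintf("c%03d", seq_len(n))
  colnames(Y) <- sprintf("g%03d", seq_len(d))
  list(Y = cell_matrix(Y, modality = "test"), t_true = t_true)
}

# Small config used throughout the unit tests (full defaults are exercised
# in the acceptance tests).
quick_config <- function(seed = 1, ...) {
  run_config(seed = seed, n_restarts = 2, max_iter = 250, ...)
}

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

ks_uniform <- function(x) mastertime:::.ks_uniform_stat(x)
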