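# Internal helpers shared across modules.

#' @importFrom stats approx cor mad median optim pnorm prcomp quantile rnorm runif
#'   sd setNames var plogis pbeta
NULL

# Deterministic sub-seed derivation: one user-facing seed drives every
# stochastic step; each named step gets its own stream.  Kept below 2^31.
.sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(offset) * 7919) %% 2147483629)
}

.with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# One-sample Kolmogorov-Smirnov statistic against uniform(0, 1), computed
# directly so tied values never warn.
.ks_uniform_stat <- function(x) {
  x <- sort(x)
  n <- length(x)
  i <- seq_len(n)
  max(pmax(abs(i / n - x), abs(x - (i - 1) / n)))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.logf <- function(fmt, ...) {
  level <- getOption("mastertime.log_level", "info")
  if (identical(level, "quiet")) return(invisible(NULL))
  message(sprintf(fmt, ...))
}

# Full-precision numeric formatting for text tables: round trips through
# as.numeric() without loss.
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# Write a file atomically: stream to a sibling temp file, then rename, so a
# failure never leaves a half-written declared output.
.write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) .stopf("could not write '%s'", path)
  invisible(path)
}
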