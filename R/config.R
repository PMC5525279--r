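# Run configuration: a single object carries every tunable that affects a run,
# so that one seed plus one config reproduces any output bitwise.

#' Run configuration
#'
#' Bundles the global seed and the tunable parameters of the alignment
#' pipeline.  One `run_config` drives all stochastic steps (model
#' initialisation restarts, the simulator, permutation tests); per-step
#' sub-seeds are derived deterministically from `seed`.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_inducing Number of inducing inputs for the variational GPLVM
#'   (default 10).
#' @param n_quantiles Number of quantile anchors for the warping function
#'   (default 50, evenly spaced levels including 0 and 1).
#' @param warp_method `"auto"` (Gaussian-process regression with linear
#'   interpolation fallback when the GP mean is non-monotone), `"gp"`, or
#'   `"interp"`.
#' @param orientation Named list (by modality) of orientation rules: `"keep"`,
#'   `"reverse"`, or `"marker:<feature_id>:<increasing|decreasing>"`.
#' @param cor_method Correlation flavour used by cross-modality analyses:
#'   `"spearman"` (default, captures non-linear monotone relationships) or
#'   `"pearson"`.
#' @param n_restarts Number of optimisation restarts for the GPLVM fit
#'   (PCA initialisation plus `n_restarts - 1` seeded perturbations).
#' @param max_iter Iteration cap for the variational optimiser.
#'
#' @return An object of class `mt_config`.
#' @export
run_config <- function(seed,
                       n_inducing = 10L,
                       n_quantiles = 50L,
                       warp_method = c("auto", "gp", "interp"),
                       orientation = list(),
                       cor_method = c("spearman", "pearson"),
                       n_restarts = 3L,
                       max_iter = 400L) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed))
    .stopf("run_config: 'seed' must be a single integer")
  warp_method <- match.arg(warp_method)
  cor_method <- match.arg(cor_method)
  n_inducing <- as.integer(n_inducing)
  n_quantiles <- as.integer(n_quantiles)
  if (n_inducing < 1L) .stopf("run_config: n_inducing must be >= 1")
  if (n_quantiles < 2L) .stopf("run_config: n_quantiles must be >= 2")
  if (n_restarts < 1L) .stopf("run_config: n_restarts must be >= 1")
  for (mod in names(orientation)) .parse_orientation(orientation[[mod]])
  structure(
    list(seed = as.integer(seed), n_inducing = n_inducing,
         n_quantiles = n_quantiles, warp_method = warp_method,
         orientation = orientation, cor_method = cor_method,
         n_restarts = as.integer(n_restarts), max_iter = as.integer(max_iter)),
    class = "mt_config")
}

# Validate and decompose an orientation rule string.
.parse_orientation <- function(rule) {
  if (!is.character(rule) || length(rule) != 1)
    .stopf("orientation rule must be a single string")
  if (rule %in% c("keep", "reverse"))
    return(list(kind = rule))
  parts <- strsplit(rule, ":", fixed = TRUE)[[1]]
  if (length(parts) == 3 && parts[1] == "marker" &&
      parts[3] %in% c("increasing", "decreasing")) {
    return(list(kind = "marker", feature = parts[2], direction = parts[3]))
  }
  .stopf(paste0("unresolvable orientation rule '%s' (expected 'keep', ",
                "'reverse', or 'marker:<feature>:<increasing|decreasing>')"),
         rule)
}

#' Read a run configuration from a flat key-value file
#'
#' The file holds one `key = value` pair per line (`#` comments allowed).
#' Orientation rules use keys of the form `orientation.<modality>`.
#'
#' @param path File to read.
#' @param seed Seed to use when the file does not set one.
#' @return An `mt_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  if (!file.exists(path)) .stopf("config file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(m) != 3) .stopf("malformed config line: '%s'", ln)
    kv[[trimws(m[2])]] <- trimws(m[3])
  }
  ori <- list()
  for (k in grep("^orientation\\.", names(kv), value = TRUE)) {
    ori[[sub("^orientation\\.", "", k)]] <- kv[[k]]
  }
  get_num <- function(key, default) {
    if (is.null(kv[[key]])) default else as.numeric(kv[[key]])
  }
  get_chr <- function(key, default) {
    if (is.null(kv[[key]])) default else kv[[key]]
  }
  run_config(
    seed = get_num("seed", if (is.null(seed)) .stopf("config '%s' sets no seed", path) else seed),
    n_inducing = get_num("n_inducing", 10L),
    n_quantiles = get_num("n_quantiles", 50L),
    warp_method = get_chr("warp_method", "auto"),
    orientation = ori,
    cor_method = get_chr("cor_method", "spearman"),
    n_restarts = get_num("n_restarts", 3L),
    max_iter = get_num("max_iter", 400L))
}

#' Write a run configuration to a flat key-value file
#'
#' @param config An `mt_config`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "mt_config"))
  lines <- c(
    sprintf("seed = %d", config$seed),
    sprintf("n_inducing = %d", config$n_inducing),
    sprintf("n_quantiles = %d", config$n_quantiles),
    sprintf("warp_method = %s", config$warp_method),
    sprintf("cor_method = %s", config$cor_method),
    sprintf("n_restarts = %d", config$n_restarts),
    sprintf("max_iter = %d", config$max_iter))
  for (mod in names(config$orientation)) {
    lines <- c(lines, sprintf("orientation.%s = %s", mod, config$orientation[[mod]]))
  }
  .write_atomic(path, function(tmp) writeLines(lines, tmp))
}

#' @export
print.mt_config <- function(x, ...) {
  cat("mastertime run configuration\n")
  cat(sprintf("  seed: %d | inducing inputs: %d | quantiles: %d\n",
              x$seed, x$n_inducing, x$n_quantiles))
  cat(sprintf("  warp: %s | correlation: %s | restarts: %d | max iter: %d\n",
              x$warp_method, x$cor_method, x$n_restarts, x$max_iter))
  if (length(x$orientation)) {
    cat("  orientation:\n")
    for (mod in names(x$orientation))
      cat(sprintf("    %s = %s\n", mod, x$orientation[[mod]]))
  }
  invisible(x)
}
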