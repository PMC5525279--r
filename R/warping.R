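# Monotone warping from pseudotime to uniform master time.
#
# Pseudotime scales are modality specific: a warping function per modality
# maps them onto a common "master time" distributed uniformly on [0, 1].  The
# warp is learned by quantile alignment: the sample quantiles of pseudotime
# are matched to the theoretical quantiles of a uniform(0, 1) variable, and
# the resulting anchor pairs are smoothed either by Gaussian process
# regression or by exact piecewise-linear interpolation.  GP means are not
# guaranteed monotone; a non-monotone mean triggers the interpolation
# fallback.

#' Normalise pseudotime to the unit interval
#'
#' Affine map sending the minimum to 0 and the maximum to 1; order
#' preserving.
#'
#' @param t Numeric vector with at least two distinct values.
#' @return Vector in `[0, 1]` (names preserved).
#' @export
normalize_pseudotime <- function(t) {
  if (any(!is.finite(t))) .stopf("normalize_pseudotime: non-finite values")
  r <- range(t)
  if (r[1] == r[2])
    .stopf("normalize_pseudotime: all values equal; no ordering information")
  (t - r[1]) / (r[2] - r[1])
}

#' Learn a monotone warping function by quantile alignment
#'
#' Computes `n_quantiles` evenly spaced sample quantiles of `t` (levels
#' include 0 and 1, so the extremes are anchors and map exactly to 0 and 1)
#' and pairs them with the matching uniform(0, 1) theoretical quantiles.
#' With `method = "auto"` or `"gp"` the anchor pairs are smoothed by RBF
#' Gaussian process regression (hyperparameters by marginal likelihood); if
#' the GP mean is non-monotone on a 1000-point grid the exact
#' piecewise-linear interpolant through the anchors is used instead and
#' `method_used` records the fallback.
#'
#' @param t Pseudotime values (any scale; typically normalised to `[0, 1]`).
#' @param n_quantiles Number of quantile anchors (default 50).
#' @param method `"auto"`, `"gp"`, or `"interp"`.
#' @return An object of class `warping_function` with fields
#'   `anchor_pseudotime`, `anchor_master`, `method_used`, and (for GP warps)
#'   the smoother state.
#' @export
learn_warping <- function(t, n_quantiles = 50L, method = c("auto", "gp", "interp")) {
  method <- match.arg(method)
  n_quantiles <- as.integer(n_quantiles)
  if (n_quantiles < 2L) .stopf("learn_warping: n_quantiles must be >= 2")
  if (any(!is.finite(t))) .stopf("learn_warping: non-finite pseudotime")
  if (length(unique(t)) < 2L)
    .stopf("learn_warping: all pseudotime values equal")
  if (length(unique(t)) < n_quantiles)
    warning(sprintf("only %d distinct pseudotime values for %d quantiles",
                    length(unique(t)), n_quantiles), call. = FALSE)
  probs <- seq(0, 1, length.out = n_quantiles)
  anchors_p <- unname(quantile(t, probs = probs, type = 7))
  w <- structure(list(anchor_pseudotime = anchors_p, anchor_master = probs,
                      method_used = "interp", gp = NULL),
                 class = "warping_function")
  if (method == "interp") return(w)
  gp <- tryCatch(.gp_regress_1d(anchors_p, probs), error = function(e) NULL)
  if (!is.null(gp)) {
    raw <- .gp_predict_1d(gp, seq(anchors_p[1], anchors_p[n_quantiles],
                                  length.out = 1000))
    if (all(diff(raw) >= -1e-9) && raw[1000] > raw[1]) {
      w$method_used <- "gp"
      w$gp <- gp
      # affine rescale of the mean so the endpoint anchors hit 0 and 1
      ends <- .gp_predict_1d(gp, anchors_p[c(1, n_quantiles)])
      w$gp$rescale <- c(a = ends[1], b = ends[2] - ends[1])
      return(w)
    }
  }
  if (method == "gp")
    warning("GP warp mean is non-monotone; falling back to linear interpolation",
            call. = FALSE)
  w
}

# Plain 1-D GP regression with RBF kernel and noise, hyperparameters by
# marginal likelihood (L-BFGS-B on log parameters, numerical gradients).
# Small-n only: this smooths ~50 quantile anchors.  The anchors are exact
# sample quantiles, so the noise variance is capped at (1% of the master
# range)^2: the GP must track the quantile curve rather than smooth it away
# (badly skewed pseudotime distributions otherwise lose uniformity).  The
# price is an occasionally wiggly mean, which the monotonicity fallback in
# learn_warping() catches.
.gp_regress_1d <- function(x, y) {
  n <- length(x)
  ybar <- mean(y)
  yc <- y - ybar
  xs <- sd(x)
  if (xs == 0) .stopf("degenerate anchor set")
  nll <- function(lp) {
    sf2 <- exp(lp[1]); l2 <- exp(lp[2]); sn2 <- exp(lp[3])
    K <- .rbf_gram(x, x, sf2, l2) + sn2 * diag(n)
    R <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    v <- backsolve(R, yc, transpose = TRUE)
    val <- sum(log(diag(R))) + sum(v^2) / 2 + n * log(2 * pi) / 2
    if (!is.finite(val)) 1e10 else val
  }
  sn_hi <- 1e-4
  lp0 <- log(c(var(yc) + 1e-6, xs^2, sn_hi / 10))
  opt <- optim(lp0, nll, method = "L-BFGS-B",
               lower = rep(-18, 3), upper = c(10, 10, log(sn_hi)))
  sf2 <- exp(opt$par[1]); l2 <- exp(opt$par[2]); sn2 <- exp(opt$par[3])
  K <- .rbf_gram(x, x, sf2, l2) + sn2 * diag(n)
  R <- .chol_jitter(K)
  alpha <- backsolve(R, backsolve(R, yc, transpose = TRUE))
  list(x = x, alpha = alpha, sf2 = sf2, l2 = l2, sn2 = sn2, ybar = ybar,
       rescale = NULL)
}

.gp_predict_1d <- function(gp, xstar) {
  m <- as.vector(.rbf_gram(xstar, gp$x, gp$sf2, gp$l2) %*% gp$alpha) + gp$ybar
  if (!is.null(gp$rescale)) m <- (m - gp$rescale["a"]) / gp$rescale["b"]
  unname(m)
}

#' Apply a warping function
#'
#' Maps pseudotime to master time.  Inputs outside the anchor range are
#' clamped (master time is bounded by construction), outputs are clipped to
#' `[0, 1]`, and the map is nondecreasing; tied inputs receive identical
#' outputs.
#'
#' @param w A [learn_warping()] result.
#' @param t Pseudotime values.
#' @return Master time values in `[0, 1]`.
#' @export
apply_warping <- function(w, t) {
  stopifnot(inherits(w, "warping_function"))
  if (any(!is.finite(t))) .stopf("apply_warping: non-finite input")
  ap <- w$anchor_pseudotime
  t <- pmin(pmax(t, ap[1]), ap[length(ap)])
  out <- if (w$method_used == "gp") {
    .gp_predict_1d(w$gp, t)
  } else {
    approx(ap, w$anchor_master, xout = t, ties = list("ordered", mean))$y
  }
  pmin(pmax(out, 0), 1)
}

#' Invert a warping function
#'
#' Maps master time back to pseudotime, the direction needed to generate
#' measurements for a cell observed in another modality.  The warp is
#' evaluated on a fine grid over the anchor range and inverted by monotone
#' interpolation.
#'
#' @param w A [learn_warping()] result.
#' @param m Master time values in `[0, 1]`.
#' @return Pseudotime values within the anchor range.
#' @export
invert_warping <- function(w, m) {
  stopifnot(inherits(w, "warping_function"))
  if (any(!is.finite(m)) || any(m < 0 | m > 1))
    .stopf("invert_warping: master time must lie in [0, 1]")
  ap <- w$anchor_pseudotime
  xs <- seq(ap[1], ap[length(ap)], length.out = 1001)
  ys <- apply_warping(w, xs)
  approx(ys, xs, xout = m, ties = list("ordered", mean), rule = 2)$y
}

#' @export
print.warping_function <- function(x, ...) {
  cat(sprintf("warping_function: %d quantile anchors, method '%s'\n",
              length(x$anchor_pseudotime), x$method_used))
  cat(sprintf("  pseudotime range [%.4g, %.4g] -> master time [0, 1]\n",
              x$anchor_pseudotime[1], x$anchor_pseudotime[length(x$anchor_pseudotime)]))
  invisible(x)
}
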