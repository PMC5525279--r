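# One-dimensional Bayesian GPLVM pseudotime inference.
#
# Model: Y = f(t) + eps, f ~ GP(0, k_rbf), eps ~ N(0, sigma^2 I), with a
# single latent coordinate t per cell and a standard-normal prior on t.
# Inference maximises the collapsed variational lower bound of Titsias-style
# sparse GPLVMs: q(t_n) = N(mu_n, S_n), M inducing inputs Z, and the RBF
# "psi statistics" integrate the kernel against q(t).  The bound for one
# modality (D features, data standardised per feature, YY' precomputed) is
#
#   F = -ND/2 log(2 pi s2) - D/2 (log|C| - log|Kmm|) - tr(YY')/(2 s2)
#       + tr(Psi1' YY' Psi1 C^{-1})/(2 s2^2) - D psi0/(2 s2)
#       + D tr(Kmm^{-1} Psi2)/(2 s2)  - KL[q(t) || N(0,1)]
#
# with C = Kmm + Psi2/s2.  Gradients with respect to mu and S are analytic;
# the M + 3 inducing/kernel parameters per modality use central finite
# differences (documented numerical choice).

#' RBF kernel hyperparameters
#'
#' @param rbf_variance Signal variance (sigma_rbf^2) of the squared
#'   exponential kernel; strictly positive.
#' @param lengthscale Kernel lengthscale l; strictly positive.
#' @param noise_variance Observation noise variance (sigma^2); strictly
#'   positive.
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(rbf_variance, lengthscale, noise_variance) {
  vals <- c(rbf_variance, lengthscale, noise_variance)
  if (any(!is.finite(vals)) || any(vals <= 0))
    .stopf("kernel_params: all hyperparameters must be finite and strictly positive")
  structure(list(rbf_variance = rbf_variance, lengthscale = lengthscale,
                 noise_variance = noise_variance),
            class = "kernel_params")
}

#' Squared exponential (RBF) covariance
#'
#' `k(t_i, t_j) = sigma_rbf^2 exp(-(t_i - t_j)^2 / (2 l^2))`, vectorised over
#' its arguments.
#'
#' @param t_i,t_j Numeric vectors of latent coordinates (recycled).
#' @param params A [kernel_params()].
#' @return Numeric vector of covariances.
#' @export
rbf_kernel <- function(t_i, t_j, params) {
  stopifnot(inherits(params, "kernel_params"))
  if (any(!is.finite(t_i)) || any(!is.finite(t_j)))
    .stopf("rbf_kernel: non-finite inputs")
  params$rbf_variance *
    exp(-(t_i - t_j)^2 / (2 * params$lengthscale^2))
}

# Gram matrix between coordinate vectors.
.rbf_gram <- function(x1, x2, sf2, l2) {
  sf2 * exp(-outer(x1, x2, "-")^2 / (2 * l2))
}

# Cholesky with adaptive diagonal jitter: none if the factorisation succeeds,
# otherwise 1e-8 escalating tenfold to 1e-2 (relative to the mean diagonal)
# before raising.
.chol_jitter <- function(K) {
  scale <- mean(diag(K))
  jit <- 0
  repeat {
    R <- tryCatch(chol(K + diag(jit * scale, nrow(K))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    jit <- if (jit == 0) 1e-8 else jit * 10
    if (jit > 1e-2)
      .stopf("covariance matrix numerically singular even at maximum jitter")
  }
}

# Psi statistics of the RBF kernel under q(t_n) = N(mu_n, S_n).
.psi_stats <- function(mu, S, Z, sf2, l2) {
  denom1 <- l2 + S
  Dmu1 <- outer(mu, Z, "-")
  Psi1 <- sf2 * sqrt(l2 / denom1) * exp(-Dmu1^2 / (2 * denom1))
  dz2 <- outer(Z, Z, "-")^2
  e1v <- as.vector(exp(-dz2 / (4 * l2)))
  zbv <- as.vector(outer(Z, Z, "+") / 2)
  d2 <- l2 + 2 * S
  Dmu2 <- outer(mu, zbv, "-")
  Tn <- (sf2^2 * sqrt(l2 / d2)) * exp(-Dmu2^2 / d2)
  Psi2 <- matrix(colSums(Tn) * e1v, length(Z), length(Z))
  list(Psi1 = Psi1, Psi2 = Psi2, psi0 = length(mu) * sf2,
       Dmu1 = Dmu1, denom1 = denom1, Tn = Tn, Dmu2 = Dmu2, d2 = d2, e1v = e1v)
}

# Data term of the bound for one modality (KL excluded), optionally with
# analytic gradients w.r.t. mu and S.
#
# Numerically stable parameterisation: with Lm the Cholesky factor of Kmm and
# A = I + Lm^{-1} Psi2 Lm^{-T} / s2 (so A >= I and its factorisation is
# always well conditioned), log|C| - log|Kmm| = log|A| and
# tr(Psi1' YY' Psi1 C^{-1}) = tr(H YY' H' A^{-1}) with H = Lm^{-1} Psi1'.
# This keeps the data-fit term bounded even when Kmm is nearly singular
# (long lengthscales), which a naive C^{-1} computation does not.
.bgplvm_term <- function(mu, S, Z, sf2, l2, sn2, YYT, trY, D, want_grad = FALSE) {
  N <- length(mu)
  M <- length(Z)
  # Plateau fallback: in pathological parameter regions (overflowing solves,
  # unfactorable matrices) report a very poor but finite bound so the line
  # search backs off rather than aborting the whole optimisation.
  bad <- function() {
    out <- list(value = -1e10)
    if (want_grad) { out$gmu <- rep(0, N); out$gS <- rep(0, N) }
    out
  }
  ps <- .psi_stats(mu, S, Z, sf2, l2)
  K <- .rbf_gram(Z, Z, sf2, l2)
  R <- tryCatch(.chol_jitter(K), error = function(e) NULL)
  if (is.null(R)) return(bad())
  Lm <- t(R)
  V <- forwardsolve(Lm, t(forwardsolve(Lm, ps$Psi2)))   # Lm^{-1} Psi2 Lm^{-T}
  A <- diag(M) + (V + t(V)) / (2 * sn2)       # symmetrise
  if (any(!is.finite(A))) return(bad())
  RA <- tryCatch(.chol_jitter(A), error = function(e) NULL)
  if (is.null(RA)) return(bad())
  Ainv <- chol2inv(RA)
  H <- forwardsolve(Lm, t(ps$Psi1))           # M x N
  HY <- H %*% YYT                             # M x N
  G2 <- tcrossprod(HY, H)                     # Lm^{-1} G Lm^{-T}
  val <- -N * D / 2 * log(2 * pi * sn2) -
    D * sum(log(diag(RA))) -
    trY / (2 * sn2) +
    sum(G2 * Ainv) / (2 * sn2^2) -
    D * ps$psi0 / (2 * sn2) +
    D * sum(diag(V)) / (2 * sn2)
  # In exact arithmetic every non-constant term of the bound is <= 0, so the
  # bound can never exceed the Gaussian density ceiling -ND/2 log(2 pi s2).
  # A value above it is catastrophic cancellation (near-singular Kmm at very
  # long lengthscales); treat it as out of bounds rather than let the
  # optimiser ride numerical noise.
  ceiling <- -N * D / 2 * log(2 * pi * sn2)
  if (!is.finite(val) || val > ceiling + 1e-6 * abs(ceiling)) return(bad())
  if (!want_grad)
    return(list(value = val))
  Lminv <- forwardsolve(Lm, diag(M))
  Cinv <- crossprod(Lminv, Ainv %*% Lminv)    # Lm^{-T} A^{-1} Lm^{-1}
  Kinv <- chol2inv(R)
  W1 <- (YYT %*% ps$Psi1 %*% Cinv) / sn2^2
  G <- crossprod(ps$Psi1, YYT %*% ps$Psi1)
  CGC <- Cinv %*% G %*% Cinv
  W2 <- -D / (2 * sn2) * Cinv - CGC / (2 * sn2^3) + D / (2 * sn2) * Kinv
  w2v <- as.vector(W2) * ps$e1v
  WP <- W1 * ps$Psi1
  gmu <- rowSums(WP * (-ps$Dmu1 / ps$denom1)) +
    as.vector((ps$Tn * (-2 * ps$Dmu2 / ps$d2)) %*% w2v)
  gS <- rowSums(WP * (-1 / (2 * ps$denom1) + ps$Dmu1^2 / (2 * ps$denom1^2))) +
    as.vector((ps$Tn * (-1 / ps$d2 + 2 * ps$Dmu2^2 / ps$d2^2)) %*% w2v)
  if (any(!is.finite(gmu)) || any(!is.finite(gS))) {
    gmu <- rep(0, N); gS <- rep(0, N)
  }
  list(value = val, gmu = gmu, gS = gS,
       Psi1 = ps$Psi1, Cinv = Cinv, Kinv = Kinv)
}

# Parameter packing: c(mu, log S, then per modality c(Z, log sf2, log l2,
# log sn2)).
.unpack_par <- function(par, N, M, nmod) {
  mu <- par[seq_len(N)]
  S <- exp(par[N + seq_len(N)])
  mods <- vector("list", nmod)
  off <- 2 * N
  for (k in seq_len(nmod)) {
    Z <- par[off + seq_len(M)]
    th <- exp(par[off + M + 1:3])
    mods[[k]] <- list(Z = Z, sf2 = th[1], l2 = th[2], sn2 = th[3])
    off <- off + M + 3
  }
  list(mu = mu, S = S, mods = mods)
}

.kl_term <- function(mu, S) 0.5 * sum(mu^2 + S - log(S) - 1)

# Core optimiser shared by the single-modality and shared fits.  `data` is a
# list with one element per modality: list(YYT, trY, D).
.fit_core <- function(data, init, M, max_iter) {
  N <- length(init$mu)
  nmod <- length(data)
  par0 <- c(init$mu, log(init$S),
            unlist(lapply(seq_len(nmod), function(k)
              c(init$mods[[k]]$Z, log(init$mods[[k]]$sf2),
                log(init$mods[[k]]$l2), log(init$mods[[k]]$sn2)))))

  term_value <- function(p, k) {
    u <- .unpack_par(p, N, M, nmod)
    m <- u$mods[[k]]
    .bgplvm_term(u$mu, u$S, m$Z, m$sf2, m$l2, m$sn2,
                 data[[k]]$YYT, data[[k]]$trY, data[[k]]$D)$value
  }
  fn <- function(p) {
    u <- .unpack_par(p, N, M, nmod)
    tot <- -.kl_term(u$mu, u$S)
    for (k in seq_len(nmod)) {
      m <- u$mods[[k]]
      tot <- tot + .bgplvm_term(u$mu, u$S, m$Z, m$sf2, m$l2, m$sn2,
                                data[[k]]$YYT, data[[k]]$trY, data[[k]]$D)$value
    }
    if (!is.finite(tot)) return(1e12)
    -tot
  }
  gr <- function(p) {
    u <- .unpack_par(p, N, M, nmod)
    gmu <- -u$mu                               # -d KL / d mu
    glS <- -0.5 * (u$S - 1)                    # -d KL / d log S
    gmod <- numeric(0)
    for (k in seq_len(nmod)) {
      m <- u$mods[[k]]
      tm <- .bgplvm_term(u$mu, u$S, m$Z, m$sf2, m$l2, m$sn2,
                         data[[k]]$YYT, data[[k]]$trY, data[[k]]$D,
                         want_grad = TRUE)
      gmu <- gmu + tm$gmu
      glS <- glS + tm$gS * u$S
      # central finite differences for this modality's Z and kernel scalars
      off <- 2 * N + (k - 1) * (M + 3)
      gk <- numeric(M + 3)
      for (j in seq_len(M + 3)) {
        h <- 1e-5 * max(1, abs(p[off + j]))
        pp <- p; pp[off + j] <- p[off + j] + h
        pm <- p; pm[off + j] <- p[off + j] - h
        gk[j] <- (term_value(pp, k) - term_value(pm, k)) / (2 * h)
      }
      gmod <- c(gmod, gk)
    }
    -c(gmu, glS, gmod)
  }
  # Box constraints keep the optimiser away from overflow regions: the data
  # are standardised and the latent prior is N(0, 1), so these are slack.
  lower <- c(rep(-8, N), rep(log(1e-6), N), rep(c(rep(-8, M), rep(-12, 3)), nmod))
  upper <- c(rep(8, N), rep(log(100), N), rep(c(rep(8, M), rep(8, 3)), nmod))
  par0 <- pmin(pmax(par0, lower), upper)
  elbo_init <- -fn(par0)
  # Chained warm restarts: L-BFGS-B occasionally declares convergence on its
  # very first line search when the objective magnitude is large; restarting
  # from the current iterate resets its step scaling and costs only a couple
  # of evaluations when the optimum has truly been reached.
  opt <- list(par = par0, value = -elbo_init, convergence = 0L, message = NULL)
  for (chain in 1:3) {
    prev <- opt$value
    opt <- optim(opt$par, fn, gr, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = max_iter, factr = 1e4))
    if (prev - opt$value < abs(prev) * 1e-8) break
  }
  u <- .unpack_par(opt$par, N, M, nmod)
  list(mu = u$mu, S = u$S, mods = u$mods, elbo = -opt$value,
       elbo_init = elbo_init, convergence = opt$convergence,
       message = opt$message)
}

# Standardise features: zero mean, unit variance per feature; zero-variance
# features dropped with a logged warning.
.standardize <- function(Y) {
  vals <- Y$values
  ctr <- colMeans(vals)
  scl <- apply(vals, 2, sd)
  keep <- scl > 0
  if (!any(keep))
    .stopf("degenerate data: every feature has zero variance (all cells identical)")
  if (any(!keep))
    .logf("dropping %d zero-variance feature(s) before fitting", sum(!keep))
  Ys <- sweep(sweep(vals[, keep, drop = FALSE], 2, ctr[keep], "-"),
              2, scl[keep], "/")
  list(Ystd = Ys, center = ctr[keep], scale = scl[keep],
       features = colnames(vals)[keep])
}

.pca_init <- function(Ystd) {
  sv <- svd(Ystd, nu = 1, nv = 0)
  mu0 <- sv$u[, 1] * sv$d[1]
  s <- sd(mu0)
  if (!is.finite(s) || s == 0)
    .stopf("degenerate data: no variation across cells")
  mu0 / s
}

.inducing_init <- function(mu0, M) {
  Z <- unname(quantile(mu0, probs = seq(0, 1, length.out = M)))
  if (anyDuplicated(Z)) Z <- Z + seq(-1e-4, 1e-4, length.out = M)
  Z
}

# Build the posterior-predictive machinery at the optimum for one modality.
.predictor_at <- function(mu, S, Z, sf2, l2, sn2, Ystd) {
  ps <- .psi_stats(mu, S, Z, sf2, l2)
  M <- length(Z)
  K <- .rbf_gram(Z, Z, sf2, l2)
  R <- .chol_jitter(K)
  Lm <- t(R)
  Kinv <- chol2inv(R)
  V <- forwardsolve(Lm, t(forwardsolve(Lm, ps$Psi2)))
  A <- diag(M) + (V + t(V)) / (2 * sn2)
  Ainv <- chol2inv(.chol_jitter(A))
  Lminv <- forwardsolve(Lm, diag(M))
  Cinv <- crossprod(Lminv, Ainv %*% Lminv)
  B <- Cinv %*% crossprod(ps$Psi1, Ystd) / sn2   # M x D
  list(B = B, Kinv = Kinv, Cinv = Cinv)
}

#' Fit a one-dimensional Bayesian GPLVM
#'
#' Infers a per-cell pseudotime posterior `N(mu_n, S_n)` by maximising the
#' collapsed variational lower bound with inducing inputs.  Features are
#' standardised to zero mean and unit variance before fitting (zero-variance
#' features are dropped with a log message).  Initialisation uses the first
#' principal component; `config$n_restarts - 1` additional seeded restarts
#' perturb the initialisation and the fit with the largest final bound is
#' kept.  The latent sign is arbitrary; orientation is handled downstream
#' (see [orient_latent()]).
#'
#' @param Y A [cell_matrix()] with at least 3 cells and at least
#'   `config$n_inducing` cells.
#' @param config A [run_config()].
#' @return An object of class `gplvm_fit` with elements `latent_mean`,
#'   `latent_variance` (named by cell), `kernel` ([kernel_params()]),
#'   `inducing_inputs`, `elbo`, `elbo_init`, standardisation constants, and
#'   the training matrix.
#' @export
fit_gplvm <- function(Y, config) {
  stopifnot(inherits(Y, "cell_matrix"), inherits(config, "mt_config"))
  N <- n_cells(Y)
  M <- config$n_inducing
  if (N < 3) .stopf("fit_gplvm: need at least 3 cells, got %d", N)
  if (N < M) .stopf("fit_gplvm: n_cells (%d) must be >= n_inducing (%d)", N, M)
  std <- .standardize(Y)
  YYT <- tcrossprod(std$Ystd)
  data <- list(list(YYT = YYT, trY = sum(diag(YYT)), D = ncol(std$Ystd)))
  mu0 <- .pca_init(std$Ystd)
  best <- NULL
  failures <- character(0)
  for (r in seq_len(config$n_restarts)) {
    init <- .with_seed(.sub_seed(config$seed, 100 + r), {
      if (r == 1) {
        list(mu = mu0, S = rep(0.1, N),
             mods = list(list(Z = .inducing_init(mu0, M),
                              sf2 = 1, l2 = 1, sn2 = 0.5)))
      } else {
        mur <- mu0 + rnorm(N, 0, 0.3)
        th <- exp(log(c(1, 1, 0.5)) + rnorm(3, 0, 0.3))
        list(mu = mur, S = rep(0.1, N),
             mods = list(list(Z = .inducing_init(mur, M),
                              sf2 = th[1], l2 = th[2], sn2 = th[3])))
      }
    })
    res <- tryCatch(.fit_core(data, init, M, config$max_iter),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("restart %d: %s", r, res))
      next
    }
    if (is.null(best) || res$elbo > best$elbo) best <- res
  }
  if (is.null(best))
    .stopf("fit_gplvm: optimisation failed in all %d restarts [%s]",
           config$n_restarts, paste(failures, collapse = "; "))
  m <- best$mods[[1]]
  pred <- .predictor_at(best$mu, best$S, m$Z, m$sf2, m$l2, m$sn2, std$Ystd)
  structure(
    list(latent_mean = setNames(best$mu, cell_ids(Y)),
         latent_variance = setNames(best$S, cell_ids(Y)),
         kernel = kernel_params(m$sf2, sqrt(m$l2), m$sn2),
         inducing_inputs = m$Z,
         elbo = best$elbo, elbo_init = best$elbo_init,
         convergence = best$convergence,
         B = pred$B, Kinv = pred$Kinv, Cinv = pred$Cinv,
         center = std$center, scale = std$scale, features = std$features,
         training = Y, modality = Y$modality,
         n_inducing = M, seed = config$seed),
    class = "gplvm_fit")
}

#' @export
print.gplvm_fit <- function(x, ...) {
  cat(sprintf("gplvm_fit '%s': %d cells, %d features, %d inducing inputs\n",
              x$modality, length(x$latent_mean), length(x$features),
              x$n_inducing))
  cat(sprintf("  ELBO %.3f (init %.3f) | sigma_rbf^2 %.3g, l %.3g, sigma^2 %.3g\n",
              x$elbo, x$elbo_init, x$kernel$rbf_variance,
              x$kernel$lengthscale, x$kernel$noise_variance))
  invisible(x)
}

#' Posterior predictive features at latent coordinates
#'
#' The generative map of the GPLVM: for any latent value `t_star` it returns
#' the posterior predictive mean (and per-feature predictive variance) of the
#' feature vector an unobserved cell at that manifold position would show.
#' Far outside the training latent range predictions revert to the GP prior
#' mean (zero on the standardised scale).
#'
#' @param fit A [fit_gplvm()] result (or one modality of a shared fit).
#' @param t_star Numeric vector of latent coordinates.
#' @param scale `"standardized"` (default; zero-mean unit-variance feature
#'   space the model was fit in) or `"original"` (de-standardised back to the
#'   input units).
#' @return List with `mean` and `variance`, each `length(t_star)` x
#'   `n_features` matrices.
#' @export
predict_from_latent <- function(fit, t_star,
                                scale = c("standardized", "original")) {
  scale <- match.arg(scale)
  if (any(!is.finite(t_star))) .stopf("predict_from_latent: non-finite t_star")
  sf2 <- fit$kernel$rbf_variance
  l2 <- fit$kernel$lengthscale^2
  sn2 <- fit$kernel$noise_variance
  Kstar <- .rbf_gram(t_star, fit$inducing_inputs, sf2, l2)
  mu <- Kstar %*% fit$B
  v <- pmax(sf2 - rowSums((Kstar %*% (fit$Kinv - fit$Cinv)) * Kstar), 0) + sn2
  if (scale == "original") {
    mu <- sweep(sweep(mu, 2, fit$scale, "*"), 2, fit$center, "+")
    varm <- outer(v, fit$scale^2)
  } else {
    varm <- matrix(v, length(t_star), ncol(mu))
  }
  dimnames(mu) <- list(names(t_star), fit$features)
  dimnames(varm) <- dimnames(mu)
  list(mean = mu, variance = varm)
}

#' Fit a shared GPLVM on two simultaneously measured modalities
#'
#' When two data types are measured on the same physical cells, a single
#' latent pseudotime is inferred for both: each modality keeps its own
#' mapping function (separate RBF kernel and noise hyperparameters) but the
#' variational posterior over the latent coordinate is shared.  This is the
#' relevance-determination construction constrained to an ordinary RBF
#' kernel.  Initialisation is PCA on the column-concatenated standardised
#' matrices.
#'
#' @param Y1,Y2 [cell_matrix()] objects over the same cell IDs.  If the sets
#'   match but the order differs, `Y2` is reordered to `Y1`; a set mismatch
#'   is an error listing the symmetric difference.
#' @param config A [run_config()].
#' @return An object of class `shared_gplvm_fit` with shared `latent_mean` /
#'   `latent_variance` and a per-modality list of kernels and predictive
#'   maps.
#' @export
fit_shared_gplvm <- function(Y1, Y2, config) {
  stopifnot(inherits(Y1, "cell_matrix"), inherits(Y2, "cell_matrix"),
            inherits(config, "mt_config"))
  ids1 <- cell_ids(Y1); ids2 <- cell_ids(Y2)
  if (!setequal(ids1, ids2)) {
    diff <- c(setdiff(ids1, ids2), setdiff(ids2, ids1))
    .stopf("fit_shared_gplvm: cell correspondence mismatch; unmatched IDs: %s",
           paste(diff, collapse = ", "))
  }
  if (!identical(ids1, ids2)) {
    Y2$values <- Y2$values[ids1, , drop = FALSE]
  }
  N <- n_cells(Y1)
  M <- config$n_inducing
  if (N < 3) .stopf("fit_shared_gplvm: need at least 3 cells")
  if (N < M) .stopf("fit_shared_gplvm: n_cells must be >= n_inducing")
  std <- lapply(list(Y1, Y2), .standardize)
  data <- lapply(std, function(s) {
    YYT <- tcrossprod(s$Ystd)
    list(YYT = YYT, trY = sum(diag(YYT)), D = ncol(s$Ystd))
  })
  mu0 <- .pca_init(cbind(std[[1]]$Ystd, std[[2]]$Ystd))
  best <- NULL
  failures <- character(0)
  for (r in seq_len(config$n_restarts)) {
    init <- .with_seed(.sub_seed(config$seed, 200 + r), {
      mur <- if (r == 1) mu0 else mu0 + rnorm(N, 0, 0.3)
      ths <- lapply(1:2, function(k) {
        if (r == 1) c(1, 1, 0.5) else exp(log(c(1, 1, 0.5)) + rnorm(3, 0, 0.3))
      })
      list(mu = mur, S = rep(0.1, N),
           mods = lapply(ths, function(th)
             list(Z = .inducing_init(mur, M),
                  sf2 = th[1], l2 = th[2], sn2 = th[3])))
    })
    res <- tryCatch(.fit_core(data, init, M, config$max_iter),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("restart %d: %s", r, res))
      next
    }
    if (is.null(best) || res$elbo > best$elbo) best <- res
  }
  if (is.null(best))
    .stopf("fit_shared_gplvm: optimisation failed in all restarts [%s]",
           paste(failures, collapse = "; "))
  mods <- lapply(1:2, function(k) {
    m <- best$mods[[k]]
    pred <- .predictor_at(best$mu, best$S, m$Z, m$sf2, m$l2, m$sn2,
                          std[[k]]$Ystd)
    Yk <- list(Y1, Y2)[[k]]
    structure(
      list(latent_mean = setNames(best$mu, ids1),
           latent_variance = setNames(best$S, ids1),
           kernel = kernel_params(m$sf2, sqrt(m$l2), m$sn2),
           inducing_inputs = m$Z,
           elbo = best$elbo, elbo_init = best$elbo_init,
           B = pred$B, Kinv = pred$Kinv, Cinv = pred$Cinv,
           center = std[[k]]$center, scale = std[[k]]$scale,
           features = std[[k]]$features,
           training = Yk, modality = Yk$modality,
           n_inducing = M, seed = config$seed),
      class = "gplvm_fit")
  })
  names(mods) <- vapply(mods, `[[`, character(1), "modality")
  structure(
    list(latent_mean = setNames(best$mu, ids1),
         latent_variance = setNames(best$S, ids1),
         modalities = mods,
         elbo = best$elbo, elbo_init = best$elbo_init,
         convergence = best$convergence,
         n_inducing = M, seed = config$seed),
    class = "shared_gplvm_fit")
}

#' @export
print.shared_gplvm_fit <- function(x, ...) {
  cat(sprintf("shared_gplvm_fit: %d cells, modalities [%s], ELBO %.3f\n",
              length(x$latent_mean), paste(names(x$modalities), collapse = ", "),
              x$elbo))
  invisible(x)
}
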