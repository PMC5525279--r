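# Seeded synthetic-data generator with known ground truth.
#
# Study design emulated: master time uniform on [0, 1]; a monotone warping
# maps it to modality-specific pseudotime; each feature is a smooth
# (logistic-sigmoid) function of pseudotime with randomised centre, slope
# and sign, amplitude-scaled to a common feature range; i.i.d. Gaussian
# noise is added.  Defaults are the benchmark conditions: 100 cells, 600
# features, feature range 16 and noise sigma 9 (56% of the range).

#' Simulation specification
#'
#' @param n_cells Number of cells (default 100).
#' @param n_features Number of features (default 600).
#' @param warp_family Monotone warp from master time to pseudotime:
#'   `"identity"`, `"power:<a>"` (t^a), or `"beta_cdf:<alpha>:<beta>"`.
#'   Default `"power:1.5"`, a non-trivial smooth monotone warp that still
#'   leaves every part of the process resolvable by smooth features of
#'   pseudotime (stronger compressions push many cells into a featureless
#'   regime where no method can recover their order).
#' @param noise_sigma Gaussian noise standard deviation (default 9).
#' @param feature_range Approximate noiseless range of each feature
#'   (default 16, making the default noise 56% of the range).
#' @param seed Seed for this draw.
#' @param modality Modality tag for the generated matrix.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_cells = 100L, n_features = 600L,
                     warp_family = "power:1.5", noise_sigma = 9,
                     feature_range = 16, seed = 1L, modality = "sim") {
  if (noise_sigma < 0) .stopf("sim_spec: noise_sigma must be >= 0")
  if (feature_range <= 0) .stopf("sim_spec: feature_range must be > 0")
  .warp_fun(warp_family)   # validate
  structure(list(n_cells = as.integer(n_cells),
                 n_features = as.integer(n_features),
                 warp_family = warp_family, noise_sigma = noise_sigma,
                 feature_range = feature_range, seed = as.integer(seed),
                 modality = modality),
            class = "sim_spec")
}

# Parse a warp-family string into a monotone function on [0, 1].
.warp_fun <- function(family) {
  parts <- strsplit(family, ":", fixed = TRUE)[[1]]
  switch(parts[1],
    identity = identity,
    power = {
      a <- as.numeric(parts[2])
      if (is.na(a) || a <= 0) .stopf("invalid power warp '%s'", family)
      function(t) t^a
    },
    beta_cdf = {
      ab <- as.numeric(parts[2:3])
      if (any(is.na(ab)) || any(ab <= 0)) .stopf("invalid beta_cdf warp '%s'", family)
      function(t) pbeta(t, ab[1], ab[2])
    },
    .stopf("unknown warp family '%s'", family))
}

# Noiseless feature values: sign * amplitude * logistic(slope * (t - centre)),
# amplitude chosen so the range over t in [0, 1] equals feature_range.
.sim_feature_values <- function(params, t) {
  A <- params$range / (plogis(params$slope * (1 - params$centre)) -
                         plogis(-params$slope * params$centre))
  params$sign * A * plogis(params$slope * (t - params$centre))
}

#' Simulate one modality with known ground truth
#'
#' @param spec A [sim_spec()].
#' @return An object of class `sim_result`: `true_master`,
#'   `true_pseudotime`, `Y` (a [cell_matrix()]), and `feature_params` (data
#'   frame of per-feature centre, slope, sign).
#' @export
simulate_modality <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  warp <- .warp_fun(spec$warp_family)
  .with_seed(spec$seed, {
    master <- runif(spec$n_cells)
    pt <- warp(master)
    fp <- data.frame(centre = runif(spec$n_features, 0.1, 0.9),
                     slope = runif(spec$n_features, 4, 12),
                     sign = sample(c(-1, 1), spec$n_features, replace = TRUE),
                     range = spec$feature_range)
    Y <- vapply(seq_len(spec$n_features), function(j)
      .sim_feature_values(fp[j, ], pt) + rnorm(spec$n_cells, 0, spec$noise_sigma),
      numeric(spec$n_cells))
    Y <- matrix(Y, nrow = spec$n_cells,
                dimnames = list(sprintf("cell_%03d", seq_len(spec$n_cells)),
                                sprintf("feature_%03d", seq_len(spec$n_features))))
    structure(
      list(true_master = setNames(master, rownames(Y)),
           true_pseudotime = setNames(pt, rownames(Y)),
           Y = cell_matrix(Y, modality = spec$modality),
           feature_params = fp, spec = spec),
      class = "sim_result")
  })
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result '%s': %d cells x %d features, warp %s, sigma %.3g\n",
              x$spec$modality, x$spec$n_cells, x$spec$n_features,
              x$spec$warp_family, x$spec$noise_sigma))
  invisible(x)
}

#' Simulate a pair of modalities sharing one master-time draw
#'
#' Both modalities are generated from a single master-time sample; each
#' applies its own warp, feature set and noise, emulating two assays of the
#' same process.  Optional disjoint subsampling emulates assays run on
#' different physical cells.
#'
#' @param specA,specB [sim_spec()] objects with equal `n_cells`.  The shared
#'   master draw uses `specA$seed`.
#' @param subsample Optional fractions `c(fA, fB)`; each modality keeps a
#'   random disjoint `floor(f * n)`-cell subset (error below 10 cells).
#' @param n_pairs Number of scored cross-modality feature pairs (default
#'   50).
#' @return List with `modA`, `modB` (subsampled [sim_result()]s),
#'   `correspondence` (data frame of cell_id and shared `true_master`), and
#'   `true_correlation` (data frame: `feature_a`, `feature_b`,
#'   `true_spearman` computed over all cells with true correspondence).
#' @export
simulate_paired_modalities <- function(specA, specB, subsample = NULL,
                                       n_pairs = 50L) {
  stopifnot(inherits(specA, "sim_spec"), inherits(specB, "sim_spec"))
  if (specA$n_cells != specB$n_cells)
    .stopf("paired simulation requires equal n_cells before subsampling")
  simA <- simulate_modality(specA)
  # modality B reuses A's master draw, then applies its own warp/features
  simB <- .with_seed(.sub_seed(specB$seed, 17), {
    warpB <- .warp_fun(specB$warp_family)
    master <- simA$true_master
    pt <- warpB(master)
    fp <- data.frame(centre = runif(specB$n_features, 0.1, 0.9),
                     slope = runif(specB$n_features, 4, 12),
                     sign = sample(c(-1, 1), specB$n_features, replace = TRUE),
                     range = specB$feature_range)
    Y <- vapply(seq_len(specB$n_features), function(j)
      .sim_feature_values(fp[j, ], pt) + rnorm(specB$n_cells, 0, specB$noise_sigma),
      numeric(specB$n_cells))
    Y <- matrix(Y, nrow = specB$n_cells,
                dimnames = list(names(master),
                                sprintf("feature_%03d", seq_len(specB$n_features))))
    structure(
      list(true_master = master, true_pseudotime = setNames(pt, names(master)),
           Y = cell_matrix(Y, modality = specB$modality),
           feature_params = fp, spec = specB),
      class = "sim_result")
  })
  pairs <- .with_seed(.sub_seed(specA$seed, 29), {
    data.frame(
      feature_a = sample(feature_ids(simA$Y), n_pairs, replace = TRUE),
      feature_b = sample(feature_ids(simB$Y), n_pairs, replace = TRUE),
      stringsAsFactors = FALSE)
  })
  pairs$true_spearman <- vapply(seq_len(nrow(pairs)), function(i)
    cor(simA$Y$values[, pairs$feature_a[i]], simB$Y$values[, pairs$feature_b[i]],
        method = "spearman"), numeric(1))
  correspondence <- data.frame(cell_id = names(simA$true_master),
                               true_master = unname(simA$true_master),
                               stringsAsFactors = FALSE)
  if (!is.null(subsample)) {
    stopifnot(length(subsample) == 2, all(subsample > 0), sum(subsample) <= 1)
    n <- specA$n_cells
    nA <- floor(subsample[1] * n); nB <- floor(subsample[2] * n)
    if (nA < 10 || nB < 10)
      .stopf("subsample fractions leave fewer than 10 cells per modality")
    sel <- .with_seed(.sub_seed(specA$seed, 43), sample.int(n, nA + nB))
    keepA <- sort(sel[seq_len(nA)]); keepB <- sort(sel[nA + seq_len(nB)])
    simA <- .subset_sim(simA, keepA)
    simB <- .subset_sim(simB, keepB)
  }
  list(modA = simA, modB = simB, correspondence = correspondence,
       true_correlation = pairs)
}

#' Orientation rule from simulator ground truth
#'
#' The latent sign of a fitted model is arbitrary; on real data a marker
#' with known direction resolves it.  For simulated data the generator
#' plays that role: the chosen feature's true sign (monotone increasing or
#' decreasing in master time) is declared as the marker direction.
#'
#' @param sim A [simulate_modality()] result.
#' @param feature_index Index of the marker feature; by default the feature
#'   whose sigmoid centre lies closest to mid-process (the analogue of a
#'   validated marker changing mid-way, maximally informative about
#'   direction).
#' @return An orientation rule string usable in [run_config()] /
#'   [build_modality_model()].
#' @export
sim_orientation_rule <- function(sim, feature_index = NULL) {
  stopifnot(inherits(sim, "sim_result"))
  if (is.null(feature_index))
    feature_index <- which.min(abs(sim$feature_params$centre - 0.5))
  dir <- if (sim$feature_params$sign[feature_index] > 0) "increasing" else "decreasing"
  sprintf("marker:%s:%s", feature_ids(sim$Y)[feature_index], dir)
}

.subset_sim <- function(sim, idx) {
  sim$true_master <- sim$true_master[idx]
  sim$true_pseudotime <- sim$true_pseudotime[idx]
  sim$Y$values <- sim$Y$values[idx, , drop = FALSE]
  sim
}

#' Accuracy sweep over noise levels
#'
#' For each noise level and replicate: simulate a modality, run the full
#' pipeline (fit, orient, normalise, warp), and record the absolute Pearson
#' correlation between true and inferred master time.
#'
#' @param base_spec A [sim_spec()] providing all settings except
#'   `noise_sigma` and `seed`.
#' @param sigmas Noise standard deviations to evaluate.
#' @param n_reps Replicates per noise level.
#' @param seed Seed from which per-replicate seeds are derived.
#' @param config Optional [run_config()] template for the pipeline.
#' @return Data frame with columns `sigma`, `rep`, `accuracy`, plus a
#'   `summary` attribute of per-sigma means.
#' @export
noise_sweep <- function(base_spec, sigmas, n_reps = 10L, seed = 1L,
                        config = NULL) {
  stopifnot(inherits(base_spec, "sim_spec"), all(sigmas >= 0))
  rows <- list()
  for (si in seq_along(sigmas)) {
    for (r in seq_len(n_reps)) {
      sub <- .sub_seed(seed, si * 1000 + r)
      spec <- base_spec
      spec$noise_sigma <- sigmas[si]
      spec$seed <- sub
      sim <- simulate_modality(spec)
      cfg <- if (is.null(config)) run_config(seed = sub) else {
        config$seed <- sub; config
      }
      model <- build_modality_model(sim$Y, cfg, orientation = "keep")
      rows[[length(rows) + 1]] <- data.frame(
        sigma = sigmas[si], rep = r,
        accuracy = abs(cor(model$master_time, sim$true_master)))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- vapply(split(out$accuracy, out$sigma), mean, numeric(1))
  out
}
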