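# Orchestration of per-modality models into a common master-time frame:
# orientation, correspondence generation, cross-modality correlation,
# decoupling statistics, shared master time and lagging-cell calls.

#' Orient a fitted latent ordering
#'
#' The sign of a GPLVM latent coordinate is arbitrary and cannot be inferred
#' from the data; orientation encodes biological prior knowledge.  Explicit
#' rules keep or reverse the ordering; marker rules
#' (`marker:<feature>:<increasing|decreasing>`) reverse it when the Spearman
#' correlation between the latent coordinate and a marker feature
#' contradicts the declared direction.
#'
#' @param fit A [fit_gplvm()] result (or one modality of a shared fit).
#' @param rule `"keep"`, `"reverse"`, or `"marker:<feature>:<direction>"`.
#' @return List with `orientation` (`"keep"` or `"reverse"`), `sign` (+1 or
#'   -1) and `latent` (the oriented latent mean).
#' @export
orient_latent <- function(fit, rule = "keep") {
  parsed <- .parse_orientation(rule)
  latent <- fit$latent_mean
  decision <- parsed$kind
  if (parsed$kind == "marker") {
    Y <- fit$training
    if (!(parsed$feature %in% feature_ids(Y)))
      .stopf("orientation marker '%s' not present in modality '%s'",
             parsed$feature, fit$modality)
    r <- suppressWarnings(
      cor(latent, Y$values[names(latent), parsed$feature], method = "spearman"))
    if (is.na(r) || abs(r) < 0.1)
      .stopf(paste0("uninformative marker '%s' (|Spearman| = %.3f < 0.1): ",
                    "refusing to guess an orientation"),
             parsed$feature, if (is.na(r)) 0 else abs(r))
    observed <- if (r > 0) "increasing" else "decreasing"
    decision <- if (observed == parsed$direction) "keep" else "reverse"
    .logf("orientation for '%s': marker %s is %s (Spearman %.3f), declared %s -> %s",
          fit$modality, parsed$feature, observed, r, parsed$direction, decision)
  }
  sign <- if (decision == "reverse") -1 else 1
  list(orientation = decision, sign = sign, latent = sign * latent)
}

#' Build a full modality model
#'
#' Composes the per-modality pipeline: GPLVM fit, orientation, normalisation
#' of the latent ordering to `[0, 1]`, quantile-alignment warping, and the
#' master-time assignment for every training cell.
#'
#' @param Y A [cell_matrix()].
#' @param config A [run_config()]; the orientation rule for `Y$modality` is
#'   looked up in `config$orientation` unless `orientation` is given.
#' @param orientation Optional rule overriding the config.
#' @return An object of class `modality_model`.
#' @export
build_modality_model <- function(Y, config, orientation = NULL) {
  stopifnot(inherits(Y, "cell_matrix"), inherits(config, "mt_config"))
  if (is.null(orientation))
    orientation <- config$orientation[[Y$modality]] %||% "keep"
  fit <- fit_gplvm(Y, config)
  .modality_model_from_fit(fit, config, orientation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared tail of the pipeline, reused for shared-GPLVM master time.
.modality_model_from_fit <- function(fit, config, orientation) {
  ori <- orient_latent(fit, orientation)
  pseudotime <- normalize_pseudotime(ori$latent)
  warp <- learn_warping(pseudotime, n_quantiles = config$n_quantiles,
                        method = config$warp_method)
  master <- apply_warping(warp, pseudotime)
  names(master) <- names(pseudotime)
  structure(
    list(modality = fit$modality, fit = fit,
         orientation_applied = ori$orientation, sign = ori$sign,
         norm_range = range(ori$latent),
         warp = warp, pseudotime = pseudotime, master_time = master,
         config = config),
    class = "modality_model")
}

#' @export
print.modality_model <- function(x, ...) {
  cat(sprintf("modality_model '%s': %d cells, orientation %s, warp '%s'\n",
              x$modality, length(x$master_time), x$orientation_applied,
              x$warp$method_used))
  invisible(x)
}

#' Master-time records of a modality model
#'
#' @param model A [build_modality_model()] result.
#' @return Data frame with `cell_id`, `modality`, `pseudotime`,
#'   `master_time`, ready for [write_master_time_table()].
#' @export
master_time_table <- function(model) {
  stopifnot(inherits(model, "modality_model"))
  data.frame(cell_id = names(model$master_time),
             modality = model$modality,
             pseudotime = unname(model$pseudotime),
             master_time = unname(model$master_time),
             stringsAsFactors = FALSE)
}

# Master time -> latent coordinate of a modality (inverse of the model's
# orientation/normalisation/warping chain).
.latent_from_master <- function(model, m) {
  t01 <- invert_warping(model$warp, m)
  oriented <- model$norm_range[1] + t01 * diff(model$norm_range)
  model$sign * oriented
}

#' Infer corresponding measurements in another modality
#'
#' For each query cell of the source modality, its master time is carried
#' through the target modality's inverse warping to a target pseudotime, and
#' the target GPLVM's generative map produces the measurement an equivalent
#' cell would show there.  The two modalities may contain different cells
#' and different cell counts.
#'
#' @param source,target [build_modality_model()] results.
#' @param cells Optional subset of source cell IDs (default: all).
#' @return An object of class `correspondence_set`: `cell_ids`,
#'   `master_time` (the pivot values), `target_modality`, `values`
#'   (cells x target features, original units) and `variance`.
#' @export
infer_correspondence <- function(source, target, cells = NULL) {
  stopifnot(inherits(source, "modality_model"), inherits(target, "modality_model"))
  if (is.null(cells)) cells <- names(source$master_time)
  if (length(cells) == 0) .stopf("infer_correspondence: empty cell subset")
  missing <- setdiff(cells, names(source$master_time))
  if (length(missing))
    .stopf("infer_correspondence: unknown source cells: %s",
           paste(missing, collapse = ", "))
  m <- source$master_time[cells]
  t_lat <- .latent_from_master(target, m)
  pred <- predict_from_latent(target$fit, t_lat, scale = "original")
  rownames(pred$mean) <- cells
  rownames(pred$variance) <- cells
  structure(
    list(cell_ids = cells, master_time = m,
         target_modality = target$modality,
         values = pred$mean, variance = pred$variance),
    class = "correspondence_set")
}

#' @export
print.correspondence_set <- function(x, ...) {
  cat(sprintf("correspondence_set: %d cells -> modality '%s' (%d features)\n",
              length(x$cell_ids), x$target_modality, ncol(x$values)))
  invisible(x)
}

#' Cross-modality feature correlation
#'
#' Correlates observed source features against generated target features
#' over the source cells.  Spearman is the default because both linear and
#' non-linear monotone relationships are of interest.
#'
#' @param source,target [build_modality_model()] results.
#' @param features_a Feature IDs in the source modality (observed values).
#' @param features_b Feature IDs in the target modality (generated values).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Correlation matrix `length(features_a)` x `length(features_b)`;
#'   entries involving a zero-variance feature are `NA` (undefined, never
#'   silently 0).
#' @export
cross_modality_correlation <- function(source, target, features_a, features_b,
                                       method = c("spearman", "pearson")) {
  method <- match.arg(method)
  obs_feats <- feature_ids(source$fit$training)
  missing_a <- setdiff(features_a, obs_feats)
  if (length(missing_a))
    .stopf("features absent from source modality: %s", paste(missing_a, collapse = ", "))
  gen <- infer_correspondence(source, target)
  missing_b <- setdiff(features_b, colnames(gen$values))
  if (length(missing_b))
    .stopf("features absent from target modality: %s", paste(missing_b, collapse = ", "))
  A <- source$fit$training$values[gen$cell_ids, features_a, drop = FALSE]
  B <- gen$values[, features_b, drop = FALSE]
  suppressWarnings(cor(A, B, method = method))
}

# Fisher r-to-z comparison of two independent correlations; one-tailed
# p for H0: r1 <= r2.
.fisher_rz <- function(r1, n1, r2, n2) {
  clamp <- function(r) pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  z <- (atanh(clamp(r1)) - atanh(clamp(r2))) /
    sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = pnorm(z, lower.tail = FALSE))
}

#' Test for decoupling of two master-time orderings
#'
#' Splits cells (with known correspondence) at a master-time threshold on
#' `m1`, computes the Pearson correlation between `m1` and `m2` separately
#' in the early and late groups, and compares them with Fisher's r-to-z
#' transformation (one-tailed p for the null that the early correlation is
#' less than or equal to the late one).  A complementary permutation test
#' redraws random early/late divisions of sizes `floor(split * n)` and the
#' remainder, using the Spearman correlation difference as the statistic;
#' the empirical p uses the add-one estimator.
#'
#' @param m1,m2 Master-time vectors over the same cells (same order).
#' @param split Threshold in `(0, 1)` applied to `m1` (default 0.3).
#' @param n_perm Number of permutation draws (default 100000).
#' @param seed Seed for the permutation draws.
#' @return An object of class `decoupling_result` with `r_before`,
#'   `r_after`, `fisher_z`, `p_fisher`, `p_perm`, `n_perm`, `split_point`,
#'   and group sizes.
#' @export
decoupling_test <- function(m1, m2, split = 0.3, n_perm = 100000L, seed = 1L) {
  if (length(m1) != length(m2))
    .stopf("decoupling_test: m1 and m2 must cover the same cells")
  if (split <= 0 || split >= 1) .stopf("decoupling_test: split must lie in (0, 1)")
  before <- m1 < split
  n1 <- sum(before); n2 <- sum(!before)
  if (n1 < 4 || n2 < 4)
    .stopf("decoupling_test: need >= 4 cells on each side of the split (got %d/%d)",
           n1, n2)
  r_before <- cor(m1[before], m2[before])
  r_after <- cor(m1[!before], m2[!before])
  ft <- .fisher_rz(r_before, n1, r_after, n2)
  obs <- suppressWarnings(
    cor(m1[before], m2[before], method = "spearman") -
      cor(m1[!before], m2[!before], method = "spearman"))
  n <- length(m1)
  k <- max(2L, as.integer(floor(split * n)))
  exceed <- .with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n, k)
      d <- suppressWarnings(
        cor(m1[idx], m2[idx], method = "spearman") -
          cor(m1[-idx], m2[-idx], method = "spearman"))
      if (!is.na(d) && d >= obs) cnt <- cnt + 1L
    }
    cnt
  })
  structure(
    list(split_point = split, r_before = r_before, r_after = r_after,
         n_before = n1, n_after = n2,
         fisher_z = ft$z, p_fisher = ft$p,
         p_perm = (1 + exceed) / (1 + n_perm), n_perm = as.integer(n_perm),
         observed_diff = obs),
    class = "decoupling_result")
}

#' @export
print.decoupling_result <- function(x, ...) {
  cat(sprintf("decoupling test at master time = %.2f\n", x$split_point))
  cat(sprintf("  r(early, n=%d) = %.3f | r(late, n=%d) = %.3f\n",
              x$n_before, x$r_before, x$n_after, x$r_after))
  cat(sprintf("  Fisher z = %.3f (one-tailed p = %.4g) | permutation p = %.4g (%d draws)\n",
              x$fisher_z, x$p_fisher, x$p_perm, x$n_perm))
  invisible(x)
}

#' Decoupling robustness across alternative split points
#'
#' Re-runs [decoupling_test()] at each supplied split.
#'
#' @inheritParams decoupling_test
#' @param splits Thresholds to evaluate.
#' @return Named list of `decoupling_result` objects.
#' @export
decoupling_robustness <- function(m1, m2, splits = c(0.3, 0.5),
                                  n_perm = 100000L, seed = 1L) {
  setNames(lapply(splits, function(s)
    decoupling_test(m1, m2, split = s, n_perm = n_perm, seed = seed)),
    paste0("split_", splits))
}

#' Master time from a shared-latent fit
#'
#' For simultaneously measured modalities, the shared GPLVM's single latent
#' ordering is oriented, normalised and warped to uniform master time in the
#' same way as a single-modality pseudotime.
#'
#' @param sfit A [fit_shared_gplvm()] result.
#' @param config A [run_config()]; an orientation rule under the name
#'   `"shared"` (or the first modality's name) is honoured.
#' @param orientation Optional explicit rule; marker rules are resolved
#'   against the first modality's features.
#' @param compare_models Optional named list of single-modality
#'   [build_modality_model()] objects; their master times are correlated
#'   (Pearson, over shared cells) with the shared master time.
#' @return List with `master_time` (named per cell), `pseudotime`, `warp`,
#'   `model` (a `modality_model` over the first modality's features), and
#'   `comparison` (named Pearson correlations, if requested).
#' @export
shared_master_time <- function(sfit, config, orientation = NULL,
                               compare_models = NULL) {
  stopifnot(inherits(sfit, "shared_gplvm_fit"))
  if (is.null(orientation))
    orientation <- config$orientation[["shared"]] %||%
      config$orientation[[names(sfit$modalities)[1]]] %||% "keep"
  model <- .modality_model_from_fit(sfit$modalities[[1]], config, orientation)
  comparison <- NULL
  if (!is.null(compare_models)) {
    comparison <- vapply(compare_models, function(mm) {
      shared_cells <- intersect(names(model$master_time), names(mm$master_time))
      cor(model$master_time[shared_cells], mm$master_time[shared_cells])
    }, numeric(1))
  }
  list(master_time = model$master_time, pseudotime = model$pseudotime,
       warp = model$warp, model = model, comparison = comparison)
}

#' Identify lagging cells
#'
#' A cell lags when its master time does not exceed the maximum master time
#' observed at the immediately preceding experimental time point; cells of
#' the first time point never lag.
#'
#' @param master Named numeric vector of master-time values.
#' @param time_point Ordered factor of time-point labels, aligned with
#'   `master`.
#' @return Named logical vector.
#' @export
identify_lagging_cells <- function(master, time_point) {
  if (!is.ordered(time_point))
    .stopf("identify_lagging_cells: time_point must be an ordered factor")
  if (length(time_point) != length(master))
    .stopf("identify_lagging_cells: length mismatch")
  time_point <- droplevels(time_point)
  levs <- levels(time_point)
  lag <- rep(FALSE, length(master))
  names(lag) <- names(master)
  if (length(levs) < 2) return(lag)
  for (i in seq_along(levs)[-1]) {
    prev_max <- max(master[time_point == levs[i - 1]])
    here <- time_point == levs[i]
    lag[here] <- master[here] <= prev_max
  }
  lag
}
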