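# Alignment orchestration: orientation, modality models, correspondence
# generation, cross-modality correlation, decoupling, shared master time and
# lagging-cell calls.

# One small fitted model reused across orientation tests.
dat_ori <- make_smooth_data(n = 40, d = 12, sigma = 0.3, seed = 21)
fit_ori <- fit_gplvm(dat_ori$Y, quick_config())

test_that("marker orientation reverses exactly when the declared direction is contradicted", {
  lat <- fit_ori$latent_mean
  with_marker <- function(marker) {
    f <- fit_ori
    f$training$values <- cbind(f$training$values, MK = marker)
    f
  }
  up <- with_marker(lat + rnorm(length(lat), 0, 0.01))
  expect_identical(orient_latent(up, "marker:MK:increasing")$orientation, "keep")
  expect_identical(orient_latent(up, "marker:MK:decreasing")$orientation, "reverse")
  down <- with_marker(-lat + rnorm(length(lat), 0, 0.01))
  expect_identical(orient_latent(down, "marker:MK:decreasing")$orientation, "keep")
  expect_equal(orient_latent(down, "marker:MK:decreasing")$latent, lat)

  set.seed(10)   # frozen draw with |Spearman| ~ 0.016 against this latent
  noise <- with_marker(rnorm(length(lat)))
  expect_error(orient_latent(noise, "marker:MK:increasing"), "uninformative marker")
  expect_error(orient_latent(fit_ori, "marker:absent:increasing"), "not present")
  expect_identical(orient_latent(fit_ori, "reverse")$sign, -1)
})

test_that("marker-oriented master time is positively correlated with truth across seeded runs", {
  ok <- vapply(1:25, function(s) {
    spec <- sim_spec(n_cells = 30, n_features = 12, noise_sigma = 2,
                     seed = 300 + s)
    sim <- simulate_modality(spec)
    cfg <- run_config(seed = s, n_restarts = 1, max_iter = 150)
    model <- build_modality_model(sim$Y, cfg,
                                  orientation = sim_orientation_rule(sim))
    cor(model$master_time, sim$true_master) > 0
  }, logical(1))
  expect_true(all(ok))
})

test_that("a noiseless modality honours the master-time composition contract", {
  # the near-exact (>= 0.99) recovery claim is asserted at full study scale
  # in the acceptance suite; this narrower fixture checks the composition
  # invariants and strong recovery
  spec <- sim_spec(n_cells = 100, n_features = 80, noise_sigma = 0, seed = 31)
  sim <- simulate_modality(spec)
  model <- build_modality_model(sim$Y, quick_config(seed = 31),
                                orientation = sim_orientation_rule(sim))
  expect_gte(cor(model$master_time, sim$true_master), 0.95)
  expect_lt(ks_uniform(model$master_time), 0.1)
  expect_true(all(model$master_time >= 0 & model$master_time <= 1))
  expect_equal(model$master_time,
               setNames(apply_warping(model$warp, model$pseudotime),
                        names(model$pseudotime)))
})

test_that("two modalities sharing a master draw align to matching quantiles", {
  sA <- sim_spec(n_cells = 80, n_features = 60, warp_family = "identity",
                 noise_sigma = 1, seed = 33, modality = "a")
  sB <- sim_spec(n_cells = 80, n_features = 60, warp_family = "beta_cdf:2:1",
                 noise_sigma = 1, seed = 34, modality = "b")
  pr <- simulate_paired_modalities(sA, sB)
  cfg <- quick_config(seed = 33)
  mA <- build_modality_model(pr$modA$Y, cfg, orientation = sim_orientation_rule(pr$modA))
  mB <- build_modality_model(pr$modB$Y, cfg, orientation = sim_orientation_rule(pr$modB))
  qa <- quantile(mA$master_time, probs = seq(0.05, 0.95, 0.05))
  qb <- quantile(mB$master_time, probs = seq(0.05, 0.95, 0.05))
  expect_lt(max(abs(qa - qb)), 0.1)
})

# Paired low-noise benchmark reused by the correspondence tests below.
pr_corr <- simulate_paired_modalities(
  sim_spec(n_cells = 70, n_features = 50, warp_family = "identity",
           noise_sigma = 0.8, seed = 41, modality = "src"),
  sim_spec(n_cells = 70, n_features = 50, warp_family = "power:2",
           noise_sigma = 0.8, seed = 42, modality = "tgt"))
cfg_corr <- quick_config(seed = 41)
mod_src <- build_modality_model(pr_corr$modA$Y, cfg_corr,
                                orientation = sim_orientation_rule(pr_corr$modA))
mod_tgt <- build_modality_model(pr_corr$modB$Y, cfg_corr,
                                orientation = sim_orientation_rule(pr_corr$modB))

test_that("self-correspondence regenerates each cell's own measurement profile", {
  cs <- infer_correspondence(mod_src, mod_src)
  obs <- mod_src$fit$training$values[cs$cell_ids, colnames(cs$values)]
  rowcor <- vapply(seq_len(nrow(obs)),
                   function(i) cor(obs[i, ], cs$values[i, ]), numeric(1))
  expect_gte(median(rowcor), 0.8)
  expect_true(all(is.finite(cs$values)))
  expect_error(infer_correspondence(mod_src, mod_tgt, cells = character(0)),
               "empty cell subset")
})

test_that("a cell at master time zero maps to the target's smallest anchor", {
  cell0 <- names(which.min(mod_src$master_time))
  m0 <- mod_src$master_time[cell0]
  cs <- infer_correspondence(mod_src, mod_tgt, cells = cell0)
  t_anchor <- mastertime:::.latent_from_master(mod_tgt, m0)
  direct <- predict_from_latent(mod_tgt$fit, t_anchor, scale = "original")
  expect_equal(unname(cs$values[1, ]), unname(direct$mean[1, ]))
})

test_that("generated features track the target's true generating functions", {
  pr <- simulate_paired_modalities(
    sim_spec(n_cells = 100, n_features = 60, warp_family = "identity",
             noise_sigma = 0.8, seed = 43, modality = "src"),
    sim_spec(n_cells = 100, n_features = 60, warp_family = "power:2",
             noise_sigma = 0.8, seed = 44, modality = "tgt"),
    subsample = c(0.5, 0.25))
  expect_gt(nrow(pr$modA$Y$values), nrow(pr$modB$Y$values))
  expect_length(intersect(rownames(pr$modA$Y$values), rownames(pr$modB$Y$values)), 0)
  cfg <- quick_config(seed = 43)
  mA <- build_modality_model(pr$modA$Y, cfg, orientation = sim_orientation_rule(pr$modA))
  mB <- build_modality_model(pr$modB$Y, cfg, orientation = sim_orientation_rule(pr$modB))
  cs <- infer_correspondence(mA, mB)
  truth <- vapply(seq_len(ncol(cs$values)), function(j)
    mastertime:::.sim_feature_values(
      pr$modB$feature_params[j, ],
      mastertime:::.warp_fun("power:2")(pr$modA$true_master[cs$cell_ids])),
    numeric(length(cs$cell_ids)))
  rmse <- sqrt(mean((cs$values - truth)^2))
  expect_lte(rmse, 2 * 0.8)
})

test_that("inferred cross-modality correlations carry the right signs", {
  tc <- pr_corr$true_correlation
  cm <- cross_modality_correlation(mod_src, mod_tgt, tc$feature_a, tc$feature_b)
  inferred <- diag(cm)
  big <- abs(tc$true_spearman) > 0.3
  expect_gte(mean(sign(inferred[big]) == sign(tc$true_spearman[big])), 0.9)

  # an increasing/decreasing pair is negatively correlated both ways
  fp_a <- pr_corr$modA$feature_params
  fp_b <- pr_corr$modB$feature_params
  up_a <- feature_ids(pr_corr$modA$Y)[which(fp_a$sign > 0 &
                                              abs(fp_a$centre - 0.5) < 0.2)[1]]
  dn_b <- feature_ids(pr_corr$modB$Y)[which(fp_b$sign < 0 &
                                              abs(fp_b$centre - 0.5) < 0.2)[1]]
  inf_r <- cross_modality_correlation(mod_src, mod_tgt, up_a, dn_b)[1, 1]
  true_r <- cor(pr_corr$modA$Y$values[, up_a], pr_corr$modB$Y$values[, dn_b],
                method = "spearman")
  expect_lt(inf_r, 0)
  expect_lt(true_r, 0)
})

test_that("self-correlation of one feature is near one on low-noise data", {
  f <- feature_ids(pr_corr$modA$Y)[3]
  r <- cross_modality_correlation(mod_src, mod_src, f, f)[1, 1]
  expect_gte(r, 0.9)
  # zero-variance features are flagged undefined, not silently zero
  m2 <- mod_src
  m2$fit$training$values[, 1] <- 5
  r0 <- cross_modality_correlation(m2, mod_src, feature_ids(pr_corr$modA$Y)[1], f)
  expect_true(is.na(r0[1, 1]))
})

test_that("decoupling statistics match their closed-form and enumeration oracles", {
  set.seed(51)
  m <- runif(60)
  same <- decoupling_test(m, m, n_perm = 200, seed = 1)
  expect_equal(same$r_before, 1)
  expect_equal(same$r_after, 1)
  expect_equal(same$fisher_z, 0)
  expect_equal(same$p_fisher, 0.5)

  # closed-form oracle, recomputed here independently and frozen
  ft <- mastertime:::.fisher_rz(0.8, 30, 0.5, 70)
  expect_equal(ft$z, 2.40973792944177, tolerance = 1e-12)
  expect_equal(ft$p, 0.00798199155305161, tolerance = 1e-12)

  # 8-cell toy: exhaustive enumeration over all C(8, 2) early groups
  m1 <- c(0.05, 0.12, 0.2, 0.28, 0.45, 0.6, 0.78, 0.92)
  m2 <- c(0.1, 0.05, 0.33, 0.2, 0.7, 0.41, 0.82, 0.7)
  res <- decoupling_test(m1, m2, split = 0.3, n_perm = 20000, seed = 5)
  combs <- combn(8, 2)
  dif <- apply(combs, 2, function(idx)
    cor(m1[idx], m2[idx], method = "spearman") -
      cor(m1[-idx], m2[-idx], method = "spearman"))
  p_exact <- mean(dif >= res$observed_diff, na.rm = TRUE)
  expect_lt(abs(res$p_perm - p_exact), 0.02)

  expect_error(decoupling_test(m1, m2, split = 1.2), "split")
  expect_error(decoupling_test(runif(8), runif(8), split = 0.01), ">= 4 cells")
})

test_that("decoupling robustness re-evaluates alternative split points", {
  set.seed(52)
  m1 <- runif(60); m2 <- m1 + rnorm(60, 0, 0.2)
  rb <- decoupling_robustness(m1, m2, splits = c(0.3, 0.5), n_perm = 500, seed = 1)
  expect_named(rb, c("split_0.3", "split_0.5"))
  expect_equal(rb$split_0.5$split_point, 0.5)
})

test_that("shared master time agrees with the single-modality orderings", {
  dat <- make_smooth_data(n = 100, d = 40, sigma = 1, seed = 53)
  Y1 <- dat$Y; Y1$modality <- "m1"
  Y2 <- dat$Y; Y2$modality <- "m2"
  cfg <- quick_config(seed = 53)
  sfit <- fit_shared_gplvm(Y1, Y2, cfg)
  smt <- shared_master_time(sfit, cfg)
  single <- build_modality_model(Y1, cfg)
  r <- abs(cor(smt$master_time, single$master_time))
  expect_gte(r, 0.95)
  expect_lt(ks_uniform(smt$master_time), 0.1)
})

test_that("lagging cells are those overtaken by the previous time point", {
  master <- c(a = 0.1, b = 0.2, c = 0.15, d = 0.5)
  tp <- factor(c("t0", "t0", "t1", "t1"), ordered = TRUE)
  expect_equal(identify_lagging_cells(master, tp),
               c(a = FALSE, b = FALSE, c = TRUE, d = FALSE))
  # all later cells ahead: no flags
  master2 <- c(a = 0.1, b = 0.2, c = 0.35, d = 0.5)
  expect_false(any(identify_lagging_cells(master2, tp)))
  # single time point: no flags
  expect_false(any(identify_lagging_cells(master[1:2],
                                          factor(c("t0", "t0"), ordered = TRUE))))
  expect_error(identify_lagging_cells(master, factor(c("t0", "t0", "t1", "t1"))),
               "ordered factor")
  # only the immediately preceding time point counts
  master3 <- c(a = 0.9, b = 0.1, c = 0.5)
  tp3 <- factor(c("t0", "t1", "t2"), levels = c("t0", "t1", "t2"), ordered = TRUE)
  expect_equal(unname(identify_lagging_cells(master3, tp3)),
               c(FALSE, TRUE, FALSE))
})
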