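# Text (JSON) serialization of fitted objects, full numeric precision.
# Archives are plain JSON so runs are inspectable and diffable; identical
# objects serialize byte-identically.

.ser_matrix <- function(m) {
  list(dim = dim(m), rownames = rownames(m), colnames = colnames(m),
       data = as.vector(m))
}

.deser_matrix <- function(s) {
  m <- matrix(s$data, nrow = s$dim[1], ncol = s$dim[2])
  if (length(s$rownames)) rownames(m) <- s$rownames
  if (length(s$colnames)) colnames(m) <- s$colnames
  m
}

.ser_fit <- function(fit) {
  list(type = "gplvm_fit",
       latent_mean = unname(fit$latent_mean),
       latent_variance = unname(fit$latent_variance),
       cell_ids = names(fit$latent_mean),
       kernel = unclass(fit$kernel),
       inducing_inputs = fit$inducing_inputs,
       elbo = fit$elbo, elbo_init = fit$elbo_init,
       B = .ser_matrix(fit$B), Kinv = .ser_matrix(fit$Kinv),
       Cinv = .ser_matrix(fit$Cinv),
       center = unname(fit$center), scale = unname(fit$scale),
       features = fit$features,
       training = .ser_matrix(fit$training$values),
       modality = fit$modality,
       n_inducing = fit$n_inducing, seed = fit$seed)
}

.deser_fit <- function(s) {
  structure(
    list(latent_mean = setNames(s$latent_mean, s$cell_ids),
         latent_variance = setNames(s$latent_variance, s$cell_ids),
         kernel = do.call(kernel_params, s$kernel),
         inducing_inputs = s$inducing_inputs,
         elbo = s$elbo, elbo_init = s$elbo_init,
         B = .deser_matrix(s$B), Kinv = .deser_matrix(s$Kinv),
         Cinv = .deser_matrix(s$Cinv),
         center = setNames(s$center, s$features),
         scale = setNames(s$scale, s$features),
         features = s$features,
         training = cell_matrix(.deser_matrix(s$training), modality = s$modality),
         modality = s$modality,
         n_inducing = s$n_inducing, seed = s$seed),
    class = "gplvm_fit")
}

.ser_warp <- function(w) {
  gp <- NULL
  if (!is.null(w$gp))
    gp <- list(x = w$gp$x, alpha = w$gp$alpha, sf2 = w$gp$sf2, l2 = w$gp$l2,
               sn2 = w$gp$sn2, ybar = w$gp$ybar,
               rescale = unname(w$gp$rescale))
  list(type = "warping_function",
       anchor_pseudotime = w$anchor_pseudotime,
       anchor_master = w$anchor_master,
       method_used = w$method_used, gp = gp)
}

.deser_warp <- function(s) {
  gp <- NULL
  if (!is.null(s$gp) && length(s$gp)) {
    gp <- s$gp
    if (!is.null(gp$rescale)) gp$rescale <- setNames(gp$rescale, c("a", "b"))
  }
  structure(list(anchor_pseudotime = s$anchor_pseudotime,
                 anchor_master = s$anchor_master,
                 method_used = s$method_used, gp = gp),
            class = "warping_function")
}

.ser_model <- function(m) {
  list(type = "modality_model",
       modality = m$modality,
       fit = .ser_fit(m$fit),
       orientation_applied = m$orientation_applied, sign = m$sign,
       norm_range = m$norm_range,
       warp = .ser_warp(m$warp),
       pseudotime = unname(m$pseudotime),
       master_time = unname(m$master_time),
       cell_ids = names(m$master_time),
       config = list(seed = m$config$seed, n_inducing = m$config$n_inducing,
                     n_quantiles = m$config$n_quantiles,
                     warp_method = m$config$warp_method,
                     cor_method = m$config$cor_method,
                     n_restarts = m$config$n_restarts,
                     max_iter = m$config$max_iter))
}

.deser_model <- function(s) {
  cfg <- run_config(seed = s$config$seed, n_inducing = s$config$n_inducing,
                    n_quantiles = s$config$n_quantiles,
                    warp_method = s$config$warp_method,
                    cor_method = s$config$cor_method,
                    n_restarts = s$config$n_restarts,
                    max_iter = s$config$max_iter)
  structure(
    list(modality = s$modality, fit = .deser_fit(s$fit),
         orientation_applied = s$orientation_applied, sign = s$sign,
         norm_range = s$norm_range, warp = .deser_warp(s$warp),
         pseudotime = setNames(s$pseudotime, s$cell_ids),
         master_time = setNames(s$master_time, s$cell_ids),
         config = cfg),
    class = "modality_model")
}

#' Save a fitted object as JSON
#'
#' Supports [fit_gplvm()] fits, [learn_warping()] warps and
#' [build_modality_model()] models; values are stored at full precision so
#' save/load round trips are exact.
#'
#' @param x Object to save.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_model <- function(x, path) {
  s <- if (inherits(x, "gplvm_fit")) .ser_fit(x)
  else if (inherits(x, "warping_function")) .ser_warp(x)
  else if (inherits(x, "modality_model")) .ser_model(x)
  else .stopf("save_model: unsupported class '%s'", class(x)[1])
  .write_atomic(path, function(tmp)
    jsonlite::write_json(s, tmp, digits = NA, auto_unbox = TRUE,
                         null = "null", pretty = FALSE))
}

#' Load an object saved by [save_model()]
#'
#' @param path JSON file to read.
#' @return The restored object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) .stopf("model file '%s' does not exist", path)
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(s$type,
         gplvm_fit = .deser_fit(s),
         warping_function = .deser_warp(s),
         modality_model = .deser_model(s),
         .stopf("unknown model type '%s' in '%s'", s$type, path))
}
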