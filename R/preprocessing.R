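# Feature engineering for aggregated single-cell epigenomic signatures:
# peak binarization, signature aggregation over region groups, per-cell
# scale-factor normalization, cell filtering, methylation-site selection and
# gene-expression signature construction.

#' Binarize a count matrix
#'
#' Sparse single-cell epigenomic counts are predominantly 0 or 1 per region;
#' values above 0 become 1 (accessible/detected), avoiding confounders such
#' as copy-number variation that inflate counts.
#'
#' @param counts A [cell_matrix()] or numeric matrix of non-negative
#'   integers.
#' @return Same type as the input, with values in `{0, 1}`.
#' @export
binarize_counts <- function(counts) {
  vals <- if (inherits(counts, "cell_matrix")) counts$values else counts
  if (any(vals < 0) || any(vals != round(vals)))
    .stopf("binarize_counts: counts must be non-negative integers")
  out <- (vals > 0) * 1
  if (inherits(counts, "cell_matrix")) {
    counts$values <- out
    counts
  } else out
}

#' Aggregate features into group signatures
#'
#' Sums member features per cell for each group of a feature-to-group
#' membership map (e.g. ATAC peaks grouped by transcription-factor motif).
#' A feature may belong to several groups and then contributes to each.
#'
#' @param X A [cell_matrix()] (binary or real values).
#' @param map Data frame with columns `feature_id` and `group`.
#' @param modality Modality tag for the aggregated matrix.
#' @return A [cell_matrix()] of cells x groups.
#' @export
aggregate_signatures <- function(X, map, modality = X$modality) {
  stopifnot(inherits(X, "cell_matrix"), is.data.frame(map),
            all(c("feature_id", "group") %in% names(map)))
  unknown <- setdiff(unique(map$feature_id), feature_ids(X))
  if (length(unknown))
    .stopf("aggregate_signatures: features in map but not in matrix: %s",
           paste(unknown, collapse = ", "))
  groups <- unique(as.character(map$group))
  agg <- vapply(groups, function(g) {
    members <- map$feature_id[map$group == g]
    rowSums(X$values[, members, drop = FALSE])
  }, numeric(n_cells(X)))
  agg <- matrix(agg, nrow = n_cells(X),
                dimnames = list(cell_ids(X), groups))
  cell_matrix(agg, modality = modality)
}

#' Filter cells by minimum detected events
#'
#' Keeps cells with at least `threshold` detected events (non-zero
#' entries), removing the near-empty cells whose signatures are too sparse
#' to order.  The threshold is inclusive: a cell with exactly `threshold`
#' events is kept.
#'
#' @param X A [cell_matrix()] (binary or count values).
#' @param threshold Minimum number of detected events (default 1000).
#' @return List with `matrix` (retained cells) and `removed` (data frame of
#'   removed cell IDs and their totals).
#' @export
filter_cells_min_events <- function(X, threshold = 1000L) {
  stopifnot(inherits(X, "cell_matrix"))
  totals <- rowSums(X$values != 0)
  keep <- totals >= threshold
  removed <- data.frame(cell_id = cell_ids(X)[!keep],
                        n_events = unname(totals[!keep]),
                        stringsAsFactors = FALSE)
  if (!any(keep))
    warning("all cells fall below the event threshold; downstream fitting will fail",
            call. = FALSE)
  X$values <- X$values[keep, , drop = FALSE]
  list(matrix = X, removed = removed)
}

#' Per-cell scale-factor normalization
#'
#' Corrects aggregated signatures for differences in per-cell totals.  For
#' chromatin accessibility (`kind = "atac"`) every entry of cell j is
#' multiplied by `s_j = (sum_j t_j / n) / (1000 t_j)`, which equalises the
#' scaled per-cell totals exactly (the constant 1000 keeps values near 1).
#' For histone-mark signatures (`kind = "chip"`) the factor is
#' `s_j = 10 (sum_j t_j / n) / t_j`.
#'
#' @param F A [cell_matrix()] of aggregated signatures.
#' @param kind `"atac"` or `"chip"`.
#' @param totals Per-cell event totals `t_j` (strictly positive, one per
#'   cell); defaults to the per-cell sums of `F`.
#' @return List with `matrix` (normalised) and `scale_factors` (named per
#'   cell).
#' @export
scale_normalize <- function(F, kind = c("atac", "chip"), totals = NULL) {
  stopifnot(inherits(F, "cell_matrix"))
  kind <- match.arg(kind)
  if (is.null(totals)) totals <- rowSums(F$values)
  if (length(totals) != n_cells(F))
    .stopf("scale_normalize: need one total per cell")
  if (any(totals <= 0)) {
    bad <- cell_ids(F)[totals <= 0][1]
    .stopf("scale_normalize: cell '%s' has non-positive total", bad)
  }
  s <- if (kind == "atac") mean(totals) / (1000 * totals)
       else 10 * mean(totals) / totals
  F$values <- F$values * s
  list(matrix = F, scale_factors = setNames(s, cell_ids(F)))
}

#' Select methylation sites by correlation with a marker
#'
#' Genome-wide methylation calls are dominated by technical variation; only
#' sites co-varying with a validated differentiation marker carry the signal
#' of interest.  Retains features whose Pearson correlation with the marker
#' feature is at least `min_corr` (the marker itself has r = 1 and is always
#' retained); features with undefined correlation (zero variance) are
#' excluded.
#'
#' @param M A [cell_matrix()] of methylation levels.
#' @param marker_feature Feature ID of the marker.
#' @param min_corr Minimum Pearson correlation (default 0.2).
#' @return Character vector of retained feature IDs.
#' @export
select_methylation_sites <- function(M, marker_feature, min_corr = 0.2) {
  stopifnot(inherits(M, "cell_matrix"))
  if (!(marker_feature %in% feature_ids(M)))
    .stopf("marker feature '%s' not present", marker_feature)
  marker <- M$values[, marker_feature]
  if (sd(marker) == 0)
    .stopf("marker feature '%s' has zero variance", marker_feature)
  r <- suppressWarnings(as.vector(cor(marker, M$values)))
  keep <- !is.na(r) & r >= min_corr
  feature_ids(M)[keep]
}

#' Gene-expression signatures for region groups
#'
#' Builds per-cell aggregate expression values comparable with aggregated
#' epigenomic signatures: (1) genes occurring in more than one list are
#' dropped from all lists; (2) each remaining gene is z-scored across cells
#' (zero-variance genes dropped with a log message); (3) per cell, each
#' list's sum over its member z-scored genes and the total sum over all
#' z-scored genes are computed; (4) each signature is the across-cell
#' z-score of (list sum - total sum).
#'
#' @param E A [cell_matrix()] of (log-normalised) expression.
#' @param gene_lists Named list of character vectors of gene IDs.
#' @return A [cell_matrix()] of cells x signatures (one per list), each
#'   column with mean 0 and unit variance.
#' @export
expression_signatures <- function(E, gene_lists) {
  stopifnot(inherits(E, "cell_matrix"), is.list(gene_lists),
            !is.null(names(gene_lists)))
  all_genes <- unlist(gene_lists, use.names = FALSE)
  dup <- unique(all_genes[duplicated(all_genes)])
  lists <- lapply(gene_lists, function(g) setdiff(intersect(g, feature_ids(E)), dup))
  empty <- names(lists)[lengths(lists) == 0]
  if (length(empty))
    .stopf("gene list(s) empty after deduplication/intersection: %s",
           paste(empty, collapse = ", "))
  sds <- apply(E$values, 2, sd)
  if (any(sds == 0))
    .logf("dropping %d zero-variance gene(s) from signature construction",
          sum(sds == 0))
  Z <- scale(E$values[, sds > 0, drop = FALSE])
  total <- rowSums(Z)
  sig <- vapply(lists, function(g) {
    g <- intersect(g, colnames(Z))
    rowSums(Z[, g, drop = FALSE]) - total
  }, numeric(nrow(Z)))
  sig <- scale(matrix(sig, nrow = nrow(Z),
                      dimnames = list(cell_ids(E), names(lists))))
  cell_matrix(sig[, , drop = FALSE], modality = "expression_signatures")
}

#' Drop latent-space outlier cells
#'
#' Pilot-fits the 1-D latent model and removes cells whose latent coordinate
#' lies more than `k` median absolute deviations from the median — a
#' reproducible stand-in for by-inspection outlier removal.
#'
#' @param Y A [cell_matrix()].
#' @param config A [run_config()].
#' @param k MAD multiplier (default 5).
#' @return List with `matrix` (retained cells) and `removed` (cell IDs).
#' @export
filter_latent_outliers <- function(Y, config, k = 5) {
  fit <- fit_gplvm(Y, config)
  lat <- fit$latent_mean
  dev <- abs(lat - median(lat))
  cut <- k * mad(lat)
  removed <- names(lat)[dev > cut]
  if (length(removed))
    .logf("removing %d latent-outlier cell(s): %s", length(removed),
          paste(removed, collapse = ", "))
  Y$values <- Y$values[setdiff(cell_ids(Y), removed), , drop = FALSE]
  list(matrix = Y, removed = removed)
}

#' Keep the most variable features
#'
#' Plain per-feature variance ranking, provided as plumbing for selecting an
#' informative gene subset before fitting.
#'
#' @param Y A [cell_matrix()].
#' @param k Number of features to keep.
#' @return A [cell_matrix()] restricted to the top-`k` variance features.
#' @export
filter_top_variance <- function(Y, k) {
  stopifnot(inherits(Y, "cell_matrix"))
  v <- apply(Y$values, 2, var)
  keep <- names(sort(v, decreasing = TRUE))[seq_len(min(k, length(v)))]
  Y$values <- Y$values[, keep, drop = FALSE]
  Y
}
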