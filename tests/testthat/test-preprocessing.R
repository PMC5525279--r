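# Feature-engineering math: binarization, aggregation, filtering, the two
# scale factors, methylation-site selection and expression signatures.

toy_counts <- function() {
  vals <- matrix(c(0, 1, 7,
                   2, 0, 1,
                   0, 0, 0,
                   5, 1, 0), nrow = 3,
                 dimnames = list(c("c1", "c2", "c3"),
                                 c("p1", "p2", "p3", "p4")))
  cell_matrix(vals, modality = "atac")
}

test_that("binarization thresholds at zero and is idempotent", {
  b <- binarize_counts(toy_counts())
  expect_equal(unname(b$values[, "p1"]), c(0, 1, 1))
  expect_equal(unname(b$values["c3", ]), c(1, 1, 0, 0))
  expect_equal(binarize_counts(b)$values, b$values)
  expect_error(binarize_counts(cell_matrix(matrix(-1, 3, 2))), "non-negative")
  expect_error(binarize_counts(cell_matrix(matrix(0.5, 3, 2))), "integers")
})

test_that("signature aggregation sums member features, with multi-group membership", {
  X <- binarize_counts(toy_counts())
  map <- data.frame(feature_id = c("p1", "p2", "p2", "p3"),
                    group = c("G1", "G1", "G2", "G2"))
  agg <- aggregate_signatures(X, map)
  # hand-computed: binarized p1 = (0,1,1), p2 = (1,0,1), p3 = (0,0,0), so
  # G1 = p1 + p2 = (1,1,2) and G2 = p2 + p3 = (1,0,1)
  expect_equal(agg$values,
               matrix(c(1, 1, 2, 1, 0, 1), nrow = 3,
                      dimnames = list(c("c1", "c2", "c3"), c("G1", "G2"))))
  bad <- data.frame(feature_id = "missing", group = "G1")
  expect_error(aggregate_signatures(X, bad), "missing")
})

test_that("the event filter keeps cells at the threshold and reports removals", {
  set.seed(1)
  vals <- matrix(0, 3, 6000)
  vals[1, seq_len(999)] <- 1
  vals[2, seq_len(1000)] <- 1
  vals[3, seq_len(5000)] <- 1
  X <- cell_matrix(vals, cell_ids = c("low", "edge", "high"), modality = "atac")
  flt <- filter_cells_min_events(X, 1000)
  expect_identical(cell_ids(flt$matrix), c("edge", "high"))
  expect_equal(flt$removed$cell_id, "low")
  expect_equal(flt$removed$n_events, 999)

  all_in <- filter_cells_min_events(X, 10)
  expect_equal(all_in$matrix$values, X$values)
  expect_warning(flt0 <- filter_cells_min_events(X, 10000), "below the event threshold")
  expect_equal(n_cells(flt0$matrix), 0L)
})

test_that("scale factors match hand-evaluated values exactly", {
  # accessibility: s_j = mean(totals) / (1000 t_j)
  F2 <- cell_matrix(matrix(1, 2, 3), cell_ids = c("a", "b"))
  sn <- scale_normalize(F2, "atac", totals = c(1000, 3000))
  expect_identical(unname(sn$scale_factors),
                   c(2000 / (1000 * 1000), 2000 / (1000 * 3000)))
  expect_equal(unname(sn$scale_factors)[1], 0.002)
  expect_equal(unname(sn$scale_factors)[2], 6.667e-4, tolerance = 1e-4)

  # a cell at the mean total gets exactly 1/1000 (atac) and 10 (chip)
  sn_mean <- scale_normalize(F2, "atac", totals = c(2000, 2000))
  expect_identical(unname(sn_mean$scale_factors), c(1e-3, 1e-3))
  ch <- scale_normalize(F2, "chip", totals = c(2000, 2000))
  expect_identical(unname(ch$scale_factors), c(10, 10))

  expect_error(scale_normalize(F2, "atac", totals = c(0, 10)), "non-positive")
})

test_that("accessibility normalization equalizes per-cell scaled totals exactly", {
  set.seed(2)
  vals <- matrix(rpois(40 * 25, 3), 40, 25)
  X <- cell_matrix(vals, modality = "atac")
  totals <- rowSums(vals)
  sn <- scale_normalize(X, "atac", totals = totals)
  scaled_totals <- totals * sn$scale_factors
  expect_lt(max(scaled_totals) / min(scaled_totals) - 1, 1e-12)
  expect_equal(unname(scaled_totals[1]), mean(totals) / 1000)
  # histone-mark factor makes the scaled total exactly 10 x mean
  ch <- scale_normalize(X, "chip", totals = totals)
  expect_equal(unname(unique(round(totals * ch$scale_factors, 9))),
               round(10 * mean(totals), 9))
})

test_that("preprocessing is equivariant under cell permutation", {
  X <- toy_counts()
  perm <- c(3, 1, 2)
  Xp <- cell_matrix(X$values[perm, ], modality = "atac")
  map <- data.frame(feature_id = c("p1", "p2"), group = c("G", "G"))
  a1 <- aggregate_signatures(binarize_counts(X), map)
  a2 <- aggregate_signatures(binarize_counts(Xp), map)
  expect_equal(a2$values, a1$values[perm, , drop = FALSE])
})

test_that("methylation sites are selected by marker correlation", {
  set.seed(3)
  n <- 200
  marker <- rnorm(n)
  vals <- cbind(marker = marker,
                same = marker,
                anti = -marker,
                weak = 0.3 * marker + rnorm(n),
                flat = rep(1, n))
  M <- cell_matrix(vals, modality = "meth")
  keep <- select_methylation_sites(M, "marker")
  expect_true(all(c("marker", "same") %in% keep))
  expect_false("anti" %in% keep)
  expect_false("flat" %in% keep)

  # independent noise is excluded in almost all seeded draws
  excl <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    !("noise" %in% select_methylation_sites(
      cell_matrix(cbind(marker = marker, noise = rnorm(n))), "marker"))
  }, logical(1))
  expect_gte(mean(excl), 0.95)

  expect_error(select_methylation_sites(
    cell_matrix(cbind(marker = rep(1, 5), x = rnorm(5))), "marker"),
    "zero variance")
})

test_that("expression signatures follow the four-step construction", {
  # 3 cells x 4 genes, two lists; g4 appears on both lists and must vanish
  E <- cell_matrix(matrix(c(1, 2, 3,
                            4, 6, 2,
                            0, 1, 5,
                            7, 2, 9), nrow = 3,
                          dimnames = list(c("c1", "c2", "c3"),
                                          c("g1", "g2", "g3", "g4"))),
                   modality = "rna")
  sig <- expression_signatures(E, list(A = c("g1", "g4"), B = c("g2", "g4")))
  # independent step-by-step oracle
  Z <- apply(E$values, 2, function(x) (x - mean(x)) / sd(x))
  tot <- rowSums(Z)
  zf <- function(x) (x - mean(x)) / sd(x)
  expected <- cbind(A = zf(Z[, "g1"] - tot), B = zf(Z[, "g2"] - tot))
  rownames(expected) <- c("c1", "c2", "c3")
  expect_equal(sig$values, expected)
  expect_equal(unname(colMeans(sig$values)), c(0, 0))
  expect_equal(unname(apply(sig$values, 2, sd)), c(1, 1))

  expect_error(expression_signatures(E, list(A = "g4", B = c("g1", "g4"))),
               "empty after deduplication")
})

test_that("the composed pipeline reproduces the frozen golden output bit-exactly", {
  set.seed(7)
  vals <- matrix(rpois(8 * 30, 1.2), nrow = 8,
                 dimnames = list(sprintf("c%02d", 1:8), sprintf("p%02d", 1:30)))
  X <- cell_matrix(vals, modality = "atac")
  map <- data.frame(feature_id = sprintf("p%02d", 1:30),
                    group = rep(c("TF1", "TF2", "TF3"), each = 10))
  b <- binarize_counts(X)
  flt <- filter_cells_min_events(b, 8)
  agg <- aggregate_signatures(flt$matrix, map)
  norm <- scale_normalize(agg, "atac", totals = rowSums(flt$matrix$values))
  out <- tempfile(fileext = ".tsv")
  write_matrix(norm$matrix, out)
  golden <- test_path("golden", "atac_pipeline_golden.tsv")
  expect_identical(readLines(out), readLines(golden))
})

test_that("top-variance filtering keeps the k most variable features", {
  set.seed(4)
  vals <- cbind(a = rnorm(30, sd = 0.1), b = rnorm(30, sd = 5), c = rnorm(30, sd = 1))
  Y <- filter_top_variance(cell_matrix(vals), 2)
  expect_identical(feature_ids(Y), c("b", "c"))
})
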