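# Cell-by-feature matrices and their on-disk formats.
#
# One internal convention everywhere: cells in rows, features in columns.
# Transposed inputs must be declared explicitly at load time.

#' Construct a cell-by-feature matrix
#'
#' The basic observation container: a dense numeric matrix with unique cell
#' IDs in rows and unique feature IDs in columns, tagged with a modality name.
#'
#' @param values Numeric matrix (cells x features).  Row/column names are used
#'   as IDs when `cell_ids`/`feature_ids` are not given.
#' @param cell_ids Character vector of unique cell IDs.
#' @param feature_ids Character vector of unique feature IDs.
#' @param modality Modality tag (e.g. `"rna"`, `"atac"`).
#' @param impute_missing If `TRUE`, missing entries are replaced by the
#'   per-feature mean (count logged); if `FALSE` (default) missing values are
#'   an error.
#'
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(values, cell_ids = rownames(values),
                        feature_ids = colnames(values),
                        modality = "unnamed", impute_missing = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  feature_ids <- as.character(feature_ids)
  if (length(cell_ids) != nrow(values) || length(feature_ids) != ncol(values))
    .stopf("cell_matrix: ID lengths do not match matrix dimensions")
  .check_unique(cell_ids, "cell")
  .check_unique(feature_ids, "feature")
  if (anyNA(values)) {
    if (!impute_missing)
      .stopf("cell_matrix: %d missing values (set impute_missing = TRUE for per-feature mean imputation)",
             sum(is.na(values)))
    n_imp <- sum(is.na(values))
    for (j in seq_len(ncol(values))) {
      nas <- is.na(values[, j])
      if (any(nas)) values[nas, j] <- mean(values[, j], na.rm = TRUE)
    }
    if (anyNA(values)) .stopf("cell_matrix: features with all values missing cannot be imputed")
    .logf("imputed %d missing values with per-feature means", n_imp)
  }
  if (any(!is.finite(values)))
    .stopf("cell_matrix: non-finite values are not allowed")
  dimnames(values) <- list(cell_ids, feature_ids)
  structure(list(values = values, modality = modality), class = "cell_matrix")
}

.check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    .stopf("duplicate %s IDs: %s", what, paste(dup, collapse = ", "))
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix '%s': %d cells x %d features\n",
              x$modality, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname cell_matrix
#' @param x A `cell_matrix`.
#' @export
n_cells <- function(x) nrow(x$values)

#' @rdname cell_matrix
#' @export
n_features <- function(x) ncol(x$values)

#' @rdname cell_matrix
#' @export
cell_ids <- function(x) rownames(x$values)

#' @rdname cell_matrix
#' @export
feature_ids <- function(x) colnames(x$values)

#' Per-cell metadata
#'
#' Optional per-cell annotations: an ordered time-point label and/or a
#' correspondence key linking the same physical cell across modalities.
#' When attached to a `cell_matrix` the cell IDs must match one-to-one.
#'
#' @param cell_ids Character vector of unique cell IDs.
#' @param time_point Optional ordered factor (or vector coercible with the
#'   order of appearance of its unique values) of time-point labels.
#' @param correspondence_key Optional character vector.
#' @param matrix Optional `cell_matrix` to validate alignment against.
#' @return An object of class `cell_metadata`.
#' @export
cell_metadata <- function(cell_ids, time_point = NULL,
                          correspondence_key = NULL, matrix = NULL) {
  cell_ids <- as.character(cell_ids)
  .check_unique(cell_ids, "cell")
  if (!is.null(time_point)) {
    if (!is.ordered(time_point))
      .stopf("cell_metadata: time_point must be an ordered factor")
    if (length(time_point) != length(cell_ids))
      .stopf("cell_metadata: time_point length mismatch")
  }
  if (!is.null(correspondence_key) && length(correspondence_key) != length(cell_ids))
    .stopf("cell_metadata: correspondence_key length mismatch")
  if (!is.null(matrix) && !setequal(cell_ids, rownames(matrix$values)))
    .stopf("cell_metadata: cell IDs do not align with the matrix")
  structure(list(cell_ids = cell_ids, time_point = time_point,
                 correspondence_key = correspondence_key),
            class = "cell_metadata")
}

#' Read a cell-by-feature matrix from disk
#'
#' Dense TSV/CSV: first column `cell_id`, header row of feature IDs, `.`
#' decimal separator.  Sparse: MatrixMarket coordinate file plus sidecar
#' `rows.txt` (cell IDs) and `cols.txt` (feature IDs) in the same directory,
#' overridable via `row_file`/`col_file`.  Dense and sparse encodings of the
#' same data load to identical values.
#'
#' @param path File to read.
#' @param format `"auto"` (from extension), `"tsv"`, `"csv"`, or `"mtx"`.
#' @param modality Modality tag for the result.
#' @param transpose Set `TRUE` when the file stores features in rows.
#' @param impute_missing Passed to [cell_matrix()].
#' @param drop_zero_cells Drop cells whose entire feature vector is zero,
#'   with a warning (default `TRUE`); such cells carry no ordering
#'   information for downstream fitting.
#' @param row_file,col_file Sidecar label files for `mtx` input.
#'
#' @return A [cell_matrix()].
#' @export
read_matrix <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                        modality = "unnamed", transpose = FALSE,
                        impute_missing = FALSE, drop_zero_cells = TRUE,
                        row_file = NULL, col_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file '%s' does not exist", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     .stopf("cannot infer format from extension '.%s'", ext))
  }
  if (format == "mtx") {
    mat <- as.matrix(Matrix::readMM(path))
    if (is.null(row_file)) row_file <- file.path(dirname(path), "rows.txt")
    if (is.null(col_file)) col_file <- file.path(dirname(path), "cols.txt")
    if (!file.exists(row_file)) .stopf("mtx sidecar row-label file '%s' missing", row_file)
    if (!file.exists(col_file)) .stopf("mtx sidecar column-label file '%s' missing", col_file)
    rid <- readLines(row_file, warn = FALSE)
    cid <- readLines(col_file, warn = FALSE)
    if (length(rid) != nrow(mat) || length(cid) != ncol(mat))
      .stopf("mtx label files do not match matrix dimensions")
    dimnames(mat) <- list(rid, cid)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    mat <- .read_dense(path, sep)
  }
  if (transpose) mat <- t(mat)
  out <- cell_matrix(mat, modality = modality, impute_missing = impute_missing)
  if (drop_zero_cells) {
    zero <- rowSums(out$values != 0) == 0
    if (any(zero)) {
      warning(sprintf("dropping %d all-zero cell(s): %s", sum(zero),
                      paste(rownames(out$values)[zero], collapse = ", ")),
              call. = FALSE)
      out$values <- out$values[!zero, , drop = FALSE]
    }
  }
  out
}

# Hand-parsed dense reader: the error contract requires positional reporting
# for non-numeric cells and explicit ragged-row detection.
.read_dense <- function(path, sep) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) .stopf("'%s': need a header plus at least one data row", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1]]
  n_col <- length(header)
  feature_ids <- header[-1]
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1]
    .stopf("'%s': ragged row %d has %d fields, expected %d",
           path, bad + 1L, widths[bad], n_col)
  }
  cell_ids <- vapply(body, `[[`, character(1), 1L)
  raw <- vapply(body, function(f) f[-1], character(n_col - 1L))
  raw <- matrix(raw, nrow = n_col - 1L)          # features x cells
  num <- suppressWarnings(as.numeric(raw))
  bad <- is.na(num) & !(trimws(raw) %in% c("NA", "nan", "NaN", ""))
  if (any(bad)) {
    idx <- which(bad)[1]
    fi <- (idx - 1L) %% (n_col - 1L) + 1L
    ci <- (idx - 1L) %/% (n_col - 1L) + 1L
    .stopf("'%s': non-numeric value '%s' at data row %d, column '%s'",
           path, raw[idx], ci, feature_ids[fi])
  }
  mat <- t(matrix(num, nrow = n_col - 1L,
                  dimnames = list(feature_ids, cell_ids)))
  mat
}

#' Write a cell-by-feature matrix
#'
#' Values are written with 17 significant digits so read/write round trips
#' are value-preserving.
#'
#' @param x A [cell_matrix()].
#' @param path Destination file.
#' @param format `"tsv"`, `"csv"`, or `"mtx"` (the latter writes `rows.txt`
#'   and `cols.txt` sidecars next to the matrix file).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("tsv", "csv", "mtx")) {
  stopifnot(inherits(x, "cell_matrix"))
  format <- match.arg(format)
  if (format == "mtx") {
    .write_atomic(path, function(tmp)
      Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE), tmp))
    writeLines(rownames(x$values), file.path(dirname(path), "rows.txt"))
    writeLines(colnames(x$values), file.path(dirname(path), "cols.txt"))
    return(invisible(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  .write_atomic(path, function(tmp) {
    header <- paste(c("cell_id", colnames(x$values)), collapse = sep)
    rows <- vapply(seq_len(nrow(x$values)), function(i)
      paste(c(rownames(x$values)[i], .fmt_num(x$values[i, ])), collapse = sep),
      character(1))
    writeLines(c(header, rows), tmp)
  })
}

#' Write a master-time table
#'
#' @param records Data frame with columns `cell_id`, `modality`,
#'   `pseudotime`, `master_time`.  Master time must lie in `[0, 1]`.
#' @param path Destination TSV.
#' @return `path`, invisibly.
#' @export
write_master_time_table <- function(records, path) {
  need <- c("cell_id", "modality", "pseudotime", "master_time")
  if (!all(need %in% names(records)))
    .stopf("records must carry columns: %s", paste(need, collapse = ", "))
  records <- records[, need, drop = FALSE]
  if (any(records$master_time < 0 | records$master_time > 1))
    .stopf("master_time outside [0, 1] violates the master-time contract")
  .write_atomic(path, function(tmp) {
    lines <- c(paste(need, collapse = "\t"),
               vapply(seq_len(nrow(records)), function(i)
                 paste(records$cell_id[i], records$modality[i],
                       .fmt_num(records$pseudotime[i]),
                       .fmt_num(records$master_time[i]), sep = "\t"),
                 character(1)))
    writeLines(lines, tmp)
  })
}

#' Read a master-time table written by [write_master_time_table()]
#'
#' @param path TSV to read.
#' @return Data frame with the four stored columns.
#' @export
read_master_time_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  out <- data.frame(
    cell_id = vapply(body, `[[`, character(1), 1L),
    modality = vapply(body, `[[`, character(1), 2L),
    pseudotime = as.numeric(vapply(body, `[[`, character(1), 3L)),
    master_time = as.numeric(vapply(body, `[[`, character(1), 4L)),
    stringsAsFactors = FALSE)
  stopifnot(identical(header, names(out)))
  out
}
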