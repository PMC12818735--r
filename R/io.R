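#' Write a count matrix as 10x-style Matrix Market triplet files
#'
#' Emits `matrix.mtx` (Matrix Market coordinate format, 1-based indices),
#' `features.tsv` (one gene id per line) and `barcodes.tsv` (one cell id per
#' line). Integer matrices round-trip bit-exactly through [read_counts()].
#'
#' @param counts Sparse (or dense) nonnegative integer gene x cell matrix
#'   with gene rownames and cell colnames.
#' @param matrix_path,features_path,barcodes_path Output paths.
#' @return Invisibly, the three paths.
#' @export
write_counts <- function(counts, matrix_path, features_path, barcodes_path) {
  assert_count_matrix(counts)
  m <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(m, matrix_path)
  writeLines(rownames(counts), features_path)
  writeLines(colnames(counts), barcodes_path)
  invisible(c(matrix = matrix_path, features = features_path,
              barcodes = barcodes_path))
}

format_error <- function(path, msg) {
  stop(sprintf("format error in %s: %s", path, msg), call. = FALSE)
}

#' Read a 10x-style Matrix Market count triplet
#'
#' Validates dimensions against the feature/barcode files, integerness and
#' nonnegativity of the entries, and uniqueness of identifiers. Reading is
#' gzip-transparent.
#'
#' @param matrix_path Matrix Market coordinate file.
#' @param features_path One gene identifier per line (extra tab-separated
#'   columns, as in 10x `features.tsv`, are ignored).
#' @param barcodes_path One cell identifier per line.
#' @return A sparse `dgCMatrix` (genes x cells) with identifiers as dimnames.
#' @export
read_counts <- function(matrix_path, features_path, barcodes_path) {
  for (p in c(matrix_path, features_path, barcodes_path))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) format_error(matrix_path, conditionMessage(e)))
  # undo symmetric/pattern storage optimizations of the format
  m <- methods::as(methods::as(m, "generalMatrix"), "dMatrix")
  read_ids <- function(p)           # tolerate CRLF and a trailing newline
    sub("\r$", "", readLines(p))
  features <- vapply(strsplit(read_ids(features_path), "\t", fixed = TRUE),
                     `[[`, character(1), 1L)
  barcodes <- read_ids(barcodes_path)
  if (nrow(m) != length(features))
    format_error(matrix_path,
                 sprintf("declares %d rows but %s has %d lines",
                         nrow(m), features_path, length(features)))
  if (ncol(m) != length(barcodes))
    format_error(matrix_path,
                 sprintf("declares %d columns but %s has %d lines",
                         ncol(m), barcodes_path, length(barcodes)))
  if (anyDuplicated(features))
    format_error(features_path, sprintf("duplicate gene identifier `%s` (line %d)",
                 features[anyDuplicated(features)], anyDuplicated(features)))
  if (anyDuplicated(barcodes))
    format_error(barcodes_path, sprintf("duplicate cell identifier `%s` (line %d)",
                 barcodes[anyDuplicated(barcodes)], anyDuplicated(barcodes)))
  x <- m@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    format_error(matrix_path, "entries must be nonnegative integers")
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(features, barcodes)
  m
}

#' Read a per-cell annotation table
#'
#' @param path CSV with header `cell_id,age,subtype,class` (extra columns
#'   kept).
#' @param age_order Declared ordered age labels; any age outside this set is
#'   an error.
#' @return A data.frame with `age` as a factor ordered by `age_order`.
#' @export
read_annotation <- function(path, age_order) {
  ann <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "age", "subtype", "class")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    format_error(path, paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(ann$cell_id))
    format_error(path, sprintf("duplicate cell_id `%s`",
                               ann$cell_id[anyDuplicated(ann$cell_id)]))
  bad <- setdiff(unique(ann$age), age_order)
  if (length(bad))
    format_error(path, sprintf("unknown age label(s) %s; allowed: %s",
                               paste(bad, collapse = ", "),
                               paste(age_order, collapse = ", ")))
  ann$age <- factor(ann$age, levels = age_order)
  ann
}

#' @rdname read_annotation
#' @param ann Annotation data.frame with columns `cell_id,age,subtype,class`.
#' @export
write_annotation <- function(ann, path) {
  write.csv(ann[, c("cell_id", "age", "subtype", "class")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a segmented-cell spatial expression table
#'
#' @param path CSV with header `cell_id,x,y,ligand,receptor`.
#' @return `read_spatial()`: a data.frame with those columns, validated
#'   (finite coordinates, nonnegative expression, unique cell ids).
#' @export
read_spatial <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "x", "y", "ligand", "receptor")
  miss <- setdiff(need, names(d))
  if (length(miss))
    format_error(path, paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(d$cell_id))
    format_error(path, sprintf("duplicate cell_id `%s`",
                               d$cell_id[anyDuplicated(d$cell_id)]))
  if (!all(is.finite(d$x)) || !all(is.finite(d$y)))
    format_error(path, "coordinates must be finite")
  if (any(d$ligand < 0) || any(d$receptor < 0))
    format_error(path, "expression values must be nonnegative")
  d
}

#' @rdname read_spatial
#' @param spatial Data.frame with columns `cell_id,x,y,ligand,receptor`.
#' @export
write_spatial <- function(spatial, path) {
  write.csv(spatial[, c("cell_id", "x", "y", "ligand", "receptor")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a spot x subtype deconvolution abundance matrix
#'
#' @param path CSV whose first column is `spot_id` and remaining columns are
#'   subtype abundance scores.
#' @return `read_abundance()`: a numeric matrix (spots x subtypes) with spot
#'   rownames and subtype colnames; all entries finite and >= 0.
#' @export
read_abundance <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "spot_id")
    format_error(path, "first column must be `spot_id`")
  if (ncol(d) < 2L) format_error(path, "no subtype columns")
  if (anyDuplicated(d$spot_id))
    format_error(path, sprintf("duplicate spot_id `%s`",
                               d$spot_id[anyDuplicated(d$spot_id)]))
  ab <- as.matrix(d[, -1, drop = FALSE])
  rownames(ab) <- d$spot_id
  if (!all(is.finite(ab)) || any(ab < 0))
    format_error(path, "abundance scores must be finite and >= 0")
  ab
}

#' @rdname read_abundance
#' @param ab Abundance matrix with spot rownames and subtype colnames.
#' @export
write_abundance <- function(ab, path) {
  d <- data.frame(spot_id = rownames(ab), ab, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
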