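#' Construct and validate an OTU table
#'
#' An OTU table is a base integer matrix with samples as rows and taxa as
#' columns, carrying unique row (sample) and column (taxon) names. All
#' analysis functions in the package expect this canonical orientation.
#'
#' @param counts numeric matrix of non-negative integers; rows are samples,
#'   columns are taxa. Dimnames are required and must be unique.
#' @return the validated count matrix (invisibly unchanged).
#' @export
otu_table <- function(counts) {
  if (!is.matrix(counts))
    stop("OTU table must be a matrix (samples x taxa)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("OTU table must carry sample (row) and taxon (column) names")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup))
    stop("duplicate taxon id(s): ", paste(unique(dup), collapse = ", "))
  if (!is.numeric(counts))
    stop("OTU table must be numeric")
  bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "invalid count (negative or non-integer) at sample '%s', taxon '%s': %s",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, , drop = FALSE]])))
  }
  storage.mode(counts) <- "double"
  counts <- round(counts)
  empty <- rownames(counts)[rowSums(counts) == 0]
  if (length(empty))
    stop("sample(s) with zero total count: ", paste(empty, collapse = ", "))
  counts
}

#' Read an OTU table from a tab-separated file
#'
#' The file must have one header row of ids and one leading id column.
#' `orientation` declares whether the file's rows are samples or taxa;
#' taxa-as-rows input is transposed to the canonical samples-as-rows form.
#'
#' @param path path to a TSV file.
#' @param orientation `"samples"` if rows are samples (default), `"taxa"` if
#'   rows are taxa.
#' @return a validated OTU table matrix, see [otu_table()].
#' @export
read_otu_table <- function(path, orientation = c("samples", "taxa")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", row.names = NULL,
                   check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate id(s) in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (orientation == "taxa") m <- t(m)
  otu_table(m)
}

#' Write an OTU table to a tab-separated file
#'
#' @param x OTU table matrix (samples x taxa).
#' @param path output path.
#' @param orientation orientation to write; default samples-as-rows.
#' @export
write_otu_table <- function(x, path, orientation = c("samples", "taxa")) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "taxa") t(x) else x
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- if (orientation == "taxa") "taxon_id" else "sample_id"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample-to-group assignment)
#'
#' Expects a tab-separated file with columns `sample_id` and `group`.
#' Row order is irrelevant.
#'
#' @param path path to a TSV file.
#' @return a data.frame with character columns `sample_id` and `group`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(df)))
    stop("metadata must have columns 'sample_id' and 'group'")
  sample_metadata(data.frame(sample_id = as.character(df$sample_id),
                             group = as.character(df$group),
                             stringsAsFactors = FALSE))
}

#' Validate a sample metadata data.frame
#'
#' @param metadata data.frame with columns `sample_id` and `group`.
#' @return the validated data.frame.
#' @export
sample_metadata <- function(metadata) {
  if (!is.data.frame(metadata) ||
      !all(c("sample_id", "group") %in% colnames(metadata)))
    stop("metadata must be a data.frame with columns 'sample_id' and 'group'")
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$group <- as.character(metadata$group)
  dup <- metadata$sample_id[duplicated(metadata$sample_id)]
  if (length(dup))
    stop("duplicated sample row(s) in metadata: ",
         paste(unique(dup), collapse = ", "))
  if (anyNA(metadata$group) || any(!nzchar(metadata$group)))
    stop("sample(s) with missing group: ",
         paste(metadata$sample_id[is.na(metadata$group) |
                                    !nzchar(metadata$group)], collapse = ", "))
  metadata
}

# group labels for a vector of sample ids, erroring on samples not covered
.groups_of <- function(metadata, sample_ids) {
  idx <- match(sample_ids, metadata$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from metadata: ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  metadata$group[idx]
}

#' Write a square distance matrix as TSV
#'
#' @param d square numeric matrix with matching row/column names.
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square distance matrix from TSV
#'
#' @param path path written by [write_distance_matrix()].
#' @return a validated symmetric matrix with zero diagonal.
#' @export
read_distance_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  d <- as.matrix(df)
  .validate_distance_matrix(d)
  d
}

.validate_distance_matrix <- function(d, tol = 1e-9) {
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (!identical(rownames(d), colnames(d)))
    stop("distance matrix row and column ids must match")
  if (any(d < 0)) stop("distance matrix must be non-negative")
  if (max(abs(d - t(d))) > tol) stop("distance matrix must be symmetric")
  if (max(abs(diag(d))) > tol) stop("distance matrix diagonal must be zero")
  invisible(d)
}
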