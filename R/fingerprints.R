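# Packed binary fingerprints shared by the SPAD and atom-pair descriptors.
# Rows (peptides) are stored as packed bitsets -- complement patterns make
# SPAD fingerprints roughly half-dense, so bitsets beat triplet-sparse
# storage by an order of magnitude in both time and memory.  Conversion to a
# conventional sparse matrix restricted to the observed columns is provided
# for export and interoperability.

# 8-bit popcount lookup table
POPCOUNT8 <- as.integer(colSums(matrix(as.integer(
  intToBits(0:255)), nrow = 32L)[1:8, , drop = FALSE]))

new_fingerprint_set <- function(bits, n_features, ids, labels, meta,
                                subclass) {
  stopifnot(is.matrix(bits), is.raw(bits), length(ids) == ncol(bits))
  fs <- list(bits = bits, n_features = n_features, ids = ids,
             labels = labels, meta = meta)
  class(fs) <- c(subclass, "fingerprint_set")
  fs
}

pack_rows <- function(logical_rows, n_features) {
  # logical_rows: list of logical vectors of length n_features
  padded <- ceiling(n_features / 8L) * 8L
  cols <- lapply(logical_rows, function(v) {
    if (length(v) < padded) v <- c(v, logical(padded - length(v)))
    packBits(v)
  })
  do.call(cbind, cols)
}

#' Number of peptides and features of a fingerprint set
#' @param x a `fingerprint_set`.
#' @export
dim.fingerprint_set <- function(x) c(length(x$ids), x$n_features)

#' @export
print.fingerprint_set <- function(x, ...) {
  cat(sprintf("%s fingerprints: %d peptides x %d features (%.1f%% dense)\n",
              x$meta$type, length(x$ids), x$n_features,
              100 * mean(fp_popcounts(x)) / max(1L, x$n_features)))
  invisible(x)
}

#' Per-peptide fingerprint cardinalities
#' @param fs a `fingerprint_set`.
#' @return Integer vector of set-bit counts, one per peptide.
#' @export
fp_popcounts <- function(fs) {
  out <- integer(ncol(fs$bits))
  for (a in seq_len(ncol(fs$bits)))
    out[a] <- sum(POPCOUNT8[as.integer(fs$bits[, a]) + 1L])
  names(out) <- fs$ids
  out
}

#' Set-bit positions of one peptide row
#' @param fs a `fingerprint_set`.
#' @param id peptide id or row index.
#' @return Sorted integer feature positions (1-based).
#' @export
fp_row_bits <- function(fs, id) {
  a <- if (is.character(id)) match(id, fs$ids) else as.integer(id)
  if (is.na(a) || a < 1L || a > length(fs$ids)) stop("unknown peptide: ", id)
  w <- which(as.logical(rawToBits(fs$bits[, a])))
  w[w <= fs$n_features]
}

fp_intersection <- function(fs, a, b) {
  sum(POPCOUNT8[as.integer(fs$bits[, a] & fs$bits[, b]) + 1L])
}

# column support counts over a subset of peptides (accumulated unpacked)
fp_col_counts <- function(fs, rows = seq_along(fs$ids)) {
  acc <- numeric(nrow(fs$bits) * 8L)
  for (a in rows) acc <- acc + as.integer(rawToBits(fs$bits[, a]))
  acc[seq_len(fs$n_features)]
}

#' Convert fingerprints to a sparse 0/1 matrix
#'
#' Columns are restricted to features observed in at least one peptide
#' (`observed_only = TRUE`, the default) and ordered canonically; column
#' names are the feature identifiers.
#'
#' @param fs a `fingerprint_set`.
#' @param observed_only drop all-zero columns.
#' @return A [Matrix::sparseMatrix()] (ngCMatrix), rows = peptides.
#' @export
fp_as_sparse <- function(fs, observed_only = TRUE) {
  ii <- vector("list", length(fs$ids))
  jj <- vector("list", length(fs$ids))
  for (a in seq_along(fs$ids)) {
    w <- which(as.logical(rawToBits(fs$bits[, a])))
    w <- w[w <= fs$n_features]
    ii[[a]] <- rep.int(a, length(w))
    jj[[a]] <- w
  }
  m <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                            dims = c(length(fs$ids), fs$n_features),
                            dimnames = list(fs$ids, feature_names(fs)))
  if (observed_only) m <- m[, Matrix::colSums(m) > 0, drop = FALSE]
  m
}

#' Feature identifiers of a fingerprint set
#' @param fs a `fingerprint_set`.
#' @return Character vector of length `n_features`.
#' @export
feature_names <- function(fs) UseMethod("feature_names")

#' @export
feature_names.default <- function(fs) fs$meta$keys

#' Write a fingerprint set as MatrixMarket plus a column sidecar
#'
#' @param fs a `fingerprint_set`.
#' @param path_mtx output `.mtx` path (observed columns only).
#' @param path_cols sidecar TSV mapping column index to feature id.
#' @param header optional provenance lines for the sidecar.
#' @export
write_feature_matrix <- function(fs, path_mtx, path_cols, header = NULL) {
  m <- fp_as_sparse(fs, observed_only = TRUE)
  Matrix::writeMM(methods::as(m, "dMatrix"), path_mtx)
  con <- file(path_cols, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("column\tfeature", con)
  writeLines(sprintf("%d\t%s", seq_len(ncol(m)), colnames(m)), con)
  invisible(path_mtx)
}
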