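# The substructure-pair descriptor: a peptide fires the feature
# (x_i, y_k, x_j) when some residue at position q1 carries pattern x_i, some
# residue at a later position q2 carries pattern x_j, and the number of
# residues strictly between them belongs to the intermediate binding y_k.
# Pairs are directional (N-to-C) by default and the two positions are always
# distinct residues.

#' Construct a single intermediate-binding (gap) specification
#'
#' @param gaps non-negative integers: allowed counts of residues strictly
#'   between the two substructure carriers.
#' @param id optional identifier; derived from `gaps` when omitted.
#' @return List of class `gap_spec` with fields `id` and `gaps`.
#' @export
gap_spec <- function(gaps, id = NULL) {
  gaps <- sort(unique(as.integer(gaps)))
  if (!length(gaps) || any(gaps < 0L)) stop("gaps must be non-negative")
  if (is.null(id)) {
    id <- if (length(gaps) == 1L) sprintf("g%d", gaps)
          else if (identical(gaps, gaps[1L]:gaps[length(gaps)]))
            sprintf("g%d-%d", gaps[1L], gaps[length(gaps)])
          else paste0("g", paste(gaps, collapse = "_"))
  }
  structure(list(id = id, gaps = gaps), class = "gap_spec")
}

#' Default set of intermediate bindings
#'
#' Exact gaps `{0}, {1}, ..., {max_gap}` plus the ranged specifications
#' `{0..2}`, `{0..4}` and `{0..max_gap}` (deduplicated), mirroring the idea
#' of adding "bindings within some length" for conformational flexibility.
#'
#' @param max_gap largest allowed gap (default 8).
#' @return List of [gap_spec()] objects; its length is the descriptor's M.
#' @export
default_gap_set <- function(max_gap = 8L) {
  max_gap <- as.integer(max_gap)
  if (is.na(max_gap) || max_gap < 0L) stop("max_gap must be >= 0")
  specs <- lapply(0:max_gap, gap_spec)
  for (r in unique(pmin(c(2L, 4L, max_gap), max_gap))) {
    cand <- gap_spec(0:r)
    if (!any(vapply(specs, function(s) identical(s$gaps, cand$gaps), TRUE)))
      specs <- c(specs, list(cand))
  }
  specs
}

gap_ids <- function(gaps) vapply(gaps, `[[`, "", "id")

#' Evaluate one substructure-pair feature on one peptide
#'
#' @param tokens residue codes (N-to-C) or a single sequence string.
#' @param bits residue bit table from [residue_bit_table()].
#' @param pattern_i combined pattern id on the N-terminal side.
#' @param gap a [gap_spec()] or an integer vector of allowed gaps.
#' @param pattern_j combined pattern id on the C-terminal side.
#' @return 0 or 1.
#' @export
spad_feature <- function(tokens, bits, pattern_i, gap, pattern_j) {
  if (length(tokens) == 1L && !(tokens %in% rownames(bits)))
    tokens <- tokenize_sequence(tokens)
  if (!all(tokens %in% rownames(bits)))
    stop("unknown residue code(s): ",
         paste(setdiff(tokens, rownames(bits)), collapse = ", "))
  for (p in c(pattern_i, pattern_j))
    if (!p %in% colnames(bits)) stop("unknown pattern id: ", p)
  allowed <- if (inherits(gap, "gap_spec")) gap$gaps else as.integer(gap)
  L <- length(tokens)
  if (L < 2L) return(0L)
  bi <- bits[tokens, pattern_i]
  bj <- bits[tokens, pattern_j]
  for (q1 in seq_len(L - 1L)) {
    if (!bi[q1]) next
    for (q2 in (q1 + 1L):L) {
      if (bj[q2] && (q2 - q1 - 1L) %in% allowed) return(1L)
    }
  }
  0L
}

# canonical bit position of triple (i, k, j); column-major within each k-slab
spad_bitpos <- function(i, k, j, N) (k - 1L) * N * N + (j - 1L) * N + i

spad_feature_id <- function(pattern_ids, gids, i, k, j) {
  paste(pattern_ids[i], gids[k], pattern_ids[j], sep = "|")
}

#' Build the peptide-by-feature SPAD matrix
#'
#' Evaluates every substructure-pair triple on every peptide. Internally the
#' rows are packed bitsets over the full `N x M x N` triple grid; use
#' [fp_as_sparse()] to obtain a sparse 0/1 matrix restricted to the triples
#' observed at least once, with columns in canonical `(i, k, j)` order named
#' `"<pattern_i>|<gap>|<pattern_j>"`.
#'
#' @param peps [peptide_set()].
#' @param bits residue bit table from [residue_bit_table()].
#' @param gaps list of [gap_spec()], e.g. [default_gap_set()].
#' @param ordered keep pairs directional N-to-C (default). With
#'   `ordered = FALSE` mirror triples are merged: the feature fires if either
#'   orientation occurs.
#' @return A `fingerprint_set` of subclass `spad_fm`.
#' @export
build_feature_matrix <- function(peps, bits, gaps = default_gap_set(),
                                 ordered = TRUE) {
  stopifnot(inherits(peps, "peptide_set"))
  if (nrow(peps) == 0L) stop("empty peptide list")
  codes <- rownames(bits)
  N <- ncol(bits)
  M <- length(gaps)
  n_features <- N * N * M
  NN <- N * N

  gapsets <- lapply(gaps, `[[`, "gaps")
  rows <- vector("list", nrow(peps))
  for (a in seq_len(nrow(peps))) {
    toks <- tokenize_sequence(peps$sequence[a])
    idx <- match(toks, codes)
    if (anyNA(idx))
      stop(sprintf("peptide '%s': unknown residue code(s): %s", peps$id[a],
                   paste(unique(toks[is.na(idx)]), collapse = ", ")))
    B <- bits[idx, , drop = FALSE]
    L <- nrow(B)
    v <- logical(n_features)
    if (L >= 2L) {
      maxg <- L - 2L
      # pair-count matrices per exact gap: Cg[i, j] = number of position
      # pairs (q1 < q2) at gap g with pattern i at q1 and pattern j at q2
      Cg <- lapply(0:maxg, function(g)
        crossprod(B[seq_len(L - 1L - g), , drop = FALSE],
                  B[(2L + g):L, , drop = FALSE]))
      for (k in seq_len(M)) {
        gs <- gapsets[[k]]
        gs <- gs[gs <= maxg]
        if (!length(gs)) next
        S <- if (length(gs) == 1L) Cg[[gs + 1L]] else Reduce(`+`, Cg[gs + 1L])
        if (!ordered) S <- S + t(S)
        v[((k - 1L) * NN + 1L):(k * NN)] <- S > 0
      }
    }
    rows[[a]] <- v
  }

  keys <- NULL # generated lazily via feature_names.spad_fm
  new_fingerprint_set(
    bits = pack_rows(rows, n_features),
    n_features = n_features,
    ids = peps$id,
    labels = peps$label,
    meta = list(type = "spad", N = N, M = M,
                pattern_ids = colnames(bits), gap_ids = gap_ids(gaps),
                gap_max = vapply(gaps, function(g) max(g$gaps), 0L),
                ordered = ordered),
    subclass = "spad_fm")
}

#' @export
feature_names.spad_fm <- function(fs) {
  N <- fs$meta$N; M <- fs$meta$M
  # position = (k-1)*N*N + (j-1)*N + i
  i <- rep.int(seq_len(N), N * M)
  j <- rep.int(rep(seq_len(N), each = N), M)
  k <- rep(seq_len(M), each = N * N)
  spad_feature_id(fs$meta$pattern_ids, fs$meta$gap_ids, i, k, j)
}

# decode bit positions to (i, k, j)
spad_decode <- function(fs, pos) {
  N <- fs$meta$N
  k <- (pos - 1L) %/% (N * N) + 1L
  r <- (pos - 1L) %% (N * N)
  data.frame(i = r %% N + 1L, k = k, j = r %/% N + 1L)
}

#' Rank observed triples by association with activity
#'
#' Computes the phi coefficient between every observed feature column and the
#' activity labels (`active` and `active_reference` versus `non_active`;
#' unlabeled peptides are excluded), together with the spatial span of each
#' triple (its largest allowed gap plus the two carrier residues). Rows are
#' sorted by absolute phi, descending, with ties broken by canonical
#' `(i, k, j)` column order; undefined phi values are reported as `NA` and
#' sorted last.
#'
#' @param fm a `spad_fm` from [build_feature_matrix()].
#' @param labels optional label vector (defaults to the labels stored in
#'   `fm`).
#' @return Data frame: `feature`, `pattern_i`, `gap`, `pattern_j`, `phi`,
#'   `span`, `n_active_on`, `n_inactive_on`.
#' @export
feature_span_report <- function(fm, labels = fm$labels) {
  stopifnot(inherits(fm, "spad_fm"))
  if (length(labels) != length(fm$ids)) stop("label length mismatch")
  pos_rows <- which(labels %in% c("active", "active_reference"))
  neg_rows <- which(labels == "non_active")
  if (!length(pos_rows) && !length(neg_rows))
    stop("no labeled peptides")
  n1 <- length(pos_rows); n0 <- length(neg_rows)
  cnt1 <- fp_col_counts(fm, pos_rows)
  cnt0 <- fp_col_counts(fm, neg_rows)
  observed <- which(cnt1 + cnt0 > 0)

  tp <- cnt1[observed]; fp <- cnt0[observed]
  fn <- n1 - tp; tn <- n0 - fp
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  phi <- ifelse(denom == 0, NA_real_, (tp * tn - fp * fn) / denom)

  dec <- spad_decode(fm, observed)
  span <- fm$meta$gap_max[dec$k] + 2L
  out <- data.frame(
    feature = spad_feature_id(fm$meta$pattern_ids, fm$meta$gap_ids,
                              dec$i, dec$k, dec$j),
    pattern_i = fm$meta$pattern_ids[dec$i],
    gap = fm$meta$gap_ids[dec$k],
    pattern_j = fm$meta$pattern_ids[dec$j],
    phi = phi,
    span = span,
    n_active_on = tp,
    n_inactive_on = fp,
    stringsAsFactors = FALSE)
  # canonical (i, k, j) order as tie-break, |phi| descending, NAs last
  canon <- order(dec$i, dec$k, dec$j)
  out <- out[canon, ]
  out <- out[order(-abs(out$phi), na.last = TRUE), ]
  rownames(out) <- NULL
  out
}
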