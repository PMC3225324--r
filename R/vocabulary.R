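# Vocabulary: the base substructure set Z, derived complements Z*, and the
# combined set X = Z followed by Z*.  A complement z* fires exactly when its
# base z does not (z and z* partition the residue space), so complements are
# never matched structurally -- their bits are the negation of the base bits.

VOCAB_CATEGORIES <- c("atom_count", "substructure", "property")

#' Load a substructure vocabulary
#'
#' The file (YAML) lists base patterns with fields `id`, `category`
#' (`atom_count`, `substructure` or `property`), a `smarts` pattern (or, for
#' `atom_count`, an `atom_class` SMARTS plus integer `threshold`) and an
#' optional `description`. Complements are derived automatically; the
#' combined set is the base set followed by the complements, so its size is
#' twice the base size.
#'
#' @param path YAML file.
#' @return Object of class `vocabulary`.
#' @export
read_vocabulary <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$patterns)) stop("vocabulary file has no 'patterns' list")
  rows <- lapply(spec$patterns, function(p) {
    if (is.null(p$id) || is.null(p$category))
      stop("every pattern needs 'id' and 'category'")
    if (!p$category %in% VOCAB_CATEGORIES)
      stop(sprintf("pattern '%s': unknown category '%s'", p$id, p$category))
    if (identical(p$category, "atom_count")) {
      if (is.null(p$atom_class) || is.null(p$threshold))
        stop(sprintf("atom_count pattern '%s' needs atom_class and threshold",
                     p$id))
      thr <- as.integer(p$threshold)
      if (is.na(thr) || thr < 1L)
        stop(sprintf("pattern '%s': threshold must be >= 1", p$id))
      data.frame(id = p$id, category = p$category, smarts = p$atom_class,
                 threshold = thr,
                 description = p$description %||% "",
                 stringsAsFactors = FALSE)
    } else {
      if (is.null(p$smarts))
        stop(sprintf("pattern '%s' needs a smarts field", p$id))
      data.frame(id = p$id, category = p$category, smarts = p$smarts,
                 threshold = 1L,
                 description = p$description %||% "",
                 stringsAsFactors = FALSE)
    }
  })
  vocabulary(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a vocabulary from a base-pattern data frame
#'
#' @param base data frame with columns `id`, `category`, `smarts`,
#'   `threshold`, `description`.
#' @return Object of class `vocabulary`.
#' @export
vocabulary <- function(base) {
  stopifnot(is.data.frame(base), nrow(base) >= 1L)
  if (anyDuplicated(base$id))
    stop("duplicate pattern id(s): ",
         paste(unique(base$id[duplicated(base$id)]), collapse = ", "))
  # SMARTS validity: OpenBabel raises on malformed patterns
  probe <- ChemmineOB::forEachMol("SMILES", "NCC(=O)O", identity)
  for (r in seq_len(nrow(base))) {
    ok <- tryCatch({
      ChemmineOB::smartsSearch_OB(probe, base$smarts[r], uniqueMatches = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok)
      stop(sprintf("pattern '%s': invalid SMARTS '%s'",
                   base$id[r], base$smarts[r]))
  }
  v <- list(base = base,
            combined = c(base$id, paste0(base$id, "*")))
  class(v) <- "vocabulary"
  v
}

#' The packaged default 49-pattern vocabulary
#' @return A [vocabulary()] with 49 base patterns (combined size 98).
#' @export
default_vocabulary <- function() {
  read_vocabulary(system.file("extdata", "vocabulary_default.yaml",
                              package = "spadkit"))
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("substructure vocabulary: %d base patterns (%s), combined size %d\n",
              nrow(x$base),
              paste(sprintf("%s %d", names(table(x$base$category)),
                            as.integer(table(x$base$category))), collapse = ", "),
              length(x$combined)))
  invisible(x)
}

#' Number of combined patterns (base plus complements)
#' @param v [vocabulary()].
#' @export
vocabulary_size <- function(v) length(v$combined)

#' Compute the residue-by-pattern bit table
#'
#' Each base pattern is matched against every monomer (attachment dummies in
#' place); `atom_count` patterns compare the atom-class match count against
#' their threshold, the others test substructure presence. Complement columns
#' are the exact negation of their base columns.
#'
#' @param lib [residue_library()].
#' @param v [vocabulary()].
#' @return Integer matrix, rows = residue codes, columns = combined pattern
#'   ids (base set followed by complements), entries 0/1.
#' @export
residue_bit_table <- function(lib, v) {
  mols <- lib_mols(lib)
  nb <- nrow(v$base)
  base_bits <- matrix(0L, nrow = length(mols), ncol = nb,
                      dimnames = list(names(mols), v$base$id))
  for (p in seq_len(nb)) {
    counts <- ChemmineOB::smartsSearch_OB(mols, v$base$smarts[p],
                                          uniqueMatches = FALSE)
    base_bits[, p] <- as.integer(counts >= v$base$threshold[p])
  }
  cbind(base_bits, `colnames<-`(1L - base_bits, paste0(v$base$id, "*")))
}

#' Match one residue against one pattern
#'
#' @param lib [residue_library()].
#' @param code residue code.
#' @param v [vocabulary()].
#' @param pattern_id a combined pattern id (a trailing `*` selects the
#'   complement, which returns the negation of its base).
#' @return 0 or 1.
#' @export
match_residue <- function(lib, code, v, pattern_id) {
  if (!pattern_id %in% v$combined) stop("unknown pattern id: ", pattern_id)
  is_comp <- endsWith(pattern_id, "*")
  base_id <- sub("\\*$", "", pattern_id)
  p <- match(base_id, v$base$id)
  mol <- lib_mols(lib)[lib_index(lib, code)]
  cnt <- ChemmineOB::smartsSearch_OB(mol, v$base$smarts[p],
                                     uniqueMatches = FALSE)
  bit <- as.integer(cnt >= v$base$threshold[p])
  if (is_comp) 1L - bit else bit
}

#' Shannon entropy of bit-table columns
#'
#' Entropy (log base 2, non-negative) of the empirical 0/1 distribution of a
#' column: constant columns carry 0 bits, a balanced column carries 1 bit.
#'
#' @param table bit table from [residue_bit_table()], or any 0/1 matrix.
#' @param pattern_id optional column name; if omitted, entropies of all
#'   columns are returned as a named vector.
#' @return Entropy in bits.
#' @export
column_entropy <- function(table, pattern_id = NULL) {
  ent1 <- function(col) {
    p <- mean(col)
    if (p <= 0 || p >= 1) return(0)
    -p * log2(p) - (1 - p) * log2(1 - p)
  }
  if (!is.null(pattern_id)) {
    if (!pattern_id %in% colnames(table))
      stop("unknown pattern id: ", pattern_id)
    ent1(table[, pattern_id])
  } else {
    apply(table, 2L, ent1)
  }
}

#' Screen a vocabulary for low entropy and redundancy
#'
#' Implements the statistical part of the base-set conditions: base patterns
#' whose residue-level column entropy falls below `entropy_min` are dropped
#' (too specific), and for every surviving pair of base columns with Jaccard
#' similarity at least `redundancy_max` the lower-entropy member is dropped
#' (redundant; ties drop the later pattern in vocabulary order). Complements
#' follow their bases. Screening the result again with the same thresholds
#' changes nothing.
#'
#' @param table bit table over the residue library from [residue_bit_table()].
#' @param v [vocabulary()].
#' @param entropy_min minimum column entropy in bits (default 0.08).
#' @param redundancy_max Jaccard similarity at or above which two columns are
#'   considered redundant (default 0.95); must lie in `[0, 1]`.
#' @return List with `vocabulary` (the reduced vocabulary) and `report`
#'   (per-pattern data frame: entropy, status, and what it was dropped for).
#' @export
screen_vocabulary <- function(table, v, entropy_min = 0.08,
                              redundancy_max = 0.95) {
  if (entropy_min < 0) stop("entropy_min must be >= 0")
  if (redundancy_max < 0 || redundancy_max > 1)
    stop("redundancy_max must lie in [0, 1]")
  ids <- v$base$id
  cols <- table[, ids, drop = FALSE]
  ent <- column_entropy(cols)
  alive <- ent >= entropy_min
  dropped_for <- ifelse(alive, "", "low_entropy")

  jaccard <- function(a, b) {
    u <- sum(a | b)
    if (u == 0) 1 else sum(a & b) / u   # two all-zero columns are duplicates
  }
  n <- length(ids)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      if (!alive[i]) next
      for (j in (i + 1L):n) {
        if (!alive[j]) next
        if (jaccard(cols[, i] == 1L, cols[, j] == 1L) >= redundancy_max) {
          # drop the lower-entropy member; tie -> later in vocabulary order
          drop <- if (ent[j] <= ent[i]) j else i
          alive[drop] <- FALSE
          dropped_for[drop] <- sprintf("redundant_with:%s",
                                       ids[if (drop == j) i else j])
          if (drop == i) break
        }
      }
    }
  }
  report <- data.frame(id = ids, entropy = unname(ent),
                       retained = alive, dropped_for = dropped_for,
                       stringsAsFactors = FALSE)
  list(vocabulary = vocabulary(v$base[alive, , drop = FALSE]),
       report = report)
}

#' Phi coefficient between a binary feature and binary activity labels
#'
#' The Matthews/phi correlation of the 2x2 contingency table. Undefined for
#' constant inputs (any zero marginal), in which case `NA` is returned rather
#' than zero.
#'
#' @param bits 0/1 (or logical) feature vector over peptides.
#' @param labels 0/1 (or logical) activity vector of the same length.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
feature_activity_correlation <- function(bits, labels) {
  bits <- as.integer(as.logical(bits))
  labels <- as.integer(as.logical(labels))
  if (length(bits) != length(labels)) stop("length mismatch")
  if (length(bits) < 2L) stop("need at least two observations")
  tp <- sum(bits == 1L & labels == 1L)
  fp <- sum(bits == 1L & labels == 0L)
  fn <- sum(bits == 0L & labels == 1L)
  tn <- sum(bits == 0L & labels == 0L)
  denom <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  if (denom == 0) return(NA_real_)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
}
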