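# Tanimoto similarity screening and enrichment-factor curves.

#' Tanimoto coefficient between two binary vectors
#'
#' `sum(x & y) / sum(x | y)`; the coefficient of two all-zero vectors is
#' defined as 0 so that featureless peptides do not appear maximally similar.
#'
#' @param x,y binary (0/1 or logical) vectors of equal length.
#' @return Coefficient in `[0, 1]`.
#' @export
tanimoto <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  x <- as.logical(x); y <- as.logical(y)
  if (anyNA(x) || anyNA(y)) stop("vectors must be binary")
  u <- sum(x | y)
  if (u == 0L) return(0)
  sum(x & y) / u
}

#' Rank peptides by Tanimoto similarity to active references
#'
#' Every non-reference peptide is scored against the reference set and the
#' screen is sorted by score, descending, with ties kept in input order.
#' References never appear in the ranked list.
#'
#' @param fm a `fingerprint_set` ([build_feature_matrix()] or
#'   [atom_pair_matrix()]).
#' @param references peptide ids used as the query set; defaults to the
#'   peptides labeled `active_reference`.
#' @param aggregate how to combine similarities over multiple references:
#'   `"max"` (default) or `"mean"`.
#' @return Data frame of class `ranked_screen`: `id`, `score`, `label`,
#'   `rank`.
#' @export
rank_by_reference <- function(fm, references = NULL,
                              aggregate = c("max", "mean")) {
  stopifnot(inherits(fm, "fingerprint_set"))
  aggregate <- match.arg(aggregate)
  if (is.null(references)) references <- fm$ids[fm$labels == "active_reference"]
  if (!length(references)) stop("empty reference set")
  ridx <- match(references, fm$ids)
  if (anyNA(ridx))
    stop("reference id(s) not present: ",
         paste(references[is.na(ridx)], collapse = ", "))
  cidx <- setdiff(seq_along(fm$ids), ridx)
  if (!length(cidx)) stop("no candidate peptides outside the reference set")

  sz <- fp_popcounts(fm)
  scores <- numeric(length(cidx))
  for (a in seq_along(cidx)) {
    tc <- numeric(length(ridx))
    for (r in seq_along(ridx)) {
      inter <- fp_intersection(fm, cidx[a], ridx[r])
      un <- sz[cidx[a]] + sz[ridx[r]] - inter
      tc[r] <- if (un == 0L) 0 else inter / un
    }
    scores[a] <- if (aggregate == "max") max(tc) else mean(tc)
  }
  ord <- order(-scores)  # stable: ties keep input order
  out <- data.frame(id = fm$ids[cidx][ord], score = scores[ord],
                    label = fm$labels[cidx][ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "references") <- references
  class(out) <- c("ranked_screen", "data.frame")
  out
}

#' Enrichment-factor curve of a ranked screen
#'
#' Sweeping the similarity threshold over the observed scores, each point is
#' (fraction of all ranked peptides with score at or above the threshold,
#' fraction of active peptides with score at or above the threshold). The
#' curve starts at (0, 0), ends at (1, 1), and its area under the curve is
#' computed by the trapezoid rule; random ordering gives the diagonal and an
#' area of one half.
#'
#' @param rs a `ranked_screen` from [rank_by_reference()].
#' @return Object of class `enrichment_curve`: list with `points` (data
#'   frame `x`, `y`, `threshold`), `auc`, `n_active`, `n_total`.
#' @export
enrichment_curve <- function(rs) {
  stopifnot(inherits(rs, "ranked_screen"))
  is_active <- rs$label == "active"
  n_active <- sum(is_active)
  n_total <- nrow(rs)
  if (n_active == 0L) stop("ranked screen contains no active peptides")
  if (!any(rs$label == "non_active"))
    stop("ranked screen contains no non-active peptides")

  thr <- sort(unique(rs$score), decreasing = TRUE)
  # rs is sorted by score descending; cumulative counts at each threshold
  x <- vapply(thr, function(a) sum(rs$score >= a), 0L) / n_total
  y <- vapply(thr, function(a) sum(is_active & rs$score >= a), 0L) / n_active
  pts <- data.frame(x = c(0, x), y = c(0, y), threshold = c(Inf, thr))
  auc <- sum(diff(pts$x) * (utils::head(pts$y, -1) + utils::tail(pts$y, -1)) / 2)
  structure(list(points = pts, auc = auc, n_active = n_active,
                 n_total = n_total, ids = sort(rs$id)),
            class = "enrichment_curve")
}

#' @export
print.enrichment_curve <- function(x, ...) {
  cat(sprintf("enrichment curve: %d actives / %d ranked peptides, AUC %.3f\n",
              x$n_active, x$n_total, x$auc))
  invisible(x)
}

# curve value at a screened fraction, by linear interpolation
curve_y_at <- function(curve, x) {
  stats::approx(curve$points$x, curve$points$y, xout = x, ties = max,
                yleft = 0, yright = 1)$y
}

#' Compare enrichment curves of several descriptors
#'
#' @param curves named list of [enrichment_curve()] objects computed on the
#'   same peptide set.
#' @param at screened fractions at which early enrichment is reported.
#' @return Data frame: descriptor name, AUC and recall at each fraction.
#' @export
compare_descriptors <- function(curves, at = c(0.05, 0.10, 0.25)) {
  if (length(curves) < 2L) stop("need at least two curves to compare")
  if (is.null(names(curves)) || any(!nzchar(names(curves))))
    stop("curves must be named")
  idsets <- lapply(curves, `[[`, "ids")
  if (!all(vapply(idsets[-1], identical, TRUE, idsets[[1]])))
    stop("curves were computed on different peptide sets")
  rows <- lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    ys <- curve_y_at(cv, at)
    cbind(data.frame(descriptor = nm, auc = cv$auc, stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(ys, sprintf("y_at_%g", at)))))
  })
  do.call(rbind, rows)
}

#' Split actives into references and screened actives
#'
#' Relabels a seeded random subset of the `active` peptides as
#' `active_reference` (the query set for similarity ranking).
#'
#' @param peps [peptide_set()].
#' @param fraction fraction of actives to relabel (default 0.1; at least one).
#' @param seed integer seed.
#' @return The peptide set with updated labels.
#' @export
assign_references <- function(peps, fraction = 0.1, seed = 1L) {
  stopifnot(inherits(peps, "peptide_set"), fraction > 0, fraction < 1)
  act <- which(peps$label == "active")
  if (!length(act)) stop("no active peptides to draw references from")
  n_ref <- max(1L, round(fraction * length(act)))
  ref <- withr::with_seed(seed, sample(act, n_ref))
  peps$label[ref] <- "active_reference"
  peps
}
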