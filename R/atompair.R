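# Atom-pair baseline descriptor over the assembled peptide graph: one bit
# per (type_a, type_b, topological distance) with the distance measured in
# bonds along the shortest heavy-atom path. Key-atom typing is a simple,
# replaceable table: element, aromaticity flag, and donor/acceptor flags.

#' Default key-atom typing
#'
#' @param atoms atom data frame from [assemble_peptide_graph()].
#' @return Character vector of atom type labels.
#' @export
default_atom_typer <- function(atoms) {
  paste0(atoms$element,
         ifelse(atoms$aromatic, ".ar", ""),
         ifelse(atoms$donor, ".d", ""),
         ifelse(atoms$acceptor, ".a", ""))
}

#' Atom-pair fingerprint of one peptide
#'
#' Assembles the peptide graph, types every heavy atom and records each
#' unordered atom-type pair together with its shortest-path length in bonds,
#' keeping lengths within `range` (default 3 to 7).
#'
#' @param tokens residue codes (N-to-C) or a single sequence string.
#' @param library [residue_library()].
#' @param range inclusive path-length range in bonds.
#' @param typer function mapping the atom data frame to type labels.
#' @return Sorted character vector of distinct feature keys
#'   `"<type_a>|<type_b>|<length>"` with `type_a <= type_b`.
#' @export
atom_pair_fingerprint <- function(tokens, library, range = c(3L, 7L),
                                  typer = default_atom_typer) {
  g <- assemble_peptide_graph(tokens, library)
  types <- typer(g$atoms)
  ig <- igraph::graph_from_edgelist(g$bonds, directed = FALSE)
  d <- igraph::distances(ig)
  sel <- which(upper.tri(d) & d >= range[1L] & d <= range[2L], arr.ind = TRUE)
  if (!nrow(sel)) return(character(0))
  ta <- types[sel[, 1L]]; tb <- types[sel[, 2L]]
  lo <- pmin(ta, tb); hi <- pmax(ta, tb)
  sort(unique(paste(lo, hi, d[sel], sep = "|")))
}

#' Atom-pair fingerprint matrix for a peptide set
#'
#' @param peps [peptide_set()].
#' @param library [residue_library()].
#' @inheritParams atom_pair_fingerprint
#' @return A `fingerprint_set` of subclass `aph_fm`; feature columns are the
#'   union of keys observed across the set, sorted.
#' @export
atom_pair_matrix <- function(peps, library, range = c(3L, 7L),
                             typer = default_atom_typer) {
  stopifnot(inherits(peps, "peptide_set"))
  if (nrow(peps) == 0L) stop("empty peptide list")
  keysets <- lapply(peps$sequence, atom_pair_fingerprint,
                    library = library, range = range, typer = typer)
  keys <- sort(unique(unlist(keysets)))
  rows <- lapply(keysets, function(ks) keys %in% ks)
  new_fingerprint_set(
    bits = pack_rows(rows, length(keys)),
    n_features = length(keys),
    ids = peps$id,
    labels = peps$label,
    meta = list(type = "atompair", keys = keys, range = range),
    subclass = "aph_fm")
}
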