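# Independent oracles, written separately from the implementation paths they
# check.

# Brute-force substructure-pair evaluation: explicit double loop over residue
# positions, no matrix algebra, no packing.
oracle_spad <- function(tokens, bits, pattern_i, gaps, pattern_j) {
  L <- length(tokens)
  if (L < 2) return(0L)
  for (q1 in 1:(L - 1)) {
    for (q2 in (q1 + 1):L) {
      if (bits[tokens[q1], pattern_i] == 1L &&
          bits[tokens[q2], pattern_j] == 1L &&
          (q2 - q1 - 1) %in% gaps) return(1L)
    }
  }
  0L
}

# All triples fired by one peptide, as feature-id strings, by brute force.
oracle_spad_all <- function(tokens, bits, gaps) {
  pats <- colnames(bits)
  fired <- character(0)
  L <- length(tokens)
  if (L >= 2) {
    for (q1 in 1:(L - 1)) {
      pi_on <- pats[bits[tokens[q1], ] == 1L]
      for (q2 in (q1 + 1):L) {
        pj_on <- pats[bits[tokens[q2], ] == 1L]
        g <- q2 - q1 - 1
        for (k in seq_along(gaps)) {
          if (g %in% gaps[[k]]$gaps) {
            fired <- c(fired, as.vector(outer(
              pi_on, pj_on, function(a, b)
                paste(a, gaps[[k]]$id, b, sep = "|"))))
          }
        }
      }
    }
  }
  sort(unique(fired))
}

# Set-based Tanimoto on index sets.
oracle_tanimoto_sets <- function(ia, ib) {
  u <- length(union(ia, ib))
  if (u == 0) 0 else length(intersect(ia, ib)) / u
}

# Floyd-Warshall all-pairs shortest paths on a bond list (independent of
# igraph's BFS).
oracle_shortest_paths <- function(n_atoms, bonds) {
  d <- matrix(Inf, n_atoms, n_atoms)
  diag(d) <- 0
  for (r in seq_len(nrow(bonds))) {
    d[bonds[r, 1], bonds[r, 2]] <- 1
    d[bonds[r, 2], bonds[r, 1]] <- 1
  }
  for (k in seq_len(n_atoms))
    for (i in seq_len(n_atoms))
      for (j in seq_len(n_atoms))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# RDKit (through the system python) as an independent SMARTS matcher.
# Returns an integer matrix of match counts, molecules x patterns.
rdkit_match_counts <- function(smiles, smarts) {
  script <- paste(
    "import sys, json",
    "from rdkit import Chem",
    "data = json.load(sys.stdin)",
    "out = []",
    "for smi in data['smiles']:",
    "    mol = Chem.MolFromSmiles(smi)",
    "    row = []",
    "    for sm in data['smarts']:",
    "        patt = Chem.MolFromSmarts(sm)",
    "        row.append(len(mol.GetSubstructMatches(patt, uniquify=False)))",
    "    out.append(row)",
    "print(json.dumps(out))",
    sep = "\n")
  payload <- jsonlite::toJSON(list(smiles = smiles, smarts = smarts))
  res <- system2("python", c("-c", shQuote(script)), input = as.character(payload),
                 stdout = TRUE, stderr = FALSE)
  m <- do.call(rbind, lapply(jsonlite::fromJSON(res, simplifyVector = FALSE),
                             function(r) as.integer(unlist(r))))
  rownames(m) <- names(smiles)
  m
}
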