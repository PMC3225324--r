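#' @importFrom utils read.csv write.table
NULL

# Monomer SMILES convention: the string starts with the N-terminal attachment
# dummy [*:1] and ends with the C-terminal attachment dummy [*:2], with the
# backbone written through (e.g. glycine "[*:1]NCC(=O)[*:2]").  Under this
# convention peptide assembly is exact string concatenation: dropping [*:1]
# leaves a free amine, replacing the final [*:2] by "O" leaves a free acid,
# and joining monomer bodies end-to-end forms the amide bond.
N_ATTACH <- "[*:1]"
C_ATTACH <- "[*:2]"

PEPTIDE_LABELS <- c("active", "active_reference", "non_active", "unlabeled")

#' Create a residue library from a data frame
#'
#' A residue library holds peptide monomers: a short residue code, a free-text
#' name and a monomer SMILES in which the two backbone attachment points are
#' marked by the dummy atoms `[*:1]` (N-terminal side) and `[*:2]`
#' (C-terminal side).
#'
#' @param df data frame with columns `code`, `name`, `smiles`.
#' @return An object of class `residue_library`.
#' @seealso [read_residue_library()] to load one from CSV.
#' @export
residue_library <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("code", "name", "smiles")
  if (!all(need %in% names(df)))
    stop("residue library needs columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df[] <- lapply(df, as.character)
  if (nrow(df) == 0L) stop("residue library is empty")
  dup <- df$code[duplicated(df$code)]
  if (length(dup))
    stop("duplicate residue code(s): ", paste(unique(dup), collapse = ", "))
  for (r in seq_len(nrow(df))) {
    err <- validate_monomer_smiles(df$smiles[r])
    if (!is.null(err))
      stop(sprintf("residue '%s' (row %d): %s", df$code[r], r, err))
  }
  lib <- list(table = df, cache = new.env(parent = emptyenv()))
  class(lib) <- "residue_library"
  lib
}

# Syntactic validation; OpenBabel itself is permissive, so balance and
# attachment-marker checks are done here and the parse is checked afterwards.
validate_monomer_smiles <- function(s) {
  if (!nzchar(s)) return("empty SMILES")
  if (grepl("\\.", s, fixed = FALSE)) return("disconnected SMILES (contains '.')")
  n1 <- length(gregexpr(N_ATTACH, s, fixed = TRUE)[[1]])
  if (!grepl(N_ATTACH, s, fixed = TRUE)) n1 <- 0L
  n2 <- length(gregexpr(C_ATTACH, s, fixed = TRUE)[[1]])
  if (!grepl(C_ATTACH, s, fixed = TRUE)) n2 <- 0L
  if (n1 != 1L || n2 != 1L)
    return("monomer must carry exactly one [*:1] and one [*:2] attachment marker")
  if (!startsWith(s, N_ATTACH) || !endsWith(s, C_ATTACH))
    return("monomer SMILES must start with [*:1] and end with [*:2]")
  chars <- strsplit(s, "")[[1]]
  if (sum(chars == "(") != sum(chars == ")")) return("unbalanced parentheses")
  if (sum(chars == "[") != sum(chars == "]")) return("unbalanced brackets")
  mol <- tryCatch(
    ChemmineOB::forEachMol("SMILES", s, identity),
    error = function(e) NULL)
  if (is.null(mol) || length(mol) != 1L) return("SMILES failed to parse")
  NULL
}

#' Read a residue library from CSV
#'
#' @param path CSV file with header `code,name,smiles`.
#' @return A [residue_library()].
#' @export
read_residue_library <- function(path) {
  # '#' only marks full comment lines: SMILES legitimately contain '#'
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  df <- read.csv(text = lines, stringsAsFactors = FALSE,
                 colClasses = "character")
  residue_library(df)
}

#' The packaged 20 natural amino-acid monomers
#' @return A [residue_library()] of the 20 proteinogenic residues.
#' @export
natural_residues <- function() {
  read_residue_library(system.file("extdata", "residues_natural20.csv",
                                   package = "spadkit"))
}

#' @export
print.residue_library <- function(x, ...) {
  cat(sprintf("residue library: %d monomers (%s%s)\n", nrow(x$table),
              paste(utils::head(x$table$code, 8), collapse = " "),
              if (nrow(x$table) > 8) " ..." else ""))
  invisible(x)
}

#' @export
length.residue_library <- function(x) nrow(x$table)

#' Residue codes of a library, in order
#' @param lib [residue_library()].
#' @return Character vector of codes.
#' @export
residue_codes <- function(lib) lib$table$code

lib_index <- function(lib, codes) {
  idx <- match(codes, lib$table$code)
  if (anyNA(idx))
    stop("unknown residue code(s): ",
         paste(unique(codes[is.na(idx)]), collapse = ", "))
  idx
}

# Cached OpenBabel molecule handles, one per residue, parsed from the monomer
# SMILES with the attachment dummies left in place.
lib_mols <- function(lib) {
  if (is.null(lib$cache$mols)) {
    txt <- paste(lib$table$smiles, collapse = "\n")
    mols <- ChemmineOB::forEachMol("SMILES", txt, identity)
    if (length(mols) != nrow(lib$table))
      stop("internal: monomer SMILES parse count mismatch")
    names(mols) <- lib$table$code
    lib$cache$mols <- mols
  }
  lib$cache$mols
}

#' Tokenize an extended peptide sequence
#'
#' Sequences are written N-to-C with one-letter codes; multi-letter codes for
#' non-natural residues are enclosed in square brackets, e.g. `"AC[Cha]DE"`.
#'
#' @param s sequence string.
#' @return Character vector of residue codes in N-to-C order.
#' @export
tokenize_sequence <- function(s) {
  chars <- strsplit(s, "")[[1]]
  out <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) stop("unbalanced bracket in sequence: ", s)
      if (j == i + 1L) stop("empty residue code in sequence: ", s)
      out <- c(out, paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L
    } else if (ch == "]") {
      stop("unbalanced bracket in sequence: ", s)
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  if (!length(out)) stop("empty sequence")
  out
}

format_sequence <- function(tokens) {
  paste(ifelse(nchar(tokens) > 1L, paste0("[", tokens, "]"), tokens),
        collapse = "")
}

#' Construct a peptide set
#'
#' @param id peptide identifiers (unique).
#' @param sequence extended sequence strings (see [tokenize_sequence()]).
#' @param label one of `"active"`, `"active_reference"`, `"non_active"`,
#'   `"unlabeled"`; recycled if length 1.
#' @param library optional [residue_library()]; if given, every residue code
#'   is checked against it.
#' @return A data frame of class `peptide_set` with columns
#'   `id`, `sequence`, `label`.
#' @export
peptide_set <- function(id, sequence, label = "unlabeled", library = NULL) {
  id <- as.character(id); sequence <- as.character(sequence)
  label <- rep_len(as.character(label), length(id))
  if (length(sequence) != length(id)) stop("id/sequence length mismatch")
  if (anyDuplicated(id)) stop("duplicate peptide ids")
  bad <- setdiff(unique(label), PEPTIDE_LABELS)
  if (length(bad))
    stop("invalid label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(PEPTIDE_LABELS, collapse = "/"), ")")
  for (r in seq_along(id)) {
    toks <- tryCatch(tokenize_sequence(sequence[r]),
                     error = function(e) stop(sprintf(
                       "peptide '%s': %s", id[r], conditionMessage(e))))
    if (!is.null(library)) {
      unknown <- setdiff(toks, residue_codes(library))
      if (length(unknown))
        stop(sprintf("peptide '%s': unknown residue code(s): %s",
                     id[r], paste(unknown, collapse = ", ")))
    }
  }
  out <- data.frame(id = id, sequence = sequence, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("peptide_set", "data.frame")
  out
}

#' Read peptides from tab-separated text
#'
#' One record per line: `id<TAB>sequence[<TAB>label]`. Lines starting with
#' `#` are ignored. Missing labels default to `"unlabeled"`.
#'
#' @param path file path.
#' @param library [residue_library()] used to validate residue codes.
#' @return A [peptide_set()].
#' @export
read_peptides <- function(path, library) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no peptide records in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L | nf > 3L))
    stop("malformed peptide record(s) at line(s): ",
         paste(which(nf < 2L | nf > 3L), collapse = ", "))
  peptide_set(id = vapply(parts, `[[`, "", 1L),
              sequence = vapply(parts, `[[`, "", 2L),
              label = vapply(parts, function(p)
                if (length(p) >= 3L) p[[3L]] else "unlabeled", ""),
              library = library)
}

#' Write peptides to tab-separated text
#'
#' @param peps [peptide_set()].
#' @param path output file.
#' @param header optional provenance header lines (written with `#` prefix).
#' @export
write_peptides <- function(peps, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(sprintf("%s\t%s\t%s", peps$id, peps$sequence, peps$label), con)
  invisible(path)
}

#' Assemble the SMILES of a whole peptide
#'
#' Monomers are joined N-to-C by amide bonds at the attachment markers;
#' the N-terminus is left as a free amine and the C-terminus is capped as a
#' free carboxylic acid. No protonation states are assigned.
#'
#' @param tokens residue codes (N-to-C) or a single sequence string.
#' @param library [residue_library()].
#' @return A SMILES string.
#' @export
peptide_smiles <- function(tokens, library) {
  if (length(tokens) == 1L && !(tokens %in% residue_codes(library)))
    tokens <- tokenize_sequence(tokens)
  idx <- lib_index(library, tokens)
  bodies <- sub(C_ATTACH, "", sub(N_ATTACH, "", library$table$smiles[idx],
                                  fixed = TRUE), fixed = TRUE)
  paste0(paste(bodies, collapse = ""), "O")
}

# --- per-residue molecular graphs -------------------------------------------

# Parse the monomer (dummies in place, explicit H) into a small graph record
# via OpenBabel MOL2. Atom order in MOL2 follows the input SMILES, so the
# first dummy is the N-side attachment and the second the C-side.
monomer_graph <- function(lib, code) {
  key <- paste0("g_", code)
  g <- lib$cache[[key]]
  if (!is.null(g)) return(g)
  smi <- lib$table$smiles[lib_index(lib, code)]
  m2 <- ChemmineOB::convertFormat("SMI", "MOL2", smi,
                                  options = data.frame(names = "h", args = ""))
  g <- parse_mol2_graph(m2)
  lib$cache[[key]] <- g
  g
}

parse_mol2_graph <- function(mol2_text) {
  lines <- strsplit(mol2_text, "\n", fixed = TRUE)[[1]]
  a0 <- which(lines == "@<TRIPOS>ATOM")
  b0 <- which(lines == "@<TRIPOS>BOND")
  if (!length(a0) || !length(b0)) stop("internal: malformed MOL2")
  sec_end <- function(start) {
    nxt <- which(startsWith(lines, "@<TRIPOS>") & seq_along(lines) > start)
    if (length(nxt)) min(nxt) - 1L else length(lines)
  }
  atom_lines <- lines[(a0 + 1L):sec_end(a0)]
  bond_lines <- lines[(b0 + 1L):sec_end(b0)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
  af <- strsplit(trimws(atom_lines), "[[:space:]]+")
  types <- vapply(af, `[[`, "", 6L)
  element <- sub("\\..*$", "", types)
  bf <- strsplit(trimws(bond_lines), "[[:space:]]+")
  bonds <- cbind(as.integer(vapply(bf, `[[`, "", 2L)),
                 as.integer(vapply(bf, `[[`, "", 3L)))

  is_h <- element == "H"
  is_du <- element %in% c("Du", "*")
  nH <- tabulate(c(bonds[is_h[bonds[, 2L]], 1L],
                   bonds[is_h[bonds[, 1L]], 2L]), nbins = length(element))

  keep <- !is_h & !is_du
  dummies <- which(is_du)
  if (length(dummies) != 2L) stop("internal: expected two attachment dummies")
  neighbor_of <- function(d) {
    nb <- c(bonds[bonds[, 1L] == d, 2L], bonds[bonds[, 2L] == d, 1L])
    nb <- nb[keep[nb]]
    if (length(nb) != 1L) stop("internal: dummy atom valence != 1")
    nb
  }
  n_attach_full <- neighbor_of(dummies[1L])  # first dummy written = [*:1]
  c_attach_full <- neighbor_of(dummies[2L])

  newidx <- cumsum(keep)
  heavy_bonds <- bonds[keep[bonds[, 1L]] & keep[bonds[, 2L]], , drop = FALSE]
  heavy_bonds <- cbind(newidx[heavy_bonds[, 1L]], newidx[heavy_bonds[, 2L]])

  el <- element[keep]
  arom <- grepl("\\.ar$", types[keep])
  hh <- nH[keep]
  list(element = el,
       aromatic = arom,
       donor = el %in% c("N", "O") & hh > 0L,
       acceptor = el %in% c("N", "O"),
       bonds = heavy_bonds,
       n_attach = newidx[n_attach_full],
       c_attach = newidx[c_attach_full])
}

#' Assemble the molecular graph of a peptide
#'
#' Joins the heavy-atom graphs of the monomers N-to-C with amide bonds at the
#' marked attachment points and caps the termini (free amine, free acid; the
#' C-terminal hydroxyl oxygen is added as an extra atom). Used by the
#' atom-pair baseline descriptor.
#'
#' @param tokens residue codes (N-to-C) or a single sequence string.
#' @param library [residue_library()].
#' @return List with `atoms` (data frame: `element`, `aromatic`, `donor`,
#'   `acceptor`, `residue`) and `bonds` (two-column integer matrix).
#' @export
assemble_peptide_graph <- function(tokens, library) {
  if (length(tokens) == 1L && !(tokens %in% residue_codes(library)))
    tokens <- tokenize_sequence(tokens)
  stopifnot(length(tokens) >= 1L)
  graphs <- lapply(tokens, function(cc) monomer_graph(library, cc))
  sizes <- vapply(graphs, function(g) length(g$element), 0L)
  offs <- cumsum(c(0L, sizes[-length(sizes)]))

  atoms <- data.frame(
    element = unlist(lapply(graphs, `[[`, "element")),
    aromatic = unlist(lapply(graphs, `[[`, "aromatic")),
    donor = unlist(lapply(graphs, `[[`, "donor")),
    acceptor = unlist(lapply(graphs, `[[`, "acceptor")),
    residue = rep(seq_along(tokens), sizes),
    stringsAsFactors = FALSE)
  bonds <- do.call(rbind, lapply(seq_along(graphs), function(r)
    graphs[[r]]$bonds + offs[r]))

  # amide bonds between consecutive residues
  if (length(tokens) > 1L) {
    amide <- cbind(
      vapply(seq_len(length(tokens) - 1L), function(r)
        graphs[[r]]$c_attach + offs[r], 0L),
      vapply(seq_len(length(tokens) - 1L), function(r)
        graphs[[r + 1L]]$n_attach + offs[r + 1L], 0L))
    bonds <- rbind(bonds, amide)
  }
  # C-terminal hydroxyl oxygen of the free acid
  last <- length(tokens)
  oxt <- nrow(atoms) + 1L
  atoms <- rbind(atoms, data.frame(element = "O", aromatic = FALSE,
                                   donor = TRUE, acceptor = TRUE,
                                   residue = last, stringsAsFactors = FALSE))
  bonds <- rbind(bonds, cbind(graphs[[last]]$c_attach + offs[last], oxt))
  list(atoms = atoms, bonds = bonds)
}
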