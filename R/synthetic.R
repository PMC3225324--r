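# Synthetic benchmark generator: a residue universe of the 20 natural
# monomers plus procedurally decorated side-chain variants, and labeled
# peptide datasets in which actives carry a planted two-point motif
# (pattern, gap, pattern) and negatives are random sequences.

#' Generator configuration
#'
#' Defaults mirror the C5a-inhibitor screen layout (116 actives, 451
#' negatives, a 450-residue universe) with peptide lengths of 8 to 15
#' residues. The default planted motif pairs a guanidine group with a fused
#' aromatic bicycle three residues downstream -- the cationic-anchor plus
#' bulky-aromatic two-point pharmacophore typical of C5a-receptor antagonist
#' peptides (Arg/Trp-like); both patterns are rare in the residue universe,
#' which is what makes the motif discriminative.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_residues size of the residue universe (>= 20; the first 20 are
#'   the natural monomers).
#' @param n_active,n_non_active dataset layout.
#' @param length_range inclusive peptide length range in residues.
#' @param planted_motif list with `pattern_a`, `gap`, `pattern_b`: combined
#'   vocabulary pattern ids and the exact number of residues between the two
#'   carriers.
#' @param motif_penetrance probability that an active carries the motif.
#' @param decoy_rate probability that a negative carries it as well.
#' @param negative_mode `"random"` (default): negatives are uniform random
#'   sequences. `"composition_matched"`: each negative additionally carries
#'   one residue matching each motif pattern, placed at a random gap
#'   different from the planted one -- negatives then share the actives'
#'   chemistry and only the spatial relationship separates the classes,
#'   emulating screens whose negatives are inactive analogues rather than
#'   random arrays.
#' @param reference_fraction fraction of actives relabeled
#'   `active_reference` (0 disables).
#' @param max_gap largest gap of the descriptor's default gap set.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_residues = 450L,
                             n_active = 116L,
                             n_non_active = 451L,
                             length_range = c(8L, 15L),
                             planted_motif = list(pattern_a = "s_guanidinium",
                                                  gap = 3L,
                                                  pattern_b = "s_fused_arom"),
                             motif_penetrance = 1.0,
                             decoy_rate = 0.0,
                             negative_mode = c("random", "composition_matched"),
                             reference_fraction = 0.1,
                             max_gap = 8L) {
  negative_mode <- match.arg(negative_mode)
  stopifnot(n_residues >= 1L, n_active >= 1L, n_non_active >= 1L,
            length(length_range) == 2L, length_range[1L] >= 2L,
            length_range[1L] <= length_range[2L],
            motif_penetrance >= 0, motif_penetrance <= 1,
            decoy_rate >= 0, decoy_rate <= 1,
            reference_fraction >= 0, reference_fraction < 1)
  if (planted_motif$gap < 0L || planted_motif$gap > max_gap)
    stop("planted motif gap must lie in [0, max_gap]")
  if (planted_motif$gap > length_range[2L] - 2L)
    stop("planted motif gap does not fit the maximum peptide length")
  cfg <- list(seed = as.integer(seed), n_residues = as.integer(n_residues),
              n_active = as.integer(n_active),
              n_non_active = as.integer(n_non_active),
              length_range = as.integer(length_range),
              planted_motif = planted_motif,
              motif_penetrance = motif_penetrance,
              decoy_rate = decoy_rate,
              negative_mode = negative_mode,
              reference_fraction = reference_fraction,
              max_gap = as.integer(max_gap))
  class(cfg) <- "generator_config"
  cfg
}

# Side-chain decoration grammar.  A candidate monomer is
# [*:1]N[CH](<side>)C(=O)[*:2] with <side> = chain + terminal, where the
# chain is a short aliphatic linker with occasional ether/amine/thioether
# heteroatoms and the terminal is a polar group, halogen or ring system.
# Every fragment is a valid SMILES branch, so candidates always parse.
SIDE_TERMINALS <- c("", "O", "N", "S", "F", "Cl", "C(F)(F)F", "C#N",
                    "C(=O)O", "C(=O)N", "NC(=N)N", "OC", "SC",
                    "c1ccccc1", "c1ccc(F)cc1", "c1ccc(Cl)cc1",
                    "c1ccc(O)cc1", "c1ccc(C)cc1", "c1ccc(OC)cc1",
                    "c1ccncc1", "c1cccs1", "c1ccco1", "c1cc[nH]c1",
                    "c1ccc2ccccc2c1", "c1cnc[nH]1", "C1CCCCC1", "C1CCCC1")
HALOGEN_TERMINALS <- c("F", "Cl", "C(F)(F)F", "C#N")

sample_side_chain <- function() {
  n_chain <- sample(0:4, 1L, prob = c(0.15, 0.3, 0.25, 0.2, 0.1))
  units <- character(n_chain)
  prev_het <- TRUE  # first unit attaches to the alpha carbon; keep it carbon
  for (u in seq_len(n_chain)) {
    units[u] <- if (prev_het) "C"
                else sample(c("C", "O", "N", "S"), 1L,
                            prob = c(0.82, 0.07, 0.06, 0.05))
    prev_het <- units[u] != "C"
  }
  term <- sample(SIDE_TERMINALS, 1L)
  # no halogen/nitrile directly on a heteroatom
  if (prev_het && term %in% HALOGEN_TERMINALS) term <- "C"
  side <- paste0(paste(units, collapse = ""), term)
  if (!nzchar(side)) "C" else side
}

#' Generate a residue library
#'
#' The first 20 residues are the packaged natural monomers; the remainder are
#' seed-deterministic decorated variants (halogenation, heteroatom chains,
#' ring additions on the side chain), unique up to canonical SMILES.
#'
#' @param cfg [generator_config()].
#' @return A [residue_library()] of `cfg$n_residues` monomers.
#' @export
generate_residue_library <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_residues < 20L)
    stop("n_residues must be at least 20 (the natural monomers)")
  nat <- natural_residues()
  if (cfg$n_residues == 20L) return(nat)
  n_extra <- cfg$n_residues - 20L

  canon <- function(smi) ChemmineOB::convertFormat("SMI", "CAN", smi)
  seen <- vapply(nat$table$smiles, canon, "")
  extra <- character(0)
  withr::with_seed(cfg$seed, {
    attempts <- 0L
    while (length(extra) < n_extra) {
      attempts <- attempts + 1L
      if (attempts > 200L * n_extra)
        stop("decoration grammar exhausted before reaching n_residues")
      smi <- sprintf("[*:1]N[CH](%s)C(=O)[*:2]", sample_side_chain())
      key <- tryCatch(canon(smi), error = function(e) NA_character_)
      if (is.na(key) || !nzchar(key) || key %in% seen) next
      seen <- c(seen, key)
      extra <- c(extra, smi)
    }
  })
  df <- rbind(nat$table,
              data.frame(code = sprintf("X%03d", seq_len(n_extra)),
                         name = sprintf("synthetic residue X%03d",
                                        seq_len(n_extra)),
                         smiles = extra, stringsAsFactors = FALSE))
  residue_library(df)
}

#' Residue codes matching a vocabulary pattern
#'
#' @param lib [residue_library()].
#' @param v [vocabulary()].
#' @param pattern_id combined pattern id (trailing `*` for a complement).
#' @return Character vector of matching residue codes.
#' @export
residues_matching <- function(lib, v, pattern_id) {
  is_comp <- endsWith(pattern_id, "*")
  base_id <- sub("\\*$", "", pattern_id)
  p <- match(base_id, v$base$id)
  if (is.na(p)) stop("unknown pattern id: ", pattern_id)
  counts <- ChemmineOB::smartsSearch_OB(lib_mols(lib), v$base$smarts[p],
                                        uniqueMatches = FALSE)
  hit <- counts >= v$base$threshold[p]
  residue_codes(lib)[if (is_comp) !hit else hit]
}

#' Generate a labeled peptide dataset
#'
#' Actives are uniform random sequences into which, with probability
#' `motif_penetrance`, one residue matching `pattern_a` and one matching
#' `pattern_b` are placed exactly `gap` residues apart at a random feasible
#' position; negatives are uniform random sequences (optionally planted at
#' `decoy_rate`). A `reference_fraction` of the actives is relabeled
#' `active_reference`.
#'
#' @param cfg [generator_config()].
#' @param lib [residue_library()], e.g. from [generate_residue_library()].
#' @param v [vocabulary()] the planted motif patterns refer to.
#' @param seed dataset seed; defaults to `cfg$seed` and can be varied to
#'   draw replicate datasets over a fixed residue universe.
#' @return A [peptide_set()].
#' @export
generate_dataset <- function(cfg, lib, v, seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"),
            inherits(lib, "residue_library"), inherits(v, "vocabulary"))
  codes <- residue_codes(lib)
  pm <- cfg$planted_motif
  match_a <- residues_matching(lib, v, pm$pattern_a)
  match_b <- residues_matching(lib, v, pm$pattern_b)
  if (!length(match_a) || !length(match_b))
    stop(sprintf("planted motif infeasible: no residues match %s",
                 if (!length(match_a)) pm$pattern_a else pm$pattern_b))
  g <- pm$gap

  withr::with_seed(seed, {
    draw <- function(n, plant_prob, match_gap = TRUE) {
      lapply(seq_len(n), function(dummy) {
        L <- sample(cfg$length_range[1L]:cfg$length_range[2L], 1L)
        toks <- sample(codes, L, replace = TRUE)
        if (stats::runif(1L) < plant_prob && L >= g + 2L) {
          gap <- if (match_gap) g else {
            wrong <- setdiff(0:(L - 2L), g)
            wrong[sample.int(length(wrong), 1L)]
          }
          q1 <- sample.int(L - gap - 1L, 1L)
          toks[q1] <- sample(match_a, 1L)
          toks[q1 + gap + 1L] <- sample(match_b, 1L)
        }
        toks
      })
    }
    act <- draw(cfg$n_active, cfg$motif_penetrance)
    neg <- if (identical(cfg$negative_mode, "composition_matched"))
      draw(cfg$n_non_active, 1.0, match_gap = FALSE)
    else
      draw(cfg$n_non_active, cfg$decoy_rate)
    peps <- peptide_set(
      id = c(sprintf("act%04d", seq_len(cfg$n_active)),
             sprintf("neg%04d", seq_len(cfg$n_non_active))),
      sequence = vapply(c(act, neg), format_sequence, ""),
      label = rep(c("active", "non_active"),
                  c(cfg$n_active, cfg$n_non_active)))
    if (cfg$reference_fraction > 0) {
      idx <- which(peps$label == "active")
      n_ref <- max(1L, round(cfg$reference_fraction * length(idx)))
      peps$label[sample(idx, n_ref)] <- "active_reference"
    }
    peps
  })
}
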