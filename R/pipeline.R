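# End-to-end screening pipeline and provenance-stamped output writers.

#' Deterministic hash of a configuration object
#'
#' A djb2-style rolling hash over the deparsed object, kept in exact double
#' arithmetic modulo 2^32; used to stamp output files so that runs are
#' attributable to an exact configuration.
#'
#' @param x any R object.
#' @return 8-hex-digit string.
#' @export
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

provenance_header <- function(seed, cfg) {
  sprintf("spadkit %s seed=%s config=%s",
          as.character(utils::packageVersion("spadkit")),
          as.character(seed), config_hash(cfg))
}

#' Write a data frame as TSV with a provenance header
#'
#' @param df data frame.
#' @param path output file.
#' @param seed seed recorded in the header.
#' @param cfg configuration object hashed into the header.
#' @export
write_tsv_provenance <- function(df, path, seed, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", provenance_header(seed, cfg)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run one simulated screen end to end
#'
#' Generates a labeled dataset over a fixed residue universe, featurizes it
#' with the requested descriptor, ranks the non-reference peptides against
#' the active references by Tanimoto similarity and computes the enrichment
#' curve.
#'
#' @param cfg [generator_config()].
#' @param lib [residue_library()] (the residue universe).
#' @param v [vocabulary()].
#' @param bits optional precomputed [residue_bit_table()] for `lib` and `v`.
#' @param seed dataset seed (defaults to `cfg$seed`).
#' @param descriptor `"spad"` or `"atompair"`.
#' @param gaps gap set for the SPAD descriptor.
#' @param peps optional pre-generated [peptide_set()]; when supplied the
#'   generator is skipped (used to screen the same dataset with several
#'   descriptors).
#' @return List with `peptides`, `fm`, `ranked`, `curve`.
#' @export
run_screen <- function(cfg, lib, v, bits = NULL, seed = cfg$seed,
                       descriptor = c("spad", "atompair"),
                       gaps = default_gap_set(cfg$max_gap), peps = NULL) {
  descriptor <- match.arg(descriptor)
  if (is.null(peps)) peps <- generate_dataset(cfg, lib, v, seed = seed)
  fm <- if (descriptor == "spad") {
    if (is.null(bits)) bits <- residue_bit_table(lib, v)
    build_feature_matrix(peps, bits, gaps)
  } else {
    atom_pair_matrix(peps, lib)
  }
  ranked <- rank_by_reference(fm)
  curve <- enrichment_curve(ranked)
  list(peptides = peps, fm = fm, ranked = ranked, curve = curve)
}

#' Write a ranked screen to TSV
#'
#' @param rs `ranked_screen`.
#' @inheritParams write_tsv_provenance
#' @export
write_ranked_screen <- function(rs, path, seed, cfg) {
  write_tsv_provenance(as.data.frame(rs), path, seed, cfg)
}

#' Write an enrichment curve to TSV plus a JSON summary
#'
#' @param curve `enrichment_curve`.
#' @param path TSV of curve points; a `.json` summary with the AUC and early
#'   enrichment is written next to it.
#' @inheritParams write_tsv_provenance
#' @export
write_enrichment_curve <- function(curve, path, seed, cfg) {
  write_tsv_provenance(curve$points, path, seed, cfg)
  summ <- list(auc = curve$auc,
               n_active = curve$n_active,
               n_total = curve$n_total,
               early = as.list(stats::setNames(
                 curve_y_at(curve, c(0.05, 0.10, 0.25)),
                 c("y_at_0.05", "y_at_0.1", "y_at_0.25"))),
               seed = seed,
               config = config_hash(cfg))
  jsonlite::write_json(summ, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
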