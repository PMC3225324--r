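# Shared fixtures, memoised across test files.  Everything is built in code;
# the only stored inputs are the packaged natural-residue CSV and the default
# vocabulary.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

nat_lib <- function() memo("nat_lib", natural_residues())
def_vocab <- function() memo("def_vocab", default_vocabulary())
nat_bits <- function() memo("nat_bits", residue_bit_table(nat_lib(), def_vocab()))

# Synthetic residue universe shared by the simulation-based tests: one fixed
# universe, datasets drawn over it with varying seeds.
sim_cfg <- function(...) generator_config(seed = 7L, ...)
sim_lib <- function() memo("sim_lib", generate_residue_library(sim_cfg()))
sim_bits <- function() memo("sim_bits", residue_bit_table(sim_lib(), def_vocab()))

# Reduced vocabulary (10 base patterns, 20 combined) for exhaustive
# brute-force comparisons.
small_vocab <- function() memo("small_vocab", {
  ids <- c("n_S", "n_O", "s_hydroxyl", "s_arom6", "s_prim_amine",
           "s_methyl", "s_carboxyl", "s_arom_nh", "s_guanidinium", "s_ch2x2")
  v <- def_vocab()
  vocabulary(v$base[match(ids, v$base$id), ])
})
small_bits <- function() memo("small_bits",
                              residue_bit_table(nat_lib(), small_vocab()))

random_peptides <- function(n, len_range, codes, seed) {
  withr::with_seed(seed, {
    peptide_set(
      id = sprintf("r%04d", seq_len(n)),
      sequence = vapply(seq_len(n), function(i) {
        L <- sample(len_range[1]:len_range[2], 1)
        spadkit:::format_sequence(sample(codes, L, replace = TRUE))
      }, ""))
  })
}
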