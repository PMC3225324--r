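test_that("default gap set enumerates exact and ranged bindings", {
  gs <- default_gap_set(2)
  expect_equal(length(gs), 4L)
  expect_equal(lapply(gs, `[[`, "gaps"),
               list(0L, 1L, 2L, 0:2))
  expect_equal(length(default_gap_set(0)), 1L)
  expect_equal(length(default_gap_set(8)), 12L)
  # ranged spec {0..2} admits a pair at gap 1
  expect_true(1L %in% gap_spec(0:2)$gaps)
})

test_that("single features honour direction, gaps and degenerate inputs", {
  bits <- nat_bits()
  # S (hydroxyl donor) - G - F (aromatic): one residue between carriers
  expect_equal(spad_feature(c("S", "G", "F"), bits,
                            "s_hydroxyl", gap_spec(1), "s_arom6"), 1L)
  expect_equal(spad_feature(c("S", "G", "F"), bits,
                            "s_arom6", gap_spec(1), "s_hydroxyl"), 0L)
  expect_equal(spad_feature(c("S", "G", "F"), bits,
                            "s_hydroxyl", gap_spec(0:2), "s_arom6"), 1L)
  expect_equal(spad_feature(c("S", "G", "F"), bits,
                            "s_hydroxyl", gap_spec(0), "s_arom6"), 0L)
  # a single residue can never carry a pair
  expect_equal(spad_feature("F", bits, "s_arom6", gap_spec(0), "s_arom6"), 0L)
  expect_error(spad_feature(c("A", "Zz"), bits, "s_arom6", gap_spec(0),
                            "s_arom6"), "Zz")
})

test_that("matrix rows equal brute-force triple enumeration bit for bit", {
  bits <- small_bits()
  gaps <- default_gap_set(3)
  peps <- random_peptides(200, c(2, 8), residue_codes(nat_lib()), seed = 11)
  fm <- build_feature_matrix(peps, bits, gaps)
  fnames <- feature_names(fm)
  for (a in seq_len(nrow(peps))) {
    got <- sort(fnames[fp_row_bits(fm, a)])
    want <- oracle_spad_all(tokenize_sequence(peps$sequence[a]), bits, gaps)
    expect_identical(got, want)
  }
})

test_that("single-feature evaluation matches the brute-force oracle", {
  bits <- small_bits()
  gaps <- default_gap_set(3)
  pats <- colnames(bits)
  withr::with_seed(23, {
    for (rep in 1:300) {
      toks <- sample(residue_codes(nat_lib()), sample(2:8, 1), replace = TRUE)
      i <- sample(pats, 1); j <- sample(pats, 1)
      k <- gaps[[sample(length(gaps), 1)]]
      expect_identical(spad_feature(toks, bits, i, k, j),
                       oracle_spad(toks, bits, i, k$gaps, j))
    }
  })
})

test_that("features are monotone in the gap set and under extension", {
  bits <- small_bits()
  pats <- colnames(bits)
  codes <- residue_codes(nat_lib())
  withr::with_seed(31, {
    for (rep in 1:100) {
      toks <- sample(codes, sample(2:8, 1), replace = TRUE)
      i <- sample(pats, 1); j <- sample(pats, 1)
      g1 <- sort(sample(0:4, sample(1:3, 1)))
      g2 <- sort(unique(c(g1, sample(0:6, 2))))
      # allowed-gap superset can only turn 0 into 1
      expect_lte(spad_feature(toks, bits, i, gap_spec(g1), j),
                 spad_feature(toks, bits, i, gap_spec(g2), j))
      # appending a residue never destroys an existential feature
      ext <- c(toks, sample(codes, 1))
      expect_lte(spad_feature(toks, bits, i, gap_spec(g1), j),
                 spad_feature(ext, bits, i, gap_spec(g1), j))
    }
  })
})

test_that("feature matrices are deterministic and duplicate rows exactly", {
  bits <- small_bits()
  gaps <- default_gap_set(3)
  peps <- random_peptides(20, c(4, 10), residue_codes(nat_lib()), seed = 5)
  fm1 <- build_feature_matrix(peps, bits, gaps)
  fm2 <- build_feature_matrix(peps, bits, gaps)
  expect_identical(fm1$bits, fm2$bits)

  dup <- peps
  dup$sequence[2] <- dup$sequence[1]
  fmd <- build_feature_matrix(dup, bits, gaps)
  expect_identical(fmd$bits[, 1], fmd$bits[, 2])

  expect_error(build_feature_matrix(peps[0, ], bits, gaps), "empty")
})

test_that("unordered mode merges mirror triples", {
  bits <- nat_bits()
  peps <- peptide_set("p", "FGS", library = nat_lib())
  fm_dir <- build_feature_matrix(peps, bits, default_gap_set(2))
  fm_sym <- build_feature_matrix(peps, bits, default_gap_set(2),
                                 ordered = FALSE)
  fn <- feature_names(fm_dir)
  on_dir <- fn[fp_row_bits(fm_dir, 1)]
  on_sym <- fn[fp_row_bits(fm_sym, 1)]
  # F precedes S, so the directional matrix has aromatic->hydroxyl only
  expect_true("s_arom6|g1|s_hydroxyl" %in% on_dir)
  expect_false("s_hydroxyl|g1|s_arom6" %in% on_dir)
  expect_true(all(c("s_arom6|g1|s_hydroxyl", "s_hydroxyl|g1|s_arom6")
                  %in% on_sym))
  expect_true(all(on_dir %in% on_sym))
})

test_that("sparse export keeps observed columns in canonical order", {
  bits <- small_bits()
  peps <- random_peptides(10, c(3, 6), residue_codes(nat_lib()), seed = 9)
  fm <- build_feature_matrix(peps, bits, default_gap_set(2))
  m <- fp_as_sparse(fm)
  expect_true(all(Matrix::colSums(m) > 0))
  expect_equal(nrow(m), 10L)
  # every stored entry agrees with the packed representation
  fn <- feature_names(fm)
  for (a in c(1L, 5L)) {
    expect_setequal(colnames(m)[which(as.vector(m[a, ]) > 0)],
                    fn[fp_row_bits(fm, a)])
  }
})

test_that("span report ranks the decisive triple first on a planted toy set", {
  bits <- nat_bits()
  # actives share hydroxyl ... gap 1 ... aromatic; negatives avoid it
  peps <- peptide_set(
    id = sprintf("p%d", 1:8),
    sequence = c("SGF", "SAF", "TGY", "SGW", "AGA", "GGG", "AAG", "GAV"),
    label = rep(c("active", "non_active"), each = 4), library = nat_lib())
  fm <- build_feature_matrix(peps, bits, default_gap_set(2))
  rep_tab <- feature_span_report(fm)
  expect_equal(rep_tab$phi[1], 1)
  top_perfect <- rep_tab$feature[rep_tab$phi == 1 & !is.na(rep_tab$phi)]
  expect_true("s_hydroxyl|g1|s_arom6" %in% top_perfect)
  # span definition: largest allowed gap plus the two carriers
  expect_equal(unique(rep_tab$span[rep_tab$gap == "g0-2"]), 4L)
  # undefined phi flagged as NA when labels are constant
  fm1 <- build_feature_matrix(peps[1:4, ], bits, default_gap_set(2))
  rep1 <- feature_span_report(fm1)
  expect_true(all(is.na(rep1$phi)))
})
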