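toy_fm <- function(rows, labels, ids = sprintf("p%d", seq_along(rows)),
                   n_features = 8L) {
  spadkit:::new_fingerprint_set(
    bits = spadkit:::pack_rows(
      lapply(rows, function(r) seq_len(n_features) %in% r), n_features),
    n_features = n_features, ids = ids, labels = labels,
    meta = list(type = "toy", keys = sprintf("f%d", seq_len(n_features))),
    subclass = "toy_fm")
}

test_that("tanimoto matches its closed form and the set-based oracle", {
  expect_equal(tanimoto(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(tanimoto(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 0)  # all-zero convention
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length")

  withr::with_seed(17, {
    for (rep in 1:1000) {
      x <- rbinom(40, 1, 0.3); y <- rbinom(40, 1, 0.3)
      tc <- tanimoto(x, y)
      expect_equal(tc, oracle_tanimoto_sets(which(x == 1), which(y == 1)))
      expect_equal(tc, tanimoto(y, x))
      expect_gte(tc, 0); expect_lte(tc, 1)
    }
  })
})

test_that("reference ranking scores, sorts and excludes references", {
  fm <- toy_fm(rows = list(1:4, 1:4, c(1, 2, 5, 6), c(1, 2, 3, 5)),
               labels = c("active_reference", "active", "non_active",
                          "active"))
  rs <- rank_by_reference(fm)
  expect_s3_class(rs, "ranked_screen")
  expect_false("p1" %in% rs$id)
  expect_equal(rs$id, c("p2", "p4", "p3"))       # scores 1, 0.6, 1/3
  expect_equal(rs$score, c(1, 0.6, 1 / 3))
  expect_equal(rs$rank, 1:3)

  # disjoint candidates keep input order at score zero
  fm0 <- toy_fm(rows = list(1:2, c(5, 6), c(7, 8), c(5, 8)),
                labels = c("active_reference", rep("non_active", 3)))
  rs0 <- rank_by_reference(fm0)
  expect_equal(rs0$score, rep(0, 3))
  expect_equal(rs0$id, c("p2", "p3", "p4"))

  # max over multiple references, and the mean alternative
  fm2 <- toy_fm(rows = list(1:4, 5:8, 1:4),
                labels = c("active_reference", "active_reference", "active"))
  expect_equal(rank_by_reference(fm2)$score, 1)
  expect_equal(rank_by_reference(fm2, aggregate = "mean")$score, 0.5)

  expect_error(rank_by_reference(fm, references = character(0)), "empty")
  expect_error(rank_by_reference(fm, references = "nope"), "not present")
})

test_that("enrichment curves match hand-enumerated threshold sweeps", {
  rs <- structure(
    data.frame(id = sprintf("c%d", 1:4),
               score = c(0.9, 0.8, 0.7, 0.1),
               label = c("active", "non_active", "active", "non_active"),
               rank = 1:4, stringsAsFactors = FALSE),
    class = c("ranked_screen", "data.frame"))
  cv <- enrichment_curve(rs)
  expect_equal(cv$points$x, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(cv$points$y, c(0, 0.5, 0.5, 1, 1))
  expect_equal(cv$auc, 0.625)
  expect_true(all(diff(cv$points$x) >= 0) && all(diff(cv$points$y) >= 0))

  # perfect separation: closed-form step-curve area 1 - f/2
  n <- 40L; na <- 10L
  rsp <- structure(
    data.frame(id = sprintf("c%d", 1:n),
               score = seq(1, 0.1, length.out = n),
               label = rep(c("active", "non_active"), c(na, n - na)),
               rank = 1:n, stringsAsFactors = FALSE),
    class = c("ranked_screen", "data.frame"))
  cvp <- enrichment_curve(rsp)
  expect_equal(cvp$auc, 1 - na / (2 * n))
  expect_equal(curve_values <- max(cvp$points$y[cvp$points$x <= na / n]), 1)

  # relabeling peptide ids does not change the curve
  rs2 <- rs; rs2$id <- sprintf("z%d", 1:4)
  cv2 <- enrichment_curve(rs2)
  expect_equal(cv2$points[, c("x", "y")], cv$points[, c("x", "y")])
  expect_equal(cv2$auc, cv$auc)

  rs_na <- rs; rs_na$label <- rep("non_active", 4)
  expect_error(enrichment_curve(rs_na), "no active")
})

test_that("label-permutation null centres the area at one half", {
  n <- 40L
  withr::with_seed(29, {
    scores <- sort(runif(n), decreasing = TRUE)
    aucs <- vapply(1:200, function(dummy) {
      lab <- sample(rep(c("active", "non_active"), c(15, n - 15)))
      rs <- structure(
        data.frame(id = sprintf("c%d", 1:n), score = scores, label = lab,
                   rank = 1:n, stringsAsFactors = FALSE),
        class = c("ranked_screen", "data.frame"))
      enrichment_curve(rs)$auc
    }, 0)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("descriptor comparison reports AUC and early enrichment per curve", {
  rs <- structure(
    data.frame(id = sprintf("c%d", 1:4),
               score = c(0.9, 0.8, 0.7, 0.1),
               label = c("active", "non_active", "active", "non_active"),
               rank = 1:4, stringsAsFactors = FALSE),
    class = c("ranked_screen", "data.frame"))
  cv <- enrichment_curve(rs)
  tab <- compare_descriptors(list(a = cv, b = cv))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$auc, rep(cv$auc, 2))
  expect_equal(tab[1, -1], tab[2, -1], ignore_attr = TRUE)
  expect_error(compare_descriptors(list(a = cv)), "at least two")
  cv2 <- cv; cv2$ids <- c("x", cv$ids[-1])
  expect_error(compare_descriptors(list(a = cv, b = cv2)), "different")
})

test_that("reference assignment relabels a seeded subset of actives", {
  peps <- peptide_set(sprintf("p%d", 1:30), rep("AGSF", 30),
                      rep(c("active", "non_active"), c(20, 10)), nat_lib())
  out <- assign_references(peps, fraction = 0.1, seed = 4)
  expect_equal(sum(out$label == "active_reference"), 2L)
  expect_equal(sum(out$label == "active"), 18L)
  out2 <- assign_references(peps, fraction = 0.1, seed = 4)
  expect_identical(out$label, out2$label)
})
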