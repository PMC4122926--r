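test_that("Mann-Whitney U is exact for small untied samples", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_true(mw$exact)
  expect_equal(mw$p, 0.1)
  expect_equal(mw$p, enum_mw_p(c(1, 2, 3), c(4, 5, 6)))
  # U identity: U_x + U_y = n_x * n_y
  set.seed(8)
  x <- rnorm(6); y <- rnorm(4)
  ux <- mann_whitney_u(x, y)$U
  uy <- mann_whitney_u(y, x)$U
  expect_equal(ux + uy, 24)
  # spot enumeration checks at several shapes
  for (r in 1:5) {
    x <- rnorm(sample(2:5, 1)); y <- rnorm(sample(2:5, 1))
    expect_equal(mann_whitney_u(x, y)$p, enum_mw_p(x, y),
                 tolerance = 1e-12)
  }
  # identical samples cannot separate
  z <- c(1, 2, 3, 4)
  expect_gte(mann_whitney_u(z, z)$p, 0.99)
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("large or tied samples use the corrected normal approximation", {
  set.seed(2)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  mw <- mann_whitney_u(x, y)
  expect_false(mw$exact)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mw$p, ref$p.value)
  tied <- mann_whitney_u(c(1, 1, 2), c(2, 3, 3))
  expect_false(tied$exact)
  expect_true(tied$p > 0 && tied$p <= 1)
})

test_that("one-way ANOVA matches hand computation and the pooled t test", {
  g <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  res <- one_way_anova(g)
  # SSB = 3*((2-3)^2 + 0 + (4-3)^2) = 6, SSW = 6, F = (6/2)/(6/6) = 3
  expect_equal(res$F, 3)
  expect_equal(res$p, stats::pf(3, 2, 6, lower.tail = FALSE))
  # two groups: F is the squared pooled t statistic
  set.seed(3)
  a <- rnorm(8); b <- rnorm(9, 1)
  res2 <- one_way_anova(list(a, b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-12)
  # degenerate inputs
  expect_equal(one_way_anova(list(c(2, 2), c(2, 2)))$F, 0)
  expect_error(one_way_anova(list(1:3)), "2 groups")
  expect_error(one_way_anova(list(1:3, 5)), "2 values")
})

test_that("Bonferroni thresholds truncate to three decimals", {
  expect_equal(as.numeric(bonferroni_threshold(0.05, 3)), 0.016)
  expect_equal(attr(bonferroni_threshold(0.05, 3), "exact"), 0.05 / 3)
  expect_equal(as.numeric(bonferroni_threshold(0.05, 1)), 0.05)
  expect_equal(as.numeric(bonferroni_threshold(0.04, 4)), 0.01)
  expect_error(bonferroni_threshold(1.2, 2), "alpha")
})

test_that("percentile profiles follow the inclusive interpolation rule", {
  p1 <- percentile_profile(list(a = 0.1))
  expect_true(all(p1[, c("p10", "p25", "p50", "p75", "p90")] == 0.1))
  expect_equal(percentile_profile(list(a = c(0, 1)))$p50, 0.5)
  v <- (1:10) / 10
  pr <- percentile_profile(list(a = v))
  # h = (n-1)p + 1 = 1.9 -> 0.1 + 0.9*(0.2-0.1)
  expect_equal(pr$p10, 0.19)
  expect_equal(pr$p90, 0.91)
  expect_error(percentile_profile(list(a = numeric())), "non-empty")
})

test_that("classical MDS embeds Euclidean distances exactly", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  xy <- classical_mds(d, 1, standardize = FALSE)
  emb <- as.matrix(stats::dist(xy))
  expect_lt(max(abs(emb - d)), 1e-8)
  # full-rank embedding of genuinely Euclidean inputs is exact
  set.seed(5)
  pts <- matrix(rnorm(12), 6, 2)
  rownames(pts) <- paste0("p", 1:6)
  dd <- as.matrix(stats::dist(pts))
  expect_warning(emb2 <- classical_mds(dd, 5, standardize = FALSE),
                 "nonpositive")
  expect_lt(max(abs(as.matrix(stats::dist(emb2)) - dd)), 1e-8)
  # zero matrix: all coordinates zero (warning for dropped dimensions)
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(cz <- classical_mds(z, 2, standardize = FALSE),
                 "nonpositive")
  expect_true(all(cz == 0))
  expect_error(classical_mds(d, 3), "k")
  # standardization shifts but preserves the ordering of distances
  xs <- classical_mds(dd, 2, standardize = TRUE)
  expect_equal(nrow(xs), 6L)
})

test_that("per-clade comparisons carry the right sets, tests and stars", {
  # identical sequences with their ancestor: all-zero sets, not significant
  aln <- aa_alignment(c(t1 = "AAAA", t2 = "AAAA", t3 = "AAAA",
                        "mama-X" = "AAAA"))
  comp <- compare_distances(aln, c(t1 = "X", t2 = "X", t3 = "X"))
  expect_length(comp, 1)
  expect_equal(comp$X$anc_member, rep(0, 3), ignore_attr = TRUE)
  expect_equal(comp$X$member_member, rep(0, 3), ignore_attr = TRUE)
  expect_identical(comp$X$stars, "ns")
  expect_length(comp$X$member_member, 3)   # 3 choose 2
  # simulated deep clades: ancestors are closer than members are to each
  # other, for every clade
  m <- build_wag()
  sd <- small_dataset(seed = 37, tips = 6L, sites = 300L, crown = 0.5)
  ds <- sd$dataset
  mamas <- reconstruct_mamas(ds$tree, ds$alignment, m, ds$clade_labels)
  anc <- stats::setNames(
    vapply(mamas, `[[`, character(1), "map_sequence"),
    paste0("mama-", names(mamas)))
  full <- aa_alignment(c(aln_strings(ds$alignment), anc),
                       labels = ds$clade_labels)
  comp2 <- compare_distances(full, ds$clade_labels)
  for (cl in names(comp2))
    expect_lt(comp2[[cl]]$mean_anc_member,
              comp2[[cl]]$mean_member_member)
  # adding the root ancestor adds a third set without touching the others
  luc <- reconstruct_lucar(ds$tree, ds$alignment, m)
  full2 <- aa_alignment(c(aln_strings(ds$alignment), anc,
                          LUCAR = luc$map_sequence),
                        labels = ds$clade_labels)
  comp3 <- compare_distances(full2, ds$clade_labels)
  for (cl in names(comp2)) {
    expect_equal(comp3[[cl]]$anc_member, comp2[[cl]]$anc_member)
    expect_equal(comp3[[cl]]$member_member, comp2[[cl]]$member_member)
    expect_length(comp3[[cl]]$lucar_member, 6)
  }
  tab <- comparison_table(comp3)
  expect_setequal(unique(tab$set),
                  c("anc_member", "member_member", "lucar_member"))
  # a clade of one member is skipped with a warning
  labs <- c(ds$clade_labels, z1 = "Z")
  full3 <- aa_alignment(c(aln_strings(full2), z1 = aln_strings(full2)[[1]]),
                        labels = labs)
  expect_warning(compare_distances(full3, labs), "fewer than 2")
})

test_that("significance stars follow the reporting convention", {
  expect_identical(significance_stars(1e-7), "***")
  expect_identical(significance_stars(1e-4), "**")
  expect_identical(significance_stars(0.01), "*")
  expect_identical(significance_stars(0.2), "ns")
})
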