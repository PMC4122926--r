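test_that("pruning likelihood equals explicit enumeration on a hand tree", {
  m <- build_wag()
  tr <- ape::read.tree(text = "(A:0.1,B:0.1)r;")
  aln <- aa_alignment(c(A = "A", B = "A"))
  res <- site_conditional_likelihoods(tr, aln, m)
  p <- transition_matrix(m, 0.1)
  direct <- log(sum(m$frequencies * p[, "A"]^2))
  expect_equal(res$loglik, direct, tolerance = 1e-10)
})

test_that("pruning and marginal posteriors match enumeration on random small trees", {
  m <- build_wag()
  set.seed(21)
  for (r in 1:6) {
    n_tip <- sample(3:4, 1)
    tr <- ape::rtree(n_tip)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.02, 0.8)
    n_sites <- sample(1:3, 1)
    chars <- matrix(sample(c(AA20, "-"), n_tip * n_sites, replace = TRUE,
                           prob = c(rep(1, 20), 3)),
                    n_tip, n_sites)
    # keep at least one residue per column so likelihoods stay informative
    chars[1, ] <- sample(AA20, n_sites, replace = TRUE)
    seqs <- stats::setNames(apply(chars, 1, paste, collapse = ""),
                            tr$tip.label)
    aln <- aa_alignment(seqs)
    res <- site_conditional_likelihoods(tr, aln, m)
    node <- sample(seq_len(tr$Nnode), 1) + n_tip
    prof <- marginal_posteriors(tr, aln, m, node)
    for (s in seq_len(n_sites)) {
      site_chars <- stats::setNames(chars[, s], tr$tip.label)
      enum <- enum_site_likelihood(tr, m, site_chars)
      expect_equal(res$site_loglik[s], log(enum), tolerance = 1e-8)
      expect_equal(unname(prof$posteriors[s, ]),
                   unname(enum_posterior(tr, m, site_chars, node)),
                   tolerance = 1e-8)
    }
  }
})

test_that("gapped tips act as marginalized subtrees", {
  m <- build_wag()
  tr3 <- ape::read.tree(text = "((A:0.2,B:0.3)n1:0.1,C:0.4)r;")
  aln3 <- aa_alignment(c(A = "L", B = "-", C = "K"))
  tr2 <- ape::read.tree(text = "(A:0.3,C:0.4)r;")   # B's subtree removed
  aln2 <- aa_alignment(c(A = "L", C = "K"))
  l3 <- site_conditional_likelihoods(tr3, aln3, m)$loglik
  l2 <- site_conditional_likelihoods(tr2, aln2, m)$loglik
  expect_equal(l3, l2, tolerance = 1e-10)
})

test_that("the total likelihood is invariant to rerooting", {
  m <- build_wag()
  sd <- small_dataset(seed = 13, tips = 3L, sites = 40L)
  tr <- sd$dataset$tree
  aln <- sd$dataset$alignment
  l0 <- site_conditional_likelihoods(tr, aln, m)$loglik
  un <- ape::unroot(tr)
  for (tip in c("A1", "E2", "V3")) {
    rr <- ape::root(un, outgroup = tip, resolve.root = TRUE)
    l1 <- site_conditional_likelihoods(rr, aln, m)$loglik
    expect_equal(l1, l0, tolerance = 1e-8)
  }
})

test_that("the likelihood matches an established engine given the same model", {
  m <- build_wag()
  sd <- small_dataset(seed = 17, tips = 3L, sites = 60L)
  aln <- sd$dataset$alignment
  tr <- sd$dataset$tree
  mine <- site_conditional_likelihoods(tr, aln, m)$loglik
  pd <- phangorn::phyDat(aln$matrix, type = "AA")
  lev <- attr(pd, "levels")
  perm <- match(lev, m$alphabet)
  S <- m$exchangeabilities[perm, perm]
  fit <- phangorn::pml(ape::unroot(tr), pd,
                       bf = unname(m$frequencies[perm]),
                       Q = S[lower.tri(S)])
  expect_equal(mine, fit$logLik, tolerance = 1e-6)
})

test_that("degenerate posteriors behave as expected", {
  m <- build_wag()
  # star tree with zero branch lengths and identical tips
  tr <- ape::read.tree(text = "(A:0,B:0,C:0)r;")
  aln <- aa_alignment(c(A = "WW", B = "WW", C = "WW"))
  prof <- marginal_posteriors(tr, aln, m, "r")
  expect_equal(unname(prof$posteriors[, "W"]), c(1, 1))
  expect_identical(prof$map_sequence, "WW")
  # two close tips: posterior mass concentrates on the shared residue
  tr2 <- ape::read.tree(text = "(A:0.01,B:0.01)r;")
  aln2 <- aa_alignment(c(A = "L", B = "L"))
  prof2 <- marginal_posteriors(tr2, aln2, m, "r")
  expect_gt(prof2$posteriors[1, "L"], 0.99)
  # rows always sum to 1
  expect_equal(rowSums(prof2$posteriors), 1, ignore_attr = TRUE)
  expect_error(marginal_posteriors(tr2, aln2, m, "nope"), "unknown")
})

test_that("clade ancestors are reconstructed at the right nodes and accurately", {
  m <- build_wag()
  sd <- small_dataset(seed = 29, tips = 5L, sites = 120L)
  ds <- sd$dataset
  mamas <- reconstruct_mamas(ds$tree, ds$alignment, m, ds$clade_labels)
  expect_setequal(names(mamas), c("A", "B", "E", "V"))
  expect_identical(mamas$A$node, "mama-A")
  # accuracy against the recorded truth over replicate simulations
  accs <- vapply(1:6, function(s) {
    tr <- simulate_clade_tree(4, 5, 1.0, 0.3, seed = 100 + s)
    d <- evolve(tr, m, 420, seed = 200 + s)
    mm <- reconstruct_mamas(d$tree, d$alignment, m, d$clade_labels)
    mean(vapply(names(mm), function(cl)
      1 - p_distance(mm[[cl]]$map_sequence,
                     d$true_ancestors[[paste0("mama-", cl)]]), 1))
  }, 1)
  expect_gt(mean(accs), 0.80)
  # single-member clades are rejected
  bad <- ds$clade_labels
  bad[bad == "A"] <- c("A", rep("Z", 4))
  expect_error(reconstruct_mamas(ds$tree, ds$alignment, m, bad),
               "fewer than 2")
  # non-monophyletic clades are rejected by name
  bad2 <- ds$clade_labels
  bad2[c(1, 6)] <- c("B", "A")
  expect_error(reconstruct_mamas(ds$tree, ds$alignment, m, bad2),
               "monophyletic")
})

test_that("the root ancestor is closer to the truth than extant tips", {
  m <- build_wag()
  wins <- vapply(1:10, function(s) {
    tr <- simulate_clade_tree(4, 4, 0.8, 0.4, seed = 300 + s)
    d <- evolve(tr, m, 300, seed = 400 + s)
    luc <- reconstruct_lucar(d$tree, d$alignment, m)
    truth <- d$true_ancestors[["LUCAR-node"]]
    d_luc <- p_distance(luc$map_sequence, truth)
    d_tips <- min(vapply(aln_strings(d$alignment), p_distance, 1,
                         b = truth))
    d_luc < d_tips
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("ASR accuracy improves as crowns get shallower", {
  m <- build_wag()
  acc_at <- function(depth) {
    mean(vapply(1:3, function(s) {
      tr <- simulate_clade_tree(4, 4, 0.8, depth, seed = 500 + s)
      d <- evolve(tr, m, 300, seed = 600 + s)
      mm <- reconstruct_mamas(d$tree, d$alignment, m, d$clade_labels)
      mean(vapply(names(mm), function(cl)
        1 - p_distance(mm[[cl]]$map_sequence,
                       d$true_ancestors[[paste0("mama-", cl)]]), 1))
    }, 1))
  }
  accs <- vapply(c(0.1, 0.3, 0.6), acc_at, 1)
  expect_true(all(diff(accs) < 0))
})

test_that("root and star modes of the global ancestor are both available", {
  m <- build_wag()
  # a single clade: the root ancestor IS the clade ancestor
  tr1 <- simulate_clade_tree(1, 4, 0.5, 0.3, seed = 3)
  d1 <- evolve(tr1, m, 80, seed = 4)
  luc1 <- reconstruct_lucar(d1$tree, d1$alignment, m)
  mam1 <- marginal_posteriors(d1$tree, d1$alignment, m, "LUCAR-node")
  expect_identical(luc1$map_sequence, mam1$map_sequence)
  expect_equal(luc1$posteriors, mam1$posteriors)
  # star mode returns a normalized profile over the same sites
  sd <- small_dataset(seed = 31, tips = 4L, sites = 100L)
  star <- reconstruct_lucar(sd$dataset$tree, sd$dataset$alignment, m,
                            mode = "star",
                            clade_labels = sd$dataset$clade_labels)
  expect_equal(nrow(star$posteriors), 100L)
  expect_equal(rowSums(star$posteriors), rep(1, 100), ignore_attr = TRUE)
  expect_error(reconstruct_lucar(sd$dataset$tree, sd$dataset$alignment, m,
                                 mode = "star"), "clade_labels")
})
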