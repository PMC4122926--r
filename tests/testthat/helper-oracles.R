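# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the aligner oracle is a naive R dynamic
# program, the likelihood oracle an explicit enumeration over all internal
# state assignments, and the rank-test oracle a full enumeration of group
# assignments.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# Naive affine-gap local alignment score (Gotoh recurrences written
# directly, full matrices, no traceback).  Gap of length k costs
# open + k * extend.
naive_local_score <- function(query, target, smat, open = 11, extend = 1) {
  q <- strsplit(query, "")[[1]]
  t <- strsplit(target, "")[[1]]
  m <- length(q); n <- length(t)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + smat[q[i - 1], t[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  get("BLOSUM62", envir = env)
}

# Explicit phylogenetic likelihood: sum over every assignment of states to
# internal nodes of pi(root) * prod(edge transition probabilities) *
# prod(tip emission factors).  Gap/X tips contribute factor 1.
enum_site_likelihood <- function(tree, model, tip_chars,
                                 fix_node = NULL, fix_state = NULL) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  root <- n_tip + 1L
  P <- lapply(tree$edge.length, transition_matrix, model = model)
  combos <- as.matrix(expand.grid(rep(list(1:20), n_int)))
  if (!is.null(fix_node)) {
    combos <- combos[combos[, fix_node - n_tip] == fix_state, ,
                     drop = FALSE]
  }
  tip_idx <- match(tip_chars, AA20)          # NA = gap/X/missing
  # one weight per assignment of states to internal nodes: the stationary
  # prior at the root times every edge's transition probability
  w <- unname(model$frequencies[combos[, root - n_tip]])
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    ps <- combos[, par - n_tip]
    if (ch <= n_tip) {
      ci <- tip_idx[ch]
      if (!is.na(ci)) w <- w * P[[e]][cbind(ps, ci)]
    } else {
      w <- w * P[[e]][cbind(ps, combos[, ch - n_tip])]
    }
  }
  sum(w)
}

# Marginal posterior at an internal node by restricted enumeration.
enum_posterior <- function(tree, model, tip_chars, node) {
  v <- vapply(1:20, function(s)
    enum_site_likelihood(tree, model, tip_chars,
                         fix_node = node, fix_state = s), 1)
  v / sum(v)
}

# Exact two-sided Mann-Whitney p by enumerating all assignments of the
# pooled values to group x (requires no ties), mirroring the conventional
# doubled one-sided definition.
enum_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  idx <- utils::combn(nx + ny, nx)
  u_all <- apply(idx, 2, function(ii) {
    xx <- pool[ii]; yy <- pool[-ii]
    sum(outer(xx, yy, ">"))
  })
  u_obs <- sum(outer(x, y, ">"))
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Small simulated dataset shared by several tests.
small_dataset <- function(seed = 7, tips = 5L, sites = 150L,
                          stem = 1.0, crown = 0.4) {
  m <- build_wag()
  tr <- simulate_clade_tree(4L, tips, stem, crown, seed = seed)
  list(model = m, dataset = evolve(tr, m, sites, seed = seed + 1L))
}
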