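# Marginal maximum-likelihood ancestral sequence reconstruction under a
# reversible amino-acid model: Felsenstein pruning (up-pass) plus the
# standard down-pass, giving per-site posterior state distributions at any
# internal node of a rooted tree.

node_number <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (is.numeric(node)) {
    if (node <= n_tip || node > n_tip + tree$Nnode)
      stop("not an internal node: ", node, call. = FALSE)
    return(as.integer(node))
  }
  if (is.null(tree$node.label))
    stop("tree has no internal node names; address nodes by number",
         call. = FALSE)
  i <- match(node, tree$node.label)
  if (is.na(i)) stop("unknown internal node: ", node, call. = FALSE)
  n_tip + i
}

# Core up+down pass.  Returns per-node scaled conditional likelihoods (L),
# their per-site log scaling, above-likelihoods (D, root row = pi), the
# per-site and total log-likelihood.  All matrices are 20 x n_sites in
# alphabet order.
asr_engine <- function(tree, aln, model) {
  stopifnot(inherits(tree, "phylo"), inherits(aln, "aa_alignment"),
            inherits(model, "subst_model"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths", call. = FALSE)
  ids <- aln_ids(aln)
  if (!setequal(tree$tip.label, ids))
    stop("tree tips and alignment ids do not match; missing from alignment: ",
         paste(utils::head(setdiff(tree$tip.label, ids), 5L), collapse = ", "),
         call. = FALSE)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  n_sites <- ncol(aln$matrix)
  root <- n_tip + 1L
  pi <- unname(model$frequencies)

  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  P <- lapply(elen, transition_matrix, model = model)

  L <- vector("list", n_node)
  logscale <- matrix(0, n_node, n_sites)
  msg <- vector("list", nrow(edge))          # P_e %*% L_child per edge

  for (i in seq_len(n_tip)) {
    chars <- aln$matrix[tree$tip.label[i], ]
    idx <- match(chars, model$alphabet)
    li <- matrix(0, 20L, n_sites)
    known <- !is.na(idx)
    li[cbind(idx[known], which(known))] <- 1
    li[, !known] <- 1                        # gap or X: missing data
    L[[i]] <- li
  }
  children_of <- split(seq_len(nrow(edge)), edge[, 1L])
  # postorder edge list guarantees children before parents
  for (e in seq_len(nrow(edge))) {
    ch <- edge[e, 2L]
    msg[[e]] <- P[[e]] %*% L[[ch]]
    par <- edge[e, 1L]
    if (is.null(L[[par]])) {
      L[[par]] <- msg[[e]]
      logscale[par, ] <- logscale[ch, ]
    } else {
      L[[par]] <- L[[par]] * msg[[e]]
      logscale[par, ] <- logscale[par, ] + logscale[ch, ]
    }
  }
  for (v in (n_tip + 1L):n_node) {           # rescale internal nodes
    sc <- apply(L[[v]], 2L, max)
    sc[sc == 0] <- 1
    L[[v]] <- sweep(L[[v]], 2L, sc, "/")
    logscale[v, ] <- logscale[v, ] + log(sc)
  }
  site_loglik <- log(colSums(pi * L[[root]])) + logscale[root, ]

  # Down-pass: D[v] = above-likelihood propagated to v (root = pi).
  D <- vector("list", n_node)
  D[[root]] <- matrix(pi, 20L, n_sites)
  for (e in rev(seq_len(nrow(edge)))) {      # parents before children
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    sibs <- setdiff(children_of[[as.character(par)]], e)
    part <- D[[par]]
    for (s in sibs) part <- part * msg[[s]]
    dch <- crossprod(P[[e]], part)
    sc <- apply(dch, 2L, max)
    sc[sc == 0] <- 1
    D[[ch]] <- sweep(dch, 2L, sc, "/")
  }
  list(tree = tree, L = L, D = D, logscale = logscale,
       site_loglik = site_loglik, loglik = sum(site_loglik),
       alphabet = model$alphabet, n_tip = n_tip)
}

profile_from_engine <- function(eng, node, node_name) {
  post <- eng$L[[node]] * eng$D[[node]]
  post <- sweep(post, 2L, colSums(post), "/")
  posteriors <- t(post)
  colnames(posteriors) <- eng$alphabet
  map_idx <- apply(post, 2L, which.max)     # ties: first = alphabetical
  structure(list(
    node = node_name,
    posteriors = posteriors,
    map_sequence = paste(eng$alphabet[map_idx], collapse = ""),
    mean_posterior = mean(apply(post, 2L, max))
  ), class = "ancestral_profile")
}

#' @export
print.ancestral_profile <- function(x, ...) {
  cat("Ancestral profile at node '", x$node, "': ",
      nrow(x$posteriors), " sites, mean max posterior ",
      format(x$mean_posterior, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Per-site phylogenetic likelihood by Felsenstein pruning
#'
#' Computes conditional likelihoods for every node of a rooted tree by the
#' pruning algorithm: tips carry indicator vectors (gaps and \code{'X'} are
#' treated as missing data, i.e. all-ones), internal nodes accumulate
#' products of child messages, and per-node log-scaling prevents underflow.
#'
#' @param tree Rooted \code{phylo} tree with branch lengths; tips must match
#'   the alignment ids.
#' @param aln An \code{aa_alignment}.
#' @param model A \code{subst_model}.
#' @return A list: \code{loglik} (total log-likelihood), \code{site_loglik},
#'   \code{conditionals} (per node, 20 x sites, rescaled), and
#'   \code{log_scaling} (per node x site log of the factored-out scale).
#' @export
site_conditional_likelihoods <- function(tree, aln, model) {
  eng <- asr_engine(tree, aln, model)
  list(loglik = eng$loglik, site_loglik = eng$site_loglik,
       conditionals = eng$L, log_scaling = eng$logscale)
}

#' Marginal ancestral posteriors at one internal node
#'
#' Standard marginal reconstruction for the tree rooted as given: the
#' posterior of state a at the node is proportional to the product of the
#' conditional likelihood of the subtree below it and the likelihood of the
#' rest of the tree propagated to it (including the stationary prior),
#' normalized per site.  The MAP sequence takes the alphabetically smallest
#' residue on ties.
#'
#' @inheritParams site_conditional_likelihoods
#' @param node Internal node name (or number).
#' @return An \code{ancestral_profile}: \code{posteriors} (sites x 20, rows
#'   sum to 1), \code{map_sequence}, \code{mean_posterior}.
#' @export
marginal_posteriors <- function(tree, aln, model, node) {
  eng <- asr_engine(tree, aln, model)
  num <- node_number(tree, node)
  nm <- if (is.character(node)) node else
    if (!is.null(tree$node.label)) tree$node.label[num - eng$n_tip] else
      as.character(num)
  profile_from_engine(eng, num, nm)
}

clade_tip_sets <- function(clade_labels) {
  split(names(clade_labels), unname(clade_labels))
}

#' Reconstruct clade ancestors ("mamas")
#'
#' Computes the marginal ancestral profile at the most recent common
#' ancestor of every clade.  Each clade must contain at least two tips and
#' be monophyletic in the tree.
#'
#' @inheritParams site_conditional_likelihoods
#' @param clade_labels Named character vector tip -> clade.
#' @return Named list of \code{ancestral_profile} objects, one per clade.
#' @export
reconstruct_mamas <- function(tree, aln, model, clade_labels) {
  sets <- clade_tip_sets(clade_labels)
  for (cl in names(sets)) {
    if (length(sets[[cl]]) < 2L)
      stop("clade '", cl, "' has fewer than 2 members; ancestor undefined",
           call. = FALSE)
    if (!ape::is.monophyletic(tree, sets[[cl]]))
      stop("clade '", cl, "' is not monophyletic in the tree",
           call. = FALSE)
  }
  eng <- asr_engine(tree, aln, model)
  out <- lapply(names(sets), function(cl) {
    num <- ape::getMRCA(tree, sets[[cl]])
    profile_from_engine(eng, num, paste0("mama-", cl))
  })
  stats::setNames(out, names(sets))
}

#' Reconstruct the global root ancestor ("LUCAR")
#'
#' In \code{"root"} mode (default) the profile is the marginal
#' reconstruction at the root of the full tree, using all data.  In
#' \code{"star"} mode the clade ancestors' MAP sequences are first
#' reconstructed, then treated as the four tips of a star tree whose branch
#' lengths are least-squares fits to their pairwise ML distances, and the
#' profile is the marginal reconstruction at the star's center.
#'
#' @inheritParams site_conditional_likelihoods
#' @param mode \code{"root"} or \code{"star"}.
#' @param clade_labels Required for \code{"star"} mode.
#' @return An \code{ancestral_profile} named \code{"LUCAR"}.
#' @export
reconstruct_lucar <- function(tree, aln, model, mode = c("root", "star"),
                              clade_labels = NULL) {
  mode <- match.arg(mode)
  if (mode == "root") {
    eng <- asr_engine(tree, aln, model)
    prof <- profile_from_engine(eng, eng$n_tip + 1L, "LUCAR")
    return(prof)
  }
  if (is.null(clade_labels))
    stop("'star' mode needs clade_labels", call. = FALSE)
  mamas <- reconstruct_mamas(tree, aln, model, clade_labels)
  seqs <- vapply(mamas, `[[`, character(1L), "map_sequence")
  names(seqs) <- paste0("mama-", names(mamas))
  n <- length(seqs)
  if (n < 2L) stop("'star' mode needs >= 2 clades", call. = FALSE)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- ml_distance(seqs[i], seqs[j], model)
  if (n == 2L) b <- rep(d[1, 2] / 2, 2L)
  else {
    r <- rowSums(d)
    tot <- sum(r) / (2 * n - 2)
    b <- pmax((r - tot) / (n - 2), 0)
  }
  fmt <- function(x) formatC(x, digits = 12, format = "g")
  nwk <- paste0("(", paste0(names(seqs), ":", fmt(b), collapse = ","),
                ")LUCAR-node;")
  star <- ape::read.tree(text = nwk)
  star_aln <- aa_alignment(seqs)
  eng <- asr_engine(star, star_aln, model)
  profile_from_engine(eng, length(seqs) + 1L, "LUCAR")
}

#' Write ancestral profiles as FASTA and a posterior table
#'
#' @param profiles List of \code{ancestral_profile} objects.
#' @param fasta_path Output FASTA of MAP sequences (optional).
#' @param table_path Output TSV of per-site posteriors: node, 1-based site,
#'   the 20 state probabilities, MAP residue, max posterior (optional).
#' @param min_posterior Sites whose max posterior falls below this are
#'   masked to \code{'X'} in the FASTA (default 0 = no masking).
#' @return Named character vector of (possibly masked) MAP sequences.
#' @export
write_ancestors <- function(profiles, fasta_path = NULL, table_path = NULL,
                            min_posterior = 0) {
  seqs <- vapply(profiles, function(p) {
    s <- strsplit(p$map_sequence, "")[[1L]]
    s[apply(p$posteriors, 1L, max) < min_posterior] <- "X"
    paste(s, collapse = "")
  }, character(1L))
  names(seqs) <- vapply(profiles, `[[`, character(1L), "node")
  if (!is.null(fasta_path)) write_fasta(seqs, fasta_path)
  if (!is.null(table_path)) {
    tabs <- lapply(profiles, function(p) {
      data.frame(node = p$node, site = seq_len(nrow(p$posteriors)),
                 round(p$posteriors, 6),
                 map = strsplit(p$map_sequence, "")[[1L]],
                 max_posterior = round(apply(p$posteriors, 1L, max), 6))
    })
    utils::write.table(do.call(rbind, tabs), table_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(seqs)
}
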