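# p-distances, maximum-likelihood pairwise distances under the substitution
# model, neighbor-joining, and Newick I/O.

seq_chars <- function(x) {
  if (length(x) == 1L && nchar(x[1L]) > 1L) strsplit(x, "")[[1L]] else x
}

#' Proportion of differing amino-acid sites (p-distance)
#'
#' The proportion of sites at which two aligned sequences differ, over the
#' comparable sites.  Under pairwise deletion a site is comparable when both
#' sequences carry a plain residue (neither gap nor \code{'X'}).
#'
#' @param a,b Equal-length gapped sequences (strings or character vectors).
#' @param deletion Only \code{"pairwise"} is meaningful for a single pair;
#'   complete deletion is applied alignment-wide by
#'   \code{\link{p_distance_matrix}}.
#' @return A number in [0, 1].
#' @examples
#' p_distance("AC-E", "ACDF")  # 1/3
#' @export
p_distance <- function(a, b, deletion = "pairwise") {
  a <- seq_chars(a); b <- seq_chars(b)
  if (length(a) != length(b))
    stop("sequences must have equal aligned length", call. = FALSE)
  ok <- a %in% AA_ALPHABET20 & b %in% AA_ALPHABET20
  if (!any(ok))
    stop("no comparable sites between the two sequences", call. = FALSE)
  sum(a[ok] != b[ok]) / sum(ok)
}

#' All-pairs p-distance matrix
#'
#' @param aln An \code{aa_alignment} (typically trimmed).
#' @param deletion \code{"pairwise"} (per-pair comparable sites, the
#'   default) or \code{"complete"} (drop every column containing a gap or
#'   \code{'X'} first).
#' @return A \code{dist_matrix}: list with \code{ids}, symmetric matrix
#'   \code{d}, and \code{kind = "p"}.
#' @export
p_distance_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  stopifnot(inherits(aln, "aa_alignment"))
  deletion <- match.arg(deletion)
  m <- aln$matrix
  if (deletion == "complete") {
    keep <- colSums(!matrix(m %in% AA_ALPHABET20, nrow(m))) == 0L
    if (!any(keep)) stop("complete deletion removed all columns",
                         call. = FALSE)
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- p_distance(m[i, ], m[j, ])
  structure(list(ids = rownames(m), d = d, kind = "p"),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("Distance matrix (", x$kind, "): ", length(x$ids), " taxa\n", sep = "")
  invisible(x)
}

# 20x20 count matrix of aligned residue pairs over comparable sites.
pair_counts <- function(a, b) {
  a <- seq_chars(a); b <- seq_chars(b)
  ia <- match(a, AA_ALPHABET20); ib <- match(b, AA_ALPHABET20)
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok))
    stop("no comparable sites between the two sequences", call. = FALSE)
  matrix(tabulate((ia[ok] - 1L) * 20L + ib[ok], nbins = 400L), 20, 20,
         byrow = TRUE)
}

#' Maximum-likelihood pairwise distance under the model
#'
#' Estimates the expected number of substitutions per site separating two
#' aligned sequences by maximizing \code{sum_sites log(pi[a] * P[a,b](t))}
#' over t in [1e-6, 20] (Brent).  Saturated pairs return the cap.
#'
#' @param a,b Equal-length gapped sequences.
#' @param model A \code{subst_model}.
#' @param t_max Upper bound / saturation cap (default 20).
#' @return Estimated distance in expected substitutions per site.
#' @export
ml_distance <- function(a, b, model, t_max = 20) {
  stopifnot(inherits(model, "subst_model"))
  cnt <- pair_counts(a, b)
  logpi <- sum(rowSums(cnt) * log(model$frequencies))
  nll <- function(t) {
    p <- transition_matrix(model, t)
    -(logpi + sum(cnt * log(pmax(p, 1e-300))))
  }
  opt <- stats::optimize(nll, interval = c(1e-6, t_max), tol = 1e-8)
  # detect saturation / boundary optimum
  if (opt$minimum > t_max * 0.999 || nll(t_max) <= opt$objective)
    return(t_max)
  opt$minimum
}

#' All-pairs ML distance matrix
#'
#' @inheritParams ml_distance
#' @param aln An \code{aa_alignment}.
#' @return A \code{dist_matrix} with \code{kind = "ml"}.
#' @export
ml_distance_matrix <- function(aln, model, t_max = 20) {
  stopifnot(inherits(aln, "aa_alignment"))
  m <- aln$matrix
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- ml_distance(m[i, ], m[j, ], model, t_max)
  structure(list(ids = rownames(m), d = d, kind = "ml"),
            class = "dist_matrix")
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining with the Q-criterion.  Ties in the
#' Q-criterion are broken deterministically toward the lexicographically
#' smallest id pair.  Negative branch lengths are clamped to zero with the
#' deficit transferred to the sibling branch, preserving the pair's summed
#' length.  The unrooted result is midpoint-rooted for output.
#'
#' @param dm A \code{dist_matrix} or a symmetric numeric matrix with
#'   dimnames.
#' @param root Rooting: \code{"midpoint"} (default) or the id of a tip to
#'   use as outgroup.
#' @return A rooted \code{phylo} tree (ape).
#' @export
neighbor_joining <- function(dm, root = "midpoint") {
  if (inherits(dm, "dist_matrix")) { ids <- dm$ids; d <- dm$d }
  else { d <- as.matrix(dm); ids <- rownames(d) }
  if (is.null(ids)) stop("distance matrix must carry ids", call. = FALSE)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix is not symmetric", call. = FALSE)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 taxa", call. = FALSE)
  # working state: newick fragment and representative (smallest) id per node
  frag <- stats::setNames(ids, ids)
  rep_id <- stats::setNames(ids, ids)
  act <- ids
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  while (length(act) > 3L) {
    nn <- length(act)
    dd <- d[act, act]
    r <- rowSums(dd)
    q <- (nn - 2) * dd - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- apply(cand, 1L, function(ij) {
      k <- sort(c(rep_id[act[ij[1]]], rep_id[act[ij[2]]]))
      paste(k, collapse = "\r")
    })
    pick <- cand[order(pair_key)[1L], ]
    i <- act[pick[1]]; j <- act[pick[2]]
    bi <- dd[i, j] / 2 + (r[pick[1]] - r[pick[2]]) / (2 * (nn - 2))
    bj <- dd[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new <- paste0("(", frag[i], ":", fmt(bi), ",", frag[j], ":", fmt(bj), ")")
    key <- paste0("\001", i)
    frag[key] <- new
    rep_id[key] <- min(rep_id[i], rep_id[j])
    dnew <- (d[i, act] + d[j, act] - d[i, j]) / 2
    d <- rbind(cbind(d, 0), 0)
    rownames(d)[nrow(d)] <- colnames(d)[ncol(d)] <- key
    d[key, act] <- dnew; d[act, key] <- dnew; d[key, key] <- 0
    act <- c(setdiff(act, c(i, j)), key)
  }
  if (length(act) == 2L) {
    b <- max(d[act[1], act[2]], 0)
    nwk <- paste0("(", frag[act[1]], ":", fmt(b / 2), ",",
                  frag[act[2]], ":", fmt(b / 2), ");")
  } else {
    a1 <- act[1]; a2 <- act[2]; a3 <- act[3]
    b1 <- (d[a1, a2] + d[a1, a3] - d[a2, a3]) / 2
    b2 <- (d[a1, a2] + d[a2, a3] - d[a1, a3]) / 2
    b3 <- (d[a1, a3] + d[a2, a3] - d[a1, a2]) / 2
    nwk <- paste0("(", frag[a1], ":", fmt(max(b1, 0)), ",",
                  frag[a2], ":", fmt(max(b2, 0)), ",",
                  frag[a3], ":", fmt(max(b3, 0)), ");")
  }
  tr <- ape::read.tree(text = nwk)
  # residual negatives can arise from non-additive noise in the final
  # 3-cluster join; clamp (additive inputs are unaffected)
  tr$edge.length[tr$edge.length < 0] <- 0
  if (identical(root, "midpoint")) {
    if (length(tr$tip.label) > 2L) tr <- phangorn::midpoint(tr)
  } else {
    if (!root %in% tr$tip.label)
      stop("outgroup tip not in tree: ", root, call. = FALSE)
    tr <- ape::root(tr, outgroup = root, resolve.root = TRUE)
  }
  tr
}

#' Read a Newick tree file
#'
#' @param path File containing one Newick string.
#' @return A \code{phylo} tree; internal node names and branch lengths are
#'   preserved.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  if (is.null(tr)) stop("Newick parse error in '", path, "'", call. = FALSE)
  tr
}

#' Write a tree in Newick format
#'
#' @param tree A \code{phylo} tree.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Path-length (patristic) distances between all tips of a tree
#' @param tree A \code{phylo} tree with branch lengths.
#' @return Symmetric matrix of tip-to-tip path lengths.
#' @export
tree_path_distances <- function(tree) ape::cophenetic.phylo(tree)

# Name of the root node (ape convention: node Ntip+1).
root_node_name <- function(tree) {
  if (is.null(tree$node.label) || tree$node.label[1L] == "")
    stop("tree root is unnamed", call. = FALSE)
  tree$node.label[1L]
}
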