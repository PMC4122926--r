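# Synthetic-data generator: deep-clade phylogenies, sequence evolution with
# recorded true ancestors, fishing databases with a distant unknown clade
# and non-homologous decoys, and host scaffolds with embedded viral-like
# genes.  Provides the ground truth against which every downstream stage is
# validated.

clade_names <- function(n_clades) {
  base <- c("A", "B", "E", "V")
  if (n_clades <= 4L) base[seq_len(n_clades)]
  else c(base, paste0("C", seq_len(n_clades - 4L)))
}

# Yule (pure-birth) ultrametric clade of n tips, rescaled to the requested
# root-to-tip depth; tips renamed <clade>1..<clade>n, crown node labeled
# mama-<clade>.
yule_clade <- function(n_tips, depth, clade) {
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  cur <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (depth / cur)
  tr$tip.label <- paste0(clade, seq_len(n_tips))
  tr$node.label <- c(paste0("mama-", clade),
                     paste0(clade, "-n", seq_len(tr$Nnode - 1L)))
  tr
}

#' Simulate a multi-clade phylogeny
#'
#' Builds a rooted binary tree with \code{n_clades} monophyletic clades,
#' each an ultrametric Yule radiation of \code{tips_per_clade} tips with
#' root-to-tip depth \code{crown_depth}, hanging from the global root on a
#' stem of \code{stem_length}.  With more than two clades the root is
#' resolved binarily through zero-length connector edges, so every clade
#' ancestor sits exactly \code{stem_length} below the root.  The root is
#' named \code{"LUCAR-node"} and each clade ancestor \code{"mama-<clade>"};
#' clades are labeled A, B, E, V (then C1, C2, ...).
#'
#' @param n_clades Number of clades (>= 1).
#' @param tips_per_clade Tips per clade (>= 2).
#' @param stem_length Stem branch length, expected substitutions/site.
#' @param crown_depth Root-to-tip depth within each clade.
#' @param seed Optional seed.
#' @return A \code{phylo} tree with attribute \code{"clade_labels"}
#'   (named character vector tip -> clade).
#' @export
simulate_clade_tree <- function(n_clades, tips_per_clade, stem_length,
                                crown_depth, seed = NULL) {
  if (n_clades < 1L || tips_per_clade < 2L)
    stop("need n_clades >= 1 and tips_per_clade >= 2", call. = FALSE)
  if (stem_length <= 0 || crown_depth <= 0)
    stop("branch lengths must be positive", call. = FALSE)
  cl <- clade_names(n_clades)
  with_seed(seed, {
    clades <- lapply(cl, function(x) yule_clade(tips_per_clade,
                                                crown_depth, x))
    if (n_clades == 1L) {
      tr <- clades[[1L]]
      tr$node.label[1L] <- "LUCAR-node"
    } else {
      frags <- vapply(clades, function(x)
        sub(";$", "", ape::write.tree(x)), character(1L))
      fmt <- function(x) formatC(x, digits = 12, format = "g")
      # fold clade stems into a binary comb with zero-length connectors
      cur <- paste0(frags[1L], ":", fmt(stem_length))
      for (k in 2:n_clades) {
        nm <- if (k == n_clades) "LUCAR-node" else paste0("join", k)
        blen <- if (k == n_clades) "" else ":0"
        cur <- paste0("(", cur, ",", frags[k], ":", fmt(stem_length), ")",
                      nm, blen)
      }
      tr <- ape::read.tree(text = paste0(cur, ";"))
    }
    labels <- stats::setNames(rep(cl, each = tips_per_clade),
                              paste0(rep(cl, each = tips_per_clade),
                                     rep(seq_len(tips_per_clade), n_clades)))
    attr(tr, "clade_labels") <- labels[tr$tip.label]
    tr
  })
}

# Evolve one sequence along a branch of length t: per-site draw from the
# parent residue's row of P(t).
evolve_branch <- function(chars, p) {
  idx <- match(chars, AA_ALPHABET20)
  out <- character(length(chars))
  for (s in unique(idx)) {
    w <- idx == s
    out[w] <- sample(AA_ALPHABET20, sum(w), replace = TRUE, prob = p[s, ])
  }
  out
}

#' Evolve sequences along a tree
#'
#' Simulates indel-free protein evolution: the root sequence is drawn from
#' the model's stationary distribution and each child sequence is obtained
#' site-wise from the transition matrix of its branch.  Every node sequence
#' is recorded, so ancestral-reconstruction accuracy can be measured
#' exactly.
#'
#' @param tree A \code{phylo} tree with branch lengths (and, optionally, a
#'   \code{"clade_labels"} attribute from \code{\link{simulate_clade_tree}}).
#' @param model A \code{subst_model}.
#' @param n_sites Number of sites (>= 1).
#' @param seed Optional seed.
#' @return A \code{sim_dataset}: list with \code{tree}, \code{alignment}
#'   (an \code{aa_alignment} of the tips), \code{true_ancestors} (named
#'   character vector, one sequence per named internal node, including the
#'   root and every clade ancestor), and \code{clade_labels}.
#' @export
evolve <- function(tree, model, n_sites, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "subst_model"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths", call. = FALSE)
  if (n_sites < 1L) stop("'n_sites' must be >= 1", call. = FALSE)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  node_seq <- vector("list", n_tip + tree$Nnode)
  with_seed(seed, {
    node_seq[[root]] <- strsplit(sample_stationary(model, n_sites), "")[[1L]]
    edges <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(edges$edge))) {
      par <- edges$edge[e, 1L]; ch <- edges$edge[e, 2L]
      p <- transition_matrix(model, edges$edge.length[e])
      node_seq[[ch]] <- evolve_branch(node_seq[[par]], p)
    }
  })
  tips <- stats::setNames(
    vapply(seq_len(n_tip), function(i) paste(node_seq[[i]], collapse = ""),
           character(1L)), tree$tip.label)
  node_names <- if (is.null(tree$node.label))
    paste0("node", seq_len(tree$Nnode)) else tree$node.label
  anc <- stats::setNames(
    vapply(seq_len(tree$Nnode), function(i)
      paste(node_seq[[n_tip + i]], collapse = ""), character(1L)),
    node_names)
  anc <- anc[names(anc) != ""]
  labels <- attr(tree, "clade_labels")
  structure(list(tree = tree,
                 alignment = aa_alignment(tips, labels = labels),
                 true_ancestors = anc,
                 clade_labels = labels),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated dataset: ", length(x$tree$tip.label), " tips, ",
      ncol(x$alignment$matrix), " sites, ",
      length(x$true_ancestors), " recorded ancestors\n", sep = "")
  invisible(x)
}

#' Build a labeled fishing database
#'
#' Assembles the protein collection searched by the fishing experiment:
#' all extant tip sequences (ungapped, labeled by clade), a distant
#' "unknown" clade of homologs evolved from the recorded true root along an
#' extra stem of \code{distant_stem} (then a shallow Yule radiation of depth
#' \code{unknown_crown}), and i.i.d. stationary decoys labeled
#' \code{"decoy"}.
#'
#' @param dataset A \code{sim_dataset} from \code{\link{evolve}} whose tree
#'   root is named and recorded in \code{true_ancestors}.
#' @param model A \code{subst_model}.
#' @param n_decoys Number of non-homologous decoy sequences (>= 0).
#' @param decoy_length Decoy length in residues.
#' @param distant_stem Stem length from the root to the unknown clade's
#'   ancestor, expected substitutions/site.
#' @param n_unknown Size of the unknown clade (default 6).
#' @param unknown_crown Depth of the unknown clade's radiation (default 0.1).
#' @param seed Optional seed.
#' @return A data.frame with columns \code{id}, \code{taxon}, \code{seq},
#'   with attribute \code{"unknown_ancestor"} (the unknown clade's true
#'   ancestor sequence).
#' @export
make_fishing_database <- function(dataset, model, n_decoys, decoy_length,
                                  distant_stem, n_unknown = 6L,
                                  unknown_crown = 0.1, seed = NULL) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (n_decoys < 0L) stop("'n_decoys' must be >= 0", call. = FALSE)
  root_name <- root_node_name(dataset$tree)
  root_seq <- dataset$true_ancestors[[root_name]]
  labels <- dataset$clade_labels
  tips <- aln_strings(dataset$alignment)
  with_seed(seed, {
    p <- transition_matrix(model, distant_stem)
    unk_anc <- evolve_branch(strsplit(root_seq, "")[[1L]], p)
    unk_tree <- yule_clade(n_unknown, unknown_crown, "U")
    # evolve the radiation from the unknown ancestor, not a stationary root
    seqs <- vector("list", n_unknown + unk_tree$Nnode)
    seqs[[n_unknown + 1L]] <- unk_anc
    ed <- ape::reorder.phylo(unk_tree, "cladewise")
    for (e in seq_len(nrow(ed$edge))) {
      pm <- transition_matrix(model, ed$edge.length[e])
      seqs[[ed$edge[e, 2L]]] <- evolve_branch(seqs[[ed$edge[e, 1L]]], pm)
    }
    unknown <- vapply(seq_len(n_unknown),
                      function(i) paste(seqs[[i]], collapse = ""),
                      character(1L))
    decoys <- vapply(seq_len(n_decoys),
                     function(i) sample_stationary(model, decoy_length),
                     character(1L))
    db <- data.frame(
      id = c(names(tips), paste0("unknown", seq_len(n_unknown)),
             if (n_decoys > 0L) paste0("decoy", seq_len(n_decoys))),
      taxon = c(unname(labels[names(tips)]), rep("unknown", n_unknown),
                rep("decoy", n_decoys)),
      seq = c(gsub("-", "", tips, fixed = TRUE), unknown, decoys),
      stringsAsFactors = FALSE)
    attr(db, "unknown_ancestor") <- paste(unk_anc, collapse = "")
    db
  })
}

#' Write a labeled protein database as FASTA
#'
#' Headers carry the taxon label as \code{"id|taxon"}.
#'
#' @param db Data frame with columns \code{id}, \code{taxon}, \code{seq}.
#' @param path Output file.
#' @export
write_database_fasta <- function(db, path) {
  write_fasta(stats::setNames(db$seq, paste0(db$id, "|", db$taxon)), path)
}

#' Read a labeled protein database from FASTA
#'
#' @param path FASTA with \code{"id|taxon"} headers; missing taxon fields
#'   become \code{"unlabeled"}.
#' @return Data frame with columns \code{id}, \code{taxon}, \code{seq}.
#' @export
read_database_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  hdr <- sub("\\s.*$", "", names(set))
  parts <- strsplit(hdr, "|", fixed = TRUE)
  data.frame(
    id = unname(vapply(parts, `[`, character(1L), 1L)),
    taxon = unname(vapply(parts, function(x)
      if (length(x) > 1L) x[2L] else "unlabeled", character(1L))),
    seq = unname(toupper(as.character(set))),
    stringsAsFactors = FALSE, row.names = NULL)
}

# ---- host scaffold with embedded genes --------------------------------

CODON_TABLE <- Biostrings::GENETIC_CODE
STOP_CODONS <- names(CODON_TABLE)[CODON_TABLE == "*"]

# one uniformly chosen sense codon per residue
reverse_translate <- function(protein) {
  res <- strsplit(protein, "")[[1L]]
  vapply(res, function(a) {
    cands <- names(CODON_TABLE)[CODON_TABLE == a]
    cands[sample.int(length(cands), 1L)]
  }, character(1L), USE.NAMES = FALSE)
}

mutate_protein <- function(protein, rate) {
  res <- strsplit(protein, "")[[1L]]
  hit <- which(stats::runif(length(res)) < rate)
  hit <- hit[hit > 1L]                     # keep the initial M
  res[hit] <- sample(AA_ALPHABET20, length(hit), replace = TRUE)
  paste(res, collapse = "")
}

# Spacer with stop codons in all six frames and no G (hence no ATG on
# either strand): "TAAA" repeats, whose reverse complement is itself a
# "TAAA" repeat after the leading Ts.
SPACER <- paste(c(rep("TAAA", 6L), rep("TTTA", 6L)), collapse = "")

#' Synthesize a host DNA scaffold with embedded viral-like genes
#'
#' Emulates a eukaryotic assembly scaffold that accidentally carries genes
#' from a co-sequenced virus: \code{host_genes} members of a "host" protein
#' family and \code{viral_genes} members of a distinct "viral" family
#' (each family = point-mutated copies of its own random seed protein) are
#' reverse-translated with uniformly random synonymous codons, terminated
#' with a stop codon, placed on alternating strands, and separated by
#' spacers containing stops in all six reading frames.  The true source and
#' coordinates of every gene are returned.
#'
#' @param host_genes,viral_genes Gene counts (>= 0).
#' @param gene_length_aa Protein length per gene (>= 100), including the
#'   initial methionine.
#' @param mutation_rate Per-site substitution probability within a family
#'   (default 0.08).
#' @param seed Optional seed.
#' @return A list: \code{scaffold} (DNA string) and \code{genes} (data.frame
#'   with \code{id}, \code{source}, \code{strand}, \code{start}, \code{end}
#'   -- 1-based inclusive forward-axis coordinates covering start codon
#'   through stop codon -- and \code{protein}).
#' @export
make_host_scaffold <- function(host_genes, viral_genes, gene_length_aa,
                               mutation_rate = 0.08, seed = NULL) {
  if (host_genes < 0L || viral_genes < 0L)
    stop("gene counts must be >= 0", call. = FALSE)
  if (gene_length_aa < 100L)
    stop("'gene_length_aa' must be >= 100", call. = FALSE)
  with_seed(seed, {
    model <- build_wag()
    fam_seed <- function() paste0("M", sample_stationary(
      model, gene_length_aa - 1L))
    host_fam <- fam_seed(); viral_fam <- fam_seed()
    src <- c(rep("host", host_genes), rep("viral", viral_genes))
    prots <- vapply(src, function(s)
      mutate_protein(if (s == "host") host_fam else viral_fam,
                     mutation_rate), character(1L), USE.NAMES = FALSE)
    chunks <- SPACER
    rows <- vector("list", length(src))
    pos <- nchar(SPACER)
    for (g in seq_along(src)) {
      dna <- paste(c(reverse_translate(prots[g]),
                     STOP_CODONS[sample.int(3L, 1L)]), collapse = "")
      strand <- if (g %% 2L == 0L) "-" else "+"
      if (strand == "-") dna <- revcomp(dna)
      rows[[g]] <- data.frame(
        id = paste0("gene", g), source = src[g], strand = strand,
        start = pos + 1L, end = pos + nchar(dna),
        protein = prots[g], stringsAsFactors = FALSE)
      chunks <- c(chunks, dna, SPACER)
      pos <- pos + nchar(dna) + nchar(SPACER)
    }
    list(scaffold = paste(chunks, collapse = ""),
         genes = do.call(rbind, rows))
  })
}

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Write a gene coordinate table as TSV
#'
#' @param genes Gene table from \code{\link{make_host_scaffold}} or
#'   \code{\link{orf_finder}} (1-based inclusive coordinates).
#' @param path Output file.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
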