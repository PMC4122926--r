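# Orchestration of the two end-to-end experiments: ancestor distance
# reduction and ancestor-probe fishing.  One global seed is fanned out to
# per-stage child seeds so stages can be re-run in isolation.

#' Pipeline configuration
#'
#' Collects all simulation, trimming, tree, reconstruction and fishing
#' settings of the two experiments.  Defaults emulate the study design: a
#' 420-column protein alignment over four deeply diverged clades (stems of
#' 1.0 expected substitutions/site, crown radiations of depth 0.5, 12 tips
#' per clade), an unknown clade hanging 1.5 substitutions/site below the
#' root, and 20 non-homologous decoys.
#'
#' @param seed Global seed (integer).
#' @param n_clades,tips_per_clade,n_sites,stem_length,crown_depth
#'   Simulation shape; see \code{\link{simulate_clade_tree}} and
#'   \code{\link{evolve}}.
#' @param distant_stem,n_unknown,n_decoys,decoy_length Fishing database
#'   shape; see \code{\link{make_fishing_database}}.
#' @param n_gap_blocks,gap_block_len Optional gap corruption applied before
#'   trimming (0 blocks = skip).
#' @param gap_threshold Manual trimming cutoff (NULL = automatic).
#' @param tree_source \code{"infer"} (neighbor joining on ML distances,
#'   midpoint-rooted), \code{"true"} (the simulated tree), or
#'   \code{"file"}.
#' @param tree_file Newick file when \code{tree_source = "file"}.
#' @param root \code{"midpoint"} or a tip id, for inferred trees.
#' @param lucar_mode Root-ancestor mode, \code{"root"} or \code{"star"};
#'   see \code{\link{reconstruct_lucar}}.
#' @param min_posterior Mask ancestor MAP sites below this posterior to
#'   \code{'X'} when used as probes (default 0).
#' @param fishing A \code{\link{fishing_config}}.
#' @param out_dir Output directory (NULL = return results only).
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(seed = 1L, n_clades = 4L, tips_per_clade = 12L,
                            n_sites = 420L, stem_length = 1.0,
                            crown_depth = 0.5, distant_stem = 1.5,
                            n_unknown = 6L, n_decoys = 20L,
                            decoy_length = 420L, n_gap_blocks = 0L,
                            gap_block_len = 30L, gap_threshold = NULL,
                            tree_source = c("infer", "true", "file"),
                            tree_file = NULL, root = "midpoint",
                            lucar_mode = c("root", "star"),
                            min_posterior = 0,
                            fishing = fishing_config(), out_dir = NULL) {
  structure(list(seed = as.integer(seed), n_clades = n_clades,
                 tips_per_clade = tips_per_clade, n_sites = n_sites,
                 stem_length = stem_length, crown_depth = crown_depth,
                 distant_stem = distant_stem, n_unknown = n_unknown,
                 n_decoys = n_decoys, decoy_length = decoy_length,
                 n_gap_blocks = n_gap_blocks,
                 gap_block_len = gap_block_len,
                 gap_threshold = gap_threshold,
                 tree_source = match.arg(tree_source),
                 tree_file = tree_file, root = root,
                 lucar_mode = match.arg(lucar_mode),
                 min_posterior = min_posterior, fishing = fishing,
                 out_dir = out_dir),
            class = "pipeline_config")
}

echo_config <- function(cfg, dir) {
  x <- unclass(cfg)
  x$fishing <- unclass(x$fishing)
  yaml::write_yaml(x, file.path(dir, "config.yaml"))
}

# simulate -> (corrupt + trim) -> tree -> ASR; shared by both experiments.
prepare_stages <- function(cfg, model) {
  tree0 <- simulate_clade_tree(cfg$n_clades, cfg$tips_per_clade,
                               cfg$stem_length, cfg$crown_depth,
                               seed = child_seed(cfg$seed, 1L))
  ds <- evolve(tree0, model, cfg$n_sites, seed = child_seed(cfg$seed, 2L))
  aln <- ds$alignment
  trim_report <- NULL
  if (cfg$n_gap_blocks > 0L) {
    aln <- corrupt_with_gaps(aln, cfg$n_gap_blocks, cfg$gap_block_len,
                             seed = child_seed(cfg$seed, 3L))
    tr <- gappyout_trim(aln, gap_threshold = cfg$gap_threshold)
    aln <- tr$alignment
    trim_report <- tr
  }
  tree <- switch(cfg$tree_source,
    infer = neighbor_joining(ml_distance_matrix(aln, model),
                             root = cfg$root),
    true = ds$tree,
    file = read_newick(cfg$tree_file))
  labels <- ds$clade_labels
  mamas <- reconstruct_mamas(tree, aln, model, labels)
  lucar <- reconstruct_lucar(tree, aln, model, mode = cfg$lucar_mode,
                             clade_labels = labels)
  list(dataset = ds, alignment = aln, trim = trim_report, tree = tree,
       labels = labels, mamas = mamas, lucar = lucar)
}

masked_map <- function(profile, min_posterior) {
  s <- strsplit(profile$map_sequence, "")[[1L]]
  s[apply(profile$posteriors, 1L, max) < min_posterior] <- "X"
  paste(s, collapse = "")
}

#' One replicate of the combined ancestor study
#'
#' Runs both experiment measurements on one simulated dataset: the
#' distance-reduction comparison (per-clade means and Mann-Whitney
#' p-values) and the fishing sensitivity comparison (unknown-clade members
#' passing the stringent filters under the root-ancestor probe versus
#' under every extant probe, decoy false positives under the root-ancestor
#' probe, and worst unknown-clade E-values).  Extant probes are aligned
#' against the unknown clade only, with the E-value database size held at
#' the full database's residue count, which leaves their E-values and
#' detection counts identical to a full-database search.  Ancestor accuracy
#' is measured against the simulation's recorded true ancestors.
#'
#' @param seed Replicate seed.
#' @param cfg A \code{\link{pipeline_config}}; its seed is replaced by
#'   \code{seed}.
#' @return A list of per-replicate measurements.
#' @export
study_replicate <- function(seed, cfg = pipeline_config()) {
  cfg$seed <- as.integer(seed)
  cfg$out_dir <- NULL
  model <- build_wag()
  st <- prepare_stages(cfg, model)
  anc_seqs <- c(
    stats::setNames(
      vapply(st$mamas, `[[`, character(1L), "map_sequence"),
      paste0("mama-", names(st$mamas))),
    LUCAR = st$lucar$map_sequence)
  combined <- aa_alignment(c(aln_strings(st$alignment), anc_seqs),
                           labels = st$labels)
  comp <- compare_distances(combined, st$labels)
  direction_ok <- vapply(comp, function(x)
    x$mean_anc_member < x$mean_member_member, logical(1L))
  mw_p <- vapply(comp, `[[`, 1, "p_value")

  db <- make_fishing_database(st$dataset, model, cfg$n_decoys,
                              cfg$decoy_length, cfg$distant_stem,
                              n_unknown = cfg$n_unknown,
                              seed = child_seed(cfg$seed, 4L))
  lucar_probe <- masked_map(st$lucar, cfg$min_posterior)
  lres <- fish(lucar_probe, db, cfg$fishing, probe_id = "LUCAR")
  lucar_count <- sum(lres$hits$target_taxon == "unknown")
  decoy_fp <- sum(lres$hits$target_taxon == "decoy")
  lucar_unk <- lres$unfiltered[lres$unfiltered$target_taxon == "unknown", ]
  sub_cfg <- cfg$fishing
  sub_cfg$db_size <- sum(nchar(db$seq))
  unk_db <- db[db$taxon == "unknown", , drop = FALSE]
  tips <- gsub("-", "", aln_strings(st$dataset$alignment), fixed = TRUE)
  extant <- vapply(names(tips), function(tid) {
    r <- fish(tips[[tid]], unk_db, sub_cfg, probe_id = tid)
    c(count = sum(r$hits$target_taxon == "unknown"),
      worst_e = max(r$unfiltered$e_value))
  }, c(count = 0, worst_e = 0))
  true_anc <- st$dataset$true_ancestors
  mama_acc <- vapply(names(st$mamas), function(cl)
    1 - p_distance(st$mamas[[cl]]$map_sequence,
                   true_anc[[paste0("mama-", cl)]]), 1)
  list(direction_ok = direction_ok,
       mw_p = mw_p,
       lucar_count = lucar_count,
       extant_counts = unname(extant["count", ]),
       median_extant_count = stats::median(extant["count", ]),
       decoy_fp = decoy_fp,
       lucar_worst_unknown_e = max(lucar_unk$e_value),
       median_extant_worst_e = stats::median(extant["worst_e", ]),
       lucar_unknown_ranks = sort(lucar_unk$rank),
       mama_accuracy = mama_acc,
       lucar_accuracy = 1 - p_distance(st$lucar$map_sequence,
                                       true_anc[[root_node_name(
                                         st$dataset$tree)]]))
}

#' Run the ancestor distance-reduction experiment
#'
#' Simulates the multi-clade dataset, optionally corrupts and trims the
#' alignment, builds (or loads) the tree, reconstructs the clade ancestors
#' and the root ancestor, and compares ancestor-to-member against
#' member-to-member p-distances per clade, with percentile profiles and a
#' classical MDS embedding.  All artifacts are written to
#' \code{cfg$out_dir} when set.
#'
#' @param cfg A \code{\link{pipeline_config}}.
#' @return A list: \code{comparisons}, \code{table}, \code{percentiles},
#'   \code{mds}, \code{bonferroni}, \code{mamas}, \code{lucar},
#'   \code{tree}, \code{dataset}.
#' @export
run_distance_experiment <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  model <- build_wag()
  st <- prepare_stages(cfg, model)
  anc_seqs <- c(
    stats::setNames(
      vapply(st$mamas, `[[`, character(1L), "map_sequence"),
      paste0("mama-", names(st$mamas))),
    LUCAR = st$lucar$map_sequence)
  combined <- aa_alignment(c(aln_strings(st$alignment), anc_seqs),
                           labels = st$labels)
  comp <- compare_distances(combined, st$labels)
  tab <- comparison_table(comp)
  sets <- list(
    anc_member = unlist(lapply(comp, `[[`, "anc_member")),
    member_member = unlist(lapply(comp, `[[`, "member_member")))
  lm <- unlist(lapply(comp, `[[`, "lucar_member"))
  if (length(lm) > 0L) sets$lucar_member <- lm
  pct <- percentile_profile(sets)
  mds <- classical_mds(p_distance_matrix(combined), k = 2L)
  bonf <- bonferroni_threshold(0.05, max(length(comp), 1L))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    echo_config(cfg, cfg$out_dir)
    write_fasta(combined, file.path(cfg$out_dir, "alignment.fasta"))
    write_newick(st$tree, file.path(cfg$out_dir, "tree.nwk"))
    write_ancestors(c(st$mamas, list(st$lucar)),
                    fasta_path = file.path(cfg$out_dir, "ancestors.fasta"),
                    table_path = file.path(cfg$out_dir, "posteriors.tsv"),
                    min_posterior = cfg$min_posterior)
    utils::write.table(tab, file.path(cfg$out_dir, "comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pct, file.path(cfg$out_dir, "percentiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(id = rownames(mds), round(mds, 6)),
      file.path(cfg$out_dir, "mds.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(comparisons = comp, table = tab, percentiles = pct,
                 mds = mds, bonferroni = bonf, mamas = st$mamas,
                 lucar = st$lucar, tree = st$tree, dataset = st$dataset))
}

#' Run the ancestor-probe fishing experiment
#'
#' Simulates the dataset and a fishing database (extant tips, a distant
#' unknown clade, stationary decoys), reconstructs ancestor probes, then
#' fishes the database with the root-ancestor probe and with every extant
#' tip, reporting per-probe counts of detected unknown-clade members and
#' decoy false positives, plus the unfiltered ranks of every unknown-clade
#' member under the root-ancestor probe.
#'
#' @param cfg A \code{\link{pipeline_config}}.
#' @return A list: \code{report} (per-probe data.frame),
#'   \code{lucar_result} (\code{fishing_result}), \code{unknown_ranks},
#'   \code{db}, \code{lucar_probe}, \code{tree}, \code{dataset}.
#' @export
run_fishing_experiment <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  model <- build_wag()
  st <- prepare_stages(cfg, model)
  db <- make_fishing_database(st$dataset, model, cfg$n_decoys,
                              cfg$decoy_length, cfg$distant_stem,
                              n_unknown = cfg$n_unknown,
                              seed = child_seed(cfg$seed, 4L))
  lucar_probe <- masked_map(st$lucar, cfg$min_posterior)
  tips <- gsub("-", "", aln_strings(st$dataset$alignment), fixed = TRUE)
  probes <- c(stats::setNames(list(lucar_probe), "LUCAR"), as.list(tips))
  rows <- vector("list", length(probes))
  lucar_result <- NULL
  for (i in seq_along(probes)) {
    pid <- names(probes)[i]
    res <- fish(probes[[i]], db, cfg$fishing, probe_id = pid)
    if (pid == "LUCAR") lucar_result <- res
    rows[[i]] <- data.frame(
      probe = pid,
      n_unknown_detected = sum(res$hits$target_taxon == "unknown"),
      n_decoy_fp = sum(res$hits$target_taxon == "decoy"),
      n_hits = nrow(res$hits), stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  unk <- lucar_result$unfiltered[
    lucar_result$unfiltered$target_taxon == "unknown", , drop = FALSE]
  extant <- report$n_unknown_detected[report$probe != "LUCAR"]
  summary <- list(
    lucar_detected = report$n_unknown_detected[report$probe == "LUCAR"],
    median_extant_detected = stats::median(extant),
    decoy_false_positives = sum(report$n_decoy_fp))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    echo_config(cfg, cfg$out_dir)
    write_database_fasta(db, file.path(cfg$out_dir, "database.fasta"))
    write_fasta(c(LUCAR = lucar_probe),
                file.path(cfg$out_dir, "lucar_probe.fasta"))
    write_hit_table(lucar_result$hits,
                    file.path(cfg$out_dir, "lucar_hits.tsv"))
    write_hit_table(lucar_result$unfiltered,
                    file.path(cfg$out_dir, "lucar_hits_unfiltered.tsv"))
    utils::write.table(report, file.path(cfg$out_dir, "probe_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_hit_table(unk, file.path(cfg$out_dir, "unknown_ranks.tsv"))
  }
  invisible(list(report = report, summary = summary,
                 lucar_result = lucar_result, unknown_ranks = unk,
                 db = db, lucar_probe = lucar_probe, tree = st$tree,
                 dataset = st$dataset))
}
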