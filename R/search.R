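# Homology fishing and classification: affine-gap local alignment with
# Karlin-Altschul E-values, threshold filtering, best-hit taxonomic
# classification, taxon exclusion, and six-frame ORF finding.

# Published gapped Karlin-Altschul parameters per scoring scheme.
KA_PARAMS <- list(
  "BLOSUM62/11/1" = c(lambda = 0.267, K = 0.041),
  "BLOSUM62/0/0"  = c(lambda = 0.3176, K = 0.134),   # ungapped
  "BLOSUM50/13/2" = c(lambda = 0.212, K = 0.021)
)

ka_lookup <- function(matrix_name, gap_open, gap_extend) {
  key <- paste(matrix_name, gap_open, gap_extend, sep = "/")
  p <- KA_PARAMS[[key]]
  if (is.null(p))
    stop("no Karlin-Altschul parameters tabulated for ", key,
         "; supply 'lambda' and 'K' explicitly", call. = FALSE)
  p
}

# Residue scoring matrix; X optionally neutralized to 0 so that
# posterior-masked probe sites neither reward nor penalize.
scoring_matrix <- function(name = "BLOSUM62", x_neutral = TRUE) {
  mat <- switch(name,
    BLOSUM62 = get_blosum("BLOSUM62"),
    BLOSUM50 = get_blosum("BLOSUM50"),
    stop("unknown scoring matrix: ", name, call. = FALSE))
  if (x_neutral) {
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
  }
  mat
}

get_blosum <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

#' Fishing configuration
#'
#' Thresholds and scoring parameters for \code{\link{fish}} and
#' \code{\link{best_hit_classify}}.  Defaults are the stringent filters of
#' the probe-fishing protocol: at least 70 percent query coverage, E-value
#' at most 1e-10, targets longer than 400 residues, BLOSUM62 with gap
#' open 11 / extend 1.
#'
#' @param min_coverage Minimum fraction of the query covered by the local
#'   alignment, in (0, 1].
#' @param max_evalue Maximum E-value.
#' @param min_target_len Targets must be strictly longer than this.
#' @param matrix Scoring matrix name ("BLOSUM62" or "BLOSUM50").
#' @param gap_open,gap_extend Affine gap penalties (a length-k gap costs
#'   \code{gap_open + k * gap_extend}).
#' @param db_size Database size in residues for E-values; default (NULL)
#'   uses the total residue count of the searched database.
#' @param lambda,K Karlin-Altschul parameters; default looks them up from
#'   the published table for the scoring scheme.
#' @return A \code{fishing_config} list.
#' @export
fishing_config <- function(min_coverage = 0.70, max_evalue = 1e-10,
                           min_target_len = 400L, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1, db_size = NULL,
                           lambda = NULL, K = NULL) {
  if (min_coverage <= 0 || min_coverage > 1)
    stop("'min_coverage' must be in (0, 1]", call. = FALSE)
  if (max_evalue <= 0 || min_target_len < 0)
    stop("thresholds must be positive", call. = FALSE)
  if (is.null(lambda) || is.null(K)) {
    p <- ka_lookup(matrix, gap_open, gap_extend)
    if (is.null(lambda)) lambda <- unname(p["lambda"])
    if (is.null(K)) K <- unname(p["K"])
  }
  structure(list(min_coverage = min_coverage, max_evalue = max_evalue,
                 min_target_len = min_target_len, matrix = matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 db_size = db_size, lambda = lambda, K = K),
            class = "fishing_config")
}

# 128 x 128 score lookup indexed by ASCII code, built from the named
# scoring matrix; characters outside the matrix alphabet score as 'X'
# (neutral 0).
score_lookup <- function(name = "BLOSUM62", x_neutral = TRUE) {
  mat <- scoring_matrix(name, x_neutral = x_neutral)
  lk <- matrix(0, 128L, 128L)
  codes <- utf8ToInt(paste(rownames(mat), collapse = ""))
  lk[codes + 1L, codes + 1L] <- mat
  lk
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Optimal local alignment of two ungapped protein sequences under affine
#' gap penalties, by the Gotoh dynamic program (compiled); a gap of length
#' k costs \code{gap_open + k * gap_extend}.  Unknown residues score
#' through the \code{'X'} row of the matrix, which is neutralized to 0.
#' If no segment pair scores positively the result is an empty alignment
#' with score 0.
#'
#' @param query,target Ungapped protein sequences.
#' @param matrix Scoring matrix name ("BLOSUM62" or "BLOSUM50").
#' @param gap_open,gap_extend Affine gap penalties.
#' @return A list: \code{raw_score}, \code{identity} (fraction over
#'   aligned columns), \code{aln_len}, \code{n_ident}, \code{mismatch},
#'   \code{gap_openings}, \code{q_start}, \code{q_end}, \code{t_start},
#'   \code{t_end} (1-based inclusive), \code{q_aln}, \code{t_aln}
#'   (aligned strings).
#' @export
smith_waterman <- function(query, target, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1) {
  if (nchar(query) == 0L || nchar(target) == 0L)
    stop("sequences must be non-empty", call. = FALSE)
  lk <- score_lookup(matrix)
  r <- .gotoh_pair_strings(query, target, lk, gap_open, gap_extend)
  if (r$score <= 0)
    return(list(raw_score = 0, identity = NA_real_, aln_len = 0L,
                n_ident = 0L, mismatch = 0L, gap_openings = 0L,
                q_start = 0L, q_end = 0L, t_start = 0L, t_end = 0L,
                q_aln = "", t_aln = ""))
  qc <- strsplit(r$q_aln, "")[[1L]]
  tc <- strsplit(r$t_aln, "")[[1L]]
  gaps <- qc == "-" | tc == "-"
  list(raw_score = r$score,
       identity = sum(qc == tc & !gaps) / length(qc),
       aln_len = length(qc),
       n_ident = sum(qc == tc & !gaps),
       mismatch = sum(!gaps & qc != tc),
       gap_openings = sum(diff(c(FALSE, gaps)) == 1L),
       q_start = r$q_start, q_end = r$q_end,
       t_start = r$t_start, t_end = r$t_end,
       q_aln = r$q_aln, t_aln = r$t_aln)
}

#' Bit score and Karlin-Altschul E-value
#'
#' \code{bit = (lambda * S - ln K) / ln 2}; \code{E = m * n * 2^(-bit)}.
#'
#' @param raw_score Raw alignment score S.
#' @param query_len,db_len Query length m and database size n, residues.
#' @param lambda,K Karlin-Altschul parameters (defaults: gapped
#'   BLOSUM62/11/1).
#' @return A list: \code{bit_score}, \code{e_value}.
#' @export
evalue <- function(raw_score, query_len, db_len, lambda = 0.267,
                   K = 0.041) {
  if (query_len <= 0 || db_len <= 0 || lambda <= 0 || K <= 0)
    stop("lengths and parameters must be positive", call. = FALSE)
  bit <- (lambda * raw_score - log(K)) / log(2)
  list(bit_score = bit, e_value = query_len * db_len * 2^(-bit))
}

# Align one probe against every database sequence in one vectorized call;
# returns the full (unfiltered) ranked hit table.
align_probe <- function(probe, probe_id, db, cfg) {
  lk <- score_lookup(cfg$matrix)
  res <- .gotoh_batch(probe, db$seq, lk, cfg$gap_open, cfg$gap_extend)
  qlen <- nchar(probe)
  n_db <- if (is.null(cfg$db_size)) sum(nchar(db$seq)) else cfg$db_size
  ev <- evalue(res[, "raw_score"], qlen, n_db, cfg$lambda, cfg$K)
  hits <- data.frame(
    query_id = probe_id,
    target_id = db$id,
    target_taxon = db$taxon,
    raw_score = res[, "raw_score"],
    bit_score = ev$bit_score,
    e_value = ev$e_value,
    identity = ifelse(res[, "aln_len"] > 0,
                      res[, "n_ident"] / res[, "aln_len"], NA_real_),
    aln_len = as.integer(res[, "aln_len"]),
    mismatch = as.integer(res[, "mismatch"]),
    gap_openings = as.integer(res[, "gap_openings"]),
    q_start = as.integer(res[, "q_start"]),
    q_end = as.integer(res[, "q_end"]),
    t_start = as.integer(res[, "t_start"]),
    t_end = as.integer(res[, "t_end"]),
    target_len = nchar(db$seq),
    stringsAsFactors = FALSE)
  hits$q_coverage <- ifelse(hits$aln_len == 0L, 0,
                            (hits$q_end - hits$q_start + 1L) / qlen)
  ord <- order(hits$e_value, -hits$bit_score, hits$target_id)
  hits <- hits[ord, , drop = FALSE]
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  hits
}

#' Fish for homologs with a probe sequence
#'
#' Aligns the probe against every database sequence and applies the
#' stringent filters (E-value, query coverage, minimum target length).  All
#' pre-filter hits are retained, ranked by ascending E-value (then
#' descending bit score, then target id), so the rank of any target among
#' the raw results can be reported.
#'
#' @param probe Ungapped probe sequence (masked \code{'X'} sites allowed).
#' @param db Labeled database: data.frame with columns \code{id},
#'   \code{taxon}, \code{seq}.
#' @param cfg A \code{\link{fishing_config}}.
#' @param probe_id Query id recorded in the hit tables.
#' @return A list of class \code{fishing_result}: \code{hits} (filtered)
#'   and \code{unfiltered} (all targets, ranked).
#' @export
fish <- function(probe, db, cfg = fishing_config(), probe_id = "probe") {
  if (is.null(db) || nrow(db) == 0L)
    stop("empty database", call. = FALSE)
  all_hits <- align_probe(probe, probe_id, db, cfg)
  keep <- all_hits$e_value <= cfg$max_evalue &
    all_hits$q_coverage >= cfg$min_coverage &
    all_hits$target_len > cfg$min_target_len
  structure(list(hits = all_hits[keep, , drop = FALSE],
                 unfiltered = all_hits, config = cfg),
            class = "fishing_result")
}

#' @export
print.fishing_result <- function(x, ...) {
  cat("Fishing result: ", nrow(x$hits), " of ", nrow(x$unfiltered),
      " targets pass filters (cov >= ", x$config$min_coverage,
      ", E <= ", format(x$config$max_evalue),
      ", len > ", x$config$min_target_len, ")\n", sep = "")
  invisible(x)
}

#' Best-hit taxonomic classification
#'
#' Classifies each protein by the taxon label of its best database hit
#' (lowest E-value; ties broken by target id), and flags whether a taxon of
#' interest occurs at any rank among the top \code{top_n} hits.  Proteins
#' with no hit at or below \code{cfg$max_evalue} are labeled
#' \code{"unclassified"}.
#'
#' @param proteins Named character vector of protein sequences.
#' @param reference_db Labeled reference database (\code{id}, \code{taxon},
#'   \code{seq}).
#' @param cfg A \code{\link{fishing_config}}; classification defaults relax
#'   the fishing filters (E <= 1e-3, no coverage or length filter).
#' @param top_n Window for the any-rank flag (default 20).
#' @return A list: \code{assignments} (data.frame protein, best_label,
#'   best_evalue, top labels comma-joined) and \code{counts} (table of
#'   best-hit labels).
#' @export
best_hit_classify <- function(proteins, reference_db,
                              cfg = fishing_config(min_coverage = 1e-9,
                                                   max_evalue = 1e-3,
                                                   min_target_len = 0L),
                              top_n = 20L) {
  if (is.null(names(proteins)))
    names(proteins) <- paste0("protein", seq_along(proteins))
  rows <- lapply(names(proteins), function(pid) {
    res <- fish(proteins[[pid]], reference_db, cfg, probe_id = pid)
    h <- res$hits
    if (nrow(h) == 0L)
      return(data.frame(protein = pid, best_label = "unclassified",
                        best_evalue = NA_real_, top_labels = "",
                        stringsAsFactors = FALSE))
    top <- utils::head(h, top_n)
    data.frame(protein = pid, best_label = h$target_taxon[1L],
               best_evalue = h$e_value[1L],
               top_labels = paste(unique(top$target_taxon),
                                  collapse = ","),
               stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  list(assignments = assignments,
       counts = table(assignments$best_label))
}

#' Filter hits by excluded taxa
#'
#' @param hits Hit table (data.frame with a \code{target_taxon} column).
#' @param excluded_taxa Character vector of taxon labels to drop.
#' @return The hit table without excluded taxa, order preserved.
#' @export
taxon_filter <- function(hits, excluded_taxa) {
  hits[!(hits$target_taxon %in% excluded_taxa), , drop = FALSE]
}

#' Six-frame open reading frame finder
#'
#' Scans all six reading frames of a DNA sequence.  An ORF runs from the
#' first ATG after the previous in-frame stop to the next in-frame stop
#' codon; only ORFs whose protein (start codon included, stop excluded) has
#' at least \code{min_len_aa} residues are reported.  ORFs lacking an
#' in-frame stop before the sequence end are not reported.  Coordinates are
#' 1-based inclusive on the forward strand and cover start codon through
#' stop codon; reverse-strand ORFs carry strand \code{"-"}.  Codons
#' containing \code{'N'} translate to \code{'X'}.
#'
#' @param dna DNA string over A, C, G, T, N.
#' @param min_len_aa Minimum protein length (default 100).
#' @return Data frame: \code{protein}, \code{frame} (1-3 within strand),
#'   \code{strand}, \code{start}, \code{end}, \code{length_aa}.
#' @export
orf_finder <- function(dna, min_len_aa = 100L) {
  dna <- toupper(dna)
  if (grepl("[^ACGTN]", dna))
    stop("DNA sequence contains characters other than A, C, G, T, N",
         call. = FALSE)
  len <- nchar(dna)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else revcomp(dna)
    chars <- strsplit(s, "")[[1L]]
    for (off in 0:2) {
      n_codon <- (len - off) %/% 3L
      if (n_codon < 2L) next
      starts <- off + 1L + 3L * (seq_len(n_codon) - 1L)
      codons <- substring(s, starts, starts + 2L)
      aa <- unname(CODON_TABLE[codons])
      aa[is.na(aa)] <- "X"
      is_stop <- codons %in% STOP_CODONS
      is_atg <- codons == "ATG"
      seg_start <- 1L
      stops <- which(is_stop)
      for (st in stops) {
        cand <- which(is_atg[seg_start:(st - 1L)])
        if (st > seg_start && length(cand) > 0L) {
          a <- seg_start + cand[1L] - 1L
          n_aa <- st - a
          if (n_aa >= min_len_aa) {
            p1 <- starts[a]; p2 <- starts[st] + 2L   # strand-local coords
            out[[length(out) + 1L]] <- data.frame(
              protein = paste(aa[a:(st - 1L)], collapse = ""),
              frame = off + 1L, strand = strand,
              start = if (strand == "+") p1 else len - p2 + 1L,
              end = if (strand == "+") p2 else len - p1 + 1L,
              length_aa = n_aa, stringsAsFactors = FALSE)
          }
        }
        seg_start <- st + 1L
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(protein = character(), frame = integer(),
                      strand = character(), start = integer(),
                      end = integer(), length_aa = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Write a hit table in tabular BLAST-compatible TSV
#'
#' Columns follow the conventional 12-column tabular output (qseqid,
#' sseqid, pident as a 0-100 percentage, length, mismatch, gapopen, qstart,
#' qend, sstart, send, evalue, bitscore) plus \code{taxon}, \code{qcov} and
#' \code{rank}.
#'
#' @param hits Hit table from \code{\link{fish}} (either element).
#' @param path Output file.
#' @export
write_hit_table <- function(hits, path) {
  tab <- data.frame(
    qseqid = hits$query_id, sseqid = hits$target_id,
    pident = round(100 * hits$identity, 2), length = hits$aln_len,
    mismatch = hits$mismatch, gapopen = hits$gap_openings,
    qstart = hits$q_start, qend = hits$q_end,
    sstart = hits$t_start, send = hits$t_end,
    evalue = format(hits$e_value, digits = 3),
    bitscore = round(hits$bit_score, 1),
    taxon = hits$target_taxon, qcov = round(hits$q_coverage, 3),
    rank = hits$rank, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
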