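# Aligned protein sequences with gap characters, column addressable.
# Internal representation: a character matrix (rows = sequences, columns =
# alignment columns) plus an optional id -> clade label map.  Column indices
# are 0-based nowhere: everything user-visible is 1-based.

VALID_CHARS <- c(AA_ALPHABET20, "-", "X")

#' Construct an alignment object
#'
#' @param seqs Named character vector of equal-length gapped sequences
#'   (residues, \code{'-'} gaps, \code{'X'} unknowns).
#' @param labels Optional named character vector mapping sequence ids to
#'   clade labels.
#' @return An object of class \code{aa_alignment}.
#' @export
aa_alignment <- function(seqs, labels = NULL) {
  if (length(seqs) == 0L) stop("alignment has no sequences", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids) || any(ids == "") || anyNA(ids))
    stop("all sequences must be named", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L], call. = FALSE)
  n <- nchar(seqs)
  if (length(unique(n)) != 1L)
    stop("ragged alignment: sequence '",
         ids[which(n != n[1L])[1L]], "' has length ", n[n != n[1L]][1L],
         ", expected ", n[1L], call. = FALSE)
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- ids
  bad <- !(m %in% VALID_CHARS)
  if (any(bad)) {
    warning(sum(bad), " non-standard residue(s) normalized to 'X'",
            call. = FALSE)
    m[bad] <- "X"
  }
  structure(list(matrix = m, labels = labels), class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("Protein alignment: ", nrow(x$matrix), " sequences x ",
      ncol(x$matrix), " columns\n", sep = "")
  if (!is.null(x$labels))
    cat("  clades:", paste(sort(unique(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.aa_alignment <- function(x) dim(x$matrix)

#' Sequence ids of an alignment
#' @param aln An \code{aa_alignment}.
#' @return Character vector of ids, in order.
#' @export
aln_ids <- function(aln) rownames(aln$matrix)

#' Alignment rows as named strings
#' @param aln An \code{aa_alignment}.
#' @return Named character vector of gapped sequences.
#' @export
aln_strings <- function(aln) {
  stats::setNames(apply(aln$matrix, 1L, paste, collapse = ""), aln_ids(aln))
}

#' Read a pre-aligned protein FASTA file
#'
#' Sequences are upper-cased; characters outside the 20-residue alphabet,
#' \code{'-'} and \code{'X'} are normalized to \code{'X'} with a warning.
#' Ids are the headers up to the first whitespace.
#'
#' @param path FASTA file with \code{'-'} gap characters.
#' @param labels Optional id -> clade map attached to the result.
#' @return An \code{aa_alignment}.
#' @export
read_fasta_alignment <- function(path, labels = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  aa_alignment(seqs, labels = labels)
}

#' Write sequences to FASTA
#'
#' @param seqs An \code{aa_alignment} or a named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "aa_alignment")) seqs <- aln_strings(seqs)
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Per-column gap fractions
#'
#' @param aln An \code{aa_alignment}.
#' @return Numeric vector, fraction of \code{'-'} per column.  \code{'X'}
#'   counts as a residue, not a gap.
#' @export
gap_fractions <- function(aln) {
  stopifnot(inherits(aln, "aa_alignment"))
  unname(colMeans(aln$matrix == "-"))
}

#' Trim gappy alignment columns
#'
#' Gap-driven column trimming in the spirit of TrimAl's gappyout mode (the
#' exact TrimAl internals are not reproduced; this is a documented
#' stand-in).  The automatic cutoff is chosen from the distribution of
#' per-column gap fractions: the distinct fractions are sorted ascending and
#' scanned for the first jump of at least \code{min_jump} between
#' consecutive values; all columns whose gap fraction lies above that jump
#' are removed.  Because every jump remaining after trimming is below
#' \code{min_jump}, the procedure is idempotent.  Gap-free columns are never
#' removed.  A fixed \code{gap_threshold} overrides the automatic rule:
#' columns with gap fraction greater than the threshold are removed.
#'
#' @param aln An \code{aa_alignment} with >= 2 sequences.
#' @param gap_threshold Optional fixed gap-fraction cutoff in [0, 1].
#' @param min_jump Minimum gap-fraction jump treated as separating
#'   well-aligned from gappy columns (default 0.2).
#' @return A list: \code{alignment} (trimmed), \code{kept} (1-based original
#'   column indices), \code{cutoff} (gap-fraction cutoff applied).
#' @export
gappyout_trim <- function(aln, gap_threshold = NULL, min_jump = 0.2) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (nrow(aln$matrix) < 2L)
    stop("trimming needs at least 2 sequences", call. = FALSE)
  g <- gap_fractions(aln)
  if (!is.null(gap_threshold)) {
    if (!is.numeric(gap_threshold) || gap_threshold < 0 || gap_threshold > 1)
      stop("'gap_threshold' must be in [0, 1]", call. = FALSE)
    cutoff <- gap_threshold
  } else {
    d <- sort(unique(g))
    cutoff <- d[length(d)]                 # default: keep everything
    if (length(d) > 1L) {
      jumps <- diff(d)
      big <- which(jumps >= min_jump)
      if (length(big) > 0L) cutoff <- d[big[1L]]
    }
  }
  keep <- which(g <= cutoff)
  if (length(keep) == 0L)
    stop("all columns removed at gap cutoff ", format(cutoff),
         "; supply a manual 'gap_threshold'", call. = FALSE)
  out <- aln
  out$matrix <- aln$matrix[, keep, drop = FALSE]
  list(alignment = out, kept = keep, cutoff = cutoff)
}

#' Mask random blocks of an alignment with gaps
#'
#' Test utility emulating ragged alignments: overwrites \code{n_blocks}
#' randomly placed blocks of \code{block_len} columns in random rows with
#' \code{'-'}.
#'
#' @param aln An \code{aa_alignment}.
#' @param n_blocks Number of blocks to mask.
#' @param block_len Columns per block.
#' @param seed Optional seed.
#' @return The corrupted \code{aa_alignment}.
#' @export
corrupt_with_gaps <- function(aln, n_blocks, block_len, seed = NULL) {
  stopifnot(inherits(aln, "aa_alignment"))
  m <- aln$matrix
  with_seed(seed, {
    for (b in seq_len(n_blocks)) {
      row <- sample.int(nrow(m), 1L)
      start <- sample.int(max(1L, ncol(m) - block_len + 1L), 1L)
      m[row, start:min(ncol(m), start + block_len - 1L)] <- "-"
    }
  })
  aln$matrix <- m
  aln
}
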