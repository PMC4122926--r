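# Group p-distance comparison statistics: ancestor-to-member versus
# member-to-member distances per clade, Mann-Whitney / ANOVA tests,
# Bonferroni threshold, percentile profiles, and classical MDS.

#' Significance stars for a p-value
#'
#' \code{"***"} for p < 1e-6, \code{"**"} for 1e-6 <= p < 1e-3, \code{"*"}
#' for 1e-3 <= p < 0.05, else \code{"ns"}.
#'
#' @param p A p-value.
#' @return A character string.
#' @export
significance_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-6) "***" else if (p < 1e-3) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U. The p-value is exact (full enumeration of rank
#' assignments) when \code{length(x) + length(y) <= 12} and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' corrections is used.
#'
#' @param x,y Non-empty numeric samples.
#' @return A list: \code{U} (statistic for \code{x}), \code{p}
#'   (two-sided), \code{exact} (logical).
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1   # fully tied pooled sample: no separation
  list(U = unname(wt$statistic), p = p, exact = exact)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way F test (equal variances assumed).
#' Degenerate inputs are resolved explicitly: zero between-group variation
#' gives F = 0 (p = 1); positive between- with zero within-group variation
#' gives F = Inf (p = 0).
#'
#' @param groups List of >= 2 numeric samples, each with >= 2 values.
#' @return A list: \code{F}, \code{p}, \code{df}.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs >= 2 values", call. = FALSE)
  k <- length(groups)
  n <- vapply(groups, length, 1L)
  gm <- vapply(groups, mean, 1)
  overall <- sum(n * gm) / sum(n)
  ssb <- sum(n * (gm - overall)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df1 <- k - 1L; df2 <- sum(n) - k
  if (ssb <= 0) return(list(F = 0, p = 1, df = c(df1, df2)))
  if (ssw <= 0) return(list(F = Inf, p = 0, df = c(df1, df2)))
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df = c(df1, df2))
}

#' Bonferroni-corrected per-comparison threshold
#'
#' \code{alpha / m}, reported truncated (floor) at 3 decimal places, which
#' reproduces the conventional printed value (e.g. 0.05/3 -> 0.016).  The
#' untruncated quotient is attached as attribute \code{"exact"} and used
#' internally for decisions.
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return The truncated threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)",
                                     call. = FALSE)
  if (m < 1L) stop("'m' must be >= 1", call. = FALSE)
  exact <- alpha / m
  structure(floor(exact * 1000) / 1000, exact = exact)
}

#' Percentiles of distance sets
#'
#' 10th/25th/50th/75th/90th percentiles per set, by the inclusive
#' linear-interpolation definition (quantile type 7).
#'
#' @param dist_sets Named list of non-empty numeric vectors.
#' @return Data frame: set, n, p10, p25, p50, p75, p90.
#' @export
percentile_profile <- function(dist_sets) {
  if (any(vapply(dist_sets, length, 1L) == 0L))
    stop("each set must be non-empty", call. = FALSE)
  probs <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  rows <- lapply(names(dist_sets), function(nm) {
    q <- stats::quantile(dist_sets[[nm]], probs, type = 7, names = FALSE)
    data.frame(set = nm, n = length(dist_sets[[nm]]),
               p10 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p90 = q[5],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-clade ancestor-vs-member distance comparison
#'
#' For every clade: the p-distances between the clade ancestor and each
#' member (\code{anc_member}), between all within-clade member pairs
#' (\code{member_member}), and optionally between the global root ancestor
#' and each member (\code{lucar_member}).  The primary test of
#' anc_member vs member_member is Mann-Whitney (two sets); a one-way ANOVA
#' p-value is additionally reported when both sets pass a Shapiro-Wilk
#' normality pre-check (alpha 0.05, samples truncated to 50).  Clades with
#' fewer than 2 members are skipped with a warning.
#'
#' @param aln An \code{aa_alignment} containing member sequences plus
#'   ancestor sequences with ids \code{"mama-<clade>"} and optionally
#'   \code{"LUCAR"}, all in the same column coordinates.
#' @param clade_labels Named character vector member id -> clade.
#' @return A list of per-clade comparison objects (class
#'   \code{distance_comparison}); see \code{\link{comparison_table}}.
#' @export
compare_distances <- function(aln, clade_labels) {
  stopifnot(inherits(aln, "aa_alignment"))
  ids <- aln_ids(aln)
  has_lucar <- "LUCAR" %in% ids
  m <- aln$matrix
  out <- list()
  for (cl in sort(unique(unname(clade_labels)))) {
    members <- intersect(names(clade_labels)[clade_labels == cl], ids)
    if (length(members) < 2L) {
      warning("clade '", cl, "' has fewer than 2 members; skipped",
              call. = FALSE)
      next
    }
    anc_id <- paste0("mama-", cl)
    if (!anc_id %in% ids)
      stop("ancestor sequence '", anc_id, "' not in alignment",
           call. = FALSE)
    anc_member <- vapply(members, function(t)
      p_distance(m[anc_id, ], m[t, ]), 1)
    pairs <- utils::combn(members, 2L)
    member_member <- apply(pairs, 2L, function(pr)
      p_distance(m[pr[1L], ], m[pr[2L], ]))
    lucar_member <- if (has_lucar)
      vapply(members, function(t) p_distance(m["LUCAR", ], m[t, ]), 1)
    else NULL
    mw <- mann_whitney_u(anc_member, member_member)
    normal_ok <- function(v) {
      v <- utils::head(v, 50L)
      length(v) >= 3L && length(unique(v)) > 2L &&
        stats::shapiro.test(v)$p.value >= 0.05
    }
    p_anova <- if (normal_ok(anc_member) && normal_ok(member_member))
      one_way_anova(list(anc_member, member_member))$p else NA_real_
    out[[cl]] <- structure(list(
      clade = cl,
      anc_member = anc_member,
      member_member = member_member,
      lucar_member = lucar_member,
      mean_anc_member = mean(anc_member),
      mean_member_member = mean(member_member),
      sd_anc_member = stats::sd(anc_member),
      sd_member_member = stats::sd(member_member),
      test = "mann-whitney",
      p_value = mw$p,
      p_anova = p_anova,
      stars = significance_stars(mw$p)
    ), class = "distance_comparison")
  }
  out
}

#' @export
print.distance_comparison <- function(x, ...) {
  cat(sprintf(
    "Clade %s: mean p(anc, member) = %.4f (sd %.4f), mean p(member, member) = %.4f (sd %.4f), MW p = %.3g %s\n",
    x$clade, x$mean_anc_member, x$sd_anc_member, x$mean_member_member,
    x$sd_member_member, x$p_value, x$stars))
  invisible(x)
}

#' Flatten distance comparisons into a summary table
#'
#' One row per clade and distance set, with n, mean, sd, the Mann-Whitney
#' p-value and its stars (the ANOVA p-value is carried alongside).
#'
#' @param comparisons Result of \code{\link{compare_distances}}.
#' @return A data.frame.
#' @export
comparison_table <- function(comparisons) {
  rows <- lapply(comparisons, function(x) {
    sets <- list(anc_member = x$anc_member,
                 member_member = x$member_member)
    if (!is.null(x$lucar_member)) sets$lucar_member <- x$lucar_member
    do.call(rbind, lapply(names(sets), function(nm) {
      data.frame(clade = x$clade, set = nm, n = length(sets[[nm]]),
                 mean = mean(sets[[nm]]), sd = stats::sd(sets[[nm]]),
                 p_mw = x$p_value, p_anova = x$p_anova, stars = x$stars,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Classical (Torgerson) multidimensional scaling of a distance matrix
#'
#' Double-centering plus top-k eigendecomposition, following the usual
#' treatment of p-distance matrices as Euclidean-like dissimilarities.
#' With \code{standardize = TRUE} the off-diagonal distances are z-scored
#' and shifted by their minimum to restore nonnegativity before embedding.
#' Requested dimensions with nonpositive eigenvalues are dropped with a
#' warning.
#'
#' @param dm A \code{dist_matrix} or symmetric matrix with dimnames.
#' @param k Number of dimensions, 1 <= k < n.
#' @param standardize Standardize distances first (default TRUE).
#' @return Matrix of coordinates (ids x <= k), with attribute
#'   \code{"eigenvalues"}.
#' @export
classical_mds <- function(dm, k = 2L, standardize = TRUE) {
  if (inherits(dm, "dist_matrix")) d <- dm$d else d <- as.matrix(dm)
  n <- nrow(d)
  if (k < 1L || k >= n) stop("'k' must satisfy 1 <= k < n", call. = FALSE)
  if (standardize && n > 1L) {
    off <- d[row(d) != col(d)]
    if (stats::sd(off) > 0) {
      z <- (d - mean(off)) / stats::sd(off)
      z <- z - min(z[row(z) != col(z)])
      d <- z
      diag(d) <- 0
    }
  }
  fit <- suppressWarnings(stats::cmdscale(d, k = k, eig = TRUE))
  pos <- sum(fit$eig[seq_len(k)] > 1e-12)
  if (pos < k)
    warning("dropping ", k - pos,
            " dimension(s) with nonpositive eigenvalues", call. = FALSE)
  coords <- if (pos == 0L) matrix(0, n, 1L)
  else fit$points[, seq_len(pos), drop = FALSE]
  rownames(coords) <- rownames(d)
  attr(coords, "eigenvalues") <- fit$eig
  coords
}
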