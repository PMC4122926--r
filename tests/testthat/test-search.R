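test_that("local alignment matches direct scoring on canonical cases", {
  b62 <- blosum62_matrix()
  s <- "MKWVTFISLLFLFSSAYS"
  sw <- smith_waterman(s, s)
  chars <- strsplit(s, "")[[1]]
  expect_equal(sw$raw_score, sum(diag(b62[chars, chars])))
  expect_equal(sw$identity, 1)
  expect_equal(c(sw$q_start, sw$q_end), c(1, nchar(s)))
  # classic textbook pair under BLOSUM50
  sw2 <- smith_waterman("HEAGAWGHEE", "PAWHEAE", matrix = "BLOSUM50",
                        gap_open = 10, gap_extend = 1)
  b50 <- local({
    env <- new.env()
    utils::data("BLOSUM50", package = "Biostrings", envir = env)
    get("BLOSUM50", envir = env)
  })
  expect_equal(sw2$raw_score,
               naive_local_score("HEAGAWGHEE", "PAWHEAE", b50, 10, 1))
  # all-negative pairs floor at an empty alignment
  sw3 <- smith_waterman("WWWW", "PPPP")
  expect_equal(sw3$raw_score, 0)
  expect_equal(sw3$aln_len, 0L)
})

test_that("local alignment scores equal an independent naive dynamic program", {
  b62 <- blosum62_matrix()
  set.seed(14)
  for (r in 1:20) {
    q <- random_protein(sample(5:60, 1))
    t <- random_protein(sample(5:60, 1))
    expect_equal(smith_waterman(q, t)$raw_score,
                 naive_local_score(q, t, b62, 11, 1))
    # symmetry for a symmetric matrix
    expect_equal(smith_waterman(q, t)$raw_score,
                 smith_waterman(t, q)$raw_score)
  }
})

test_that("masked probe sites are score-neutral", {
  t <- "MKWVTFISLLFL"
  full <- smith_waterman("MKWVTFISLLFL", t)
  masked <- smith_waterman("MKWVXFISXLFL", t)
  b62 <- blosum62_matrix()
  expect_equal(masked$raw_score,
               full$raw_score - b62["T", "T"] - b62["L", "L"])
})

test_that("E-values follow the Karlin-Altschul algebra", {
  e1 <- evalue(100, 400, 1e5, lambda = 0.267, K = 0.041)
  # hand evaluation of the two formulas
  bit <- (0.267 * 100 - log(0.041)) / log(2)
  expect_equal(e1$bit_score, bit)
  expect_equal(e1$e_value, 400 * 1e5 * 2^(-bit))
  # S = 0 reduces to m * n * K
  e0 <- evalue(0, 37, 1000, lambda = 0.267, K = 0.041)
  expect_equal(e0$e_value, 37 * 1000 * 0.041)
  # strictly decreasing in the raw score
  es <- vapply(seq(0, 200, by = 25),
               function(s) evalue(s, 400, 1e5)$e_value, 1)
  expect_true(all(diff(es) < 0))
  expect_error(evalue(10, -1, 10), "positive")
})

test_that("fishing applies the stringent filters and keeps ranked raw hits", {
  set.seed(6)
  probe <- random_protein(420)
  db <- data.frame(
    id = c("self", "short", "noise1", "noise2"),
    taxon = c("A", "A", "decoy", "decoy"),
    seq = c(probe, substr(probe, 1, 350), random_protein(420),
            random_protein(450)),
    stringsAsFactors = FALSE)
  res <- fish(probe, db, fishing_config(), probe_id = "probe")
  expect_s3_class(res, "fishing_result")
  expect_identical(res$hits$target_id, "self")
  expect_equal(res$hits$identity, 1)
  expect_equal(res$hits$q_coverage, 1)
  # the 350-residue perfect prefix is excluded by the length filter but
  # present in the unfiltered ranked list
  expect_false("short" %in% res$hits$target_id)
  expect_true("short" %in% res$unfiltered$target_id)
  expect_equal(res$unfiltered$rank, 1:4)
  expect_lte(nrow(res$hits), nrow(res$unfiltered))
  expect_true(all(res$hits$target_id %in% res$unfiltered$target_id))
  # deterministic under re-runs
  res2 <- fish(probe, db, fishing_config(), probe_id = "probe")
  expect_identical(res$unfiltered, res2$unfiltered)
  expect_error(fish(probe, db[0, ], fishing_config()), "empty")
})

test_that("best-hit classification assigns reference labels", {
  set.seed(7)
  fam_a <- random_protein(150)
  fam_b <- random_protein(150)
  refs <- data.frame(id = c("ra", "rb"), taxon = c("host", "viral"),
                     seq = c(fam_a, fam_b), stringsAsFactors = FALSE)
  cl <- best_hit_classify(c(p1 = fam_a, p2 = fam_b,
                            p3 = random_protein(150)), refs)
  expect_identical(cl$assignments$best_label[1], "host")
  expect_identical(cl$assignments$best_label[2], "viral")
  expect_identical(cl$assignments$best_label[3], "unclassified")
  # the synthetic scaffold round trip: counts match the true sources
  sc <- make_host_scaffold(10, 3, 150, seed = 1)
  refs2 <- data.frame(id = c("h", "v"), taxon = c("host", "viral"),
                      seq = c(sc$genes$protein[1], sc$genes$protein[11]),
                      stringsAsFactors = FALSE)
  cl2 <- best_hit_classify(stats::setNames(sc$genes$protein,
                                           sc$genes$id), refs2)
  expect_equal(unname(cl2$counts["host"]), 10)
  expect_equal(unname(cl2$counts["viral"]), 3)
})

test_that("taxon filtering drops labels while preserving order", {
  hits <- data.frame(target_id = c("a", "b", "c", "d"),
                     target_taxon = c("x", "decoy", "y", "decoy"),
                     stringsAsFactors = FALSE)
  expect_identical(taxon_filter(hits, character()), hits)
  expect_equal(nrow(taxon_filter(hits, c("x", "y", "decoy"))), 0L)
  kept <- taxon_filter(hits, "decoy")
  expect_identical(kept$target_id, c("a", "c"))
})

test_that("the ORF finder honors frames, strands and length bounds", {
  set.seed(10)
  body <- paste(replicate(99, {
    repeat {
      cod <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                   collapse = "")
      if (!cod %in% c("TAA", "TAG", "TGA", "ATG")) break
    }
    cod
  }), collapse = "")
  dna <- paste0("ATG", body, "TAA")
  o100 <- orf_finder(dna, min_len_aa = 100)
  expect_equal(nrow(o100[o100$strand == "+", ]), 1L)
  expect_equal(o100$length_aa[o100$strand == "+"], 100L)
  expect_equal(o100$start[o100$strand == "+"], 1L)
  expect_equal(o100$end[o100$strand == "+"], nchar(dna))
  expect_equal(nrow(orf_finder(dna, min_len_aa = 101)), 0L)
  expect_error(orf_finder("ACGU"), "characters")
  # N codons translate to X and do not terminate the ORF
  dnan <- paste0("ATG", "AAN", body, "TAA")
  on <- orf_finder(dnan, min_len_aa = 100)
  expect_true(any(grepl("^MX", on$protein)))
})
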