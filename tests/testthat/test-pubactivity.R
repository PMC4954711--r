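medlineFixture <- function(path) {
  writeLines(c(
    "PMID- 1001",
    "DP  - 1995 Jan",
    "MH  - Anaphylaxis",
    "MH  - *Histamine/immunology",
    "MH  - Mast Cells",
    "",
    "PMID- 1002",
    "DP  - 1996",
    "MH  - Anaphylaxis",
    "OT  - mast cells",
    "",
    "PMID- 1002",              # byte-identical duplicate
    "DP  - 1996",
    "MH  - Anaphylaxis",
    "OT  - mast cells",
    "",
    "PMID- 1003",              # no year: skipped
    "MH  - Orphan Term"), path)
  path
}

test_that("MEDLINE parsing extracts, normalizes and deduplicates", {
  path <- withr::local_tempfile(fileext = ".txt")
  medlineFixture(path)
  expect_message(recs <- parseRecords(path, "medline"), "1 record")
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$year, 1995L)
  # 3 MH terms, star and subheading stripped, case-folded
  expect_setequal(recs[[1]]$keywords,
                  c("anaphylaxis", "histamine", "mast cells"))
  expect_setequal(recs[[2]]$keywords, c("anaphylaxis", "mast cells"))
})

test_that("WoS and patent dialects parse what writeCorpus emits", {
  recs <- list(makeRecord("A1", 1990, c("physics", "optics")),
               makeRecord("A2", 1991, "physics"))
  for (d in c("wos", "patent")) {
    path <- withr::local_tempfile(fileext = ".txt")
    writeCorpus(recs, path, d)
    back <- parseRecords(path, d)
    expect_length(back, 2L)
    expect_setequal(back[[1]]$keywords, c("physics", "optics"))
    expect_equal(back[[2]]$year, 1991L)
  }
  expect_error(parseRecords(tempfile(), "nope"))
})

test_that("keyword normalization trims, folds and collapses", {
  expect_equal(normalizeKeyword("  Mast   Cells. "), "mast cells")
  expect_equal(normalizeKeyword("*Histamine"), "histamine")
  expect_equal(normalizeKeyword("GAME THEORY"), "game theory")
})

test_that("yearly counts are per-record incidences on a contiguous axis", {
  recs <- list(makeRecord("r1", 1990, c("a", "b")),
               makeRecord("r2", 1990, c("a", "a", "b")),  # 'a' once
               makeRecord("r3", 1993, "b"))
  kym <- countByYear(recs)
  expect_equal(yearAxis(kym), 1990:1993)
  counts <- keywordCounts(kym)
  expect_equal(counts["a", "1990"], 2L)
  expect_equal(counts["b", "1990"], 2L)
  expect_equal(unname(counts["a", "1991"]), 0L)
  expect_equal(counts["b", "1993"], 1L)
  # total equals total record-keyword incidences
  expect_equal(sum(counts), 5L)
})

test_that("a 20-record corpus matches an independent hand tally", {
  set.seed(42)
  kws <- c("x", "y", "z")
  recs <- lapply(1:20, function(i)
    makeRecord(paste0("r", i), sample(2000:2004, 1),
               sample(kws, sample(1:3, 1))))
  kym <- countByYear(recs)
  counts <- keywordCounts(kym)
  # oracle: flat table over (keyword, year) incidences
  df <- do.call(rbind, lapply(recs, function(r)
    data.frame(k = unique(r$keywords), y = r$year)))
  tallied <- table(df$k, df$y)
  for (k in rownames(tallied)) for (y in colnames(tallied))
    expect_equal(unname(counts[k, y]), unname(tallied[k, y]))
})

test_that("pearson hits the printed endpoints and the hand-computed value", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(pearsonCorrelation(x, 2 * x + 3), 1)
  expect_equal(pearsonCorrelation(x, -x), -1)
  # direct evaluation of the sample formula for (1,2,4) vs (2,1,9)
  expect_equal(pearsonCorrelation(c(1, 2, 4), c(2, 1, 9)),
               12 / sqrt((42 / 9) * 38))
  # agrees with the standard implementation on random data
  set.seed(5)
  for (q in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    expect_equal(pearsonCorrelation(a, b), cor(a, b))
  }
  expect_true(is.na(pearsonCorrelation(rep(1, 5), 1:5)))
  expect_error(pearsonCorrelation(1:3, 1:4), "equal length")
})

test_that("pearson is affine-invariant and flips sign under negation", {
  set.seed(6)
  for (q in 1:10) {
    a <- rnorm(12); b <- rnorm(12)
    r <- pearsonCorrelation(a, b)
    expect_equal(pearsonCorrelation(3 * a + 7, b), r)
    expect_equal(pearsonCorrelation(a, 0.2 * b - 5), r)
    expect_equal(pearsonCorrelation(-a, b), -r)
    expect_equal(pearsonCorrelation(b, a), r)
  }
})

test_that("correlation table is gated by co-occurrence and stored once", {
  recs <- list(makeRecord("r1", 1990, c("a", "b")),
               makeRecord("r2", 1990, "b"),
               makeRecord("r3", 1991, c("a", "b")),
               makeRecord("r4", 1992, c("a", "b")),
               makeRecord("r5", 1992, "a"),
               makeRecord("r6", 1990, "c"),
               makeRecord("r7", 1992, "c"))
  kym <- countByYear(recs)
  tab <- correlatePairs(kym, recs)
  # a-c and b-c never co-occur: absent despite defined correlations
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$keywordA, "a")
  expect_equal(tab$keywordB, "b")
  expect_equal(tab$coOccurrence, 3L)
  # value matches a direct computation on the count series
  counts <- keywordCounts(kym)
  expect_equal(tab$r, pearsonCorrelation(counts["a", ], counts["b", ]))
})

test_that("ranking sorts by r, then appearances, then lexicographically", {
  tab <- data.frame(
    keywordA = c("k1", "k3", "k5", "k7", "aa"),
    keywordB = c("k2", "k4", "k6", "k8", "ab"),
    r = c(0.9, 0.9, 0.8, 0.5, 0.9),
    coOccurrence = c(10L, 5L, 50L, 1L, 10L),
    totalAppearances = c(20L, 40L, 60L, 2L, 20L))
  sel <- rankKeywords(tab, 4)
  # equal r: count 10 beats count 5; equal r and count: 'aa' < 'k1'
  expect_equal(sel$ranking$keywordA[1:3], c("aa", "k1", "k3"))
  expect_equal(sel$keywords, c("aa", "ab", "k1", "k2"))
  # rerun identical
  expect_identical(rankKeywords(tab, 4)$keywords, sel$keywords)
  expect_warning(rankKeywords(tab, 100), "only")
})

test_that("activity movies normalize globally and place nodes at positions", {
  recs <- list(makeRecord("r1", 2000, c("a", "b")),
               makeRecord("r2", 2001, c("a", "b")),
               makeRecord("r3", 2002, c("a", "b")),
               makeRecord("r4", 2001, "b"))
  kym <- countByYear(recs)
  pos <- generatePositions(10, seed = 4)
  mv <- buildActivityMovie(kym, c("a", "b"), pos, seed = 2)
  expect_s4_class(mv, "ActivityMovie")
  intens <- intensityMatrix(mv)
  expect_equal(dim(intens), c(3L, 2L))
  expect_equal(min(intens), 0)
  expect_equal(max(intens), 1)
  # layout positions are a subset of the supplied set, no repeats
  lay <- nodeLayout(mv)
  expect_true(all(paste(lay$x, lay$y) %in% paste(pos[, 1], pos[, 2])))
  expect_false(anyDuplicated(paste(lay$x, lay$y)) > 0)
  # same seed, same assignment
  expect_identical(nodeLayout(buildActivityMovie(kym, c("a", "b"), pos,
                                                 seed = 2)), lay)

  # constant counts: all frames identical after normalization
  recsConst <- lapply(1:3, function(y)
    makeRecord(paste0("c", y), 1999 + y, "k"))
  mvc <- buildActivityMovie(countByYear(recsConst), "k", pos, seed = 1)
  expect_true(all(intensityMatrix(mvc) == intensityMatrix(mvc)[1, 1]))

  # keyword present in a single year: one bright frame at that node
  recsOne <- list(makeRecord("o1", 2000, "solo"),
                  makeRecord("o2", 2001, "other"),
                  makeRecord("o3", 2002, "other"))
  mvo <- buildActivityMovie(countByYear(recsOne), "solo", pos, seed = 1)
  expect_equal(which(intensityMatrix(mvo)[, "solo"] == 1), 1L)
  expect_true(all(intensityMatrix(mvo)[-1, "solo"] == 0))

  expect_error(buildActivityMovie(kym, c("a", "b"), pos[1, , drop = FALSE]),
               "fewer positions")
})

test_that("correlation-mode movies paint windowed pair correlation", {
  set.seed(8)
  recs <- unlist(lapply(1:12, function(i) {
    y <- 1999 + i
    lapply(seq_len(2 + (i %% 3)), function(j)
      makeRecord(paste0("m", i, j), y, c("p", "q")))
  }), recursive = FALSE)
  kym <- countByYear(recs)
  pairs <- data.frame(keywordA = "p", keywordB = "q")
  mv <- buildActivityMovie(kym, c("p", "q"), generatePositions(5, 1),
                           seed = 3, mode = "correlation", pairs = pairs)
  expect_equal(dim(intensityMatrix(mv)), c(12L, 2L))
  expect_true(all(intensityMatrix(mv) >= 0 & intensityMatrix(mv) <= 1))
  # both endpoints carry the same painted series
  expect_equal(intensityMatrix(mv)[, 1], intensityMatrix(mv)[, 2])
})

test_that("tables and movies serialize to TSV/CSV", {
  tab <- data.frame(keywordA = "a", keywordB = "b", r = 0.5,
                    coOccurrence = 2L, totalAppearances = 7L)
  tp <- withr::local_tempfile(fileext = ".tsv")
  writeCorrelationTable(tab, tp)
  expect_equal(read.delim(tp)$r, 0.5)

  recs <- list(makeRecord("r1", 2000, "a"), makeRecord("r2", 2001, "a"),
               makeRecord("r3", 2001, "a"))
  mv <- buildActivityMovie(countByYear(recs), "a",
                           generatePositions(3, 1), seed = 1)
  mp <- withr::local_tempfile(fileext = ".csv")
  writeActivityMovie(mv, mp)
  df <- read.csv(mp, check.names = FALSE)
  expect_equal(df$frame, c(2000L, 2001L))
  expect_equal(df$a, c(0, 1))

  fm <- asFluorescenceMovie(mv)
  expect_s4_class(fm, "FluorescenceMovie")
  expect_equal(dim(fluorValues(fm)), dim(intensityMatrix(mv)))
})
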