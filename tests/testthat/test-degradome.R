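# Complementarity scoring, cleavage arithmetic, profile building and
# category classification.

mk_site_transcript <- function(mirna, pad5 = 100, pad3 = 100) {
  paste0(strrep("A", pad5), revcomp(mirna), strrep("C", pad3))
}

test_that("alignment scores follow the plant rubric", {
  mir <- "TGACAGAAGAGAGTGAGCACA"
  tr <- mk_site_transcript(mir)
  s <- align_mirna(mir, tr, method = "full")
  perfect <- s[s$score == 0, ]
  expect_equal(nrow(perfect), 1)
  expect_equal(perfect$start, 101)
  expect_equal(perfect$end, 121)

  # G:U at miRNA position 15 costs 0.5 (outside the doubled region):
  # miRNA G pairs transcript T instead of C
  expect_identical(substr(mir, 15, 15), "G")
  tv <- tr
  site_pos <- 121 - 15 + 1  # transcript base paired to miRNA position 15
  expect_identical(substr(tv, site_pos, site_pos), "C")
  substr(tv, site_pos, site_pos) <- "T"
  s2 <- align_mirna(mir, tv, method = "full")
  expect_equal(min(s2$score), 0.5)

  # a mismatch at miRNA position 5 costs 2 (doubled region)
  tm <- tr
  p5 <- 121 - 5 + 1
  substr(tm, p5, p5) <- "A"  # miRNA pos 5 is A; A:A does not pair
  expect_identical(substr(mir, 5, 5), "A")
  s3 <- align_mirna(mir, tm, method = "full")
  expect_equal(min(s3$score), 2)

  expect_equal(nrow(align_mirna(mir, "ACGT")), 0)  # shorter than miRNA
  expect_error(align_mirna("ACGT", tr), "18-25")
})

test_that("vectorized scanner equals the brute-force oracle (ungapped)", {
  set.seed(20)
  for (i in 1:25) {
    mir <- mirdegnet:::random_dna(1, sample(19:23, 1))
    tr <- mirdegnet:::random_dna(1, sample(60:400, 1), 0.45)
    if (i %% 5 == 0) {
      # ensure some hits exist: embed a decayed site
      site <- revcomp(mir)
      substr(site, 3, 3) <- "A"
      pos <- sample(nchar(tr) - nchar(site), 1)
      substr(tr, pos, pos + nchar(site) - 1) <- site
    }
    got <- align_mirna(mir, tr, max_score = 6, max_gap = 0,
                       method = "full")
    want <- oracle_allen_sites(mir, tr, max_score = 6)
    expect_equal(got[, c("start", "end", "score")], want,
                 ignore_attr = TRUE)
  }
})

test_that("gapped scanner equals the gapped brute-force oracle", {
  set.seed(21)
  for (i in 1:8) {
    mir <- mirdegnet:::random_dna(1, 20)
    tr <- mirdegnet:::random_dna(1, 80, 0.45)
    got <- align_mirna(mir, tr, max_score = 10, max_gap = 1,
                       method = "full")
    want <- oracle_allen_sites_gapped(mir, tr, max_score = 10)
    # compare best score per (start, end) span
    key <- function(d) paste(d$start, d$end)
    want_best <- tapply(want$score, key(want), min)
    got_best <- tapply(got$score, key(got), min)
    expect_identical(sort(names(got_best)), sort(names(want_best)))
    expect_equal(as.numeric(got_best[names(want_best)]),
                 as.numeric(want_best))
  }
})

test_that("prescreen path equals the full scan", {
  set.seed(22)
  for (i in 1:6) {
    mir <- mirdegnet:::random_dna(1, 21)
    tr <- mirdegnet:::random_dna(1, 900, 0.45)
    site <- revcomp(mir)
    substr(site, 15, 15) <- "T"
    pos <- 400
    substr(tr, pos, pos + nchar(site) - 1) <- site
    a <- align_mirna(mir, tr, method = "full")
    b <- align_mirna(mir, tr, method = "prescreen")
    expect_equal(a, b)
  }
})

test_that("canonical cleavage arithmetic follows the position-10 rule", {
  # miRNA position 1 paired to transcript position 1600 -> site 1591
  expect_equal(canonical_cleavage_position(1600L), 1591L)
  # gap-free: independent of miRNA length by construction of the rule
  mir20 <- mirdegnet:::random_dna(1, 20, 0.5)
  mir24 <- mirdegnet:::random_dna(1, 24, 0.5)
  tr <- paste0(strrep("G", 50), revcomp(mir20), strrep("T", 30))
  s <- align_mirna(mir20, tr, method = "full")
  expect_equal(s$cleavage[s$score == 0], s$end[s$score == 0] - 9)
  tr2 <- paste0(strrep("G", 50), revcomp(mir24), strrep("T", 30))
  s2 <- align_mirna(mir24, tr2, method = "full")
  expect_equal(s2$cleavage[s2$score == 0], s2$end[s2$score == 0] - 9)
  # gap adjustments 5' of position 10
  expect_equal(canonical_cleavage_position(100L, "target_bulge", 5L), 90L)
  expect_equal(canonical_cleavage_position(100L, "target_bulge", 12L), 91L)
  expect_equal(canonical_cleavage_position(100L, "mirna_bulge", 5L), 92L)
  expect_equal(canonical_cleavage_position(100L, "mirna_bulge", 12L), 91L)
  # out of bounds -> no call
  expect_true(is.na(canonical_cleavage_position(5L)))
})

test_that("degradome profiles place tag 5' ends exactly", {
  tr <- data.frame(id = "t1", seq = strrep("ACGTG", 60))
  tag <- substr(tr$seq, 101, 120)
  tags <- data.frame(tag = tag, count = 5L)
  prof <- suppressMessages(map_degradome(tags, tr))
  # the repeat makes the tag multi-mapping: every exact locus counts
  # (overlapping loci included, so scan position by position)
  loci <- which(vapply(1:(nchar(tr$seq) - 19), function(p) {
    substr(tr$seq, p, p + 19) == tag
  }, logical(1)))
  expect_setequal(as.integer(names(prof$t1)), loci)
  expect_true(all(prof$t1 == 5L))

  empty <- suppressMessages(
    map_degradome(data.frame(tag = strrep("T", 20), count = 1L), tr))
  expect_length(empty$t1, 0)
  expect_message(map_degradome(data.frame(tag = "ACG", count = 1L), tr),
                 "dropped")
})

test_that("category classification matches the stated decision tree", {
  expect_equal(classify_category(c(`100` = 1L), 100), 4L)
  expect_equal(classify_category(c(`100` = 7L, `200` = 3L), 100), 0L)
  expect_equal(classify_category(c(`100` = 7L, `200` = 7L, `300` = 2L),
                                 100), 1L)
  # below max, above the nonzero median
  prof <- c(`10` = 9L, `20` = 5L, `30` = 2L, `40` = 2L)
  expect_equal(classify_category(prof, 20), 2L)
  expect_equal(classify_category(prof, 30), 3L)
  expect_error(classify_category(prof, 99), "no degradome read")
  # median over all positions makes sparse counts rise above the median
  expect_equal(classify_category(prof, 30, median_mode = "all",
                                 transcript_length = 1000), 2L)
  expect_error(classify_category(prof, 30, median_mode = "all"),
               "transcript_length")

  set.seed(23)
  for (i in 1:1000) {
    p <- random_profile()
    pos <- as.integer(sample(names(p), 1))
    expect_identical(classify_category(p, pos), oracle_category(p, pos))
  }
})

test_that("call_targets recovers planted sites and ignores decoys", {
  exp <- simulate_experiment(n_transcripts = 16, n_mirnas = 6,
                             n_negative_pairs = 2, n_positive_pairs = 1,
                             n_background_tags = 30, seed = 41)
  hits <- suppressMessages(
    call_targets(exp$mirnas, exp$transcripts, exp$degradome))
  truth <- exp$truth$planted_interactions
  found <- merge(truth, hits,
                 by.x = c("mirna_id", "transcript_id", "cleavage_pos"),
                 by.y = c("mirna_id", "transcript_id", "cleavage_site"))
  expect_equal(nrow(found), nrow(truth))
  expect_true(all(found$category == 0))
  decoys <- setdiff(exp$transcripts$id, truth$transcript_id)
  expect_equal(sum(hits$transcript_id %in% decoys), 0)
  # category partition sanity on every emitted hit
  expect_true(all(hits$category %in% 0:4))
  expect_true(all(hits$peak_count[hits$category %in% c(0, 1)] > 1))
})

test_that("tplot data dumps the profile with one flagged row", {
  prof <- c(`5` = 2L, `17` = 9L, `40` = 1L)
  tp <- tplot_data(prof, 17)
  expect_equal(tp$pos, c(5L, 17L, 40L))
  expect_equal(sum(tp$is_cleavage_site), 1)
  expect_equal(tp$count[tp$is_cleavage_site], 9L)
  expect_equal(nrow(tplot_data(integer(0), 5)), 0)
})
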