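# Tag catalog: collapsing, filtering, contaminant removal, matching,
# length distribution and expression tiers.

test_that("collapse_reads collapses duplicates and keeps library counts", {
  cat1 <- collapse_reads(list(S1 = c("ACGU", "ACGT"), S2 = character(0)))
  expect_equal(nrow(cat1), 1)
  expect_equal(cat1$S1, 2L)
  expect_equal(cat1$S2, 0L)
  expect_equal(cat1$total, 2L)

  expect_equal(nrow(collapse_reads(list(S1 = character(0)))), 0)

  # disjoint tags across 3 libraries: unit indicator count vectors
  libs <- list(S1 = c("AAAA", "AAAA"), S2 = "CCCC", S3 = c("GGGG", "TTTT"))
  cat3 <- collapse_reads(libs)
  expect_equal(nrow(cat3), 4)
  hand <- data.frame(tag = c("AAAA", "CCCC", "GGGG", "TTTT"),
                     S1 = c(2L, 0L, 0L, 0L), S2 = c(0L, 1L, 0L, 0L),
                     S3 = c(0L, 0L, 1L, 1L))
  got <- cat3[order(cat3$tag), c("tag", "S1", "S2", "S3")]
  rownames(got) <- NULL
  expect_identical(got, hand)

  expect_message(collapse_reads(list(S1 = c("ACGT", "ACNT"))), "skipped")
})

test_that("length filter bounds are inclusive and equal a direct scan", {
  tags <- c(strrep("A", 16), strrep("C", 17), strrep("G", 25),
            strrep("T", 26))
  cat <- collapse_reads(list(S1 = tags))
  filt <- filter_by_length(cat)
  expect_setequal(filt$tag, c(strrep("C", 17), strrep("G", 25)))

  set.seed(1)
  rnd <- collapse_reads(list(S1 = mirdegnet:::random_dna(
    200, sample(10:30, 200, replace = TRUE))))
  got <- filter_by_length(rnd, 17, 25)$tag
  expect_setequal(got, rnd$tag[nchar(rnd$tag) >= 17 & nchar(rnd$tag) <= 25])
})

test_that("contaminant removal equals brute-force substring search", {
  set.seed(2)
  contams <- mirdegnet:::random_dna(10, 120)
  frag <- substr(contams[1], 11, 31)           # a contaminant 5' fragment
  frag_rc <- revcomp(substr(contams[2], 40, 60))
  clean <- mirdegnet:::random_dna(50, 21)
  cat <- collapse_reads(list(S1 = c(frag, frag_rc, clean)))
  parts <- remove_contaminants(cat, contams)
  expect_true(frag %in% parts$removed$tag)
  expect_true(frag_rc %in% parts$removed$tag)
  expect_equal(nrow(parts$kept) + nrow(parts$removed), nrow(cat))

  # quadratic scan oracle
  both <- c(contams, revcomp(contams))
  oracle_removed <- vapply(cat$tag, function(tg) {
    any(vapply(both, function(cs) grepl(tg, cs, fixed = TRUE), logical(1)))
  }, logical(1))
  expect_setequal(parts$removed$tag, cat$tag[oracle_removed])

  expect_warning(out <- remove_contaminants(cat, character(0)), "empty")
  expect_identical(out$kept, cat)
})

test_that("match_known renders the expected variant names", {
  ref <- data.frame(id = c("miR156a", "miR157x"),
                    seq = c("TGACAGAAGAGAGTGAGCACA",
                            "TTGACAGAAGATAGAGAGCAC"))
  # identity match: no suffix
  cat <- collapse_reads(list(S1 = ref$seq[1]))
  m <- match_known(cat, ref)
  expect_identical(m$variant_name, "miR156a")
  expect_identical(m$n_sub, 0L)

  # extended 1 nt on the right with G->A at reference position 15
  v <- ref$seq[1]
  substr(v, 15, 15) <- "A"  # reference has G at position 15
  expect_identical(substr(ref$seq[1], 15, 15), "G")
  v <- paste0(v, "T")
  m2 <- match_known(collapse_reads(list(S1 = v)), ref)
  expect_identical(m2$variant_name, "miR156a_R+1_1ss15GA")

  # unmatched tag flagged as novel candidate
  m3 <- match_known(collapse_reads(list(S1 = strrep("AC", 10))), ref)
  expect_false(m3$known)
  expect_true(is.na(m3$variant_name))
})

test_that("planted matures match their reference with zero substitutions", {
  exp <- simulate_experiment(n_transcripts = 16, n_mirnas = 8,
                             n_negative_pairs = 3, n_positive_pairs = 2,
                             n_background_tags = 40, seed = 31)
  catalog <- build_catalog(exp$srna, reference = exp$mirnas)
  mature <- catalog[catalog$tag %in% exp$mirnas$seq, ]
  well_read <- mature[mature$total >= 10, ]
  expect_gt(nrow(well_read), 0)
  expect_true(all(well_read$known))
  expect_true(all(well_read$n_sub == 0))
  expect_identical(well_read$ref_id,
                   exp$mirnas$id[match(well_read$tag, exp$mirnas$seq)])
})

test_that("length distribution conserves totals and finds the 24-nt mode", {
  cat1 <- collapse_reads(list(S1 = rep(strrep("A", 21), 5)))
  ld <- length_distribution(cat1)
  expect_equal(ld$redundant[ld$length == 21], 5)
  expect_equal(ld$unique[ld$length == 21], 1)
  expect_equal(sum(ld$redundant), sum(cat1$total))
  expect_equal(sum(ld$unique), nrow(cat1))

  bg <- simulate_srna_background(1500, seed = 8)
  catbg <- build_catalog(bg, reference = data.frame(id = character(0),
                                                    seq = character(0)))
  ldbg <- length_distribution(catbg)
  expect_equal(ldbg$length[which.max(ldbg$redundant)], 24)
})

test_that("expression tiers follow the <10 / mean rules", {
  expect_identical(expression_tier(5, 100), "low")
  expect_identical(expression_tier(100, 100), "middle")  # at mean: middle
  expect_identical(expression_tier(101, 100), "high")
  set.seed(3)
  totals <- rpois(500, 30)
  mu <- mean(totals)
  got <- expression_tier(totals, mu)
  brute <- ifelse(totals < 10, "low", ifelse(totals > mu, "high", "middle"))
  expect_identical(got, brute)
})

test_that("collapse and filters never alter surviving per-library counts", {
  set.seed(4)
  reads <- list(S1 = sample(mirdegnet:::random_dna(30, 20), 80, TRUE),
                S2 = sample(mirdegnet:::random_dna(30, 24), 60, TRUE))
  cat <- collapse_reads(reads)
  filt <- filter_by_length(cat, 17, 25)
  keep <- remove_contaminants(filt, mirdegnet:::random_dna(3, 100))$kept
  for (i in seq_len(nrow(keep))) {
    orig <- cat[cat$tag == keep$tag[i], c("S1", "S2")]
    expect_identical(keep[i, c("S1", "S2")], orig,
                     ignore_attr = TRUE)
  }
})
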