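# Precursor excision, MFE statistics, folding contract and hairpin
# validation.

test_that("excise_candidates truncates at bounds and sizes correctly", {
  tr <- strrep("ACGT", 100)  # 400 nt
  # tag at position 1: only the downstream (5'-arm) candidate exists
  c1 <- excise_candidates(tr, 1, 21, windows = 80, slack = 0)
  expect_equal(nrow(c1), 1)
  expect_identical(c1$arm, "5p")
  expect_equal(c1$end, 1 + 21 - 1 + 80)

  # mid-transcript: both arms, lengths tag_len + w
  c2 <- excise_candidates(tr, 200, 21, windows = 80, slack = 0)
  expect_equal(nrow(c2), 2)
  expect_true(all(nchar(c2$seq) == 21 + 80))
  # tag-side slack extends the tag-proximal side
  c3 <- excise_candidates(tr, 200, 21, windows = 80, slack = 20)
  expect_true(all(nchar(c3$seq) == 21 + 80 + 20))

  # unknown position outside the transcript: nothing, with a message
  expect_message(c0 <- excise_candidates(tr, 500, 21), "no candidates")
  expect_equal(nrow(c0), 0)
})

test_that("planted precursors are contained in an excision candidate", {
  exp <- simulate_experiment(n_transcripts = 16, n_mirnas = 6,
                             n_negative_pairs = 2, n_positive_pairs = 1,
                             n_background_tags = 30, seed = 13)
  for (i in seq_along(exp$hairpins)) {
    hp <- exp$hairpins[[i]]
    host <- exp$hairpin_hosts$seq[i]
    pos <- regexpr(hp$mature, host, fixed = TRUE)
    expect_gt(pos, 0)
    cand <- excise_candidates(host, as.integer(pos), nchar(hp$mature))
    pre_start <- regexpr(hp$precursor, host, fixed = TRUE)
    pre_end <- pre_start + nchar(hp$precursor) - 1
    contained <- any(cand$start <= pre_start & cand$end >= pre_end)
    expect_true(contained)
  }
})

test_that("AMFE and MFEI arithmetic and scale consistency", {
  r <- compute_mfei(-40, 100, 50)
  expect_equal(r$amfe, 40)
  expect_equal(r$mfei, 0.8)
  expect_equal(compute_mfei(0, 100, 50)$mfei, 0)
  r2 <- compute_mfei(-60, 120, 40)
  expect_equal(r2$amfe, 50)
  expect_equal(r2$mfei, 1.25)
  # doubling length at fixed MFE halves AMFE and MFEI
  a <- compute_mfei(-30, 90, 45)
  b <- compute_mfei(-30, 180, 45)
  expect_equal(b$amfe, a$amfe / 2)
  expect_equal(b$mfei, a$mfei / 2)
  expect_error(compute_mfei(-10, 100, 0), "gc")
})

test_that("folding respects the engine contract", {
  f <- fold(strrep("A", 30))
  expect_identical(f$structure, strrep(".", 30))
  expect_equal(f$mfe, 0)
  # determinism
  hp <- plant_hairpin("TGACAGAAGAGAGTGAGCACA", seed = 2)
  f1 <- fold(hp$precursor)
  f2 <- fold(hp$precursor)
  expect_identical(f1, f2)
  expect_lt(f1$mfe, 0)
  # the maxpair stub obeys the same structural contract
  fm <- fold(hp$precursor, engine = fold_engine_maxpair)
  expect_equal(nchar(fm$structure), nchar(hp$precursor))
  p <- pairing_partners(fm$structure)
  expect_true(all(p[!is.na(p)] %in% seq_along(p)))
})

test_that("planted hairpins pass validation; mis-specified ones fail", {
  hp <- plant_hairpin("TGACAGAAGAGAGTGAGCACA", seed = 6)
  f <- fold(hp$precursor)
  reads <- data.frame(pos = c(hp$mature_span[1], hp$star_span[1]),
                      count = c(40, 4))
  v <- validate_hairpin(hp$precursor, f$structure, hp$mature_span, reads)
  expect_true(v$pass)
  expect_gte(v$frac_paired, 0.75)
  expect_identical(v$arm, "5p")

  # mature placed over the terminal loop: loop-spanning failure
  loop_span <- c(hp$mature_span[2] - 4L, hp$mature_span[2] + 16L)
  vl <- validate_hairpin(hp$precursor, f$structure, loop_span, reads)
  expect_false(vl$pass)
  expect_true("loop-spanning" %in% vl$reasons)

  # no reads: no-coverage
  v0 <- validate_hairpin(hp$precursor, f$structure, hp$mature_span, NULL)
  expect_false(v0$pass)
  expect_true("no-coverage" %in% v0$reasons)

  # dispersed reads fail; concentrating reads at the mature 5' end can
  # only help (monotone in coverage concentration)
  spread <- data.frame(pos = seq(5, nchar(hp$precursor) - 5, by = 7),
                       count = 5)
  vs <- validate_hairpin(hp$precursor, f$structure, hp$mature_span, spread)
  expect_true("dispersed-reads" %in% vs$reasons)
  boosted <- rbind(spread,
                   data.frame(pos = hp$mature_span[1], count = 500))
  vb <- validate_hairpin(hp$precursor, f$structure, hp$mature_span, boosted)
  expect_gte(vb$coverage_frac, vs$coverage_frac)
})

test_that("dinucleotide shuffle preserves dinucleotide composition", {
  set.seed(5)
  for (i in 1:10) {
    s <- mirdegnet:::random_dna(1, 80, 0.5)
    sh <- mirdegnet:::shuffle_dinucleotide(s, seed = i)
    expect_equal(nchar(sh), nchar(s))
    din <- function(x) {
      v <- strsplit(x, "")[[1]]
      sort(table(paste0(v[-length(v)], v[-1])))
    }
    expect_identical(din(sh), din(s))
    # endpoints fixed by the Eulerian-path construction
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
    expect_identical(substr(sh, 80, 80), substr(s, 80, 80))
  }
})

test_that("find_hairpins recovers planted precursors on host sequences", {
  exp <- simulate_experiment(n_transcripts = 16, n_mirnas = 6,
                             n_negative_pairs = 2, n_positive_pairs = 1,
                             n_background_tags = 30, seed = 17)
  catalog <- build_catalog(exp$srna, reference = exp$mirnas)
  seed_tags <- data.frame(tag = exp$mirnas$seq, stringsAsFactors = FALSE)
  pre <- find_hairpins(seed_tags, exp$hairpin_hosts, catalog = catalog)
  expect_equal(nrow(pre), 6)
  expect_true(all(pre$pass))
  expect_true(all(pre$mfei > 0))
  expect_equal(sort(pre$source_id),
               sort(exp$truth$planted_mirnas$precursor_id))
})
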