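# Generators: determinism, planted structure, parameter validation.

test_that("gen_transcriptome honours n, lengths, GC and determinism", {
  expect_equal(nrow(gen_transcriptome(0, seed = 1)), 0)

  tr1 <- gen_transcriptome(200, c(500, 1500), gc = 0.45, seed = 42)
  tr2 <- gen_transcriptome(200, c(500, 1500), gc = 0.45, seed = 42)
  expect_identical(tr1, tr2)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(tr1$seq, tr1$id, f1)
  write_fasta(tr2$seq, tr2$id, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_true(all(tr1$length >= 500 & tr1$length <= 1500))
  expect_false(anyDuplicated(tr1$id) > 0)
  # realized per-set GC by direct base counting
  bases <- strsplit(paste(tr1$seq, collapse = ""), "")[[1]]
  gc <- mean(bases %in% c("G", "C"))
  expect_lt(abs(gc - 0.45), 0.02)

  expect_error(gen_transcriptome(5, c(500, 900), gc = 1.2), "gc")
  expect_error(gen_transcriptome(5, c(100, 900)), "200")
  expect_error(gen_transcriptome(5, c(900, 500)), "range")
})

test_that("plant_hairpin builds a precursor containing the mature", {
  mat <- "TGACAGAAGAGAGTGAGCACA"
  hp <- plant_hairpin(mat, seed = 3)
  expect_true(grepl(mat, hp$precursor, fixed = TRUE))
  expect_identical(substr(hp$precursor, hp$mature_span[1],
                          hp$mature_span[2]), mat)
  # wobble_count = 0: opposite arm is the exact reverse complement
  arm <- substr(hp$precursor, hp$star_arm_span[1], hp$star_arm_span[2])
  expect_identical(arm, revcomp(mat))
  # star span = opposite arm with a 2-nt 3' overhang
  expect_identical(hp$star_span, hp$star_arm_span + 2L)

  hp3 <- plant_hairpin(mat, arm = "3p", seed = 3)
  expect_true(hp3$mature_span[1] > hp3$star_arm_span[2])

  expect_error(plant_hairpin("ACGUNACGUACGUACGUACGU"), "non-ACGU")
  expect_error(plant_hairpin("ACGT"), "20")
  expect_error(plant_hairpin(mat, wobble_count = 4), "wobble")
})

test_that("simulate_counts matches its sampling model", {
  feats <- sprintf("f%04d", 1:1000)
  m <- simulate_counts(feats, base_mean = 100, dispersion = 0,
                       n_samples = 8, seed = 11)
  expect_identical(dim(m), c(1000L, 8L))
  # Poisson: per-sample mean within 3 standard errors of 100
  se <- sqrt(100 / 1000)
  expect_true(all(abs(colMeans(m) - 100) < 3 * se))

  expect_identical(m, simulate_counts(feats, 100, 0, n_samples = 8,
                                      seed = 11))

  up <- c(1, 1, 1, 1, 1, 8, 1, 1)
  planted <- feats[1:200]
  plan <- setNames(replicate(200, up, simplify = FALSE), planted)
  m2 <- simulate_counts(feats, 100, dispersion = 0.1, de_plan = plan,
                        n_samples = 8, seed = 12)
  ratio_up <- m2[planted, "S6"] / pmax(m2[planted, "S1"], 1)
  expect_gte(mean(ratio_up > 1), 0.95)

  expect_error(simulate_counts(feats, 100, de_plan = list(zz = up)),
               "absent")
  expect_error(simulate_counts(feats, -1), "base_mean")
})

test_that("simulate_degradome plants peaks and count-1 background", {
  tr <- gen_transcriptome(4, c(500, 600), seed = 5)
  # empty library
  d0 <- simulate_degradome(tr, NULL, background_rate = 0, seed = 1)
  expect_equal(nrow(d0), 0)

  ints <- data.frame(mirna_id = "m1", transcript_id = tr$id[1],
                     cleavage_pos = 101L)
  d <- simulate_degradome(tr, ints, peak_count = 5, background_rate = 2,
                          seed = 2)
  pk <- d[d$kind == "peak", ]
  expect_equal(pk$pos, 101L)
  expect_equal(pk$count, 5)
  expect_identical(pk$tag,
                   substr(tr$seq[1], 101, 101 + nchar(pk$tag) - 1))
  expect_true(all(nchar(d$tag) %in% c(20, 21)))
  # decoys carry only count-1 signatures at distinct positions
  bg <- d[d$kind == "background" & d$transcript_id != tr$id[1], ]
  expect_true(all(bg$count == 1))
  expect_false(any(duplicated(bg[, c("transcript_id", "pos")])))

  far <- data.frame(mirna_id = "m1", transcript_id = tr$id[1],
                    cleavage_pos = nchar(tr$seq[1]) - 5L)
  expect_warning(simulate_degradome(tr, far, background_rate = 0, seed = 3),
                 "skipped")
})

test_that("background sRNA length histogram peaks at 24 nt", {
  bg <- simulate_srna_background(2000, seed = 9)
  lens <- nchar(bg$tag)
  redundant <- tapply(rowSums(bg[, sprintf("S%d", 1:8)]), lens, sum)
  expect_equal(names(which.max(redundant)), "24")
  expect_equal(names(which.max(table(lens))), "24")
})

test_that("coexpression blocks realize planted loadings exactly", {
  bl <- gen_coexpression_blocks(n_blocks = 3, genes_per_block = 20,
                                seed = 4)
  expect_equal(dim(bl$expr), c(60, 8))
  expect_length(bl$hubs, 3)
  # hub is wired to its block factor at hub_cor by construction: its
  # correlation with the block mean dominates every member's
  for (b in unique(bl$labels)) {
    genes <- names(bl$labels)[bl$labels == b]
    hub <- intersect(bl$hubs, genes)
    z <- colMeans(bl$expr[genes, ])
    cors <- apply(bl$expr[genes, ], 1, cor, z)
    expect_identical(names(which.max(cors)), hub)
  }
})

test_that("the truth manifest resolves and is reproducible", {
  exp1 <- simulate_experiment(n_transcripts = 20, n_mirnas = 8,
                              n_negative_pairs = 3, n_positive_pairs = 2,
                              n_background_tags = 50, seed = 21)
  expect_true(validate_manifest(exp1))
  exp2 <- simulate_experiment(n_transcripts = 20, n_mirnas = 8,
                              n_negative_pairs = 3, n_positive_pairs = 2,
                              n_background_tags = 50, seed = 21)
  expect_identical(exp1$truth, exp2$truth)
  expect_identical(exp1$srna, exp2$srna)
  d1 <- tempfile(); d2 <- tempfile()
  write_experiment(exp1, d1); write_experiment(exp2, d2)
  expect_identical(readLines(file.path(d1, "truth_manifest.json")),
                   readLines(file.path(d2, "truth_manifest.json")))
  # planted cleavage sites sit inside their transcripts
  ints <- exp1$truth$planted_interactions
  lens <- setNames(exp1$transcripts$length, exp1$transcripts$id)
  expect_true(all(ints$cleavage_pos >= 1 &
                    ints$cleavage_pos <= lens[ints$transcript_id]))
})
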