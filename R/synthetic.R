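# Synthetic-data generators with planted ground truth.
#
# The generators emulate the study design the pipeline is built for: an
# eight-point stress time course (samples S1..S8) with small-RNA tag
# libraries peaking at 24 nt, hairpin precursors carrying mature/star read
# stacks, a degradome library of 20-21 nt tags peaking at canonical
# cleavage sites, negative-binomial count trajectories with planted up/down
# regulation, and block-correlated gene sets with planted hubs. Every
# planted feature is recorded in a machine-readable truth manifest so that
# downstream stages can be scored against known answers.

#' Generate a random transcript set
#'
#' A stand-in for an assembled unigene set: `n` random sequences with
#' lengths uniform over `length_range` and a target GC fraction.
#'
#' @param n number of transcripts (>= 0).
#' @param length_range two-element integer range (min >= 200 nt).
#' @param gc target GC fraction in (0, 1).
#' @param seed integer seed; identical (parameters, seed) give identical
#'   output.
#' @return data.frame with columns `id`, `seq`, `length`.
#' @export
gen_transcriptome <- function(n, length_range = c(500, 1500), gc = 0.45,
                              seed = 1) {
  stopifnot(length(length_range) == 2, n >= 0)
  if (!(gc > 0 && gc < 1)) stop("gc must lie strictly between 0 and 1")
  if (length_range[1] < 200) stop("minimum transcript length is 200 nt")
  if (length_range[1] > length_range[2]) stop("invalid length range")
  if (n == 0) {
    return(data.frame(id = character(0), seq = character(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    seqs <- random_dna(n, lens, gc)
    data.frame(id = sprintf("TR%05d", seq_len(n)), seq = seqs,
               length = lens, stringsAsFactors = FALSE)
  })
}

#' Plant a miRNA hairpin precursor
#'
#' Builds a precursor as 5' flank + mature + terminal loop + (near-)reverse
#' complement of the mature + 3' flank (arm-swapped for `arm = "3p"`).
#' Up to `wobble_count` G:C pairs on the opposite arm are converted to G:U
#' wobbles (C -> T on the star side), which keeps the duplex foldable while
#' making the star an inexact reverse complement. The star span is recorded
#' with the canonical 2-nt 3' overhang of a Dicer product.
#'
#' @param mature mature miRNA sequence, 20-24 nt, RNA or DNA alphabet.
#' @param loop_len terminal loop length (nt).
#' @param flank_len flank length on each side (nt).
#' @param wobble_count number of G:U wobbles to introduce (<= 3).
#' @param arm which precursor arm carries the mature: "5p" or "3p".
#' @param seed integer seed.
#' @return list with `precursor`, `mature`, `mature_span`, `star_span`
#'   (both 1-based inclusive), `arm`, `star_arm_span` (the paired segment).
#' @export
plant_hairpin <- function(mature, loop_len = 12, flank_len = 15,
                          wobble_count = 0, arm = c("5p", "3p"), seed = 1) {
  arm <- match.arg(arm)
  if (!is_nucleotide(mature)) {
    stop("mature sequence contains non-ACGU symbols")
  }
  mature <- dna_normalize(mature)
  m <- nchar(mature)
  if (m < 20 || m > 24) stop("mature length must be in [20, 24] nt")
  if (wobble_count > 3) stop("wobble_count must be <= 3")
  with_seed(seed, {
    star_arm <- revcomp(mature)
    if (wobble_count > 0) {
      cand <- which(strsplit(star_arm, "")[[1]] == "C")
      take <- cand[sample.int(length(cand),
                              min(wobble_count, length(cand)))]
      v <- strsplit(star_arm, "")[[1]]
      v[take] <- "T"
      star_arm <- paste(v, collapse = "")
    }
    loop <- random_dna(1, loop_len, 0.4)
    f5 <- random_dna(1, flank_len, 0.5)
    f3 <- random_dna(1, flank_len, 0.5)
    if (arm == "5p") {
      precursor <- paste0(f5, mature, loop, star_arm, f3)
      mature_span <- c(flank_len + 1, flank_len + m)
      sa <- flank_len + m + loop_len + 1
      star_arm_span <- c(sa, sa + m - 1)
    } else {
      precursor <- paste0(f5, star_arm, loop, mature, f3)
      sa <- flank_len + 1
      star_arm_span <- c(sa, sa + m - 1)
      ms <- flank_len + m + loop_len + 1
      mature_span <- c(ms, ms + m - 1)
    }
    # star = opposite-arm duplex partner with a 2-nt 3' overhang
    star_span <- star_arm_span + 2L
    list(precursor = precursor, mature = mature,
         mature_span = as.integer(mature_span),
         star_span = as.integer(star_span),
         star_arm_span = as.integer(star_arm_span),
         star = substr(precursor, star_span[1], star_span[2]),
         arm = arm)
  })
}

# Default eight-point trajectories used for planted regulation: an 8-fold
# rise peaking at S6 and its exact mirror (cor = -1 between the two).
trajectory_up <- function(k = 8) {
  base <- c(1, 1.2, 2, 3, 5, 8, 6, 4)
  if (k == 8) base else stats::approx(seq(0, 1, length.out = 8), base,
                                      seq(0, 1, length.out = k))$y
}

trajectory_down <- function(k = 8) {
  up <- trajectory_up(k)
  max(up) + min(up) - up
}

#' Simulate a negative-binomial count matrix over the time course
#'
#' Null features draw counts at `base_mean`; features named in `de_plan`
#' have their mean multiplied per sample by the planted trajectory.
#' `dispersion = 0` degenerates to Poisson sampling.
#'
#' @param features character vector of feature ids.
#' @param base_mean mean expression (scalar or per-feature vector, > 0).
#' @param dispersion NB overdispersion (variance = mu + dispersion * mu^2);
#'   >= 0.
#' @param de_plan named list: feature id -> multiplier vector of length
#'   `n_samples`.
#' @param n_samples number of samples (columns S1..Sk), k >= 2.
#' @param seed integer seed.
#' @return integer matrix, features x samples.
#' @export
simulate_counts <- function(features, base_mean = 100, dispersion = 0.1,
                            de_plan = NULL, n_samples = 8, seed = 1) {
  stopifnot(all(base_mean > 0), dispersion >= 0, n_samples >= 2)
  if (!is.null(de_plan)) {
    unknown <- setdiff(names(de_plan), features)
    if (length(unknown) > 0) {
      stop("de_plan names absent from features: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    }
  }
  n <- length(features)
  mu <- matrix(rep_len(base_mean, n), nrow = n, ncol = n_samples)
  for (f in names(de_plan)) {
    traj <- de_plan[[f]]
    if (length(traj) != n_samples) stop("trajectory length mismatch for ", f)
    mu[match(f, features), ] <- mu[match(f, features), ] * traj
  }
  with_seed(seed, {
    cnt <- if (dispersion == 0) {
      stats::rpois(n * n_samples, lambda = as.vector(mu))
    } else {
      stats::rnbinom(n * n_samples, mu = as.vector(mu),
                     size = 1 / dispersion)
    }
    m <- matrix(as.integer(cnt), nrow = n, ncol = n_samples,
                dimnames = list(features, sprintf("S%d", seq_len(n_samples))))
    m
  })
}

#' Simulate a degradome tag library
#'
#' For each planted interaction, `peak_count` reads of 20-21 nt whose 5'
#' ends sit exactly at the planted cleavage position are excised from the
#' target transcript. Background decay tags of count 1 are placed at
#' distinct uniform-random positions at `background_rate` tags per kb, so
#' transcripts without a planted peak carry only count-1 signatures.
#'
#' @param transcripts data.frame with `id`, `seq` (see
#'   [gen_transcriptome()]).
#' @param interactions data.frame with `mirna_id`, `transcript_id`,
#'   `cleavage_pos` (1-based), or `NULL`.
#' @param peak_count reads planted at each cleavage site (> 1 for a
#'   classifiable peak).
#' @param background_rate expected count-1 tags per kb of transcript.
#' @param tag_lengths allowed degradome tag lengths.
#' @param seed integer seed.
#' @return data.frame with `tag_id`, `tag`, `count`, `transcript_id`,
#'   `pos`, `kind` ("peak"/"background"). Interactions whose cleavage
#'   position is too close to the 3' end to excise a 20-nt tag are skipped
#'   with a warning.
#' @export
simulate_degradome <- function(transcripts, interactions = NULL,
                               peak_count = 5, background_rate = 2,
                               tag_lengths = c(20L, 21L), seed = 1) {
  stopifnot(all(tag_lengths %in% c(20L, 21L)))
  rows <- list()
  with_seed(seed, {
    tlen <- stats::setNames(nchar(transcripts$seq), transcripts$id)
    if (!is.null(interactions) && nrow(interactions) > 0) {
      for (i in seq_len(nrow(interactions))) {
        tr <- interactions$transcript_id[i]
        pos <- interactions$cleavage_pos[i]
        L <- tlen[[tr]]
        if (pos + min(tag_lengths) - 1 > L) {
          warning("cleavage position ", pos, " on ", tr,
                  " too close to the 3' end; interaction skipped")
          next
        }
        w <- sample(tag_lengths, 1)
        if (pos + w - 1 > L) w <- min(tag_lengths)
        seqi <- transcripts$seq[match(tr, transcripts$id)]
        rows[[length(rows) + 1]] <- data.frame(
          tag = substr(seqi, pos, pos + w - 1), count = peak_count,
          transcript_id = tr, pos = pos, kind = "peak",
          stringsAsFactors = FALSE)
      }
    }
    if (background_rate > 0 && nrow(transcripts) > 0) {
      peak_pos <- if (length(rows)) {
        do.call(rbind, rows)[, c("transcript_id", "pos")]
      } else NULL
      for (j in seq_len(nrow(transcripts))) {
        L <- transcripts$length[j] %||% nchar(transcripts$seq[j])
        maxstart <- L - max(tag_lengths) + 1
        if (maxstart < 1) next
        n_bg <- stats::rpois(1, background_rate * L / 1000)
        if (n_bg == 0) next
        pos <- sample.int(maxstart, min(n_bg, maxstart))
        if (!is.null(peak_pos)) {
          used <- peak_pos$pos[peak_pos$transcript_id == transcripts$id[j]]
          pos <- setdiff(pos, used)
        }
        if (length(pos) == 0) next
        w <- sample(tag_lengths, length(pos), replace = TRUE)
        rows[[length(rows) + 1]] <- data.frame(
          tag = substring(transcripts$seq[j], pos, pos + w - 1),
          count = 1L, transcript_id = transcripts$id[j], pos = pos,
          kind = "background", stringsAsFactors = FALSE)
      }
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(tag = character(0), count = integer(0),
               transcript_id = character(0), pos = integer(0),
               kind = character(0), stringsAsFactors = FALSE)
  }
  if (nrow(out) > 0) out <- cbind(tag_id = sprintf("dt%05d", seq_len(nrow(out))), out)
  else out <- cbind(data.frame(tag_id = character(0)), out)
  rownames(out) <- NULL
  out
}

#' Simulate background small-RNA tags
#'
#' Random tags whose length histogram has its mode at 24 nt -- the
#' signature size class of plant heterochromatic siRNAs -- with a secondary
#' 21-nt miRNA-like class. Total counts are heavy-tailed and spread over
#' the `n_samples` libraries.
#'
#' @param n_tags number of distinct tags.
#' @param n_samples number of libraries.
#' @param seed integer seed.
#' @return data.frame: `tag` plus integer columns S1..Sk.
#' @export
simulate_srna_background <- function(n_tags = 500, n_samples = 8, seed = 1) {
  len_weights <- c(`18` = 0.04, `19` = 0.05, `20` = 0.07, `21` = 0.12,
                   `22` = 0.08, `23` = 0.10, `24` = 0.38, `25` = 0.16)
  with_seed(seed, {
    lens <- as.integer(sample(names(len_weights), n_tags, replace = TRUE,
                              prob = len_weights))
    tags <- random_dna(n_tags, lens, 0.45)
    tags <- make.unique(tags, sep = "")  # vanishing collision chance anyway
    totals <- 1L + stats::rnbinom(n_tags, size = 0.6, mu = 4)
    counts <- t(vapply(totals, function(tt) {
      as.integer(stats::rmultinom(1, tt, rep(1, n_samples)))
    }, integer(n_samples)))
    colnames(counts) <- sprintf("S%d", seq_len(n_samples))
    cbind(data.frame(tag = tags, stringsAsFactors = FALSE),
          as.data.frame(counts))
  })
}

#' Generate block-correlated expression with planted hubs
#'
#' Gaussian factor blocks: gene g in block b is
#' `sqrt(rho) * z_b + sqrt(1 - rho) * e_g` over the samples, giving an
#' expected intra-block correlation of `rho` and ~0 between blocks. One
#' gene per block is wired to the block factor at `hub_cor`, making it the
#' planted hub. A positive count-like matrix (`counts`) on a log2-normal
#' scale is emitted alongside the Gaussian matrix for stages that expect
#' counts.
#'
#' @param n_blocks,genes_per_block,n_samples block design.
#' @param intra_cor target within-block correlation.
#' @param hub_cor correlation of the planted hub with its block factor.
#' @param seed integer seed.
#' @return list: `expr` (Gaussian, genes x samples), `counts` (integer),
#'   `labels` (named block labels), `hubs` (character ids).
#' @export
gen_coexpression_blocks <- function(n_blocks = 4, genes_per_block = 100,
                                    n_samples = 8, intra_cor = 0.8,
                                    hub_cor = 0.95, seed = 1) {
  stopifnot(intra_cor > 0, intra_cor < 1, hub_cor > intra_cor, hub_cor < 1)
  with_seed(seed, {
    n <- n_blocks * genes_per_block
    ids <- sprintf("G%04d", seq_len(n))
    labels <- rep(sprintf("B%d", seq_len(n_blocks)), each = genes_per_block)
    names(labels) <- ids
    hubs <- ids[(seq_len(n_blocks) - 1) * genes_per_block + 1]
    expr <- matrix(0, n, n_samples, dimnames = list(ids, sprintf("S%d", seq_len(n_samples))))
    # block factors: centered, orthogonalized and standardized, so the
    # realized inter-block factor correlation is exactly 0
    if (n_blocks >= n_samples) stop("need fewer blocks than samples")
    Z <- matrix(stats::rnorm(n_samples * n_blocks), n_samples, n_blocks)
    Z <- scale(Z, center = TRUE, scale = FALSE)
    Q <- qr.Q(qr(Z)) * sqrt(n_samples - 1)
    for (b in seq_len(n_blocks)) {
      z <- Q[, b]
      rows <- ((b - 1) * genes_per_block + 1):(b * genes_per_block)
      for (g in rows) {
        rho <- if (ids[g] %in% hubs) hub_cor else intra_cor
        # centre the gene noise and project out the block factor so the
        # realized factor loading is exactly sqrt(rho): the hub is wired
        # to its block at hub_cor by construction, not in expectation
        e <- stats::rnorm(n_samples)
        e <- e - mean(e)
        e <- e - z * sum(e * z) / sum(z * z)
        e <- e / stats::sd(e)
        expr[g, ] <- sqrt(rho) * z + sqrt(1 - rho) * e
      }
    }
    counts <- matrix(as.integer(round(2^(1.2 * expr + 7))),
                     n, n_samples, dimnames = dimnames(expr))
    list(expr = expr, counts = counts, labels = labels, hubs = hubs)
  })
}

#' Simulate a full planted experiment
#'
#' The master generator behind end-to-end tests: transcripts with embedded
#' perfect-complement miRNA target sites, hairpin precursors on dedicated
#' host sequences, eight collapsed small-RNA libraries (background tags
#' plus mature and star reads), a degradome library with planted cleavage
#' peaks, gene and miRNA count matrices with planted anti-/positively
#' correlated trajectories, block-correlated expression with hubs, a
#' synthetic gene-to-term annotation, and the truth manifest tying it all
#' together.
#'
#' Defaults mirror the study design the pipeline targets: 8 time points,
#' 30 planted score-0 interactions against 30 decoy transcripts, cleavage
#' peaks of 5 reads over count-1 background, 10 anti-correlated and 5
#' positively correlated differentially expressed miRNA-target pairs.
#'
#' @param n_transcripts total transcripts (targets + decoys).
#' @param n_mirnas planted miRNAs (each with one target interaction).
#' @param n_negative_pairs,n_positive_pairs planted DE pairs by
#'   correlation sign; the remaining miRNAs/targets stay flat.
#' @param mirna_len mature miRNA length.
#' @param base_mean_gene,base_mean_mirna,dispersion count model.
#' @param peak_count,background_rate degradome model.
#' @param n_background_tags background small-RNA tags.
#' @param n_samples time points (k >= 2; the design default is 8).
#' @param seed integer seed recorded in the manifest.
#' @return list with elements `transcripts`, `mirnas`, `hairpins`,
#'   `hairpin_hosts`, `srna` (tag x library counts), `degradome`,
#'   `gene_counts`, `mirna_counts`, `coexpr`, `gene2term`, `truth`.
#' @export
simulate_experiment <- function(n_transcripts = 60, n_mirnas = 30,
                                n_negative_pairs = 10, n_positive_pairs = 5,
                                mirna_len = 21,
                                base_mean_gene = 200, base_mean_mirna = 50,
                                dispersion = 0.05,
                                peak_count = 5, background_rate = 2,
                                n_background_tags = 300, n_samples = 8,
                                seed = 1) {
  stopifnot(n_mirnas <= n_transcripts,
            n_negative_pairs + n_positive_pairs <= n_mirnas,
            n_samples >= 2)
  seed <- as.integer(seed)
  transcripts <- gen_transcriptome(n_transcripts, c(600, 1200), 0.45,
                                   seed = seed)
  up <- trajectory_up(n_samples)
  down <- trajectory_down(n_samples)

  with_seed(seed + 1L, {
    mirnas <- data.frame(id = sprintf("mir%03d", seq_len(n_mirnas)),
                         seq = random_dna(n_mirnas, mirna_len, 0.5),
                         stringsAsFactors = FALSE)
    # embed the perfect-complement site into the first n_mirnas transcripts
    inter <- vector("list", n_mirnas)
    for (i in seq_len(n_mirnas)) {
      tr <- transcripts$id[i]
      L <- transcripts$length[i]
      site <- revcomp(mirnas$seq[i])
      start <- sample(seq(50L, L - mirna_len - 60L), 1)
      s <- transcripts$seq[i]
      substr(s, start, start + mirna_len - 1) <- site
      transcripts$seq[i] <- s
      # miRNA position 1 pairs the 3'-most site base t1; slicing between the
      # bases paired to positions 10 and 11 puts the 5' end of the 3'
      # fragment at t1 - 9
      t1 <- start + mirna_len - 1
      inter[[i]] <- data.frame(mirna_id = mirnas$id[i], transcript_id = tr,
                               cleavage_pos = t1 - 9L,
                               peak_count = peak_count,
                               stringsAsFactors = FALSE)
    }
    interactions <- do.call(rbind, inter)
  })

  # hairpin precursors on dedicated host sequences
  hairpins <- lapply(seq_len(n_mirnas), function(i) {
    hp <- plant_hairpin(mirnas$seq[i], wobble_count = 0,
                        arm = if (i %% 2 == 0) "3p" else "5p",
                        seed = seed + 100L + i)
    hp$id <- sprintf("hp%03d", i)
    hp$mirna_id <- mirnas$id[i]
    hp
  })
  hairpin_hosts <- with_seed(seed + 2L, {
    pads <- random_dna(2 * n_mirnas, 60, 0.45)
    data.frame(
      id = vapply(hairpins, `[[`, character(1), "id"),
      seq = vapply(seq_len(n_mirnas), function(i) {
        paste0(pads[2 * i - 1], hairpins[[i]]$precursor, pads[2 * i])
      }, character(1)),
      stringsAsFactors = FALSE)
  })
  hairpin_hosts$length <- nchar(hairpin_hosts$seq)

  # planted DE pairs: negative = miRNA up / target down, positive = both up
  neg_idx <- seq_len(n_negative_pairs)
  pos_idx <- seq_len(n_positive_pairs) + n_negative_pairs
  pairs <- data.frame(
    mirna_id = mirnas$id[c(neg_idx, pos_idx)],
    target_id = transcripts$id[c(neg_idx, pos_idx)],
    sign = rep(c("negative", "positive"),
               c(n_negative_pairs, n_positive_pairs)),
    stringsAsFactors = FALSE)

  gene_plan <- c(
    stats::setNames(replicate(n_negative_pairs, down, simplify = FALSE),
                    transcripts$id[neg_idx]),
    stats::setNames(replicate(n_positive_pairs, up, simplify = FALSE),
                    transcripts$id[pos_idx]))
  mirna_plan <- stats::setNames(
    replicate(n_negative_pairs + n_positive_pairs, up, simplify = FALSE),
    mirnas$id[c(neg_idx, pos_idx)])

  gene_counts <- simulate_counts(transcripts$id, base_mean_gene, dispersion,
                                 gene_plan, n_samples, seed = seed + 3L)
  mirna_counts <- simulate_counts(mirnas$id, base_mean_mirna, dispersion,
                                  mirna_plan, n_samples, seed = seed + 4L)

  # small-RNA tag table: background + mature + star reads
  srna_bg <- simulate_srna_background(n_background_tags, n_samples,
                                      seed = seed + 5L)
  mature_tab <- cbind(data.frame(tag = mirnas$seq, stringsAsFactors = FALSE),
                      as.data.frame(mirna_counts))
  star_counts <- pmax(round(mirna_counts * 0.1), 1L)  # pmax keeps dim of arg 1
  star_tab <- cbind(
    data.frame(tag = vapply(hairpins, `[[`, character(1), "star"),
               stringsAsFactors = FALSE),
    as.data.frame(star_counts))
  srna <- rbind(mature_tab, star_tab, srna_bg)
  rownames(srna) <- NULL

  degradome <- simulate_degradome(transcripts, interactions, peak_count,
                                  background_rate, seed = seed + 6L)

  coexpr <- gen_coexpression_blocks(seed = seed + 7L)

  # synthetic annotation: every transcript gets 1-3 generic terms; planted
  # DE targets share a dedicated stress term so enrichment has signal
  gene2term <- with_seed(seed + 8L, {
    terms <- sprintf("T%03d", 1:20)
    rows <- lapply(transcripts$id, function(g) {
      data.frame(gene = g, term = sample(terms, sample(1:3, 1)),
                 stringsAsFactors = FALSE)
    })
    g2t <- do.call(rbind, rows)
    de_targets <- transcripts$id[c(neg_idx, pos_idx)]
    rbind(g2t, data.frame(gene = de_targets, term = "T_stress",
                          stringsAsFactors = FALSE))
  })

  planted_de <- data.frame(
    feature_id = c(transcripts$id[neg_idx], transcripts$id[pos_idx]),
    direction = rep(c("down", "up"), c(n_negative_pairs, n_positive_pairs)),
    stringsAsFactors = FALSE)

  truth <- list(
    planted_mirnas = data.frame(
      id = mirnas$id, mature = mirnas$seq,
      precursor_id = vapply(hairpins, `[[`, character(1), "id"),
      arm = vapply(hairpins, `[[`, character(1), "arm"),
      stringsAsFactors = FALSE),
    planted_interactions = interactions,
    planted_de = planted_de,
    planted_de_trajectories = c(gene_plan, mirna_plan),
    planted_pairs = pairs,
    planted_modules = as.list(coexpr$labels),
    planted_hubs = coexpr$hubs,
    n_samples = n_samples,
    seed = seed)

  list(transcripts = transcripts, mirnas = mirnas, hairpins = hairpins,
       hairpin_hosts = hairpin_hosts, srna = srna, degradome = degradome,
       gene_counts = gene_counts, mirna_counts = mirna_counts,
       coexpr = coexpr, gene2term = gene2term, truth = truth)
}

#' Check that every planted id in the truth manifest resolves
#'
#' @param experiment a [simulate_experiment()] result.
#' @return `TRUE` invisibly; errors on the first unresolved id or
#'   out-of-range cleavage position.
#' @export
validate_manifest <- function(experiment) {
  tr <- experiment$truth
  stopifnot(all(tr$planted_mirnas$id %in% experiment$mirnas$id))
  stopifnot(all(tr$planted_mirnas$precursor_id %in%
                  experiment$hairpin_hosts$id))
  stopifnot(all(tr$planted_mirnas$mature %in% experiment$srna$tag))
  ints <- tr$planted_interactions
  stopifnot(all(ints$transcript_id %in% experiment$transcripts$id))
  lens <- stats::setNames(experiment$transcripts$length,
                          experiment$transcripts$id)
  if (!all(ints$cleavage_pos >= 1 &
             ints$cleavage_pos <= lens[ints$transcript_id])) {
    stop("cleavage position outside its transcript")
  }
  stopifnot(all(tr$planted_de$feature_id %in% rownames(experiment$gene_counts)))
  stopifnot(all(tr$planted_pairs$mirna_id %in% rownames(experiment$mirna_counts)),
            all(tr$planted_pairs$target_id %in% rownames(experiment$gene_counts)))
  stopifnot(all(tr$planted_hubs %in% rownames(experiment$coexpr$expr)))
  invisible(TRUE)
}

#' Write a simulated experiment to disk
#'
#' Emits `transcripts.fa`, `hairpin_hosts.fa`, `mature_mirnas.fa`,
#' `srna_S*.fa` (collapsed-tag FASTA, `>tagid_count` headers),
#' `degradome.fa`, `counts.tsv`, `mirna_counts.tsv`, `coexpr_counts.tsv`,
#' `gene2term.tsv` and `truth_manifest.json`.
#'
#' @param experiment a [simulate_experiment()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir` invisibly.
#' @export
write_experiment <- function(experiment, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_fasta(experiment$transcripts$seq, experiment$transcripts$id,
              p("transcripts.fa"))
  write_fasta(experiment$hairpin_hosts$seq, experiment$hairpin_hosts$id,
              p("hairpin_hosts.fa"))
  write_fasta(experiment$mirnas$seq, experiment$mirnas$id,
              p("mature_mirnas.fa"))
  samp <- grep("^S[0-9]+$", names(experiment$srna), value = TRUE)
  for (s in samp) {
    keep <- experiment$srna[[s]] > 0
    write_fasta(experiment$srna$tag[keep],
                sprintf("t%05d", which(keep)),
                p(sprintf("srna_%s.fa", s)),
                counts = experiment$srna[[s]][keep])
  }
  if (nrow(experiment$degradome) > 0) {
    write_fasta(experiment$degradome$tag, experiment$degradome$tag_id,
                p("degradome.fa"), counts = experiment$degradome$count)
  } else {
    write_fasta(character(0), character(0), p("degradome.fa"))
  }
  write_counts_tsv(experiment$gene_counts, p("counts.tsv"),
                   lengths = experiment$transcripts$length)
  write_counts_tsv(experiment$mirna_counts, p("mirna_counts.tsv"))
  write_counts_tsv(experiment$coexpr$counts, p("coexpr_counts.tsv"))
  write_tsv(experiment$gene2term, p("gene2term.tsv"))
  jsonlite::write_json(experiment$truth, p("truth_manifest.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
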