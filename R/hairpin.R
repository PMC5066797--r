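# Hairpin precursor discovery: excision of candidate precursors around
# mapped tags, MFE statistics (MFE, AMFE, MFEI), and validation of the
# duplex geometry and read coverage in the mature and star regions.

#' Excise candidate precursor subsequences around a mapped tag
#'
#' For each window size w, two candidates are cut: one with the tag on the
#' 5' arm (extended w nt downstream) and one with the tag on the 3' arm
#' (extended w nt upstream), truncated at the transcript bounds. A
#' candidate whose flank is entirely truncated away (tag at a transcript
#' edge) is dropped. `slack` nucleotides are additionally taken on the
#' tag-proximal side so that the short flank a real precursor carries
#' outside its mature arm is not clipped off.
#'
#' @param transcript_seq transcript sequence.
#' @param tag_position 1-based position of the tag's 5' end.
#' @param tag_len tag length.
#' @param windows flank sizes in nt (default c(80, 150, 250), covering
#'   typical plant precursor lengths).
#' @param slack tag-side flank allowance in nt (default 20; 0 cuts
#'   exactly from the tag boundary).
#' @return data.frame `start`, `end`, `seq`, `arm`, `window`,
#'   `mature_span_start`, `mature_span_end` (mature coordinates within the
#'   candidate).
#' @export
excise_candidates <- function(transcript_seq, tag_position, tag_len,
                              windows = c(80, 150, 250), slack = 20) {
  L <- nchar(transcript_seq)
  tag_end <- tag_position + tag_len - 1
  if (tag_position < 1 || tag_end > L) {
    message("tag span outside transcript; no candidates")
    return(data.frame(start = integer(0), end = integer(0),
                      seq = character(0), arm = character(0),
                      window = integer(0), mature_span_start = integer(0),
                      mature_span_end = integer(0)))
  }
  rows <- list()
  for (w in windows) {
    if (tag_end < L) {  # tag on the 5' arm, extend downstream
      start <- max(1, tag_position - slack)
      end <- min(L, tag_end + w)
      rows[[length(rows) + 1]] <- data.frame(
        start = start, end = end,
        seq = substr(transcript_seq, start, end),
        arm = "5p", window = w,
        mature_span_start = tag_position - start + 1L,
        mature_span_end = tag_end - start + 1L,
        stringsAsFactors = FALSE)
    }
    if (tag_position > 1) {  # tag on the 3' arm, extend upstream
      start <- max(1, tag_position - w)
      end <- min(L, tag_end + slack)
      rows[[length(rows) + 1]] <- data.frame(
        start = start, end = end,
        seq = substr(transcript_seq, start, end),
        arm = "3p", window = w,
        mature_span_start = tag_position - start + 1L,
        mature_span_end = tag_end - start + 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' AMFE and MFEI of a folded precursor
#'
#' AMFE is the minimum free energy adjusted per 100 nt,
#' `|MFE| / length * 100`; MFEI divides AMFE by the GC percentage, the
#' dimensionless hairpin-quality index.
#'
#' @param mfe minimum free energy in kcal/mol (<= 0).
#' @param length sequence length in nt (> 0).
#' @param gc GC content in percent (0 < gc < 100).
#' @return list with `amfe` and `mfei`.
#' @export
compute_mfei <- function(mfe, length, gc) {
  stopifnot(length > 0)
  if (any(gc <= 0) || any(gc >= 100)) {
    stop("gc must be a percentage strictly between 0 and 100")
  }
  amfe <- abs(mfe) / length * 100
  list(amfe = amfe, mfei = amfe / gc)
}

#' Validate a candidate hairpin
#'
#' A candidate passes when (a) at least `min_paired_frac` of the mature
#' bases are paired, (b) all pairing partners lie on the opposite arm (no
#' partner inside the mature span, and no partners on both sides of it),
#' and (c) at least `min_coverage_frac` of the reads mapped to the
#' precursor start within +/- `coverage_window` nt of the mature or star
#' 5' ends. MFE statistics are reported, not gated. Reason codes enumerate
#' the failed criteria.
#'
#' @param precursor_seq precursor sequence.
#' @param structure dot-bracket structure of the precursor.
#' @param mature_span 1-based inclusive (start, end) of the mature on the
#'   precursor.
#' @param reads data.frame with `pos` (5'-end positions of reads on the
#'   precursor, 1-based) and `count`; `NULL` or empty fails with
#'   "no-coverage".
#' @param min_paired_frac duplex pairing threshold (default 0.75).
#' @param min_coverage_frac read-concentration threshold (default 0.8).
#' @param coverage_window tolerance around the 5' ends in nt (default 2).
#' @return list: `pass`, `reasons` (character), `frac_paired`,
#'   `coverage_frac`, `star_span` (inferred from the pairing, with the
#'   2-nt 3' overhang), `arm`.
#' @export
validate_hairpin <- function(precursor_seq, structure, mature_span,
                             reads = NULL,
                             min_paired_frac = 0.75,
                             min_coverage_frac = 0.8,
                             coverage_window = 2) {
  reasons <- character(0)
  partner <- pairing_partners(structure)
  mpos <- mature_span[1]:mature_span[2]
  mpart <- partner[mpos]
  frac_paired <- mean(!is.na(mpart))
  if (frac_paired < min_paired_frac) reasons <- c(reasons, "low-pairing")
  inside <- any(!is.na(mpart) & mpart >= mature_span[1] &
                  mpart <= mature_span[2])
  outside <- mpart[!is.na(mpart)]
  outside <- outside[outside < mature_span[1] | outside > mature_span[2]]
  straddles <- length(outside) > 0 &&
    any(outside < mature_span[1]) && any(outside > mature_span[2])
  if (inside || straddles || length(outside) == 0) {
    reasons <- c(reasons, "loop-spanning")
    star_span <- c(NA_integer_, NA_integer_)
    arm <- NA_character_
  } else {
    # star arm = the duplex partner region; star strand runs 5'->3' along
    # the precursor, so the canonical 2-nt 3' overhang shifts it +2
    star_arm <- range(outside)
    star_span <- as.integer(star_arm + 2L)
    arm <- if (star_arm[1] > mature_span[2]) "5p" else "3p"
  }
  coverage_frac <- NA_real_
  if (is.null(reads) || nrow(reads) == 0 || sum(reads$count) == 0) {
    reasons <- c(reasons, "no-coverage")
  } else {
    anchors <- c(mature_span[1], star_span[1])
    anchors <- anchors[!is.na(anchors)]
    near <- vapply(reads$pos, function(p) {
      any(abs(p - anchors) <= coverage_window)
    }, logical(1))
    coverage_frac <- sum(reads$count[near]) / sum(reads$count)
    if (coverage_frac < min_coverage_frac) {
      reasons <- c(reasons, "dispersed-reads")
    }
  }
  list(pass = length(reasons) == 0, reasons = reasons,
       frac_paired = frac_paired, coverage_frac = coverage_frac,
       star_span = star_span, arm = arm)
}

#' Characterize and validate hairpin candidates around unannotated tags
#'
#' The discovery stage: for each candidate tag, its exact loci on the
#' supplied sequences are found, candidate precursors are excised and
#' folded, and the best candidate per locus (most mature bases paired) is
#' validated against the precursor-mapped read stack and annotated with
#' MFE, AMFE, MFEI and GC.
#'
#' @param tags data.frame with `tag` and per-library counts (a catalog);
#'   only rows with `known == FALSE` are used when the column exists.
#' @param sequences data.frame `id`, `seq` to search (e.g. transcripts).
#' @param catalog full tag catalog used to build per-precursor read
#'   stacks (defaults to `tags`).
#' @param engine folding engine.
#' @param windows flank sizes for [excise_candidates()].
#' @param min_mfei optional MFEI gate (default `NULL`: MFEI is reported,
#'   not thresholded).
#' @return data.frame, one row per validated candidate: id, source
#'   sequence, spans, MFE/AMFE/MFEI/GC, structure, pass flag and reasons.
#' @export
find_hairpins <- function(tags, sequences, catalog = tags,
                          engine = fold_engine_default(),
                          windows = c(80, 150, 250), min_mfei = NULL) {
  if ("known" %in% names(tags)) tags <- tags[!tags$known, , drop = FALSE]
  rows <- list()
  subj <- Biostrings::DNAStringSet(
    stats::setNames(sequences$seq, sequences$id))
  for (i in seq_len(nrow(tags))) {
    tg <- tags$tag[i]
    hits <- Biostrings::vmatchPattern(tg, subj)
    for (si in seq_along(hits)) {
      starts <- Biostrings::start(hits[[si]])
      for (pos in starts) {
        cand <- excise_candidates(sequences$seq[si], pos, nchar(tg), windows)
        if (nrow(cand) == 0) next
        folded <- fold(cand$seq, engine)
        paired <- vapply(seq_len(nrow(cand)), function(ci) {
          partner <- pairing_partners(folded$structure[ci])
          span <- cand$mature_span_start[ci]:cand$mature_span_end[ci]
          sum(!is.na(partner[span]))
        }, integer(1))
        best <- which.max(paired)
        pre_seq <- cand$seq[best]
        pre_start <- cand$start[best]
        mspan <- c(cand$mature_span_start[best], cand$mature_span_end[best])
        reads <- precursor_read_stack(catalog, pre_seq)
        gc <- 100 * gc_fraction(pre_seq)
        st <- compute_mfei(folded$mfe[best], nchar(pre_seq), gc)
        val <- validate_hairpin(pre_seq, folded$structure[best], mspan, reads)
        pass <- val$pass
        reasons <- val$reasons
        if (!is.null(min_mfei) && st$mfei < min_mfei) {
          pass <- FALSE; reasons <- c(reasons, "low-mfei")
        }
        rows[[length(rows) + 1]] <- data.frame(
          id = sprintf("%s:%d", sequences$id[si], pre_start),
          tag = tg, source_id = sequences$id[si],
          precursor_start = pre_start, precursor_end = cand$end[best],
          arm = cand$arm[best],
          mature_start = mspan[1], mature_end = mspan[2],
          star_start = val$star_span[1], star_end = val$star_span[2],
          mfe = folded$mfe[best], amfe = st$amfe, mfei = st$mfei, gc = gc,
          frac_paired = val$frac_paired,
          coverage_frac = val$coverage_frac,
          structure = folded$structure[best],
          pass = pass, reasons = paste(reasons, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(id = character(0), tag = character(0),
                      source_id = character(0), pass = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# 5'-end read stack of catalog tags exactly matching a precursor sequence
precursor_read_stack <- function(catalog, precursor_seq) {
  if (is.null(catalog) || nrow(catalog) == 0) {
    return(data.frame(pos = integer(0), count = integer(0)))
  }
  total <- if ("total" %in% names(catalog)) catalog$total else {
    rowSums(catalog[, catalog_sample_cols(catalog), drop = FALSE])
  }
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    m <- gregexpr(catalog$tag[i], precursor_seq, fixed = TRUE)[[1]]
    if (m[1] == -1) next
    rows[[length(rows) + 1]] <- data.frame(pos = as.integer(m),
                                           count = total[i])
  }
  if (length(rows) == 0) {
    return(data.frame(pos = integer(0), count = integer(0)))
  }
  agg <- stats::aggregate(count ~ pos, do.call(rbind, rows), sum)
  agg[order(agg$pos), , drop = FALSE]
}
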