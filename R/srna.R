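# Small-RNA tag catalog: collapsing, length filtering, contaminant removal,
# reference matching with variant nomenclature, length distributions and
# expression tiers.
#
# A catalog is a data.frame with one row per distinct tag: columns `tag`,
# one integer count column per library (S1..Sk) and `total`. Sequences are
# held in the DNA alphabet (U -> T on input).

catalog_sample_cols <- function(catalog) {
  grep("^S[0-9]+$", names(catalog), value = TRUE)
}

empty_catalog <- function(n_samples) {
  df <- data.frame(tag = character(0), stringsAsFactors = FALSE)
  for (s in sprintf("S%d", seq_len(n_samples))) df[[s]] <- integer(0)
  df$total <- integer(0)
  df
}

#' Collapse per-library reads into a tag catalog
#'
#' One row per distinct sequence with per-library counts; reads containing
#' non-nucleotide symbols are skipped with a message. Rows are ordered by
#' total count (descending), ties broken lexicographically, so the catalog
#' is deterministic.
#'
#' @param libraries named list (S1..Sk, in sample order) of character
#'   vectors of reads; RNA or DNA alphabet.
#' @return a catalog data.frame (`tag`, S1..Sk, `total`).
#' @export
collapse_reads <- function(libraries) {
  stopifnot(is.list(libraries), length(libraries) >= 1)
  if (is.null(names(libraries)) || any(!nzchar(names(libraries)))) {
    names(libraries) <- sprintf("S%d", seq_along(libraries))
  }
  k <- length(libraries)
  cleaned <- lapply(libraries, function(reads) {
    reads <- dna_normalize(reads)
    bad <- !is_nucleotide(reads) | !nzchar(reads)
    if (any(bad)) {
      message(sum(bad), " read(s) with non-nucleotide symbols skipped")
    }
    reads[!bad]
  })
  tags <- sort(unique(unlist(cleaned, use.names = FALSE)))
  if (length(tags) == 0) return(empty_catalog(k))
  counts <- vapply(cleaned, function(reads) {
    tab <- table(factor(reads, levels = tags))
    as.integer(tab)
  }, integer(length(tags)))
  counts <- matrix(counts, nrow = length(tags),
                   dimnames = list(NULL, names(libraries)))
  out <- cbind(data.frame(tag = tags, stringsAsFactors = FALSE),
               as.data.frame(counts))
  out$total <- as.integer(rowSums(counts))
  out <- out[order(-out$total, out$tag), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict a catalog to a tag-length window
#'
#' Bounds are inclusive; counts of surviving tags are untouched.
#'
#' @param catalog a tag catalog.
#' @param min,max length window in nt (defaults 17-25).
#' @return the filtered catalog.
#' @export
filter_by_length <- function(catalog, min = 17, max = 25) {
  stopifnot(min <= max)
  len <- nchar(catalog$tag)
  out <- catalog[len >= min & len <= max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove contaminant-derived tags (rRNA/tRNA/snRNA/snoRNA)
#'
#' A tag is removed iff it occurs as an exact substring of any contaminant
#' sequence, on either strand. Exact matching replaces a similarity search
#' for determinism at desk scale.
#'
#' @param catalog a tag catalog.
#' @param contaminants character vector of contaminant sequences, or a
#'   data.frame with a `seq` column.
#' @return list with `kept` and `removed` catalogs (a partition of the
#'   input).
#' @export
remove_contaminants <- function(catalog, contaminants) {
  if (is.data.frame(contaminants)) contaminants <- contaminants$seq
  contaminants <- dna_normalize(contaminants)
  if (length(contaminants) == 0) {
    warning("empty contaminant set; nothing removed")
    return(list(kept = catalog, removed = catalog[0, , drop = FALSE]))
  }
  both <- c(contaminants, revcomp(contaminants))
  hit <- vapply(catalog$tag, function(tg) {
    any(vapply(both, function(cs) grepl(tg, cs, fixed = TRUE), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  kept <- catalog[!hit, , drop = FALSE]
  removed <- catalog[hit, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Match catalog tags against a reference mature-miRNA set
#'
#' Each tag is assigned to the reference mature that minimizes
#' (substitutions, total end shift) within the supported variant grammar
#' (<= `max_sub` substitutions, |shift| <= `max_shift` per end); remaining
#' ties are broken by reference id (lexicographic). Matched tags receive
#' the rendered variant name; unmatched tags are flagged as novel
#' candidates.
#'
#' @param catalog a tag catalog.
#' @param reference data.frame with `id`, `seq` (unique ids).
#' @param max_sub maximum substitutions (default 2).
#' @param max_shift maximum |offset| per end in nt (default 2).
#' @return the catalog with added columns `ref_id`, `variant_name`,
#'   `n_sub`, `left_offset`, `right_offset`, `known` (logical).
#' @export
match_known <- function(catalog, reference, max_sub = 2, max_shift = 2) {
  stopifnot(!anyDuplicated(reference$id))
  ref_seq <- dna_normalize(reference$seq)
  ord <- order(reference$id)  # lexicographic tie-break
  out <- catalog
  out$ref_id <- NA_character_
  out$variant_name <- NA_character_
  out$n_sub <- NA_integer_
  out$left_offset <- NA_integer_
  out$right_offset <- NA_integer_
  if (nrow(catalog) == 0 || nrow(reference) == 0) {
    out$known <- logical(nrow(out))
    return(out)
  }
  for (i in seq_len(nrow(catalog))) {
    best <- NULL; best_id <- NULL
    for (j in ord) {
      cand <- derive_variant(catalog$tag[i], ref_seq[j], max_sub, max_shift)
      if (is.null(cand)) next
      if (is.null(best) ||
            cand$n_sub < best$n_sub ||
            (cand$n_sub == best$n_sub && cand$shift < best$shift)) {
        best <- cand; best_id <- reference$id[j]
      }
    }
    if (!is.null(best)) {
      out$ref_id[i] <- best_id
      out$variant_name[i] <- render_variant_name(
        best_id, best$left_offset, best$right_offset, best$subs)
      out$n_sub[i] <- best$n_sub
      out$left_offset[i] <- best$left_offset
      out$right_offset[i] <- best$right_offset
    }
  }
  out$known <- !is.na(out$ref_id)
  out
}

#' Tag length distribution
#'
#' The redundant histogram weighs each tag by its total read count, the
#' unique histogram by 1; their sums equal the catalog's total reads and
#' tag count.
#'
#' @param catalog a tag catalog.
#' @param range lengths to tabulate (default 17:25).
#' @return data.frame `length`, `unique`, `redundant`.
#' @export
length_distribution <- function(catalog, range = 17:25) {
  len <- nchar(catalog$tag)
  data.frame(
    length = range,
    unique = vapply(range, function(l) sum(len == l), integer(1)),
    redundant = vapply(range, function(l) sum(catalog$total[len == l]),
                       numeric(1)))
}

#' Expression tier of a tag
#'
#' `low` below 10 reads; `high` above the catalog mean abundance; `middle`
#' otherwise (a total exactly at the mean is middle: "high" means strictly
#' over average).
#'
#' @param total total read count(s).
#' @param catalog_mean mean total abundance over the catalog.
#' @return character vector of tiers.
#' @export
expression_tier <- function(total, catalog_mean) {
  stopifnot(all(total >= 0))
  ifelse(total < 10, "low",
         ifelse(total > catalog_mean, "high", "middle"))
}

#' Build an annotated tag catalog from raw libraries
#'
#' Convenience wrapper running collapse -> length filter -> contaminant
#' removal -> reference matching -> tiering; the pipeline's `srna` stage.
#'
#' @param libraries named list of per-library read vectors (S1..Sk), or a
#'   pre-collapsed catalog data.frame.
#' @param contaminants contaminant sequences (may be empty).
#' @param reference mature miRNA reference (data.frame `id`, `seq`).
#' @param min_len,max_len,max_sub,max_shift filtering/matching parameters.
#' @return annotated catalog with `length` and `tier` columns.
#' @export
build_catalog <- function(libraries, contaminants = character(0),
                          reference, min_len = 17, max_len = 25,
                          max_sub = 2, max_shift = 2) {
  catalog <- if (is.data.frame(libraries)) {
    df <- libraries
    df$tag <- dna_normalize(df$tag)
    if (!"total" %in% names(df)) {
      df$total <- as.integer(rowSums(df[, catalog_sample_cols(df),
                                        drop = FALSE]))
    }
    df[order(-df$total, df$tag), , drop = FALSE]
  } else {
    collapse_reads(libraries)
  }
  catalog <- filter_by_length(catalog, min_len, max_len)
  if (length(contaminants) > 0) {
    catalog <- remove_contaminants(catalog, contaminants)$kept
  }
  catalog <- match_known(catalog, reference, max_sub, max_shift)
  catalog$length <- nchar(catalog$tag)
  catalog$tier <- expression_tier(catalog$total, mean(catalog$total))
  rownames(catalog) <- NULL
  catalog
}
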