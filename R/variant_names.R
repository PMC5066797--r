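# Variant nomenclature for sequenced tags relative to a reference mature
# miRNA: end shifts rendered as L+/-n and R+/-n (extension/trim on the 5'
# and 3' ends) and substitutions as "<k>ss<pos><ref><alt>..." with positions
# 1-based on the reference mature. A fully rendered name looks like
# "miR156a_R+1_1ss15GA"; zero components are omitted.

#' Render a variant name
#'
#' @param ref_id reference mature miRNA id.
#' @param left_offset,right_offset signed end shifts (positive = the tag
#'   extends beyond the reference on that side), |offset| <= 2.
#' @param subs data.frame with columns `pos` (1-based on the reference),
#'   `ref`, `alt`; at most 2 rows.
#' @return the rendered name, e.g. `"miR156a_L-1R+1_1ss15GA"`.
#' @export
render_variant_name <- function(ref_id, left_offset = 0, right_offset = 0,
                                subs = NULL) {
  stopifnot(abs(left_offset) <= 2, abs(right_offset) <= 2)
  name <- ref_id
  off <- ""
  if (left_offset != 0) off <- sprintf("L%+d", left_offset)
  if (right_offset != 0) off <- paste0(off, sprintf("R%+d", right_offset))
  if (nzchar(off)) name <- paste0(name, "_", off)
  if (!is.null(subs) && nrow(subs) > 0) {
    if (nrow(subs) > 2) stop("at most 2 substitutions are supported")
    subs <- subs[order(subs$pos), , drop = FALSE]
    name <- paste0(name, "_", nrow(subs), "ss",
                   paste0(subs$pos, subs$ref, subs$alt, collapse = ""))
  }
  name
}

#' Parse a variant name
#'
#' Inverse of [render_variant_name()] on the supported grammar
#' (|offsets| <= 2, <= 2 substitutions). Reference ids may themselves
#' contain underscores; suffix components are stripped from the right.
#'
#' @param name a rendered variant name.
#' @return list with `ref_id`, `left_offset`, `right_offset`, `subs`
#'   (data.frame pos/ref/alt, possibly empty).
#' @export
parse_variant_name <- function(name) {
  stopifnot(length(name) == 1, is.character(name))
  rest <- name
  subs <- data.frame(pos = integer(0), ref = character(0),
                     alt = character(0), stringsAsFactors = FALSE)
  sub_rex <- "_([0-9]+)ss((?:[0-9]+[ACGTU][ACGTU])+)$"
  m <- regmatches(rest, regexec(sub_rex, rest))[[1]]
  if (length(m) == 3) {
    k <- as.integer(m[2])
    body <- m[3]
    pieces <- regmatches(body, gregexpr("[0-9]+[ACGTU][ACGTU]", body))[[1]]
    if (length(pieces) != k) {
      stop("substitution count prefix ", k, " does not match ",
           length(pieces), " rendered substitutions in '", name, "'")
    }
    subs <- data.frame(
      pos = as.integer(sub("[ACGTU][ACGTU]$", "", pieces)),
      ref = substr(sub("^[0-9]+", "", pieces), 1, 1),
      alt = substr(sub("^[0-9]+", "", pieces), 2, 2),
      stringsAsFactors = FALSE)
    rest <- sub(sub_rex, "", rest)
  }
  left <- 0L; right <- 0L
  off_rex <- "_(L[+-][0-9]+)?(R[+-][0-9]+)?$"
  m <- regmatches(rest, regexec("_((?:L[+-][0-9]+)?(?:R[+-][0-9]+)?)$", rest))[[1]]
  if (length(m) == 2 && nzchar(m[2])) {
    tok <- m[2]
    lm <- regmatches(tok, regexec("L([+-][0-9]+)", tok))[[1]]
    rm_ <- regmatches(tok, regexec("R([+-][0-9]+)", tok))[[1]]
    if (length(lm) == 2) left <- as.integer(lm[2])
    if (length(rm_) == 2) right <- as.integer(rm_[2])
    rest <- substr(rest, 1, nchar(rest) - nchar(tok) - 1)
  }
  list(ref_id = rest, left_offset = left, right_offset = right, subs = subs)
}

#' Build a tag sequence from a reference and a variant description
#'
#' Applies substitutions on the reference, then trims or extends each end;
#' extension bases must be supplied (they are not recorded in the name).
#'
#' @param ref_seq reference mature sequence (DNA alphabet).
#' @param left_offset,right_offset signed end shifts.
#' @param subs data.frame pos/ref/alt (positions 1-based on the reference,
#'   inside the surviving region when an end is trimmed).
#' @param fill_left,fill_right bases used for extensions.
#' @return the variant tag sequence.
#' @export
apply_variant <- function(ref_seq, left_offset = 0, right_offset = 0,
                          subs = NULL, fill_left = "", fill_right = "") {
  s <- strsplit(dna_normalize(ref_seq), "")[[1]]
  if (!is.null(subs) && nrow(subs) > 0) {
    for (i in seq_len(nrow(subs))) {
      if (s[subs$pos[i]] != subs$ref[i]) {
        stop("reference base mismatch at position ", subs$pos[i])
      }
      s[subs$pos[i]] <- subs$alt[i]
    }
  }
  if (left_offset < 0) s <- s[-seq_len(-left_offset)]
  if (right_offset < 0) s <- s[seq_len(length(s) + right_offset)]
  paste0(
    if (left_offset > 0) dna_normalize(fill_left) else "",
    paste(s, collapse = ""),
    if (right_offset > 0) dna_normalize(fill_right) else "")
}

# Best variant description of `tag` against one reference: enumerates the
# feasible (left, right) offset pairs (|offset| <= max_shift, lengths must
# agree), counts substitutions over the overlap, and returns the
# description minimizing (substitutions, |L|+|R|), ties broken by smaller
# left then right offset. NULL when nothing fits the grammar.
derive_variant <- function(tag, ref_seq, max_sub = 2, max_shift = 2) {
  tag <- dna_normalize(tag); ref_seq <- dna_normalize(ref_seq)
  tv <- strsplit(tag, "")[[1]]; rv <- strsplit(ref_seq, "")[[1]]
  nt <- length(tv); nr <- length(rv)
  best <- NULL
  for (a in seq(-max_shift, max_shift)) {
    b <- nt - nr - a
    if (abs(b) > max_shift) next
    i <- seq(max(1, 1 - a), min(nr, nt - a))  # reference positions compared
    if (length(i) == 0) next
    mism <- which(rv[i] != tv[i + a])
    if (length(mism) > max_sub) next
    cand <- list(left_offset = a, right_offset = b,
                 n_sub = length(mism),
                 shift = abs(a) + abs(b),
                 subs = if (length(mism) > 0) {
                   data.frame(pos = i[mism], ref = rv[i[mism]],
                              alt = tv[i[mism] + a],
                              stringsAsFactors = FALSE)
                 } else NULL)
    if (is.null(best) ||
          cand$n_sub < best$n_sub ||
          (cand$n_sub == best$n_sub && cand$shift < best$shift) ||
          (cand$n_sub == best$n_sub && cand$shift == best$shift &&
             cand$left_offset < best$left_offset)) {
      best <- cand
    }
  }
  best
}
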