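# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' All generators in the package route their randomness through this helper
#' so that they behave as pure functions of (parameters, seed): the global
#' RNG state is saved and restored afterwards.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Reverse complement of DNA/RNA strings
#'
#' Accepts either alphabet; output is DNA (T, not U).
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTU", "TGCAA", dna_normalize(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Normalize a sequence to the DNA alphabet
#'
#' Sequences are stored internally in the DNA alphabet (U -> T, upper case);
#' [rna_render()] converts back for display.
#'
#' @param x character vector.
#' @return character vector over A/C/G/T (other symbols untouched; use
#'   [is_nucleotide()] to screen).
#' @export
dna_normalize <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

#' @rdname dna_normalize
#' @export
rna_render <- function(x) chartr("T", "U", toupper(x))

#' @rdname dna_normalize
#' @export
is_nucleotide <- function(x) !grepl("[^ACGT]", dna_normalize(x))

# GC fraction of each sequence (0..1)
gc_fraction <- function(x) {
  x <- dna_normalize(x)
  n <- nchar(x)
  gc <- nchar(gsub("[^GC]", "", x))
  ifelse(n == 0, NA_real_, gc / n)
}

# Random DNA strings with a target GC fraction
random_dna <- function(n, len, gc = 0.5) {
  stopifnot(gc > 0, gc < 1)
  if (n == 0) return(character(0))
  len <- rep_len(len, n)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(probs), sum(len), replace = TRUE, prob = probs)
  ends <- cumsum(len)
  starts <- ends - len + 1
  vapply(seq_len(n),
         function(i) paste(bases[starts[i]:ends[i]], collapse = ""),
         character(1))
}

# Dinucleotide-preserving shuffle (Altschul-Erikson): builds the dinucleotide
# multigraph, fixes a random "last edge" arborescence into the terminal
# vertex, shuffles the remaining edges and walks an Eulerian path.
shuffle_dinucleotide <- function(seq, seed = NULL) {
  run <- function() {
    s <- strsplit(dna_normalize(seq), "", fixed = TRUE)[[1]]
    n <- length(s)
    if (n <= 3) return(paste(s, collapse = ""))
    from <- s[-n]; to <- s[-1]
    verts <- unique(s)
    last <- s[n]
    out <- split(to, factor(from, levels = verts))
    # choose last edges forming paths into `last`; rejection-sample until
    # every vertex with outgoing edges reaches `last` through them
    repeat {
      last_edge <- vapply(verts, function(v) {
        if (v == last || length(out[[v]]) == 0) NA_character_
        else sample(out[[v]], 1)
      }, character(1))
      ok <- TRUE
      for (v in verts) {
        if (v == last || length(out[[v]]) == 0) next
        cur <- v; seen <- character(0); reached <- FALSE
        while (!is.na(cur) && !(cur %in% seen)) {
          seen <- c(seen, cur)
          if (cur == last) { reached <- TRUE; break }
          cur <- last_edge[[cur]]
        }
        if (identical(cur, last)) reached <- TRUE
        if (!reached) { ok <- FALSE; break }
      }
      if (ok) break
    }
    # shuffle remaining edges, appending the designated last edge
    lists <- lapply(verts, function(v) {
      e <- out[[v]]
      if (v != last && length(e) > 0) {
        le <- last_edge[[v]]
        i <- match(le, e)
        e <- e[-i]
      } else le <- NULL
      c(sample(e), le)
    })
    names(lists) <- verts
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    res <- character(n)
    res[1] <- s[1]
    cur <- s[1]
    for (i in 2:n) {
      nxt <- lists[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      res[i] <- nxt
      cur <- nxt
    }
    paste(res, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
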