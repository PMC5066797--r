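# RNA secondary-structure folding.
#
# Folding is an injected engine: an engine is a function taking a character
# vector of sequences and returning a data.frame with columns `structure`
# (dot-bracket) and `mfe` (kcal/mol, <= 0). The default engine shells out
# to RNAfold (nearest-neighbour thermodynamic model); a base-pair
# maximization engine is provided for structure-only work and is clearly
# non-thermodynamic (its "mfe" is a pseudo-energy proportional to the pair
# count). Energy-dependent statistics (MFE/AMFE/MFEI) require the
# thermodynamic engine.

#' Default folding engine
#'
#' Returns the RNAfold-backed engine when the `RNAfold` binary is on the
#' PATH; otherwise raises a configuration error (there is no silent
#' fallback for energy-dependent paths).
#'
#' @return an engine function (see [fold()]).
#' @export
fold_engine_default <- function() {
  if (nzchar(Sys.which("RNAfold"))) return(fold_engine_rnafold)
  stop("no thermodynamic folding engine available: RNAfold not found on ",
       "PATH; pass engine = fold_engine_maxpair for structure-only work")
}

#' RNAfold-backed engine
#'
#' @param seqs character vector of sequences (DNA or RNA alphabet).
#' @return data.frame `structure`, `mfe`.
#' @export
fold_engine_rnafold <- function(seqs) {
  if (length(seqs) == 0) {
    return(data.frame(structure = character(0), mfe = numeric(0)))
  }
  inp <- as.vector(rbind(paste0(">s", seq_along(seqs)), rna_render(seqs)))
  out <- suppressWarnings(
    system2("RNAfold", c("--noPS"), input = inp, stdout = TRUE))
  lines <- out[!startsWith(out, ">")]
  # records come as sequence line then "structure ( -x.xx)"
  sl <- lines[seq(2, length(lines), by = 2)]
  m <- regmatches(sl, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", sl))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) stop("unparseable RNAfold output: ", sl[which(bad)[1]])
  data.frame(structure = vapply(m, `[`, character(1), 2),
             mfe = as.numeric(vapply(m, `[`, character(1), 3)))
}

#' Base-pair maximization engine (non-thermodynamic)
#'
#' Nussinov-style dynamic program with a minimum hairpin loop of 3 nt.
#' The reported `mfe` is `-0.1 * pairs`, a pseudo-energy: use only where
#' kcal/mol do not matter.
#'
#' @param seqs character vector of sequences.
#' @return data.frame `structure`, `mfe`.
#' @export
fold_engine_maxpair <- function(seqs) {
  fold1 <- function(s) {
    v <- strsplit(dna_normalize(s), "")[[1]]
    n <- length(v)
    pairs_ok <- function(a, b) {
      (a == "A" && b == "T") || (a == "T" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G") ||
        (a == "G" && b == "T") || (a == "T" && b == "G")
    }
    if (n < 5) return(list(structure = strrep(".", n), mfe = 0))
    D <- matrix(0L, n, n)
    for (span in 4:(n - 1)) {
      for (i in 1:(n - span)) {
        j <- i + span
        best <- D[i + 1, j]  # i unpaired
        for (k in (i + 4):j) {
          if (pairs_ok(v[i], v[k])) {
            left <- if (k - 1 >= i + 1) D[i + 1, k - 1] else 0L
            right <- if (k + 1 <= j) D[k + 1, j] else 0L
            best <- max(best, 1L + left + right)
          }
        }
        D[i, j] <- best
      }
    }
    st <- rep(".", n)
    tb <- function(i, j) {
      while (i < j) {
        if (D[i, j] == (if (i + 1 <= j) D[i + 1, j] else 0L)) { i <- i + 1; next }
        for (k in (i + 4):j) {
          if (pairs_ok(v[i], v[k])) {
            left <- if (k - 1 >= i + 1) D[i + 1, k - 1] else 0L
            right <- if (k + 1 <= j) D[k + 1, j] else 0L
            if (D[i, j] == 1L + left + right) {
              st[i] <<- "("; st[k] <<- ")"
              if (k + 1 <= j) tb(k + 1, j)
              j <- k - 1; i <- i + 1
              break
            }
          }
        }
      }
    }
    tb(1, n)
    np <- sum(st == "(")
    list(structure = paste(st, collapse = ""), mfe = -0.1 * np)
  }
  res <- lapply(seqs, fold1)
  data.frame(structure = vapply(res, `[[`, character(1), "structure"),
             mfe = vapply(res, `[[`, numeric(1), "mfe"))
}

#' Fold sequences
#'
#' Deterministic for fixed input; the result satisfies the folding
#' contract (balanced dot-bracket of the sequence's length, MFE <= 0).
#'
#' @param seqs character vector of sequences.
#' @param engine an engine function; defaults to [fold_engine_default()].
#' @return data.frame `seq`, `structure`, `mfe`.
#' @export
fold <- function(seqs, engine = fold_engine_default()) {
  stopifnot(all(is_nucleotide(seqs)))
  res <- engine(dna_normalize(seqs))
  stopifnot(nrow(res) == length(seqs))
  if (any(nchar(res$structure) != nchar(seqs))) {
    stop("engine violated the contract: structure/sequence length mismatch")
  }
  bal <- vapply(res$structure, function(st) {
    v <- strsplit(st, "")[[1]]
    depth <- cumsum((v == "(") - (v == ")"))
    all(depth >= 0) && depth[length(depth)] == 0
  }, logical(1))
  if (!all(bal)) stop("engine violated the contract: unbalanced brackets")
  if (any(res$mfe > 1e-9)) {
    stop("engine violated the contract: positive MFE")
  }
  cbind(data.frame(seq = as.character(seqs), stringsAsFactors = FALSE), res)
}

#' Pairing partners from a dot-bracket string
#'
#' @param structure dot-bracket string.
#' @return integer vector: `partner[i]` is the paired position of base i,
#'   or `NA` if unpaired.
#' @export
pairing_partners <- function(structure) {
  v <- strsplit(structure, "")[[1]]
  partner <- rep(NA_integer_, length(v))
  stack <- integer(0)
  for (i in seq_along(v)) {
    if (v[i] == "(") stack <- c(stack, i)
    else if (v[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    }
  }
  partner
}
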