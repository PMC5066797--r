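# Readers and writers for the plain-text formats the pipeline touches:
# FASTA (plain and collapsed-tag ">id_count" headers), FASTQ, TSV tables
# and JSON manifests. All tables are written as unquoted, UTF-8 TSV.

#' Read a FASTA file
#'
#' Wrapped records are handled by Biostrings. Collapsed-tag headers of the
#' form `>id_count` (the usual export of read collapsing) can be parsed
#' into a count column.
#'
#' @param path FASTA file.
#' @param collapsed if `TRUE`, parse a trailing `_<integer>` on each header
#'   as the tag's read count.
#' @return a data.frame with columns `id`, `seq`, `length` and, for
#'   `collapsed = TRUE`, `count`.
#' @export
read_fasta <- function(path, collapsed = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  ids <- sub("\\s.*$", "", ids)  # drop description after first whitespace
  seqs <- dna_normalize(as.character(set))
  out <- data.frame(id = ids, seq = unname(seqs),
                    length = nchar(seqs), stringsAsFactors = FALSE)
  if (collapsed) {
    m <- regmatches(out$id, regexec("^(.*)_([0-9]+)$", out$id))
    bad <- vapply(m, length, integer(1)) != 3L
    if (any(bad)) {
      stop("header(s) without a _count suffix: ",
           paste(utils::head(out$id[bad], 3), collapse = ", "))
    }
    out$count <- as.integer(vapply(m, `[`, character(1), 3L))
    out$id <- vapply(m, `[`, character(1), 2L)
  }
  rownames(out) <- NULL
  out
}

#' Write sequences as FASTA
#'
#' @param seqs character vector of sequences.
#' @param ids header ids (recycled names attribute used when missing).
#' @param path output file.
#' @param counts optional integer vector; when given, headers are written
#'   in collapsed-tag form `>id_count`.
#' @export
write_fasta <- function(seqs, ids = names(seqs), path, counts = NULL) {
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (!is.null(counts)) ids <- paste0(ids, "_", as.integer(counts))
  set <- Biostrings::BStringSet(stats::setNames(as.character(seqs), ids))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a FASTQ file
#'
#' A strict four-line-per-record reader for desk-scale libraries; malformed
#' records are reported with their line number.
#'
#' @param path FASTQ file.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  ln <- ln[!(seq_along(ln) > length(ln) - 1 & ln == "")]  # tolerate final blank
  if (length(ln) %% 4 != 0) {
    stop("FASTQ file has ", length(ln), " lines; not a multiple of 4")
  }
  idx <- seq(1, length(ln), by = 4)
  heads <- ln[idx]
  bad <- !startsWith(heads, "@")
  if (any(bad)) {
    stop("line ", idx[which(bad)[1]], ": expected '@' header, got: ",
         heads[which(bad)[1]])
  }
  seqs <- ln[idx + 1]
  quals <- ln[idx + 3]
  mism <- nchar(seqs) != nchar(quals)
  if (any(mism)) {
    i <- which(mism)[1]
    stop("record '", sub("^@", "", heads[i]), "' (line ", idx[i],
         "): sequence and quality lengths differ (",
         nchar(seqs[i]), " vs ", nchar(quals[i]), ")")
  }
  data.frame(id = sub("\\s.*$", "", sub("^@", "", heads)),
             seq = dna_normalize(seqs), qual = quals,
             stringsAsFactors = FALSE)
}

#' Write / read pipeline TSV tables
#'
#' All stage outputs are headered, unquoted, tab-separated text; ids are
#' never quoted.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv_file <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

# counts matrix <-> TSV with a leading feature id column (+ optional length)
write_counts_tsv <- function(counts, path, lengths = NULL) {
  df <- data.frame(feature = rownames(counts), stringsAsFactors = FALSE)
  if (!is.null(lengths)) df$length <- as.integer(lengths)
  df <- cbind(df, as.data.frame(counts))
  write_tsv(df, path)
}

read_counts_tsv <- function(path) {
  df <- read_tsv_file(path)
  has_len <- "length" %in% names(df)
  keep <- setdiff(names(df), c("feature", "length"))
  m <- as.matrix(df[, keep, drop = FALSE])
  rownames(m) <- df$feature
  list(counts = m,
       lengths = if (has_len) stats::setNames(df$length, df$feature) else NULL)
}
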