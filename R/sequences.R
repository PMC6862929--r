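#' Create a sequence store from named sequences
#'
#' A sequence store maps sequence names to nucleotide strings with per-base
#' case preserved: lowercase marks soft-masked (repeat) bases, which is the
#' only masking signal honoured; `N` never matches a seed regardless of case.
#'
#' @param seqs named character vector of sequences (alphabet `ACGTN`, either
#'   case).
#' @return An object of class `"seq_store"`.
#' @export
seq_store <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence name: ",
         names(seqs)[duplicated(names(seqs))][1])
  seqs <- vapply(seqs, as.character, character(1))
  if (any(nchar(seqs) == 0)) stop("empty sequence record")
  bad <- !grepl("^[ACGTNacgtn]*$", seqs)
  if (any(bad))
    stop("non-nucleotide symbols (beyond IUPAC N) in sequence: ",
         names(seqs)[bad][1])
  structure(list(seq = seqs, len = nchar(seqs)), class = "seq_store")
}

#' Load soft-masked FASTA sequences
#'
#' Case (soft-masking) is preserved. Headers are truncated at the first
#' whitespace. Plain and gzip-compressed FASTA are accepted.
#'
#' @param path FASTA file path.
#' @return A `"seq_store"`.
#' @export
load_sequences <- function(path) {
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  names(seqs) <- nm
  seq_store(seqs)
}

#' Write a sequence store to FASTA
#'
#' @param store a `"seq_store"` or named character vector.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(store, path, width = 60L) {
  seqs <- if (inherits(store, "seq_store")) store$seq else store
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement, preserving case
#'
#' @param x nucleotide string.
#' @return reverse-complemented string; lowercase stays lowercase, `N` stays
#'   `N`.
#' @export
reverse_complement <- function(x) {
  y <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(y, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Fetch a subsequence, strand- and mask-aware
#'
#' Coordinates are 0-based half-open. On strand `"-"` the interval addresses
#' the reverse-complemented sequence (UCSC chain convention): the plus-strand
#' equivalent of `[start, end)` is `[size - end, size - start)`.
#'
#' @param store a `"seq_store"`.
#' @param name sequence name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @param unmask if `TRUE`, return uppercase (soft-masking removed); `N`
#'   stays `N`.
#' @return nucleotide string of length `end - start`.
#' @export
fetch_seq <- function(store, name, start, end, strand = "+", unmask = FALSE) {
  stopifnot(inherits(store, "seq_store"))
  if (!name %in% names(store$seq)) stop("unknown sequence: ", name)
  len <- store$len[[name]]
  if (start < 0 || end < start || end > len)
    stop("interval [", start, ",", end, ") out of bounds for ", name,
         " (length ", len, ")")
  if (strand == "+") {
    out <- substr(store$seq[[name]], start + 1, end)
  } else if (strand == "-") {
    out <- substr(store$seq[[name]], len - end + 1, len - start)
    out <- reverse_complement(out)
  } else stop("strand must be '+' or '-'")
  if (unmask) out <- toupper(out)
  out
}

#' @export
print.seq_store <- function(x, ...) {
  cat("<seq_store> ", length(x$seq), " sequence(s)\n", sep = "")
  for (nm in utils::head(names(x$seq), 10))
    cat(sprintf("  %s  %d bp\n", nm, x$len[[nm]]))
  if (length(x$seq) > 10) cat("  ...\n")
  invisible(x)
}
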