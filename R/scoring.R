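#' Construct a scoring scheme
#'
#' Bundles the nucleotide substitution matrix, affine gap penalties (a gap of
#' length `L` costs `gap_open + L * gap_extend`) and the three alignment
#' thresholds: `K` (minimum ungapped/HSP score), `L` (minimum gapped
#' alignment score) and `Y` (Y-drop: a gapped extension abandons any cell
#' whose best score falls more than `Y` below the best seen). `H` is
#' accepted for configuration compatibility but unused (no inner-alignment
#' stage). The ungapped X-drop bound defaults to ten times the largest
#' diagonal matrix entry.
#'
#' @param matrix 4x4 integer substitution matrix with dimnames
#'   `c("A","C","G","T")`.
#' @param gap_open,gap_extend positive affine gap penalties.
#' @param K,L,Y positive score thresholds.
#' @param H ignored; kept so LASTZ-style configurations can be passed
#'   through.
#' @param x_drop ungapped extension termination bound.
#' @return An object of class `"scoring_scheme"`.
#' @export
scoring_scheme <- function(matrix, gap_open = 400, gap_extend = 30,
                           K = 2400, L = 3000, Y = 9400, H = 2000,
                           x_drop = 10 * max(diag(matrix))) {
  bases <- c("A", "C", "G", "T")
  stopifnot(is.matrix(matrix), nrow(matrix) == 4, ncol(matrix) == 4,
            identical(rownames(matrix), bases),
            identical(colnames(matrix), bases))
  if (any(diag(matrix) <= 0)) stop("diagonal matrix entries must be positive")
  if (K <= 0 || L <= 0 || Y <= 0) stop("K, L and Y must be positive")
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be positive")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, K = K, L = L, Y = Y, H = H,
                 x_drop = x_drop),
            class = "scoring_scheme")
}

#' Read a LASTZ-style score file
#'
#' Recognises `O = <gap open>` and `E = <gap extend>` assignments, a header
#' row naming the four bases and four labelled matrix rows; `#` starts a
#' comment.
#'
#' @param path score file path.
#' @param ... thresholds passed on to [scoring_scheme()].
#' @return A `"scoring_scheme"`.
#' @export
read_score_file <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  gap_open <- 400; gap_extend <- 30
  bases <- c("A", "C", "G", "T")
  mat <- NULL
  col_order <- NULL
  for (ln in lines) {
    if (grepl("^[OE]\\s*=", ln)) {
      val <- as.numeric(sub("^[OE]\\s*=\\s*", "", ln))
      if (startsWith(ln, "O")) gap_open <- val else gap_extend <- val
    } else {
      tok <- strsplit(ln, "\\s+")[[1]]
      if (all(tok %in% bases) && length(tok) == 4) {
        col_order <- tok
        mat <- matrix(NA_real_, 4, 4, dimnames = list(bases, bases))
      } else if (!is.null(mat) && tok[1] %in% bases && length(tok) == 5) {
        mat[tok[1], col_order] <- as.numeric(tok[-1])
      } else stop("unrecognised score file line: ", ln)
    }
  }
  if (is.null(mat) || anyNA(mat)) stop("incomplete substitution matrix in ", path)
  scoring_scheme(mat, gap_open = gap_open, gap_extend = gap_extend, ...)
}

#' Default scoring scheme
#'
#' The LASTZ default substitution matrix (HOXD70) with gap open 400 and gap
#' extend 30, read from the score file shipped with the package, and the
#' default thresholds `K = 2400`, `L = 3000`, `Y = 9400` used for first-pass
#' alignment. The gap-filling stage lowers `K` to 2000.
#'
#' @param ... threshold overrides passed to [scoring_scheme()].
#' @return A `"scoring_scheme"`.
#' @export
default_scoring_scheme <- function(...) {
  read_score_file(system.file("extdata", "hoxd70.txt",
                              package = "chaingapfill", mustWork = TRUE),
                  ...)
}

# Expand a 4x4 ACGT matrix to the 5x5 (A,C,G,T,N) integer matrix the C++
# core uses: any column involving N scores the worst matrix entry.
expand_matrix5 <- function(mat) {
  m5 <- matrix(as.integer(min(mat)), 5, 5)
  m5[1:4, 1:4] <- as.integer(mat)
  m5
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "<scoring_scheme> gap %g/%g  K=%g L=%g Y=%g x_drop=%g\n",
    x$gap_open, x$gap_extend, x$K, x$L, x$Y, x$x_drop))
  print(x$matrix)
  invisible(x)
}
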