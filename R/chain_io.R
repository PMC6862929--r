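#' Construct an alignment chain
#'
#' A chain is a co-linear list of ungapped aligned blocks between one
#' reference (target) interval and one query interval, in the UCSC chain
#' convention: each block has a `size` and the numbers of unaligned target
#' (`dt`) and query (`dq`) bases before the next block; the last block has
#' `dt = dq = 0`. Target strand is always `+`; query coordinates on strand
#' `-` are expressed on the reverse-complemented query.
#'
#' @param score chain score (numeric, matrix units).
#' @param tName,tSize,tStart,tEnd target sequence name, length and span
#'   (0-based, half-open).
#' @param qName,qSize,qStrand,qStart,qEnd query sequence name, length,
#'   strand (`"+"` or `"-"`) and span in strand coordinates.
#' @param id chain identifier (kept verbatim on output).
#' @param blocks data frame with integer columns `size`, `dt`, `dq`.
#' @return An object of class `"chain"`.
#' @export
chain <- function(score, tName, tSize, tStart, tEnd,
                  qName, qSize, qStrand, qStart, qEnd, id, blocks) {
  x <- structure(list(
    score = as.numeric(score),
    tName = as.character(tName), tSize = as.numeric(tSize),
    tStart = as.numeric(tStart), tEnd = as.numeric(tEnd),
    qName = as.character(qName), qSize = as.numeric(qSize),
    qStrand = as.character(qStrand),
    qStart = as.numeric(qStart), qEnd = as.numeric(qEnd),
    id = as.character(id),
    blocks = data.frame(size = as.numeric(blocks$size),
                        dt = as.numeric(blocks$dt),
                        dq = as.numeric(blocks$dq))
  ), class = "chain")
  validate_chain(x)
  x
}

#' Validate chain invariants
#'
#' Checks block-span arithmetic (`sum(size) + sum(dt) == tEnd - tStart`, and
#' likewise for the query), positive block sizes, non-negative gaps, a
#' gapless terminal block, in-bounds spans, and the `+` target strand.
#' Called on every parse and before every write.
#'
#' @param x a `"chain"` object.
#' @return `x`, invisibly; an error names the violated invariant.
#' @export
validate_chain <- function(x) {
  stopifnot(inherits(x, "chain"))
  b <- x$blocks
  fail <- function(msg) stop("invalid chain ", x$id, ": ", msg, call. = FALSE)
  if (nrow(b) < 1) fail("chain has no blocks")
  if (any(b$size < 1)) fail("block size < 1")
  if (any(b$dt < 0) || any(b$dq < 0)) fail("negative inter-block gap")
  n <- nrow(b)
  if (b$dt[n] != 0 || b$dq[n] != 0) fail("last block must have dt = dq = 0")
  if (x$qStrand != "+" && x$qStrand != "-") fail("qStrand must be + or -")
  if (x$tStart < 0 || x$tStart > x$tEnd || x$tEnd > x$tSize)
    fail("target span out of bounds")
  if (x$qStart < 0 || x$qStart > x$qEnd || x$qEnd > x$qSize)
    fail("query span out of bounds")
  if (sum(b$size) + sum(b$dt) != x$tEnd - x$tStart)
    fail("block sizes + dt do not sum to the target span")
  if (sum(b$size) + sum(b$dq) != x$qEnd - x$qStart)
    fail("block sizes + dq do not sum to the query span")
  invisible(x)
}

#' Absolute block coordinates of a chain
#'
#' @param x a `"chain"` object.
#' @return data frame with 0-based half-open `t_start`, `t_end`, `q_start`,
#'   `q_end` per block (query in chain strand coordinates).
#' @export
chain_blocks <- function(x) {
  b <- x$blocks
  t0 <- x$tStart + c(0, cumsum(b$size + b$dt))[seq_len(nrow(b))]
  q0 <- x$qStart + c(0, cumsum(b$size + b$dq))[seq_len(nrow(b))]
  data.frame(t_start = t0, t_end = t0 + b$size,
             q_start = q0, q_end = q0 + b$size)
}

#' @export
print.chain <- function(x, ...) {
  cat(sprintf("<chain %s> score %s  %s:%s-%s  %s:%s-%s (%s)  %d block(s)\n",
              x$id, format(x$score, scientific = FALSE),
              x$tName, format(x$tStart, scientific = FALSE),
              format(x$tEnd, scientific = FALSE),
              x$qName, format(x$qStart, scientific = FALSE),
              format(x$qEnd, scientific = FALSE), x$qStrand,
              nrow(x$blocks)))
  invisible(x)
}

#' Parse UCSC chain records from text
#'
#' @param text character vector of lines, or a single string containing
#'   newlines.
#' @return list of `"chain"` objects in input order.
#' @seealso [read_chain_file()], [write_chain_file()]
#' @export
parse_chain_text <- function(text) {
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  chains <- list()
  i <- 1L
  n <- length(text)
  perr <- function(line, msg) stop("chain parse error at line ", line, ": ",
                                   msg, call. = FALSE)
  while (i <= n) {
    line <- trimws(text[i])
    if (line == "" || startsWith(line, "#")) { i <- i + 1L; next }
    tok <- strsplit(line, "[ \t]+")[[1]]
    if (tok[1] != "chain") perr(i, "expected a 'chain' header")
    if (length(tok) != 13) perr(i, "header must have 13 fields")
    num <- suppressWarnings(as.numeric(tok[c(2, 4, 6, 7, 9, 11, 12)]))
    if (anyNA(num) || any(num[-1] != floor(num[-1])))
      perr(i, "non-integer coordinate field in header")
    if (tok[5] != "+") perr(i, "target strand must be '+'")
    if (!tok[10] %in% c("+", "-")) perr(i, "query strand must be '+' or '-'")
    hdr_line <- i
    i <- i + 1L
    size <- numeric(0); dt <- numeric(0); dq <- numeric(0)
    repeat {
      if (i > n) break
      bl <- trimws(text[i])
      if (bl == "") break
      btok <- suppressWarnings(as.numeric(strsplit(bl, "[ \t]+")[[1]]))
      if (anyNA(btok) || !length(btok) %in% c(1, 3) ||
          any(btok != floor(btok)))
        perr(i, "block line must be 'size' or 'size dt dq' (integers)")
      size <- c(size, btok[1])
      dt <- c(dt, if (length(btok) == 3) btok[2] else 0)
      dq <- c(dq, if (length(btok) == 3) btok[3] else 0)
      i <- i + 1L
      if (length(btok) == 1) break
    }
    if (length(size) == 0) perr(hdr_line, "chain has no block lines")
    ch <- tryCatch(
      chain(score = num[1], tName = tok[3], tSize = num[2],
            tStart = num[3], tEnd = num[4],
            qName = tok[8], qSize = num[4 + 1], qStrand = tok[10],
            qStart = num[6], qEnd = num[7], id = tok[13],
            blocks = data.frame(size = size, dt = dt, dq = dq)),
      error = function(e) perr(hdr_line, conditionMessage(e)))
    chains[[length(chains) + 1L]] <- ch
  }
  chains
}

#' Read a UCSC chain file
#'
#' Plain or gzip-compressed files are both accepted.
#'
#' @param path file path.
#' @return list of `"chain"` objects in file order.
#' @export
read_chain_file <- function(path) {
  parse_chain_text(readLines(path))
}

#' Format chains as UCSC chain text
#'
#' Every chain is validated first; block lines are tab-separated, the
#' terminal block line carries the size only, and records are separated by a
#' blank line. Chain ids are preserved verbatim.
#'
#' @param chains list of `"chain"` objects.
#' @return character vector of lines.
#' @export
format_chain_text <- function(chains) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  if (length(chains) == 0) return(character(0))
  out <- vector("list", length(chains))
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    validate_chain(ch)
    hdr <- paste("chain", fmt(ch$score), ch$tName, fmt(ch$tSize), "+",
                 fmt(ch$tStart), fmt(ch$tEnd), ch$qName, fmt(ch$qSize),
                 ch$qStrand, fmt(ch$qStart), fmt(ch$qEnd), ch$id)
    b <- ch$blocks
    n <- nrow(b)
    lines <- character(n)
    if (n > 1)
      lines[seq_len(n - 1)] <- paste(fmt(b$size[-n]), fmt(b$dt[-n]),
                                     fmt(b$dq[-n]), sep = "\t")
    lines[n] <- fmt(b$size[n])
    out[[i]] <- c(hdr, lines, "")
  }
  unlist(out, use.names = FALSE)
}

#' Write chains to a UCSC chain file
#'
#' @param chains list of `"chain"` objects.
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @return `path`, invisibly.
#' @export
write_chain_file <- function(chains, path) {
  lines <- format_chain_text(chains)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
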