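#' Read a piecewise-linear gap cost table
#'
#' The file has a comment header and three tab-separated columns: gap `size`
#' (bp), `single` (cost when only one genome has unaligned bases) and `both`
#' (cost, evaluated at `dt + dq`, when both do). Costs are interpolated
#' linearly between breakpoints using integer (floor) arithmetic and
#' extrapolated with the last slope beyond the table; `cost(0) = 0`.
#'
#' @param path table path.
#' @return An object of class `"gap_cost_table"`.
#' @export
read_gap_cost_file <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  stopifnot(all(c("size", "single", "both") %in% names(tab)))
  gap_cost_table(tab$size, tab$single, tab$both)
}

#' Construct a gap cost table
#'
#' @param size strictly increasing positive gap sizes (breakpoints, bp).
#' @param single per-breakpoint costs for one-sided gaps.
#' @param both per-breakpoint costs for two-sided gaps (applied at
#'   `dt + dq`).
#' @return An object of class `"gap_cost_table"`.
#' @export
gap_cost_table <- function(size, single, both) {
  stopifnot(length(size) >= 2, length(single) == length(size),
            length(both) == length(size))
  if (any(diff(size) <= 0)) stop("breakpoints must be strictly increasing")
  if (any(size < 1)) stop("breakpoints must be >= 1")
  if (any(single < 0) || any(both < 0)) stop("costs must be non-negative")
  if (any(diff(single) < 0) || any(diff(both) < 0))
    stop("costs must be non-decreasing in gap size")
  structure(list(size = as.numeric(size), single = as.numeric(single),
                 both = as.numeric(both)),
            class = "gap_cost_table")
}

#' Default gap cost table
#'
#' The UCSC axtChain "loose" linear-gap schedule shipped with the package.
#'
#' @return A `"gap_cost_table"`.
#' @export
default_gap_costs <- function() {
  read_gap_cost_file(system.file("extdata", "loose_gap_costs.txt",
                                 package = "chaingapfill", mustWork = TRUE))
}

# floor-interpolate one cost column at the given sizes (vectorised)
interp_cost <- function(bp, costs, sizes) {
  out <- numeric(length(sizes))
  nz <- sizes > 0
  s <- sizes[nz]
  i <- findInterval(s, bp)
  v <- numeric(length(s))
  below <- i == 0            # 0 < size < first breakpoint
  v[below] <- (costs[1] * s[below]) %/% bp[1]
  last <- i >= length(bp)    # extrapolate with the last slope
  if (any(last)) {
    nb <- length(bp)
    v[last] <- costs[nb] +
      ((costs[nb] - costs[nb - 1]) * (s[last] - bp[nb])) %/%
        (bp[nb] - bp[nb - 1])
  }
  mid <- !below & !last
  if (any(mid)) {
    im <- i[mid]
    v[mid] <- costs[im] +
      ((costs[im + 1] - costs[im]) * (s[mid] - bp[im])) %/%
        (bp[im + 1] - bp[im])
  }
  out[nz] <- v
  out
}

#' Gap cost of a chain connection
#'
#' `dt = dq = 0` costs 0; a one-sided gap uses the `single` schedule at its
#' size; a two-sided gap uses the `both` schedule at `dt + dq`.
#'
#' @param table a `"gap_cost_table"`.
#' @param dt,dq unaligned target/query bases (non-negative; vectorised).
#' @return integer-valued numeric cost(s).
#' @export
gap_cost <- function(table, dt, dq) {
  stopifnot(inherits(table, "gap_cost_table"))
  if (any(dt < 0) || any(dq < 0)) stop("gap sizes must be non-negative")
  n <- max(length(dt), length(dq))
  dt <- rep_len(dt, n); dq <- rep_len(dq, n)
  out <- numeric(n)
  one <- xor(dt > 0, dq > 0)
  two <- dt > 0 & dq > 0
  out[one] <- interp_cost(table$size, table$single, (dt + dq)[one])
  out[two] <- interp_cost(table$size, table$both, (dt + dq)[two])
  out
}

# Trim leading alignment columns from a local alignment until its start
# clears (t_min, q_min) on both genomes. The trimmed score is scaled by the
# kept fraction of aligned columns, floored to an integer. Returns NULL when
# nothing survives.
trim_alignment_start <- function(aln, t_min, q_min) {
  segs <- aln$segments
  total <- sum(segs$size)
  keep <- list()
  trimmed <- 0
  for (r in seq_len(nrow(segs))) {
    t0 <- segs$t_start[r]; q0 <- segs$q_start[r]; len <- segs$size[r]
    adv <- max(0, t_min - t0, q_min - q0)
    if (adv >= len) { trimmed <- trimmed + len; next }
    if (adv > 0) {
      trimmed <- trimmed + adv
      t0 <- t0 + adv; q0 <- q0 + adv; len <- len - adv
      t_min <- -Inf; q_min <- -Inf   # later segments already clear
    }
    keep[[length(keep) + 1]] <- data.frame(t_start = t0, q_start = q0,
                                           size = len)
    t_min <- -Inf; q_min <- -Inf
  }
  if (length(keep) == 0) return(NULL)
  segs2 <- do.call(rbind, keep)
  kept <- sum(segs2$size)
  local_alignment(floor(aln$score * kept / total), segs2)
}

#' Construct a local alignment object
#'
#' @param score alignment score (matrix units, includes gap penalties).
#' @param segments data frame of ungapped segments with 0-based columns
#'   `t_start`, `q_start`, `size`; strictly co-linear.
#' @return An object of class `"local_alignment"`.
#' @export
local_alignment <- function(score, segments) {
  segments <- data.frame(t_start = as.numeric(segments$t_start),
                         q_start = as.numeric(segments$q_start),
                         size = as.numeric(segments$size))
  if (nrow(segments) == 0) stop("alignment must have at least one segment")
  if (any(segments$size < 1)) stop("segment size < 1")
  te <- segments$t_start + segments$size
  qe <- segments$q_start + segments$size
  if (nrow(segments) > 1) {
    ok <- all(segments$t_start[-1] >= te[-nrow(segments)]) &&
      all(segments$q_start[-1] >= qe[-nrow(segments)])
    if (!ok) stop("segments are not co-linear")
  }
  structure(list(score = as.numeric(score), segments = segments,
                 t_start = segments$t_start[1], t_end = te[nrow(segments)],
                 q_start = segments$q_start[1], q_end = qe[nrow(segments)]),
            class = "local_alignment")
}

#' Chain local alignments of one gap into the best co-linear mini chain
#'
#' Dynamic programming over fragments ordered by start coordinate: each
#' fragment's best predecessor maximises cumulative score minus the
#' [gap_cost()] of the connection. A successor that overlaps its predecessor
#' on either genome is trimmed from its start (whole alignment columns) and
#' its score reduced proportionally. The single best-scoring chain is
#' returned; secondary chains are not.
#'
#' @param alignments list of `"local_alignment"` objects from one gap, all
#'   in the same orientation.
#' @param table a `"gap_cost_table"`.
#' @return A `"mini_chain"` (list with `score`, `members` - the possibly
#'   trimmed member alignments in order - and `member_idx`, their indices in
#'   `alignments`), or `NULL` when `alignments` is empty.
#' @export
chain_fragments <- function(alignments, table = default_gap_costs()) {
  alignments <- Filter(Negate(is.null), alignments)
  n <- length(alignments)
  if (n == 0) return(NULL)
  ts <- vapply(alignments, `[[`, numeric(1), "t_start")
  qs <- vapply(alignments, `[[`, numeric(1), "q_start")
  te <- vapply(alignments, `[[`, numeric(1), "t_end")
  qe <- vapply(alignments, `[[`, numeric(1), "q_end")
  sc <- vapply(alignments, `[[`, numeric(1), "score")
  ord <- order(ts, qs, te, qe, -sc)
  dp <- sc[ord]
  prev <- rep(0L, n)
  used <- vector("list", n)      # fragment as used (possibly trimmed)
  for (i in seq_len(n)) used[[i]] <- alignments[[ord[i]]]
  for (i in seq_len(n)) {
    ai <- alignments[[ord[i]]]
    for (j in seq_len(i - 1L)) {
      aj_end_t <- te[ord[j]]; aj_end_q <- qe[ord[j]]
      if (te[ord[i]] <= aj_end_t || qe[ord[i]] <= aj_end_q) next
      cand <- ai
      if (ts[ord[i]] < aj_end_t || qs[ord[i]] < aj_end_q) {
        cand <- trim_alignment_start(ai, aj_end_t, aj_end_q)
        if (is.null(cand)) next
      }
      cost <- gap_cost(table, cand$t_start - aj_end_t,
                       cand$q_start - aj_end_q)
      val <- dp[j] + cand$score - cost
      if (val > dp[i]) {
        dp[i] <- val
        prev[i] <- j
        used[[i]] <- cand
      }
    }
  }
  best <- which.max(dp)
  idx <- best
  while (prev[idx[1]] != 0L) idx <- c(prev[idx[1]], idx)
  structure(list(score = dp[best],
                 members = used[idx],
                 member_idx = ord[idx]),
            class = "mini_chain")
}

#' @export
print.mini_chain <- function(x, ...) {
  cat(sprintf("<mini_chain> score %g, %d member(s)\n", x$score,
              length(x$members)))
  invisible(x)
}

#' Recompute a chain score from sequence
#'
#' The score is the sum of substitution-matrix scores over all aligned
#' columns (on uppercased sequence; any column involving `N` scores the
#' worst matrix entry) minus the [gap_cost()] of every interior gap.
#'
#' @param chain a `"chain"`.
#' @param target_store,query_store `"seq_store"` objects resolving the chain
#'   coordinates.
#' @param scheme a `"scoring_scheme"` (only the matrix is used).
#' @param table a `"gap_cost_table"`.
#' @return numeric score.
#' @export
score_chain <- function(chain, target_store, query_store,
                        scheme = default_scoring_scheme(),
                        table = default_gap_costs()) {
  validate_chain(chain)
  tseq <- fetch_seq(target_store, chain$tName, chain$tStart, chain$tEnd,
                    "+", unmask = TRUE)
  qseq <- fetch_seq(query_store, chain$qName, chain$qStart, chain$qEnd,
                    chain$qStrand, unmask = TRUE)
  m5 <- expand_matrix5(scheme$matrix)
  code <- integer(256)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[code == 0L] <- 5L
  ct <- code[utf8ToInt(tseq)]
  cq <- code[utf8ToInt(qseq)]
  b <- chain$blocks
  rel_t <- c(0, cumsum(b$size + b$dt))[seq_len(nrow(b))]
  rel_q <- c(0, cumsum(b$size + b$dq))[seq_len(nrow(b))]
  it <- sequence(b$size) + rep(rel_t, b$size)
  iq <- sequence(b$size) + rep(rel_q, b$size)
  col_score <- sum(m5[cbind(ct[it], cq[iq])])
  gaps <- b[-nrow(b), , drop = FALSE]
  gcost <- if (nrow(gaps)) sum(gap_cost(table, gaps$dt, gaps$dq)) else 0
  col_score - gcost
}
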