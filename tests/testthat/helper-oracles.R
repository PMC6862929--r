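# Independent oracles and fixture generators used across the suite.
# These deliberately re-derive results by brute force, straight from the
# definitions, and share no code with the implementation paths they check.

DNA <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

mutate_subs <- function(x, nsub) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  if (nsub > 0) {
    for (p in sample(length(ch), nsub))
      ch[p] <- sample(setdiff(DNA, ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# expand a 4x4 ACGT matrix so row/col 5 (N) scores the worst entry
mat5_of <- function(scheme) {
  m5 <- matrix(min(scheme$matrix), 5, 5)
  m5[1:4, 1:4] <- scheme$matrix
  m5
}

# Brute-force affine-gap local alignment score (3-state Smith-Waterman).
# A gap of length L costs open + L*ext (first gap base: open + ext).
sw_affine <- function(a, b, m5, open, ext) {
  A <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  B <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  if (n == 0 || m == 0) return(0)
  NEG <- -1e15
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  ai <- match(A, DNA, nomatch = 5)
  bi <- match(B, DNA, nomatch = 5)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      d <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1], 0)
      M[i, j] <- d + m5[ai[i - 1], bi[j - 1]]
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

best_align_score <- function(alns) {
  if (length(alns) == 0) 0 else max(vapply(alns, `[[`, numeric(1), "score"))
}

# brute-force enumeration of all matching N-free k-mer position pairs
seeds_brute <- function(ref, query, k) {
  r <- toupper(ref); q <- toupper(query)
  out <- NULL
  if (nchar(r) >= k && nchar(q) >= k) {
    rk <- substring(r, 1:(nchar(r) - k + 1), k:nchar(r))
    qk <- substring(q, 1:(nchar(q) - k + 1), k:nchar(q))
    for (i in seq_along(rk)) {
      if (grepl("N", rk[i], fixed = TRUE)) next
      j <- which(qk == rk[i])
      if (length(j))
        out <- rbind(out, data.frame(t_pos = i - 1, q_pos = j - 1))
    }
  }
  if (is.null(out))
    out <- data.frame(t_pos = integer(0), q_pos = integer(0))
  out[order(out$t_pos, out$q_pos), , drop = FALSE]
}

# best ungapped diagonal sub-segment containing the seed columns, by
# exhaustive scan over all (left, right) bounds
ungapped_brute <- function(ref, query, t, q, k, m5) {
  A <- match(strsplit(toupper(ref), "")[[1]], DNA, nomatch = 5)
  B <- match(strsplit(toupper(query), "")[[1]], DNA, nomatch = 5)
  col <- function(i) m5[A[t + 1 + i], B[q + 1 + i]]  # offset from seed start
  lmax <- min(t, q); rmax <- min(length(A) - t, length(B) - q) - k
  best <- -Inf; bl <- 0; br <- 0
  for (l in 0:lmax) {
    for (r in 0:rmax) {
      s <- sum(vapply((-l):(k - 1 + r), col, numeric(1)))
      if (s > best) { best <- s; bl <- l; br <- r }
    }
  }
  list(score = best, t_start = t - bl, t_end = t + k + br)
}

# naive single-pass chain scorer, independent of score_chain's vectorised path
score_chain_naive <- function(chain, tstore, qstore, scheme, table) {
  m5 <- mat5_of(scheme)
  tseq <- toupper(fetch_seq(tstore, chain$tName, chain$tStart, chain$tEnd))
  qseq <- toupper(fetch_seq(qstore, chain$qName, chain$qStart, chain$qEnd,
                            chain$qStrand))
  A <- match(strsplit(tseq, "")[[1]], DNA, nomatch = 5)
  B <- match(strsplit(qseq, "")[[1]], DNA, nomatch = 5)
  total <- 0
  ti <- 1; qi <- 1
  b <- chain$blocks
  for (r in seq_len(nrow(b))) {
    for (z in seq_len(b$size[r])) {
      total <- total + m5[A[ti], B[qi]]
      ti <- ti + 1; qi <- qi + 1
    }
    if (r < nrow(b)) {
      total <- total - gap_cost(table, b$dt[r], b$dq[r])
      ti <- ti + b$dt[r]; qi <- qi + b$dq[r]
    }
  }
  total
}

# exhaustive mini-chain search: every subset of fragments, ordered by
# t_start, connected under the documented trim + gap-cost rule
chain_brute <- function(alignments, table) {
  n <- length(alignments)
  ts <- vapply(alignments, `[[`, numeric(1), "t_start")
  best <- -Inf
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) != 0)
    idx <- idx[order(ts[idx])]
    score <- NA
    end_t <- -Inf; end_q <- -Inf
    ok <- TRUE
    for (i in idx) {
      a <- alignments[[i]]
      if (is.infinite(end_t)) {
        score <- a$score
      } else {
        if (a$t_end <= end_t || a$q_end <= end_q) { ok <- FALSE; break }
        a2 <- trim_brute(a, end_t, end_q)
        if (is.null(a2)) { ok <- FALSE; break }
        score <- score + a2$score -
          gap_cost(table, a2$t_start - end_t, a2$q_start - end_q)
        a <- a2
      }
      end_t <- a$t_end; end_q <- a$q_end
    }
    if (ok && score > best) best <- score
  }
  best
}

# independent re-statement of the trim rule: drop whole leading columns
# until the start clears (t_min, q_min); score scaled by floor
trim_brute <- function(a, t_min, q_min) {
  cols <- NULL
  for (r in seq_len(nrow(a$segments))) {
    s <- a$segments[r, ]
    cols <- rbind(cols, data.frame(t = s$t_start + 0:(s$size - 1),
                                   q = s$q_start + 0:(s$size - 1)))
  }
  keep <- cols$t >= t_min & cols$q >= q_min
  first <- which(keep)[1]
  if (is.na(first)) return(NULL)
  cols <- cols[first:nrow(cols), , drop = FALSE]
  kept <- nrow(cols)
  segs <- data.frame(t_start = numeric(0), q_start = numeric(0),
                     size = numeric(0))
  for (r in seq_len(nrow(cols))) {
    nlast <- nrow(segs)
    if (nlast > 0 && cols$t[r] == segs$t_start[nlast] + segs$size[nlast] &&
        cols$q[r] == segs$q_start[nlast] + segs$size[nlast]) {
      segs$size[nlast] <- segs$size[nlast] + 1
    } else {
      segs <- rbind(segs, data.frame(t_start = cols$t[r], q_start = cols$q[r],
                                     size = 1))
    }
  }
  local_alignment(floor(a$score * kept / sum(a$segments$size)), segs)
}

# random but valid chain record generator for round-trip fuzzing
random_chain <- function(id) {
  nb <- sample(1:6, 1)
  size <- sample(1:50, nb, replace = TRUE)
  dt <- c(sample(0:40, nb - 1, replace = TRUE), 0)
  dq <- c(sample(0:40, nb - 1, replace = TRUE), 0)
  tlen <- sum(size) + sum(dt)
  qlen <- sum(size) + sum(dq)
  tstart <- sample(0:100, 1)
  qstart <- sample(0:100, 1)
  chain(score = sample(1:1e6, 1), tName = "tChr", tSize = tstart + tlen + 50,
        tStart = tstart, tEnd = tstart + tlen,
        qName = "qChr", qSize = qstart + qlen + 50,
        qStrand = sample(c("+", "-"), 1),
        qStart = qstart, qEnd = qstart + qlen,
        id = as.character(id),
        blocks = data.frame(size = size, dt = dt, dq = dq))
}

# all aligned (t, q) base pairs of a chain, for before/after comparisons
chain_pairs <- function(chain) {
  co <- chain_blocks(chain)
  do.call(rbind, lapply(seq_len(nrow(co)), function(i) {
    len <- co$t_end[i] - co$t_start[i]
    data.frame(t = co$t_start[i] + 0:(len - 1),
               q = co$q_start[i] + 0:(len - 1))
  }))
}

# small soft-masked genome pair sharing a planted repeat copy inside
# otherwise random (unrelated) gap interiors, for fill_gap tests
planted_gap_pair <- function(copy_len = 300, divergence = 0.1,
                             flank = 60) {
  copy <- rand_seq(copy_len)
  t_gap <- paste0(rand_seq(flank), tolower(mutate_subs(copy, rbinom(1, copy_len, divergence))),
                  rand_seq(flank))
  q_gap <- paste0(rand_seq(flank), tolower(mutate_subs(copy, rbinom(1, copy_len, divergence))),
                  rand_seq(flank))
  list(t_gap = t_gap, q_gap = q_gap, copy_len = copy_len, flank = flank)
}
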