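cfg0 <- fill_config()

test_that("the default configuration is the published operating point", {
  expect_equal(cfg0$min_gap, 30L)
  expect_equal(cfg0$max_gap, 20000L)
  expect_equal(cfg0$min_chain_score, 25000)
  expect_equal(cfg0$min_mini_score, 5000)
  expect_equal(cfg0$scheme$K, 2000)
  expect_equal(cfg0$scheme$L, 3000)
  expect_equal(cfg0$scheme$Y, 9400)
  expect_error(fill_config(min_gap = 50, max_gap = 40), "min_gap")
})

# a chain with five interior gaps probing the size rule
gapped_chain <- function(score) {
  dt <- c(29, 30, 40, 20000, 20001, 0)
  dq <- c(35, 30, 10, 20000, 300, 0)
  size <- rep(10, 6)
  tlen <- sum(size) + sum(dt); qlen <- sum(size) + sum(dq)
  chain(score = score, tName = "t", tSize = tlen, tStart = 0, tEnd = tlen,
        qName = "q", qSize = qlen, qStrand = "+", qStart = 0, qEnd = qlen,
        id = "1", blocks = data.frame(size = size, dt = dt, dq = dq))
}

test_that("gap enumeration applies the 30-20000 bp rule to both genomes", {
  gaps <- enumerate_gaps(gapped_chain(30000), cfg0)
  # dt=29 fails min on target; dq=10 fails min on query; dt=20001 fails max;
  # only (30,30) and (20000,20000) qualify
  expect_equal(gaps$block_index, c(2L, 4L))
  expect_equal(gaps$t_end - gaps$t_start, c(30, 20000))
  expect_equal(gaps$q_end - gaps$q_start, c(30, 20000))

  single <- chain(score = 30000, tName = "t", tSize = 10, tStart = 0,
                  tEnd = 10, qName = "q", qSize = 10, qStrand = "+",
                  qStart = 0, qEnd = 10, id = "s",
                  blocks = data.frame(size = 10, dt = 0, dq = 0))
  expect_equal(nrow(enumerate_gaps(single, cfg0)), 0)
})

test_that("the chain score filter is strict: score must exceed 25,000", {
  expect_equal(nrow(enumerate_gaps(gapped_chain(24999), cfg0)), 0)
  expect_equal(nrow(enumerate_gaps(gapped_chain(25000), cfg0)), 0)
  expect_gt(nrow(enumerate_gaps(gapped_chain(25001), cfg0)), 0)
})

# build a two-block chain whose single gap holds the given fragments
chain_with_gap <- function(t_gap, q_gap, flank_seq, score = 30000) {
  fl <- nchar(flank_seq)
  tseq <- paste0(flank_seq, t_gap, flank_seq)
  qseq <- paste0(flank_seq, q_gap, flank_seq)
  ch <- chain(score = score, tName = "t", tSize = nchar(tseq), tStart = 0,
              tEnd = nchar(tseq), qName = "q", qSize = nchar(qseq),
              qStart = 0, qEnd = nchar(qseq), qStrand = "+", id = "1",
              blocks = data.frame(size = c(fl, fl),
                                  dt = c(nchar(t_gap), 0),
                                  dq = c(nchar(q_gap), 0)))
  list(chain = ch,
       tstore = seq_store(c(t = tseq)),
       qstore = seq_store(c(q = qseq)))
}

test_that("fill_gap recovers a planted repeat copy and rejects noise", {
  set.seed(43)
  pg <- planted_gap_pair(copy_len = 300, divergence = 0.1, flank = 60)
  sc <- chain_with_gap(pg$t_gap, pg$q_gap, rand_seq(50))
  gap <- enumerate_gaps(sc$chain, cfg0)
  expect_equal(nrow(gap), 1)
  mini <- fill_gap(sc$chain, gap[1, ], sc$tstore, sc$qstore, cfg0)
  expect_false(is.null(mini))
  segs <- do.call(rbind, lapply(mini$members, `[[`, "segments"))
  copy_cov <- sum(pmin(segs$t_start + segs$size, pg$flank + pg$copy_len) -
                    pmax(segs$t_start, pg$flank))
  expect_gte(copy_cov, 0.8 * pg$copy_len)

  # unrelated random gap sequences: nothing reaches the thresholds
  for (i in 1:5) {
    sc <- chain_with_gap(rand_seq(400), rand_seq(400), rand_seq(50))
    gap <- enumerate_gaps(sc$chain, cfg0)
    expect_null(fill_gap(sc$chain, gap[1, ], sc$tstore, sc$qstore, cfg0))
  }
})

test_that("the mini-chain score threshold is inclusive", {
  set.seed(47)
  shared <- rand_seq(55)
  sc <- chain_with_gap(paste0(rand_seq(80), shared, rand_seq(80)),
                       paste0(rand_seq(80), shared, rand_seq(80)),
                       rand_seq(50))
  gap <- enumerate_gaps(sc$chain, cfg0)
  probe <- fill_gap(sc$chain, gap[1, ], sc$tstore, sc$qstore,
                    fill_config(min_mini_score = 0))
  expect_false(is.null(probe))
  s <- probe$score
  at <- fill_gap(sc$chain, gap[1, ], sc$tstore, sc$qstore,
                 fill_config(min_mini_score = s))
  expect_equal(at$score, s)
  above <- fill_gap(sc$chain, gap[1, ], sc$tstore, sc$qstore,
                    fill_config(min_mini_score = s + 1))
  expect_null(above)
})

mini_of <- function(t_off, q_off, size, score = 6000) {
  structure(list(score = score,
                 members = list(local_alignment(
                   score, data.frame(t_start = t_off, q_start = q_off,
                                     size = size))),
                 member_idx = 1L), class = "mini_chain")
}

test_that("insertion subdivides the gap, conserving span sums", {
  sc <- chain_with_gap(strrep("A", 200), strrep("C", 200), strrep("G", 50))
  gap <- enumerate_gaps(sc$chain, cfg0)[1, ]
  mini <- mini_of(75, 75, 50)
  out <- insert_mini_chain(sc$chain, gap, mini)
  expect_equal(nrow(out$blocks), 3)
  b <- out$blocks
  expect_equal(b$dt[1] + 50 + b$dt[2], 200)   # old dt = dt1 + size + dt2
  expect_equal(b$dq[1] + 50 + b$dq[2], 200)
  expect_equal(sum(b$size) + sum(b$dt), sc$chain$tEnd - sc$chain$tStart)
  validate_chain(out)
})

test_that("blocks flush against a neighbour are merged", {
  sc <- chain_with_gap(strrep("A", 200), strrep("C", 200), strrep("G", 50))
  gap <- enumerate_gaps(sc$chain, cfg0)[1, ]
  # flush upstream on both genomes: absorbed into the preceding block
  out <- insert_mini_chain(sc$chain, gap, mini_of(0, 0, 40))
  expect_equal(nrow(out$blocks), 2)
  expect_equal(out$blocks$size[1], 90)
  # flush downstream on both genomes: absorbed into the following block
  out <- insert_mini_chain(sc$chain, gap, mini_of(160, 160, 40))
  expect_equal(nrow(out$blocks), 2)
  expect_equal(out$blocks$size[2], 90)
  # spanning the whole gap: single merged block remains
  out <- insert_mini_chain(sc$chain, gap, mini_of(0, 0, 200))
  expect_equal(nrow(out$blocks), 1)
  expect_equal(out$blocks$size, 300)
})

test_that("a mini chain escaping its gap is an internal error", {
  sc <- chain_with_gap(strrep("A", 200), strrep("C", 200), strrep("G", 50))
  gap <- enumerate_gaps(sc$chain, cfg0)[1, ]
  expect_error(insert_mini_chain(sc$chain, gap, mini_of(180, 180, 40)),
               "escape")
})

test_that("fuzzed insertions keep all original aligned pairs intact", {
  set.seed(53)
  for (case in 1:30) {
    gl_t <- sample(60:200, 1); gl_q <- sample(60:200, 1)
    sc <- chain_with_gap(rand_seq(gl_t), rand_seq(gl_q), rand_seq(40))
    gap <- enumerate_gaps(sc$chain, cfg0)[1, ]
    # random co-linear mini inside the gap (one or two segments)
    s1 <- sample(5:20, 1)
    t1 <- sample(0:(gl_t - s1), 1); q1 <- sample(0:(gl_q - s1), 1)
    segs <- data.frame(t_start = t1, q_start = q1, size = s1)
    if (t1 + s1 + 10 < gl_t && q1 + s1 + 10 < gl_q) {
      s2 <- min(sample(3:8, 1), gl_t - t1 - s1 - 2, gl_q - q1 - s1 - 2)
      segs <- rbind(segs, data.frame(t_start = t1 + s1 + 1,
                                     q_start = q1 + s1 + 1, size = s2))
    }
    mini <- structure(list(score = 6000,
                           members = list(local_alignment(6000, segs)),
                           member_idx = 1L), class = "mini_chain")
    before <- chain_pairs(sc$chain)
    out <- insert_mini_chain(sc$chain, gap, mini)
    validate_chain(out)
    after <- chain_pairs(out)
    expect_true(all(paste(before$t, before$q) %in% paste(after$t, after$q)))
    expect_equal(nrow(after), nrow(before) + sum(segs$size))
  }
})

test_that("fill_chains honours the strict chain-score filter end to end", {
  set.seed(59)
  pg <- planted_gap_pair(copy_len = 300, divergence = 0.08, flank = 50)
  fl <- rand_seq(50)
  sc <- chain_with_gap(pg$t_gap, pg$q_gap, fl)
  mk <- function(score, id) {
    ch <- sc$chain; ch$score <- score; ch$id <- id; ch
  }
  chains <- list(mk(24999, "a"), mk(25000, "b"), mk(25001, "c"))
  res <- fill_chains(chains, sc$tstore, sc$qstore, cfg0)
  expect_equal(res$report$per_chain$gaps_filled, c(0L, 0L, 1L))
  # untouched chains are emitted verbatim, including their input score
  expect_identical(res$chains[[1]], chains[[1]])
  expect_identical(res$chains[[2]], chains[[2]])
  # the filled chain was rescored from sequence
  expect_equal(res$chains[[3]]$score,
               round(score_chain(res$chains[[3]], sc$tstore, sc$qstore,
                                 cfg0$scheme, cfg0$table)))
  expect_gt(res$report$totals$bases_added, 0)
  expect_equal(res$report$totals$bases_added,
               sum(res$report$new_blocks$t_end - res$report$new_blocks$t_start))
})

test_that("newly aligned bases are classified against repeat annotations", {
  blocks <- data.frame(chain_id = "1", t_start = c(100, 150),
                       t_end = c(120, 160), q_start = 0, q_end = 0)
  bed <- data.frame(chrom = "t", start = 90, end = 200, name = "SINE")
  ov <- summarize_overlap(blocks, bed)
  expect_equal(ov$class, "SINE")
  expect_equal(ov$bases, 30)

  empty_bed <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), name = character(0))
  ov <- summarize_overlap(blocks, empty_bed)
  expect_equal(ov$class, "non_repetitive")
  expect_equal(ov$bases, 30)

  # fuzzed blocks/intervals against a per-base oracle
  set.seed(61)
  for (case in 1:20) {
    nb <- sample(1:5, 1)
    bs <- sort(sample(0:500, nb))
    blocks <- data.frame(chain_id = "1", t_start = bs,
                         t_end = bs + sample(5:40, nb, replace = TRUE),
                         q_start = 0, q_end = 0)
    ni <- sample(0:6, 1)
    bed <- if (ni > 0) {
      is <- sample(0:500, ni)
      data.frame(chrom = "t", start = is,
                 end = is + sample(10:80, ni, replace = TRUE),
                 name = sample(c("SINE", "LINE", "LTR"), ni, replace = TRUE))
    } else empty_bed
    got <- summarize_overlap(blocks, bed)
    # per-base oracle: first covering interval in sorted order wins
    bed_s <- bed[order(bed$start, bed$end), , drop = FALSE]
    tally <- list()
    for (r in seq_len(nrow(blocks))) {
      for (p in seq(blocks$t_start[r], blocks$t_end[r] - 1)) {
        hit <- which(bed_s$start <= p & p < bed_s$end)
        cls <- if (length(hit)) as.character(bed_s$name[hit[1]]) else
          "non_repetitive"
        tally[[cls]] <- (if (is.null(tally[[cls]])) 0 else tally[[cls]]) + 1
      }
    }
    want <- data.frame(class = names(tally),
                       bases = unlist(tally, use.names = FALSE))
    want <- want[order(-want$bases, want$class), ]
    expect_equal(got$class, want$class)
    expect_equal(got$bases, want$bases)
    expect_equal(sum(got$bases), sum(blocks$t_end - blocks$t_start))
  }
})
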