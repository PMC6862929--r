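test_that("ancestor generation plants soft-masked repeat copies", {
  set.seed(67)
  cfg <- sim_config(ancestor_length = 5000,
                    repeat_families = data.frame(length = numeric(0),
                                                 copies = numeric(0),
                                                 divergence = numeric(0)))
  anc <- generate_ancestor(cfg)
  expect_equal(nchar(anc$sequence), 5000)
  expect_false(grepl("[a-z]", anc$sequence))
  expect_equal(nrow(anc$repeats), 0)

  cfg <- sim_config(ancestor_length = 30000, min_separation = 100,
                    repeat_families = data.frame(length = 500, copies = 10,
                                                 divergence = 0))
  anc <- generate_ancestor(cfg)
  expect_equal(nrow(anc$repeats), 10)
  copies <- substring(anc$sequence, anc$repeats$start + 1, anc$repeats$end)
  expect_true(all(grepl("^[acgt]+$", copies)))
  # zero divergence: all copies identical to the (single) consensus
  expect_equal(length(unique(copies)), 1)
  # placements do not overlap
  expect_true(all(diff(anc$repeats$start) >= 500))
})

test_that("per-copy divergence matches the binomial expectation", {
  set.seed(71)
  d <- 0.1
  cfg <- sim_config(ancestor_length = 60000, min_separation = 100,
                    repeat_families = data.frame(length = 1000, copies = 12,
                                                 divergence = d))
  anc <- generate_ancestor(cfg)
  copies <- toupper(substring(anc$sequence, anc$repeats$start + 1,
                              anc$repeats$end))
  # two copies differ per site when at least one mutated, minus coincidences:
  # P(match) = (1-d)^2 + d^2/3
  p_match <- (1 - d)^2 + d^2 / 3
  pairs <- utils::combn(length(copies), 2)[, 1:20]
  for (k in seq_len(ncol(pairs))) {
    a <- strsplit(copies[pairs[1, k]], "")[[1]]
    b <- strsplit(copies[pairs[2, k]], "")[[1]]
    obs <- mean(a == b)
    se <- sqrt(p_match * (1 - p_match) / length(a))
    expect_lt(abs(obs - p_match), 3 * se + 1e-9)
  }
})

test_that("evolution is neutral at rate zero and reproducible under a seed", {
  cfg <- sim_config(substitution_rate = 0, indel_rate = 0)
  s <- "ACGTacgtNNNN"
  ev <- evolve(s, cfg)
  expect_identical(ev$sequence, s)
  expect_identical(ev$map, 1:12)

  cfg <- sim_config(substitution_rate = 0.1, indel_rate = 0.01)
  set.seed(73); a <- evolve(strrep("ACGT", 2500), cfg)
  set.seed(73); b <- evolve(strrep("ACGT", 2500), cfg)
  expect_identical(a, b)
})

test_that("realized substitution and indel behaviour match the configuration", {
  set.seed(79)
  n <- 100000
  src <- rand_seq(n)
  cfg <- sim_config(substitution_rate = 0.1, indel_rate = 0)
  ev <- evolve(src, cfg)
  expect_equal(nchar(ev$sequence), n)
  a <- strsplit(src, "")[[1]]
  b <- strsplit(ev$sequence, "")[[1]]
  rate <- mean(a != b)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(rate - 0.1), 3 * se)

  # case is preserved through substitutions
  set.seed(83)
  src2 <- paste0(rand_seq(500), tolower(rand_seq(500)))
  ev2 <- evolve(src2, sim_config(substitution_rate = 0.2, indel_rate = 0))
  expect_false(grepl("[a-z]", substr(ev2$sequence, 1, 500)))
  expect_false(grepl("[A-Z]", substr(ev2$sequence, 501, 1000)))

  # indels shift the coordinate map; surviving bases keep their ancestor
  set.seed(89)
  ev3 <- evolve(src, sim_config(substitution_rate = 0, indel_rate = 0.01))
  surv <- !is.na(ev3$map)
  b3 <- strsplit(ev3$sequence, "")[[1]]
  expect_true(all(b3[surv] == a[ev3$map[surv]]))
  expect_true(all(diff(ev3$map[surv]) > 0))
})

test_that("truth pairs are exactly the co-maximal orthologous runs", {
  # ancestor of 10 bp; target deletes base 4, query inserts after base 7
  t_map <- c(1:3, 5:10)
  q_map <- c(1:7, NA, 8:10)
  reps <- data.frame(start = 5, end = 8, family = "famX")
  tp <- truth_pairs(t_map, q_map, reps, 10)
  # runs break at the deleted ancestor base 4, at the label switches into
  # and out of the repeat (anc 6-8), and at the query insertion (anc 7|8)
  expect_equal(tp$t_start, c(0, 3, 4, 6, 7))
  expect_equal(tp$t_end,   c(3, 4, 6, 7, 9))
  expect_equal(tp$q_start, c(0, 4, 5, 8, 9))
  expect_equal(tp$q_end,   c(3, 5, 7, 9, 11))
  expect_equal(tp$label, c("background", "background", "famX", "famX",
                           "background"))
})

test_that("without repeats the first pass aligns almost everything", {
  set.seed(97)
  cfg <- sim_config(ancestor_length = 40000,
                    repeat_families = data.frame(length = numeric(0),
                                                 copies = numeric(0),
                                                 divergence = numeric(0)),
                    substitution_rate = 0.08, indel_rate = 0.003)
  anc <- generate_ancestor(cfg)
  tgt <- evolve(anc$sequence, cfg)
  qry <- evolve(anc$sequence, cfg)
  chains <- first_pass_chain(tgt$sequence, qry$sequence)
  expect_gt(length(chains), 0)
  aligned <- sum(vapply(chains, function(c) sum(c$blocks$size), numeric(1)))
  truth <- truth_pairs(tgt$map, qry$map, anc$repeats, cfg$ancestor_length)
  orth <- sum(truth$t_end - truth$t_start)
  expect_gt(aligned / orth, 0.95)
  # and the filler then has (almost) nothing to add
  res <- fill_chains(chains, seq_store(c(chr1 = tgt$sequence)),
                     seq_store(c(chr1 = qry$sequence)))
  expect_lt(res$report$totals$bases_added, 0.005 * orth)
})

test_that("planted repeats fall into first-pass chain gaps", {
  set.seed(101)
  cfg <- sim_config(ancestor_length = 60000, min_separation = 500,
                    repeat_families = data.frame(length = c(300, 700),
                                                 copies = c(4, 3),
                                                 divergence = 0.08))
  anc <- generate_ancestor(cfg)
  tgt <- evolve(anc$sequence, cfg)
  qry <- evolve(anc$sequence, cfg)
  chains <- first_pass_chain(tgt$sequence, qry$sequence)
  # mark target bases that are masked (planted repeat) and those inside gaps
  n <- nchar(tgt$sequence)
  in_block <- logical(n)
  for (ch in chains) {
    co <- chain_blocks(ch)
    for (i in seq_len(nrow(co)))
      in_block[(co$t_start[i] + 1):co$t_end[i]] <- TRUE
  }
  masked <- logical(n)
  m <- gregexpr("[acgt]+", tgt$sequence)[[1]]
  for (i in seq_along(m))
    masked[m[i]:(m[i] + attr(m, "match.length")[i] - 1)] <- TRUE
  expect_gt(sum(masked & !in_block) / sum(masked), 0.8)

  # determinism of the first pass
  chains2 <- first_pass_chain(tgt$sequence, qry$sequence)
  expect_identical(format_chain_text(chains2), format_chain_text(chains))
})

test_that("generate_dataset writes a mutually consistent, reproducible set", {
  cfg <- sim_config(ancestor_length = 30000, min_separation = 300,
                    repeat_families = data.frame(length = 400, copies = 3,
                                                 divergence = 0.08),
                    rng_seed = 11)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  ds <- generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  for (f in c("target.fa", "query.fa", "in.chain", "truth.bed",
              "truth_pairs.tsv", "manifest.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # the chain file parses, validates, and is consistent with the FASTA
  chains <- read_chain_file(file.path(d1, "in.chain"))
  tst <- load_sequences(file.path(d1, "target.fa"))
  qst <- load_sequences(file.path(d1, "query.fa"))
  for (ch in chains) {
    validate_chain(ch)
    expect_equal(ch$tSize, unname(tst$len[ch$tName]))
    expect_equal(ch$qSize, unname(qst$len[ch$qName]))
  }
  # truth intervals in bounds
  expect_true(all(ds$truth$t_end <= tst$len["chr1"]))
  expect_true(all(ds$truth$q_end <= qst$len["chr1"]))
  # and the filler adds aligned bases on this dataset
  res <- fill_chains(chains, tst, qst)
  expect_gt(res$report$totals$bases_added, 0)
  unlink(c(d1, d2), recursive = TRUE)
})
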