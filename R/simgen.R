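#' Configuration for the synthetic genome-pair simulator
#'
#' The simulator plants repeat-family copies in a random ancestral sequence,
#' soft-masks them, evolves two descendants independently by substitutions
#' and indels, and computes a first-pass chain under a repeat-masked
#' alignment regime, so that gaps over the planted repeats exist for the
#' filler to recover. Defaults: a 1 Mb ancestor, three repeat families with
#' 300/800/1500 bp consensi and 40/25/15 copies, 8% per-copy divergence
#' from consensus, 10% substitutions and 0.5% indels (geometric lengths,
#' mean 3 bp) per lineage.
#'
#' @param ancestor_length ancestral sequence length (bp).
#' @param repeat_families data frame with columns `length` (consensus bp),
#'   `copies` and `divergence` (per-copy substitution fraction from
#'   consensus).
#' @param substitution_rate per-site substitution probability per lineage.
#' @param indel_rate per-site indel initiation probability per lineage.
#' @param indel_length_mean mean indel length (geometric, bp).
#' @param min_separation minimum unmasked spacer between planted copies
#'   (bp), so that first-pass seeds exist between repeats.
#' @param margin repeat-free margin at both sequence ends (bp).
#' @param rng_seed integer seed; one pseudo-random stream drives the whole
#'   dataset.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(ancestor_length = 1e6,
                       repeat_families = data.frame(
                         length = c(300, 800, 1500),
                         copies = c(40, 25, 15),
                         divergence = 0.08),
                       substitution_rate = 0.10,
                       indel_rate = 0.005,
                       indel_length_mean = 3,
                       min_separation = 800,
                       margin = 1000,
                       rng_seed = 1L) {
  stopifnot(ancestor_length > 0,
            all(repeat_families$length > 0),
            all(repeat_families$copies >= 0),
            all(repeat_families$divergence >= 0 &
                  repeat_families$divergence < 1),
            substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1,
            indel_length_mean >= 1)
  structure(list(ancestor_length = ancestor_length,
                 repeat_families = repeat_families,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 indel_length_mean = indel_length_mean,
                 min_separation = min_separation,
                 margin = margin,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

# substitute a fraction `rate` of positions, uniformly among the 3
# alternatives; operates on an uppercase character vector
mutate_chars <- function(chars, rate) {
  n <- length(chars)
  hit <- which(runif(n) < rate & chars %in% BASES)
  if (length(hit)) {
    cur <- match(chars[hit], BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- BASES[(cur - 1L + shift) %% 4L + 1L]
  }
  chars
}

#' Generate an ancestral sequence with planted repeat families
#'
#' The background is i.i.d. uniform over `ACGT` (uppercase). Each family's
#' consensus is generated once; copies are derived from it by per-site
#' substitution at the configured per-copy divergence, written in lowercase
#' (soft-masked), and planted at uniformly sampled non-overlapping positions
#' separated by at least `min_separation` bp. Uses the current RNG stream.
#'
#' @param config a `"sim_config"`.
#' @return list with `sequence` (string) and `repeats`, a data frame of
#'   planted intervals (`start`, `end` 0-based half-open, `family`).
#' @export
generate_ancestor <- function(config) {
  n <- config$ancestor_length
  chars <- sample(BASES, n, replace = TRUE)
  fam <- config$repeat_families
  consensi <- lapply(seq_len(nrow(fam)),
                     function(f) sample(BASES, fam$length[f], replace = TRUE))
  # sample placements family by family, longest first for packability
  placed <- data.frame(start = numeric(0), end = numeric(0),
                       family = character(0))
  ord <- order(-fam$length)
  for (f in ord) {
    len <- fam$length[f]
    k <- fam$copies[f]
    tries <- 0L
    while (k > 0) {
      if (tries > 200L * fam$copies[f])
        stop("cannot place requested repeat copies without overlap")
      tries <- tries + 1L
      pos <- floor(runif(1, config$margin,
                         n - config$margin - len))
      if (nrow(placed) == 0 ||
          all(pos + len + config$min_separation <= placed$start |
                placed$end + config$min_separation <= pos)) {
        placed <- rbind(placed,
                        data.frame(start = pos, end = pos + len,
                                   family = paste0("fam", f)))
        copy <- mutate_chars(consensi[[f]], fam$divergence[f])
        chars[(pos + 1):(pos + len)] <- tolower(copy)
        k <- k - 1L
      }
    }
  }
  placed <- placed[order(placed$start), , drop = FALSE]
  rownames(placed) <- NULL
  list(sequence = paste(chars, collapse = ""), repeats = placed)
}

#' Evolve a sequence along one lineage
#'
#' Applies per-site substitutions (uniform among the three alternatives,
#' case preserved) and indels with geometrically distributed lengths.
#' Inserted bases take the case of the base they follow, so insertions
#' inside a masked repeat stay masked. Uses the current RNG stream.
#'
#' @param sequence nucleotide string (soft-masked allowed).
#' @param config a `"sim_config"`.
#' @return list with `sequence` (the derived string) and `map`, an integer
#'   vector giving, for every derived base, its 1-based ancestral
#'   coordinate (`NA` for inserted bases).
#' @export
evolve <- function(sequence, config) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  lower <- chars %in% c("a", "c", "g", "t", "n")
  up <- toupper(chars)
  up <- mutate_chars(up, config$substitution_rate)
  chars <- ifelse(lower, tolower(up), up)

  map <- seq_len(n)
  if (config$indel_rate > 0) {
    pos <- which(runif(n) < config$indel_rate)
    if (length(pos)) {
      is_del <- runif(length(pos)) < 0.5
      lens <- 1L + rgeom(length(pos), prob = 1 / config$indel_length_mean)
      out_c <- list(); out_m <- list()
      cur <- 1L
      for (e in seq_along(pos)) {
        p <- pos[e]
        if (p < cur) next               # inside a previous deletion
        if (is_del[e]) {
          stop_at <- min(p + lens[e] - 1L, n)
          if (p > cur) {
            out_c[[length(out_c) + 1L]] <- chars[cur:(p - 1L)]
            out_m[[length(out_m) + 1L]] <- map[cur:(p - 1L)]
          }
          cur <- stop_at + 1L
        } else {
          ins <- sample(BASES, lens[e], replace = TRUE)
          if (lower[p]) ins <- tolower(ins)
          out_c[[length(out_c) + 1L]] <- c(chars[cur:p], ins)
          out_m[[length(out_m) + 1L]] <- c(map[cur:p],
                                           rep(NA_integer_, lens[e]))
          cur <- p + 1L
        }
      }
      if (cur <= n) {
        out_c[[length(out_c) + 1L]] <- chars[cur:n]
        out_m[[length(out_m) + 1L]] <- map[cur:n]
      }
      chars <- unlist(out_c, use.names = FALSE)
      map <- unlist(out_m, use.names = FALSE)
    }
  }
  list(sequence = paste(chars, collapse = ""), map = map)
}

#' Ground-truth orthologous interval pairs
#'
#' Matches derived coordinates of the two lineages through their shared
#' ancestral coordinates and reports maximal co-linear runs as interval
#' pairs, labelled by the planted repeat family of their ancestral position
#' (or `"background"`).
#'
#' @param target_map,query_map coordinate maps from [evolve()].
#' @param ancestor_repeats `repeats` data frame from [generate_ancestor()].
#' @param ancestor_length ancestral length (bp).
#' @return data frame with 0-based half-open `t_start`, `t_end`, `q_start`,
#'   `q_end` and `label`.
#' @export
truth_pairs <- function(target_map, query_map, ancestor_repeats,
                        ancestor_length) {
  pos_t <- rep(NA_integer_, ancestor_length)
  idx <- which(!is.na(target_map))
  pos_t[target_map[idx]] <- idx
  pos_q <- rep(NA_integer_, ancestor_length)
  idx <- which(!is.na(query_map))
  pos_q[query_map[idx]] <- idx
  both <- which(!is.na(pos_t) & !is.na(pos_q))
  if (length(both) == 0)
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      q_start = numeric(0), q_end = numeric(0),
                      label = character(0)))
  in_rep <- rep(NA_character_, ancestor_length)
  for (r in seq_len(nrow(ancestor_repeats)))
    in_rep[(ancestor_repeats$start[r] + 1):ancestor_repeats$end[r]] <-
      ancestor_repeats$family[r]
  lab <- in_rep[both]
  lab[is.na(lab)] <- "background"
  tp <- pos_t[both]; qp <- pos_q[both]
  brk <- c(TRUE, diff(both) != 1 | diff(tp) != 1 | diff(qp) != 1 |
             lab[-1] != lab[-length(lab)])
  run <- cumsum(brk)
  first <- which(brk)
  last <- c(first[-1] - 1L, length(both))
  data.frame(t_start = tp[first] - 1, t_end = tp[last],
             q_start = qp[first] - 1, q_end = qp[last],
             label = lab[first])
}

#' First-pass chain under the repeat-masked regime
#'
#' Runs the seed-and-extend aligner genome-wide with `masked = TRUE`
#' (soft-masked bases neither seed nor score above the worst matrix entry,
#' so alignments stop at repeat boundaries), then greedily decomposes the
#' local alignments into co-linear chains with [chain_fragments()],
#' reproducing the regime where repeat-internal alignments are missing and
#' appear as chain gaps.
#'
#' @param target,query nucleotide strings (soft-masked).
#' @param target_name,query_name sequence names for the chain records.
#' @param scheme a `"scoring_scheme"` (first-pass defaults `K = 2400`).
#' @param table a `"gap_cost_table"`.
#' @param chain_min_score chains scoring below this are dropped.
#' @param k seed length.
#' @param seed_cap genome-scale seed cap.
#' @param max_extend maximum gapped extension per direction (bp).
#' @return list of `"chain"` objects sorted by descending score, ids
#'   `1..n`.
#' @export
first_pass_chain <- function(target, query,
                             target_name = "chr1", query_name = "chr1",
                             scheme = default_scoring_scheme(),
                             table = default_gap_costs(),
                             chain_min_score = 1000, k = 12L,
                             seed_cap = 2e6, max_extend = 30000L) {
  alns <- align_region(target, query, scheme = scheme, k = k,
                       masked = TRUE, seed_cap = seed_cap,
                       subsample_seed = 1, max_extend = max_extend)
  chains <- list()
  remaining <- alns
  while (length(remaining) > 0) {
    mini <- chain_fragments(remaining, table)
    if (is.null(mini) || mini$score < chain_min_score) break
    chains[[length(chains) + 1L]] <- mini
    remaining <- remaining[-mini$member_idx]
  }
  if (length(chains) == 0) return(list())
  ord <- order(-vapply(chains, `[[`, numeric(1), "score"))
  out <- vector("list", length(chains))
  for (i in seq_along(ord)) {
    out[[i]] <- mini_to_chain(chains[[ord[i]]], id = as.character(i),
                              tName = target_name, tSize = nchar(target),
                              qName = query_name, qSize = nchar(query))
  }
  out
}

# build a chain record from a mini chain whose segment offsets are genome
# coordinates (strand '+', as produced by the simulator's first pass)
mini_to_chain <- function(mini, id, tName, tSize, qName, qSize) {
  segs <- do.call(rbind, lapply(mini$members, `[[`, "segments"))
  te <- segs$t_start + segs$size
  qe <- segs$q_start + segs$size
  blocks <- data.frame(size = segs$size,
                       dt = c(segs$t_start[-1], te[nrow(segs)]) - te,
                       dq = c(segs$q_start[-1], qe[nrow(segs)]) - qe)
  # merge zero-gap neighbours
  keep <- list(); cur <- blocks[1, ]
  for (r in seq_len(nrow(blocks))[-1]) {
    if (cur$dt == 0 && cur$dq == 0) {
      cur$size <- cur$size + blocks$size[r]
      cur$dt <- blocks$dt[r]; cur$dq <- blocks$dq[r]
    } else {
      keep[[length(keep) + 1]] <- cur
      cur <- blocks[r, ]
    }
  }
  keep[[length(keep) + 1]] <- cur
  blocks <- do.call(rbind, keep)
  chain(score = round(mini$score), tName = tName, tSize = tSize,
        tStart = segs$t_start[1], tEnd = te[nrow(segs)],
        qName = qName, qSize = qSize, qStrand = "+",
        qStart = segs$q_start[1], qEnd = qe[nrow(segs)],
        id = id, blocks = blocks)
}

#' Generate a complete synthetic dataset
#'
#' Seeds the RNG once from `config$rng_seed`, generates the ancestor,
#' evolves the target and query lineages, computes the ground truth and the
#' first-pass chain, and writes `target.fa`, `query.fa`, `in.chain`,
#' `truth.bed` (repeat annotation on the target, family in the name
#' column), `truth_pairs.tsv` and `manifest.json` to `out_dir`. Two runs
#' with the same seed produce byte-identical files.
#'
#' @param config a `"sim_config"`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the file paths and the in-memory objects
#'   (`target`, `query`, their maps, `chains`, `truth`, `repeat_bed`).
#' @export
generate_dataset <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$rng_seed)
  anc <- generate_ancestor(config)
  tgt <- evolve(anc$sequence, config)
  qry <- evolve(anc$sequence, config)
  truth <- truth_pairs(tgt$map, qry$map, anc$repeats,
                       config$ancestor_length)
  chains <- first_pass_chain(tgt$sequence, qry$sequence)
  rep_bed <- target_repeat_bed(tgt$sequence, tgt$map, anc$repeats)

  paths <- list(
    target_fa = file.path(out_dir, "target.fa"),
    query_fa = file.path(out_dir, "query.fa"),
    chain = file.path(out_dir, "in.chain"),
    truth_bed = file.path(out_dir, "truth.bed"),
    truth_pairs = file.path(out_dir, "truth_pairs.tsv"),
    manifest = file.path(out_dir, "manifest.json"))
  write_fasta(c(chr1 = tgt$sequence), paths$target_fa)
  write_fasta(c(chr1 = qry$sequence), paths$query_fa)
  write_chain_file(chains, paths$chain)
  write_bed(rep_bed, paths$truth_bed)
  utils::write.table(truth, paths$truth_pairs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(config)), paths$manifest,
    pretty = TRUE, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(target = tgt, query = qry, ancestor = anc,
                          chains = chains, truth = truth,
                          repeat_bed = rep_bed, config = config)))
}

# repeat annotation on the derived target genome: maximal soft-masked runs,
# labelled with the family of their ancestral position
target_repeat_bed <- function(target_seq, target_map, ancestor_repeats) {
  m <- gregexpr("[acgtn]+", target_seq)[[1]]
  if (m[1] == -1)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0)))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  fam <- character(length(starts))
  for (i in seq_along(starts)) {
    anc <- target_map[starts[i]:(starts[i] + lens[i] - 1L)]
    anc <- anc[!is.na(anc)][1]
    hit <- which(ancestor_repeats$start < anc & anc <= ancestor_repeats$end)
    fam[i] <- if (length(hit)) ancestor_repeats$family[hit[1]] else "unknown"
  }
  data.frame(chrom = "chr1", start = starts - 1, end = starts - 1 + lens,
             name = fam)
}

# BED6 writer via rtracklayer
write_bed <- function(bed, path) {
  if (nrow(bed) == 0) { file.create(path); return(invisible(path)) }
  gr <- GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1, end = bed$end),
    strand = "+")
  gr$name <- bed$name
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Evaluate a fill run against the simulator's ground truth
#'
#' Computes, over the target genome: the newly aligned bases (union of
#' inserted blocks), the recall of planted orthologous repeat bases inside
#' qualifying gaps of the input chains, the fraction of newly aligned bases
#' falling outside any orthologous region (precision proxy), and the
#' fraction overlapping the repeat annotation.
#'
#' @param dataset result of [generate_dataset()].
#' @param fill result of [fill_chains()] run on `dataset$chains`.
#' @param config the `"fill_config"` used for the run.
#' @return list with `new_bases`, `recall_pct`, `outside_orthologous_pct`,
#'   `repeat_overlap_pct`.
#' @export
evaluate_fill <- function(dataset, fill, config = fill_config()) {
  n <- nchar(dataset$target$sequence)
  mark <- function(df, s = "t_start", e = "t_end") {
    v <- logical(n)
    for (r in seq_len(nrow(df))) {
      if (df[[e]][r] > df[[s]][r])
        v[(df[[s]][r] + 1):df[[e]][r]] <- TRUE
    }
    v
  }
  new_cov <- mark(fill$report$new_blocks)
  truth <- dataset$truth
  orth <- mark(truth)
  rep_orth <- mark(truth[truth$label != "background", , drop = FALSE])
  gaps <- do.call(rbind, lapply(dataset$chains, enumerate_gaps, config))
  qual <- mark(gaps)
  masked <- mark(dataset$repeat_bed, "start", "end")
  denom <- sum(rep_orth & qual)
  list(
    new_bases = sum(new_cov),
    recall_pct = if (denom > 0) 100 * sum(new_cov & rep_orth & qual) / denom
                 else NA_real_,
    outside_orthologous_pct =
      if (sum(new_cov) > 0) 100 * sum(new_cov & !orth) / sum(new_cov)
      else NA_real_,
    repeat_overlap_pct =
      if (sum(new_cov) > 0) 100 * sum(new_cov & masked) / sum(new_cov)
      else NA_real_)
}
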