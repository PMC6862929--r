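#' Configuration for gap filling
#'
#' The defaults are the method's published operating point: only unaligned
#' regions whose target and query sides are both 30-20,000 bp long are
#' re-examined; only chains scoring strictly above 25,000 are processed; a
#' mini chain is inserted only when its score is at least 5,000; the
#' re-alignment uses the default scoring scheme with the more sensitive
#' ungapped threshold `K = 2000` (`L = 3000`, `Y = 9400` unchanged).
#'
#' @param min_gap,max_gap inclusive gap size bounds (bp), applied to `dt`
#'   and `dq` jointly.
#' @param min_chain_score chains must score strictly above this to be
#'   processed.
#' @param min_mini_score minimum (inclusive) mini-chain score for insertion.
#' @param scheme `"scoring_scheme"` for the re-alignment.
#' @param table `"gap_cost_table"` for mini-chain construction and chain
#'   rescoring.
#' @param k seed length.
#' @param seed_cap seed-explosion guard per gap.
#' @param rng_seed integer mixed into the deterministic per-gap subsample
#'   seed.
#' @param max_extend maximum gapped extension per direction (bp).
#' @return An object of class `"fill_config"`.
#' @export
fill_config <- function(min_gap = 30L, max_gap = 20000L,
                        min_chain_score = 25000,
                        min_mini_score = 5000,
                        scheme = default_scoring_scheme(K = 2000),
                        table = default_gap_costs(),
                        k = 12L, seed_cap = 50000L, rng_seed = 1L,
                        max_extend = 30000L) {
  if (min_gap < 1 || min_gap > max_gap)
    stop("need 1 <= min_gap <= max_gap")
  structure(list(min_gap = min_gap, max_gap = max_gap,
                 min_chain_score = min_chain_score,
                 min_mini_score = min_mini_score,
                 scheme = scheme, table = table, k = k,
                 seed_cap = seed_cap, rng_seed = rng_seed,
                 max_extend = max_extend),
            class = "fill_config")
}

#' Enumerate fillable gaps of a chain
#'
#' One gap per interior inter-block region whose `dt` AND `dq` both lie in
#' `[min_gap, max_gap]` (a one-sidedly tiny gap has nothing to align
#' against). Chains scoring at or below `min_chain_score` yield no gaps.
#' Gaps are always bounded by aligned blocks on both sides.
#'
#' @param chain a `"chain"`.
#' @param config a `"fill_config"`.
#' @return data frame with `block_index` (the preceding block) and 0-based
#'   `t_start`, `t_end`, `q_start`, `q_end` (query in chain strand
#'   coordinates).
#' @export
enumerate_gaps <- function(chain, config = fill_config()) {
  empty <- data.frame(block_index = integer(0), t_start = numeric(0),
                      t_end = numeric(0), q_start = numeric(0),
                      q_end = numeric(0))
  if (chain$score <= config$min_chain_score) return(empty)
  b <- chain$blocks
  if (nrow(b) < 2) return(empty)
  co <- chain_blocks(chain)
  i <- seq_len(nrow(b) - 1L)
  ok <- b$dt[i] >= config$min_gap & b$dt[i] <= config$max_gap &
        b$dq[i] >= config$min_gap & b$dq[i] <= config$max_gap
  i <- i[ok]
  data.frame(block_index = i,
             t_start = co$t_end[i], t_end = co$t_end[i] + b$dt[i],
             q_start = co$q_end[i], q_end = co$q_end[i] + b$dq[i])
}

# deterministic per-gap seed for the seed-explosion subsample
gap_subseed <- function(chain_id, block_index, rng_seed) {
  h <- sum(utf8ToInt(as.character(chain_id)) *
             seq_along(utf8ToInt(as.character(chain_id))))
  (h * 2654435761 + block_index * 97 + rng_seed) %% 2147483647 + 1
}

#' Re-align one gap and build its mini chain
#'
#' Fetches the gap's target and query fragments with the soft-masking
#' removed (uppercase) in chain orientation, runs [align_region()] with the
#' configured scheme, and chains the resulting local alignments with
#' [chain_fragments()]. The mini chain is returned only when its score
#' reaches `min_mini_score`.
#'
#' @param chain the parent `"chain"`.
#' @param gap one row of [enumerate_gaps()] output.
#' @param target_store,query_store `"seq_store"` objects.
#' @param config a `"fill_config"`.
#' @return A `"mini_chain"` or `NULL`.
#' @export
fill_gap <- function(chain, gap, target_store, query_store,
                     config = fill_config()) {
  ref_frag <- fetch_seq(target_store, chain$tName, gap$t_start, gap$t_end,
                        "+", unmask = TRUE)
  q_frag <- fetch_seq(query_store, chain$qName, gap$q_start, gap$q_end,
                      chain$qStrand, unmask = TRUE)
  alns <- align_region(ref_frag, q_frag, scheme = config$scheme,
                       k = config$k, masked = FALSE,
                       seed_cap = config$seed_cap,
                       subsample_seed = gap_subseed(chain$id,
                                                    gap$block_index,
                                                    config$rng_seed),
                       max_extend = config$max_extend)
  mini <- chain_fragments(alns, config$table)
  if (is.null(mini) || mini$score < config$min_mini_score) return(NULL)
  mini
}

#' Splice a mini chain into its parent chain
#'
#' The mini chain's segments (offsets within the gap fragments) are mapped
#' to genome coordinates, inserted between the flanking blocks, and the
#' flanking `dt`/`dq` values recomputed so that the gap is subdivided, never
#' resized. New blocks flush against a neighbour (zero gap on both genomes)
#' are merged into it. The result passes the full chain validator; the
#' chain score is left for [score_chain()] to recompute.
#'
#' @param chain the parent `"chain"`.
#' @param gap the gap row the mini chain was computed for.
#' @param mini a `"mini_chain"` from [fill_gap()].
#' @return the updated `"chain"`.
#' @export
insert_mini_chain <- function(chain, gap, mini) {
  segs <- do.call(rbind, lapply(mini$members, `[[`, "segments"))
  t_abs <- gap$t_start + segs$t_start
  q_abs <- gap$q_start + segs$q_start
  sz <- segs$size
  if (any(t_abs < gap$t_start) || any(t_abs + sz > gap$t_end) ||
      any(q_abs < gap$q_start) || any(q_abs + sz > gap$q_end))
    stop("internal error: mini-chain block escapes its gap")
  i <- gap$block_index
  b <- chain$blocks
  m <- length(sz)
  new <- data.frame(
    size = sz,
    dt = c(t_abs[-1], gap$t_end) - (t_abs + sz),
    dq = c(q_abs[-1], gap$q_end) - (q_abs + sz))
  upd <- rbind(
    data.frame(size = b$size[i], dt = t_abs[1] - gap$t_start,
               dq = q_abs[1] - gap$q_start),
    new)
  # merge blocks separated by a zero gap on both genomes
  merged <- upd[1, , drop = FALSE]
  for (r in seq_len(nrow(upd))[-1]) {
    last <- nrow(merged)
    if (merged$dt[last] == 0 && merged$dq[last] == 0) {
      merged$size[last] <- merged$size[last] + upd$size[r]
      merged$dt[last] <- upd$dt[r]
      merged$dq[last] <- upd$dq[r]
    } else {
      merged <- rbind(merged, upd[r, ])
    }
  }
  # a trailing zero gap merges the last new block into the following block
  after <- b[-seq_len(i), , drop = FALSE]
  last <- nrow(merged)
  if (merged$dt[last] == 0 && merged$dq[last] == 0 && nrow(after) > 0) {
    after$size[1] <- after$size[1] + merged$size[last]
    merged <- merged[-last, , drop = FALSE]
  }
  chain$blocks <- rbind(b[seq_len(i - 1), , drop = FALSE], merged, after)
  rownames(chain$blocks) <- NULL
  validate_chain(chain)
  chain
}

#' Fill all qualifying gaps of a set of chains
#'
#' Every chain scoring strictly above `min_chain_score` is processed gap by
#' gap (gaps are aligned independently; results do not depend on processing
#' order). Chains that received insertions get their score recomputed from
#' sequence with [score_chain()]; untouched chains keep their input score
#' verbatim. Chain order is preserved.
#'
#' @param chains list of `"chain"` objects.
#' @param target_store,query_store `"seq_store"` objects.
#' @param config a `"fill_config"`.
#' @return list with `chains` (the updated list) and `report`, a
#'   `"fill_report"`: per-chain counts, the inserted blocks, and totals.
#' @export
fill_chains <- function(chains, target_store, query_store,
                        config = fill_config()) {
  per <- vector("list", length(chains))
  blocks_out <- list()
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    gaps <- enumerate_gaps(ch, config)
    filled <- 0L; rejected <- 0L; added <- 0
    minis <- vector("list", nrow(gaps))
    for (g in seq_len(nrow(gaps))) {
      mini <- fill_gap(ch, gaps[g, ], target_store, query_store, config)
      if (is.null(mini)) rejected <- rejected + 1L else minis[[g]] <- mini
    }
    # insert right-to-left so earlier block indices stay valid
    for (g in rev(seq_len(nrow(gaps)))) {
      mini <- minis[[g]]
      if (is.null(mini)) next
      gp <- gaps[g, ]
      ch <- insert_mini_chain(ch, gp, mini)
      filled <- filled + 1L
      segs <- do.call(rbind, lapply(mini$members, `[[`, "segments"))
      added <- added + sum(segs$size)
      blocks_out[[length(blocks_out) + 1L]] <- data.frame(
        chain_id = ch$id,
        t_start = gp$t_start + segs$t_start,
        t_end = gp$t_start + segs$t_start + segs$size,
        q_start = gp$q_start + segs$q_start,
        q_end = gp$q_start + segs$q_start + segs$size)
    }
    score_in <- chains[[ci]]$score
    if (filled > 0)
      ch$score <- round(score_chain(ch, target_store, query_store,
                                    config$scheme, config$table))
    chains[[ci]] <- ch
    per[[ci]] <- data.frame(chain_id = ch$id, score_in = score_in,
                            score_out = ch$score,
                            gaps_examined = nrow(gaps),
                            gaps_filled = filled,
                            minis_rejected = rejected,
                            bases_added = added)
  }
  per_chain <- do.call(rbind, per)
  new_blocks <- if (length(blocks_out)) do.call(rbind, blocks_out) else
    data.frame(chain_id = character(0), t_start = numeric(0),
               t_end = numeric(0), q_start = numeric(0),
               q_end = numeric(0))
  report <- structure(list(
    per_chain = per_chain,
    new_blocks = new_blocks,
    totals = list(chains = length(chains),
                  gaps_examined = sum(per_chain$gaps_examined),
                  gaps_filled = sum(per_chain$gaps_filled),
                  minis_rejected = sum(per_chain$minis_rejected),
                  bases_added = sum(per_chain$bases_added))),
    class = "fill_report")
  list(chains = chains, report = report)
}

#' @export
print.fill_report <- function(x, ...) {
  t <- x$totals
  cat(sprintf(paste0("<fill_report> %d chain(s): %d gap(s) examined, ",
                     "%d filled, %d mini chain(s) rejected, ",
                     "%s aligned base(s) added\n"),
              t$chains, t$gaps_examined, t$gaps_filled, t$minis_rejected,
              format(t$bases_added, big.mark = ",")))
  invisible(x)
}

#' File-level gap filling
#'
#' Reads a chain file and the two soft-masked genomes, fills all qualifying
#' gaps, and writes the output chain file (same chains plus the newly added
#' blocks, in input order). Optionally classifies the newly aligned
#' reference bases against a repeat annotation and writes a TSV report.
#'
#' @param chain_file input UCSC chain file.
#' @param target_fasta,query_fasta soft-masked FASTA files.
#' @param out_chain output chain file path.
#' @param config a `"fill_config"`.
#' @param repeat_bed optional BED file of repeat annotations on the target
#'   assembly (class label in the name column).
#' @param report_path optional TSV path for the per-chain report.
#' @return invisibly, a list with `chains`, `report` and (when `repeat_bed`
#'   is given) `overlap`.
#' @export
fill_all <- function(chain_file, target_fasta, query_fasta, out_chain,
                     config = fill_config(), repeat_bed = NULL,
                     report_path = NULL) {
  chains <- read_chain_file(chain_file)
  tstore <- load_sequences(target_fasta)
  qstore <- load_sequences(query_fasta)
  res <- fill_chains(chains, tstore, qstore, config)
  write_chain_file(res$chains, out_chain)
  overlap <- NULL
  if (!is.null(repeat_bed))
    overlap <- summarize_overlap(res$report$new_blocks, repeat_bed)
  if (!is.null(report_path))
    utils::write.table(res$report$per_chain, report_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(list(chains = res$chains, report = res$report,
                 overlap = overlap))
}

#' Classify newly aligned reference bases by repeat annotation
#'
#' Each newly aligned reference base is assigned to exactly one category:
#' the class label of the first (in sorted order) repeat interval covering
#' it, or `"non_repetitive"`. Category totals sum to the bases added.
#'
#' @param new_blocks data frame of inserted blocks (`fill_report$new_blocks`:
#'   columns `t_start`, `t_end`, 0-based half-open, on the target assembly).
#' @param bed repeat annotation: a BED file path (name column = class), or a
#'   data frame with columns `start`, `end` (0-based half-open) and `name`.
#' @return data frame with columns `class` and `bases`, sorted by
#'   descending `bases`.
#' @export
summarize_overlap <- function(new_blocks, bed) {
  if (is.character(bed)) bed <- read_bed(bed)
  stopifnot(all(c("start", "end", "name") %in% names(bed)))
  bed <- bed[order(bed$start, bed$end), , drop = FALSE]
  counts <- list()
  add <- function(cls, n) counts[[cls]] <<- (counts[[cls]] %||% 0) + n
  `%||%` <- function(a, b) if (is.null(a)) b else a
  for (r in seq_len(nrow(new_blocks))) {
    pieces <- data.frame(start = new_blocks$t_start[r],
                         end = new_blocks$t_end[r])
    for (j in seq_len(nrow(bed))) {
      if (nrow(pieces) == 0) break
      s <- bed$start[j]; e <- bed$end[j]
      kept <- list(); claimed <- 0
      for (p in seq_len(nrow(pieces))) {
        ps <- pieces$start[p]; pe <- pieces$end[p]
        ov <- max(0, min(pe, e) - max(ps, s))
        if (ov == 0) { kept[[length(kept) + 1]] <- pieces[p, ]; next }
        claimed <- claimed + ov
        if (ps < s) kept[[length(kept) + 1]] <- data.frame(start = ps, end = s)
        if (pe > e) kept[[length(kept) + 1]] <- data.frame(start = e, end = pe)
      }
      if (claimed > 0) add(as.character(bed$name[j]), claimed)
      pieces <- if (length(kept)) do.call(rbind, kept) else
        data.frame(start = numeric(0), end = numeric(0))
    }
    if (nrow(pieces) > 0) add("non_repetitive", sum(pieces$end - pieces$start))
  }
  if (length(counts) == 0)
    return(data.frame(class = character(0), bases = numeric(0)))
  out <- data.frame(class = names(counts),
                    bases = unlist(counts, use.names = FALSE))
  out[order(-out$bases, out$class), , drop = FALSE]
}

#' Read a BED file of repeat annotations
#'
#' @param path BED file (at least 4 columns; 0-based half-open).
#' @return data frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) as.character(gr$name) else
               rep("repeat", length(gr)))
}
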