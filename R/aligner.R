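#' Find exact k-mer seed matches between two fragments
#'
#' Reports every position pair whose k-mers are identical after uppercasing
#' and contain no `N`, in deterministic `(t_pos, q_pos)` order. With
#' `masked = TRUE` (the first-pass regime) lowercase bases are treated as
#' unalignable, so no seed may overlap soft-masked sequence. Fragments
#' shorter than `k` yield an empty set.
#'
#' @param ref,query nucleotide fragments.
#' @param k seed length (contiguous exact match), `k >= 4`.
#' @param masked honour soft-masking (lowercase) when seeding.
#' @param seed_cap if more matches are found, keep a deterministic uniform
#'   subsample of this size (with a warning).
#' @param subsample_seed integer seed for the subsample.
#' @return data frame with 0-based columns `t_pos`, `q_pos`; attribute
#'   `n_total` carries the pre-cap match count.
#' @export
find_seeds <- function(ref, query, k = 12L, masked = FALSE,
                       seed_cap = 50000L, subsample_seed = 1) {
  if (k < 4) stop("seed length k must be >= 4")
  cap <- if (is.finite(seed_cap)) as.integer(seed_cap) else -1L
  res <- cpp_find_seeds(ref, query, as.integer(k), masked, cap,
                        as.numeric(subsample_seed))
  if (res$capped)
    warning("seed explosion: ", res$n_total, " seed matches capped to ",
            seed_cap, " (deterministic subsample)")
  out <- as.data.frame(res$seeds)
  attr(out, "n_total") <- res$n_total
  out
}

#' Ungapped X-drop extension of a seed
#'
#' Extends the seed diagonally in both directions, tracking the running
#' score and stopping once it drops more than the X-drop bound below the
#' running maximum. The maximal-scoring ungapped segment containing the seed
#' is returned, or `NULL` when its score is below `scheme$K`.
#'
#' @param ref,query nucleotide fragments.
#' @param t_pos,q_pos 0-based seed positions.
#' @param k seed length.
#' @param scheme a `"scoring_scheme"`.
#' @param masked treat lowercase as unalignable.
#' @return list with `t_start`, `t_end`, `q_start`, `q_end`, `score` and the
#'   anchor (maximum running-prefix point) `anchor_t`, `anchor_q`; or
#'   `NULL`.
#' @export
extend_ungapped <- function(ref, query, t_pos, q_pos, k = 12L,
                            scheme = default_scoring_scheme(),
                            masked = FALSE) {
  cpp_extend_ungapped(ref, query, as.integer(t_pos), as.integer(q_pos),
                      as.integer(k), expand_matrix5(scheme$matrix),
                      scheme$gap_open, scheme$gap_extend, scheme$K,
                      scheme$x_drop, masked)
}

#' Gapped Y-drop extension of an HSP
#'
#' Affine-gap dynamic programming anchored at the HSP's maximum-scoring
#' point, extended independently leftward and rightward; any cell whose best
#' score falls more than `scheme$Y` below the best score seen is abandoned.
#' Traceback yields co-linear ungapped segments. Returns `NULL` when the
#' total score is below `scheme$L`.
#'
#' @param ref,query nucleotide fragments.
#' @param hsp an HSP as returned by [extend_ungapped()] (the `anchor_t` /
#'   `anchor_q` fields are used).
#' @param scheme a `"scoring_scheme"`.
#' @param max_extend maximum extension length (bp) per direction.
#' @param masked treat lowercase as unalignable.
#' @return A `"local_alignment"`, or `NULL`.
#' @export
extend_gapped <- function(ref, query, hsp,
                          scheme = default_scoring_scheme(),
                          max_extend = 30000L, masked = FALSE) {
  res <- cpp_extend_gapped(ref, query, as.integer(hsp$anchor_t),
                           as.integer(hsp$anchor_q),
                           expand_matrix5(scheme$matrix), scheme$gap_open,
                           scheme$gap_extend, scheme$L, scheme$Y,
                           as.integer(max_extend), masked)
  if (is.null(res)) return(NULL)
  local_alignment(res$score, as.data.frame(res$segments))
}

#' Seed-and-extend local alignment of two fragments
#'
#' The full pipeline: [find_seeds()], ungapped X-drop extension of each seed
#' (seeds already inside an extension on the same diagonal are skipped),
#' deduplication of HSPs covered by a previously extended gapped alignment,
#' then gapped Y-drop extension. All alignments scoring at least `scheme$L`
#' are returned, sorted by descending score.
#'
#' @param ref,query nucleotide fragments.
#' @param scheme a `"scoring_scheme"`.
#' @param k seed length.
#' @param masked honour soft-masking (first-pass regime: lowercase neither
#'   seeds nor scores above the worst matrix entry).
#' @param seed_cap,subsample_seed seed-explosion guard, see [find_seeds()].
#' @param max_extend maximum gapped extension length per direction (bp).
#' @param dedup skip HSPs covered by an already-extended alignment.
#' @return list of `"local_alignment"` objects (possibly empty), attributes
#'   `n_seeds` and `n_hsps`.
#' @export
align_region <- function(ref, query, scheme = default_scoring_scheme(),
                         k = 12L, masked = FALSE, seed_cap = 50000L,
                         subsample_seed = 1, max_extend = 30000L,
                         dedup = TRUE) {
  if (nchar(ref) == 0 || nchar(query) == 0) return(list())
  cap <- if (is.finite(seed_cap)) as.integer(seed_cap) else -1L
  res <- cpp_align_region(ref, query, expand_matrix5(scheme$matrix),
                          scheme$gap_open, scheme$gap_extend, scheme$K,
                          scheme$L, scheme$Y, scheme$x_drop, as.integer(k),
                          masked, cap, as.numeric(subsample_seed),
                          as.integer(max_extend), dedup)
  if (res$capped)
    warning("seed explosion: ", res$n_seeds, " seed matches capped to ",
            seed_cap, " (deterministic subsample)")
  out <- lapply(res$alignments, function(a)
    local_alignment(a$score, as.data.frame(a$segments)))
  attr(out, "n_seeds") <- res$n_seeds
  attr(out, "n_hsps") <- res$n_hsps
  out
}
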