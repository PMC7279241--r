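#' Similarity-based target ranking
#'
#' Targets are ordered by the maximum Tanimoto coefficient between the
#' query and any active ligand of the target (maxTC). Where several targets
#' share the same maxTC, the comparison walks down the similarity profile --
#' the next-nearest neighbor, then the one after -- until the tie resolves,
#' so every target receives a unique rank.
#'
#' @name simrank
NULL

#' Compare two similarity profiles
#'
#' Lexicographic comparison of descending TC vectors. A profile that is a
#' strict prefix of another (smaller ligand set) is compared as if padded
#' with zeros: the longer profile wins only if its next entry is positive,
#' i.e. it offers additional non-trivial neighbor evidence; otherwise the
#' profiles are identical and the caller falls back to the target-id
#' tie-break.
#'
#' @param p,q numeric vectors, sorted descending.
#' @return `1` if `p` ranks first, `-1` if `q` ranks first, `0` if
#'   identical to exhaustion.
#' @export
#' @examples
#' compare_profiles(c(0.8, 0.6), c(0.8, 0.5))  #  1: tie broken at depth 1
#' compare_profiles(c(0.9), c(0.7, 0.7))       #  1: maxTC decides
compare_profiles <- function(p, q) {
  len <- max(length(p), length(q))
  pp <- c(p, rep(0, len - length(p)))
  qq <- c(q, rep(0, len - length(q)))
  d <- which(pp != qq)
  if (length(d) == 0) return(0L)
  if (pp[d[1]] > qq[d[1]]) 1L else -1L
}

# order profile rows of a zero-padded matrix lexicographically (descending),
# breaking full ties by id; returns the permutation
order_profiles <- function(pmat, ids) {
  keys <- lapply(seq_len(ncol(pmat)), function(j) -pmat[, j])
  do.call(order, c(keys, list(ids)))
}

# depth (in profile positions consumed beyond maxTC) needed to separate
# adjacently ranked targets; full ties (id tie-break) report the padded
# profile length
adjacent_depths <- function(pmat, perm) {
  t_n <- length(perm)
  if (t_n == 1) return(0L)
  sep <- vapply(seq_len(t_n - 1), function(i) {
    d <- which(pmat[perm[i], ] != pmat[perm[i + 1], ])
    if (length(d)) d[1] - 1L else ncol(pmat)
  }, integer(1))
  vapply(seq_len(t_n), function(i) {
    max(c(if (i > 1) sep[i - 1], if (i < t_n) sep[i]))
  }, integer(1))
}

# zero-padded profile matrix of one query against a set of targets
profile_matrix <- function(kb, query, targets) {
  profs <- lapply(targets, function(t) similarity_profile(query, ligand_fps(kb, t)))
  len <- max(lengths(profs))
  do.call(rbind, lapply(profs, function(p) c(p, rep(0, len - length(p)))))
}

#' Rank all knowledge-base targets for one or more queries
#'
#' @param queries 0/1 fingerprint vector, or a matrix of fingerprints (one
#'   query per row, row names as query ids).
#' @param kb a [knowledge_base][build_knowledge_base()].
#' @param targets optional target subset to rank (defaults to the full
#'   similarity scope of `kb`).
#' @return tibble with one row per (query, target): `query_id`, `rank`
#'   (1..T, no gaps or duplicates), `target_id`, `max_tc`, `tie_depth`
#'   (profile positions consumed beyond maxTC to separate the target from
#'   its ranked neighbors; 0 when maxTC alone decided) and `method`
#'   (`"similarity"`).
#' @export
rank_targets_similarity <- function(queries, kb, targets = NULL) {
  targets <- targets %||% kb$targets
  check_that(all(targets %in% kb$targets), "target outside similarity scope")
  if (!is.matrix(queries)) {
    queries <- matrix(queries, nrow = 1, dimnames = list("query", NULL))
  }
  check_that(ncol(queries) == kb$nbits, "query fingerprint length mismatch")
  ids <- rownames(queries) %||% paste0("query_", seq_len(nrow(queries)))

  purrr::map2_dfr(seq_len(nrow(queries)), ids, function(i, id) {
    pmat <- profile_matrix(kb, queries[i, ], targets)
    perm <- order_profiles(pmat, targets)
    depths <- adjacent_depths(pmat, perm)
    tibble::tibble(
      query_id = id,
      rank = seq_along(targets),
      target_id = targets[perm],
      max_tc = pmat[perm, 1],
      tie_depth = depths,
      method = "similarity"
    )
  })
}
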