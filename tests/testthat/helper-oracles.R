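# Independent oracles and fixture builders. Everything here is written as
# plainly as possible — literal walks and nested loops — and never calls the
# package's own ranking or counting internals.

# literal pairwise profile comparison: walk the zero-padded vectors
oracle_cmp <- function(p, q) {
  len <- max(length(p), length(q))
  pp <- c(p, rep(0, len - length(p)))
  qq <- c(q, rep(0, len - length(q)))
  for (i in seq_len(len)) {
    if (pp[i] > qq[i]) return(1L)
    if (pp[i] < qq[i]) return(-1L)
  }
  0L
}

# insertion sort of targets by (profile desc, id asc); profiles computed by
# brute force: all pairwise TCs, sorted
oracle_rank <- function(kb, query, targets = kb$targets) {
  profs <- lapply(targets, function(t) {
    keys <- kb$ligands[[t]]
    tcs <- vapply(keys, function(k) {
      a <- kb$fingerprints[k, ]
      inter <- sum(a == 1 & query == 1)
      uni <- sum(a == 1 | query == 1)
      if (uni == 0) 0 else inter / uni
    }, numeric(1))
    sort(tcs, decreasing = TRUE)
  })
  ord <- seq_along(targets)
  for (i in seq_along(ord)[-1]) {
    j <- i
    while (j > 1) {
      a <- ord[j - 1]; b <- ord[j]
      c <- oracle_cmp(profs[[a]], profs[[b]])
      swap <- (c == -1) || (c == 0 && targets[a] > targets[b])
      if (!swap) break
      ord[c(j - 1, j)] <- ord[c(j, j - 1)]
      j <- j - 1
    }
  }
  targets[ord]
}

# random knowledge base of unique-fingerprint compounds; optionally with
# ligand sharing across targets so maxTC ties occur and tie-breaks run deep
random_kb <- function(n_targets, max_ligands, nbits, seed,
                      share_ligands = FALSE) {
  withr::with_seed(seed, {
    n_cpd <- n_targets * max_ligands
    repeat {
      fp <- matrix(rbinom(n_cpd * nbits, 1, 0.3), n_cpd, nbits)
      if (!any(duplicated(fp))) break
    }
    rownames(fp) <- sprintf("C%03d", seq_len(n_cpd))
    targets <- sprintf("T%02d", seq_len(n_targets))
    pairs <- purrr::map_dfr(targets, function(t) {
      n <- sample(max_ligands, 1)
      keys <- if (share_ligands) {
        sample(rownames(fp), n)  # targets may share compounds
      } else {
        i <- match(t, targets)
        rownames(fp)[(i - 1) * max_ligands + seq_len(n)]
      }
      tibble::tibble(structure_key = keys, compound_id = keys,
                     target_id = t, median_activity_nm = 100,
                     label = "active")
    })
    build_knowledge_base(pairs, fp)
  })
}

# brute-force recounts of the two evaluation metrics
oracle_success <- function(rankings, truth, k) {
  hits <- 0
  queries <- unique(truth$query_id)
  for (q in queries) {
    tt <- truth$target_id[truth$query_id == q]
    rr <- rankings[rankings$query_id == q & rankings$target_id %in% tt, ]
    if (nrow(rr) > 0 && any(rr$rank <= k)) hits <- hits + 1
  }
  c(hits, length(queries))
}

oracle_recovery <- function(rankings, truth, k) {
  hits <- 0
  for (i in seq_len(nrow(truth))) {
    rr <- rankings[rankings$query_id == truth$query_id[i] &
                     rankings$target_id == truth$target_id[i], ]
    if (nrow(rr) == 1 && rr$rank <= k) hits <- hits + 1
  }
  c(hits, nrow(truth))
}

# one fully compliant raw record, overridable field by field
compliant_record <- function(...) {
  base <- tibble::tibble(
    compound_id = "CPD1", smiles = NA_character_, target_id = "T1",
    standard_type = "IC50", standard_relation = "=",
    standard_value = 100, standard_units = "nM", confidence_score = 9L,
    data_validity_comment = NA_character_,
    activity_comment = NA_character_, potential_duplicate = "0"
  )
  dplyr::mutate(base, ...)
}

# small deterministic study for evaluation tests (fast: fewer queries)
small_study <- function(seed = 3, ...) {
  simulate_study(synthetic_spec(
    n_targets = 8, ligands_per_target = 15, inactives_per_target = 3,
    queries_per_band = c(high = 6, medium = 6, low = 6),
    violations = c(confidence_score = 3), seed = seed, ...))
}

# a perfectly separable KB: actives of target t carry bit-block t, nothing
# else in the pool does
separable_kb <- function(n_targets = 2, n_act = 12, n_extra = 260,
                         nbits = 64, seed = 1) {
  withr::with_seed(seed, {
    n_cpd <- n_targets * n_act + n_extra
    fp <- matrix(rbinom(n_cpd * nbits, 1, 0.2), n_cpd, nbits)
    fp[, 1:(4 * n_targets)] <- 0L
    rownames(fp) <- sprintf("C%04d", seq_len(n_cpd))
    pairs <- purrr::map_dfr(seq_len(n_targets), function(t) {
      idx <- (t - 1) * n_act + seq_len(n_act)
      fp[idx, (t - 1) * 4 + 1:4] <<- 1L
      tibble::tibble(structure_key = rownames(fp)[idx],
                     compound_id = rownames(fp)[idx],
                     target_id = sprintf("T%02d", t),
                     median_activity_nm = 100, label = "active")
    })
    build_knowledge_base(pairs, fp)
  })
}
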