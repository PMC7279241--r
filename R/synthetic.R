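#' Synthetic bioactivity study generator
#'
#' Emulates, at desk scale, the data regimes the pipeline is built for:
#' per-target ligand clusters with controllable Tanimoto similarity
#' structure, an active/inactive/ambiguous activity-value distribution,
#' records planted to trip each curation filter in known numbers, and a
#' later-release increment with queries at prescribed similarity bands for
#' time-split testing. Compounds are opaque keys with precomputed
#' fingerprints, so no molecular parsing is involved; generation is a pure
#' function of the spec and its seed.
#'
#' @name synthdata
NULL

#' Specification of a synthetic study
#'
#' The defaults define the package's reference study conditions: 20 targets
#' whose ligand clusters live on 256-bit fingerprints, 40 ligands per
#' cluster built from 48-bit cores at a 4% within-cluster flip rate, 90% of
#' core bits drawn from a tight shared pool (inter-target confusability,
#' calibrated so queries far from their target rank near-randomly while
#' close queries rank it first), 5 confirmed inactives per target, 5%
#' ambiguous activity values, 20 planted violations per curation rule, and
#' a release increment of 40 queries per similarity band with 10%
#' novel-only queries.
#'
#' @param n_targets number of targets (ligand clusters).
#' @param ligands_per_target active ligands per cluster (scalar or vector).
#' @param nbits fingerprint length.
#' @param core_bits set bits in each cluster core.
#' @param flip_rate independent per-position flip probability within a
#'   cluster (must be < 0.5).
#' @param overlap_rate fraction of core positions drawn from a pool shared
#'   by all clusters; raises inter-target confusability.
#' @param shared_pool_factor size of the shared pool relative to
#'   `core_bits`; a tighter pool makes distinct clusters share more
#'   positions, so off-target ligands compete harder with the true target.
#' @param inactives_per_target confirmed inactive annotations per target.
#' @param active_range,inactive_range log-uniform activity value ranges
#'   (nM) for actives (upper end 10,000) and inactives (lower end 20,000).
#' @param ambiguous_fraction fraction of extra pairs given values strictly
#'   between 10,000 and 20,000 nM (consolidated then discarded).
#' @param replicate_fraction fraction of pairs measured 2-3 times instead
#'   of once (exercises median consolidation).
#' @param violations named integer vector: planted records violating each
#'   filter rule (names from the audit categories of [filter_records()]).
#' @param queries_per_band release-increment queries per similarity band,
#'   named `high`/`medium`/`low`.
#' @param novel_fraction fraction (of the banded query count) of additional
#'   release queries annotated only to novel targets absent from the
#'   knowledge base.
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_targets = 20,
                           ligands_per_target = 40,
                           nbits = 256,
                           core_bits = 48,
                           flip_rate = 0.04,
                           overlap_rate = 0.9,
                           shared_pool_factor = 1.0,
                           inactives_per_target = 5,
                           active_range = c(10, 10000),
                           inactive_range = c(20000, 1e6),
                           ambiguous_fraction = 0.05,
                           replicate_fraction = 0.2,
                           violations = c(malformed = 20,
                                          confidence_score = 20,
                                          data_validity = 20,
                                          potential_duplicate = 20,
                                          standard_type = 20,
                                          activity_comment = 20,
                                          missing_relation = 20,
                                          censored_low = 20),
                           queries_per_band = c(high = 40, medium = 40,
                                                low = 40),
                           novel_fraction = 0.1,
                           seed = 1) {
  check_that(flip_rate >= 0 && flip_rate < 0.5, "flip_rate must be in [0, 0.5)")
  check_that(all(c(overlap_rate, ambiguous_fraction, replicate_fraction,
                   novel_fraction) >= 0 &
                   c(overlap_rate, ambiguous_fraction, replicate_fraction,
                     novel_fraction) <= 1),
             "fractions must lie in [0, 1]")
  check_that(all(names(violations) %in% FILTER_RULES),
             "violation names must be filter audit categories")
  spec <- list(n_targets = n_targets,
               ligands_per_target = rep_len(ligands_per_target, n_targets),
               nbits = nbits, core_bits = core_bits, flip_rate = flip_rate,
               overlap_rate = overlap_rate,
               shared_pool_factor = shared_pool_factor,
               inactives_per_target = inactives_per_target,
               active_range = active_range, inactive_range = inactive_range,
               ambiguous_fraction = ambiguous_fraction,
               replicate_fraction = replicate_fraction,
               violations = violations, queries_per_band = queries_per_band,
               novel_fraction = novel_fraction, seed = seed)
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate one ligand cluster
#'
#' Every ligand is the core bit pattern with independent per-position flips
#' at `flip_rate`, so a flip rate of 0 reproduces the core exactly and
#' higher rates loosen the cluster.
#'
#' @param core integer vector of set-bit positions (the cluster core).
#' @param n_ligands cluster size.
#' @param flip_rate per-position flip probability, `[0, 0.5)`.
#' @param nbits fingerprint length.
#' @param seed integer seed.
#' @param keys optional row names.
#' @return 0/1 fingerprint matrix, `n_ligands` rows.
#' @export
make_cluster <- function(core, n_ligands, flip_rate, nbits, seed,
                         keys = NULL) {
  check_that(flip_rate >= 0 && flip_rate < 0.5, "flip_rate must be in [0, 0.5)")
  base <- rep(0L, nbits)
  base[core] <- 1L
  m <- with_local_seed(seed, {
    t(vapply(seq_len(n_ligands), function(i) {
      flips <- stats::runif(nbits) < flip_rate
      as.integer(xor(base, flips))
    }, integer(nbits)))
  })
  rownames(m) <- keys %||% paste0("L", seq_len(n_ligands))
  m
}

band_interval <- function(band) {
  switch(band,
         high = c(0.66 + 1e-9, 1),
         medium = c(0.33, 0.66),
         low = c(0, 0.33 - 1e-9),
         abort(paste0("unknown band: ", band)))
}

#' Generate a query at a prescribed similarity band
#'
#' Starting from a random cluster member, random bit edits (clearing set
#' bits, setting clear ones, in equal numbers) are applied in increasing
#' amounts until the maxTC of the candidate against the cluster falls in
#' the requested band: > 0.66 for `high`, `[0.33, 0.66]` for `medium`,
#' < 0.33 for `low`. Rejection sampling; errors if the band cannot be hit
#' within the edit budget.
#'
#' @param cluster 0/1 fingerprint matrix of the cluster ligands.
#' @param band `"high"`, `"medium"` or `"low"`.
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget.
#' @param bit_pool optional positions from which added bits are drawn
#'   (e.g. the frequently-set positions of the whole knowledge base); moves
#'   edited queries toward occupied chemical space instead of empty bit
#'   space, so distant queries become confusable with other targets.
#' @return list with `fingerprint` (0/1 vector) and `max_tc` (achieved).
#' @export
make_query_at_band <- function(cluster, band, seed, max_tries = 400,
                               bit_pool = NULL) {
  iv <- band_interval(band)
  nbits <- ncol(cluster)
  with_local_seed(seed, {
    for (try in seq_len(max_tries)) {
      base <- cluster[sample(nrow(cluster), 1), ]
      on_bits <- which(base == 1)
      off_bits <- which(base == 0)
      add_pool <- if (is.null(bit_pool)) off_bits else {
        p <- intersect(bit_pool, off_bits)
        if (length(p) >= 1) p else off_bits
      }
      # edit counts from light (high band) to heavy (low band)
      n_edit <- switch(band,
                       high = sample(0:max(1, length(on_bits) %/% 5), 1),
                       medium = sample(seq(length(on_bits) %/% 5,
                                           length(on_bits) %/% 1.5), 1),
                       low = sample(seq(length(on_bits) %/% 2,
                                        length(on_bits)), 1))
      n_edit <- min(n_edit, length(on_bits), length(off_bits))
      q <- base
      if (n_edit > 0) {
        q[sample(on_bits, n_edit)] <- 0L
        added <- sample(add_pool, min(n_edit, length(add_pool)))
        extra <- n_edit - length(added)
        if (extra > 0) added <- c(added, sample(setdiff(off_bits, added), extra))
        q[added] <- 1L
      }
      tc <- max(tanimoto_rows(cluster, q))
      if (tc >= iv[1] && tc <= iv[2]) {
        return(list(fingerprint = q, max_tc = tc))
      }
    }
    abort(paste0("could not reach band ", band, " within the edit budget"))
  })
}

# draw activity values log-uniformly within a range, optionally avoiding
# the discarded interval endpoints
r_log_uniform <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

# cluster cores: `overlap_rate` of positions from a shared pool, the rest
# private per target
make_cores <- function(spec) {
  with_local_seed(derive_seed(spec$seed, "cores"), {
    pool_size <- min(spec$nbits,
                     max(spec$core_bits,
                         round(spec$core_bits * spec$shared_pool_factor)))
    shared_pool <- sample(spec$nbits, pool_size)
    lapply(seq_len(spec$n_targets), function(t) {
      n_shared <- round(spec$overlap_rate * spec$core_bits)
      shared <- sample(shared_pool, n_shared)
      private <- sample(setdiff(seq_len(spec$nbits), shared),
                        spec$core_bits - n_shared)
      sort(unique(c(shared, private)))
    })
  })
}

clean_record <- function(compound_id, target_id, value_nm) {
  tibble::tibble(
    compound_id = compound_id,
    smiles = NA_character_,
    target_id = target_id,
    standard_type = "IC50",
    standard_relation = "=",
    standard_value = value_nm,
    standard_units = "nM",
    confidence_score = 9L,
    data_validity_comment = NA_character_,
    activity_comment = NA_character_,
    potential_duplicate = "0"
  )
}

# one record violating exactly the named rule, built from a clean template
violation_record <- function(rule, compound_id, target_id, value_nm) {
  r <- clean_record(compound_id, target_id, value_nm)
  switch(rule,
         malformed = {r$compound_id <- NA_character_},
         confidence_score = {r$confidence_score <- 5L},
         data_validity = {r$data_validity_comment <- "outside typical range"},
         potential_duplicate = {r$potential_duplicate <- "1"},
         standard_type = {r$standard_type <- "Inhibition"},
         activity_comment = {r$activity_comment <- "Inconclusive"},
         missing_relation = {r$standard_relation <- NA_character_},
         censored_low = {r$standard_relation <- ">"
                         r$standard_value <- 5000})
  r
}

#' Generate a raw bioactivity table with a ground-truth ledger
#'
#' Builds the per-target ligand clusters, emits clean records for every
#' planted (compound, target) pair -- actives log-uniform at or below
#' 10,000 nM, confirmed inactives at or above 20,000 nM, a fraction of
#' ambiguous pairs strictly between, with a fraction of pairs measured in
#' replicate -- and appends records violating each curation filter in the
#' exact numbers the spec plants. The ledger records everything a test
#' needs to verify the pipeline by construction.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `records` (raw bioactivity tibble, shuffled),
#'   `fingerprints` (0/1 matrix of all compounds) and `truth` (list:
#'   `pairs` -- planted pair labels, `clusters` -- compound/target cluster
#'   membership, `planted_violations`, `n_clean_records`, `cores`).
#' @export
make_bioactivity_table <- function(spec) {
  cores <- make_cores(spec)
  cluster_fps <- vector("list", spec$n_targets)
  target_ids <- sprintf("T%03d", seq_len(spec$n_targets))
  offset <- 0L
  for (t in seq_len(spec$n_targets)) {
    n <- spec$ligands_per_target[t]
    keys <- sprintf("CPD%05d", offset + seq_len(n))
    offset <- offset + n
    cluster_fps[[t]] <- make_cluster(cores[[t]], n, spec$flip_rate,
                                     spec$nbits,
                                     derive_seed(spec$seed,
                                                 paste0("cluster:", t)),
                                     keys = keys)
  }
  fp <- do.call(rbind, cluster_fps)
  clusters <- tibble::tibble(
    compound_id = rownames(fp),
    cluster_target = rep(target_ids, spec$ligands_per_target)
  )

  pairs <- with_local_seed(derive_seed(spec$seed, "pairs"), {
    active <- tibble::tibble(
      compound_id = clusters$compound_id,
      target_id = clusters$cluster_target,
      value_nm = r_log_uniform(nrow(clusters), spec$active_range),
      label = "active"
    )
    # confirmed inactives: compounds from other clusters
    inactive <- purrr::map_dfr(seq_len(spec$n_targets), function(t) {
      pool <- clusters$compound_id[clusters$cluster_target != target_ids[t]]
      tibble::tibble(
        compound_id = sample(pool, spec$inactives_per_target),
        target_id = target_ids[t],
        value_nm = r_log_uniform(spec$inactives_per_target,
                                 spec$inactive_range),
        label = "inactive"
      )
    })
    annotated <- dplyr::bind_rows(active, inactive)
    # ambiguous pairs: unannotated (compound, target) combinations given
    # values in the discarded interval
    n_amb <- round(spec$ambiguous_fraction * nrow(annotated))
    amb <- NULL
    if (n_amb > 0) {
      all_keys <- paste(clusters$compound_id, rep(target_ids,
                                                  each = nrow(clusters)))
      used <- paste(annotated$compound_id, annotated$target_id)
      free <- setdiff(all_keys, used)
      pick <- sample(free, min(n_amb, length(free)))
      parts <- strsplit(pick, " ")
      amb <- tibble::tibble(
        compound_id = vapply(parts, `[`, "", 1),
        target_id = vapply(parts, `[`, "", 2),
        value_nm = exp(stats::runif(length(pick), log(10000 + 1),
                                    log(20000 - 1))),
        label = "discarded"
      )
    }
    dplyr::bind_rows(annotated, amb)
  })

  records <- with_local_seed(derive_seed(spec$seed, "records"), {
    n_rep <- stats::rbinom(nrow(pairs), 1, spec$replicate_fraction) *
      sample(1:2, nrow(pairs), replace = TRUE) + 1L
    idx <- rep(seq_len(nrow(pairs)), n_rep)
    # replicate values jitter within the pair's label interval so the
    # consolidated median keeps the planted label
    lo <- c(active = spec$active_range[1], inactive = spec$inactive_range[1],
            discarded = 10000 + 1)[pairs$label[idx]]
    hi <- c(active = spec$active_range[2], inactive = spec$inactive_range[2],
            discarded = 20000 - 1)[pairs$label[idx]]
    vals <- pairs$value_nm[idx]
    jitter_these <- n_rep[idx] > 1
    vals[jitter_these] <- pmin(pmax(
      vals[jitter_these] * exp(stats::runif(sum(jitter_these), -0.3, 0.3)),
      lo[jitter_these]), hi[jitter_these])
    recs <- clean_record(pairs$compound_id[idx], pairs$target_id[idx], vals)
    # planted violations, drawn over existing compounds/targets
    bad <- purrr::map_dfr(names(spec$violations), function(rule) {
      k <- spec$violations[[rule]]
      if (k == 0) return(NULL)
      purrr::map_dfr(seq_len(k), function(j) {
        violation_record(rule,
                         sample(clusters$compound_id, 1),
                         sample(target_ids, 1),
                         r_log_uniform(1, spec$active_range))
      })
    })
    all <- dplyr::bind_rows(recs, bad)
    all[sample(nrow(all)), ]
  })

  n_clean <- nrow(records) - sum(spec$violations)
  list(
    records = records,
    fingerprints = fp,
    truth = list(pairs = pairs, clusters = clusters,
                 planted_violations = spec$violations,
                 n_clean_records = n_clean, cores = cores,
                 target_ids = target_ids)
  )
}

#' Generate a later-release increment for time-split testing
#'
#' New query compounds are drawn per similarity band against the
#' knowledge-base ligand sets (each annotated as active to the target whose
#' cluster seeded it), plus a planted count of novel-only queries whose
#' single known target is absent from the knowledge base -- the
#' close-to-real-world material.
#'
#' @param kb a [knowledge_base][build_knowledge_base()] (the "earlier
#'   release").
#' @param spec the [synthetic_spec()] (uses `queries_per_band`,
#'   `novel_fraction`, `seed`).
#' @return list with `query_fp` (fingerprint matrix), `pairs` (active test
#'   pairs: `structure_key`, `target_id`, `band`, `planted_max_tc`) and
#'   `n_novel` (the planted novel-only query count).
#' @export
make_release_increment <- function(kb, spec) {
  # positions set in at least 5% of knowledge-base compounds: the occupied
  # chemical space that edited queries drift into
  occupied <- which(colSums(kb$fingerprints) >= 0.05 * nrow(kb$fingerprints))
  bands <- names(spec$queries_per_band)
  rows <- list()
  fps <- list()
  qn <- 0L
  for (band in bands) {
    for (j in seq_len(spec$queries_per_band[[band]])) {
      qn <- qn + 1L
      sd <- derive_seed(spec$seed, paste0("relq:", band, ":", j))
      target <- with_local_seed(sd, sample(kb$targets, 1))
      q <- make_query_at_band(ligand_fps(kb, target), band,
                              derive_seed(sd, "edit"), bit_pool = occupied)
      id <- sprintf("NEW%04d", qn)
      fps[[id]] <- q$fingerprint
      rows[[id]] <- tibble::tibble(structure_key = id, target_id = target,
                                   band = band, planted_max_tc = q$max_tc)
    }
  }
  n_novel <- round(spec$novel_fraction * qn)
  if (n_novel > 0) {
    for (j in seq_len(n_novel)) {
      qn <- qn + 1L
      id <- sprintf("NEW%04d", qn)
      fps[[id]] <- with_local_seed(
        derive_seed(spec$seed, paste0("novelq:", j)),
        as.integer(stats::runif(kb$nbits) < spec$core_bits / spec$nbits)
      )
      rows[[id]] <- tibble::tibble(structure_key = id,
                                   target_id = sprintf("NOVEL%03d", j),
                                   band = "novel", planted_max_tc = NA_real_)
    }
  }
  list(
    query_fp = do.call(rbind, fps),
    pairs = dplyr::bind_rows(rows),
    n_novel = n_novel
  )
}

#' Run the full synthetic study setup
#'
#' Generates the raw table, curates it, performs the 90:10 compound split,
#' builds the knowledge base from the knowledge-side pairs, and draws the
#' release increment against it.
#'
#' @param spec a [synthetic_spec()].
#' @param fraction knowledge share of the compound split.
#' @return list: `records`, `audit`, `pairs`, `split`, `kb`, `release`,
#'   `fingerprints`, `truth`.
#' @export
simulate_study <- function(spec = synthetic_spec(), fraction = 0.9) {
  gen <- make_bioactivity_table(spec)
  cur <- curate_records(gen$records)
  split <- split_global(cur$pairs, fraction = fraction, seed = spec$seed)
  kb <- build_knowledge_base(split$knowledge, gen$fingerprints)
  release <- make_release_increment(kb, spec)
  list(records = gen$records, audit = cur$audit, pairs = cur$pairs,
       split = split, kb = kb, release = release,
       fingerprints = gen$fingerprints, truth = gen$truth)
}
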