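#' Top-k evaluation with similarity deconvolution
#'
#' Two metrics, three scenarios. The success rate at k is the fraction of
#' queries with at least one known target ranked within the top k; the
#' recovery rate at k is the fraction of known active (query, target) pairs
#' whose target is ranked within the top k. Both are deconvoluted by the
#' similarity of the query to the knowledge base: queries are binned by the
#' median maxTC over their known, covered targets; pairs are binned by
#' their own maxTC. Classes are high (TC > 0.66), medium (0.33 <= TC <=
#' 0.66) and low (TC < 0.33); a finer axis uses TC bins of width 0.2.
#'
#' @name evalframe
NULL

SCENARIOS <- c("external_split", "time_split_covered", "real_world")

#' Similarity class and bin of a Tanimoto coefficient
#'
#' @param tc numeric vector in `[0, 1]`.
#' @return tibble with `tc`, `class` (`"high"` if > 0.66, `"low"` if
#'   < 0.33, else `"medium"`) and `bin` (half-open width-0.2 bins
#'   `floor(tc / 0.2)`, 0-based; tc = 1 falls in the top bin, index 4).
#' @export
#' @examples
#' similarity_class(c(0.2, 0.5, 0.7, 1))
similarity_class <- function(tc) {
  check_that(all(tc >= 0 & tc <= 1, na.rm = TRUE), "TC must lie in [0, 1]")
  tibble::tibble(
    tc = tc,
    class = dplyr::case_when(is.na(tc) ~ NA_character_,
                             tc > 0.66 ~ "high",
                             tc < 0.33 ~ "low",
                             TRUE ~ "medium"),
    bin = pmin(as.integer(floor(tc / 0.2)), 4L)
  )
}

bin_label <- function(bin) {
  ifelse(is.na(bin), "uncovered",
         sprintf("[%.1f,%.1f%s", bin * 0.2, bin * 0.2 + 0.2,
                 ifelse(bin == 4L, "]", ")")))
}

#' Ground truth of test queries against a knowledge base
#'
#' For every known active (query, target) pair, computes whether the target
#' is covered by the knowledge base (has at least one active ligand) and,
#' if so, the maxTC between the query and that target's ligand set -- the
#' distance of the query to the nearest ligand of that target.
#'
#' @param test_pairs tibble of active test pairs with `structure_key` (the
#'   query compound) and `target_id`.
#' @param kb a [knowledge_base][build_knowledge_base()].
#' @param query_fp 0/1 fingerprint matrix whose row names cover every query
#'   `structure_key`.
#' @return tibble `query_id`, `target_id`, `covered`, `max_tc` (NA when
#'   uncovered), of class `query_truth`.
#' @export
build_truth <- function(test_pairs, kb, query_fp) {
  validate_fp_matrix(query_fp)
  check_that(ncol(query_fp) == kb$nbits, "fingerprint length mismatch")
  pairs <- tibble::as_tibble(test_pairs)
  check_that(all(pairs$structure_key %in% rownames(query_fp)),
             "missing query fingerprint")
  out <- pairs |>
    dplyr::transmute(query_id = .data$structure_key,
                     target_id = .data$target_id) |>
    dplyr::mutate(
      covered = .data$target_id %in% kb$targets,
      max_tc = purrr::map2_dbl(.data$query_id, .data$target_id, function(q, t) {
        if (!t %in% kb$targets) return(NA_real_)
        max(tanimoto_rows(ligand_fps(kb, t), query_fp[q, ]))
      })
    )
  class(out) <- c("query_truth", class(out))
  out
}

#' Per-query truth summary
#'
#' Collapses a [build_truth()] table to one row per query: number of known
#' targets, number covered by the knowledge base, and the median maxTC over
#' the covered targets (NA -- flagged `uncovered` -- when none is covered;
#' possible only in the close-to-real-world scenario).
#'
#' @param truth a `query_truth` tibble.
#' @return tibble `query_id`, `n_targets`, `n_covered`, `median_max_tc`.
#' @export
summarize_truth <- function(truth) {
  truth |>
    dplyr::group_by(.data$query_id) |>
    dplyr::summarise(
      n_targets = dplyr::n(),
      n_covered = sum(.data$covered),
      median_max_tc = if (any(.data$covered)) {
        median(.data$max_tc[.data$covered])
      } else NA_real_,
      .groups = "drop"
    )
}

#' Select the evaluation set of a testing scenario
#'
#' * `external_split` -- held-out pairs of the random knowledge/test split;
#'   queries restricted to those with at least one covered target, and
#'   pairs to covered targets (the uncovered remainder is reported in the
#'   attributes).
#' * `time_split_covered` -- identical restriction applied to a later
#'   release: only queries with at least one known target inside the
#'   approach's target scope, and only their covered pairs.
#' * `real_world` -- the full later release: every query and every known
#'   active pair, including pairs whose target is absent from the scope.
#'   Those pairs are unrecoverable by construction and stay in the
#'   denominators.
#'
#' @param truth a [build_truth()] tibble for the candidate pairs.
#' @param scenario one of `"external_split"`, `"time_split_covered"`,
#'   `"real_world"`.
#' @return the filtered `query_truth`, with attributes `n_excluded_pairs`
#'   and `n_excluded_queries` counting what the covered-only scenarios
#'   dropped.
#' @export
scenario_filter <- function(truth, scenario) {
  check_that(scenario %in% SCENARIOS,
             paste0("unknown scenario: ", scenario))
  if (scenario == "real_world") {
    attr(truth, "n_excluded_pairs") <- 0L
    attr(truth, "n_excluded_queries") <- 0L
    return(truth)
  }
  covered_queries <- unique(truth$query_id[truth$covered])
  kept <- truth[truth$covered & truth$query_id %in% covered_queries, ,
                drop = FALSE]
  attr(kept, "n_excluded_pairs") <- nrow(truth) - nrow(kept)
  attr(kept, "n_excluded_queries") <-
    length(setdiff(unique(truth$query_id), covered_queries))
  kept
}

# ranks of known targets per (query, target) pair; NA when the target is
# not ranked (uncovered) or the query has no ranking
pair_ranks <- function(rankings, truth) {
  dplyr::left_join(
    truth,
    dplyr::select(rankings, "query_id", "target_id", "rank"),
    by = c("query_id", "target_id")
  )
}

#' Success rate at k
#'
#' Fraction of queries with at least one known target ranked within the
#' top k. Queries without any ranking are counted as failures in the
#' close-to-real-world scenario and are an error otherwise.
#'
#' @param rankings ranking tibble (both rankers emit the same shape).
#' @param truth a (scenario-filtered) `query_truth` tibble.
#' @param k rank cutoff.
#' @return one-row tibble `k`, `numerator`, `denominator`, `rate`.
#' @export
success_at_k <- function(rankings, truth, k) {
  per_query <- pair_ranks(rankings, truth) |>
    dplyr::group_by(.data$query_id) |>
    dplyr::summarise(hit = any(!is.na(.data$rank) & .data$rank <= k),
                     .groups = "drop")
  tibble::tibble(k = k, numerator = sum(per_query$hit),
                 denominator = nrow(per_query),
                 rate = sum(per_query$hit) / nrow(per_query))
}

#' Recovery rate at k
#'
#' Fraction of known active (query, target) pairs whose target is ranked
#' within the top k for its query.
#'
#' @inheritParams success_at_k
#' @return one-row tibble `k`, `numerator`, `denominator`, `rate`.
#' @export
recovery_at_k <- function(rankings, truth, k) {
  pr <- pair_ranks(rankings, truth)
  hit <- !is.na(pr$rank) & pr$rank <= k
  tibble::tibble(k = k, numerator = sum(hit), denominator = nrow(pr),
                 rate = sum(hit) / nrow(pr))
}

#' Evaluate rankings under a scenario
#'
#' Computes, for every k, the overall success and recovery rates and their
#' deconvolution over similarity classes and width-0.2 TC bins. Success is
#' binned by each query's median maxTC over its covered known targets;
#' recovery is binned by each pair's own maxTC. Queries (or pairs) without
#' any covered target form the dedicated `uncovered` bin, so the per-bin
#' numerators and denominators always partition the overall counts.
#'
#' @param rankings ranking tibble from [rank_targets_similarity()] or
#'   [rank_targets_ml()] (possibly several queries stacked).
#' @param truth a [build_truth()] tibble, already passed through
#'   [scenario_filter()].
#' @param scenario scenario id (recorded in the report; also controls
#'   whether unranked queries are failures or an error).
#' @param ks integer vector of rank cutoffs, default `c(1, 3, 5, 10, 15)`.
#' @return an `evaluation_report`: long tibble `scenario`, `method`, `k`,
#'   `metric` (`success`/`recovery`), `axis` (`overall`/`class`/`bin`),
#'   `group`, `numerator`, `denominator`, `rate`.
#' @export
evaluate_rankings <- function(rankings, truth, scenario,
                              ks = c(1, 3, 5, 10, 15)) {
  check_that(scenario %in% SCENARIOS, paste0("unknown scenario: ", scenario))
  check_that(nrow(truth) > 0, "empty evaluation set")
  unranked <- setdiff(unique(truth$query_id), unique(rankings$query_id))
  if (length(unranked) && scenario != "real_world") {
    abort(paste0(length(unranked), " quer(ies) without rankings in scenario ",
                 scenario))
  }
  method <- unique(rankings$method) %||% "unknown"

  qsum <- summarize_truth(truth)
  qcls <- similarity_class(qsum$median_max_tc)
  qsum$class <- ifelse(is.na(qcls$class), "uncovered", qcls$class)
  qsum$bin <- bin_label(qcls$bin)

  pcls <- similarity_class(truth$max_tc)
  truth$pair_class <- ifelse(is.na(pcls$class), "uncovered", pcls$class)
  truth$pair_bin <- bin_label(pcls$bin)

  slice_queries <- function(q) truth[truth$query_id %in% q, , drop = FALSE]

  one_k <- function(k) {
    succ_groups <- function(axis, col) {
      purrr::map_dfr(unique(qsum[[col]]), function(g) {
        success_at_k(rankings, slice_queries(qsum$query_id[qsum[[col]] == g]), k) |>
          dplyr::mutate(axis = axis, group = g)
      })
    }
    rec_groups <- function(axis, col) {
      purrr::map_dfr(unique(truth[[col]]), function(g) {
        recovery_at_k(rankings, truth[truth[[col]] == g, , drop = FALSE], k) |>
          dplyr::mutate(axis = axis, group = g)
      })
    }
    dplyr::bind_rows(
      success_at_k(rankings, truth, k) |>
        dplyr::mutate(metric = "success", axis = "overall", group = "overall"),
      succ_groups("class", "class") |> dplyr::mutate(metric = "success"),
      succ_groups("bin", "bin") |> dplyr::mutate(metric = "success"),
      recovery_at_k(rankings, truth, k) |>
        dplyr::mutate(metric = "recovery", axis = "overall", group = "overall"),
      rec_groups("class", "pair_class") |> dplyr::mutate(metric = "recovery"),
      rec_groups("bin", "pair_bin") |> dplyr::mutate(metric = "recovery")
    )
  }

  report <- purrr::map_dfr(ks, one_k) |>
    dplyr::mutate(scenario = scenario, method = method) |>
    dplyr::select("scenario", "method", "k", "metric", "axis", "group",
                  "numerator", "denominator", "rate")
  class(report) <- c("evaluation_report", class(report))
  report
}

#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  x |>
    dplyr::filter(.data$axis == "overall") |>
    tidyr::pivot_wider(id_cols = c("scenario", "method", "k"),
                       names_from = "metric", values_from = "rate")
}

#' Plot an evaluation report
#'
#' Success and recovery rates against the rank cutoff k, faceted by metric,
#' one line per similarity class (plus the overall line).
#'
#' @param object an `evaluation_report`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- dplyr::filter(object, .data$axis %in% c("overall", "class"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$rate,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_y_continuous(limits = c(0, 1),
                                labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = "top-k", y = "rate", colour = "similarity",
                  title = paste0("Top-k performance (", object$scenario[1],
                                 ", ", object$method[1], ")")) +
    ggplot2::theme_minimal()
}
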