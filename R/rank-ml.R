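#' Binary-relevance random-forest target ranking
#'
#' The multi-label target-prediction problem is decomposed into one binary
#' random-forest classifier per target (binary relevance). Each target's
#' training set holds its confirmed actives and inactives, supplemented
#' with presumed inactives -- compounds with no annotation for that target --
#' up to a 10:1 inactive:active ratio. Hyperparameters (number of trees,
#' maximum depth) are tuned per target by grid search under stratified
#' 10-fold cross-validation scored by the mean Matthews correlation
#' coefficient, and queries are ranked by the final models' probability of
#' the active class, with similarity-profile tie-breaking.
#'
#' @name mlrank
NULL

#' Default hyperparameter grid
#'
#' Number of trees in {200, 500, 1000} crossed with maximum tree depth in
#' {25, 45, 50, 75, 100}.
#'
#' @return tibble with columns `num_trees`, `max_depth`.
#' @export
default_grid <- function() {
  tidyr::crossing(num_trees = c(200L, 500L, 1000L),
                  max_depth = c(25L, 45L, 50L, 75L, 100L))
}

#' Select the targets eligible for model building
#'
#' A target enters the machine-learning scope when its knowledge-base
#' active ligand count reaches `min_actives` (default 25). Raising the
#' threshold can only shrink the list.
#'
#' @param kb a [knowledge_base][build_knowledge_base()].
#' @param min_actives minimum number of active ligands.
#' @return character vector of target ids.
#' @export
select_model_targets <- function(kb, min_actives = 25) {
  check_that(min_actives >= 1, "min_actives must be >= 1")
  n_act <- vapply(kb$ligands[kb$targets], length, integer(1))
  kb$targets[n_act >= min_actives]
}

#' Assemble the training set of one target
#'
#' Actives are the target's knowledge-base ligands; confirmed inactives are
#' its inactive-labeled compounds and are always kept in full. If confirmed
#' inactives already exceed `ratio` times the actives, no augmentation
#' happens; otherwise presumed inactives -- compounds drawn uniformly
#' without replacement from the knowledge-base compounds that carry no
#' annotation (active or inactive) for this target -- top the inactive class
#' up to exactly `ratio * n_actives`. Sampling is reproducible in
#' isolation: the RNG stream is derived from (seed, target id).
#'
#' @param kb a [knowledge_base][build_knowledge_base()].
#' @param target_id target to assemble.
#' @param ratio inactive:active ratio to reach, default 10.
#' @param seed integer seed.
#' @return a `training_set`: tibble with `structure_key`, `class`
#'   (`"active"`/`"inactive"`), `origin` (`"confirmed"`/`"presumed"`),
#'   and attributes `target_id` and `seed`.
#' @export
assemble_training_set <- function(kb, target_id, ratio = 10, seed = 1) {
  actives <- kb$ligands[[target_id]]
  check_that(!is.null(actives), paste0("target ", target_id, " not in scope"))
  confirmed <- kb$pairs$structure_key[kb$pairs$target_id == target_id &
                                        kb$pairs$label == "inactive"]
  annotated <- unique(c(actives, confirmed))
  quota <- ratio * length(actives)

  if (length(confirmed) > quota) {
    inactives <- tibble::tibble(structure_key = confirmed, origin = "confirmed")
  } else {
    pool <- sort(setdiff(rownames(kb$fingerprints), annotated))
    need <- quota - length(confirmed)
    check_that(length(pool) >= need,
               sprintf("presumed-inactive pool too small for %s: need %d, have %d",
                       target_id, need, length(pool)))
    presumed <- with_local_seed(derive_seed(seed, paste0("ts:", target_id)),
                                sample(pool, need))
    inactives <- dplyr::bind_rows(
      tibble::tibble(structure_key = confirmed, origin = "confirmed"),
      tibble::tibble(structure_key = presumed, origin = "presumed")
    )
  }
  out <- dplyr::bind_rows(
    tibble::tibble(structure_key = actives, class = "active", origin = "confirmed"),
    dplyr::mutate(inactives, class = "inactive")
  )
  structure(out, target_id = target_id, seed = seed,
            class = c("training_set", class(out)))
}

#' Matthews correlation coefficient from a confusion matrix
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; whenever any
#' factor of the denominator is zero the coefficient is defined as 0 (the
#' usual convention for degenerate folds).
#'
#' @param tp,fp,tn,fn non-negative counts (vectorized).
#' @return numeric in `[-1, 1]`.
#' @export
#' @examples
#' mcc(50, 0, 500, 0)  # 1: perfect classification
mcc <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  check_that(all(c(tp, fp, tn, fn) >= 0) && all(tp + fp + tn + fn > 0),
             "counts must be non-negative with a positive total")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  ifelse(den == 0, 0, (tp * tn - fp * fn) / sqrt(den))
}

# class-stratified fold assignment, fixed per seed so every grid point sees
# the identical partition
stratified_folds <- function(classes, folds, seed) {
  fold <- integer(length(classes))
  with_local_seed(seed, {
    for (cl in unique(classes)) {
      idx <- which(classes == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold
}

fit_forest <- function(x, y, num_trees, max_depth, seed) {
  ranger::ranger(x = x, y = y, num.trees = num_trees, max.depth = max_depth,
                 probability = TRUE, seed = seed, num.threads = 1)
}

predict_active <- function(forest, x) {
  p <- stats::predict(forest, data = x, num.threads = 1)$predictions
  as.numeric(p[, "active"])
}

#' Grid search with stratified cross-validated MCC
#'
#' Evaluates every (num_trees, max_depth) combination by the mean MCC over
#' the folds of a single class-stratified partition shared across grid
#' points (so grid cells differ only in hyperparameters, never in folds).
#' Class predictions use the 0.5 probability threshold. Ties on mean MCC
#' are broken toward fewer trees, then smaller depth -- the cheapest
#' adequate model.
#'
#' @param kb a [knowledge_base][build_knowledge_base()].
#' @param train a [training_set][assemble_training_set()].
#' @param grid tibble of `num_trees`, `max_depth` ([default_grid()]).
#' @param folds number of CV folds, default 10; requires at least `folds`
#'   actives so every fold is stratified.
#' @param seed integer seed.
#' @return a `model_spec`: one-row tibble `target_id`, `num_trees`,
#'   `max_depth`, `cv_mean_mcc`, `seed`.
#' @export
grid_search_cv <- function(kb, train, grid = default_grid(), folds = 10,
                           seed = 1) {
  target_id <- attr(train, "target_id")
  n_act <- sum(train$class == "active")
  check_that(n_act >= folds,
             sprintf("only %d actives for %d folds; reduce folds", n_act, folds))
  x <- kb$fingerprints[train$structure_key, , drop = FALSE]
  colnames(x) <- paste0("b", seq_len(ncol(x)))
  y <- factor(train$class, levels = c("active", "inactive"))
  fold <- stratified_folds(train$class, folds,
                           derive_seed(seed, paste0("folds:", target_id)))

  scores <- purrr::pmap_dbl(grid, function(num_trees, max_depth) {
    fold_mcc <- vapply(seq_len(folds), function(f) {
      hold <- fold == f
      forest <- fit_forest(x[!hold, , drop = FALSE], y[!hold],
                           num_trees, max_depth,
                           derive_seed(seed, paste0("cv:", target_id, ":", f)))
      p <- predict_active(forest, x[hold, , drop = FALSE])
      pred_active <- p >= 0.5
      truth_active <- y[hold] == "active"
      mcc(tp = sum(pred_active & truth_active),
          fp = sum(pred_active & !truth_active),
          tn = sum(!pred_active & !truth_active),
          fn = sum(!pred_active & truth_active))
    }, numeric(1))
    mean(fold_mcc)
  })
  best <- order(-scores, grid$num_trees, grid$max_depth)[1]
  structure(
    tibble::tibble(target_id = target_id,
                   num_trees = grid$num_trees[best],
                   max_depth = grid$max_depth[best],
                   cv_mean_mcc = scores[best],
                   seed = seed),
    class = c("model_spec", "tbl_df", "tbl", "data.frame")
  )
}

#' Fit the final model of one target
#'
#' Refits a probability random forest with the selected hyperparameters on
#' the complete training set.
#'
#' @param kb a [knowledge_base][build_knowledge_base()].
#' @param train a [training_set][assemble_training_set()].
#' @param spec a [model_spec][grid_search_cv()] (or any one-row tibble with
#'   `num_trees`, `max_depth`).
#' @return a `target_model`: list with the fitted forest, the spec and the
#'   training keys.
#' @export
train_final <- function(kb, train, spec) {
  target_id <- attr(train, "target_id")
  x <- kb$fingerprints[train$structure_key, , drop = FALSE]
  colnames(x) <- paste0("b", seq_len(ncol(x)))
  y <- factor(train$class, levels = c("active", "inactive"))
  forest <- fit_forest(x, y, spec$num_trees, spec$max_depth,
                       derive_seed(spec$seed %||% 1,
                                   paste0("final:", target_id)))
  structure(list(target_id = target_id, forest = forest, spec = spec,
                 training_keys = train$structure_key),
            class = "target_model")
}

#' Probability of the active class for query fingerprints
#'
#' @param model a [target_model][train_final()].
#' @param queries 0/1 fingerprint vector or matrix (queries in rows).
#' @return numeric vector of active-class probabilities in `[0, 1]`.
#' @export
predict_probability <- function(model, queries) {
  if (!is.matrix(queries)) queries <- matrix(queries, nrow = 1)
  colnames(queries) <- paste0("b", seq_len(ncol(queries)))
  predict_active(model$forest, queries)
}

#' @export
print.target_model <- function(x, ...) {
  cat("<target_model>", x$target_id,
      sprintf("(%d trees, depth %d, cv MCC %s)\n", x$spec$num_trees,
              x$spec$max_depth,
              ifelse(is.na(x$spec$cv_mean_mcc), "-",
                     format(round(x$spec$cv_mean_mcc, 3)))))
  invisible(x)
}

#' Train models for every target in the machine-learning scope
#'
#' Convenience wrapper over [select_model_targets()],
#' [assemble_training_set()], [grid_search_cv()] and [train_final()]. With a
#' single-row grid the cross-validation is skipped (`cv_mean_mcc = NA`) and
#' the models are fitted directly with those hyperparameters.
#'
#' @param kb a [knowledge_base][build_knowledge_base()].
#' @param min_actives model-scope threshold (default 25 active ligands).
#' @param grid hyperparameter grid, default [default_grid()].
#' @param folds CV folds, default 10.
#' @param ratio inactive:active augmentation ratio, default 10.
#' @param seed integer seed.
#' @return a `target_model_set`: named list of `target_model`s with
#'   attribute `min_actives`.
#' @export
train_target_models <- function(kb, min_actives = 25, grid = default_grid(),
                                folds = 10, ratio = 10, seed = 1) {
  targets <- select_model_targets(kb, min_actives)
  check_that(length(targets) >= 1, "no target reaches min_actives")
  models <- lapply(targets, function(t) {
    train <- assemble_training_set(kb, t, ratio = ratio, seed = seed)
    spec <- if (nrow(grid) == 1) {
      tibble::tibble(target_id = t, num_trees = grid$num_trees,
                     max_depth = grid$max_depth, cv_mean_mcc = NA_real_,
                     seed = seed)
    } else {
      grid_search_cv(kb, train, grid = grid, folds = folds, seed = seed)
    }
    train_final(kb, train, spec)
  })
  structure(setNames(models, targets), min_actives = min_actives,
            class = "target_model_set")
}

#' @export
print.target_model_set <- function(x, ...) {
  cat("<target_model_set>", length(x), "target models (min_actives =",
      attr(x, "min_actives"), ")\n")
  invisible(x)
}

#' @method tidy target_model_set
#' @export
tidy.target_model_set <- function(x, ...) {
  purrr::map_dfr(unclass(x), function(m) m$spec)
}

#' @method glance target_model_set
#' @export
glance.target_model_set <- function(x, ...) {
  specs <- tidy(x)
  tibble::tibble(n_models = length(x),
                 min_actives = attr(x, "min_actives"),
                 mean_cv_mcc = mean(specs$cv_mean_mcc))
}

#' Rank targets for queries with the machine-learning models
#'
#' Each query is scored by every target model's probability of the active
#' class and targets are ranked by descending probability. Targets with
#' exactly equal probabilities are ordered by the iterative
#' similarity-profile comparison against the knowledge base
#' ([compare_profiles()]); profiles identical to exhaustion fall back to
#' the target-id tie-break.
#'
#' @param queries fingerprint vector or matrix (one query per row).
#' @param models a [target_model_set][train_target_models()].
#' @param kb the knowledge base used for similarity tie-breaking.
#' @return tibble as in [rank_targets_similarity()] with `score` = active
#'   probability and `method = "ml"`.
#' @export
rank_targets_ml <- function(queries, models, kb) {
  if (!is.matrix(queries)) {
    queries <- matrix(queries, nrow = 1, dimnames = list("query", NULL))
  }
  check_that(ncol(queries) == kb$nbits, "query fingerprint length mismatch")
  targets <- names(models)
  check_that(all(targets %in% kb$targets), "model target missing from kb")
  ids <- rownames(queries) %||% paste0("query_", seq_len(nrow(queries)))
  x <- queries
  colnames(x) <- paste0("b", seq_len(ncol(x)))

  # probability matrix: queries x targets (batch predict per model)
  probs <- vapply(targets, function(t) predict_active(models[[t]]$forest, x),
                  numeric(nrow(x)))
  probs <- matrix(probs, nrow = nrow(x),
                  dimnames = list(ids, targets))

  purrr::map2_dfr(seq_len(nrow(x)), ids, function(i, id) {
    p <- probs[i, ]
    ord <- order(-p, targets)
    depth <- rep(0L, length(targets))
    # resolve exact-probability ties with similarity profiles
    for (val in unique(p[duplicated(p)])) {
      grp <- which(p[ord] == val)
      if (length(grp) < 2) next
      tied <- targets[ord[grp]]
      pmat <- profile_matrix(kb, queries[i, ], tied)
      perm <- order_profiles(pmat, tied)
      ord[grp] <- ord[grp][perm]
      depth[grp] <- adjacent_depths(pmat, perm)
    }
    tibble::tibble(
      query_id = id,
      rank = seq_along(targets),
      target_id = targets[ord],
      score = unname(p[ord]),
      tie_depth = depth,
      method = "ml"
    )
  })
}
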