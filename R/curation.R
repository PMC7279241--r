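#' Curation of raw bioactivity records
#'
#' Transforms ChEMBL-style bioactivity tables into labeled compound-target
#' pairs: record-level extraction filters, unit conversion to nM,
#' consolidation of duplicate pairs by the median activity, activity
#' labeling at the 10 uM / 20 uM thresholds, and the compound-level
#' 90:10 knowledge/test split.
#'
#' A record table has one row per measured bioactivity with columns
#' `compound_id`, `smiles`, `target_id`, `standard_type`,
#' `standard_relation`, `standard_value`, `standard_units`,
#' `confidence_score`, `data_validity_comment`, `activity_comment`,
#' `potential_duplicate`. Absent values are `NA` (empty fields in TSV).
#'
#' @name curation
NULL

ALLOWED_TYPES <- c("Kd", "Potency", "AC50", "IC50", "Ki", "EC50")
INCONCLUSIVE_COMMENTS <- c("Inconclusive", "inconclusive", "unspecified")
ACTIVE_COMMENTS <- c("Active", "active")
# ">=" and the Unicode >= sign are the same relation
GT_RELATIONS <- c(">", "\u2265", ">=", ">>")

FILTER_RULES <- c(
  "malformed",           # missing compound or target identity
  "confidence_score",    # not 7 or 9
  "data_validity",       # data_validity_comment neither null nor "manually validated"
  "potential_duplicate", # flag not "0"
  "standard_type",       # type outside Kd/Potency/AC50/IC50/Ki/EC50
  "activity_comment",    # Inconclusive/inconclusive/unspecified
  "missing_relation",    # relation null and comment not Active/active
  "censored_low"         # relation >, >=, >> with value < 20,000
)

#' Record-level extraction filters
#'
#' Applies the eight extraction predicates to a raw record table. A record
#' is kept only if it passes all of them; the audit attributes each removed
#' record to the first rule (in the order below) that rejects it, so rule
#' order never changes the kept set, only the attribution:
#'
#' 1. `malformed` -- `compound_id`/`smiles` or `target_id` missing;
#' 2. `confidence_score` -- assay confidence is not 7 or 9 (single protein
#'    or protein complex);
#' 3. `data_validity` -- `data_validity_comment` is neither absent nor
#'    `"manually validated"`;
#' 4. `potential_duplicate` -- the flag is not `"0"`;
#' 5. `standard_type` -- not one of Kd, Potency, AC50, IC50, Ki, EC50;
#' 6. `activity_comment` -- `"Inconclusive"`, `"inconclusive"` or
#'    `"unspecified"` (matched literally, case as listed);
#' 7. `missing_relation` -- `standard_relation` absent while
#'    `activity_comment` is not `"Active"`/`"active"`;
#' 8. `censored_low` -- censored relation (`>`, `>=`, `>>`) with
#'    `standard_value` below 20,000.
#'
#' @param records tibble of raw bioactivity records (see [curation]).
#' @return list with `kept` (tibble of surviving records) and `audit`
#'   (tibble `rule`, `n_removed`, one row per rule in order). Conservation
#'   holds: `nrow(kept) + sum(audit$n_removed) == nrow(records)`.
#' @export
filter_records <- function(records) {
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  get <- function(col, default = NA) {
    if (col %in% names(records)) records[[col]] else rep(default, n)
  }
  blank_na <- function(x) ifelse(is.na(x) | x == "", NA, as.character(x))

  compound_ok <- !(is.na(blank_na(get("compound_id"))) &
                     is.na(blank_na(get("smiles"))))
  target_ok <- !is.na(blank_na(get("target_id")))
  relation <- blank_na(get("standard_relation"))
  comment <- blank_na(get("activity_comment"))
  validity <- blank_na(get("data_validity_comment"))
  value <- suppressWarnings(as.numeric(get("standard_value")))

  fails <- cbind(
    malformed           = !(compound_ok & target_ok),
    confidence_score    = !(get("confidence_score") %in% c(7, 9)),
    data_validity       = !(is.na(validity) | validity == "manually validated"),
    potential_duplicate = !(as.character(get("potential_duplicate")) %in% "0"),
    standard_type       = !(get("standard_type") %in% ALLOWED_TYPES),
    activity_comment    = comment %in% INCONCLUSIVE_COMMENTS,
    missing_relation    = is.na(relation) & !(comment %in% ACTIVE_COMMENTS),
    censored_low        = !is.na(relation) & relation %in% GT_RELATIONS &
                            !is.na(value) & value < 20000
  )
  first_fail <- apply(fails, 1L, function(f) {
    w <- which(f)
    if (length(w)) w[1] else 0L
  })
  if (n == 0) first_fail <- integer(0)

  removed <- vapply(seq_along(FILTER_RULES),
                    function(i) sum(first_fail == i), integer(1))
  list(
    kept = records[first_fail == 0L, , drop = FALSE],
    audit = tibble::tibble(rule = FILTER_RULES, n_removed = removed)
  )
}

#' Convert activity values to nM
#'
#' Values reported in nM pass through; values in ug/mL are converted using
#' the molecular weight: `value * 1e6 / mol_weight` (1 ug/mL of a compound
#' of mass M g/mol is `1e-6/M` mol/L = `1e9 * 1e-6 / M` nM). Any other unit
#' yields `NA` so the caller can discard the record with an audit entry.
#'
#' @param value numeric vector of activity values (must be positive).
#' @param units character vector; `"nM"` or `"ug.mL-1"` (the ChEMBL
#'   spelling with the micro sign is accepted too).
#' @param mol_weight molecular weight in g/mol, needed where units are
#'   ug/mL (absent weights leave the value `NA`, i.e. unconvertible).
#' @return numeric vector in nM; `NA` where units are unknown or a ug/mL
#'   value has no molecular weight.
#' @export
#' @examples
#' convert_to_nM(1, "ug.mL-1", mol_weight = 500)  # 2000 nM
convert_to_nM <- function(value, units, mol_weight = NA_real_) {
  n <- max(length(value), length(units))
  value <- rep_len(as.numeric(value), n)
  units <- rep_len(as.character(units), n)
  mol_weight <- rep_len(as.numeric(mol_weight), n)
  # normalize micro signs and exponent carets so ChEMBL's unicode spelling,
  # "ug.mL-1", "ug/mL" etc. all match
  u_norm <- gsub("\u00b5|\u03bc", "u", units)
  u_norm <- gsub("\\^", "", u_norm)
  ug_ml <- u_norm %in% c("ug.mL-1", "ug/mL", "ug mL-1", "ugmL-1")
  check_that(!any(ug_ml & (!is.na(mol_weight) & mol_weight <= 0)),
             "molecular weight must be positive for ug/mL conversion")
  out <- rep(NA_real_, n)
  out[units == "nM"] <- value[units == "nM"]
  # ug/mL without a molecular weight stays NA: unconvertible, so the caller
  # discards it with an audit entry
  conv <- ug_ml & !is.na(mol_weight)
  out[conv] <- value[conv] * 1e6 / mol_weight[conv]
  out
}

#' Label a consolidated pair by its median activity
#'
#' Pairs at or below 10,000 nM are `active`; pairs at or above 20,000 nM are
#' `inactive`; pairs strictly between the two thresholds are `discarded`
#' (not used for model building or validation).
#'
#' @param median_activity numeric vector, nM, positive.
#' @return character vector of labels.
#' @export
#' @examples
#' label_pair(c(10000, 15000, 20000))  # active, discarded, inactive
label_pair <- function(median_activity) {
  check_that(all(median_activity > 0), "activities must be positive")
  dplyr::case_when(
    median_activity <= 10000 ~ "active",
    median_activity >= 20000 ~ "inactive",
    TRUE ~ "discarded"
  )
}

#' Consolidate records into unique compound-target pairs
#'
#' Multiple measurements of the same (structure key, target) -- replicate
#' assays, or stereoisomers collapsing to one key -- are merged into a single
#' pair whose representative activity is the median of the contributing
#' values (arithmetic mean of the two central values for even counts). The
#' pair is then labeled with [label_pair()].
#'
#' @param records tibble with columns `structure_key`, `compound_id`,
#'   `target_id`, `value_nm`.
#' @return tibble of pairs: `structure_key`, `compound_id` (first seen id
#'   for the key), `target_id`, `median_activity_nm`, `label`.
#' @export
consolidate_pairs <- function(records) {
  records |>
    dplyr::group_by(.data$structure_key, .data$target_id) |>
    dplyr::summarise(
      compound_id = dplyr::first(.data$compound_id),
      median_activity_nm = median(.data$value_nm),
      n_measurements = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(label = label_pair(.data$median_activity_nm)) |>
    dplyr::select("structure_key", "compound_id", "target_id",
                  "median_activity_nm", "n_measurements", "label")
}

#' Split pairs into a global knowledge base and a global test set
#'
#' The split is by compound, not by pair: every annotation of a given
#' compound lands on the same side, so no query compound ever leaks into
#' the knowledge base. Compounds are ordered by a deterministic per-compound
#' hash of (seed, structure key) and the first `round(fraction * n)` go to
#' the knowledge side; the same seed always reproduces the identical split,
#' and the expected knowledge share equals `fraction` exactly up to
#' rounding.
#'
#' @param pairs tibble of consolidated pairs (must have `structure_key`).
#' @param fraction knowledge-base share of compounds, default 0.9.
#' @param seed integer seed.
#' @return list with `knowledge` and `test` pair tibbles.
#' @export
split_global <- function(pairs, fraction = 0.9, seed = 1) {
  check_that(fraction > 0 && fraction < 1, "fraction must be in (0, 1)")
  compounds <- sort(unique(pairs$structure_key))
  # per-compound uniform drawn from an RNG seeded by (seed, key): a pure,
  # well-scrambled function of the pair, unlike a raw string hash whose
  # ordering would correlate with the key's trailing characters
  u <- vapply(compounds, function(k) {
    with_local_seed(derive_seed(seed, paste0("split:", k)), stats::runif(1))
  }, numeric(1))
  ord <- order(u, compounds)
  n_kb <- round(fraction * length(compounds))
  kb_compounds <- compounds[ord][seq_len(n_kb)]
  list(
    knowledge = pairs[pairs$structure_key %in% kb_compounds, , drop = FALSE],
    test = pairs[!pairs$structure_key %in% kb_compounds, , drop = FALSE]
  )
}

#' Curate a raw record table end to end
#'
#' Runs the full protocol: extraction filters, unit conversion (records
#' whose units are neither nM nor ug/mL are discarded with an audit entry),
#' structure standardization, consolidation by median, and labeling. In
#' synthetic mode (`chemistry = FALSE`, the default) the compound id is used
#' directly as the structure key and molecular weights are taken from a
#' `mol_weight` column when present; with `chemistry = TRUE` SMILES are
#' standardized via [standardize_compound()].
#'
#' @param records raw record tibble.
#' @param chemistry standardize SMILES through the chemistry adapter?
#' @param elements element allow-list passed to [standardize_compound()].
#' @param mass mass convention for molecular weights computed from the
#'   structure (chemistry mode only): `"monoisotopic"` (default) or
#'   `"average"`. A `mol_weight` column, when present, takes precedence.
#' @return list with `pairs` (consolidated labeled pairs) and `audit`
#'   (filter audit extended with `unknown_units` and, under chemistry,
#'   `structure_rejected` rows).
#' @export
curate_records <- function(records, chemistry = FALSE,
                           elements = ORGANIC_ELEMENTS,
                           mass = c("monoisotopic", "average")) {
  flt <- filter_records(records)
  kept <- flt$kept
  audit <- flt$audit

  if (chemistry) {
    std <- standardize_compound(unique(kept$smiles), elements = elements)
    kept <- dplyr::left_join(kept, std, by = "smiles")
    audit <- dplyr::bind_rows(
      audit,
      tibble::tibble(rule = "structure_rejected",
                     n_removed = sum(is.na(kept$key)))
    )
    kept <- kept[!is.na(kept$key), , drop = FALSE]
    kept$structure_key <- kept$key
  } else {
    kept$structure_key <- kept$compound_id
  }

  mw <- if ("mol_weight" %in% names(kept)) kept$mol_weight else
    rep(NA_real_, nrow(kept))
  if (chemistry) {
    # molecular weight from the standardized structure where not supplied
    need <- is.na(mw) & kept$standard_units != "nM"
    if (any(need)) {
      mw[need] <- molecular_weight(kept$structure_key[need],
                                   kind = match.arg(mass))
    }
  }
  value_nm <- convert_to_nM(kept$standard_value, kept$standard_units, mw)
  known_units <- !is.na(value_nm)
  audit <- dplyr::bind_rows(
    audit,
    tibble::tibble(rule = "unknown_units", n_removed = sum(!known_units))
  )
  kept <- kept[known_units, , drop = FALSE]
  kept$value_nm <- value_nm[known_units]

  list(pairs = consolidate_pairs(kept), audit = audit)
}
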