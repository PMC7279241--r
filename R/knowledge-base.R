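#' Build a knowledge base from labeled pairs and fingerprints
#'
#' The knowledge base is the reference against which queries are ranked:
#' per-target active ligand sets (only `active` pairs constitute a target's
#' ligands; `inactive` pairs are retained separately for model training),
#' plus the global compound/fingerprint index. `discarded` pairs (ambiguous
#' activity) are dropped.
#'
#' @param pairs tibble of consolidated pairs with `structure_key`,
#'   `target_id`, `label` (see [consolidate_pairs()]).
#' @param fingerprints 0/1 matrix with row names covering every
#'   `structure_key` in `pairs`.
#' @return a `knowledge_base` object: list with `pairs` (active + inactive),
#'   `fingerprints`, `targets` (character vector of targets with >= 1 active
#'   ligand, the similarity scope), `ligands` (named list of active
#'   structure keys per target) and `nbits`.
#' @export
build_knowledge_base <- function(pairs, fingerprints) {
  validate_fp_matrix(fingerprints)
  pairs <- dplyr::filter(tibble::as_tibble(pairs), .data$label != "discarded")
  missing <- setdiff(pairs$structure_key, rownames(fingerprints))
  check_that(length(missing) == 0,
             paste0("no fingerprint for ", length(missing), " compound(s), e.g. ",
                    missing[1]))
  actives <- dplyr::filter(pairs, .data$label == "active")
  ligands <- split(actives$structure_key, actives$target_id)
  kb <- list(
    pairs = pairs,
    fingerprints = fingerprints,
    targets = sort(names(ligands)),
    ligands = ligands,
    nbits = ncol(fingerprints)
  )
  class(kb) <- "knowledge_base"
  kb
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base>\n")
  cat("  targets in similarity scope:", length(x$targets), "\n")
  cat("  compounds:", nrow(x$fingerprints), " (", x$nbits, "bits )\n")
  cat("  pairs:", nrow(x$pairs),
      sprintf("(%d active / %d inactive)\n",
              sum(x$pairs$label == "active"), sum(x$pairs$label == "inactive")))
  invisible(x)
}

#' Active-ligand fingerprints of one target
#' @keywords internal
#' @noRd
ligand_fps <- function(kb, target_id) {
  keys <- kb$ligands[[target_id]]
  check_that(!is.null(keys) && length(keys) >= 1,
             paste0("target ", target_id, " has no active ligands"))
  kb$fingerprints[keys, , drop = FALSE]
}

#' Restrict a knowledge base to a target subset
#'
#' Used to compare the similarity ranker on the reduced target scope of the
#' machine-learning ranker: only the listed targets stay rankable; the
#' compound index is untouched.
#'
#' @param kb a `knowledge_base`.
#' @param targets character vector of targets to keep.
#' @return a `knowledge_base` covering only `targets`.
#' @export
restrict_targets <- function(kb, targets) {
  check_that(all(targets %in% kb$targets), "unknown target in restriction")
  kb$targets <- sort(intersect(kb$targets, targets))
  kb$ligands <- kb$ligands[kb$targets]
  kb$pairs <- dplyr::filter(kb$pairs, .data$target_id %in% targets)
  kb
}

#' @method tidy knowledge_base
#' @export
tidy.knowledge_base <- function(x, ...) {
  tibble::tibble(
    target_id = x$targets,
    n_active = vapply(x$ligands[x$targets], length, integer(1)),
    n_inactive = vapply(x$targets, function(t) {
      sum(x$pairs$target_id == t & x$pairs$label == "inactive")
    }, integer(1))
  )
}

#' @method glance knowledge_base
#' @export
glance.knowledge_base <- function(x, ...) {
  tibble::tibble(
    n_targets = length(x$targets),
    n_compounds = nrow(x$fingerprints),
    n_pairs = nrow(x$pairs),
    n_active_pairs = sum(x$pairs$label == "active"),
    n_inactive_pairs = sum(x$pairs$label == "inactive"),
    nbits = x$nbits
  )
}

#' Write / read a knowledge base directory
#'
#' Plain-text store: `pairs.tsv`, `fingerprints.tsv` (hex strings) and a
#' JSON manifest with counts and the fingerprint length.
#'
#' @param kb a `knowledge_base`.
#' @param dir directory path.
#' @return `read_knowledge_base()` returns the `knowledge_base`.
#' @export
write_knowledge_base <- function(kb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(kb$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fingerprints(kb$fingerprints, file.path(dir, "fingerprints.tsv"))
  jsonlite::write_json(as.list(glance(kb)), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_knowledge_base
#' @export
read_knowledge_base <- function(dir) {
  pairs <- tibble::as_tibble(
    read.delim(file.path(dir, "pairs.tsv"),
               colClasses = c(structure_key = "character",
                              compound_id = "character",
                              target_id = "character"))
  )
  fp <- read_fingerprints(file.path(dir, "fingerprints.tsv"))
  build_knowledge_base(pairs, fp)
}
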