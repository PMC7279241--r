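#' Structure standardization and circular fingerprints from SMILES
#'
#' The adapter between real chemistry and the bit-vector pipeline. Raw
#' SMILES are standardized to a stereochemistry-free canonical structure key
#' (salt stripping, element allow-list, stereo removal, canonicalization via
#' OpenBabel), and keys are fingerprinted with a radius-2 circular
#' (Morgan/ECFP4-style) hashed fingerprint computed over the atom/bond graph
#' parsed by ChemmineR. Every synthetic-data workflow bypasses this file and
#' feeds raw bit vectors instead.
#'
#' @name chemistry
NULL

# default element allow-list: the common organic subset
ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                      "Cl", "Se", "Br", "I")

chem_available <- function() {
  nzchar(Sys.which("obabel")) && requireNamespace("ChemmineR", quietly = TRUE)
}

require_chem <- function() {
  check_that(chem_available(),
             "chemistry support needs the obabel binary and the ChemmineR package")
}

# canonical SMILES with stereo/isotope markings dropped (obabel -ocan -xi);
# returns NA for unparsable input
obabel_canonical <- function(smiles) {
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = ".smi")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  # one molecule per line; titles keep the output aligned with the input
  writeLines(paste(smiles, seq_along(smiles)), infile)
  suppressWarnings(system2("obabel", c(infile, "-ocan", "-xi"),
                           stdout = outfile, stderr = FALSE))
  out <- if (file.exists(outfile)) readLines(outfile) else character(0)
  res <- rep(NA_character_, length(smiles))
  if (length(out)) {
    parts <- strsplit(out, "\t|[ ]+")
    for (p in parts) {
      if (length(p) >= 2) {
        i <- suppressWarnings(as.integer(p[[2]]))
        if (!is.na(i)) res[i] <- p[[1]]
      }
    }
  }
  res
}

# element symbols occurring in one SMILES string
smiles_elements <- function(smi) {
  # bracket atoms: [13CH4], [nH], [Na+] ...
  br <- regmatches(smi, gregexpr("\\[[^]]*\\]", smi))[[1]]
  el_br <- unlist(lapply(br, function(b) {
    m <- regmatches(b, regexpr("(?<=\\[)[0-9]*([A-Z][a-z]?|[a-z])", b, perl = TRUE))
    sub("^[0-9]*", "", m)
  }))
  rest <- gsub("\\[[^]]*\\]", "", smi)
  # organic-subset atoms outside brackets (two-letter first), incl. aromatic
  el_out <- unlist(regmatches(rest, gregexpr("Cl|Br|[BCNOSPFI]|[bcnops]", rest)))
  unique(c(toupper(substr(el_br, 1, 1)) |>
             paste0(substring(el_br, 2)),
           ifelse(nchar(el_out) == 1, toupper(el_out), el_out)))
}

#' Standardize a compound structure
#'
#' Applies, in order: salt stripping (multi-fragment SMILES reduced to the
#' largest fragment whose elements all sit on the allow-list), the element
#' filter (reject if the surviving fragment contains any element off the
#' allow-list), stereochemistry and isotope removal, and canonicalization.
#' The result is a canonical structure key: idempotent, and identical for
#' stereoisomers of the same constitution.
#'
#' @param smiles character vector of SMILES.
#' @param elements allowed element symbols; defaults to the organic subset
#'   H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I.
#' @return tibble with columns `smiles`, `key` (canonical structure key, NA
#'   when rejected) and `status` (`"ok"`, `"unparsable"`, or
#'   `"element_filter"`).
#' @export
#' @examples
#' \dontrun{
#' standardize_compound(c("C[C@@H](N)C(=O)O", "CC(N)C(=O)O"))  # same key
#' }
standardize_compound <- function(smiles, elements = ORGANIC_ELEMENTS) {
  require_chem()
  res <- tibble::tibble(smiles = smiles, key = NA_character_, status = "unparsable")
  can <- obabel_canonical(smiles)
  for (i in seq_along(smiles)) {
    if (is.na(can[i])) next
    frags <- strsplit(can[i], ".", fixed = TRUE)[[1]]
    allowed <- vapply(frags, function(f) all(smiles_elements(f) %in% elements), TRUE)
    sizes <- nchar(gsub("[^A-Za-z]", "", frags))
    if (!any(allowed)) {
      res$status[i] <- "element_filter"
      next
    }
    keep <- frags[allowed][which.max(sizes[allowed])]
    # re-canonicalize the kept fragment so the key is stable
    key <- if (length(frags) > 1) obabel_canonical(keep) else keep
    if (is.na(key)) {
      res$status[i] <- "unparsable"
    } else {
      res$key[i] <- key
      res$status[i] <- "ok"
    }
  }
  res
}

ELEMENT_MASSES <- data.frame(
  element = c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Se",
              "Br", "I"),
  monoisotopic = c(1.0078250319, 11.0093054, 12, 14.0030740052,
                   15.9949146221, 18.9984032, 27.9769265327, 30.97376151,
                   31.97207069, 34.96885271, 79.9165218, 78.9183376,
                   126.904468),
  average = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998, 28.085,
              30.974, 32.06, 35.45, 78.971, 79.904, 126.904)
)

#' Molecular weight of structure keys
#'
#' Computes the mass from the molecular formula (via OpenBabel, so implicit
#' hydrogens are counted). The mass convention is configurable: the default
#' is monoisotopic, matching the use of exact masses for the ug/mL
#' conversion; `"average"` gives the standard-atomic-weight mass.
#'
#' @param keys character vector of structure keys (or SMILES).
#' @param kind `"monoisotopic"` (default) or `"average"`.
#' @return numeric vector in g/mol; `NA` for unparsable input or elements
#'   without a tabulated mass.
#' @export
molecular_weight <- function(keys, kind = c("monoisotopic", "average")) {
  require_chem()
  kind <- match.arg(kind)
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = ".txt")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(paste(keys, seq_along(keys)), infile)
  suppressWarnings(system2("obabel", c(infile, "-otxt", "--append", "formula"),
                           stdout = outfile, stderr = FALSE))
  out <- if (file.exists(outfile)) readLines(outfile) else character(0)
  res <- rep(NA_real_, length(keys))
  masses <- setNames(ELEMENT_MASSES[[kind]], ELEMENT_MASSES$element)
  for (line in out) {
    p <- strsplit(line, "[ \t]+")[[1]]
    if (length(p) < 2) next
    i <- suppressWarnings(as.integer(p[[1]]))
    if (is.na(i)) next
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", p[[2]])[[1]]
    toks <- regmatches(p[[2]], list(m))[[1]]
    el <- sub("[0-9]*$", "", toks)
    cnt <- as.integer(sub("^[A-Za-z]+", "", toks))
    cnt[is.na(cnt)] <- 1L
    if (all(el %in% names(masses))) res[i] <- sum(masses[el] * cnt)
  }
  res
}

# atom/bond graph of one structure key, via ChemmineR::smiles2sdf
mol_graph <- function(key) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(key))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    matrix(numeric(0), ncol = 3)
  } else {
    cbind(bb[, 1], bb[, 2], bb[, 3])
  }
  list(elements = elem, bonds = bonds)
}

#' Radius-2 circular hashed fingerprint of a structure key
#'
#' An ECFP4-style fingerprint: each atom starts from an invariant built from
#' its element and connectivity; two rounds of neighborhood updates extend
#' the invariants to radius 2 (diameter 4 bonds); every invariant from every
#' round is hashed onto the configured number of bits. Deterministic by
#' construction.
#'
#' @param keys character vector of canonical structure keys (see
#'   [standardize_compound()]).
#' @param nbits fingerprint length (default 2048).
#' @return 0/1 integer matrix with one row per key.
#' @export
fingerprint_compound <- function(keys, nbits = 2048) {
  require_chem()
  bits <- lapply(keys, function(k) {
    g <- tryCatch(mol_graph(k), error = function(e) NULL)
    check_that(!is.null(g), paste0("cannot parse structure key: ", k))
    n <- length(g$elements)
    deg <- tabulate(c(g$bonds[, 1], g$bonds[, 2]), nbins = n)
    # neighbor lists with bond orders
    nbr <- vector("list", n)
    if (nrow(g$bonds)) {
      for (r in seq_len(nrow(g$bonds))) {
        a <- g$bonds[r, 1]; b <- g$bonds[r, 2]; o <- g$bonds[r, 3]
        nbr[[a]] <- rbind(nbr[[a]], c(b, o))
        nbr[[b]] <- rbind(nbr[[b]], c(a, o))
      }
    }
    inv <- hash31(paste(g$elements, deg, sep = ":"))
    all_inv <- inv
    for (round in 1:2) {
      inv <- vapply(seq_len(n), function(i) {
        if (is.null(nbr[[i]])) return(hash31(paste0("r", round, ":", inv[i])))
        env <- paste(sort(paste(nbr[[i]][, 2], inv[nbr[[i]][, 1]], sep = "-")),
                     collapse = "|")
        hash31(paste0("r", round, ":", inv[i], ":", env))
      }, integer(1))
      all_inv <- c(all_inv, inv)
    }
    unique(all_inv %% nbits + 1L)
  })
  fp_from_bits(bits, nbits = nbits, keys = keys)
}
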