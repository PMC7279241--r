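#' Fingerprints and Tanimoto similarity
#'
#' Fingerprints are fixed-length binary vectors (default 2048 bits, the
#' Morgan2/ECFP4 convention). A set of fingerprints is stored as a plain
#' 0/1 integer matrix with one row per compound; row names are the compound
#' (structure) keys. All downstream machinery -- both rankers, the evaluation
#' framework and the synthetic generator -- operates on these matrices, so
#' molecular parsing is only needed when starting from SMILES (see
#' [fingerprint_compound()]).
#'
#' @name fingerprints
NULL

#' Assemble a fingerprint matrix from bit-index lists
#'
#' @param bits list of integer vectors; each vector holds the 1-based indices
#'   of the set bits of one compound.
#' @param nbits fingerprint length.
#' @param keys character vector of compound keys (row names).
#' @return 0/1 integer matrix, `length(bits)` rows by `nbits` columns.
#' @export
#' @examples
#' fp_from_bits(list(a = c(1, 2, 3), b = c(2, 3, 4)), nbits = 8)
fp_from_bits <- function(bits, nbits, keys = names(bits)) {
  check_that(all(vapply(bits, function(b) all(b >= 1 & b <= nbits), TRUE)),
             "bit indices must lie in [1, nbits]")
  m <- matrix(0L, nrow = length(bits), ncol = nbits)
  for (i in seq_along(bits)) m[i, bits[[i]]] <- 1L
  rownames(m) <- keys
  m
}

validate_fp_matrix <- function(fp) {
  check_that(is.matrix(fp) && all(fp %in% c(0L, 1L)),
             "fingerprints must be a 0/1 matrix with one row per compound")
  check_that(!is.null(rownames(fp)), "fingerprint matrix must have row names")
  invisible(fp)
}

#' Tanimoto coefficient of two binary fingerprints
#'
#' `|a AND b| / |a OR b|`. The degenerate case of two all-zero fingerprints
#' is defined as 0, the conservative choice for ranking: an empty query
#' carries no evidence of similarity to anything.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1))  # 2 shared / 4 in union = 0.5
tanimoto <- function(a, b) {
  check_that(length(a) == length(b), "fingerprint lengths differ")
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(0)
  inter / uni
}

#' Tanimoto coefficients of one query against a fingerprint matrix
#'
#' Vectorized over the rows of `fp`; used everywhere a query is compared to
#' a ligand set.
#'
#' @param fp 0/1 matrix (compounds in rows).
#' @param query 0/1 vector, `ncol(fp)` long.
#' @return numeric vector, one coefficient per row of `fp`.
#' @export
tanimoto_rows <- function(fp, query) {
  check_that(ncol(fp) == length(query), "fingerprint lengths differ")
  q <- as.numeric(query)
  inter <- as.numeric(fp %*% q)
  uni <- rowSums(fp) + sum(q) - inter
  tc <- ifelse(uni == 0, 0, inter / uni)
  setNames(as.numeric(tc), rownames(fp))
}

#' Similarity profile of a query against one target's ligand set
#'
#' The profile is the full vector of Tanimoto coefficients between the query
#' and every active ligand of the target, sorted in descending order. Its
#' first entry is the target's maxTC -- the primary similarity score -- and the
#' remaining entries are consumed, in order, by the iterative tie-break of
#' the similarity ranker (next-nearest neighbor, then the one after, ...).
#'
#' @param query 0/1 fingerprint vector.
#' @param ligand_fp 0/1 matrix of the target's active-ligand fingerprints
#'   (at least one row).
#' @return numeric vector, non-increasing, entries in `[0, 1]`.
#' @export
similarity_profile <- function(query, ligand_fp) {
  check_that(is.matrix(ligand_fp) && nrow(ligand_fp) >= 1,
             "target has no active ligands; it is outside similarity scope")
  sort(tanimoto_rows(ligand_fp, query), decreasing = TRUE, method = "radix")
}

# hex serialization of fingerprint rows, for the TSV store ------------------

HEX_DIGITS <- strsplit("0123456789abcdef", "")[[1]]

fp_to_hex <- function(fp) {
  pad <- (-ncol(fp)) %% 4L
  apply(fp, 1L, function(row) {
    nib <- matrix(c(row, rep(0L, pad)), nrow = 4L)
    paste(HEX_DIGITS[colSums(nib * c(8L, 4L, 2L, 1L)) + 1L], collapse = "")
  })
}

fp_from_hex <- function(hex, nbits, keys = names(hex)) {
  lut <- matrix(0L, 16, 4)
  for (v in 0:15) lut[v + 1, ] <- as.integer(intToBits(v))[4:1]
  rows <- lapply(hex, function(h) {
    vals <- match(strsplit(tolower(h), "")[[1]], HEX_DIGITS) - 1L
    as.integer(t(lut[vals + 1L, , drop = FALSE]))[seq_len(nbits)]
  })
  m <- do.call(rbind, rows)
  rownames(m) <- keys
  m
}

#' Write / read a fingerprint store
#'
#' Plain two-column TSV: compound key and the fingerprint as a hex string,
#' most-significant bit first. Human-inspectable and diff-friendly.
#'
#' @param fp 0/1 fingerprint matrix with row names.
#' @param path file path.
#' @return `read_fingerprints()` returns the fingerprint matrix.
#' @export
write_fingerprints <- function(fp, path) {
  validate_fp_matrix(fp)
  df <- data.frame(key = rownames(fp), hex = fp_to_hex(fp), nbits = ncol(fp))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  df <- read.delim(path, colClasses = c("character", "character", "integer"))
  fp_from_hex(setNames(df$hex, df$key), nbits = df$nbits[1])
}
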