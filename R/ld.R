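#' LD reference provider
#'
#' An `ld_provider` abstracts a pairwise linkage-disequilibrium (r-squared)
#' reference panel as a lookup: `ld_r2(ld, a, b)` and
#' `ld_neighbors(ld, snp, r2_min)`. Pairs absent from the reference are
#' treated as r2 = 0 (independent). Each stored pair may carry an
#' `aligned` flag indicating whether the two SNPs' effect alleles are on
#' the same haplotype orientation; proxy substitution requires it.
#'
#' @name ld_provider
NULL

new_ld_provider <- function(pairs, ids) {
  # pairs: data.frame(snp_a, snp_b, r2, aligned) stored with snp_a < snp_b
  stopifnot(all(c("snp_a", "snp_b", "r2", "aligned") %in% names(pairs)))
  if (any(pairs$r2 < 0 | pairs$r2 > 1)) stop_param("r2 values must lie in [0,1]")
  swap <- pairs$snp_a > pairs$snp_b
  tmp <- pairs$snp_a[swap]
  pairs$snp_a[swap] <- pairs$snp_b[swap]
  pairs$snp_b[swap] <- tmp
  pairs <- pairs[pairs$snp_a != pairs$snp_b, , drop = FALSE]
  pairs <- pairs[!duplicated(pairs[, c("snp_a", "snp_b")]), , drop = FALSE]
  key <- paste(pairs$snp_a, pairs$snp_b, sep = "\r")
  structure(
    list(ids = sort(unique(ids)),
         r2 = setNames(pairs$r2, key),
         aligned = setNames(pairs$aligned, key),
         pairs = pairs),
    class = "ld_provider"
  )
}

#' Build an LD provider from a pair table
#'
#' @param x data.frame (or path to a delimited file) with columns
#'   `snp_a`, `snp_b`, `r2` and optionally `aligned` (logical; assumed
#'   `TRUE` when absent).
#' @return an `ld_provider`.
#' @export
ld_from_table <- function(x) {
  if (is.character(x)) x <- data.table::fread(x, data.table = FALSE)
  x <- as.data.frame(x)
  if (!all(c("snp_a", "snp_b", "r2") %in% names(x))) {
    stop_config("LD table needs columns snp_a, snp_b, r2")
  }
  if (is.null(x$aligned)) x$aligned <- TRUE
  new_ld_provider(x, ids = c(x$snp_a, x$snp_b))
}

#' Build an LD provider from a labeled square r-squared matrix
#'
#' @param m square numeric matrix with identical row/column names
#'   (SNP ids); must be symmetric with unit diagonal.
#' @return an `ld_provider`.
#' @export
ld_from_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m))) {
    stop_config("matrix must have identical row and column SNP-id labels")
  }
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop_config("r2 matrix must be symmetric")
  }
  if (any(abs(diag(m) - 1) > 1e-8)) stop_config("r2 matrix diagonal must be 1")
  idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  pairs <- data.frame(
    snp_a = rownames(m)[idx[, 1]],
    snp_b = colnames(m)[idx[, 2]],
    r2 = m[idx],
    aligned = TRUE
  )
  new_ld_provider(pairs, ids = rownames(m))
}

#' Pairwise r-squared lookup
#'
#' @param ld an `ld_provider`.
#' @param a,b SNP ids (vectorized, recycled).
#' @return numeric vector of r2 values; 1 on the diagonal, 0 for pairs
#'   not present in the reference.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_provider"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  out <- unname(ld$r2[key])
  out[is.na(out)] <- 0
  out[a == b] <- 1
  out
}

#' Neighbors of a SNP above an r-squared threshold
#'
#' @param ld an `ld_provider`.
#' @param snp SNP id.
#' @param r2_min minimum r2 (inclusive).
#' @return data.frame with columns `snp_id`, `r2`, `aligned`, sorted by
#'   decreasing r2 then snp_id.
#' @export
ld_neighbors <- function(ld, snp, r2_min = 0.8) {
  stopifnot(inherits(ld, "ld_provider"))
  p <- ld$pairs
  hit <- p$snp_a == snp | p$snp_b == snp
  p <- p[hit & p$r2 >= r2_min, , drop = FALSE]
  out <- data.frame(
    snp_id = ifelse(p$snp_a == snp, p$snp_b, p$snp_a),
    r2 = p$r2,
    aligned = p$aligned,
    stringsAsFactors = FALSE
  )
  out[order(-out$r2, out$snp_id), , drop = FALSE]
}

#' @export
print.ld_provider <- function(x, ...) {
  cat("<ld_provider> ", length(x$ids), " SNPs, ",
      nrow(x$pairs), " stored pairs\n", sep = "")
  invisible(x)
}
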