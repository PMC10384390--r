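#' GWAS summary-statistics set
#'
#' A `sumstats_set` holds one trait's per-SNP association records: rsID,
#' chromosome, 1-based position, effect/other allele, effect-allele
#' frequency, effect size (beta), standard error, p-value and sample size.
#' Records are validated on construction; rows violating the invariants
#' (non-positive SE, frequency outside \[0,1\], identical alleles, p-value
#' outside (0,1\], duplicated rsID) are dropped with a message.
#'
#' @param records data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'   `eaf` and `n` may be `NA`.
#' @param trait_id short machine identifier for the trait.
#' @param trait_label human-readable trait name (defaults to `trait_id`).
#' @param role `"exposure"` or `"outcome"`; fixed at construction.
#' @param allow_indels keep multi-base alleles instead of dropping them.
#'   Harmonization is only defined for single-nucleotide variants, so
#'   indels pass through untested; default `FALSE`.
#'
#' @return An object of class `sumstats_set`: a list with elements
#'   `trait_id`, `trait_label`, `role`, `records` (validated data.frame)
#'   and `n_dropped` (rows rejected during validation).
#' @export
sumstats_set <- function(records, trait_id, trait_label = trait_id,
                         role = c("exposure", "outcome"),
                         allow_indels = FALSE) {
  role <- match.arg(role)
  req <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop_config("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  rec <- as.data.frame(records)[, req]
  rec$snp_id <- as.character(rec$snp_id)
  rec$chrom <- as.character(rec$chrom)
  rec$pos <- as.integer(rec$pos)
  rec$effect_allele <- toupper(as.character(rec$effect_allele))
  rec$other_allele <- toupper(as.character(rec$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) rec[[col]] <- as.numeric(rec[[col]])
  rec$n <- as.numeric(rec$n)

  n_in <- nrow(rec)
  ok <- !is.na(rec$snp_id) & nzchar(rec$snp_id) &
    !is.na(rec$pos) & rec$pos >= 1L &
    !is.na(rec$beta) &
    !is.na(rec$se) & rec$se > 0 &
    !is.na(rec$pval) & rec$pval > 0 & rec$pval <= 1 &
    rec$effect_allele != rec$other_allele &
    (is.na(rec$eaf) | (rec$eaf >= 0 & rec$eaf <= 1))
  if (!allow_indels) {
    ok <- ok & is_snv_allele(rec$effect_allele) & is_snv_allele(rec$other_allele)
  }
  rec <- rec[ok, , drop = FALSE]
  dup <- duplicated(rec$snp_id)
  if (any(dup)) {
    warning(sum(dup), " duplicated snp_id(s) dropped (first occurrence kept)")
    rec <- rec[!dup, , drop = FALSE]
  }
  n_dropped <- n_in - nrow(rec)
  if (n_dropped > 0) {
    message("sumstats_set[", trait_id, "]: dropped ", n_dropped, " of ",
            n_in, " rows failing validation")
  }
  rownames(rec) <- NULL
  structure(
    list(trait_id = trait_id, trait_label = trait_label, role = role,
         records = rec, n_dropped = n_dropped),
    class = "sumstats_set"
  )
}

#' @export
print.sumstats_set <- function(x, ...) {
  cat("<sumstats_set> ", x$trait_id, " (", x$role, "): ",
      nrow(x$records), " SNPs\n", sep = "")
  print(head(x$records, 5))
  invisible(x)
}

#' @export
length.sumstats_set <- function(x) nrow(x$records)

# Replace the record table, preserving metadata.
replace_records <- function(s, rec) {
  s$records <- rec
  rownames(s$records) <- NULL
  s
}

#' Default column mapping for summary-statistic files
#'
#' Maps the internal field names to header names in the input file.
#' Override any entry to match a published dialect, e.g.
#' `default_column_map(snp_id = "rsid", pval = "P")`.
#'
#' @param ... named overrides, `internal_field = "file_column"`.
#' @return named character vector, internal field -> file column.
#' @export
default_column_map <- function(...) {
  map <- c(snp_id = "snp_id", chrom = "chrom", pos = "pos",
           effect_allele = "effect_allele", other_allele = "other_allele",
           eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n")
  dots <- c(...)
  if (length(dots)) map[names(dots)] <- dots
  map
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-delimited text file (optionally gzipped; the
#' delimiter is sniffed by [data.table::fread()]), renames columns via
#' `column_map`, and validates the result into a [sumstats_set].
#' `eaf` and `n` columns are optional: if absent from the map or file
#' they are filled with `NA`.
#'
#' @param path file path.
#' @param role `"exposure"` or `"outcome"`.
#' @param column_map named mapping from internal field names to file
#'   column names; see [default_column_map()].
#' @param trait_id trait identifier (defaults to the file stem).
#' @param trait_label human-readable name.
#' @param allow_indels passed to [sumstats_set()].
#' @return a validated [sumstats_set].
#' @export
read_sumstats <- function(path, role = c("exposure", "outcome"),
                          column_map = default_column_map(),
                          trait_id = NULL, trait_label = NULL,
                          allow_indels = FALSE) {
  role <- match.arg(role)
  if (!file.exists(path)) stop_input("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (nrow(dt) == 0) stop_input("empty summary-statistics file: ", path)

  optional <- c("eaf", "n")
  required <- setdiff(names(default_column_map()), optional)
  out <- data.frame(row.names = seq_len(nrow(dt)))
  for (field in names(default_column_map())) {
    src <- unname(column_map[field])
    if (!is.na(src) && !is.null(src) && src %in% names(dt)) {
      out[[field]] <- dt[[src]]
    } else if (field %in% optional) {
      out[[field]] <- NA
    } else {
      stop_config("column '", src %||% field, "' (field '", field,
                  "') not found in ", path)
    }
  }
  trait_id <- trait_id %||% sub("\\.(tsv|csv|txt)(\\.gz)?$", "", basename(path))
  sumstats_set(out, trait_id = trait_id,
               trait_label = trait_label %||% trait_id,
               role = role, allow_indels = allow_indels)
}

#' Write a result table to TSV or JSON
#'
#' Numeric fields survive a round-trip (write then read) to at least
#' 1e-12 relative tolerance: TSV output uses 17 significant digits and
#' JSON output is written with full precision.
#'
#' @param results a data.frame, or an object with an `as.data.frame` method
#'   (e.g. the output of [run_mr()] or [sensitivity_report()]).
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `invisible(path)`.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(results)
  if (format == "tsv") {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    old <- options(digits = 17)
    on.exit(options(old), add = TRUE)
    data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  } else {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path file path.
#' @param format `"tsv"` or `"json"`.
#' @return data.frame.
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}
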