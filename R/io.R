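# Tab-separated readers and writers for the tables the pipeline
# exchanges: GWAS summary statistics, family and pair tables, LD scores
# and per-SNP fit output.  TSV is the lingua franca of deposited summary
# statistics; gzipped files are handled transparently by readr.

.read_tsv_quiet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = c("", "NA"))
}

.apply_column_map <- function(data, column_map) {
  if (is.null(column_map)) return(data)
  # column_map: named character vector, canonical = file column.
  for (canon in names(column_map)) {
    src <- column_map[[canon]]
    if (!src %in% names(data)) {
      stop("column override '", src, "' not found in file", call. = FALSE)
    }
    names(data)[names(data) == src] <- canon
  }
  data
}

.require_columns <- function(data, required, what) {
  miss <- setdiff(required, names(data))
  if (length(miss)) {
    stop("schema error: ", what, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(data)
}

#' Read a GWAS summary-statistics file
#'
#' Expects a TSV (optionally gzipped) with a header.  Required columns:
#' `snp_id`, `effect_allele`, `other_allele`, `beta`, `se`; `eaf`, `n`
#' and `p` are carried through when present.  Rows missing `beta` or
#' `se` are dropped with a message; allele strings are upper-cased.
#'
#' @param path Path to the file.
#' @param column_map Optional named character vector mapping canonical
#'   names to the file's column names, e.g.
#'   `c(snp_id = "SNP", beta = "BETA")`.
#' @return A tibble of typed GWAS records.
#' @export
read_gwas <- function(path, column_map = NULL) {
  data <- .apply_column_map(.read_tsv_quiet(path), column_map)
  .require_columns(data, c("snp_id", "effect_allele", "other_allele",
                           "beta", "se"), "GWAS file")
  n0 <- nrow(data)
  data <- data[!is.na(data$beta) & !is.na(data$se), , drop = FALSE]
  if (nrow(data) < n0) {
    message("dropped ", n0 - nrow(data), " row(s) with missing beta or se")
  }
  if (any(data$se <= 0)) {
    stop("schema error: non-positive se in GWAS file", call. = FALSE)
  }
  data$effect_allele <- toupper(data$effect_allele)
  data$other_allele <- toupper(data$other_allele)
  if (any(data$effect_allele == data$other_allele)) {
    stop("schema error: effect_allele equals other_allele for some rows",
         call. = FALSE)
  }
  keep <- intersect(c("snp_id", "effect_allele", "other_allele", "eaf",
                      "beta", "se", "n", "p"), names(data))
  tibble::as_tibble(data[keep])
}

#' Read a family table
#'
#' TSV with columns `id`, `snp`, `own_pheno`, `offspring_pheno`; empty
#' cells are missing values.  Missingness patterns are derived on read.
#'
#' @inheritParams read_gwas
#' @return A tibble with a derived `pattern` column (see
#'   [family_patterns()]).
#' @export
read_family_table <- function(path, column_map = NULL) {
  data <- .apply_column_map(.read_tsv_quiet(path), column_map)
  .require_columns(data, c("snp", "own_pheno", "offspring_pheno"),
                   "family table")
  family_patterns(data)
}

#' Read a mother-offspring pair table
#'
#' TSV with columns `offspring_pheno`, `offspring_snp`, `maternal_snp`.
#'
#' @inheritParams read_gwas
#' @return A tibble of pair records.
#' @export
read_pair_table <- function(path, column_map = NULL) {
  data <- .apply_column_map(.read_tsv_quiet(path), column_map)
  .require_columns(data, c("offspring_pheno", "offspring_snp",
                           "maternal_snp"), "pair table")
  tibble::as_tibble(data)
}

#' Read an LD-score table
#'
#' TSV with columns `snp_id` and `ld_score`.
#'
#' @inheritParams read_gwas
#' @return A tibble.
#' @export
read_ld_scores <- function(path, column_map = NULL) {
  data <- .apply_column_map(.read_tsv_quiet(path), column_map)
  .require_columns(data, c("snp_id", "ld_score"), "LD-score table")
  tibble::as_tibble(data)
}

#' Write a result table as TSV
#'
#' Thin wrapper over [readr::write_tsv()]; numeric columns keep full
#' precision so written tables round-trip through the readers.
#'
#' @param data A data frame.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_table <- function(data, path) {
  readr::write_tsv(data, path, progress = FALSE)
  invisible(data)
}
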