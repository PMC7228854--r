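# Reading, validating and writing GWAS summary-statistics tables and LD matrices.
#
# The on-disk convention is the de-facto GWAS sumstats one: a delimited text
# table with a header row, one SNP per row. Tables are represented in R as a
# data.frame with canonical columns plus attributes carrying trait metadata
# (class "sumstat_table"), in the spirit of how limma/DESeq2 wrap plain
# containers rather than inventing opaque ones.

SUMSTAT_COLS <- c("snp", "effect_allele", "other_allele", "eaf", "beta",
                  "se", "pval", "n", "n_case", "n_control")

#' Construct a summary-statistics table
#'
#' Builds a validated `sumstat_table` from a data.frame holding per-SNP GWAS
#' associations. Rows violating the record invariants (invalid alleles,
#' non-positive SE, p-value outside (0, 1], effect-allele frequency outside
#' (0, 1), missing sample size for a binary trait, duplicated SNP id) are
#' dropped and recorded in the validation report attached as attribute
#' `"validation"`. Values are never silently altered: every conversion
#' (odds ratio to log-odds, zero p-value clamped to the smallest positive
#' double) also appears in the report with a reason code.
#'
#' @param x data.frame with (a subset of) columns `snp`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`, `n_case`, `n_control`.
#'   Alleles are upper-cased; only single-base A/C/G/T alleles are accepted
#'   (indels are dropped with reason `indel_allele`).
#' @param trait_name label for the trait.
#' @param trait_type `"continuous"` or `"binary"`. For binary traits `beta`
#'   is interpreted as natural-log odds; each record must carry `n` or both
#'   `n_case` and `n_control`.
#' @return A data.frame of class `sumstat_table` with canonical columns,
#'   attributes `trait_name`, `trait_type`, and `validation` (a data.frame
#'   `snp`/`action`/`reason`, zero rows when nothing was dropped or converted).
#' @export
sumstat_table <- function(x, trait_name = "trait",
                          trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in SUMSTAT_COLS) {
    if (!col %in% names(x)) x[[col]] <- rep(NA, nrow(x))
  }
  x <- x[SUMSTAT_COLS]
  x$snp <- as.character(x$snp)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n", "n_case", "n_control"))
    x[[col]] <- as.numeric(x[[col]])

  report <- list()
  note <- function(snp, action, reason) {
    report[[length(report) + 1L]] <<- data.frame(
      snp = snp, action = action, reason = reason, stringsAsFactors = FALSE)
  }
  drop <- rep(FALSE, nrow(x))
  flag <- function(bad, reason) {
    bad <- bad & !drop
    if (any(bad)) note(x$snp[bad], "dropped", reason)
    drop <<- drop | bad
  }

  flag(is.na(x$snp) | x$snp == "", "missing_snp_id")
  allele_ok <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  indel <- (!is.na(x$effect_allele) & nchar(x$effect_allele) > 1L) |
           (!is.na(x$other_allele) & nchar(x$other_allele) > 1L)
  flag(indel, "indel_allele")
  flag(!allele_ok(x$effect_allele) | !allele_ok(x$other_allele),
       "invalid_allele")
  flag(x$effect_allele == x$other_allele, "alleles_identical")
  flag(is.na(x$beta) | !is.finite(x$beta), "missing_beta")
  flag(is.na(x$se) | !is.finite(x$se) | x$se <= 0, "nonpositive_se")
  # p = 0 is clamped (downstream log transforms), not dropped
  clamp <- !drop & !is.na(x$pval) & x$pval == 0
  if (any(clamp)) {
    note(x$snp[clamp], "converted", "pval_zero_clamped")
    x$pval[clamp] <- .Machine$double.xmin
  }
  flag(is.na(x$pval) | x$pval <= 0 | x$pval > 1, "bad_pval")
  flag(!is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1), "bad_eaf")
  if (trait_type == "binary")
    flag(is.na(x$n) & (is.na(x$n_case) | is.na(x$n_control)),
         "missing_n_binary")
  dup <- duplicated(x$snp)
  flag(dup, "duplicate_snp_id")

  out <- x[!drop, , drop = FALSE]
  rownames(out) <- NULL
  rep_df <- if (length(report)) do.call(rbind, report) else
    data.frame(snp = character(), action = character(), reason = character(),
               stringsAsFactors = FALSE)
  structure(out,
            trait_name = trait_name, trait_type = trait_type,
            validation = rep_df,
            class = c("sumstat_table", "data.frame"))
}

#' @export
print.sumstat_table <- function(x, ...) {
  cat(sprintf("Summary statistics: %s (%s), %d SNPs\n",
              attr(x, "trait_name"), attr(x, "trait_type"), nrow(x)))
  v <- attr(x, "validation")
  if (!is.null(v) && nrow(v))
    cat(sprintf("  validation report: %d row(s) dropped/converted\n", nrow(v)))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file (tab, comma or whitespace separated; sniffed)
#' with a header row into a [sumstat_table]. `"NA"`, the empty string and
#' `"."` all parse as missing. An odds-ratio column mapped via
#' `column_map["or"]` is converted to `beta` by natural log and recorded in
#' the validation report.
#'
#' @param path file path.
#' @param column_map named character vector mapping standard field names
#'   (`snp`, `effect_allele`, `other_allele`, `eaf`, `beta` or `or`, `se`,
#'   `pval`, `n`, `n_case`, `n_control`) to the file's column names. Fields
#'   left unmapped default to their canonical names when present in the file.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param trait_name label; defaults to the file name.
#' @return A [sumstat_table].
#' @export
read_sumstats <- function(path, column_map = NULL,
                          trait_type = c("continuous", "binary"),
                          trait_name = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path))
    stop_mrb("summary-statistics file not found: %s", path, class = "io_error")
  if (file.size(path) == 0L)
    stop_mrb("summary-statistics file is empty (no header): %s", path,
             class = "empty_table_error")
  raw <- data.table::fread(path, header = TRUE, sep = "auto",
                           na.strings = c("NA", "", "."),
                           data.table = FALSE, showProgress = FALSE)
  cmap <- as.list(column_map %||% character())
  mandatory <- c("snp", "effect_allele", "other_allele", "se", "pval")
  fields <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "or",
              "se", "pval", "n", "n_case", "n_control")
  got <- list()
  for (f in fields) {
    colname <- cmap[[f]] %||% f
    if (colname %in% names(raw)) got[[f]] <- raw[[colname]]
    else if (!is.null(cmap[[f]]))
      stop_mrb("mapped column '%s' (field '%s') not found in %s",
               colname, f, path, class = "format_error")
  }
  for (f in mandatory)
    if (is.null(got[[f]]))
      stop_mrb("mandatory column missing: %s", cmap[[f]] %||% f,
               class = "format_error")
  converted <- NULL
  if (is.null(got$beta)) {
    if (is.null(got$or))
      stop_mrb("mandatory column missing: beta (or an 'or' mapping)",
               class = "format_error")
    or <- as.numeric(got$or)
    got$beta <- log(or)
    converted <- data.frame(snp = as.character(got$snp),
                            action = "converted", reason = "or_to_log_beta",
                            stringsAsFactors = FALSE)[!is.na(or), , drop = FALSE]
  }
  got$or <- NULL
  tab <- sumstat_table(as.data.frame(got, stringsAsFactors = FALSE),
                       trait_name = trait_name %||% basename(path),
                       trait_type = trait_type)
  if (!is.null(converted))
    attr(tab, "validation") <- rbind(converted, attr(tab, "validation"))
  tab
}

#' Write a summary-statistics table
#'
#' Writes tab-delimited text with the canonical header
#' `snp effect_allele other_allele eaf beta se pval n n_case n_control`.
#' Numerics are written at 10 significant digits so that
#' `read_sumstats(write_sumstats(x))` round-trips losslessly at that
#' precision; missing values are written as `NA`.
#'
#' @param table a [sumstat_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstat_table"))
  out <- as.data.frame(table)[SUMSTAT_COLS]
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.10g", x))
  for (col in c("eaf", "beta", "se", "pval", "n", "n_case", "n_control"))
    out[[col]] <- fmt(out[[col]])
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop_mrb("cannot write summary statistics to %s: %s", path,
             conditionMessage(ok), class = "io_error")
  invisible(path)
}

#' Construct an LD correlation matrix
#'
#' @param r square numeric matrix of pairwise LD correlations, unit diagonal.
#' @param snp_ids SNP identifiers for rows/columns; defaults to `colnames(r)`.
#' @return A matrix of class `ld_matrix` with `snp_ids` as dimnames.
#'   Asymmetry or diagonal deviation beyond `1e-8` is an error; within the
#'   tolerance the matrix is symmetrized exactly and the diagonal set to 1.
#' @export
ld_matrix <- function(r, snp_ids = colnames(r)) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r))
    stop_mrb("LD matrix must be square (got %d x %d)", nrow(r), ncol(r),
             class = "format_error")
  if (is.null(snp_ids) || length(snp_ids) != nrow(r))
    stop_mrb("LD matrix needs one SNP id per row/column",
             class = "format_error")
  if (!is.numeric(r) || anyNA(r))
    stop_mrb("LD matrix must be numeric with no missing values",
             class = "format_error")
  if (any(abs(r) > 1 + 1e-12))
    stop_mrb("LD correlations must lie in [-1, 1]", class = "range_error")
  if (max(abs(r - t(r))) > 1e-8)
    stop_mrb("LD matrix asymmetric beyond 1e-8", class = "format_error")
  if (max(abs(diag(r) - 1)) > 1e-8)
    stop_mrb("LD matrix diagonal must be 1", class = "format_error")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  dimnames(r) <- list(snp_ids, snp_ids)
  class(r) <- c("ld_matrix", class(matrix()))
  r
}

#' Read an LD matrix from delimited text
#'
#' Expects a square numeric matrix with SNP ids as the header row; an
#' optional first column of row ids must match the header.
#'
#' @param path file path.
#' @return An [ld_matrix].
#' @export
read_ld_matrix <- function(path) {
  raw <- data.table::fread(path, header = TRUE, sep = "auto",
                           data.table = FALSE, showProgress = FALSE)
  if (ncol(raw) >= 1L && !is.numeric(raw[[1]])) {
    row_ids <- as.character(raw[[1]])
    raw <- raw[, -1, drop = FALSE]
    if (!identical(row_ids, names(raw)))
      stop_mrb("LD matrix row ids do not match column ids",
               class = "format_error")
  }
  ld_matrix(as.matrix(raw), snp_ids = names(raw))
}

#' Convert an odds ratio to a log-odds effect
#' @param or odds ratio(s), positive.
#' @return natural log of `or`.
#' @export
or_to_logodds <- function(or) {
  stopifnot(all(or > 0))
  log(or)
}
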