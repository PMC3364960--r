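# Readers and writers for the package's tab-delimited formats and VCF.
#
# The summary-statistics dialect has one exact header (STATS_COLUMNS); files
# with missing, extra or reordered columns are rejected by name, and
# malformed cells are rejected with their line number. All numerics are
# written with 17 significant digits so that write -> read is the identity
# at full double precision.

STATS_NUMERIC <- c("eaf", "beta", "se", "z", "p", "chi2", "info")
STATS_INTEGER <- c("pos", "n_cases", "n_controls", "gc_applied")

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write summary statistics in the package dialect
#'
#' @param records summary-statistics data frame with exactly the dialect
#'   columns (`variant_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `z`, `p`, `chi2`, `info`,
#'   `n_cases`, `n_controls`, `analysis_tag`, `gc_applied`,
#'   `exclusion_reason`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(records, path) {
  if (!identical(sort(names(records)), sort(STATS_COLUMNS))) {
    stop_bmistrat("records do not match the summary-statistics dialect",
                  "bmistrat_format_error")
  }
  records <- records[, STATS_COLUMNS]
  out <- records
  for (col in c(STATS_NUMERIC)) out[[col]] <- fmt_num(records[[col]])
  # p in scientific notation (full precision)
  out$p <- ifelse(is.na(records$p), "NA", sprintf("%.16e", records$p))
  for (col in STATS_INTEGER) out[[col]] <- as.character(records[[col]])
  lines <- c(paste(STATS_COLUMNS, collapse = "\t"),
             do.call(paste, c(unname(as.list(out)), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

parse_numeric_col <- function(cells, col, lines_idx, integer = FALSE) {
  x <- suppressWarnings(as.numeric(cells))
  bad <- is.na(x) & cells != "NA"
  if (any(bad)) {
    stop_bmistrat(sprintf("non-numeric value '%s' in column '%s' at line %d",
                          cells[bad][1L], col, lines_idx[bad][1L]),
                  "bmistrat_format_error")
  }
  if (integer) as.integer(x) else x
}

#' Read summary statistics in the package dialect
#'
#' The header must match the dialect exactly (same columns, same order);
#' the first offending column is named otherwise. Rows are validated:
#' numeric cells must parse (line number reported otherwise), `se` must be
#' positive and `p` must lie in (0, 1\] (`NA` estimates from failed
#' per-variant fits are allowed).
#'
#' @param path input file path.
#' @return Summary-statistics data frame.
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) {
    stop_bmistrat(paste0("file not found: ", path), "bmistrat_format_error")
  }
  lines <- readLines(path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, STATS_COLUMNS)) {
    miss <- setdiff(STATS_COLUMNS, header)
    extra <- setdiff(header, STATS_COLUMNS)
    bad <- c(miss, extra,
             if (!length(miss) && !length(extra)) "(column order)")
    stop_bmistrat(paste0("summary-statistics header mismatch: ",
                         paste(bad, collapse = ", ")),
                  "bmistrat_format_error")
  }
  body <- lines[-1L]
  if (!length(body)) return(empty_stats())
  cells <- strsplit(body, "\t", fixed = TRUE)
  # a trailing empty field (blank exclusion_reason) is dropped by strsplit
  cells <- lapply(cells, function(x) {
    if (length(x) == length(STATS_COLUMNS) - 1L) c(x, "") else x
  })
  nfield <- lengths(cells)
  if (any(nfield != length(STATS_COLUMNS))) {
    stop_bmistrat(sprintf("wrong field count at line %d",
                          which(nfield != length(STATS_COLUMNS))[1L] + 1L),
                  "bmistrat_format_error")
  }
  m <- matrix(unlist(cells), ncol = length(STATS_COLUMNS), byrow = TRUE)
  colnames(m) <- STATS_COLUMNS
  idx <- seq_along(body) + 1L
  out <- data.frame(m, stringsAsFactors = FALSE)
  for (col in STATS_NUMERIC) out[[col]] <- parse_numeric_col(m[, col], col, idx)
  for (col in STATS_INTEGER) {
    out[[col]] <- parse_numeric_col(m[, col], col, idx, integer = TRUE)
  }
  bad_p <- !is.na(out$p) & (out$p <= 0 | out$p > 1)
  if (any(bad_p)) {
    stop_bmistrat(sprintf("p must lie in (0, 1] (line %d)",
                          idx[bad_p][1L]),
                  "bmistrat_format_error")
  }
  bad_se <- !is.na(out$se) & out$se <= 0
  if (any(bad_se)) {
    stop_bmistrat(sprintf("se must be positive (line %d)", idx[bad_se][1L]),
                  "bmistrat_format_error")
  }
  out
}

#' Write a genotype matrix as TSV
#'
#' Rows are individuals (first column `individual_id`), remaining columns
#' are variant dosages written with 4 decimal places.
#'
#' @param genotypes dosage matrix with variant-ID column names.
#' @param path output path.
#' @param ids individual identifiers (defaults to `ind000001`...).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path, ids = NULL) {
  n <- nrow(genotypes)
  ids <- ids %||% sprintf("ind%06d", seq_len(n))
  dt <- data.table::as.data.table(round(genotypes, 4))
  dt <- cbind(data.table::data.table(individual_id = ids), dt)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read genotypes from TSV or VCF
#'
#' TSV: the format of [write_genotypes()]. VCF (4.x): per-sample dosage is
#' taken from the `DS` FORMAT field when present, else derived from `GT` as
#' the count of ALT alleles (the effect allele is the ALT allele).
#' Multi-allelic records are skipped with a warning; dosages outside
#' \[0, 2\] are an error reported with their coordinates. Missing entries
#' are returned as `NA`.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @return A list with `dosages` (individuals x variants matrix) and
#'   `variants` (data frame: `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`).
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- as.data.frame(data.table::fread(path, sep = "\t"))
    ids <- df$individual_id
    g <- as.matrix(df[setdiff(names(df), "individual_id")])
    rownames(g) <- ids
    bad <- which(!is.na(g) & (g < 0 | g > 2), arr.ind = TRUE)
    if (nrow(bad)) {
      stop_bmistrat(
        sprintf("dosage outside [0, 2] for individual '%s', variant '%s'",
                rownames(g)[bad[1L, 1L]] %||% bad[1L, 1L],
                colnames(g)[bad[1L, 2L]]),
        "bmistrat_format_error")
    }
    list(dosages = g,
         variants = data.frame(variant_id = colnames(g),
                               chrom = NA_character_, pos = NA_integer_,
                               effect_allele = NA_character_,
                               other_allele = NA_character_,
                               stringsAsFactors = FALSE))
  } else {
    read_genotypes_vcf(path)
  }
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("skipping %d multi-allelic record(s): %s",
                    sum(multi), paste(fix$ID[multi], collapse = ", ")))
  }
  keep <- which(!multi)
  formats <- strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)
  get_dosage <- function(i) {
    if ("DS" %in% formats[[i]]) {
      ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)[i, ]
      ds
    } else {
      gt <- vcfR::extract.gt(vcf, element = "GT")[i, ]
      gt <- gsub("|", "/", gt, fixed = TRUE)
      vapply(gt, function(x) {
        if (is.na(x) || x %in% c("./.", ".")) return(NA_real_)
        sum(as.integer(strsplit(x, "/", fixed = TRUE)[[1L]]))
      }, numeric(1))
    }
  }
  g <- vapply(keep, get_dosage, numeric(ncol(vcf@gt) - 1L))
  g <- matrix(g, ncol = length(keep))
  ids <- ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
                paste0(fix$CHROM[keep], ":", fix$POS[keep]), fix$ID[keep])
  colnames(g) <- ids
  rownames(g) <- colnames(vcf@gt)[-1L]
  bad <- which(!is.na(g) & (g < 0 | g > 2), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_bmistrat(
      sprintf("dosage outside [0, 2] for sample '%s', variant '%s'",
              rownames(g)[bad[1L, 1L]], colnames(g)[bad[1L, 2L]]),
      "bmistrat_format_error")
  }
  list(dosages = g,
       variants = data.frame(variant_id = ids,
                             chrom = fix$CHROM[keep],
                             pos = as.integer(fix$POS[keep]),
                             effect_allele = fix$ALT[keep],
                             other_allele = fix$REF[keep],
                             stringsAsFactors = FALSE))
}

#' Write/read a phenotype table
#'
#' Columns: `individual_id`, `study_id`, `status` (0/1), `bmi`.
#'
#' @param phenotypes data frame with the four columns above.
#' @param path file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_phenotypes <- function(phenotypes, path) {
  stopifnot(all(c("individual_id", "study_id", "status", "bmi") %in%
                  names(phenotypes)))
  data.table::fwrite(
    phenotypes[, c("individual_id", "study_id", "status", "bmi")],
    path, sep = "\t")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  out <- as.data.frame(data.table::fread(path, sep = "\t"))
  stopifnot(all(c("individual_id", "study_id", "status", "bmi") %in%
                  names(out)))
  if (!all(out$status %in% c(0L, 1L))) {
    stop_bmistrat("status must be 0/1", "bmistrat_format_error")
  }
  out
}

#' Write/read a variant panel table
#'
#' @param panel variant panel (see [validate_panel()]).
#' @param path file path.
#' @return `path` (write) or the validated panel (read).
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  data.table::fwrite(panel[, PANEL_COLUMNS], path, sep = "\t")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  out <- as.data.frame(data.table::fread(path, sep = "\t",
                                         colClasses = list(character = "chrom")))
  validate_panel(out)
  out
}

#' Convert a minimal beta/se/p table to the package dialect
#'
#' Accepts the common minimal summary-statistics format (columns
#' `variant_id`, `effect_allele`, `other_allele`, `beta`, `se`, plus any
#' of `chrom`, `pos`, `eaf`, `p`, `info`, `n_cases`, `n_controls`) and
#' fills the remaining dialect columns (`z`, `chi2` recomputed from
#' beta/se; `p` recomputed when absent).
#'
#' @param df minimal-format data frame.
#' @param analysis_tag tag for the resulting records.
#' @return Dialect-conformant data frame.
#' @export
convert_minimal_stats <- function(df, analysis_tag = "all") {
  need <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_bmistrat(paste0("minimal format missing columns: ",
                         paste(miss, collapse = ", ")),
                  "bmistrat_format_error")
  }
  z <- df$beta / df$se
  data.frame(
    variant_id = df$variant_id,
    chrom = as.character(df$chrom %||% NA_character_),
    pos = as.integer(df$pos %||% NA_integer_),
    effect_allele = df$effect_allele, other_allele = df$other_allele,
    eaf = df$eaf %||% NA_real_,
    beta = df$beta, se = df$se, z = z,
    p = df$p %||% (2 * stats::pnorm(-abs(z))),
    chi2 = z^2,
    info = df$info %||% 1,
    n_cases = as.integer(df$n_cases %||% NA_integer_),
    n_controls = as.integer(df$n_controls %||% NA_integer_),
    analysis_tag = analysis_tag, gc_applied = 0L, exclusion_reason = "",
    stringsAsFactors = FALSE
  )
}
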