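#' Construct a genotype matrix
#'
#' Container for additively coded genotype dosages: one row per sample, one
#' column per SNP, entries counting minor alleles (0/1/2, `NA` = missing).
#'
#' @param dosages numeric/integer matrix of minor-allele counts with sample
#'   ids as rownames and SNP ids as colnames.
#' @param minor,major optional character vectors of per-SNP allele labels;
#'   `major` may be `NA` (PLINK `.raw` files only record the counted allele).
#' @return An object of class `"GenotypeMatrix"`: a list with elements
#'   `sample_ids`, `snp_ids`, `dosages`, `alleles` (data.frame with columns
#'   `minor`, `major`) and `missingness` (per-SNP missing fraction).
#' @export
genotype_matrix <- function(dosages, minor = NULL, major = NULL) {
  if (!is.matrix(dosages)) stop("`dosages` must be a matrix")
  sample_ids <- rownames(dosages) %||%
    if (nrow(dosages) == 0) character(0)
  snp_ids <- colnames(dosages) %||%
    if (ncol(dosages) == 0) character(0)
  if (is.null(sample_ids) || is.null(snp_ids))
    stop("`dosages` must carry sample rownames and SNP colnames")
  if (anyDuplicated(sample_ids))
    stop("validation error: duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(snp_ids))
    stop("validation error: duplicate SNP ids: ",
         paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad))
    stop("validation error: dosages must be 0, 1, 2 or NA")
  storage.mode(dosages) <- "integer"
  M <- ncol(dosages)
  minor <- minor %||% rep(NA_character_, M)
  major <- major %||% rep(NA_character_, M)
  miss <- if (M > 0L && nrow(dosages) > 0L) colMeans(is.na(dosages)) else
    rep(0, M)
  structure(
    list(sample_ids = sample_ids, snp_ids = snp_ids, dosages = dosages,
         alleles = data.frame(minor = as.character(minor),
                              major = as.character(major),
                              row.names = snp_ids %||% NULL,
                              stringsAsFactors = FALSE),
         missingness = stats::setNames(as.numeric(miss), snp_ids)),
    class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", length(x$sample_ids), "samples x",
      length(x$snp_ids), "SNPs\n")
  if (length(x$snp_ids))
    cat("  mean per-SNP missingness:",
        format(mean(x$missingness), digits = 3), "\n")
  invisible(x)
}

.plink_fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")

#' Read genotype dosages from a text file
#'
#' Supports two dialects: PLINK `.raw` additive files (whitespace-separated,
#' fixed columns `FID IID PAT MAT SEX PHENOTYPE` then one `SNP_A` column per
#' SNP, where the `_A` suffix names the counted/minor allele) and a plain
#' headerized TSV (`sample_id` then one column per SNP).  Cells that do not
#' parse as 0/1/2 become missing and are reported via a message.
#'
#' @param path file path.
#' @param dialect `"auto"` (default; sniffed from the header), `"plink_raw"`
#'   or `"tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("auto", "plink_raw", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1]]
  if (length(hdr) < 2L)
    stop("format error: genotype header must name at least one SNP column")
  if (dialect == "auto")
    dialect <- if (identical(hdr[seq_len(min(6, length(hdr)))],
                             .plink_fixed)) "plink_raw" else "tsv"
  if (dialect == "plink_raw") {
    if (!identical(hdr[1:6], .plink_fixed))
      stop("format error: PLINK .raw header must start with ",
           paste(.plink_fixed, collapse = " "))
    tab <- read.table(path, header = TRUE, check.names = FALSE,
                      colClasses = "character")
    ids <- tab$IID
    raw <- as.matrix(tab[, -(1:6), drop = FALSE])
    snp_cols <- colnames(raw)
    snp_ids <- sub("_[^_]*$", "", snp_cols)
    minor <- sub("^.*_", "", snp_cols)
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = "character")
    if (colnames(tab)[1] != "sample_id")
      stop("format error: TSV genotype header must start with 'sample_id'")
    ids <- tab[[1]]
    raw <- as.matrix(tab[, -1, drop = FALSE])
    snp_ids <- colnames(raw)
    minor <- NULL
  }
  suppressWarnings(num <- matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- (!is.na(raw) & raw != "NA") & (is.na(num) | !(num %in% c(0, 1, 2)))
  num[bad] <- NA
  n_bad <- sum(bad)
  if (n_bad > 0)
    message("read_genotypes: ", n_bad,
            " unparseable dosage cell(s) set to missing")
  dimnames(num) <- list(ids, snp_ids)
  genotype_matrix(num, minor = minor)
}

#' Write genotype dosages to a text file
#'
#' Inverse of [read_genotypes()]; a write/read round trip reproduces the
#' dosage matrix, sample/SNP ids and (for `plink_raw`) minor-allele labels.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @param dialect `"plink_raw"` or `"tsv"`.
#' @export
write_genotypes <- function(g, path, dialect = c("tsv", "plink_raw")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(g, "GenotypeMatrix"))
  d <- g$dosages
  if (dialect == "plink_raw") {
    minor <- g$alleles$minor
    minor[is.na(minor)] <- "A"
    tab <- data.frame(FID = g$sample_ids, IID = g$sample_ids, PAT = 0L,
                      MAT = 0L, SEX = 0L, PHENOTYPE = -9L,
                      stringsAsFactors = FALSE)
    tab <- cbind(tab, as.data.frame(d))
    colnames(tab)[-(1:6)] <- paste0(g$snp_ids, "_", minor)
    write.table(tab, path, sep = " ", quote = FALSE, row.names = FALSE)
  } else {
    tab <- data.frame(sample_id = g$sample_ids, stringsAsFactors = FALSE)
    tab <- cbind(tab, as.data.frame(d))
    colnames(tab)[-1] <- g$snp_ids
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

.pheno_cols <- c("subject_id", "visit", "time", "fev1", "age0", "sex",
                 "height", "bmi", "smoking", "pack_years")
.smoking_levels <- c("never", "former", "current")

#' Validate a longitudinal phenotype table
#'
#' One row per subject-visit.  Enforced invariants: required columns
#' present; visit indices positive, unique and increasing within subject,
#' with the baseline visit (index 1, time 0) present; `time` non-decreasing
#' in visit; `smoking` in never/former/current and constant per subject (as
#' are `sex` and `age0`); `pack_years` non-negative and identically zero
#' for never smokers.  Interior visit gaps (e.g. visits 1,3) are allowed:
#' the mixed-model machinery uses the matching principal submatrix of the
#' residual covariance.
#'
#' @param df data.frame of subject-visit rows.
#' @param max_visits optional cap on the number of visits per subject.
#' @return `df`, ordered by (subject_id, visit), invisibly classed.
#' @export
validate_phenotypes <- function(df, max_visits = Inf) {
  miss <- setdiff(.pheno_cols, colnames(df))
  if (length(miss))
    stop("validation error: missing phenotype columns: ",
         paste(miss, collapse = ", "))
  df <- df[order(df$subject_id, df$visit), , drop = FALSE]
  rownames(df) <- NULL
  if (!all(df$smoking %in% .smoking_levels))
    stop("validation error: smoking must be one of ",
         paste(.smoking_levels, collapse = "/"))
  if (any(df$visit < 1L) || any(df$visit != as.integer(df$visit)))
    stop("validation error: visit indices must be positive integers")
  if (any(df$pack_years < 0))
    stop("validation error: negative pack_years")
  by_sub <- split(seq_len(nrow(df)), df$subject_id)
  for (id in names(by_sub)) {
    i <- by_sub[[id]]
    v <- df$visit[i]
    if (anyDuplicated(v))
      stop("validation error: duplicated visit index for subject ", id)
    if (v[1] != 1L)
      stop("validation error: visit index gap for subject ", id,
           " (baseline visit 1 missing)")
    if (length(i) > max_visits)
      stop("validation error: subject ", id, " has more than ",
           max_visits, " visits")
    tt <- df$time[i]
    if (tt[1] != 0)
      stop("validation error: time must be 0 at baseline for subject ", id)
    if (is.unsorted(tt))
      stop("validation error: time must be non-decreasing for subject ", id)
    for (col in c("smoking", "sex", "age0"))
      if (length(unique(df[[col]][i])) != 1L)
        stop("validation error: ", col, " varies within subject ", id)
    if (df$smoking[i[1]] == "never" && any(df$pack_years[i] != 0))
      stop("validation error: never smoker ", id, " has pack_years > 0")
  }
  df
}

#' Read a longitudinal phenotype table
#'
#' TSV with columns `subject_id, visit, time, fev1, age0, sex, height, bmi,
#' smoking, pack_years`; rows are validated with [validate_phenotypes()]
#' and returned ordered by (subject_id, visit).
#'
#' @param path file path.
#' @param max_visits optional cap on visits per subject.
#' @return data.frame of subject-visit records.
#' @export
read_phenotypes <- function(path, max_visits = Inf) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c(subject_id = "character",
                                  smoking = "character", visit = "integer", sex = "integer",
                                  time = "numeric", fev1 = "numeric",
                                  age0 = "numeric",
                                  height = "numeric", bmi = "numeric",
                                  pack_years = "numeric"),
                   stringsAsFactors = FALSE)
  validate_phenotypes(df, max_visits = max_visits)
}

#' Write a longitudinal phenotype table
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/read round trip reproduces doubles exactly.
#'
#' @param df phenotype data.frame (see [validate_phenotypes()]).
#' @param path output path.
#' @export
write_phenotypes <- function(df, path) {
  out <- df
  for (cn in colnames(out))
    if (is.double(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
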