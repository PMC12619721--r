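#' pmipf: PMI estimation from pericardial-fluid NMR metabolomics
#'
#' Chemometric pipeline built around age-constrained PLS (oCPLS2 / oCPLS2C):
#' dataset handling, synthetic-data generation, autoscaling/PCA preprocessing,
#' cluster-representative train/test splitting, NIPALS-based constrained PLS
#' with VIP scores, repeated cross-validation and permutation testing,
#' stability selection by binary matrix sampling, univariate screens, and
#' reproducibility assessment between analytical batches.
#'
#' @importFrom stats sd cor pt pbinom rnorm runif hclust cutree dist lm glm
#'   binomial coef pnorm p.adjust quantile setNames var residuals
#' @importFrom utils read.csv write.csv write.table head
"_PACKAGE"

# ---- sample metadata --------------------------------------------------------

.metadata_core_cols <- c("sample_id", "pmi_hours", "sex", "age_years", "site", "cause")

validate_sample_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(c("sample_id", "pmi_hours", "age_years"), names(records))
  if (length(missing) > 0L) {
    stop("metadata is missing required columns: ", paste(missing, collapse = ", "))
  }
  records$sample_id <- as.character(records$sample_id)
  if (anyDuplicated(records$sample_id)) {
    dup <- unique(records$sample_id[duplicated(records$sample_id)])
    stop("duplicate sample IDs in metadata: ", paste(dup, collapse = ", "))
  }
  if (any(!is.finite(records$pmi_hours)) || any(records$pmi_hours <= 0)) {
    stop("pmi_hours must be positive and finite for every sample")
  }
  if (any(!is.finite(records$age_years)) || any(records$age_years <= 0)) {
    stop("age_years must be positive and finite for every sample")
  }
  records
}

#' Load the packaged study covariate table
#'
#' Returns the 66-case covariate table bundled with the package: sample ID,
#' PMI in hours, sex, age in years, autopsy site (CA/RM) and cause of death,
#' plus two bookkeeping flags: `proof_of_concept` (cases 1-24, re-analysed in
#' the two-batch reproducibility experiment) and `in_extended` (all cases
#' except #6, whose specimen was depleted; the extended dataset therefore has
#' 65 cases).
#'
#' @param extended_only if `TRUE`, drop the case flagged as excluded from the
#'   extended dataset and return 65 rows.
#' @return a data frame of sample records, one row per autopsy case.
#' @export
#' @examples
#' tab <- load_table1_fixture()
#' nrow(tab)                      # 66
#' nrow(load_table1_fixture(TRUE))  # 65
load_table1_fixture <- function(extended_only = FALSE) {
  path <- system.file("extdata", "table1_covariates.csv", package = "pmipf")
  records <- read.csv(path, colClasses = c(sample_id = "character"))
  records <- validate_sample_records(records)
  if (extended_only) records <- records[records$in_extended, , drop = FALSE]
  rownames(records) <- NULL
  records
}

# ---- dataset container ------------------------------------------------------

#' Construct a PMI dataset
#'
#' Bundles an aligned, non-negative concentration matrix (samples x
#' metabolites) with its sample metadata. Rows of `concentrations` are matched
#' to `samples$sample_id`; metabolite names must be unique and no cell may be
#' missing.
#'
#' @param concentrations numeric matrix, samples in rows, metabolites in
#'   columns; rownames are sample IDs, colnames metabolite names.
#' @param samples data frame of sample records (needs at least `sample_id`,
#'   `pmi_hours`, `age_years`).
#' @return an object of class `pmi_dataset`.
#' @export
pmi_dataset <- function(concentrations, samples) {
  samples <- validate_sample_records(samples)
  concentrations <- as.matrix(concentrations)
  if (is.null(rownames(concentrations))) {
    if (nrow(concentrations) != nrow(samples)) {
      stop("concentration matrix has ", nrow(concentrations),
           " rows but metadata has ", nrow(samples), " samples")
    }
    rownames(concentrations) <- samples$sample_id
  }
  if (is.null(colnames(concentrations))) {
    stop("concentration matrix must carry metabolite names as colnames")
  }
  if (anyDuplicated(colnames(concentrations))) {
    stop("metabolite names must be unique")
  }
  missing_ids <- setdiff(samples$sample_id, rownames(concentrations))
  extra_ids <- setdiff(rownames(concentrations), samples$sample_id)
  if (length(missing_ids) || length(extra_ids)) {
    stop("sample IDs do not align between concentrations and metadata; ",
         "missing from concentrations: [", paste(missing_ids, collapse = ", "),
         "]; absent from metadata: [", paste(extra_ids, collapse = ", "), "]")
  }
  concentrations <- concentrations[samples$sample_id, , drop = FALSE]
  if (anyNA(concentrations)) stop("concentration matrix contains missing values")
  if (!is.numeric(concentrations)) stop("concentration matrix must be numeric")
  if (any(concentrations < 0)) {
    bad <- which(concentrations < 0, arr.ind = TRUE)[1L, ]
    stop("negative concentration at sample '", rownames(concentrations)[bad[1L]],
         "', metabolite '", colnames(concentrations)[bad[2L]], "'")
  }
  structure(list(concentrations = concentrations, samples = samples),
            class = "pmi_dataset")
}

#' @export
print.pmi_dataset <- function(x, ...) {
  cat("<pmi_dataset> ", nrow(x$concentrations), " samples x ",
      ncol(x$concentrations), " metabolites\n", sep = "")
  cat("  PMI range: ", min(x$samples$pmi_hours), "-",
      max(x$samples$pmi_hours), " h\n", sep = "")
  invisible(x)
}

#' @export
dim.pmi_dataset <- function(x) dim(x$concentrations)

.delim_for <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

.read_delim_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, sep = .delim_for(path), check.names = FALSE,
           colClasses = "character")
}

.as_numeric_cells <- function(df, path) {
  out <- matrix(NA_real_, nrow(df), ncol(df), dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) & nzchar(df[[j]]))
    if (length(bad) > 0L) {
      stop("non-numeric value '", df[[j]][bad[1L]], "' in ", path,
           " at row ", bad[1L], ", column '", names(df)[j], "'")
    }
    out[, j] <- v
  }
  out
}

#' Read a dataset from concentration and metadata tables
#'
#' The concentration file holds one `sample_id` column plus one numeric column
#' per metabolite; the metadata file holds `sample_id,pmi_hours,sex,age_years,
#' site,cause`. Delimiter is chosen from the file extension (`.tsv`/`.txt` ->
#' tab, otherwise comma). Rows are returned in metadata order.
#'
#' @param concentration_path,metadata_path paths to the two tables.
#' @return a [pmi_dataset()].
#' @export
read_dataset <- function(concentration_path, metadata_path) {
  conc_raw <- .read_delim_checked(concentration_path)
  if (!"sample_id" %in% names(conc_raw)) {
    stop("concentration file must have a 'sample_id' column")
  }
  meta <- .read_delim_checked(metadata_path)
  for (col in c("pmi_hours", "age_years")) {
    if (col %in% names(meta)) meta[[col]] <- as.numeric(meta[[col]])
  }
  ids <- conc_raw$sample_id
  if (anyDuplicated(ids)) {
    stop("duplicate sample IDs in concentration file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mat <- .as_numeric_cells(conc_raw[setdiff(names(conc_raw), "sample_id")],
                           concentration_path)
  rownames(mat) <- ids
  pmi_dataset(mat, meta)
}

#' Write a dataset to concentration and metadata tables
#'
#' Inverse of [read_dataset()]; the round trip is lossless to the printed
#' precision (values are written with full double precision).
#'
#' @param ds a `pmi_dataset`.
#' @param concentration_path,metadata_path output paths; delimiter from
#'   extension as in [read_dataset()].
#' @export
write_dataset <- function(ds, concentration_path, metadata_path) {
  stopifnot(inherits(ds, "pmi_dataset"))
  conc <- data.frame(sample_id = rownames(ds$concentrations),
                     ds$concentrations, check.names = FALSE)
  write.table(conc, concentration_path, sep = .delim_for(concentration_path),
              row.names = FALSE, quote = TRUE)
  write.table(ds$samples, metadata_path, sep = .delim_for(metadata_path),
              row.names = FALSE, quote = TRUE)
  invisible(ds)
}

# ---- filtering and summaries ------------------------------------------------

#' Restrict to a PMI window
#'
#' Keeps samples whose PMI lies in `[min_h, max_h]`; both bounds inclusive
#' (the inclusive upper bound is what makes the 16-130 h window contain the
#' 130 h case). Works on either a `pmi_dataset` or a plain record data frame.
#'
#' @param x a `pmi_dataset` or a data frame of sample records.
#' @param min_h,max_h window bounds in hours.
#' @return object of the same type, order preserved.
#' @export
filter_by_pmi <- function(x, min_h, max_h) {
  if (min_h > max_h) stop("min_h must not exceed max_h")
  UseMethod("filter_by_pmi")
}

#' @export
filter_by_pmi.data.frame <- function(x, min_h, max_h) {
  keep <- x$pmi_hours >= min_h & x$pmi_hours <= max_h
  if (!any(keep)) stop("no samples in PMI window [", min_h, ", ", max_h, "] h")
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
filter_by_pmi.pmi_dataset <- function(x, min_h, max_h) {
  samples <- filter_by_pmi(x$samples, min_h, max_h)
  pmi_dataset(x$concentrations[samples$sample_id, , drop = FALSE], samples)
}

#' Summarise study covariates
#'
#' Sample mean, sample standard deviation (n-1 denominator), and range of PMI
#' and age, plus sex and site counts.
#'
#' @param records data frame of sample records (n >= 2).
#' @return a list with elements `n`, `pmi`, `age` (each mean/sd/min/max),
#'   `sex` and `site` count tables.
#' @export
summarize_covariates <- function(records) {
  records <- validate_sample_records(records)
  if (nrow(records) < 2L) stop("need at least 2 samples to summarise")
  num <- function(v) c(mean = mean(v), sd = sd(v), min = min(v), max = max(v))
  list(n = nrow(records),
       pmi = num(records$pmi_hours),
       age = num(records$age_years),
       sex = table(records$sex),
       site = if ("site" %in% names(records)) table(records$site) else NULL)
}
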