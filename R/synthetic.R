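# Synthetic-data generator: concentration tables with the statistical
# structure the pipeline assumes (planted linear PMI trends, age acting both
# as confounder of PMI and as driver of some metabolites, an optional second
# analytical batch with controllable noise).

#' Default metabolite panel
#'
#' Names for a synthetic concentration table. The leading names are the
#' metabolites that recur as relevant PMI predictors in pericardial-fluid
#' NMR work (choline, glycine, ornithine, beta-alanine, betaine,
#' ethanolamine, glutamate, proline, uracil, formate, citrate, glucose,
#' inosine, uridine, aspartate, histidine, valine, hypoxanthine); the rest
#' are generic placeholders.
#'
#' @param n_metabolites panel size (default 46).
#' @return character vector of length `n_metabolites`.
#' @export
default_metabolite_names <- function(n_metabolites = 46L) {
  named <- c("Choline", "Glycine", "Ornithine", "beta-Alanine", "Betaine",
             "Ethanolamine", "Glutamate", "Proline", "Uracil", "Formate",
             "Citrate", "Glucose", "Inosine", "Uridine", "Aspartate",
             "Histidine", "Valine", "Hypoxanthine")
  if (n_metabolites <= length(named)) return(named[seq_len(n_metabolites)])
  c(named, sprintf("Metabolite_%02d", seq.int(length(named) + 1L, n_metabolites)))
}

.default_planted <- function() {
  # eight planted predictors mirroring the 16-199 h regression panel:
  # five increasing (Choline, Glycine, Ornithine, beta-Alanine, Formate),
  # three decreasing (Citrate, Glucose, Inosine)
  data.frame(index = c(1L, 2L, 3L, 4L, 10L, 11L, 12L, 13L),
             sign = c("+", "+", "+", "+", "+", "-", "-", "-"),
             magnitude = 0.08)
}

#' Specification of a synthetic study
#'
#' Collects every knob of the generator. Defaults state the emulated world:
#' a 46-metabolite panel with 8 planted linear PMI trends (slope 0.08
#' concentration units per hour, signs 5+/3-), age correlated with PMI at
#' r = 0.35 and acting as an independent driver of a few non-planted
#' metabolites, PMI uniform on 16-199 h, i.i.d. Gaussian measurement noise
#' of SD 5, and a replicate batch with per-column noise proportional to the
#' column SD (5x inflated for designated unstable metabolites).
#'
#' @param n_samples number of autopsy cases to simulate.
#' @param n_metabolites panel size.
#' @param planted data frame with columns `index`, `sign` ("+"/"-"),
#'   `magnitude` (slope in concentration units per hour); `NULL` for the
#'   default 8-predictor panel, truncated to the columns the panel holds.
#' @param age_confound target population Pearson correlation between PMI and
#'   age, in `[0, 1)`.
#' @param noise_sd SD of the additive measurement noise (concentration units).
#' @param pmi_range sampling range of PMI in hours.
#' @param batch_noise_sd replicate-batch noise as a fraction of each
#'   column SD.
#' @param unstable_metabolites column indices whose replicate noise is
#'   inflated 5-fold (emulating deconvolution/assignment instability).
#' @param age_driven column indices receiving an age effect
#'   (`age_slope` units per year) so the orthogonal constraint has real
#'   variation to remove.
#' @param age_slope age effect size for `age_driven` columns.
#' @param baseline_range range of per-metabolite baseline concentrations.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a `synthetic_spec` object (a validated list).
#' @export
synthetic_spec <- function(n_samples,
                           n_metabolites = 46L,
                           planted = NULL,
                           age_confound = 0.35,
                           noise_sd = 5,
                           pmi_range = c(16, 199),
                           batch_noise_sd = 0.1,
                           unstable_metabolites = integer(),
                           age_driven = NULL,
                           age_slope = 0.15,
                           baseline_range = c(20, 60),
                           seed = 1L) {
  if (is.null(planted)) {
    planted <- .default_planted()
    planted <- planted[planted$index <= n_metabolites, , drop = FALSE]
  }
  if (is.null(age_driven)) {
    # default age-driven columns (Aspartate, Histidine, Valine in the default
    # panel), dropped when the panel is too small to hold them
    age_driven <- intersect(c(15L, 16L, 17L), seq_len(n_metabolites))
  }
  spec <- list(n_samples = as.integer(n_samples),
               n_metabolites = as.integer(n_metabolites),
               planted = planted, age_confound = age_confound,
               noise_sd = noise_sd, pmi_range = pmi_range,
               batch_noise_sd = batch_noise_sd,
               unstable_metabolites = as.integer(unstable_metabolites),
               age_driven = as.integer(age_driven), age_slope = age_slope,
               baseline_range = baseline_range, seed = seed)
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
}

validate_synthetic_spec <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_samples < 4L) stop("n_samples must be at least 4")
  if (spec$n_metabolites < 1L) stop("n_metabolites must be positive")
  p <- spec$planted
  if (nrow(p) > 0L) {
    if (anyDuplicated(p$index)) stop("planted metabolite indices must be distinct")
    if (any(p$index < 1L | p$index > spec$n_metabolites)) {
      stop("planted indices must lie in 1..n_metabolites")
    }
    if (!all(p$sign %in% c("+", "-"))) stop("planted signs must be '+' or '-'")
    if (any(p$magnitude < 0)) stop("planted slope magnitudes must be non-negative")
  }
  if (spec$age_confound < 0 || spec$age_confound >= 1) {
    stop("age_confound must lie in [0, 1)")
  }
  if (spec$noise_sd < 0 || spec$batch_noise_sd < 0) {
    stop("noise SDs must be non-negative")
  }
  if (diff(spec$pmi_range) <= 0) stop("pmi_range must be an increasing pair")
  if (any(spec$unstable_metabolites < 1L |
          spec$unstable_metabolites > spec$n_metabolites)) {
    stop("unstable_metabolites out of range")
  }
  if (any(spec$age_driven < 1L | spec$age_driven > spec$n_metabolites)) {
    stop("age_driven indices out of range")
  }
  spec
}

#' Generate synthetic sample covariates
#'
#' PMI is uniform on `pmi_range`. Age is built as
#' `r * z(PMI) + sqrt(1 - r^2) * N(0,1)` with the PMI z-score taken against
#' the population moments of the uniform, so the population correlation
#' equals `age_confound`; it is then shifted/scaled to mean 52 y, SD 20 y
#' and truncated to 15-90 y (truncation perturbs the realised correlation
#' only slightly). Sex is drawn 2:1 M:F, site 2:1 CA:RM.
#'
#' @param spec a [synthetic_spec()].
#' @return data frame of sample records.
#' @export
generate_covariates <- function(spec) {
  spec <- validate_synthetic_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_samples
    a <- spec$pmi_range[1L]; b <- spec$pmi_range[2L]
    pmi <- runif(n, a, b)
    z_pmi <- (pmi - (a + b) / 2) / ((b - a) / sqrt(12))
    r <- spec$age_confound
    age_std <- r * z_pmi + sqrt(1 - r^2) * rnorm(n)
    age <- pmin(90, pmax(15, 52 + 20 * age_std))
    data.frame(sample_id = sprintf("S%04d", seq_len(n)),
               pmi_hours = pmi,
               sex = sample(c("M", "F"), n, replace = TRUE, prob = c(2, 1) / 3),
               age_years = age,
               site = sample(c("CA", "RM"), n, replace = TRUE, prob = c(2, 1) / 3),
               cause = "synthetic")
  })
}

#' Generate a synthetic concentration table
#'
#' Each metabolite j is `baseline_j + slope_j * PMI + gamma_j * age + eps`,
#' `eps ~ N(0, noise_sd)`, clipped at 0. Planted columns carry the signed
#' slopes from `spec$planted`; `age_driven` columns carry `age_slope`; all
#' other slopes are 0. Baselines are drawn once (uniform on
#' `baseline_range`) under the spec seed, so the same spec always yields the
#' same table.
#'
#' @param records sample records, e.g. from [generate_covariates()].
#' @param spec a [synthetic_spec()].
#' @return a [pmi_dataset()].
#' @export
generate_concentrations <- function(records, spec) {
  spec <- validate_synthetic_spec(spec)
  records <- validate_sample_records(records)
  if (nrow(records) == 0L) stop("records must be non-empty")
  with_seed(spec$seed + 1L, {
    n <- nrow(records); k <- spec$n_metabolites
    slopes <- numeric(k)
    if (nrow(spec$planted) > 0L) {
      slopes[spec$planted$index] <-
        ifelse(spec$planted$sign == "+", 1, -1) * spec$planted$magnitude
    }
    gammas <- numeric(k)
    gammas[spec$age_driven] <- spec$age_slope
    baselines <- runif(k, spec$baseline_range[1L], spec$baseline_range[2L])
    mat <- outer(records$pmi_hours, slopes) + outer(records$age_years, gammas)
    mat <- sweep(mat, 2L, baselines, "+")
    if (spec$noise_sd > 0) mat <- mat + matrix(rnorm(n * k, 0, spec$noise_sd), n, k)
    mat[mat < 0] <- 0
    dimnames(mat) <- list(records$sample_id,
                          default_metabolite_names(k))
    pmi_dataset(mat, records)
  })
}

#' Replicate a dataset as a second analytical batch
#'
#' Adds per-cell Gaussian noise with SD `batch_noise_sd` times the column SD
#' of the original batch; columns listed in `spec$unstable_metabolites`
#' receive 5x that SD. Sample IDs and metadata are unchanged; values are
#' clipped at 0.
#'
#' @param ds dataset produced by [generate_concentrations()].
#' @param spec a [synthetic_spec()].
#' @return a [pmi_dataset()] representing the replicate batch.
#' @export
replicate_batch <- function(ds, spec) {
  spec <- validate_synthetic_spec(spec)
  stopifnot(inherits(ds, "pmi_dataset"))
  with_seed(spec$seed + 2L, {
    x <- ds$concentrations
    sds <- col_sds(x)
    noise_sd <- spec$batch_noise_sd * sds
    if (length(spec$unstable_metabolites) > 0L) {
      noise_sd[spec$unstable_metabolites] <- 5 * noise_sd[spec$unstable_metabolites]
    }
    noise <- sweep(matrix(rnorm(length(x)), nrow(x), ncol(x)), 2L, noise_sd, "*")
    y <- x + noise
    y[y < 0] <- 0
    pmi_dataset(y, ds$samples)
  })
}

#' One-call synthetic study
#'
#' Convenience wrapper: covariates, concentrations and (optionally) a
#' replicate batch from a single spec.
#'
#' @param spec a [synthetic_spec()].
#' @param batches 1 or 2.
#' @return a `pmi_dataset`, or a list of two for `batches = 2`.
#' @export
simulate_dataset <- function(spec, batches = 1L) {
  records <- generate_covariates(spec)
  ds <- generate_concentrations(records, spec)
  if (batches == 1L) return(ds)
  list(batch1 = ds, batch2 = replicate_batch(ds, spec))
}
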