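# shared builders for small in-code fixtures

toy_dataset <- function(n = 12, k = 4, seed = 1) {
  set.seed(seed)
  mat <- matrix(abs(rnorm(n * k, 10, 2)), n, k,
                dimnames = list(as.character(seq_len(n)),
                                paste0("M", seq_len(k))))
  samples <- data.frame(sample_id = as.character(seq_len(n)),
                        pmi_hours = seq(16, 100, length.out = n),
                        sex = rep(c("M", "F"), length.out = n),
                        age_years = runif(n, 20, 80),
                        site = "CA", cause = "toy")
  pmi_dataset(mat, samples)
}

# a null world: no planted PMI slopes, no age-driven columns
null_spec <- function(seed, n = 24, k = 5, ...) {
  synthetic_spec(n, n_metabolites = k,
                 planted = data.frame(index = integer(), sign = character(),
                                      magnitude = numeric()),
                 age_driven = integer(), seed = seed, ...)
}

planted_panel <- function() {
  default_metabolite_names(46)[c(1L, 2L, 3L, 4L, 10L, 11L, 12L, 13L)]
}

age_driven_panel <- function() {
  default_metabolite_names(46)[c(15L, 16L, 17L)]
}
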