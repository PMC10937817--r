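# Shared fixtures, memoized so expensive fits are built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# light sampler settings for module-level tests
light_control <- function() hbr_control(n_iter = 300L, burn = 120L, thin = 3L)

small_config <- function(...) {
  generator_config(n_reference = 400L, n_sites = 4L, seed = 7L, ...)
}

# small end-to-end fixture: generator + fit + adaptation
small_world <- function() {
  memo("small_world", {
    cfg <- small_config()
    ref <- generate_reference(cfg)
    fit <- suppressWarnings(
      fit_reference(ref$cohort, ref$thickness, seed = cfg$seed,
                    control = light_control()))
    adp <- generate_adaptation(cfg, ref$truth)
    ad <- adapt_site(fit, adp$cohort, adp$thickness)
    list(cfg = cfg, ref = ref, adp = adp, fit = fit, ad = ad)
  })
}

# full-scale fixture used by the acceptance-grade checks
reference_world <- function() {
  memo("reference_world", {
    cfg <- generator_config(n_reference = 2000L, n_sites = 10L, seed = 1L)
    ref <- generate_reference(cfg)
    fit <- suppressWarnings(
      fit_reference(ref$cohort, ref$thickness, seed = cfg$seed))
    list(cfg = cfg, ref = ref, fit = fit)
  })
}

# deviation scores computed against the true generative normative
# distribution (used where the property under test concerns the generator or
# downstream statistics, not the fitted model)
true_zscores <- function(truth, cohort, thickness) {
  pars <- truth$params
  female <- as.numeric(cohort$sex == "female")
  mu <- matrix(pars$baseline, nrow(thickness), ncol(thickness), byrow = TRUE) +
    outer(cohort$age, pars$age_slope) + outer(female, pars$sex_effect) +
    matrix(truth$clinical_site$u, nrow(thickness), ncol(thickness), byrow = TRUE)
  sdm <- matrix(pars$sigma * truth$clinical_site$lambda,
                nrow(thickness), ncol(thickness), byrow = TRUE)
  (thickness - mu) / sdm
}

random_outlier_matrix <- function(n, p = 148L, rate = 0.2) {
  o <- matrix(rbinom(n * p, 1L, rate), n, p)
  colnames(o) <- if (p == 148L) load_atlas()$name else sprintf("r%03d", seq_len(p))
  rownames(o) <- sprintf("s%03d", seq_len(n))
  o
}
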