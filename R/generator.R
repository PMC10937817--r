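#' Configuration for the multi-site cohort simulator
#'
#' Builds the parameter set driving all three simulated cohorts: a multi-site
#' healthy reference cohort, a small single-site adaptation (calibration) set,
#' and a clinical cohort with heterogeneous regional atrophy concentrated in,
#' but not limited to, the temporal lobe. Region-level generative parameters
#' (baseline thickness, age slope, sex effect, residual sd) are drawn once per
#' configuration from the stated ranges, so a configuration fixes a complete
#' generative truth.
#'
#' @param n_reference Number of reference subjects (default 2000; a
#'   desk-scale stand-in for a large pooled reference cohort).
#' @param n_sites Number of reference acquisition sites (>= 2).
#' @param n_adaptation Number of healthy controls at the clinical site used
#'   for site adaptation (default 20).
#' @param n_clinical Number of clinical subjects (default 86).
#' @param age_range_reference,age_range_clinical Age intervals in years.
#' @param sex_ratio Fraction female (default 0.488).
#' @param baseline_range Range (mm) from which per-region baseline mean
#'   thickness is drawn.
#' @param age_slope_range Range (mm/year) for per-region age slopes;
#'   negative by default (cortical thinning).
#' @param sex_effect_range Range (mm) for the additive effect of female sex.
#' @param sigma_range Range (mm) for per-region residual sd.
#' @param site_intercept_sd Sd (mm) of per-site, per-region intercept offsets.
#' @param site_scale_sdlog Sd of log site noise-scale multipliers
#'   (lambda_s ~ lognormal(0, site_scale_sdlog)); heteroscedasticity across
#'   sites is the motivation for the hierarchical model.
#' @param atrophy List: \code{core_regions} (region names, default bilateral
#'   superior temporal sulcus), \code{core_penetrance} (per-subject,
#'   per-core-region probability of atrophy), \code{idiosyncratic_rate}
#'   (mean per-region probability of idiosyncratic atrophy),
#'   \code{effect_range} (downward shift in units of the region residual sd),
#'   \code{temporal_weight} (relative idiosyncratic rate of temporal vs
#'   extratemporal regions; rates are renormalised to keep the configured
#'   mean rate).
#' @param subgroups Named list of label specs for \code{stage},
#'   \code{phenotype} and \code{depression}. Each spec has \code{levels},
#'   \code{probs}, and per-level multipliers \code{idio_multiplier},
#'   \code{penetrance_multiplier}, optional
#'   \code{temporal_weight_multiplier}. \code{NA} levels are allowed via an
#'   \code{NA} entry in \code{levels}.
#' @param suvr List with \code{mean}, \code{sd} (residual sd) and
#'   \code{slope} for the SUVR generator; \code{slope} is the coefficient on
#'   the standardized atrophy burden (negative by default).
#' @param seed Integer master seed; every generator call derives a
#'   deterministic substream from it.
#' @return An object of class \code{hbr_config}.
#' @export
generator_config <- function(n_reference = 2000L,
                             n_sites = 10L,
                             n_adaptation = 20L,
                             n_clinical = 86L,
                             age_range_reference = c(18, 90),
                             age_range_clinical = c(49.1, 87.4),
                             sex_ratio = 0.488,
                             baseline_range = c(2.0, 3.0),
                             age_slope_range = c(-0.012, -0.002),
                             sex_effect_range = c(-0.04, 0.04),
                             sigma_range = c(0.08, 0.18),
                             site_intercept_sd = 0.05,
                             site_scale_sdlog = 0.2,
                             atrophy = list(),
                             subgroups = NULL,
                             suvr = list(),
                             seed = 1L) {
  atrophy_default <- list(
    core_regions = c("lh_S_temporal_sup", "rh_S_temporal_sup"),
    core_penetrance = 0.6,
    idiosyncratic_rate = 0.15,
    effect_range = c(2.5, 5),
    temporal_weight = 2)
  atrophy <- utils::modifyList(atrophy_default, atrophy)
  suvr_default <- list(mean = 1.4, sd = 0.2, slope = -0.1)
  suvr <- utils::modifyList(suvr_default, suvr)
  if (is.null(subgroups)) subgroups <- default_subgroups()

  cfg <- list(
    n_reference = as.integer(n_reference), n_sites = as.integer(n_sites),
    n_adaptation = as.integer(n_adaptation), n_clinical = as.integer(n_clinical),
    age_range_reference = age_range_reference,
    age_range_clinical = age_range_clinical,
    sex_ratio = sex_ratio,
    baseline_range = baseline_range, age_slope_range = age_slope_range,
    sex_effect_range = sex_effect_range, sigma_range = sigma_range,
    site_intercept_sd = site_intercept_sd, site_scale_sdlog = site_scale_sdlog,
    atrophy = atrophy, subgroups = subgroups, suvr = suvr,
    seed = as.integer(seed))
  class(cfg) <- "hbr_config"
  validate_config(cfg)
  cfg
}

# Subgroup composition mirrors a mixed MCI/dementia amnestic-dominant memory
# clinic cohort; multipliers encode more spread at later stage, more
# extratemporal spread in non-amnestic presentations, and reduced atrophy
# burden with ongoing depressive symptoms.
default_subgroups <- function() {
  list(
    stage = list(
      levels = c("MCI", "dementia"), probs = c(38, 48) / 86,
      idio_multiplier = c(1, 1.6), penetrance_multiplier = c(0.85, 1.15)),
    phenotype = list(
      levels = c("amnestic", "non-amnestic"), probs = c(64, 22) / 86,
      idio_multiplier = c(1, 1.4), penetrance_multiplier = c(0.8, 1.3),
      temporal_weight_multiplier = c(1, 0.5)),
    depression = list(
      levels = c("ongoing", "past", "none", NA), probs = c(24, 7, 51, 4) / 86,
      idio_multiplier = c(0.6, 1, 1.2, 1), penetrance_multiplier = c(0.8, 1, 1.1, 1)))
}

validate_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  counts <- c(cfg$n_reference, cfg$n_sites, cfg$n_adaptation, cfg$n_clinical)
  stopifnot_msg(all(counts > 0), "all cohort counts must be positive")
  stopifnot_msg(diff(cfg$age_range_reference) > 0 && diff(cfg$age_range_clinical) > 0,
                "age ranges must be well-ordered")
  stopifnot_msg(cfg$sex_ratio >= 0 && cfg$sex_ratio <= 1, "sex_ratio must be in [0,1]")
  stopifnot_msg(all(cfg$sigma_range > 0), "residual sd range must be positive")
  stopifnot_msg(cfg$atrophy$core_penetrance >= 0 && cfg$atrophy$core_penetrance <= 1,
                "core_penetrance must be in [0,1]")
  stopifnot_msg(cfg$atrophy$idiosyncratic_rate >= 0 && cfg$atrophy$idiosyncratic_rate <= 1,
                "idiosyncratic_rate must be in [0,1]")
  stopifnot_msg(all(cfg$atrophy$effect_range >= 0), "atrophy effect sizes must be >= 0")
  stopifnot_msg(cfg$site_intercept_sd >= 0 && cfg$site_scale_sdlog >= 0,
                "site effect scales must be >= 0")
  invisible(cfg)
}

# Functions that seed their own substreams must not disturb the caller's RNG
# stream; registers restoration of .Random.seed in the calling function.
restore_rng_on_exit <- function(envir = parent.frame()) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  expr <- if (has) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call("on.exit", list(expr, add = TRUE), envir = envir)
}

# Deterministic substream seed: mixes the master seed with a stage tag so the
# generators are reproducible independently of call order. Kept < 2^31.
substream_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (as.double(seed) * 7919 + h * 104729) %% 2147483629
}

draw_region_params <- function(cfg, atlas) {
  n <- nrow(atlas)
  data.frame(
    name = atlas$name,
    baseline = stats::runif(n, cfg$baseline_range[1], cfg$baseline_range[2]),
    age_slope = stats::runif(n, cfg$age_slope_range[1], cfg$age_slope_range[2]),
    sex_effect = stats::runif(n, cfg$sex_effect_range[1], cfg$sex_effect_range[2]),
    sigma = stats::runif(n, cfg$sigma_range[1], cfg$sigma_range[2]),
    stringsAsFactors = FALSE)
}

# Simulate a thickness matrix given covariates, site offsets u (length 148)
# and noise multiplier lambda (scalar).
simulate_thickness <- function(params, age, female, u, lambda) {
  n <- length(age)
  p <- nrow(params)
  mu <- matrix(params$baseline, n, p, byrow = TRUE) +
    outer(age, params$age_slope) +
    outer(as.numeric(female), params$sex_effect) +
    matrix(u, n, p, byrow = TRUE)
  eps <- matrix(stats::rnorm(n * p), n, p) *
    matrix(params$sigma * lambda, n, p, byrow = TRUE)
  y <- mu + eps
  colnames(y) <- params$name
  y
}

#' Generate the multi-site healthy reference cohort
#'
#' Thickness for subject i in region j at site s is drawn as
#' \code{baseline_j + slope_j*age_i + sexfx_j*[female_i] + u_{s,j} + eps},
#' \code{eps ~ N(0, (sigma_j*lambda_s)^2)}, with per-site per-region
#' intercept offsets \code{u_{s,j} ~ N(0, site_intercept_sd^2)} and per-site
#' noise multipliers \code{lambda_s} log-normal around 1. The generative
#' parameters of the held-out clinical site are drawn here too and stored in
#' the returned truth record, so later generator calls are deterministic
#' regardless of order.
#'
#' @param config An \code{hbr_config}.
#' @return List with \code{cohort} (data frame of covariates),
#'   \code{thickness} (subjects x 148 matrix, mm) and \code{truth}
#'   (class \code{hbr_truth}: generative parameters, site effects,
#'   clinical-site effects).
#' @export
generate_reference <- function(config) {
  restore_rng_on_exit()
  validate_config(config)
  if (config$n_sites < 2L) {
    stop("n_sites must be >= 2: the site hierarchy is unidentifiable from one site",
         call. = FALSE)
  }
  atlas <- load_atlas()
  n <- config$n_reference
  p <- nrow(atlas)

  set.seed(substream_seed(config$seed, "reference"))
  params <- draw_region_params(config, atlas)
  sites <- sprintf("site_%02d", seq_len(config$n_sites))
  site_u <- matrix(stats::rnorm(config$n_sites * p, 0, config$site_intercept_sd),
                   nrow = config$n_sites, dimnames = list(sites, atlas$name))
  site_lambda <- stats::setNames(
    exp(stats::rnorm(config$n_sites, 0, config$site_scale_sdlog)), sites)
  # held-out clinical site, drawn once here
  clin_u <- stats::rnorm(p, 0, config$site_intercept_sd)
  clin_lambda <- exp(stats::rnorm(1, 0, config$site_scale_sdlog))

  age <- stats::runif(n, config$age_range_reference[1], config$age_range_reference[2])
  female <- stats::rbinom(n, 1, config$sex_ratio)
  site <- sample(rep_len(sites, n))

  thickness <- matrix(0, n, p, dimnames = list(NULL, atlas$name))
  for (s in sites) {
    idx <- which(site == s)
    thickness[idx, ] <- simulate_thickness(params, age[idx], female[idx],
                                           site_u[s, ], site_lambda[[s]])
  }
  cohort <- data.frame(
    subject_id = sprintf("ref_%04d", seq_len(n)),
    age = age,
    sex = ifelse(female == 1, "female", "male"),
    site = site,
    role = "reference",
    phenotype = NA_character_, stage = NA_character_,
    depression = NA_character_, suvr = NA_real_,
    stringsAsFactors = FALSE)
  rownames(thickness) <- cohort$subject_id

  truth <- structure(list(
    params = params,
    site_u = site_u,
    site_lambda = site_lambda,
    clinical_site = list(label = "site_clinical", u = clin_u, lambda = clin_lambda),
    atrophy = NULL,
    config = config), class = "hbr_truth")
  list(cohort = cohort, thickness = thickness, truth = truth)
}

#' Generate the adaptation (calibration) set at the clinical site
#'
#' Healthy controls scanned at the held-out clinical site; no atrophy is
#' applied. Site effects are the clinical-site parameters stored in the truth
#' record by \code{\link{generate_reference}}.
#'
#' @param config An \code{hbr_config}.
#' @param truth Truth record from \code{\link{generate_reference}}.
#' @param n Number of subjects (defaults to \code{config$n_adaptation}).
#' @param role Role label for the generated rows (default
#'   \code{"adaptation"}; used internally to draw extra held-out healthy
#'   subjects at the same site).
#' @return List with \code{cohort} and \code{thickness}.
#' @export
generate_adaptation <- function(config, truth, n = config$n_adaptation,
                                role = "adaptation") {
  restore_rng_on_exit()
  stopifnot(inherits(truth, "hbr_truth"))
  if (n < 2L) stop("n_adaptation must be >= 2: site variance is unestimable", call. = FALSE)
  set.seed(substream_seed(config$seed, paste0("adaptation_", role)))
  age <- stats::runif(n, config$age_range_clinical[1], config$age_range_clinical[2])
  female <- stats::rbinom(n, 1, config$sex_ratio)
  thickness <- simulate_thickness(truth$params, age, female,
                                  truth$clinical_site$u, truth$clinical_site$lambda)
  cohort <- data.frame(
    subject_id = sprintf("%s_%04d", substr(role, 1, 3), seq_len(n)),
    age = age,
    sex = ifelse(female == 1, "female", "male"),
    site = truth$clinical_site$label,
    role = role,
    phenotype = NA_character_, stage = NA_character_,
    depression = NA_character_, suvr = NA_real_,
    stringsAsFactors = FALSE)
  rownames(thickness) <- cohort$subject_id
  list(cohort = cohort, thickness = thickness)
}

subgroup_draw <- function(spec, n) {
  idx <- sample.int(length(spec$levels), n, replace = TRUE, prob = spec$probs)
  list(label = spec$levels[idx], idx = idx)
}

subgroup_multiplier <- function(spec, idx, field) {
  if (is.null(spec[[field]])) rep(1, length(idx)) else spec[[field]][idx]
}

#' Generate the clinical cohort with heterogeneous regional atrophy
#'
#' Each clinical subject receives (a) core atrophy in each configured core
#' region (default: bilateral superior temporal sulcus) with probability
#' equal to the core penetrance, and (b) an idiosyncratic set of additional
#' atrophied regions drawn per region with a rate that up-weights temporal
#' regions. Affected regions are shifted downward by an effect size drawn in
#' units of the region residual sd. Subgroup labels (stage, phenotype,
#' depression) modulate the rates per the configured multipliers, e.g.
#' dementia spreads more than MCI and non-amnestic presentations spread
#' further outside the temporal lobe.
#'
#' @param config An \code{hbr_config}.
#' @param truth Truth record from \code{\link{generate_reference}}.
#' @return List with \code{cohort}, \code{thickness} and an updated
#'   \code{truth} whose \code{atrophy} element records, per subject, the
#'   truly atrophied regions and applied effect sizes.
#' @export
generate_clinical <- function(config, truth) {
  restore_rng_on_exit()
  stopifnot(inherits(truth, "hbr_truth"))
  atlas <- load_atlas()
  core <- config$atrophy$core_regions
  core_idx <- match(core, atlas$name)
  if (anyNA(core_idx)) {
    stop("core region(s) not in atlas: ",
         paste(core[is.na(core_idx)], collapse = ", "), call. = FALSE)
  }
  n <- config$n_clinical
  p <- nrow(atlas)
  set.seed(substream_seed(config$seed, "clinical"))

  age <- stats::runif(n, config$age_range_clinical[1], config$age_range_clinical[2])
  female <- stats::rbinom(n, 1, config$sex_ratio)
  thickness <- simulate_thickness(truth$params, age, female,
                                  truth$clinical_site$u, truth$clinical_site$lambda)

  sg <- lapply(config$subgroups, subgroup_draw, n = n)
  idio_mult <- rep(1, n); pen_mult <- rep(1, n); tw_mult <- rep(1, n)
  for (nm in names(sg)) {
    spec <- config$subgroups[[nm]]
    idio_mult <- idio_mult * subgroup_multiplier(spec, sg[[nm]]$idx, "idio_multiplier")
    pen_mult <- pen_mult * subgroup_multiplier(spec, sg[[nm]]$idx, "penetrance_multiplier")
    tw_mult <- tw_mult * subgroup_multiplier(spec, sg[[nm]]$idx, "temporal_weight_multiplier")
  }

  temporal <- atlas$lobe_group == "temporal"
  atrophy_regions <- vector("list", n)
  atrophy_effects <- vector("list", n)
  for (i in seq_len(n)) {
    pen <- min(1, config$atrophy$core_penetrance * pen_mult[i])
    hit_core <- core_idx[stats::runif(length(core_idx)) < pen]
    # per-region idiosyncratic rates, temporal-weighted, renormalised to the
    # configured mean rate, then scaled by the subject's subgroup multiplier
    w <- ifelse(temporal, config$atrophy$temporal_weight * tw_mult[i], 1)
    rate <- config$atrophy$idiosyncratic_rate * idio_mult[i] * w / mean(w)
    rate <- pmin(rate, 0.95)
    hit_idio <- setdiff(which(stats::runif(p) < rate), core_idx)
    regions <- sort(unique(c(hit_core, hit_idio)))
    if (length(regions)) {
      eff <- stats::runif(length(regions), config$atrophy$effect_range[1],
                          config$atrophy$effect_range[2])
      thickness[i, regions] <- thickness[i, regions] - eff * truth$params$sigma[regions]
      atrophy_effects[[i]] <- eff
    } else {
      atrophy_effects[[i]] <- numeric(0)
    }
    atrophy_regions[[i]] <- regions
  }

  label_of <- function(nm) {
    if (is.null(sg[[nm]])) rep(NA_character_, n) else as.character(sg[[nm]]$label)
  }
  cohort <- data.frame(
    subject_id = sprintf("clin_%04d", seq_len(n)),
    age = age,
    sex = ifelse(female == 1, "female", "male"),
    site = truth$clinical_site$label,
    role = "clinical",
    phenotype = label_of("phenotype"),
    stage = label_of("stage"),
    depression = label_of("depression"),
    suvr = NA_real_,
    stringsAsFactors = FALSE)
  rownames(thickness) <- cohort$subject_id
  names(atrophy_regions) <- cohort$subject_id

  truth$atrophy <- list(regions = atrophy_regions, effects = atrophy_effects)
  list(cohort = cohort, thickness = thickness, truth = truth)
}

#' Generate per-subject mean SUVR values
#'
#' SUVR is modeled as \code{a + b * standardized(burden) + noise} where
#' burden is a per-subject atrophy load (e.g. the true number of atrophied
#' regions or the total outlier count) and the sign of \code{b} is taken from
#' the configuration (negative by default: higher atrophy burden, lower
#' amyloid SUVR). Values are floored at a small positive constant.
#'
#' @param config An \code{hbr_config}.
#' @param burden Numeric vector of per-subject atrophy burden, aligned with
#'   the clinical cohort.
#' @return Numeric vector of positive SUVR values.
#' @export
generate_suvr <- function(config, burden) {
  restore_rng_on_exit()
  set.seed(substream_seed(config$seed, "suvr"))
  z <- if (stats::sd(burden) > 0) as.numeric(scale(burden)) else rep(0, length(burden))
  suvr <- config$suvr$mean + config$suvr$slope * z +
    stats::rnorm(length(burden), 0, config$suvr$sd)
  pmax(suvr, 0.05)
}
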