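#' Sampler settings for the hierarchical normative model
#'
#' @param n_iter Total Gibbs iterations per region.
#' @param burn Burn-in iterations discarded from the front.
#' @param thin Thinning interval for retained draws.
#' @param a0 Fixed inverse-gamma shape of the site noise-variance prior
#'   \code{sigma_s^2 ~ IG(a0, b0)}; the scale \code{b0} is sampled
#'   conjugately, so \code{a0} sets the pooling strength of site variances.
#' @param rhat_bound Regions whose split-chain diagnostic on the age slope
#'   exceeds this bound are flagged (never dropped).
#' @return A list of class \code{hbr_control}.
#' @export
hbr_control <- function(n_iter = 900L, burn = 300L, thin = 3L,
                        a0 = 3, rhat_bound = 1.05) {
  stopifnot(n_iter > burn, thin >= 1, a0 > 1)
  structure(list(n_iter = as.integer(n_iter), burn = as.integer(burn),
                 thin = as.integer(thin), a0 = a0, rhat_bound = rhat_bound),
            class = "hbr_control")
}

# Validate and align a thickness matrix against the atlas column order.
check_thickness <- function(thickness, atlas, cohort) {
  canon <- canonical_region_names(colnames(thickness), atlas$name)
  if (anyNA(canon)) {
    stop("thickness columns not in atlas: ",
         paste(colnames(thickness)[is.na(canon)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(canon) || length(canon) != nrow(atlas)) {
    stop("thickness matrix must have exactly one column per atlas region",
         call. = FALSE)
  }
  colnames(thickness) <- canon
  thickness <- thickness[, atlas$name, drop = FALSE]
  if (!all(is.finite(thickness))) {
    bad <- which(!is.finite(thickness), arr.ind = TRUE)
    subj <- if (!is.null(cohort$subject_id)) cohort$subject_id[bad[, 1]] else bad[, 1]
    stop("non-finite thickness values, e.g. subject ",
         subj[1], " region ", colnames(thickness)[bad[1, 2]], call. = FALSE)
  }
  thickness
}

design_matrix <- function(age, female, age_center) {
  cbind(intercept = 1, age_c = age - age_center, female = as.numeric(female))
}

# Univariate slice sampler (stepping-out + shrinkage), used for the
# site-variance hyperparameter whose full conditional is not conjugate once
# the site offsets are integrated out.
slice_sample1 <- function(x0, logf, w = 1, max_steps = 30L) {
  y <- logf(x0) - stats::rexp(1)
  lo <- x0 - stats::runif(1) * w
  hi <- lo + w
  k <- max_steps
  while (k > 0L && logf(lo) > y) { lo <- lo - w; k <- k - 1L }
  k <- max_steps
  while (k > 0L && logf(hi) > y) { hi <- hi + w; k <- k - 1L }
  repeat {
    x1 <- stats::runif(1, lo, hi)
    if (logf(x1) > y) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
  }
}

# Split-chain potential scale reduction on a single retained chain.
split_rhat <- function(x) {
  m <- length(x) %/% 2L
  if (m < 2L) return(NA_real_)
  halves <- list(x[seq_len(m)], x[m + seq_len(m)])
  w <- mean(vapply(halves, stats::var, 0))
  b <- m * stats::var(vapply(halves, mean, 0))
  if (w <= 0) return(1)
  sqrt(((m - 1) / m * w + b / m) / w)
}

#' Fit the hierarchical Bayesian normative model on the reference cohort
#'
#' Fits, independently for each of the 148 atlas regions, the hierarchical
#' Gaussian regression
#' \deqn{y_{ij} = x_i' \beta_j + u_{s(i),j} + \epsilon_{ij}, \quad
#'       \epsilon_{ij} \sim N(0, \sigma_{s(i),j}^2)}
#' with covariates age (centered at the reference mean) and sex (female = 1),
#' site random intercepts \eqn{u_{s,j} \sim N(0, \tau_j^2)} and per-site
#' noise variances pooled through \eqn{\sigma_{s,j}^2 \sim IG(a_0, b_{0j})}.
#' Inference is a blocked Gibbs sampler with conjugate updates operating on
#' per-site sufficient statistics; a single pipeline seed fans out to
#' per-region substreams indexed by region id, so results do not depend on
#' execution order. Retained posterior draws are stored in the fit so that
#' site adaptation and posterior-predictive scoring propagate parameter
#' uncertainty.
#'
#' @param cohort Cohort data frame with columns \code{age}, \code{sex},
#'   \code{site} and (optionally) \code{role}; if a \code{role} column is
#'   present only \code{role == "reference"} rows are used.
#' @param thickness Subjects x 148 matrix (mm), columns named by atlas
#'   regions, rows aligned with \code{cohort}.
#' @param seed Integer pipeline seed.
#' @param control Sampler settings from \code{\link{hbr_control}}.
#' @return Object of class \code{hbr_fit}: per-region posterior summaries
#'   (fixed effects, age-slope credible interval, site effects, noise
#'   hyperparameters, split-chain diagnostic and convergence flag) plus the
#'   retained draws and fit metadata.
#' @export
fit_reference <- function(cohort, thickness, seed = 1L, control = hbr_control()) {
  restore_rng_on_exit()
  atlas <- load_atlas()
  if (!is.null(cohort$role)) {
    keep <- cohort$role == "reference"
    cohort <- cohort[keep, , drop = FALSE]
    thickness <- thickness[keep, , drop = FALSE]
  }
  if (nrow(cohort) != nrow(thickness)) {
    stop("cohort and thickness must have matching rows", call. = FALSE)
  }
  thickness <- check_thickness(thickness, atlas, cohort)
  sites <- sort(unique(cohort$site))
  if (length(sites) < 2L) {
    stop("reference data must span >= 2 sites; the site hierarchy is ",
         "unidentifiable from a single site", call. = FALSE)
  }
  female <- as.numeric(cohort$sex == "female")
  age_center <- mean(cohort$age)
  X <- design_matrix(cohort$age, female, age_center)
  S <- length(sites)
  p <- nrow(atlas)

  # per-site sufficient statistics, shared across regions where possible
  site_idx <- lapply(sites, function(s) which(cohort$site == s))
  n_s <- vapply(site_idx, length, 0L)
  XtX <- vapply(site_idx, function(ix) crossprod(X[ix, , drop = FALSE]),
                matrix(0, 3, 3))                      # 3 x 3 x S
  XtX_flat <- matrix(XtX, nrow = 9L)                  # 9 x S
  X1 <- XtX[, 1, ]                                    # 3 x S (column sums of X)
  XtY <- lapply(site_idx, function(ix)
    crossprod(X[ix, , drop = FALSE], thickness[ix, , drop = FALSE]))  # 3 x p each
  yty <- vapply(site_idx, function(ix)
    colSums(thickness[ix, , drop = FALSE]^2), numeric(p))             # p x S

  keep_iters <- seq(control$burn + control$thin, control$n_iter, by = control$thin)
  Tk <- length(keep_iters)
  a0 <- control$a0
  tau_scale <- 0.5                 # half-Cauchy scale (mm) on tau
  g1 <- 0.1; g2 <- 0.1             # weak gamma prior on b0
  prior_beta_prec <- 1e-4          # N(0, 100^2) on each coefficient

  beta_draws <- array(NA_real_, c(p, Tk, 3L))
  tau2_draws <- matrix(NA_real_, p, Tk)
  b0_draws <- matrix(NA_real_, p, Tk)
  u_draws <- array(NA_real_, c(p, Tk, S))
  sigma2_draws <- array(NA_real_, c(p, Tk, S))

  for (j in seq_len(p)) {
    set.seed(substream_seed(seed, paste0("fit_region_", j - 1L)))
    xty_j <- vapply(XtY, function(m) m[, j], numeric(3))   # 3 x S
    yty_j <- yty[j, ]

    # initial values from pooled least squares
    A0 <- matrix(rowSums(XtX_flat), 3, 3)
    beta <- solve(A0 + diag(1e-8, 3), rowSums(xty_j))
    u <- (xty_j[1, ] - as.vector(crossprod(X1, beta))) / n_s
    qf <- as.vector(crossprod(XtX_flat, as.vector(tcrossprod(beta))))
    ss0 <- yty_j - 2 * as.vector(crossprod(xty_j, beta)) + qf
    sigma2 <- pmax(ss0 / n_s - u^2, 1e-8)
    tau2 <- max(stats::var(u), 1e-8)
    b0 <- (a0 - 1) * stats::median(sigma2)

    kk <- 0L
    for (it in seq_len(control$n_iter)) {
      inv_s2 <- 1 / sigma2
      # beta | u, sigma
      A <- matrix(XtX_flat %*% inv_s2, 3, 3) + diag(prior_beta_prec, 3)
      rhs <- as.vector((xty_j - X1 * rep(u, each = 3)) %*% inv_s2)
      ch <- chol(A)
      beta <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE)) +
        backsolve(ch, stats::rnorm(3))
      x1b <- as.vector(crossprod(X1, beta))
      rbar <- (xty_j[1, ] - x1b) / n_s
      # tau^2 | beta, sigma with the site offsets integrated out
      # (partially-collapsed step; avoids the funnel degeneracy at tau -> 0):
      # rbar_s ~ N(0, tau^2 + sigma_s^2/n_s), prior tau ~ half-Cauchy(tau_scale)
      v_s <- sigma2 / n_s
      lpt <- function(lt) {
        tt <- exp(lt) + v_s
        -0.5 * sum(log(tt) + rbar^2 / tt) + 0.5 * lt - log1p(exp(lt) / tau_scale^2)
      }
      tau2 <- max(exp(slice_sample1(log(tau2), lpt)), 1e-14)
      # u_s | beta, sigma, tau
      prec <- n_s * inv_s2 + 1 / tau2
      u <- stats::rnorm(S, (n_s * inv_s2) * rbar / prec, sqrt(1 / prec))
      # sigma_s^2 | beta, u, b0
      qf <- as.vector(crossprod(XtX_flat, as.vector(tcrossprod(beta))))
      ss <- pmax(yty_j - 2 * as.vector(crossprod(xty_j, beta)) -
                   2 * u * xty_j[1, ] + 2 * u * x1b + qf + n_s * u^2, 0)
      sigma2 <- pmax((b0 + ss / 2) / stats::rgamma(S, a0 + n_s / 2), 1e-12)
      # b0 | sigma (conjugate gamma)
      b0 <- max(stats::rgamma(1, g1 + S * a0, rate = g2 + sum(1 / sigma2)), 1e-300)

      if (it > control$burn && (it - control$burn) %% control$thin == 0L) {
        kk <- kk + 1L
        beta_draws[j, kk, ] <- beta
        tau2_draws[j, kk] <- tau2
        b0_draws[j, kk] <- b0
        u_draws[j, kk, ] <- u
        sigma2_draws[j, kk, ] <- sigma2
      }
    }
  }

  slope <- beta_draws[, , 2L, drop = FALSE][, , 1L]
  if (is.null(dim(slope))) slope <- matrix(slope, nrow = p)
  rhat <- apply(slope, 1L, split_rhat)
  summaries <- data.frame(
    name = atlas$name,
    intercept = rowMeans(beta_draws[, , 1L]),
    age_slope = rowMeans(slope),
    age_slope_lo = apply(slope, 1L, stats::quantile, 0.025),
    age_slope_hi = apply(slope, 1L, stats::quantile, 0.975),
    sex_effect = rowMeans(beta_draws[, , 3L]),
    tau2 = rowMeans(tau2_draws),
    b0 = rowMeans(b0_draws),
    rhat = rhat,
    flagged = !is.na(rhat) & rhat > control$rhat_bound,
    stringsAsFactors = FALSE)
  if (any(summaries$flagged)) {
    warning(sum(summaries$flagged), " region(s) flagged for split-chain ",
            "diagnostic > ", control$rhat_bound, call. = FALSE)
  }

  structure(list(
    regions = atlas$name,
    sites = sites,
    n_subjects = nrow(cohort),
    age_center = age_center,
    age_range = range(cohort$age),
    control = control,
    seed = as.integer(seed),
    n_draws = Tk,
    summaries = summaries,
    draws = list(beta = beta_draws, tau2 = tau2_draws, b0 = b0_draws,
                 u = u_draws, sigma2 = sigma2_draws),
    site_summary = list(u_mean = apply(u_draws, c(1, 3), mean),
                        sigma2_mean = apply(sigma2_draws, c(1, 3), mean))
  ), class = "hbr_fit")
}

#' @export
print.hbr_fit <- function(x, ...) {
  cat("Hierarchical Bayesian normative model fit\n")
  cat("  regions:", length(x$regions),
      " sites:", length(x$sites),
      " subjects:", x$n_subjects, "\n")
  cat("  retained draws/region:", x$n_draws,
      " flagged regions:", sum(x$summaries$flagged), "\n")
  invisible(x)
}
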