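# Lightweight container for a single statistical result. Kept as a classed
# list so optional fields (permutation p, companion tests) can attach without
# reshaping; as.data.frame() flattens it for the results table.
stat_result <- function(test, estimate = NA_real_, statistic = NA_real_,
                        df1 = NA_real_, df2 = NA_real_, p = NA_real_,
                        p_adj = NA_real_, method = NA_character_,
                        n = NA_integer_, note = NA_character_, ...) {
  structure(list(test = test, estimate = estimate, statistic = statistic,
                 df1 = df1, df2 = df2, p = p, p_adj = p_adj, method = method,
                 n = n, note = note, ...), class = "hbr_stat")
}

#' @export
print.hbr_stat <- function(x, ...) {
  cat(x$test, ": ", sep = "")
  if (!is.na(x$statistic)) {
    cat("stat = ", signif(x$statistic, 4), sep = "")
    if (!is.na(x$df1)) cat(" (df ", x$df1, ", ", x$df2, ")", sep = "")
    cat(", ")
  }
  if (!is.na(x$estimate)) cat("estimate = ", signif(x$estimate, 4), ", ", sep = "")
  cat("p = ", format.pval(x$p, digits = 3), "\n", sep = "")
  if (!is.na(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.hbr_stat <- function(x, ...) {
  keep <- vapply(x, function(v) is.atomic(v) && length(v) == 1L, TRUE)
  as.data.frame(unclass(x)[keep], stringsAsFactors = FALSE)
}

ancova_f <- function(response, group, covariates) {
  d <- data.frame(.y = response, .g = factor(group))
  if (!is.null(covariates)) d <- cbind(d, covariates)
  covs <- if (is.null(covariates)) "1" else paste(names(covariates), collapse = " + ")
  full <- stats::lm(stats::as.formula(paste(".y ~", covs, "+ .g")), data = d)
  if (any(is.na(stats::coef(full)))) {
    return(stat_result("ancova", note = "non-estimable: collinear design"))
  }
  reduced <- stats::lm(stats::as.formula(paste(".y ~", covs)), data = d)
  an <- stats::anova(reduced, full)
  stat_result("ancova",
              estimate = unname(stats::coef(full)[length(stats::coef(full))]),
              statistic = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2],
              p = an$`Pr(>F)`[2], n = nrow(d),
              method = "partial F, group adjusted for covariates")
}

#' Case-control comparison of mean cortical thickness
#'
#' ANCOVA with age and sex as covariates comparing per-subject mean
#' thickness (over all 148 regions) between the clinical and control groups.
#'
#' @param clinical_thickness,control_thickness Subject x region matrices.
#' @param clinical_cov,control_cov Data frames with \code{age} and
#'   \code{sex} columns, row-aligned with the matrices.
#' @return An \code{hbr_stat} with the group F test plus per-group mean and
#'   sd of mean thickness.
#' @export
casecontrol_mean_thickness <- function(clinical_thickness, control_thickness,
                                       clinical_cov, control_cov) {
  if (nrow(clinical_thickness) < 3L || nrow(control_thickness) < 3L) {
    stop("each group needs >= 3 subjects", call. = FALSE)
  }
  m <- c(rowMeans(clinical_thickness), rowMeans(control_thickness))
  grp <- rep(c("clinical", "control"),
             c(nrow(clinical_thickness), nrow(control_thickness)))
  covs <- rbind(clinical_cov[, c("age", "sex")], control_cov[, c("age", "sex")])
  covs$sex <- as.numeric(covs$sex == "female")
  out <- ancova_f(m, grp, covs)
  out$test <- "casecontrol_mean_thickness"
  out$group_means <- tapply(m, grp, mean)
  out$group_sds <- tapply(m, grp, stats::sd)
  out
}

#' Region-wise Welch t-tests with FDR correction
#'
#' Two-tailed Welch (unequal-variance) t-tests of thickness at each region
#' between groups, with Benjamini-Hochberg q-values. Regions with zero
#' pooled variance are reported as NA.
#'
#' @param clinical_thickness,control_thickness Subject x region matrices
#'   with identical column sets.
#' @param alpha Significance level on the q-values (default 0.05).
#' @return List: \code{results} data frame (region, t, df, p, q,
#'   significant), \code{n_significant}.
#' @export
regionwise_ttests_fdr <- function(clinical_thickness, control_thickness,
                                  alpha = 0.05) {
  stopifnot(identical(colnames(clinical_thickness), colnames(control_thickness)))
  n1 <- nrow(clinical_thickness); n2 <- nrow(control_thickness)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 subjects", call. = FALSE)
  m1 <- colMeans(clinical_thickness); m2 <- colMeans(control_thickness)
  v1 <- apply(clinical_thickness, 2, stats::var)
  v2 <- apply(control_thickness, 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  t[se2 == 0] <- NA; df[se2 == 0] <- NA
  p <- 2 * stats::pt(-abs(t), df)
  q <- stats::p.adjust(p, method = "BH")
  res <- data.frame(region = colnames(clinical_thickness),
                    mean_diff = m1 - m2, t = t, df = df, p = p, q = q,
                    significant = !is.na(q) & q < alpha,
                    stringsAsFactors = FALSE)
  list(results = res, n_significant = sum(res$significant))
}

#' Group test on (transformed) total outlier counts
#'
#' ANCOVA of the transformed total outlier count on group with the supplied
#' covariates, with a companion Mann-Whitney U test on the raw counts (for
#' two groups) and a Shapiro-Wilk normality check of the raw counts.
#' The default transform is log(count + 1), which keeps the attainable
#' count of 0 finite.
#'
#' @param toc Integer vector of total outlier counts.
#' @param groups Group labels (NA dropped); each group needs >= 3 members.
#' @param covariates Optional data frame of covariates (e.g. age, numeric
#'   sex), row-aligned with \code{toc}.
#' @param transform \code{"log1p"} (default) or \code{"none"}.
#' @return An \code{hbr_stat} for the ANCOVA, with \code{shapiro_p},
#'   \code{mannwhitney_U} and \code{mannwhitney_p} attached.
#' @export
outliercount_group_test <- function(toc, groups, covariates = NULL,
                                    transform = c("log1p", "none")) {
  transform <- match.arg(transform)
  keep <- !is.na(groups)
  toc <- toc[keep]; groups <- as.character(groups[keep])
  if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  if (any(table(groups) < 3L)) stop("each group needs >= 3 members", call. = FALSE)
  y <- if (transform == "log1p") log1p(toc) else toc
  out <- ancova_f(y, groups, covariates)
  out$test <- "outliercount_group_test"
  out$transform <- transform
  sw <- tryCatch(stats::shapiro.test(toc), error = function(e) NULL)
  out$shapiro_p <- if (is.null(sw)) NA_real_ else sw$p.value
  if (length(unique(groups)) == 2L) {
    gl <- sort(unique(groups))
    exact <- length(toc) < 20L
    mw <- suppressWarnings(stats::wilcox.test(toc[groups == gl[1]],
                                              toc[groups == gl[2]],
                                              exact = exact, correct = TRUE))
    out$mannwhitney_U <- unname(mw$statistic)
    out$mannwhitney_p <- mw$p.value
  }
  out
}

#' Pearson correlation between total outlier count and age
#'
#' @param toc Total outlier counts.
#' @param age Ages in years.
#' @return An \code{hbr_stat} with r as the estimate; NA when either input
#'   has zero variance.
#' @export
age_correlation <- function(toc, age) {
  if (length(toc) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(toc) == 0 || stats::sd(age) == 0) {
    return(stat_result("age_correlation", note = "zero variance: r undefined"))
  }
  ct <- stats::cor.test(toc, age, method = "pearson")
  stat_result("age_correlation", estimate = unname(ct$estimate),
              statistic = unname(ct$statistic), df1 = unname(ct$parameter),
              p = ct$p.value, n = length(toc), method = "Pearson")
}

#' Two-way ANOVA: outlier location by phenotype
#'
#' Region-level outlier prevalences are computed within each phenotype group
#' and modeled by a two-way ANOVA with factors location (temporal vs
#' extratemporal) and phenotype; the interaction term asks whether the
#' temporal excess of outliers differs between phenotypes. The one-way
#' location ANOVA on prevalences pooled over the whole cohort is also
#' reported.
#'
#' @param o Binary outlier matrix.
#' @param phenotype Per-subject phenotype labels (NA dropped).
#' @param atlas Region table.
#' @return List of \code{hbr_stat}: \code{interaction},
#'   \code{location_main} (from the two-way model) and
#'   \code{location_oneway} (pooled prevalences), plus the region-level
#'   \code{data} used.
#' @export
location_phenotype_interaction <- function(o, phenotype, atlas = load_atlas()) {
  check_binary(o)
  keep <- !is.na(phenotype)
  o <- o[keep, , drop = FALSE]
  phenotype <- factor(as.character(phenotype[keep]))
  if (nlevels(phenotype) < 2L) {
    stop("phenotype must have >= 2 observed levels", call. = FALSE)
  }
  grp <- atlas$lobe_group[match(colnames(o), atlas$name)]
  d <- do.call(rbind, lapply(levels(phenotype), function(ph) {
    data.frame(region = colnames(o),
               prevalence = 100 * colMeans(o[phenotype == ph, , drop = FALSE]),
               location = grp, phenotype = ph, stringsAsFactors = FALSE)
  }))
  an <- stats::anova(stats::lm(prevalence ~ location * phenotype, data = d))
  row_i <- "location:phenotype"
  interaction <- stat_result("location_phenotype_interaction",
                             statistic = an[row_i, "F value"],
                             df1 = an[row_i, "Df"], df2 = an["Residuals", "Df"],
                             p = an[row_i, "Pr(>F)"])
  location_main <- stat_result("location_main_effect",
                               statistic = an["location", "F value"],
                               df1 = an["location", "Df"],
                               df2 = an["Residuals", "Df"],
                               p = an["location", "Pr(>F)"])
  pooled <- data.frame(prevalence = 100 * colMeans(o), location = grp)
  an1 <- stats::anova(stats::lm(prevalence ~ location, data = pooled))
  location_oneway <- stat_result("location_oneway",
                                 statistic = an1$`F value`[1],
                                 df1 = an1$Df[1], df2 = an1$Df[2],
                                 p = an1$`Pr(>F)`[1])
  list(interaction = interaction, location_main = location_main,
       location_oneway = location_oneway, data = d)
}

#' Associations between amyloid SUVR, outlier count and mean thickness
#'
#' Linear regressions of total outlier count and of raw mean cortical
#' thickness on mean SUVR, with and without age adjustment, plus the
#' median-split labeling (high = strictly above the group median; ties go to
#' low).
#'
#' @param toc Total outlier counts.
#' @param mean_thickness Per-subject mean thickness (mm).
#' @param suvr Per-subject mean SUVR (must be present for all subjects).
#' @param age Ages in years.
#' @return List of \code{hbr_stat} (\code{toc_suvr}, \code{toc_suvr_age},
#'   \code{thickness_suvr}, \code{thickness_suvr_age}; each carries slope,
#'   \code{r_squared}, F and p) and \code{suvr_group} factor
#'   (\code{low}/\code{high}).
#' @export
suvr_association <- function(toc, mean_thickness, suvr, age) {
  if (anyNA(suvr)) stop("SUVR must be present for all analyzed subjects", call. = FALSE)
  if (stats::sd(suvr) == 0) {
    return(list(toc_suvr = stat_result("toc_suvr", note = "constant SUVR"),
                suvr_group = factor(rep("low", length(suvr)),
                                    levels = c("low", "high"))))
  }
  reg <- function(name, y, adjust_age) {
    d <- data.frame(y = y, suvr = suvr, age = age)
    f <- if (adjust_age) y ~ suvr + age else y ~ suvr
    fit <- stats::lm(f, data = d)
    sm <- summary(fit)
    stat_result(name, estimate = unname(stats::coef(fit)["suvr"]),
                statistic = sm$fstatistic[1],
                df1 = sm$fstatistic[2], df2 = sm$fstatistic[3],
                p = sm$coefficients["suvr", "Pr(>|t|)"],
                n = length(y), r_squared = sm$r.squared)
  }
  grp <- factor(ifelse(suvr > stats::median(suvr), "high", "low"),
                levels = c("low", "high"))
  list(toc_suvr = reg("toc_suvr", toc, FALSE),
       toc_suvr_age = reg("toc_suvr_age", toc, TRUE),
       thickness_suvr = reg("thickness_suvr", mean_thickness, FALSE),
       thickness_suvr_age = reg("thickness_suvr_age", mean_thickness, TRUE),
       suvr_group = grp)
}

#' Three-group comparisons by STS outlier status
#'
#' Compares a clinical or demographic variable across the three STS outlier
#' status groups (none / unilateral / bilateral): one-way ANOVA with
#' Bonferroni-adjusted pairwise t-tests for numeric variables, chi-squared
#' test (no continuity correction) for categorical ones.
#'
#' @param status Factor from \code{\link{sts_status}}.
#' @param value Numeric or categorical variable, one per subject.
#' @return An \code{hbr_stat}; numeric comparisons attach the
#'   Bonferroni-adjusted pairwise p matrix.
#' @export
sts_group_comparison <- function(status, value) {
  keep <- !is.na(value) & !is.na(status)
  status <- droplevels(factor(status[keep]))
  value <- value[keep]
  if (is.numeric(value)) {
    an <- stats::anova(stats::lm(value ~ status))
    pw <- stats::pairwise.t.test(value, status, p.adjust.method = "bonferroni")
    out <- stat_result("sts_status_anova", statistic = an$`F value`[1],
                       df1 = an$Df[1], df2 = an$Df[2], p = an$`Pr(>F)`[1],
                       n = length(value), method = "one-way ANOVA")
    out$pairwise_bonferroni <- pw$p.value
    out
  } else {
    ct <- suppressWarnings(stats::chisq.test(table(status, value), correct = FALSE))
    stat_result("sts_status_chisq", statistic = unname(ct$statistic),
                df1 = unname(ct$parameter), p = ct$p.value,
                n = length(value), method = "chi-squared, no continuity correction")
  }
}
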