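make_groups <- function(n1 = 30, n2 = 30, shift = 0, seed = 1) {
  set.seed(seed)
  atlas_names <- load_atlas()$name
  a <- matrix(rnorm(n1 * 148, 2.4, 0.12), n1, 148, dimnames = list(NULL, atlas_names))
  b <- matrix(rnorm(n2 * 148, 2.4 + shift, 0.12), n2, 148, dimnames = list(NULL, atlas_names))
  cov_a <- data.frame(age = runif(n1, 50, 85), sex = sample(c("female", "male"), n1, TRUE))
  cov_b <- data.frame(age = runif(n2, 50, 85), sex = sample(c("female", "male"), n2, TRUE))
  list(a = a, b = b, cov_a = cov_a, cov_b = cov_b)
}

test_that("mean-thickness ANCOVA is null on identical groups and detects a real shift", {
  g <- make_groups()
  same <- casecontrol_mean_thickness(g$a, g$a, g$cov_a, g$cov_a)
  expect_equal(same$statistic, 0, tolerance = 1e-10)
  expect_equal(same$p, 1, tolerance = 1e-10)

  gs <- make_groups(79, 79, shift = -0.17, seed = 2)
  shifted <- casecontrol_mean_thickness(gs$a, gs$b, gs$cov_a, gs$cov_b)
  expect_lt(shifted$p, 0.001)
  expect_equal(shifted$df1, 1)
  expect_equal(shifted$df2, 158 - 4)
  expect_gt(shifted$group_means["clinical"], shifted$group_means["control"])
})

test_that("the group partial F agrees with an independent type-III computation", {
  g <- make_groups(25, 31, shift = -0.1, seed = 3)
  res <- casecontrol_mean_thickness(g$a, g$b, g$cov_a, g$cov_b)
  d <- data.frame(
    y = c(rowMeans(g$a), rowMeans(g$b)),
    grp = factor(rep(c("clinical", "control"), c(25, 31))),
    age = c(g$cov_a$age, g$cov_b$age),
    sex = c(as.numeric(g$cov_a$sex == "female"), as.numeric(g$cov_b$sex == "female")))
  ca <- car::Anova(lm(y ~ age + sex + grp, data = d), type = 3)
  expect_equal(res$statistic, ca["grp", "F value"], tolerance = 1e-8)
  expect_equal(res$p, ca["grp", "Pr(>F)"], tolerance = 1e-8)
})

test_that("region-wise Welch t-tests match t.test and control the FDR bookkeeping", {
  set.seed(4)
  a <- matrix(rnorm(20 * 12), 20, 12, dimnames = list(NULL, paste0("r", 1:12)))
  b <- matrix(rnorm(15 * 12, 0.2, 1.4), 15, 12, dimnames = list(NULL, paste0("r", 1:12)))
  out <- regionwise_ttests_fdr(a, b)
  for (j in c(1, 5, 12)) {
    tt <- t.test(a[, j], b[, j])
    expect_equal(out$results$t[j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(out$results$df[j], unname(tt$parameter), tolerance = 1e-10)
    expect_equal(out$results$p[j], tt$p.value, tolerance = 1e-10)
  }
  expect_true(all(out$results$q >= out$results$p))
  # zero-variance region reported as NA, not dropped
  a0 <- a; a0[, 2] <- 1; b0 <- b; b0[, 2] <- 1
  out0 <- regionwise_ttests_fdr(a0, b0)
  expect_true(is.na(out0$results$t[2]) && is.na(out0$results$q[2]))
  expect_equal(nrow(out0$results), 12L)
})

test_that("widespread large shifts are detected region-wise after FDR", {
  g <- make_groups(79, 79, seed = 5)
  shifted <- g$b
  shifted[, 1:104] <- shifted[, 1:104] - 0.15
  out <- regionwise_ttests_fdr(shifted, g$a)
  expect_gte(out$n_significant, 100L)
  sig_regions <- out$results$region[out$results$significant]
  # discoveries are overwhelmingly among the truly shifted regions
  expect_gte(mean(sig_regions %in% colnames(g$a)[1:104]), 0.95)
})

test_that("outlier-count ANCOVA reports transform, normality and Mann-Whitney companions", {
  set.seed(6)
  toc <- c(rpois(48, 30), rpois(38, 15))
  groups <- rep(c("dementia", "MCI"), c(48, 38))
  covs <- data.frame(age = runif(86, 50, 85), sexf = rbinom(86, 1, 0.5))
  res <- outliercount_group_test(toc, groups, covs, transform = "log1p")
  expect_lt(res$p, 0.01)
  expect_equal(res$transform, "log1p")
  expect_true(is.finite(res$shapiro_p))
  expect_true(is.finite(res$mannwhitney_U))
  expect_lt(res$mannwhitney_p, 0.01)
  expect_error(outliercount_group_test(c(1, 2, 3, 4), c("a", "a", "a", "b")),
               ">= 3 members")
  # zero counts survive the log transform
  res0 <- outliercount_group_test(c(0, 0, 1, 2, 0, 3), rep(c("x", "y"), each = 3))
  expect_true(is.finite(res0$p))
})

test_that("age correlation handles exact, null and degenerate inputs", {
  expect_equal(age_correlation(c(30, 20, 10), c(50, 60, 70))$estimate, -1)
  set.seed(7)
  r <- age_correlation(rpois(86, 20), runif(86, 50, 85))
  expect_true(abs(r$estimate) < 0.3)
  cst <- age_correlation(rep(5L, 10), runif(10, 50, 85))
  expect_true(is.na(cst$p))
  expect_match(cst$note, "zero variance")
  expect_error(age_correlation(1:2, 1:2), "n >= 3")
})

test_that("location-by-phenotype ANOVA is symmetric and detects selective atrophy", {
  set.seed(8)
  atlas <- load_atlas()
  temporal <- region_mask(atlas, lobe_group = "temporal")
  o <- matrix(rbinom(60 * 148, 1, 0.15), 60, 148, dimnames = list(NULL, atlas$name))
  ph <- rep(c("amnestic", "non-amnestic"), each = 30)
  # temporal-selective atrophy in one phenotype only
  o[1:30, temporal] <- rbinom(30 * 30, 1, 0.55)
  res <- location_phenotype_interaction(o, ph, atlas)
  expect_lt(res$interaction$p, 0.05)
  swapped <- location_phenotype_interaction(
    o, ifelse(ph == "amnestic", "non-amnestic", "amnestic"), atlas)
  expect_equal(res$interaction$statistic, swapped$interaction$statistic,
               tolerance = 1e-10)
  expect_equal(res$location_oneway$df1, 1)
  expect_equal(res$location_oneway$df2, 146)
  expect_error(location_phenotype_interaction(o, rep("amnestic", 60), atlas),
               ">= 2 observed levels")
})

test_that("SUVR associations recover sign, report R-squared, and split at the median", {
  set.seed(9)
  toc <- rpois(86, 25)
  suvr <- 1.4 - 0.01 * toc + rnorm(86, 0, 0.05)
  thick <- 2.4 - 0.002 * toc + rnorm(86, 0, 0.02)
  age <- runif(86, 50, 85)
  res <- suvr_association(toc, thick, suvr, age)
  expect_lt(res$toc_suvr$estimate, 0)
  expect_gt(res$thickness_suvr$estimate, 0)
  expect_lt(res$toc_suvr$p, 0.05)
  expect_equal(res$toc_suvr$r_squared, cor(toc, suvr)^2, tolerance = 1e-10)
  expect_true(is.finite(res$toc_suvr_age$p))
  expect_lte(abs(sum(res$suvr_group == "high") - sum(res$suvr_group == "low")), 1L)
  # values tied with the median go to the low group
  # degenerate toy (perfect fit warnings are expected and irrelevant here)
  res_tie <- suppressWarnings(
    suvr_association(1:5, 2.4 + 0.01 * (1:5), c(1, 1.2, 1.3, 1.3, 1.5), 50:54))
  expect_equal(sum(res_tie$suvr_group == "low"), 4L)
  expect_equal(sum(res_tie$suvr_group == "high"), 1L)
  resc <- suvr_association(toc, thick, rep(1.4, 86), age)
  expect_true(is.na(resc$toc_suvr$p))
})

test_that("STS-status comparisons use the documented tests and adjusted p-values", {
  set.seed(10)
  status <- factor(sample(c("none", "unilateral", "bilateral"), 86, TRUE,
                          prob = c(0.35, 0.17, 0.48)),
                   levels = c("none", "unilateral", "bilateral"))
  age <- rnorm(86, 67, 8) - 3 * (status == "bilateral")
  res <- sts_group_comparison(status, age)
  # independent one-way ANOVA oracle from sums of squares
  k <- nlevels(status); n <- length(age)
  ssb <- sum(tapply(age, status, function(x) length(x) * (mean(x) - mean(age))^2))
  ssw <- sum(tapply(age, status, function(x) sum((x - mean(x))^2)))
  f_oracle <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(res$statistic, f_oracle, tolerance = 1e-10)
  expect_true(all(res$pairwise_bonferroni <= 1, na.rm = TRUE))
  raw <- pairwise.t.test(age, status, p.adjust.method = "none")$p.value
  expect_true(all(res$pairwise_bonferroni >= raw, na.rm = TRUE))

  sexf <- factor(ifelse(rbinom(86, 1, 0.5) == 1, "female", "male"))
  resc <- sts_group_comparison(status, sexf)
  expect_equal(resc$df1, 2)
  expect_true(is.finite(resc$statistic))
})
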