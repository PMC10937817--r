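#' Pairwise Hamming distance matrix of outlier profiles
#'
#' Counts, for every pair of subjects, the regions at which their binary
#' outlier flags disagree. Distances are raw counts over the 148 regions
#' (not normalised), matching the count scale on which group medians are
#' reported.
#'
#' @param o Binary outlier matrix (subjects x regions).
#' @return Integer symmetric matrix with zero diagonal, entries in
#'   \code{[0, ncol(o)]}, dimnames carrying subject ids.
#' @export
hamming_matrix <- function(o) {
  if (nrow(o) < 2L) stop("need at least two subjects", call. = FALSE)
  check_binary(o)
  toc <- rowSums(o)
  H <- outer(toc, toc, "+") - 2 * tcrossprod(o)
  H <- round(H)
  storage.mode(H) <- "integer"
  dimnames(H) <- list(rownames(o), rownames(o))
  H
}

#' Intragroup dissimilarity summaries
#'
#' For each subject, the median Hamming distance to the other members of the
#' same group; per group, the median and IQR of those per-subject medians.
#' Singleton groups are skipped with a warning. The pooled off-diagonal
#' within-group distances are returned as well, for density displays.
#'
#' @param H Hamming distance matrix from \code{\link{hamming_matrix}}.
#' @param groups Group labels, one per subject (NA rows are dropped).
#' @return List: \code{per_subject} (data frame of subject, group, median
#'   distance), \code{groups} (data frame with group median, IQR, n),
#'   \code{pooled} (named list of within-group off-diagonal distances).
#' @export
group_dissimilarity <- function(H, groups) {
  stopifnot(nrow(H) == length(groups))
  keep <- !is.na(groups)
  H <- H[keep, keep, drop = FALSE]
  groups <- as.character(groups[keep])
  sizes <- table(groups)
  if (any(sizes < 2)) {
    warning("skipping singleton group(s): ",
            paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
    keep2 <- groups %in% names(sizes)[sizes >= 2]
    H <- H[keep2, keep2, drop = FALSE]
    groups <- groups[keep2]
  }
  subj <- rownames(H)
  if (is.null(subj)) subj <- as.character(seq_along(groups))
  med <- vapply(seq_along(groups), function(i) {
    peers <- which(groups == groups[i])
    peers <- setdiff(peers, i)
    stats::median(H[i, peers])
  }, 0)
  per_subject <- data.frame(subject = subj, group = groups,
                            median_distance = med, stringsAsFactors = FALSE)
  gl <- sort(unique(groups))
  group_tab <- data.frame(
    group = gl,
    median = vapply(gl, function(g) stats::median(med[groups == g]), 0),
    iqr = vapply(gl, function(g) stats::IQR(med[groups == g]), 0),
    n = vapply(gl, function(g) sum(groups == g), 0L),
    stringsAsFactors = FALSE)
  pooled <- lapply(stats::setNames(gl, gl), function(g) {
    Hg <- H[groups == g, groups == g, drop = FALSE]
    Hg[lower.tri(Hg)]
  })
  list(per_subject = per_subject, groups = group_tab, pooled = pooled)
}

#' Compare intragroup dissimilarity between groups
#'
#' Regresses per-subject median within-group Hamming distances on the group
#' indicator. Because the per-subject medians are functions of one shared
#' distance matrix they are not independent observations, and the parametric
#' F-test on them is anti-conservative; the reported p-value is therefore a
#' label-permutation p (per-subject medians recomputed under each permuted
#' labeling), with the parametric p retained as \code{p_param} for
#' reference.
#'
#' @param H Hamming matrix.
#' @param groups Group labels (>= 2 groups with >= 2 members each).
#' @param n_perm Number of label permutations (default 999; 0 falls back to
#'   the parametric p with a warning note).
#' @param seed Seed for the permutations.
#' @return An \code{hbr_stat}: group coefficient, F, degrees of freedom,
#'   permutation p (\code{p}), parametric p (\code{p_param}), group sizes.
#' @export
compare_group_dissimilarity <- function(H, groups, n_perm = 999L, seed = 1L) {
  restore_rng_on_exit()
  gd <- group_dissimilarity(H, groups)
  d <- gd$per_subject
  if (length(unique(d$group)) < 2L) {
    stop("need >= 2 groups with >= 2 members", call. = FALSE)
  }
  if (stats::var(d$median_distance) == 0) {
    return(stat_result("dissimilarity_regression", estimate = 0,
                       statistic = NA_real_, df1 = NA, df2 = NA, p = NA_real_,
                       note = "non-estimable: zero variance in medians"))
  }
  fit <- stats::lm(median_distance ~ group, data = d)
  an <- stats::anova(fit)
  est <- stats::coef(fit)[-1]
  out <- stat_result(
    "dissimilarity_regression",
    estimate = unname(est[1]),
    statistic = an$`F value`[1],
    df1 = an$Df[1], df2 = an$Df[2],
    p = NA_real_,
    n = nrow(d))
  out$p_param <- an$`Pr(>F)`[1]
  if (n_perm > 0L) {
    gk <- d$group
    # subset H to the analyzed subjects, in per_subject order
    idx <- if (!is.null(rownames(H))) match(d$subject, rownames(H))
           else as.integer(d$subject)
    Hk <- H[idx, idx, drop = FALSE]
    obs <- an$`F value`[1]
    set.seed(seed)
    hits <- 0L
    group_f <- function(g) {
      medp <- vapply(seq_along(g), function(i) {
        peers <- setdiff(which(g == g[i]), i)
        stats::median(Hk[i, peers])
      }, 0)
      if (stats::var(medp) == 0) return(NA_real_)
      m <- tapply(medp, g, mean)
      nn <- tapply(medp, g, length)
      ssb <- sum(nn * (m - mean(medp))^2)
      ssw <- sum((medp - m[g])^2)
      k <- length(m)
      (ssb / (k - 1)) / (ssw / (length(g) - k))
    }
    for (b in seq_len(n_perm)) {
      fp <- group_f(sample(gk))
      if (!is.na(fp) && fp >= obs) hits <- hits + 1L
    }
    out$p <- (hits + 1) / (n_perm + 1)
  } else {
    out$p <- out$p_param
    out$note <- "parametric p only; anti-conservative under dependence"
  }
  out
}
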