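#' Flag outlier regions from deviation z-scores
#'
#' A region is an outlier for a subject when its deviation z-score falls
#' strictly below the threshold (default -1.96, the lower 2.5% quantile of
#' the standard normal). Only negative deviations are flagged; positive
#' deviations, however extreme, are not outliers here.
#'
#' @param z An \code{hbr_deviation} or a subjects x regions z-score matrix.
#' @param threshold Lower-tail threshold, must be negative (default -1.96).
#' @return Binary integer matrix of the same shape, with the threshold kept
#'   in attribute \code{"threshold"}.
#' @examples
#' flag_outliers(matrix(c(-2, -1.96, 3.5, 0), 1))  # 1 0 0 0
#' @export
flag_outliers <- function(z, threshold = -1.96) {
  z <- as.matrix(z)
  if (!all(is.finite(z))) stop("z-scores must be finite", call. = FALSE)
  if (threshold >= 0) {
    stop("threshold must be negative: outliers are lower-tail deviations",
         call. = FALSE)
  }
  o <- (z < threshold) + 0L
  attr(o, "threshold") <- threshold
  o
}

check_binary <- function(o) {
  if (!all(o %in% c(0L, 1L))) stop("outlier matrix must be binary", call. = FALSE)
  o
}

#' Per-subject total outlier count
#'
#' Sums outlier flags across the 148 regions for each subject; ranges from 0
#' (no region outlying) to 148 (all regions outlying).
#'
#' @param o Binary outlier matrix from \code{\link{flag_outliers}}.
#' @return Integer vector, one count per subject.
#' @export
total_outlier_count <- function(o) {
  check_binary(o)
  as.integer(rowSums(o))
}

#' Regional outlier prevalence
#'
#' Percentage of subjects flagged as outliers in each region, with a table
#' ranked by prevalence and per-hemisphere totals.
#'
#' @param o Binary outlier matrix (columns named by atlas regions).
#' @param atlas Region table (default \code{\link{load_atlas}}).
#' @return List: \code{prevalence} (named % vector in atlas order),
#'   \code{ranked} (data frame sorted descending with hemisphere and lobe
#'   labels), \code{hemisphere_totals} (total flags per hemisphere).
#' @export
outlier_prevalence <- function(o, atlas = load_atlas()) {
  check_binary(o)
  if (nrow(o) < 1L) stop("need at least one subject", call. = FALSE)
  p <- 100 * colMeans(o)
  ord <- order(p, decreasing = TRUE)
  idx <- match(colnames(o), atlas$name)
  ranked <- data.frame(
    name = colnames(o)[ord],
    prevalence = p[ord],
    hemisphere = atlas$hemisphere[idx][ord],
    lobe_group = atlas$lobe_group[idx][ord],
    stringsAsFactors = FALSE)
  hemi <- tapply(colSums(o), atlas$hemisphere[idx], sum)
  list(prevalence = p, ranked = ranked, hemisphere_totals = hemi)
}

#' Superior temporal sulcus outlier status
#'
#' Classifies each subject by bilateral, unilateral or absent STS
#' involvement; the three categories partition the cohort.
#'
#' @param o Binary outlier matrix.
#' @param atlas Region table.
#' @return Factor with levels \code{none}, \code{unilateral},
#'   \code{bilateral}.
#' @export
sts_status <- function(o, atlas = load_atlas()) {
  check_binary(o)
  sts <- sts_indices(atlas)
  il <- match(atlas$name[sts$left], colnames(o))
  ir <- match(atlas$name[sts$right], colnames(o))
  n_sts <- o[, il] + o[, ir]
  factor(c("none", "unilateral", "bilateral")[n_sts + 1L],
         levels = c("none", "unilateral", "bilateral"))
}

#' Temporal vs extratemporal outlier prevalence summary
#'
#' Mean and sd of region-level outlier prevalence within the 30 temporal and
#' 118 extratemporal regions.
#'
#' @param o Binary outlier matrix.
#' @param atlas Region table.
#' @return Data frame with one row per lobe group: mean and sd prevalence
#'   (%), number of regions.
#' @export
lobe_prevalence_summary <- function(o, atlas = load_atlas()) {
  check_binary(o)
  if (nrow(o) < 1L) stop("need at least one subject", call. = FALSE)
  p <- 100 * colMeans(o)
  grp <- atlas$lobe_group[match(colnames(o), atlas$name)]
  data.frame(
    lobe_group = c("temporal", "extratemporal"),
    mean_prevalence = c(mean(p[grp == "temporal"]), mean(p[grp == "extratemporal"])),
    sd_prevalence = c(stats::sd(p[grp == "temporal"]), stats::sd(p[grp == "extratemporal"])),
    n_regions = c(sum(grp == "temporal"), sum(grp == "extratemporal")),
    stringsAsFactors = FALSE)
}
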