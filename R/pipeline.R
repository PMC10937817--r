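#' Write / read cohort and thickness tables
#'
#' Stable CSV formats tying the pipeline stages together: UTF-8,
#' comma-separated, mandatory header, "." decimal. Thickness files carry a
#' \code{subject_id} column followed by one column per atlas region; columns
#' are validated against the atlas on read, with mismatches listed
#' explicitly.
#'
#' @param cohort Cohort data frame.
#' @param thickness Subject x region matrix.
#' @param path Output file.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname cohort_io
#' @export
write_thickness_csv <- function(thickness, path) {
  ids <- rownames(thickness)
  if (is.null(ids)) ids <- sprintf("sub_%04d", seq_len(nrow(thickness)))
  df <- data.frame(subject_id = ids, thickness, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_thickness_csv <- function(path) {
  if (!file.exists(path)) stop("thickness file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  rownames(m) <- df$subject_id
  atlas <- load_atlas()
  check_thickness(m, atlas, data.frame(subject_id = df$subject_id))
}

#' Run the full normative-modeling pipeline
#'
#' Orchestrates simulate, fit, adapt, score and analyze on one seeded
#' configuration, writing every documented output plus a manifest recording
#' the package version, seed, settings, and an MD5 checksum per output file,
#' so each file is re-derivable from the manifest alone. On failure a
#' \code{FAILED} marker naming the failed stage is left in the output
#' directory and the error is re-signalled.
#'
#' @param config An \code{hbr_config} (or a YAML file path with fields
#'   matching \code{\link{generator_config}} arguments).
#' @param output_dir Output directory, created if needed.
#' @param threshold Outlier threshold (default -1.96).
#' @param transform Outlier-count transform for the group tests.
#' @param control Sampler settings.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = generator_config(), output_dir,
                         threshold = -1.96, transform = "log1p",
                         control = hbr_control()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    config <- do.call(generator_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "hbr_config"))
  if (threshold >= 0) stop("threshold must be negative", call. = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "init"
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(output_dir, name)
    writer(path)
    outputs[[length(outputs) + 1L]] <<- path
    path
  }
  result <- tryCatch({
    stage <- "simulate"
    ref <- generate_reference(config)
    adp <- generate_adaptation(config, ref$truth)
    cli <- generate_clinical(config, ref$truth)
    emit("reference_cohort.csv", function(p) write_cohort_csv(ref$cohort, p))
    emit("reference_thickness.csv", function(p) write_thickness_csv(ref$thickness, p))
    emit("adaptation_cohort.csv", function(p) write_cohort_csv(adp$cohort, p))
    emit("adaptation_thickness.csv", function(p) write_thickness_csv(adp$thickness, p))

    stage <- "fit"
    fit <- fit_reference(ref$cohort, ref$thickness, seed = config$seed,
                         control = control)
    emit("normative_fit.json", function(p) write_normative_fit(fit, p))

    stage <- "adapt"
    adapt <- adapt_site(fit, adp$cohort, adp$thickness)

    stage <- "score"
    dev <- score(fit, adapt, cli$cohort, cli$thickness)

    stage <- "analyze"
    o <- flag_outliers(dev, threshold)
    toc <- total_outlier_count(o)
    prev <- outlier_prevalence(o)
    status <- sts_status(o)
    lobe <- lobe_prevalence_summary(o)
    H <- hamming_matrix(o)
    cli$cohort$suvr <- generate_suvr(config, toc)
    covs <- data.frame(age = cli$cohort$age,
                       sex = as.numeric(cli$cohort$sex == "female"))
    stats_list <- list(
      stage_toc = outliercount_group_test(toc, cli$cohort$stage, covs, transform),
      phenotype_toc = outliercount_group_test(toc, cli$cohort$phenotype,
                                              cbind(covs, stage = as.numeric(
                                                cli$cohort$stage == "dementia")),
                                              transform),
      age_toc = age_correlation(toc, cli$cohort$age),
      interaction = location_phenotype_interaction(o, cli$cohort$phenotype)$interaction,
      stage_dissimilarity = compare_group_dissimilarity(H, cli$cohort$stage),
      suvr_toc = suvr_association(toc, rowMeans(cli$thickness),
                                  cli$cohort$suvr, cli$cohort$age)$toc_suvr)

    emit("clinical_cohort.csv", function(p) write_cohort_csv(cli$cohort, p))
    emit("clinical_thickness.csv", function(p) write_thickness_csv(cli$thickness, p))
    emit("zscores.csv", function(p) write_thickness_csv(dev$z, p))
    emit("outlier_matrix.csv", function(p) write_thickness_csv(o, p))
    emit("subject_summary.csv", function(p) utils::write.csv(
      data.frame(subject_id = cli$cohort$subject_id, total_outlier_count = toc,
                 sts_status = as.character(status)), p, row.names = FALSE))
    emit("region_prevalence.csv", function(p) utils::write.csv(
      prev$ranked, p, row.names = FALSE))
    emit("lobe_summary.csv", function(p) utils::write.csv(lobe, p, row.names = FALSE))
    emit("hamming_matrix.csv", function(p) utils::write.csv(
      data.frame(subject_id = rownames(H), H, check.names = FALSE), p,
      row.names = FALSE))
    stat_rows <- lapply(stats_list, as.data.frame)
    cols <- Reduce(union, lapply(stat_rows, names))
    stat_rows <- lapply(stat_rows, function(d) {
      d[setdiff(cols, names(d))] <- NA
      d[cols]
    })
    emit("stat_results.tsv", function(p) utils::write.table(
      do.call(rbind, stat_rows), p, sep = "\t",
      row.names = FALSE, quote = FALSE))
    list(stats = stats_list, toc = toc)
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(output_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(
    package = "hbrnorm",
    version = as.character(utils::packageVersion("hbrnorm")),
    seed = config$seed,
    threshold = threshold,
    transform = transform,
    settings = unclass(config)[c("n_reference", "n_sites", "n_adaptation",
                                 "n_clinical")],
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(result, list(manifest = manifest)))
}
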