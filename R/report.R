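#' Run the end-to-end study analysis
#'
#' The full pipeline on a study: attendance filter, feature extraction
#' for every compound, split enumeration, per-compound evaluation over
#' all train/test combinations, and (optionally) the film-level
#' permutation test. The result is a pure function of (study, config).
#'
#' @param study a [voc_study()] (or a list with `metadata`/`compounds`
#'   file paths, which is read first).
#' @param config a [pipeline_config()].
#' @param compound_ids compounds to analyse (default: all in the
#'   study).
#' @param permute run the permutation test (the expensive stage).
#' @return an object of class `study_results`: `auc_mean` and `auc_sd`
#'   (compounds x classes), `auc_long` (per-combination values),
#'   `pvalues` (compounds x classes, when permuted), `per_film`
#'   (per-test-film AUC/p breakdown), `prc`, `evals`,
#'   `top_peak_summary` (height of each screening's highest robust
#'   peak, by class), `features`, `plan`, `config`.
#' @export
run_study <- function(study, config = pipeline_config(),
                      compound_ids = NULL, permute = TRUE) {
  if (!inherits(study, "voc_study") && is.list(study) &&
      !is.null(study$metadata))
    study <- read_study(study$metadata, study$compounds)
  stopifnot(inherits(study, "voc_study"))
  if (is.null(compound_ids)) compound_ids <- names(study$compounds)

  study$screenings <- attendance_filter(study$screenings, config$min_viewers)
  features <- feature_table(study, compound_ids, config)
  plan <- enumerate_splits(study$screenings[!study$screenings$excluded, ],
                           config$min_test_screenings,
                           config$always_together)
  mcfg <- model_config(config$model$n_trees, config$model$vars_per_split,
                       seed = config$seed)

  evals <- list(); perms <- list()
  for (id in compound_ids) {
    feats <- features[features$compound_id == id, , drop = FALSE]
    attr(feats, "feature_cols") <- attr(features, "feature_cols")
    evals[[id]] <- evaluate_compound(feats, plan, mcfg)
    if (permute)
      perms[[id]] <- permutation_test(feats, plan, evals[[id]], mcfg,
                                      k = config$permutations)
  }

  classes <- plan$classes
  pick <- function(field) {
    out <- do.call(rbind, lapply(compound_ids, function(id) {
      s <- evals[[id]]$auc_summary
      stats::setNames(as.list(s[[field]]), s$age_class)
    }))
    df <- data.frame(compound_id = compound_ids, out,
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("compound_id", classes)
    df[-1] <- lapply(df[-1], as.numeric)
    df
  }
  auc_mean <- pick("mean_auc")
  auc_sd <- pick("sd_auc")
  auc_long <- do.call(rbind, lapply(compound_ids, function(id)
    cbind(compound_id = id, evals[[id]]$auc)))
  pvalues <- NULL
  if (permute) {
    pvalues <- data.frame(
      compound_id = compound_ids,
      do.call(rbind, lapply(compound_ids, function(id) perms[[id]]$pvalues)),
      check.names = FALSE, stringsAsFactors = FALSE)
    names(pvalues) <- c("compound_id", classes)
  }

  # per-test-film breakdown: the combinations testing a film partition
  # the AUC set; per-film permutation p-values restrict the same way
  test_films <- unique(unlist(plan$options, use.names = FALSE))
  per_film <- do.call(rbind, lapply(compound_ids, function(id) {
    do.call(rbind, lapply(test_films, function(f) {
      sub <- auc_by_test_film(evals[[id]], f)
      do.call(rbind, lapply(classes, function(cl) {
        v <- sub$auc[sub$age_class == cl]
        data.frame(compound_id = id, film_title = f, age_class = cl,
                   mean_auc = mean(v, na.rm = TRUE),
                   sd_auc = stats::sd(v, na.rm = TRUE),
                   n = sum(!is.na(v)),
                   pvalue = if (permute)
                     suppressWarnings(per_film_pvalue(perms[[id]], f, cl))
                   else NA_real_,
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(per_film) <- NULL

  # highest robust peak per screening, for the per-class comparison
  tp <- features[, c("screening_id", "compound_id", "age_class", "height_1")]
  names(tp)[4L] <- "highest_peak"

  structure(list(auc_mean = auc_mean, auc_sd = auc_sd,
                 auc_long = auc_long, pvalues = pvalues,
                 prc = lapply(evals, `[[`, "prc_mean"),
                 per_film = per_film,
                 evals = evals, perms = if (permute) perms else NULL,
                 top_peak_summary = tp, features = features,
                 plan = plan, config = config),
            class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("<study_results> %d compound(s), %d combinations, seed %d\n",
              nrow(x$auc_mean), length(x$plan$combos), x$config$seed))
  print(x$auc_mean, row.names = FALSE, digits = 3)
  if (!is.null(x$pvalues)) {
    cat("permutation p-values:\n")
    print(x$pvalues, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write the report tables of a study analysis
#'
#' Emits the plot-ready tab-separated tables: per-compound mean AUC per
#' class (values of 0.70 and higher flagged in a companion column,
#' mirroring the bold-font convention of the summary table), the AUC
#' standard deviations, the per-combination AUC long table (box-plot
#' data), permutation p-values, averaged PRC curves, the
#' highest-peak-per-class table, and the feature table. Every file
#' carries a header comment stamping the seed.
#'
#' @param results a [run_study()] result.
#' @param dir output directory (created if needed).
#' @param highlight AUC threshold for the flag column.
#' @return invisibly, the written paths.
#' @export
write_report_tables <- function(results, dir, highlight = 0.70) {
  stopifnot(inherits(results, "study_results"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stamp <- sprintf("# seed=%d", results$config$seed)
  wr <- function(df, file) {
    path <- file.path(dir, file)
    con <- file(path, "w")
    writeLines(stamp, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    path
  }
  classes <- results$plan$classes
  am <- results$auc_mean
  for (cl in classes)
    am[[paste0("high_", cl)]] <- ifelse(am[[cl]] >= highlight, "*", "")
  paths <- c(
    wr(am, "auc_mean.tsv"),
    wr(results$auc_sd, "auc_sd.tsv"),
    wr(results$auc_long, "auc_per_combo.tsv"),
    wr(results$per_film, "auc_per_test_film.tsv"),
    wr(results$top_peak_summary, "highest_peaks.tsv"),
    wr(results$features, "features.tsv"))
  if (!is.null(results$pvalues))
    paths <- c(paths, wr(results$pvalues, "pvalues.tsv"))
  prc_long <- do.call(rbind, lapply(names(results$prc), function(id) {
    do.call(rbind, lapply(names(results$prc[[id]]), function(cl)
      cbind(compound_id = id, age_class = cl, results$prc[[id]][[cl]])))
  }))
  if (!is.null(prc_long)) paths <- c(paths, wr(prc_long, "prc_mean.tsv"))
  invisible(paths)
}
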