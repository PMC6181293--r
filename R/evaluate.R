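#' Evaluate one compound over all train/test combinations
#'
#' For each combination of the split plan: train the ensemble on the
#' training screenings' feature vectors, score the test screenings, and
#' compute per-class one-vs-rest ROC AUC and precision-recall curves
#' (test instances are screenings). AUCs are aggregated to a mean and
#' standard deviation per class; PRC curves are averaged point-wise on
#' the common recall grid. A (combination, class) AUC whose test set
#' lacks positives or negatives is missing and excluded from the mean
#' (count logged), never imputed at 0.5.
#'
#' Per-combination training seeds are derived deterministically from
#' the config seed, so an evaluation is a pure function of
#' (features, plan, config).
#'
#' @param features a [feature_table()] restricted to one compound, or a
#'   multi-compound table plus `compound_id`.
#' @param plan an [enumerate_splits()] plan.
#' @param config a [model_config()].
#' @param compound_id compound to evaluate when `features` holds
#'   several.
#' @param recall_grid common recall abscissa for PRC averaging.
#' @return an object of class `eval_result`: `auc` (long data frame
#'   combo x class), `auc_summary` (per class mean, sd, n, n_missing),
#'   `prc_mean` (per class averaged curve), `scores` (per-combo test
#'   scores, reused by the permutation test).
#' @export
evaluate_compound <- function(features, plan, config = model_config(),
                              compound_id = NULL,
                              recall_grid = seq(0, 1, length.out = 101)) {
  stopifnot(inherits(plan, "split_plan"))
  if (!is.null(compound_id))
    features <- features[features$compound_id == compound_id, , drop = FALSE]
  if (length(unique(features$compound_id)) != 1L)
    stop("evaluate_compound expects features of exactly one compound")
  if (nrow(features) == 0L) stop("empty feature table")
  classes <- plan$classes
  X <- feature_matrix(features)

  auc_rows <- list(); prc_acc <- list(); scores <- list()
  for (ci in seq_along(plan$combos)) {
    combo <- plan$combos[[ci]]
    test_films <- unlist(combo, use.names = FALSE)
    is_test <- features$film_title %in% test_films
    if (!any(is_test) || !any(!is_test)) next
    cfg <- model_config(config$n_trees, config$vars_per_split,
                        seed = derive_seed(config$seed, ci))
    clf <- train_classifier(X[!is_test, , drop = FALSE],
                            features$age_class[!is_test], cfg)
    prob <- predict(clf, X[is_test, , drop = FALSE], classes = classes)
    truth <- as.character(features$age_class[is_test])
    scores[[ci]] <- list(prob = prob, truth = truth)
    for (cl in classes) {
      pos <- truth == cl
      a <- if (any(pos) && any(!pos))
        roc_auc(prob[, cl], pos) else NA_real_
      auc_rows[[length(auc_rows) + 1L]] <-
        data.frame(combo = ci, age_class = cl, auc = a,
                   test_films = paste(test_films, collapse = " + "),
                   stringsAsFactors = FALSE)
      if (any(pos)) {
        pr <- prc_curve(prob[, cl], pos, recall_grid)
        prc_acc[[cl]] <- c(prc_acc[[cl]], list(pr$precision))
      }
    }
  }
  auc <- do.call(rbind, auc_rows)
  auc_summary <- do.call(rbind, lapply(classes, function(cl) {
    v <- auc$auc[auc$age_class == cl]
    data.frame(age_class = cl,
               mean_auc = mean(v, na.rm = TRUE),
               sd_auc = stats::sd(v, na.rm = TRUE),
               n = sum(!is.na(v)), n_missing = sum(is.na(v)),
               stringsAsFactors = FALSE)
  }))
  prc_mean <- lapply(prc_acc, function(curves) {
    data.frame(recall = recall_grid,
               precision = Reduce(`+`, curves) / length(curves))
  })
  structure(list(compound_id = features$compound_id[1L],
                 auc = auc, auc_summary = auc_summary,
                 prc_mean = prc_mean, scores = scores,
                 plan = plan, classes = classes),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> compound %s, %d combinations\n",
              x$compound_id, length(x$plan$combos)))
  s <- x$auc_summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  FSK %-3s mean AUC %.3f +/- %.3f (n = %d%s)\n",
                s$age_class[i], s$mean_auc[i], s$sd_auc[i], s$n[i],
                if (s$n_missing[i]) sprintf(", %d missing", s$n_missing[i]) else ""))
  invisible(x)
}

#' Per-test-film AUC breakdown
#'
#' Restricts the per-combination AUCs of one class to the combinations
#' whose test set contains a named film — a partition of the full AUC
#' set that changes no value (used for the per-film comparisons of
#' genre and audience-age robustness).
#'
#' @param result an [evaluate_compound()] result.
#' @param film film title.
#' @return the rows of `result$auc` whose test set contains the film.
#' @export
auc_by_test_film <- function(result, film) {
  stopifnot(inherits(result, "eval_result"))
  in_test <- vapply(result$plan$combos, function(cb)
    film %in% unlist(cb, use.names = FALSE), logical(1))
  if (!any(in_test))
    stop(sprintf("film '%s' never appears in a test set", film))
  result$auc[result$auc$combo %in% which(in_test), , drop = FALSE]
}
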