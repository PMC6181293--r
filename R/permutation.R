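#' Shuffle film labels, preserving the class distribution
#'
#' Assigns a uniformly random permutation of the existing age classes
#' to the films: the multiset of labels is unchanged, every screening
#' of a film receives that film's new label, and only training films
#' are ever shuffled (the test set keeps its original ratings).
#'
#' @param film_classes named character vector or factor mapping film
#'   title to age class.
#' @return the permuted mapping, same names.
#' @export
shuffle_film_labels <- function(film_classes) {
  stopifnot(length(film_classes) >= 2L, !is.null(names(film_classes)))
  stats::setNames(sample(film_classes), names(film_classes))
}

#' Pooled permutation p-value
#'
#' Exceedances are counted pairwise within each train/test combination
#' (permuted AUC >= original AUC; ties count against the original) and
#' pooled over combinations. The p-value uses the add-one permutation
#' formula p = (b + 1) / (n + 1), which can never be exactly 0; the raw
#' fraction b / n is available as a variant.
#'
#' @param original per-combination original AUCs (NA = undefined).
#' @param permuted matrix of permuted AUCs, rows = combinations,
#'   columns = shuffles.
#' @param variant `"plus_one"` (default) or `"raw"`.
#' @param strict use `>` instead of `>=` for the exceedance comparison.
#' @return the pooled p-value, or `NA` when no valid (original,
#'   permuted) pair exists.
#' @export
permutation_pvalue <- function(original, permuted,
                               variant = c("plus_one", "raw"),
                               strict = FALSE) {
  variant <- match.arg(variant)
  permuted <- as.matrix(permuted)
  stopifnot(length(original) == nrow(permuted))
  valid <- which(!is.na(original))
  b <- 0L; n <- 0L
  for (i in valid) {
    perm <- permuted[i, ]
    perm <- perm[!is.na(perm)]
    if (!length(perm)) next
    b <- b + if (strict) sum(perm > original[i]) else sum(perm >= original[i])
    n <- n + length(perm)
  }
  if (n == 0L) {
    warning("no valid (original, permuted) pair; p-value reported as NA")
    return(NA_real_)
  }
  if (variant == "plus_one") (b + 1) / (n + 1) else b / n
}

#' Film-level label-permutation significance test
#'
#' For every train/test combination, the training films' labels are
#' shuffled `k` times (class distribution retained, test labels kept);
#' each shuffled training set retrains the ensemble and rescores the
#' unchanged test set, giving per-class null AUCs. The pooled p-value
#' per class compares the original per-combination AUCs with their
#' matched permuted values via [permutation_pvalue()]. No correction
#' for multiple compounds is applied by default; p-values are reported
#' uncorrected.
#'
#' @param features one compound's [feature_table()] rows.
#' @param plan an [enumerate_splits()] plan.
#' @param result the original [evaluate_compound()] result for the same
#'   features/plan/config.
#' @param config a [model_config()]; permutation seeds derive from its
#'   seed.
#' @param k shuffles per combination (default 50).
#' @return an object of class `permutation_result`: `pvalues` (per
#'   class), `permuted` (list per class of combo x k AUC matrices),
#'   `original` (per-class original AUC vectors), `k`.
#' @export
permutation_test <- function(features, plan, result,
                             config = model_config(), k = 50L) {
  stopifnot(inherits(plan, "split_plan"), inherits(result, "eval_result"))
  classes <- plan$classes
  X <- feature_matrix(features)
  n_combo <- length(plan$combos)
  permuted <- lapply(classes, function(cl)
    matrix(NA_real_, nrow = n_combo, ncol = k))
  names(permuted) <- classes

  for (ci in seq_len(n_combo)) {
    combo <- plan$combos[[ci]]
    test_films <- unlist(combo, use.names = FALSE)
    is_test <- features$film_title %in% test_films
    if (!any(is_test) || !any(!is_test)) next
    train <- features[!is_test, , drop = FALSE]
    Xtr <- X[!is_test, , drop = FALSE]
    Xte <- X[is_test, , drop = FALSE]
    truth <- as.character(features$age_class[is_test])
    film_lab <- tapply(as.character(train$age_class), train$film_title,
                       function(v) v[1L])
    for (pi in seq_len(k)) {
      set.seed(derive_seed(config$seed, ci, pi))
      shuffled <- shuffle_film_labels(film_lab)
      lab <- factor(unname(shuffled[train$film_title]),
                    levels = levels(features$age_class))
      if (nlevels(droplevels(lab)) < 2L) next
      cfg <- model_config(config$n_trees, config$vars_per_split,
                          seed = derive_seed(config$seed, ci, k + pi))
      clf <- train_classifier(Xtr, lab, cfg)
      prob <- predict(clf, Xte, classes = classes)
      for (cl in classes) {
        pos <- truth == cl
        if (any(pos) && any(!pos))
          permuted[[cl]][ci, pi] <- roc_auc(prob[, cl], pos)
      }
    }
  }

  original <- lapply(classes, function(cl) {
    v <- result$auc[result$auc$age_class == cl, ]
    v$auc[order(v$combo)]
  })
  names(original) <- classes
  pvalues <- vapply(classes, function(cl)
    suppressWarnings(permutation_pvalue(original[[cl]], permuted[[cl]])),
    numeric(1))
  structure(list(pvalues = pvalues, permuted = permuted,
                 original = original, k = k, plan = plan,
                 compound_id = result$compound_id),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> compound %s, k = %d shuffles per combination\n",
              x$compound_id, x$k))
  for (cl in names(x$pvalues))
    cat(sprintf("  FSK %-3s p = %.4f\n", cl, x$pvalues[[cl]]))
  invisible(x)
}

#' Per-test-film permutation p-value
#'
#' The pooled p-value restricted to the combinations whose test set
#' contains a named film, comparing those original AUCs with their own
#' permuted values. Restricting to all combinations reproduces the
#' global p-value.
#'
#' @param perm a [permutation_test()] result.
#' @param film film title.
#' @param age_class class whose AUCs are compared.
#' @return the restricted pooled p-value.
#' @export
per_film_pvalue <- function(perm, film, age_class) {
  stopifnot(inherits(perm, "permutation_result"))
  age_class <- as.character(age_class)
  if (!age_class %in% names(perm$permuted))
    stop(sprintf("unknown age class '%s'", age_class))
  in_test <- vapply(perm$plan$combos, function(cb)
    film %in% unlist(cb, use.names = FALSE), logical(1))
  if (!any(in_test))
    stop(sprintf("film '%s' never appears in a test set", film))
  sel <- which(in_test)
  permutation_pvalue(perm$original[[age_class]][sel],
                     perm$permuted[[age_class]][sel, , drop = FALSE])
}
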