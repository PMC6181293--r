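#' Train the randomized-tree ensemble
#'
#' One multiclass ensemble per training set: `n_trees` randomized
#' decision trees, each split drawing `vars_per_split` candidate
#' features (default `floor(p/3)`, i.e. 6 for the 18-feature set).
#' Class probabilities are the fraction of tree votes. Training is
#' reproducible given the config seed. Backed by a `ranger`
#' probability forest.
#'
#' @param train_features data frame or matrix of feature columns.
#' @param train_labels factor of age classes, one per training row.
#' @param config a [model_config()].
#' @return an object of class `voc_classifier`.
#' @export
train_classifier <- function(train_features, train_labels,
                             config = model_config()) {
  train_features <- as.data.frame(train_features)
  train_labels <- droplevels(as.factor(train_labels))
  if (nlevels(train_labels) < 2L)
    stop("training set contains a single class; cannot train a classifier")
  p <- ncol(train_features)
  mtry <- config$vars_per_split
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))
  if (mtry > p) stop("vars_per_split exceeds the number of features")
  dat <- cbind(train_features, .class = train_labels)
  fit <- ranger::ranger(dependent.variable.name = ".class", data = dat,
                        num.trees = config$n_trees, mtry = mtry,
                        probability = TRUE, seed = config$seed,
                        num.threads = 1L, respect.unordered.factors = TRUE)
  structure(list(forest = fit, levels = levels(train_labels),
                 n_trees = config$n_trees, mtry = mtry,
                 importance = NULL),
            class = "voc_classifier")
}

#' @export
print.voc_classifier <- function(x, ...) {
  cat(sprintf("<voc_classifier> %d trees, %d vars/split, classes: %s\n",
              x$n_trees, x$mtry, paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Class-probability predictions
#'
#' @param object a [train_classifier()] result.
#' @param newdata feature data frame.
#' @param classes column order of the returned matrix; classes unseen
#'   in training get probability 0.
#' @param ... unused.
#' @return a matrix (rows = items, columns = `classes`) of
#'   probabilities summing to 1 per row.
#' @export
predict.voc_classifier <- function(object, newdata,
                                   classes = object$levels, ...) {
  pr <- stats::predict(object$forest, data = as.data.frame(newdata),
                       num.threads = 1L)$predictions
  out <- matrix(0, nrow = nrow(pr), ncol = length(classes),
                dimnames = list(NULL, classes))
  shared <- intersect(colnames(pr), classes)
  out[, shared] <- pr[, shared, drop = FALSE]
  out
}
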