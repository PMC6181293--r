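test_that("split enumeration is the product of per-class test options", {
  plan <- enumerate_splits(cinema_film_summary())
  expect_length(plan, 24L)
  expect_equal(unname(vapply(plan$options, length, integer(1))),
               c(2L, 3L, 2L, 2L))
  # the paired single-screening films form one joint option
  expect_true(any(vapply(plan$options[["16"]], function(o)
    setequal(o, c("The Counselor", "Machete Kills")), logical(1))))
  # every combination holds exactly one test selection per class and
  # never a film in both sets
  for (cb in plan$combos) expect_named(cb, c("0", "6", "12", "16"))

  # product rule on arbitrary synthetic film lists, no grouping
  set.seed(3)
  for (rep in 1:10) {
    counts <- sample(1:4, 4, replace = TRUE)
    fs <- toy_film_summary(counts)
    pl <- enumerate_splits(fs, min_test_screenings = 1,
                           always_together = character())
    expect_length(pl, prod(counts))
  }
  pl24 <- enumerate_splits(toy_film_summary(c(2L, 3L, 2L, 2L)),
                           min_test_screenings = 1,
                           always_together = character())
  expect_length(pl24, 24L)
})

test_that("a single eligible film tests in every combination; none is an error", {
  fs <- toy_film_summary(c(2L, 2L, 2L, 2L), n_screenings = 10L)
  fs$n_screenings[fs$age_class == "6"] <- c(10L, 3L)
  pl <- enumerate_splits(fs, min_test_screenings = 8,
                         always_together = character())
  expect_length(pl, 8L)
  expect_true(all(vapply(pl$combos, function(cb)
    identical(cb[["6"]], "film 6-1"), logical(1))))

  fs$n_screenings[fs$age_class == "6"] <- c(3L, 3L)
  expect_error(enumerate_splits(fs, min_test_screenings = 8,
                                always_together = character()),
               "class 6")
})

test_that("the attendance filter drops screenings below the threshold", {
  scr <- data.frame(film_title = c("A", "B", "C"),
                    viewer_count = c(5L, 15L, 25L))
  expect_equal(nrow(attendance_filter(scr, 0)), 3L)
  expect_equal(nrow(attendance_filter(scr, 10)), 2L)
  expect_equal(nrow(attendance_filter(scr, 20)), 1L)
})

test_that("ROC AUC equals the pairwise ordering probability with half-credit ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(0.4, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_warning(a <- roc_auc(c(0.1, 0.2), c(TRUE, TRUE)), "absent")
  expect_true(is.na(a))

  set.seed(11)
  for (rep in 1:200) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
    # complement symmetry
    expect_equal(roc_auc(scores, labels) + roc_auc(scores, !labels), 1)
  }
})

test_that("ROC AUC matches an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (rep in 1:20) {
    scores <- round(runif(30), 2)
    labels <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (!any(labels) || all(labels)) next
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(labels, scores, direction = "<", quiet = TRUE))))
    expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("PRC curves live on the fixed recall grid and average to prevalence under random scores", {
  pr <- prc_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(nrow(pr), 101L)
  expect_equal(pr$precision, rep(1, 101))
  expect_warning(bad <- prc_curve(c(0.4, 0.2), c(FALSE, FALSE)), "no positive")
  expect_true(all(is.na(bad)))

  set.seed(31)
  n <- 1000; prev <- 0.25
  ap <- replicate(300, {
    labels <- sample(rep(c(TRUE, FALSE), times = c(n * prev, n * (1 - prev))))
    mean(prc_curve(runif(n), labels)$precision)
  })
  expect_equal(mean(ap), prev, tolerance = 0.02)
})

test_that("ensemble training memorizes separable toys and is seed-deterministic", {
  set.seed(2)
  X <- data.frame(f1 = c(rnorm(20, 0), rnorm(20, 8)),
                  f2 = c(rnorm(20, 0), rnorm(20, -8)))
  y <- factor(rep(c("0", "12"), each = 20), levels = c("0", "6", "12", "16"))
  clf <- train_classifier(X, y, model_config(seed = 7))
  pr <- predict(clf, X, classes = c("0", "6", "12", "16"))
  expect_true(all(pr[1:20, "0"] >= 0.9))
  expect_true(all(pr[21:40, "12"] >= 0.9))
  expect_equal(rowSums(pr), rep(1, 40), tolerance = 1e-9)
  # unseen classes carry zero probability
  expect_equal(unname(pr[, "6"]), rep(0, 40))

  clf2 <- train_classifier(X, y, model_config(seed = 7))
  expect_equal(predict(clf2, X), predict(clf, X))
  expect_error(train_classifier(X, factor(rep("0", 40))), "single class")

  # default split sampling: floor(p/3) features, 6 for the 18-feature set
  X18 <- as.data.frame(matrix(rnorm(40 * 18), 40,
                              dimnames = list(NULL, feature_names())))
  clf18 <- train_classifier(X18, y, model_config())
  expect_equal(clf18$mtry, 6L)
})

test_that("compound evaluation aggregates per-class AUCs over all combinations", {
  st <- quick_study(seed = 6, separation = 5)
  ft <- feature_table(st)
  pl <- enumerate_splits(st$screenings, min_test_screenings = 1,
                         always_together = character())
  expect_length(pl, 16L)
  ev <- evaluate_compound(ft, pl, model_config(n_trees = 100, seed = 1))
  expect_equal(nrow(ev$auc), 16L * 4L)
  expect_true(all(ev$auc$auc >= 0 & ev$auc$auc <= 1, na.rm = TRUE))
  expect_equal(ev$auc_summary$n + ev$auc_summary$n_missing, rep(16L, 4L))

  # restricting to combinations with a named test film partitions the
  # AUC set without changing any value
  f1 <- pl$options[["0"]][[1L]]
  f2 <- pl$options[["0"]][[2L]]
  sub1 <- auc_by_test_film(ev, f1)
  sub2 <- auc_by_test_film(ev, f2)
  expect_equal(sort(c(sub1$combo, sub2$combo)), sort(rep(1:16, each = 4)))
  expect_equal(rbind(sub1, sub2)[order(c(sub1$combo, sub2$combo),
                                       c(sub1$age_class, sub2$age_class)), ]$auc,
               ev$auc[order(ev$auc$combo, ev$auc$age_class), ]$auc)
  expect_error(auc_by_test_film(ev, "no such film"), "never appears")

  # determinism: identical rerun
  ev2 <- evaluate_compound(ft, pl, model_config(n_trees = 100, seed = 1))
  expect_equal(ev2$auc, ev$auc)
})
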