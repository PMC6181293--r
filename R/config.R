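#' Ensemble configuration
#'
#' Settings of the randomized-tree ensemble: 500 trees and
#' `floor(p/3)` candidate variables per split (6 for the default
#' 18-feature set), with a seed for reproducible training.
#'
#' @param n_trees number of trees.
#' @param vars_per_split variables sampled at each split; `NULL` derives
#'   `floor(p/3)` from the feature count at training time.
#' @param seed master seed for ensemble training.
#' @return an object of class `model_config`.
#' @export
model_config <- function(n_trees = 500L, vars_per_split = NULL, seed = 1L) {
  stopifnot(n_trees >= 1L)
  if (!is.null(vars_per_split)) stopifnot(vars_per_split >= 1L)
  structure(list(n_trees = as.integer(n_trees),
                 vars_per_split = vars_per_split,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Pipeline configuration
#'
#' All tunable settings of the end-to-end analysis, with the defaults
#' used throughout: a 5-minute tail trim, the 3-step robust peak rule,
#' top-5 peak retention, the measured room constants, test-set
#' eligibility at 8+ screenings with the two single-screening FSK-16
#' films grouped as one joint test option, and 50 label shuffles per
#' train/test combination in the permutation test.
#'
#' @param trim_minutes minutes removed from each screening's end.
#' @param min_steps_robust flank length of the robust peak rule.
#' @param top_k peaks retained per key.
#' @param feature_variant see [feature_names()].
#' @param room a [room_params()].
#' @param baseline_minutes pre-entry window for [estimate_inflow()];
#'   the default 0 takes the inflow mixing ratio from the room
#'   configuration. Estimating it from the pre-entry window assumes
#'   the room is flushed before entry; with a 5-h air-residence time
#'   and back-to-back screenings the pre-entry air still carries the
#'   previous audience, which overstates the inflow and pushes the
#'   emission-rate bound into play.
#' @param max_gap_steps longest NA gap interpolated by [fill_gaps()].
#' @param allow_negative_E permit negative fitted emission rates.
#' @param min_test_screenings screenings a film needs to be eligible
#'   for the test set.
#' @param always_together films always placed in the same set and
#'   evaluated jointly.
#' @param min_viewers attendance filter threshold (0 disables).
#' @param model a [model_config()].
#' @param permutations label shuffles per combination.
#' @param seed master seed for all stochastic stages.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(trim_minutes = 5,
                            min_steps_robust = 3L,
                            top_k = 5L,
                            feature_variant = "drop_aggregates",
                            room = room_params(),
                            baseline_minutes = 0,
                            max_gap_steps = 3L,
                            allow_negative_E = FALSE,
                            min_test_screenings = 8L,
                            always_together = c("The Counselor", "Machete Kills"),
                            min_viewers = 0L,
                            model = model_config(),
                            permutations = 50L,
                            seed = 1L) {
  structure(list(trim_minutes = trim_minutes,
                 min_steps_robust = as.integer(min_steps_robust),
                 top_k = as.integer(top_k),
                 feature_variant = feature_variant,
                 room = room,
                 baseline_minutes = baseline_minutes,
                 max_gap_steps = as.integer(max_gap_steps),
                 allow_negative_E = allow_negative_E,
                 min_test_screenings = as.integer(min_test_screenings),
                 always_together = always_together,
                 min_viewers = as.integer(min_viewers),
                 model = model,
                 permutations = as.integer(permutations),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown fields raise an error naming the field; recognised fields
#' override the defaults of [pipeline_config()] (nested `room` and
#' `model` blocks map onto [room_params()] and [model_config()]).
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
  if (!is.null(raw$room)) raw$room <- do.call(room_params, raw$room)
  if (!is.null(raw$model)) raw$model <- do.call(model_config, raw$model)
  do.call(pipeline_config, raw)
}

# internal: derive a reproducible 31-bit stream seed from a master seed
# and one or two stage indices.
derive_seed <- function(master, i, j = 0L) {
  (as.numeric(master) * 48271 + i * 7919 + j * 104729) %% 2147483647
}
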