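#' Per-screening, per-compound feature table
#'
#' Runs the full preprocessing chain for every (screening, compound)
#' pair — window extraction, short-gap interpolation, tail trim,
#' per-person normalization, box-model fit and residualization — and
#' extracts the feature vector from each residual series.
#'
#' Screenings flagged `excluded` (QC) are skipped; a screening whose
#' trace has an over-long gap inside the window is skipped and logged.
#' The inflow mixing ratio is estimated from the pre-entry baseline
#' window when the trace extends before the screening start, else the
#' configured room value is used.
#'
#' @param study a [voc_study()].
#' @param compound_ids compounds to featurize (default: all).
#' @param config a [pipeline_config()].
#' @return a data frame with identifier columns `screening_id`,
#'   `film_title`, `age_class`, `viewer_count`, `compound_id`, then the
#'   feature columns ([feature_names()]). Attribute `audit` holds the
#'   per-pair box-model fits (E, C0, C_in, rms misfit); attribute
#'   `skipped` lists skipped (screening, compound) pairs with reasons.
#' @export
feature_table <- function(study, compound_ids = NULL,
                          config = pipeline_config()) {
  stopifnot(inherits(study, "voc_study"))
  if (is.null(compound_ids)) compound_ids <- names(study$compounds)
  scr <- study$screenings[!study$screenings$excluded, , drop = FALSE]
  fnames <- feature_names(config$feature_variant)

  rows <- list(); audit <- list(); skipped <- list()
  for (id in compound_ids) {
    full <- study$compounds[[id]]
    if (is.null(full)) stop(sprintf("compound '%s' not present in the study", id))
    for (i in seq_len(nrow(scr))) {
      rec <- scr[i, , drop = FALSE]
      key <- sprintf("%s:%s", rec$screening_id, id)
      res <- tryCatch({
        win <- slice_screening(full, rec)
        win <- fill_gaps(win, config$max_gap_steps)
        if (isTRUE(attr(win, "excluded")))
          stop("gap longer than the interpolation tolerance")
        c_in <- config$room$inflow_mixing_ratio
        if (config$baseline_minutes > 0) {
          base <- estimate_inflow(full, rec$start_time, config$baseline_minutes)
          if (!is.na(base)) c_in <- base
        }
        win <- trim_tail(win, config$trim_minutes)
        win <- normalize_per_person(win, rec$viewer_count)
        fit <- fit_box_model(win, config$room, c_in = c_in / rec$viewer_count,
                             allow_negative_E = config$allow_negative_E)
        resid <- compute_residuals(win, fit)
        feats <- extract_features(resid, config$min_steps_robust,
                                  config$top_k, config$feature_variant)
        list(feats = feats, fit = fit)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        skipped[[key]] <- conditionMessage(res)
        next
      }
      rows[[key]] <- data.frame(
        screening_id = rec$screening_id, film_title = rec$film_title,
        age_class = rec$age_class, viewer_count = rec$viewer_count,
        compound_id = id, as.list(res$feats),
        stringsAsFactors = FALSE, check.names = FALSE)
      audit[[key]] <- data.frame(
        screening_id = rec$screening_id, compound_id = id,
        emission_rate = res$fit$emission_rate,
        initial_value = res$fit$initial_value,
        inflow = res$fit$inflow, rms_misfit = res$fit$rms_misfit,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop("no (screening, compound) pair produced features")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  audit_df <- do.call(rbind, audit); rownames(audit_df) <- NULL
  attr(out, "audit") <- audit_df
  attr(out, "skipped") <- unlist(skipped)
  attr(out, "feature_cols") <- fnames
  out
}

# internal: split a feature table into the matrix of feature columns
# and the identifier columns.
feature_matrix <- function(features) {
  fcols <- attr(features, "feature_cols")
  if (is.null(fcols))
    fcols <- setdiff(names(features),
                     c("screening_id", "film_title", "age_class",
                       "viewer_count", "compound_id"))
  features[, fcols, drop = FALSE]
}

#' Write a feature table as tab-separated text
#'
#' @param features a [feature_table()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
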