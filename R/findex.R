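# The functional index F = E * S: relative expression times relative
# substrate-stimulated ATPase activity, both normalised to wild type.
# F close to 1 means wild-type-like function; F close to 0 means loss of
# expression and/or activity.

#' Relative expression E
#'
#' E is the variant's mean relative expression divided by the wild type's.
#' For summaries already on the %-of-WT scale this is `mean / 100`.
#'
#' @param summary_variant,summary_wt One-row assay summaries (or named lists)
#'   carrying `rel_expression_mean`.
#' @return E as a fraction of wild type.
#' @export
compute_E <- function(summary_variant, summary_wt) {
  wt <- as.numeric(summary_wt[["rel_expression_mean"]])
  if (!is.finite(wt) || wt <= 0) {
    rlang::abort("wild-type expression mean must be > 0",
                 class = "abca4_nonpositive_wt")
  }
  as.numeric(summary_variant[["rel_expression_mean"]]) / wt
}

#' Relative substrate-stimulated activity S
#'
#' S is the variant's stimulation window (stimulated minus basal activity)
#' divided by the wild type's stimulation window. S may be negative when the
#' substrate nominally inhibits the residual activity.
#'
#' @param summary_variant,summary_wt One-row assay summaries (or named lists)
#'   carrying `rel_basal_mean` and `rel_stimulated_mean`.
#' @return S as a fraction of the wild-type stimulation window.
#' @export
compute_S <- function(summary_variant, summary_wt) {
  window_wt <- as.numeric(summary_wt[["rel_stimulated_mean"]]) -
    as.numeric(summary_wt[["rel_basal_mean"]])
  if (!is.finite(window_wt) || window_wt == 0) {
    rlang::abort("wild-type stimulation window is zero",
                 class = "abca4_zero_stimulation")
  }
  window_var <- as.numeric(summary_variant[["rel_stimulated_mean"]]) -
    as.numeric(summary_variant[["rel_basal_mean"]])
  window_var / window_wt
}

#' Functional index F = E * S
#'
#' @param E,S Numeric vectors (recycled elementwise).
#' @return F, unrounded. Tabular output rounds to two decimals.
#' @export
compute_findex <- function(E, S) {
  E * S
}

#' Severity band configuration
#'
#' Default bands: F < 0.15 severe; 0.15 <= F <= 0.50 moderate (closed
#' interval); 0.50 < F < 0.70 indeterminate; F >= 0.70 normal/mild. The
#' indeterminate band is reported explicitly rather than snapped to a
#' neighbouring category.
#'
#' @param severe_max Upper bound (exclusive) of the severe band.
#' @param moderate_max Upper bound (inclusive) of the moderate band.
#' @param normal_min Lower bound (inclusive) of the normal/mild band.
#' @return A `findex_bands` list.
#' @export
severity_bands <- function(severe_max = 0.15, moderate_max = 0.50,
                           normal_min = 0.70) {
  if (!(severe_max <= moderate_max && moderate_max <= normal_min)) {
    rlang::abort("bands must satisfy severe_max <= moderate_max <= normal_min",
                 class = "abca4_bad_config")
  }
  structure(
    list(severe_max = severe_max, moderate_max = moderate_max,
         normal_min = normal_min),
    class = "findex_bands"
  )
}

severity_levels <- c("severe", "moderate", "indeterminate", "normal_mild")

#' Map F-index values to functional-severity categories
#'
#' @param f Numeric vector of F-index values.
#' @param bands A [severity_bands()] configuration.
#' @return Factor with levels severe, moderate, indeterminate, normal_mild.
#' @export
categorize_severity <- function(f, bands = severity_bands()) {
  stopifnot(inherits(bands, "findex_bands"))
  out <- rep(NA_character_, length(f))
  out[f < bands$severe_max] <- "severe"
  out[f >= bands$severe_max & f <= bands$moderate_max] <- "moderate"
  out[f > bands$moderate_max & f < bands$normal_min] <- "indeterminate"
  out[f >= bands$normal_min] <- "normal_mild"
  factor(out, levels = severity_levels)
}

# First-order (delta-method) propagation of the summary SDs into F.
# Contributions: expression SD of variant and wild type into E; basal and
# stimulated SDs of variant and wild type into S. Missing SDs count as 0.
propagate_f_sd <- function(svar, swt, E, S) {
  num <- function(x) {
    x <- suppressWarnings(as.numeric(x))
    if (length(x) == 0 || !is.finite(x)) 0 else x
  }
  m_wt <- num(swt[["rel_expression_mean"]])
  var_E <- (num(svar[["rel_expression_sd"]]) / m_wt)^2 +
    (num(svar[["rel_expression_mean"]]) * num(swt[["rel_expression_sd"]]) /
       m_wt^2)^2
  window_wt <- num(swt[["rel_stimulated_mean"]]) - num(swt[["rel_basal_mean"]])
  window_var <- num(svar[["rel_stimulated_mean"]]) -
    num(svar[["rel_basal_mean"]])
  var_S <- (num(svar[["rel_stimulated_sd"]])^2 +
              num(svar[["rel_basal_sd"]])^2) / window_wt^2 +
    window_var^2 * (num(swt[["rel_stimulated_sd"]])^2 +
                      num(swt[["rel_basal_sd"]])^2) / window_wt^4
  sqrt(S^2 * var_E + E^2 * var_S)
}

#' F-index from per-variant assay summaries
#'
#' Computes E, S and F = E * S for every variant in a summary table against
#' the wild-type row of the same table. The SD of F is obtained by
#' first-order propagation of the summary SDs.
#'
#' @param summaries Assay-summary tibble (see [summarize_assays()]); may also
#'   be any tibble carrying `variant_id`, `rel_expression_mean/sd` and
#'   `rel_basal_mean/sd`, `rel_stimulated_mean/sd` columns.
#' @param wt_id Identifier of the wild-type row.
#' @param bands Severity bands, see [severity_bands()].
#' @return F-index result tibble: `variant_id`, `E`, `S`, `F`, `F_sd`,
#'   `severity`, `method = "from_means"`.
#' @export
findex_from_means <- function(summaries, wt_id = "WT",
                              bands = severity_bands()) {
  summaries <- tibble::as_tibble(summaries)
  wt <- summaries[summaries$variant_id == wt_id, , drop = FALSE]
  if (nrow(wt) != 1) {
    rlang::abort(paste0("expected exactly one ", wt_id, " summary row"),
                 class = "abca4_missing_wt")
  }
  rows <- lapply(seq_len(nrow(summaries)), function(i) {
    svar <- summaries[i, , drop = FALSE]
    E <- compute_E(svar, wt)
    S <- compute_S(svar, wt)
    f <- compute_findex(E, S)
    tibble::tibble(
      variant_id = svar$variant_id,
      E = E, S = S, F = f,
      F_sd = propagate_f_sd(svar, wt, E, S)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$severity <- categorize_severity(out$F, bands)
  out$method <- "from_means"
  out
}

#' F-index computed within each experiment, then averaged
#'
#' E, S and F are formed inside every experiment shared by the variant and
#' the wild type, and the per-experiment F values are averaged; `F_sd` is
#' their sample SD. With noiseless replicates this agrees exactly with
#' [findex_from_means()]; with noisy replicates the two can differ, which is
#' why both modes are exposed.
#'
#' @param expression Expression replicate tibble (raw densitometry).
#' @param atpase ATPase replicate tibble (raw luminescence).
#' @param wt_id Identifier of the wild-type rows.
#' @param bands Severity bands, see [severity_bands()].
#' @return F-index result tibble with `method = "per_replicate"`.
#' @export
findex_per_replicate <- function(expression, atpase, wt_id = "WT",
                                 bands = severity_bands()) {
  expr_rel <- normalize_expression(expression, wt_id = wt_id)
  atp_rel <- relative_atpase(atpase, wt_id = wt_id)
  wt_atp <- atp_rel[atp_rel$variant_id == wt_id, , drop = FALSE]
  wt_window <- tibble::tibble(
    experiment_id = wt_atp$experiment_id,
    wt_window = wt_atp$rel_stimulated - wt_atp$rel_basal
  )
  if (any(wt_window$wt_window == 0)) {
    rlang::abort("wild-type stimulation window is zero in an experiment",
                 class = "abca4_zero_stimulation")
  }
  per_exp <- expr_rel |>
    dplyr::inner_join(atp_rel, by = c("variant_id", "experiment_id")) |>
    dplyr::inner_join(wt_window, by = "experiment_id") |>
    dplyr::mutate(
      E = .data$rel_expression / 100,
      S = (.data$rel_stimulated - .data$rel_basal) / .data$wt_window,
      F = .data$E * .data$S
    )
  empty <- setdiff(unique(c(expression$variant_id, atpase$variant_id)),
                   unique(per_exp$variant_id))
  if (length(empty) > 0) {
    rlang::abort(
      paste0("no experiment shared by both assays for: ",
             paste(empty, collapse = ", ")),
      class = "abca4_no_common_experiments"
    )
  }
  out <- per_exp |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(
      E = mean(.data$E), S = mean(.data$S),
      F_sd = sample_sd(.data$F), F = mean(.data$F),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("variant_id", "E", "S", "F", "F_sd", "n_replicates")
  out$severity <- categorize_severity(out$F, bands)
  out$method <- "per_replicate"
  out
}
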