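# Assay-level normalisation: raw replicate measurements are scaled within
# each experiment to that experiment's wild-type reference, then summarised
# as mean +/- sample SD across independent experiments.

#' Read replicate Western-blot densitometry from TSV
#'
#' Expects UTF-8 TSV with header columns `variant_id`, `experiment_id`,
#' `band_intensity`, `loading_control_intensity`. Missing values are coded
#' as `"."`.
#'
#' @param path Path to a TSV file.
#' @return A tibble of expression replicates.
#' @export
read_expression_tsv <- function(path) {
  out <- readr::read_tsv(
    path,
    na = c(".", "NA", ""),
    col_types = readr::cols(
      variant_id = readr::col_character(),
      experiment_id = readr::col_character(),
      band_intensity = readr::col_double(),
      loading_control_intensity = readr::col_double()
    ),
    progress = FALSE
  )
  validate_expression_replicates(out)
}

#' Read replicate ATPase luminescence readings from TSV
#'
#' Expects columns `variant_id`, `experiment_id`, `lum_basal`,
#' `lum_stimulated`, `lum_background` and optionally `amount_scale` (a
#' per-sample protein-amount scale factor; defaults to 1 when absent).
#' The background column is the 0-hour ATP reaction measured per variant
#' per experiment. Missing values are coded as `"."`.
#'
#' @param path Path to a TSV file.
#' @return A tibble of ATPase replicates.
#' @export
read_atpase_tsv <- function(path) {
  out <- readr::read_tsv(path, na = c(".", "NA", ""), show_col_types = FALSE,
                         progress = FALSE)
  validate_atpase_replicates(out)
}

validate_expression_replicates <- function(replicates) {
  replicates <- tibble::as_tibble(replicates)
  need <- c("variant_id", "experiment_id", "band_intensity",
            "loading_control_intensity")
  missing <- setdiff(need, names(replicates))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("expression replicates lack column(s): ",
             paste(missing, collapse = ", ")),
      class = "abca4_bad_input"
    )
  }
  if (any(replicates$loading_control_intensity <= 0, na.rm = TRUE)) {
    rlang::abort("loading_control_intensity must be > 0",
                 class = "abca4_bad_input")
  }
  if (any(replicates$band_intensity < 0, na.rm = TRUE)) {
    rlang::abort("band_intensity must be >= 0", class = "abca4_bad_input")
  }
  replicates
}

validate_atpase_replicates <- function(replicates) {
  replicates <- tibble::as_tibble(replicates)
  need <- c("variant_id", "experiment_id", "lum_basal", "lum_stimulated",
            "lum_background")
  missing <- setdiff(need, names(replicates))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("ATPase replicates lack column(s): ",
             paste(missing, collapse = ", ")),
      class = "abca4_bad_input"
    )
  }
  if (!"amount_scale" %in% names(replicates)) {
    replicates$amount_scale <- 1
  }
  replicates$amount_scale[is.na(replicates$amount_scale)] <- 1
  bad <- !is.finite(replicates$lum_basal) |
    !is.finite(replicates$lum_stimulated) |
    !is.finite(replicates$lum_background)
  if (any(bad)) {
    rlang::abort("luminescence readings must be finite",
                 class = "abca4_bad_input")
  }
  replicates
}

#' Per-experiment relative expression (% of wild type)
#'
#' Each lane is first corrected for loading (band / loading control); within
#' each experiment the corrected value is expressed as a percentage of that
#' experiment's wild-type lane, so the wild type is 100 by construction and
#' the result is invariant to rescaling all intensities of one experiment
#' by a common positive factor.
#'
#' @param replicates Expression replicate tibble (see [read_expression_tsv()]).
#' @param wt_id Identifier of the wild-type reference rows.
#' @return Tibble with `variant_id`, `experiment_id`, `rel_expression`.
#' @export
normalize_expression <- function(replicates, wt_id = "WT") {
  replicates <- validate_expression_replicates(replicates)
  wt <- replicates[replicates$variant_id == wt_id, , drop = FALSE]
  experiments <- unique(replicates$experiment_id)
  missing <- setdiff(experiments, unique(wt$experiment_id))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("experiment(s) without a ", wt_id, " reference: ",
             paste(missing, collapse = ", ")),
      class = "abca4_missing_wt"
    )
  }
  wt_ratio <- tibble::tibble(
    experiment_id = wt$experiment_id,
    wt_ratio = wt$band_intensity / wt$loading_control_intensity
  )
  if (any(wt_ratio$wt_ratio <= 0)) {
    rlang::abort(paste0(wt_id, " band intensity is zero in at least one",
                        " experiment"),
                 class = "abca4_zero_wt")
  }
  out <- dplyr::inner_join(replicates, wt_ratio, by = "experiment_id")
  # ratio-of-ratios first so the WT lane is exactly 100 in floating point
  out$rel_expression <-
    100 * ((out$band_intensity / out$loading_control_intensity) /
             out$wt_ratio)
  dplyr::select(out, "variant_id", "experiment_id", "rel_expression")
}

#' Per-experiment relative ATPase activities (% of wild-type basal)
#'
#' Background (0-hour ATP reaction) is subtracted from each reading and the
#' result divided by the per-sample `amount_scale`; both basal and
#' substrate-stimulated activities are then expressed as a percentage of the
#' same experiment's wild-type *basal* activity. Negative background-corrected
#' activities are retained as-is (clamping them would bias the stimulation
#' ratio upward) and flagged in `negative_activity`.
#'
#' @param replicates ATPase replicate tibble (see [read_atpase_tsv()]).
#' @param wt_id Identifier of the wild-type reference rows.
#' @return Tibble with `variant_id`, `experiment_id`, `rel_basal`,
#'   `rel_stimulated`, `negative_activity`.
#' @export
relative_atpase <- function(replicates, wt_id = "WT") {
  replicates <- validate_atpase_replicates(replicates)
  act_basal <- (replicates$lum_basal - replicates$lum_background) /
    replicates$amount_scale
  act_stim <- (replicates$lum_stimulated - replicates$lum_background) /
    replicates$amount_scale
  acts <- tibble::tibble(
    variant_id = replicates$variant_id,
    experiment_id = replicates$experiment_id,
    act_basal = act_basal,
    act_stim = act_stim
  )
  wt <- acts[acts$variant_id == wt_id, , drop = FALSE]
  missing <- setdiff(unique(acts$experiment_id), unique(wt$experiment_id))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("experiment(s) without a ", wt_id, " reference: ",
             paste(missing, collapse = ", ")),
      class = "abca4_missing_wt"
    )
  }
  if (any(wt$act_basal <= 0)) {
    rlang::abort(
      paste0(wt_id, " background-corrected basal activity is <= 0 in at",
             " least one experiment"),
      class = "abca4_nonpositive_wt_activity"
    )
  }
  wt_basal <- tibble::tibble(experiment_id = wt$experiment_id,
                             wt_act_basal = wt$act_basal)
  out <- dplyr::inner_join(acts, wt_basal, by = "experiment_id")
  tibble::tibble(
    variant_id = out$variant_id,
    experiment_id = out$experiment_id,
    rel_basal = 100 * (out$act_basal / out$wt_act_basal),
    rel_stimulated = 100 * (out$act_stim / out$wt_act_basal),
    negative_activity = out$act_basal < 0 | out$act_stim < 0
  )
}

sample_sd <- function(x) {
  if (length(x) < 2) 0 else stats::sd(x)
}

#' Summarise per-experiment relative values as mean +/- SD
#'
#' Arithmetic mean and sample SD (n - 1 denominator) across independent
#' experiments. Variants observed in fewer than three experiments raise a
#' warning (condition class `abca4_few_replicates`) but are still summarised;
#' a single experiment yields SD 0 with `sd_undefined = TRUE`.
#'
#' @param expression Output of [normalize_expression()], or `NULL`.
#' @param atpase Output of [relative_atpase()], or `NULL`.
#' @return An assay-summary tibble with one row per variant: relative
#'   expression and basal/stimulated ATPase means and SDs (all % of wild
#'   type, stimulated relative to wild-type basal) plus `n_replicates`.
#' @export
summarize_assays <- function(expression = NULL, atpase = NULL) {
  if (is.null(expression) && is.null(atpase)) {
    rlang::abort("supply at least one of expression or atpase",
                 class = "abca4_bad_input")
  }
  expr_sum <- NULL
  if (!is.null(expression)) {
    expr_sum <- expression |>
      dplyr::group_by(.data$variant_id) |>
      dplyr::summarise(
        rel_expression_mean = mean(.data$rel_expression),
        rel_expression_sd = sample_sd(.data$rel_expression),
        n_expr = dplyr::n(),
        .groups = "drop"
      )
  }
  atp_sum <- NULL
  if (!is.null(atpase)) {
    atp_sum <- atpase |>
      dplyr::group_by(.data$variant_id) |>
      dplyr::summarise(
        rel_basal_mean = mean(.data$rel_basal),
        rel_basal_sd = sample_sd(.data$rel_basal),
        rel_stimulated_mean = mean(.data$rel_stimulated),
        rel_stimulated_sd = sample_sd(.data$rel_stimulated),
        n_atp = dplyr::n(),
        .groups = "drop"
      )
  }
  out <- if (is.null(expr_sum)) {
    atp_sum
  } else if (is.null(atp_sum)) {
    expr_sum
  } else {
    dplyr::full_join(expr_sum, atp_sum, by = "variant_id")
  }
  n_cols <- intersect(c("n_expr", "n_atp"), names(out))
  out$n_replicates <- do.call(
    pmin, c(unname(as.list(out[n_cols])), list(na.rm = TRUE))
  )
  out$sd_undefined <- out$n_replicates < 2
  few <- out$variant_id[out$n_replicates < 3]
  if (length(few) > 0) {
    rlang::warn(
      paste0("fewer than 3 replicates for: ", paste(few, collapse = ", ")),
      class = "abca4_few_replicates"
    )
  }
  dplyr::select(out, -dplyr::any_of(c("n_expr", "n_atp")))
}
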