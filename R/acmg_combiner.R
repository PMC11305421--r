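# Five-tier combination of ACMG-AMP evidence. Pure categorical combining
# rules are used when all evidence points one way; when pathogenic and
# benign evidence genuinely conflict, the codes are scored on the published
# point scale (supporting 1, moderate 2, strong 4, very strong 8; benign
# negative) and the total mapped to a tier. Before either route, PM2 at
# supporting is ignored when it is the only pathogenic-direction evidence
# standing against benign evidence, since rarity alone should not hold a
# variant in conflict.

POINTS <- c(supporting = 1, moderate = 2, strong = 4, very_strong = 8)

VERDICTS <- c("pathogenic", "likely_pathogenic", "vus", "likely_benign",
              "benign", "hypomorphic_na")

verdict_labels <- c(
  pathogenic = "Pathogenic",
  likely_pathogenic = "Likely pathogenic",
  vus = "VUS",
  likely_benign = "Likely benign",
  benign = "Benign",
  hypomorphic_na = "NA"
)

#' Human-readable verdict label
#'
#' @param verdict One of the internal verdict identifiers.
#' @return The tabular label (e.g. `"Likely pathogenic"`; the hypomorphic
#'   override prints as `"NA"`).
#' @export
verdict_label <- function(verdict) {
  unname(verdict_labels[verdict])
}

strength_counts <- function(evidence) {
  sapply(STRENGTHS, function(s) sum(evidence$strength == s))
}

categorical_pathogenic <- function(n) {
  vs <- n[["very_strong"]]; s <- n[["strong"]]; m <- n[["moderate"]]
  p <- n[["supporting"]]
  (vs >= 1 && (s >= 1 || m >= 2 || (m >= 1 && p >= 1) || p >= 2)) ||
    s >= 2 ||
    (s >= 1 && (m >= 3 || (m >= 2 && p >= 2) || (m >= 1 && p >= 4)))
}

categorical_likely_pathogenic <- function(n) {
  vs <- n[["very_strong"]]; s <- n[["strong"]]; m <- n[["moderate"]]
  p <- n[["supporting"]]
  (vs >= 1 && m >= 1) ||
    (s >= 1 && m >= 1 && m <= 2) ||
    (s >= 1 && p >= 2) ||
    m >= 3 ||
    (m >= 2 && p >= 2) ||
    (m >= 1 && p >= 4)
}

categorical_benign <- function(n) {
  n[["stand_alone"]] >= 1 || n[["strong"]] >= 2
}

categorical_likely_benign <- function(n) {
  (n[["strong"]] >= 1 && n[["supporting"]] >= 1) ||
    n[["supporting"]] >= 2
}

classification_row <- function(verdict, route, matched_rule,
                               points = NA_integer_, dropped = NULL) {
  tibble::tibble(
    verdict = verdict,
    route = route,
    points = as.integer(points),
    matched_rule = matched_rule,
    dropped_codes = list(if (is.null(dropped)) empty_evidence() else dropped)
  )
}

#' Combine an evidence set into a five-tier classification
#'
#' The procedure has three steps. Step 1: if PM2 (at supporting) is the only
#' pathogenic-direction code and benign-direction codes exist, it is dropped
#' and recorded in `dropped_codes`. Step 2: if both directions remain
#' represented the evidence is scored on the point scale (supporting 1,
#' moderate 2, strong 4, very strong 8; benign codes negative) and the total
#' mapped to a tier (>= 10 pathogenic, 6-9 likely pathogenic, 0-5 VUS,
#' -1 to -6 likely benign, <= -7 benign). Step 3: otherwise the categorical
#' combining tables apply; when both the pathogenic and likely-pathogenic
#' patterns match, the stronger tier wins. A stand-alone benign code yields
#' benign directly in any route. Strength-modified codes count at their
#' modified level throughout. An empty set is VUS.
#'
#' @param evidence An evidence tibble (see [evidence_code()]); duplicates
#'   by code should already have been resolved by [collect_evidence()]. The
#'   attribute `verdict_override = "hypomorphic"` short-circuits to the
#'   hypomorphic non-verdict.
#' @return A one-row classification tibble: `verdict`, `route`
#'   (categorical, points_conflict or override), `points`, `matched_rule`,
#'   `dropped_codes` (list-column).
#' @export
combine_evidence <- function(evidence) {
  override <- attr(evidence, "verdict_override", exact = TRUE)
  if (identical(override, "hypomorphic")) {
    return(classification_row("hypomorphic_na", "override",
                              "hypomorphic allele"))
  }
  if (nrow(evidence) == 0) {
    return(classification_row("vus", "categorical", "no evidence"))
  }
  path <- evidence[evidence$direction == "pathogenic", , drop = FALSE]
  ben <- evidence[evidence$direction == "benign", , drop = FALSE]
  if (any(ben$strength == "stand_alone")) {
    return(classification_row("benign", "categorical",
                              "stand-alone benign"))
  }
  dropped <- NULL
  if (nrow(path) == 1 && nrow(ben) > 0 && path$code == "PM2" &&
      path$strength == "supporting") {
    dropped <- path
    path <- path[0, , drop = FALSE]
  }
  if (nrow(path) > 0 && nrow(ben) > 0) {
    total <- sum(POINTS[path$strength]) - sum(POINTS[ben$strength])
    verdict <- if (total >= 10) "pathogenic"
      else if (total >= 6) "likely_pathogenic"
      else if (total >= 0) "vus"
      else if (total >= -6) "likely_benign"
      else "benign"
    return(classification_row(verdict, "points_conflict",
                              sprintf("point total %+d", total),
                              points = total, dropped = dropped))
  }
  if (nrow(path) > 0) {
    n <- strength_counts(path)
    if (categorical_pathogenic(n)) {
      return(classification_row("pathogenic", "categorical",
                                "pathogenic combining rule",
                                dropped = dropped))
    }
    if (categorical_likely_pathogenic(n)) {
      return(classification_row("likely_pathogenic", "categorical",
                                "likely-pathogenic combining rule",
                                dropped = dropped))
    }
    return(classification_row("vus", "categorical",
                              "no pathogenic rule matched",
                              dropped = dropped))
  }
  if (nrow(ben) > 0) {
    n <- strength_counts(ben)
    if (categorical_benign(n)) {
      return(classification_row("benign", "categorical",
                                "benign combining rule", dropped = dropped))
    }
    if (categorical_likely_benign(n)) {
      return(classification_row("likely_benign", "categorical",
                                "likely-benign combining rule",
                                dropped = dropped))
    }
    return(classification_row("vus", "categorical",
                              "no benign rule matched", dropped = dropped))
  }
  classification_row("vus", "categorical", "no evidence", dropped = dropped)
}

#' Classify a batch of evidence sets
#'
#' Order-preserving; per-variant errors are caught and reported as rows
#' with `verdict = NA` and the condition message in `matched_rule` rather
#' than aborting the batch.
#'
#' @param evidence_sets A named list of evidence tibbles (names are variant
#'   ids), or a tibble with columns `variant_id` and a list-column
#'   `evidence`.
#' @return A classification tibble with one row per input variant.
#' @export
classify_batch <- function(evidence_sets) {
  if (is.data.frame(evidence_sets)) {
    ids <- evidence_sets$variant_id
    sets <- evidence_sets$evidence
  } else {
    ids <- names(evidence_sets)
    if (is.null(ids)) ids <- as.character(seq_along(evidence_sets))
    sets <- evidence_sets
  }
  rows <- lapply(seq_along(sets), function(i) {
    res <- tryCatch(combine_evidence(sets[[i]]), error = function(e) {
      classification_row(NA_character_, "error", conditionMessage(e))
    })
    res$variant_id <- ids[i]
    res
  })
  dplyr::bind_rows(rows) |>
    dplyr::select("variant_id", dplyr::everything())
}
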