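# ACMG-AMP evidence assignment. Computed codes: PS3/BS3 from the F-index,
# PP3/BP4 from REVEL (missense) or SpliceAI plus auxiliary splice predictors
# (intronic), PM2 from gnomAD, PM5 from same-residue ClinVar records.
# PVS1, PM3, PP5, BP2, BP5 and externally derived PS3 strengths are
# delegated to upstream frameworks and enter as passthrough codes.

STRENGTHS <- c("supporting", "moderate", "strong", "very_strong",
               "stand_alone")

CODE_DEFAULT_STRENGTH <- c(
  PVS1 = "very_strong",
  PS1 = "strong", PS2 = "strong", PS3 = "strong", PS4 = "strong",
  PM1 = "moderate", PM2 = "moderate", PM3 = "moderate", PM4 = "moderate",
  PM5 = "moderate", PM6 = "moderate",
  PP1 = "supporting", PP2 = "supporting", PP3 = "supporting",
  PP4 = "supporting", PP5 = "supporting",
  BA1 = "stand_alone",
  BS1 = "strong", BS2 = "strong", BS3 = "strong", BS4 = "strong",
  BP1 = "supporting", BP2 = "supporting", BP3 = "supporting",
  BP4 = "supporting", BP5 = "supporting", BP6 = "supporting",
  BP7 = "supporting"
)

strength_rank <- function(strength) match(strength, STRENGTHS)

code_direction <- function(code) {
  ifelse(substr(code, 1, 1) == "P", "pathogenic", "benign")
}

empty_evidence <- function() {
  tibble::tibble(code = character(), direction = character(),
                 strength = character(), source = character(),
                 rationale = character())
}

#' Build an ACMG-AMP evidence code
#'
#' @param code One of the ACMG-AMP code names (PVS1, PS1-4, PM1-6, PP1-5,
#'   BA1, BS1-4, BP1-7).
#' @param strength Applied strength; defaults to the code's canonical level
#'   (e.g. strong for PS3, moderate for PM2). A non-canonical strength is a
#'   strength modifier, e.g. PM2 at supporting.
#' @param source `"computed"` or `"passthrough"`.
#' @param rationale Free-text audit note.
#' @return A one-row evidence tibble with columns `code`, `direction`,
#'   `strength`, `source`, `rationale`.
#' @export
evidence_code <- function(code, strength = NULL, source = "computed",
                          rationale = "") {
  if (!code %in% names(CODE_DEFAULT_STRENGTH)) {
    rlang::abort(paste0("unknown ACMG-AMP code: '", code, "'"),
                 class = "abca4_bad_code")
  }
  if (is.null(strength)) strength <- unname(CODE_DEFAULT_STRENGTH[code])
  if (!strength %in% STRENGTHS) {
    rlang::abort(paste0("unknown strength: '", strength, "'"),
                 class = "abca4_bad_code")
  }
  tibble::tibble(code = code, direction = code_direction(code),
                 strength = strength, source = source,
                 rationale = rationale)
}

#' Threshold configuration for evidence assignment
#'
#' Defaults encode the ABCA4-specific rule set: PS3 for F-index < 0.5 and
#' BS3 at supporting for F-index >= 0.9 (the lower bound is inclusive so
#' that a variant printing F = 0.90 qualifies); PP3 for REVEL >= 0.7 and
#' BP4 for REVEL <= 0.4 (missense); BP4 for intronic variants with SpliceAI
#' < 0.2 and no auxiliary prediction of a novel splice site; PM2 at
#' supporting when the gnomAD allele frequency is at most `pm2_max_af` and
#' at most 3 homozygotes are observed. The allele-frequency ceiling is a
#' configuration choice of this package (population databases report AF,
#' the homozygote cap alone does not exclude common variants).
#'
#' @param ps3_fmax F-index strictly below this assigns PS3.
#' @param bs3_fmin F-index at or above this assigns BS3 at supporting.
#' @param revel_pp3 REVEL at or above this assigns PP3 (missense).
#' @param revel_bp4 REVEL at or below this assigns BP4 (missense).
#' @param spliceai_bp4 SpliceAI max delta strictly below this is required
#'   for intronic BP4.
#' @param pm2_max_homozygotes Maximum gnomAD homozygote count for PM2.
#' @param pm2_max_af Maximum gnomAD allele frequency for PM2.
#' @param splice_region_window Maximum |intron offset| classed as
#'   splice-region rather than deep intronic.
#' @return A `rule_config` list.
#' @export
rule_config <- function(ps3_fmax = 0.5, bs3_fmin = 0.9, revel_pp3 = 0.7,
                        revel_bp4 = 0.4, spliceai_bp4 = 0.2,
                        pm2_max_homozygotes = 3L, pm2_max_af = 0.001,
                        splice_region_window = 20L) {
  if (!(revel_bp4 < revel_pp3)) {
    rlang::abort("revel_bp4 must be below revel_pp3",
                 class = "abca4_bad_config")
  }
  probs <- c(ps3_fmax = NA, revel_pp3 = revel_pp3, revel_bp4 = revel_bp4,
             spliceai_bp4 = spliceai_bp4, pm2_max_af = pm2_max_af)
  in01 <- stats::na.omit(probs)
  if (any(in01 < 0 | in01 > 1)) {
    rlang::abort("score thresholds must lie in [0, 1]",
                 class = "abca4_bad_config")
  }
  structure(
    list(ps3_fmax = ps3_fmax, bs3_fmin = bs3_fmin, revel_pp3 = revel_pp3,
         revel_bp4 = revel_bp4, spliceai_bp4 = spliceai_bp4,
         pm2_max_homozygotes = as.integer(pm2_max_homozygotes),
         pm2_max_af = pm2_max_af,
         splice_region_window = as.integer(splice_region_window)),
    class = "rule_config"
  )
}

findex_value <- function(findex) {
  if (is.numeric(findex)) return(findex[1])
  as.numeric(findex[["F"]])[1]
}

#' Functional evidence from the F-index (PS3 / BS3)
#'
#' F < `ps3_fmax` assigns PS3 at strong; F >= `bs3_fmin` assigns BS3 at
#' supporting; intermediate values assign nothing. Never emits both.
#'
#' @param findex A one-row F-index result (or a bare numeric F value).
#' @param cfg A [rule_config()].
#' @return A one-row evidence tibble, or an empty one.
#' @export
assign_functional <- function(findex, cfg = rule_config()) {
  f <- findex_value(findex)
  if (is.na(f)) return(empty_evidence())
  if (f < cfg$ps3_fmax) {
    return(evidence_code("PS3", rationale = sprintf(
      "F-index %.2f < %.2f", f, cfg$ps3_fmax)))
  }
  if (f >= cfg$bs3_fmin) {
    return(evidence_code("BS3", strength = "supporting", rationale = sprintf(
      "F-index %.2f >= %.2f", f, cfg$bs3_fmin)))
  }
  empty_evidence()
}

#' Computational (in-silico) evidence (PP3 / BP4)
#'
#' Missense variants are scored with REVEL: PP3 when REVEL >= `revel_pp3`,
#' BP4 when REVEL <= `revel_bp4`, nothing in between. Intronic and
#' splice-region variants are scored with SpliceAI: BP4 when the max delta
#' is below `spliceai_bp4` *and* no auxiliary tool predicts a novel
#' exonic/deep-intronic splice site; no PP3 route is defined for intronic
#' variants. A missing required score assigns nothing and warns.
#'
#' @param annotation A one-row annotation tibble (needs `consequence`,
#'   `revel`, `spliceai_max_delta`, `aux_splice_novel_site`).
#' @param cfg A [rule_config()].
#' @return A one-row evidence tibble, or an empty one.
#' @export
assign_computational <- function(annotation, cfg = rule_config()) {
  consequence <- annotation[["consequence"]][1]
  if (is.na(consequence)) return(empty_evidence())
  if (consequence == "missense") {
    revel <- as.numeric(annotation[["revel"]])[1]
    if (is.na(revel)) {
      rlang::warn(paste0("missense variant without REVEL score: ",
                         annotation[["variant_id"]][1]),
                  class = "abca4_missing_score")
      return(empty_evidence())
    }
    if (revel >= cfg$revel_pp3) {
      return(evidence_code("PP3", rationale = sprintf(
        "REVEL %.3f >= %.2f", revel, cfg$revel_pp3)))
    }
    if (revel <= cfg$revel_bp4) {
      return(evidence_code("BP4", rationale = sprintf(
        "REVEL %.3f <= %.2f", revel, cfg$revel_bp4)))
    }
    return(empty_evidence())
  }
  if (consequence %in% c("intronic", "splice_region")) {
    delta <- as.numeric(annotation[["spliceai_max_delta"]])[1]
    if (is.na(delta)) {
      rlang::warn(paste0("intronic variant without SpliceAI score: ",
                         annotation[["variant_id"]][1]),
                  class = "abca4_missing_score")
      return(empty_evidence())
    }
    aux <- isTRUE(as.logical(annotation[["aux_splice_novel_site"]])[1])
    if (delta < cfg$spliceai_bp4 && !aux) {
      return(evidence_code("BP4", rationale = sprintf(
        "SpliceAI %.2f < %.2f, no auxiliary novel-site prediction",
        delta, cfg$spliceai_bp4)))
    }
    return(empty_evidence())
  }
  empty_evidence()
}

#' Population-rarity evidence (PM2 at supporting)
#'
#' PM2 is assigned at supporting strength when the variant is absent from or
#' rare in gnomAD: allele frequency missing or at most `pm2_max_af`, and
#' homozygote count missing or at most `pm2_max_homozygotes`.
#'
#' @param annotation A one-row annotation tibble (needs `gnomad_af`,
#'   `gnomad_homozygotes`).
#' @param cfg A [rule_config()].
#' @return A one-row evidence tibble, or an empty one.
#' @export
assign_pm2 <- function(annotation, cfg = rule_config()) {
  af <- as.numeric(annotation[["gnomad_af"]])[1]
  hom <- as.integer(annotation[["gnomad_homozygotes"]])[1]
  af_ok <- is.na(af) || af <= cfg$pm2_max_af
  hom_ok <- is.na(hom) || hom <= cfg$pm2_max_homozygotes
  if (af_ok && hom_ok) {
    return(evidence_code("PM2", strength = "supporting", rationale = sprintf(
      "gnomAD AF %s, homozygotes %s",
      if (is.na(af)) "absent" else format(af),
      if (is.na(hom)) "absent" else hom)))
  }
  empty_evidence()
}

#' Same-residue evidence (PM5)
#'
#' PM5 (moderate) requires that the variant under examination has been
#' reported in a patient with ABCA4-related disease, that a different change
#' at the same residue is classified P/LP in ClinVar, and that either the
#' new variant's REVEL score is at least the reference variant's, or both
#' scores are at least 0.7.
#'
#' @param annotation A one-row annotation tibble (needs
#'   `reported_in_patient`, `revel`, and list-column `clinvar_same_residue`
#'   whose entries have `classification` and `revel`).
#' @return A one-row evidence tibble, or an empty one.
#' @export
assign_pm5 <- function(annotation) {
  if (!isTRUE(as.logical(annotation[["reported_in_patient"]])[1])) {
    return(empty_evidence())
  }
  refs <- annotation[["clinvar_same_residue"]]
  if (is.list(refs) && !is.data.frame(refs)) refs <- refs[[1]]
  if (is.null(refs) || nrow(refs) == 0) return(empty_evidence())
  refs <- refs[refs$classification %in% c("P", "LP"), , drop = FALSE]
  if (nrow(refs) == 0) return(empty_evidence())
  revel_new <- as.numeric(annotation[["revel"]])[1]
  if (is.na(revel_new)) return(empty_evidence())
  revel_ref <- suppressWarnings(as.numeric(refs$revel))
  qualifies <- !is.na(revel_ref) &
    (revel_new >= revel_ref | (revel_new >= 0.7 & revel_ref >= 0.7))
  if (any(qualifies)) {
    ref <- refs[which(qualifies)[1], , drop = FALSE]
    return(evidence_code("PM5", rationale = paste0(
      "same-residue P/LP reference ", ref$protein_change[1],
      " (REVEL ", format(ref$revel[1]), ")")))
  }
  empty_evidence()
}

dedupe_evidence <- function(evidence) {
  if (nrow(evidence) == 0) return(evidence)
  pass <- evidence[evidence$source == "passthrough", , drop = FALSE]
  dup <- pass |>
    dplyr::group_by(.data$code) |>
    dplyr::summarise(n_strength = dplyr::n_distinct(.data$strength),
                     .groups = "drop")
  if (any(dup$n_strength > 1)) {
    rlang::abort(
      paste0("conflicting passthrough strengths for: ",
             paste(dup$code[dup$n_strength > 1], collapse = ", ")),
      class = "abca4_conflicting_passthrough"
    )
  }
  evidence |>
    dplyr::mutate(.rank = strength_rank(.data$strength)) |>
    dplyr::group_by(.data$code) |>
    dplyr::arrange(dplyr::desc(.data$.rank), .data$source,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-".rank")
}

order_evidence <- function(evidence) {
  if (nrow(evidence) == 0) return(evidence)
  evidence[order(evidence$direction != "pathogenic",
                 -strength_rank(evidence$strength),
                 evidence$code), , drop = FALSE]
}

#' Assemble the full evidence set for one variant
#'
#' Computes PS3/BS3 (from the F-index), PP3/BP4, PM2 and PM5, merges them
#' with the variant's passthrough codes, deduplicates by code keeping the
#' stronger level, and applies the intronic suppression rule: for intronic
#' and splice-region variants a functional PS3/BS3 code displaces the
#' computational PP3/BP4 code (functional or RNA evidence outranks the
#' splice predictor it already subsumes). Variants flagged hypomorphic get
#' an empty evidence set with a verdict override, since the five-tier rules
#' do not apply to partially functional alleles.
#'
#' @param annotation A one-row annotation tibble.
#' @param findex Optional one-row F-index result (or numeric F) for the
#'   variant; when `NULL`, no functional code is computed.
#' @param cfg A [rule_config()].
#' @return An evidence tibble in canonical order (pathogenic codes by
#'   descending strength, then benign), with attributes `verdict_override`
#'   (`"hypomorphic"` or NULL) and `notes` (character log of suppressions).
#' @export
collect_evidence <- function(annotation, findex = NULL,
                             cfg = rule_config()) {
  if (isTRUE(as.logical(annotation[["hypomorphic_flag"]])[1])) {
    out <- empty_evidence()
    attr(out, "verdict_override") <- "hypomorphic"
    attr(out, "notes") <- "hypomorphic allele: five-tier rules not applied"
    return(out)
  }
  computed <- dplyr::bind_rows(
    if (!is.null(findex)) assign_functional(findex, cfg) else
      empty_evidence(),
    assign_computational(annotation, cfg),
    assign_pm2(annotation, cfg),
    assign_pm5(annotation)
  )
  pass <- annotation[["passthrough"]]
  if (is.list(pass) && !is.data.frame(pass)) pass <- pass[[1]]
  if (is.null(pass)) pass <- empty_evidence()
  evidence <- dedupe_evidence(dplyr::bind_rows(computed, pass))
  notes <- character()
  consequence <- annotation[["consequence"]][1]
  if (!is.na(consequence) &&
      consequence %in% c("intronic", "splice_region") &&
      any(evidence$code %in% c("PS3", "BS3"))) {
    drop <- evidence$code %in% c("PP3", "BP4") &
      evidence$source == "computed"
    if (any(drop)) {
      notes <- paste0("computational ",
                      paste(evidence$code[drop], collapse = "/"),
                      " suppressed by functional evidence for ",
                      consequence, " variant")
      evidence <- evidence[!drop, , drop = FALSE]
    }
  }
  out <- order_evidence(evidence)
  attr(out, "verdict_override") <- NULL
  attr(out, "notes") <- notes
  out
}

#' Parse a printed subscore string into an evidence tibble
#'
#' Accepts the tabular rendering of evidence sets, e.g.
#' `"PM3_very strong, PS3, PM2_sup, PP5"`: comma-separated codes with
#' optional strength suffixes `_sup`, `_mod`, `_strong`, `_very strong`
#' (or `_very_strong`). Codes without a suffix take their canonical
#' strength. The token `Hypomorphic` yields an empty set with a verdict
#' override.
#'
#' @param text A single string.
#' @param source Source recorded on the parsed codes.
#' @return An evidence tibble (attributes as in [collect_evidence()]).
#' @export
parse_subscores <- function(text, source = "passthrough") {
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text))) {
    return(empty_evidence())
  }
  if (tolower(trimws(text)) == "hypomorphic") {
    out <- empty_evidence()
    attr(out, "verdict_override") <- "hypomorphic"
    return(out)
  }
  tokens <- trimws(strsplit(text, ",")[[1]])
  suffix_map <- c(sup = "supporting", supporting = "supporting",
                  mod = "moderate", moderate = "moderate",
                  strong = "strong",
                  `very strong` = "very_strong",
                  very_strong = "very_strong")
  rows <- lapply(tokens, function(tok) {
    m <- regmatches(tok, regexec("^([A-Z]{2,3}\\d)(?:_(.+))?$", tok))[[1]]
    if (length(m) == 0) {
      rlang::abort(paste0("cannot parse subscore token: '", tok, "'"),
                   class = "abca4_parse_error")
    }
    strength <- if (m[3] == "") NULL else {
      s <- suffix_map[[tolower(m[3])]]
      if (is.null(s)) {
        rlang::abort(paste0("unknown strength suffix in: '", tok, "'"),
                     class = "abca4_parse_error")
      }
      s
    }
    evidence_code(m[2], strength = strength, source = source)
  })
  order_evidence(dplyr::bind_rows(rows))
}

#' Render an evidence tibble in canonical subscore notation
#'
#' Pathogenic codes first (descending strength), then benign; codes applied
#' at a non-canonical strength carry a suffix (`_sup`, `_mod`, `_strong`,
#' `_very strong`).
#'
#' @param evidence An evidence tibble.
#' @return A single string (empty string for an empty set).
#' @export
format_subscores <- function(evidence) {
  if (nrow(evidence) == 0) return("")
  evidence <- order_evidence(evidence)
  suffixes <- c(supporting = "_sup", moderate = "_mod", strong = "_strong",
                very_strong = "_very strong", stand_alone = "_stand alone")
  tokens <- ifelse(
    evidence$strength == unname(CODE_DEFAULT_STRENGTH[evidence$code]),
    evidence$code,
    paste0(evidence$code, suffixes[evidence$strength])
  )
  paste(tokens, collapse = ", ")
}
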