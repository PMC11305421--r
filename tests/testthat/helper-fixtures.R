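# Small in-code builders shared across the test files.

expr_row <- function(variant, experiment, band, loading) {
  tibble::tibble(variant_id = variant, experiment_id = experiment,
                 band_intensity = band, loading_control_intensity = loading)
}

atp_row <- function(variant, experiment, basal, stim, bg, amount = 1) {
  tibble::tibble(variant_id = variant, experiment_id = experiment,
                 lum_basal = basal, lum_stimulated = stim,
                 lum_background = bg, amount_scale = amount)
}

make_summary <- function(variant_id, expr, basal, stim,
                         expr_sd = 0, basal_sd = 0, stim_sd = 0, n = 3L) {
  tibble::tibble(
    variant_id = variant_id,
    rel_expression_mean = expr, rel_expression_sd = expr_sd,
    rel_basal_mean = basal, rel_basal_sd = basal_sd,
    rel_stimulated_mean = stim, rel_stimulated_sd = stim_sd,
    n_replicates = n
  )
}

make_annotation <- function(variant_id = "v1", consequence = "missense",
                            revel = NA, spliceai = NA, aux = FALSE,
                            af = NA, hom = NA, reported = TRUE,
                            hypomorphic = FALSE,
                            clinvar = tibble::tibble(),
                            passthrough = "") {
  tibble::tibble(
    variant_id = variant_id,
    cdna = NA_character_, protein = NA_character_,
    consequence = consequence,
    revel = as.numeric(revel),
    spliceai_max_delta = as.numeric(spliceai),
    aux_splice_novel_site = aux,
    gnomad_af = as.numeric(af),
    gnomad_homozygotes = as.integer(hom),
    reported_in_patient = reported,
    hypomorphic_flag = hypomorphic,
    localization = NA_character_,
    clinvar_same_residue = list(clinvar),
    passthrough = list(parse_passthrough(passthrough))
  )
}

clinvar_row <- function(protein_change, classification, revel) {
  tibble::tibble(protein_change = protein_change,
                 classification = classification,
                 reported_in_abca4rd_patient = TRUE, revel = revel)
}

# Raw evidence rows from strength counts; codes are synthetic so no
# code-specific rule (like the PM2 drop) can fire by accident.
evidence_from_counts <- function(direction, very_strong = 0, strong = 0,
                                 moderate = 0, supporting = 0,
                                 stand_alone = 0) {
  strengths <- rep(
    c("stand_alone", "very_strong", "strong", "moderate", "supporting"),
    c(stand_alone, very_strong, strong, moderate, supporting)
  )
  tibble::tibble(
    code = paste0(if (direction == "pathogenic") "PX" else "BX",
                  seq_along(strengths)),
    direction = direction, strength = strengths,
    source = "computed", rationale = ""
  )
}

# Independent transcription of the categorical combining tables: a verdict
# qualifies when the strength counts dominate any of its listed minimal
# patterns (very_strong, strong, moderate, supporting).
oracle_pathogenic_side <- function(vs, s, m, p) {
  dominated <- function(req) {
    vs >= req[1] && s >= req[2] && m >= req[3] && p >= req[4]
  }
  path_patterns <- list(c(1, 1, 0, 0), c(1, 0, 2, 0), c(1, 0, 1, 1),
                        c(1, 0, 0, 2), c(0, 2, 0, 0), c(0, 1, 3, 0),
                        c(0, 1, 2, 2), c(0, 1, 1, 4))
  lp_patterns <- list(c(1, 0, 1, 0), c(0, 1, 1, 0), c(0, 1, 0, 2),
                      c(0, 0, 3, 0), c(0, 0, 2, 2), c(0, 0, 1, 4))
  if (any(vapply(path_patterns, dominated, logical(1)))) return("pathogenic")
  if (any(vapply(lp_patterns, dominated, logical(1)))) {
    return("likely_pathogenic")
  }
  "vus"
}

oracle_benign_side <- function(sa, s, p) {
  if (sa >= 1 || s >= 2) return("benign")
  if ((s >= 1 && p >= 1) || p >= 2) return("likely_benign")
  "vus"
}

# All strength-count multisets of at most `max_n` pathogenic codes.
pathogenic_multisets <- function(max_n = 6) {
  grid <- expand.grid(vs = 0:max_n, s = 0:max_n, m = 0:max_n, p = 0:max_n)
  grid[rowSums(grid) >= 1 & rowSums(grid) <= max_n, , drop = FALSE]
}
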