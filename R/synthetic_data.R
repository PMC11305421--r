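# Synthetic replicate generator and bundled case-study fixtures.
#
# The generator emulates the measurement structure the assay pipeline
# assumes: positive densitometry and luminescence intensities with
# multiplicative (lognormal, mean-preserving) noise, a per-experiment plate
# background added to every luminescence well and measured in a separate
# 0-hour reading, and per-experiment wild-type references. At zero noise the
# pipeline inverts the generator exactly.

# Mean-preserving lognormal draws; a zero mean stays exactly zero and
# cv = 0 degenerates to the mean itself.
rln <- function(mean, cv) {
  n <- length(mean)
  if (cv <= 0) return(mean)
  s2 <- log(1 + cv^2)
  out <- numeric(n)
  pos <- mean > 0
  out[pos] <- stats::rlnorm(sum(pos), meanlog = log(mean[pos]) - s2 / 2,
                            sdlog = sqrt(s2))
  out
}

#' Simulation specification for synthetic assay replicates
#'
#' @param variants Tibble with `variant_id`, `true_E` (relative expression,
#'   fraction of WT), `true_S` (relative substrate-stimulated activity) and
#'   optionally `true_B` (relative basal activity, default 1). The id `"WT"`
#'   is reserved for the generated wild-type reference.
#' @param n_replicates Number of independent experiments (>= 1).
#' @param cv_expression Coefficient of variation of densitometry
#'   intensities.
#' @param cv_luminescence Coefficient of variation of luminescence readings.
#' @param wt_band,wt_loading Wild-type band and loading-control intensity
#'   scales (arbitrary densitometry units).
#' @param wt_basal_lum Wild-type basal activity scale (luminescence units).
#' @param wt_fold_stimulation Fold increase of wild-type activity under
#'   substrate stimulation; the default 1.71 matches the case-study data.
#' @param background_mean Mean plate background (0-hour ATP reaction).
#' @param seed Integer seed fixing the whole random stream.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(variants, n_replicates = 3,
                            cv_expression = 0.1, cv_luminescence = 0.1,
                            wt_band = 1000, wt_loading = 500,
                            wt_basal_lum = 1000,
                            wt_fold_stimulation = 1.71,
                            background_mean = 100, seed = 1L) {
  variants <- tibble::as_tibble(variants)
  stopifnot(all(c("variant_id", "true_E", "true_S") %in% names(variants)))
  if (!"true_B" %in% names(variants)) variants$true_B <- 1
  variants$true_B[is.na(variants$true_B)] <- 1
  if ("WT" %in% variants$variant_id) {
    rlang::abort("the id 'WT' is reserved for the generated reference",
                 class = "abca4_bad_config")
  }
  if (n_replicates < 1 || cv_expression < 0 || cv_luminescence < 0 ||
      wt_basal_lum <= 0 || background_mean < 0) {
    rlang::abort("invalid simulation parameters", class = "abca4_bad_config")
  }
  structure(
    list(variants = variants, n_replicates = as.integer(n_replicates),
         cv_expression = cv_expression, cv_luminescence = cv_luminescence,
         wt_band = wt_band, wt_loading = wt_loading,
         wt_basal_lum = wt_basal_lum,
         wt_fold_stimulation = wt_fold_stimulation,
         background_mean = background_mean, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Generate synthetic expression and ATPase replicate tables
#'
#' Per experiment: each sample's band and loading intensities are drawn
#' lognormally at `cv_expression`, the variant band around
#' `true_E * wt_band`; a plate background is drawn, added to every
#' luminescence reading and measured in a separate noisy 0-hour reading;
#' basal activities are drawn around `true_B * wt_basal_lum`, the wild-type
#' stimulated activity is the drawn wild-type basal times
#' `wt_fold_stimulation`, and each variant's stimulated activity is set so
#' that the within-experiment S equals `true_S` before measurement noise,
#' which then multiplies the stimulated reading. The draw order is fixed,
#' so a given spec (including its seed) reproduces byte-identical tables,
#' and at zero noise the assay pipeline recovers (`true_E`, `true_S`,
#' `true_E * true_S`) exactly.
#'
#' @param spec A [simulation_spec()].
#' @return List with tibbles `expression` and `atpase` in the raw replicate
#'   formats consumed by [normalize_expression()] and [relative_atpase()].
#' @export
simulate_assays <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  true_E <- c(1, spec$variants$true_E)
  true_S <- c(1, spec$variants$true_S)
  true_B <- c(1, spec$variants$true_B)
  ids <- c("WT", spec$variants$variant_id)
  ns <- length(ids)
  ne <- spec$n_replicates
  idx_e <- rep(seq_len(ne), each = ns)
  idx_s <- rep(seq_len(ns), times = ne)
  exp_id <- sprintf("E%d", idx_e)
  bg <- rln(rep(spec$background_mean, ne), spec$cv_luminescence)
  band <- rln(true_E[idx_s] * spec$wt_band, spec$cv_expression)
  loading <- rln(rep(spec$wt_loading, ns * ne), spec$cv_expression)
  act_basal <- rln(true_B[idx_s] * spec$wt_basal_lum, spec$cv_luminescence)
  wt_basal <- act_basal[idx_s == 1]
  window <- wt_basal[idx_e] * (spec$wt_fold_stimulation - 1)
  stim_target <- ifelse(
    idx_s == 1,
    act_basal * spec$wt_fold_stimulation,
    act_basal + true_S[idx_s] * window
  )
  act_stim <- stim_target * rln(rep(1, ns * ne), spec$cv_luminescence)
  bg_read <- bg[idx_e] * rln(rep(1, ns * ne), spec$cv_luminescence)
  list(
    expression = tibble::tibble(
      variant_id = ids[idx_s], experiment_id = exp_id,
      band_intensity = band, loading_control_intensity = loading
    ),
    atpase = tibble::tibble(
      variant_id = ids[idx_s], experiment_id = exp_id,
      lum_basal = act_basal + bg[idx_e],
      lum_stimulated = act_stim + bg[idx_e],
      lum_background = bg_read
    )
  )
}

#' F-index recovery experiment on synthetic replicates
#'
#' Repeatedly simulates assay replicates from `spec`, runs the full
#' pipeline ([findex_per_replicate()]) and reports, per variant, the
#' fraction of simulations in which the estimated F-index lies within
#' `tolerance` of the true value `true_E * true_S`, together with
#' severity-category confusion counts. Deterministic given `spec$seed`
#' (simulation `i` uses seed `spec$seed + i - 1`).
#'
#' @param spec A [simulation_spec()].
#' @param n_sims Number of simulations (>= 1).
#' @param tolerance Absolute recovery tolerance on F.
#' @param bands Severity bands for the confusion counts.
#' @param path Optional path; when given, the report is written as TSV.
#' @return List with `report` (per-variant tibble: true F, mean/SD of the
#'   estimates, recovery fraction) and `confusion` (true vs estimated
#'   severity counts).
#' @export
recovery_experiment <- function(spec, n_sims, tolerance = 0.15,
                                bands = severity_bands(), path = NULL) {
  stopifnot(inherits(spec, "simulation_spec"), n_sims >= 1)
  true <- tibble::tibble(
    variant_id = spec$variants$variant_id,
    true_F = spec$variants$true_E * spec$variants$true_S
  )
  true$true_severity <- categorize_severity(true$true_F, bands)
  ests <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    spec_i <- spec
    spec_i$seed <- spec$seed + i - 1L
    sim <- simulate_assays(spec_i)
    fx <- findex_per_replicate(sim$expression, sim$atpase, wt_id = "WT",
                               bands = bands)
    fx <- fx[fx$variant_id != "WT", c("variant_id", "F", "severity")]
    fx$sim <- i
    ests[[i]] <- fx
  }
  est <- dplyr::bind_rows(ests) |>
    dplyr::left_join(true, by = "variant_id")
  report <- est |>
    dplyr::group_by(.data$variant_id, .data$true_F) |>
    dplyr::summarise(
      n_sims = dplyr::n(),
      mean_F = mean(.data$F),
      sd_F = sample_sd(.data$F),
      recovery_fraction = mean(abs(.data$F - .data$true_F) <= tolerance),
      .groups = "drop"
    )
  confusion <- est |>
    dplyr::count(.data$true_severity, estimated = .data$severity,
                 name = "n")
  if (!is.null(path)) readr::write_tsv(report, path, progress = FALSE)
  list(report = report, confusion = confusion)
}

# ---------------------------------------------------------------------------
# Bundled case study: ten ABCA4 missense variants characterized in HEK293T
# cells plus the other alleles of the ten carrier patients. The functional
# summary, predictor scores, externally derived evidence codes and expected
# classifications are the published tabular values; population-frequency
# fields are synthetic representative values chosen to be consistent with
# the recorded evidence decisions (the source tables print only REVEL and
# SpliceAI), as are the same-residue ClinVar reference records.

fixture_functional_summary <- function() {
  tibble::tribble(
    ~variant_id, ~cdna,
    ~rel_expression_mean, ~rel_expression_sd, ~localization,
    ~rel_basal_mean, ~rel_basal_sd,
    ~rel_stimulated_mean, ~rel_stimulated_sd,
    ~f_index, ~predicted_severity,
    "WT", NA, 100, NA, "Vesicles", 100, NA, 171, 14, 1.00, "Normal",
    "Tyr106Phe", "c.317A>T", 111, 10, "Vesicles", 95, 10, 153, 14,
      0.94, "Normal/mild",
    "Gly172Ser", "c.514G>A", 113, 6, "Vesicles", 100, 4, 183, 13,
      1.35, "Normal/mild",
    "Cys205Phe", "c.614G>T", 50, 11, "ER/Vesicles", 41, 10, 42, 1,
      0.00, "Severe",
    "Asn415Thr", "c.1244A>C", 72, 11, "Vesicles", 58, 9, 56, 10,
      -0.02, "Severe",
    "Val643Gly", "c.1928T>G", 121, 12, "Vesicles", 83, 6, 115, 15,
      0.48, "Moderate",
    "Pro799Leu", "c.2396C>T", 43, 5, "ER/small vesicles", 70, 13, 99, 16,
      0.17, "Moderate",
    "Pro940Arg", "c.2819C>G", 100, 18, "Vesicles", 100, 7, 170, 20,
      1.01, "Normal/mild",
    "Lys1164Arg", "c.3491A>G", 115, 23, "Vesicles", 93, 4, 155, 30,
      0.90, "Normal/mild",
    "Val1433Ile", "c.4297G>A", 86, 12, "Vesicles", 76, 17, 112, 28,
      0.41, "Moderate",
    "Val2050Leu", "c.6148G>C", 107, 13, "Vesicles", 98, 10, 157, 3,
      0.92, "Normal/mild"
  )
}

fixture_classification_expected <- function() {
  tibble::tribble(
    ~patient_id, ~variant_id, ~cdna, ~protein, ~study_variant,
    ~revel, ~spliceai, ~subscores, ~classification,
    "P1, P2", "Tyr106Phe", "c.317A>T", "p.(Tyr106Phe)", TRUE,
      0.261, 0.01, "BS3_sup, BP4, PM2_sup", "Likely benign",
    "P1, P2", "Arg290Trp", "c.868C>T", "p.(Arg290Trp)", FALSE,
      0.525, 0.06, "PM3_very strong, PM5, PM2_sup", "Pathogenic",
    "P1, P2", "Thr959Ala", "c.2875A>G", "p.(Thr959Ala)", FALSE,
      0.962, 0.00, "PM3, PM5, PM2_sup, PP3", "Likely pathogenic",
    "P3", "Gly172Ser", "c.514G>A", "p.(Gly172Ser)", TRUE,
      0.496, 0.03, "PM3_strong, PM2_sup, BS3_sup, BP2, BP5", "VUS",
    "P3", "Val2050Leu", "c.6148G>C", "p.(Val2050Leu)", TRUE,
      0.795, 0.01, "BS3_sup, BP2, BP5, PP3", "Likely benign",
    "P4", "Cys205Phe", "c.614G>T", "p.(Cys205Phe)", TRUE,
      0.967, 0.00, "PS3, PM2_sup, PM3, PM5, PP3, PP5", "Pathogenic",
    "P4", "Gly1961Glu", "c.5882G>A", "p.(Gly1961Glu)", FALSE,
      0.76, 0.01, "PM3_very strong, PM5, PP3, PP5", "Pathogenic",
    "P4", "c.3523-9C>G", "c.3523-9C>G", NA, FALSE,
      NA, 0.02, "PM2_sup, BP2, BP4", "Likely benign",
    "P5", "Asn415Thr", "c.1244A>C", "p.(Asn415Thr)", TRUE,
      0.817, 0.00, "PS3, PM2_sup, PM3_sup, PP3", "Likely pathogenic",
    "P5", "c.5461-10T>C", "c.5461-10T>C", "p.Thr1821Aspfs*6", FALSE,
      NA, 0.07, "PM3_very strong, PS3, PM2_sup, PP5", "Pathogenic",
    "P5", "Asn1868Ile", "c.5603A>T", "p.(Asn1868Ile)", FALSE,
      0.402, 0.00, "Hypomorphic", "NA",
    "P6", "Val643Gly", "c.1928T>G", "p.(Val643Gly)", TRUE,
      0.944, 0.01, "PS3, PP3", "VUS",
    "P6", "Cys2150Tyr", "c.6449G>A", "p.(Cys2150Tyr)", FALSE,
      0.923, 0.02, "PM3_very strong, PM2_sup, PP3, PP5", "Pathogenic",
    "P7", "Pro799Leu", "c.2396C>T", "p.(Pro799Leu)", TRUE,
      0.542, 0.01, "PS3, PM2_sup, PM3_sup", "Likely pathogenic",
    "P7", "Leu1580Ter", "c.4734del", "p.(Leu1580*)", FALSE,
      NA, 0.01, "PVS1, PM3, PM2_sup", "Pathogenic",
    "P8", "Pro940Arg", "c.2819C>G", "p.(Pro940Arg)", TRUE,
      0.273, 0.00, "PM2_sup, BS3_sup, BP4, BP2", "Likely benign",
    "P8", "Glu1122Lys", "c.3364G>A", "p.(Glu1122Lys)", FALSE,
      0.939, 0.02, "PM3_very strong, PM2_sup, PP3, PP5", "Pathogenic",
    "P8", "c.161-23T>G", "c.161-23T>G", "p.(Cys54=, Cys54Serfs*14)", FALSE,
      NA, 0.02, "PM3_strong, PS3_mod, PM2_sup", "Likely pathogenic",
    "P9", "Lys1164Arg", "c.3491A>G", "p.(Lys1164Arg)", TRUE,
      0.199, 0.01, "PM2_sup, BS3_sup, BP4", "Likely benign",
    "P9", "c.769-784C>T", "c.769-784C>T", "p.(Leu257=, Leu257Aspfs*3)",
      FALSE, NA, 0.08, "PM2_sup, PS3_sup, PM3_strong, BP2", "VUS",
    "P9", "c.4540-2077C>T", "c.4540-2077C>T", NA, FALSE,
      NA, 0.00, "PM2_sup", "VUS",
    "P10", "Val1433Ile", "c.4297G>A", "p.(Val1433Ile)", TRUE,
      0.605, 0.10, "PS3", "VUS",
    "P10", "c.3607+771G>A", "c.3607+771G>A", NA, FALSE,
      NA, 0.00, "PM2_sup, BP4", "VUS"
  )
}

clinvar_ref <- function(protein_change, classification, revel) {
  tibble::tibble(protein_change = protein_change,
                 classification = classification,
                 reported_in_abca4rd_patient = TRUE,
                 revel = revel)
}

fixture_annotations <- function() {
  t4 <- fixture_classification_expected()
  rare_af <- 2e-5
  # gnomAD fields: synthetic representative values; the four alleles known
  # to be too common for PM2 get frequencies above the PM2 ceiling.
  common <- c(Val643Gly = 0.002, Val1433Ile = 0.003, Val2050Leu = 0.012,
              Gly1961Glu = 0.004, Asn1868Ile = 0.04)
  common_hom <- c(Val643Gly = 6L, Val1433Ile = 9L, Val2050Leu = 60L,
                  Gly1961Glu = 25L, Asn1868Ile = 400L)
  clinvar <- list(
    Arg290Trp = clinvar_ref("Arg290Gln", "P", 0.50),
    Thr959Ala = clinvar_ref("Thr959Ile", "LP", 0.90),
    Cys205Phe = clinvar_ref("Cys205Arg", "P", 0.90),
    Gly1961Glu = clinvar_ref("Gly1961Arg", "P", 0.85)
  )
  passthrough <- c(
    Tyr106Phe = "",
    Arg290Trp = "PM3:very_strong",
    Thr959Ala = "PM3:moderate",
    Gly172Ser = "PM3:strong;BP2:supporting;BP5:supporting",
    Val2050Leu = "BP2:supporting;BP5:supporting",
    Cys205Phe = "PM3:moderate;PP5:supporting",
    Gly1961Glu = "PM3:very_strong;PP5:supporting",
    `c.3523-9C>G` = "BP2:supporting",
    Asn415Thr = "PM3:supporting",
    `c.5461-10T>C` = "PM3:very_strong;PS3:strong;PP5:supporting",
    Asn1868Ile = "",
    Val643Gly = "",
    Cys2150Tyr = "PM3:very_strong;PP5:supporting",
    Pro799Leu = "PM3:supporting",
    Leu1580Ter = "PVS1:very_strong;PM3:moderate",
    Pro940Arg = "BP2:supporting",
    Glu1122Lys = "PM3:very_strong;PP5:supporting",
    `c.161-23T>G` = "PM3:strong;PS3:moderate",
    Lys1164Arg = "",
    `c.769-784C>T` = "PS3:supporting;PM3:strong;BP2:supporting",
    `c.4540-2077C>T` = "",
    Val1433Ile = "",
    `c.3607+771G>A` = ""
  )
  loc_map <- c(Vesicles = "vesicles", `ER/Vesicles` = "mixed",
               `ER/small vesicles` = "er")
  t3 <- fixture_functional_summary()
  ann <- tibble::tibble(
    variant_id = t4$variant_id,
    cdna = t4$cdna,
    protein = t4$protein,
    revel = t4$revel,
    spliceai_max_delta = t4$spliceai,
    aux_splice_novel_site = t4$variant_id == "c.4540-2077C>T",
    gnomad_af = ifelse(t4$variant_id %in% names(common),
                       common[t4$variant_id], rare_af),
    gnomad_homozygotes = ifelse(t4$variant_id %in% names(common_hom),
                                common_hom[t4$variant_id], 0L),
    reported_in_patient = TRUE,
    hypomorphic_flag = t4$variant_id == "Asn1868Ile",
    localization = unname(loc_map[
      t3$localization[match(t4$variant_id, t3$variant_id)]]),
    clinvar_same_residue = lapply(t4$variant_id, function(v) {
      if (v %in% names(clinvar)) clinvar[[v]] else tibble::tibble()
    }),
    passthrough = lapply(unname(passthrough[t4$variant_id]),
                         parse_passthrough)
  )
  annotate_consequences(ann)
}

fixture_genotypes <- function() {
  tibble::tribble(
    ~patient_id, ~allele, ~variant_id, ~origin, ~stage,
    ~age_at_presentation, ~disease_duration,
    "P1", 1L, "Tyr106Phe", NA, "I", 16, 14,
    "P1", 2L, "Arg290Trp", NA, "I", 16, 14,
    "P1", 3L, "Thr959Ala", NA, "I", 16, 14,
    "P2", 1L, "Tyr106Phe", NA, "I", 16, 14,
    "P2", 2L, "Arg290Trp", NA, "I", 16, 14,
    "P2", 3L, "Thr959Ala", NA, "I", 16, 14,
    "P3", 1L, "Gly172Ser", "maternal", NA, 31, NA,
    "P3", 2L, "Val2050Leu", "paternal", NA, 31, NA,
    "P4", 1L, "Cys205Phe", NA, "I", 36, 25,
    "P4", 2L, "Gly1961Glu", NA, "I", 36, 25,
    "P4", 3L, "c.3523-9C>G", NA, "I", 36, 25,
    "P5", 1L, "Asn415Thr", NA, "IIIC", 6, 43,
    "P5", 2L, "c.5461-10T>C", NA, "IIIC", 6, 43,
    "P5", 3L, "Asn1868Ile", NA, "IIIC", 6, 43,
    "P6", 1L, "Val643Gly", NA, "II", 60, 2,
    "P6", 2L, "Cys2150Tyr", NA, "II", 60, 2,
    "P7", 1L, "Pro799Leu", NA, "IIIA", 46, 5,
    "P7", 2L, "Leu1580Ter", NA, "IIIA", 46, 5,
    "P8", 1L, "Pro940Arg", "maternal", "IIIB", 10, 38,
    "P8", 2L, "Glu1122Lys", "maternal", "IIIB", 10, 38,
    "P8", 3L, "c.161-23T>G", "paternal", "IIIB", 10, 38,
    "P9", 1L, "Lys1164Arg", "maternal", "IIIB", 19, 38,
    "P9", 2L, "c.769-784C>T", "maternal", "IIIB", 19, 38,
    "P9", 3L, "c.4540-2077C>T", "paternal", "IIIB", 19, 38,
    "P10", 1L, "Val1433Ile", NA, NA, 60, NA,
    "P10", 2L, "c.3607+771G>A", NA, NA, 60, NA
  )
}

#' Bundled case-study fixture tables
#'
#' Returns the in-package fixtures for the ten-variant ABCA4 case study:
#' `functional_summary` (relative expression, localization,
#' basal/stimulated ATPase activities, printed F-index and severity),
#' `classification_expected` (per-allele REVEL, SpliceAI, evidence
#' subscores and expected five-tier classification for all 23 alleles
#' carried by the ten patients), `annotations` (the machine-readable
#' annotation table feeding the rule engine; gnomAD and ClinVar reference
#' fields are synthetic representative values consistent with the recorded
#' decisions), `genotypes` (per-patient alleles with stage and age at
#' presentation) and `findex` (F-index results built from the published
#' F-index column of `functional_summary`).
#'
#' @return Named list of tibbles.
#' @export
make_fixture_tables <- function() {
  t3 <- fixture_functional_summary()
  findex <- tibble::tibble(
    variant_id = t3$variant_id,
    F = t3$f_index,
    severity = categorize_severity(t3$f_index),
    method = "from_means"
  )
  list(functional_summary = t3, classification_expected = fixture_classification_expected(),
       annotations = fixture_annotations(),
       genotypes = fixture_genotypes(), findex = findex)
}

#' Write the bundled fixtures as TSV files
#'
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture_tables <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- make_fixture_tables()
  readr::write_tsv(fx$functional_summary, file.path(dir, "functional_summary.tsv"),
                   na = ".", progress = FALSE)
  readr::write_tsv(fx$classification_expected, file.path(dir, "classification_expected.tsv"),
                   na = ".", progress = FALSE)
  write_annotation_tsv(fx$annotations, file.path(dir, "annotations.tsv"))
  readr::write_tsv(fx$genotypes, file.path(dir, "genotypes.tsv"),
                   na = ".", progress = FALSE)
  invisible(dir)
}
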