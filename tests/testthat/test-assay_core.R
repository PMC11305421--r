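test_that("expression is normalized to the within-experiment WT lane", {
  reps <- dplyr::bind_rows(
    expr_row("var", "E1", 50, 10),
    expr_row("WT", "E1", 100, 10),
    expr_row("var2", "E1", 60, 12),
    expr_row("WT", "E2", 80, 16),
    expr_row("var2", "E2", 60, 12)
  )
  out <- normalize_expression(reps)
  get <- function(v, e) {
    out$rel_expression[out$variant_id == v & out$experiment_id == e]
  }
  expect_equal(get("var", "E1"), 50)
  expect_equal(get("WT", "E1"), 100)   # WT against itself
  expect_equal(get("WT", "E2"), 100)
  # ratio-of-ratios: (60/12) / (80/16) = 1
  expect_equal(get("var2", "E2"), 100)
})

test_that("expression normalization rejects bad references with named errors", {
  no_wt <- dplyr::bind_rows(expr_row("var", "E1", 50, 10),
                            expr_row("WT", "E2", 50, 10),
                            expr_row("var", "E2", 25, 10))
  expect_error(normalize_expression(no_wt), class = "abca4_missing_wt")
  zero_wt <- dplyr::bind_rows(expr_row("var", "E1", 50, 10),
                              expr_row("WT", "E1", 0, 10))
  expect_error(normalize_expression(zero_wt), class = "abca4_zero_wt")
  expect_error(
    normalize_expression(expr_row("WT", "E1", 10, 0)),
    class = "abca4_bad_input"
  )
})

test_that("expression normalization is invariant to per-experiment rescaling", {
  set.seed(11)
  for (i in 1:20) {
    reps <- dplyr::bind_rows(
      expr_row("WT", "E1", runif(1, 10, 100), runif(1, 10, 100)),
      expr_row("a", "E1", runif(1, 10, 100), runif(1, 10, 100)),
      expr_row("b", "E1", runif(1, 10, 100), runif(1, 10, 100))
    )
    scaled <- reps
    k <- runif(1, 0.1, 10)
    scaled$band_intensity <- scaled$band_intensity * k
    scaled$loading_control_intensity <- scaled$loading_control_intensity * k
    expect_equal(normalize_expression(scaled), normalize_expression(reps))
  }
})

test_that("ATPase activities are background-corrected and scaled to WT basal", {
  reps <- dplyr::bind_rows(
    atp_row("var", "E1", 900, 950, 100),
    atp_row("WT", "E1", 900, 1500, 100)
  )
  out <- relative_atpase(reps)
  var <- out[out$variant_id == "var", ]
  wt <- out[out$variant_id == "WT", ]
  expect_equal(var$rel_basal, 100)
  expect_equal(var$rel_stimulated, 106.25)
  expect_equal(wt$rel_basal, 100)        # WT against itself
  expect_false(any(out$negative_activity))
})

test_that("zero and negative background-corrected activities are flagged", {
  reps <- dplyr::bind_rows(
    atp_row("var", "E1", 100, 150, 100),  # basal equals background
    atp_row("neg", "E1", 80, 150, 100),   # negative basal, kept as-is
    atp_row("WT", "E1", 900, 1500, 100)
  )
  out <- relative_atpase(reps)
  expect_equal(out$rel_basal[out$variant_id == "var"], 0)
  expect_false(out$negative_activity[out$variant_id == "var"])
  expect_equal(out$rel_basal[out$variant_id == "neg"], 100 * -20 / 800)
  expect_true(out$negative_activity[out$variant_id == "neg"])
  bad_wt <- atp_row("WT", "E1", 100, 150, 100)
  expect_error(relative_atpase(bad_wt),
               class = "abca4_nonpositive_wt_activity")
})

test_that("ATPase ratios shift-invariance holds only when background shifts too", {
  reps <- dplyr::bind_rows(
    atp_row("var", "E1", 700, 1000, 90),
    atp_row("WT", "E1", 900, 1500, 110)
  )
  base <- relative_atpase(reps)
  all_shifted <- reps
  all_shifted$lum_basal <- all_shifted$lum_basal + 250
  all_shifted$lum_stimulated <- all_shifted$lum_stimulated + 250
  all_shifted$lum_background <- all_shifted$lum_background + 250
  expect_equal(relative_atpase(all_shifted), base)
  partial <- reps
  partial$lum_basal <- partial$lum_basal + 250
  partial$lum_stimulated <- partial$lum_stimulated + 250
  expect_false(isTRUE(all.equal(relative_atpase(partial), base)))
})

test_that("amount_scale divides activities before the WT ratio", {
  reps <- dplyr::bind_rows(
    atp_row("var", "E1", 1700, 2500, 100, amount = 2),
    atp_row("WT", "E1", 900, 1500, 100)
  )
  out <- relative_atpase(reps)
  expect_equal(out$rel_basal[out$variant_id == "var"], 100 * 800 / 800)
})

test_that("summaries use the arithmetic mean and n-1 sample SD", {
  vals <- tibble::tibble(
    variant_id = "v", experiment_id = c("E1", "E2", "E3"),
    rel_expression = c(111, 101, 121)
  )
  out <- summarize_assays(expression = vals)
  expect_equal(out$rel_expression_mean, 111)
  expect_equal(out$rel_expression_sd, 10)
  expect_equal(out$n_replicates, 3L)
  expect_false(out$sd_undefined)
})

test_that("a single replicate reports SD 0 with a flag and a warning", {
  vals <- tibble::tibble(variant_id = "v", experiment_id = "E1",
                         rel_expression = 50)
  expect_warning(out <- summarize_assays(expression = vals),
                 class = "abca4_few_replicates")
  expect_equal(out$rel_expression_mean, 50)
  expect_equal(out$rel_expression_sd, 0)
  expect_true(out$sd_undefined)
})

test_that("replicates constructed at mean 171 sd 14 summarize to 171 +/- 14", {
  atp <- dplyr::bind_rows(
    atp_row("WT", "E1", 1100, 100 + 1570, 100),
    atp_row("WT", "E2", 1100, 100 + 1710, 100),
    atp_row("WT", "E3", 1100, 100 + 1850, 100)
  )
  out <- summarize_assays(atpase = relative_atpase(atp))
  expect_equal(out$rel_stimulated_mean, 171)
  expect_equal(out$rel_stimulated_sd, 14)
})

test_that("summaries of identical experiments have the common value and sd 0", {
  expr <- dplyr::bind_rows(lapply(1:4, function(e) {
    dplyr::bind_rows(expr_row("WT", paste0("E", e), 100, 10),
                     expr_row("v", paste0("E", e), 55, 10))
  }))
  out <- summarize_assays(expression = normalize_expression(expr))
  row <- out[out$variant_id == "v", ]
  expect_equal(row$rel_expression_mean, 55)
  expect_equal(row$rel_expression_sd, 0)
  wt <- out[out$variant_id == "WT", ]
  expect_equal(wt$rel_expression_mean, 100)
})

test_that("assay TSV readers accept '.' as missing and validate columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "variant_id\texperiment_id\tband_intensity\tloading_control_intensity",
    "WT\tE1\t100\t10", "v\tE1\t50\t10"
  ), path)
  reps <- read_expression_tsv(path)
  expect_equal(nrow(reps), 2)
  atp_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("variant_id", "experiment_id", "lum_basal", "lum_stimulated",
          "lum_background", "amount_scale", sep = "\t"),
    "WT\tE1\t900\t1500\t100\t.", "v\tE1\t900\t950\t100\t1"
  ), atp_path)
  atp <- read_atpase_tsv(atp_path)
  expect_equal(atp$amount_scale, c(1, 1))
})
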