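test_that("worked evidence sets combine to the expected tiers", {
  verdict_of <- function(subscores) {
    combine_evidence(parse_subscores(subscores))$verdict
  }
  expect_equal(verdict_of("PS3, PM2_sup, PM3, PM5, PP3, PP5"), "pathogenic")
  expect_equal(verdict_of("PS3, PM2_sup, PM3_sup, PP3"), "likely_pathogenic")
  expect_equal(verdict_of("BS3_sup, BP4, PM2_sup"), "likely_benign")
  expect_equal(verdict_of("BS3_sup, BP2, BP5, PP3"), "likely_benign")
  expect_equal(verdict_of("PM3_strong, PM2_sup, BS3_sup, BP2, BP5"), "vus")
  expect_equal(verdict_of("PS3, PP3"), "vus")
  expect_equal(verdict_of("PM2_sup, BP4"), "vus")
  expect_equal(combine_evidence(parse_subscores(""))$verdict, "vus")
})

test_that("PM2 at supporting is dropped when it alone opposes benign evidence", {
  cls <- combine_evidence(parse_subscores("BS3_sup, BP4, PM2_sup"))
  expect_equal(cls$verdict, "likely_benign")
  expect_equal(cls$route, "categorical")
  expect_equal(cls$dropped_codes[[1]]$code, "PM2")
  # PM2 alone with no benign evidence is kept and yields VUS
  alone <- combine_evidence(parse_subscores("PM2_sup"))
  expect_equal(alone$verdict, "vus")
  expect_equal(nrow(alone$dropped_codes[[1]]), 0)
  # PM2 alongside other pathogenic evidence is never dropped
  kept <- combine_evidence(parse_subscores("PM3_strong, PM2_sup, BS3_sup"))
  expect_equal(nrow(kept$dropped_codes[[1]]), 0)
  expect_equal(kept$route, "points_conflict")
})

test_that("conflicting evidence is scored on the point scale", {
  gly172 <- combine_evidence(
    parse_subscores("PM3_strong, PM2_sup, BS3_sup, BP2, BP5"))
  expect_equal(gly172$route, "points_conflict")
  expect_equal(gly172$points, 2L)   # 4 + 1 - 1 - 1 - 1
  expect_equal(gly172$verdict, "vus")
  val2050 <- combine_evidence(parse_subscores("BS3_sup, BP2, BP5, PP3"))
  expect_equal(val2050$points, -2L)  # 1 - 3
  expect_equal(val2050$verdict, "likely_benign")
  c769 <- combine_evidence(
    parse_subscores("PM2_sup, PS3_sup, PM3_strong, BP2"))
  expect_equal(c769$points, 5L)      # 1 + 1 + 4 - 1
  expect_equal(c769$verdict, "vus")
  # band edges of the point scale
  pts <- function(path, ben) {
    combine_evidence(dplyr::bind_rows(
      evidence_from_counts("pathogenic", very_strong = path %/% 8,
                           strong = (path %% 8) %/% 4,
                           moderate = (path %% 4) %/% 2,
                           supporting = path %% 2),
      evidence_from_counts("benign", supporting = ben)))
  }
  expect_equal(pts(11, 1)$verdict, "pathogenic")        # +10
  expect_equal(pts(7, 1)$verdict, "likely_pathogenic")  # +6
  expect_equal(pts(1, 1)$verdict, "vus")                # 0
  expect_equal(pts(1, 2)$verdict, "likely_benign")      # -1
  expect_equal(pts(1, 8)$verdict, "benign")             # -7
})

test_that("a stand-alone benign code yields benign outright", {
  cls <- combine_evidence(parse_subscores("BA1, PM2_sup, PP3"))
  expect_equal(cls$verdict, "benign")
})

test_that("categorical combiner matches brute-force rule enumeration", {
  sets <- pathogenic_multisets(6)
  for (i in seq_len(nrow(sets))) {
    n <- sets[i, ]
    got <- combine_evidence(evidence_from_counts(
      "pathogenic", very_strong = n$vs, strong = n$s,
      moderate = n$m, supporting = n$p))$verdict
    want <- oracle_pathogenic_side(n$vs, n$s, n$m, n$p)
    expect_equal(got, want, info = paste(n, collapse = "/"))
  }
  ben <- expand.grid(sa = 0:1, s = 0:3, p = 0:3)
  ben <- ben[rowSums(ben) >= 1, ]
  for (i in seq_len(nrow(ben))) {
    n <- ben[i, ]
    got <- combine_evidence(evidence_from_counts(
      "benign", stand_alone = n$sa, strong = n$s,
      supporting = n$p))$verdict
    expect_equal(got, oracle_benign_side(n$sa, n$s, n$p),
                 info = paste(n, collapse = "/"))
  }
})

test_that("adding pathogenic evidence never demotes a categorical verdict", {
  rank <- c(vus = 0, likely_pathogenic = 1, pathogenic = 2)
  sets <- pathogenic_multisets(5)
  strengths <- c("very_strong", "strong", "moderate", "supporting")
  for (i in seq_len(nrow(sets))) {
    n <- sets[i, ]
    base <- combine_evidence(evidence_from_counts(
      "pathogenic", very_strong = n$vs, strong = n$s,
      moderate = n$m, supporting = n$p))$verdict
    for (add in strengths) {
      counts <- c(vs = n$vs, s = n$s, m = n$m, p = n$p)
      counts[match(add, strengths)] <- counts[match(add, strengths)] + 1
      more <- combine_evidence(evidence_from_counts(
        "pathogenic", very_strong = counts["vs"], strong = counts["s"],
        moderate = counts["m"], supporting = counts["p"]))$verdict
      expect_gte(rank[more], rank[base])
    }
  }
})

test_that("points route is monotone in added evidence", {
  set.seed(101)
  for (i in 1:50) {
    path <- evidence_from_counts("pathogenic",
                                 strong = sample(0:2, 1),
                                 moderate = sample(0:2, 1),
                                 supporting = sample(1:3, 1))
    ben <- evidence_from_counts("benign", strong = sample(0:1, 1),
                                supporting = sample(1:3, 1))
    base <- combine_evidence(dplyr::bind_rows(path, ben))
    extra_p <- evidence_from_counts("pathogenic", moderate = 1)
    extra_p$code <- "PZ99"
    more_path <- combine_evidence(dplyr::bind_rows(path, ben, extra_p))
    expect_gte(more_path$points, base$points)
    extra_b <- evidence_from_counts("benign", supporting = 1)
    extra_b$code <- "BZ99"
    more_ben <- combine_evidence(dplyr::bind_rows(path, ben, extra_b))
    expect_lte(more_ben$points, base$points)
  }
})

test_that("evidence order never changes the verdict", {
  set.seed(7)
  sets <- list(
    parse_subscores("PS3, PM2_sup, PM3, PM5, PP3, PP5"),
    parse_subscores("PM3_strong, PM2_sup, BS3_sup, BP2, BP5"),
    parse_subscores("BS3_sup, BP4, PM2_sup")
  )
  for (ev in sets) {
    base <- combine_evidence(ev)$verdict
    for (k in 1:5) {
      shuffled <- ev[sample(nrow(ev)), ]
      expect_equal(combine_evidence(shuffled)$verdict, base)
    }
  }
})

test_that("purely benign evidence never classifies pathogenic and vice versa", {
  for (p in 1:4) {
    ben_only <- combine_evidence(
      evidence_from_counts("benign", strong = p %% 3, supporting = p))
    expect_false(ben_only$verdict %in% c("pathogenic",
                                         "likely_pathogenic"))
    path_only <- combine_evidence(
      evidence_from_counts("pathogenic", strong = p %% 3, supporting = p))
    expect_false(path_only$verdict %in% c("benign", "likely_benign"))
  }
})

test_that("classify_batch preserves order and isolates per-row failures", {
  sets <- list(a = parse_subscores("PS3, PM3, PM2_sup"),
               b = parse_subscores(""),
               c = parse_subscores("BS3_sup, BP4"))
  out <- classify_batch(sets)
  expect_equal(out$variant_id, c("a", "b", "c"))
  expect_equal(out$verdict, c("likely_pathogenic", "vus", "likely_benign"))
  shuffled <- classify_batch(sets[c(3, 1, 2)])
  expect_equal(shuffled$verdict, out$verdict[c(3, 1, 2)])
})
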