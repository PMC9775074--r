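# Timed-score inversion, z-composites, diagnostic classification and
# marker transforms.

test_that("timed scores are negated, other tests untouched", {
  co <- tiny_cohort()
  inv <- invert_timed_scores(co)
  expect_equal(inv$tmt_a_inv, -co$tmt_a)
  expect_equal(inv$scwt_c_inv, -co$scwt_c)
  expect_equal(inv$bnt, co$bnt)
  # order reversal: the slower subject ranks lower on the inverted scale
  expect_equal(order(inv$tmt_a_inv), rev(order(co$tmt_a)))

  rec <- invert_timed_scores(co, mode = "reciprocal")
  expect_equal(rec$tmt_a_inv, 1 / co$tmt_a)

  co$tmt_b[2] <- 0
  expect_error(invert_timed_scores(co), "non-positive.*tmt_b")
})

test_that("whole-sample z-transform standardizes and composites average", {
  co <- score_cohort(tiny_cohort())
  for (nm in c("z_wms_vr_dr", "z_bnt", "z_tmt_a_inv", "z_cdt")) {
    expect_equal(mean(co[[nm]]), 0, tolerance = 1e-12)
    expect_equal(sd(co[[nm]]), 1, tolerance = 1e-12)
  }
  # hand-computed composite for the first subject
  z1 <- (co$wms_vr_dr[1] - mean(co$wms_vr_dr)) / sd(co$wms_vr_dr)
  z2 <- (co$avlt_dr[1] - mean(co$avlt_dr)) / sd(co$avlt_dr)
  expect_equal(co$z_episodic_memory[1], (z1 + z2) / 2, tolerance = 1e-12)
  zb <- (co$bnt - mean(co$bnt)) / sd(co$bnt)
  zc <- (co$cvf - mean(co$cvf)) / sd(co$cvf)
  expect_equal(co$z_language, (zb + zc) / 2, tolerance = 1e-12)
})

test_that("z-transform is idempotent and honors the NC reference", {
  co <- score_cohort(tiny_cohort())
  z <- co$z_bnt
  expect_equal((z - mean(z)) / sd(z), z, tolerance = 1e-12)

  co2 <- rbind(tiny_cohort(), tiny_cohort())
  tests <- setdiff(names(co2), c("id", "group"))
  co2[5:8, tests] <- co2[5:8, tests] + 0.5  # break exact duplication
  nc_ref <- score_cohort(co2, reference = "nc_group")
  # standardizing against the NC subset centers the NC rows at zero
  nc_rows <- nc_ref$group == "NC"
  expect_equal(mean(nc_ref$z_bnt[nc_rows]), 0, tolerance = 1e-12)
  expect_equal(sd(nc_ref$z_bnt[nc_rows]), 1, tolerance = 1e-12)
})

test_that("missing constituents propagate to the composite", {
  co <- tiny_cohort()
  co$avlt_dr[2] <- NA
  sc <- score_cohort(co)
  expect_true(is.na(sc$z_episodic_memory[2]))
  expect_false(anyNA(sc$z_language))
})

test_that("zero reference variance names the offending test", {
  co <- tiny_cohort()
  co$cdt <- rep(20, 4)
  expect_error(score_cohort(co), "zero variance.*cdt")
})

test_that("worked classification cases follow the education-adjusted rules", {
  rec <- function(mmse, moca, cdr, adl, education, csvd = TRUE)
    data.frame(mmse = mmse, moca = moca, cdr = cdr, adl = adl,
               education = education, csvd = csvd)
  # dementia: MMSE 19 <= 24 (8 years of education) with CDR 1
  expect_equal(as.character(classify_cognition(rec(19, 15, 1, 10, 8))),
               "CSVD-VaD")
  # normal cognition: MMSE 29 > 24, MoCA 26 > 24, CDR 0, ADL 8
  expect_equal(as.character(classify_cognition(rec(29, 26, 0, 8, 10))),
               "CSVD-non-CI")
  expect_equal(as.character(classify_cognition(rec(29, 26, 0, 8, 10,
                                                   csvd = FALSE))), "NC")
  # MCI: MMSE 28 > 24, MoCA 20 <= 24, CDR 0.5, ADL 8
  expect_equal(as.character(classify_cognition(rec(28, 20, 0.5, 8, 10))),
               "CSVD-MCI")
  # illiteracy bracket: MMSE 17 is dementia, 18 is not
  expect_equal(as.character(classify_cognition(rec(17, 10, 1, 9, 0))),
               "CSVD-VaD")
  expect_equal(as.character(classify_cognition(rec(18, 13, 0.5, 8, 0))),
               "CSVD-MCI")  # MoCA 13 <= 13
  # 1-6 year bracket cutoffs 20 / 19
  expect_equal(as.character(classify_cognition(rec(20, 12, 1, 9, 4))),
               "CSVD-VaD")
  expect_equal(as.character(classify_cognition(rec(21, 19, 0.5, 8, 4))),
               "CSVD-MCI")
  expect_equal(as.character(classify_cognition(rec(21, 20, 0, 8, 4))),
               "CSVD-non-CI")
  # failing the CDR/ADL constraints is unclassifiable, not coerced
  expect_equal(as.character(classify_cognition(rec(28, 20, 0, 8, 10))),
               "unclassifiable")
  expect_equal(as.character(classify_cognition(rec(28, 20, 0.5, 9, 10))),
               "unclassifiable")
  # dementia-range MMSE without CDR >= 1 is unclassifiable
  expect_equal(as.character(classify_cognition(rec(19, 15, 0.5, 8, 8))),
               "unclassifiable")
  # cognitively impaired without CSVD has no study group
  expect_equal(as.character(classify_cognition(rec(28, 20, 0.5, 8, 10,
                                                   csvd = FALSE))),
               "unclassifiable")
})

test_that("classification is a partition over a boundary grid", {
  grid <- expand.grid(mmse = c(16, 17, 18, 20, 21, 24, 25, 30),
                      moca = c(12, 13, 14, 19, 20, 24, 25, 30),
                      cdr = c(0, 0.5, 1, 2), adl = c(8, 9),
                      education = c(0, 1, 6, 7, 12, 16),
                      csvd = c(TRUE, FALSE))
  lab <- classify_cognition(grid)
  expect_false(anyNA(lab))
  expect_equal(length(lab), nrow(grid))
  # re-deriving the rules independently for every grid point
  mc <- ifelse(grid$education < 1, 17, ifelse(grid$education <= 6, 20, 24))
  oc <- ifelse(grid$education < 1, 13, ifelse(grid$education <= 6, 19, 24))
  expected <- rep("unclassifiable", nrow(grid))
  expected[grid$mmse <= mc & grid$cdr >= 1 & grid$csvd] <- "CSVD-VaD"
  expected[grid$mmse > mc & grid$moca <= oc & grid$cdr == 0.5 &
             grid$adl == 8 & grid$csvd] <- "CSVD-MCI"
  normal <- grid$mmse > mc & grid$moca > oc & grid$cdr == 0 & grid$adl == 8
  expected[normal & grid$csvd] <- "CSVD-non-CI"
  expected[normal & !grid$csvd] <- "NC"
  expect_equal(as.character(lab), expected)
})

test_that("missing classification inputs are reported by name", {
  d <- data.frame(mmse = 25, moca = 22, cdr = 0.5, adl = 8, education = 10)
  expect_error(classify_cognition(d), "csvd")
  d2 <- data.frame(mmse = 25, moca = NA, cdr = 0.5, adl = 8,
                   education = 10, csvd = TRUE)
  expect_error(classify_cognition(d2), "moca")
})

test_that("marker transforms use log10(x + 1) and 0/1 EPVS coding", {
  co <- data.frame(wmh_volume = c(9, 0, 99), li_count = c(0, 3, 1),
                   cmb_count = c(0, 0, 9), epvs_bg = c(TRUE, FALSE, TRUE))
  tr <- transform_markers(co)
  expect_equal(tr$log_wmh, c(1, 0, 2))
  expect_equal(tr$log_li[1], 0)
  expect_equal(tr$log_cmb[3], 1)
  expect_equal(tr$epvs, c(1L, 0L, 1L))
  co$wmh_volume[2] <- -1
  expect_error(transform_markers(co), "negative")
})

test_that("generated cohorts classify back to their intended groups", {
  co <- generate_cohort(cohort_spec(seed = 2024))
  predicted <- classify_cognition(co)
  agreement <- mean(as.character(predicted) == as.character(co$group))
  expect_gte(agreement, 0.95)
  # discrepancies, if any, are flagged rather than hidden
  expect_equal(as.character(predicted) == as.character(co$group),
               co$label_consistent)
})
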