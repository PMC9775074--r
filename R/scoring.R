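# Neuropsychological scoring: timed-score inversion, z-transformation,
# domain composites, education-adjusted diagnostic classification and CSVD
# marker transforms.

# raw test -> domain map; the timed tests enter composites on their
# inverted (larger-is-better) scale
DOMAIN_TESTS <- list(
  episodic_memory  = c("wms_vr_dr", "avlt_dr"),
  language         = c("bnt", "cvf"),
  processing_speed = c("tmt_a_inv", "scwt_b_inv"),
  executive        = c("tmt_b_inv", "scwt_c_inv"),
  visuospatial     = c("cdt", "vrt")
)

TIMED_TESTS <- c("tmt_a", "tmt_b", "scwt_b", "scwt_c")

GROUP_LEVELS <- c("NC", "CSVD-non-CI", "CSVD-MCI", "CSVD-VaD")

#' Invert timed test scores
#'
#' The Trail Making Test (A/B) and Stroop Color and Word Test (B/C) are
#' scored as completion time in seconds, so larger raw values mean worse
#' performance. Before z-transformation they are inverted so that larger
#' means better, like every other test. The default inversion is negation
#' (order-reversing, keeps z magnitudes symmetric); `"reciprocal"` (1/time)
#' is available as an alternative.
#'
#' @param cohort data frame with columns `tmt_a`, `tmt_b`, `scwt_b`,
#'   `scwt_c` (seconds, > 0).
#' @param mode `"negate"` or `"reciprocal"`.
#' @return The cohort with added columns `tmt_a_inv`, `tmt_b_inv`,
#'   `scwt_b_inv`, `scwt_c_inv`; all other columns untouched.
#' @export
invert_timed_scores <- function(cohort, mode = c("negate", "reciprocal")) {
  mode <- match.arg(mode)
  missing_cols <- setdiff(TIMED_TESTS, names(cohort))
  if (length(missing_cols))
    stop_("cohort lacks timed-test column(s): %s",
          paste(missing_cols, collapse = ", "))
  for (nm in TIMED_TESTS) {
    x <- cohort[[nm]]
    if (any(x <= 0, na.rm = TRUE))
      stop_("non-positive completion time in %s; times must be > 0", nm)
    cohort[[paste0(nm, "_inv")]] <- if (mode == "negate") -x else 1 / x
  }
  cohort
}

#' z-transform raw test scores and build domain composites
#'
#' Each raw test score is standardized against a reference population
#' (`z = (x - ref_mean) / ref_sd`), and each cognitive domain composite is
#' the mean of exactly its two constituent z-scores: episodic memory =
#' (z WMS-VR-DR + z AVLT-DR)/2, language = (z BNT + z CVF)/2, processing
#' speed = (z TMT-A + z SCWT-B)/2 (inverted scale), executive = (z TMT-B +
#' z SCWT-C)/2 (inverted scale), visuospatial = (z CDT + z VRT)/2. A missing
#' constituent propagates to a missing composite; nothing is imputed.
#'
#' @param cohort data frame with the ten raw test columns (`wms_vr_dr`,
#'   `avlt_dr`, `bnt`, `cvf`, `tmt_a`, `tmt_b`, `scwt_b`, `scwt_c`, `cdt`,
#'   `vrt`); timed tests are inverted internally via
#'   [invert_timed_scores()].
#' @param reference `"whole_sample"` (default) standardizes against the full
#'   cohort; `"nc_group"` against the rows with `group == "NC"`.
#' @param inversion passed to [invert_timed_scores()].
#' @return The cohort with `z_` columns per test and composite columns
#'   `z_episodic_memory`, `z_language`, `z_processing_speed`, `z_executive`,
#'   `z_visuospatial`.
#' @export
score_cohort <- function(cohort, reference = c("whole_sample", "nc_group"),
                         inversion = c("negate", "reciprocal")) {
  reference <- match.arg(reference)
  cohort <- invert_timed_scores(cohort, mode = match.arg(inversion))
  tests <- unique(unlist(DOMAIN_TESTS))
  missing_cols <- setdiff(tests, names(cohort))
  if (length(missing_cols))
    stop_("cohort lacks test column(s): %s",
          paste(missing_cols, collapse = ", "))
  ref_rows <- if (reference == "nc_group") {
    if (!"group" %in% names(cohort))
      stop_("reference = 'nc_group' needs a 'group' column")
    which(cohort$group == "NC")
  } else {
    seq_len(nrow(cohort))
  }
  if (length(ref_rows) < 2L)
    stop_("reference population must contain at least 2 subjects")
  for (nm in tests) {
    ref <- cohort[[nm]][ref_rows]
    m <- mean(ref, na.rm = TRUE)
    s <- sd(ref, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop_("zero variance in reference population for test %s", nm)
    cohort[[paste0("z_", nm)]] <- (cohort[[nm]] - m) / s
  }
  for (dom in names(DOMAIN_TESTS)) {
    zc <- paste0("z_", DOMAIN_TESTS[[dom]])
    cohort[[paste0("z_", dom)]] <- (cohort[[zc[1]]] + cohort[[zc[2]]]) / 2
  }
  cohort
}

#' Education-adjusted MMSE dementia cutoff
#'
#' Scores at or below the cutoff indicate dementia: 17 for illiteracy
#' (0 years of education), 20 for 1-6 years, 24 for more than 6 years.
#'
#' @param education years of education (>= 0).
#' @return Numeric vector of cutoffs.
#' @export
mmse_dementia_cutoff <- function(education) {
  if (any(education < 0, na.rm = TRUE)) stop_("education must be >= 0 years")
  ifelse(education < 1, 17, ifelse(education <= 6, 20, 24))
}

#' Education-adjusted MoCA normal-cognition cutoff
#'
#' Scores above the cutoff indicate normal cognition: 13 for illiteracy,
#' 19 for 1-6 years of education, 24 for 7-12 years. For more than 12 years
#' the 7-12-year cutoff (24) is carried upward, the conventional handling
#' when no higher-education norm is published; a message notes this
#' extension whenever it is used.
#'
#' @inheritParams mmse_dementia_cutoff
#' @return Numeric vector of cutoffs.
#' @export
moca_normal_cutoff <- function(education) {
  if (any(education < 0, na.rm = TRUE)) stop_("education must be >= 0 years")
  if (any(education > 12, na.rm = TRUE))
    message("moca_normal_cutoff: education > 12 years present; ",
            "extending the 7-12-year cutoff (>24) upward")
  ifelse(education < 1, 13, ifelse(education <= 6, 19, 24))
}

#' Classify cognitive status from screening scores
#'
#' Applies the education-adjusted diagnostic rules:
#' * **VaD** (vascular dementia): MMSE at or below its education-adjusted
#'   dementia cutoff and CDR >= 1;
#' * **MCI**: MMSE above the dementia cutoff, MoCA at or below its
#'   education-adjusted normal cutoff, CDR = 0.5 and ADL = 8;
#' * cognitively normal: MMSE and MoCA above their cutoffs, CDR = 0 and
#'   ADL = 8 — labelled `NC` when `csvd` is `FALSE` and `CSVD-non-CI` when
#'   `TRUE`;
#' * anything else (including cognitive impairment without CSVD) is
#'   returned as `unclassifiable`, never coerced.
#'
#' @param cohort data frame with columns `mmse`, `moca`, `cdr`, `adl`,
#'   `education` and logical `csvd`.
#' @return Factor with levels `NC`, `CSVD-non-CI`, `CSVD-MCI`, `CSVD-VaD`,
#'   `unclassifiable`.
#' @export
classify_cognition <- function(cohort) {
  need <- c("mmse", "moca", "cdr", "adl", "education", "csvd")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop_("classification needs column(s): %s",
          paste(missing_cols, collapse = ", "))
  bad <- vapply(need, function(nm) anyNA(cohort[[nm]]), logical(1))
  if (any(bad))
    stop_("missing values in classification input(s): %s",
          paste(need[bad], collapse = ", "))
  mmse_cut <- mmse_dementia_cutoff(cohort$education)
  moca_cut <- suppressMessages(moca_normal_cutoff(cohort$education))
  dementia <- cohort$mmse <= mmse_cut
  vad <- dementia & cohort$cdr >= 1
  mci <- !dementia & cohort$moca <= moca_cut & cohort$cdr == 0.5 &
    cohort$adl == 8
  normal <- !dementia & cohort$moca > moca_cut & cohort$cdr == 0 &
    cohort$adl == 8
  out <- rep("unclassifiable", nrow(cohort))
  out[vad & cohort$csvd] <- "CSVD-VaD"
  out[mci & cohort$csvd] <- "CSVD-MCI"
  out[normal & !cohort$csvd] <- "NC"
  out[normal & cohort$csvd] <- "CSVD-non-CI"
  factor(out, levels = c(GROUP_LEVELS, "unclassifiable"))
}

#' Derive transformed CSVD marker columns
#'
#' Adds `log_wmh = log10(wmh_volume + 1)`, `log_li = log10(li_count + 1)`,
#' `log_cmb = log10(cmb_count + 1)` and the 0/1 indicator `epvs` for
#' basal-ganglia enlarged perivascular spaces. Base 10 with a +1 offset is
#' used because the count markers include zeros.
#'
#' @param cohort data frame with `wmh_volume` (mL), `li_count`, `cmb_count`
#'   (non-negative counts) and logical or 0/1 `epvs_bg`.
#' @return The cohort with the derived columns appended.
#' @export
transform_markers <- function(cohort) {
  need <- c("wmh_volume", "li_count", "cmb_count", "epvs_bg")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop_("cohort lacks marker column(s): %s",
          paste(missing_cols, collapse = ", "))
  for (nm in c("wmh_volume", "li_count", "cmb_count"))
    if (any(cohort[[nm]] < 0, na.rm = TRUE))
      stop_("negative values in %s", nm)
  cohort$log_wmh <- log10(cohort$wmh_volume + 1)
  cohort$log_li <- log10(cohort$li_count + 1)
  cohort$log_cmb <- log10(cohort$cmb_count + 1)
  cohort$epvs <- as.integer(as.logical(cohort$epvs_bg))
  cohort
}
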