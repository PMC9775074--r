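# Synthetic cohort generator. Emulates a four-group CSVD study (normal
# controls, CSVD with normal cognition, CSVD-MCI, CSVD-VaD) with the
# statistical structure the downstream analysis assumes: group-calibrated
# demographics, vascular risk factors, CSVD imaging markers, screening and
# domain test scores, and a linear mediation chain on the transformed
# scales: log-WMH -> ALPS (path a) and ALPS + log-WMH -> episodic memory
# (paths b and c').

# raw-test linear maps from the domain latents (z scale); timed tests are
# reversed (time grows as the latent falls) and floored at a plausible
# minimum
RAW_TEST_MAP <- data.frame(
  test   = c("wms_vr_dr", "avlt_dr", "bnt", "cvf", "tmt_a", "scwt_b",
             "tmt_b", "scwt_c", "cdt", "vrt"),
  latent = c("episodic_memory", "episodic_memory", "language", "language",
             "processing_speed", "processing_speed", "executive",
             "executive", "visuospatial", "visuospatial"),
  base   = c(8, 6, 24, 45, 55, 65, 130, 95, 24, 10),
  slope  = c(3, 2.5, 3, 8, -12, -10, -25, -15, 3, 2.5),
  floor  = c(0, 0, 0, 0, 10, 10, 20, 15, 0, 0),
  stringsAsFactors = FALSE
)

#' Specify a synthetic four-group cohort
#'
#' Per-group calibration defaults follow a published four-group CSVD cohort
#' (52 normal controls and 137 CSVD patients split 56/52/29 into
#' non-impaired, MCI and VaD): group means and SDs for age, education,
#' MMSE/MoCA, the ALPS index and the five domain composites; risk-factor
#' and EPVS prevalences; WMH volume log-normal on the log10(x+1) scale; and
#' zero-inflated Poisson lacune/microbleed counts.
#'
#' The mediation chain is generated on the transformed scales:
#' `alps = mu_alps(g) + a * (log_wmh - mu_lw(g)) + age effect + noise` and
#' `memory = mu_mem(g) + b * (alps - mu_alps(g)) + c' * (log_wmh - mu_lw(g))
#' + age/education effects + noise`. The default paths `a = -0.19`,
#' `b = 0.814`, `c' = -0.05` give an indirect effect `a * b` of about
#' -0.155, matching the published WMH -> ALPS -> episodic-memory estimate
#' used as calibration.
#'
#' Screening scores are redrawn (up to `max_redraws` times) for subjects
#' whose draw is inconsistent with their intended diagnostic label under
#' [classify_cognition()]; subjects still inconsistent afterwards are kept
#' and flagged via `label_consistent = FALSE`, never silently relabelled.
#'
#' @param n_per_group integer length-4: NC, CSVD-non-CI, CSVD-MCI,
#'   CSVD-VaD; all >= 2.
#' @param age_mean,age_sd,edu_mean,edu_sd,female_p demographics per group.
#' @param risk_prevalence 5 x 4 matrix of prevalences (rows hypertension,
#'   diabetes, hyperlipidemia, smoking, alcohol), entries in \[0, 1\].
#' @param mmse_mean,mmse_sd,moca_mean,moca_sd screening score moments.
#' @param alps_mean ALPS index group means.
#' @param log_wmh_mean,log_wmh_sd WMH burden on the log10(mL + 1) scale.
#' @param li_zero_p,li_lambda,cmb_zero_p,cmb_lambda zero-inflated Poisson
#'   parameters for lacune and microbleed counts.
#' @param epvs_p basal-ganglia EPVS prevalence per group.
#' @param domain_means 5 x 4 matrix of domain-composite means (rows
#'   episodic_memory, language, processing_speed, executive, visuospatial).
#' @param mediation_paths named numeric `c(a, b, c_prime)` on the
#'   transformed scales.
#' @param residual_sds named numeric `c(alps, memory, domain, test)`:
#'   residual SDs of the ALPS chain, the memory chain, the non-memory
#'   domain latents, and the per-test noise (scaled by each test's slope).
#' @param covariate_effects named numeric `c(alps_age, mem_age, mem_edu)`
#'   linear covariate effects entering the chain.
#' @param max_redraws screening-score redraw limit per subject.
#' @param seed integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(
    n_per_group = c(52L, 56L, 52L, 29L),
    age_mean = c(58.88, 66.28, 67.48, 66.07),
    age_sd = c(6.41, 9.25, 6.74, 8.75),
    edu_mean = c(14.48, 12.96, 10.19, 9.41),
    edu_sd = c(3.58, 3.46, 3.07, 3.19),
    female_p = c(25 / 52, 28 / 56, 26 / 52, 15 / 29),
    risk_prevalence = rbind(
      hypertension  = c(0.462, 0.714, 0.750, 0.655),
      diabetes      = c(0.154, 0.214, 0.314, 0.207),
      hyperlipidemia = c(0.250, 0.214, 0.157, 0.069),
      smoking       = c(0.192, 0.179, 0.235, 0.172),
      alcohol       = c(0.192, 0.167, 0.216, 0.034)),
    mmse_mean = c(29.36, 28.84, 27.48, 20.24),
    mmse_sd = c(0.77, 1.06, 1.39, 2.73),
    moca_mean = c(27.40, 26.87, 21.07, 14.52),
    moca_sd = c(1.30, 1.41, 2.60, 3.42),
    alps_mean = c(1.76, 1.64, 1.52, 1.44),
    log_wmh_mean = c(0.286, 0.884, 0.954, 1.150),
    log_wmh_sd = c(0.20, 0.45, 0.50, 0.55),
    li_zero_p = c(0.92, 0.60, 0.40, 0.35),
    li_lambda = c(0.3, 1.0, 1.5, 1.6),
    cmb_zero_p = c(0.95, 0.60, 0.50, 0.35),
    cmb_lambda = c(0.5, 2.0, 4.0, 10.0),
    epvs_p = c(0, 0.339, 0.365, 0.379),
    domain_means = rbind(
      episodic_memory  = c(0.34, 0.44, -0.23, -1.03),
      language         = c(0.53, 0.30, -0.31, -1.21),
      processing_speed = c(0.40, 0.32, -0.38, -0.88),
      executive        = c(0.17, 0.27, -0.26, -0.53),
      visuospatial     = c(0.30, 0.34, -0.06, -1.54)),
    mediation_paths = c(a = -0.19, b = 0.814, c_prime = -0.05),
    residual_sds = c(alps = 0.17, memory = 0.55, domain = 0.7, test = 0.5),
    covariate_effects = c(alps_age = -0.005, mem_age = -0.005,
                          mem_edu = 0.02),
    max_redraws = 30L,
    seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  if (length(n_per_group) != 4L || any(n_per_group < 2L))
    stop_("n_per_group must be four integers, all >= 2")
  len4 <- list(age_mean = age_mean, age_sd = age_sd, edu_mean = edu_mean,
               edu_sd = edu_sd, female_p = female_p, mmse_mean = mmse_mean,
               mmse_sd = mmse_sd, moca_mean = moca_mean, moca_sd = moca_sd,
               alps_mean = alps_mean, log_wmh_mean = log_wmh_mean,
               log_wmh_sd = log_wmh_sd, li_zero_p = li_zero_p,
               li_lambda = li_lambda, cmb_zero_p = cmb_zero_p,
               cmb_lambda = cmb_lambda, epvs_p = epvs_p)
  for (nm in names(len4))
    if (length(len4[[nm]]) != 4L) stop_("%s must have one value per group", nm)
  sds <- c(age_sd, edu_sd, mmse_sd, moca_sd, log_wmh_sd)
  if (any(sds <= 0)) stop_("all group standard deviations must be > 0")
  if (any(residual_sds < 0)) stop_("residual_sds must be >= 0")
  probs <- c(female_p, as.vector(risk_prevalence), li_zero_p, cmb_zero_p,
             epvs_p)
  if (any(probs < 0 | probs > 1)) stop_("all prevalences must lie in [0, 1]")
  if (!all(c("a", "b", "c_prime") %in% names(mediation_paths)))
    stop_("mediation_paths must name a, b and c_prime")
  stopifnot(identical(dim(risk_prevalence), c(5L, 4L)),
            identical(dim(domain_means), c(5L, 4L)))
  structure(list(
    n_per_group = n_per_group, age_mean = age_mean, age_sd = age_sd,
    edu_mean = edu_mean, edu_sd = edu_sd, female_p = female_p,
    risk_prevalence = risk_prevalence, mmse_mean = mmse_mean,
    mmse_sd = mmse_sd, moca_mean = moca_mean, moca_sd = moca_sd,
    alps_mean = alps_mean, log_wmh_mean = log_wmh_mean,
    log_wmh_sd = log_wmh_sd, li_zero_p = li_zero_p, li_lambda = li_lambda,
    cmb_zero_p = cmb_zero_p, cmb_lambda = cmb_lambda, epvs_p = epvs_p,
    domain_means = domain_means, mediation_paths = mediation_paths,
    residual_sds = residual_sds, covariate_effects = covariate_effects,
    max_redraws = as.integer(max_redraws), seed = seed),
    class = "cohort_spec")
}

rzip <- function(n, zero_p, lambda) {
  ifelse(rbinom(n, 1L, 1 - zero_p) == 1L, rpois(n, lambda), 0L)
}

#' Generate a synthetic cohort table
#'
#' Draws one subject table per the group structure and mediation chain of
#' the supplied [cohort_spec()]. The returned table carries one row per
#' subject with demographics, vascular risk factors, screening scores
#' (drawn consistently with the intended diagnostic label, see
#' [cohort_spec()]), the ten raw neuropsychological test scores, the CSVD
#' markers, the generated ALPS index, and `episodic_memory` — the latent
#' memory outcome of the mediation chain on the composite z scale (the raw
#' memory tests are noisy linear functions of it).
#'
#' @param spec a [cohort_spec()].
#' @return A data frame with attribute `spec`; column `label_consistent`
#'   flags subjects whose screening draws classify to the intended group.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_per_group
    g <- rep(1:4, n)
    N <- sum(n)
    group <- factor(GROUP_LEVELS[g], levels = GROUP_LEVELS)
    csvd <- g > 1L

    age <- pmin(85, pmax(45, round(rnorm(N, spec$age_mean[g], spec$age_sd[g]))))
    education <- pmin(22, pmax(0, round(rnorm(N, spec$edu_mean[g],
                                              spec$edu_sd[g]))))
    gender <- factor(ifelse(rbinom(N, 1L, spec$female_p[g]) == 1L, "F", "M"),
                     levels = c("F", "M"))
    risks <- lapply(rownames(spec$risk_prevalence), function(rf)
      rbinom(N, 1L, spec$risk_prevalence[rf, g]) == 1L)
    names(risks) <- rownames(spec$risk_prevalence)

    # CSVD markers
    log_wmh <- pmax(0, rnorm(N, spec$log_wmh_mean[g], spec$log_wmh_sd[g]))
    wmh_volume <- 10^log_wmh - 1
    li_count <- rzip(N, spec$li_zero_p[g], spec$li_lambda[g])
    cmb_count <- rzip(N, spec$cmb_zero_p[g], spec$cmb_lambda[g])
    epvs_bg <- rbinom(N, 1L, spec$epvs_p[g]) == 1L

    # mediation chain on the transformed scales
    paths <- spec$mediation_paths
    ce <- spec$covariate_effects
    rs <- spec$residual_sds
    alps <- spec$alps_mean[g] +
      paths[["a"]] * (log_wmh - spec$log_wmh_mean[g]) +
      ce[["alps_age"]] * (age - spec$age_mean[g]) +
      rnorm(N, 0, rs[["alps"]])
    memory <- spec$domain_means["episodic_memory", g] +
      paths[["b"]] * (alps - spec$alps_mean[g]) +
      paths[["c_prime"]] * (log_wmh - spec$log_wmh_mean[g]) +
      ce[["mem_age"]] * (age - spec$age_mean[g]) +
      ce[["mem_edu"]] * (education - spec$edu_mean[g]) +
      rnorm(N, 0, rs[["memory"]])

    # screening scores drawn to agree with the intended label; CDR/ADL are
    # set by group, MMSE/MoCA redrawn for inconsistent subjects
    cdr <- c(0, 0, 0.5, NA)[g]
    cdr[g == 4L] <- sample(c(1, 2), sum(g == 4L), replace = TRUE,
                           prob = c(0.8, 0.2))
    adl <- rep(8, N)
    adl[g == 4L] <- 8 + rpois(sum(g == 4L), 2)
    draw_screen <- function(rows) {
      list(mmse = pmin(30, pmax(0, round(rnorm(length(rows),
             spec$mmse_mean[g[rows]], spec$mmse_sd[g[rows]])))),
           moca = pmin(30, pmax(0, round(rnorm(length(rows),
             spec$moca_mean[g[rows]], spec$moca_sd[g[rows]])))))
    }
    sc <- draw_screen(seq_len(N))
    mmse <- sc$mmse; moca <- sc$moca
    intended <- as.character(group)
    check <- function() {
      got <- classify_cognition(data.frame(
        mmse = mmse, moca = moca, cdr = cdr, adl = adl,
        education = education, csvd = csvd))
      as.character(got) == intended
    }
    ok <- check()
    tries <- 0L
    while (any(!ok) && tries < spec$max_redraws) {
      rows <- which(!ok)
      sc <- draw_screen(rows)
      mmse[rows] <- sc$mmse; moca[rows] <- sc$moca
      ok <- check()
      tries <- tries + 1L
    }

    # domain latents and raw test scores
    latents <- list(episodic_memory = memory)
    for (dom in c("language", "processing_speed", "executive",
                  "visuospatial"))
      latents[[dom]] <- spec$domain_means[dom, g] +
        rnorm(N, 0, rs[["domain"]])
    tests <- list()
    for (i in seq_len(nrow(RAW_TEST_MAP))) {
      tm <- RAW_TEST_MAP[i, ]
      val <- tm$base + tm$slope * latents[[tm$latent]] +
        rnorm(N, 0, rs[["test"]] * abs(tm$slope))
      tests[[tm$test]] <- pmax(tm$floor + 0.5 * (tm$floor > 0), val)
    }

    out <- data.frame(
      id = sprintf("S%03d", seq_len(N)), group = group, csvd = csvd,
      gender = gender, age = age, education = education,
      hypertension = risks$hypertension, diabetes = risks$diabetes,
      hyperlipidemia = risks$hyperlipidemia, smoking = risks$smoking,
      alcohol = risks$alcohol, mmse = mmse, moca = moca, cdr = cdr,
      adl = adl, stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(tests))
    out$wmh_volume <- wmh_volume
    out$li_count <- li_count
    out$cmb_count <- cmb_count
    out$epvs_bg <- epvs_bg
    out$alps_index <- alps
    out$episodic_memory <- memory
    out$label_consistent <- ok
    attr(out, "spec") <- spec
    out
  })
}
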