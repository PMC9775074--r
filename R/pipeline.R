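# End-to-end orchestration: imaging (optional) -> ALPS -> cohort scoring ->
# group tables -> correlations -> mediation, with input validation and a
# deterministic, config-stamped report bundle.

#' Default analysis configuration
#'
#' Returns the configuration list [run_full_analysis()] consumes, populated
#' with the study's default analysis plan: group GLMs adjusted for gender,
#' age, hypertension and education; cognition-ALPS partial correlations
#' additionally adjusted for WMH volume (log) and microbleed count (log);
#' mediation of log-WMH on episodic memory through the ALPS index in the
#' MCI group, k = 5000 bootstrap; alpha = 0.05.
#'
#' @param cohort a cohort data frame or a CSV path.
#' @param imaging optional list: `bundle` (fixture-bundle directory),
#'   `roi_proj`, `roi_asso` (voxel center triples; `NULL` auto-suggests).
#' @param seed integer seed for the bootstrap stage.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return A configuration list.
#' @export
analysis_config <- function(cohort, imaging = NULL, seed = 1L,
                            out_dir = NULL) {
  list(
    cohort = cohort,
    imaging = imaging,
    z_reference = "whole_sample",
    inversion = "negate",
    alpha = 0.05,
    covariates = list(
      glm = c("gender", "age", "hypertension", "education"),
      correlation = c("gender", "age", "education", "hypertension",
                      "log_wmh", "log_cmb"),
      mediation = c("gender", "age", "education", "hypertension")),
    mediation = list(exposure = "log_wmh", mediator = "alps_index",
                     outcome = "z_episodic_memory", group = "CSVD-MCI",
                     k = 5000L, method = "bias_corrected"),
    seed = seed,
    out_dir = out_dir)
}

REQUIRED_COHORT_COLS <- c(
  "group", "gender", "age", "education", "hypertension", "diabetes",
  "hyperlipidemia", "smoking", "alcohol", "mmse", "moca",
  "wms_vr_dr", "avlt_dr", "bnt", "cvf", "tmt_a", "tmt_b", "scwt_b",
  "scwt_c", "cdt", "vrt", "wmh_volume", "li_count", "cmb_count", "epvs_bg")

#' Validate pipeline inputs
#'
#' Itemized schema and consistency checks: cohort columns present and of
#' the right kind, timed scores positive, marker counts non-negative,
#' classification inputs present when requested, configured covariates
#' resolving to columns, and — when an imaging stage is configured — the
#' bundle readable, b-vectors unit-norm and ROI centers in bounds.
#'
#' @param config a configuration list (see [analysis_config()]).
#' @return Data frame with columns `check`, `ok`, `detail`; attribute
#'   `ok` is `TRUE` iff every check passed.
#' @export
validate_inputs <- function(config) {
  checks <- list()
  add <- function(check, ok, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = check, ok = ok,
                                                 detail = detail)
  }
  cohort <- tryCatch(load_cohort(config$cohort), error = function(e) e)
  if (inherits(cohort, "error")) {
    add("cohort readable", FALSE, conditionMessage(cohort))
  } else {
    missing_cols <- setdiff(REQUIRED_COHORT_COLS, names(cohort))
    add("cohort columns", length(missing_cols) == 0L,
        if (length(missing_cols)) paste("missing:",
                                        paste(missing_cols, collapse = ", "))
        else "")
    if (!length(missing_cols)) {
      timed_ok <- all(vapply(TIMED_TESTS, function(nm)
        all(cohort[[nm]] > 0, na.rm = TRUE), logical(1)))
      add("timed scores positive", timed_ok,
          if (!timed_ok) "non-positive completion times present" else "")
      cnt_ok <- all(cohort$li_count >= 0, cohort$cmb_count >= 0,
                    cohort$wmh_volume >= 0, na.rm = TRUE)
      add("marker values non-negative", cnt_ok,
          if (!cnt_ok) "negative marker values present" else "")
      for (cv in unique(unlist(config$covariates))) {
        resolvable <- cv %in% names(cohort) ||
          cv %in% c("log_wmh", "log_li", "log_cmb", "epvs")
        add(paste("covariate", cv), resolvable,
            if (!resolvable) "does not resolve to a cohort column" else "")
      }
      cls_cols <- c("mmse", "moca", "cdr", "adl", "education", "csvd")
      cls_missing <- setdiff(cls_cols, names(cohort))
      cls_extra <- c("cdr", "adl", "csvd")
      if (all(cls_extra %in% cls_missing)) {
        add("classification inputs", TRUE,
            "cdr/adl/csvd absent; classification stage will be skipped")
      } else {
        add("classification inputs", length(cls_missing) == 0L,
            if (length(cls_missing)) paste("missing:",
                                           paste(cls_missing, collapse = ", "))
            else "")
      }
    }
  }
  if (!is.null(config$imaging)) {
    bundle <- tryCatch(read_fixture_bundle(config$imaging$bundle),
                       error = function(e) e)
    if (inherits(bundle, "error") || is.null(bundle$dwi)) {
      add("imaging bundle readable", FALSE,
          if (inherits(bundle, "error")) conditionMessage(bundle)
          else "bundle has no DWI")
    } else {
      dwi <- bundle$dwi
      dw <- dwi$bvals > 0
      nrm <- sqrt(rowSums(dwi$bvecs[dw, , drop = FALSE]^2))
      add("bvec unit norm", all(abs(nrm - 1) < 1e-6),
          if (any(abs(nrm - 1) >= 1e-6))
            sprintf("%d b-vector(s) not unit norm", sum(abs(nrm - 1) >= 1e-6))
          else "")
      add("bval/bvec frame count",
          length(dwi$bvals) == dim(dwi$signal)[4], "")
      sp <- dim(dwi$signal)[1:3]
      for (side in c("roi_proj", "roi_asso")) {
        ctr <- config$imaging[[side]]
        if (!is.null(ctr)) {
          ok <- !inherits(tryCatch(sphere_roi(roi_spec(ctr), sp),
                                   error = function(e) e), "error")
          add(paste(side, "in bounds"), ok,
              if (!ok) "ROI clipped by the volume boundary" else "")
        }
      }
    }
  }
  out <- do.call(rbind, checks)
  attr(out, "ok") <- all(out$ok)
  out
}

load_cohort <- function(cohort) {
  if (is.character(cohort)) read_cohort_csv(cohort)
  else as.data.frame(cohort)
}

#' Run the full analysis pipeline
#'
#' Produces a report bundle with five sections mirroring a four-group
#' cohort study: (1) demographics comparison, (2) covariate-adjusted
#' cognitive comparison, (3) CSVD markers + ALPS comparison,
#' (4) correlation analyses (pooled CSVD and per group), (5) a bootstrap
#' mediation report. Stages whose inputs are absent are skipped with an
#' explicit entry in `$skipped`, never silently. Reruns with the same
#' configuration and seed are numerically identical.
#'
#' @param config configuration list from [analysis_config()] (any entry may
#'   be overridden before the call).
#' @return List of class `alps_report`; if `config$out_dir` is set, the
#'   tables are also written there as TSV plus a JSON summary.
#' @export
run_full_analysis <- function(config) {
  val <- validate_inputs(config)
  if (!attr(val, "ok"))
    stop_("input validation failed:\n%s",
          paste(sprintf("- %s: %s", val$check[!val$ok], val$detail[!val$ok]),
                collapse = "\n"))
  cohort <- load_cohort(config$cohort)
  skipped <- character()
  imaging_out <- NULL

  # imaging stage: one phantom bundle -> ALPS measurement; fills
  # alps_index where the cohort lacks it
  if (!is.null(config$imaging)) {
    bundle <- read_fixture_bundle(config$imaging$bundle)
    tf <- fit_tensor(bundle$dwi)
    centers <- if (is.null(config$imaging$roi_proj)) {
      sg <- suggest_roi_centers(tf)
      list(proj = sg$projection$center, asso = sg$association$center)
    } else {
      list(proj = config$imaging$roi_proj, asso = config$imaging$roi_asso)
    }
    meas <- measure_alps(tf,
                         roi_spec(centers$proj, fiber = "projection"),
                         roi_spec(centers$asso, fiber = "association"))
    imaging_out <- list(measurement = meas, centers = centers,
                        n_clamped = tf$n_clamped)
    if (!"alps_index" %in% names(cohort)) cohort$alps_index <- NA_real_
    cohort$alps_index[is.na(cohort$alps_index)] <- meas$alps_index
  } else {
    skipped <- c(skipped, "imaging: no bundle configured; using supplied alps_index column")
    if (!"alps_index" %in% names(cohort))
      stop_("cohort has no alps_index column and no imaging stage is configured")
  }

  # scoring stage
  cohort <- score_cohort(cohort, reference = config$z_reference,
                         inversion = config$inversion)
  cohort <- transform_markers(cohort)
  classification <- NULL
  if (all(c("cdr", "adl", "csvd") %in% names(cohort))) {
    predicted <- classify_cognition(cohort)
    agreement <- if ("group" %in% names(cohort))
      mean(as.character(predicted) == as.character(cohort$group))
    else NA_real_
    classification <- list(predicted = predicted, agreement = agreement)
  } else {
    skipped <- c(skipped, "classification: cdr/adl/csvd columns absent")
  }

  grp <- factor(cohort$group, levels = GROUP_LEVELS)

  # section 1: demographics
  demo_rows <- list()
  for (v in c("age", "education")) {
    st <- anova_oneway(cohort[[v]], grp)
    demo_rows[[v]] <- section_row(v, cohort[[v]], grp, st)
  }
  for (v in c("gender", "hypertension", "diabetes", "smoking",
              "hyperlipidemia", "alcohol")) {
    tab <- table(cohort[[v]], grp)
    st <- chi_square_test(tab)
    demo_rows[[v]] <- data.frame(
      variable = v, test = st$test, statistic = st$statistic,
      p = st$p.value,
      display = paste(sprintf("%s n=%d", colnames(tab), tab[nrow(tab), ]),
                      collapse = "; "),
      note = if (st$low_expected > 0)
        sprintf("%d cell(s) with expected count < 5; exact test advisable",
                st$low_expected) else "")
  }
  table1 <- do.call(rbind, c(demo_rows, make.row.names = FALSE))

  # section 2: adjusted cognitive comparison
  cog_vars <- c("mmse", "moca", paste0("z_", names(DOMAIN_TESTS)))
  table2 <- glm_section(cohort, cog_vars, grp, config$covariates$glm)

  # section 3: markers + ALPS
  alps_st <- glm_section(cohort, "alps_index", grp, config$covariates$glm)
  marker_rows <- list()
  for (v in c("wmh_volume", "cmb_count", "li_count")) {
    st <- kruskal_wallis(cohort[[v]], grp)
    marker_rows[[v]] <- section_row(v, cohort[[v]], grp, st)
  }
  epvs_tab <- table(factor(cohort$epvs, levels = 0:1), grp)
  epvs_st <- chi_square_test(epvs_tab)
  table3 <- rbind(alps_st,
                  do.call(rbind, c(marker_rows, make.row.names = FALSE)),
                  data.frame(variable = "epvs_bg", test = epvs_st$test,
                             statistic = epvs_st$statistic,
                             p = epvs_st$p.value,
                             display = paste(sprintf("%s n=%d",
                               colnames(epvs_tab), epvs_tab["1", ]),
                               collapse = "; "),
                             note = ""))

  # section 4: correlations
  csvd_rows <- cohort$group != "NC"
  correlations <- list(
    age_alps = correlation_block(cohort, "age", "alps_index", grp,
                                 csvd_rows),
    log_wmh_alps = correlation_block(cohort, "log_wmh", "alps_index", grp,
                                     csvd_rows),
    cognition_partial = cognition_partial_block(cohort, csvd_rows,
                                                config$covariates$correlation))

  # section 5: mediation
  med_cfg <- config$mediation
  med_rows <- if (is.null(med_cfg$group)) csvd_rows
              else cohort$group == med_cfg$group
  med_data <- cohort[med_rows, , drop = FALSE]
  mediation <- NULL
  if (sum(stats::complete.cases(
        med_data[c(med_cfg$exposure, med_cfg$mediator, med_cfg$outcome,
                   config$covariates$mediation)])) >
      length(config$covariates$mediation) + 3L) {
    fit <- fit_mediation(med_data, exposure = med_cfg$exposure,
                         mediator = med_cfg$mediator,
                         outcome = med_cfg$outcome,
                         covariates = config$covariates$mediation,
                         k = med_cfg$k, method = med_cfg$method,
                         seed = config$seed)
    mediation <- list(fit = fit, report = mediation_report(fit))
  } else {
    skipped <- c(skipped, sprintf("mediation: too few complete cases in group %s",
                                  med_cfg$group %||% "(pooled)"))
  }

  cfg_for_hash <- config
  cfg_for_hash$cohort <- NULL
  report <- structure(list(
    table1 = table1, table2 = table2, table3 = table3,
    correlations = correlations, mediation = mediation,
    imaging = imaging_out, classification = classification,
    skipped = skipped, seed = config$seed,
    config_hash = fnv1a(paste(deparse(cfg_for_hash), collapse = "")),
    n = nrow(cohort)), class = "alps_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

section_row <- function(v, values, grp, st) {
  gs <- group_summary(values, grp)
  data.frame(variable = v, test = st$test, statistic = st$statistic,
             p = st$p.value,
             display = paste(sprintf("%s %s", gs$group, gs$display),
                             collapse = "; "),
             note = "")
}

glm_section <- function(cohort, vars, grp, covariates) {
  rows <- lapply(vars, function(v) {
    st <- glm_adjusted(cbind(cohort, .grp = grp), outcome = v,
                       group = ".grp", covariates = covariates)
    sig <- st$posthoc$contrast[st$posthoc$p_adj < 0.05]
    gs <- group_summary(cohort[[v]], grp)
    data.frame(variable = v, test = st$test, statistic = st$statistic,
               p = st$p.value,
               display = paste(sprintf("%s %s", gs$group, gs$display),
                               collapse = "; "),
               note = if (length(sig)) paste("post hoc:",
                                             paste(sig, collapse = "; "))
                      else "")
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

correlation_block <- function(cohort, xv, yv, grp, csvd_rows) {
  blocks <- c(list(`all CSVD` = which(csvd_rows)),
              lapply(setNames(GROUP_LEVELS, GROUP_LEVELS),
                     function(gl) which(grp == gl)))
  rows <- lapply(names(blocks), function(nm) {
    rows_i <- blocks[[nm]]
    if (length(rows_i) < 3L)
      return(data.frame(subset = nm, x = xv, y = yv, r = NA, p = NA,
                        n = length(rows_i)))
    st <- pearson_corr(cohort[[xv]][rows_i], cohort[[yv]][rows_i])
    data.frame(subset = nm, x = xv, y = yv, r = st$estimate,
               p = st$p.value, n = st$n)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

cognition_partial_block <- function(cohort, csvd_rows, covariates) {
  idx <- which(csvd_rows)
  outcomes <- c("mmse", "moca", paste0("z_", names(DOMAIN_TESTS)))
  rows <- lapply(outcomes, function(v) {
    st <- partial_corr(cohort$alps_index[idx], cohort[[v]][idx],
                       cohort[idx, covariates, drop = FALSE])
    data.frame(outcome = v, r = st$estimate, p = st$p.value, n = st$n,
               covariates = paste(covariates, collapse = ","))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' @export
print.alps_report <- function(x, ...) {
  cat(sprintf("<alps_report> n = %d, seed = %s, config %s\n", x$n,
              x$seed %||% "none", x$config_hash))
  for (tb in c("table1", "table2", "table3")) {
    cat(sprintf("\n-- %s --\n", tb))
    print(x[[tb]][c("variable", "statistic", "p", "note")], digits = 4,
          row.names = FALSE)
  }
  cat("\n-- correlations (pooled CSVD) --\n")
  print(x$correlations$cognition_partial, digits = 3, row.names = FALSE)
  if (!is.null(x$mediation)) {
    cat("\n-- mediation --\n")
    print(x$mediation$report)
  }
  if (length(x$skipped))
    cat("\nSkipped stages:\n", paste("-", x$skipped, collapse = "\n"), "\n")
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, nm)
    write.table(df, file.path(out_dir, paste0(nm, ".tsv")), sep = "\t",
                row.names = FALSE, quote = FALSE)
  wt(report$table1, "table1_demographics")
  wt(report$table2, "table2_cognition")
  wt(report$table3, "table3_markers")
  wt(report$correlations$cognition_partial, "correlations_cognition")
  wt(report$correlations$log_wmh_alps, "correlations_wmh_alps")
  wt(report$correlations$age_alps, "correlations_age_alps")
  summary_json <- list(seed = report$seed, config_hash = report$config_hash,
                       n = report$n, skipped = report$skipped)
  if (!is.null(report$mediation))
    summary_json$mediation <- unclass(report$mediation$report)
  jsonlite::write_json(summary_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
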