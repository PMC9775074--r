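# Phantom tensor construction, the DWI forward model, and the cohort
# generator.

test_that("phantom tensors are assembled from base + PVS boost + WMH scale", {
  iso <- diag(3) * 0.8e-3
  base <- list(projection = iso, association = iso,
               subcortical_other = iso, background = iso)
  spec0 <- phantom_spec(base_tensors = base, pvs_axis_boost = 0,
                        wmh_scale = 1)
  tf0 <- generate_tensor_field(spec0)
  v <- alpskit:::tensor_to_vec6(iso)
  Dm <- matrix(tf0$D, prod(spec0$grid_shape), 6)
  expect_true(all(apply(Dm, 1, function(r) identical(unname(r), v))))

  # additive construction: boost lands on the xx element of fiber regions
  spec1 <- phantom_spec(pvs_axis_boost = 0.6e-3)
  tf1 <- generate_tensor_field(spec1)
  proj <- which(spec1$region_map == "projection", arr.ind = TRUE)[1, ]
  expect_equal(tf1$dxx[proj[1], proj[2], proj[3]], 0.6e-3 + 0.6e-3)
  surround <- which(spec1$region_map == "subcortical_other",
                    arr.ind = TRUE)[1, ]
  expect_equal(tf1$dxx[surround[1], surround[2], surround[3]], 0.8e-3)

  # multiplicative construction: wmh_scale multiplies the whole field
  spec_s <- phantom_spec(pvs_axis_boost = 0.6e-3, wmh_scale = 1.5)
  tf_s <- generate_tensor_field(spec_s)
  expect_equal(tf_s$D, tf1$D * 1.5)
})

test_that("principal axes follow the region fiber directions", {
  tf <- generate_tensor_field(phantom_spec())
  rm <- phantom_spec()$region_map
  proj <- which(rm == "projection", arr.ind = TRUE)[5, ]
  asso <- which(rm == "association", arr.ind = TRUE)[5, ]
  pd_p <- abs(tf$principal_direction[proj[1], proj[2], proj[3], ])
  pd_a <- abs(tf$principal_direction[asso[1], asso[2], asso[3], ])
  expect_equal(which.max(pd_p), 3L)  # cranio-caudal
  expect_equal(which.max(pd_a), 2L)  # anterior-posterior
})

test_that("invalid phantom specs are rejected", {
  notspd <- diag(c(1, 1, -1)) * 1e-3
  expect_error(phantom_spec(base_tensors = list(
    projection = notspd, association = diag(3) * 1e-3,
    subcortical_other = diag(3) * 1e-3, background = diag(3) * 1e-3)),
    "positive-definite")
  expect_error(phantom_spec(wmh_scale = 0.9), "wmh_scale")
  expect_error(phantom_spec(grid_shape = c(4, 4, 4)), "12")
})

test_that("noiseless DWI matches the monoexponential closed form", {
  d <- 0.9e-3
  tf <- uniform_field(diag(3) * d, g = c(3, 3, 3))
  sch <- dwi_scheme(8)
  dwi <- generate_dwi(tf, sch$bvals, sch$bvecs, s0 = 500, noise_sigma = 0)
  for (j in seq_along(sch$bvals)) {
    expected <- 500 * exp(-sch$bvals[j] * d)   # isotropic: direction drops out
    expect_equal(as.vector(dwi$signal[, , , j]),
                 rep(expected, 27), tolerance = 1e-15)
  }

  # anisotropic tensor probed along its principal axis
  tf2 <- uniform_field(diag(c(1.7, 0.4, 0.4)) * 1e-3, g = c(2, 2, 2))
  bv <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
              c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2),
              c(0, 1, 1) / sqrt(2))
  dwi2 <- generate_dwi(tf2, c(0, rep(1000, 6)), bv, s0 = 1)
  expect_equal(dwi2$signal[1, 1, 1, 2], exp(-1.7), tolerance = 1e-15)
})

test_that("DWI generation is reproducible and validates its gradient table", {
  tf <- uniform_field(diag(3) * 1e-3, g = c(4, 4, 4))
  a <- generate_dwi(tf, noise_sigma = 0.05, seed = 11)
  b <- generate_dwi(tf, noise_sigma = 0.05, seed = 11)
  expect_identical(a$signal, b$signal)
  c_ <- generate_dwi(tf, noise_sigma = 0.05, seed = 12)
  expect_false(identical(a$signal, c_$signal))

  sch <- dwi_scheme(8)
  expect_error(generate_dwi(tf, sch$bvals[1:5], sch$bvecs[1:5, ]),
               "6 unique non-collinear")
  bad <- sch$bvecs; bad[2, ] <- bad[2, ] * 2
  expect_error(generate_dwi(tf, sch$bvals, bad), "unit norm")
})

test_that("cohort generator honors group sizes and is reproducible", {
  spec <- cohort_spec(n_per_group = c(5, 7, 6, 4), seed = 99)
  co <- generate_cohort(spec)
  expect_equal(as.vector(table(co$group)[alpskit:::GROUP_LEVELS]),
               c(5, 7, 6, 4))
  co2 <- generate_cohort(spec)
  expect_identical(co, co2)
})

test_that("the near-noiseless mediation chain reproduces its paths downstream", {
  # deterministic outcome equation plus vanishing mediator noise (an
  # exactly deterministic mediator would make the outcome design singular)
  spec <- cohort_spec(
    n_per_group = c(10, 10, 30, 10),
    mediation_paths = c(a = 0.5, b = 2, c_prime = 0),
    residual_sds = c(alps = 1e-5, memory = 0, domain = 0, test = 0),
    covariate_effects = c(alps_age = 0, mem_age = 0, mem_edu = 0),
    seed = 7)
  co <- transform_markers(generate_cohort(spec))
  mci <- co[co$group == "CSVD-MCI", ]
  fit <- fit_mediation(mci, "log_wmh", "alps_index", "episodic_memory",
                       k = 200, seed = 1, force = TRUE)
  expect_equal(fit$a, 0.5, tolerance = 1e-4)
  expect_equal(fit$b, 2, tolerance = 1e-4)
  expect_equal(fit$c_prime, 0, tolerance = 1e-3)
  expect_equal(fit$indirect, 1.0, tolerance = 1e-3)
})

test_that("cohort moments recover the generator calibration at large n", {
  n <- 10000L
  spec <- cohort_spec(n_per_group = rep(n, 4), seed = 123)
  co <- generate_cohort(spec)
  for (gi in 1:4) {
    rows <- co$group == alpskit:::GROUP_LEVELS[gi]
    # 3 standard errors of the generator's own spread (rounding to integer
    # years adds < 0.3 of one s.e. and is covered by the margin)
    for (fld in c("age", "education", "alps_index")) {
      mu <- switch(fld, age = spec$age_mean[gi],
                   education = spec$edu_mean[gi],
                   alps_index = spec$alps_mean[gi])
      sdv <- switch(fld, age = spec$age_sd[gi],
                    education = spec$edu_sd[gi],
                    alps_index = 0.2)
      expect_lt(abs(mean(co[[fld]][rows]) - mu), 3.5 * sdv / sqrt(n))
    }
  }
})

test_that("fixture bundles round-trip bit-exactly and record their seeds", {
  dir <- withr::local_tempdir()
  ph <- small_phantom(seed = 21, noise_sigma = 0.02)
  cs <- cohort_spec(n_per_group = c(4, 4, 4, 4), seed = 21)
  mf <- write_fixture_bundle(dir, phantom = ph, cohort = cs)
  expect_equal(mf$phantom$seed, 21)
  b <- read_fixture_bundle(dir)

  regen <- generate_dwi(generate_tensor_field(ph),
                        noise_sigma = ph$noise_sigma, seed = ph$seed)
  expect_identical(as.vector(b$dwi$signal), as.vector(regen$signal))
  expect_equal(b$dwi$bvals, regen$bvals)
  expect_equal(b$dwi$bvecs, unname(regen$bvecs), tolerance = 1e-15)

  co <- generate_cohort(cs)
  expect_identical(b$cohort$alps_index, co$alps_index)
  expect_identical(b$cohort$wmh_volume, co$wmh_volume)
  expect_identical(as.character(b$cohort$group), as.character(co$group))
})

test_that("cohort-only bundles omit imaging files", {
  dir <- withr::local_tempdir()
  write_fixture_bundle(dir, cohort = cohort_spec(n_per_group = c(3, 3, 3, 3),
                                                 seed = 5))
  expect_false(file.exists(file.path(dir, "dwi.nii.gz")))
  b <- read_fixture_bundle(dir)
  expect_null(b$dwi)
  expect_s3_class(b$cohort, "data.frame")
  expect_error(write_fixture_bundle(withr::local_tempdir()), "nothing to write")
})
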