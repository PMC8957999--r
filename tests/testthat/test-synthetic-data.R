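# Rule-based default plans, the surgeon-correction simulator and dataset
# generation.

test_that("sizing rules pick the boundary-correct sizes", {
  catalog <- test_catalog()
  # bone AP depth exactly equal to a size's AP dimension -> that size
  ap4 <- catalog$femur$ap[5L]  # size index 4
  expect_identical(kneeplan:::pick_femoral_size(ap4, catalog), 4L)
  expect_identical(kneeplan:::pick_femoral_size(ap4 + 0.1, catalog), 5L)
  ml3 <- catalog$tibia$ml[4L]  # size index 3
  expect_identical(kneeplan:::pick_tibial_size(ml3, catalog), 3L)
  expect_identical(kneeplan:::pick_tibial_size(ml3 - 0.1, catalog), 2L)
  expect_warning(kneeplan:::pick_femoral_size(200, catalog), "largest")
  expect_warning(kneeplan:::pick_tibial_size(10, catalog), "smallest")
})

test_that("generate_mpp is a pure function with the configured defaults", {
  model <- tiny_model()
  catalog <- test_catalog()
  a <- sample_anatomy(model, seed = 21)
  p1 <- suppressWarnings(generate_mpp(a, catalog))
  p2 <- suppressWarnings(generate_mpp(a, catalog))
  expect_plans_equal(p1, p2)
  r <- mpp_rules()
  for (nm in names(r)) expect_equal(unclass(p1)[[nm]], r[[nm]])
  expect_true(kneeplan:::is_snapped(p1, catalog))
})

test_that("default plans avoid femoral notching and tibial overhang by construction", {
  model <- tiny_model()
  catalog <- test_catalog()
  worst_notch <- Inf; worst_over <- 0
  skipped <- 0L
  for (i in 1:400) {
    a <- sample_anatomy(model, seed = 9000 + i)
    # boundary-clamped cases may legitimately violate the rule; exclude them
    p <- withCallingHandlers(
      generate_mpp(a, catalog),
      warning = function(w) { skipped <<- skipped + 1L; invokeRestart("muffleWarning") })
    if (a$dims[["fem_ap_depth"]] > max(catalog$femur$ap) ||
        a$dims[["tib_ml_width"]] < min(catalog$tibia$ml)) next
    m <- compute_measurements(a, p, catalog)
    worst_notch <- min(worst_notch, m[["notching_distance"]])
    worst_over <- max(worst_over, m[["tib_overhang_medial"]],
                      m[["tib_overhang_lateral"]])
  }
  expect_gte(worst_notch, 0)
  expect_equal(worst_over, 0)
})

test_that("the surgeon simulator honours gates, preferences and determinism", {
  model <- tiny_model()
  catalog <- test_catalog()
  a <- sample_anatomy(model, seed = 31)
  mpp <- suppressWarnings(generate_mpp(a, catalog))

  # all gates closed -> SCP == MPP
  scp0 <- simulate_surgeon(silent_surgeon_profile(), mpp, a, catalog, seed = 1)
  expect_plans_equal(scp0, mpp)
  expect_equal(count_corrections(scp0, mpp, catalog)$total, 0L)

  # pi = 1, sigma = 0, rho = 0, known beta -> exact noiseless shift
  beta <- matrix(0, 14, 4); beta[5, 2] <- 0.1   # distal resection ~ AP depth
  prof <- surgeon_profile(pi = 1, beta = beta,
                          intercept = stats::setNames(rep(1, 14), dof_schema()$name),
                          sigma = 0, outlier_prob = 0)
  scp <- simulate_surgeon(prof, mpp, a, catalog, seed = 2)
  f <- kneeplan:::pref_features(a)
  expected <- unclass(mpp)
  expected <- expected + as.vector(beta %*% f) + 1
  manual <- snap_to_grid(implant_plan(stats::setNames(expected, dof_schema()$name)),
                         catalog)
  expect_plans_equal(scp, manual)

  # determinism
  expect_plans_equal(simulate_surgeon(prof, mpp, a, catalog, seed = 7),
                     simulate_surgeon(prof, mpp, a, catalog, seed = 7))
})

test_that("gate frequency matches the binomial expectation", {
  model <- tiny_model()
  catalog <- test_catalog()
  # large noise so that snapping almost never cancels a correction
  beta <- matrix(0, 14, 4)
  prof <- surgeon_profile(pi = 0.3, beta = beta, intercept = 5, sigma = 2,
                          outlier_prob = 0)
  n <- 2000L
  dof <- "femur_distal_resection"
  changed <- 0L
  for (i in seq_len(n)) {
    a <- sample_anatomy(model, seed = 40000 + i)
    mpp <- suppressWarnings(generate_mpp(a, catalog))
    scp <- simulate_surgeon(prof, mpp, a, catalog, seed = 40000 + i)
    changed <- changed + (unclass(scp)[[dof]] != unclass(mpp)[[dof]])
  }
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(changed / n - 0.3), 3 * se)
})

test_that("generate_dataset is reproducible with exact per-surgeon counts", {
  model <- tiny_model()
  profs <- list(A = sample_surgeon_profile(model, seed = 1),
                B = silent_surgeon_profile())
  d1 <- suppressWarnings(generate_dataset(model, profs, 10L, seed = 5))
  d2 <- suppressWarnings(generate_dataset(model, profs, 10L, seed = 5))
  expect_equal(length(d1), 20L)
  expect_identical(vapply(d1, `[[`, "", "case_id"),
                   vapply(d2, `[[`, "", "case_id"))
  for (i in seq_along(d1)) expect_plans_equal(d1[[i]]$scp, d2[[i]]$scp)
  surg <- vapply(d1, `[[`, "", "surgeon")
  expect_equal(unname(table(surg)[c("A", "B")]), c(10L, 10L),
               ignore_attr = TRUE)
  # the silent surgeon never corrects
  for (cs in d1[surg == "B"]) expect_plans_equal(cs$scp, cs$mpp)
  expect_error(generate_dataset(model, profs, 1L), "at least 2 cases")
})

test_that("datasets round-trip through JSON lines", {
  ds <- tiny_dataset(n_cases = 4L, seed = 17L)
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  write_dataset(ds, tmp)
  back <- read_dataset(tmp)
  expect_equal(length(back), length(ds))
  for (i in seq_along(ds)) {
    expect_identical(back[[i]]$case_id, ds[[i]]$case_id)
    expect_plans_equal(back[[i]]$mpp, ds[[i]]$mpp)
    expect_plans_equal(back[[i]]$scp, ds[[i]]$scp)
    expect_equal(back[[i]]$anatomy$landmarks, ds[[i]]$anatomy$landmarks,
                 tolerance = 1e-12)
  }
  # landmark-only anatomies still support the default feature profile
  f1 <- assemble_features(back[[1L]], test_catalog())
  f2 <- assemble_features(ds[[1L]], test_catalog())
  expect_equal(f1, f2, tolerance = 1e-10)
})
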