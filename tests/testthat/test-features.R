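# Anatomical frames, the 57-measurement vector and the 149-feature schema.

test_that("anatomical frames are orthonormal and right-handed", {
  model <- tiny_model()
  for (s in 1:10) {
    a <- sample_anatomy(model, seed = 100 + s)
    for (fr in a$frames) {
      expect_lt(max(abs(crossprod(fr$axes) - diag(3))), 1e-8)
      expect_equal(det(fr$axes), 1, tolerance = 1e-8)
    }
  }
  # collinear defining landmarks -> degenerate-frame error
  lm <- sample_anatomy(model, seed = 1)$landmarks
  lm["fem_med_epicondyle", ] <- lm["fem_lat_epicondyle", ] +
    5 * (lm["hip_center", ] - lm["fem_knee_center", ])
  expect_error(build_frames(lm), "collinear")
  expect_error(build_frames(lm[1:10, , drop = FALSE]), "missing landmarks")
})

test_that("landmark and measurement schemas have the documented sizes", {
  expect_equal(nrow(landmark_schema()), 26L)
  expect_equal(anyDuplicated(landmark_schema()$name), 0L)
  expect_equal(nrow(measurement_schema()), 57L)
  expect_equal(anyDuplicated(measurement_schema()$name), 0L)
  expect_equal(length(feature_schema("paper149")), 149L)
  expect_equal(length(feature_schema("full")), 179L)
})

test_that("features are invariant to rigid motion of the anatomy", {
  catalog <- test_catalog()
  cs <- tiny_case(seed = 9)
  f0 <- assemble_features(cs, catalog)
  for (s in 1:5) {
    R <- random_rotation(300 + s)
    tvec <- with_seed(400 + s, rnorm(3, 0, 50))
    cs2 <- cs
    cs2$anatomy <- transform_anatomy(cs$anatomy, R, tvec)
    f1 <- assemble_features(cs2, catalog)
    expect_equal(f1, f0, tolerance = 1e-6)
  }
})

test_that("measurement geometry: overhang/underhang cases and exclusivity", {
  cs <- tiny_case(seed = 12)
  a <- cs$anatomy
  width <- a$dims[["tib_ml_width"]]
  # a catalog whose tibial implant exactly matches the plateau width
  exact_cat <- implant_catalog(
    femur = data.frame(ap = c(a$dims[["fem_ap_depth"]], a$dims[["fem_ap_depth"]] + 5),
                       ml = c(a$dims[["fem_condylar_width"]],
                              a$dims[["fem_condylar_width"]] + 5)),
    tibia = data.frame(ap = c(40, 45), ml = c(width, width + 4)))
  base <- unclass(cs$mpp)
  base[c("femur_size", "tibia_size")] <- 0
  base["tibia_ml_displacement"] <- 0
  plan <- snap_to_grid(implant_plan(base), exact_cat)
  m <- compute_measurements(a, plan, exact_cat)
  expect_equal(unname(m[c("tib_overhang_medial", "tib_overhang_lateral",
                          "tib_underhang_medial", "tib_underhang_lateral")]),
               rep(0, 4))
  # implant 4 mm wider than the bone, centered -> 2 mm overhang per side
  base["tibia_size"] <- 1
  plan <- snap_to_grid(implant_plan(base), exact_cat)
  m <- compute_measurements(a, plan, exact_cat)
  expect_equal(unname(m["tib_overhang_medial"]), 2)
  expect_equal(unname(m["tib_overhang_lateral"]), 2)
  expect_equal(unname(m["tib_underhang_medial"]), 0)

  # exclusivity on random cases: never overhang and underhang on one side
  catalog <- test_catalog()
  for (s in 1:50) {
    csr <- tiny_case(seed = 500 + s)
    mm <- compute_measurements(csr$anatomy, csr$mpp, catalog)
    expect_equal(length(mm), 57L)
    expect_identical(names(mm), measurement_schema()$name)
    expect_true(mm[["tib_overhang_medial"]] == 0 || mm[["tib_underhang_medial"]] == 0)
    expect_true(mm[["tib_overhang_lateral"]] == 0 || mm[["tib_underhang_lateral"]] == 0)
  }
})

test_that("notching sign agrees with a point-in-halfspace check", {
  catalog <- test_catalog()
  for (s in 1:25) {
    cs <- tiny_case(seed = 700 + s)
    a <- cs$anatomy
    for (size in c(0L, 4L, 7L)) {
      v <- unclass(cs$mpp); v["femur_size"] <- size
      plan <- snap_to_grid(implant_plan(v), catalog)
      m <- compute_measurements(a, plan, catalog)
      # brute force: does the anterior cortex landmark lie anterior of the
      # implant flange plane (posterior condyles + implant AP dimension)?
      Lf <- kneeplan:::to_frame(a$landmarks, a$frames$femoral)
      rownames(Lf) <- rownames(a$landmarks)
      flange <- mean(Lf[c("fem_med_posterior", "fem_lat_posterior"), "ap"]) +
        catalog$femur$ap[size + 1L]
      notched <- Lf["fem_anterior_cortex", "ap"] > flange
      expect_identical(unname(m[["notching_distance"]] < 0), unname(notched))
    }
  }
})

test_that("the assembled vector passes through the MPP block deterministically", {
  catalog <- test_catalog()
  cs <- tiny_case(seed = 14)
  f <- assemble_features(cs, catalog)
  expect_identical(names(f), feature_schema("paper149"))
  expect_equal(unname(f[paste0("mpp_", dof_schema()$name)]),
               unname(unclass(cs$mpp)))
  expect_identical(f, assemble_features(cs, catalog))
  # full profile appends 15 + 15 fitted/stored shape coefficients
  ff <- assemble_features(cs, catalog, profile = "full", model = tiny_model())
  expect_equal(length(ff), 179L)
  expect_equal(unname(ff[paste0("femur_ssm_", 1:12)]),
               cs$anatomy$coefficients$femur[1:12], tolerance = 1e-10)
})

test_that("feature matrices round-trip through CSV with schema hash check", {
  catalog <- test_catalog()
  ds <- tiny_dataset(n_cases = 5L, seed = 23L)
  X <- feature_matrix(ds, catalog)
  expect_equal(dim(X), c(5L, 149L))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(X, tmp)
  X2 <- read_feature_matrix(tmp)
  expect_equal(X2, X, tolerance = 1e-12)
})
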