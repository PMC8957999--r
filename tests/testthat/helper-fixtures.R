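# Shared fixtures, built once per test run and memoized.

with_seed <- kneeplan:::with_seed

.fixtures <- new.env(parent = emptyenv())

# small but fully featured knee shape model
tiny_model <- function() {
  if (is.null(.fixtures$model))
    .fixtures$model <- build_synthetic_knee_model(n_training = 30L,
                                                  n_modes = 12L, seed = 42L)
  .fixtures$model
}

test_catalog <- function() default_catalog()

# a snapped random plan on the grids
random_plan <- function(seed, catalog = test_catalog()) {
  with_seed(seed, {
    v <- stats::setNames(numeric(14L), kneeplan::dof_schema()$name)
    for (i in seq_len(14L)) {
      nm <- names(v)[i]
      v[i] <- if (nm %in% c("femur_size", "tibia_size"))
        sample(0:7, 1L) else sample(seq(-10, 10, by = 0.5), 1L)
    }
    implant_plan(v)
  })
}

# small per-surgeon dataset with a learnable profile
tiny_dataset <- function(n_cases = 30L, seed = 7L, profile = NULL,
                         n_surgeons = 1L) {
  model <- tiny_model()
  profiles <- lapply(seq_len(n_surgeons), function(s)
    if (is.null(profile)) sample_surgeon_profile(model, seed = seed + s)
    else profile)
  names(profiles) <- sprintf("S%02d", seq_len(n_surgeons))
  suppressWarnings(generate_dataset(model, profiles, n_cases,
                                    catalog = test_catalog(), seed = seed))
}

# a deterministic small case record (anatomy + plans)
tiny_case <- function(seed = 3L) {
  model <- tiny_model()
  catalog <- test_catalog()
  a <- sample_anatomy(model, seed = seed)
  mpp <- suppressWarnings(generate_mpp(a, catalog))
  prof <- sample_surgeon_profile(model, seed = seed)
  scp <- simulate_surgeon(prof, mpp, a, catalog, seed = seed)
  list(case_id = sprintf("T%03d", seed), surgeon = "T", anatomy = a,
       mpp = mpp, scp = scp)
}

random_rotation <- function(seed) {
  with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(9), 3L)))
    if (det(q) < 0) q[, 1L] <- -q[, 1L]
    q
  })
}

expect_plans_equal <- function(a, b, tol = 1e-9) {
  expect_equal(unclass(a), unclass(b), tolerance = tol)
}
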