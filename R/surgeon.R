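# Parameterized surgeon-correction behaviour. A surgeon profile says, per
# DOF: how often the surgeon touches it (gate probability), how the intended
# value depends on the patient's anatomy (linear preference over a small set
# of interpretable anatomical features), how consistent the surgeon is (noise
# SD), and how often/large occasional outlier corrections are.

pref_feature_names <- function() {
  c("fem_ml_width", "fem_ap_depth", "joint_line_varus", "fem_shape_coef1")
}

# The anatomy features surgeon preferences act on: mediolateral width,
# anteroposterior depth, a joint-line varus proxy, and the first femoral
# shape coefficient.
pref_features <- function(anatomy) {
  c1 <- if (!is.null(anatomy$coefficients)) anatomy$coefficients$femur[1L] else 0
  stats::setNames(c(anatomy$dims[["fem_ml_width"]], anatomy$dims[["fem_ap_depth"]],
                    anatomy$dims[["joint_line_varus"]], c1),
                  pref_feature_names())
}

#' Create a surgeon profile
#'
#' @param pi named length-14 vector of per-DOF gate probabilities in `[0,1]`
#'   (probability that the surgeon corrects the DOF at all).
#' @param beta 14 x 4 matrix of linear preference coefficients over the
#'   anatomy features (`fem_ml_width`, `fem_ap_depth`, `joint_line_varus`,
#'   `fem_shape_coef1`), rows in [dof_schema()] order.
#' @param intercept named length-14 vector of preference intercepts.
#' @param sigma named length-14 vector of per-DOF noise SDs (>= 0), in the
#'   DOF's unit (sizes: ordinal units).
#' @param outlier_prob named length-14 vector of outlier probabilities.
#' @param outlier_sd SD of the outlier disturbance (mm/deg; sizes: ordinal).
#' @return An object of class `surgeon_profile`.
#' @export
surgeon_profile <- function(pi, beta, intercept, sigma, outlier_prob,
                            outlier_sd = 8) {
  nm <- dof_names()
  fix <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, 14L)
    if (is.null(names(x))) names(x) <- nm
    if (!all(nm %in% names(x))) stop(what, " must cover all 14 DOFs")
    x[nm]
  }
  pi <- fix(pi, "pi"); intercept <- fix(intercept, "intercept")
  sigma <- fix(sigma, "sigma"); outlier_prob <- fix(outlier_prob, "outlier_prob")
  if (any(pi < 0 | pi > 1)) stop("gate probabilities must be in [0, 1]")
  if (any(outlier_prob < 0 | outlier_prob > 1)) stop("outlier probabilities must be in [0, 1]")
  if (any(sigma < 0)) stop("noise SDs must be non-negative")
  beta <- as.matrix(beta)
  if (!all(dim(beta) == c(14L, 4L))) stop("beta must be 14 x 4")
  rownames(beta) <- nm; colnames(beta) <- pref_feature_names()
  structure(list(pi = pi, beta = beta, intercept = intercept, sigma = sigma,
                 outlier_prob = outlier_prob, outlier_sd = outlier_sd),
            class = "surgeon_profile")
}

#' @export
print.surgeon_profile <- function(x, ...) {
  cat("Surgeon profile: mean gate probability", round(mean(x$pi), 2),
      "| mean noise SD", round(mean(x$sigma), 2),
      "| outlier prob", round(mean(x$outlier_prob), 3), "\n")
  invisible(x)
}

#' A surgeon who never corrects the default plan
#'
#' @return A `surgeon_profile` with all gate probabilities zero.
#' @export
silent_surgeon_profile <- function() {
  surgeon_profile(pi = 0, beta = matrix(0, 14, 4), intercept = 0, sigma = 0,
                  outlier_prob = 0)
}

#' Sample a surgeon profile with learnable, anatomy-driven preferences
#'
#' Draws a random but reproducible profile representing a surgeon who
#' corrects most DOFs most of the time (`gate_prob`), with corrections that
#' depend linearly on one or two anatomy features plus an intercept. Effect
#' sizes are calibrated against the feature variability of the supplied knee
#' model (estimated once from `n_calib` sampled anatomies) so that the
#' systematic correction SD is `shift_sd` in the DOF's unit and the
#' signal-to-noise ratio `var(systematic)/var(noise)` equals `snr`.
#'
#' @param model a [build_synthetic_knee_model()] result.
#' @param seed integer seed.
#' @param gate_prob per-DOF gate probability (default 0.9).
#' @param shift_sd target SD of the systematic correction: mm/deg for
#'   continuous DOFs, ordinal units for sizes (default 1.5 and 0.8).
#' @param snr signal-to-noise variance ratio (default 10).
#' @param outlier_prob probability of an occasional large extra correction
#'   (default 0.03).
#' @param outlier_sd SD of that disturbance in mm/deg (default 8).
#' @param n_calib anatomies used to calibrate feature SDs (default 200).
#' @return A `surgeon_profile`.
#' @export
sample_surgeon_profile <- function(model, seed, gate_prob = 0.9,
                                   shift_sd = c(continuous = 1.5, size = 0.8),
                                   snr = 10, outlier_prob = 0.03,
                                   outlier_sd = 8, n_calib = 200L) {
  stopifnot(inherits(model, "knee_shape_model"))
  fstats <- pref_feature_stats(model, n_calib)
  nm <- dof_names()
  with_seed(seed_stream(seed, "surgeon-profile"), {
    beta <- matrix(0, 14L, 4L, dimnames = list(nm, pref_feature_names()))
    intercept <- stats::setNames(numeric(14L), nm)
    sigma <- stats::setNames(numeric(14L), nm)
    for (i in seq_along(nm)) {
      tgt <- if (nm[i] %in% size_dofs()) shift_sd[["size"]] else shift_sd[["continuous"]]
      k <- sample(1:2, 1L)                      # 1 or 2 active features
      j <- sample.int(4L, k)
      w <- rnorm(k); w <- w / sqrt(sum(w^2))    # unit direction, random signs
      beta[i, j] <- w * tgt / fstats$sd[j]
      # center the systematic shift, then add a deliberate offset
      intercept[i] <- -sum(beta[i, ] * fstats$mean) + rnorm(1L, 0, tgt)
      sigma[i] <- tgt / sqrt(snr)
    }
    surgeon_profile(pi = gate_prob, beta = beta, intercept = intercept,
                    sigma = sigma, outlier_prob = outlier_prob,
                    outlier_sd = outlier_sd)
  })
}

# mean/SD of the preference features across the model population (memoized
# per model inside the calling session is unnecessary: cheap at default n).
pref_feature_stats <- function(model, n = 200L) {
  F <- vapply(seq_len(n), function(i)
    pref_features(sample_anatomy(model, seed = 1e6 + i)), numeric(4L))
  list(mean = rowMeans(F), sd = apply(F, 1L, sd))
}

#' Simulate a surgeon's corrected plan (SCP)
#'
#' Per DOF, with the profile's gate probability the surgeon replaces the
#' default value by `MPP + beta' f(anatomy) + intercept + noise`, plus an
#' occasional outlier disturbance; otherwise the default value is kept.
#' Continuous DOFs are snapped to the 0.5 grids; sizes are perturbed on the
#' ordinal scale, rounded and clamped into the catalog. Deterministic given
#' the seed.
#'
#' @param profile a [surgeon_profile()].
#' @param mpp the snapped default plan.
#' @param anatomy the case anatomy.
#' @param catalog the [implant_catalog()].
#' @param seed integer seed.
#' @return A snapped [implant_plan()].
#' @export
simulate_surgeon <- function(profile, mpp, anatomy, catalog, seed) {
  stopifnot(inherits(profile, "surgeon_profile"), inherits(mpp, "implant_plan"))
  f <- pref_features(anatomy)
  nm <- dof_names()
  with_seed(seed_stream(seed, "surgeon-correction"), {
    gates <- runif(14L) < profile$pi
    noise <- rnorm(14L, 0, profile$sigma)
    outl <- (runif(14L) < profile$outlier_prob) * rnorm(14L, 0, profile$outlier_sd)
    shift <- as.vector(profile$beta %*% f) + profile$intercept + noise + outl
    v <- unclass(mpp)
    v[gates] <- v[gates] + shift[gates]
    snap_to_grid(implant_plan(stats::setNames(v, nm)), catalog)
  })
}

#' Generate a multi-surgeon synthetic dataset
#'
#' For each surgeon and case: sample an anatomy from the shape model, derive
#' the manufacturer's default plan by the fixed rules, and simulate the
#' surgeon's corrected plan from their profile. Fully reproducible given the
#' seed; every case carries its surgeon ID.
#'
#' @param model a [build_synthetic_knee_model()] result.
#' @param profiles list of [surgeon_profile()]s, one per surgeon.
#' @param cases_per_surgeon number of cases per surgeon (>= 2).
#' @param catalog an [implant_catalog()] (default [default_catalog()]).
#' @param seed integer master seed.
#' @param rules MPP rule configuration (default [mpp_rules()]).
#' @return A list of case records (class `tka_dataset`); each record has
#'   `case_id`, `surgeon`, `anatomy`, `mpp`, `scp`.
#' @export
generate_dataset <- function(model, profiles, cases_per_surgeon,
                             catalog = default_catalog(), seed = 1L,
                             rules = mpp_rules()) {
  if (cases_per_surgeon < 2L) stop("need at least 2 cases per surgeon")
  if (!length(profiles)) stop("need at least one surgeon profile")
  if (is.null(names(profiles)))
    names(profiles) <- sprintf("S%02d", seq_along(profiles))
  cases <- list()
  for (s in seq_along(profiles)) {
    sid <- names(profiles)[s]
    for (k in seq_len(cases_per_surgeon)) {
      cseed <- seed_stream(seed, sprintf("case-%s-%d", sid, k))
      anat <- sample_anatomy(model, seed = cseed)
      mpp <- generate_mpp(anat, catalog, rules)
      scp <- simulate_surgeon(profiles[[s]], mpp, anat, catalog, seed = cseed)
      cases[[length(cases) + 1L]] <- list(
        case_id = sprintf("%s_C%04d", sid, k), surgeon = sid,
        anatomy = anat, mpp = mpp, scp = scp)
    }
  }
  structure(cases, class = "tka_dataset")
}

#' @export
print.tka_dataset <- function(x, ...) {
  surg <- vapply(x, `[[`, "", "surgeon")
  cat("TKA dataset:", length(x), "cases,", length(unique(surg)), "surgeons\n")
  invisible(x)
}

dataset_surgeons <- function(cases) unique(vapply(cases, `[[`, "", "surgeon"))

subset_surgeon <- function(cases, surgeon) {
  structure(Filter(function(cs) cs$surgeon == surgeon, cases),
            class = "tka_dataset")
}
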