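#' Default rank-correlation targets for the cohort generator
#'
#' Targets among the generated per-condyle variables `pain_duration`, `age`,
#' `interval` (months between CBCT scans), `relief` (duration of pain relief,
#' months), `nrs` (0-10 pain intensity), `dv_minus` and `dv_plus` (voxels).
#' Magnitudes follow the correlation structure reported for condyles with
#' both erosion and pain; the pain-duration/NRS entry is taken as -0.079 (the
#' source table prints a value outside the plausible range there, read as a
#' misplaced decimal point). `dV` itself is derived row-wise as
#' `dv_plus - dv_minus`, so its correlations are emergent, not targets.
#'
#' @return A symmetric 7x7 named matrix of Spearman targets.
#' @export
default_correlation_targets <- function() {
  vars <- c("pain_duration", "age", "interval", "relief", "nrs",
            "dv_minus", "dv_plus")
  m <- diag(7)
  dimnames(m) <- list(vars, vars)
  set <- function(a, b, v) {
    m[a, b] <<- v
    m[b, a] <<- v
  }
  set("pain_duration", "age", 0.180)
  set("pain_duration", "interval", -0.053)
  set("pain_duration", "relief", -0.045)
  set("pain_duration", "nrs", -0.079)
  set("pain_duration", "dv_minus", -0.155)
  set("pain_duration", "dv_plus", 0.052)
  set("age", "interval", 0.027)
  set("age", "relief", 0.188)
  set("age", "nrs", -0.098)
  set("age", "dv_minus", 0.091)
  set("age", "dv_plus", 0.136)
  set("interval", "relief", 0.422)
  set("interval", "nrs", 0.005)
  set("interval", "dv_minus", 0.221)
  set("interval", "dv_plus", 0.316)
  set("relief", "nrs", 0.208)
  set("relief", "dv_minus", 0.509)
  set("relief", "dv_plus", 0.068)
  set("nrs", "dv_minus", 0.143)
  set("nrs", "dv_plus", -0.348)
  set("dv_minus", "dv_plus", 0.105)
  m
}

#' Default per-stratum volume-change parameters
#'
#' Mean and SD (voxels) of `dv_minus` and `dv_plus` per erosion-by-pain
#' stratum, at the magnitudes reported for the study cohort: the two
#' erosion-positive strata follow the pain-split values, the erosion-negative
#' strata the erosion-negative column (which the source prints with the same
#' SD as the positive column; the printed values are used as-is).
#'
#' @return A tibble with columns `erosion`, `pain`, `dv_minus_mean`,
#'   `dv_minus_sd`, `dv_plus_mean`, `dv_plus_sd`.
#' @export
default_strata_params <- function() {
  tibble::tribble(
    ~erosion, ~pain, ~dv_minus_mean, ~dv_minus_sd, ~dv_plus_mean, ~dv_plus_sd,
    "yes", "yes", 111.74, 135.54, 39.02, 36.85,
    "yes", "no",   39.64,  60.84, 43.14, 36.98,
    "no",  "yes",  13.41, 122.96, 19.75, 36.77,
    "no",  "no",   13.41, 122.96, 19.75, 36.77
  )
}

#' Specification of a synthetic cohort table
#'
#' Describes a condyle-level cohort with the stratification of the study
#' design: erosion-positive condyles split by TMJ pain, a planted set of
#' patients with *bilateral* erosion-and-pain (which the clinical-factor
#' stage must exclude), and patient-level clinical factor labels. Continuous
#' variables are generated through a Gaussian copula with the given rank
#' correlation targets; nonnegative quantities (volume changes, durations,
#' scan interval) use moment-matched gamma marginals so configured means/SDs
#' are exact, bounded quantities (NRS, age) use truncated normals. The
#' identity `dV = dv_plus - dv_minus` is enforced row-wise: `dv_minus` and
#' `dv_plus` are generated, `dV` is derived.
#'
#' @param n_bilateral_pain_erosion number of patients with erosion and pain
#'   in both TMJs (each contributes 2 condyles).
#' @param n_unilateral_pain_erosion number of erosion-and-pain condyles held
#'   by distinct patients (at most one per patient).
#' @param n_erosion_nopain,n_no_erosion condyle counts of the remaining
#'   strata.
#' @param strata_params per-stratum `dv_minus`/`dv_plus` means and SDs; see
#'   [default_strata_params()].
#' @param correlation_targets symmetric named Spearman-correlation target
#'   matrix over a subset of `pain_duration`, `age`, `interval`, `relief`,
#'   `nrs`, `dv_minus`, `dv_plus` and optionally `dv`; a target involving the
#'   derived `dv` is realized by splitting its implied covariance onto
#'   `dv_minus` (negatively) and `dv_plus` (positively) in proportion to
#'   their variance contributions, *replacing* any component targets for that
#'   variable.
#' @param age_mean,age_sd,interval_mean,interval_sd,relief_mean,relief_sd,pain_duration_mean,pain_duration_sd,nrs_mean,nrs_sd
#'   covariate marginal parameters (years / months / NRS points).
#' @param pain_prevalence_noerosion probability that an erosion-negative
#'   condyle is painful (label only).
#' @param clinical_prevalence named per-patient prevalences of the binary
#'   clinical factors.
#' @param clinical_effects optional named list of per-factor additive shifts
#'   of the stratum means, e.g.
#'   `list(parafunction = c(dv_minus = 80, dv_plus = 0))`, applied to
#'   condyles of factor-positive patients.
#' @param seed integer seed; one seed controls all randomness of a call.
#' @return An object of class `cv_cohort_spec`.
#' @export
cohort_spec <- function(n_bilateral_pain_erosion = 10L,
                        n_unilateral_pain_erosion = 45L,
                        n_erosion_nopain = 25L,
                        n_no_erosion = 42L,
                        strata_params = default_strata_params(),
                        correlation_targets = default_correlation_targets(),
                        age_mean = 44.21, age_sd = 20.84,
                        interval_mean = 14.18, interval_sd = 6.19,
                        relief_mean = 6, relief_sd = 4,
                        pain_duration_mean = 8, pain_duration_sd = 6,
                        nrs_mean = 5, nrs_sd = 2,
                        pain_prevalence_noerosion = 0.5,
                        clinical_prevalence = c(
                          appliance_use = 38 / 45, stress = 11 / 45,
                          parafunction = 20 / 45, MOL = 28 / 45,
                          missing_posterior_teeth = 2 / 45,
                          occlusion_change = 11 / 45),
                        clinical_effects = NULL,
                        seed = 1L) {
  if (any(abs(correlation_targets) > 1))
    stop("cohort spec error: correlation targets must lie in [-1, 1]",
         call. = FALSE)
  if (!isSymmetric(unname(correlation_targets)))
    stop("cohort spec error: correlation target matrix must be symmetric",
         call. = FALSE)
  sp <- strata_params
  if (any(sp$dv_minus_mean <= 0 | sp$dv_plus_mean <= 0 |
            sp$dv_minus_sd <= 0 | sp$dv_plus_sd <= 0))
    stop("cohort spec error: stratum means and SDs must be positive",
         call. = FALSE)
  structure(
    list(n_bilateral_pain_erosion = as.integer(n_bilateral_pain_erosion),
         n_unilateral_pain_erosion = as.integer(n_unilateral_pain_erosion),
         n_erosion_nopain = as.integer(n_erosion_nopain),
         n_no_erosion = as.integer(n_no_erosion),
         strata_params = strata_params,
         correlation_targets = correlation_targets,
         age_mean = age_mean, age_sd = age_sd,
         interval_mean = interval_mean, interval_sd = interval_sd,
         relief_mean = relief_mean, relief_sd = relief_sd,
         pain_duration_mean = pain_duration_mean,
         pain_duration_sd = pain_duration_sd,
         nrs_mean = nrs_mean, nrs_sd = nrs_sd,
         pain_prevalence_noerosion = pain_prevalence_noerosion,
         clinical_prevalence = clinical_prevalence,
         clinical_effects = clinical_effects,
         seed = as.integer(seed)),
    class = "cv_cohort_spec"
  )
}

#' Generate a synthetic cohort table
#'
#' One row per condyle with patient id, side, stratum labels, clinical
#' covariates and the volume-change triple (`dV_minus`, `dV_plus` generated;
#' `dV` derived). Same seed, same table.
#'
#' @param spec a [cohort_spec()].
#' @return A tibble with columns `condyle_id`, `patient_id`, `side`,
#'   `erosion`, `pain`, `NRS`, `parafunction`, `MOL`, `appliance_use`,
#'   `stress`, `missing_posterior_teeth`, `occlusion_change`, `age`,
#'   `CBCT_interval`, `pain_duration`, `pain_relief_duration`, `dV`,
#'   `dV_minus`, `dV_plus`.
#' @export
make_cohort_table <- function(spec) {
  stopifnot(inherits(spec, "cv_cohort_spec"))
  with_seed(spec$seed, {
    frame <- cohort_frame(spec)
    pats <- cohort_patients(spec, frame)
    frame <- dplyr::left_join(frame, pats, by = "patient_id")
    frame <- generate_continuous(spec, frame)
    frame$dV <- frame$dV_plus - frame$dV_minus
    tibble::as_tibble(frame[order(frame$patient_id, frame$side),
                            c("condyle_id", "patient_id", "side", "erosion",
                              "pain", "NRS", "parafunction", "MOL",
                              "appliance_use", "stress",
                              "missing_posterior_teeth", "occlusion_change",
                              "age", "CBCT_interval", "pain_duration",
                              "pain_relief_duration", "dV", "dV_minus",
                              "dV_plus")])
  })
}

# --- layout: condyles -> patients -------------------------------------------

cohort_frame <- function(spec) {
  nb <- spec$n_bilateral_pain_erosion
  nu <- spec$n_unilateral_pain_erosion
  ne <- spec$n_erosion_nopain
  nn <- spec$n_no_erosion

  rows <- list()
  if (nb > 0)
    rows$bilateral <- tibble::tibble(
      patient_id = rep(seq_len(nb), each = 2),
      side = rep(c("L", "R"), nb),
      erosion = "yes", pain = "yes")
  # one erosion+pain condyle per distinct patient
  pain_pat <- nb + seq_len(nu)
  other <- c(rep("erosion_nopain", ne), rep("no_erosion", nn))
  other <- sample(other)  # mix the second condyles across patients
  extra_pat <- max(0L, ceiling(max(0L, length(other) - nu) / 2))
  # open slots: second condyle of each unilateral-pain patient, then two per
  # extra patient
  slots_pat <- c(pain_pat, rep(nb + nu + seq_len(extra_pat), each = 2))
  slots_side <- c(rep("R", nu), rep(c("L", "R"), extra_pat))
  if (length(other) > length(slots_pat))
    stop("cohort spec error: cannot place all condyles on two-TMJ patients",
         call. = FALSE)
  placed <- tibble::tibble(
    patient_id = slots_pat[seq_along(other)],
    side = slots_side[seq_along(other)],
    stratum = other)
  rows$unilateral <- tibble::tibble(patient_id = pain_pat, side = "L",
                                    erosion = "yes", pain = "yes")
  rows$others <- tibble::tibble(
    patient_id = placed$patient_id, side = placed$side,
    erosion = ifelse(placed$stratum == "no_erosion", "no", "yes"),
    pain = ifelse(placed$stratum == "erosion_nopain", "no",
                  ifelse(stats::runif(nrow(placed)) <
                           spec$pain_prevalence_noerosion, "yes", "no")))
  out <- dplyr::bind_rows(rows)
  out$condyle_id <- sprintf("C%04d", seq_len(nrow(out)))
  out
}

cohort_patients <- function(spec, frame) {
  ids <- sort(unique(frame$patient_id))
  prev <- spec$clinical_prevalence
  pats <- tibble::tibble(patient_id = ids)
  for (f in names(prev))
    pats[[f]] <- ifelse(stats::runif(length(ids)) < prev[[f]], "yes", "no")
  pats
}

# --- continuous variables through a Gaussian copula -------------------------

gamma_par <- function(m, s) list(shape = (m / s)^2, rate = m / s^2)

q_truncnorm <- function(u, m, s, lo, hi) {
  plo <- stats::pnorm(lo, m, s)
  phi <- stats::pnorm(hi, m, s)
  stats::qnorm(plo + u * (phi - plo), m, s)
}

# Spearman target -> latent Gaussian correlation
latent_cor <- function(rho_s) 2 * sin(pi * rho_s / 6)

project_psd <- function(m, tol = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= tol) return(m)
  v <- pmax(e$values, tol)
  p <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(p))
  p <- p / outer(d, d)
  if (max(abs(p - m)) > 0.2)
    stop("cohort spec error: correlation targets are infeasible ",
         "(PSD projection changed an entry by more than 0.2)", call. = FALSE)
  p
}

# split a rank-correlation target on the derived dV onto its components
apply_dv_targets <- function(targets, sm, sp_) {
  if (!"dv" %in% rownames(targets)) return(targets)
  keep <- setdiff(rownames(targets), "dv")
  rho_mp <- if (all(c("dv_minus", "dv_plus") %in% keep))
    targets["dv_minus", "dv_plus"] else 0
  sd_dv <- sqrt(sm^2 + sp_^2 - 2 * rho_mp * sm * sp_)
  out <- targets[keep, keep, drop = FALSE]
  for (x in setdiff(keep, c("dv_minus", "dv_plus"))) {
    t_dv <- targets[x, "dv"]
    if (t_dv == 0) next
    # a dv target replaces the component targets for that variable
    out[x, "dv_minus"] <- out["dv_minus", x] <-
      -t_dv * sm * sd_dv / (sm^2 + sp_^2)
    out[x, "dv_plus"] <- out["dv_plus", x] <-
      t_dv * sp_ * sd_dv / (sm^2 + sp_^2)
  }
  if (any(abs(out) > 1))
    stop("cohort spec error: dv target split yields correlation outside [-1, 1]",
         call. = FALSE)
  out
}

generate_continuous <- function(spec, frame) {
  n <- nrow(frame)
  frame$age <- NA_real_
  frame$CBCT_interval <- NA_real_
  frame$pain_duration <- NA_real_
  frame$pain_relief_duration <- NA_real_
  frame$NRS <- NA_real_
  frame$dV_minus <- NA_real_
  frame$dV_plus <- NA_real_

  sp <- spec$strata_params
  for (r in seq_len(nrow(sp))) {
    sel <- which(frame$erosion == sp$erosion[r] & frame$pain == sp$pain[r])
    if (length(sel) == 0) next
    painful <- sp$pain[r] == "yes"
    vars <- if (painful)
      c("pain_duration", "age", "interval", "relief", "nrs", "dv_minus", "dv_plus")
    else c("age", "interval", "dv_minus", "dv_plus")

    targets <- spec$correlation_targets
    targets <- apply_dv_targets(targets, sp$dv_minus_sd[r], sp$dv_plus_sd[r])
    miss <- setdiff(vars, rownames(targets))
    if (length(miss) > 0) {  # absent variables default to independence
      grow <- diag(length(miss))
      dimnames(grow) <- list(miss, miss)
      old <- targets
      targets <- diag(length(vars))
      dimnames(targets) <- list(vars, vars)
      common <- intersect(vars, rownames(old))
      targets[common, common] <- old[common, common]
    }
    sigma <- project_psd(latent_cor(targets[vars, vars, drop = FALSE]))
    z <- matrix(stats::rnorm(length(sel) * length(vars)), ncol = length(vars)) %*%
      chol(sigma)
    u <- stats::pnorm(z)
    colnames(u) <- vars

    mm <- sp$dv_minus_mean[r]
    pm <- sp$dv_plus_mean[r]
    # optional per-patient clinical effects shift the stratum means
    dm_shift <- rep(0, length(sel))
    dp_shift <- rep(0, length(sel))
    for (f in names(spec$clinical_effects %||% list())) {
      eff <- spec$clinical_effects[[f]]
      hit <- frame[[f]][sel] == "yes"
      dm_shift[hit] <- dm_shift[hit] + (eff[["dv_minus"]] %||% 0)
      dp_shift[hit] <- dp_shift[hit] + (eff[["dv_plus"]] %||% 0)
    }
    gm <- gamma_par(pmax(mm + dm_shift, 1e-6), sp$dv_minus_sd[r])
    gp <- gamma_par(pmax(pm + dp_shift, 1e-6), sp$dv_plus_sd[r])
    frame$dV_minus[sel] <- stats::qgamma(u[, "dv_minus"], gm$shape, gm$rate)
    frame$dV_plus[sel] <- stats::qgamma(u[, "dv_plus"], gp$shape, gp$rate)

    ga <- gamma_par(spec$interval_mean, spec$interval_sd)
    frame$CBCT_interval[sel] <- stats::qgamma(u[, "interval"], ga$shape, ga$rate)
    frame$age[sel] <- round(q_truncnorm(u[, "age"], spec$age_mean, spec$age_sd,
                                        15, 90), 1)
    if (painful) {
      gr <- gamma_par(spec$relief_mean, spec$relief_sd)
      frame$pain_relief_duration[sel] <-
        stats::qgamma(u[, "relief"], gr$shape, gr$rate)
      gd <- gamma_par(spec$pain_duration_mean, spec$pain_duration_sd)
      frame$pain_duration[sel] <- stats::qgamma(u[, "pain_duration"], gd$shape, gd$rate)
      frame$NRS[sel] <- pmin(10, pmax(1, round(
        q_truncnorm(u[, "nrs"], spec$nrs_mean, spec$nrs_sd, 0, 10))))
    } else {
      frame$pain_relief_duration[sel] <- 0
      frame$pain_duration[sel] <- 0
      frame$NRS[sel] <- 0
    }
  }

  # age and scan interval are patient-level: the patient's first condyle's
  # draw is shared by the second (slightly diluting their correlation
  # targets, which are defined on the one-condyle-per-patient analysis set)
  first <- !duplicated(frame$patient_id)
  fmap <- match(frame$patient_id, frame$patient_id[first])
  frame$age <- frame$age[first][fmap]
  frame$CBCT_interval <- frame$CBCT_interval[first][fmap]
  frame
}

#' Write a cohort table as CSV
#'
#' @param cohort tibble from [make_cohort_table()].
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path CSV path with the columns documented in [make_cohort_table()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
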