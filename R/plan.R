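#' Run the staged cohort analysis plan
#'
#' Executes the study's staged nonparametric comparison design on a
#' condyle-level cohort table:
#' \enumerate{
#'   \item erosion vs no-erosion on all condyles (dV, dV-, dV+ by
#'     Mann-Whitney);
#'   \item pain vs no-pain within erosion-positive condyles;
#'   \item each binary clinical factor within erosion-and-pain condyles,
#'     after excluding patients with *bilateral* erosion-and-pain, so that
#'     patient-level clinical factors map to exactly one condyle per
#'     remaining patient;
#'   \item Spearman correlation matrix of pain duration, age, scan interval,
#'     pain-relief duration, NRS and the volume changes on the stage-3
#'     analysis set.
#' }
#' A Shapiro-Wilk normality gate is recorded for the stage-1 groups (the
#' rationale for rank-based tests). No multiple-testing correction is
#' applied (alpha = 0.05 per test, as in the study design); the report
#' counts the tests run so readers can judge. Records with missing values in
#' a stage's variables are dropped for that stage (complete-case) and
#' logged. A stage whose stratum is empty is skipped with a warning, never a
#' crash.
#'
#' @param cohort a tibble/data.frame with the columns of
#'   [make_cohort_table()].
#' @param clinical_factors character vector of binary (yes/no) per-patient
#'   factor columns compared in stage 3.
#' @return An object of class `condyle_report`: a list of per-stage tibbles
#'   (`stage1`, `stage2`, `stage3`), `spearman` (rho and p matrices),
#'   `normality`, `n_tests` and a `log` character vector. See
#'   [tidy.condyle_report()].
#' @export
run_analysis_plan <- function(cohort,
                              clinical_factors = c(
                                "appliance_use", "stress", "parafunction",
                                "MOL", "missing_posterior_teeth",
                                "occlusion_change")) {
  cohort <- tibble::as_tibble(cohort)
  required <- c("patient_id", "erosion", "pain", "dV", "dV_minus", "dV_plus")
  miss <- setdiff(required, names(cohort))
  if (length(miss) > 0)
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  outcomes <- c("dV", "dV_minus", "dV_plus")
  n_tests <- 0L

  two_group <- function(data, by, stage) {
    yes <- data[data[[by]] == "yes", ]
    no <- data[data[[by]] == "no", ]
    purrr::map_dfr(outcomes, function(v) {
      a <- yes[[v]][!is.na(yes[[v]])]
      b <- no[[v]][!is.na(no[[v]])]
      dropped <- (nrow(yes) - length(a)) + (nrow(no) - length(b))
      if (dropped > 0)
        note(stage, ": dropped ", dropped, " incomplete record(s) for ", v)
      cmp <- mann_whitney_u(a, b)
      n_tests <<- n_tests + 1L
      tibble::tibble(
        factor = by, outcome = v,
        n_yes = length(a), n_no = length(b),
        mean_yes = mean(a), sd_yes = stats::sd(a),
        mean_no = mean(b), sd_no = stats::sd(b),
        test = cmp$test, statistic = cmp$statistic,
        p.value = cmp$p, significant = cmp$significant)
    })
  }

  # stage 1: erosion vs no erosion, all condyles
  report <- list()
  if (length(unique(cohort$erosion)) < 2) {
    warning("stage 1 skipped: only one erosion stratum present", call. = FALSE)
    note("stage1: skipped (single stratum)")
    report$stage1 <- NULL
  } else {
    report$stage1 <- two_group(cohort, "erosion", "stage1")
    note("stage1: erosion yes n=", sum(cohort$erosion == "yes"),
         " vs no n=", sum(cohort$erosion == "no"))
  }

  # normality gate on the stage-1 groups
  report$normality <- purrr::map_dfr(outcomes, function(v) {
    purrr::map_dfr(unique(cohort$erosion), function(g) {
      vals <- cohort[[v]][cohort$erosion == g & !is.na(cohort[[v]])]
      res <- tryCatch(shapiro_wilk(vals), error = function(e) NULL)
      if (is.null(res)) return(tibble::tibble())
      tibble::tibble(outcome = v, erosion = g, n = length(vals),
                     W = res$W, p.value = res$p, normal = res$p >= 0.05)
    })
  })

  # stage 2: pain vs no pain within erosion-positive condyles
  eros <- cohort[cohort$erosion == "yes", ]
  if (nrow(eros) == 0 || length(unique(eros$pain)) < 2) {
    warning("stage 2 skipped: no pain contrast among erosion-positive condyles",
            call. = FALSE)
    note("stage2: skipped")
    report$stage2 <- NULL
  } else {
    report$stage2 <- two_group(eros, "pain", "stage2")
    note("stage2: within erosion, pain yes n=", sum(eros$pain == "yes"),
         " vs no n=", sum(eros$pain == "no"))
  }

  # stage 3: clinical factors within erosion+pain, bilateral cases excluded
  ep <- cohort[cohort$erosion == "yes" & cohort$pain == "yes", ]
  report$stage3 <- NULL
  report$stage3_set <- NULL
  if (nrow(ep) == 0) {
    warning("stage 3 skipped: no erosion-and-pain condyles", call. = FALSE)
    note("stage3: skipped")
  } else {
    bilateral <- names(which(table(ep$patient_id) >= 2))
    s3 <- ep[!ep$patient_id %in% bilateral, ]
    note("stage3: excluded ", nrow(ep) - nrow(s3),
         " condyle(s) of ", length(bilateral),
         " patient(s) with bilateral erosion and pain; analyzing ",
         nrow(s3), " condyles (one per patient)")
    report$stage3_set <- s3
    if (nrow(s3) < 3) {
      warning("stage 3 skipped: fewer than 3 condyles after bilateral exclusion",
              call. = FALSE)
      note("stage3: skipped (too few records)")
    } else {
      factors <- intersect(clinical_factors, names(s3))
      report$stage3 <- purrr::map_dfr(factors, function(f) {
        if (length(unique(s3[[f]])) < 2) {
          note("stage3: factor ", f, " has a single level; skipped")
          return(tibble::tibble())
        }
        two_group(s3, f, paste0("stage3[", f, "]"))
      })
    }
  }

  # stage 4: Spearman correlations on the stage-3 analysis set
  report$spearman <- NULL
  s4_vars <- intersect(
    c("pain_duration", "age", "CBCT_interval", "pain_relief_duration", "NRS",
      "dV", "dV_minus", "dV_plus"),
    names(cohort))
  if (!is.null(report$stage3_set) && nrow(report$stage3_set) >= 3) {
    s4 <- report$stage3_set
    k <- length(s4_vars)
    rho <- matrix(NA_real_, k, k, dimnames = list(s4_vars, s4_vars))
    pmat <- rho
    diag(rho) <- 1
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      res <- tryCatch(spearman_cor(s4[[s4_vars[i]]], s4[[s4_vars[j]]]),
                      error = function(e) NULL)
      if (is.null(res)) next
      rho[i, j] <- rho[j, i] <- res$rho
      pmat[i, j] <- pmat[j, i] <- res$p
      n_tests <- n_tests + 1L
    }
    report$spearman <- list(rho = rho, p = pmat, n = nrow(s4))
    note("stage4: Spearman matrix over ", k, " variables, n = ", nrow(s4))
  } else {
    warning("stage 4 skipped: no stage-3 analysis set", call. = FALSE)
    note("stage4: skipped")
  }

  report$n_tests <- n_tests
  report$log <- log
  class(report) <- "condyle_report"
  report
}

#' @export
print.condyle_report <- function(x, ...) {
  cat("<condyle_report> staged cohort analysis (", x$n_tests,
      " tests, alpha = 0.05, no multiplicity correction)\n", sep = "")
  for (s in c("stage1", "stage2", "stage3")) {
    if (is.null(x[[s]]) || nrow(x[[s]]) == 0) next
    cat("--", s, "--\n")
    df <- x[[s]]
    cat(paste0("  ", df$factor, " / ", df$outcome, ": p = ",
               signif(df$p.value, 3),
               ifelse(df$significant, " *", ""), collapse = "\n"), "\n")
  }
  if (!is.null(x$spearman))
    cat("-- stage4 -- Spearman matrix over ", nrow(x$spearman$rho),
        " variables (n = ", x$spearman$n, ")\n", sep = "")
  invisible(x)
}

#' Tidy the staged analysis report
#'
#' Returns all group comparisons as one long tibble with a `stage` column;
#' stage-4 correlations are available via `glance()` or directly from the
#' report's `spearman` element.
#'
#' @param x a `condyle_report`.
#' @param ... unused.
#' @export
tidy.condyle_report <- function(x, ...) {
  dplyr::bind_rows(
    if (!is.null(x$stage1)) dplyr::mutate(x$stage1, stage = "stage1", .before = 1),
    if (!is.null(x$stage2)) dplyr::mutate(x$stage2, stage = "stage2", .before = 1),
    if (!is.null(x$stage3) && nrow(x$stage3) > 0)
      dplyr::mutate(x$stage3, stage = "stage3", .before = 1)
  )
}

#' @rdname tidy.condyle_report
#' @export
glance.condyle_report <- function(x, ...) {
  tibble::tibble(
    n_tests = x$n_tests,
    n_significant = sum(tidy(x)$significant, na.rm = TRUE),
    stage4_n = if (is.null(x$spearman)) NA_integer_ else x$spearman$n
  )
}

#' @export
#' @importFrom generics glance
generics::glance

#' Write the analysis report to a directory
#'
#' Per-stage CSV tables, the Spearman matrices, a JSON summary of every test
#' and a plain-text log.
#'
#' @param report a `condyle_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in c("stage1", "stage2", "stage3", "normality")) {
    if (is.null(report[[s]]) || nrow(report[[s]]) == 0) next
    utils::write.csv(report[[s]], file.path(dir, paste0(s, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(report$spearman)) {
    utils::write.csv(report$spearman$rho, file.path(dir, "stage4_rho.csv"))
    utils::write.csv(report$spearman$p, file.path(dir, "stage4_p.csv"))
  }
  jsonlite::write_json(
    list(tests = tidy(report), n_tests = report$n_tests, log = report$log),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(report$log, file.path(dir, "report.log"))
  invisible(dir)
}
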