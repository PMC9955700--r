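#' Family-clustered random-intercept logistic regression
#'
#' Fits a logistic model with a per-family (cluster) random intercept by
#' adaptive Gauss--Hermite quadrature (lme4, default 15 nodes) and returns
#' one Wald association row per requested predictor. Used for the pooled
#' twin-and-sibling analyses, where family membership induces outcome
#' correlation; parent analyses use ordinary logistic regression instead.
#'
#' Non-convergence and quasi-separation are flagged in the `converged`
#' column (diagnostics attached as the `"fit_messages"` attribute), never
#' reported as silent estimates.
#'
#' @param cohort Data with the outcome, predictors and cluster columns.
#' @param outcome Binary outcome column name.
#' @param predictors Character vector of predictor column names entering the
#'   model jointly.
#' @param covariates Covariates always included (default `"age"`).
#' @param cluster Cluster id column (default `"family_id"`).
#' @param nagq Number of adaptive quadrature nodes (default 15).
#' @return An association tibble with one row per predictor
#'   (`model = "random_intercept_logit"`), carrying the estimated
#'   random-intercept standard deviation in `cluster_sd`.
#' @export
random_intercept_logit <- function(cohort, outcome, predictors,
                                   covariates = "age",
                                   cluster = "family_id", nagq = 15) {
  d <- tidyr::drop_na(
    dplyr::select(cohort, dplyr::all_of(c(outcome, predictors, covariates,
                                          cluster))))
  if (dplyr::n_distinct(d[[cluster]]) < 2) {
    abort("Need at least two clusters", class = "twinfam_validation_error")
  }
  const <- predictors[vapply(predictors, function(p) {
    dplyr::n_distinct(d[[p]]) < 2
  }, logical(1))]
  if (length(const) > 0) {
    abort(paste0("Constant predictor(s): ", paste(const, collapse = ", ")),
          class = "twinfam_validation_error")
  }
  fml <- as.formula(paste(
    outcome, "~", paste(c(predictors, covariates), collapse = " + "),
    "+ (1 |", cluster, ")"))
  msgs <- character()
  fit <- withCallingHandlers(
    suppressMessages(lme4::glmer(fml, data = d, family = binomial(),
                                 nAGQ = nagq)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  sd_c <- sqrt(unname(lme4::VarCorr(fit)[[cluster]][1]))
  conv_msgs <- fit@optinfo$conv$lme4$messages %||% character()
  # a singular (zero-variance boundary) fit is a valid limiting case
  conv <- length(grep("boundary|singular", conv_msgs, invert = TRUE,
                      value = TRUE)) == 0
  rows <- purrr::map(predictors, function(p) {
    b <- unname(est[p]); s <- unname(se[p])
    tibble::tibble(
      outcome = outcome, predictor = p, odds_ratio = exp(b), log_or = b,
      log_or_variance = s^2, ci_low = exp(b - z975 * s),
      ci_high = exp(b + z975 * s),
      p_value = 2 * pnorm(abs(b / s), lower.tail = FALSE),
      n = nrow(d), covariates = paste(covariates, collapse = ","),
      model = "random_intercept_logit", cluster_sd = sd_c,
      converged = conv && is.finite(b) && is.finite(s) && s < 10)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fit_messages") <- msgs
  out
}

ordinary_logit_table <- function(d, outcome, predictors, covariates) {
  fml <- as.formula(paste(
    outcome, "~", paste(c(predictors, covariates), collapse = " + ")))
  fit <- glm(fml, data = d, family = binomial())
  dplyr::bind_rows(purrr::map(predictors, function(p) {
    logit_wald(fit, p, "ordinary_logit", nrow(d), outcome, p, covariates)
  }))
}

population_roles <- list(
  twins_and_siblings = c("twin1", "twin2", "first_sibling"),
  mothers = "mother",
  fathers = "father"
)

outcome_regions <- list(
  lbp_life = "lower_back",
  tlbp_current = c("lower_back", "middle_back")
)

#' Univariate and multivariable association table
#'
#' Builds the association table for a back-pain outcome against either the
#' body-region predictors or the condition predictors, in the style of the
#' published tables: one univariate fit per predictor plus a single joint
#' multivariable fit containing all retained predictors, with a retention
#' flag where the multivariable p-value is below 0.05.
#'
#' For the regions predictor set, the outcome's own region(s) are removed
#' from the predictors and from the multiple-sites count (`multiple_sites` =
#' pain in two or more non-outcome regions). Predictors with fewer positive
#' individuals than `min_count` in the analysed subset are dropped with a
#' logged reason. The twins-and-siblings population is fitted with a
#' per-family random-intercept logit adjusted for age; mothers and fathers
#' use ordinary logistic regression, unadjusted by default.
#'
#' @param cohort A classified cohort (see [classify_back_pain()]).
#' @param outcome `"lbp_life"` or `"tlbp_current"`.
#' @param predictor_set `"regions"` or `"conditions"`.
#' @param population `"twins_and_siblings"`, `"mothers"` or `"fathers"`.
#' @param covariates Covariates; default age for offspring, none for
#'   parents.
#' @param min_count Minimum positive count for a predictor to enter
#'   (default 10).
#' @param nagq Quadrature nodes for the random-intercept fits.
#' @param p_adjust Optional multiple-testing correction for the univariate
#'   p-values (`"none"`, default, matching the published presentation, or
#'   any method of [stats::p.adjust()]).
#' @return An object of class `association_table`; `tidy()` gives rows
#'   (predictor, n, OR_uni, CI, p_uni, OR_multi, CI, p_multi, retained).
#' @export
build_association_table <- function(cohort,
                                    outcome = c("lbp_life", "tlbp_current"),
                                    predictor_set = c("regions", "conditions"),
                                    population = c("twins_and_siblings",
                                                   "mothers", "fathers"),
                                    covariates = NULL, min_count = 10,
                                    nagq = 15, p_adjust = "none") {
  outcome <- match.arg(outcome)
  predictor_set <- match.arg(predictor_set)
  population <- match.arg(population)
  clustered <- population == "twins_and_siblings"
  if (is.null(covariates)) covariates <- if (clustered) "age" else character()

  excl <- if ("analysis_excluded" %in% names(cohort)) {
    cohort$analysis_excluded
  } else rep(FALSE, nrow(cohort))
  d <- cohort[cohort$role %in% population_roles[[population]] & !excl, ,
              drop = FALSE]

  if (predictor_set == "regions") {
    own <- outcome_regions[[outcome]]
    others <- setdiff(region_names(), own)
    rc <- paste0("region_", others)
    stopifnot(all(rc %in% names(d)))
    d$multiple_sites <- as.integer(rowSums(d[rc]) >= 2)
    for (col in rc) d[[col]] <- as.integer(d[[col]])
    predictors <- c("multiple_sites", rc)
  } else {
    predictors <- c(condition_ids[condition_ids %in% names(d)],
                    "chronic_pain_other",
                    "anxious_depression_score", "sensory_sensitivity_score")
    predictors <- intersect(unique(predictors), names(d))
  }

  d <- d[!is.na(d[[outcome]]), , drop = FALSE]
  dropped <- character()
  keep <- character()
  for (p in predictors) {
    v <- d[[p]]
    binary <- all(stats::na.omit(v) %in% c(0, 1))
    npos <- if (binary) sum(v == 1, na.rm = TRUE) else sum(!is.na(v))
    if (dplyr::n_distinct(stats::na.omit(v)) < 2 || npos < min_count) {
      dropped <- c(dropped, p)
    } else {
      keep <- c(keep, p)
    }
  }
  if (length(keep) == 0) {
    abort("All predictors dropped (constant or below min_count)",
          class = "twinfam_empty_table_error")
  }

  fit_uni <- function(p) {
    if (clustered) {
      random_intercept_logit(d, outcome, p, covariates = covariates,
                             nagq = nagq)
    } else {
      dd <- tidyr::drop_na(d, dplyr::all_of(c(outcome, p, covariates)))
      ordinary_logit_table(dd, outcome, p, covariates)
    }
  }
  uni <- dplyr::bind_rows(purrr::map(keep, fit_uni))
  uni$p_value <- stats::p.adjust(uni$p_value, method = p_adjust)

  multi <- if (clustered) {
    random_intercept_logit(d, outcome, keep, covariates = covariates,
                           nagq = nagq)
  } else {
    dd <- tidyr::drop_na(d, dplyr::all_of(c(outcome, keep, covariates)))
    ordinary_logit_table(dd, outcome, keep, covariates)
  }

  rows <- dplyr::left_join(
    dplyr::select(uni, "predictor", n = "n", or_uni = "odds_ratio",
                  ci_low_uni = "ci_low", ci_high_uni = "ci_high",
                  p_uni = "p_value", converged_uni = "converged"),
    dplyr::select(multi, "predictor", or_multi = "odds_ratio",
                  ci_low_multi = "ci_low", ci_high_multi = "ci_high",
                  p_multi = "p_value", converged_multi = "converged"),
    by = "predictor")
  rows$retained <- !is.na(rows$p_multi) & rows$p_multi < 0.05

  structure(list(rows = rows, outcome = outcome,
                 predictor_set = predictor_set, population = population,
                 covariates = covariates, dropped = dropped,
                 n_analysed = max(rows$n),
                 model = if (clustered) "random_intercept_logit" else "ordinary_logit"),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("Association table: %s ~ %s predictors, %s (%s)\n",
              x$outcome, x$predictor_set, x$population, x$model))
  if (length(x$dropped) > 0) {
    cat("  dropped (low numbers):", paste(x$dropped, collapse = ", "), "\n")
  }
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @describeIn build_association_table Tidy rows of the table.
#' @param x An `association_table`.
#' @param ... Unused.
#' @export
tidy.association_table <- function(x, ...) x$rows

#' @describeIn build_association_table One-row model summary.
#' @export
glance.association_table <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, predictor_set = x$predictor_set,
                 population = x$population, model = x$model,
                 n_analysed = x$n_analysed, n_predictors = nrow(x$rows),
                 n_retained = sum(x$rows$retained),
                 n_dropped = length(x$dropped))
}

#' @describeIn build_association_table Forest plot of univariate and
#'   multivariable odds ratios.
#' @param object An `association_table`.
#' @export
autoplot.association_table <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$rows,
    cols = c("or_uni", "or_multi"),
    names_to = "fit", values_to = "or")
  d$ci_low <- ifelse(d$fit == "or_uni", d$ci_low_uni, d$ci_low_multi)
  d$ci_high <- ifelse(d$fit == "or_uni", d$ci_high_uni, d$ci_high_multi)
  d$fit <- factor(d$fit, c("or_uni", "or_multi"),
                  c("univariate", "multivariable"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$predictor,
                                  colour = .data$fit)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI, log scale)", y = NULL,
                  title = sprintf("%s ~ %s (%s)", object$outcome,
                                  object$predictor_set, object$population)) +
    ggplot2::theme_minimal()
}

#' Positive-control cross-trait association
#'
#' The pipeline's diagnostic check: lifetime low back pain as predictor of
#' current thoracolumbar back pain, fitted per population (age-adjusted
#' random-intercept logit for the pooled twins and siblings; ordinary logit
#' for each parent). A strongly positive odds ratio is expected whenever
#' the two back-pain traits share liability.
#'
#' @param cohort A classified cohort.
#' @param nagq Quadrature nodes for the offspring fit.
#' @return An association tibble with one row per population, tagged
#'   `check = "cross_trait_positive_control"`.
#' @export
expected_cross_trait_check <- function(cohort, nagq = 15) {
  excl <- if ("analysis_excluded" %in% names(cohort)) {
    cohort$analysis_excluded
  } else rep(FALSE, nrow(cohort))
  cohort <- cohort[!excl, , drop = FALSE]
  rows <- list()
  off <- cohort[cohort$role %in% population_roles$twins_and_siblings, ,
                drop = FALSE]
  r <- random_intercept_logit(off, "tlbp_current", "lbp_life",
                              covariates = "age", nagq = nagq)
  r$population <- "twins_and_siblings"
  rows$offspring <- r
  for (pop in c("mothers", "fathers")) {
    dd <- cohort[cohort$role == population_roles[[pop]], , drop = FALSE]
    dd <- tidyr::drop_na(dd, dplyr::all_of(c("tlbp_current", "lbp_life")))
    rr <- ordinary_logit_table(dd, "tlbp_current", "lbp_life", character())
    rr$population <- pop
    rows[[pop]] <- rr
  }
  out <- dplyr::bind_rows(rows)
  out$check <- "cross_trait_positive_control"
  out
}
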