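#' Randomly select one twin per pair
#'
#' Splits the complete twin pairs of a cohort into two disjoint arms:
#' exactly one randomly chosen member of each pair in the `selected` arm and
#' the other in the `cotwin` arm. The draw is reproducible given `seed` and
#' does not disturb the global RNG state; the per-family selection indicator
#' is recorded in the returned column.
#'
#' @param cohort A cohort tibble.
#' @param seed Integer seed for the selection.
#' @return The cohort with a `twin_arm` column (`"selected"` / `"cotwin"`
#'   for twins in complete pairs, `NA` otherwise). Incomplete pairs are
#'   excluded from both arms with a warning.
#' @export
select_random_twin <- function(cohort, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  twins <- cohort[cohort$role %in% c("twin1", "twin2"), , drop = FALSE]
  tab <- table(twins$family_id, twins$role)
  fams <- rownames(tab)
  complete <- fams[tab[, "twin1"] == 1 & tab[, "twin2"] == 1]
  if (length(complete) < length(unique(twins$family_id))) {
    warn(sprintf("%d incomplete twin pair(s) excluded from selection",
                 length(unique(twins$family_id)) - length(complete)))
  }
  complete <- sort(complete)
  pick <- withr::with_seed(as.integer(seed),
                           sample(c("twin1", "twin2"), length(complete),
                                  replace = TRUE))
  names(pick) <- complete
  arm <- rep(NA_character_, nrow(cohort))
  is_twin <- cohort$role %in% c("twin1", "twin2") &
    cohort$family_id %in% complete
  arm[is_twin] <- ifelse(
    cohort$role[is_twin] == pick[cohort$family_id[is_twin]],
    "selected", "cotwin")
  cohort$twin_arm <- arm
  cohort
}

logit_wald <- function(fit, term, model, n, outcome, predictor, covariates) {
  est <- coef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  converged <- isTRUE(fit$converged %||% TRUE) &&
    is.finite(est[term]) && is.finite(se[term]) && se[term] < 10
  b <- unname(est[term]); s <- unname(se[term])
  tibble::tibble(
    outcome = outcome, predictor = predictor,
    odds_ratio = exp(b), log_or = b, log_or_variance = s^2,
    ci_low = exp(b - z975 * s), ci_high = exp(b + z975 * s),
    p_value = 2 * pnorm(abs(b / s), lower.tail = FALSE),
    n = n, covariates = paste(covariates, collapse = ","),
    model = model, converged = converged)
}

# Covariate policy: fit with the candidate covariates, then refit keeping
# only those with Wald p < 0.05 ("adjusted for age and gender, if
# significant"). `keep` forces covariates in regardless of significance.
fit_logit_policy <- function(data, outcome, predictor, covariates,
                             keep = character(), model_label) {
  fml <- function(covs) {
    as.formula(paste(outcome, "~", paste(c(predictor, covs), collapse = " + ")))
  }
  fit <- glm(fml(covariates), data = data, family = binomial())
  drop_candidates <- setdiff(covariates, keep)
  if (length(drop_candidates) > 0) {
    se <- sqrt(diag(as.matrix(vcov(fit))))
    p <- 2 * pnorm(abs(coef(fit) / se), lower.tail = FALSE)
    keep_cov <- covariates[!(covariates %in% drop_candidates &
                               covariates %in% names(p) & p[covariates] >= 0.05)]
    # covariates expanded to factor terms (e.g. sex) need name matching
    term_p <- function(cv) {
      hits <- grep(paste0("^", cv), names(p), value = TRUE)
      if (length(hits) == 0) NA_real_ else min(p[hits])
    }
    keep_cov <- covariates[vapply(covariates, function(cv) {
      cv %in% keep || isTRUE(term_p(cv) < 0.05)
    }, logical(1))]
    if (!identical(sort(keep_cov), sort(covariates))) {
      fit <- glm(fml(keep_cov), data = data, family = binomial())
      covariates <- keep_cov
    }
  }
  list(fit = fit, covariates = covariates)
}

#' Logistic regression of a twin's trait on a relative's trait
#'
#' Pairs each twin of one selection arm with a family member of the given
#' role and fits an ordinary maximum-likelihood logistic regression of the
#' twin's trait on the relative's same trait, with the covariate policy
#' "age and sex if significant" (each candidate covariate is kept only when
#' its Wald p-value is below 0.05; the applied set is recorded in the
#' result). Separation or non-convergence is flagged in the `converged`
#' column rather than silently reported.
#'
#' @param cohort A cohort tibble carrying a `twin_arm` column (see
#'   [select_random_twin()]).
#' @param trait Trait column name (binary).
#' @param relative One of `"mz_cotwin"`, `"dz_cotwin"`, `"first_sibling"`,
#'   `"mother"`, `"father"`.
#' @param arm Which twin arm provides the outcome (`"selected"` or
#'   `"cotwin"`).
#' @param covariates Candidate covariates, default `c("age", "sex")`.
#' @return A one-row association tibble (`model = "ordinary_logit"`).
#' @export
relative_logit <- function(cohort, trait,
                           relative = c("mz_cotwin", "dz_cotwin",
                                        "first_sibling", "mother", "father"),
                           arm = c("selected", "cotwin"),
                           covariates = c("age", "sex")) {
  relative <- match.arg(relative)
  arm <- match.arg(arm)
  if (!"twin_arm" %in% names(cohort)) {
    abort("Run select_random_twin() before relative_logit()",
          class = "twinfam_validation_error")
  }
  excl <- if ("analysis_excluded" %in% names(cohort)) {
    cohort$analysis_excluded
  } else rep(FALSE, nrow(cohort))
  cohort <- cohort[!excl, , drop = FALSE]

  child <- cohort[!is.na(cohort$twin_arm) & cohort$twin_arm == arm, , drop = FALSE]
  if (relative %in% c("mz_cotwin", "dz_cotwin")) {
    zy <- if (relative == "mz_cotwin") "MZ" else "DZ"
    child <- child[!is.na(child$zygosity) & child$zygosity == zy, , drop = FALSE]
    other_arm <- setdiff(c("selected", "cotwin"), arm)
    rel <- cohort[!is.na(cohort$twin_arm) & cohort$twin_arm == other_arm, ,
                  drop = FALSE]
  } else {
    rel <- cohort[cohort$role == relative, , drop = FALSE]
  }

  d <- dplyr::inner_join(
    dplyr::select(child, "family_id", y = dplyr::all_of(trait),
                  dplyr::any_of(c("age", "sex"))),
    dplyr::select(rel, "family_id", x = dplyr::all_of(trait)),
    by = "family_id")
  d <- d[!is.na(d$y) & !is.na(d$x), , drop = FALSE]
  covariates <- covariates[covariates %in% names(d)]
  d <- tidyr::drop_na(d, dplyr::any_of(covariates))

  predictor_label <- paste0(relative, "_", trait)
  if (nrow(d) < 4 || dplyr::n_distinct(d$y) < 2 || dplyr::n_distinct(d$x) < 2) {
    return(tibble::tibble(
      outcome = trait, predictor = predictor_label, odds_ratio = NA_real_,
      log_or = NA_real_, log_or_variance = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, p_value = NA_real_, n = nrow(d),
      covariates = "", model = "ordinary_logit", converged = FALSE))
  }
  res <- fit_logit_policy(d, "y", "x", covariates, model_label = "ordinary_logit")
  out <- logit_wald(res$fit, "x", "ordinary_logit", nrow(d), trait,
                    predictor_label, res$covariates)
  out
}

#' Inverse-variance-weighted combination of two odds ratios
#'
#' Combines two association results for the same outcome and predictor on
#' the log odds-ratio scale with weights equal to the reciprocal variances:
#' the combined log OR is `sum(w_i * logOR_i) / sum(w_i)` with variance
#' `1 / sum(w_i)`; the Wald interval and p-value are recomputed on the
#' combined scale. The operation is symmetric in its arguments and the
#' combined variance never exceeds the smaller input variance.
#'
#' @param first,second One-row association tibbles with finite, positive
#'   `log_or_variance` (as returned by [relative_logit()]).
#' @return A one-row association tibble (`model = "ivw_combined"`).
#' @export
ivw_combine <- function(first, second) {
  stopifnot(nrow(first) == 1, nrow(second) == 1)
  if (!identical(first$outcome, second$outcome) ||
      !identical(first$predictor, second$predictor)) {
    abort("ivw_combine() requires results for the same outcome and predictor",
          class = "twinfam_validation_error")
  }
  v <- c(first$log_or_variance, second$log_or_variance)
  if (any(!is.finite(v)) || any(v <= 0)) {
    abort("ivw_combine() requires finite positive variances",
          class = "twinfam_validation_error")
  }
  w <- 1 / v
  b <- sum(w * c(first$log_or, second$log_or)) / sum(w)
  vc <- 1 / sum(w)
  tibble::tibble(
    outcome = first$outcome, predictor = first$predictor,
    odds_ratio = exp(b), log_or = b, log_or_variance = vc,
    ci_low = exp(b - z975 * sqrt(vc)), ci_high = exp(b + z975 * sqrt(vc)),
    p_value = 2 * pnorm(abs(b / sqrt(vc)), lower.tail = FALSE),
    n = first$n + second$n,
    covariates = first$covariates, model = "ivw_combined",
    converged = first$converged && second$converged)
}

#' Child-relative family association analysis
#'
#' The family analysis of the twin design: one twin per pair is selected at
#' random, regressed on each family member for the same trait by ordinary
#' logistic regression, the analysis is repeated with the co-twins, and the
#' two arm estimates are combined by inverse-variance weighting (the
#' default; `combine = FALSE` reports the selected arm only).
#'
#' @param cohort A classified cohort tibble.
#' @param trait Trait column name.
#' @param relatives Relative roles to analyse (default all five).
#' @param seed Integer seed for the twin selection (mandatory; echoed in the
#'   result).
#' @param combine Combine both selection arms by IVW (default `TRUE`).
#' @param covariates Candidate covariates for [relative_logit()].
#' @return An object of class `family_association` wrapping the per-relative
#'   association tibble; `tidy()` returns it, `autoplot()` draws a forest
#'   plot.
#' @export
family_association <- function(cohort, trait = "lbp_life",
                               relatives = c("mz_cotwin", "dz_cotwin",
                                             "first_sibling", "mother",
                                             "father"),
                               seed, combine = TRUE,
                               covariates = c("age", "sex")) {
  cohort <- select_random_twin(cohort, seed)
  rows <- purrr::map(relatives, function(rel) {
    first <- relative_logit(cohort, trait, rel, arm = "selected",
                            covariates = covariates)
    if (!combine) return(first)
    # second arm: co-twins as outcome (for co-twin relatives this is the
    # same pairs with index/co-twin roles swapped)
    second <- relative_logit(cohort, trait, rel, arm = "cotwin",
                             covariates = covariates)
    if (isTRUE(first$converged) && isTRUE(second$converged)) {
      comb <- ivw_combine(first, second)
      comb$n <- first$n # families, not twin-observations
      comb
    } else {
      first
    }
  })
  out <- dplyr::bind_rows(rows)
  out$relative <- relatives
  structure(list(results = out, trait = trait, seed = as.integer(seed),
                 combine = combine),
            class = "family_association")
}

#' @export
print.family_association <- function(x, ...) {
  cat(sprintf("Family association for %s (seed %d, %s)\n", x$trait, x$seed,
              if (x$combine) "IVW over both twin arms" else "single arm"))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @describeIn family_association Tidy per-relative association table.
#' @param x A `family_association` object.
#' @param ... Unused.
#' @export
tidy.family_association <- function(x, ...) {
  dplyr::select(x$results, "relative", "outcome", "n", "odds_ratio",
                "ci_low", "ci_high", "p_value", "model", "covariates",
                "converged")
}

#' @describeIn family_association Forest plot of per-relative odds ratios.
#' @param object A `family_association` object.
#' @export
autoplot.family_association <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio, y = .data$relative)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI, log scale)", y = NULL,
                  title = paste("Family association:", object$trait)) +
    ggplot2::theme_minimal()
}
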