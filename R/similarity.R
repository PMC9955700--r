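#' Construct a pair-count table
#'
#' Per-zygosity tallies of complete twin pairs for a binary trait: `Nc`
#' pairs with both members affected, `Nd` with exactly one, `N00` with
#' neither. Pairs in which either member is missing for the trait are
#' excluded before counting.
#'
#' @param trait Trait id (character).
#' @param zygosity `"MZ"` or `"DZ"` (vectorised).
#' @param Nc,Nd,N00 Non-negative integer counts (vectorised).
#' @return A tibble of class `pair_counts` with columns `trait`, `zygosity`,
#'   `Nc`, `Nd`, `N00`, `n_pairs`.
#' @export
pair_counts <- function(trait, zygosity, Nc, Nd, N00) {
  stopifnot(all(zygosity %in% c("MZ", "DZ")))
  if (any(c(Nc, Nd, N00) < 0) || any(c(Nc, Nd, N00) != floor(c(Nc, Nd, N00)))) {
    abort("Pair counts must be non-negative integers",
          class = "twinfam_validation_error")
  }
  out <- tibble::tibble(trait = as.character(trait),
                        zygosity = as.character(zygosity),
                        Nc = as.integer(Nc), Nd = as.integer(Nd),
                        N00 = as.integer(N00))
  out$n_pairs <- out$Nc + out$Nd + out$N00
  class(out) <- c("pair_counts", class(out))
  out
}

#' Tabulate concordant and discordant twin pairs from a cohort
#'
#' Counts complete twin pairs by zygosity for one or more binary traits.
#' Only families contributing both `twin1` and `twin2` with a known zygosity
#' are eligible; a pair is counted for a trait only when both members are
#' non-missing for it and neither member is flagged `analysis_excluded`.
#' Dropped pairs (singletons, missing zygosity, missing trait values) are
#' reported in the attached `"drop_log"` attribute.
#'
#' @param cohort A classified cohort tibble (see [classify_back_pain()]).
#' @param traits Character vector of trait column names (default the two
#'   back-pain outcomes).
#' @return A [pair_counts()] tibble with one row per trait x zygosity.
#' @export
tabulate_pairs <- function(cohort, traits = c("lbp_life", "tlbp_current")) {
  stopifnot(all(traits %in% names(cohort)))
  excl <- if ("analysis_excluded" %in% names(cohort)) {
    cohort$analysis_excluded
  } else rep(FALSE, nrow(cohort))
  twins <- cohort[cohort$role %in% c("twin1", "twin2") & !excl, , drop = FALSE]

  wide_ids <- tidyr::pivot_wider(
    dplyr::count(twins, .data$family_id, .data$role),
    names_from = "role", values_from = "n", values_fill = 0L)
  complete_fams <- if (all(c("twin1", "twin2") %in% names(wide_ids))) {
    wide_ids$family_id[wide_ids[["twin1"]] == 1L & wide_ids[["twin2"]] == 1L]
  } else character(0)
  n_singleton <- dplyr::n_distinct(twins$family_id) - length(complete_fams)

  pairs <- twins[twins$family_id %in% complete_fams, , drop = FALSE]
  zyg <- dplyr::summarise(dplyr::group_by(pairs, .data$family_id),
                          zygosity = dplyr::first(stats::na.omit(.data$zygosity)),
                          .groups = "drop")
  n_nozyg <- sum(is.na(zyg$zygosity))
  if (n_nozyg > 0) {
    warn(sprintf("%d complete pair(s) dropped for missing zygosity", n_nozyg))
  }

  drop_log <- list(singleton_families = n_singleton,
                   missing_zygosity_pairs = n_nozyg,
                   missing_trait_pairs = integer())
  res <- list()
  for (tr in traits) {
    w <- tidyr::pivot_wider(
      dplyr::select(pairs, "family_id", "role", value = dplyr::all_of(tr)),
      names_from = "role", values_from = "value")
    w <- dplyr::inner_join(w, zyg, by = "family_id")
    w <- w[!is.na(w$zygosity), , drop = FALSE]
    ok <- !is.na(w$twin1) & !is.na(w$twin2)
    drop_log$missing_trait_pairs[tr] <- sum(!ok)
    w <- w[ok, , drop = FALSE]
    naff <- w$twin1 + w$twin2
    for (z in c("MZ", "DZ")) {
      nz <- naff[w$zygosity == z]
      res[[paste(tr, z)]] <- pair_counts(tr, z, sum(nz == 2L), sum(nz == 1L),
                                         sum(nz == 0L))
    }
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("pair_counts", class(out))
  attr(out, "drop_log") <- drop_log
  out
}

similarity_row <- function(counts, measure, estimate, working, variance,
                           ci_low, ci_high) {
  tibble::tibble(trait = counts$trait, zygosity = counts$zygosity,
                 measure = measure, estimate = estimate,
                 working_estimate = working, working_variance = variance,
                 ci_low = ci_low, ci_high = ci_high)
}

#' Casewise concordance with its normal-approximation interval
#'
#' The casewise (probandwise) concordance is the probability that the
#' co-twin of an affected twin is affected, estimated from pair counts as
#' `C = 2*Nc / (2*Nc + Nd)`. Its variance is estimated as
#' `4*Nc*Nd*(Nc + Nd) / (2*Nc + Nd)^4` and the 95% interval is
#' `C +/- 1.96*sqrt(var)`, truncated to `[0, 1]`.
#'
#' @param counts A [pair_counts()] tibble (vectorised over rows).
#' @return A similarity tibble with one row per input row: `measure`
#'   `"concordance"`, `estimate`, working-scale (`identity`) variance and
#'   the confidence bounds.
#' @export
casewise_concordance <- function(counts) {
  if (any(2 * counts$Nc + counts$Nd == 0)) {
    abort("Casewise concordance undefined: no affected individuals",
          class = "twinfam_undefined_estimate")
  }
  C <- 2 * counts$Nc / (2 * counts$Nc + counts$Nd)
  v <- 4 * counts$Nc * counts$Nd * (counts$Nc + counts$Nd) /
    (2 * counts$Nc + counts$Nd)^4
  similarity_row(counts, "concordance", C, C, v,
                 pmax(0, C - z975 * sqrt(v)), pmin(1, C + z975 * sqrt(v)))
}

#' Double-enter a pair-count table
#'
#' Each pair is tabulated twice (each member once as index, once as
#' co-twin), giving the symmetric 2x2 table `(a, b, c, d) = (2*Nc, Nd, Nd,
#' 2*N00)` on which the pairwise odds ratio and the phi correlation are
#' computed. Cell totals equal twice the number of pairs.
#'
#' @param counts A [pair_counts()] tibble.
#' @return A tibble with columns `trait`, `zygosity`, `a`, `b`, `c`, `d`,
#'   `n_pairs`.
#' @export
double_entry <- function(counts) {
  tibble::tibble(trait = counts$trait, zygosity = counts$zygosity,
                 a = 2L * counts$Nc, b = counts$Nd, c = counts$Nd,
                 d = 2L * counts$N00, n_pairs = counts$n_pairs)
}

as_double_entry <- function(x) {
  if (all(c("a", "b", "c", "d") %in% names(x))) x else double_entry(x)
}

#' Phi correlation of the double-entered table
#'
#' The Pearson correlation of the two binary indicators tabulated by double
#' entry: `(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`. The 95% interval uses
#' the Fisher z-transform with `n` equal to the number of pairs; note this
#' is a documented package choice (see the methods vignette) and does not
#' correspond to every published interval for this statistic.
#'
#' @param x A [pair_counts()] or [double_entry()] tibble.
#' @return A similarity tibble with `measure` `"correlation"`; the working
#'   scale is Fisher z.
#' @export
phi_correlation <- function(x) {
  de <- as_double_entry(x)
  m1 <- as.numeric(de$a + de$b); m2 <- as.numeric(de$c + de$d)
  m3 <- as.numeric(de$a + de$c); m4 <- as.numeric(de$b + de$d)
  if (any(m1 == 0 | m2 == 0 | m3 == 0 | m4 == 0)) {
    abort("Phi correlation undefined: zero margin in the double-entry table",
          class = "twinfam_undefined_estimate")
  }
  phi <- (as.numeric(de$a) * de$d - as.numeric(de$b) * de$c) /
    sqrt(m1 * m2 * m3 * m4)
  vz <- 1 / pmax(de$n_pairs - 3, 1)
  z <- atanh(pmin(pmax(phi, -1 + 1e-12), 1 - 1e-12))
  similarity_row(de, "correlation", phi, z, vz,
                 tanh(z - z975 * sqrt(vz)), tanh(z + z975 * sqrt(vz)))
}

#' Within-pair odds ratio with the Woolf interval
#'
#' The odds ratio of the double-entered table, `ad/(bc) = 4*Nc*N00/Nd^2`,
#' with the Woolf variance of the log odds ratio `1/a + 1/b + 1/c + 1/d`
#' and interval `exp(log OR +/- 1.96*sqrt(var))`.
#'
#' @param x A [pair_counts()] or [double_entry()] tibble.
#' @param continuity `"none"` (default) errors on any zero cell;
#'   `"haldane"` adds 0.5 to every cell of a table containing a zero
#'   (Haldane--Anscombe correction).
#' @return A similarity tibble with `measure` `"odds_ratio"`; the working
#'   scale is log.
#' @export
pairwise_odds_ratio <- function(x, continuity = c("none", "haldane")) {
  continuity <- match.arg(continuity)
  de <- as_double_entry(x)
  a <- as.numeric(de$a); b <- as.numeric(de$b)
  cc <- as.numeric(de$c); d <- as.numeric(de$d)
  zero <- a == 0 | b == 0 | cc == 0 | d == 0
  if (any(zero)) {
    if (continuity == "none") {
      abort("Odds ratio undefined: zero cell in the double-entry table (set continuity = \"haldane\" to apply the 0.5 correction)",
            class = "twinfam_undefined_estimate")
    }
    a[zero] <- a[zero] + 0.5; b[zero] <- b[zero] + 0.5
    cc[zero] <- cc[zero] + 0.5; d[zero] <- d[zero] + 0.5
  }
  or <- a * d / (b * cc)
  v <- 1 / a + 1 / b + 1 / cc + 1 / d
  similarity_row(de, "odds_ratio", or, log(or), v,
                 exp(log(or) - z975 * sqrt(v)), exp(log(or) + z975 * sqrt(v)))
}

#' Test the MZ-DZ difference of a similarity measure
#'
#' Greater similarity of monozygotic (MZ) than dizygotic (DZ) pairs is the
#' classic twin design's evidence for genetic influence. The test compares
#' the two estimates on the measure's working scale (identity for
#' concordance, Fisher z for the correlation, log for the odds ratio):
#' `z = (g(MZ) - g(DZ)) / sqrt(var_MZ + var_DZ)`, with the one-sided
#' p-value the upper-tail normal probability (alternative: MZ more similar)
#' and the two-sided p-value `2 * min(p1, 1 - p1)`.
#'
#' @param similarity A similarity tibble containing an MZ and a DZ row per
#'   trait x measure (as produced by the estimators or [twin_similarity()]).
#' @return A tibble with one row per trait x measure: `z_statistic`,
#'   `p_one_sided`, `p_two_sided`.
#' @export
zygosity_difference <- function(similarity) {
  paired <- tidyr::pivot_wider(
    dplyr::select(similarity, "trait", "measure", "zygosity",
                  "working_estimate", "working_variance"),
    names_from = "zygosity",
    values_from = c("working_estimate", "working_variance"))
  need <- c("working_estimate_MZ", "working_estimate_DZ",
            "working_variance_MZ", "working_variance_DZ")
  if (!all(need %in% names(paired))) {
    abort("Need both an MZ and a DZ estimate per trait and measure",
          class = "twinfam_validation_error")
  }
  vsum <- paired$working_variance_MZ + paired$working_variance_DZ
  if (any(vsum <= 0)) {
    abort("Degenerate zygosity test: zero combined variance",
          class = "twinfam_degenerate_test")
  }
  z <- (paired$working_estimate_MZ - paired$working_estimate_DZ) / sqrt(vsum)
  p1 <- pnorm(z, lower.tail = FALSE)
  tibble::tibble(trait = paired$trait, measure = paired$measure,
                 z_statistic = z, p_one_sided = p1,
                 p_two_sided = 2 * pmin(p1, 1 - p1))
}

#' Twin-pair similarity analysis
#'
#' Computes the three similarity measures -- casewise concordance, phi
#' correlation of the double-entered table, and the within-pair odds ratio
#' with Woolf interval -- for each trait and zygosity in a pair-count
#' table, together with the MZ-versus-DZ difference test for each measure.
#'
#' @param counts A [pair_counts()] tibble (or a classified cohort, which is
#'   first passed through [tabulate_pairs()]).
#' @param measures Subset of `c("concordance", "correlation",
#'   "odds_ratio")`; default all three.
#' @param continuity Passed to [pairwise_odds_ratio()].
#' @param traits Traits to tabulate when `counts` is a cohort.
#' @return An object of class `twin_similarity`: a list with `estimates`
#'   (one row per trait x zygosity x measure), `comparisons` (the zygosity
#'   difference tests) and `counts`. Use [tidy()] for a single tidy table,
#'   [glance()] for a one-row summary, and [autoplot()] for a forest-style
#'   display.
#' @examples
#' counts <- pair_counts(
#'   trait = c("lbp_life", "lbp_life"), zygosity = c("MZ", "DZ"),
#'   Nc = c(19, 10), Nd = c(41, 59), N00 = c(215, 307))
#' fit <- twin_similarity(counts)
#' tidy(fit)
#' @export
twin_similarity <- function(counts,
                            measures = c("concordance", "correlation", "odds_ratio"),
                            continuity = c("none", "haldane"),
                            traits = c("lbp_life", "tlbp_current")) {
  continuity <- match.arg(continuity)
  measures <- match.arg(measures, several.ok = TRUE)
  if (!inherits(counts, "pair_counts")) {
    counts <- tabulate_pairs(counts, traits = traits)
  }
  est <- dplyr::bind_rows(
    if ("concordance" %in% measures) casewise_concordance(counts),
    if ("correlation" %in% measures) phi_correlation(counts),
    if ("odds_ratio" %in% measures) pairwise_odds_ratio(counts, continuity)
  )
  cmp <- if (all(c("MZ", "DZ") %in% counts$zygosity)) {
    zygosity_difference(est)
  } else {
    tibble::tibble(trait = character(), measure = character(),
                   z_statistic = double(), p_one_sided = double(),
                   p_two_sided = double())
  }
  structure(list(estimates = est, comparisons = cmp, counts = counts),
            class = "twin_similarity")
}

#' @export
print.twin_similarity <- function(x, ...) {
  cat("Twin-pair similarity analysis\n")
  cat(sprintf("  %d trait(s), %d pair-count rows\n",
              dplyr::n_distinct(x$counts$trait), nrow(x$counts)))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @describeIn twin_similarity Tidy table of estimates joined with the
#'   per-measure zygosity comparison p-values.
#' @param x A `twin_similarity` object.
#' @param ... Unused.
#' @export
tidy.twin_similarity <- function(x, ...) {
  dplyr::left_join(
    dplyr::select(x$estimates, "trait", "zygosity", "measure", "estimate",
                  "ci_low", "ci_high"),
    dplyr::select(x$comparisons, "trait", "measure", "p_one_sided",
                  "p_two_sided"),
    by = c("trait", "measure"))
}

#' @describeIn twin_similarity One row per trait with pair totals and the
#'   smallest one-sided comparison p-value.
#' @export
glance.twin_similarity <- function(x, ...) {
  totals <- dplyr::summarise(dplyr::group_by(x$counts, .data$trait),
                             n_pairs = sum(.data$n_pairs), .groups = "drop")
  if (nrow(x$comparisons) > 0) {
    pmin_ <- dplyr::summarise(dplyr::group_by(x$comparisons, .data$trait),
                              min_p_one_sided = min(.data$p_one_sided),
                              .groups = "drop")
    totals <- dplyr::left_join(totals, pmin_, by = "trait")
  }
  totals
}

#' @describeIn twin_similarity Forest-style plot of the estimates by
#'   zygosity; odds ratios are shown on a log scale.
#' @param object A `twin_similarity` object.
#' @export
autoplot.twin_similarity <- function(object, ...) {
  d <- tidy(object)
  d$measure <- factor(d$measure,
                      levels = c("concordance", "correlation", "odds_ratio"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$trait,
                                  colour = .data$zygosity)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~measure, scales = "free_x") +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL,
                  title = "Twin-pair similarity by zygosity") +
    ggplot2::theme_minimal()
}

#' Render a similarity table in report style
#'
#' Applies the report rounding conventions (half-up; concordance and
#' correlation to 2 decimals, odds ratios to 3 significant figures,
#' p-values to 3 decimals) to a [twin_similarity()] fit.
#'
#' @param fit A `twin_similarity` object.
#' @return A tibble in printed-table style.
#' @export
similarity_report <- function(fit) {
  d <- tidy(fit)
  rnd <- function(measure, x) {
    ifelse(measure == "odds_ratio", signif_half_up(x, 3), round_half_up(x, 2))
  }
  dplyr::transmute(d, .data$trait, .data$zygosity, .data$measure,
                   estimate = rnd(.data$measure, .data$estimate),
                   ci_low = rnd(.data$measure, .data$ci_low),
                   ci_high = rnd(.data$measure, .data$ci_high),
                   p_one_sided = round_half_up(.data$p_one_sided, 3),
                   p_two_sided = round_half_up(.data$p_two_sided, 3))
}
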