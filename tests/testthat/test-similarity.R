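mz_lbp <- pair_counts("lbp_life", "MZ", 19, 41, 215)
dz_lbp <- pair_counts("lbp_life", "DZ", 10, 59, 307)
mz_tlbp <- pair_counts("tlbp_current", "MZ", 13, 36, 223)
dz_tlbp <- pair_counts("tlbp_current", "DZ", 5, 52, 316)

test_that("casewise concordance matches hand-derived values and intervals", {
  c1 <- casewise_concordance(mz_lbp)
  expect_equal(c1$estimate, 38 / 79, tolerance = 1e-12)
  expect_equal(c1$working_variance, 4 * 19 * 41 * 60 / (79^4))
  expect_equal(round(c1$ci_low, 2), 0.35, tolerance = 1e-8)
  expect_equal(round(c1$ci_high, 2), 0.62, tolerance = 1e-8)
  expect_equal(casewise_concordance(mz_tlbp)$estimate, 26 / 62)
  # perfect concordance: no discordant pairs
  perf <- casewise_concordance(pair_counts("t", "MZ", 5, 0, 10))
  expect_equal(perf$estimate, 1)
  expect_equal(perf$working_variance, 0)
  expect_error(casewise_concordance(pair_counts("t", "MZ", 0, 0, 10)),
               class = "twinfam_undefined_estimate")
})

test_that("concordance equals the enumeration conditional probability", {
  withr::with_seed(11, {
    for (i in 1:25) {
      Nc <- sample(1:15, 1); Nd <- sample(1:15, 1); N00 <- sample(0:20, 1)
      est <- casewise_concordance(pair_counts("t", "MZ", Nc, Nd, N00))$estimate
      expect_equal(est, concordance_by_enumeration(Nc, Nd, N00))
    }
  })
})

test_that("double entry doubles concordant cells and mirrors discordants", {
  de <- double_entry(mz_lbp)
  expect_equal(unlist(de[c("a", "b", "c", "d")], use.names = FALSE),
               c(38, 41, 41, 430))
  expect_equal(unlist(double_entry(pair_counts("t", "MZ", 0, 0, 10))[
    c("a", "b", "c", "d")], use.names = FALSE), c(0, 0, 0, 20))
  expect_equal(unlist(double_entry(dz_tlbp)[c("a", "b", "c", "d")],
                      use.names = FALSE), c(10, 52, 52, 632))
  expect_equal(de$a + de$b + de$c + de$d, 2 * mz_lbp$n_pairs)
})

test_that("phi correlation reproduces hand-computed values", {
  expect_equal(round(phi_correlation(mz_lbp)$estimate, 2), 0.39)
  expect_equal(phi_correlation(mz_lbp)$estimate,
               (38 * 430 - 41 * 41) / sqrt(79 * 471 * 79 * 471))
  expect_equal(round(phi_correlation(dz_tlbp)$estimate, 2), 0.09)
  expect_equal(phi_correlation(dz_tlbp)$estimate,
               (10 * 632 - 52 * 52) / (62 * 684))
  # independence: ad = bc
  ind <- phi_correlation(tibble::tibble(trait = "t", zygosity = "MZ",
                                        a = 4, b = 2, c = 2, d = 1,
                                        n_pairs = 5))
  expect_equal(ind$estimate, 0)
  expect_error(phi_correlation(pair_counts("t", "MZ", 0, 0, 10)),
               class = "twinfam_undefined_estimate")
})

test_that("phi is symmetric under transposition and bounded in [-1, 1]", {
  withr::with_seed(12, {
    for (i in 1:30) {
      x <- pair_counts("t", "MZ", sample(1:20, 1), sample(1:20, 1),
                       sample(1:20, 1))
      de <- double_entry(x)
      phi <- phi_correlation(de)$estimate
      tr <- tibble::tibble(trait = "t", zygosity = "MZ", a = de$a, b = de$c,
                           c = de$b, d = de$d, n_pairs = de$n_pairs)
      expect_equal(phi_correlation(tr)$estimate, phi)
      expect_gte(phi, -1); expect_lte(phi, 1)
    }
  })
})

test_that("pairwise odds ratio reproduces published-style values with Woolf CIs", {
  or1 <- pairwise_odds_ratio(mz_lbp)
  expect_equal(or1$estimate, 38 * 430 / (41 * 41))
  expect_equal(signif(or1$estimate, 3), 9.72)
  expect_equal(round(or1$ci_low, 2), 5.63)
  expect_equal(signif(or1$ci_high, 3), 16.8)
  or2 <- pairwise_odds_ratio(dz_lbp)
  expect_equal(signif(or2$estimate, 3), 3.53)
  expect_equal(round(or2$ci_low, 2), 1.99)
  expect_equal(round(or2$ci_high, 2), 6.26)
  # uniform table
  unif <- pairwise_odds_ratio(tibble::tibble(trait = "t", zygosity = "MZ",
                                             a = 3, b = 3, c = 3, d = 3,
                                             n_pairs = 6))
  expect_equal(unif$estimate, 1)
})

test_that("zero cells error by default and shift by 0.5 under Haldane", {
  zc <- pair_counts("t", "MZ", 5, 0, 10)
  expect_error(pairwise_odds_ratio(zc), class = "twinfam_undefined_estimate")
  h <- pairwise_odds_ratio(zc, continuity = "haldane")
  expect_equal(h$estimate, 10.5 * 20.5 / 0.25)
})

test_that("the double-entry identity OR = 4*Nc*N00/Nd^2 holds exhaustively", {
  for (total in c(5, 10, 20)) {
    for (Nc in 1:(total - 2)) {
      for (Nd in 1:(total - Nc - 1)) {
        N00 <- total - Nc - Nd
        x <- pair_counts("t", "MZ", Nc, Nd, N00)
        or <- pairwise_odds_ratio(x)$estimate
        expect_equal(or, 4 * Nc * N00 / Nd^2)
        expect_equal(or, odds_ratio_by_enumeration(Nc, Nd, N00))
      }
    }
  }
})

test_that("moving a pair from discordant to concordant raises all measures", {
  base <- pair_counts("t", "MZ", 5, 10, 30)
  more <- pair_counts("t", "MZ", 6, 8, 31) # one discordant pair made concordant
  expect_gt(casewise_concordance(more)$estimate,
            casewise_concordance(base)$estimate)
  expect_gt(phi_correlation(more)$estimate, phi_correlation(base)$estimate)
  expect_gt(pairwise_odds_ratio(more)$estimate,
            pairwise_odds_ratio(base)$estimate)
})

test_that("MZ-DZ comparison reproduces the hand-derived z-tests", {
  counts <- dplyr::bind_rows(mz_lbp, dz_lbp)
  fit <- twin_similarity(counts)
  cmp <- fit$comparisons
  p_conc <- cmp$p_one_sided[cmp$measure == "concordance"]
  expect_equal(round(p_conc, 3), 0.008)
  p_or <- cmp$p_two_sided[cmp$measure == "odds_ratio"]
  expect_equal(round(p_or, 3), 0.012)
  # the OR z-statistic, by hand
  z_hand <- (log(9.720405) - log(3.527722)) /
    sqrt((1 / 38 + 2 / 41 + 1 / 430) + (1 / 20 + 2 / 59 + 1 / 614))
  expect_equal(cmp$z_statistic[cmp$measure == "odds_ratio"], z_hand,
               tolerance = 1e-5)
})

test_that("identical MZ and DZ estimates give z = 0 and one-sided p = 0.5", {
  counts <- dplyr::bind_rows(pair_counts("t", "MZ", 5, 10, 30),
                             pair_counts("t", "DZ", 5, 10, 30))
  cmp <- twin_similarity(counts)$comparisons
  expect_equal(cmp$z_statistic, rep(0, 3))
  expect_equal(cmp$p_one_sided, rep(0.5, 3))
  expect_equal(cmp$p_two_sided, rep(1, 3))
})

test_that("tabulate_pairs counts complete non-missing pairs once", {
  coh <- dplyr::bind_rows(
    make_cohort("A", "twin1", "MZ", lbp_endorsed = 1L),
    make_cohort("A", "twin2", "MZ", lbp_endorsed = 1L),
    make_cohort("B", "twin1", "MZ", lbp_endorsed = 1L),
    make_cohort("B", "twin2", "MZ", lbp_endorsed = 0L),
    make_cohort("C", "twin1", "MZ", lbp_endorsed = 0L),
    make_cohort("C", "twin2", "MZ", lbp_endorsed = NA),
    make_cohort("D", "twin1", "MZ", lbp_endorsed = 0L)) # singleton
  cl <- classify_back_pain(coh)
  pc <- tabulate_pairs(cl, "lbp_life")
  mz <- pc[pc$zygosity == "MZ", ]
  expect_equal(c(mz$Nc, mz$Nd, mz$N00), c(1L, 1L, 0L))
  log <- attr(pc, "drop_log")
  expect_equal(log$singleton_families, 1L)
  expect_equal(unname(log$missing_trait_pairs["lbp_life"]), 1L)
})

test_that("a cohort with no affected twins tabulates to (0, 0, n)", {
  coh <- dplyr::bind_rows(
    make_cohort(c("A", "A"), c("twin1", "twin2"), "MZ"),
    make_cohort(c("B", "B"), c("twin1", "twin2"), "DZ"))
  pc <- tabulate_pairs(classify_back_pain(coh), "lbp_life")
  expect_equal(pc$Nc, c(0L, 0L))
  expect_equal(pc$Nd, c(0L, 0L))
  expect_equal(pc$N00, c(1L, 1L))
})

test_that("one-sided rejection rate tracks asymptotic power on sampled pairs", {
  n_pairs <- 600; q <- 0.2
  r_mz <- 0.6; r_dz <- 0.3
  th_mz <- theoretical_similarity(q = q, r = r_mz)
  th_dz <- theoretical_similarity(q = q, r = r_dz)
  # expected counts -> asymptotic noncentrality of the concordance z-test
  exp_var <- function(th) {
    Nc <- n_pairs * th$p11; Nd <- n_pairs * 2 * (q - th$p11)
    4 * Nc * Nd * (Nc + Nd) / (2 * Nc + Nd)^4
  }
  ncp <- (th_mz$concordance - th_dz$concordance) /
    sqrt(exp_var(th_mz) + exp_var(th_dz))
  power <- pnorm(qnorm(0.95), mean = ncp, lower.tail = FALSE)
  n_rep <- 300
  rej <- withr::with_seed(77, vapply(seq_len(n_rep), function(i) {
    counts <- dplyr::bind_rows(
      sample_pair_counts(n_pairs, q, r_mz, zygosity = "MZ"),
      sample_pair_counts(n_pairs, q, r_dz, zygosity = "DZ"))
    twin_similarity(counts, measures = "concordance")$
      comparisons$p_one_sided < 0.05
  }, logical(1)))
  mc_se <- sqrt(power * (1 - power) / n_rep)
  expect_lt(abs(mean(rej) - power), 3 * mc_se + 0.01)
})

test_that("tidy/glance/report render a similarity fit", {
  fit <- twin_similarity(dplyr::bind_rows(mz_lbp, dz_lbp, mz_tlbp, dz_tlbp))
  td <- tidy(fit)
  expect_equal(nrow(td), 12)
  expect_true(all(td$ci_low <= td$estimate & td$estimate <= td$ci_high))
  gl <- glance(fit)
  expect_equal(gl$n_pairs, c(651L, 645L))
  rep_ <- similarity_report(fit)
  expect_equal(rep_$estimate[rep_$measure == "odds_ratio"],
               c(9.72, 3.53, 8.95, 2.34))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
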