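clustered_sim <- function(n_fam, beta, sigma, per_fam = 2, beta0 = -1,
                          x_between = FALSE) {
  u <- rnorm(n_fam, 0, sigma)
  fam <- rep(sprintf("F%04d", seq_len(n_fam)), each = per_fam)
  x <- if (x_between) {
    rep(rbinom(n_fam, 1, 0.5), each = per_fam)
  } else {
    rbinom(n_fam * per_fam, 1, 0.5)
  }
  eta <- beta0 + beta * x + rep(u, each = per_fam)
  tibble::tibble(family_id = fam, y = rbinom(length(x), 1, stats::plogis(eta)),
                 x = x)
}

test_that("at the zero-variance boundary the random-intercept fit matches glm", {
  # data simulated with no cluster effect; the variance MLE lands on the
  # boundary and the fixed effect must then equal the ordinary logit
  d <- withr::with_seed(4, clustered_sim(400, beta = log(2), sigma = 0,
                                         per_fam = 3))
  ri <- random_intercept_logit(d, "y", "x", covariates = character())
  or_glm <- exp(coef(glm(y ~ x, binomial(), d))["x"])
  expect_equal(ri$cluster_sd, 0, tolerance = 1e-6)
  expect_lt(abs(ri$log_or - log(or_glm)), 1e-4)
  expect_true(ri$converged)
})

test_that("univariate OR without covariates equals the cross-tab ad/bc", {
  d <- withr::with_seed(6, clustered_sim(300, beta = log(3), sigma = 0))
  tab <- table(d$x, d$y)
  or_tab <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  ri <- random_intercept_logit(d, "y", "x", covariates = character())
  expect_equal(ri$odds_ratio, or_tab, tolerance = 1e-3)
})

test_that("between-cluster-only predictors are still estimable", {
  d <- withr::with_seed(7, clustered_sim(500, beta = log(2), sigma = 0.7,
                                         x_between = TRUE))
  ri <- random_intercept_logit(d, "y", "x", covariates = character())
  expect_true(is.finite(ri$log_or))
  expect_true(ri$converged)
})

test_that("degenerate regression inputs raise informative errors", {
  d <- withr::with_seed(8, clustered_sim(50, beta = 0, sigma = 0.5))
  d$z <- 1L
  expect_error(random_intercept_logit(d, "y", "z", covariates = character()),
               "Constant", class = "twinfam_validation_error")
  d1 <- d[d$family_id == d$family_id[1], ]
  expect_error(random_intercept_logit(d1, "y", "x", covariates = character()),
               class = "twinfam_validation_error")
})

region_cohort <- function(n, planted_site = NULL, null_site = NULL,
                          or_planted = 6, prev = 0.25, role = "mother") {
  y <- rbinom(n, 1, prev)
  mk_site <- function(site, or) {
    p0 <- 0.15
    odds <- p0 / (1 - p0) * ifelse(y == 1, or, 1)
    ifelse(rbinom(n, 1, odds / (1 + odds)) == 1, site, "")
  }
  sites <- rep("", n)
  if (!is.null(planted_site)) {
    sites <- paste(sites, mk_site(planted_site, or_planted), sep = ";")
  }
  if (!is.null(null_site)) {
    sites <- paste(sites, mk_site(null_site, 1), sep = ";")
  }
  sites <- gsub("^;+|;+$", "", sites)
  make_cohort(sprintf("F%05d", seq_len(n)), role,
              if (role %in% c("twin1", "twin2")) "MZ" else NA_character_,
              age = 45, pain_sites = sites, lbp_endorsed = y,
              current_pain = as.integer(sites != ""))
}

test_that("planted region effects are detected and nulls are not retained", {
  coh <- withr::with_seed(41, region_cohort(1200, planted_site = "neck",
                                            null_site = "head"))
  cl <- classify_back_pain(coh)
  tab <- build_association_table(cl, "lbp_life", "regions", "mothers")
  rows <- tidy(tab)
  neck <- rows[rows$predictor == "region_neck", ]
  head_ <- rows[rows$predictor == "region_head", ]
  expect_lt(neck$p_uni, 0.001)
  expect_true(neck$retained)
  expect_gt(head_$p_uni, 0.05)
  expect_false(head_$retained)
  expect_gt(neck$or_uni, head_$or_uni)
})

test_that("the outcome's own regions never appear as predictors", {
  coh <- withr::with_seed(42, region_cohort(600, planted_site = "neck"))
  cl <- classify_back_pain(coh)
  tab <- build_association_table(cl, "lbp_life", "regions", "mothers",
                                 min_count = 1)
  expect_false("region_lower_back" %in% tidy(tab)$predictor)
  # for the thoracolumbar outcome both back regions are excluded, and
  # multiple_sites counts non-outcome regions only
  coh2 <- withr::with_seed(43, region_cohort(600, planted_site = "neck"))
  coh2$pain_sites <- paste0(coh2$pain_sites,
                            ifelse(seq_len(600) %% 2 == 0, ";middle_back", ""))
  coh2$pain_sites <- gsub("^;", "", coh2$pain_sites)
  cl2 <- classify_back_pain(coh2)
  tab2 <- build_association_table(cl2, "tlbp_current", "regions", "mothers",
                                  min_count = 1)
  expect_false(any(c("region_lower_back", "region_middle_back") %in%
                     tidy(tab2)$predictor))
})

test_that("parent populations use ordinary logistic regression", {
  coh <- withr::with_seed(44, region_cohort(400, planted_site = "neck"))
  cl <- classify_back_pain(coh)
  tab <- build_association_table(cl, "lbp_life", "regions", "mothers",
                                 min_count = 1)
  expect_equal(tab$model, "ordinary_logit")
  expect_equal(glance(tab)$population, "mothers")
  expect_error(
    build_association_table(cl[0, ], "lbp_life", "regions", "mothers"),
    class = "twinfam_empty_table_error")
})

test_that("all predictors below the low-count threshold raise an empty-table error", {
  coh <- withr::with_seed(45, region_cohort(200, planted_site = NULL))
  cl <- classify_back_pain(coh)
  expect_error(
    build_association_table(cl, "lbp_life", "regions", "mothers"),
    class = "twinfam_empty_table_error")
})

test_that("retention flags on null predictors fire near the nominal 5% rate", {
  n_rep <- 150
  flags <- withr::with_seed(46, unlist(lapply(seq_len(n_rep), function(i) {
    coh <- region_cohort(400, planted_site = "neck", null_site = "head",
                         or_planted = 1) # both null
    cl <- classify_back_pain(coh)
    tab <- tryCatch(
      build_association_table(cl, "lbp_life", "regions", "mothers"),
      error = function(e) NULL)
    if (is.null(tab)) return(NULL)
    rows <- tidy(tab)
    rows$retained[rows$predictor %in% c("region_neck", "region_head")]
  })))
  rate <- mean(flags)
  mc_se <- sqrt(0.05 * 0.95 / length(flags))
  expect_lt(abs(rate - 0.05), 3 * mc_se)
})

test_that("the cross-trait positive control behaves under shared and null liability", {
  cfg <- ace_config(n_families = 900, seed = 17)
  cl <- classify_back_pain(simulate_cohort(cfg))
  chk <- expected_cross_trait_check(cl, nagq = 7)
  expect_equal(chk$check, rep("cross_trait_positive_control", 3))
  expect_true(all(chk$odds_ratio > 3)) # strongly positive in every population
  # independent traits: association near the null
  traits0 <- cfg$traits
  traits0$loading[2] <- 0
  cfg0 <- ace_config(n_families = 2500, traits = traits0, seed = 18)
  cl0 <- classify_back_pain(simulate_cohort(cfg0))
  chk0 <- expected_cross_trait_check(cl0, nagq = 7)
  off <- chk0[chk0$population == "twins_and_siblings", ]
  expect_lt(abs(off$log_or), 3 * sqrt(off$log_or_variance))
})
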