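default_traits <- function() {
  tibble::tibble(
    trait = c("lbp_life", "tlbp_current"),
    kind = c("lbp", "tlbp"),
    a2 = c(0.69, 0.65),
    c2 = c(0, 0),
    prev_twin = c(0.121, 0.096),
    prev_sibling = c(0.121, 0.100),
    prev_mother = c(0.420, 0.266),
    prev_father = c(0.399, 0.231),
    age_or = c(1.24, 1.15),
    loading = c(NA_real_, 0.748),
    site = c(NA_character_, "lower_back")
  )
}

default_ages <- function() {
  list(twin = list(mean = 15.3, sd = 2.42, range = c(6, 20)),
       first_sibling = list(mean = 15.7, sd = 4.61, range = c(4, 36)),
       mother = list(mean = 46.3, sd = 4.93, range = c(30, 64)),
       father = list(mean = 48.7, sd = 5.78, range = c(35, 78)))
}

#' Configuration for the ACE liability-threshold cohort simulator
#'
#' Describes a twin-family cohort generator under the liability-threshold
#' model: each binary trait arises when a standard-normal latent liability
#' exceeds a role-specific threshold set by that role's prevalence.
#' Familial resemblance is modelled as liability correlation: `a2 + c2`
#' within MZ pairs, `a2/2 + c2` within DZ pairs and sibling pairs, and
#' `a2/2` between parents and offspring (`a2` additive genetic, `c2` shared
#' environment, `e2 = 1 - a2 - c2` unique).
#'
#' Defaults are calibrated to the study this package emulates: 651 families
#' with a 42.2% MZ fraction, a first sibling in 64.5% and mother/father in
#' 98.3%/86.9% of families; lifetime low back pain (`lbp_life`) at
#' offspring prevalence 12.1% and parental prevalences 42.0%/39.9% with
#' liability `a2 = 0.69` (solved from the printed twin concordances via the
#' orthant oracle); current thoracolumbar pain (`tlbp_current`) at
#' 9.6--10% / 26.6% / 23.1% with `a2 = 0.65` and a within-person
#' cross-trait loading of 0.748 on the low-back liability (reproducing a
#' cross-trait odds ratio near 17.7). Age enters through a probit bridge of
#' the logistic slope (`log(age_or) / 1.7` per year) for offspring; parents
#' receive their own thresholds instead of age extrapolation.
#'
#' @param n_families Number of families.
#' @param mz_fraction Proportion of twin pairs that are MZ.
#' @param sibling_prob,mother_prob,father_prob Probability that a family
#'   contributes a first sibling / mother / father.
#' @param traits Trait specification tibble; see `default_traits()` in the
#'   source for the column layout (`kind` is one of `"lbp"` -- lifetime
#'   endorsement column, `"tlbp"`/`"site"` -- current pain at `site`,
#'   `"indicator"` -- its own tristate column).
#' @param ages Per-role age distributions (mean, sd, range; truncated
#'   normal).
#' @param missing_rate MCAR missingness applied to the trait answer columns
#'   (default 0).
#' @param injury_rate Fraction of lifetime low-back-pain cases that also
#'   report a minor injury attribution (default 0.319; such cases remain
#'   cases).
#' @param seed Default integer seed used by [simulate_cohort()].
#' @return A list of class `ace_config`.
#' @export
ace_config <- function(n_families = 651, mz_fraction = 0.422,
                       sibling_prob = 420 / 651, mother_prob = 640 / 651,
                       father_prob = 566 / 651, traits = default_traits(),
                       ages = default_ages(), missing_rate = 0,
                       injury_rate = 0.319, seed = 20230214) {
  stopifnot(n_families >= 1, mz_fraction > 0, mz_fraction < 1,
            missing_rate >= 0, missing_rate < 1)
  traits <- tibble::as_tibble(traits)
  if (any(traits$a2 < 0 | traits$c2 < 0 | traits$a2 + traits$c2 > 1)) {
    abort("Need a2 >= 0, c2 >= 0 and a2 + c2 <= 1 for every trait",
          class = "twinfam_config_error")
  }
  prev_cols <- c("prev_twin", "prev_sibling", "prev_mother", "prev_father")
  pv <- unlist(traits[prev_cols])
  if (any(pv <= 0 | pv >= 1)) {
    abort("Prevalences must lie in (0, 1)", class = "twinfam_config_error")
  }
  if (any(!is.na(traits$loading) & abs(traits$loading) >= 1)) {
    abort("Cross-trait loadings must lie in (-1, 1)",
          class = "twinfam_config_error")
  }
  structure(list(n_families = as.integer(n_families),
                 mz_fraction = mz_fraction, sibling_prob = sibling_prob,
                 mother_prob = mother_prob, father_prob = father_prob,
                 traits = traits, ages = ages, missing_rate = missing_rate,
                 injury_rate = injury_rate, seed = as.integer(seed)),
            class = "ace_config")
}

# Familial liability correlation matrix for the 5 potential members
# (twin1, twin2, first_sibling, mother, father).
liability_sigma <- function(a2, c2, zygosity) {
  r_tw <- if (zygosity == "MZ") a2 + c2 else a2 / 2 + c2
  r_sib <- a2 / 2 + c2
  r_po <- a2 / 2
  S <- diag(5)
  S[1, 2] <- S[2, 1] <- r_tw
  S[1, 3] <- S[3, 1] <- S[2, 3] <- S[3, 2] <- r_sib
  for (i in 1:3) for (j in 4:5) S[i, j] <- S[j, i] <- r_po
  S
}

truncnorm_draw <- function(n, mean, sd, range) {
  lo <- pnorm(range[1], mean, sd)
  hi <- pnorm(range[2], mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

# exact mean/variance of the truncated normal used for age draws
truncnorm_moments <- function(mean, sd, range) {
  a <- (range[1] - mean) / sd
  b <- (range[2] - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  dm <- (stats::dnorm(a) - stats::dnorm(b)) / Z
  m <- mean + sd * dm
  v <- sd^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / Z - dm^2)
  list(mean = m, var = v)
}

truncnorm_density <- function(x, mean, sd, range) {
  Z <- pnorm(range[2], mean, sd) - pnorm(range[1], mean, sd)
  stats::dnorm(x, mean, sd) / Z
}

#' Simulate a twin-family cohort under the ACE liability-threshold model
#'
#' Draws multivariate-normal liabilities with the familial correlation
#' structure of [ace_config()], converts them to binary traits by
#' role-specific thresholds `qnorm(1 - prevalence)` (inflated by
#' `sqrt(1 + beta^2 * var(age))` where the per-year probit age slope
#' `beta = log(age_or) / 1.7` enters the offspring liability, so that the
#' marginal prevalence stays at its target), and assembles individual
#' records in the same cohort schema that [read_cohort()] ingests. Traits
#' after the first receive within-person cross-trait correlation through
#' their `loading` on the first trait's liability.
#'
#' The draw is fully determined by `seed` (the global RNG state is left
#' untouched): the same seed yields a byte-identical cohort CSV via
#' [write_cohort()].
#'
#' @param config An [ace_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A cohort tibble.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "ace_config"))
  withr::with_seed(as.integer(seed), simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  nf <- config$n_families
  fam <- sprintf("F%05d", seq_len(nf))
  zyg <- ifelse(runif(nf) < config$mz_fraction, "MZ", "DZ")
  has_sib <- runif(nf) < config$sibling_prob
  has_mo <- runif(nf) < config$mother_prob
  has_fa <- runif(nf) < config$father_prob

  ages <- config$ages
  age_tw <- round(truncnorm_draw(nf, ages$twin$mean, ages$twin$sd,
                                 ages$twin$range), 1)
  age_sib <- round(truncnorm_draw(nf, ages$first_sibling$mean,
                                  ages$first_sibling$sd,
                                  ages$first_sibling$range), 1)
  age_mo <- round(truncnorm_draw(nf, ages$mother$mean, ages$mother$sd,
                                 ages$mother$range), 1)
  age_fa <- round(truncnorm_draw(nf, ages$father$mean, ages$father$sd,
                                 ages$father$range), 1)
  sex1 <- ifelse(runif(nf) < 0.5, "male", "female")
  sex2 <- ifelse(zyg == "MZ", sex1, ifelse(runif(nf) < 0.5, "male", "female"))
  sex_sib <- ifelse(runif(nf) < 0.5, "male", "female")

  traits <- config$traits
  age_mat <- cbind(age_tw, age_tw, age_sib, age_mo, age_fa)
  roles <- c("twin1", "twin2", "first_sibling", "mother", "father")
  prev_col <- c(twin1 = "prev_twin", twin2 = "prev_twin",
                first_sibling = "prev_sibling", mother = "prev_mother",
                father = "prev_father")
  mom <- lapply(list(ages$twin, ages$twin, ages$first_sibling, ages$mother,
                     ages$father),
                function(a) truncnorm_moments(a$mean, a$sd, a$range))
  age_mean <- vapply(mom, `[[`, numeric(1), "mean")
  age_var <- vapply(mom, `[[`, numeric(1), "var")

  # liability draws: n_families x 5 per trait, familial structure by zygosity
  draw_liab <- function(a2, c2) {
    L <- matrix(0, nf, 5)
    for (z in c("MZ", "DZ")) {
      idx <- which(zyg == z)
      if (length(idx) == 0) next
      S <- liability_sigma(a2, c2, z)
      R <- tryCatch(chol(S), error = function(e) {
        abort("Infeasible liability correlation matrix (not positive definite)",
              class = "twinfam_config_error")
      })
      Z <- matrix(rnorm(length(idx) * 5), ncol = 5)
      L[idx, ] <- Z %*% R
    }
    L
  }

  liab <- vector("list", nrow(traits))
  case <- vector("list", nrow(traits))
  for (k in seq_len(nrow(traits))) {
    tr <- traits[k, ]
    own <- draw_liab(tr$a2, tr$c2)
    L <- if (k > 1 && !is.na(tr$loading) && tr$loading != 0) {
      tr$loading * liab[[1]] + sqrt(1 - tr$loading^2) * own
    } else own
    liab[[k]] <- L
    beta <- log(tr$age_or) / 1.7
    cs <- matrix(FALSE, nf, 5)
    for (j in seq_along(roles)) {
      q <- tr[[prev_col[roles[j]]]]
      offspring <- j <= 3
      b <- if (offspring) beta else 0
      thr <- qnorm(1 - q) * sqrt(1 + b^2 * age_var[j])
      cs[, j] <- (L[, j] + b * (age_mat[, j] - age_mean[j])) > thr
    }
    case[[k]] <- cs
  }
  names(case) <- traits$trait

  present <- cbind(TRUE, TRUE, has_sib, has_mo, has_fa)
  rows <- list()
  for (j in seq_along(roles)) {
    idx <- which(present[, j])
    if (length(idx) == 0) next
    rj <- roles[j]
    rec <- tibble::tibble(
      family_id = fam[idx], role = rj,
      zygosity = if (rj %in% c("twin1", "twin2")) zyg[idx] else NA_character_,
      age = age_mat[idx, j],
      sex = switch(rj, twin1 = sex1[idx], twin2 = sex2[idx],
                   first_sibling = sex_sib[idx],
                   mother = rep("female", length(idx)),
                   father = rep("male", length(idx))))
    sites <- rep("", length(idx))
    for (k in seq_len(nrow(traits))) {
      tr <- traits[k, ]
      pos <- case[[k]][idx, j]
      if (tr$kind %in% c("tlbp", "site")) {
        sites <- ifelse(pos, ifelse(sites == "", tr$site,
                                    paste(sites, tr$site, sep = ";")), sites)
      }
    }
    rec$pain_sites <- sites
    rec$most_important_site <- NA_character_
    k_lbp <- which(traits$kind == "lbp")
    rec$lbp_endorsed <- if (length(k_lbp) == 1) {
      as.integer(case[[k_lbp]][idx, j])
    } else NA_integer_
    rec$current_pain <- as.integer(sites != "")
    rec$injury_flag <- 0L
    if (length(k_lbp) == 1 && config$injury_rate > 0) {
      lbp_pos <- case[[k_lbp]][idx, j]
      rec$injury_flag[lbp_pos] <-
        as.integer(runif(sum(lbp_pos)) < config$injury_rate)
    }
    rec$serious_injury_or_disease <- 0L
    for (col in c("migraine", "headache", "growing_pains",
                  "recurrent_abdominal_pain", "chronic_pain_other",
                  "restless_legs", "iron_deficiency_history")) {
      k_c <- which(traits$trait == col & traits$kind == "indicator")
      rec[[col]] <- if (length(k_c) == 1) {
        as.integer(case[[k_c]][idx, j])
      } else NA_integer_
    }
    rec$anxious_depression_score <- NA_integer_
    rec$sensory_sensitivity_score <- NA_integer_
    rows[[rj]] <- rec
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$family_id,
                        factor(.data$role, levels = roles))
  if (config$missing_rate > 0) {
    for (col in c("lbp_endorsed", "current_pain")) {
      mask <- runif(nrow(out)) < config$missing_rate
      out[[col]][mask] <- NA_integer_
    }
  }
  out
}

#' Expected pair similarity under the liability-threshold model
#'
#' Closed-form oracle for what [twin_similarity()] estimates: for
#' prevalence `q` and within-pair liability (tetrachoric) correlation `r`,
#' the both-affected cell probability is the bivariate-normal orthant
#' probability `P(L1 > t, L2 > t)` with `t = qnorm(1 - q)`, evaluated by
#' numerical integration (mvtnorm). Expected casewise concordance is
#' `p11 / q`; the expected double-entry odds ratio and phi coefficient
#' follow from the implied 2x2 cell probabilities
#' (`p10 = p01 = q - p11`, `p00 = 1 - 2q + p11`).
#'
#' @param config An [ace_config()] (or `NULL` if `q` and `r` are given
#'   directly).
#' @param zygosity `"MZ"` or `"DZ"` (used with `config`).
#' @param trait Trait name in `config$traits`.
#' @param q,r Optional direct prevalence and liability correlation,
#'   bypassing `config`.
#' @return A one-row tibble: `q`, `r`, `p11`, `concordance`, `phi`,
#'   `odds_ratio`.
#' @export
theoretical_similarity <- function(config = NULL, zygosity = c("MZ", "DZ"),
                                   trait = "lbp_life", q = NULL, r = NULL) {
  if (is.null(q) || is.null(r)) {
    stopifnot(inherits(config, "ace_config"))
    zygosity <- match.arg(zygosity)
    k <- which(config$traits$trait == trait)
    if (length(k) != 1) {
      abort(paste0("Unknown trait: ", trait), class = "twinfam_config_error")
    }
    tr <- config$traits[k, ]
    pair_r <- function(a2, c2) if (zygosity == "MZ") a2 + c2 else a2 / 2 + c2
    q <- tr$prev_twin
    r <- pair_r(tr$a2, tr$c2)
    # a cross-trait loading mixes in the focal trait's familial structure
    if (k > 1 && !is.na(tr$loading) && tr$loading != 0) {
      r1 <- pair_r(config$traits$a2[1], config$traits$c2[1])
      r <- tr$loading^2 * r1 + (1 - tr$loading^2) * r
    }
    if (tr$age_or != 1) {
      # twins share their age, so the age term is integrated out exactly:
      # q = E_A[ P(L + b(A - m) > t_s) ], p11 = E_A[ P2(both | A) ]
      aw <- config$ages$twin
      b <- log(tr$age_or) / 1.7
      mo <- truncnorm_moments(aw$mean, aw$sd, aw$range)
      t_s <- qnorm(1 - q) * sqrt(1 + b^2 * mo$var)
      f <- function(a) truncnorm_density(a, aw$mean, aw$sd, aw$range)
      q_real <- integrate(function(a) {
        f(a) * pnorm(b * (a - mo$mean) - t_s)
      }, aw$range[1], aw$range[2], rel.tol = 1e-9)$value
      p11 <- integrate(function(a) {
        thr <- t_s - b * (a - mo$mean)
        f(a) * vapply(thr, function(tt) {
          mvtnorm::pmvnorm(lower = c(tt, tt), upper = c(Inf, Inf),
                           corr = matrix(c(1, r, r, 1), 2))[1]
        }, numeric(1))
      }, aw$range[1], aw$range[2], rel.tol = 1e-8)$value
      p10 <- q_real - p11
      p00 <- 1 - 2 * q_real + p11
      return(tibble::tibble(
        q = q_real, r = r, p11 = p11, concordance = p11 / q_real,
        phi = (p11 - q_real^2) / (q_real * (1 - q_real)),
        odds_ratio = if (p10 > 0) p11 * p00 / p10^2 else Inf))
    }
  }
  stopifnot(q > 0, q < 1, r >= -1, r <= 1)
  t <- qnorm(1 - q)
  p11 <- if (r >= 1) {
    q
  } else if (r <= -1) {
    max(0, 2 * q - 1)
  } else {
    mvtnorm::pmvnorm(lower = c(t, t), upper = c(Inf, Inf),
                     corr = matrix(c(1, r, r, 1), 2))[1]
  }
  p10 <- q - p11
  p00 <- 1 - 2 * q + p11
  tibble::tibble(
    q = q, r = r, p11 = p11,
    concordance = p11 / q,
    phi = (p11 - q^2) / (q * (1 - q)),
    odds_ratio = if (p10 > 0) p11 * p00 / p10^2 else Inf)
}

cross_trait_or <- function(lambda, q1, q2) {
  t1 <- qnorm(1 - q1); t2 <- qnorm(1 - q2)
  p11 <- mvtnorm::pmvnorm(lower = c(t1, t2), upper = c(Inf, Inf),
                          corr = matrix(c(1, lambda, lambda, 1), 2))[1]
  p10 <- q1 - p11; p01 <- q2 - p11; p00 <- 1 - q1 - q2 + p11
  p11 * p00 / (p10 * p01)
}

#' Solve a cross-trait loading for a target odds ratio
#'
#' One-dimensional root finding against the theoretical 2x2 cell
#' probabilities: returns a config whose `loading` for `trait` makes the
#' population-level (offspring) cross-trait odds ratio with the first trait
#' equal to `target_or` within `tol`.
#'
#' @param config An [ace_config()].
#' @param trait Trait whose loading is solved (must not be the first trait).
#' @param target_or Target odds ratio (> 0).
#' @param tol Absolute tolerance on the achieved odds ratio (default 1e-3).
#' @return The modified config.
#' @export
plant_cross_trait_effect <- function(config, trait, target_or, tol = 1e-3) {
  stopifnot(inherits(config, "ace_config"), target_or > 0)
  k <- which(config$traits$trait == trait)
  if (length(k) != 1 || k == 1) {
    abort("trait must name a non-focal trait of the config",
          class = "twinfam_config_error")
  }
  q1 <- config$traits$prev_twin[1]
  q2 <- config$traits$prev_twin[k]
  if (abs(target_or - 1) < 1e-12) {
    config$traits$loading[k] <- 0
    return(config)
  }
  f <- function(l) cross_trait_or(l, q1, q2) - target_or
  lim <- 0.999
  if (sign(f(-lim)) == sign(f(lim))) {
    abort(sprintf("Target odds ratio %.3g unattainable for prevalences %.3g/%.3g",
                  target_or, q1, q2),
          class = "twinfam_infeasible_error")
  }
  lam <- uniroot(f, c(-lim, lim), tol = 1e-9)$root
  if (abs(cross_trait_or(lam, q1, q2) - target_or) > tol) {
    abort("Root finding did not reach the requested tolerance",
          class = "twinfam_infeasible_error")
  }
  config$traits$loading[k] <- lam
  config
}
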