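# Shared fixtures and independent oracles for the test suite.

# A tiny handmade family: MZ twins, a mother and a father.
toy_cohort_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "family_id,role,zygosity,age,sex,pain_sites,most_important_site,lbp_endorsed,current_pain,injury_flag,serious_injury_or_disease",
    "F1,twin1,MZ,14,female,lower_back;neck,lower_back,1,1,0,0",
    "F1,twin2,MZ,14,male,,NA,0,0,NA,0",
    "F1,mother,NA,45,female,head,head,1,1,0,0",
    "F1,father,NA,47,male,,NA,0,0,0,0"
  ), path)
  path
}

quiet_read <- function(path, ...) {
  suppressMessages(read_cohort(path, ...))
}

# Build a cohort tibble directly (bypassing CSV) with sensible defaults.
make_cohort <- function(family_id, role, zygosity = NA_character_,
                        age = 15, sex = "female", pain_sites = "",
                        lbp_endorsed = 0L, current_pain = 0L,
                        serious_injury_or_disease = 0L, ...) {
  tibble::tibble(family_id = family_id, role = role, zygosity = zygosity,
                 age = age, sex = sex, pain_sites = pain_sites,
                 most_important_site = NA_character_,
                 lbp_endorsed = as.integer(lbp_endorsed),
                 current_pain = as.integer(current_pain),
                 injury_flag = 0L,
                 serious_injury_or_disease = as.integer(serious_injury_or_disease),
                 ...)
}

# Enumeration oracle: casewise concordance as the conditional probability
# P(co-twin affected | twin affected) over the explicitly double-entered
# list of individuals.
concordance_by_enumeration <- function(Nc, Nd, N00) {
  # each pair contributes both orderings (index, co-twin)
  index <- c(rep(1, 2 * Nc), rep(1, Nd), rep(0, Nd), rep(0, 2 * N00))
  cotwin <- c(rep(1, 2 * Nc), rep(0, Nd), rep(1, Nd), rep(0, 2 * N00))
  mean(cotwin[index == 1])
}

# Cross-tab odds ratio oracle from a double-entered individual list.
odds_ratio_by_enumeration <- function(Nc, Nd, N00) {
  index <- c(rep(1, 2 * Nc), rep(1, Nd), rep(0, Nd), rep(0, 2 * N00))
  cotwin <- c(rep(1, 2 * Nc), rep(0, Nd), rep(1, Nd), rep(0, 2 * N00))
  tab <- table(factor(index, 0:1), factor(cotwin, 0:1))
  (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
}

# Draw pair categories directly from liability-threshold cell probabilities.
sample_pair_counts <- function(n_pairs, q, r, trait = "t", zygosity = "MZ") {
  th <- theoretical_similarity(q = q, r = r)
  p <- c(th$p11, q - th$p11, q - th$p11, 1 - 2 * q + th$p11)
  x <- as.vector(stats::rmultinom(1, n_pairs, p))
  pair_counts(trait, zygosity, x[1], x[2] + x[3], x[4])
}
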