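#' Prevalence table by population
#'
#' Case and control counts with percentages for each trait and population
#' (twins pooled across zygosity, first siblings, mothers, fathers).
#' Percentages are computed over non-missing classified individuals after
#' removing `analysis_excluded` rows, and are rounded half-up to one
#' decimal so each row sums to 100 within rounding.
#'
#' @param cohort A classified cohort tibble.
#' @param traits Trait column names.
#' @return A tibble: population, trait, n_case, n_control, pct_case,
#'   pct_control.
#' @export
prevalence_table <- function(cohort, traits = c("lbp_life", "tlbp_current")) {
  stopifnot(all(traits %in% names(cohort)))
  excl <- if ("analysis_excluded" %in% names(cohort)) {
    cohort$analysis_excluded
  } else rep(FALSE, nrow(cohort))
  d <- cohort[!excl, , drop = FALSE]
  d$population <- dplyr::case_match(d$role,
    c("twin1", "twin2") ~ "twins",
    "first_sibling" ~ "siblings",
    "mother" ~ "mothers",
    "father" ~ "fathers")
  long <- tidyr::pivot_longer(
    dplyr::select(d, "population", dplyr::all_of(traits)),
    cols = dplyr::all_of(traits), names_to = "trait", values_to = "value")
  long <- long[!is.na(long$value), , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$population, .data$trait),
    n_case = sum(.data$value == 1L),
    n_control = sum(.data$value == 0L), .groups = "drop")
  out$pct_case <- round_half_up(100 * out$n_case / (out$n_case + out$n_control), 1)
  out$pct_control <- round_half_up(100 * out$n_control / (out$n_case + out$n_control), 1)
  pop_order <- c("twins", "siblings", "mothers", "fathers")
  dplyr::arrange(out, factor(.data$population, pop_order), .data$trait)
}

#' Prevalence percentages from printed case/control counts
#'
#' Convenience for recomputing a published prevalence table from its
#' printed counts: takes a tibble with `population`, `trait`, `n_case`,
#' `n_control` and appends half-up percentages over the case+control total
#' (the denominator is always derived from the printed counts, not from a
#' separate header N).
#'
#' @param counts A tibble with columns `population`, `trait`, `n_case`,
#'   `n_control`.
#' @return The input with `pct_case` and `pct_control` appended.
#' @export
prevalence_from_counts <- function(counts) {
  stopifnot(all(c("n_case", "n_control") %in% names(counts)))
  total <- counts$n_case + counts$n_control
  counts$pct_case <- round_half_up(100 * counts$n_case / total, 1)
  counts$pct_control <- round_half_up(100 * counts$n_control / total, 1)
  counts
}

#' Run the full twin-family analysis pipeline
#'
#' Orchestrates simulate-or-ingest, classification, twin similarity, the
#' family analysis and (optionally) the association tables, returning all
#' report tables with a run manifest recording the configuration, seed and
#' per-stage record counts.
#'
#' @param cohort_file Path to a cohort CSV, or `NULL` to simulate.
#' @param config An [ace_config()] used when simulating.
#' @param seed Integer seed; overrides `config$seed` and seeds the random
#'   twin selection.
#' @param traits Trait columns for the similarity and family stages.
#' @param associations Also build the region association tables (slower;
#'   default `FALSE`).
#' @param dialect Passed to [read_cohort()] when ingesting.
#' @return A list of class `twinfam_report`: `prevalence`, `pair_counts`,
#'   `similarity` (a [twin_similarity()] object), `similarity_table`,
#'   `family` (per-trait [family_association()] tidies), `associations`
#'   (when requested) and `manifest`.
#' @export
run_pipeline <- function(cohort_file = NULL, config = ace_config(),
                         seed = config$seed,
                         traits = c("lbp_life", "tlbp_current"),
                         associations = FALSE,
                         dialect = tristate_dialect()) {
  cohort <- if (is.null(cohort_file)) {
    simulate_cohort(config, seed = seed)
  } else {
    read_cohort(cohort_file, dialect = dialect)
  }
  if (nrow(cohort) == 0) {
    abort("Empty cohort: no records to analyse",
          class = "twinfam_schema_error")
  }
  classified <- classify_back_pain(cohort)
  n_excluded <- sum(classified$analysis_excluded)

  prev <- prevalence_table(classified, traits)
  counts <- tabulate_pairs(classified, traits)
  sim <- twin_similarity(counts)
  fam <- purrr::map(traits, function(tr) {
    tidy(family_association(classified, tr, seed = seed))
  })
  names(fam) <- traits

  assoc <- NULL
  if (associations) {
    assoc <- list()
    for (out_tr in traits) {
      for (pop in names(population_roles)) {
        key <- paste(out_tr, pop, sep = ".")
        assoc[[key]] <- tryCatch(
          build_association_table(classified, out_tr, "regions", pop),
          error = function(e) e$message)
      }
    }
  }

  manifest <- list(
    package_version = as.character(packageVersion("twinfam")),
    seed = as.integer(seed),
    input = if (is.null(cohort_file)) "simulated" else cohort_file,
    config = if (is.null(cohort_file)) unclass(config) else NULL,
    counts = list(loaded = nrow(cohort),
                  excluded = n_excluded,
                  analysed = nrow(cohort) - n_excluded,
                  families = dplyr::n_distinct(cohort$family_id),
                  pairs = attr(counts, "drop_log")),
    notes = "Population N is always derived from case+control sums, never from a separate header count."
  )
  structure(list(prevalence = prev, pair_counts = counts, similarity = sim,
                 similarity_table = similarity_report(sim), family = fam,
                 associations = assoc, manifest = manifest),
            class = "twinfam_report")
}

#' @export
print.twinfam_report <- function(x, ...) {
  cat("twinfam pipeline report (seed", x$manifest$seed, ")\n\n")
  cat("Prevalence:\n"); print(x$prevalence, n = Inf)
  cat("\nPair counts:\n")
  print(tibble::as_tibble(x$pair_counts), n = Inf)
  cat("\nSimilarity (report rounding):\n")
  print(x$similarity_table, n = Inf)
  invisible(x)
}

#' Write the report tables of a pipeline run to CSV
#'
#' Emits tidy, diff-able CSV renderings of each report table plus the run
#' manifest as JSON.
#'
#' @param report A `twinfam_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$prevalence, file.path(dir, "prevalence.csv"))
  readr::write_csv(tibble::as_tibble(report$pair_counts),
                   file.path(dir, "pair_counts.csv"))
  readr::write_csv(report$similarity_table, file.path(dir, "similarity.csv"))
  for (tr in names(report$family)) {
    readr::write_csv(report$family[[tr]],
                     file.path(dir, paste0("family_", tr, ".csv")))
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
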