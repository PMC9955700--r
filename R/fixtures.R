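#' Published pediatric back-pain twin-study counts
#'
#' Two small tables transcribed from the published pediatric back-pain
#' twin-family study that this package's methods emulate, bundled so the
#' similarity and prevalence stages can be exercised without raw data
#' (which the study does not deposit):
#'
#' * `backpain_pair_counts()` -- concordant/discordant/neither pair tallies
#'   for lifetime low back pain (`lbp_life`) and current thoracolumbar back
#'   pain (`tlbp_current`) in 275 MZ and 376 DZ twin pairs, as a
#'   [pair_counts()] table.
#' * `backpain_prevalence_counts()` -- case/control counts per population
#'   (twins, first siblings, mothers, fathers) for the same two traits.
#'
#' @return A tibble; see Details.
#' @examples
#' twin_similarity(backpain_pair_counts())
#' @export
backpain_pair_counts <- function() {
  path <- system.file("extdata", "backpain_pair_counts.csv",
                      package = "twinfam")
  d <- readr::read_csv(path, col_types = "cciii", progress = FALSE)
  pair_counts(d$trait, d$zygosity, d$Nc, d$Nd, d$N00)
}

#' @rdname backpain_pair_counts
#' @export
backpain_prevalence_counts <- function() {
  path <- system.file("extdata", "backpain_prevalence_counts.csv",
                      package = "twinfam")
  readr::read_csv(path, col_types = "ccii", progress = FALSE)
}
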