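#' Apply the back-pain case definitions
#'
#' Derives the two analysis outcomes from the raw questionnaire columns:
#'
#' * `lbp_life` — lifetime low back pain of at least three months duration:
#'   case iff `lbp_endorsed` is positive and the pain is not attributed to
#'   disease or serious injury. Minor-injury attribution (`injury_flag`)
#'   does **not** exclude; analyses use the total irrespective of minor
#'   injury history.
#' * `tlbp_current` — pain for most of the last month in the lower and/or
#'   middle back: case iff `current_pain` is positive with a marked site in
#'   the thoracolumbar region, under the same disease/serious-injury
#'   exclusion. Current pain confined to other regions is a control.
#'
#' Disease- or serious-injury-related records are not deleted: the classified
#' value is forced to control and the row is flagged `analysis_excluded`, so
#' downstream tabulations can drop it while keeping denominators auditable.
#' Missing inputs propagate to missing, never to control.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @return The cohort with region-profile columns, `lbp_life`,
#'   `tlbp_current` (integer tristate) and `analysis_excluded` (logical)
#'   appended.
#' @export
classify_back_pain <- function(cohort) {
  out <- add_region_profile(cohort)
  serious <- out$serious_injury_or_disease

  excl <- !is.na(serious) & serious == 1L

  lbp <- out$lbp_endorsed
  lbp[excl] <- 0L # excluded-from-analysis, never case
  out$lbp_life <- lbp

  cur <- out$current_pain
  tlbp <- ifelse(is.na(cur), NA_integer_,
                 ifelse(cur == 1L & out$tlbp_region, 1L, 0L))
  tlbp[excl] <- 0L
  out$tlbp_current <- as.integer(tlbp)

  out$analysis_excluded <- excl
  out
}

condition_ids <- c("migraine", "headache", "growing_pains",
                   "recurrent_abdominal_pain", "restless_legs",
                   "iron_deficiency_history")

#' Classify a condition from its raw questionnaire items
#'
#' Applies the study's rule table for one condition to a named list (or
#' one-row data frame) of raw item answers, returning an integer tristate
#' (1 case, 0 control, NA missing). A rule returns missing whenever an item
#' it needs is absent; it never defaults to control.
#'
#' Item schemas (all items tristate unless noted):
#' * `migraine`: `recurrent_headache`, `attacks_5plus`, `duration_4_72h`,
#'   `n_pain_features` (integer 0--4: unilateral, pulsating, moderate/severe,
#'   aggravated by routine activity), `accompanying` (nausea/vomiting and/or
#'   photophobia with phonophobia). Case iff all endorsed with at least two
#'   of the four pain features.
#' * `headache`: same items; case iff the migraine criteria are **not** met
#'   but recurring headaches with 4--72 h episodes are endorsed.
#' * `growing_pains`: `bilateral_lower_limb`, `onset_age` (years; must lie
#'   in 3--12), `night_pain`, `no_limitation`, `exclusion_present`
#'   (orthopedic disorder or abnormal investigations). Case iff the four
#'   essential criteria hold and no exclusion is present.
#' * `recurrent_abdominal_pain`: `endorsed`.
#' * `restless_legs`: `urge_to_move` (screening) and `essential_criteria`.
#' * `iron_deficiency_history`: `had_iron_deficiency` and
#'   `doctor_diagnosed`; both parts of the two-part question are required.
#'
#' @param items Named list or one-row data frame of raw answers.
#' @param condition One of the condition ids above.
#' @return Integer tristate.
#' @export
classify_condition <- function(items, condition) {
  condition <- match.arg(condition, condition_ids)
  items <- as.list(items)
  get <- function(nm) {
    v <- items[[nm]]
    if (is.null(v)) NA_integer_ else v
  }
  all3 <- function(...) { # tristate AND: any 0 -> 0, else any NA -> NA
    v <- c(...)
    if (any(!is.na(v) & v == 0)) 0L else if (anyNA(v)) NA_integer_ else 1L
  }
  not3 <- function(v) ifelse(is.na(v), NA_integer_, 1L - as.integer(v))

  migraine_rule <- function() {
    feats <- get("n_pain_features")
    all3(get("recurrent_headache"), get("attacks_5plus"), get("duration_4_72h"),
         if (is.na(feats)) NA_integer_ else as.integer(feats >= 2),
         get("accompanying"))
  }

  switch(condition,
    migraine = migraine_rule(),
    headache = {
      mig <- migraine_rule()
      # positive only when migraine criteria are definitively not met
      base <- all3(get("recurrent_headache"), get("duration_4_72h"))
      all3(base, not3(mig))
    },
    growing_pains = {
      onset <- get("onset_age")
      all3(get("bilateral_lower_limb"),
           if (is.na(onset)) NA_integer_ else as.integer(onset >= 3 & onset <= 12),
           get("night_pain"), get("no_limitation"),
           not3(get("exclusion_present")))
    },
    recurrent_abdominal_pain = all3(get("endorsed")),
    restless_legs = all3(get("urge_to_move"), get("essential_criteria")),
    iron_deficiency_history = all3(get("had_iron_deficiency"),
                                   get("doctor_diagnosed"))
  )
}

scale_specs <- list(
  anxious_depression_adult = list(n_items = 18, item_range = c(0, 2), total = c(0, 36)),
  anxious_depression_child = list(n_items = 13, item_range = c(0, 2), total = c(0, 26)),
  # declared instrument range is 5-35 even though 7 items scored 1-5 would
  # give a 7-35 minimum; the declared range is what is validated
  sensory_sensitivity = list(n_items = 7, item_range = c(1, 5), total = c(5, 35))
)

#' Score a questionnaire scale by summation
#'
#' Simple sums with range validation: the anxious-depression subscale
#' (Achenbach checklist; items scored 0/1/2, totals 0--36 for adults and
#' 0--26 for children) and the seven-item sensory-sensitivity scale
#' (five-point Likert items; declared total range 5--35).
#'
#' @param items Numeric vector of item answers, complete for the scale.
#' @param scale One of `"anxious_depression_adult"`,
#'   `"anxious_depression_child"`, `"sensory_sensitivity"`.
#' @return Integer total, or `NA` if any item is missing.
#' @export
score_scale <- function(items, scale = names(scale_specs)) {
  scale <- match.arg(scale)
  spec <- scale_specs[[scale]]
  if (length(items) != spec$n_items) {
    abort(sprintf("%s expects %d items, got %d", scale, spec$n_items,
                  length(items)),
          class = "twinfam_validation_error")
  }
  if (anyNA(items)) return(NA_integer_)
  if (any(items < spec$item_range[1] | items > spec$item_range[2])) {
    abort(sprintf("item answers out of range [%d, %d] for %s",
                  spec$item_range[1], spec$item_range[2], scale),
          class = "twinfam_validation_error")
  }
  as.integer(sum(items))
}
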