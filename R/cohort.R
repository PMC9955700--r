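#' Tristate dialect for questionnaire indicator columns
#'
#' Binary questionnaire indicators are tristate: case, control, or missing.
#' Source files encode these differently ("1/0/NA", "yes/no", ...), so
#' [read_cohort()] takes a dialect describing the raw strings for each state.
#' Unparseable values become missing (never control) and are counted in the
#' read log.
#'
#' @param case,control,missing Character vectors of raw values mapped to each
#'   state. Matching is case-insensitive after trimming whitespace.
#' @return A list of class `tristate_dialect`.
#' @examples
#' tristate_dialect(case = "yes", control = "no")
#' @export
tristate_dialect <- function(case = c("1", "true", "case"),
                             control = c("0", "false", "control"),
                             missing = c("", "na", "nan", "missing")) {
  structure(list(case = tolower(case), control = tolower(control),
                 missing = tolower(missing)),
            class = "tristate_dialect")
}

parse_tristate <- function(x, dialect) {
  raw <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(x))
  out[raw %in% dialect$case] <- 1L
  out[raw %in% dialect$control] <- 0L
  known <- is.na(x) | raw %in% c(dialect$case, dialect$control, dialect$missing)
  attr(out, "n_unparseable") <- sum(!known)
  out
}

cohort_roles <- c("twin1", "twin2", "first_sibling", "mother", "father")

tristate_columns <- c(
  "lbp_endorsed", "current_pain", "injury_flag", "serious_injury_or_disease",
  "migraine", "headache", "growing_pains", "recurrent_abdominal_pain",
  "chronic_pain_other", "restless_legs", "iron_deficiency_history"
)

#' Read a twin-family cohort file
#'
#' Reads a delimited cohort file (one row per individual) into the package's
#' canonical tibble. Mandatory columns are `family_id`, `role`, `zygosity`,
#' `age` and `sex`; trait indicator columns, `pain_sites` (a `;`-separated
#' site list), `most_important_site` and the two questionnaire scores are
#' read when present. Tristate indicators are decoded with `dialect`;
#' unparseable values become missing and are logged, never silently coerced
#' to control.
#'
#' Structural checks: a missing mandatory column raises a schema error naming
#' the column; a duplicated `(family_id, role)` among twins raises an
#' integrity error; a `most_important_site` outside the individual's
#' `pain_sites` is loaded but recorded as a validation warning. Zygosity is
#' forced to missing for non-twin roles.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect A [tristate_dialect()].
#' @return A cohort tibble. The read log (rows read, unparseable tristates,
#'   validation warnings) is attached as attribute `"read_log"`.
#' @export
read_cohort <- function(path, dialect = tristate_dialect()) {
  if (!file.exists(path)) {
    abort(paste0("Cohort file not found: ", path), class = "twinfam_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  mandatory <- c("family_id", "role", "zygosity", "age", "sex")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss) > 0) {
    abort(paste0("Cohort file is missing mandatory column(s): ",
                 paste(miss, collapse = ", ")),
          class = "twinfam_schema_error")
  }
  as_cohort(raw, dialect = dialect)
}

#' @rdname read_cohort
#' @param x A data frame in the cohort column layout (e.g. from another
#'   reader); coerced and validated the same way as a file.
#' @export
as_cohort <- function(x, dialect = tristate_dialect()) {
  raw <- tibble::as_tibble(x)
  log <- list(rows_read = nrow(raw), unparseable = 0L, warnings = character())

  bad_role <- setdiff(unique(raw$role), cohort_roles)
  if (length(bad_role) > 0) {
    abort(paste0("Unknown role value(s): ", paste(bad_role, collapse = ", ")),
          class = "twinfam_schema_error")
  }
  for (r in c("twin1", "twin2")) {
    dup <- raw$family_id[raw$role == r]
    dup <- unique(dup[duplicated(dup)])
    if (length(dup) > 0) {
      abort(paste0("Duplicate (family_id, role=", r, ") for family ",
                   paste(dup, collapse = ", ")),
            class = "twinfam_integrity_error")
    }
  }

  out <- tibble::tibble(
    family_id = as.character(raw$family_id),
    role = as.character(raw$role),
    zygosity = toupper(as.character(raw$zygosity)),
    age = suppressWarnings(as.numeric(raw$age)),
    sex = tolower(as.character(raw$sex))
  )
  out$zygosity[!out$role %in% c("twin1", "twin2")] <- NA_character_
  out$zygosity[!out$zygosity %in% c("MZ", "DZ")] <- NA_character_
  out$sex[!out$sex %in% c("male", "female")] <- NA_character_

  out$pain_sites <- if ("pain_sites" %in% names(raw)) {
    s <- as.character(raw$pain_sites); s[is.na(s)] <- ""; s
  } else ""
  out$most_important_site <- if ("most_important_site" %in% names(raw)) {
    as.character(raw$most_important_site)
  } else NA_character_

  for (col in tristate_columns) {
    if (col %in% names(raw)) {
      v <- parse_tristate(raw[[col]], dialect)
      log$unparseable <- log$unparseable + attr(v, "n_unparseable")
      attr(v, "n_unparseable") <- NULL
      out[[col]] <- v
    } else {
      out[[col]] <- NA_integer_
    }
  }
  for (col in c("anxious_depression_score", "sensory_sensitivity_score")) {
    out[[col]] <- if (col %in% names(raw)) {
      suppressWarnings(as.integer(raw[[col]]))
    } else NA_integer_
  }

  sites_list <- strsplit(out$pain_sites, ";", fixed = TRUE)
  mis_ok <- mapply(function(mis, s) is.na(mis) || mis %in% s,
                   out$most_important_site, sites_list)
  if (any(!mis_ok)) {
    log$warnings <- c(log$warnings, paste0(
      sum(!mis_ok), " record(s) have most_important_site outside pain_sites"))
    warn(log$warnings[length(log$warnings)])
  }

  inform(sprintf("Read %d individuals in %d families (%d unparseable tristate values -> missing)",
                 nrow(out), dplyr::n_distinct(out$family_id), log$unparseable))
  attr(out, "read_log") <- log
  out
}

#' Write a cohort tibble to CSV
#'
#' Writes the canonical cohort layout with "1/0/NA" tristate encoding.
#' Output is deterministic: the same tibble always produces byte-identical
#' files.
#'
#' @param cohort A cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "NA", progress = FALSE)
  invisible(path)
}
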