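#' The 18 tracked symptoms
#'
#' Symptom identifiers tracked by the weekly ePRO questionnaire, in catalog
#' order. These are the most common immune-related adverse events reported
#' in anti-PD-(L)1 / anti-CTLA-4 monotherapy trials.
#'
#' @format Character vector of length 18.
#' @export
epro_symptoms <- c(
  "blood_in_stool", "hematuria", "blurred_vision", "chest_pain", "cough",
  "loss_of_appetite", "diarrhea", "dizziness", "fatigue", "fever",
  "headache", "itching", "nausea", "pain_in_joints", "rash",
  "shortness_of_breath", "stomach_pain", "vomiting"
)

#' Load a symptom catalog
#'
#' Reads a declarative symptom rule file (YAML) describing, for each tracked
#' symptom, its question items (with answer domains) and an ordered,
#' first-match list of grade rules mapping answers to NCI-CTCAE severity
#' grades 0-4. The shipped default catalog encodes CTCAE v4.03 criteria
#' restricted to patient-reportable wording.
#'
#' @param path Path to a catalog YAML file. Defaults to the catalog shipped
#'   with the package.
#' @return An object of class `epro_catalog`: a named list of symptom
#'   definitions (one per symptom id), each with elements `symptom_id`,
#'   `label`, `max_grade`, `items` (named list of item definitions) and
#'   `rules`.
#' @examples
#' cat18 <- read_symptom_catalog()
#' names(cat18)
#' @export
read_symptom_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "symptom_catalog.yaml", package = "eprowatch")
  }
  raw <- yaml::read_yaml(path)
  defs <- purrr::map(raw$symptoms, normalize_symptom_def)
  names(defs) <- purrr::map_chr(defs, "symptom_id")
  catalog <- structure(defs, class = "epro_catalog", version = raw$version)
  validate_catalog(catalog)
  catalog
}

# Cache for the default catalog; loading + validating the YAML is cheap but
# called from many vectorized paths.
the <- new.env(parent = emptyenv())

#' @rdname read_symptom_catalog
#' @export
default_symptom_catalog <- function() {
  if (is.null(the$catalog)) the$catalog <- read_symptom_catalog()
  the$catalog
}

normalize_symptom_def <- function(def) {
  items <- def$items
  names(items) <- purrr::map_chr(items, "item_id")
  list(
    symptom_id = def$symptom_id,
    label = def$label %||% def$symptom_id,
    max_grade = as.integer(def$max_grade %||% 4L),
    items = items,
    rules = def$rules
  )
}

validate_catalog <- function(catalog) {
  ids <- purrr::map_chr(catalog, "symptom_id")
  if (!setequal(ids, epro_symptoms) || anyDuplicated(ids)) {
    rlang::abort("catalog must contain each of the 18 tracked symptoms exactly once")
  }
  for (def in catalog) {
    if (def$max_grade < 1 || def$max_grade > 4) {
      rlang::abort(paste0(def$symptom_id, ": max_grade must be in 1..4"))
    }
    grades <- purrr::map_int(def$rules, ~ as.integer(.x$grade))
    if (any(grades > def$max_grade)) {
      rlang::abort(paste0(def$symptom_id, ": a rule emits a grade above max_grade"))
    }
    last <- def$rules[[length(def$rules)]]
    if (length(last$when) > 0) {
      rlang::abort(paste0(def$symptom_id, ": final rule must be the unconditional catch-all"))
    }
    for (rule in def$rules) {
      for (cond in rule$when) {
        if (!cond$item %in% names(def$items)) {
          rlang::abort(paste0(def$symptom_id, ": rule condition on unknown item '", cond$item, "'"))
        }
      }
    }
    # absence must map to grade 0
    if (!"present" %in% names(def$items)) {
      rlang::abort(paste0(def$symptom_id, ": catalog items must include 'present'"))
    }
  }
  invisible(catalog)
}

# --- answer validation -------------------------------------------------------

check_answer <- function(def, item_id, value) {
  item <- def$items[[item_id]]
  ok <- switch(item$type,
    boolean = is.logical(value) && length(value) == 1 && !is.na(value),
    category = is.character(value) && length(value) == 1 && value %in% item$levels,
    count = is.numeric(value) && length(value) == 1 && !is.na(value) &&
      value >= 0 && value == floor(value),
    FALSE
  )
  if (!ok) {
    rlang::abort(paste0(
      def$symptom_id, ".", item_id, ": answer ",
      deparse(value), " is missing or outside the item's ", item$type, " domain"
    ), class = "epro_validation_error")
  }
  invisible(TRUE)
}

validate_answers <- function(def, answers) {
  missing <- setdiff(names(def$items), names(answers))
  if (length(missing) > 0) {
    rlang::abort(
      paste0(def$symptom_id, ": incomplete answer vector, missing item(s) ",
             paste(missing, collapse = ", ")),
      class = "epro_validation_error"
    )
  }
  for (item_id in names(def$items)) check_answer(def, item_id, answers[[item_id]])
  invisible(TRUE)
}

condition_holds <- function(def, cond, answers) {
  value <- answers[[cond$item]]
  item <- def$items[[cond$item]]
  if (!is.null(cond$equals)) {
    return(identical(value, cond$equals) || isTRUE(value == cond$equals))
  }
  if (!is.null(cond$at_least)) {
    if (item$type == "category") {
      return(match(value, item$levels) >= match(cond$at_least, item$levels))
    }
    return(value >= cond$at_least)
  }
  rlang::abort(paste0(def$symptom_id, ": rule condition must use 'equals' or 'at_least'"))
}

#' Grade one symptom from its raw answers
#'
#' Applies a symptom's ordered grade rules (first match wins) to a complete
#' answer vector, returning the approximated NCI-CTCAE grade. Grade 0 is
#' returned exactly when the symptom is reported absent or no severity
#' indicator exceeds its null level, per the catalog's absence rule.
#'
#' @param symptom A symptom definition (one element of an `epro_catalog`) or
#'   a symptom id string looked up in `catalog`.
#' @param answers Named list of answers covering every item of the symptom.
#' @param catalog Catalog used when `symptom` is given as an id.
#' @return Integer grade in `0:4`, never above the symptom's `max_grade`.
#' @examples
#' grade_symptom("diarrhea", list(
#'   present = TRUE, stools_per_day_over_baseline = 5,
#'   hospitalization_level_symptoms = FALSE, limits_self_care = FALSE
#' ))
#' @export
grade_symptom <- function(symptom, answers, catalog = default_symptom_catalog()) {
  def <- if (is.character(symptom)) {
    if (!symptom %in% names(catalog)) {
      rlang::abort(paste0("unknown symptom '", symptom, "'"), class = "epro_validation_error")
    }
    catalog[[symptom]]
  } else {
    symptom
  }
  validate_answers(def, answers)
  for (rule in def$rules) {
    if (all(purrr::map_lgl(rule$when, condition_holds, def = def, answers = answers))) {
      return(as.integer(rule$grade))
    }
  }
  # unreachable: validated catalogs end in a catch-all
  rlang::abort(paste0(def$symptom_id, ": no grade rule matched"))
}

# --- whole-questionnaire grading --------------------------------------------

raw_column <- function(symptom_id, item_id) paste0(symptom_id, ".", item_id)

#' Grade a table of raw questionnaire responses
#'
#' Converts raw answers (one row per completed questionnaire, item columns
#' named `<symptom>.<item>`) into per-symptom CTCAE grades by applying
#' [grade_symptom()] to every symptom of every row. Identifier columns
#' (`patient_id`, `week_index`, `answer_date`) are carried through unchanged.
#'
#' @param responses Data frame of raw responses with columns `patient_id`,
#'   `week_index`, `answer_date` and one `<symptom>.<item>` column for every
#'   catalog item.
#' @param catalog An `epro_catalog`.
#' @return Tibble with the identifier columns plus one integer grade column
#'   per symptom (named by symptom id).
#' @export
grade_responses <- function(responses, catalog = default_symptom_catalog()) {
  responses <- tibble::as_tibble(responses)
  id_cols <- intersect(c("patient_id", "week_index", "answer_date"), names(responses))
  out <- responses[id_cols]
  for (def in catalog) {
    cols <- raw_column(def$symptom_id, names(def$items))
    missing <- setdiff(cols, names(responses))
    if (length(missing) > 0) {
      rlang::abort(
        paste0("responses are missing answer column(s): ", paste(missing, collapse = ", ")),
        class = "epro_validation_error"
      )
    }
    out[[def$symptom_id]] <- purrr::map_int(seq_len(nrow(responses)), function(i) {
      answers <- purrr::map(rlang::set_names(names(def$items)), function(item_id) {
        responses[[raw_column(def$symptom_id, item_id)]][[i]]
      })
      tryCatch(
        grade_symptom(def, answers, catalog),
        epro_validation_error = function(e) {
          rlang::abort(paste0("row ", i, ": ", conditionMessage(e)),
                       class = "epro_validation_error")
        }
      )
    })
  }
  out
}

# --- answer-domain enumeration ----------------------------------------------

item_domain <- function(item) {
  switch(item$type,
    boolean = list(FALSE, TRUE),
    category = as.list(item$levels),
    count = as.list(0:(item$sweep_max %||% 10L))
  )
}

#' Enumerate a symptom's full answer domain
#'
#' Expands the Cartesian product of every item's answer domain (counts are
#' bounded by the catalog's `sweep_max`). Used for exhaustive rule-table
#' checks and to find canonical answer vectors for a target grade.
#'
#' @param symptom Symptom id or definition.
#' @param catalog An `epro_catalog`.
#' @return Tibble with one list-column per item, one row per point of the
#'   answer domain.
#' @export
symptom_answer_grid <- function(symptom, catalog = default_symptom_catalog()) {
  def <- if (is.character(symptom)) catalog[[symptom]] else symptom
  domains <- purrr::map(def$items, item_domain)
  grid <- rev(expand.grid(rev(purrr::map(domains, seq_along))))
  names(grid) <- names(domains)
  tibble::as_tibble(purrr::imap(grid, function(idx, item_id) {
    domains[[item_id]][idx]
  }))
}

#' Canonical raw answers achieving a target grade
#'
#' Searches the symptom's answer domain for the first answer vector that
#' grades to `grade`. Useful to build raw-answer fixtures from grade-level
#' specifications.
#'
#' @param symptom Symptom id or definition.
#' @param grade Target grade, `0` to the symptom's `max_grade`.
#' @param catalog An `epro_catalog`.
#' @return Named list of answers, or an error if the grade is unreachable.
#' @export
answers_for_grade <- function(symptom, grade, catalog = default_symptom_catalog()) {
  def <- if (is.character(symptom)) catalog[[symptom]] else symptom
  grid <- symptom_answer_grid(def, catalog)
  for (i in seq_len(nrow(grid))) {
    answers <- purrr::map(grid, i)
    if (grade_symptom(def, answers, catalog) == grade) return(answers)
  }
  rlang::abort(paste0(def$symptom_id, ": grade ", grade, " is not reachable"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
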