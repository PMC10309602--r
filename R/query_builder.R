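#' Load a reference-range table
#'
#' Reference tables convert numeric laboratory and organ-size measurements
#' into clinical terms ("thrombocytopenia") or their negated/normal phrasing
#' ("no thrombocytopenia", "normal haemoglobin level"). The bundled defaults
#' use common adult reference ranges: platelets 150-450 x 10^9/L, haemoglobin
#' 130-170 g/L (male) / 120-150 (female), organ size above 1.25 multiples of
#' normal counting as organomegaly, and sex-specific left-ventricular mass
#' index cut-offs (48 / 44 g/m^2.7). Tables are data, not code: edit the CSV
#' to change clinical conventions.
#'
#' @param path CSV path; default the table shipped with the package. Columns:
#'   measurement, sex ("male"/"female"/"any"), low, high, term_low,
#'   term_normal, term_high, units.
#' @return data.frame with class \code{"reference_table"}.
#' @export
reference_table <- function(path = system.file("extdata",
                                               "reference_ranges.csv",
                                               package = "zebracase")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = character(0))
  needed <- c("measurement", "sex", "low", "high", "term_low", "term_normal",
              "term_high", "units")
  if (!all(needed %in% names(tab))) {
    stop("reference table missing columns: ",
         paste(setdiff(needed, names(tab)), collapse = ", "), call. = FALSE)
  }
  if (any(tab$low > tab$high)) {
    stop("reference table has low > high", call. = FALSE)
  }
  class(tab) <- c("reference_table", "data.frame")
  tab
}

#' Map a numeric measurement to a clinical term
#'
#' A value below the lower reference limit yields the low-side term, above
#' the upper limit the high-side term, and inside the closed reference
#' interval \code{[low, high]} the normal-side term (values exactly at a
#' threshold count as normal). Empty terms in the table mean "emit nothing"
#' and return \code{NA}.
#'
#' @param name measurement name matching the table (e.g. "platelet_count").
#' @param value numeric value; must be finite.
#' @param units unit string; must equal the table's units (no silent
#'   conversion).
#' @param sex "male" or "female"; used where ranges are sex-specific.
#' @param tables a \code{reference_table}.
#' @return A clinical term, or \code{NA_character_} for a suppressed side.
#' @export
#' @examples
#' tab <- reference_table()
#' map_measurement("platelet_count", 87, "10^9/L", "male", tab)
map_measurement <- function(name, value, units, sex, tables = reference_table()) {
  if (!is.finite(value)) stop("measurement value must be finite", call. = FALSE)
  rows <- tables[tables$measurement == name &
                   (tables$sex == sex | tables$sex == "any"), , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("unknown measurement '", name, "' (sex ", sex, ") in reference table",
         call. = FALSE)
  }
  row <- rows[1, ]
  if (!identical(row$units, units)) {
    stop("unit mismatch for ", name, ": got '", units, "', table uses '",
         row$units, "'", call. = FALSE)
  }
  term <- if (value < row$low) row$term_low
          else if (value > row$high) row$term_high
          else row$term_normal
  if (!nzchar(term)) NA_character_ else term
}

#' Age to query terms
#'
#' Emits the exact phrase "<n>-year-old" plus one age-band term: infant
#' (under 2), child (2-11), adolescent (12-17), adult (18-64), elderly (65+).
#'
#' @param age age in whole years, >= 0.
#' @return Character vector of two terms.
#' @export
map_age <- function(age) {
  if (!is.finite(age) || age < 0) stop("age must be >= 0", call. = FALSE)
  band <- if (age < 2) "infant" else if (age < 12) "child" else
    if (age < 18) "adolescent" else if (age < 65) "adult" else "elderly"
  c(sprintf("%d-year-old", as.integer(age)), band)
}

#' Chronic-kidney-disease severity term
#'
#' CKD stage takes precedence when both a stage and an eGFR are recorded;
#' otherwise the eGFR (mL/min/1.73m^2) is banded KDIGO-style: >= 60 maps like
#' stages 1-2, 30-59 stage 3, 15-29 stage 4, below 15 stage 5. Stage 1 emits
#' no term, stage 2 "mild chronic kidney disease", stage 3 "moderate chronic
#' kidney disease", stage 4 "severe chronic kidney disease", stage 5
#' "end-stage renal disease".
#'
#' @param stage CKD stage 1-5, or NA.
#' @param egfr estimated glomerular filtration rate, or NA.
#' @return A term or \code{NA_character_} when no severity applies.
#' @export
map_ckd <- function(stage = NA, egfr = NA) {
  if (is.na(stage) && !is.na(egfr)) {
    if (egfr <= 0) stop("eGFR must be positive", call. = FALSE)
    stage <- if (egfr >= 90) 1L else if (egfr >= 60) 2L else
      if (egfr >= 30) 3L else if (egfr >= 15) 4L else 5L
  }
  if (is.na(stage)) return(NA_character_)
  if (!stage %in% 1:5) stop("CKD stage must be in 1..5", call. = FALSE)
  switch(stage,
         NA_character_,
         "mild chronic kidney disease",
         "moderate chronic kidney disease",
         "severe chronic kidney disease",
         "end-stage renal disease")
}

#' Construct a survey record
#'
#' One row of a patient outcomes survey: demographics, numeric measurements
#' with units, free-text symptom terms, optional mutation, treatment flag.
#'
#' @param patient_id identifier.
#' @param age years.
#' @param sex "male" or "female".
#' @param measurements named list; each element \code{list(value=, units=)}.
#' @param symptoms character vector of free-text terms (passed through
#'   verbatim to queries).
#' @param mutation optional mutation string.
#' @param ckd_stage optional CKD stage 1-5.
#' @param treated logical.
#' @param disease disease tag.
#' @return List with class \code{"survey_record"}.
#' @export
survey_record <- function(patient_id, age, sex,
                          measurements = list(), symptoms = character(0),
                          mutation = NA_character_, ckd_stage = NA_integer_,
                          treated = FALSE, disease = NA_character_) {
  stopifnot(age >= 0, sex %in% c("male", "female"))
  if (!is.na(ckd_stage) && !ckd_stage %in% 1:5) {
    stop("CKD stage must be in 1..5", call. = FALSE)
  }
  structure(list(patient_id = as.character(patient_id), age = age, sex = sex,
                 measurements = measurements, symptoms = symptoms,
                 mutation = mutation, ckd_stage = as.integer(ckd_stage),
                 treated = isTRUE(treated), disease = disease),
            class = "survey_record")
}

#' Convert a survey record to a comma-separated text query
#'
#' Demographics come first ("<n>-year-old", sex, age band), then one term per
#' numeric measurement via the reference table, the CKD severity term if any,
#' the symptom strings verbatim, and the mutation string. Duplicates are
#' removed keeping the first occurrence.
#'
#' @param record a \code{survey_record}.
#' @param tables a \code{reference_table}.
#' @return List with class \code{"patient_query"}: \code{patient_id},
#'   \code{terms} (ordered character vector) and \code{fields} (empty until
#'   \code{\link{segment_query}} routes the terms).
#' @export
build_query <- function(record, tables = reference_table()) {
  age_terms <- map_age(record$age)
  terms <- c(age_terms[1], record$sex, age_terms[2])
  for (name in names(record$measurements)) {
    m <- record$measurements[[name]]
    if (identical(name, "egfr")) next  # handled with the CKD severity term
    term <- map_measurement(name, m$value, m$units, record$sex, tables)
    if (!is.na(term)) terms <- c(terms, term)
  }
  egfr <- if ("egfr" %in% names(record$measurements))
    record$measurements$egfr$value else NA
  ckd <- map_ckd(record$ckd_stage, egfr)
  if (!is.na(ckd)) terms <- c(terms, ckd)
  terms <- c(terms, record$symptoms)
  if (!is.na(record$mutation) && nzchar(record$mutation)) {
    terms <- c(terms, record$mutation)
  }
  structure(list(patient_id = record$patient_id,
                 terms = unique(terms), fields = list()),
            class = "patient_query")
}

#' Route query terms into segmentation-category fields
#'
#' Joins the query terms with ", ", runs the trained segmenter over the
#' joined string, and assigns each term to the category of the predicted
#' span with the largest character overlap. Terms no span covers fall back
#' to DIAGNOSIS_SIGNS_SYMPTOMS, the catch-all clinical-content field.
#'
#' @param query a \code{patient_query} from \code{\link{build_query}}.
#' @param model a trained \code{segmenter_model}.
#' @return The query with \code{fields} populated: a named list mapping each
#'   used category to its terms (a partition of \code{terms}).
#' @export
segment_query <- function(query, model) {
  fields <- list()
  if (length(query$terms) == 0) {
    query$fields <- fields
    return(query)
  }
  text <- paste(query$terms, collapse = ", ")
  segs <- segment_text(model, text)
  # character range of each term inside the joined string
  starts <- cumsum(c(0, nchar(query$terms) + 2))[seq_along(query$terms)]
  ends <- starts + nchar(query$terms)
  for (i in seq_along(query$terms)) {
    overlap <- vapply(segs, function(s) {
      max(0, min(s$end, ends[i]) - max(s$start, starts[i]))
    }, numeric(1))
    cat_i <- if (length(segs) > 0 && max(overlap) > 0) {
      segs[[which.max(overlap)]]$category
    } else "DIAGNOSIS_SIGNS_SYMPTOMS"
    fields[[cat_i]] <- c(fields[[cat_i]], query$terms[i])
  }
  query$fields <- fields
  query
}

#' @export
print.patient_query <- function(x, ...) {
  cat(sprintf("<patient_query %s> %d terms\n", x$patient_id, length(x$terms)))
  cat(" ", paste(x$terms, collapse = ", "), "\n")
  for (f in names(x$fields)) {
    cat(sprintf("  %-26s %s\n", f, paste(x$fields[[f]], collapse = ", ")))
  }
  invisible(x)
}
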