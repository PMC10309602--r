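#' Maximum expert grade per retrieved document
#'
#' Expert ratings arrive as one row per (patient, rank, expert) with grades
#' on a 1-5 scale; relevance of each retrieved document is judged by the
#' maximum grade over the experts who rated it.
#'
#' @param ratings data.frame with columns patient_id, rank, expert_id, grade.
#' @return data.frame with columns patient_id, rank, max_grade — one row per
#'   rated (patient, rank) unit.
#' @export
max_grade <- function(ratings) {
  needed <- c("patient_id", "rank", "expert_id", "grade")
  if (!all(needed %in% names(ratings))) {
    stop("ratings need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(ratings) == 0) stop("ratings table is empty", call. = FALSE)
  if (!all(ratings$grade %in% 1:5)) {
    stop("grades must be integers in 1..5", call. = FALSE)
  }
  agg <- stats::aggregate(grade ~ patient_id + rank, data = ratings, FUN = max)
  names(agg)[names(agg) == "grade"] <- "max_grade"
  agg[order(agg$patient_id, agg$rank), , drop = FALSE]
}

#' Precision at 3 for a relevance threshold
#'
#' Fraction of rated (patient, rank) units whose maximum expert grade meets
#' the threshold. With 20 patients and 3 results each this is a count out of
#' 60 units.
#'
#' @param maxgrades data.frame from \code{\link{max_grade}}.
#' @param threshold relevance threshold in 2..5.
#' @return Proportion in [0, 1].
#' @export
precision_at_3 <- function(maxgrades, threshold) {
  if (!threshold %in% 2:5) stop("threshold must be in 2..5", call. = FALSE)
  if (nrow(maxgrades) == 0) stop("no rated units", call. = FALSE)
  mean(maxgrades$max_grade >= threshold)
}

#' Precision report across all thresholds
#'
#' @param ratings raw ratings data.frame (see \code{\link{max_grade}}).
#' @return data.frame with columns threshold, n_units, n_relevant, p_at_3;
#'   p_at_3 is non-increasing in threshold.
#' @export
precision_report <- function(ratings) {
  mg <- max_grade(ratings)
  do.call(rbind, lapply(2:5, function(t) {
    data.frame(threshold = t, n_units = nrow(mg),
               n_relevant = sum(mg$max_grade >= t),
               p_at_3 = precision_at_3(mg, t))
  }))
}

#' Flag atypical patients
#'
#' A symptom is atypical when it occurs in fewer than \code{freq_cutoff}
#' (default 10 percent) of the population; a patient is atypical when they
#' carry at least one atypical symptom. Symptom identity is the exact
#' normalised string (lowercased, trimmed).
#'
#' @param population list of \code{survey_record}s.
#' @param freq_cutoff frequency threshold in (0, 1].
#' @return Logical vector, TRUE for atypical patients.
#' @export
label_atypical <- function(population, freq_cutoff = 0.10) {
  if (length(population) == 0) stop("population is empty", call. = FALSE)
  norm <- function(x) trimws(tolower(x))
  sym_sets <- lapply(population, function(p) unique(norm(p$symptoms)))
  freq <- table(unlist(sym_sets, use.names = FALSE)) / length(population)
  rare <- names(freq)[freq < freq_cutoff]
  vapply(sym_sets, function(s) any(s %in% rare), logical(1))
}

#' Group statistics for typical and atypical patients
#'
#' @param population list of \code{survey_record}s.
#' @param flags logical vector from \code{\link{label_atypical}}.
#' @return data.frame with one row per group (all, atypical, typical):
#'   number of patients, percentage treated and mean symptom count, the
#'   latter two rounded to 1 decimal.
#' @export
group_stats <- function(population, flags) {
  stopifnot(length(population) == length(flags))
  one <- function(sub, name) {
    treated <- vapply(sub, `[[`, logical(1), "treated")
    nsym <- vapply(sub, function(p) length(p$symptoms), integer(1))
    data.frame(group = name, n_patients = length(sub),
               pct_treated = round(100 * mean(treated), 1),
               mean_symptoms = round(mean(nsym), 1))
  }
  rbind(one(population, "all"),
        one(population[flags], "atypical"),
        one(population[!flags], "typical"))
}
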