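#' Patient-profile segmentation categories
#'
#' The eight clinical dimensions into which spans of a case-report abstract
#' (or of a generated patient query) are classified. Each category captures
#' one facet of a patient profile: demographics (sex, age, ethnicity),
#' positive clinical content (diagnosis/signs/symptoms, medications and
#' interventions, genetics), explicitly negated or normal findings, and
#' family history.
#'
#' @return Character vector of the 8 category names, in canonical order.
#' @export
#' @examples
#' segment_categories()
segment_categories <- function() {
  c(
    "SEX",
    "AGE",
    "ETHNICITY",
    "DIAGNOSIS_SIGNS_SYMPTOMS",
    "MEDICATIONS_INTERVENTIONS",
    "GENETICS",
    "NEGATIVE_FINDINGS",
    "FAMILY_HISTORY"
  )
}

#' BIO label set over the segmentation categories
#'
#' Begin/Inside/Outside tagging scheme: one \code{B-} and one \code{I-} label
#' per category plus the \code{O} (outside) label, 17 labels in total.
#' \code{O} is always first; \code{B-c} precedes \code{I-c} for each category
#' in canonical category order. The position of a label in this vector is its
#' index for deterministic tie-breaking in decoding.
#'
#' @return Character vector of 17 BIO labels.
#' @export
bio_labels <- function() {
  cats <- segment_categories()
  c("O", as.vector(rbind(paste0("B-", cats), paste0("I-", cats))))
}

#' Category of a BIO label, or NA for "O"
#' @param labels character vector of BIO labels.
#' @return Character vector of category names (NA for "O").
#' @export
bio_category <- function(labels) {
  out <- rep(NA_character_, length(labels))
  tagged <- labels != "O"
  out[tagged] <- sub("^[BI]-", "", labels[tagged])
  out
}

assert_category <- function(category) {
  bad <- setdiff(unique(category), segment_categories())
  if (length(bad) > 0) {
    stop("unknown segment category: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(category)
}

#' Construct a labelled segment
#'
#' @param category one of \code{segment_categories()}.
#' @param start,end 0-based half-open character offsets into the source text.
#' @param text the covered text; when the source is supplied it must equal
#'   \code{substr(source, start + 1, end)}.
#' @return A list with class \code{"segment"}.
#' @export
segment <- function(category, start, end, text) {
  assert_category(category)
  if (start < 0 || end <= start) {
    stop("segment offsets must satisfy 0 <= start < end", call. = FALSE)
  }
  structure(
    list(category = category, start = as.integer(start), end = as.integer(end),
         text = text),
    class = "segment"
  )
}

#' Construct a labelled abstract
#'
#' The document unit of the pipeline: raw abstract text plus metadata and a
#' (possibly empty) list of non-overlapping labelled segments.
#'
#' @param doc_id unique document identifier.
#' @param text abstract text (UTF-8; offsets count code points).
#' @param disease disease tag used to select the per-disease index.
#' @param pub_year publication year (integer, > 1800) or NA.
#' @param segments list of \code{segment} objects, sorted by start.
#' @param is_pseudo_query TRUE for augmentation examples built from segments.
#' @return A list with class \code{"labeled_abstract"}.
#' @export
labeled_abstract <- function(doc_id, text, disease = NA_character_,
                             pub_year = NA_integer_, segments = list(),
                             is_pseudo_query = FALSE) {
  segments <- validate_segments(segments, text)
  if (!is.na(pub_year) && pub_year <= 1800) {
    stop("pub_year must be > 1800 when present", call. = FALSE)
  }
  structure(
    list(doc_id = as.character(doc_id), text = text, disease = disease,
         pub_year = as.integer(pub_year), segments = segments,
         is_pseudo_query = isTRUE(is_pseudo_query)),
    class = "labeled_abstract"
  )
}

# Sorts segments by start, checks pairwise non-overlap and slice consistency.
validate_segments <- function(segments, text) {
  if (length(segments) == 0) return(list())
  starts <- vapply(segments, `[[`, integer(1), "start")
  segments <- segments[order(starts)]
  starts <- sort(starts)
  ends <- vapply(segments, `[[`, integer(1), "end")
  n <- nchar(text)
  if (any(ends > n)) stop("segment extends past end of text", call. = FALSE)
  if (length(segments) > 1 && any(starts[-1] < ends[-length(ends)])) {
    stop("segments overlap", call. = FALSE)
  }
  for (s in segments) {
    sliced <- substr(text, s$start + 1L, s$end)
    if (!identical(sliced, s$text)) {
      stop("segment text does not match its offsets: '", s$text, "' vs '",
           sliced, "'", call. = FALSE)
    }
  }
  segments
}

#' @export
print.labeled_abstract <- function(x, ...) {
  cat(sprintf("<labeled_abstract %s> %s (%s)\n", x$doc_id,
              if (is.na(x$disease)) "untagged" else x$disease,
              if (is.na(x$pub_year)) "year NA" else x$pub_year))
  cat(sprintf("  %d chars, %d segments%s\n", nchar(x$text), length(x$segments),
              if (x$is_pseudo_query) ", pseudo-query" else ""))
  for (s in x$segments) {
    cat(sprintf("  [%d,%d) %-26s %s\n", s$start, s$end, s$category, s$text))
  }
  invisible(x)
}
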