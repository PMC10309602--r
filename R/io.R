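#' Write a corpus as JSONL
#'
#' One JSON object per line: doc_id, text, disease, pub_year, segments
#' (category/start/end/text) and is_pseudo_query. Offsets are 0-based
#' half-open unicode code-point offsets; the round trip is lossless.
#'
#' @param corpus list of \code{labeled_abstract}s.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(doc) {
    jsonlite::toJSON(list(
      doc_id = doc$doc_id, text = doc$text, disease = doc$disease,
      pub_year = doc$pub_year,
      segments = lapply(doc$segments, function(s) {
        list(category = s$category, start = s$start, end = s$end)
      }),
      is_pseudo_query = doc$is_pseudo_query
    ), auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Read a JSONL corpus
#'
#' @param path JSONL file from \code{\link{write_corpus}} (or hand-written
#'   annotations in the same format).
#' @return List of \code{labeled_abstract}s.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) {
                      stop("malformed JSONL at line ", i, " of ", path, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    if (is.null(obj$doc_id) || is.null(obj$text)) {
      stop("malformed JSONL at line ", i, " of ", path,
           ": missing doc_id or text", call. = FALSE)
    }
    segs <- lapply(obj$segments, function(s) {
      segment(s$category, s$start, s$end,
              substr(obj$text, s$start + 1, s$end))
    })
    labeled_abstract(obj$doc_id, obj$text,
                     disease = obj$disease %||% NA_character_,
                     pub_year = obj$pub_year %||% NA_integer_,
                     segments = segs,
                     is_pseudo_query = isTRUE(obj$is_pseudo_query))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a trained segmenter model to versioned JSON
#'
#' Weights are written at full precision so that write/read round-trips
#' reproduce decoding exactly. The encoder is stored by name; models using a
#' custom encoder must be re-attached via the \code{encoder} argument of
#' \code{\link{read_segmenter}}.
#'
#' @param model a \code{segmenter_model}.
#' @param path output JSON file.
#' @return Invisibly, \code{path}.
#' @export
write_segmenter <- function(model, path) {
  payload <- list(
    format = "zebracase-segmenter", version = 1L,
    labels = model$labels, features = model$features,
    W = as.vector(model$W), trans = as.vector(model$trans),
    start = unname(model$start), stop = unname(model$stop),
    encoder_name = model$encoder_name, config = model$config
  )
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Read a serialised segmenter model
#'
#' @param path JSON file from \code{\link{write_segmenter}}.
#' @param encoder encoder function; default resolves the bundled
#'   \code{sparse_encoder} by its stored name.
#' @return A \code{segmenter_model}.
#' @export
read_segmenter <- function(path, encoder = NULL) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "zebracase-segmenter")) {
    stop("not a segmenter model file: ", path, call. = FALSE)
  }
  if (is.null(encoder)) {
    if (!identical(obj$encoder_name, "sparse_handcrafted")) {
      stop("model uses custom encoder '", obj$encoder_name,
           "'; pass it via the encoder argument", call. = FALSE)
    }
    encoder <- sparse_encoder
  }
  model <- segmenter_model(labels = obj$labels,
                           features = as.character(obj$features),
                           encoder = encoder, config = obj$config)
  L <- length(obj$labels)
  model$W <- matrix(obj$W, ncol = L,
                    dimnames = list(model$features, obj$labels))
  model$trans <- matrix(obj$trans, L, L,
                        dimnames = list(obj$labels, obj$labels))
  model$start <- stats::setNames(obj$start, obj$labels)
  model$stop <- stats::setNames(obj$stop, obj$labels)
  model$encoder_name <- obj$encoder_name
  model
}

#' Write patient queries as JSONL
#'
#' @param queries list of \code{patient_query} objects.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_queries <- function(queries, path) {
  lines <- vapply(queries, function(q) {
    jsonlite::toJSON(list(patient_id = q$patient_id, terms = q$terms,
                          fields = q$fields), auto_unbox = FALSE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read patient queries from JSONL
#' @param path file from \code{\link{write_queries}}.
#' @return List of \code{patient_query} objects.
#' @export
read_queries <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      stop("malformed JSONL at line ", i, " of ", path,
                           call. = FALSE)
                    })
    structure(list(patient_id = as.character(obj$patient_id[[1]]),
                   terms = as.character(obj$terms),
                   fields = lapply(obj$fields, as.character)),
              class = "patient_query")
  })
}

#' Read survey records from CSV
#'
#' Wide format: patient_id, age, sex, treated, ckd_stage, mutation, symptoms
#' (";"-separated), plus one "<measurement>" and "<measurement>_units" column
#' pair per numeric measurement.
#'
#' @param path CSV file.
#' @return List of \code{survey_record}s.
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  unit_cols <- grep("_units$", names(df), value = TRUE)
  meas_names <- sub("_units$", "", unit_cols)
  lapply(seq_len(nrow(df)), function(i) {
    meas <- list()
    for (m in meas_names) {
      if (!is.na(df[[m]][i])) {
        meas[[m]] <- list(value = df[[m]][i], units = df[[paste0(m, "_units")]][i])
      }
    }
    syms <- if (is.na(df$symptoms[i]) || !nzchar(df$symptoms[i])) character(0)
      else trimws(strsplit(df$symptoms[i], ";", fixed = TRUE)[[1]])
    survey_record(df$patient_id[i], df$age[i], df$sex[i],
                  measurements = meas, symptoms = syms,
                  mutation = if ("mutation" %in% names(df)) df$mutation[i]
                    else NA_character_,
                  ckd_stage = if ("ckd_stage" %in% names(df)) df$ckd_stage[i]
                    else NA_integer_,
                  treated = isTRUE(df$treated[i]),
                  disease = if ("disease" %in% names(df)) df$disease[i]
                    else NA_character_)
  })
}

#' Read an expert-ratings table from CSV
#' @param path CSV with columns patient_id, rank, expert_id, grade.
#' @return data.frame validated for the ratings schema.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "rank", "expert_id", "grade")
  if (!all(needed %in% names(df))) {
    stop("ratings CSV needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  df
}
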