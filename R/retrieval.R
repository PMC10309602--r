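#' Structured document for the composite index
#'
#' The unit of indexing: one term bag per segmentation category (the
#' tokenised, lowercased texts of the document's spans in that category)
#' plus an \code{all_text} catch-all bag over the whole abstract, and the
#' publication year used by the date filter.
#'
#' @param doc_id unique identifier.
#' @param pub_year publication year or NA.
#' @param fields named list mapping categories to character vectors of terms.
#' @param all_text character vector of terms over the full text.
#' @return List with class \code{"structured_document"}.
#' @export
structured_document <- function(doc_id, pub_year = NA_integer_,
                                fields = list(), all_text = character(0)) {
  assert_category(names(fields))
  structure(list(doc_id = as.character(doc_id),
                 pub_year = as.integer(pub_year),
                 fields = fields, all_text = all_text),
            class = "structured_document")
}

#' Convert a segmented abstract into a structured document
#'
#' Groups the document's (gold or predicted) segments by category and
#' tokenises each span's text into a lowercased term bag.
#'
#' @param doc a \code{labeled_abstract} whose segments populate the fields.
#' @return A \code{structured_document}.
#' @export
structure_document <- function(doc) {
  fields <- list()
  for (s in doc$segments) {
    fields[[s$category]] <- c(fields[[s$category]],
                              tolower(tokenize(s$text)$text))
  }
  structured_document(doc$doc_id, doc$pub_year, fields,
                      all_text = tolower(tokenize(doc$text)$text))
}

#' Ranking configuration for the composite BM25 score
#'
#' @param k1 BM25 term-frequency saturation (default 1.2).
#' @param b BM25 length normalisation in [0,1] (default 0.75).
#' @param weights named non-negative weights, one per category field plus
#'   \code{all_text}; defaults: 1.0 per category, 0.25 for the low-weight
#'   all_text catch-all. At least one weight must be positive.
#' @param min_year drop documents published before this year (NA = no filter).
#' @param top_k number of results to return (default 3).
#' @return List with class \code{"ranking_config"}.
#' @export
ranking_config <- function(k1 = 1.2, b = 0.75, weights = NULL,
                           min_year = NA_integer_, top_k = 3L) {
  stopifnot(k1 >= 0, b >= 0, b <= 1)
  default_w <- stats::setNames(c(rep(1, 8), 0.25),
                               c(segment_categories(), "all_text"))
  if (!is.null(weights)) default_w[names(weights)] <- weights
  if (any(default_w < 0) || all(default_w == 0)) {
    stop("field weights must be >= 0 with at least one positive", call. = FALSE)
  }
  structure(list(k1 = k1, b = b, weights = default_w,
                 min_year = as.integer(min_year), top_k = as.integer(top_k)),
            class = "ranking_config")
}

#' Build the composite inverted index
#'
#' One searchable field per segmentation category plus \code{all_text}. For
#' each field the index keeps term frequencies per document, document
#' frequencies, per-document field lengths and the average field length —
#' the sufficient statistics of BM25.
#'
#' @param docs list of \code{structured_document}s with unique doc_ids.
#' @return List with class \code{"composite_index"}.
#' @export
index_documents <- function(docs) {
  ids <- vapply(docs, `[[`, character(1), "doc_id")
  if (anyDuplicated(ids)) {
    stop("duplicate doc_id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  ord <- order(ids)
  docs <- docs[ord]; ids <- ids[ord]
  field_names <- c(segment_categories(), "all_text")
  fields <- list()
  for (f in field_names) {
    lens <- stats::setNames(numeric(length(ids)), ids)
    doc_v <- character(0); term_v <- character(0); tf_v <- integer(0)
    for (k in seq_along(docs)) {
      bag <- if (f == "all_text") docs[[k]]$all_text else docs[[k]]$fields[[f]]
      if (is.null(bag)) bag <- character(0)
      lens[k] <- length(bag)
      if (length(bag) > 0) {
        tf <- table(bag)
        doc_v <- c(doc_v, rep(ids[k], length(tf)))
        term_v <- c(term_v, names(tf))
        tf_v <- c(tf_v, as.integer(tf))
      }
    }
    # postings: term -> named tf vector over the documents containing it
    postings <- if (length(term_v) > 0) {
      lapply(split(stats::setNames(tf_v, doc_v), term_v), identity)
    } else list()
    df <- vapply(postings, length, integer(1))
    fields[[f]] <- list(postings = postings, df = df, len = lens,
                        avglen = mean(lens))
  }
  structure(list(N = length(docs), doc_ids = ids,
                 pub_year = stats::setNames(
                   vapply(docs, `[[`, integer(1), "pub_year"), ids),
                 fields = fields),
            class = "composite_index")
}

#' @export
print.composite_index <- function(x, ...) {
  cat(sprintf("<composite_index> %d documents, %d fields\n",
              x$N, length(x$fields)))
  invisible(x)
}

#' Okapi BM25 score of a term bag against one field of one document
#'
#' \deqn{\sum_t idf(t) \frac{tf(t,d)(k_1+1)}{tf(t,d) + k_1(1-b+b\,len_d/avglen)}}
#' with \eqn{idf(t) = \ln(1 + (N - df_t + 0.5)/(df_t + 0.5))}, which is
#' floored at zero by construction. Query terms are counted with
#' multiplicity; terms absent from the document contribute 0, terms absent
#' from the corpus use the df = 0 form of the idf.
#'
#' @param terms character vector of (already tokenised, lowercased) terms.
#' @param doc_id document to score.
#' @param field field name (a category or "all_text").
#' @param index a \code{composite_index}.
#' @param cfg a \code{ranking_config}.
#' @return Non-negative scalar score.
#' @export
bm25_field_score <- function(terms, doc_id, field, index,
                             cfg = ranking_config()) {
  fl <- index$fields[[field]]
  if (is.null(fl)) stop("unknown field '", field, "'", call. = FALSE)
  if (length(terms) == 0) return(0)
  len <- fl$len[[doc_id]]
  norm <- cfg$k1 * (1 - cfg$b + cfg$b * if (fl$avglen > 0) len / fl$avglen else 0)
  score <- 0
  for (t in terms) {
    post <- fl$postings[[t]]
    tf <- if (!is.null(post) && !is.na(post[doc_id])) as.numeric(post[[doc_id]]) else 0
    if (tf == 0) next
    df <- as.numeric(fl$df[[t]])
    idf <- log(1 + (index$N - df + 0.5) / (df + 0.5))
    score <- score + idf * tf * (cfg$k1 + 1) / (tf + norm)
  }
  score
}

# tokenise a vector of query phrases into a lowercased term bag
query_term_bag <- function(phrases) {
  tolower(unlist(lapply(phrases, function(p) tokenize(p)$text),
                 use.names = FALSE))
}

#' Composite weighted BM25 score of a query against one document
#'
#' Total score = sum over categories of w_c * BM25 of the terms routed to
#' category c against the document's category field, plus w_all * BM25 of
#' all query terms against the all_text field. The per-field breakdown sums
#' to the total.
#'
#' @param query a \code{patient_query} with \code{fields} populated.
#' @param doc_id document to score.
#' @param index a \code{composite_index}.
#' @param cfg a \code{ranking_config}.
#' @return List with class \code{"search_result"}: doc_id, score, breakdown.
#' @export
composite_score <- function(query, doc_id, index, cfg = ranking_config()) {
  breakdown <- stats::setNames(numeric(length(cfg$weights)), names(cfg$weights))
  for (f in names(query$fields)) {
    w <- cfg$weights[[f]]
    if (is.null(w) || w == 0) next
    breakdown[f] <- w * bm25_field_score(query_term_bag(query$fields[[f]]),
                                         doc_id, f, index, cfg)
  }
  w_all <- cfg$weights[["all_text"]]
  if (!is.null(w_all) && w_all > 0) {
    breakdown["all_text"] <- w_all * bm25_field_score(
      query_term_bag(query$terms), doc_id, "all_text", index, cfg)
  }
  structure(list(doc_id = doc_id, score = sum(breakdown),
                 breakdown = breakdown, rank = NA_integer_),
            class = "search_result")
}

#' Ranked retrieval over the composite index
#'
#' Scores every document passing the publication-date filter and returns the
#' top \code{cfg$top_k} by descending composite score; ties are broken by
#' ascending doc_id so results are deterministic.
#'
#' @param query a \code{patient_query} with routed fields.
#' @param index a \code{composite_index}.
#' @param cfg a \code{ranking_config} (holds \code{min_year} and
#'   \code{top_k}).
#' @return List of \code{search_result}s with ranks assigned.
#' @export
search_index <- function(query, index, cfg = ranking_config()) {
  ids <- index$doc_ids
  if (!is.na(cfg$min_year)) {
    ids <- ids[!is.na(index$pub_year[ids]) & index$pub_year[ids] >= cfg$min_year]
  }
  if (length(ids) == 0) return(list())
  # term-at-a-time accumulation over postings; algebraically identical to
  # composite_score applied to every document
  scores <- stats::setNames(numeric(length(index$doc_ids)), index$doc_ids)
  score_field <- function(field, phrases, w) {
    bag <- query_term_bag(phrases)
    if (length(bag) == 0 || w == 0) return()
    fl <- index$fields[[field]]
    if (fl$avglen == 0) return()
    denom <- cfg$k1 * (1 - cfg$b + cfg$b * fl$len / fl$avglen)
    qtf <- table(bag)
    for (t in names(qtf)) {
      post <- fl$postings[[t]]
      if (is.null(post)) next
      df <- as.numeric(fl$df[[t]])
      idf <- log(1 + (index$N - df + 0.5) / (df + 0.5))
      d <- names(post)
      contrib <- idf * post * (cfg$k1 + 1) / (post + denom[d])
      scores[d] <<- scores[d] + w * as.numeric(qtf[[t]]) * contrib
    }
  }
  for (f in names(query$fields)) {
    w <- cfg$weights[[f]]
    if (!is.null(w)) score_field(f, query$fields[[f]], w)
  }
  if (!is.null(cfg$weights[["all_text"]])) {
    score_field("all_text", query$terms, cfg$weights[["all_text"]])
  }
  scores <- scores[ids]
  ord <- order(-scores, ids)
  top <- ids[ord[seq_len(min(cfg$top_k, length(ord)))]]
  out <- lapply(top, function(d) composite_score(query, d, index, cfg))
  for (r in seq_along(out)) out[[r]]$rank <- r
  out
}
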