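#' Tokenise text into offset-tracked tokens
#'
#' Splits on whitespace and at punctuation boundaries while keeping
#' clinically meaningful composites intact: internal hyphens, dots and
#' mutation punctuation inside alphanumeric runs stay in one token, so
#' "66-year-old" and "c.427G>A" each come out as a single token. Any other
#' punctuation character becomes its own token. Offsets are 0-based,
#' half-open, counted in unicode code points, so
#' \code{substr(text, start + 1, end)} recovers each token's text.
#'
#' @param text a single character string (may be empty).
#' @return A data.frame with columns \code{text}, \code{start}, \code{end},
#'   one row per token, sorted by \code{start}.
#' @export
#' @examples
#' tokenize("a 43-year-old male")$text
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  empty <- data.frame(text = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  text <- enc2utf8(text)
  # alphanumeric core with internal joining punctuation, or a lone symbol
  pat <- "[\\p{L}\\p{N}](?:[\\p{L}\\p{N}.'>_+-]*[\\p{L}\\p{N}])?|[^\\s\\p{L}\\p{N}]"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(empty)
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  data.frame(
    text = regmatches(text, list(m))[[1]],
    start = starts,
    end = starts + as.integer(lens),
    stringsAsFactors = FALSE
  )
}

#' Encode gold segments as per-token BIO labels
#'
#' A token receives \code{B-c} if it is the first token intersecting a
#' segment of category \code{c}, \code{I-c} for later intersecting tokens,
#' and \code{O} otherwise. A token intersects a segment when their half-open
#' character ranges overlap.
#'
#' @param abstract a \code{labeled_abstract} (segments must be non-overlapping).
#' @param tokens data.frame from \code{\link{tokenize}} over \code{abstract$text}.
#' @return Character vector of BIO labels, one per token.
#' @export
encode_bio <- function(abstract, tokens) {
  stopifnot(inherits(abstract, "labeled_abstract"))
  labels <- rep("O", nrow(tokens))
  if (nrow(tokens) == 0) return(labels)
  for (s in abstract$segments) {
    hit <- which(tokens$start < s$end & tokens$end > s$start)
    if (length(hit) == 0) next
    if (any(labels[hit] != "O")) stop("segments overlap on a token", call. = FALSE)
    labels[hit] <- paste0("I-", s$category)
    labels[hit[1]] <- paste0("B-", s$category)
  }
  labels
}

#' Decode BIO labels back to segments
#'
#' Maximal runs of same-category labels become one segment spanning from the
#' first token's start to the last token's end. An \code{I-c} that does not
#' follow a \code{B-c} or \code{I-c} of the same category is repaired to
#' \code{B-c}.
#'
#' @param tokens data.frame from \code{\link{tokenize}}.
#' @param labels character vector of BIO labels, same length as tokens.
#' @param text optional source text used to fill segment text slices.
#' @return List of \code{segment} objects.
#' @export
decode_bio <- function(tokens, labels, text = NULL) {
  if (nrow(tokens) != length(labels)) {
    stop("tokens and labels have different lengths", call. = FALSE)
  }
  segs <- list()
  open_cat <- NA_character_
  open_start <- NA_integer_
  open_end <- NA_integer_
  flush <- function() {
    if (is.na(open_cat)) return()
    txt <- if (is.null(text)) NA_character_ else
      substr(text, open_start + 1L, open_end)
    segs[[length(segs) + 1L]] <<- segment(open_cat, open_start, open_end, txt)
  }
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (lab == "O") {
      flush(); open_cat <- NA_character_
      next
    }
    cat_i <- sub("^[BI]-", "", lab)
    # maximal same-category runs merge into one segment; orphan I- begins one
    begin <- is.na(open_cat) || cat_i != open_cat
    if (begin) {
      flush()
      open_cat <- cat_i
      open_start <- tokens$start[i]
    }
    open_end <- tokens$end[i]
  }
  flush()
  segs
}
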