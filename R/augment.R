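#' Augmentation configuration for pseudo-query training
#'
#' Pseudo-queries make the segmenter robust to the comma-separated query
#' strings generated from survey records: a training abstract is replaced by
#' the concatenation of \code{N ~ Poisson(lambda)} of its gold segments
#' (clamped to the number available), joined by a separator, with the gold
#' spans carried over at their new offsets.
#'
#' @param lambda Poisson rate for the number of segments (default 5).
#' @param swap_fraction probability that a training example is replaced by a
#'   fresh pseudo-query at each iteration (default 0.5: half the iterations).
#' @param separator string between concatenated segments (default ", ").
#' @param seed integer seed controlling augmentation randomness.
#' @return List with class \code{"augmentation_config"}.
#' @export
augmentation_config <- function(lambda = 5, swap_fraction = 0.5,
                                separator = ", ", seed = 1L) {
  stopifnot(lambda > 0, swap_fraction >= 0, swap_fraction <= 1)
  structure(list(lambda = lambda, swap_fraction = swap_fraction,
                 separator = separator, seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Build a pseudo-query from an annotated abstract
#'
#' Draws \code{N ~ Poisson(lambda)}, clamps it to \code{[1, n_segments]},
#' samples that many distinct gold segments uniformly without replacement,
#' and concatenates their texts with the configured separator. The returned
#' document carries the sampled spans at their new character offsets and is
#' flagged \code{is_pseudo_query}.
#'
#' @param abstract a \code{labeled_abstract} with at least one gold segment.
#' @param cfg an \code{augmentation_config}.
#' @return A new \code{labeled_abstract}.
#' @export
make_pseudo_query <- function(abstract, cfg = augmentation_config()) {
  k <- length(abstract$segments)
  if (k == 0) {
    stop("abstract '", abstract$doc_id,
         "' has no gold segments; unusable for pseudo-query augmentation",
         call. = FALSE)
  }
  n <- max(1L, min(k, stats::rpois(1, cfg$lambda)))
  picked <- abstract$segments[sample.int(k, n)]
  sep_n <- nchar(cfg$separator)
  pieces <- vapply(picked, `[[`, character(1), "text")
  text <- paste(pieces, collapse = cfg$separator)
  offset <- 0L
  segs <- vector("list", n)
  for (i in seq_len(n)) {
    len <- nchar(pieces[i])
    segs[[i]] <- segment(picked[[i]]$category, offset, offset + len, pieces[i])
    offset <- offset + len + sep_n
  }
  labeled_abstract(paste0(abstract$doc_id, "-pq"), text,
                   disease = abstract$disease, pub_year = abstract$pub_year,
                   segments = segs, is_pseudo_query = TRUE)
}

#' One augmentation draw for a training iteration
#'
#' The mechanism used at every training iteration: with probability
#' \code{cfg$swap_fraction} the abstract is replaced by a fresh pseudo-query
#' (so the default 0.5 makes half the training iterations query-shaped);
#' otherwise the original document is returned unchanged. Documents without
#' gold segments are never swapped.
#'
#' @param doc a \code{labeled_abstract}.
#' @param cfg an \code{augmentation_config}.
#' @return A \code{labeled_abstract}; check \code{is_pseudo_query} to see
#'   whether the swap happened.
#' @export
augment_iteration <- function(doc, cfg = augmentation_config()) {
  if (length(doc$segments) > 0 && cfg$swap_fraction > 0 &&
      stats::runif(1) < cfg$swap_fraction) {
    make_pseudo_query(doc, cfg)
  } else {
    doc
  }
}

#' Split a corpus into train / validation / test partitions
#'
#' Seeded uniform shuffle, then the first \code{n_test} documents form the
#' test set, the next \code{n_val} the validation set, and the remainder the
#' training set. Deterministic for a fixed seed.
#'
#' @param corpus list of \code{labeled_abstract}s.
#' @param n_test,n_val partition sizes.
#' @param seed integer seed.
#' @return List with elements \code{train}, \code{val}, \code{test}.
#' @export
#' @examples
#' # a 200-document corpus yields the 160/20/20 split used for training
split_corpus <- function(corpus, n_test = 20L, n_val = 20L, seed = 1L) {
  n <- length(corpus)
  if (n <= n_test + n_val) {
    stop("corpus too small for requested split: ", n, " docs, need more than ",
         n_test + n_val, call. = FALSE)
  }
  perm <- with_seed(seed, sample.int(n))
  list(
    test = corpus[perm[seq_len(n_test)]],
    val = corpus[perm[n_test + seq_len(n_val)]],
    train = corpus[perm[(n_test + n_val + 1):n]]
  )
}

# Evaluate expr with a temporary RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
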