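#' Hand-crafted sparse per-token features
#'
#' The bundled token encoder. For token \code{i} of a tokenised text it emits
#' a sparse set of indicator features: the lowercased token, its collapsed
#' word shape (uppercase runs -> "X", lowercase -> "x", digits -> "d",
#' punctuation kept), prefixes and suffixes of length 1-3, digit / hyphen /
#' mutation-cue flags (">" and "." inside the token), the identities of the
#' two tokens on either side, and a quartile position bucket. Deterministic:
#' the same token in the same context always yields the same features.
#'
#' Encoder contract: training and decoding accept any function
#' \code{f(tokens)} returning a list with one named numeric vector per token
#' (names are feature identifiers, values real scores); this encoder is the
#' indicator-valued special case.
#'
#' @param tokens data.frame from \code{\link{tokenize}}.
#' @param i token index (1-based).
#' @return Named numeric vector of feature values for token \code{i}.
#' @export
featurize <- function(tokens, i) {
  n <- nrow(tokens)
  if (i < 1 || i > n) stop("token index out of range", call. = FALSE)
  w <- tokens$text[i]
  lw <- tolower(w)
  feats <- c(
    paste0("w=", lw),
    paste0("shape=", word_shape(w)),
    paste0("p1=", substr(lw, 1, 1)),
    paste0("s1=", substr(lw, nchar(lw), nchar(lw)))
  )
  if (nchar(lw) >= 2) {
    feats <- c(feats,
               paste0("p2=", substr(lw, 1, 2)),
               paste0("s2=", substr(lw, nchar(lw) - 1, nchar(lw))))
  }
  if (nchar(lw) >= 3) {
    feats <- c(feats,
               paste0("p3=", substr(lw, 1, 3)),
               paste0("s3=", substr(lw, nchar(lw) - 2, nchar(lw))))
  }
  if (grepl("^[0-9]+$", w)) feats <- c(feats, "isdigit")
  if (grepl("[0-9]", w)) feats <- c(feats, "hasdigit")
  if (grepl("-", w, fixed = TRUE)) feats <- c(feats, "hyphen")
  if (grepl(">", w, fixed = TRUE)) feats <- c(feats, "gtcue")
  if (grepl(".", w, fixed = TRUE)) feats <- c(feats, "dotcue")
  for (d in c(-2L, -1L, 1L, 2L)) {
    j <- i + d
    ctx <- if (j < 1) "<s>" else if (j > n) "</s>" else tolower(tokens$text[j])
    feats <- c(feats, paste0("w", ifelse(d > 0, "+", ""), d, "=", ctx))
  }
  feats <- c(feats, paste0("posq=", ceiling(4 * i / n)), "bias")
  stats::setNames(rep(1, length(feats)), feats)
}

word_shape <- function(w) {
  chars <- strsplit(w, "", fixed = TRUE)[[1]]
  sh <- ifelse(grepl("[A-Z]", chars), "X",
        ifelse(grepl("[a-z]", chars), "x",
        ifelse(grepl("[0-9]", chars), "d", chars)))
  paste(rle(sh)$values, collapse = "")
}

#' Default sparse encoder over a whole token sequence
#'
#' Applies \code{\link{featurize}} to every position; the unit used by CRF
#' training and decoding.
#'
#' @param tokens data.frame from \code{\link{tokenize}}.
#' @return List of named numeric feature vectors, one per token.
#' @export
sparse_encoder <- function(tokens) {
  lapply(seq_len(nrow(tokens)), function(i) featurize(tokens, i))
}

# Stack per-token feature vectors into a sparse n_tokens x n_features design
# matrix over a fixed feature dictionary; unknown features are dropped.
feature_matrix <- function(feat_list, dictionary) {
  n <- length(feat_list)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (t in seq_len(n)) {
    f <- feat_list[[t]]
    idx <- match(names(f), dictionary)
    keep <- !is.na(idx)
    ii <- c(ii, rep(t, sum(keep)))
    jj <- c(jj, idx[keep])
    xx <- c(xx, unname(f[keep]))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(n, length(dictionary)))
}
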