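logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Construct an (untrained) linear-chain CRF segmenter model
#'
#' Holds emission weights over a sparse feature dictionary, label-to-label
#' transition weights, and start/stop transition weights. Scores a label
#' path y for a token sequence x as
#' \deqn{s(x, y) = a_{y_1} + \sum_t \phi(x, t)^\top W_{\cdot y_t}
#'   + \sum_{t>1} T_{y_{t-1} y_t} + b_{y_n}}
#' and defines \eqn{P(y | x) = \exp(s(x,y)) / Z(x)} with the partition
#' function computed by the forward recursion in log space.
#'
#' @param labels label set (default the 17 BIO labels).
#' @param features character vector: the feature dictionary.
#' @param encoder per-token encoder function (default \code{sparse_encoder}).
#' @param config list snapshot of training configuration.
#' @return A list with class \code{"segmenter_model"}.
#' @export
segmenter_model <- function(labels = bio_labels(), features = character(0),
                            encoder = sparse_encoder, config = list()) {
  L <- length(labels)
  structure(
    list(
      labels = labels,
      features = features,
      W = matrix(0, length(features), L, dimnames = list(features, labels)),
      trans = matrix(0, L, L, dimnames = list(labels, labels)),
      start = stats::setNames(rep(0, L), labels),
      stop = stats::setNames(rep(0, L), labels),
      encoder = encoder,
      encoder_name = "sparse_handcrafted",
      config = config,
      training_log = NULL
    ),
    class = "segmenter_model"
  )
}

#' @export
print.segmenter_model <- function(x, ...) {
  cat(sprintf("<segmenter_model> %d labels, %d features, encoder: %s\n",
              length(x$labels), length(x$features), x$encoder_name))
  if (!is.null(x$training_log)) {
    last <- x$training_log[nrow(x$training_log), ]
    cat(sprintf("  trained %d epochs, best val token-F1 %.3f\n",
                nrow(x$training_log), max(x$training_log$val_f1, na.rm = TRUE)))
  }
  invisible(x)
}

# Emission score matrix (n_tokens x L) for a design matrix X.
crf_emissions <- function(model, X) {
  as.matrix(X %*% model$W)
}

# Forward recursion in log space. Returns list(log_alpha, logZ).
crf_forward <- function(E, trans, start, stop) {
  n <- nrow(E); L <- ncol(E)
  la <- matrix(-Inf, n, L)
  la[1, ] <- start + E[1, ]
  if (n > 1) {
    for (t in 2:n) {
      M <- la[t - 1, ] + trans            # M[i, j] = alpha[i] + T[i, j]
      mx <- apply(M, 2, max)
      la[t, ] <- mx + log(colSums(exp(sweep(M, 2, mx)))) + E[t, ]
    }
  }
  list(log_alpha = la, logZ = logsumexp(la[n, ] + stop))
}

# Backward recursion; log_beta[t, j] includes the stop weight.
crf_backward <- function(E, trans, stop) {
  n <- nrow(E); L <- ncol(E)
  lb <- matrix(-Inf, n, L)
  lb[n, ] <- stop
  if (n > 1) {
    for (t in (n - 1):1) {
      M <- sweep(trans, 2, E[t + 1, ] + lb[t + 1, ], `+`)  # M[i,j] over next j
      mx <- apply(M, 1, max)
      lb[t, ] <- mx + log(rowSums(exp(M - mx)))
    }
  }
  lb
}

crf_path_score <- function(E, trans, start, stop, y) {
  n <- nrow(E)
  s <- start[y[1]] + sum(E[cbind(seq_len(n), y)]) + stop[y[n]]
  if (n > 1) s <- s + sum(trans[cbind(y[-n], y[-1])])
  unname(s)
}

#' Conditional log-likelihood of a gold label path
#'
#' \code{log P(y | x) = s(x, y) - log Z(x)}; always <= 0.
#'
#' @param model a \code{segmenter_model}.
#' @param tokens data.frame from \code{\link{tokenize}}.
#' @param labels gold BIO labels, one per token.
#' @return Scalar log-likelihood.
#' @export
crf_log_likelihood <- function(model, tokens, labels) {
  if (!all(labels %in% model$labels)) {
    stop("gold labels outside the model label set", call. = FALSE)
  }
  if (any(!is.finite(model$W)) || any(!is.finite(model$trans))) {
    stop("model weights are not finite", call. = FALSE)
  }
  X <- feature_matrix(model$encoder(tokens), model$features)
  y <- match(labels, model$labels)
  E <- crf_emissions(model, X)
  fwd <- crf_forward(E, model$trans, model$start, model$stop)
  crf_path_score(E, model$trans, model$start, model$stop, y) - fwd$logZ
}

# Gradient of log P(y | x) wrt (W, trans, start, stop): observed minus
# expected sufficient statistics, via forward-backward marginals.
crf_gradient <- function(model, X, y) {
  L <- length(model$labels)
  n <- nrow(X)
  E <- crf_emissions(model, X)
  fwd <- crf_forward(E, model$trans, model$start, model$stop)
  la <- fwd$log_alpha
  lb <- crf_backward(E, model$trans, model$stop)
  logZ <- fwd$logZ
  P <- exp(la + lb - logZ)                  # unary marginals (n x L)
  Yh <- matrix(0, n, L); Yh[cbind(seq_len(n), y)] <- 1
  gW <- as.matrix(Matrix::crossprod(X, Yh - P))
  gT <- matrix(0, L, L)
  if (n > 1) {
    for (t in 2:n) {
      M <- exp(outer(la[t - 1, ], E[t, ] + lb[t, ], `+`) + model$trans - logZ)
      gT <- gT - M
      gT[y[t - 1], y[t]] <- gT[y[t - 1], y[t]] + 1
    }
  }
  gs <- -P[1, ]; gs[y[1]] <- gs[y[1]] + 1
  ge <- -P[n, ]; ge[y[n]] <- ge[y[n]] + 1
  list(W = gW, trans = gT, start = gs, stop = ge,
       loglik = crf_path_score(E, model$trans, model$start, model$stop, y) - logZ)
}

#' Viterbi decoding of the most probable label path
#'
#' Returns an argmax-scoring BIO label sequence. Ties are broken towards the
#' lowest label index at every backtracking step, so decoding is
#' deterministic for fixed weights.
#'
#' @param model a \code{segmenter_model}.
#' @param tokens data.frame from \code{\link{tokenize}} (may have 0 rows).
#' @return Character vector of BIO labels (empty for empty input).
#' @export
viterbi_decode <- function(model, tokens) {
  if (nrow(tokens) == 0) return(character(0))
  X <- feature_matrix(model$encoder(tokens), model$features)
  E <- crf_emissions(model, X)
  model$labels[viterbi_path(E, model$trans, model$start, model$stop)]
}

# Core Viterbi on score matrices; returns integer path. which.max returns the
# first (lowest-index) maximiser, giving the deterministic tie-break.
viterbi_path <- function(E, trans, start, stop) {
  n <- nrow(E); L <- ncol(E)
  delta <- start + E[1, ]
  back <- matrix(1L, n, L)
  if (n > 1) {
    for (t in 2:n) {
      M <- delta + trans
      bp <- apply(M, 2, which.max)
      delta <- M[cbind(bp, seq_len(L))] + E[t, ]
      back[t, ] <- bp
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta + stop)
  if (n > 1) for (t in n:2) path[t - 1] <- back[t, path[t]]
  path
}

#' Segment a text with a trained model
#'
#' Tokenises, decodes with Viterbi and converts BIO labels to segments.
#'
#' @param model a trained \code{segmenter_model}.
#' @param text character string to segment.
#' @return List of \code{segment} objects.
#' @export
segment_text <- function(model, text) {
  tokens <- tokenize(text)
  decode_bio(tokens, viterbi_decode(model, tokens), text = text)
}

#' Predict segments for a corpus
#'
#' @param model a trained \code{segmenter_model}.
#' @param corpus list of \code{labeled_abstract}s.
#' @return Corpus with \code{segments} replaced by predictions.
#' @export
predict_corpus <- function(model, corpus) {
  lapply(corpus, function(doc) {
    doc$segments <- segment_text(model, doc$text)
    doc
  })
}
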