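#' Train the CRF segmenter
#'
#' Maximises the L2-regularised conditional log-likelihood
#' \eqn{\sum_i \log P(y_i | x_i) - \lambda_{reg} \|\theta\|^2}
#' by seeded mini-batch gradient ascent. At every iteration each training
#' example is replaced by a freshly drawn pseudo-query with probability
#' \code{aug$swap_fraction}, so that with the default 0.5 half the training
#' iterations see query-shaped inputs. After each epoch the token-level F1
#' on the validation set is computed; the returned model carries the weights
#' of the best validation epoch (early stopping with patience).
#'
#' @param train,val lists of \code{labeled_abstract}s; \code{train} non-empty.
#' @param aug an \code{augmentation_config}.
#' @param epochs maximum number of epochs (default 100).
#' @param lr learning rate (default 0.1).
#' @param lambda_reg L2 penalty weight (default 1.0).
#' @param batch_size mini-batch size (default 8).
#' @param patience epochs without validation improvement before stopping
#'   (default 10).
#' @param seed integer seed for shuffling, batching and augmentation.
#' @param encoder per-token encoder (default \code{sparse_encoder}); any
#'   function mapping a token data.frame to per-token named numeric vectors.
#' @param labels label set (default the 17 BIO labels).
#' @param verbose print per-epoch progress.
#' @return A trained \code{segmenter_model}; \code{$training_log} holds the
#'   per-epoch loss, validation F1 and pseudo-query counts.
#' @export
train_segmenter <- function(train, val = list(), aug = augmentation_config(),
                            epochs = 100L, lr = 0.1, lambda_reg = 1.0,
                            batch_size = 8L, patience = 10L, seed = 1L,
                            encoder = sparse_encoder, labels = bio_labels(),
                            verbose = FALSE) {
  if (length(train) == 0) stop("training corpus is empty", call. = FALSE)
  set.seed(seed)

  # tokenise and gold-label once; dictionary covers abstracts plus one
  # pseudo-query draw per document so query-shaped contexts have features
  prep <- function(doc) {
    tokens <- tokenize(doc$text)
    list(doc = doc, tokens = tokens, feats = encoder(tokens),
         y = encode_bio(doc, tokens))
  }
  ptrain <- lapply(train, prep)
  dict_feats <- unlist(lapply(ptrain, function(p) {
    unlist(lapply(p$feats, names), use.names = FALSE)
  }), use.names = FALSE)
  if (aug$swap_fraction > 0) {
    for (doc in train) {
      if (length(doc$segments) == 0) next
      pq <- make_pseudo_query(doc, aug)
      dict_feats <- c(dict_feats, unlist(lapply(encoder(tokenize(pq$text)),
                                                names), use.names = FALSE))
    }
  }
  dictionary <- sort(unique(dict_feats))
  model <- segmenter_model(labels = labels, features = dictionary,
                           encoder = encoder,
                           config = list(epochs = epochs, lr = lr,
                                         lambda_reg = lambda_reg,
                                         batch_size = batch_size,
                                         patience = patience, seed = seed,
                                         lambda = aug$lambda,
                                         swap_fraction = aug$swap_fraction))
  for (p in seq_along(ptrain)) {
    ptrain[[p]]$X <- feature_matrix(ptrain[[p]]$feats, dictionary)
    ptrain[[p]]$yi <- match(ptrain[[p]]$y, labels)
  }
  pval <- lapply(val, function(doc) {
    tokens <- tokenize(doc$text)
    list(tokens = tokens, y = encode_bio(doc, tokens))
  })

  n <- length(ptrain)
  best <- list(f1 = -Inf, W = model$W, trans = model$trans,
               start = model$start, stop = model$stop, epoch = 0L)
  log_rows <- list()
  stale <- 0L
  n_pseudo_total <- 0L
  n_iter_total <- 0L

  for (epoch in seq_len(epochs)) {
    order_ <- sample.int(n)
    total_ll <- 0
    n_pseudo <- 0L
    for (b_start in seq(1, n, by = batch_size)) {
      idx <- order_[b_start:min(b_start + batch_size - 1, n)]
      gW <- matrix(0, nrow(model$W), ncol(model$W))
      gT <- matrix(0, length(labels), length(labels))
      gs <- rep(0, length(labels)); ge <- rep(0, length(labels))
      for (k in idx) {
        ex <- ptrain[[k]]
        n_iter_total <- n_iter_total + 1L
        drawn <- augment_iteration(ex$doc, aug)
        if (drawn$is_pseudo_query) {
          n_pseudo <- n_pseudo + 1L
          tokens <- tokenize(drawn$text)
          X <- feature_matrix(encoder(tokens), dictionary)
          yi <- match(encode_bio(drawn, tokens), labels)
        } else {
          X <- ex$X; yi <- ex$yi
        }
        g <- crf_gradient(model, X, yi)
        if (!is.finite(g$loglik)) {
          stop("training diverged: non-finite log-likelihood at epoch ",
               epoch, call. = FALSE)
        }
        gW <- gW + g$W; gT <- gT + g$trans; gs <- gs + g$start; ge <- ge + g$stop
        total_ll <- total_ll + g$loglik
      }
      m <- length(idx)
      step <- lr / m
      shrink <- 2 * lambda_reg / n
      model$W <- model$W + step * (gW - m * shrink * model$W)
      model$trans <- model$trans + step * (gT - m * shrink * model$trans)
      model$start <- model$start + step * (gs - m * shrink * model$start)
      model$stop <- model$stop + step * (ge - m * shrink * model$stop)
    }
    n_pseudo_total <- n_pseudo_total + n_pseudo
    val_f1 <- if (length(pval) > 0) {
      mets <- token_f1_prepped(model, pval)
      mets$f1
    } else NA_real_
    log_rows[[epoch]] <- data.frame(epoch = epoch, loglik = total_ll,
                                    val_f1 = val_f1, n_pseudo = n_pseudo)
    if (verbose) {
      message(sprintf("epoch %3d  loglik %10.2f  val F1 %s  pseudo %d",
                      epoch, total_ll,
                      ifelse(is.na(val_f1), "NA", sprintf("%.3f", val_f1)),
                      n_pseudo))
    }
    track <- if (is.na(val_f1)) total_ll else val_f1
    if (track > best$f1 + 1e-9) {
      best <- list(f1 = track, W = model$W, trans = model$trans,
                   start = model$start, stop = model$stop, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  model$W <- best$W; model$trans <- best$trans
  model$start <- best$start; model$stop <- best$stop
  model$training_log <- do.call(rbind, log_rows)
  model$config$best_epoch <- best$epoch
  model$config$n_pseudo_iterations <- n_pseudo_total
  model$config$n_iterations <- n_iter_total
  model
}

# token-level F1 on pre-tokenised validation docs
token_f1_prepped <- function(model, pval) {
  tp <- 0L; np <- 0L; ng <- 0L
  for (ex in pval) {
    pred <- viterbi_decode(model, ex$tokens)
    gold <- ex$y
    tp <- tp + sum(pred != "O" & pred == gold)
    np <- np + sum(pred != "O")
    ng <- ng + sum(gold != "O")
  }
  p <- if (np > 0) tp / np else 0
  r <- if (ng > 0) tp / ng else 0
  list(precision = p, recall = r, f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}

#' Segmentation quality metrics
#'
#' Token-level micro-averaged precision/recall/F1 over non-O labels
#' (primary) and exact-span-match micro F1 (secondary). A predicted token
#' counts as a true positive when its BIO label equals the gold label and is
#' not O; a predicted span counts as a span match when its (category, start,
#' end) triple occurs in the gold annotation.
#'
#' @param gold,pred aligned lists of \code{labeled_abstract}s carrying gold
#'   and predicted segments for the same documents (matched by doc_id).
#' @return List with \code{token} and \code{span} sublists, each holding
#'   \code{precision}, \code{recall}, \code{f1}, and the underlying counts.
#' @export
evaluate_f1 <- function(gold, pred) {
  gids <- vapply(gold, `[[`, character(1), "doc_id")
  pids <- vapply(pred, `[[`, character(1), "doc_id")
  if (!identical(gids, pids)) {
    stop("gold and predicted corpora are not aligned by doc_id", call. = FALSE)
  }
  tok <- c(tp = 0L, np = 0L, ng = 0L)
  spn <- c(tp = 0L, np = 0L, ng = 0L)
  for (i in seq_along(gold)) {
    tokens <- tokenize(gold[[i]]$text)
    yg <- encode_bio(gold[[i]], tokens)
    yp <- encode_bio(pred[[i]], tokens)
    tok["tp"] <- tok["tp"] + sum(yp != "O" & yp == yg)
    tok["np"] <- tok["np"] + sum(yp != "O")
    tok["ng"] <- tok["ng"] + sum(yg != "O")
    key <- function(segs) vapply(segs, function(s)
      paste(s$category, s$start, s$end), character(1))
    kg <- key(gold[[i]]$segments); kp <- key(pred[[i]]$segments)
    spn["tp"] <- spn["tp"] + sum(kp %in% kg)
    spn["np"] <- spn["np"] + length(kp)
    spn["ng"] <- spn["ng"] + length(kg)
  }
  prf <- function(cnt) {
    p <- if (cnt["np"] > 0) cnt["tp"] / cnt["np"] else 0
    r <- if (cnt["ng"] > 0) cnt["tp"] / cnt["ng"] else 0
    list(precision = unname(p), recall = unname(r),
         f1 = unname(if (p + r > 0) 2 * p * r / (p + r) else 0),
         counts = cnt)
  }
  list(token = prf(tok), span = prf(spn))
}
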