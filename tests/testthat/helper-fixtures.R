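# Shared fixtures built in code.

# Random small CRF over a reduced label set, for brute-force comparisons.
random_crf <- function(labels = c("O", "B-AGE", "I-AGE"),
                       vocab = c("a", "b", "c"), seed = 1, sd = 1) {
  set.seed(seed)
  feats <- sort(unique(unlist(lapply(vocab, function(v) {
    toks <- tokenize(paste(rep(vocab, 3), collapse = " "))
    unlist(lapply(seq_len(nrow(toks)), function(i) names(featurize(toks, i))))
  }))))
  m <- segmenter_model(labels = labels, features = feats)
  m$W[] <- rnorm(length(m$W), sd = sd)
  m$trans[] <- rnorm(length(m$trans), sd = sd)
  m$start[] <- rnorm(length(m$start), sd = sd)
  m$stop[] <- rnorm(length(m$stop), sd = sd)
  m
}

# Enumerate the score of every label path (brute-force partition function).
enumerate_scores <- function(E, trans, start, stop) {
  n <- nrow(E); L <- ncol(E)
  paths <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
  apply(paths, 1, function(y) {
    s <- start[y[1]] + sum(E[cbind(seq_len(n), y)]) + stop[y[n]]
    if (n > 1) s <- s + sum(trans[cbind(y[-n], y[-1])])
    s
  })
}

crf_parts <- function(model, text) {
  toks <- tokenize(text)
  X <- zebracase:::feature_matrix(model$encoder(toks), model$features)
  list(tokens = toks, X = X, E = zebracase:::crf_emissions(model, X))
}

# A tiny abstract with known segments on fixed offsets.
toy_abstract <- function() {
  text <- "A 66-year-old male with anaemia."
  labeled_abstract("toy1", text, disease = "toy", pub_year = 2001,
                   segments = list(
                     segment("AGE", 2, 13, "66-year-old"),
                     segment("SEX", 14, 18, "male"),
                     segment("DIAGNOSIS_SIGNS_SYMPTOMS", 24, 31, "anaemia")
                   ))
}

# Structured documents for retrieval fixtures: terms given directly.
toy_docs <- function() {
  list(
    structured_document("d1", 1995,
                        fields = list(SEX = c("male"),
                                      DIAGNOSIS_SIGNS_SYMPTOMS = c("anaemia", "fatigue")),
                        all_text = c("male", "anaemia", "fatigue")),
    structured_document("d2", 2005,
                        fields = list(SEX = c("female"),
                                      DIAGNOSIS_SIGNS_SYMPTOMS = c("anaemia", "stroke")),
                        all_text = c("female", "anaemia", "stroke")),
    structured_document("d3", 2015,
                        fields = list(DIAGNOSIS_SIGNS_SYMPTOMS = c("vertigo")),
                        all_text = c("vertigo"))
  )
}

toy_query <- function(fields, terms = unlist(fields, use.names = FALSE)) {
  structure(list(patient_id = "p1", terms = terms, fields = fields),
            class = "patient_query")
}

# Deterministic hand-rolled Okapi BM25 for the oracle route.
hand_bm25 <- function(terms, bag, bags_all, k1 = 1.2, b = 0.75) {
  N <- length(bags_all)
  lens <- vapply(bags_all, length, integer(1))
  avgl <- mean(lens)
  s <- 0
  for (t in terms) {
    tf <- sum(bag == t)
    if (tf == 0) next
    df <- sum(vapply(bags_all, function(x) t %in% x, logical(1)))
    idf <- log(1 + (N - df + 0.5) / (df + 0.5))
    s <- s + idf * tf * (k1 + 1) /
      (tf + k1 * (1 - b + b * length(bag) / avgl))
  }
  s
}
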