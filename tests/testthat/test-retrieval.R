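test_that("index statistics match hand counts on a toy corpus", {
  idx <- index_documents(toy_docs())
  expect_equal(idx$N, 3)
  f <- idx$fields$DIAGNOSIS_SIGNS_SYMPTOMS
  expect_equal(unname(f$df[["anaemia"]]), 2)
  expect_equal(unname(f$df[["vertigo"]]), 1)
  expect_equal(unname(f$len), c(2, 2, 1))
  expect_equal(f$avglen, 5 / 3)
  expect_equal(idx$fields$SEX$avglen, 2 / 3)
  # single doc, single term
  one <- index_documents(list(structured_document(
    "s1", fields = list(SEX = "male"), all_text = "male")))
  expect_equal(unname(one$fields$SEX$df[["male"]]), 1)
  expect_equal(one$fields$SEX$avglen, 1)
  expect_error(index_documents(c(toy_docs(), toy_docs()[1])), "duplicate")
})

test_that("index statistics are invariant to insertion order", {
  i1 <- index_documents(toy_docs())
  i2 <- index_documents(rev(toy_docs()))
  expect_identical(i1, i2)
})

test_that("BM25 matches the closed-form hand computation", {
  idx <- index_documents(toy_docs())
  cfg <- ranking_config()
  # d1, field DIAGNOSIS, term "anaemia": tf=1, df=2, N=3, len=2, avglen=5/3
  idf <- log(1 + (3 - 2 + 0.5) / (2 + 0.5))
  denom <- 1 + 1.2 * (1 - 0.75 + 0.75 * 2 / (5 / 3))
  expect_equal(bm25_field_score("anaemia", "d1", "DIAGNOSIS_SIGNS_SYMPTOMS",
                                idx, cfg),
               idf * 1 * 2.2 / denom, tolerance = 1e-9)
  # absent from the document -> 0; absent from the corpus -> 0 by tf
  expect_equal(bm25_field_score("vertigo", "d1", "DIAGNOSIS_SIGNS_SYMPTOMS",
                                idx, cfg), 0)
  expect_equal(bm25_field_score("nosuchterm", "d1", "DIAGNOSIS_SIGNS_SYMPTOMS",
                                idx, cfg), 0)
  expect_equal(bm25_field_score(character(0), "d1", "SEX", idx, cfg), 0)
})

test_that("BM25 agrees with an independent implementation on random corpora", {
  set.seed(23)
  vocab <- c("anaemia", "stroke", "fatigue", "vertigo", "pain", "rash")
  for (r in 1:20) {
    bags <- lapply(1:5, function(i) sample(vocab, sample(1:8, 1), replace = TRUE))
    docs <- lapply(1:5, function(i) structured_document(
      paste0("d", i), fields = list(DIAGNOSIS_SIGNS_SYMPTOMS = bags[[i]]),
      all_text = bags[[i]]))
    idx <- index_documents(docs)
    q <- sample(vocab, 3)
    for (i in 1:5) {
      expect_equal(
        bm25_field_score(q, paste0("d", i), "DIAGNOSIS_SIGNS_SYMPTOMS", idx),
        hand_bm25(q, bags[[i]], bags), tolerance = 1e-9)
    }
  }
})

test_that("identical documents score identically", {
  docs <- list(
    structured_document("a", fields = list(SEX = "male"), all_text = "male"),
    structured_document("b", fields = list(SEX = "male"), all_text = "male"),
    structured_document("c", fields = list(SEX = "female"), all_text = "female"))
  idx <- index_documents(docs)
  q <- toy_query(list(SEX = "male"))
  ra <- composite_score(q, "a", idx)
  rb <- composite_score(q, "b", idx)
  expect_equal(ra$score, rb$score)
})

test_that("composite score is the weighted sum of per-field BM25", {
  idx <- index_documents(toy_docs())
  q <- toy_query(list(SEX = "male", DIAGNOSIS_SIGNS_SYMPTOMS = c("anaemia")))
  cfg <- ranking_config()
  r <- composite_score(q, "d1", idx, cfg)
  brute <- sum(vapply(names(q$fields), function(f) {
    cfg$weights[[f]] * bm25_field_score(tolower(q$fields[[f]]), "d1", f, idx, cfg)
  }, numeric(1))) +
    cfg$weights[["all_text"]] * bm25_field_score(tolower(q$terms), "d1",
                                                 "all_text", idx, cfg)
  expect_equal(r$score, brute, tolerance = 1e-9)
  expect_equal(sum(r$breakdown), r$score, tolerance = 1e-9)
  # zero weight everywhere except one field reduces to that field's BM25
  cfg1 <- ranking_config(weights = stats::setNames(
    c(1, rep(0, 7), 0), c("SEX", setdiff(segment_categories(), "SEX"),
                          "all_text")))
  r1 <- composite_score(q, "d1", idx, cfg1)
  expect_equal(r1$score, bm25_field_score("male", "d1", "SEX", idx, cfg1),
               tolerance = 1e-12)
  # doubling all weights doubles every score
  cfg2 <- ranking_config(weights = stats::setNames(
    rep(2, 9), c(segment_categories(), "all_text")))
  cfgu <- ranking_config(weights = stats::setNames(
    rep(1, 9), c(segment_categories(), "all_text")))
  expect_equal(composite_score(q, "d1", idx, cfg2)$score,
               2 * composite_score(q, "d1", idx, cfgu)$score, tolerance = 1e-9)
})

test_that("search equals exhaustive scoring with deterministic tie-breaks", {
  set.seed(31)
  vocab <- c("anaemia", "stroke", "fatigue", "vertigo", "pain", "rash", "male")
  for (r in 1:20) {
    docs <- lapply(1:10, function(i) {
      bag <- sample(vocab, sample(2:6, 1), replace = TRUE)
      structured_document(sprintf("doc%02d", i), 1990 + i,
                          fields = list(DIAGNOSIS_SIGNS_SYMPTOMS = bag),
                          all_text = bag)
    })
    idx <- index_documents(docs)
    q <- toy_query(list(DIAGNOSIS_SIGNS_SYMPTOMS = sample(vocab, 3)))
    cfg <- ranking_config(top_k = 3)
    got <- search_index(q, idx, cfg)
    all_scores <- vapply(sprintf("doc%02d", 1:10), function(d)
      composite_score(q, d, idx, cfg)$score, numeric(1))
    want <- names(all_scores)[order(-all_scores, names(all_scores))][1:3]
    expect_equal(vapply(got, `[[`, character(1), "doc_id"), want)
    expect_equal(vapply(got, `[[`, integer(1), "rank"), 1:3)
  }
})

test_that("self-retrieval ranks the matching document first", {
  docs <- list(
    structured_document("x1", fields = list(DIAGNOSIS_SIGNS_SYMPTOMS =
                                              c("angiokeratomas", "stroke")),
                        all_text = c("angiokeratomas", "stroke")),
    structured_document("x2", fields = list(DIAGNOSIS_SIGNS_SYMPTOMS =
                                              c("splenomegaly")),
                        all_text = c("splenomegaly")),
    structured_document("x3", fields = list(DIAGNOSIS_SIGNS_SYMPTOMS =
                                              c("vertigo")),
                        all_text = c("vertigo")))
  idx <- index_documents(docs)
  q <- toy_query(list(DIAGNOSIS_SIGNS_SYMPTOMS = c("angiokeratomas", "stroke")))
  res <- search_index(q, idx, ranking_config(top_k = 3))
  expect_equal(res[[1]]$doc_id, "x1")
})

test_that("the publication-date filter is sound", {
  idx <- index_documents(toy_docs())  # years 1995, 2005, 2015
  q <- toy_query(list(DIAGNOSIS_SIGNS_SYMPTOMS = "anaemia"))
  res <- search_index(q, idx, ranking_config(min_year = 2000, top_k = 3))
  yrs <- idx$pub_year[vapply(res, `[[`, character(1), "doc_id")]
  expect_true(all(yrs >= 2000))
  expect_length(search_index(q, idx, ranking_config(min_year = 2050)), 0)
  expect_length(search_index(q, index_documents(list(
    structured_document("only", 1990, fields = list(),
                        all_text = character(0)))),
    ranking_config(min_year = 2000)), 0)
})
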