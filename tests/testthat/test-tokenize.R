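test_that("tokenizer splits on whitespace and keeps hyphenated clinical tokens", {
  expect_equal(tokenize("a 43-year-old male")$text, c("a", "43-year-old", "male"))
  expect_equal(nrow(tokenize("")), 0)
  expect_equal(nrow(tokenize("   ")), 0)
  t <- tokenize("c.427G>A (p.A143T) variant")
  expect_equal(t$text, c("c.427G>A", "(", "p.A143T", ")", "variant"))
})

test_that("token offsets re-slice the source text exactly", {
  texts <- c(
    "c.427G>A (p.A143T) variant",
    "Creatinine level (200 micromol/L), anaemia; no history of diabetes.",
    "a 66-year-old Ashkenazi Jewish male, splenomegaly",
    "café-au-lait spots, β-thalassaemia trait"
  )
  for (txt in texts) {
    toks <- tokenize(txt)
    for (i in seq_len(nrow(toks))) {
      expect_identical(substr(txt, toks$start[i] + 1, toks$end[i]),
                       toks$text[i])
    }
    expect_true(all(diff(toks$start) > 0))
    expect_true(all(toks$start < toks$end))
    expect_true(all(toks$end <= nchar(txt)))
    # non-overlap of consecutive tokens
    if (nrow(toks) > 1) expect_true(all(toks$start[-1] >= toks$end[-nrow(toks)]))
  }
})

test_that("BIO encoding marks first intersecting token B and later ones I", {
  a <- toy_abstract()
  toks <- tokenize(a$text)
  y <- encode_bio(a, toks)
  expect_equal(y, c("O", "B-AGE", "B-SEX", "O", "B-DIAGNOSIS_SIGNS_SYMPTOMS", "O"))

  b <- labeled_abstract("b", "one two three four five six",
                        segments = list(segment("AGE", 8, 23, "three four five")))
  yb <- encode_bio(b, tokenize(b$text))
  expect_equal(yb, c("O", "O", "B-AGE", "I-AGE", "I-AGE", "O"))

  no_seg <- labeled_abstract("c", "nothing here")
  expect_equal(encode_bio(no_seg, tokenize(no_seg$text)), c("O", "O"))
})

test_that("overlapping segments are rejected", {
  expect_error(
    labeled_abstract("x", "aa bb cc",
                     segments = list(segment("AGE", 0, 5, "aa bb"),
                                     segment("SEX", 3, 8, "bb cc"))),
    "overlap")
})

test_that("decode matches a hand-enumerated table on all length<=3 sequences", {
  toks <- tokenize("w1 w2 w3")
  labs <- c("O", "B-AGE", "I-AGE")
  # independent oracle: maximal non-O runs (same category) become segments;
  # hand-specified via run-length encoding over the category sequence
  oracle <- function(y) {
    cat_seq <- ifelse(y == "O", NA, "AGE")
    r <- rle(cat_seq)
    ends <- cumsum(r$lengths)
    starts_i <- ends - r$lengths + 1
    keep <- !is.na(r$values)
    Map(function(s, e) c(toks$start[s], toks$end[e]),
        starts_i[keep], ends[keep])
  }
  for (n in 1:3) {
    grid <- expand.grid(rep(list(labs), n), stringsAsFactors = FALSE)
    for (r in seq_len(nrow(grid))) {
      y <- as.character(unlist(grid[r, ]))
      got <- decode_bio(toks[seq_len(n), , drop = FALSE], y)
      want <- oracle(y)
      expect_equal(length(got), length(want))
      for (k in seq_along(got)) {
        expect_equal(c(got[[k]]$start, got[[k]]$end), unname(want[[k]]))
        expect_equal(got[[k]]$category, "AGE")
      }
    }
  }
})

test_that("orphan I- labels are repaired to segment starts", {
  toks <- tokenize("w1 w2")
  segs <- decode_bio(toks, c("I-AGE", "I-AGE"))
  expect_length(segs, 1)
  expect_equal(segs[[1]]$start, 0)
  expect_equal(segs[[1]]$end, 5)
  expect_error(decode_bio(toks, c("O")), "length")
})

test_that("encode/decode round-trips token-aligned segments on random docs", {
  set.seed(41)
  for (rep in 1:50) {
    n_tok <- sample(5:25, 1)
    words <- sample(c("alpha", "beta", "gamma", "x1"), n_tok, replace = TRUE)
    text <- paste(words, collapse = " ")
    toks <- tokenize(text)
    # random non-overlapping, non-adjacent token runs
    segs <- list()
    i <- 1
    while (i <= n_tok) {
      if (runif(1) < 0.4) {
        j <- min(n_tok, i + sample(0:2, 1))
        cat_k <- sample(segment_categories(), 1)
        segs[[length(segs) + 1]] <- segment(
          cat_k, toks$start[i], toks$end[j],
          substr(text, toks$start[i] + 1, toks$end[j]))
        i <- j + 2  # gap token keeps same-category runs separated
      } else i <- i + 1
    }
    a <- labeled_abstract(paste0("r", rep), text, segments = segs)
    decoded <- decode_bio(toks, encode_bio(a, toks), text)
    expect_equal(length(decoded), length(a$segments))
    for (k in seq_along(decoded)) {
      expect_equal(decoded[[k]]$start, a$segments[[k]]$start)
      expect_equal(decoded[[k]]$end, a$segments[[k]]$end)
      expect_equal(decoded[[k]]$category, a$segments[[k]]$category)
    }
  }
})

test_that("feature extraction is deterministic and exposes shape cues", {
  toks <- tokenize("a 43-year-old male")
  f <- featurize(toks, 2)
  expect_true("shape=d-x-x" %in% names(f))
  expect_true("hyphen" %in% names(f))
  expect_identical(f, featurize(toks, 2))
  expect_error(featurize(toks, 9), "range")
  fg <- featurize(tokenize("c.427G>A variant"), 1)
  expect_true(all(c("gtcue", "dotcue") %in% names(fg)))
})

test_that("feature extraction matches a frozen golden set on a fixture sentence", {
  toks <- tokenize("male, elderly")
  expect_setequal(
    names(featurize(toks, 1)),
    c("w=male", "shape=x", "p1=m", "s1=e", "p2=ma", "s2=le", "p3=mal",
      "s3=ale", "w-2=<s>", "w-1=<s>", "w+1=,", "w+2=elderly", "posq=2",
      "bias"))
  expect_setequal(
    names(featurize(toks, 3)),
    c("w=elderly", "shape=x", "p1=e", "s1=y", "p2=el", "s2=ly", "p3=eld",
      "s3=rly", "w-2=male", "w-1=,", "w+1=</s>", "w+2=</s>", "posq=4",
      "bias"))
})
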