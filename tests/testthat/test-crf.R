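test_that("uniform (all-zero) model gives log-likelihood -n*log(L)", {
  m <- segmenter_model(labels = c("O", "B-AGE", "I-AGE"),
                       features = c("bias", "w=a", "w=b"))
  toks <- tokenize("a b a b a")
  ll <- crf_log_likelihood(m, toks, rep("O", 5))
  expect_equal(ll, -5 * log(3), tolerance = 1e-12)
})

test_that("forward logZ equals brute-force path enumeration (n<=4, L=3)", {
  for (seed in 1:5) {
    m <- random_crf(seed = seed)
    for (text in c("a", "a b", "b c a", "a b c a")) {
      p <- crf_parts(m, text)
      fwd <- zebracase:::crf_forward(p$E, m$trans, m$start, m$stop)
      scores <- enumerate_scores(p$E, m$trans, m$start, m$stop)
      mx <- max(scores)
      expect_equal(fwd$logZ, mx + log(sum(exp(scores - mx))), tolerance = 1e-8)
    }
  }
})

test_that("log-likelihood is never positive and errors on non-finite weights", {
  m <- random_crf(seed = 3)
  toks <- tokenize("a b c")
  for (y in list(c("O", "O", "O"), c("B-AGE", "I-AGE", "O"))) {
    expect_lte(crf_log_likelihood(m, toks, y), 0)
  }
  m$W[1, 1] <- NaN
  expect_error(crf_log_likelihood(m, toks, c("O", "O", "O")), "finite")
  expect_error(crf_log_likelihood(random_crf(), toks, c("O", "O", "BAD")),
               "label")
})

test_that("analytic gradient matches central finite differences", {
  eps <- 1e-6
  for (seed in 1:3) {
    m <- random_crf(seed = seed)
    p <- crf_parts(m, "a b c a")
    y <- c(1L, 2L, 3L, 1L)
    g <- zebracase:::crf_gradient(m, p$X, y)
    ll_of <- function(model) {
      E <- zebracase:::crf_emissions(model, p$X)
      zebracase:::crf_path_score(E, model$trans, model$start, model$stop, y) -
        zebracase:::crf_forward(E, model$trans, model$start, model$stop)$logZ
    }
    check <- function(get, set, analytic) {
      m2a <- set(m, get(m) + eps); m2b <- set(m, get(m) - eps)
      fd <- (ll_of(m2a) - ll_of(m2b)) / (2 * eps)
      expect_equal(unname(analytic), unname(fd), tolerance = 1e-5)
    }
    # a used emission weight, a transition, start and stop entries
    fid <- which(m$features == "w=b")
    check(function(mm) mm$W[fid, 2],
          function(mm, v) { mm$W[fid, 2] <- v; mm }, g$W[fid, 2])
    check(function(mm) mm$trans[2, 3],
          function(mm, v) { mm$trans[2, 3] <- v; mm }, g$trans[2, 3])
    check(function(mm) mm$start[1],
          function(mm, v) { mm$start[1] <- v; mm }, g$start[1])
    check(function(mm) mm$stop[3],
          function(mm, v) { mm$stop[3] <- v; mm }, g$stop[3])
  }
})

test_that("Viterbi equals brute-force argmax and beats random paths", {
  set.seed(9)
  for (seed in 1:5) {
    m <- random_crf(seed = seed + 10)
    for (text in c("a", "b a", "c b a", "a c b a")) {
      p <- crf_parts(m, text)
      path <- zebracase:::viterbi_path(p$E, m$trans, m$start, m$stop)
      vit_score <- zebracase:::crf_path_score(p$E, m$trans, m$start, m$stop, path)
      scores <- enumerate_scores(p$E, m$trans, m$start, m$stop)
      expect_equal(vit_score, max(scores), tolerance = 1e-10)
      n <- nrow(p$E)
      for (r in 1:200) {
        y <- sample.int(3, n, replace = TRUE)
        expect_gte(vit_score + 1e-10,
                   zebracase:::crf_path_score(p$E, m$trans, m$start, m$stop, y))
      }
    }
  }
})

test_that("decoding prefers the emission-favoured label and is shift-invariant", {
  m <- random_crf(seed = 2, sd = 0)
  fid <- which(m$features == "w=a")
  m$W[fid, which(m$labels == "B-AGE")] <- 5
  expect_equal(viterbi_decode(m, tokenize("a")), "B-AGE")
  expect_equal(viterbi_decode(m, data.frame(text = character(0),
                                            start = integer(0),
                                            end = integer(0))), character(0))
  # adding a constant to all emissions at one position leaves the path alone
  m2 <- random_crf(seed = 6)
  p <- crf_parts(m2, "a b c")
  path1 <- zebracase:::viterbi_path(p$E, m2$trans, m2$start, m2$stop)
  E2 <- p$E; E2[2, ] <- E2[2, ] + 7.3
  path2 <- zebracase:::viterbi_path(E2, m2$trans, m2$start, m2$stop)
  expect_identical(path1, path2)
})

test_that("Viterbi ties break towards the lowest label index", {
  m <- segmenter_model(labels = c("O", "B-AGE", "I-AGE"),
                       features = c("bias"))
  # perfectly tied scores everywhere -> all-O (label 1) path
  expect_equal(viterbi_decode(m, tokenize("a b c")), rep("O", 3))
})

test_that("model serialisation round-trips weights exactly", {
  m <- random_crf(seed = 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_segmenter(m, path)
  m2 <- read_segmenter(path)
  expect_identical(m2$labels, m$labels)
  expect_identical(m2$features, m$features)
  expect_equal(m2$W, m$W, tolerance = 0)
  expect_equal(m2$trans, m$trans, tolerance = 0)
  expect_equal(unname(m2$start), unname(m$start), tolerance = 0)
  expect_equal(unname(m2$stop), unname(m$stop), tolerance = 0)
  toks <- tokenize("a b c a b")
  expect_identical(viterbi_decode(m2, toks), viterbi_decode(m, toks))
})
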