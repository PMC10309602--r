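tab <- reference_table()

test_that("measurement mapping reproduces the worked survey conversions", {
  expect_equal(map_measurement("platelet_count", 87, "10^9/L", "male", tab),
               "thrombocytopenia")
  expect_equal(map_measurement("haemoglobin", 154, "g/L", "male", tab),
               "normal haemoglobin level")
  expect_equal(map_measurement("spleen_size", 0.85, "multiples of normal",
                               "male", tab), "no splenomegaly")
  # boundary values sit on the normal (closed-interval) side
  expect_equal(map_measurement("platelet_count", 150, "10^9/L", "female", tab),
               "no thrombocytopenia")
  expect_equal(map_measurement("platelet_count", 450, "10^9/L", "female", tab),
               "no thrombocytopenia")
  # sex-specific ranges differ
  expect_equal(map_measurement("haemoglobin", 125, "g/L", "male", tab), "anaemia")
  expect_equal(map_measurement("haemoglobin", 125, "g/L", "female", tab),
               "normal haemoglobin level")
  expect_error(map_measurement("platelet_count", 87, "10^3/uL", "male", tab),
               "unit mismatch")
  expect_error(map_measurement("unknown_lab", 1, "x", "male", tab), "unknown")
  expect_error(map_measurement("haemoglobin", Inf, "g/L", "male", tab), "finite")
})

test_that("term assignment is monotone across thresholds", {
  for (v in seq(10, 600, by = 10)) {
    term <- map_measurement("platelet_count", v, "10^9/L", "male", tab)
    expected <- if (v < 150) "thrombocytopenia" else if (v > 450)
      "thrombocytosis" else "no thrombocytopenia"
    expect_equal(term, expected)
  }
})

test_that("age maps to the year phrase plus one band term", {
  expect_setequal(map_age(66), c("66-year-old", "elderly"))
  expect_setequal(map_age(43), c("43-year-old", "adult"))
  expect_setequal(map_age(0), c("0-year-old", "infant"))
  expect_setequal(map_age(12), c("12-year-old", "adolescent"))
  expect_setequal(map_age(65), c("65-year-old", "elderly"))
  expect_error(map_age(-1), ">= 0")
})

test_that("CKD severity terms follow stage, with stage overriding eGFR", {
  expect_equal(map_ckd(stage = 4), "severe chronic kidney disease")
  expect_equal(map_ckd(stage = 3), "moderate chronic kidney disease")
  expect_equal(map_ckd(stage = 5), "end-stage renal disease")
  expect_true(is.na(map_ckd(stage = 1)))
  expect_equal(map_ckd(egfr = 20), "severe chronic kidney disease")
  expect_equal(map_ckd(egfr = 45), "moderate chronic kidney disease")
  expect_true(is.na(map_ckd()))
  # stage 4 with a stage-2-looking eGFR: the recorded stage wins
  expect_equal(map_ckd(stage = 4, egfr = 76.02), "severe chronic kidney disease")
})

test_that("build_query reproduces the worked example queries", {
  pts <- example_patients()
  qG <- build_query(pts$G, tab)
  expect_true(all(c("43-year-old", "male", "adult", "thrombocytopenia",
                    "normal haemoglobin level", "no splenomegaly",
                    "lipid profile-low ldl", "jaw-big osteolytic lesion",
                    "elevated ast", "no hepatosplenomegaly") %in% qG$terms))
  expect_equal(qG$terms[1:3], c("43-year-old", "male", "adult"))
  qF <- build_query(pts$F, tab)
  expect_true(all(c("66-year-old", "male", "elderly",
                    "severe chronic kidney disease", "sign angiokeratomas",
                    "heart failure") %in% qF$terms))
  expect_false(any(duplicated(qF$terms)))
  # idempotence
  expect_identical(build_query(pts$G, tab), build_query(pts$G, tab))
})

test_that("demographics-only records give demographics-only queries", {
  rec <- survey_record("p0", age = 30, sex = "female")
  q <- build_query(rec, tab)
  expect_setequal(q$terms, c("30-year-old", "female", "adult"))
})

test_that("every measurement contributes exactly one term", {
  set.seed(17)
  for (r in 1:25) {
    pop <- generate_population(gaucher_like_profile(), 1, seed = r)
    rec <- pop[[1]]
    q <- build_query(rec, tab)
    # terms = 3 demographics + 1 per measurement + symptoms + mutation
    n_meas <- length(rec$measurements)
    n_mut <- as.integer(!is.na(rec$mutation))
    # deduplication can only shrink; verbatim symptoms are distinct already
    expect_lte(length(q$terms), 3 + n_meas + length(rec$symptoms) + n_mut)
    expect_gte(length(q$terms), 3 + n_meas)
  }
})

test_that("routing partitions the query terms over fields", {
  corpus <- generate_corpus(gaucher_like_profile(), 24, seed = 42)
  model <- train_segmenter(corpus[1:20], corpus[21:24], epochs = 10, seed = 3)
  pop <- generate_population(gaucher_like_profile(), 5, seed = 9)
  for (rec in pop) {
    q <- segment_query(build_query(rec, tab), model)
    routed <- unlist(q$fields, use.names = FALSE)
    expect_setequal(routed, q$terms)
    expect_equal(length(routed), length(q$terms))
    expect_true(all(names(q$fields) %in% segment_categories()))
  }
  empty <- structure(list(patient_id = "e", terms = character(0),
                          fields = list()), class = "patient_query")
  expect_length(segment_query(empty, model)$fields, 0)
})
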