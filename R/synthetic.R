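#' Synthetic disease profile
#'
#' Parameters of the generator that emulates a rare-disease population and
#' its case-report literature: a symptom vocabulary with per-symptom
#' population frequencies, a demographic model, genetics and treatment
#' vocabulary, and a heterogeneity mode. "diffuse" populations share a
#' compact core of frequent symptoms (queries resemble each other, so
#' retrieval concentrates on few articles); "clustered" populations split
#' into genotype blocks with mostly disjoint symptom sets.
#'
#' @param name profile name.
#' @param symptoms named numeric vector: symptom -> population frequency in
#'   (0, 1].
#' @param sex_ratio probability that a patient is male; an X-linked-like
#'   profile sets this high to skew severe presentations to males.
#' @param age_mean,age_sd age distribution (years).
#' @param mutations character vector of mutation string templates.
#' @param ethnicities character vector (may be empty).
#' @param medications character vector of treatment phrases.
#' @param negative_findings character vector of negated/normal phrases.
#' @param family_history character vector of family-history phrases.
#' @param heterogeneity "diffuse" or "clustered".
#' @param n_blocks number of genotype blocks when clustered.
#' @param neg_rate Poisson rate for the number of negated/normal findings
#'   mentioned per case report (default 1.2).
#' @param measurements character vector of measurement names drawn for the
#'   survey records (must exist in the reference table).
#' @param treat_base,treat_slope logistic intercept/slope linking treatment
#'   probability to symptom count (treatment tracks severity).
#' @return List with class \code{"disease_profile"}.
#' @export
disease_profile <- function(name, symptoms, sex_ratio = 0.5,
                            age_mean = 40, age_sd = 18,
                            mutations = character(0),
                            ethnicities = character(0),
                            medications = character(0),
                            negative_findings = character(0),
                            family_history = character(0),
                            heterogeneity = c("diffuse", "clustered"),
                            n_blocks = 2L, neg_rate = 1.2,
                            measurements = character(0),
                            treat_base = -1.5, treat_slope = 0.5) {
  stopifnot(all(symptoms > 0), all(symptoms <= 1),
            sex_ratio >= 0, sex_ratio <= 1, neg_rate >= 0)
  heterogeneity <- match.arg(heterogeneity)
  structure(list(name = name, symptoms = symptoms, sex_ratio = sex_ratio,
                 age_mean = age_mean, age_sd = age_sd, mutations = mutations,
                 ethnicities = ethnicities, medications = medications,
                 negative_findings = negative_findings,
                 family_history = family_history,
                 heterogeneity = heterogeneity, n_blocks = as.integer(n_blocks),
                 neg_rate = neg_rate, measurements = measurements,
                 treat_base = treat_base, treat_slope = treat_slope),
            class = "disease_profile")
}

#' Bundled "fabry-like" profile
#'
#' X-linked-like (male-skewed), diffuse phenotype: a compact core of
#' frequent symptoms shared across the population, which drives high
#' article reuse in the retrieval network.
#'
#' @return A \code{disease_profile}.
#' @export
fabry_like_profile <- function() {
  disease_profile(
    name = "fabry-like",
    symptoms = c(
      "sign angiokeratomas" = 0.97, "acroparesthesia" = 0.96,
      "sign lv hypertrophy" = 0.95, "proteinuria" = 0.94,
      "cornea verticillata" = 0.93, "hypohidrosis" = 0.92,
      "hearing loss" = 0.04, "sign stroke" = 0.04,
      "symptoms vertigo" = 0.03, "sign arrhythmia" = 0.03,
      "heart failure" = 0.03, "haematuria" = 0.02,
      "sign haemorrhoids" = 0.02, "tumours" = 0.02,
      "lymphoedema" = 0.02, "priapism" = 0.02
    ),
    sex_ratio = 0.7, age_mean = 42, age_sd = 6,
    mutations = "missense mutation in the GLA gene",
    ethnicities = c("Caucasian", "Hispanic", "Japanese"),
    medications = c("enzyme replacement therapy", "agalsidase beta",
                    "chaperone therapy", "ACE inhibitors"),
    negative_findings = c("no hepatomegaly", "no splenomegaly",
                          "normal haemoglobin level", "no thrombocytopenia",
                          "normal blood count", "no history of diabetes",
                          "no proteinuria"),
    family_history = c("history of early strokes in the family",
                       "a brother with the same disease",
                       "family history of renal failure"),
    heterogeneity = "diffuse",
    measurements = c("egfr", "lvmi"),
    treat_base = -2, treat_slope = 0.45
  )
}

#' Bundled "gaucher-like" profile
#'
#' Sex-uninformative, genotype-clustered phenotype: two blocks with mostly
#' disjoint symptom sets and a wider, lower-frequency vocabulary, which
#' spreads retrieval over more articles.
#'
#' @return A \code{disease_profile}.
#' @export
gaucher_like_profile <- function() {
  disease_profile(
    name = "gaucher-like",
    symptoms = c(
      "splenomegaly" = 0.42, "hepatomegaly" = 0.34, "bone pain" = 0.30,
      "thrombocytopenia" = 0.30, "anaemia" = 0.26, "fatigue" = 0.24,
      "bone crisis" = 0.20, "avascular necrosis" = 0.17,
      "pathological fracture" = 0.15, "growth retardation" = 0.14,
      "elevated ast" = 0.14, "lipid profile-low ldl" = 0.12,
      "jaw-big osteolytic lesion" = 0.10, "pulmonary involvement" = 0.10,
      "gaucheroma" = 0.09, "pingueculae" = 0.09,
      "myoclonic epilepsy" = 0.09, "oculomotor apraxia" = 0.07,
      "parkinsonism" = 0.07, "polyneuropathy" = 0.07
    ),
    sex_ratio = 0.5, age_mean = 38, age_sd = 22,
    mutations = c("N370S mutation in the GBA gene", "L444P GBA mutation",
                  "rare mutation in the GBA gene"),
    ethnicities = c("Ashkenazi Jewish", "Caucasian", "Egyptian"),
    medications = c("enzyme replacement therapy", "imiglucerase",
                    "substrate reduction therapy", "splenectomy"),
    negative_findings = c("no hepatosplenomegaly", "no splenomegaly",
                          "normal haemoglobin level", "no thrombocytopenia",
                          "no neurological involvement", "no bone disease",
                          "no hepatomegaly"),
    family_history = c("an affected sibling", "consanguineous parents",
                       "family history of splenectomy"),
    heterogeneity = "clustered", n_blocks = 2L, neg_rate = 3,
    measurements = c("haemoglobin", "platelet_count", "liver_size",
                     "spleen_size"),
    treat_base = -1.2, treat_slope = 0.5
  )
}

# Latent patient shared by the abstract and survey generators.
sample_patient <- function(profile) {
  sex <- if (stats::runif(1) < profile$sex_ratio) "male" else "female"
  age <- max(1L, min(90L, as.integer(round(stats::rnorm(1, profile$age_mean,
                                                        profile$age_sd)))))
  freqs <- profile$symptoms
  if (profile$heterogeneity == "clustered") {
    block <- sample.int(profile$n_blocks, 1)
    idx <- (seq_along(freqs) - 1) %% profile$n_blocks + 1
    boost <- ifelse(idx == block, 1.4, 0.2)
    freqs <- pmin(freqs * boost, 1)  # freqs first so names survive pmin
  } else {
    block <- 1L
  }
  present <- names(freqs)[stats::runif(length(freqs)) < freqs]
  if (length(present) == 0) present <- names(which.max(freqs))
  nsym <- length(present)
  list(
    sex = sex, age = age, block = block, symptoms = present,
    mutation = if (length(profile$mutations) > 0 && stats::runif(1) < 0.6)
      sample(profile$mutations, 1) else NA_character_,
    ethnicity = if (length(profile$ethnicities) > 0 && stats::runif(1) < 0.3)
      sample(profile$ethnicities, 1) else NA_character_,
    medication = if (length(profile$medications) > 0 && stats::runif(1) < 0.6)
      sample(profile$medications, 1) else NA_character_,
    negatives = if (length(profile$negative_findings) > 0)
      sample(profile$negative_findings,
             min(length(profile$negative_findings),
                 stats::rpois(1, profile$neg_rate)))
      else character(0),
    family = if (length(profile$family_history) > 0 && stats::runif(1) < 0.25)
      sample(profile$family_history, 1) else NA_character_,
    treated = stats::runif(1) < stats::plogis(profile$treat_base +
                                                profile$treat_slope * nsym)
  )
}

# Incremental text builder that records labelled spans at their offsets.
span_writer <- function() {
  env <- new.env(parent = emptyenv())
  env$text <- ""
  env$segments <- list()
  env$add <- function(txt) env$text <- paste0(env$text, txt)
  env$slot <- function(category, txt) {
    start <- nchar(env$text)
    env$text <- paste0(env$text, txt)
    env$segments[[length(env$segments) + 1L]] <-
      segment(category, start, start + nchar(txt), txt)
  }
  env
}

#' Generate one annotated case-report abstract
#'
#' Samples a latent patient from the profile and renders it through sentence
#' templates, recording a gold span for every rendered slot. All eight
#' categories are reachable: sex, age and diagnosis always appear; symptoms
#' always appear; ethnicity, genetics, medications, negative findings and
#' family history appear with the profile's inclusion probabilities.
#'
#' @param profile a \code{disease_profile}.
#' @param doc_id document identifier.
#' @param pub_year publication year (default drawn 1970-2022).
#' @return A \code{labeled_abstract} with gold segments.
#' @export
generate_abstract <- function(profile, doc_id = "doc1", pub_year = NULL) {
  pt <- sample_patient(profile)
  if (is.null(pub_year)) pub_year <- sample(1970:2022, 1)
  w <- span_writer()
  w$add("We report the case of a ")
  w$slot("AGE", sprintf("%d-year-old", pt$age))
  w$add(" ")
  if (!is.na(pt$ethnicity)) {
    w$slot("ETHNICITY", pt$ethnicity)
    w$add(" ")
  }
  w$slot("SEX", pt$sex)
  w$add(" patient diagnosed with ")
  w$slot("DIAGNOSIS_SIGNS_SYMPTOMS", paste(profile$name, "disease"))
  w$add(". ")
  w$add(ifelse(pt$sex == "male", "He", "She"))
  w$add(" presented with ")
  for (i in seq_along(pt$symptoms)) {
    if (i > 1) w$add(ifelse(i == length(pt$symptoms), " and ", ", "))
    w$slot("DIAGNOSIS_SIGNS_SYMPTOMS", pt$symptoms[i])
  }
  w$add(". ")
  if (!is.na(pt$mutation)) {
    w$add("Genetic testing revealed a ")
    w$slot("GENETICS", pt$mutation)
    w$add(". ")
  }
  if (length(pt$negatives) > 0) {
    w$add("Examination showed ")
    for (i in seq_along(pt$negatives)) {
      if (i > 1) w$add(ifelse(i == length(pt$negatives), " and ", ", "))
      w$slot("NEGATIVE_FINDINGS", pt$negatives[i])
    }
    w$add(". ")
  }
  if (!is.na(pt$medication)) {
    w$add("The patient was started on ")
    w$slot("MEDICATIONS_INTERVENTIONS", pt$medication)
    w$add(". ")
  }
  if (!is.na(pt$family)) {
    w$add("There was ")
    w$slot("FAMILY_HISTORY", pt$family)
    w$add(". ")
  }
  w$add("The clinical course is discussed.")
  labeled_abstract(doc_id, w$text, disease = profile$name,
                   pub_year = pub_year, segments = w$segments)
}

#' Generate an annotated corpus
#'
#' @param profile a \code{disease_profile}.
#' @param n number of abstracts.
#' @param seed integer seed; generation is reproducible.
#' @return List of \code{labeled_abstract}s with doc_ids
#'   "<profile>-<i>".
#' @export
generate_corpus <- function(profile, n, seed = 1L) {
  stopifnot(n > 0)
  with_seed(seed, lapply(seq_len(n), function(i) {
    generate_abstract(profile, doc_id = sprintf("%s-%03d", profile$name, i))
  }))
}

#' Generate a synthetic survey population
#'
#' Records mirror the structure of an outcomes-survey table: age, sex,
#' numeric measurements drawn from sex-specific normal/abnormal mixtures
#' spanning the reference thresholds, free-text symptoms drawn from the
#' profile frequencies, and a treated flag whose probability increases with
#' symptom count (severity proxy).
#'
#' @param profile a \code{disease_profile}.
#' @param n number of patients.
#' @param seed integer seed.
#' @param p_abnormal probability that a measurement falls outside its
#'   reference range (default 0.4).
#' @return List of \code{survey_record}s.
#' @export
generate_population <- function(profile, n, seed = 1L, p_abnormal = 0.4) {
  stopifnot(n > 0)
  tab <- reference_table()
  with_seed(seed, lapply(seq_len(n), function(i) {
    pt <- sample_patient(profile)
    meas <- list()
    ckd <- NA_integer_
    for (m in profile$measurements) {
      if (m == "egfr") {
        v <- if (stats::runif(1) < p_abnormal)
          stats::runif(1, 10, 55) else stats::runif(1, 65, 110)
        meas$egfr <- list(value = round(v, 2), units = "mL/min/1.73m^2")
        if (stats::runif(1) < 0.7) {
          ckd <- if (v >= 90) 1L else if (v >= 60) 2L else
            if (v >= 30) 3L else if (v >= 15) 4L else 5L
        }
        next
      }
      row <- tab[tab$measurement == m & (tab$sex == pt$sex | tab$sex == "any"), ][1, ]
      span <- row$high - row$low
      v <- if (stats::runif(1) < p_abnormal) {
        if (stats::runif(1) < 0.7) row$low - stats::runif(1, 0.05, 0.6) * max(span, 1)
        else row$high + stats::runif(1, 0.05, 0.6) * max(span, 1)
      } else stats::runif(1, row$low, row$high)
      meas[[m]] <- list(value = round(max(v, 0.01), 2), units = row$units)
    }
    survey_record(sprintf("%s-pt-%04d", profile$name, i),
                  age = pt$age, sex = pt$sex, measurements = meas,
                  symptoms = pt$symptoms, mutation = pt$mutation,
                  ckd_stage = ckd, treated = pt$treated,
                  disease = profile$name)
  }))
}

#' Planted two-block retrieval pattern
#'
#' Synthetic retrieval table with known community structure, used to check
#' that community detection recovers a planted partition: patients belong to
#' one of two blocks, each block owns a pool of articles, and every top-3
#' retrieval slot draws from the patient's own pool with probability
#' within/(within + cross) (defaults 0.9 and 0.02), else from the other
#' block's pool. Blocks are kept dense (few articles, many patients) so the
#' partition is identifiable from the graph.
#'
#' @param n_per_block patients per block (default 60).
#' @param arts_per_block articles per block pool (default 4).
#' @param within,cross relative retrieval rates for own- and other-block
#'   articles.
#' @param seed integer seed.
#' @return List: \code{retrievals} (named list patient -> doc_ids) and
#'   \code{blocks} (named integer vector of planted labels per patient).
#' @export
planted_block_retrievals <- function(n_per_block = 60L, arts_per_block = 4L,
                                     within = 0.9, cross = 0.02, seed = 1L) {
  blocks <- rep(1:2, each = n_per_block)
  names(blocks) <- paste0("p", seq_along(blocks))
  pools <- split(paste0("art", seq_len(2 * arts_per_block)),
                 rep(1:2, each = arts_per_block))
  p_own <- within / (within + cross)
  retrievals <- with_seed(seed, stats::setNames(
    lapply(seq_along(blocks), function(i) {
      picked <- character(0)
      for (k in 1:3) {
        pool <- if (stats::runif(1) < p_own) pools[[blocks[i]]]
                else pools[[3 - blocks[i]]]
        picked <- union(picked, sample(pool, 1))
      }
      picked
    }), names(blocks)))
  list(retrievals = retrievals, blocks = blocks)
}

#' Simulate expert ratings for retrieval results
#'
#' Two simulated experts grade each (patient, rank) unit: a shared latent
#' relevance is drawn from \code{quality} (a probability vector over grades
#' 1-5, configurable to mimic observed grade distributions) and each expert
#' reports the latent grade plus independent integer noise, clamped to 1-5.
#' Alternatively \code{max_grades} imposes the exact maximum grade per unit
#' (calibration fixtures): expert 1 reports it, expert 2 at most it.
#'
#' @param retrievals named list patient_id -> retrieved doc_ids (<= 3).
#' @param quality probability vector over grades 1..5.
#' @param expert_noise standard deviation of expert noise (0 = identical
#'   experts).
#' @param max_grades optional integer vector, one per (patient, rank) unit in
#'   row order, forcing the per-unit maximum grade.
#' @param seed integer seed.
#' @return data.frame: patient_id, rank, expert_id, grade.
#' @export
generate_ratings <- function(retrievals, quality = c(.05, .1, .25, .35, .25),
                             expert_noise = 0.7, max_grades = NULL,
                             seed = 1L) {
  if (length(retrievals) == 0) stop("no retrievals", call. = FALSE)
  units <- do.call(rbind, lapply(names(retrievals), function(p) {
    k <- length(retrievals[[p]])
    if (k == 0) return(NULL)
    data.frame(patient_id = p, rank = seq_len(k))
  }))
  n <- nrow(units)
  with_seed(seed, {
    if (!is.null(max_grades)) {
      stopifnot(length(max_grades) == n, all(max_grades %in% 1:5))
      g1 <- as.integer(max_grades)
      g2 <- pmax(1L, g1 - sample(0:2, n, replace = TRUE))
    } else {
      latent <- sample.int(5, n, replace = TRUE, prob = quality)
      jitter <- function() as.integer(pmin(5, pmax(1, round(
        latent + stats::rnorm(n, 0, expert_noise)))))
      g1 <- jitter(); g2 <- jitter()
    }
    rbind(
      data.frame(units, expert_id = "expert1", grade = g1),
      data.frame(units, expert_id = "expert2", grade = g2)
    )
  })
}
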