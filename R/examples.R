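#' Bundled example survey records
#'
#' Two worked-example patients used throughout the documentation: "F", a
#' 66-year-old male Fabry patient with CKD stage 4, an eGFR of 76.02 and an
#' LVMI of 109.51, and "G", a 43-year-old male Gaucher patient with
#' haemoglobin 154 g/L, platelets 87 x 10^9/L, liver 4.60 and spleen 0.85
#' multiples of normal. Their symptom lists are survey-style free-text terms
#' passed through to queries verbatim.
#'
#' @return Named list of two \code{survey_record}s, \code{F} and \code{G}.
#' @export
#' @examples
#' build_query(example_patients()$G)$terms
example_patients <- function() {
  list(
    F = survey_record(
      "F", age = 66, sex = "male",
      measurements = list(
        egfr = list(value = 76.02, units = "mL/min/1.73m^2"),
        lvmi = list(value = 109.51, units = "g/m^2.7")
      ),
      symptoms = c("sign angiokeratomas", "sign haemorrhoids",
                   "sign lv hypertrophy", "symptoms vertigo",
                   "sign arrhythmia", "haematuria", "sign stroke",
                   "tumours", "heart failure"),
      ckd_stage = 4L, treated = TRUE, disease = "fabry-like"
    ),
    G = survey_record(
      "G", age = 43, sex = "male",
      measurements = list(
        haemoglobin = list(value = 154, units = "g/L"),
        platelet_count = list(value = 87, units = "10^9/L"),
        liver_size = list(value = 4.60, units = "multiples of normal"),
        spleen_size = list(value = 0.85, units = "multiples of normal")
      ),
      symptoms = c("lipid profile-low ldl", "jaw-big osteolytic lesion",
                   "elevated ast", "no hepatosplenomegaly"),
      treated = FALSE, disease = "gaucher-like"
    )
  )
}
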