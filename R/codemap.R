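#' Default encounter code-to-category mapping
#'
#' A synthetic service-code map in the style of provincial billing fee
#' codes.  Real extracts come with jurisdiction-specific code lists;
#' this default exists so the bundled generator and the examples run
#' out of the box, and it documents the category vocabulary the rest of
#' the pipeline expects.  Unmapped codes fall into category `"other"`.
#'
#' @return tibble with columns `code`, `category`.
#' @export
#' @examples
#' default_codemap()
default_codemap <- function() {
  tibble::tribble(
    ~code,   ~category,
    "L179",  "gfobt",
    "L181",  "gfobt",
    "Z555",  "lower_gi_endoscopy",   # colonoscopy
    "Z536",  "lower_gi_endoscopy",   # sigmoidoscopy
    "A135",  "consultation",
    "A035",  "consultation",
    "A553",  "gi_symptoms",
    "A554",  "gi_symptoms",
    "A007",  "family_physician",
    "X231",  "imaging_ct",
    "X195",  "imaging_us",
    "X112",  "imaging_contrast",
    "L001",  "lab_general",
    "H101",  "hospital_admission")
}

#' Category groups used by the pathway classifier
#'
#' Names which categories count as screening tests, consultations,
#' lower GI endoscopy, imaging, and procedures (the encounters eligible
#' for referring-physician linkage).
#'
#' @return named list of character vectors.
#' @export
category_groups <- function() {
  list(
    screening    = c("gfobt", "lower_gi_endoscopy"),
    consultation = c("consultation", "family_physician"),
    scope        = "lower_gi_endoscopy",
    imaging      = c("imaging_ct", "imaging_us", "imaging_contrast"),
    procedure    = c("lower_gi_endoscopy", "imaging_ct", "imaging_us",
                     "imaging_contrast"),
    # categories whose pre-diagnosis frequency is elevated by the
    # simulated cancer-related surge
    cancer_related = c("gi_symptoms", "lower_gi_endoscopy", "consultation",
                       "imaging_ct", "imaging_us"))
}
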