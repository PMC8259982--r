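#' Validation-cohort deletion table
#'
#' The five 22q13 terminal deletions of the validation individuals
#' (hg19 breakpoints as printed; lengths follow the half-open convention,
#' e.g. PMS 1: 51244566 - 42740931 = 8503635 bp).
#'
#' @param size_cutoffs Passed to [assign_size_class()].
#' @return Deletion table with `size_class` assigned.
#' @export
pms_deletions <- function(size_cutoffs = c(5e6, 8e6)) {
  d <- deletion_table(
    patient_id = paste0("PMS", 1:5),
    chrom = "chr22",
    start = c(42740931, 42816484, 43800990, 47731071, 51123491),
    end   = c(51244566, 51244566, 51244566, 51193680, 51224252),
    terminal = TRUE)
  assign_size_class(d, size_cutoffs)
}

#' Candidate-gene panel for the 22q13 validation locus
#'
#' The nine blood-expressed candidate genes carry their printed hg19
#' coordinates. With `include_blood_silent = TRUE`, the three candidates
#' with no blood expression (FBLN1, SHANK3, SCO2) are added with
#' approximate hg19 spans (their printed coordinates are not tabulated);
#' they are excluded from qPCR by their `expressed_in_blood` flag.
#' Haploinsufficiency magnitudes are representative values: the only
#' sourced constraint is that ADSL and EP300 are the genes at or below
#' 10%. Phenotype terms are left empty here; see
#' [pms_patient_phenotypes()] for the patient side.
#'
#' @param include_blood_silent Add FBLN1/SHANK3/SCO2? Default `TRUE`.
#' @return Gene annotation data frame.
#' @export
pms_gene_panel <- function(include_blood_silent = TRUE) {
  g <- data.frame(
    symbol = c("ADSL", "EP300", "TNFRSF13C", "NAGA", "A4GALT", "TRMU",
               "TUBGCP6", "SBF1", "ARSA"),
    chrom = "chr22",
    start = c(40742504, 41488614, 42321036, 42454338, 43088127, 46731298,
              50656118, 50883431, 51061182),
    end   = c(40762575, 41576081, 42322821, 42466846, 43116876, 46753237,
              50683400, 50913464, 51066601),
    hi_pct = c(9.3, 1.6, 70, 50, 55, 60, 40, 30, 45),
    phenotype_terms = "",
    expressed_in_blood = TRUE,
    stringsAsFactors = FALSE)
  if (include_blood_silent) {
    g <- rbind(g, data.frame(
      symbol = c("FBLN1", "SHANK3", "SCO2"),
      chrom = "chr22",
      start = c(45898712, 51113070, 50961997),
      end   = c(45997440, 51171640, 50964033),
      hi_pct = c(15, 12, 65),
      phenotype_terms = "",
      expressed_in_blood = FALSE,
      stringsAsFactors = FALSE))
  }
  validate_annotation(g)
}

#' Clinical feature sets of the five validation individuals
#'
#' Per-patient phenotype term sets encoding the published summary of
#' signs and symptoms (developmental delay, language delay, seizures,
#' hypotonia, sleep issues, gastrointestinal issues, cranial dysmorphic
#' traits, behavioural issues, kidney reflux, skeletal abnormalities,
#' hyperconvex fingernails).
#'
#' @return Named list of character term vectors, one per patient.
#' @export
pms_patient_phenotypes <- function() {
  list(
    PMS1 = c("dev_delay", "language_delay", "seizures", "hypotonia",
             "sleep_issues", "gi_issues", "head_shape",
             "periorbital_puffiness", "eye_abnormalities",
             "ear_abnormalities", "broad_nasal_tip", "behavioral_issues",
             "kidney_reflux", "skeletal_abnormalities",
             "hyperconvex_fingernails"),
    PMS2 = c("dev_delay", "language_delay", "seizures", "hypotonia",
             "sleep_issues", "gi_issues", "eye_abnormalities",
             "ear_abnormalities", "broad_nasal_tip", "behavioral_issues",
             "skeletal_abnormalities"),
    PMS3 = c("dev_delay", "language_delay", "hypotonia", "head_shape",
             "periorbital_puffiness", "eye_abnormalities",
             "ear_abnormalities", "broad_nasal_tip", "behavioral_issues",
             "kidney_reflux", "hyperconvex_fingernails"),
    PMS4 = c("dev_delay", "language_delay", "behavioral_issues"),
    PMS5 = c("dev_delay", "language_delay", "seizures", "hypotonia",
             "sleep_issues", "gi_issues", "head_shape",
             "ear_abnormalities", "broad_nasal_tip", "behavioral_issues"))
}
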