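#' kidneyCES: clinical exome triage for pediatric kidney disease
#'
#' Implements a diagnostic workflow for pediatric nephropathies analysed by
#' clinical exome sequencing (CES): variant filtering, panel-restricted
#' prioritisation with "kidneyome" escalation, ACMG classification, trio
#' segregation, report-outcome classification and cohort diagnostic-yield
#' statistics, together with a synthetic cohort generator carrying a
#' ground-truth ledger.
#'
#' @keywords internal
"_PACKAGE"

## ---- controlled vocabularies -----------------------------------------------

#' @rdname vocab
#' @name vocab
#' @title Controlled vocabularies used across the pipeline
#' @description Character vectors enumerating the legal values of the
#'   categorical fields carried on variant calls, patients, panels and
#'   outcomes. Exported so callers can validate their own tables.
#' @export
CONSEQUENCES <- c("missense", "nonsense", "frameshift", "splicing",
                  "synonymous", "intronic", "inframe_indel",
                  "cnv_del", "cnv_dup", "other")

#' @rdname vocab
#' @export
GENOTYPES <- c("het", "hom_alt", "hemizygous", "hom_ref", "missing")

#' @rdname vocab
#' @export
MACRO_CATEGORIES <- c("CAKUT", "ciliopathy", "glomerulopathy",
                      "nephrolithiasis", "tubulopathy", "other")

#' @rdname vocab
#' @export
INHERITANCE_MODES <- c("AD", "AR", "XLD", "XLR", "NA")

#' @rdname vocab
#' @export
ACMG_CLASSES <- c("C1", "C2", "C3", "C3_C4", "C4", "C5")

#' @rdname vocab
#' @export
OUTCOMES <- c("conclusive", "uncertain", "inconclusive")

#' @rdname vocab
#' @export
PHENOTYPE_FITS <- c("full", "partial", "none")

## outcome precedence used when aggregating gene groups to a patient verdict
.OUTCOME_RANK <- c(inconclusive = 1L, uncertain = 2L, conclusive = 3L)

## ---- VariantCall -----------------------------------------------------------

#' Construct a table of variant calls
#'
#' One row per alternate allele per patient. This is the central exchange
#' format of the pipeline: readers produce it, the filter cascade consumes and
#' returns it, and the report classifier annotates it.
#'
#' @param patient_id,chrom,ref,alt,gene character vectors.
#' @param pos 1-based position (VCF convention, fully closed).
#' @param consequence one of [CONSEQUENCES].
#' @param splice_region logical; does the variant fall in a splice region?
#' @param pop_af external population allele frequency in `[0, 1]`; `NA` is
#'   treated downstream as 0 (novel variant).
#' @param vaf variant allele fraction in the patient (`NA` for CNV records).
#' @param depth read depth at the site (`NA` for CNV records).
#' @param genotype one of [GENOTYPES].
#' @return A `data.frame` with class `variant_calls`.
#' @export
variant_calls <- function(patient_id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), gene = character(),
                          consequence = character(),
                          splice_region = logical(),
                          pop_af = numeric(), vaf = numeric(),
                          depth = numeric(), genotype = character()) {
  df <- data.frame(
    patient_id = as.character(patient_id), chrom = as.character(chrom),
    pos = as.integer(pos), ref = as.character(ref), alt = as.character(alt),
    gene = as.character(gene), consequence = as.character(consequence),
    splice_region = as.logical(splice_region), pop_af = as.numeric(pop_af),
    vaf = as.numeric(vaf), depth = as.numeric(depth),
    genotype = as.character(genotype), stringsAsFactors = FALSE
  )
  validate_variant_calls(df)
}

#' Validate a variant-call table
#'
#' Checks the invariants of the call table: legal enum values, positions
#' `>= 1`, fractions in `[0, 1]`, non-negative depth, and uniqueness of
#' `(patient_id, chrom, pos, ref, alt)`.
#'
#' @param df a data.frame shaped like [variant_calls()].
#' @return `df`, invisibly classed as `variant_calls`.
#' @export
validate_variant_calls <- function(df) {
  req <- c("patient_id", "chrom", "pos", "ref", "alt", "gene", "consequence",
           "splice_region", "pop_af", "vaf", "depth", "genotype")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("variant call table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    bad <- setdiff(unique(df$consequence), CONSEQUENCES)
    if (length(bad)) stop("unknown consequence value(s): ",
                          paste(bad, collapse = ", "))
    bad <- setdiff(unique(df$genotype), GENOTYPES)
    if (length(bad)) stop("unknown genotype value(s): ",
                          paste(bad, collapse = ", "))
    if (any(df$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
    if (any(df$depth < 0, na.rm = TRUE)) stop("negative read depth")
    if (any(df$vaf < 0 | df$vaf > 1, na.rm = TRUE))
      stop("vaf outside [0, 1]")
    if (any(df$pop_af < 0 | df$pop_af > 1, na.rm = TRUE))
      stop("pop_af outside [0, 1]")
    key <- paste(df$patient_id, df$chrom, df$pos, df$ref, df$alt)
    if (anyDuplicated(key))
      stop("duplicate (patient, chrom, pos, ref, alt) record(s)")
  }
  class(df) <- unique(c("variant_calls", class(df)))
  df
}

is_cnv <- function(consequence) consequence %in% c("cnv_del", "cnv_dup")

## ---- PatientRecord ---------------------------------------------------------

#' Construct a patient metadata table
#'
#' @param patient_id character ids, unique.
#' @param sex `"F"` or `"M"`.
#' @param age_years non-negative age at recruitment.
#' @param macro_category one of [MACRO_CATEGORIES].
#' @param primary_disease free-text clinical suspicion.
#' @param family_history logical, positive family history for kidney disease.
#' @param ethnicity one of European, African, Asian, LatinAmerican, mixed.
#' @param consanguinity logical.
#' @param phenotype_unclear,phenotype_overlapping clinician-supplied flags
#'   driving escalation to the kidneyome super-panel (see [should_escalate()]).
#' @return A `data.frame` with class `patient_records`.
#' @export
patient_records <- function(patient_id, sex, age_years, macro_category,
                            primary_disease = "", family_history = FALSE,
                            ethnicity = "European", consanguinity = FALSE,
                            phenotype_unclear = FALSE,
                            phenotype_overlapping = FALSE) {
  df <- data.frame(
    patient_id = as.character(patient_id), sex = as.character(sex),
    age_years = as.numeric(age_years),
    macro_category = as.character(macro_category),
    primary_disease = as.character(primary_disease),
    family_history = as.logical(family_history),
    ethnicity = as.character(ethnicity),
    consanguinity = as.logical(consanguinity),
    phenotype_unclear = as.logical(phenotype_unclear),
    phenotype_overlapping = as.logical(phenotype_overlapping),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id")
  bad <- setdiff(unique(df$macro_category), MACRO_CATEGORIES)
  if (length(bad)) stop("unknown macro_category: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$sex), c("F", "M"))
  if (length(bad)) stop("sex must be F or M")
  if (any(df$age_years < 0, na.rm = TRUE)) stop("negative age")
  class(df) <- unique(c("patient_records", class(df)))
  df
}

## ---- rounding --------------------------------------------------------------

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for every printed percentage: 0.05 at
#' the last kept digit always rounds up, unlike [round()]'s banker's rounding.
#' A tiny epsilon guards against values like 45.4499999 produced by binary
#' floating point for an exact decimal .45.
#'
#' @param x numeric vector.
#' @param digits decimals kept (default 1).
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Percentage with half-up rounding to one decimal
#'
#' @param num,den numerator and denominator counts.
#' @param digits decimals kept.
#' @return `100 * num / den` rounded half-up; 0 when `den` is 0.
#' @export
pct <- function(num, den, digits = 1) {
  den <- rep_len(den, length(num))
  out <- numeric(length(num))
  nz <- den != 0
  out[nz] <- round_half_up(100 * num[nz] / den[nz], digits)
  out
}
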