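## Cohort-level summaries: diagnostic yield by stratum, report-category
## proportions, reported-variant tallies, and the patient-flow (Sankey)
## counts. "Diagnostic" means a conclusive report; uncertain reports do not
## count towards yield. All percentages are rounded half-up to one decimal
## and every denominator is kept explicit in the output.

#' Diagnostic yield by stratum
#'
#' @param outcomes list of [report_outcome()] objects.
#' @param patients a [patient_records()] table covering every outcome.
#' @param stratify_by patient column to stratify on (`"macro_category"` or
#'   `"family_history"`).
#' @return data.frame with `stratum`, `n_cases`, `n_diagnostic`,
#'   `yield_percent` (half-up, one decimal).
#' @export
diagnostic_yield <- function(outcomes, patients,
                             stratify_by = "macro_category") {
  ot <- outcomes_table(outcomes)
  missing_ <- setdiff(ot$patient_id, patients$patient_id)
  if (length(missing_))
    stop("outcome for unknown patient_id: ", paste(missing_, collapse = ", "))
  m <- merge(ot, patients, by = "patient_id")
  strata <- split(m, m[[stratify_by]])
  out <- do.call(rbind, lapply(names(strata), function(s) {
    g <- strata[[s]]
    n <- nrow(g)
    d <- sum(g$outcome == "conclusive")
    data.frame(stratum = s, n_cases = n, n_diagnostic = d,
               yield_percent = pct(d, n), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Overall report-category proportions
#'
#' @param outcomes list of [report_outcome()] objects.
#' @param variant_positive named logical from [classify_cohort()]; when
#'   omitted, patients whose only reason is `no_variants` are taken as
#'   variant-negative.
#' @return one-row data.frame: cohort size, variant-positive /
#'   variant-negative counts with percentages of the cohort, and conclusive /
#'   uncertain / inconclusive counts with percentages of the variant-positive
#'   group (the denominator used when reporting the split of patients in whom
#'   CES identified variants).
#' @export
report_split <- function(outcomes, variant_positive = NULL) {
  ot <- outcomes_table(outcomes)
  n <- nrow(ot)
  if (is.null(variant_positive))
    variant_positive <- !grepl("\\bno_variants\\b", ot$reasons)
  else
    variant_positive <- unname(variant_positive[ot$patient_id])
  n_pos <- sum(variant_positive)
  cnt <- function(o) sum(ot$outcome == o & variant_positive)
  data.frame(
    n_patients = n, n_variant_positive = n_pos,
    n_no_variants = n - n_pos,
    pct_variant_positive = pct(n_pos, n),
    pct_no_variants = pct(n - n_pos, n),
    n_conclusive = cnt("conclusive"), n_uncertain = cnt("uncertain"),
    n_inconclusive = cnt("inconclusive"),
    pct_conclusive = pct(cnt("conclusive"), n_pos),
    pct_uncertain = pct(cnt("uncertain"), n_pos),
    pct_inconclusive = pct(cnt("inconclusive"), n_pos))
}

## zygosity mode of one patient-gene group of reported variants
.group_mode <- function(genotypes, consequences) {
  if (any(is_cnv(consequences))) "cnv"
  else if (any(genotypes == "hemizygous")) "hemizygous"
  else if (any(genotypes == "hom_alt")) "homozygous"
  else if (sum(genotypes == "het") >= 2) "compound_het"
  else "heterozygous"
}

#' Tally reported variants of conclusive reports
#'
#' Counts and shares (half-up, one decimal) of the variants listed on
#' conclusive reports: by consequence class, by patient-level leading ACMG
#' class, by zygosity mode of the patient-gene group, plus distinct variant
#' and gene counts.
#'
#' @param outcomes list of [report_outcome()] objects.
#' @return list with `n_variants`, `n_genes`, `by_consequence`, `by_class`
#'   (patient level), `by_mode` (patient-gene-group level), each a data.frame
#'   with `count` and `percent`.
#' @export
variant_tallies <- function(outcomes) {
  rv <- reported_variants(outcomes, "conclusive")
  tally <- function(x, den) {
    if (!length(x))
      return(data.frame(level = character(), count = integer(),
                        percent = numeric(), stringsAsFactors = FALSE))
    t <- sort(table(x), decreasing = TRUE)
    data.frame(level = names(t), count = as.integer(t),
               percent = pct(as.integer(t), den), stringsAsFactors = FALSE)
  }
  if (!nrow(rv))
    return(list(n_variants = 0L, n_genes = 0L,
                by_consequence = tally(character(), 0),
                by_class = tally(character(), 0),
                by_mode = tally(character(), 0)))
  key <- paste(rv$chrom, rv$pos, rv$ref, rv$alt, rv$patient_id)
  stopifnot(!anyDuplicated(key))
  csq <- ifelse(is_cnv(rv$consequence), "cnv", rv$consequence)
  ## patient-level leading class (C3_C4 kept as its own label)
  lead <- vapply(split(rv, rv$patient_id), function(g)
    g$acmg_class[which.max(class_severity(g$acmg_class))], character(1))
  grp <- split(rv, paste(rv$patient_id, rv$gene))
  modes <- vapply(grp, function(g) .group_mode(g$genotype, g$consequence),
                  character(1))
  list(n_variants = nrow(rv), n_genes = length(unique(rv$gene)),
       by_consequence = tally(csq, nrow(rv)),
       by_class = tally(unname(lead), length(lead)),
       by_mode = tally(unname(modes), length(modes)))
}

#' Patient-flow counts for a Sankey summary
#'
#' Edges macro-category -> variants found / no variants -> report category,
#' with patient counts conserved along every path.
#'
#' @param outcomes list of [report_outcome()] objects.
#' @param patients a [patient_records()] table.
#' @param variant_positive named logical from [classify_cohort()]; default as
#'   in [report_split()].
#' @return data.frame of edges: `from`, `to`, `n`.
#' @export
sankey_counts <- function(outcomes, patients, variant_positive = NULL) {
  ot <- outcomes_table(outcomes)
  if (is.null(variant_positive))
    variant_positive <- !grepl("\\bno_variants\\b", ot$reasons)
  else
    variant_positive <- unname(variant_positive[ot$patient_id])
  m <- merge(cbind(ot, vpos = variant_positive), patients, by = "patient_id")
  mid <- ifelse(m$vpos, "variants_found", "no_variants")
  e1 <- stats::aggregate(list(n = m$patient_id),
                         by = list(from = m$macro_category, to = mid),
                         FUN = length)
  e2 <- stats::aggregate(list(n = m$patient_id),
                         by = list(from = mid, to = m$outcome), FUN = length)
  rbind(e1, e2)
}
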