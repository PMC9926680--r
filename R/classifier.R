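## Report classification: per gene group, the ACMG class of the leading
## variant, its fit to the clinical picture, mode-of-inheritance satisfaction
## and the segregation result decide a provisional outcome; the patient's
## report takes the best outcome across groups
## (conclusive > uncertain > inconclusive).

#' Construct a candidate bundle for one patient
#'
#' @param patient_id patient identifier.
#' @param groups list of gene groups, each a list with fields `gene`,
#'   `variants` (data.frame of classified calls with an `acmg_class` column),
#'   `moi_assessment` (from [assess_moi()]), `segregation` (from
#'   [evaluate_segregation()]), `phenotype_fit` (one of [PHENOTYPE_FITS],
#'   clinician-supplied), `found_via` (`"subpanel"` or `"kidneyome"`).
#' @return list of class `candidate_bundle`.
#' @export
candidate_bundle <- function(patient_id, groups = list()) {
  for (g in groups) {
    stopifnot(is.data.frame(g$variants), "acmg_class" %in% names(g$variants))
    if (!all(g$variants$acmg_class %in% ACMG_CLASSES))
      stop("invalid ACMG class in group ", g$gene)
    if (!g$phenotype_fit %in% PHENOTYPE_FITS)
      stop("invalid phenotype_fit in group ", g$gene)
    if (!g$found_via %in% c("subpanel", "kidneyome"))
      stop("invalid found_via in group ", g$gene)
    if (!g$segregation$status %in%
        c("confirmed", "refuted", "pending", "unavailable"))
      stop("invalid segregation status in group ", g$gene)
  }
  structure(list(patient_id = patient_id, groups = groups),
            class = "candidate_bundle")
}

## provisional outcome of a single gene group; NULL outcome means the group
## contributes no reportable finding (benign-only, or a class 4/5 variant
## with no phenotype fit, which is suppressed and logged rather than given
## an invented outcome)
.classify_group <- function(g) {
  keep <- !g$variants$acmg_class %in% c("C1", "C2")
  if (!any(keep))
    return(list(outcome = NULL, reason = "benign_only", variants = NULL))
  vars <- g$variants[keep, , drop = FALSE]
  lead <- vars$acmg_class[which.max(class_severity(vars$acmg_class))]
  fit <- g$phenotype_fit
  moi <- g$moi_assessment
  seg <- g$segregation$status
  res <- function(outcome, reason) list(outcome = outcome, reason = reason,
                                        variants = vars)
  if (seg == "refuted")                                   # rule (h)
    return(res("inconclusive", "segregation_refuted"))
  if (lead %in% c("C4", "C5", "C3_C4")) {
    if (identical(moi$reason, "ar_single_het"))           # rule (e)
      return(res("inconclusive", "single_het_recessive"))
    if (fit == "full" && isTRUE(moi$satisfied))           # rule (a)
      return(res("conclusive", "c45_phenotype_moi"))
    if (fit == "partial")                                 # rule (d)
      return(res("uncertain", "c45_phenotype_partial"))
    if (fit == "none")
      return(list(outcome = NULL, reason = "suppressed_incidental",
                  variants = NULL))
    return(res("inconclusive", "moi_incompatible"))
  }
  ## leading class C3
  if (identical(moi$reason, "ar_single_het"))             # rule (e)
    return(res("inconclusive", "single_het_recessive"))
  if (fit == "full" && seg == "confirmed")                # rule (b)
    return(res("conclusive", "c3_segregation_confirmed"))
  if (fit == "full")                                      # rule (c)
    return(res("uncertain", "c3_segregation_pending"))
  if (fit == "partial")
    return(res("uncertain", "c3_phenotype_partial"))
  if (g$found_via == "kidneyome")                         # rule (f)
    return(res("inconclusive", "c3_kidneyome_phenotype_mismatch"))
  res("inconclusive", "c3_phenotype_mismatch")
}

#' Classify a patient's report
#'
#' Applies the decision rules to each gene group and aggregates to the
#' patient level by outcome precedence (conclusive > uncertain >
#' inconclusive). An empty bundle yields an inconclusive report with reason
#' `no_variants` (negative CES analysis).
#'
#' @param bundle a [candidate_bundle()].
#' @return a [report_outcome()]; reason codes of the groups that set the
#'   outcome are primary, the rest are recorded as `secondary_reasons`.
#' @export
classify_report <- function(bundle) {
  stopifnot(inherits(bundle, "candidate_bundle"))
  if (!length(bundle$groups))
    return(report_outcome(bundle$patient_id, "inconclusive", "no_variants"))
  res <- lapply(bundle$groups, .classify_group)
  contributing <- Filter(function(r) !is.null(r$outcome), res)
  logged <- vapply(Filter(function(r) is.null(r$outcome), res),
                   `[[`, character(1), "reason")
  if (!length(contributing))
    return(report_outcome(bundle$patient_id, "inconclusive",
                          reasons = unique(c("no_reportable_variants",
                                             logged))))
  ranks <- vapply(contributing, function(r) .OUTCOME_RANK[[r$outcome]], 0)
  best <- max(ranks)
  primary <- contributing[ranks == best]
  secondary <- contributing[ranks < best]
  report_outcome(
    bundle$patient_id,
    outcome = primary[[1]]$outcome,
    reasons = unique(vapply(primary, `[[`, character(1), "reason")),
    reported_variants = do.call(rbind, lapply(primary, `[[`, "variants")),
    secondary_reasons = unique(c(
      vapply(secondary, `[[`, character(1), "reason"), logged)))
}

#' Reason codes justifying a bundle's outcome
#'
#' @param bundle a [candidate_bundle()].
#' @return list with `outcome`, `primary` and `secondary` reason codes.
#' @export
outcome_reasons <- function(bundle) {
  o <- classify_report(bundle)
  list(outcome = o$outcome, primary = o$reasons,
       secondary = o$secondary_reasons)
}
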