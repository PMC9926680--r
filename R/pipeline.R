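## End-to-end orchestration: filter each patient's calls against their
## macro-category panel (escalating to the kidneyome when warranted),
## classify survivors with the ACMG engine, evaluate trio segregation per
## gene group, and produce the per-patient report outcome.

## columns beyond the core call table that the pipeline consumes when present
.ANNOT_DEFAULTS <- list(
  pvs = 0, ps = 0, pm = 0, pp = 0, ba = 0, bs = 0, bp = 0,
  manual_class = NA_character_, phenotype_fit = "full",
  mother_gt = NA_character_, father_gt = NA_character_,
  mother_depth = NA_real_, father_depth = NA_real_)

.with_annotations <- function(calls) {
  for (nm in names(.ANNOT_DEFAULTS))
    if (!nm %in% names(calls)) calls[[nm]] <- .ANNOT_DEFAULTS[[nm]]
  calls
}

.best_fit <- function(fits) {
  PHENOTYPE_FITS[min(match(fits, PHENOTYPE_FITS))]
}

#' Build the candidate bundle for one patient
#'
#' Runs the filter cascade on the patient's subpanel, escalates to the
#' kidneyome super-panel when the subpanel is negative and the clinical
#' phenotype is unclear or overlapping (reusing the already-filtered calls:
#' a single filtering pass), classifies every surviving variant, and
#' assembles per-gene groups with mode-of-inheritance and segregation
#' assessments. Genes entered under two inheritance modes are evaluated under
#' both; the satisfied mode wins.
#'
#' @param calls [variant_calls()] rows for this patient, optionally carrying
#'   evidence counts (`pvs`..`bp`), `manual_class`, `phenotype_fit` and
#'   parental genotype columns.
#' @param patient one-row [patient_records()] table.
#' @param registry panel registry (list of `gene_panel`, one per category,
#'   plus the kidneyome).
#' @param trio optional list/row with `mother_id`, `father_id` (`NA` =
#'   unavailable parent); `NULL` = no pedigree.
#' @param cfg a [filter_config()].
#' @return a [candidate_bundle()].
#' @export
build_bundle <- function(calls, patient, registry, trio = NULL,
                         cfg = filter_config()) {
  calls <- .with_annotations(as.data.frame(calls))
  subpanel <- select_panel(patient, registry)
  run <- run_filter_cascade(calls, subpanel, cfg)
  survivors <- run$survivors
  found_via <- "subpanel"
  if (!nrow(survivors) &&
      should_escalate(TRUE, patient$phenotype_unclear,
                      patient$phenotype_overlapping)) {
    kp <- Filter(function(p) p$category == "kidneyome", registry)
    if (!length(kp)) stop("configuration error: no kidneyome panel")
    run <- run_filter_cascade(calls, kp[[1]], cfg)
    survivors <- run$survivors
    found_via <- "kidneyome"
  }
  panel_used <- if (found_via == "kidneyome")
    Filter(function(p) p$category == "kidneyome", registry)[[1]]
  else subpanel
  if (!nrow(survivors)) return(candidate_bundle(patient$patient_id))

  survivors$acmg_class <- vapply(seq_len(nrow(survivors)), function(i) {
    r <- survivors[i, ]
    classify_with_override(
      evidence_profile(r$pvs, r$ps, r$pm, r$pp, r$ba, r$bs, r$bp),
      if (is.na(r$manual_class)) NULL else r$manual_class)
  }, character(1))

  groups <- lapply(split(survivors, survivors$gene), function(g) {
    modes <- panel_moi(panel_used, g$gene[1])
    assessments <- lapply(modes, function(m)
      assess_moi(g$genotype, m, patient$sex))
    sat <- vapply(assessments, `[[`, logical(1), "satisfied")
    pick <- if (any(sat)) which(sat)[1] else 1L
    moi <- modes[pick]
    seg <- evaluate_segregation(g, moi, patient$sex, trio)
    list(gene = g$gene[1], variants = g, moi = moi,
         moi_assessment = assessments[[pick]], segregation = seg,
         phenotype_fit = .best_fit(g$phenotype_fit), found_via = found_via)
  })
  candidate_bundle(patient$patient_id, unname(groups))
}

#' Classify a whole cohort
#'
#' @param calls [variant_calls()] table for all patients (annotation columns
#'   as in [build_bundle()]).
#' @param patients a [patient_records()] table.
#' @param registry panel registry.
#' @param trios optional data.frame from [read_ped()] (or with columns
#'   `proband_id`, `mother_id`, `father_id`).
#' @param cfg a [filter_config()].
#' @return list with `outcomes` (list of [report_outcome()], one per
#'   patient, cohort order) and `variant_positive` (named logical: did any
#'   variant survive filtering and prioritisation for the patient).
#' @export
classify_cohort <- function(calls, patients, registry, trios = NULL,
                            cfg = filter_config()) {
  calls <- .with_annotations(as.data.frame(calls))
  outcomes <- vector("list", nrow(patients))
  vpos <- logical(nrow(patients))
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    pc <- calls[calls$patient_id == p$patient_id, , drop = FALSE]
    trio <- NULL
    if (!is.null(trios)) {
      tr <- trios[trios$proband_id == p$patient_id, , drop = FALSE]
      if (nrow(tr)) trio <- as.list(tr[1, ])
    }
    bundle <- build_bundle(pc, p, registry, trio, cfg)
    vpos[i] <- length(bundle$groups) > 0L
    outcomes[[i]] <- classify_report(bundle)
  }
  names(vpos) <- patients$patient_id
  list(outcomes = outcomes, variant_positive = vpos)
}
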