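## ACMG evidence combination. Evidence arrives pre-assigned by strength
## (counts of invoked criteria per tier); the engine applies the published
## 2015 ACMG/AMP combining rules to produce the class C1-C5 used on genetic
## reports. The intermediate label C3_C4 exists only as a curator override.

#' Construct an ACMG evidence profile
#'
#' Counts of invoked criteria per evidence tier: `pvs` (very strong
#' pathogenic, e.g. PVS1), `ps` (strong), `pm` (moderate), `pp` (supporting),
#' `ba` (stand-alone benign, BA1), `bs` (strong benign), `bp` (supporting
#' benign).
#'
#' @param pvs,ps,pm,pp,ba,bs,bp non-negative integer counts.
#' @return named list of class `evidence_profile`.
#' @export
evidence_profile <- function(pvs = 0, ps = 0, pm = 0, pp = 0,
                             ba = 0, bs = 0, bp = 0) {
  e <- list(pvs = pvs, ps = ps, pm = pm, pp = pp, ba = ba, bs = bs, bp = bp)
  if (any(unlist(e) < 0)) stop("evidence counts must be >= 0")
  structure(e, class = "evidence_profile")
}

#' Combine ACMG evidence into a class
#'
#' Deterministic, total mapping from evidence counts to C1-C5 following the
#' 2015 ACMG/AMP combining rules: pathogenic for 1 PVS with (>=1 PS, >=2 PM,
#' 1 PM + 1 PP, or >=2 PP), >=2 PS, or 1 PS with (>=3 PM, 2 PM + >=2 PP, or
#' 1 PM + >=4 PP); likely pathogenic for 1 PVS + 1 PM, 1 PS + 1-2 PM,
#' 1 PS + >=2 PP, >=3 PM, 2 PM + >=2 PP, or 1 PM + >=4 PP; benign for BA1 or
#' >=2 BS; likely benign for 1 BS + 1 BP or >=2 BP. Anything else — and any
#' profile meeting both a pathogenic and a benign rule — is a variant of
#' unknown significance (C3).
#'
#' Vectorised over equal-length count vectors.
#'
#' @param pvs,ps,pm,pp,ba,bs,bp evidence counts (or an `evidence_profile` as
#'   `pvs`).
#' @return character vector of classes (`"C1"`, `"C2"`, `"C3"`, `"C4"`,
#'   `"C5"`).
#' @export
combine_evidence <- function(pvs = 0, ps = 0, pm = 0, pp = 0,
                             ba = 0, bs = 0, bp = 0) {
  if (inherits(pvs, "evidence_profile")) {
    e <- pvs
    pvs <- e$pvs; ps <- e$ps; pm <- e$pm; pp <- e$pp
    ba <- e$ba; bs <- e$bs; bp <- e$bp
  }
  if (any(c(pvs, ps, pm, pp, ba, bs, bp) < 0))
    stop("evidence counts must be >= 0")
  pathogenic <-
    (pvs >= 1 & (ps >= 1 | pm >= 2 | (pm >= 1 & pp >= 1) | pp >= 2)) |
    (ps >= 2) |
    (ps >= 1 & (pm >= 3 | (pm >= 2 & pp >= 2) | (pm >= 1 & pp >= 4)))
  likely_path <-
    (pvs >= 1 & pm >= 1) |
    (ps >= 1 & pm >= 1) |
    (ps >= 1 & pp >= 2) |
    (pm >= 3) |
    (pm >= 2 & pp >= 2) |
    (pm >= 1 & pp >= 4)
  benign <- (ba >= 1) | (bs >= 2)
  likely_benign <- (bs >= 1 & bp >= 1) | (bp >= 2)
  conflict <- (pathogenic | likely_path) & (benign | likely_benign)
  out <- rep("C3", length(pathogenic))
  out[likely_benign] <- "C2"
  out[benign] <- "C1"
  out[likely_path] <- "C4"
  out[pathogenic] <- "C5"
  out[conflict] <- "C3"
  out
}

#' Classify with optional curator override
#'
#' The computed class can be overridden by the reviewing medical geneticist;
#' this is how the intermediate `C3_C4` label (not producible by the
#' combining rules) enters a report.
#'
#' @param e an [evidence_profile()].
#' @param manual optional manual class, one of [ACMG_CLASSES]; `NA`/`NULL`
#'   means no override.
#' @return a single class string.
#' @export
classify_with_override <- function(e, manual = NULL) {
  computed <- combine_evidence(e)
  if (is.null(manual) || length(manual) == 0L || is.na(manual))
    return(computed)
  if (!manual %in% ACMG_CLASSES)
    stop("invalid manual class: ", manual)
  manual
}

## numeric severity used for picking a gene group's leading class;
## C3_C4 carries C4-like weight but keeps its own label in tallies
class_severity <- function(cls) {
  unname(c(C1 = 1, C2 = 2, C3 = 3, C3_C4 = 4.5, C4 = 5, C5 = 6)[cls])
}
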