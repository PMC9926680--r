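## Trio segregation: mode-of-inheritance satisfaction, de novo detection,
## compound-heterozygote phasing and overall segregation evaluation.
##
## Parental data travel as columns on the proband's call rows (`mother_gt`,
## `father_gt`, `mother_depth`, `father_depth`; NA when not genotyped), with
## the trio skeleton (parent ids from the PED) deciding whether absent data
## mean "pending" (parents exist, not yet genotyped) or "unavailable".
## Penetrance is assumed complete: an unaffected carrier parent under AD
## still counts as confirmed transmission.

.carries <- function(gt) !is.na(gt) & gt %in% c("het", "hom_alt", "hemizygous")
.homref_ok <- function(gt, depth, min_depth)
  !is.na(gt) & gt == "hom_ref" & !is.na(depth) & depth >= min_depth

#' Assess mode-of-inheritance satisfaction for one gene
#'
#' @param genotypes proband genotypes of the candidate variants in one gene
#'   (values from [GENOTYPES]).
#' @param moi the gene's inheritance mode (one of [INHERITANCE_MODES]).
#' @param sex proband sex, `"F"` or `"M"`.
#' @return list with `satisfied` (logical) and `reason`, one of `ad_het_ok`,
#'   `ar_hom_ok`, `ar_comphet_ok`, `ar_single_het` (never satisfied),
#'   `xl_hemi_ok`, `xld_het_ok`, `incompatible`.
#' @export
assess_moi <- function(genotypes, moi, sex) {
  stopifnot(length(moi) == 1L, moi %in% INHERITANCE_MODES,
            sex %in% c("F", "M"))
  alt <- genotypes[.carries(genotypes)]
  n_het <- sum(alt == "het")
  n_hom <- sum(alt == "hom_alt")
  n_hemi <- sum(alt == "hemizygous")
  res <- function(ok, why) list(satisfied = ok, reason = why)
  if (moi == "NA" || !length(alt)) return(res(FALSE, "incompatible"))
  switch(moi,
    AD = res(TRUE, "ad_het_ok"),
    AR = if (n_hom >= 1) res(TRUE, "ar_hom_ok")
         else if (n_het >= 2) res(TRUE, "ar_comphet_ok")
         else if (n_het == 1) res(FALSE, "ar_single_het")
         else res(FALSE, "incompatible"),
    XLR = if ((sex == "M" && n_hemi >= 1) || (sex == "F" && n_hom >= 1))
            res(TRUE, "xl_hemi_ok")
          else res(FALSE, "incompatible"),
    XLD = res(TRUE, "xld_het_ok")
  )
}

#' Detect a de novo variant from trio genotypes
#'
#' @param v one call row carrying `mother_gt`, `father_gt`, `mother_depth`,
#'   `father_depth`.
#' @param min_parent_depth minimum parental coverage for a confident
#'   reference call (default 20 reads, mirroring the proband coverage rule).
#' @return `TRUE` (both parents confidently homozygous reference), `FALSE`
#'   (a parent carries the allele), or `NA` (a parent ungenotyped or below
#'   the depth gate — origin unresolvable).
#' @export
detect_de_novo <- function(v, min_parent_depth = 20) {
  if (.carries(v$mother_gt) || .carries(v$father_gt)) return(FALSE)
  if (.homref_ok(v$mother_gt, v$mother_depth, min_parent_depth) &&
      .homref_ok(v$father_gt, v$father_depth, min_parent_depth)) return(TRUE)
  NA
}

#' Phase a compound-heterozygous pair from parental carriage
#'
#' @param v1,v2 call rows (same gene, both het in the proband) carrying
#'   parental genotype columns.
#' @return `"trans"` when one variant traces exclusively to each parent,
#'   `"cis"` when both trace to the same single parent, `"unknown"`
#'   otherwise (shared parental carriage or missing data).
#' @export
phase_compound_het <- function(v1, v2) {
  m1 <- .carries(v1$mother_gt); f1 <- .carries(v1$father_gt)
  m2 <- .carries(v2$mother_gt); f2 <- .carries(v2$father_gt)
  if (anyNA(c(v1$mother_gt, v1$father_gt, v2$mother_gt, v2$father_gt)))
    return("unknown")
  if ((m1 && !f1 && f2 && !m2) || (f1 && !m1 && m2 && !f2)) return("trans")
  if ((m1 && !f1 && m2 && !f2) || (f1 && !m1 && f2 && !m2)) return("cis")
  "unknown"
}

#' Evaluate segregation of a gene group against the trio
#'
#' Checks whether the parental genotypes are consistent with the proband's
#' candidate variants under the gene's inheritance mode: an AR homozygote
#' expects both parents heterozygous; a compound heterozygote must phase in
#' trans (cis refutes the recessive model); a dominant or X-linked variant is
#' confirmed when inherited from a parent or proven de novo.
#'
#' @param variants call rows of one gene group (with parental columns).
#' @param moi the gene's inheritance mode.
#' @param sex proband sex.
#' @param trio list/row with `mother_id` and `father_id` (`NA` when the
#'   parent is unavailable); `NULL` means no pedigree at all.
#' @param min_parent_depth depth gate for confident parental reference calls.
#' @return list with `status` (`confirmed`, `refuted`, `pending`,
#'   `unavailable`), `de_novo` (logical) and `phase` (`trans`/`cis`/`unknown`,
#'   compound heterozygotes only).
#' @export
evaluate_segregation <- function(variants, moi, sex, trio = NULL,
                                 min_parent_depth = 20) {
  out <- function(status, de_novo = FALSE, phase = "unknown")
    list(status = status, de_novo = de_novo, phase = phase)
  if (is.null(trio) ||
      (is.na(trio$mother_id %||% NA) && is.na(trio$father_id %||% NA)))
    return(out("unavailable"))
  if (!all(c("mother_gt", "father_gt") %in% names(variants)) ||
      all(is.na(variants$mother_gt) & is.na(variants$father_gt)))
    return(out("pending"))

  gts <- variants$genotype
  if (moi == "AR" && any(gts == "hom_alt")) {
    v <- variants[which(gts == "hom_alt")[1], ]
    if (.carries(v$mother_gt) && .carries(v$father_gt))
      return(out("confirmed"))
    if (.homref_ok(v$mother_gt, v$mother_depth, min_parent_depth) ||
        .homref_ok(v$father_gt, v$father_depth, min_parent_depth))
      return(out("refuted"))
    return(out("pending"))
  }
  if (moi == "AR" && sum(gts == "het") >= 2) {
    hets <- which(gts == "het")
    ph <- phase_compound_het(variants[hets[1], ], variants[hets[2], ])
    return(switch(ph,
                  trans = out("confirmed", phase = "trans"),
                  cis = out("refuted", phase = "cis"),
                  out("pending", phase = "unknown")))
  }
  if (moi == "XLR") {
    v <- variants[1, ]
    if (.carries(v$mother_gt)) return(out("confirmed"))
    if (sex == "M" && .carries(v$father_gt) && !.carries(v$mother_gt) &&
        !is.na(v$mother_gt))
      return(out("refuted"))  # a father cannot transmit his X to a son
    dn <- detect_de_novo(v, min_parent_depth)
    if (isTRUE(dn)) return(out("confirmed", de_novo = TRUE))
    return(out("pending"))
  }
  ## AD / XLD (and AR single het falls through to transmission logic)
  v <- variants[1, ]
  dn <- detect_de_novo(v, min_parent_depth)
  if (isTRUE(dn)) return(out("confirmed", de_novo = TRUE))
  if (.carries(v$mother_gt) || .carries(v$father_gt))
    return(out("confirmed"))
  out("pending")
}
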