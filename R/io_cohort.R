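## On-disk artifact set for a (synthetic) cohort: a multi-sample VCF of the
## proband calls, a PED of the trios, TSVs for patients, panels, the
## per-variant annotation layer (evidence counts, curator override,
## phenotype fit, parental genotypes) and the ground-truth ledger. All plain
## text, all round-trippable.

.ANNOT_COLS <- c("pvs", "ps", "pm", "pp", "ba", "bs", "bp", "manual_class",
                 "phenotype_fit", "mother_gt", "father_gt", "mother_depth",
                 "father_depth")

#' Write a cohort artifact set
#'
#' @param cohort list as returned by [simulate_cohort()] /
#'   [build_paper_fixture()].
#' @param dir output directory (created if needed).
#' @return named vector of written file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- c(vcf = file.path(dir, "cohort.vcf"),
         ped = file.path(dir, "cohort.ped"),
         patients = file.path(dir, "patients.tsv"),
         panels = file.path(dir, "panels.tsv"),
         annotations = file.path(dir, "annotations.tsv"),
         ledger = file.path(dir, "ledger.tsv"))
  core <- intersect(names(cohort$calls),
                    c("patient_id", "chrom", "pos", "ref", "alt", "gene",
                      "consequence", "splice_region", "pop_af", "vaf",
                      "depth", "genotype"))
  write_vcf(cohort$calls[, core], f[["vcf"]])
  tsv <- function(x, path)
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$trios)) {
    ped <- data.frame(
      fam = cohort$trios$family_id, id = cohort$trios$proband_id,
      father = ifelse(is.na(cohort$trios$father_id), "0",
                      cohort$trios$father_id),
      mother = ifelse(is.na(cohort$trios$mother_id), "0",
                      cohort$trios$mother_id),
      sex = ifelse(cohort$trios$sex == "M", "1", "2"),
      phenotype = ifelse(cohort$trios$affected, "2", "1"))
    utils::write.table(ped, f[["ped"]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else writeLines(character(), f[["ped"]])
  tsv(as.data.frame(unclass(cohort$patients),
                    stringsAsFactors = FALSE), f[["patients"]])
  write_panel_registry(cohort$registry, f[["panels"]])
  tsv(cohort$calls[, c("patient_id", "chrom", "pos", "ref", "alt",
                       intersect(.ANNOT_COLS, names(cohort$calls)))],
      f[["annotations"]])
  tsv(cohort$ledger, f[["ledger"]])
  invisible(f)
}

#' Read a cohort artifact set back
#'
#' Re-reads the files written by [write_cohort()] and merges the annotation
#' layer onto the VCF-derived calls by variant key.
#'
#' @param dir directory holding the artifact set.
#' @return list with `calls`, `patients`, `trios`, `registry`.
#' @export
read_cohort <- function(dir) {
  patients <- utils::read.delim(file.path(dir, "patients.tsv"),
                                stringsAsFactors = FALSE)
  patients <- patient_records(
    patients$patient_id, patients$sex, patients$age_years,
    patients$macro_category, patients$primary_disease,
    patients$family_history, patients$ethnicity, patients$consanguinity,
    patients$phenotype_unclear, patients$phenotype_overlapping)
  sexes <- stats::setNames(patients$sex, patients$patient_id)
  calls <- read_vcf(file.path(dir, "cohort.vcf"), patient_sex = sexes)
  ann <- utils::read.delim(file.path(dir, "annotations.tsv"),
                           stringsAsFactors = FALSE)
  calls <- merge(calls, ann,
                 by = c("patient_id", "chrom", "pos", "ref", "alt"),
                 all.x = TRUE, sort = FALSE)
  ped_path <- file.path(dir, "cohort.ped")
  trios <- if (file.size(ped_path) > 0) read_ped(ped_path) else NULL
  list(calls = calls, patients = patients, trios = trios,
       registry = read_panel_registry(file.path(dir, "panels.tsv")))
}
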