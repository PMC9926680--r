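## Synthetic cohorts with known ground truth. A cohort is realised from a
## "plan": one row per patient stating the intended report outcome and the
## archetype of the causative finding (class, zygosity, gene, segregation
## intent). The realiser turns the plan into concrete annotated calls, trio
## genotypes and decoy variants, each decoy engineered to fail exactly one
## named filter; the plan doubles as the ground-truth ledger against which
## pipeline output is checked.

.ARCHETYPES <- c("concl_a", "concl_b", "unc_c", "unc_d",
                 "inc_e", "inc_f", "inc_h", "negative")

.archetype_outcome <- c(
  concl_a = "conclusive", concl_b = "conclusive",
  unc_c = "uncertain", unc_d = "uncertain",
  inc_e = "inconclusive", inc_f = "inconclusive", inc_h = "inconclusive",
  negative = "inconclusive")

## evidence counts producing each intended class under the combining rules;
## C3_C4 is a curator override on top of VUS-level evidence
.class_evidence <- function(cls) {
  switch(cls,
    C5 = list(pvs = 1, ps = 1, pm = 0, pp = 0),
    C4 = list(pvs = 0, ps = 1, pm = 1, pp = 0),
    C3 = list(pvs = 0, ps = 0, pm = 0, pp = 1),
    C3_C4 = list(pvs = 0, ps = 0, pm = 0, pp = 2),
    stop("no evidence template for class ", cls))
}

.ref_alt <- function(consequence) {
  switch(consequence,
    frameshift = c("AC", "A"),
    inframe_indel = c("AGTT", "A"),
    cnv_del = c("N", "<DEL>"),
    cnv_dup = c("N", "<DUP>"),
    c("A", "G"))
}

## one causative variant row (annotations included)
.causative_row <- function(pid, gene, chrom, pos, consequence, genotype,
                           class, fit, mother_gt = NA, father_gt = NA,
                           parent_depth = NA_real_) {
  cnv <- consequence %in% c("cnv_del", "cnv_dup")
  ra <- .ref_alt(consequence)
  ev <- .class_evidence(class)
  data.frame(
    patient_id = pid, chrom = chrom, pos = as.integer(pos),
    ref = ra[1], alt = ra[2], gene = gene, consequence = consequence,
    splice_region = consequence == "splicing",
    pop_af = if (cnv) NA_real_ else 0,
    vaf = if (cnv) NA_real_ else
      switch(genotype, het = 0.48, hom_alt = 0.98, hemizygous = 0.97, 0.5),
    depth = if (cnv) NA_real_ else 80,
    genotype = genotype,
    pvs = ev$pvs, ps = ev$ps, pm = ev$pm, pp = ev$pp, ba = 0, bs = 0, bp = 0,
    manual_class = if (class == "C3_C4") "C3_C4" else NA_character_,
    phenotype_fit = fit,
    mother_gt = mother_gt, father_gt = father_gt,
    mother_depth = parent_depth, father_depth = parent_depth,
    stringsAsFactors = FALSE)
}

## decoys: each fails exactly the named filter (and passes the others,
## panel restriction aside)
.decoy_row <- function(pid, gene, chrom, pos, fails) {
  base <- data.frame(
    patient_id = pid, chrom = chrom, pos = as.integer(pos),
    ref = "A", alt = "T", gene = gene, consequence = "missense",
    splice_region = FALSE, pop_af = 0, vaf = 0.5, depth = 90,
    genotype = "het",
    pvs = 0, ps = 0, pm = 0, pp = 0, ba = 0, bs = 0, bp = 0,
    manual_class = NA_character_, phenotype_fit = "none",
    mother_gt = NA_character_, father_gt = NA_character_,
    mother_depth = NA_real_, father_depth = NA_real_,
    stringsAsFactors = FALSE)
  switch(fails,
    common = { base$pop_af <- 0.05; base },
    low_vaf = { base$vaf <- 0.15; base },
    low_depth = { base$depth <- 12; base },
    synonymous = { base$consequence <- "synonymous"; base },
    intronic = { base$consequence <- "intronic"; base },
    off_panel = { base$gene <- "OFFPANEL1"; base },
    stop("unknown decoy type ", fails))
}

.gene_chrom <- function(registry, gene) {
  for (p in registry) {
    hit <- p$entries$chromosome[p$entries$gene == gene]
    if (length(hit)) return(hit[1])
  }
  stop("gene ", gene, " absent from registry")
}

#' Realise a cohort plan into calls, trios and a ground-truth ledger
#'
#' @param plan data.frame with one row per patient: `patient_id`, `category`,
#'   `sex`, `age_years`, `family_history`, `archetype` (one of concl_a,
#'   concl_b, unc_c, unc_d, inc_e, inc_f, inc_h, negative), `class`,
#'   `zygosity` (`het`, `hom`, `hemi`, `comphet`, `cnv_del`, `cnv_dup`),
#'   `gene`, `csq1`, `csq2` (second compound-het allele), `trio` (`none`,
#'   `pending`, `full`), `n_decoys`.
#' @param registry panel registry the genes are drawn from.
#' @return list with `calls` (annotated [variant_calls()] columns), `patients`
#'   ([patient_records()]), `trios` (PED-style data.frame), `ledger`
#'   (plan plus intended outcome and variant-positive flag) and `decoys`
#'   (per-decoy row with the filter it must fail).
#' @export
realize_cohort <- function(plan, registry) {
  stopifnot(all(plan$archetype %in% .ARCHETYPES),
            !anyDuplicated(plan$patient_id))
  calls <- list()
  decoy_ledger <- list()
  trios <- list()
  decoy_types <- c("common", "low_vaf", "synonymous", "low_depth",
                   "intronic", "off_panel")
  for (i in seq_len(nrow(plan))) {
    r <- plan[i, ]
    pid <- r$patient_id
    base_pos <- 1000000L + i * 1000L
    arch <- r$archetype
    fit <- switch(arch, unc_d = "partial", inc_f = "none",
                  negative = NA_character_, "full")
    if (arch != "negative") {
      gene <- r$gene
      chrom <- .gene_chrom(registry, gene)
      if (r$zygosity == "comphet") {
        ph <- switch(arch, inc_h = "cis", "trans")
        m1 <- if (r$trio == "full") "het" else NA_character_
        f1 <- if (r$trio == "full") "hom_ref" else NA_character_
        m2 <- if (r$trio == "full") {
          if (ph == "cis") "het" else "hom_ref"
        } else NA_character_
        f2 <- if (r$trio == "full") {
          if (ph == "cis") "hom_ref" else "het"
        } else NA_character_
        pd <- if (r$trio == "full") 60 else NA_real_
        calls[[length(calls) + 1L]] <- .causative_row(
          pid, gene, chrom, base_pos, r$csq1, "het", r$class, fit,
          m1, f1, pd)
        calls[[length(calls) + 1L]] <- .causative_row(
          pid, gene, chrom, base_pos + 7L, r$csq2, "het", r$class, fit,
          m2, f2, pd)
      } else {
        genotype <- switch(r$zygosity, het = "het", hom = "hom_alt",
                           hemi = "hemizygous", cnv_del = "het",
                           cnv_dup = "het")
        csq <- if (r$zygosity %in% c("cnv_del", "cnv_dup")) r$zygosity
               else r$csq1
        seg <- if (r$trio != "full") list(m = NA, f = NA, d = NA_real_)
          else if (arch == "concl_b") list(m = "hom_ref", f = "hom_ref",
                                           d = 60)             # de novo
          else if (r$zygosity == "hom") list(m = "het", f = "het", d = 60)
          else if (r$zygosity == "hemi") list(m = "het", f = "hom_ref",
                                              d = 60)          # carrier mother
          else list(m = "het", f = "hom_ref", d = 60)          # inherited
        calls[[length(calls) + 1L]] <- .causative_row(
          pid, gene, chrom, base_pos, csq, genotype, r$class, fit,
          seg$m, seg$f, seg$d)
      }
    }
    ## decoys, cycling through failure modes; genes from the own subpanel so
    ## each decoy fails exactly its designed filter, not panel restriction
    sub <- Filter(function(p) p$category == r$category, registry)[[1]]
    decoy_genes <- sub$entries$gene
    n_dec <- r$n_decoys
    for (k in seq_len(n_dec)) {
      type <- decoy_types[(i + k - 1L) %% length(decoy_types) + 1L]
      g <- decoy_genes[(i + k - 1L) %% length(decoy_genes) + 1L]
      d <- .decoy_row(pid, g, .gene_chrom(registry, g),
                      base_pos + 100L + k * 3L, type)
      calls[[length(calls) + 1L]] <- d
      decoy_ledger[[length(decoy_ledger) + 1L]] <- data.frame(
        patient_id = pid, chrom = d$chrom, pos = d$pos, fails = type,
        stringsAsFactors = FALSE)
    }
    if (r$trio %in% c("pending", "full"))
      trios[[length(trios) + 1L]] <- data.frame(
        family_id = pid, proband_id = pid,
        father_id = paste0(pid, "_F"), mother_id = paste0(pid, "_M"),
        sex = r$sex, affected = TRUE, stringsAsFactors = FALSE)
  }
  patients <- patient_records(
    patient_id = plan$patient_id, sex = plan$sex,
    age_years = plan$age_years, macro_category = plan$category,
    primary_disease = plan$category, family_history = plan$family_history,
    phenotype_unclear = plan$archetype == "inc_f")
  ledger <- plan
  ledger$intended_outcome <- unname(.archetype_outcome[plan$archetype])
  ledger$variant_positive <- plan$archetype != "negative"
  calls_df <- validate_variant_calls(do.call(rbind, calls))
  list(calls = calls_df, patients = patients,
       trios = if (length(trios)) do.call(rbind, trios) else NULL,
       ledger = ledger,
       decoys = do.call(rbind, decoy_ledger))
}

#' Simulation configuration
#'
#' Defaults emulate the structure of the study cohort: six macro-categories
#' with the observed proportions, per-category family-history rates, the
#' observed outcome mix, and mostly-available trios.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_patients cohort size.
#' @param category_proportions named vector over [MACRO_CATEGORIES], summing
#'   to 1.
#' @param family_history_rate named per-category rates in `[0, 1]`.
#' @param archetype_probs named vector over the patient archetypes (see
#'   [realize_cohort()]), summing to 1.
#' @param trio_rate probability a non-negative patient has a genotyped trio
#'   where the archetype leaves it free.
#' @param decoy_rate mean number of nuisance variants per patient (Poisson).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_patients = 60,
                       category_proportions = c(
                         CAKUT = 34, ciliopathy = 39, glomerulopathy = 62,
                         nephrolithiasis = 22, tubulopathy = 20,
                         other = 14) / 191,
                       family_history_rate = c(
                         CAKUT = 4 / 34, ciliopathy = 22 / 39,
                         glomerulopathy = 6 / 62,
                         nephrolithiasis = 12 / 22, tubulopathy = 2 / 20,
                         other = 1 / 14),
                       archetype_probs = c(
                         concl_a = 0.29, concl_b = 0.08, unc_c = 0.08,
                         unc_d = 0.04, inc_e = 0.24, inc_f = 0.05,
                         inc_h = 0.03, negative = 0.19),
                       trio_rate = 0.6, decoy_rate = 2) {
  stopifnot(abs(sum(category_proportions) - 1) < 1e-6,
            abs(sum(archetype_probs) - 1) < 1e-6,
            all(family_history_rate >= 0 & family_history_rate <= 1),
            trio_rate >= 0, trio_rate <= 1, decoy_rate >= 0)
  structure(list(seed = as.integer(seed), n_patients = n_patients,
                 category_proportions = category_proportions,
                 family_history_rate = family_history_rate,
                 archetype_probs = archetype_probs, trio_rate = trio_rate,
                 decoy_rate = decoy_rate),
            class = "sim_config")
}

## pick a gene of the required inheritance type from the patient's subpanel
.pick_gene <- function(registry, category, zygosity, arch) {
  if (arch == "inc_f") {
    ## a kidneyome-only finding: a gene from some other category's panel
    for (p in registry)
      if (!p$category %in% c(category, "kidneyome")) {
        g <- p$entries[p$entries$moi == "AD", , drop = FALSE]
        sub <- Filter(function(q) q$category == category, registry)[[1]]
        g <- g[!g$gene %in% sub$entries$gene, , drop = FALSE]
        if (nrow(g)) return(g$gene[1])
      }
    stop("infeasible spec: no kidneyome-only gene for category ", category)
  }
  sub <- Filter(function(p) p$category == category, registry)
  if (!length(sub)) stop("no panel for category ", category)
  e <- sub[[1]]$entries
  moi_needed <- switch(zygosity,
                       het = "AD", cnv_del = "AD", cnv_dup = "AD",
                       hom = "AR", comphet = "AR", hemi = "XLR")
  g <- e$gene[e$moi == moi_needed]
  if (arch == "inc_e") {
    ## the single-het-in-recessive-gene archetype needs a strictly recessive
    ## gene: a dual-inheritance entry would satisfy the dominant mode
    dual <- unique(e$gene[e$moi != "AR"])
    g <- setdiff(g, dual)
  }
  if (!length(g))
    stop("infeasible spec: no ", moi_needed, " gene in ", category,
         " panel for zygosity ", zygosity)
  sample(g, 1)
}

#' Simulate a synthetic cohort with ground truth
#'
#' Draws per-patient categories, family history, archetypes and causative
#' variants under `cfg`, realises the cohort, and (optionally) writes the
#' artifact set to `dir` via [write_cohort()]. Reproducible given
#' `cfg$seed`; on noise-free configurations the pipeline's outcome must
#' match the ledger for every patient.
#'
#' @param cfg a [sim_config()].
#' @param registry panel registry (default [demo_registry()]).
#' @param dir optional output directory for the on-disk artifact set.
#' @return as [realize_cohort()], plus `registry` and (when written) `files`.
#' @export
simulate_cohort <- function(cfg = sim_config(), registry = demo_registry(),
                            dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_patients
  cats <- sample(names(cfg$category_proportions), n, replace = TRUE,
                 prob = cfg$category_proportions)
  arch <- sample(names(cfg$archetype_probs), n, replace = TRUE,
                 prob = cfg$archetype_probs)
  fh <- stats::runif(n) < cfg$family_history_rate[cats]
  plan <- data.frame(
    patient_id = sprintf("S%03d", seq_len(n)), category = cats,
    sex = NA_character_, age_years = stats::rpois(n, 8) + 1,
    family_history = fh, archetype = arch,
    class = NA_character_, zygosity = NA_character_, gene = NA_character_,
    csq1 = NA_character_, csq2 = NA_character_, trio = "none",
    n_decoys = stats::rpois(n, cfg$decoy_rate), stringsAsFactors = FALSE)
  csq_pool <- c("missense", "missense", "missense", "nonsense", "frameshift",
                "splicing")
  for (i in seq_len(n)) {
    a <- plan$archetype[i]
    if (a == "negative") {
      plan$sex[i] <- sample(c("F", "M"), 1)
      plan$n_decoys[i] <- max(plan$n_decoys[i], 1L)  # negative != empty VCF
      next
    }
    ## hemizygous findings are only drawable where the subpanel actually
    ## carries an X-linked-recessive gene
    sub_moi <- Filter(function(p) p$category == plan$category[i],
                      registry)[[1]]$entries$moi
    zyg <- switch(a,
      concl_a = {
        opts <- c("het", "hom", "comphet", "hemi", "cnv_del", "cnv_dup")
        prob <- c(0.45, 0.2, 0.2, 0.05, 0.05, 0.05)
        if (!"XLR" %in% sub_moi) {
          prob <- prob[opts != "hemi"]
          opts <- opts[opts != "hemi"]
        }
        sample(opts, 1, prob = prob)
      },
      concl_b = sample(c("het", "comphet"), 1, prob = c(0.6, 0.4)),
      unc_c = "het", unc_d = "het", inc_e = "het_ar", inc_f = "het",
      inc_h = "comphet")
    cls <- switch(a,
      concl_a = sample(c("C5", "C4", "C3_C4"), 1, prob = c(0.3, 0.6, 0.1)),
      concl_b = "C3", unc_c = "C3", unc_d = sample(c("C4", "C5"), 1),
      inc_e = "C4", inc_f = "C3", inc_h = "C4")
    ## single het in a recessive gene keeps zygosity "het" but draws an AR
    ## gene; C3_C4 needs trio support when the leading rule is (a) anyway
    gene_zyg <- if (zyg == "het_ar") "hom" else zyg
    plan$gene[i] <- .pick_gene(registry, plan$category[i], gene_zyg, a)
    if (zyg == "het_ar") zyg <- "het"
    plan$zygosity[i] <- zyg
    plan$class[i] <- cls
    plan$csq1[i] <- sample(csq_pool, 1)
    plan$csq2[i] <- sample(csq_pool, 1)
    plan$sex[i] <- if (zyg == "hemi") "M" else {
      moi <- panel_moi(Filter(function(p) p$category == "kidneyome",
                              registry)[[1]], plan$gene[i])
      if ("XLD" %in% moi) "F" else sample(c("F", "M"), 1)
    }
    plan$trio[i] <- switch(a,
      concl_b = "full", inc_h = "full", unc_c = "pending",
      if (zyg %in% c("hom", "comphet")) "full"
      else if (stats::runif(1) < cfg$trio_rate) "full" else "none")
  }
  cohort <- realize_cohort(plan, registry)
  cohort$registry <- registry
  if (!is.null(dir)) cohort$files <- write_cohort(cohort, dir)
  cohort
}
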