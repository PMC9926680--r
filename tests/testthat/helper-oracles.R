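# Independent oracles used to cross-check the implementation. These are
# deliberately written as flat rule lookups / brute-force re-derivations,
# not calls into the package's own decision paths.

# --- mode-of-inheritance truth table ---------------------------------------
# Hand-coded enumeration over MOI x genotype multiset x sex.
oracle_moi <- function(genotypes, moi, sex) {
  n_het <- sum(genotypes == "het")
  n_hom <- sum(genotypes == "hom_alt")
  n_hemi <- sum(genotypes == "hemizygous")
  any_alt <- (n_het + n_hom + n_hemi) > 0
  if (!any_alt || moi == "NA") return(c(FALSE, "incompatible"))
  if (moi == "AD") return(c(TRUE, "ad_het_ok"))
  if (moi == "AR") {
    if (n_hom > 0) return(c(TRUE, "ar_hom_ok"))
    if (n_het > 1) return(c(TRUE, "ar_comphet_ok"))
    if (n_het == 1) return(c(FALSE, "ar_single_het"))
    return(c(FALSE, "incompatible"))
  }
  if (moi == "XLR") {
    if (sex == "M" && n_hemi > 0) return(c(TRUE, "xl_hemi_ok"))
    if (sex == "F" && n_hom > 0) return(c(TRUE, "xl_hemi_ok"))
    return(c(FALSE, "incompatible"))
  }
  # XLD: any alt genotype suffices in either sex
  c(TRUE, "xld_het_ok")
}

# --- report decision rules --------------------------------------------------
# Brute-force re-statement of the group rules (a)-(h); returns NA outcome
# for a group that contributes nothing (benign-only or suppressed finding).
oracle_group_outcome <- function(cls, fit, moi_sat, moi_reason, seg, via) {
  if (cls %in% c("C1", "C2")) return(NA_character_)
  strong <- cls %in% c("C4", "C5", "C3_C4")
  if (seg == "refuted") return("inconclusive")                     # (h)
  if (moi_reason == "ar_single_het") return("inconclusive")        # (e)
  if (strong) {
    if (fit == "full" && moi_sat) return("conclusive")             # (a)
    if (fit == "partial") return("uncertain")                      # (d)
    if (fit == "none") return(NA_character_)   # suppressed, logged
    return("inconclusive")                     # full fit, MOI incompatible
  }
  # leading class C3
  if (fit == "full" && seg == "confirmed") return("conclusive")    # (b)
  if (fit == "full") return("uncertain")                           # (c)
  if (fit == "partial") return("uncertain")
  if (via == "kidneyome") return("inconclusive")                   # (f)
  "inconclusive"
}

oracle_patient_outcome <- function(group_attrs) {
  if (!nrow(group_attrs)) return("inconclusive")                   # (g)
  res <- mapply(oracle_group_outcome, group_attrs$cls, group_attrs$fit,
                group_attrs$moi_sat, group_attrs$moi_reason,
                group_attrs$seg, group_attrs$via)
  res <- res[!is.na(res)]
  if (!length(res)) return("inconclusive")
  ranks <- c(inconclusive = 1, uncertain = 2, conclusive = 3)[res]
  names(which.max(ranks))
}

# build a candidate_bundle group from flat attributes
make_group <- function(cls, fit, moi_sat, moi_reason, seg, via,
                       gene = "G1", n_variants = 1L) {
  vars <- data.frame(
    gene = gene, chrom = "1", pos = seq_len(n_variants) * 100L,
    ref = "A", alt = "G", consequence = "missense", genotype = "het",
    acmg_class = cls, stringsAsFactors = FALSE)
  list(gene = gene, variants = vars, moi = "AD",
       moi_assessment = list(satisfied = moi_sat, reason = moi_reason),
       segregation = list(status = seg, de_novo = FALSE, phase = "unknown"),
       phenotype_fit = fit, found_via = via)
}

random_bundle_attrs <- function(n_groups) {
  data.frame(
    cls = sample(c("C1", "C2", "C3", "C3_C4", "C4", "C5"), n_groups,
                 replace = TRUE, prob = c(.05, .05, .3, .1, .3, .2)),
    fit = sample(c("full", "partial", "none"), n_groups, replace = TRUE),
    moi_reason = sample(c("ad_het_ok", "ar_hom_ok", "ar_comphet_ok",
                          "ar_single_het", "xl_hemi_ok", "xld_het_ok",
                          "incompatible"), n_groups, replace = TRUE),
    seg = sample(c("confirmed", "refuted", "pending", "unavailable"),
                 n_groups, replace = TRUE),
    via = sample(c("subpanel", "kidneyome"), n_groups, replace = TRUE),
    stringsAsFactors = FALSE)
}

attrs_to_bundle <- function(pid, attrs) {
  attrs$moi_sat <- !attrs$moi_reason %in% c("ar_single_het", "incompatible")
  groups <- lapply(seq_len(nrow(attrs)), function(i)
    make_group(attrs$cls[i], attrs$fit[i], attrs$moi_sat[i],
               attrs$moi_reason[i], attrs$seg[i], attrs$via[i],
               gene = paste0("G", i)))
  list(bundle = candidate_bundle(pid, groups), attrs = attrs)
}

# --- filtering conjunction oracle -------------------------------------------
# Re-derives cascade survival as the plain conjunction of the three
# predicates, coded directly from the filtering rules.
oracle_survives <- function(call, panel_genes, max_af = 0.01, min_vaf = 0.2,
                            min_depth = 20) {
  if (!call$gene %in% panel_genes) return(FALSE)
  cnv <- call$consequence %in% c("cnv_del", "cnv_dup")
  csq_ok <- if (call$consequence %in% c("synonymous", "intronic"))
    isTRUE(call$splice_region)
  else call$consequence %in% c("missense", "nonsense", "frameshift",
                               "splicing", "inframe_indel", "cnv_del",
                               "cnv_dup")
  af <- if (is.na(call$pop_af)) 0 else call$pop_af
  qf_ok <- af < max_af &&
    (cnv || (!is.na(call$vaf) && call$vaf >= min_vaf)) &&
    (cnv || (!is.na(call$depth) && call$depth >= min_depth))
  csq_ok && qf_ok
}

random_calls <- function(n, genes = c("AA1", "BB2", "CC3", "DD4")) {
  data.frame(
    patient_id = "PX", chrom = "1", pos = seq_len(n) * 10L, ref = "A",
    alt = "G", gene = sample(genes, n, replace = TRUE),
    consequence = sample(c("missense", "nonsense", "frameshift", "splicing",
                           "synonymous", "intronic", "inframe_indel",
                           "cnv_del", "other"), n, replace = TRUE),
    splice_region = sample(c(TRUE, FALSE), n, replace = TRUE),
    pop_af = sample(c(0, 0.001, 0.009, 0.01, 0.02, NA), n, replace = TRUE),
    vaf = sample(c(0.1, 0.19, 0.2, 0.35, 0.5, 1), n, replace = TRUE),
    depth = sample(c(5, 19, 20, 21, 80), n, replace = TRUE),
    genotype = sample(c("het", "hom_alt"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# --- small VCF fixture -------------------------------------------------------
# Five-record VCF exercising VAF arithmetic, zygosity mapping, the
# sex-aware hemizygous rule, multi-allelic decomposition and symbolic CNVs.
write_tiny_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"g\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"c\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"af\">",
    "##INFO=<ID=SPLICE_REGION,Number=0,Type=Flag,Description=\"s\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    "1\t100\t.\tA\tG\t.\tPASS\tGENE=PKD1;CSQ=missense;AF=0.001\tGT:AD:DP\t0/1:30,28:58\t0/0:40,0:40",
    "2\t200\t.\tC\tT\t.\tPASS\tGENE=NPHS1;CSQ=nonsense;AF=0\tGT:AD:DP\t1/1:0,55:55\t0/1:20,22:42",
    "X\t300\t.\tG\tA\t.\tPASS\tGENE=CLCN5;CSQ=missense;AF=0\tGT:AD:DP\t1:0,60:60\t0/1:25,26:51",
    "3\t400\t.\tA\tG,T\t.\tPASS\tGENE=UMOD,UMOD;CSQ=missense,synonymous;AF=0.002,0.003\tGT:AD:DP\t1/2:2,30,29:61\t0/1:30,31,0:61",
    "5\t500\t.\tN\t<DEL>\t.\tPASS\tGENE=TRPC6\tGT\t0/1\t0/0"),
    path)
}
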