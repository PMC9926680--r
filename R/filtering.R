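## The variant filtering cascade: panel restriction, consequence filter,
## then the rarity / allele-fraction / coverage filter. Boundary semantics
## follow the clinical rule as worded: population frequency strictly below
## 1%, VAF at least 0.2, coverage at least 20 reads.

#' Filtering thresholds
#'
#' Defaults are the clinical thresholds the workflow was defined with:
#' variants are kept when the external population frequency is below 1%, the
#' in-patient allele fraction is at least 0.2 and the site is covered by at
#' least 20 reads; only protein-affecting or splice-affecting consequence
#' classes are retained.
#'
#' @param max_pop_af keep `pop_af < max_pop_af` (strict).
#' @param min_vaf keep `vaf >= min_vaf`.
#' @param min_depth keep `depth >= min_depth` reads.
#' @param retained_consequences consequence classes that always pass the
#'   consequence filter.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(max_pop_af = 0.01, min_vaf = 0.2, min_depth = 20,
                          retained_consequences = c(
                            "missense", "nonsense", "frameshift", "splicing",
                            "inframe_indel", "cnv_del", "cnv_dup")) {
  stopifnot(max_pop_af >= 0, max_pop_af <= 1, min_vaf >= 0, min_vaf <= 1,
            min_depth >= 0)
  structure(list(max_pop_af = max_pop_af, min_vaf = min_vaf,
                 min_depth = min_depth,
                 retained_consequences = retained_consequences),
            class = "filter_config")
}

#' Consequence filter
#'
#' Excludes synonymous variants that do not impact splicing and intronic
#' variants outside the splice region; protein-affecting and splice-affecting
#' classes always pass.
#'
#' @param calls a [variant_calls()] table.
#' @param cfg a [filter_config()].
#' @return logical vector, `TRUE` = pass.
#' @export
consequence_filter <- function(calls, cfg = filter_config()) {
  silent <- calls$consequence %in% c("synonymous", "intronic")
  ifelse(silent, calls$splice_region,
         calls$consequence %in% cfg$retained_consequences)
}

#' Rarity / allele-fraction / coverage filter
#'
#' Pass iff `pop_af < max_pop_af` and `vaf >= min_vaf` and
#' `depth >= min_depth`. An absent (`NA`) population frequency counts as 0:
#' novel variants must pass. CNV records, which have no single-site allele
#' fraction, are exempt from the VAF and depth tests but still obey the
#' frequency test when an AF is available.
#'
#' @inheritParams consequence_filter
#' @return logical vector, `TRUE` = pass.
#' @export
quality_frequency_filter <- function(calls, cfg = filter_config()) {
  if (any(calls$depth < 0, na.rm = TRUE))
    stop("negative read depth")
  af <- ifelse(is.na(calls$pop_af), 0, calls$pop_af)
  rare <- af < cfg$max_pop_af
  cnv <- is_cnv(calls$consequence)
  vaf_ok <- cnv | (!is.na(calls$vaf) & calls$vaf >= cfg$min_vaf)
  depth_ok <- cnv | (!is.na(calls$depth) & calls$depth >= cfg$min_depth)
  rare & vaf_ok & depth_ok
}

#' Run the full filtering cascade for one patient
#'
#' Applies, in order: restriction to the analysis panel, the consequence
#' filter, and the rarity/VAF/coverage filter. Every input variant receives a
#' trace row naming the first filter it failed (or `"pass"`).
#'
#' @param calls a [variant_calls()] table for a single patient.
#' @param panel a `gene_panel`.
#' @param cfg a [filter_config()].
#' @return list with `survivors` (a [variant_calls()] subset) and `trace`
#'   (data.frame `chrom`, `pos`, `ref`, `alt`, `gene`, `first_fail` where
#'   `first_fail` is one of `panel`, `consequence`, `quality_frequency`,
#'   `pass`).
#' @export
run_filter_cascade <- function(calls, panel, cfg = filter_config()) {
  calls <- validate_variant_calls(as.data.frame(calls))
  in_panel <- calls$gene %in% panel$entries$gene
  csq_ok <- consequence_filter(calls, cfg)
  qf_ok <- quality_frequency_filter(calls, cfg)
  first_fail <- rep("pass", nrow(calls))
  first_fail[!qf_ok] <- "quality_frequency"
  first_fail[!csq_ok] <- "consequence"
  first_fail[!in_panel] <- "panel"
  trace <- data.frame(chrom = calls$chrom, pos = calls$pos, ref = calls$ref,
                      alt = calls$alt, gene = calls$gene,
                      first_fail = first_fail, stringsAsFactors = FALSE)
  list(survivors = calls[first_fail == "pass", , drop = FALSE], trace = trace)
}
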