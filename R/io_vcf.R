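## VCF input/output. Reading goes through vcfR; writing is a minimal VCFv4.2
## emitter sufficient for the fields this pipeline carries (GT:AD:DP plus
## GENE/CSQ/AF/SPLICE_REGION INFO keys), so written files re-read losslessly.

#' Read annotated variant calls from a VCF
#'
#' Decomposes multi-allelic records into one row per alternate allele per
#' carrier sample and maps genotypes onto the pipeline vocabulary
#' (het / hom_alt / hemizygous). Samples with homozygous-reference or missing
#' genotypes at a site contribute no row for it.
#'
#' Symbolic alleles `<DEL>` / `<DUP>` become consequence `cnv_del` /
#' `cnv_dup` with `vaf` and `depth` set to `NA` (no meaningful single-site
#' allele fraction).
#'
#' @param path VCF file (plain text or bgzipped).
#' @param sample_map optional named character vector mapping VCF sample names
#'   to patient ids; defaults to the sample names themselves.
#' @param patient_sex optional named character vector (`"F"`/`"M"`) per
#'   patient id, used to call hemizygous genotypes on chrX/chrY in males.
#' @param info_keys names of the INFO keys carrying the annotations; the
#'   population allele frequency key is configurable because the source
#'   database is deployment-specific. An absent AF is read as `NA` and treated
#'   as 0 (novel) by the frequency filter.
#' @return A [variant_calls()] table.
#' @export
read_vcf <- function(path, sample_map = NULL, patient_sex = NULL,
                     info_keys = list(gene = "GENE", consequence = "CSQ",
                                      pop_af = "AF",
                                      splice_region = "SPLICE_REGION")) {
  if (!file.exists(path)) stop("no such VCF: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  if (is.null(sample_map)) sample_map <- stats::setNames(samples, samples)

  info_get <- function(key) {
    if (is.null(key)) return(rep(NA_character_, n))
    vcfR::extract.info(v, element = key)
  }
  gene <- info_get(info_keys$gene)
  csq <- info_get(info_keys$consequence)
  af <- info_get(info_keys$pop_af)
  if (all(is.na(gene)))
    stop("configuration error: INFO key '", info_keys$gene,
         "' (gene symbol) absent from ", path)
  if (all(is.na(csq)))
    stop("configuration error: INFO key '", info_keys$consequence,
         "' (consequence) absent from ", path)
  info_raw <- fix[, "INFO"]
  splice <- grepl(paste0("(^|;)", info_keys$splice_region, "(;|$|=1)"),
                  ifelse(is.na(info_raw), "", info_raw))

  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                 error = function(e) NULL)
  dp <- tryCatch(suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)),
    error = function(e) NULL)

  nth <- function(s, k) {
    # k-th element of a comma-separated annotation, recycled if scalar
    parts <- strsplit(ifelse(is.na(s), "", s), ",", fixed = TRUE)[[1]]
    if (length(parts) >= k) parts[k] else if (length(parts)) parts[1] else NA
  }

  out <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    chrom <- fix[i, "CHROM"]
    rows <- list()
    for (k in seq_along(alts)) {
      alt_k <- alts[k]
      symbolic <- grepl("^<", alt_k)
      for (s in samples) {
        g <- gt[i, s]
        if (is.na(g)) next
        alleles <- strsplit(g, "[/|]")[[1]]
        if (any(alleles == ".")) next
        n_alt <- sum(alleles == as.character(k))
        if (n_alt == 0) next
        pid <- unname(sample_map[s])
        sex <- if (!is.null(patient_sex)) unname(patient_sex[pid]) else NA
        on_xy <- grepl("^(chr)?[XY]$", chrom)
        genotype <-
          if (on_xy && identical(sex, "M")) "hemizygous"
          else if (n_alt >= length(alleles)) {
            if (length(alleles) == 1L) "hemizygous" else "hom_alt"
          } else "het"
        if (symbolic) {
          vaf_k <- NA_real_; dep_k <- NA_real_
        } else {
          ads <- if (!is.null(ad) && !is.na(ad[i, s]))
            suppressWarnings(as.numeric(strsplit(ad[i, s], ",")[[1]]))
          else NULL
          dep_k <- if (!is.null(ads) && !anyNA(ads)) sum(ads)
                   else if (!is.null(dp)) dp[i, s] else NA_real_
          vaf_k <- if (!is.null(ads) && length(ads) > k && dep_k > 0)
            ads[k + 1L] / sum(ads) else NA_real_
        }
        csq_k <- nth(csq[i], k)
        if (symbolic)
          csq_k <- if (alt_k == "<DEL>") "cnv_del" else
                   if (alt_k == "<DUP>") "cnv_dup" else "other"
        af_k <- suppressWarnings(as.numeric(nth(af[i], k)))
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, chrom = chrom, pos = as.integer(fix[i, "POS"]),
          ref = fix[i, "REF"], alt = alt_k, gene = nth(gene[i], k),
          consequence = csq_k, splice_region = splice[i],
          pop_af = af_k, vaf = vaf_k, depth = dep_k, genotype = genotype,
          stringsAsFactors = FALSE
        )
      }
    }
    out[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- variant_calls()
  validate_variant_calls(res)
}

#' Write variant calls as a multi-sample VCF
#'
#' Inverse of [read_vcf()] for the fields the pipeline carries. One VCF record
#' per `(chrom, pos, ref, alt)`; samples not carrying the allele are written
#' homozygous reference. CNV rows become symbolic `<DEL>`/`<DUP>` records.
#'
#' @param calls a [variant_calls()] table.
#' @param path output file.
#' @param info_keys as in [read_vcf()].
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path,
                      info_keys = list(gene = "GENE", consequence = "CSQ",
                                       pop_af = "AF",
                                       splice_region = "SPLICE_REGION")) {
  calls <- validate_variant_calls(as.data.frame(calls))
  samples <- unique(calls$patient_id)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    sprintf("##INFO=<ID=%s,Number=A,Type=String,Description=\"Gene symbol\">",
            info_keys$gene),
    sprintf("##INFO=<ID=%s,Number=A,Type=String,Description=\"Consequence\">",
            info_keys$consequence),
    sprintf(paste0("##INFO=<ID=%s,Number=A,Type=Float,",
                   "Description=\"Population allele frequency\">"),
            info_keys$pop_af),
    sprintf("##INFO=<ID=%s,Number=0,Type=Flag,Description=\"Splice region\">",
            info_keys$splice_region),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
  ord <- order(calls$chrom, calls$pos, calls$ref, calls$alt)
  lines <- character(0)
  for (k in unique(key[ord])) {
    grp <- calls[key == k, , drop = FALSE]
    r <- grp[1, ]
    cnv <- is_cnv(r$consequence)
    alt_out <- if (cnv) {
      if (r$consequence == "cnv_del") "<DEL>" else "<DUP>"
    } else r$alt
    info <- c(
      paste0(info_keys$gene, "=", r$gene),
      if (!cnv) paste0(info_keys$consequence, "=", r$consequence),
      if (!is.na(r$pop_af)) paste0(info_keys$pop_af, "=", r$pop_af),
      if (isTRUE(r$splice_region)) info_keys$splice_region
    )
    cells <- vapply(samples, function(s) {
      row <- grp[grp$patient_id == s, , drop = FALSE]
      if (!nrow(row)) return("0/0:.:.")
      gt <- switch(row$genotype,
                   het = "0/1", hom_alt = "1/1", hemizygous = "1",
                   hom_ref = "0/0", missing = "./.")
      if (is.na(row$depth)) return(paste0(gt, ":.:."))
      alt_reads <- as.integer(round(row$depth * row$vaf))
      ref_reads <- as.integer(round(row$depth)) - alt_reads
      sprintf("%s:%d,%d:%d", gt, ref_reads, alt_reads,
              as.integer(round(row$depth)))
    }, character(1))
    lines <- c(lines, paste(c(r$chrom, r$pos, ".", r$ref, alt_out, ".",
                              "PASS", paste(info, collapse = ";"),
                              "GT:AD:DP", cells), collapse = "\t"))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
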