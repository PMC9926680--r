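## Read-depth CNV calling against a panel-of-normals baseline built from
## CNV-negative patients of both sexes. Depths are median-normalised per
## sample, per-region ratios are taken against the mean of the applicable
## baseline columns (same-sex columns on the sex chromosomes, so a male
## single-copy X is ratio 1.0), and consecutive regions sharing a state are
## merged into one call.

#' Construct a depth matrix
#'
#' @param regions data.frame with columns `gene`, `exon`, `chrom`, `start`,
#'   `end`; sorted by `chrom`, `start` on construction.
#' @param depths numeric matrix, rows = regions, columns = samples (mean read
#'   depth per target region).
#' @param sex named character vector (`"F"`/`"M"`) per sample column.
#' @return list of class `depth_matrix`.
#' @export
depth_matrix <- function(regions, depths, sex) {
  stopifnot(is.data.frame(regions),
            all(c("gene", "exon", "chrom", "start", "end") %in%
                names(regions)),
            nrow(regions) == nrow(depths),
            !is.null(colnames(depths)),
            all(colnames(depths) %in% names(sex)))
  if (any(depths < 0, na.rm = TRUE)) stop("negative depths")
  ord <- order(regions$chrom, regions$start)
  structure(list(regions = regions[ord, , drop = FALSE],
                 depths = depths[ord, , drop = FALSE],
                 sex = sex[colnames(depths)]),
            class = "depth_matrix")
}

.autosomal <- function(chrom) !grepl("^(chr)?[XY]$", chrom)

#' Normalise a depth matrix by per-sample median autosomal depth
#'
#' Each column is divided by its own median depth over autosomal regions, so
#' normalised autosomal medians are 1 and columns are comparable across
#' sequencing runs of different total yield.
#'
#' @param m a [depth_matrix()].
#' @return a `depth_matrix` of normalised depths.
#' @export
normalize_depths <- function(m) {
  stopifnot(inherits(m, "depth_matrix"))
  auto <- .autosomal(m$regions$chrom)
  if (!any(auto)) stop("no autosomal regions to normalise against")
  med <- apply(m$depths[auto, , drop = FALSE], 2, stats::median)
  zero <- med <= 0
  if (any(zero))
    stop("zero median autosomal depth in sample(s): ",
         paste(names(med)[zero], collapse = ", "))
  m$depths <- sweep(m$depths, 2, med, "/")
  m
}

#' Call CNVs for one sample against a normalised baseline
#'
#' Per-region ratio = sample depth / mean of applicable baseline columns. On
#' autosomes every baseline column applies; on chrX/chrY only same-sex
#' columns do, so copy-number expectations hold for either sex. Consecutive
#' regions (same chromosome) sharing a state are merged into one call.
#'
#' @param sample_depths normalised depth vector for the test sample (same
#'   region order as `baseline`).
#' @param baseline a normalised [depth_matrix()] of CNV-negative samples;
#'   must contain at least 2 samples of the test sample's sex for
#'   sex-chromosome calls.
#' @param sample_sex `"F"` or `"M"`.
#' @param thresholds ratio cut-offs: heterozygous deletion at or below
#'   `del_het`, homozygous (complete) deletion at or below `del_hom`,
#'   duplication at or above `dup`. Conventional values 0.7 / 0.1 / 1.3.
#' @return data.frame of calls: `gene`, `chrom`, `start`, `end`, `n_regions`,
#'   `state` (`del_het`/`del_hom`/`dup`), `ratio` (mean over merged regions).
#' @export
call_cnv <- function(sample_depths, baseline, sample_sex,
                     thresholds = c(del_het = 0.7, del_hom = 0.1,
                                    dup = 1.3)) {
  stopifnot(inherits(baseline, "depth_matrix"), sample_sex %in% c("F", "M"))
  reg <- baseline$regions
  if (length(sample_depths) != nrow(reg))
    stop("region mismatch: sample has ", length(sample_depths),
         " regions, baseline ", nrow(reg))
  same_sex <- names(baseline$sex)[baseline$sex == sample_sex]
  if (length(same_sex) < 2 && any(!.autosomal(reg$chrom)))
    stop("fewer than 2 baseline samples of sex ", sample_sex,
         " for sex-chromosome calls")
  if (ncol(baseline$depths) < 2)
    stop("fewer than 2 applicable baseline samples")
  auto <- .autosomal(reg$chrom)
  ref <- numeric(nrow(reg))
  ref[auto] <- rowMeans(baseline$depths[auto, , drop = FALSE])
  if (any(!auto))
    ref[!auto] <- rowMeans(
      baseline$depths[!auto, same_sex, drop = FALSE])
  ratio <- sample_depths / ref
  state <- rep(NA_character_, length(ratio))
  state[ratio >= thresholds[["dup"]]] <- "dup"
  state[ratio <= thresholds[["del_het"]]] <- "del_het"
  state[ratio <= thresholds[["del_hom"]]] <- "del_hom"

  calls <- list()
  i <- 1L
  n <- length(state)
  while (i <= n) {
    if (is.na(state[i])) { i <- i + 1L; next }
    j <- i
    while (j < n && !is.na(state[j + 1L]) && state[j + 1L] == state[i] &&
           reg$chrom[j + 1L] == reg$chrom[i]) j <- j + 1L
    calls[[length(calls) + 1L]] <- data.frame(
      gene = reg$gene[i], chrom = reg$chrom[i], start = reg$start[i],
      end = reg$end[j], n_regions = j - i + 1L, state = state[i],
      ratio = mean(ratio[i:j]), stringsAsFactors = FALSE)
    i <- j + 1L
  }
  if (!length(calls))
    return(data.frame(gene = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_regions = integer(), state = character(),
                      ratio = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, calls)
}

#' Convert CNV calls to variant-call records
#'
#' Lets depth-based CNV events flow through the same classification and
#' reporting path as small variants: deletions become consequence `cnv_del`,
#' duplications `cnv_dup`, with `vaf`/`depth` not applicable.
#'
#' @param cnv_calls output of [call_cnv()].
#' @param patient_id patient the calls belong to.
#' @return a [variant_calls()] table.
#' @export
cnv_to_variant_calls <- function(cnv_calls, patient_id) {
  if (!nrow(cnv_calls)) return(variant_calls())
  variant_calls(
    patient_id = patient_id, chrom = cnv_calls$chrom, pos = cnv_calls$start,
    ref = "N",
    alt = ifelse(cnv_calls$state == "dup", "<DUP>", "<DEL>"),
    gene = cnv_calls$gene,
    consequence = ifelse(cnv_calls$state == "dup", "cnv_dup", "cnv_del"),
    splice_region = FALSE, pop_af = NA_real_, vaf = NA_real_,
    depth = NA_real_,
    genotype = ifelse(cnv_calls$state == "del_hom", "hom_alt", "het"))
}

#' Write / read a depth matrix as TSV
#'
#' Region columns first, then one numeric column per sample; sample sexes are
#' stored on a `#sex:` header line.
#'
#' @param m a [depth_matrix()].
#' @param path TSV file.
#' @return `path` (write) or a `depth_matrix` (read).
#' @export
write_depth_matrix <- function(m, path) {
  stopifnot(inherits(m, "depth_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#sex:", paste(names(m$sex), m$sex, sep = "=",
                                   collapse = ",")), con)
  utils::write.table(cbind(m$regions, as.data.frame(m$depths)), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_matrix
#' @export
read_depth_matrix <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#sex:")) stop("missing #sex: header in ", path)
  pairs <- strsplit(strsplit(sub("^#sex:", "", first), ",")[[1]], "=")
  sex <- stats::setNames(vapply(pairs, `[`, "", 2),
                         vapply(pairs, `[`, "", 1))
  tab <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE)
  region_cols <- c("gene", "exon", "chrom", "start", "end")
  depth_matrix(tab[, region_cols],
               as.matrix(tab[, setdiff(names(tab), region_cols),
                             drop = FALSE]), sex)
}
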