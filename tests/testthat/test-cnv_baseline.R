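mk_matrix <- function(n_samples = 6, depth = 100, seed = NULL, sd = 0,
                      x_regions = TRUE) {
  regions <- data.frame(
    gene = rep(c("PAX2", "HNF1B", if (x_regions) "COL4A5"),
               each = 4)[1:(if (x_regions) 12 else 8)],
    exon = rep(1:4, if (x_regions) 3 else 2),
    chrom = rep(c("10", "17", if (x_regions) "X"), each = 4),
    start = seq(1000, by = 500,
                length.out = if (x_regions) 12 else 8),
    end = seq(1400, by = 500, length.out = if (x_regions) 12 else 8),
    stringsAsFactors = FALSE)
  sex <- stats::setNames(rep(c("F", "M"), length.out = n_samples),
                         paste0("N", seq_len(n_samples)))
  if (!is.null(seed)) set.seed(seed)
  d <- matrix(depth, nrow(regions), n_samples,
              dimnames = list(NULL, names(sex)))
  # males carry one X: halve their X coverage like real data
  if (x_regions)
    d[regions$chrom == "X", sex == "M"] <-
      d[regions$chrom == "X", sex == "M"] / 2
  if (sd > 0) d <- d * matrix(stats::rnorm(length(d), 1, sd), nrow(d))
  depth_matrix(regions, d, sex)
}

test_that("normalisation is scale-invariant with unit autosomal medians", {
  m <- mk_matrix()
  m$depths[, "N3"] <- m$depths[, "N3"] * 2   # a sample sequenced deeper
  norm <- normalize_depths(m)
  auto <- !grepl("X", norm$regions$chrom)
  expect_equal(unname(apply(norm$depths[auto, ], 2, median)),
               rep(1, ncol(norm$depths)))
  # N1 and N3 are both female; scaling cancels out entirely
  expect_equal(norm$depths[, "N1"], norm$depths[, "N3"])

  bad <- mk_matrix()
  bad$depths[, "N3"] <- 0
  expect_error(normalize_depths(bad), "N3")
})

test_that("a clean sample against a clean baseline yields no calls", {
  base <- normalize_depths(mk_matrix(n_samples = 5))
  smp <- normalize_depths(mk_matrix(n_samples = 5))$depths[, 1]
  expect_equal(nrow(call_cnv(smp, base, "F")), 0L)
  # with baseline-level noise the specificity must hold too
  set.seed(9)
  basen <- normalize_depths(mk_matrix(n_samples = 5, sd = 0.05, seed = 1))
  smpn <- normalize_depths(mk_matrix(n_samples = 5, sd = 0.05,
                                     seed = 2))$depths[, "N1"]
  expect_equal(nrow(call_cnv(smpn, basen, "F")), 0L)
})

test_that("injected events are recovered exactly on noise-free matrices", {
  base <- normalize_depths(mk_matrix(n_samples = 5))
  smp <- normalize_depths(mk_matrix(n_samples = 5))$depths[, 1]
  reg <- base$regions
  # three consecutive exons of PAX2 at half dose -> one het deletion call
  del_idx <- which(reg$gene == "PAX2")[1:3]
  smp_del <- smp; smp_del[del_idx] <- smp_del[del_idx] * 0.5
  calls <- call_cnv(smp_del, base, "F")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$state, "del_het")
  expect_equal(calls$gene, "PAX2")
  expect_equal(calls$n_regions, 3L)
  expect_equal(calls$ratio, 0.5, tolerance = 1e-9)
  # single-exon duplication and complete deletion
  smp_mix <- smp
  smp_mix[which(reg$gene == "HNF1B")[2]] <- smp[which(reg$gene ==
                                                        "HNF1B")[2]] * 1.5
  smp_mix[which(reg$gene == "HNF1B")[4]] <- 0
  calls <- call_cnv(smp_mix, base, "F")
  expect_setequal(calls$state, c("dup", "del_hom"))
  expect_true(all(calls$n_regions == 1L))
})

test_that("sex chromosomes are compared against a same-sex baseline", {
  base <- normalize_depths(mk_matrix(n_samples = 6))
  male <- normalize_depths(mk_matrix(n_samples = 6))$depths[, 2]  # N2 is M
  # an unremarkable male X must NOT look like a deletion
  expect_equal(nrow(call_cnv(male, base, "M")), 0L)
  # losing his single X copy halves the male ratio against male baseline
  reg <- base$regions
  xi <- which(reg$chrom == "X")
  male_del <- male; male_del[xi] <- male[xi] * 0.5
  calls <- call_cnv(male_del, base, "M")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$state, "del_het")
  expect_equal(calls$chrom, "X")
})

test_that("structural errors are reported before calling", {
  base <- normalize_depths(mk_matrix(n_samples = 5))
  expect_error(call_cnv(c(1, 1), base, "F"), "region mismatch")
  one <- mk_matrix(n_samples = 2)
  one$depths <- one$depths[, 1, drop = FALSE]
  one$sex <- one$sex[1]
  expect_error(call_cnv(rep(1, 12), normalize_depths(one), "F"),
               "fewer than 2")
})

test_that("CNV calls convert to variant records and depth TSV round-trips", {
  calls <- data.frame(gene = "PAX2", chrom = "10", start = 1000L,
                      end = 2400L, n_regions = 3L, state = "del_het",
                      ratio = 0.5, stringsAsFactors = FALSE)
  vc <- cnv_to_variant_calls(calls, "P1")
  expect_equal(vc$consequence, "cnv_del")
  expect_equal(vc$genotype, "het")
  expect_true(is.na(vc$vaf))

  m <- mk_matrix(n_samples = 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_depth_matrix(m, tsv)
  back <- read_depth_matrix(tsv)
  expect_equal(back$regions, m$regions, ignore_attr = TRUE)
  expect_equal(unname(back$depths), unname(m$depths))
  expect_equal(back$sex, m$sex)
})
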