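mk_call <- function(consequence = "missense", splice_region = FALSE,
                    pop_af = 0, vaf = 0.5, depth = 60, gene = "PKD1") {
  data.frame(patient_id = "P1", chrom = "1", pos = 1L, ref = "A", alt = "G",
             gene = gene, consequence = consequence,
             splice_region = splice_region, pop_af = pop_af, vaf = vaf,
             depth = depth, genotype = "het", stringsAsFactors = FALSE)
}

test_that("silent variants are excluded unless they touch the splice region", {
  cfg <- filter_config()
  expect_false(consequence_filter(mk_call("synonymous", FALSE), cfg))
  expect_true(consequence_filter(mk_call("synonymous", TRUE), cfg))
  expect_false(consequence_filter(mk_call("intronic", FALSE), cfg))
  expect_true(consequence_filter(mk_call("intronic", TRUE), cfg))
  for (csq in c("missense", "nonsense", "frameshift", "splicing"))
    expect_true(consequence_filter(mk_call(csq), cfg))
  expect_false(consequence_filter(mk_call("other"), cfg))
})

test_that("frequency, VAF and depth thresholds use the stated boundaries", {
  cfg <- filter_config()
  expect_false(quality_frequency_filter(mk_call(pop_af = 0.02), cfg))
  # strictly below 1%: exactly 1% fails
  expect_false(quality_frequency_filter(mk_call(pop_af = 0.01), cfg))
  expect_true(quality_frequency_filter(mk_call(pop_af = 0.009), cfg))
  # absent AF is a novel variant and must pass
  expect_true(quality_frequency_filter(mk_call(pop_af = NA), cfg))
  # VAF at least 0.2: 0.19 fails even at high depth, 0.2 passes
  expect_false(quality_frequency_filter(
    mk_call(vaf = 0.19, depth = 100, pop_af = 0), cfg))
  expect_true(quality_frequency_filter(mk_call(vaf = 0.2), cfg))
  # depth boundary inclusive at 20
  expect_true(quality_frequency_filter(
    mk_call(vaf = 0.5, depth = 20, pop_af = 0.005), cfg))
  expect_false(quality_frequency_filter(mk_call(depth = 19), cfg))
  expect_error(quality_frequency_filter(mk_call(depth = -1), cfg),
               "negative")
})

test_that("CNV records bypass VAF/depth but still obey the frequency rule", {
  cfg <- filter_config()
  cnv <- mk_call("cnv_del", vaf = NA, depth = NA)
  expect_true(quality_frequency_filter(cnv, cfg))
  cnv$pop_af <- 0.05
  expect_false(quality_frequency_filter(cnv, cfg))
  cnv$pop_af <- NA
  expect_true(quality_frequency_filter(cnv, cfg))
})

test_that("cascade keeps exactly the calls designed to pass, with a trace", {
  cil <- Filter(function(p) p$category == "ciliopathy", demo_registry())[[1]]
  calls <- rbind(
    mk_call(),                                    # pass
    mk_call("splicing", TRUE, pop_af = 0.005),    # pass
    mk_call("cnv_dup", vaf = NA, depth = NA),     # pass
    mk_call(gene = "NOTINPANEL"),                 # fails panel
    mk_call("synonymous"),                        # fails consequence
    mk_call(pop_af = 0.02),                       # fails frequency
    mk_call(vaf = 0.1),                           # fails VAF
    mk_call(depth = 10),                          # fails depth
    mk_call("intronic", FALSE),                   # fails consequence
    mk_call("synonymous", FALSE, pop_af = 0.5))   # consequence before quality
  calls$pos <- seq_len(nrow(calls)) * 10L
  res <- run_filter_cascade(validate_variant_calls(calls), cil)
  expect_equal(nrow(res$survivors), 3L)
  expect_equal(res$survivors$pos, c(10L, 20L, 30L))
  expect_equal(res$trace$first_fail,
               c("pass", "pass", "pass", "panel", "consequence",
                 "quality_frequency", "quality_frequency",
                 "quality_frequency", "consequence", "consequence"))
  # idempotence / permutation invariance of the survivor set
  res2 <- run_filter_cascade(validate_variant_calls(calls), cil)
  expect_identical(res$survivors, res2$survivors)
  shuffled <- validate_variant_calls(calls[sample(nrow(calls)), ])
  res3 <- run_filter_cascade(shuffled, cil)
  expect_setequal(res3$survivors$pos, res$survivors$pos)
})

test_that("cascade equals the conjunction-of-predicates oracle", {
  set.seed(101)
  panel <- gene_panel("t", "other",
                      data.frame(gene = c("AA1", "BB2"), moi = "AD",
                                 chromosome = "1"))
  calls <- random_calls(400)
  calls <- validate_variant_calls(calls)
  got <- run_filter_cascade(calls, panel)$trace$first_fail == "pass"
  want <- vapply(seq_len(nrow(calls)), function(i)
    oracle_survives(calls[i, ], c("AA1", "BB2")), logical(1))
  expect_equal(got, want)
})

test_that("relaxing any threshold never shrinks the survivor set", {
  set.seed(202)
  panel <- gene_panel("t", "other",
                      data.frame(gene = c("AA1", "BB2", "CC3"), moi = "AD",
                                 chromosome = "1"))
  calls <- validate_variant_calls(random_calls(200))
  for (rep in 1:10) {
    af <- stats::runif(1, 0.001, 0.05)
    vaf <- stats::runif(1, 0.05, 0.5)
    dp <- sample(5:40, 1)
    tight <- run_filter_cascade(calls, panel,
                                filter_config(af, vaf, dp))$survivors
    relaxed <- run_filter_cascade(calls, panel,
      filter_config(min(af * 2, 1), vaf / 2, max(dp - 10, 0)))$survivors
    expect_true(all(tight$pos %in% relaxed$pos))
  }
})
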