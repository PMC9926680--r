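test_that("each decision rule produces its documented outcome", {
  run <- function(...) {
    b <- candidate_bundle("P1", list(make_group(...)))
    o <- classify_report(b)
    c(o$outcome, o$reasons[1])
  }
  # (a) class 4/5 fitting the phenotype with a satisfied inheritance model
  expect_equal(run("C5", "full", TRUE, "ad_het_ok", "confirmed", "subpanel"),
               c("conclusive", "c45_phenotype_moi"))
  expect_equal(run("C4", "full", TRUE, "ar_hom_ok", "unavailable",
                   "subpanel"),
               c("conclusive", "c45_phenotype_moi"))
  expect_equal(run("C3_C4", "full", TRUE, "ar_comphet_ok", "confirmed",
                   "subpanel"),
               c("conclusive", "c45_phenotype_moi"))
  # (b) VUS, full fit, segregation confirmed
  expect_equal(run("C3", "full", TRUE, "ad_het_ok", "confirmed", "subpanel"),
               c("conclusive", "c3_segregation_confirmed"))
  # (c) VUS, full fit, segregation not (yet) available
  expect_equal(run("C3", "full", TRUE, "ad_het_ok", "pending", "subpanel"),
               c("uncertain", "c3_segregation_pending"))
  expect_equal(run("C3", "full", TRUE, "ad_het_ok", "unavailable",
                   "subpanel"),
               c("uncertain", "c3_segregation_pending"))
  # (d) class 4/5 only partially matching the phenotype
  expect_equal(run("C4", "partial", TRUE, "ad_het_ok", "confirmed",
                   "subpanel"),
               c("uncertain", "c45_phenotype_partial"))
  # (e) single heterozygous variant in a recessive gene
  expect_equal(run("C4", "full", FALSE, "ar_single_het", "unavailable",
                   "subpanel"),
               c("inconclusive", "single_het_recessive"))
  # (f) kidneyome-only VUS not matching the phenotype
  expect_equal(run("C3", "none", TRUE, "ad_het_ok", "unavailable",
                   "kidneyome"),
               c("inconclusive", "c3_kidneyome_phenotype_mismatch"))
  # (h) refuted segregation sinks the group whatever the class
  expect_equal(run("C5", "full", TRUE, "ar_comphet_ok", "refuted",
                   "subpanel"),
               c("inconclusive", "segregation_refuted"))
})

test_that("an empty bundle is a negative analysis", {
  o <- classify_report(candidate_bundle("P9"))
  expect_equal(o$outcome, "inconclusive")
  expect_equal(o$reasons, "no_variants")
  expect_equal(nrow(o$reported_variants), 0L)
})

test_that("benign-only and suppressed findings contribute no outcome", {
  b <- candidate_bundle("P1", list(
    make_group("C2", "full", TRUE, "ad_het_ok", "unavailable", "subpanel")))
  o <- classify_report(b)
  expect_equal(o$outcome, "inconclusive")
  expect_true("no_reportable_variants" %in% o$reasons)
  # class 5 with no phenotype fit is suppressed and logged, not reported
  b2 <- candidate_bundle("P2", list(
    make_group("C5", "none", TRUE, "ad_het_ok", "unavailable", "subpanel")))
  o2 <- classify_report(b2)
  expect_equal(o2$outcome, "inconclusive")
  expect_true("suppressed_incidental" %in% o2$reasons)
})

test_that("patient outcome takes precedence across gene groups", {
  concl <- make_group("C5", "full", TRUE, "ad_het_ok", "unavailable",
                      "subpanel", gene = "G1")
  unc <- make_group("C3", "full", TRUE, "ad_het_ok", "pending", "subpanel",
                    gene = "G2")
  inc <- make_group("C4", "full", FALSE, "ar_single_het", "unavailable",
                    "subpanel", gene = "G3")
  o <- classify_report(candidate_bundle("P1", list(inc, unc, concl)))
  expect_equal(o$outcome, "conclusive")
  expect_equal(o$reasons, "c45_phenotype_moi")
  expect_setequal(o$secondary_reasons,
                  c("c3_segregation_pending", "single_het_recessive"))
  # only the conclusive group's variants are reported as causative
  expect_equal(unique(o$reported_variants$gene), "G1")

  # adding a conclusive-qualifying group never downgrades
  set.seed(33)
  for (i in 1:50) {
    attrs <- random_bundle_attrs(sample(1:3, 1))
    base <- attrs_to_bundle("PX", attrs)$bundle
    more <- candidate_bundle("PX", c(base$groups, list(concl)))
    expect_equal(classify_report(more)$outcome, "conclusive")
  }
})

test_that("classifier agrees with a brute-force oracle on random bundles", {
  set.seed(77)
  for (i in 1:500) {
    attrs <- random_bundle_attrs(sample(0:3, 1))
    built <- attrs_to_bundle("PX", attrs)
    got <- classify_report(built$bundle)$outcome
    want <- oracle_patient_outcome(built$attrs)
    expect_equal(got, want, label = paste("bundle", i))
    # determinism
    expect_equal(classify_report(built$bundle)$outcome, got)
  }
})

test_that("invalid enum values are rejected at bundle construction", {
  g <- make_group("C4", "full", TRUE, "ad_het_ok", "confirmed", "subpanel")
  g$phenotype_fit <- "excellent"
  expect_error(candidate_bundle("P1", list(g)), "phenotype_fit")
  g <- make_group("C4", "full", TRUE, "ad_het_ok", "confirmed", "subpanel")
  g$variants$acmg_class <- "C7"
  expect_error(candidate_bundle("P1", list(g)), "ACMG class")
  g <- make_group("C4", "full", TRUE, "ad_het_ok", "maybe", "subpanel")
  expect_error(candidate_bundle("P1", list(g)), "segregation")
})

test_that("outcome_reasons exposes primary and secondary codes", {
  concl <- make_group("C5", "full", TRUE, "ad_het_ok", "unavailable",
                      "subpanel", gene = "G1")
  inc <- make_group("C4", "full", FALSE, "ar_single_het", "unavailable",
                    "subpanel", gene = "G2")
  r <- outcome_reasons(candidate_bundle("P1", list(concl, inc)))
  expect_equal(r$outcome, "conclusive")
  expect_equal(r$primary, "c45_phenotype_moi")
  expect_equal(r$secondary, "single_het_recessive")
})
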