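test_that("MOI assessment matches the exhaustive truth-table oracle", {
  gts <- c("het", "hom_alt", "hemizygous", "hom_ref")
  multisets <- c(
    lapply(gts, identity),
    unlist(lapply(gts, function(a) lapply(gts, function(b) c(a, b))),
           recursive = FALSE),
    list(c("het", "het", "het"), c("het", "hom_alt", "het"),
         c("hom_ref", "hom_ref")))
  for (moi in c("AD", "AR", "XLD", "XLR", "NA"))
    for (sex in c("F", "M"))
      for (gs in multisets) {
        got <- assess_moi(gs, moi, sex)
        want <- oracle_moi(gs, moi, sex)
        lbl <- paste(moi, sex, paste(gs, collapse = "+"))
        expect_equal(got$satisfied, as.logical(want[1]), label = lbl)
        expect_equal(got$reason, want[2], label = lbl)
      }
})

test_that("single het in a recessive gene is flagged and never satisfied", {
  a <- assess_moi("het", "AR", "F")
  expect_false(a$satisfied)
  expect_equal(a$reason, "ar_single_het")
})

v_row <- function(genotype = "het", m = NA, f = NA, md = NA_real_,
                  fd = NA_real_)
  data.frame(genotype = genotype, mother_gt = m, father_gt = f,
             mother_depth = md, father_depth = fd, stringsAsFactors = FALSE)

test_that("de novo detection requires confident biparental reference", {
  expect_true(detect_de_novo(v_row(m = "hom_ref", f = "hom_ref",
                                   md = 50, fd = 50)))
  expect_false(detect_de_novo(v_row(m = "hom_ref", f = "het",
                                    md = 50, fd = 50)))
  # low parental coverage: origin unresolvable, not a de novo call
  expect_true(is.na(detect_de_novo(v_row(m = "hom_ref", f = "hom_ref",
                                         md = 5, fd = 50))))
  expect_true(is.na(detect_de_novo(v_row())))
  # never TRUE when any parent carries the allele, at any depth
  for (g in c("het", "hom_alt", "hemizygous")) {
    expect_false(detect_de_novo(v_row(m = g, f = "hom_ref", md = 100,
                                      fd = 100)))
    expect_false(detect_de_novo(v_row(m = "hom_ref", f = g, md = 100,
                                      fd = 100)))
  }
})

test_that("compound-het phasing enumerates parental carriage symmetrically", {
  states <- c("het", "hom_ref", NA)
  expected <- function(m1, f1, m2, f2) {
    if (anyNA(c(m1, f1, m2, f2))) return("unknown")
    c1m <- m1 == "het"; c1f <- f1 == "het"
    c2m <- m2 == "het"; c2f <- f2 == "het"
    if ((c1m && !c1f && c2f && !c2m) || (c1f && !c1m && c2m && !c2f))
      "trans"
    else if ((c1m && !c1f && c2m && !c2f) || (c1f && !c1m && c2f && !c2m))
      "cis"
    else "unknown"
  }
  for (m1 in states) for (f1 in states) for (m2 in states) for (f2 in states) {
    v1 <- v_row(m = m1, f = f1, md = 60, fd = 60)
    v2 <- v_row(m = m2, f = f2, md = 60, fd = 60)
    lbl <- paste(m1, f1, m2, f2)
    expect_equal(phase_compound_het(v1, v2), expected(m1, f1, m2, f2),
                 label = lbl)
    # symmetry in the pair
    expect_equal(phase_compound_het(v1, v2), phase_compound_het(v2, v1),
                 label = paste("sym", lbl))
  }
  # variant present in both parents is unresolvable
  v1 <- v_row(m = "het", f = "het", md = 60, fd = 60)
  v2 <- v_row(m = "hom_ref", f = "het", md = 60, fd = 60)
  expect_equal(phase_compound_het(v1, v2), "unknown")
})

trio <- list(mother_id = "M1", father_id = "F1")

test_that("segregation evaluation covers the canonical trio configurations", {
  # AR homozygote with both parents het
  hom <- v_row("hom_alt", m = "het", f = "het", md = 60, fd = 60)
  expect_equal(evaluate_segregation(hom, "AR", "F", trio)$status, "confirmed")
  # a confidently reference parent refutes the biparental model
  bad <- v_row("hom_alt", m = "hom_ref", f = "het", md = 60, fd = 60)
  expect_equal(evaluate_segregation(bad, "AR", "F", trio)$status, "refuted")
  # compound het in trans vs cis
  trans <- rbind(v_row(m = "het", f = "hom_ref", md = 60, fd = 60),
                 v_row(m = "hom_ref", f = "het", md = 60, fd = 60))
  r <- evaluate_segregation(trans, "AR", "F", trio)
  expect_equal(r$status, "confirmed")
  expect_equal(r$phase, "trans")
  cis <- rbind(v_row(m = "het", f = "hom_ref", md = 60, fd = 60),
               v_row(m = "het", f = "hom_ref", md = 60, fd = 60))
  r <- evaluate_segregation(cis, "AR", "F", trio)
  expect_equal(r$status, "refuted")
  expect_equal(r$phase, "cis")
  # de novo dominant
  dn <- v_row(m = "hom_ref", f = "hom_ref", md = 60, fd = 60)
  r <- evaluate_segregation(dn, "AD", "M", trio)
  expect_equal(r$status, "confirmed")
  expect_true(r$de_novo)
  # inherited dominant from a carrier parent (complete penetrance assumed)
  inh <- v_row(m = "het", f = "hom_ref", md = 60, fd = 60)
  expect_equal(evaluate_segregation(inh, "AD", "M", trio)$status,
               "confirmed")
  # X-linked: carrier mother confirms; father-only carriage refutes in a son
  xl <- v_row("hemizygous", m = "het", f = "hom_ref", md = 60, fd = 60)
  expect_equal(evaluate_segregation(xl, "XLR", "M", trio)$status,
               "confirmed")
  xbad <- v_row("hemizygous", m = "hom_ref", f = "hemizygous", md = 60,
                fd = 60)
  expect_equal(evaluate_segregation(xbad, "XLR", "M", trio)$status,
               "refuted")
})

test_that("absent parental data distinguishes pending from unavailable", {
  v <- v_row()
  expect_equal(evaluate_segregation(v, "AD", "F", trio)$status, "pending")
  expect_equal(evaluate_segregation(v, "AD", "F", NULL)$status,
               "unavailable")
  no_parents <- list(mother_id = NA, father_id = NA)
  expect_equal(evaluate_segregation(v, "AD", "F", no_parents)$status,
               "unavailable")
})
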