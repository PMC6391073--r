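ref_ids <- c("Q55806", "P72587", "P73505", "Q59978")

# small matrix with the default reference set and one anchor
quant_matrix <- function(scale = rep(1, 6)) {
  ids <- c(ref_ids, "ANCHOR", "X1", "X2")
  base <- c(5, 4, 3, 2, 1, 0.5, 0.25) * 1e6
  ibaq <- outer(base, scale)
  rownames(ibaq) <- ids
  tiny_matrix(lfq = ibaq, ibaq = ibaq, groups = c("lo", "hi"), reps = 3,
              ids = ids)
}

test_that("iBAQ reference normalization is scale-invariant and idempotent", {
  im <- quant_matrix()
  spec <- calibration_spec(anchor_id = "ANCHOR", cells_per_volume = 1e5)
  norm1 <- normalize_ibaq(im, spec)
  expect_equal(unname(colSums(norm1$ibaq[ref_ids, ])), rep(1, 6))
  # rescaling one sample does not change the normalized values
  im2 <- quant_matrix(scale = c(10, 1, 1, 1, 1, 1))
  norm2 <- normalize_ibaq(im2, spec)
  expect_equal(norm2$ibaq, norm1$ibaq)
  # idempotence
  expect_equal(normalize_ibaq(norm1, spec)$ibaq, norm1$ibaq)
  # a missing reference intensity names the offending sample
  im3 <- quant_matrix()
  im3$ibaq[ref_ids[1], 2] <- NA
  expect_error(normalize_ibaq(im3, spec), "lo_2")
})

test_that("absolute calibration is linear and matches the closed form", {
  im <- normalize_ibaq(quant_matrix(),
                       calibration_spec(anchor_id = "ANCHOR",
                                        cells_per_volume = 1e5))
  spec1 <- calibration_spec(anchor_id = "ANCHOR", anchor_amount = 104,
                            cells_per_volume = 1e5)
  spec2 <- calibration_spec(anchor_id = "ANCHOR", anchor_amount = 208,
                            cells_per_volume = 1e5)
  spec3 <- calibration_spec(anchor_id = "ANCHOR", anchor_amount = 104,
                            cells_per_volume = 2e5)
  c1 <- calibrate_absolute(im, spec1)
  expect_equal(calibrate_absolute(im, spec2)$copies_per_cell,
               2 * c1$copies_per_cell)
  expect_equal(calibrate_absolute(im, spec3)$copies_per_cell,
               c1$copies_per_cell / 2)
  # anchor copies: amount (fmol/uL) * molecules per fmol / cells per uL
  anchor_mean <- mean(im$ibaq["ANCHOR", ])
  got <- mean(c1$copies_per_cell[c1$protein_id == "ANCHOR"])
  expect_equal(got, 104 * 6.02214076e8 / 1e5)
})

test_that("planted copy numbers round-trip through normalization + calibration", {
  set.seed(9)
  copies_true <- c(setNames(c(2e5, 1.5e5, 1e5, 5e4), ref_ids),
                   ANCHOR = 3e4, X1 = 1e4, X2 = 2e3)
  cells <- 2e5
  sample_scale <- rlnorm(6, 0, 0.4)
  ibaq <- outer(copies_true, sample_scale)
  im <- tiny_matrix(lfq = ibaq, ibaq = ibaq, groups = c("lo", "hi"),
                    reps = 3, ids = names(copies_true))
  # the anchor's true amount in fmol/uL consistent with copies_true
  anchor_fmol <- 3e4 * cells / 6.02214076e8
  spec <- calibration_spec(anchor_id = "ANCHOR", anchor_amount = anchor_fmol,
                           cells_per_volume = cells)
  cal <- calibrate_absolute(normalize_ibaq(im, spec), spec)
  got <- tapply(cal$copies_per_cell, cal$protein_id, mean)
  expect_equal(as.numeric(got[names(copies_true)]), unname(copies_true),
               tolerance = 1e-6)
})

test_that("stoichiometry grammar parses complex formulas", {
  rub <- parse_stoichiometry("(RbcL, RbcS)8")
  expect_equal(rub$subunits, c(RbcL = 8L, RbcS = 8L))
  expect_equal(parse_stoichiometry("TufA")$subunits, c(TufA = 1L))
  psa <- parse_stoichiometry("(PsaA,B,C,D,E,F,I,J,K,L,M,X)3")
  expect_identical(length(psa$subunits), 12L)
  expect_true(all(psa$subunits == 3L))
  expect_identical(names(psa$subunits)[1:3], c("PsaA", "PsaB", "PsaC"))
  pbs <- parse_stoichiometry("((CpcA,B)18,C1,C2,D,G)6")
  expect_equal(pbs$subunits[c("CpcA", "CpcB", "CpcC1", "CpcG")],
               c(CpcA = 108L, CpcB = 108L, CpcC1 = 6L, CpcG = 6L))
  rps <- parse_stoichiometry("Rps1A,1B,B,C")
  expect_identical(names(rps$subunits), c("Rps1A", "Rps1B", "RpsB", "RpsC"))
  expect_error(parse_stoichiometry("(RbcL, RbcS"), "parentheses")
  expect_error(parse_stoichiometry("Rbc$L"), "parse")
})

test_that("the packaged complex library parses completely", {
  lib <- read_complex_library(system.file("extdata", "complex_library.tsv",
                                          package = "cyanogrowth"))
  expect_gt(length(lib), 30)
  expect_equal(lib[["RuBisCO"]]$subunits, c(RbcL = 8L, RbcS = 8L))
  ps2 <- lib[["Photosystem II"]]$subunits
  expect_equal(unname(ps2["PsbA1"]), 2L)
  expect_equal(unname(ps2["Ycf12"]), 2L)
  expect_equal(lib[["Chaperonine GroEL"]]$subunits, c(GroL1 = 14L))
})

test_that("complex copy numbers combine subunits by stoichiometry", {
  mono <- parse_stoichiometry("PetE")
  expect_equal(complex_copy_number(c(PetE = 17000), mono)$copies, 17000)
  dimer <- parse_stoichiometry("(SodB)2")
  expect_equal(complex_copy_number(c(SodB = 30000), dimer)$copies, 15000)
  # heterotrimer with stoichiometry (1, 1, 2)
  tri <- parse_stoichiometry("(A1),(B1),(C1)2", name = "tri")
  cc <- complex_copy_number(c(A1 = 1000, B1 = 1200, C1 = 2200), tri)
  expect_equal(cc$copies, 1100)
  expect_equal(cc$copies_min, 1000)
  expect_equal(cc$copies_max, 1200)
  # weighted estimate always lies between the per-subunit bounds
  set.seed(3)
  for (i in 1:10) {
    s <- sample(1:4, 3, replace = TRUE)
    cx <- structure(list(name = "r", subunits = setNames(s, c("u", "v", "w"))),
                    class = "complex_definition")
    cp <- setNames(runif(3, 100, 1e4), c("u", "v", "w"))
    est <- complex_copy_number(cp, cx)
    expect_gte(est$copies, est$copies_min - 1e-9)
    expect_lte(est$copies, est$copies_max + 1e-9)
  }
  # missing subunits are listed; fully missing yields NA
  part <- complex_copy_number(c(A1 = 1000), tri)
  expect_identical(part$n_subunits_quantified, 1L)
  expect_match(part$missing_subunits, "B1")
  none <- complex_copy_number(c(Z = 1), tri)
  expect_true(is.na(none$copies))
})
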