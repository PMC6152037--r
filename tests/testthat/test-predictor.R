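test_that("worked predictions equal the hand-summed table contributions", {
  ## frozen oracles: sums of the transcribed contributions
  expect_equal(predictDescriptor(ref_by_name("ethanol")$graph,
                                 all_tables$dHvap)@value,
               8.61 + 3.07 + 15.79 + 14.55)            # 42.02 kJ/mol
  expect_equal(predictDescriptor(ref_by_name("benzene")$graph,
                                 all_tables$dHvap)@value,
               8.61 + 6 * 4.64 + 6 * (-0.07))          # 36.03 kJ/mol
  expect_equal(predictDescriptor(ref_by_name("cyclohexane")$graph,
                                 all_tables$dSfus)@value,
               31.12 + 6 * 8.46 + 6 * (-4.42))         # 55.36 J/mol/K
  expect_equal(predictDescriptor(ref_by_name("ethanol")$graph,
                                 all_tables$dHsolv)@value,
               -13.33 - 4.44 - 15.26 - 17.23)          # -50.26 kJ/mol
})

test_that("predictions equal the reference oracle bit-exactly across the library", {
  for (m in ref_lib) for (d in names(all_tables)) {
    want <- referenceExpectedValue(m, all_tables[[d]])
    got <- predictDescriptor(m$graph, all_tables[[d]])
    if (is.na(want)) {
      expect_false(got@predictable, label = paste(m$name, d))
      expect_true(length(got@missing) > 0L, label = paste(m$name, d))
    } else {
      expect_true(got@predictable, label = paste(m$name, d))
      expect_identical(got@value, want, label = paste(m$name, d))
      expect_identical(got@sigma, cvSigma(all_tables[[d]]))
    }
  }
})

test_that("invalid or blank groups refuse prediction per table", {
  ## triethylborane hits B|C3 (2 supporting molecules) in the vaporization
  ## table and elements absent from the solvation table
  teb <- ref_by_name("triethylborane")$graph
  p <- predictDescriptor(teb, all_tables$dHvap)
  expect_false(p@predictable)
  expect_true("B|C3" %in% p@missing)
  expect_true(is.na(p@value))
  ## but with min_support 1 the same molecule becomes predictable
  expect_true(predictDescriptor(teb, all_tables$dHvap, 1L)@predictable)

  ## furazan contains the blank dSfus cell O|N2(2pi)
  fz <- ref_by_name("furazan")$graph
  p4 <- predictDescriptor(fz, all_tables$dSfus)
  expect_false(p4@predictable)
  expect_true("O|N2(2pi)" %in% p4@missing)

  ## cyclopropane rings are unsupported in the liquid-crystal model
  p5 <- predictDescriptor(ref_by_name("cyclopropane")$graph, all_tables$tpcE)
  expect_false(p5@predictable)
  expect_true("Angle60" %in% p5@missing)

  ## at least one reference molecule hits an invalid group of each table
  for (d in names(all_tables)) {
    hit <- any(vapply(ref_lib, function(m)
      !predictDescriptor(m$graph, all_tables[[d]])@predictable, logical(1)))
    expect_true(hit, label = d)
  }
})

test_that("specials not in a descriptor's model are ignored, not missing", {
  ## cyclohexane carries Endocyclic bonds = 6, which the vaporization model
  ## does not use; the prediction must succeed without that term
  p <- predictDescriptor(ref_by_name("cyclohexane")$graph, all_tables$dHvap)
  expect_true(p@predictable)
  expect_false("Endocyclic bonds" %in% p@matched$key)
  expect_true("Alkane/No. of C atoms" %in% p@matched$key)
})

test_that("out-of-scope molecules report a distinct status", {
  skip_if_not_installed("ChemmineOB")
  sn <- readSMILES("CC[Sn](CC)(CC)CC", "tetraethylstannane")
  p <- predictDescriptor(sn, all_tables$dHvap)
  expect_false(p@predictable)
  expect_identical(p@status, "out of element scope")
})

test_that("predictions are invariant to atom ordering and reproducible", {
  set.seed(7)
  g <- ref_by_name("salicylaldehyde")$graph
  v0 <- predictDescriptor(g, all_tables$dHvap)@value
  for (r in 1:3) {
    gp <- perceiveGraph(permute_graph(g, sample(atomCount(g))))
    expect_identical(predictDescriptor(gp, all_tables$dHvap)@value, v0)
  }
})

test_that("a CH2 extension changes dHvap by exactly the chain increments", {
  skip_if_not_installed("ChemmineOB")
  e <- tableEntries(all_tables$dHvap)
  inc <- e$contribution[e$key == "C sp3|H2C2"] +
    e$contribution[e$key == "Alkane/No. of C atoms"]
  smiles <- c("CCCC", "CCCCC", "CCCCCC", "CCCCCCC")
  vals <- vapply(smiles, function(s)
    predictDescriptor(readSMILES(s), all_tables$dHvap)@value, numeric(1))
  expect_equal(unname(diff(vals)), rep(inc, 3))
})

test_that("fusion enthalpy is the sublimation-vaporization difference", {
  tabs <- list(dHsub = all_tables$dHsub, dHvap = all_tables$dHvap)
  g <- ref_by_name("ethanol")$graph
  f <- predictFusionEnthalpy(g, tables = tabs)
  sub <- predictDescriptor(g, tabs$dHsub)@value
  vap <- predictDescriptor(g, tabs$dHvap)@value
  expect_identical(f@value, sub - vap)
  expect_equal(f@sigma, propagateSigma(cvSigma(all_tables$dHsub),
                                       cvSigma(all_tables$dHvap)))

  ## inapplicability propagates and names the failing parent
  teb <- ref_by_name("triethylborane")$graph
  ff <- predictFusionEnthalpy(teb, tables = tabs)
  expect_false(ff@predictable)
  expect_match(ff@status, "dHvap")
})

test_that("sigma propagation follows the quadrature rule", {
  expect_equal(round(propagateSigma(11.39, 4.56), 2), 12.27)
  expect_identical(propagateSigma(0, 7.5), 7.5)
  expect_identical(propagateSigma(3, 4), 5)
  expect_error(propagateSigma(-1, 2), "non-negative")
})
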