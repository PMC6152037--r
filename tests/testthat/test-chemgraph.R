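test_that("an empty SDF file yields an empty list", {
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines("", f)
  expect_identical(readSDF(f), list())
})

test_that("a methane V2000 record gives one heavy atom with four implicit H", {
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("methane", "  fixture", "",
               "  1  0  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
               "M  END", "$$$$"), f)
  mols <- readSDF(f)
  expect_length(mols, 1L)
  g <- mols[[1]]
  expect_equal(atomCount(g), 1L)
  expect_equal(atomTable(g)$implicit_h, 4L)
  expect_equal(molName(g), "methane")
})

test_that("benzene from SDF is fully aromatic with six-membered rings", {
  g <- ref_by_name("benzene")$graph
  f <- withr::local_tempfile(fileext = ".sdf")
  writeSDF(g, f)
  g2 <- readSDF(f)[[1]]
  for (gr in list(g, g2)) {
    a <- atomTable(gr)
    expect_true(all(a$aromatic))
    expect_true(all(a$hybridization == "aromatic"))
    expect_true(all(a$ring_min == 6L))
    expect_true(all(bondTable(gr)$order == "aromatic"))
    expect_equal(sum(a$implicit_h), 6L)
  }
})

test_that("malformed records are reported but do not lose the others", {
  f <- withr::local_tempfile(fileext = ".sdf")
  good <- c("ethane", "  fixture", "",
            "  2  1  0  0  0  0  0  0  0  0999 V2000",
            "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
            "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
            "  1  2  1  0  0  0  0", "M  END", "$$$$")
  bad <- c("broken", "  fixture", "", "garbage counts line",
           "M  END", "$$$$")
  writeLines(c(good, bad, sub("ethane", "ethane2", good)), f)
  expect_warning(mols <- readSDF(f), "record")
  expect_length(mols, 2L)
  expect_equal(vapply(mols, molName, ""), c("ethane", "ethane2"))
})

test_that("SMILES and SDF routes agree for the reference molecules", {
  skip_if_not_installed("ChemmineOB")
  f <- withr::local_tempfile(fileext = ".sdf")
  for (nm in c("benzene", "pyridine", "furan", "nitromethane",
               "salicylaldehyde", "cyclopropane")) {
    g <- ref_by_name(nm)$graph
    writeSDF(g, f)
    g2 <- readSDF(f)[[1]]
    expect_identical(graph_signature(g2), graph_signature(g), label = nm)
    fv1 <- fragmentMolecule(g); fv2 <- fragmentMolecule(g2)
    expect_identical(groupCounts(fv2), groupCounts(fv1), label = nm)
    expect_identical(specialCounts(fv2), specialCounts(fv1), label = nm)
  }
})

test_that("basic SMILES valence handling is correct", {
  skip_if_not_installed("ChemmineOB")
  eth <- readSMILES("CCO")
  expect_equal(atomCount(eth), 3L)
  a <- atomTable(eth)
  expect_equal(a$implicit_h[a$element == "O"], 1L)
  cp <- readSMILES("C1CC1")
  expect_true(all(atomTable(cp)$ring_min == 3L))
  expect_error(readSMILES("not a smiles(("), "parse")
})

test_that("perception assigns hybridization, charge and aromaticity", {
  skip_if_not_installed("ChemmineOB")
  py <- ref_by_name("pyridine")$graph
  a <- atomTable(py)
  expect_equal(a$hybridization[a$element == "N"], "aromatic")
  expect_true(a$aromatic[a$element == "N"])

  nm <- ref_by_name("nitromethane")$graph
  a <- atomTable(nm)
  expect_equal(a$charge[a$element == "N"], 1L)
  expect_equal(sort(a$charge[a$element == "O"]), c(-1L, 0L))

  acn <- ref_by_name("acetonitrile")$graph
  a <- atomTable(acn)
  ## the nitrile carbon is sp
  sp_c <- a$element == "C" & a$hybridization == "sp"
  expect_equal(sum(sp_c), 1L)

  ## five-membered heteroaromatics stay kekulized (vocabulary convention)
  fur <- ref_by_name("furan")$graph
  expect_false(any(atomTable(fur)$aromatic))
  expect_equal(sort(table(atomTable(fur)$hybridization),
                    decreasing = TRUE)[["sp2"]], 4L)

  ## fused aromatics: every naphthalene atom is aromatic
  nap <- ref_by_name("naphthalene")$graph
  expect_true(all(atomTable(nap)$aromatic))
})

test_that("perception is idempotent", {
  for (nm in c("benzene", "furan", "salicylaldehyde", "cyclopentane")) {
    g <- ref_by_name(nm)$graph
    g2 <- perceiveGraph(g)
    expect_identical(atomTable(g2), atomTable(g), label = nm)
    expect_identical(bondTable(g2), bondTable(g), label = nm)
  }
})

test_that("heavy-atom count and implicit-H sum are invariant under atom reordering", {
  set.seed(421)
  for (nm in c("toluene", "methyl acetate", "pyrimidine")) {
    g <- ref_by_name(nm)$graph
    perm <- sample(atomCount(g))
    gp <- perceiveGraph(permute_graph(g, perm))
    expect_equal(atomCount(gp), atomCount(g))
    expect_equal(sum(atomTable(gp)$implicit_h), sum(atomTable(g)$implicit_h))
    expect_identical(graph_signature(gp), graph_signature(g), label = nm)
  }
})

test_that("SDF data fields are preserved in molProperties", {
  f <- withr::local_tempfile(fileext = ".sdf")
  g <- ref_by_name("ethanol")$graph
  g@properties <- list(EXP_VALUE = 42.3, DESCRIPTOR = "dHvap",
                       UNITS = "kJ/mol")
  writeSDF(g, f)
  g2 <- readSDF(f)[[1]]
  expect_equal(molProperties(g2)$EXP_VALUE, 42.3)
  expect_equal(molProperties(g2)$DESCRIPTOR, "dHvap")
})
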