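test_that("single atoms are typed per the vocabulary grammar", {
  eth <- ref_by_name("ethanol")$graph
  keys <- sort(vapply(seq_len(atomCount(eth)), function(i)
    typeAtom(eth, i), character(1)))
  expect_identical(keys, sort(c("C sp3|H3C", "C sp3|H2CO", "O|HC")))

  ani <- ref_by_name("aniline")$graph
  n_idx <- which(atomTable(ani)$element == "N")
  expect_identical(typeAtom(ani, n_idx), "N sp3|H2C(pi)")

  aa <- ref_by_name("acetic acid")$graph
  ## the carbonyl carbon: single-bonded C, single-bonded O, double-bonded O
  carbonyl <- which(atomTable(aa)$element == "C" &
                      atomTable(aa)$hybridization == "sp2")
  expect_identical(typeAtom(aa, carbonyl), "C sp2|CO=O")

  bz <- ref_by_name("benzene")$graph
  expect_identical(typeAtom(bz, 1L), "C aromatic|H:C2")

  ## decorations are not centers: carbonyl O of acetic acid
  dec_o <- which(atomTable(aa)$element == "O" &
                   atomTable(aa)$implicit_h == 0L)
  expect_true(is.na(typeAtom(aa, dec_o)))
})

test_that("fragmentMolecule reproduces every hand decomposition", {
  for (m in ref_lib) {
    fv <- fragmentMolecule(m$graph)
    expect_length(untypableAtoms(fv), 0L)
    expect_false(fv@out_of_scope)
    expect_same_counts(groupCounts(fv), m$groups)
    sp <- specialCounts(fv)
    want <- stats::setNames(integer(length(sp)), names(sp))
    if (length(m$specials)) want[names(m$specials)] <- m$specials
    expect_same_counts(sp, want)
  }
})

test_that("every typed center is covered exactly once (partition property)", {
  for (m in ref_lib) {
    fv <- fragmentMolecule(m$graph)
    n_centers <- sum(groupCounts(fv))
    expect_equal(n_centers + length(fv@decorations), fv@n_heavy,
                 label = m$name)
  }
})

test_that("fragmentation is invariant under atom permutations", {
  set.seed(99)
  for (nm in c("salicylaldehyde", "nitrobenzene", "trimethyl phosphate",
               "pyrrole")) {
    g <- ref_by_name(nm)$graph
    fv <- fragmentMolecule(g)
    for (r in 1:3) {
      gp <- perceiveGraph(permute_graph(g, sample(atomCount(g))))
      fvp <- fragmentMolecule(gp)
      expect_identical(groupCounts(fvp), groupCounts(fv), label = nm)
      expect_identical(specialCounts(fvp), specialCounts(fv), label = nm)
    }
  }
})

test_that("every produced key exists in the transcribed vocabulary", {
  vocab <- unique(unlist(lapply(all_tables, function(t) tableEntries(t)$key)))
  produced <- unique(unlist(lapply(ref_lib, function(m)
    names(groupCounts(fragmentMolecule(m$graph))))))
  expect_length(setdiff(produced, vocab), 0L)
})

test_that("endocyclic single bonds count only single ring bonds", {
  skip_if_not_installed("ChemmineOB")
  expect_equal(countEndocyclicSingleBonds(ref_by_name("cyclohexane")$graph), 6L)
  expect_equal(countEndocyclicSingleBonds(ref_by_name("benzene")$graph), 0L)
  cyclohexene <- readSMILES("C1=CCCCC1")
  expect_equal(countEndocyclicSingleBonds(cyclohexene), 5L)
  ## acyclic molecules have none
  expect_equal(countEndocyclicSingleBonds(ref_by_name("n-hexane")$graph), 0L)
})

test_that("angle groups count ring atoms by smallest-ring size", {
  expect_equal(countAngleGroups(ref_by_name("cyclopropane")$graph),
               c(Angle60 = 3L, Angle90 = 0L, Angle102 = 0L))
  expect_equal(countAngleGroups(ref_by_name("cyclopentane")$graph),
               c(Angle60 = 0L, Angle90 = 0L, Angle102 = 5L))
  expect_equal(countAngleGroups(ref_by_name("benzene")$graph),
               c(Angle60 = 0L, Angle90 = 0L, Angle102 = 0L))
  skip_if_not_installed("ChemmineOB")
  spiro <- readSMILES("C1CC12CC2")  # spiropentane: all atoms in 3-rings
  expect_equal(countAngleGroups(spiro)[["Angle60"]], 5L)
})

test_that("hydrocarbon corrections apply to pure hydrocarbons only", {
  hx <- countHydrocarbonCorrection(ref_by_name("n-hexane")$graph)
  expect_equal(hx, list(key = "Alkane/No. of C atoms", count = 6L))
  st <- countHydrocarbonCorrection(ref_by_name("styrene")$graph)
  expect_equal(st, list(key = "Unsaturated HC/No. of C atoms", count = 8L))
  et <- countHydrocarbonCorrection(ref_by_name("ethanol")$graph)
  expect_true(is.na(et$key))
  expect_equal(et$count, 0L)
})

test_that("intramolecular H-bond motifs are counted per donor-acceptor pair", {
  expect_equal(countHAcceptor(ref_by_name("salicylaldehyde")$graph), 1L)
  expect_equal(countHAcceptor(ref_by_name("phenol")$graph), 0L)
  expect_equal(countHAcceptor(ref_by_name("ethylene glycol")$graph), 1L)
  expect_equal(countHAcceptor(ref_by_name("ethanol")$graph), 0L)
})

test_that("pi annotation never decreases when adding an aromatic substituent", {
  skip_if_not_installed("ChemmineOB")
  pairs <- list(c("CO", "COc1ccccc1"),     # methanol -> anisole
                c("CN", "CNc1ccccc1"),     # methylamine -> N-methylaniline
                c("CS", "CSc1ccccc1"))     # methanethiol -> thioanisole
  pi_of <- function(smiles) {
    g <- readSMILES(smiles)
    ks <- names(groupCounts(fragmentMolecule(g)))
    k <- grep("^(O|N sp3|S2)\\|", ks, value = TRUE)
    m <- regmatches(k, regexpr("\\(([0-9]*)pi\\)", k))
    if (!length(m)) 0L
    else {
      d <- gsub("[^0-9]", "", m)
      if (nzchar(d)) as.integer(d) else 1L
    }
  }
  for (p in pairs) expect_gte(pi_of(p[2]), pi_of(p[1]))
})

test_that("molecules with unsupported elements are flagged out of scope", {
  skip_if_not_installed("ChemmineOB")
  sn <- readSMILES("CC[Sn](CC)(CC)CC", "tetraethylstannane")
  fv <- fragmentMolecule(sn)
  expect_true(fv@out_of_scope)
  expect_length(groupCounts(fv), 0L)
})
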