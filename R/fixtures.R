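#' @include AllClasses.R fitter.R
NULL

## Hand-decomposed reference molecules. Each entry records the expected
## atom-group counts and non-zero special-group counts of the molecule,
## derived by applying the typing grammar on paper. These anchors are
## independent of the typing code and double as prediction oracles: the
## expected value of any descriptor is the table constant plus the dot
## product of these counts with the table contributions.
.REFERENCE_MOLECULES <- list(
  list(name = "n-butane", smiles = "CCCC",
       groups = c("C sp3|H3C" = 2, "C sp3|H2C2" = 2),
       specials = c("Alkane/No. of C atoms" = 4)),
  list(name = "n-hexane", smiles = "CCCCCC",
       groups = c("C sp3|H3C" = 2, "C sp3|H2C2" = 4),
       specials = c("Alkane/No. of C atoms" = 6)),
  list(name = "isobutane", smiles = "CC(C)C",
       groups = c("C sp3|H3C" = 3, "C sp3|HC3" = 1),
       specials = c("Alkane/No. of C atoms" = 4)),
  list(name = "neopentane", smiles = "CC(C)(C)C",
       groups = c("C sp3|H3C" = 4, "C sp3|C4" = 1),
       specials = c("Alkane/No. of C atoms" = 5)),
  list(name = "cyclohexane", smiles = "C1CCCCC1",
       groups = c("C sp3|H2C2" = 6),
       specials = c("Alkane/No. of C atoms" = 6, "Endocyclic bonds" = 6)),
  list(name = "cyclopropane", smiles = "C1CC1",
       groups = c("C sp3|H2C2" = 3),
       specials = c("Alkane/No. of C atoms" = 3, "Endocyclic bonds" = 3,
                    "Angle60" = 3)),
  list(name = "cyclobutane", smiles = "C1CCC1",
       groups = c("C sp3|H2C2" = 4),
       specials = c("Alkane/No. of C atoms" = 4, "Endocyclic bonds" = 4,
                    "Angle90" = 4)),
  list(name = "cyclopentane", smiles = "C1CCCC1",
       groups = c("C sp3|H2C2" = 5),
       specials = c("Alkane/No. of C atoms" = 5, "Endocyclic bonds" = 5,
                    "Angle102" = 5)),
  list(name = "benzene", smiles = "c1ccccc1",
       groups = c("C aromatic|H:C2" = 6),
       specials = c("Unsaturated HC/No. of C atoms" = 6)),
  list(name = "toluene", smiles = "Cc1ccccc1",
       groups = c("C sp3|H3C" = 1, "C aromatic|C:C2" = 1,
                  "C aromatic|H:C2" = 5),
       specials = c("Unsaturated HC/No. of C atoms" = 7)),
  list(name = "styrene", smiles = "C=Cc1ccccc1",
       groups = c("C sp2|H2=C" = 1, "C sp2|HC=C" = 1,
                  "C aromatic|C:C2" = 1, "C aromatic|H:C2" = 5),
       specials = c("Unsaturated HC/No. of C atoms" = 8)),
  list(name = "naphthalene", smiles = "c1ccc2ccccc2c1",
       groups = c("C aromatic|H:C2" = 8, "C aromatic|:C3" = 2),
       specials = c("Unsaturated HC/No. of C atoms" = 10)),
  list(name = "ethanol", smiles = "CCO",
       groups = c("C sp3|H3C" = 1, "C sp3|H2CO" = 1, "O|HC" = 1),
       specials = c()),
  list(name = "2-propanol", smiles = "CC(C)O",
       groups = c("C sp3|H3C" = 2, "C sp3|HC2O" = 1, "O|HC" = 1),
       specials = c()),
  list(name = "diethyl ether", smiles = "CCOCC",
       groups = c("C sp3|H3C" = 2, "C sp3|H2CO" = 2, "O|C2" = 1),
       specials = c()),
  list(name = "acetone", smiles = "CC(C)=O",
       groups = c("C sp3|H3C" = 2, "C sp2|C2=O" = 1),
       specials = c()),
  list(name = "acetic acid", smiles = "CC(O)=O",
       groups = c("C sp3|H3C" = 1, "C sp2|CO=O" = 1, "O|HC(pi)" = 1),
       specials = c()),
  list(name = "methyl acetate", smiles = "COC(C)=O",
       groups = c("C sp3|H3O" = 1, "C sp3|H3C" = 1, "C sp2|CO=O" = 1,
                  "O|C2(pi)" = 1),
       specials = c()),
  list(name = "phenol", smiles = "Oc1ccccc1",
       groups = c("O|HC(pi)" = 1, "C aromatic|:C2O" = 1,
                  "C aromatic|H:C2" = 5),
       specials = c()),
  list(name = "anisole", smiles = "COc1ccccc1",
       groups = c("C sp3|H3O" = 1, "O|C2(pi)" = 1, "C aromatic|:C2O" = 1,
                  "C aromatic|H:C2" = 5),
       specials = c()),
  list(name = "aniline", smiles = "Nc1ccccc1",
       groups = c("N sp3|H2C(pi)" = 1, "C aromatic|:C2N" = 1,
                  "C aromatic|H:C2" = 5),
       specials = c()),
  list(name = "triethylamine", smiles = "CCN(CC)CC",
       groups = c("C sp3|H3C" = 3, "C sp3|H2CN" = 3, "N sp3|C3" = 1),
       specials = c()),
  list(name = "pyridine", smiles = "c1ccncc1",
       groups = c("N aromatic|:C2" = 1, "C aromatic|H:C:N" = 2,
                  "C aromatic|H:C2" = 3),
       specials = c()),
  list(name = "pyrimidine", smiles = "c1cncnc1",
       groups = c("C aromatic|H:N2" = 1, "C aromatic|H:C:N" = 2,
                  "C aromatic|H:C2" = 1, "N aromatic|:C2" = 2),
       specials = c()),
  list(name = "furan", smiles = "c1ccoc1",
       groups = c("O|C2(2pi)" = 1, "C sp2|H=CO" = 2, "C sp2|HC=C" = 2),
       specials = c("Endocyclic bonds" = 3, "Angle102" = 5)),
  list(name = "thiophene", smiles = "c1ccsc1",
       groups = c("S2|C2(2pi)" = 1, "C sp2|H=CS" = 2, "C sp2|HC=C" = 2),
       specials = c("Endocyclic bonds" = 3, "Angle102" = 5)),
  list(name = "pyrrole", smiles = "c1cc[nH]c1",
       groups = c("N sp3|HC2(2pi)" = 1, "C sp2|H=CN" = 2, "C sp2|HC=C" = 2),
       specials = c("Endocyclic bonds" = 3, "Angle102" = 5)),
  list(name = "nitromethane", smiles = "C[N+](=O)[O-]",
       groups = c("C sp3|H3N(+)" = 1, "N(+) sp2|CO=O(-)" = 1),
       specials = c()),
  list(name = "nitrobenzene", smiles = "O=[N+]([O-])c1ccccc1",
       groups = c("C aromatic|:C2N(+)" = 1, "C aromatic|H:C2" = 5,
                  "N(+) sp2|CO=O(-)" = 1),
       specials = c()),
  list(name = "acetonitrile", smiles = "CC#N",
       groups = c("C sp3|H3C" = 1, "C sp|C#N" = 1),
       specials = c()),
  list(name = "1-iodopropane", smiles = "CCCI",
       groups = c("C sp3|H3C" = 1, "C sp3|H2C2" = 1, "C sp3|H2CJ" = 1),
       specials = c()),
  list(name = "bromoethane", smiles = "CCBr",
       groups = c("C sp3|H3C" = 1, "C sp3|H2CBr" = 1),
       specials = c()),
  list(name = "2,2,2-trifluoroethanol", smiles = "OCC(F)(F)F",
       groups = c("O|HC" = 1, "C sp3|H2CO" = 1, "C sp3|CF3" = 1),
       specials = c()),
  list(name = "ethylene glycol", smiles = "OCCO",
       groups = c("C sp3|H2CO" = 2, "O|HC" = 2),
       specials = c("H/H Acceptor" = 1)),
  list(name = "salicylaldehyde", smiles = "O=Cc1ccccc1O",
       groups = c("C sp2|HC=O" = 1, "C aromatic|C:C2" = 1,
                  "C aromatic|:C2O" = 1, "C aromatic|H:C2" = 4,
                  "O|HC(pi)" = 1),
       specials = c("H/H Acceptor" = 1)),
  list(name = "dimethyl sulfide", smiles = "CSC",
       groups = c("C sp3|H3S" = 2, "S2|C2" = 1),
       specials = c()),
  list(name = "dimethyl sulfoxide", smiles = "CS(C)=O",
       groups = c("C sp3|H3S" = 2, "S4|C2=O" = 1),
       specials = c()),
  list(name = "trimethyl phosphate", smiles = "COP(=O)(OC)OC",
       groups = c("C sp3|H3O" = 3, "O|CP" = 3, "P4|O3=O" = 1),
       specials = c()),
  list(name = "tetramethylsilane", smiles = "C[Si](C)(C)C",
       groups = c("C sp3|H3Si" = 4, "Si|C4" = 1),
       specials = c()),
  list(name = "triethylborane", smiles = "CCB(CC)CC",
       groups = c("C sp3|H3C" = 3, "C sp3|H2BC" = 3, "B|C3" = 1),
       specials = c()),
  list(name = "furazan", smiles = "O1N=CC=N1",
       groups = c("O|N2(2pi)" = 1, "N sp2|=CO" = 2, "C sp2|HC=N" = 2),
       specials = c("Endocyclic bonds" = 3, "Angle102" = 5)),
  list(name = "N-methylacetamide", smiles = "CC(=O)NC",
       groups = c("C sp3|H3C" = 1, "C sp2|CN=O" = 1, "N sp3|HC2(pi)" = 1,
                  "C sp3|H3N" = 1),
       specials = c())
)

.fixtureEnv <- new.env(parent = emptyenv())

#' Reference molecule library
#'
#' Hand-decomposed molecules spanning the typing grammar: alkanes,
#' aromatics and heteroaromatics, alcohols, acids, esters, amines, nitro
#' compounds, halides, three- to five-membered rings, intramolecular
#' hydrogen-bond cases, and molecules hitting invalid or blank table
#' entries. Each record holds the molecule's name, SMILES, its expected
#' [FeatureVector] content (groups and non-zero specials, derived by hand)
#' and, on request, the perceived [MolecularGraph].
#'
#' @param graphs if TRUE (default), attach the perceived graph of each
#'   molecule (requires ChemmineOB; graphs are cached per session).
#' @return list of reference records: \code{name}, \code{smiles},
#'   \code{groups}, \code{specials}, and optionally \code{graph}.
#' @export
referenceLibrary <- function(graphs = TRUE) {
  lib <- .REFERENCE_MOLECULES
  if (graphs) {
    if (is.null(.fixtureEnv$graphs)) {
      .fixtureEnv$graphs <- lapply(lib, function(m)
        readSMILES(m$smiles, m$name))
    }
    for (i in seq_along(lib)) lib[[i]]$graph <- .fixtureEnv$graphs[[i]]
  }
  lib
}

#' Expected prediction of a reference molecule
#'
#' The independent prediction oracle: constant plus the dot product of the
#' hand-decomposed counts with the table contributions, or NA when any
#' group is absent, blank or below the support threshold. Computed entirely
#' from the reference record, bypassing the typing code.
#'
#' @param ref one record of [referenceLibrary()].
#' @param table a [ParameterTable].
#' @param min_support support threshold (default 3).
#' @return numeric value or NA.
#' @export
referenceExpectedValue <- function(ref, table, min_support = 3L) {
  e <- tableEntries(table)
  counts <- c(ref$groups, ref$specials)
  specials <- names(counts) %in% .SPECIAL_GROUPS
  counts <- counts[!specials | names(counts) %in% e$key]
  valid <- validGroups(table, min_support)
  if (!all(names(counts) %in% valid)) return(NA_real_)
  contr <- stats::setNames(e$contribution, e$key)
  tableConstant(table) + sum(counts * contr[names(counts)])
}

#' Export the reference library as SDF plus expected-value CSV
#'
#' @param dir output directory (created if needed).
#' @param min_support support threshold for the expected predictions.
#' @return invisibly, the two file paths.
#' @export
exportFixtures <- function(dir, min_support = 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- referenceLibrary(graphs = TRUE)
  sdf_path <- file.path(dir, "reference_molecules.sdf")
  writeSDF(lapply(lib, `[[`, "graph"), sdf_path)
  tabs <- lapply(names(.DESCRIPTORS), loadTable)
  names(tabs) <- names(.DESCRIPTORS)
  rows <- lapply(lib, function(m) {
    vals <- vapply(tabs, function(tb)
      referenceExpectedValue(m, tb, min_support), numeric(1))
    cbind(data.frame(name = m$name, smiles = m$smiles,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals)))
  })
  csv_path <- file.path(dir, "reference_expected.csv")
  utils::write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  invisible(c(sdf_path, csv_path))
}

#' Specification of a synthetic linear training set
#'
#' Describes the generative model of the additivity equation: counts of a
#' chosen group vocabulary plus Gaussian noise around the linear response.
#'
#' @param vocabulary character group keys.
#' @param coefficients named numeric contributions covering the vocabulary.
#' @param constant constant term.
#' @param n number of records (must exceed the number of unknowns).
#' @param noise_sigma Gaussian noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @param count_lambda Poisson mean of the group counts (default 1.2).
#' @return list of class \code{"syntheticSpec"}.
#' @export
syntheticSpec <- function(vocabulary, coefficients, constant = 0,
                          n = 100L, noise_sigma = 0, seed = 1L,
                          count_lambda = 1.2) {
  if (!all(vocabulary %in% names(coefficients)))
    stop("coefficients must cover the vocabulary")
  if (n < length(vocabulary) + 1L)
    stop("unidentifiable: need n >= ", length(vocabulary) + 1L,
         " records for ", length(vocabulary), " groups plus constant")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(vocabulary = vocabulary,
                 coefficients = coefficients[vocabulary],
                 constant = constant, n = as.integer(n),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 count_lambda = count_lambda),
            class = "syntheticSpec")
}

#' Generate a synthetic training set from the linear additivity model
#'
#' Draws per-record group counts (Poisson) over the spec's vocabulary and
#' responses \eqn{y = C + \sum_i a_i A_i + \varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma^2)}. Records are abstract count
#' vectors (no chemistry), exercising the fitting and cross-validation
#' machinery under a known ground truth; reproducible under the spec seed.
#'
#' @param spec a [syntheticSpec()].
#' @param descriptor descriptor label for the resulting [TrainingSet].
#' @return a [TrainingSet] whose features are named count vectors.
#' @export
generateSyntheticTraining <- function(spec, descriptor = "dHvap") {
  stopifnot(inherits(spec, "syntheticSpec"))
  p <- length(spec$vocabulary)
  .withSeed(spec$seed, {
    counts <- matrix(stats::rpois(spec$n * p, spec$count_lambda),
                     nrow = spec$n, ncol = p,
                     dimnames = list(NULL, spec$vocabulary))
    eps <- stats::rnorm(spec$n, 0, spec$noise_sigma)
    y <- spec$constant + drop(counts %*% spec$coefficients) + eps
    feats <- lapply(seq_len(spec$n), function(i) counts[i, ])
    trainingSet(feats, y, ids = sprintf("syn%05d", seq_len(spec$n)),
                descriptor = descriptor)
  })
}
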