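#' @import methods
NULL

## Elements the group vocabulary covers. Molecules containing anything else
## are out of scope for every descriptor.
.ALLOWED_ELEMENTS <- c("H", "B", "C", "N", "O", "P", "S", "Si",
                       "F", "Cl", "Br", "I")
.HALOGENS <- c("F", "Cl", "Br", "I")

## Closed enumeration of whole-molecule correction terms.
.SPECIAL_GROUPS <- c("H/H Acceptor",
                     "Alkane/No. of C atoms",
                     "Unsaturated HC/No. of C atoms",
                     "Endocyclic bonds",
                     "Angle60", "Angle90", "Angle102")

.DESCRIPTORS <- c(dHvap = "kJ/mol", dHsub = "kJ/mol", dHsolv = "kJ/mol",
                  dSfus = "J/mol/K", tpcE = "J/mol/K")

#' MolecularGraph: an annotated heavy-atom molecular graph
#'
#' Hydrogens are implicit: each heavy atom stores its implicit hydrogen
#' count. Atom annotations (hybridization, aromaticity, smallest-ring size)
#' are assigned by [perceiveGraph()], which the readers apply automatically.
#'
#' @slot atoms data.frame with one row per heavy atom: \code{element},
#'   \code{charge} (formal), \code{implicit_h}, \code{hybridization}
#'   (\code{"sp3"}, \code{"sp2"}, \code{"sp"}, \code{"aromatic"} or
#'   \code{"other"}), \code{aromatic} (logical), \code{ring_min} (size of the
#'   smallest ring containing the atom, 0 for acyclic atoms).
#' @slot bonds data.frame with one row per bond between heavy atoms:
#'   \code{a1}, \code{a2} (atom indices), \code{order} (\code{"single"},
#'   \code{"double"}, \code{"triple"} or \code{"aromatic"}), \code{in_ring}
#'   (logical).
#' @slot name molecule name (SDF header line or user supplied).
#' @slot properties named list of SDF data fields and other metadata.
#'
#' @exportClass MolecularGraph
setClass("MolecularGraph",
         representation(atoms = "data.frame", bonds = "data.frame",
                        name = "character", properties = "list"),
         prototype(atoms = data.frame(), bonds = data.frame(),
                   name = "", properties = list()))

setValidity("MolecularGraph", function(object) {
  msg <- character()
  a <- object@atoms; b <- object@bonds
  need_a <- c("element", "charge", "implicit_h")
  if (!all(need_a %in% names(a)))
    msg <- c(msg, paste("atoms must have columns:",
                        paste(need_a, collapse = ", ")))
  if (nrow(b)) {
    if (!all(c("a1", "a2", "order") %in% names(b)))
      msg <- c(msg, "bonds must have columns a1, a2, order")
    else {
      if (any(b$a1 == b$a2)) msg <- c(msg, "self-bonds are not allowed")
      if (any(c(b$a1, b$a2) < 1L) || any(c(b$a1, b$a2) > nrow(a)))
        msg <- c(msg, "bond references a non-existent atom")
      if (!all(b$order %in% c("single", "double", "triple", "aromatic")))
        msg <- c(msg, "unknown bond order")
    }
  }
  if (nrow(a) && any(a$implicit_h < 0))
    msg <- c(msg, "implicit_h must be >= 0")
  if (length(msg)) msg else TRUE
})

#' FeatureVector: group and special-group counts of one molecule
#'
#' The inputs of the additivity model: counts \eqn{A_i} of atom-centered
#' groups and counts \eqn{B_j} of whole-molecule special groups.
#'
#' @slot groups named integer vector of atom-group counts; names are
#'   canonical group keys \code{"<atom type>|<neighbours>"}.
#' @slot specials named integer vector over the seven special groups
#'   (always all present, zeros included).
#' @slot untypable integer indices of heavy atoms no grammar production
#'   matched.
#' @slot decorations integer indices of heavy atoms absorbed into neighbour
#'   descriptors instead of being typed as centers (halogens and terminal
#'   multiply-bonded O/N/S).
#' @slot n_heavy number of heavy atoms in the molecule.
#' @slot out_of_scope TRUE when the molecule contains an element outside the
#'   supported set (no typing attempted).
#'
#' @exportClass FeatureVector
setClass("FeatureVector",
         representation(groups = "integer", specials = "integer",
                        untypable = "integer", decorations = "integer",
                        n_heavy = "integer", out_of_scope = "logical"),
         prototype(groups = integer(), specials = integer(),
                   untypable = integer(), decorations = integer(),
                   n_heavy = 0L, out_of_scope = FALSE))

setValidity("FeatureVector", function(object) {
  msg <- character()
  if (!object@out_of_scope &&
      !identical(sort(names(object@specials)), sort(.SPECIAL_GROUPS)))
    msg <- c(msg, "specials must cover the seven special groups")
  if (length(object@groups) && any(object@groups < 1L))
    msg <- c(msg, "group counts must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ParameterTable: one descriptor's group contributions
#'
#' The packaged contribution table of one descriptor: the constant term, one
#' row per atom group or special group with its contribution, number of
#' occurrences and number of supporting molecules, plus the reported summary
#' statistics (rows A-H of the printed table).
#'
#' @slot descriptor one of \code{"dHvap"}, \code{"dHsub"}, \code{"dHsolv"},
#'   \code{"dSfus"}, \code{"tpcE"}.
#' @slot units \code{"kJ/mol"} for the enthalpies, \code{"J/mol/K"} for the
#'   entropies.
#' @slot constant the constant term C of the model.
#' @slot entries data.frame: \code{key}, \code{atom_type}, \code{neighbours},
#'   \code{contribution} (NA when the printed cell is blank), \code{occurrences},
#'   \code{molecules}, \code{special} (logical).
#' @slot stats data.frame of the reported rows A-H: \code{row}, \code{label},
#'   \code{value}, \code{n}.
#'
#' @exportClass ParameterTable
setClass("ParameterTable",
         representation(descriptor = "character", units = "character",
                        constant = "numeric", entries = "data.frame",
                        stats = "data.frame"))

setValidity("ParameterTable", function(object) {
  msg <- character()
  if (!object@descriptor %in% names(.DESCRIPTORS))
    msg <- c(msg, "unknown descriptor id")
  if (length(object@constant) != 1L || !is.finite(object@constant))
    msg <- c(msg, "exactly one finite constant required")
  if (!all(c("key", "contribution", "occurrences", "molecules", "special")
           %in% names(object@entries)))
    msg <- c(msg, "entries lack required columns")
  if (!all(LETTERS[1:8] %in% object@stats$row))
    msg <- c(msg, "stats must contain rows A-H")
  if (any(duplicated(object@entries$key)))
    msg <- c(msg, "duplicate group keys")
  if (length(msg)) msg else TRUE
})

#' PredictionResult: outcome of one descriptor prediction
#'
#' @slot descriptor descriptor id (\code{"dHfus"} for the derived fusion
#'   enthalpy).
#' @slot units descriptor units.
#' @slot value predicted value; NA when not predictable.
#' @slot predictable TRUE iff every group of the molecule is present, valid
#'   and has a usable contribution.
#' @slot matched data.frame of scored terms: \code{key}, \code{count},
#'   \code{contribution}.
#' @slot missing character keys absent from the table, invalid (below the
#'   molecule-support threshold) or with blank contributions.
#' @slot sigma the descriptor's cross-validated standard deviation, quoted
#'   as the prediction uncertainty.
#' @slot status \code{"ok"}, \code{"missing groups"}, \code{"untypable
#'   atoms"} or \code{"out of element scope"}.
#'
#' @exportClass PredictionResult
setClass("PredictionResult",
         representation(descriptor = "character", units = "character",
                        value = "numeric", predictable = "logical",
                        matched = "data.frame", missing = "character",
                        sigma = "numeric", status = "character"))

#' TrainingSet: feature vectors with experimental values
#'
#' Holds the training side's inputs: one [FeatureVector] (or bare named
#' count vector, for synthetic data) per record together with the
#' experimental descriptor value at 298.15 K.
#'
#' @slot features list of FeatureVector objects or named numeric count
#'   vectors.
#' @slot values numeric experimental values, one per record.
#' @slot ids character record identifiers (unique).
#' @slot descriptor descriptor id the values refer to.
#'
#' @exportClass TrainingSet
setClass("TrainingSet",
         representation(features = "list", values = "numeric",
                        ids = "character", descriptor = "character"))

setValidity("TrainingSet", function(object) {
  msg <- character()
  n <- length(object@features)
  if (length(object@values) != n) msg <- c(msg, "values/features length mismatch")
  if (length(object@ids) != n) msg <- c(msg, "ids/features length mismatch")
  if (any(duplicated(object@ids))) msg <- c(msg, "duplicate record ids")
  if (length(msg)) msg else TRUE
})
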