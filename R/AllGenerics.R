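#' @include AllClasses.R
NULL

#' @describeIn MolecularGraph number of heavy atoms
#' @param x,object a \code{MolecularGraph}
#' @export
atomCount <- function(x) nrow(x@atoms)

#' @describeIn MolecularGraph number of heavy-atom bonds
#' @export
bondCount <- function(x) nrow(x@bonds)

#' @describeIn MolecularGraph atom annotation table
#' @export
atomTable <- function(x) x@atoms

#' @describeIn MolecularGraph bond table
#' @export
bondTable <- function(x) x@bonds

#' @describeIn MolecularGraph molecule name
#' @export
molName <- function(x) x@name

#' @describeIn MolecularGraph SDF data fields and metadata
#' @export
molProperties <- function(x) x@properties

setMethod("show", "MolecularGraph", function(object) {
  a <- object@atoms
  cat("MolecularGraph", if (nzchar(object@name)) sQuote(object@name) else "",
      "\n  ", nrow(a), " heavy atoms (", sum(a$implicit_h),
      " implicit H), ", nrow(object@bonds), " bonds\n", sep = "")
  if (nrow(a)) {
    comp <- paste0(names(table(a$element)), table(a$element), collapse = " ")
    cat("  composition: ", comp, "\n", sep = "")
    if (any(a$aromatic)) cat("  aromatic atoms:", sum(a$aromatic), "\n")
  }
  invisible(object)
})

#' @describeIn FeatureVector atom-group counts (named integer vector)
#' @param x,object a \code{FeatureVector}
#' @export
groupCounts <- function(x) x@groups

#' @describeIn FeatureVector special-group counts (named integer vector)
#' @export
specialCounts <- function(x) x@specials

#' @describeIn FeatureVector indices of atoms no grammar production matched
#' @export
untypableAtoms <- function(x) x@untypable

setMethod("show", "FeatureVector", function(object) {
  cat("FeatureVector: ", sum(object@groups), " typed centers in ",
      object@n_heavy, " heavy atoms\n", sep = "")
  if (object@out_of_scope) {
    cat("  out of element scope\n")
  } else {
    g <- object@groups
    for (k in names(g)) cat(sprintf("  %-28s %d\n", k, g[[k]]))
    s <- object@specials[object@specials > 0L]
    for (k in names(s)) cat(sprintf("  [%s] %d\n", k, s[[k]]))
    if (length(object@untypable))
      cat("  untypable atoms:", paste(object@untypable, collapse = ", "), "\n")
  }
  invisible(object)
})

#' @describeIn ParameterTable descriptor id of a table
#' @param x,object a \code{ParameterTable}
#' @export
descriptorId <- function(x) x@descriptor

#' @describeIn ParameterTable descriptor units
#' @export
descriptorUnits <- function(x) x@units

#' @describeIn ParameterTable constant term C
#' @export
tableConstant <- function(x) x@constant

#' @describeIn ParameterTable entry data.frame (one row per group)
#' @export
tableEntries <- function(x) x@entries

#' @describeIn ParameterTable reported summary statistics (rows A-H)
#' @export
reportedStats <- function(x) x@stats

setMethod("show", "ParameterTable", function(object) {
  cat("ParameterTable <", object@descriptor, "> [", object@units, "]\n",
      "  constant ", format(object@constant), ", ",
      nrow(object@entries), " group entries (",
      sum(object@entries$special), " special)\n", sep = "")
  h <- object@stats
  for (r in c("A", "B", "F", "H"))
    cat(sprintf("  %s %-28s %-8s (N = %s)\n", r,
                h$label[h$row == r], h$value[h$row == r], h$n[h$row == r]))
  invisible(object)
})

setMethod("show", "PredictionResult", function(object) {
  cat("PredictionResult <", object@descriptor, ">\n", sep = "")
  if (object@predictable) {
    cat(sprintf("  value %.2f +/- %.2f %s\n", object@value, object@sigma,
                object@units))
  } else {
    cat("  not predictable:", object@status, "\n")
    if (length(object@missing))
      cat("  missing/invalid:", paste(object@missing, collapse = "; "), "\n")
  }
  invisible(object)
})

#' @describeIn TrainingSet number of records
#' @param object a \code{TrainingSet}
#' @export
setMethod("length", "TrainingSet", function(x) length(x@features))

setMethod("show", "TrainingSet", function(object) {
  cat("TrainingSet <", object@descriptor, ">: ", length(object@features),
      " records\n", sep = "")
  invisible(object)
})
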