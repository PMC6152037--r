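#' @include AllClasses.R grouptyper.R paramtables.R
NULL

#' Predict a thermodynamic descriptor by group additivity
#'
#' Applies the additivity model \eqn{Y = \sum_i a_i A_i + \sum_j b_j B_j +
#' C} to a molecule: the counts of its atom-centered groups and special
#' groups are multiplied by the table contributions and summed with the
#' constant. The prediction is refused (\code{predictable = FALSE}, value
#' withheld) when any group of the molecule is absent from the table, has a
#' blank contribution, or rests on fewer than \code{min_support} training
#' molecules. Special groups that the descriptor's model does not use (no
#' row in its table) are ignored.
#'
#' @param x a perceived [MolecularGraph] or a [FeatureVector].
#' @param table a [ParameterTable] (or a descriptor id, which is loaded).
#' @param min_support molecule-support threshold for valid groups
#'   (default 3, the model's own convention).
#' @return a [PredictionResult]; its \code{sigma} is the descriptor's
#'   cross-validated standard deviation.
#' @examples
#' if (requireNamespace("ChemmineOB", quietly = TRUE)) {
#'   predictDescriptor(readSMILES("CCO", "ethanol"), "dHvap")
#' }
#' @export
predictDescriptor <- function(x, table, min_support = 3L) {
  if (is.character(table)) table <- loadTable(table)
  fv <- if (methods::is(x, "MolecularGraph")) fragmentMolecule(x) else x
  stopifnot(methods::is(fv, "FeatureVector"))
  sigma <- cvSigma(table)
  empty <- data.frame(key = character(), count = integer(),
                      contribution = numeric(), stringsAsFactors = FALSE)
  fail <- function(status, missing = character()) {
    new("PredictionResult", descriptor = descriptorId(table),
        units = descriptorUnits(table), value = NA_real_,
        predictable = FALSE, matched = empty,
        missing = missing, sigma = sigma, status = status)
  }
  if (fv@out_of_scope) return(fail("out of element scope"))
  if (length(fv@untypable))
    return(fail("untypable atoms",
                paste0("atom ", fv@untypable)))

  e <- tableEntries(table)
  valid <- validGroups(table, min_support)
  contr <- stats::setNames(e$contribution, e$key)

  counts <- c(groupCounts(fv),
              specialCounts(fv)[specialCounts(fv) > 0L])
  ## specials without a row in this descriptor's table are not part of its
  ## model and are dropped; atom groups must always be present
  is_special <- names(counts) %in% .SPECIAL_GROUPS
  modeled <- !is_special | names(counts) %in% e$key
  counts <- counts[modeled]

  missing <- setdiff(names(counts), valid)
  if (length(missing)) return(fail("missing groups", missing))

  matched <- data.frame(key = names(counts), count = as.integer(counts),
                        contribution = unname(contr[names(counts)]),
                        stringsAsFactors = FALSE)
  value <- tableConstant(table) + sum(matched$count * matched$contribution)
  new("PredictionResult", descriptor = descriptorId(table),
      units = descriptorUnits(table), value = value, predictable = TRUE,
      matched = matched, missing = character(), sigma = sigma,
      status = "ok")
}

#' Derive the standard enthalpy of fusion
#'
#' The enthalpy of fusion at 298.15 K is the difference between the
#' predicted enthalpies of sublimation and vaporization; its uncertainty is
#' the error-propagated combination of the two cross-validated standard
#' deviations, \eqn{\sigma = \sqrt{\sigma_{sub}^2 + \sigma_{vap}^2}}.
#'
#' @param g a perceived [MolecularGraph].
#' @param min_support molecule-support threshold passed to both parent
#'   predictions.
#' @param tables optional named list with elements \code{dHsub} and
#'   \code{dHvap} (pre-loaded [ParameterTable]s), to avoid re-reading.
#' @return a [PredictionResult] with descriptor \code{"dHfus"}; when either
#'   parent prediction is refused the result names the failing parent.
#' @export
predictFusionEnthalpy <- function(g, min_support = 3L, tables = NULL) {
  if (is.null(tables))
    tables <- list(dHsub = loadTable("dHsub"), dHvap = loadTable("dHvap"))
  sub <- predictDescriptor(g, tables$dHsub, min_support)
  vap <- predictDescriptor(g, tables$dHvap, min_support)
  sigma <- propagateSigma(sub@sigma, vap@sigma)
  if (!sub@predictable || !vap@predictable) {
    parents <- c(if (!sub@predictable) "dHsub", if (!vap@predictable) "dHvap")
    return(new("PredictionResult", descriptor = "dHfus", units = "kJ/mol",
               value = NA_real_, predictable = FALSE,
               matched = data.frame(key = character(), count = integer(),
                                    contribution = numeric()),
               missing = unique(c(sub@missing, vap@missing)),
               sigma = sigma,
               status = paste("parent prediction failed:",
                              paste(parents, collapse = ", "))))
  }
  new("PredictionResult", descriptor = "dHfus", units = "kJ/mol",
      value = sub@value - vap@value, predictable = TRUE,
      matched = data.frame(key = c("dHsub", "dHvap"), count = c(1L, -1L),
                           contribution = c(sub@value, vap@value),
                           stringsAsFactors = FALSE),
      missing = character(), sigma = sigma, status = "ok")
}

#' Propagate two independent standard deviations
#'
#' Error propagation for a difference (or sum) of two independent
#' quantities: \eqn{\sqrt{s_1^2 + s_2^2}}. With the cross-validated
#' standard deviations of the sublimation (11.39 kJ/mol) and vaporization
#' (4.56 kJ/mol) models this yields the 12.27 kJ/mol uncertainty of the
#' derived enthalpy of fusion.
#'
#' @param s1,s2 non-negative standard deviations.
#' @return numeric scalar (full precision; round only for display).
#' @examples
#' propagateSigma(11.39, 4.56)  # 12.27 at two decimals
#' @export
propagateSigma <- function(s1, s2) {
  if (any(c(s1, s2) < 0)) stop("standard deviations must be non-negative")
  sqrt(s1^2 + s2^2)
}
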