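#' @include AllClasses.R predictor.R
NULL

## run expr with a temporary RNG state seeded by `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## named numeric count vector of one training record
.featureCounts <- function(f) {
  if (methods::is(f, "FeatureVector")) {
    sp <- specialCounts(f)
    c(groupCounts(f), sp[sp > 0L])
  } else {
    stopifnot(!is.null(names(f)))
    f[f != 0]
  }
}

#' Assemble a training set
#'
#' @param features list of [FeatureVector] objects, perceived
#'   [MolecularGraph]s (fragmented on the fly) or named count vectors.
#' @param values experimental descriptor values at 298.15 K.
#' @param ids unique record identifiers (default: names or indices).
#' @param descriptor descriptor id the values belong to.
#' @return a [TrainingSet].
#' @export
trainingSet <- function(features, values, ids = NULL, descriptor = "dHvap") {
  features <- lapply(features, function(f)
    if (methods::is(f, "MolecularGraph")) fragmentMolecule(f) else f)
  if (is.null(ids))
    ids <- if (!is.null(names(features))) names(features)
           else sprintf("rec%04d", seq_along(features))
  new("TrainingSet", features = features, values = as.numeric(values),
      ids = as.character(ids), descriptor = descriptor)
}

#' Build the design matrix with valid-group gating
#'
#' Columns are the group keys observed in the training set (plus a trailing
#' constant column of ones), rows are molecules, cells are occurrence
#' counts. Groups supported by fewer than \code{min_support} molecules are
#' removed and every molecule containing a removed group is dropped from the
#' fit; because dropping molecules can push further groups below the
#' threshold, the gate is iterated to a fixed point. Dropped molecules and
#' groups are reported.
#'
#' @param data a [TrainingSet].
#' @param min_support molecule-support threshold (default 3).
#' @return an object of class \code{"designMatrix"}: list with \code{X}
#'   (count matrix incl. constant column \code{"Const"}), \code{y},
#'   \code{ids}, \code{keys}, \code{support} (per kept column),
#'   \code{dropped_groups}, \code{dropped_molecules}.
#' @export
buildDesignMatrix <- function(data, min_support = 3L) {
  stopifnot(methods::is(data, "TrainingSet"))
  counts <- lapply(data@features, .featureCounts)
  keys <- sort(unique(unlist(lapply(counts, names))))
  if (!length(keys)) stop("no groups in training set")
  X <- matrix(0, nrow = length(counts), ncol = length(keys),
              dimnames = list(data@ids, keys))
  for (i in seq_along(counts))
    X[i, names(counts[[i]])] <- as.numeric(counts[[i]])
  y <- data@values

  keep_rows <- rep(TRUE, nrow(X))
  keep_cols <- rep(TRUE, ncol(X))
  dropped_groups <- character()
  repeat {
    support <- colSums(X[keep_rows, , drop = FALSE] > 0)
    bad <- keep_cols & support < min_support
    if (!any(bad)) break
    dropped_groups <- c(dropped_groups, colnames(X)[bad])
    keep_cols[bad] <- FALSE
    hit <- rowSums(X[, bad, drop = FALSE] > 0) > 0
    keep_rows[hit] <- FALSE
  }
  if (!any(keep_rows)) stop("gating removed every training record")
  Xk <- X[keep_rows, keep_cols, drop = FALSE]
  Xk <- cbind(Xk, Const = 1)
  structure(list(X = Xk, y = y[keep_rows], ids = data@ids[keep_rows],
                 keys = colnames(Xk),
                 support = c(colSums(Xk[, -ncol(Xk), drop = FALSE] > 0),
                             Const = nrow(Xk)),
                 dropped_groups = dropped_groups,
                 dropped_molecules = data@ids[!keep_rows],
                 descriptor = data@descriptor),
            class = "designMatrix")
}

#' Solve the least-squares normal equations by Gauss-Seidel iteration
#'
#' Forms the normal equations \eqn{X^T X \beta = X^T y} and iterates the
#' coordinate-wise Gauss-Seidel update (initialized at zero, canonical
#' column order) until the largest relative coefficient change falls below
#' \code{tol}. The normal matrix of a full-rank design is symmetric
#' positive definite, for which Gauss-Seidel convergence is guaranteed;
#' non-convergence (e.g. exactly collinear columns) is reported explicitly,
#' never returned silently.
#'
#' @param matrix a \code{"designMatrix"} from [buildDesignMatrix()].
#' @param tol relative-change convergence tolerance (default 1e-10).
#' @param max_iter iteration cap (default 200000).
#' @return an object of class \code{"gsFit"}: list with
#'   \code{contributions} (named, excluding the constant), \code{constant},
#'   \code{coefficients} (all, in column order), \code{converged},
#'   \code{unique} (FALSE when the design is rank deficient),
#'   \code{iterations}, \code{fitted}, \code{residuals}, \code{stats} (a
#'   \code{"statsSummary"}), \code{support}, \code{keys},
#'   \code{descriptor}.
#' @export
solveGaussSeidel <- function(matrix, tol = 1e-10, max_iter = 200000L) {
  stopifnot(inherits(matrix, "designMatrix"))
  X <- matrix$X; y <- matrix$y
  A <- crossprod(X)
  b <- crossprod(X, y)
  p <- ncol(A)
  d <- diag(A)
  if (any(d <= 0))
    stop("zero diagonal in normal matrix for column(s): ",
         paste(colnames(A)[d <= 0], collapse = ", "))
  unique_sol <- qr(X)$rank == p
  if (!unique_sol)
    warning("design matrix is rank deficient (collinear columns): ",
            "the solution is not unique")
  beta <- numeric(p)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    delta <- 0
    for (j in seq_len(p)) {
      new_j <- (b[j] - sum(A[j, -j] * beta[-j])) / d[j]
      delta <- max(delta, abs(new_j - beta[j]) / max(abs(new_j), 1e-12))
      beta[j] <- new_j
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("Gauss-Seidel did not converge within ", max_iter,
            " iterations (last relative change ", signif(delta, 3), ")")
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  structure(list(contributions = beta[-p], constant = unname(beta[p]),
                 coefficients = beta, converged = converged,
                 unique = unique_sol,
                 iterations = it, fitted = fitted, residuals = res,
                 stats = summaryStats(y, fitted),
                 support = matrix$support, keys = matrix$keys,
                 ids = matrix$ids, descriptor = matrix$descriptor),
            class = "gsFit")
}

#' @export
print.gsFit <- function(x, ...) {
  cat("Gauss-Seidel group-contribution fit <", x$descriptor, ">\n",
      "  ", length(x$contributions), " contributions + constant ",
      format(x$constant, digits = 4), "\n",
      "  converged: ", x$converged, " (", x$iterations, " sweeps)\n",
      "  training R2 ", format(x$stats$r2, digits = 4),
      ", std dev ", format(x$stats$std_dev, digits = 4),
      " (N = ", x$stats$n, ")\n", sep = "")
  invisible(x)
}

#' Fit group contributions with iterative outlier removal
#'
#' The full training loop of the method: gate groups by molecule support,
#' solve by Gauss-Seidel, cross-validate, then remove records whose
#' absolute residual exceeds \code{outlier_k} times the cross-validated
#' standard deviation; repeat until no record is removed or
#' \code{max_rounds} is reached. The enthalpy models used a factor of 4,
#' the entropy models a factor of 3. All removals are logged with their
#' deviations.
#'
#' @param data a [TrainingSet].
#' @param outlier_k outlier threshold in multiples of the cv standard
#'   deviation; \code{Inf} disables removal (single round).
#' @param min_support molecule-support threshold (default 3).
#' @param max_rounds cap on gate/fit/remove rounds (default 5).
#' @param cv a [cvConfig()] list controlling the embedded cross-validation.
#' @param tol,max_iter forwarded to [solveGaussSeidel()].
#' @return a \code{"gsFit"} augmented with \code{removed_outliers}
#'   (data.frame id/value/residual), \code{cv} (the final [crossValidate()]
#'   result) and \code{rounds}.
#' @export
fitDescriptor <- function(data, outlier_k = 4, min_support = 3L,
                          max_rounds = 5L, cv = cvConfig(),
                          tol = 1e-10, max_iter = 200000L) {
  stopifnot(methods::is(data, "TrainingSet"))
  removed <- data.frame(id = character(), value = numeric(),
                        residual = numeric(), round = integer(),
                        stringsAsFactors = FALSE)
  current <- data
  fit <- NULL; cvres <- NULL
  for (round in seq_len(max_rounds)) {
    dm <- buildDesignMatrix(current, min_support)
    fit <- solveGaussSeidel(dm, tol = tol, max_iter = max_iter)
    cvres <- crossValidate(current, cv, tol = tol, max_iter = max_iter)
    if (!is.finite(outlier_k)) break
    sig <- cvres$cv_sigma
    out <- abs(fit$residuals) > outlier_k * sig
    if (!any(out) || sig == 0) break
    removed <- rbind(removed, data.frame(
      id = fit$ids[out], value = dm$y[out],
      residual = fit$residuals[out], round = round,
      stringsAsFactors = FALSE))
    keep <- !current@ids %in% fit$ids[out]
    if (!any(keep)) stop("outlier removal emptied the training set")
    current <- new("TrainingSet", features = current@features[keep],
                   values = current@values[keep],
                   ids = current@ids[keep],
                   descriptor = current@descriptor)
  }
  fit$removed_outliers <- removed
  fit$cv <- cvres
  fit$rounds <- if (is.finite(outlier_k)) round else 1L
  fit
}

#' Predict from a fitted contribution set
#'
#' Scores records of a training set (or bare feature vectors) against a
#' \code{"gsFit"}; a record is predictable only if all its groups are among
#' the fitted columns.
#'
#' @param object a \code{"gsFit"}.
#' @param features list of feature vectors / named count vectors.
#' @param ... unused.
#' @return numeric vector of predictions (NA where not predictable).
#' @export
predict.gsFit <- function(object, features, ...) {
  vapply(features, function(f) {
    cnt <- .featureCounts(f)
    if (!all(names(cnt) %in% names(object$contributions)))
      return(NA_real_)
    object$constant + sum(cnt * object$contributions[names(cnt)])
  }, numeric(1))
}
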