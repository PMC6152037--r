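#' @include AllClasses.R fitter.R
NULL

#' Cross-validation configuration
#'
#' @param k number of folds (default 10, the method's convention).
#' @param seed RNG seed for the fold assignment (recorded in reports).
#' @param min_support molecule-support threshold re-applied inside folds.
#' @return list of class \code{"cvConfig"}.
#' @export
cvConfig <- function(k = 10L, seed = 1L, min_support = 3L) {
  stopifnot(k >= 2L)
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 min_support = as.integer(min_support)),
            class = "cvConfig")
}

#' Split indices into k disjoint folds
#'
#' Uniform random assignment (no stratification); fold sizes differ by at
#' most one; reproducible under a fixed seed.
#'
#' @param n number of records.
#' @param config a [cvConfig()].
#' @return list of \code{k} disjoint integer index sets partitioning
#'   \code{1..n}.
#' @export
kfoldSplit <- function(n, config = cvConfig()) {
  k <- config$k
  if (n < k) stop("n (", n, ") must be at least k (", k, ")")
  .withSeed(config$seed, {
    perm <- sample.int(n)
    fold_of <- rep_len(seq_len(k), n)
    lapply(seq_len(k), function(f) sort(perm[fold_of == f]))
  })
}

#' Summary statistics of experimental-vs-predicted pairs
#'
#' The statistics reported alongside each model: squared Pearson
#' correlation (R2 or Q2 depending on the origin of the predictions), the
#' ordinary least-squares regression of predicted on experimental
#' (intercept, slope), the average absolute deviation, the standard
#' deviation \eqn{\sqrt{\sum r^2 / N}} (no degrees-of-freedom correction,
#' consistent with the reported table rows), and the fractions of records
#' deviating by at most one and by more than two supplied standard
#' deviations.
#'
#' @param experimental,predicted numeric vectors (>= 2 finite pairs).
#' @param sigma reference standard deviation for the deviation fractions
#'   (default: the standard deviation of the residuals themselves).
#' @return list of class \code{"statsSummary"}: \code{n}, \code{r2},
#'   \code{avg_dev}, \code{std_dev}, \code{intercept}, \code{slope},
#'   \code{frac_within_1sigma}, \code{frac_beyond_2sigma}, \code{sigma_ref},
#'   \code{r2_defined}.
#' @export
summaryStats <- function(experimental, predicted, sigma = NULL) {
  ok <- is.finite(experimental) & is.finite(predicted)
  x <- experimental[ok]; yhat <- predicted[ok]
  n <- length(x)
  if (n < 2L) stop("need at least two pairs")
  res <- yhat - x
  avg_dev <- mean(abs(res))
  std_dev <- sqrt(mean(res^2))
  if (is.null(sigma)) sigma <- std_dev
  r2_defined <- stats::sd(x) > 0 && stats::sd(yhat) > 0
  r2 <- if (r2_defined) stats::cor(x, yhat)^2
        else if (std_dev == 0) 1 else NA_real_
  coefs <- if (stats::sd(x) > 0) stats::coef(stats::lm(yhat ~ x))
           else c(NA_real_, NA_real_)
  structure(list(n = n, r2 = r2, avg_dev = avg_dev, std_dev = std_dev,
                 intercept = unname(coefs[1L]), slope = unname(coefs[2L]),
                 frac_within_1sigma = if (sigma > 0) mean(abs(res) <= sigma)
                                      else mean(res == 0),
                 frac_beyond_2sigma = if (sigma > 0) mean(abs(res) > 2 * sigma)
                                      else 0,
                 sigma_ref = sigma, r2_defined = r2_defined),
            class = "statsSummary")
}

#' @export
print.statsSummary <- function(x, ...) {
  cat(sprintf(paste0("n = %d, R2 = %s, avg dev = %.3f, std dev = %.3f\n",
                     "regression: intercept = %.4f, slope = %.4f\n",
                     "within 1 sigma: %.1f%%, beyond 2 sigma: %.1f%%\n"),
              x$n, format(x$r2, digits = 4), x$avg_dev, x$std_dev,
              x$intercept, x$slope, 100 * x$frac_within_1sigma,
              100 * x$frac_beyond_2sigma))
  invisible(x)
}

#' K-fold cross-validation of a group-contribution model
#'
#' For each fold, the contributions are refitted on the remaining folds
#' (re-applying the molecule-support gate inside the fold) and the held-out
#' records are predicted. Records whose groups fall out of the fold model
#' (absent or below support within the training folds) are excluded from
#' the cross-validation statistics and counted, which is why the
#' cross-validated N is smaller than the training N. The goodness of fit is
#' \eqn{Q^2 = 1 - \sum (y - \hat y_{cv})^2 / \sum (y - \bar y)^2} with
#' \eqn{\bar y} the mean over the full training set.
#'
#' @param data a [TrainingSet].
#' @param config a [cvConfig()].
#' @param tol,max_iter forwarded to [solveGaussSeidel()].
#' @return list of class \code{"cvResult"}: \code{stats} (a
#'   \code{"statsSummary"} over held-out predictions), \code{q2},
#'   \code{cv_sigma}, \code{predictions} (data.frame id, y, yhat_cv, fold),
#'   \code{n_excluded}, \code{failed_folds}, \code{config}.
#' @export
crossValidate <- function(data, config = cvConfig(), tol = 1e-10,
                          max_iter = 200000L) {
  stopifnot(methods::is(data, "TrainingSet"))
  n <- length(data@features)
  folds <- kfoldSplit(n, config)
  preds <- data.frame(id = character(), y = numeric(), yhat_cv = numeric(),
                      fold = integer(), stringsAsFactors = FALSE)
  n_excluded <- 0L
  failed <- integer()
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(n), test_idx)
    sub <- new("TrainingSet", features = data@features[train_idx],
               values = data@values[train_idx], ids = data@ids[train_idx],
               descriptor = data@descriptor)
    fit <- tryCatch({
      dm <- buildDesignMatrix(sub, config$min_support)
      solveGaussSeidel(dm, tol = tol, max_iter = max_iter)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      warning("fold ", f, " refit failed: ", conditionMessage(fit),
              call. = FALSE)
      failed <- c(failed, f)
      n_excluded <- n_excluded + length(test_idx)
      next
    }
    yhat <- predict(fit, data@features[test_idx])
    usable <- is.finite(yhat)
    n_excluded <- n_excluded + sum(!usable)
    if (any(usable))
      preds <- rbind(preds, data.frame(
        id = data@ids[test_idx][usable], y = data@values[test_idx][usable],
        yhat_cv = yhat[usable], fold = f, stringsAsFactors = FALSE))
  }
  if (nrow(preds) < 2L) stop("cross-validation produced < 2 usable predictions")
  ybar <- mean(data@values)  # full-set mean
  press <- sum((preds$y - preds$yhat_cv)^2)
  sstot <- sum((preds$y - ybar)^2)
  q2 <- 1 - press / sstot
  cv_sigma <- sqrt(mean((preds$y - preds$yhat_cv)^2))
  stats <- summaryStats(preds$y, preds$yhat_cv, sigma = cv_sigma)
  structure(list(stats = stats, q2 = q2, cv_sigma = cv_sigma,
                 predictions = preds, n_excluded = n_excluded,
                 failed_folds = failed, config = config),
            class = "cvResult")
}

#' @export
print.cvResult <- function(x, ...) {
  cat(sprintf(paste0("%d-fold cross-validation (seed %d): N = %d",
                     " (%d excluded)\n  Q2 = %s, cv sigma = %.3f\n"),
              x$config$k, x$config$seed, x$stats$n, x$n_excluded,
              format(x$q2, digits = 4), x$cv_sigma))
  invisible(x)
}
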