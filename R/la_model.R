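#' Fit the linear PSA-to-leaf-area calibration
#'
#' Ordinary least squares of total leaf area (LA, typically cm\eqn{^2}) on
#' projected shoot area (PSA, pixels), computed from the closed form:
#' slope \eqn{= \mathrm{cov}(PSA, LA)/\mathrm{var}(PSA)}, intercept
#' \eqn{= \overline{LA} - \mathrm{slope} \cdot \overline{PSA}}, and
#' \eqn{R^2 = 1 - SSE/SST}. Out-of-sample performance is assessed by
#' k-fold cross-validation (see \code{\link{kfold_cv}}) when \code{cv_k}
#' is not \code{NULL}.
#'
#' @param pairs Data frame (or matrix) whose first two columns are
#'   \code{psa} and \code{la}.
#' @param cv_k Number of cross-validation folds, or \code{NULL} to skip CV.
#'   Default 10.
#' @param seed Seed for the CV shuffle. Default 1.
#' @return An object of class \code{la_model}: list with \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{cv_r_squared} (\code{NA} if
#'   CV was skipped), \code{n}, \code{cv_k} and \code{seed}. Supports
#'   \code{print}, \code{summary}, \code{coef}, \code{predict} and
#'   \code{residuals}.
#' @examples
#' pairs <- data.frame(psa = 1:5, la = 2 * (1:5) + 1)
#' fit_la_model(pairs, cv_k = NULL)
#' @export
fit_la_model <- function(pairs, cv_k = 10L, seed = 1L) {
  pairs <- as_psa_la(pairs)
  n <- nrow(pairs)
  if (n < 3L) stop("need at least 3 (PSA, LA) pairs to fit", call. = FALSE)
  x <- pairs$psa; y <- pairs$la
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0)
    stop("degenerate input: PSA values are all equal", call. = FALSE)
  slope <- stats::cov(x, y) / vx
  intercept <- mean(y) - slope * mean(x)
  res <- y - (slope * x + intercept)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 0
  cv_r2 <- NA_real_
  if (!is.null(cv_k)) cv_r2 <- as.numeric(kfold_cv(pairs, k = cv_k,
                                                   seed = seed))
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r2, cv_r_squared = cv_r2,
                 n = n, cv_k = if (is.null(cv_k)) NA_integer_ else cv_k,
                 seed = seed, residuals = res),
            class = "la_model")
}

as_psa_la <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2L)
    stop("pairs must have two columns (psa, la)", call. = FALSE)
  if (all(c("psa", "la") %in% names(pairs))) pairs <- pairs[c("psa", "la")]
  else pairs <- stats::setNames(pairs[, 1:2], c("psa", "la"))
  if (anyNA(pairs) || !all(vapply(pairs, is.numeric, logical(1))))
    stop("pairs must be numeric and complete", call. = FALSE)
  pairs
}

#' k-fold cross-validated R-squared of the PSA-to-leaf-area calibration
#'
#' Rows are shuffled once under \code{seed} and split into \code{k}
#' contiguous folds of size \code{floor(n/k)} or \code{ceiling(n/k)}. Each
#' fold is predicted by the model fitted on the remaining rows; every row is
#' predicted exactly once. The reported value pools all out-of-fold
#' predictions: \eqn{1 - SSE_{pooled}/SST_{pooled}}, with SST about the
#' overall LA mean. Pooling keeps the statistic stable at small fold sizes,
#' where per-fold R\eqn{^2} values degenerate.
#'
#' @param pairs Data frame with columns \code{psa} and \code{la}.
#' @param k Number of folds, between 2 and n. Default 10.
#' @param seed Shuffle seed. Default 1.
#' @return Pooled cross-validated R-squared (\eqn{\le 1}).
#' @export
kfold_cv <- function(pairs, k = 10L, seed = 1L) {
  pairs <- as_psa_la(pairs)
  n <- nrow(pairs)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (n < k) stop("need at least k rows for k-fold CV (n = ", n,
                  ", k = ", k, ")", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  fold_sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold_of <- rep(seq_len(k), fold_sizes)
  pred <- numeric(n)
  for (f in seq_len(k)) {
    test_rows <- perm[fold_of == f]
    train_rows <- perm[fold_of != f]
    x <- pairs$psa[train_rows]; y <- pairs$la[train_rows]
    slope <- stats::cov(x, y) / stats::var(x)
    intercept <- mean(y) - slope * mean(x)
    pred[test_rows] <- slope * pairs$psa[test_rows] + intercept
  }
  sse <- sum((pairs$la - pred)^2)
  sst <- sum((pairs$la - mean(pairs$la))^2)
  out <- if (sst == 0) { if (sse == 0) 1 else -Inf } else 1 - sse / sst
  # fold assignment (row indices per fold), for audits of the partition
  attr(out, "folds") <- split(perm, fold_of)
  out
}

#' @export
print.la_model <- function(x, ...) {
  cat(sprintf("Leaf-area calibration: LA' = %.4f x PSA %+.2f\n",
              x$slope, x$intercept))
  cat(sprintf("  n = %d, R^2 = %.4f", x$n, x$r_squared))
  if (!is.na(x$cv_r_squared))
    cat(sprintf(", %d-fold CV R^2 = %.4f", x$cv_k, x$cv_r_squared))
  cat("\n")
  invisible(x)
}

#' @export
summary.la_model <- function(object, ...) {
  out <- object[c("slope", "intercept", "r_squared", "cv_r_squared",
                  "n", "cv_k", "seed")]
  out$rmse <- sqrt(mean(object$residuals^2))
  class(out) <- "summary.la_model"
  out
}

#' @export
print.summary.la_model <- function(x, ...) {
  cat("Linear PSA -> leaf-area calibration\n")
  cat(sprintf("  slope      %.6f\n  intercept  %.4f\n", x$slope, x$intercept))
  cat(sprintf("  R^2        %.4f\n", x$r_squared))
  if (!is.na(x$cv_r_squared))
    cat(sprintf("  CV R^2     %.4f  (%d folds, seed %d)\n",
                x$cv_r_squared, x$cv_k, x$seed))
  cat(sprintf("  RMSE       %.4f   n = %d\n", x$rmse, x$n))
  invisible(x)
}

#' @export
coef.la_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.la_model <- function(object, ...) object$residuals

#' Predict leaf area from PSA
#'
#' @param object A fitted \code{la_model}.
#' @param psa Numeric vector of PSA values (pixels), or a data frame with a
#'   \code{psa} column.
#' @param ... Unused.
#' @return Predicted leaf area, \code{slope * psa + intercept}, vectorised.
#' @export
predict.la_model <- function(object, psa, ...) {
  if (is.data.frame(psa)) psa <- psa$psa
  object$slope * as.numeric(psa) + object$intercept
}

#' Persist a fitted calibration as JSON
#'
#' @param model A \code{la_model}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_la_model <- function(model, path) {
  keep <- model[c("slope", "intercept", "r_squared", "cv_r_squared",
                  "n", "cv_k", "seed")]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Load a calibration persisted by \code{\link{write_la_model}}
#'
#' @param path JSON path.
#' @return A \code{la_model} (without residuals).
#' @export
read_la_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$residuals <- numeric(0)
  if (is.null(x$cv_r_squared)) x$cv_r_squared <- NA_real_
  structure(x, class = "la_model")
}
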