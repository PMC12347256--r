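# Group comparison and model fitting for the diagnostic analysis.

#' Mann-Whitney U test
#'
#' U is the number of (a, b) pairs with a > b, counting ties as 1/2
#' (oriented to `group_a`). When both groups have n <= 10 the two-sided
#' p-value comes from exact enumeration of the permutation distribution of
#' U over all group assignments (valid under ties); otherwise from the
#' normal approximation with tie correction and continuity correction.
#'
#' @param group_a,group_b numeric vectors (non-empty)
#' @return list: `U`, `p`, `method`
#' @export
mann_whitney <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  n1 <- length(group_a); n2 <- length(group_b); N <- n1 + n2
  r <- rank(c(group_a, group_b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (n1 <= 10 && n2 <= 10) {
    # exact permutation distribution of the rank sum over assignments
    combos <- utils::combn(N, n1)
    Uall <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, p = p, method = "exact"))
  }

  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Group-comparison table (mean +/- SD and Mann-Whitney p per feature)
#'
#' @param table data frame with logical `is_ph` and the feature columns
#' @param features character vector of feature column names
#' @return data frame: feature, group means/SDs, U, p
#' @export
compare_groups <- function(table, features = COHORT_FEATURES) {
  rows <- lapply(features, function(f) {
    a <- table[[f]][table$is_ph]
    b <- table[[f]][!table$is_ph]
    mw <- mann_whitney(a, b)
    data.frame(feature = f,
               mean_ph = mean(a), sd_ph = stats::sd(a),
               mean_nonph = mean(b), sd_nonph = stats::sd(b),
               U = mw$U, p = mw$p)
  })
  do.call(rbind, rows)
}

#' Multivariate logistic model for PH status
#'
#' Maximum-likelihood binomial fit by iteratively reweighted least squares
#' (tolerance 1e-8, up to 100 iterations). Quasi-complete separation is
#' detected (fitted probabilities at the 0/1 boundary or diverging
#' coefficients) and flagged rather than silently reported.
#'
#' @param table data frame with logical/0-1 `is_ph` and feature columns
#' @param features character vector of predictor column names
#' @return `logistic_model`: `features`, `coefficients`, `converged`,
#'   `separated`, `fitted` (per-subject probabilities), `fit` (the glm)
#' @export
fit_logistic <- function(table, features) {
  if (!all(features %in% names(table)))
    stop("missing feature column(s): ",
         paste(setdiff(features, names(table)), collapse = ", "))
  y <- as.integer(table$is_ph)
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop("need >= 2 subjects in each class")
  X <- table[, features, drop = FALSE]
  if (any(vapply(X, function(v) stats::sd(v) == 0, logical(1))))
    stop("constant feature column")
  dat <- cbind(.y = y, X)
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  p <- stats::fitted(fit)
  eps <- 1e-8
  separated <- sep_warned || any(p < eps | p > 1 - eps) ||
    any(abs(stats::coef(fit)[-1]) > 1e3 / apply(as.matrix(X), 2, stats::sd))
  structure(list(features = features, coefficients = stats::coef(fit),
                 converged = fit$converged, separated = separated,
                 fitted = pmin(pmax(p, .Machine$double.eps),
                               1 - .Machine$double.eps),
                 fit = fit),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("Logistic model:", paste(x$features, collapse = " + "), "\n")
  print(round(x$coefficients, 4))
  if (x$separated) cat("WARNING: separation detected\n")
  if (!x$converged) cat("WARNING: IRLS did not converge\n")
  invisible(x)
}
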