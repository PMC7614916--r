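#' Fit the association null model
#'
#' Fits the logistic regression of disease status on the covariates (by
#' default sex and the leading ancestry principal components) that all
#' region-based score tests are computed under. The returned object carries
#' the fitted case probabilities, the score residuals `y - mu`, and the
#' projection pieces needed to compute score variances, so each region test
#' is a cheap quadratic form rather than a fresh model fit.
#'
#' @param formula Model formula, e.g. `status ~ sex + PC1 + ... + PC10`.
#'   The response may be a 0/1 vector, a logical, or a `"case"`/`"control"`
#'   character/factor.
#' @param data Data frame holding the response and covariates, one row per
#'   sample, in cohort order.
#' @return Object of class `rv_null` with elements `glm`, `y`, `mu`,
#'   `resid`, `X`, `V`, `XVX_inv`.
#' @examples
#' d <- data.frame(status = rep(c(1, 0), each = 20), sex = rbinom(40, 1, 0.5))
#' nm <- rv_null_model(status ~ sex, d)
#' range(fitted(nm))
#' @export
rv_null_model <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "case")
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary (case/control)")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  dat <- data
  dat$.y <- y
  labs <- attr(stats::terms(formula, data = data), "term.labels")
  rhs <- if (length(labs))
    stats::reformulate(labs, response = ".y", intercept = TRUE)
  else stats::as.formula(".y ~ 1")
  fit <- stats::glm(rhs, family = stats::binomial(), data = dat)
  if (!fit$converged) stop("null logistic model failed to converge")
  mu <- as.vector(fit$fitted.values)
  if (any(mu <= 1e-10 | mu >= 1 - 1e-10)) {
    bad <- names(which.max(abs(stats::coef(fit))[-1]))
    stop("(quasi-)separation in the null model; check covariate ", bad)
  }
  X <- stats::model.matrix(fit)
  V <- mu * (1 - mu)
  XVX_inv <- solve(crossprod(X, X * V))
  structure(list(glm = fit, formula = formula, y = y, mu = mu,
                 resid = y - mu, X = X, V = V, XVX_inv = XVX_inv,
                 n = length(y)),
            class = "rv_null")
}

#' @export
print.rv_null <- function(x, ...) {
  cat("Rare-variant association null model (logistic)\n")
  cat("  samples:", x$n, sprintf("(%d cases, %d controls)\n",
                                 sum(x$y == 1), sum(x$y == 0)))
  cat("  covariates:", paste(colnames(x$X)[-1], collapse = ", "), "\n")
  invisible(x)
}

#' @export
residuals.rv_null <- function(object, ...) object$resid

#' @export
fitted.rv_null <- function(object, ...) object$mu

#' @export
coef.rv_null <- function(object, ...) stats::coef(object$glm)

# Score covariance of columns of B under the null:
# Sigma = B' V B - (B' V X) (X' V X)^-1 (X' V B)
score_sigma <- function(null, B) {
  B <- as.matrix(B)
  BV <- B * null$V
  A <- crossprod(B, BV)
  C <- crossprod(BV, null$X)
  A - C %*% null$XVX_inv %*% t(C)
}
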