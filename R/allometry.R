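#' Species-level trait table from specimen measurements
#'
#' Aggregates per-specimen brain mass (mg) and intertegular span (mm) to one
#' row per species, averaging on the natural-log scale (log first, then mean),
#' which stabilizes variance for body-size-like traits.
#'
#' @param specimens data frame with columns `species`, `brain_mg`, `itd_mm`
#'   and optionally `region` (one of `"US"`, `"EU"`, `"both"`).
#' @return data frame with one row per species: `species`, `log_brain`,
#'   `log_body`, `n_specimens`, and `region` when present (a species sampled in
#'   more than one region is labelled `"both"`).
#' @export
species_means <- function(specimens) {
  req <- c("species", "brain_mg", "itd_mm")
  if (!all(req %in% names(specimens))) {
    stop("specimens must have columns: ", paste(req, collapse = ", "))
  }
  bad <- which(!is.finite(specimens$brain_mg) | specimens$brain_mg <= 0 |
                 !is.finite(specimens$itd_mm) | specimens$itd_mm <= 0)
  if (length(bad)) {
    stop("nonpositive or missing measurement in specimen record(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(!nzchar(trimws(specimens$species)))) stop("empty species label")
  sp <- split(seq_len(nrow(specimens)), specimens$species)
  out <- data.frame(
    species     = names(sp),
    log_brain   = vapply(sp, function(i) mean(log(specimens$brain_mg[i])), 0),
    log_body    = vapply(sp, function(i) mean(log(specimens$itd_mm[i])), 0),
    n_specimens = vapply(sp, length, 0L),
    row.names   = NULL,
    stringsAsFactors = FALSE
  )
  if ("region" %in% names(specimens)) {
    out$region <- vapply(sp, function(i) {
      r <- unique(specimens$region[i])
      if (length(r) == 1) r else "both"
    }, "")
  }
  out
}

# GLS profile likelihood machinery shared by pgls_fit() and phylo_signal().
# For fixed lambda the MVN likelihood with covariance sigma^2 * V(lambda) is
# maximized in closed form over (beta, sigma^2); lambda is then profiled by
# bounded univariate optimization on [0, 1].
gls_profile <- function(y, X, V, lambda) {
  n <- length(y)
  W <- lambda_transform(V, lambda)
  U <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(U)) return(list(loglik = -Inf))
  ys <- backsolve(U, y, transpose = TRUE)
  Xs <- backsolve(U, X, transpose = TRUE)
  XtX <- crossprod(Xs)
  beta <- tryCatch(solve(XtX, crossprod(Xs, ys)), error = function(e) NULL)
  if (is.null(beta)) stop("singular design matrix (constant predictor?)")
  res_s <- ys - Xs %*% beta
  rss <- sum(res_s^2)
  sigma2 <- rss / n
  logdet <- 2 * sum(log(diag(U)))
  loglik <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n)
  list(loglik = loglik, beta = drop(beta), sigma2 = sigma2, rss = rss,
       U = U, ys = ys, Xs = Xs, XtX = XtX)
}

profile_lambda <- function(y, X, V, tol = 1e-8) {
  f <- function(l) gls_profile(y, X, V, l)$loglik
  opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = tol)
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective, f(0), f(1))
  best <- which.max(ll)
  list(lambda = cand[best], loglik = ll[best], loglik0 = ll[2])
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `y = X beta + e`, `e ~ MVN(0, sigma^2 V(lambda))`, where `V(lambda)`
#' is the phylogenetic covariance with off-diagonals scaled by Pagel's lambda.
#' All parameters are estimated by maximum likelihood: for each lambda the
#' coefficients and variance have closed-form GLS solutions, and lambda is
#' profiled over `[0, 1]` by bounded optimization. The canonical use is the
#' log-log brain-body allometry, whose residuals are relative brain size.
#'
#' @param formula model formula, e.g. `log_brain ~ log_body`.
#' @param data data frame with a `species` column (or species row names) and
#'   the formula variables, one row per species.
#' @param V phylogenetic covariance matrix with species dimnames (from
#'   [phylo_covariance()]); rows of `data` must be a subset of its labels.
#' @param tol convergence tolerance for the lambda search.
#' @return an object of class `"pgls_fit"` with components `coefficients`,
#'   `lambda`, `sigma2`, `loglik`, `loglik_lambda0`, `residuals` (observed
#'   minus fitted, named by species), `fitted`, `r2`, `n`.
#' @examples
#' tr <- ape::rphylo(30, 1, 0)
#' V <- phylo_covariance(tr)
#' d <- data.frame(species = tr$tip.label, log_body = rnorm(30))
#' d$log_brain <- 2.5 * d$log_body + rnorm(30, sd = 0.2)
#' fit <- pgls_fit(log_brain ~ log_body, d, V)
#' coef(fit)
#' @export
pgls_fit <- function(formula, data, V, tol = 1e-8) {
  species <- data$species %||% rownames(data)
  if (is.null(species)) stop("data must carry species labels (column or rownames)")
  species <- as.character(species)
  if (anyDuplicated(species)) stop("one row per species required")
  if (nrow(data) < 4) stop("at least 4 species required")
  if (!all(species %in% rownames(V))) {
    stop("species absent from covariance matrix: ",
         paste(utils::head(setdiff(species, rownames(V)), 5), collapse = ", "))
  }
  V <- V[species, species, drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) stop("singular design (constant predictor?)")

  prof <- profile_lambda(y, X, V, tol = tol)
  g <- gls_profile(y, X, V, prof$lambda)
  fitted <- drop(X %*% g$beta)
  resid <- y - fitted
  names(resid) <- names(fitted) <- species

  # weighted R^2 under V(lambda-hat): GLS residual SS against the GLS
  # intercept-only fit under the same covariance
  g0 <- gls_profile(y, X[, 1, drop = FALSE], V, prof$lambda)
  r2 <- 1 - g$rss / g0$rss

  p <- ncol(X)
  se <- sqrt(diag(solve(g$XtX)) * g$rss / (length(y) - p))
  names(se) <- colnames(X)

  structure(list(
    coefficients = stats::setNames(g$beta, colnames(X)),
    se = se,
    lambda = prof$lambda,
    sigma2 = g$sigma2,
    loglik = prof$loglik,
    loglik_lambda0 = prof$loglik0,
    residuals = resid,
    fitted = fitted,
    r2 = r2,
    n = length(y),
    formula = formula,
    species = species,
    call = match.call()
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS (Pagel's lambda, ML)\n")
  cat("  formula: ", deparse(x$formula), "\n", sep = "")
  cat("  n =", x$n, " lambda =", format(x$lambda, digits = 4),
      " sigma2 =", format(x$sigma2, digits = 4), "\n")
  cat("  coefficients:\n")
  print(x$coefficients)
  cat("  R2 =", format(x$r2, digits = 4),
      " logLik =", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' @export
summary.pgls_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$coefficients / object$se)
  out <- list(fit = object, coef_table = tab,
              lrt_lambda = 2 * (object$loglik - object$loglik_lambda0))
  class(out) <- "summary.pgls_fit"
  out
}

#' @export
print.summary.pgls_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficient table:\n")
  print(x$coef_table)
  cat("\nLR statistic for lambda = 0:", format(x$lrt_lambda, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients

#' @export
residuals.pgls_fit <- function(object, ...) object$residuals

#' @export
fitted.pgls_fit <- function(object, ...) object$fitted

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 2,
            nobs = object$n, class = "logLik")
}

#' @export
predict.pgls_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- stats::model.matrix(stats::delete.response(stats::terms(object$formula)),
                           newdata)
  drop(X %*% object$coefficients)
}

#' Relative brain size scores from an allometric PGLS fit
#'
#' Relative brain size is the PGLS residual: positive values mean a larger
#' brain than the allometry predicts for the species' body size.
#'
#' @param fit a `"pgls_fit"` object.
#' @return data frame with `species`, `residual` and `rank` (1 = largest
#'   relative brain), ordered as the fit.
#' @export
relative_brain_size <- function(fit) {
  stopifnot(inherits(fit, "pgls_fit"))
  r <- fit$residuals
  data.frame(species = names(r), residual = unname(r),
             rank = rank(-r, ties.method = "first"),
             stringsAsFactors = FALSE)
}
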