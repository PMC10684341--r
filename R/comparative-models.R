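#' Phylogenetic signal of a continuous trait (Pagel's lambda)
#'
#' Estimates lambda by maximizing the multivariate-normal likelihood of the
#' trait with covariance `sigma^2 V(lambda)` and a free mean, and tests
#' lambda = 0 with a likelihood-ratio test against chi-square(1). The
#' chi-square(1) reference is conservative at the lambda = 0 boundary; the
#' `mixture` option uses the 50:50 point-mass/chi-square(1) mixture instead.
#'
#' @param trait named numeric vector (names = species) or unnamed vector
#'   aligned with the tree's tip order.
#' @param tree a `"phylo"` tree, or a covariance matrix from
#'   [phylo_covariance()].
#' @param mixture logical; use the boundary-corrected mixture null.
#' @return an object of class `"phylo_signal"` with `lambda`, `loglik`,
#'   `loglik0`, `lr_stat`, `p_value`, `n`.
#' @export
phylo_signal <- function(trait, tree, mixture = FALSE) {
  V <- if (inherits(tree, "phylo")) phylo_covariance(tree) else tree
  if (!is.null(names(trait))) {
    common <- intersect(rownames(V), names(trait))
    if (length(common) < 4) stop("fewer than 4 species matched to the tree")
    V <- V[common, common]
    trait <- trait[common]
  } else if (length(trait) != nrow(V)) {
    stop("unnamed trait must match the tree's tip count")
  }
  if (length(trait) < 4) stop("fewer than 4 species")
  if (stats::var(trait) == 0) stop("constant trait: signal undefined")
  X <- matrix(1, length(trait), 1)
  prof <- profile_lambda(trait, X, V)
  lr <- max(0, 2 * (prof$loglik - prof$loglik0))
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  if (mixture) p <- if (lr == 0) 1 else 0.5 * p
  structure(list(lambda = prof$lambda, loglik = prof$loglik,
                 loglik0 = prof$loglik0, lr_stat = lr,
                 p_value = min(1, p), n = length(trait),
                 mixture = mixture),
            class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat("Pagel's lambda phylogenetic signal\n")
  cat("  n =", x$n, " lambda =", format(x$lambda, digits = 4), "\n")
  cat("  LR(lambda = 0) =", format(x$lr_stat, digits = 4),
      " p =", format(x$p_value, digits = 4),
      if (x$mixture) "(boundary mixture null)" else "(chi-square 1 df)", "\n")
  invisible(x)
}

# Penalized IRLS for the joint mode of (beta, u) in the logistic phylogenetic
# mixed model, at fixed random-effect covariance Sigma = sigma2 * C.
# Returns the joint mode and the Laplace-approximate marginal log-likelihood.
plogit_inner <- function(y, X, Sigma_inv, logdet_Sigma, beta, u,
                         max_iter = 100, tol = 1e-10) {
  n <- length(y)
  p <- ncol(X)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta + u)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    # solve the joint penalized weighted LS in (beta, u)
    A11 <- crossprod(X, X * w)
    A12 <- t(X * w)
    A22 <- diag(w, n) + Sigma_inv
    A <- rbind(cbind(A11, A12), cbind(t(A12), A22))
    b <- c(crossprod(X, w * z), w * z)
    theta <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(theta)) return(NULL)
    beta_new <- theta[seq_len(p)]
    u_new <- theta[-seq_len(p)]
    if (max(abs(beta_new - beta), abs(u_new - u)) < tol) {
      beta <- beta_new; u <- u_new; break
    }
    beta <- beta_new; u <- u_new
  }
  eta <- drop(X %*% beta + u)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  log1pexp <- pmax(eta, 0) + log1p(exp(-abs(eta)))   # stable log(1 + e^eta)
  f <- sum(y * eta - log1pexp) - 0.5 * drop(crossprod(u, Sigma_inv %*% u))
  H22 <- diag(w, n) + Sigma_inv
  cholH <- tryCatch(chol(H22), error = function(e) NULL)
  if (is.null(cholH)) return(NULL)
  laplace <- f - 0.5 * logdet_Sigma - sum(log(diag(cholH)))
  list(beta = beta, u = u, w = w, loglik = laplace, eta = eta)
}

#' Phylogenetic logistic regression (Laplace-approximated ML)
#'
#' Fits `logit P(y = 1) = X beta + u`, `u ~ MVN(0, sigma^2 C)` where `C` is
#' the phylogenetic covariance standardized to unit mean diagonal (so the fit
#' is invariant to rescaling of branch lengths, with `sigma^2` absorbing the
#' scale). The random effect is integrated out by a Laplace approximation:
#' an inner penalized IRLS finds the joint mode of `(beta, u)` and an outer
#' bounded search maximizes the approximate marginal likelihood over
#' `sigma^2`. This is the maximum-likelihood counterpart of a Bayesian
#' Bernoulli phylogenetic mixed model; its canonical use here regresses
#' high-vs-low habitat occupancy on relative brain size.
#'
#' @param y binary response (0/1), named by species or aligned with `V`.
#' @param x numeric predictor, same species.
#' @param V phylogenetic covariance matrix with species dimnames.
#' @param sigma2_max upper bound of the `sigma^2` search.
#' @param sigma2_fixed optional; fix `sigma^2` at this value (0 gives an
#'   ordinary logistic regression) instead of estimating it.
#' @param beta_bound absolute coefficient value beyond which complete
#'   separation is declared.
#' @return an object of class `"phylo_logit"` with `coefficients` (`beta0`,
#'   `beta1`), `sigma2`, `se`, `r2_analogue` (latent-scale variance
#'   partition, logistic residual variance `pi^2/3`), `loglik`, `converged`,
#'   `n_used`, `u` (fitted random effects).
#' @export
phylo_logit <- function(y, x, V, sigma2_max = 20, sigma2_fixed = NULL,
                        beta_bound = 15) {
  if (!is.null(names(y))) {
    common <- intersect(rownames(V), names(y))
    y <- y[common]; x <- x[common]
    V <- V[common, common, drop = FALSE]
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2) stop("both response classes must be present")
  if (length(y) != length(x) || length(y) != nrow(V)) stop("y, x, V misaligned")
  n <- length(y)
  C <- V / mean(diag(V))                     # unit mean diagonal
  X <- cbind(`(Intercept)` = 1, x = as.numeric(x))

  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(ev$values)) stop("V is not positive semi-definite")
  ridge <- max(ev$values) * 1e-10
  C_inv <- ev$vectors %*% (t(ev$vectors) / (ev$values + ridge))
  logdet_C <- sum(log(ev$values + ridge))

  fit_at <- function(log_s2, state) {
    s2 <- exp(log_s2)
    plogit_inner(y, X, C_inv / s2, n * log(s2) + logdet_C,
                 state$beta, state$u)
  }
  state <- list(beta = c(0, 0), u = rep(0, n))
  obj <- function(log_s2) {
    r <- fit_at(log_s2, state)
    if (is.null(r)) return(-1e10)
    state$beta <<- r$beta; state$u <<- r$u
    r$loglik
  }
  if (!is.null(sigma2_fixed)) {
    stopifnot(sigma2_fixed >= 0)
    lv <- log(max(sigma2_fixed, 1e-10))
    opt <- list(maximum = lv, objective = obj(lv))
  } else {
    opt <- stats::optimize(obj, c(log(1e-6), log(sigma2_max)), maximum = TRUE,
                           tol = 1e-6)
    # the profile is flat near zero variance; snap to the boundary if it wins
    ll_floor <- obj(log(1e-8))
    if (ll_floor >= opt$objective - 1e-8) {
      opt <- list(maximum = log(1e-8), objective = ll_floor)
    }
  }
  s2 <- exp(opt$maximum)
  res <- fit_at(opt$maximum, state)
  if (is.null(res)) stop("phylogenetic logistic fit failed to converge")
  if (max(abs(res$beta)) > beta_bound) {
    stop("apparent complete separation (|beta| > ", beta_bound,
         "); consider penalization or more data")
  }
  if (s2 <= 1e-7 || isTRUE(sigma2_fixed == 0)) s2 <- 0

  # SEs from the marginal working information: Var(beta) ~ (X' M X)^-1 with
  # M = (W^-1 + sigma2 C)^-1 at the joint mode
  Winv <- 1 / res$w
  Mmat <- solve(diag(Winv, n) + s2 * C)
  info <- crossprod(X, Mmat %*% X)
  se <- sqrt(diag(solve(info)))
  names(se) <- colnames(X)

  lin <- drop(X %*% res$beta)
  r2 <- stats::var(lin) / (stats::var(lin) + s2 + pi^2 / 3)

  structure(list(
    coefficients = stats::setNames(res$beta, c("beta0", "beta1")),
    sigma2 = s2, se = se, r2_analogue = r2, loglik = opt$objective,
    converged = TRUE, n_used = n, u = res$u,
    fitted = stats::plogis(res$eta), species = rownames(V)
  ), class = "phylo_logit")
}

#' @export
print.phylo_logit <- function(x, ...) {
  cat("Phylogenetic logistic regression (Laplace ML)\n")
  cat("  n =", x$n_used, " sigma2 =", format(x$sigma2, digits = 4), "\n")
  cat("  beta0 =", format(x$coefficients[1], digits = 4),
      " beta1 =", format(x$coefficients[2], digits = 4),
      " (se", format(x$se[2], digits = 3), ")\n")
  cat("  latent-scale R2 analogue =", format(x$r2_analogue, digits = 3), "\n")
  invisible(x)
}

#' @export
coef.phylo_logit <- function(object, ...) object$coefficients

#' @export
summary.phylo_logit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(fit = object, coef_table = tab)
  class(out) <- "summary.phylo_logit"
  out
}

#' @export
print.summary.phylo_logit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficient table:\n")
  print(x$coef_table)
  invisible(x)
}

#' Two-sample rank-sum (Wilcoxon-Mann-Whitney) test
#'
#' Two-sided test of distributional difference between two groups using
#' midranks for ties. The p-value is computed by exact enumeration of all
#' group assignments when `n_a + n_b <= exact_max`, and by the tie-corrected
#' normal approximation otherwise.
#'
#' @param a,b numeric vectors (both nonempty).
#' @param exact_max largest combined sample size for exact enumeration.
#' @return a list with `statistic` (rank-sum W of group a), `p_value`,
#'   `n_a`, `n_b`, `method`.
#' @export
rank_sum_test <- function(a, b, exact_max = 12) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  pooled <- c(a, b)
  r <- rank(pooled)           # midranks for ties
  W <- sum(r[seq_len(n_a)])
  mu <- n_a * (n + 1) / 2
  if (n <= exact_max) {
    combs <- utils::combn(n, n_a)
    Ws <- colSums(matrix(r[combs], nrow = n_a))
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
    method <- "exact enumeration (midranks)"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sig2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    z <- max(0, abs(W - mu) - 0.5) / sqrt(sig2)    # continuity-corrected
    p <- 2 * stats::pnorm(-z)
    method <- "normal approximation with tie correction"
  }
  list(statistic = W, p_value = min(1, p), n_a = n_a, n_b = n_b, method = method)
}
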