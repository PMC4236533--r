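#' Logistic regression by generalized estimating equations
#'
#' Fits a marginal logistic model to clustered binary data by GEE with an
#' exchangeable (or independence) working correlation, the standard moment
#' estimators for the dispersion and the common intra-cluster correlation,
#' and the robust (sandwich) covariance of Liang and Zeger. Pan's
#' quasi-likelihood information criterion (QIC) is returned for model
#' comparison. The exchangeable working-correlation inverse is applied in
#' closed form, so clusters never materialize a correlation matrix and fits
#' with thousands of clusters take well under a second.
#'
#' @param formula Model formula with a binary (0/1 or logical) response.
#' @param data A data frame.
#' @param id Unquoted column in `data` identifying the cluster.
#' @param corstr `"exchangeable"` (default) or `"independence"`.
#' @param maxit,tol Scoring iterations and convergence tolerance on the
#'   max absolute coefficient update.
#' @return An object of class `gee_logit` with coefficients, robust and
#'   model-based covariances, the working correlation `alpha`, dispersion
#'   `phi`, `qic`, and the model frame (for refits during selection).
#' @export
gee_logit <- function(formula, data, id, corstr = c("exchangeable",
                                                    "independence"),
                      maxit = 50L, tol = 1e-8) {
  corstr <- match.arg(corstr)
  id_quo <- rlang::enquo(id)
  id_var <- if (rlang::quo_is_symbol(id_quo)) {
    rlang::as_name(id_quo)
  } else {
    rlang::eval_tidy(id_quo)
  }
  data <- as.data.frame(data)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.numeric(y)
  if (is.factor(y)) y <- as.numeric(y) - 1
  X <- model.matrix(attr(mf, "terms"), mf)
  cl <- factor(data[[id_var]][as.integer(rownames(mf))])
  # drop empty and aliased columns so saturated-but-sparse designs stay
  # invertible; callers are warned upstream with cell names
  keep <- colSums(abs(X)) > 0
  X <- X[, keep, drop = FALSE]
  qx <- qr(X)
  dropped_aliased <- character(0)
  if (qx$rank < ncol(X)) {
    aliased <- qx$pivot[(qx$rank + 1):ncol(X)]
    dropped_aliased <- colnames(X)[aliased]
    warn(paste("Dropping aliased design column(s):",
               paste(dropped_aliased, collapse = ", ")))
    X <- X[, -aliased, drop = FALSE]
  }
  p <- ncol(X)
  n <- length(y)

  csize <- as.integer(table(cl)[levels(cl)])
  n_pairs <- sum(csize * (csize - 1) / 2)

  # Fisher scoring; columns whose information vanishes (quasi-separated
  # cells where the working weights collapse to zero) are dropped with a
  # warning and the fit restarts on the reduced design.
  repeat {
    p <- ncol(X)
    beta <- suppressWarnings(glm.fit(X, y, family = binomial()))$coefficients
    alpha <- 0
    degenerate <- integer(0)
    delta <- Inf
    for (it in seq_len(maxit)) {
      eta <- drop(X %*% beta)
      mu <- plogis(eta)
      # floor the working weights so saturated fitted probabilities
      # (separated cells) cannot produce 0/0 residuals
      w <- pmax(mu * (1 - mu), 1e-10)
      r <- (y - mu) / sqrt(w)            # Pearson residuals
      phi <- sum(r^2) / (n - p)
      if (corstr == "exchangeable" && n_pairs > p) {
        rs <- rowsum(r, cl)
        alpha <- (sum(rs^2) - sum(r^2)) / 2 / (phi * (n_pairs - p))
        alpha <- min(max(alpha, -0.99 / max(csize)), 0.99)
      }
      # With a logit link, D = W X and A = W, so D'V^{-1}D reduces to
      # (1/phi) * Zt R^{-1} Z with Z = sqrt(w) X, and the exchangeable
      # inverse R^{-1} = [I - c J] / (1 - alpha), c = alpha/(1+(m-1)alpha).
      Z <- X * sqrt(w)
      s <- r
      G <- rowsum(Z, cl)                     # per-cluster column sums of Z
      S <- drop(rowsum(s, cl))
      cvec <- alpha / (1 + (csize - 1) * alpha)
      H <- (crossprod(Z) - crossprod(G, G * cvec)) / (1 - alpha) / phi
      U <- (crossprod(Z, s) - crossprod(G, cvec * S)) / (1 - alpha) / phi
      dH <- diag(H)
      degenerate <- which(!is.finite(dH) |
                            dH < max(dH[is.finite(dH)]) * 1e-8)
      if (length(degenerate) > 0) break
      delta <- solve(H, U)
      beta <- beta + drop(delta)
      if (max(abs(delta)) < tol) break
    }
    if (length(degenerate) == 0) break
    warn(paste("Dropping quasi-separated design column(s):",
               paste(colnames(X)[degenerate], collapse = ", ")))
    dropped_aliased <- c(dropped_aliased, colnames(X)[degenerate])
    X <- X[, -degenerate, drop = FALSE]
  }
  converged <- max(abs(delta)) < tol

  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  Z <- X * sqrt(w)
  s <- (y - mu) / sqrt(w)
  G <- rowsum(Z, cl)
  S <- drop(rowsum(s, cl))
  cvec <- alpha / (1 + (csize - 1) * alpha)
  H <- (crossprod(Z) - crossprod(G, G * cvec)) / (1 - alpha) / phi
  # per-cluster score contributions D'V^{-1}(y - mu)
  Uc <- (rowsum(Z * s, cl) - (cvec * S) * G) / (1 - alpha) / phi
  meat <- crossprod(as.matrix(Uc))
  bread <- solve(H)
  vrobust <- bread %*% meat %*% bread
  dimnames(vrobust) <- list(colnames(X), colnames(X))

  # Pan's QIC: -2 QL(mu; independence) + 2 trace(Omega_I %*% V_robust),
  # Omega_I the naive information under an independence working model.
  ql <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  omega_i <- crossprod(Z)
  qic <- -2 * ql + 2 * sum(diag(omega_i %*% vrobust))

  structure(
    list(coefficients = setNames(drop(beta), colnames(X)),
         vcov_robust = vrobust, vcov_naive = bread,
         alpha = alpha, phi = phi, qic = qic, converged = converged,
         iterations = it, n = n, n_clusters = nlevels(cl),
         formula = formula, corstr = corstr, id_var = id_var,
         data = data,
         dropped_columns = c(names(keep)[!keep], dropped_aliased)),
    class = "gee_logit"
  )
}

#' @export
print.gee_logit <- function(x, ...) {
  cat("GEE logistic regression (", x$corstr, " working correlation)\n",
      sep = "")
  cat(sprintf("n = %d observations in %d clusters; alpha = %.4f; QIC = %.1f\n",
              x$n, x$n_clusters, x$alpha, x$qic))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
coef.gee_logit <- function(object, ...) object$coefficients

#' @export
vcov.gee_logit <- function(object, robust = TRUE, ...) {
  if (robust) object$vcov_robust else object$vcov_naive
}

#' Tidy a GEE logistic fit
#'
#' @param x A `gee_logit` object.
#' @param exponentiate Report odds ratios (and CIs) instead of log-odds.
#' @param conf.level Confidence level for Wald intervals on robust SEs.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @method tidy gee_logit
#' @export
tidy.gee_logit <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov_robust))
  z <- est / se
  q <- qnorm(1 - (1 - conf.level) / 2)
  out <- tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(z), p.value = unname(2 * pnorm(-abs(z))),
    conf.low = unname(est - q * se), conf.high = unname(est + q * se)
  )
  if (exponentiate) {
    out <- mutate(out, across(c("estimate", "conf.low", "conf.high"), exp))
  }
  out
}

#' @method glance gee_logit
#' @export
glance.gee_logit <- function(x, ...) {
  tibble(n = x$n, n_clusters = x$n_clusters, alpha = x$alpha, phi = x$phi,
         qic = x$qic, converged = x$converged, iterations = x$iterations)
}

#' Joint Wald test of a model term (robust covariance)
#'
#' @param fit A `gee_logit` fit (or any object with `coef` and a covariance).
#' @param cols Names of the coefficient columns belonging to the term.
#' @param V Covariance matrix to use.
#' @return p-value of the chi-square Wald test.
#' @keywords internal
wald_term_p <- function(est, V, cols) {
  cols <- intersect(cols, names(est))
  if (length(cols) == 0) return(NA_real_)
  b <- est[cols]
  Vb <- V[cols, cols, drop = FALSE]
  stat <- drop(t(b) %*% solve(Vb, b))
  pchisq(stat, df = length(cols), lower.tail = FALSE)
}
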