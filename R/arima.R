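#' Noise model specification: subset ARMA with differencing
#'
#' The noise term of the transfer model follows
#' \deqn{(1 - \sum_j \phi_j B^j)(1-B)^d N_t = (1 + \sum_k \theta_k B^k)\varepsilon_t,}
#' with free coefficients only at the configured lags ("subset" AR/MA:
#' intermediate lags are fixed at zero). The default, AR at lags 1 and 5 with
#' no differencing, encodes weekly "memory" one and five weeks back.
#'
#' @param ar_lags integer lags with free AR coefficients
#' @param ma_lags integer lags with free MA coefficients
#' @param d differencing order, 0 or 1
#' @return a `noise_spec`
#' @export
noise_spec <- function(ar_lags = c(1L, 5L), ma_lags = integer(0), d = 0L) {
  ar_lags <- sort(unique(as.integer(ar_lags)))
  ma_lags <- sort(unique(as.integer(ma_lags)))
  stopifnot(all(ar_lags >= 1), all(ma_lags >= 1), d %in% c(0L, 1L))
  structure(list(ar_lags = ar_lags, ma_lags = ma_lags, d = as.integer(d)),
            class = "noise_spec")
}

#' Transfer model specification
#'
#' Structural part of the model
#' \eqn{y_t = \alpha + \beta x_t + \omega I_t + N_t}: whether the
#' contemporaneous control series enters, the intervention indicator (if
#' any), the noise model, and how many initial weeks are dropped from
#' residual reporting.
#'
#' @param noise a [noise_spec()]
#' @param include_control include the contemporaneous control regressor
#' @param intervention binary indicator vector (length T) or `NULL`
#' @param burn_in_weeks initial weeks excluded from reported residuals
#' @return a `transfer_model_spec`
#' @export
transfer_model_spec <- function(noise = noise_spec(), include_control = TRUE,
                                intervention = NULL, burn_in_weeks = 6L) {
  stopifnot(inherits(noise, "noise_spec"), burn_in_weeks >= 0)
  if (!is.null(intervention)) stopifnot(all(intervention %in% c(0, 1)))
  structure(list(noise = noise, include_control = isTRUE(include_control),
                 intervention = intervention,
                 burn_in_weeks = as.integer(burn_in_weeks)),
            class = "transfer_model_spec")
}

# full-length AR/MA coefficient vectors (zeros at fixed lags)
.expand_lags <- function(values, lags, maxlag) {
  out <- numeric(maxlag)
  out[lags] <- values
  out
}

ar_stationary <- function(phi) {
  if (length(phi) == 0 || all(phi == 0)) return(TRUE)
  all(Mod(polyroot(c(1, -phi))) > 1)
}

ma_invertible <- function(theta) {
  if (length(theta) == 0 || all(theta == 0)) return(TRUE)
  all(Mod(polyroot(c(1, theta))) > 1)
}

# Kalman whitening of each column of M under a unit-variance ARMA model.
# Harvey state-space form; returns scaled innovations E (rows t, cols of M)
# with Var(E_t) = sigma2 for a series generated with innovation variance
# sigma2, plus the log-determinant term sum(log F_t).
kalman_whiten <- function(M, phi, theta) {
  M <- as.matrix(M)
  Tn <- nrow(M); k <- ncol(M)
  p <- length(phi); q <- length(theta)
  if (p == 0 && q == 0) return(list(E = M, logdet = 0))
  m <- max(p, q + 1L)
  phi_m <- c(phi, numeric(m - p))
  Tmat <- matrix(0, m, m)
  Tmat[, 1] <- phi_m
  if (m > 1) Tmat[cbind(1:(m - 1), 2:m)] <- 1
  R <- c(1, theta, numeric(m - 1L - q))
  # stationary state covariance: P = T P T' + R R'
  P <- matrix(solve(diag(m * m) - kronecker(Tmat, Tmat), as.vector(R %o% R)), m, m)
  A <- matrix(0, m, k)          # per-column state means
  E <- matrix(0, Tn, k)
  logdet <- 0
  RR <- R %o% R
  steady <- FALSE
  Fv_prev <- Inf
  K <- numeric(m); Fv <- 1
  sqFv <- 1
  for (t in seq_len(Tn)) {
    A <- Tmat %*% A
    if (!steady) {  # gain sequence converges quickly; freeze at steady state
      P <- Tmat %*% P %*% t(Tmat) + RR
      Fv <- P[1, 1]
      K <- P[, 1] / Fv
      P <- P - K %o% P[1, ]
      sqFv <- sqrt(Fv)
      if (abs(Fv - Fv_prev) < 1e-12 * Fv) steady <- TRUE
      Fv_prev <- Fv
    }
    v <- M[t, ] - A[1, ]
    A <- A + K %o% v
    E[t, ] <- v / sqFv
    logdet <- logdet + log(Fv)
  }
  list(E = E, logdet = logdet)
}

# Conditional (CSS) whitening: filter rows maxlag+1..T of each column through
# the AR polynomial, then invert the MA part with zero pre-sample innovations.
css_whiten <- function(M, phi, theta) {
  M <- as.matrix(M)
  Tn <- nrow(M)
  p <- length(phi); q <- length(theta)
  if (p == 0 && q == 0) return(list(E = M, logdet = 0, drop = 0L))
  if (Tn <= p) stop("series shorter than the AR order")
  W <- M[(p + 1):Tn, , drop = FALSE]
  for (j in seq_len(p)) {
    if (phi[j] != 0) W <- W - phi[j] * M[(p + 1 - j):(Tn - j), , drop = FALSE]
  }
  if (q > 0 && any(theta != 0)) {
    W <- apply(W, 2, function(col)
      stats::filter(col, -theta, method = "recursive", init = numeric(q)))
    W <- matrix(W, ncol = ncol(M))
  }
  list(E = W, logdet = 0, drop = p)
}

.whiten <- function(M, phi, theta, method) {
  if (method == "exact") c(kalman_whiten(M, phi, theta), drop = 0L)
  else css_whiten(M, phi, theta)
}

# Design matrix for the structural regression
tf_design <- function(pair, spec, xreg = NULL) {
  y <- pair$dependent$counts
  X <- cbind("(Intercept)" = rep(1, length(y)))
  if (spec$include_control) X <- cbind(X, control = pair$control$counts)
  if (!is.null(spec$intervention)) {
    if (length(spec$intervention) != length(y))
      stop("intervention indicator length does not match the series")
    X <- cbind(X, intervention = spec$intervention)
  }
  if (!is.null(xreg)) {
    xreg <- as.matrix(xreg)
    if (nrow(xreg) != length(y)) stop("xreg length does not match the series")
    X <- cbind(X, xreg)
  }
  if (spec$noise$d == 1L) {
    y <- diff(y)
    X <- apply(X, 2, diff)
    X <- X[, colSums(abs(X)) > 0, drop = FALSE]  # differencing kills the intercept
  }
  list(y = y, X = X)
}

#' Gaussian log-likelihood of the transfer model at given parameters
#'
#' Evaluates the exact (state-space) or conditional-sum-of-squares Gaussian
#' log-likelihood of \eqn{y_t = \alpha + \beta x_t + \omega I_t + N_t} with
#' subset-ARMA noise. With all ARMA coefficients zero and `d = 0` this equals
#' the ordinary-least-squares Gaussian log-likelihood of the regression.
#'
#' @param params named list with `reg` (regression coefficients, design
#'   order), `phi` (free AR coefficients, `ar_lags` order), `theta` (free MA
#'   coefficients), `sigma2` (innovation variance)
#' @param pair a [series_pair()]
#' @param spec a [transfer_model_spec()]
#' @param xreg optional additional regressors (e.g. outlier terms)
#' @param method `"exact"` for the state-space likelihood, `"css"` for the
#'   conditional likelihood (conditions on the first max-lag observations)
#' @return log-likelihood (scalar)
#' @export
model_loglik <- function(params, pair, spec, xreg = NULL,
                         method = c("exact", "css")) {
  method <- match.arg(method)
  stopifnot(inherits(pair, "series_pair"), inherits(spec, "transfer_model_spec"))
  d <- tf_design(pair, spec, xreg)
  if (length(params$reg) != ncol(d$X))
    stop("params$reg length ", length(params$reg), " != ", ncol(d$X), " regressors")
  if (!all(is.finite(unlist(params)))) stop("non-finite parameters")
  if (params$sigma2 <= 0) stop("sigma2 must be positive")
  ns <- spec$noise
  phi <- .expand_lags(params$phi %||% numeric(length(ns$ar_lags)), ns$ar_lags,
                      if (length(ns$ar_lags)) max(ns$ar_lags) else 0L)
  theta <- .expand_lags(params$theta %||% numeric(length(ns$ma_lags)), ns$ma_lags,
                        if (length(ns$ma_lags)) max(ns$ma_lags) else 0L)
  if (!ar_stationary(phi)) stop("AR polynomial is not stationary")
  resid <- d$y - drop(d$X %*% params$reg)
  w <- .whiten(matrix(resid, ncol = 1), phi, theta, method)
  n <- nrow(w$E)
  -n / 2 * log(2 * pi * params$sigma2) - w$logdet / 2 -
    sum(w$E^2) / (2 * params$sigma2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Profile (concentrated) -loglik over free ARMA params; regression
# coefficients solved by GLS on the whitened design, sigma2 concentrated out.
.tf_profile <- function(arma_free, y, X, ns, method) {
  n_ar <- length(ns$ar_lags)
  phi <- .expand_lags(arma_free[seq_len(n_ar)], ns$ar_lags,
                      if (n_ar) max(ns$ar_lags) else 0L)
  theta <- .expand_lags(arma_free[n_ar + seq_len(length(ns$ma_lags))], ns$ma_lags,
                        if (length(ns$ma_lags)) max(ns$ma_lags) else 0L)
  if (!ar_stationary(phi) || !ma_invertible(theta)) return(NULL)
  w <- tryCatch(.whiten(cbind(y, X), phi, theta, method),
                error = function(e) NULL)  # near-unit-root state init
  if (is.null(w)) return(NULL)
  yw <- w$E[, 1]; Xw <- w$E[, -1, drop = FALSE]
  qx <- qr(Xw)
  if (qx$rank < ncol(Xw)) return(NULL)
  b <- qr.coef(qx, yw)
  rw <- yw - drop(Xw %*% b)
  n <- length(yw)
  s2 <- sum(rw^2) / n
  ll <- -n / 2 * (log(2 * pi * s2) + 1) - w$logdet / 2
  list(ll = ll, b = b, sigma2 = s2, phi = phi, theta = theta, qx = qx,
       Xw = Xw, yw = yw, n = n)
}

# central-difference Hessian
num_hessian <- function(f, x, h = NULL) {
  k <- length(x)
  if (is.null(h)) h <- pmax(1e-4, 1e-4 * abs(x))
  H <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    ei <- ej <- numeric(k); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- H[j, i] <- (f(x + ei + ej) - f(x + ei - ej) -
                           f(x - ei + ej) + f(x - ei - ej)) / (4 * h[i] * h[j])
  }
  H
}

#' Fit the transfer model by Gaussian maximum likelihood
#'
#' Maximizes the likelihood of [model_loglik()] over the regression
#' coefficients and the free subset-ARMA coefficients. Regression
#' coefficients are profiled by generalized least squares on the whitened
#' design at each candidate ARMA point; the innovation variance is
#' concentrated out. Standard errors come from the observed information
#' (inverse numerical Hessian of the profile log-likelihood at the optimum),
#' with 95% intervals at estimate ± 1.96·SE and two-tailed z tests.
#'
#' @inheritParams model_loglik
#' @param start optional numeric vector of starting values for the free ARMA
#'   coefficients (defaults to zero, i.e. the OLS solution)
#' @param reltol convergence tolerance on the log-likelihood
#' @return a `tf_fit` object: coefficient table (`coef`, `se`, `ci95`,
#'   `z`, `p_value`), `phi`/`theta` maps, `sigma2`, `loglik`, innovation
#'   `residuals` (burn-in weeks dropped), `fitted`, flags
#' @export
fit_transfer_model <- function(pair, spec = transfer_model_spec(), xreg = NULL,
                               method = c("exact", "css"), start = NULL,
                               reltol = 1e-10) {
  method <- match.arg(method)
  stopifnot(inherits(pair, "series_pair"), inherits(spec, "transfer_model_spec"))
  d <- tf_design(pair, spec, xreg)
  ns <- spec$noise
  n_free <- length(ns$ar_lags) + length(ns$ma_lags)
  maxlag <- max(c(ns$ar_lags, ns$ma_lags, 0))
  if (length(d$y) <= maxlag + ncol(d$X) + n_free)
    stop("series too short for the requested model")

  if (n_free == 0) {
    prof <- .tf_profile(numeric(0), d$y, d$X, ns, method)
    if (is.null(prof)) stop("singular design matrix")
    arma_hat <- numeric(0); converged <- TRUE
  } else {
    par0 <- start %||% numeric(n_free)
    fn <- function(par) {
      prof <- .tf_profile(par, d$y, d$X, ns, method)
      if (is.null(prof)) return(1e10)
      -prof$ll
    }
    opt <- if (n_free == 1) {
      stats::optim(par0, fn, method = "Brent", lower = -0.999, upper = 0.999,
                   control = list(reltol = reltol))
    } else {
      stats::optim(par0, fn, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = 5000))
    }
    if (n_free >= 2) {  # polish from the simplex solution
      opt2 <- tryCatch(stats::optim(opt$par, fn, method = "BFGS",
                                    control = list(reltol = reltol)),
                       error = function(e) NULL)
      if (!is.null(opt2) && opt2$value <= opt$value) opt <- opt2
    }
    if (opt$value >= 1e10)
      stop("optimizer failed to find a stationary, invertible model")
    arma_hat <- opt$par
    converged <- opt$convergence == 0
    prof <- .tf_profile(arma_hat, d$y, d$X, ns, method)
    if (!converged)
      warning("optimizer did not report convergence; returning best point found")
  }

  b <- prof$b
  k_reg <- length(b)
  est <- c(b, arma_hat)
  # observed information on (regression coefs, free ARMA coefs)
  f_full <- function(par) {
    bb <- par[seq_len(k_reg)]
    aa <- par[k_reg + seq_len(n_free)]
    pr <- .tf_profile_at(aa, bb, d$y, d$X, ns, method)
    if (is.null(pr)) return(1e10)
    -pr
  }
  if (n_free == 0) {
    # profile likelihood is exactly quadratic in b: closed-form information
    vc <- prof$sigma2 * solve(crossprod(prof$Xw))
  } else {
    H <- num_hessian(f_full, est)
    vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(est), length(est)))
  }
  se <- sqrt(pmax(diag(vc), 0))

  nm_arma <- c(paste0("AR(", ns$ar_lags, ")", recycle0 = TRUE),
               paste0("MA(", ns$ma_lags, ")", recycle0 = TRUE))
  names(est) <- names(se) <- c(colnames(d$X), nm_arma)
  ci95 <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  z <- est / se
  pval <- 2 * stats::pnorm(-abs(z))

  w <- .whiten(cbind(d$y, d$X), prof$phi, prof$theta, method)
  resid_all <- w$E[, 1] - drop(w$E[, -1, drop = FALSE] %*% b)
  Tn <- length(pair$dependent$counts)
  week_idx <- seq.int(Tn - length(resid_all) + 1L, Tn)  # css drops leading weeks
  keep <- week_idx > spec$burn_in_weeks
  residuals <- stats::setNames(resid_all[keep], week_idx[keep])

  near_unit <- length(prof$phi) > 0 && any(prof$phi != 0) &&
    min(Mod(polyroot(c(1, -prof$phi)))) < 1.001
  if (near_unit) warning("AR roots close to the unit circle at the optimum")

  structure(list(
    coef = est, se = se, ci95 = ci95, z = z, p_value = pval,
    beta_control = unname(est["control"])[1],
    omega_intervention = unname(est["intervention"])[1],
    phi = stats::setNames(prof$phi[ns$ar_lags], ns$ar_lags),
    theta = if (length(ns$ma_lags)) stats::setNames(prof$theta[ns$ma_lags], ns$ma_lags) else numeric(0),
    sigma2 = prof$sigma2, loglik = prof$ll,
    residuals = residuals,
    fitted = drop(d$X %*% b),
    n = length(d$y), n_free_arma = n_free, k_reg = k_reg,
    converged = converged, near_nonstationary = near_unit,
    method = method, spec = spec, xreg_names = colnames(xreg),
    vcov = vc
  ), class = "tf_fit")
}

# -loglik at explicit regression + ARMA point (sigma2 concentrated)
.tf_profile_at <- function(arma_free, b, y, X, ns, method) {
  n_ar <- length(ns$ar_lags)
  phi <- .expand_lags(arma_free[seq_len(n_ar)], ns$ar_lags,
                      if (n_ar) max(ns$ar_lags) else 0L)
  theta <- .expand_lags(arma_free[n_ar + seq_len(length(ns$ma_lags))], ns$ma_lags,
                        if (length(ns$ma_lags)) max(ns$ma_lags) else 0L)
  if (!ar_stationary(phi) || !ma_invertible(theta)) return(NULL)
  resid <- y - drop(X %*% b)
  w <- tryCatch(.whiten(matrix(resid, ncol = 1), phi, theta, method),
                error = function(e) NULL)
  if (is.null(w)) return(NULL)
  n <- nrow(w$E)
  s2 <- sum(w$E^2) / n
  -n / 2 * (log(2 * pi * s2) + 1) - w$logdet / 2
}

#' @export
print.tf_fit <- function(x, ...) {
  cat(sprintf("Transfer model fit (%s likelihood), T = %d, loglik = %.3f\n",
              x$method, x$n, x$loglik))
  tab <- data.frame(estimate = x$coef, se = x$se,
                    ci_lower = x$ci95[, 1], ci_upper = x$ci95[, 2],
                    z = x$z, p = x$p_value)
  print(round(tab, 4))
  cat(sprintf("sigma^2 = %.3f\n", x$sigma2))
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' Parameter rows are named after the model roles (control series
#' coefficient, AR lags, intervention term) so reports read like the standard
#' coefficient table of an intervention analysis.
#' @param fit a `tf_fit`
#' @param path output path
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "tf_fit"))
  params <- lapply(seq_along(fit$coef), function(i) {
    list(name = names(fit$coef)[i], estimate = fit$coef[[i]], se = fit$se[[i]],
         ci95 = c(fit$ci95[i, 1], fit$ci95[i, 2]), p_value = fit$p_value[[i]])
  })
  jsonlite::write_json(list(parameters = params, sigma2 = fit$sigma2,
                            loglik = fit$loglik, n = fit$n,
                            method = fit$method),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
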