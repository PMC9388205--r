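#' Outlier scan configuration
#'
#' Iterative detection of additive outliers (AO), temporary changes (TC) and
#' level shifts (LS) in the fitted transfer model, at a fixed |t| threshold.
#'
#' @param t_threshold detection threshold on |t| (the conventional 3.5
#'   implies a per-candidate two-sided tail probability of about 4.7e-4)
#' @param types_enabled subset of `c("AO","TC","LS")`
#' @param tc_delta geometric decay rate of the TC pattern, strictly in (0,1)
#' @param max_outliers cap on accepted outliers
#' @param robust_sigma standardize screening statistics by the MAD of the
#'   whitened residuals instead of the ML innovation SD (optional guard
#'   against scale inflation by large additive outliers)
#' @param bootstrap_threshold provisional |t| threshold for the internal
#'   de-biasing pass (see [detect_and_adjust()]); only detections clearing
#'   `t_threshold` in the final pass are reported
#' @return an `outlier_config`
#' @export
outlier_config <- function(t_threshold = 3.5,
                           types_enabled = c("AO", "TC", "LS"),
                           tc_delta = 0.7, max_outliers = 10L,
                           robust_sigma = FALSE, bootstrap_threshold = 3.0) {
  stopifnot(t_threshold > 0, tc_delta > 0, tc_delta < 1,
            all(types_enabled %in% c("AO", "TC", "LS")), length(types_enabled) > 0,
            bootstrap_threshold > 0)
  structure(list(t_threshold = t_threshold, types_enabled = types_enabled,
                 tc_delta = tc_delta, max_outliers = as.integer(max_outliers),
                 robust_sigma = isTRUE(robust_sigma),
                 bootstrap_threshold = bootstrap_threshold),
            class = "outlier_config")
}

#' Outlier regressor patterns
#'
#' AO: unit pulse at `week`. LS: unit step from `week` onward. TC: pulse at
#' `week` decaying as `delta^(t - week)` afterwards.
#'
#' @param type one of `"AO"`, `"TC"`, `"LS"`
#' @param week 1-based week index of onset
#' @param delta TC decay rate (ignored for AO/LS)
#' @param series_length series length T
#' @return numeric vector of length T
#' @export
outlier_regressor <- function(type, week, delta = 0.7, series_length) {
  week <- as.integer(week); Tn <- as.integer(series_length)
  stopifnot(week >= 1, week <= Tn)
  v <- numeric(Tn)
  switch(type,
    AO = { v[week] <- 1 },
    LS = { v[week:Tn] <- 1 },
    TC = { v[week:Tn] <- delta^(0:(Tn - week)) },
    stop("unknown outlier type: ", type))
  v
}

# type precedence for tie-breaking: LS > TC > AO
.TYPE_ORDER <- c(LS = 1L, TC = 2L, AO = 3L)

#' t statistics of every candidate outlier regressor
#'
#' For each enabled type and week, the t statistic of that regressor's
#' coefficient when added to the current model with all other parameters
#' held at their current estimates: structural residuals and the candidate
#' pattern are whitened through the fitted ARMA polynomial (conditional
#' filter) and the candidate coefficient is estimated on the whitened scale.
#' Under a pure white-noise model the AO statistic at week w reduces to the
#' standardized residual at w. Candidates collinear with the existing design
#' (e.g. a level shift at week 1 versus the intercept) are skipped.
#'
#' @param fit current `tf_fit`
#' @param pair the [series_pair()] the fit used
#' @param spec the [transfer_model_spec()] the fit used
#' @param config an [outlier_config()]
#' @param xreg extra regressors already in the model (accepted outliers)
#' @return data.frame `type, week, magnitude, t_stat`, one row per retained
#'   candidate
#' @export
scan_t_stats <- function(fit, pair, spec, config = outlier_config(), xreg = NULL) {
  stopifnot(inherits(fit, "tf_fit"), inherits(config, "outlier_config"))
  d <- tf_design(pair, spec, xreg)
  Tn <- length(d$y)
  b <- fit$coef[seq_len(fit$k_reg)]
  r <- d$y - drop(d$X %*% b)
  if (stats::sd(r) == 0) stop("degenerate (constant) residuals")
  ns <- spec$noise
  phi <- .expand_lags(unname(fit$phi), ns$ar_lags,
                      if (length(ns$ar_lags)) max(ns$ar_lags) else 0L)
  theta <- .expand_lags(unname(fit$theta), ns$ma_lags,
                        if (length(ns$ma_lags)) max(ns$ma_lags) else 0L)

  cand <- expand.grid(week = seq_len(Tn), type = config$types_enabled,
                      stringsAsFactors = FALSE)
  G <- vapply(seq_len(nrow(cand)),
              function(i) outlier_regressor(cand$type[i], cand$week[i],
                                            config$tc_delta, Tn),
              numeric(Tn))

  w <- css_whiten(cbind(r, d$X, G), phi, theta)
  rw <- w$E[, 1]
  Xw <- w$E[, 1 + seq_len(ncol(d$X)), drop = FALSE]
  Gw <- w$E[, -(seq_len(ncol(d$X) + 1)), drop = FALSE]

  # collinearity screen against the whitened design
  Q <- qr.Q(qr(Xw))
  Gres <- Gw - Q %*% (t(Q) %*% Gw)
  norm_g <- sqrt(colSums(Gw^2))
  norm_res <- sqrt(colSums(Gres^2))
  ok <- norm_g > 1e-10 & norm_res / pmax(norm_g, 1e-12) > 1e-6

  # df-corrected innovation scale: the ML estimate divides by n and is
  # biased low by the fitted parameters, which would inflate every t
  n_par <- fit$k_reg + fit$n_free_arma
  sigma <- if (config$robust_sigma) stats::mad(rw)
           else sqrt(fit$sigma2 * fit$n / max(fit$n - n_par, 1L))
  lam <- colSums(Gw * rw) / colSums(Gw^2)
  tstat <- lam * sqrt(colSums(Gw^2)) / sigma

  out <- data.frame(type = cand$type, week = cand$week,
                    magnitude = lam, t_stat = tstat)[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Iterative outlier detection with joint re-estimation
#'
#' Greedy loop: compute all candidate screening t statistics; if the
#' largest |t| exceeds the threshold, add that regressor to the model,
#' re-estimate all parameters jointly (warm-started at the current optimum,
#' so the maximized log-likelihood never decreases), record the detection,
#' and rescan under the updated model; stop when no candidate exceeds the
#' threshold or the cap is reached. Ties are broken by earlier week, then
#' type order LS > TC > AO.
#'
#' An outlier that has not yet been adjusted for biases the AR estimates
#' toward spurious persistence, which both smears its own screening
#' statistic across neighbouring weeks and deflates it (masking). The
#' procedure therefore runs in passes: a first pass at the provisional
#' `bootstrap_threshold` whose only role is to produce de-biased ARMA and
#' scale estimates, then detection passes from scratch at the full
#' `t_threshold` with the refined estimates driving the first screening,
#' repeated until the detected set stabilizes (at most three refinement
#' passes). Only the final pass's detections, each clearing `t_threshold`,
#' are reported.
#'
#' @inheritParams scan_t_stats
#' @param method likelihood method for the joint re-fits
#' @return list: `fit` (final jointly re-estimated `tf_fit`), `outliers`
#'   (data.frame `iteration, type, week, magnitude, t_stat` with the
#'   screening t at detection; magnitude from the final joint fit),
#'   `initial_fit`, `capped` (TRUE if the cap stopped the loop with
#'   candidates still above threshold), `loglik_path` (maximized
#'   log-likelihood after each acceptance of the final pass)
#' @export
detect_and_adjust <- function(pair, spec = transfer_model_spec(),
                              config = outlier_config(), xreg = NULL,
                              method = c("exact", "css"), initial_fit = NULL) {
  method <- match.arg(method)
  fit0 <- initial_fit %||% fit_transfer_model(pair, spec, xreg = xreg, method = method)
  Tn <- length(pair$dependent$counts)
  n_arma <- length(spec$noise$ar_lags) + length(spec$noise$ma_lags)

  # one greedy pass; scan_fit supplies the ARMA/scale estimates driving the
  # first screening (possibly refined by an earlier pass)
  run_pass <- function(scan_fit, threshold) {
    fit <- fit0
    accepted <- data.frame(iteration = integer(0), type = character(0),
                           week = integer(0), magnitude = numeric(0),
                           t_stat = numeric(0))
    cur_xreg <- xreg
    capped <- FALSE
    loglik_path <- fit0$loglik
    for (iter in seq_len(config$max_outliers + 1L)) {
      st <- scan_t_stats(scan_fit, pair, spec, config, xreg = cur_xreg)
      if (nrow(accepted) > 0) {
        dup <- paste(st$type, st$week) %in% paste(accepted$type, accepted$week)
        st <- st[!dup, , drop = FALSE]
      }
      if (nrow(st) == 0) break
      st <- st[order(-abs(st$t_stat), st$week, .TYPE_ORDER[st$type]), , drop = FALSE]
      best <- st[1, ]
      if (abs(best$t_stat) <= threshold) break
      if (nrow(accepted) >= config$max_outliers) {
        capped <- TRUE
        warning("outlier cap reached with candidates still above threshold")
        break
      }
      nm <- paste0(best$type, "_", best$week)
      g <- matrix(outlier_regressor(best$type, best$week, config$tc_delta, Tn),
                  ncol = 1, dimnames = list(NULL, nm))
      warm <- if (n_arma > 0) c(unname(fit$phi), unname(fit$theta)) else NULL
      refit <- tryCatch(
        fit_transfer_model(pair, spec, xreg = cbind(cur_xreg, g),
                           method = method, start = warm),
        error = function(e) NULL)
      if (is.null(refit)) break
      if (refit$loglik < fit$loglik) {  # fall back to a cold start
        refit2 <- tryCatch(fit_transfer_model(pair, spec,
                                              xreg = cbind(cur_xreg, g),
                                              method = method),
                           error = function(e) NULL)
        if (!is.null(refit2) && refit2$loglik > refit$loglik) refit <- refit2
      }
      cur_xreg <- cbind(cur_xreg, g)
      accepted <- rbind(accepted,
                        data.frame(iteration = nrow(accepted) + 1L,
                                   type = best$type, week = best$week,
                                   magnitude = best$magnitude,
                                   t_stat = best$t_stat))
      fit <- refit
      scan_fit <- fit
      loglik_path <- c(loglik_path, fit$loglik)
    }
    list(fit = fit, accepted = accepted, capped = capped,
         loglik_path = loglik_path)
  }

  # ARMA/scale estimates of `from` grafted onto the outlier-free base model,
  # for screening
  refined_scan_fit <- function(from) {
    out <- fit0
    out$phi <- from$phi
    out$theta <- from$theta
    out$sigma2 <- from$sigma2
    out
  }

  boot <- run_pass(fit0, min(config$bootstrap_threshold, config$t_threshold))
  pass <- run_pass(refined_scan_fit(boot$fit), config$t_threshold)
  for (outer in 1:2) {
    if (nrow(pass$accepted) == 0) break
    nxt <- run_pass(refined_scan_fit(pass$fit), config$t_threshold)
    same <- identical(sort(paste(pass$accepted$type, pass$accepted$week)),
                      sort(paste(nxt$accepted$type, nxt$accepted$week)))
    pass <- nxt
    if (same) break
  }

  fit <- pass$fit
  accepted <- pass$accepted
  if (nrow(accepted) > 0) {
    nm <- paste0(accepted$type, "_", accepted$week)
    accepted$magnitude <- unname(fit$coef[nm])
  }
  list(fit = fit, outliers = accepted, initial_fit = fit0,
       capped = pass$capped, loglik_path = pass$loglik_path)
}

#' Write a detected-outlier table to CSV
#'
#' Dialect: `iteration,type,week_index,week_start_date,magnitude,t_stat`.
#' @param outliers data.frame from [detect_and_adjust()]
#' @param anchor_date Friday opening week 1 (for week start dates)
#' @param path output CSV path
#' @export
write_outliers_csv <- function(outliers, anchor_date, path) {
  anchor_date <- as_date_strict(anchor_date, "anchor_date")
  df <- data.frame(iteration = outliers$iteration, type = outliers$type,
                   week_index = outliers$week,
                   week_start_date = format(anchor_date + 7 * (outliers$week - 1)),
                   magnitude = outliers$magnitude, t_stat = outliers$t_stat)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
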