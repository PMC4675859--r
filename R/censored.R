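#' Right-censored Gaussian random-intercept regression
#'
#' Fits, by maximum likelihood, the Tobit-type mixed model
#' \deqn{y_{ij} = x_{ij}'\beta + u_i + e_{ij}, \quad u_i \sim N(0,
#' \sigma_u^2), \; e_{ij} \sim N(0, \sigma_e^2),}
#' where the response is only observed up to a known bound `threshold`
#' (rows flagged censored carry the bound as their value and contribute the
#' upper-tail probability to the likelihood). The subject random intercept
#' is integrated out by fixed-order Gauss-Hermite quadrature. The fixed
#' effects are `response ~ session * group` with `session` as a numeric
#' covariate, so the `session:group` interaction terms estimate how each
#' group's learning slope differs from the reference group's.
#'
#' The optimizer is quasi-Newton (BFGS) started from an OLS-based point
#' plus `n_starts - 1` deterministically jittered restarts; the best
#' likelihood wins. Wald z tests use the inverse observed information;
#' slope-contrast p-values are Benjamini-Hochberg adjusted.
#'
#' @param data A data frame with the response column, `subject_id`,
#'   `session` (numeric), `group`, and (unless `threshold` is infinite) a
#'   logical `censored` column.
#' @param response Name of the response column.
#' @param threshold Right-censoring bound on the response scale (`Inf` for
#'   no censoring).
#' @param reference Group label used as the reference for contrasts
#'   (default: first group alphabetically).
#' @param random_intercept If `FALSE`, fit the marginal model with
#'   `sigma_u` fixed at zero (no quadrature).
#' @param quad_order Number of Gauss-Hermite nodes.
#' @param n_starts Number of optimizer starts.
#' @param start_seed Seed for the deterministic start jitter.
#'
#' @return An object of class `mwm_censfit`: `coefficients` tibble
#'   (`term`, `estimate`, `std_error`, `statistic`, `p_value`, `p_bh` on
#'   slope contrasts), `sigma_u`, `sigma_e`, `logLik`, `threshold`,
#'   `convergence` (code, iterations, gradient norm), and fit metadata.
#' @export
#' @seealso [fit_latency_model()] for the log-latency convenience wrapper,
#'   [fit_metric_lmm()] for uncensored metrics.
fit_censored_lmm <- function(data, response, threshold = Inf,
                             reference = NULL, random_intercept = TRUE,
                             quad_order = 16, n_starts = 3, start_seed = 1) {
  needed <- c(response, "subject_id", "session", "group")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("`data` is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  y <- data[[response]]
  if (is.finite(threshold)) {
    if (!"censored" %in% names(data)) {
      stop("A finite `threshold` requires a logical `censored` column.",
           call. = FALSE)
    }
    cens <- as.logical(data$censored)
  } else {
    cens <- rep(FALSE, length(y))
  }
  if (all(cens)) {
    stop("All observations are censored; the model is not identifiable.",
         call. = FALSE)
  }
  group <- factor(data$group)
  if (!is.null(reference)) {
    if (!reference %in% levels(group)) {
      stop("`reference` is not a group label.", call. = FALSE)
    }
    group <- stats::relevel(group, ref = reference)
  }
  mm_data <- data.frame(session = as.numeric(data$session), group = group)
  Xmat <- stats::model.matrix(~ session * group, mm_data)
  p <- ncol(Xmat)
  subj <- factor(data$subject_id)
  subj_idx <- as.integer(subj)
  n_subj <- nlevels(subj)

  gh <- pracma::gaussHermite(quad_order)
  log_w <- log(gh$w) - 0.5 * log(pi)

  negll <- function(par) {
    -.censored_ri_loglik(par, y, Xmat, cens, subj_idx, n_subj,
                         gh$x, log_w, random_intercept)
  }

  # OLS-based start (treat censored rows as observed at the bound)
  ols <- stats::lm.fit(Xmat, y)
  res <- ols$residuals
  s_e0 <- max(stats::sd(res), 1e-2)
  s_u0 <- max(stats::sd(tapply(res, subj_idx, mean)), 1e-2)
  par0 <- c(ols$coefficients, log(s_e0))
  if (random_intercept) par0 <- c(par0, log(s_u0))
  par0[!is.finite(par0)] <- 0

  fits <- vector("list", n_starts)
  for (j in seq_len(n_starts)) {
    start <- par0
    if (j > 1) {
      set.seed(start_seed + j)
      start <- par0 + stats::rnorm(length(par0), 0, 0.2)
    }
    fits[[j]] <- tryCatch(
      stats::optim(start, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL
    )
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("All optimizer starts failed.", call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  grad <- .num_grad(negll, best$par)
  if (best$convergence != 0 && sqrt(sum(grad^2)) > 1e-2) {
    stop(sprintf(
      "Optimizer did not converge (code %d, |grad| = %.3g, %d evaluations).",
      best$convergence, sqrt(sum(grad^2)), best$counts[1]), call. = FALSE)
  }
  H <- stats::optimHess(best$par, negll)
  vc <- tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, length(best$par), length(best$par))
  })
  se <- unname(sqrt(pmax(diag(vc), 0))[seq_len(p)])
  beta <- unname(best$par[seq_len(p)])
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  terms <- colnames(Xmat)
  is_slope <- grepl("^session:", terms)
  p_bh <- rep(NA_real_, p)
  if (any(is_slope)) p_bh[is_slope] <- bh_adjust(pval[is_slope])
  coefs <- tibble::tibble(
    term = terms, estimate = beta, std_error = se, statistic = z,
    p_value = pval, p_bh = p_bh
  )
  sigma_e <- unname(exp(best$par[p + 1]))
  sigma_u <- if (random_intercept) unname(exp(best$par[p + 2])) else 0
  structure(
    list(
      coefficients = coefs,
      sigma_u = sigma_u,
      sigma_e = sigma_e,
      logLik = -best$value,
      threshold = threshold,
      response = response,
      reference = levels(group)[1],
      random_intercept = random_intercept,
      quad_order = quad_order,
      n_obs = length(y),
      n_subjects = n_subj,
      n_censored = sum(cens),
      convergence = list(code = best$convergence,
                         iterations = unname(best$counts[1]),
                         gradient_norm = sqrt(sum(grad^2)))
    ),
    class = "mwm_censfit"
  )
}

# Marginal log-likelihood of the censored random-intercept model.
# par = (beta, log sigma_e[, log sigma_u]); nodes/log_w from Gauss-Hermite.
# The quadrature is adaptive: nodes are recentered at each subject's
# approximate conditional posterior mode and rescaled by its curvature
# (censored rows enter the centering at the bound), which makes the rule
# exact for the uncensored Gaussian case at any order and keeps fixed,
# moderate orders accurate under censoring.
.censored_ri_loglik <- function(par, y, Xmat, cens, subj_idx, n_subj,
                                nodes, log_w, random_intercept) {
  p <- ncol(Xmat)
  beta <- par[seq_len(p)]
  sigma_e <- exp(par[p + 1])
  r <- y - as.vector(Xmat %*% beta)
  if (!random_intercept) {
    ll <- sum(stats::dnorm(r[!cens], 0, sigma_e, log = TRUE))
    if (any(cens)) {
      ll <- ll + sum(stats::pnorm(r[cens] / sigma_e, lower.tail = FALSE,
                                  log.p = TRUE))
    }
    return(ll)
  }
  sigma_u <- exp(par[p + 2])
  n_i <- tabulate(subj_idx, n_subj)
  mean_r <- as.vector(rowsum(r, subj_idx)) / n_i
  shrink <- sigma_u^2 / (sigma_u^2 + sigma_e^2 / n_i)
  mu_hat <- shrink * mean_r                        # posterior mode (approx)
  lambda <- 1 / sqrt(1 / sigma_u^2 + n_i / sigma_e^2)  # posterior SD (approx)
  if (any(cens)) {
    # refine the mode and curvature by Newton steps on the true conditional
    # log-density (censored rows contribute through the normal hazard)
    prec0 <- 1 / sigma_u^2
    unc <- !cens
    n_unc <- tabulate(subj_idx[unc], n_subj)
    sum_r_unc <- .rowsum_full(r[unc], subj_idx[unc], n_subj)
    idx_c <- subj_idx[cens]
    r_c <- r[cens]
    gp <- NULL
    for (it in 1:4) {
      # clamp to keep the hazard finite when the tail probability underflows
      zc <- pmin((r_c - mu_hat[idx_c]) / sigma_e, 35)
      lam <- exp(stats::dnorm(zc, log = TRUE) -
                   stats::pnorm(zc, lower.tail = FALSE, log.p = TRUE))
      g <- -mu_hat * prec0 + (sum_r_unc - n_unc * mu_hat) / sigma_e^2 +
        .rowsum_full(lam, idx_c, n_subj) / sigma_e
      gp <- -prec0 - n_unc / sigma_e^2 -
        .rowsum_full(lam * (lam - zc), idx_c, n_subj) / sigma_e^2
      mu_hat <- mu_hat - g / gp
    }
    lambda <- 1 / sqrt(pmax(-gp, 1e-12))
  }
  Q <- length(nodes)
  # u_{ik} = mu_hat_i + sqrt(2) lambda_i t_k
  U <- mu_hat + sqrt(2) * outer(lambda, nodes)     # n_subj x Q
  RES <- r - U[subj_idx, , drop = FALSE]           # n x Q
  L <- matrix(0, nrow(RES), Q)
  if (any(!cens)) {
    L[!cens, ] <- stats::dnorm(RES[!cens, , drop = FALSE], 0, sigma_e,
                               log = TRUE)
  }
  if (any(cens)) {
    L[cens, ] <- stats::pnorm(RES[cens, , drop = FALSE] / sigma_e,
                              lower.tail = FALSE, log.p = TRUE)
  }
  A <- rowsum(L, subj_idx)                         # n_subj x Q
  A <- A + stats::dnorm(U, 0, sigma_u, log = TRUE) +
    rep(nodes^2 + log_w + 0.5 * log(pi), each = n_subj) +
    log(sqrt(2) * lambda)
  m <- apply(A, 1, max)
  sum(m + log(rowSums(exp(A - m))))
}

# rowsum() that keeps absent groups as zeros.
.rowsum_full <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x)) {
    tmp <- rowsum(x, idx)
    out[as.integer(rownames(tmp))] <- tmp
  }
  out
}

# Central-difference gradient (convergence diagnostic).
.num_grad <- function(f, par, eps = 1e-5) {
  vapply(seq_along(par), function(i) {
    up <- par; up[i] <- up[i] + eps
    dn <- par; dn[i] <- dn[i] - eps
    (f(up) - f(dn)) / (2 * eps)
  }, numeric(1))
}

#' Censored log-latency learning-slope model
#'
#' Convenience wrapper around [fit_censored_lmm()] for the canonical
#' latency analysis: the response is `log(latency)`, right-censored at
#' `log(cutoff)` because trials are stopped at the cutoff.
#'
#' @param session_metrics Per-subject-session table with `latency` and
#'   `censored` columns.
#' @param cutoff Trial cutoff in seconds.
#' @inheritParams fit_censored_lmm
#' @param ... Passed on to [fit_censored_lmm()].
#' @return An `mwm_censfit`.
#' @export
fit_latency_model <- function(session_metrics, cutoff = 60, reference = NULL,
                              ...) {
  df <- session_metrics
  df$log_latency <- log(pmin(df$latency, cutoff))
  fit_censored_lmm(df, response = "log_latency", threshold = log(cutoff),
                   reference = reference, ...)
}

#' Uncensored random-intercept model for a behavioral metric
#'
#' The same random-intercept regression as [fit_censored_lmm()] with no
#' censoring bound (the censored likelihood reduces exactly to the
#' Gaussian mixed-model likelihood when no row is censored). Used for
#' metrics such as the Gallagher index or thigmotaxis.
#'
#' @inheritParams fit_censored_lmm
#' @param ... Passed on to [fit_censored_lmm()].
#' @return An `mwm_censfit`.
#' @export
fit_metric_lmm <- function(data, response, reference = NULL, ...) {
  fit_censored_lmm(data, response = response, threshold = Inf,
                   reference = reference, ...)
}

#' @export
print.mwm_censfit <- function(x, ...) {
  cat("<mwm_censfit> ", x$response,
      if (is.finite(x$threshold)) sprintf(" (right-censored at %.3g)", x$threshold),
      "\n", sep = "")
  cat(sprintf("  %d obs (%d censored), %d subjects, reference %s\n",
              x$n_obs, x$n_censored, x$n_subjects, x$reference))
  cat(sprintf("  sigma_u = %.3f, sigma_e = %.3f, logLik = %.2f\n",
              x$sigma_u, x$sigma_e, x$logLik))
  print(x$coefficients)
  invisible(x)
}

#' @describeIn fit_censored_lmm Coefficient table as a tibble.
#' @param x An `mwm_censfit` object.
#' @param ... Unused.
#' @export
tidy.mwm_censfit <- function(x, ...) x$coefficients

#' @describeIn fit_censored_lmm One-row fit summary (sigmas, logLik,
#'   convergence).
#' @export
glance.mwm_censfit <- function(x, ...) {
  tibble::tibble(
    sigma_u = x$sigma_u,
    sigma_e = x$sigma_e,
    logLik = x$logLik,
    n_obs = x$n_obs,
    n_subjects = x$n_subjects,
    n_censored = x$n_censored,
    convergence_code = x$convergence$code,
    gradient_norm = x$convergence$gradient_norm
  )
}
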