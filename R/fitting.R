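# Phase-wise nonlinear least squares.
#
# Each phase is an exponential-saturation curve in (kA, kE); the pooled model
# fits one pair, the habitat model fits one pair per habitat in a SINGLE
# joint regression so RSS, AIC and the extra-sum-of-squares F are comparable
# with the pooled fit.  The optimizer is plain Gauss-Newton with step-halving
# and a small multi-start grid, matching the algorithm behind stats::nls.

# analytic Jacobian of .onecomp w.r.t. (kA, kE)
.onecomp_jac <- function(t, c0, ce, kA, kE) {
  E <- exp(-kE * t)
  dA <- ce / kE * (1 - E)
  dE <- -c0 * t * E - ce * kA / kE^2 * (1 - E) + ce * (kA / kE) * t * E
  cbind(kA = dA, kE = dE)
}

#' Optimizer settings for Gauss-Newton fitting
#'
#' @param tol relative-RSS convergence tolerance (default 1e-10).
#' @param max_iter maximum Gauss-Newton iterations (default 200).
#' @param max_halvings maximum step halvings per iteration (default 30).
#' @param start_grid values crossed to build the default multi-start grid
#'   for (kA, kE) when the caller supplies no start.
#' @return A list of class `gn_control`.
#' @export
gn_control <- function(tol = 1e-10, max_iter = 200L, max_halvings = 30L,
                       start_grid = c(0.1, 1, 5)) {
  stopifnot(tol > 0, max_iter >= 1, max_halvings >= 1,
            all(start_grid > 0))
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 max_halvings = as.integer(max_halvings),
                 start_grid = start_grid),
            class = "gn_control")
}

# Gauss-Newton with step-halving on a generic residual problem.
# predict_fn(theta) -> fitted values; jac_fn(theta) -> n x p Jacobian.
# Parameters are unconstrained; kE passing through 0 makes the kernel error,
# which we trap and treat as a failed step/start.
.gauss_newton <- function(y, predict_fn, jac_fn, start, control) {
  theta <- start
  f <- try(predict_fn(theta), silent = TRUE)
  if (inherits(f, "try-error") || !all(is.finite(f)))
    return(list(theta = theta, rss = Inf, converged = FALSE, n_iter = 0L))
  rss <- sum((y - f)^2)
  converged <- FALSE
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    r <- y - f
    J <- jac_fn(theta)
    if (!all(is.finite(J))) break
    A <- crossprod(J)
    b <- crossprod(J, r)
    delta <- try(solve(A, b), silent = TRUE)
    if (inherits(delta, "try-error")) {
      # computationally singular normal matrix: take a damped step instead
      ridge <- 1e-8 * max(diag(A), .Machine$double.eps)
      delta <- try(solve(A + diag(ridge, ncol(A)), b), silent = TRUE)
      if (inherits(delta, "try-error")) break
    }
    delta <- drop(delta)
    # step-halving line search
    lambda <- 1
    improved <- FALSE
    for (h in seq_len(control$max_halvings)) {
      cand <- theta + lambda * delta
      fc <- try(predict_fn(cand), silent = TRUE)
      if (!inherits(fc, "try-error") && all(is.finite(fc))) {
        rss_c <- sum((y - fc)^2)
        if (rss_c <= rss) {
          theta <- cand; f <- fc
          improved <- TRUE
          rel <- (rss - rss_c) / max(rss, .Machine$double.eps)
          rss <- rss_c
          if (rel < control$tol || rss == 0) converged <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!improved) { converged <- TRUE; break }  # stationary within search
    if (converged) break
  }
  list(theta = theta, rss = rss, converged = converged, n_iter = iter)
}

# fingerprint so nested comparisons can verify they saw the same data
.data_fingerprint <- function(y, t) {
  c(n = length(y), sum_y = sum(y), sum_y2 = sum(y^2), sum_t = sum(t))
}

.check_obs_cols <- function(data) {
  need <- c("habitat", "time_days", "concentration")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("observation table lacks column(s): ", paste(miss, collapse = ", "))
}

#' Fit one phase of the toxicokinetic model by Gauss-Newton least squares
#'
#' Minimizes the residual sum of squares of the phase's exponential solution
#' over the colonies observed in that phase.  The contamination phase uses
#' observations with `0 < t <= t_C` (day-0 colonies enter only through the
#' fixed constant `C_I0`); the decontamination phase uses `t > t_C`, with
#' its starting concentration `C_ItC` computed from a pooled contamination
#' fit and held fixed (the default anchoring rule; see `anchor`).
#'
#' `grouping = "pooled"` estimates a single (kA, kE); `"by_habitat"`
#' estimates one pair per habitat level in one joint regression, so its RSS
#' and AIC are directly comparable with the pooled fit via
#' [compare_nested()].
#'
#' @param data observation table: data frame with at least `habitat`,
#'   `time_days`, `concentration` (mg/kg). May contain both phases; rows are
#'   filtered to the requested phase internally.
#' @param phase `"contamination"` or `"decontamination"`.
#' @param schedule an [exposure_schedule()].
#' @param grouping `"pooled"` or `"by_habitat"`.
#' @param start optional [kinetic_params()] (or named vector for
#'   `by_habitat`) used as the single start; otherwise a multi-start grid
#'   from `control$start_grid` is used and the best converged optimum kept.
#' @param anchor for the decontamination phase, how `C_ItC` is obtained:
#'   `"pooled"` (default; one anchor from the pooled contamination fit) or
#'   `"by_habitat"` (sensitivity option: habitat-specific anchors from
#'   habitat-wise contamination fits).
#' @param c_switch optional explicit `C_ItC` (scalar, or named by habitat),
#'   bypassing the internal contamination fit; ignored for the
#'   contamination phase.
#' @param control a [gn_control()].
#' @return A `tk_fit` object: estimates, standard errors, asymptotic 95%
#'   CIs, RSS, adjusted R-squared, AIC, convergence report and the
#'   multi-start table.
#' @examples
#' sch <- exposure_schedule(C_I0 = 2)
#' sim <- generate_dataset(simulation_config(seed = 1))
#' fit_phase(sim$observations, "contamination", sch, "pooled")
#' @export
fit_phase <- function(data,
                      phase = c("contamination", "decontamination"),
                      schedule,
                      grouping = c("pooled", "by_habitat"),
                      start = NULL,
                      anchor = c("pooled", "by_habitat"),
                      c_switch = NULL,
                      control = gn_control()) {
  phase <- match.arg(phase)
  grouping <- match.arg(grouping)
  anchor <- match.arg(anchor)
  stopifnot(inherits(schedule, "exposure_schedule"),
            inherits(control, "gn_control"))
  .check_obs_cols(data)

  t_C <- schedule$t_C
  if (phase == "contamination") {
    keep <- data$time_days > 0 & data$time_days <= t_C
  } else {
    keep <- data$time_days > t_C
  }
  sub <- data[keep, , drop = FALSE]
  n <- nrow(sub)
  if (length(unique(sub$time_days)) < 3)
    stop("fit_phase: need >= 3 distinct time points in the ", phase,
         " phase (got ", length(unique(sub$time_days)), ")")
  habitats <- sort(unique(as.character(sub$habitat)))
  if (grouping == "by_habitat" && length(habitats) < 2)
    stop("fit_phase: by_habitat grouping needs both habitat levels; found ",
         paste(habitats, collapse = ", "))

  # phase constants: starting concentration c0 and food concentration ce
  anchor_info <- NULL
  if (phase == "contamination") {
    c0_of <- function(hab) schedule$C_I0
    ce <- schedule$C_Eu
    tt <- sub$time_days
  } else {
    ce <- schedule$C_Ed
    tt <- sub$time_days - t_C
    if (!is.null(c_switch)) {
      if (is.null(names(c_switch))) {
        cs <- setNames(rep(as.numeric(c_switch[1]), length(habitats)),
                       habitats)
      } else cs <- c_switch
      anchor_info <- list(type = "user", values = cs)
    } else if (anchor == "pooled") {
      p1 <- fit_phase(data, "contamination", schedule, "pooled",
                      control = control)
      v <- concentration_at_switch(
        kinetic_params(p1$estimates[["kA"]], p1$estimates[["kE"]],
                       quiet = TRUE), schedule)
      cs <- setNames(rep(v, length(habitats)), habitats)
      anchor_info <- list(type = "pooled", values = cs,
                          phase1 = p1$estimates)
    } else {
      p1 <- fit_phase(data, "contamination", schedule, "by_habitat",
                      control = control)
      cs <- vapply(habitats, function(h) {
        concentration_at_switch(
          kinetic_params(p1$estimates[[paste0("kA_", h)]],
                         p1$estimates[[paste0("kE_", h)]], quiet = TRUE),
          schedule)
      }, numeric(1))
      anchor_info <- list(type = "by_habitat", values = cs,
                          phase1 = p1$estimates)
    }
    c0_of <- function(hab) unname(cs[hab])
  }

  y <- sub$concentration
  hab_chr <- as.character(sub$habitat)
  c0_row <- vapply(hab_chr, c0_of, numeric(1))

  if (grouping == "pooled") {
    pnames <- c("kA", "kE")
    predict_fn <- function(th) .onecomp(tt, c0_row, ce, th[1], th[2])
    jac_fn <- function(th) .onecomp_jac(tt, c0_row, ce, th[1], th[2])
  } else {
    pnames <- as.vector(outer(c("kA_", "kE_"), habitats, paste0))
    idx <- lapply(habitats, function(h) which(hab_chr == h))
    predict_fn <- function(th) {
      out <- numeric(length(y))
      for (k in seq_along(habitats)) {
        i <- idx[[k]]
        out[i] <- .onecomp(tt[i], c0_row[i], ce, th[2 * k - 1], th[2 * k])
      }
      out
    }
    jac_fn <- function(th) {
      J <- matrix(0, length(y), length(pnames),
                  dimnames = list(NULL, pnames))
      for (k in seq_along(habitats)) {
        i <- idx[[k]]
        J[i, (2 * k - 1):(2 * k)] <-
          .onecomp_jac(tt[i], c0_row[i], ce, th[2 * k - 1], th[2 * k])
      }
      J
    }
  }
  p <- length(pnames)
  if (n <= p)
    stop("fit_phase: ", n, " observations cannot identify ", p,
         " parameters")

  # starts: user-supplied single start, or grid
  if (!is.null(start)) {
    if (inherits(start, "kinetic_params")) start <- c(start$kA, start$kE)
    starts <- matrix(rep(as.numeric(start), length.out = p),
                     nrow = 1, dimnames = list(NULL, pnames))
  } else {
    g <- expand.grid(kA = control$start_grid, kE = control$start_grid)
    starts <- as.matrix(g[, rep(1:2, length.out = p), drop = FALSE])
    colnames(starts) <- pnames
  }
  runs <- vector("list", nrow(starts))
  for (s in seq_len(nrow(starts)))
    runs[[s]] <- .gauss_newton(y, predict_fn, jac_fn, starts[s, ], control)
  ok <- vapply(runs, function(r) r$converged && is.finite(r$rss), logical(1))
  if (!any(ok)) {
    msg <- paste(apply(starts, 1, function(z)
      paste0("(", paste(signif(z, 3), collapse = ", "), ")")),
      collapse = " ")
    stop("fit_phase: Gauss-Newton failed to converge from all starts: ", msg)
  }
  rss_all <- vapply(runs, function(r) r$rss, numeric(1))
  best <- runs[[which.min(ifelse(ok, rss_all, Inf))]]
  theta <- setNames(best$theta, pnames)
  fitted <- predict_fn(theta)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  J <- jac_fn(theta)

  if (any(theta <= 0))
    warning("fit_phase: non-positive estimate(s): ",
            paste(pnames[theta <= 0], collapse = ", "), call. = FALSE)

  multistart <- data.frame(starts,
                           rss = rss_all,
                           converged = vapply(runs, `[[`, logical(1),
                                              "converged"),
                           n_iter = vapply(runs, `[[`, integer(1), "n_iter"))

  fit <- structure(list(
    phase = phase, grouping = grouping,
    estimates = as.list(theta), se = NULL, ci95 = NULL,
    rss = rss, tss = tss, n_obs = n, n_params = p,
    adjusted_r2 = NA_real_, aic = NA_real_,
    converged = best$converged, n_iterations = best$n_iter,
    schedule = schedule, anchor = anchor_info,
    habitats = habitats, param_names = pnames,
    fitted = fitted, residuals = resid, times = sub$time_days,
    observed = y, jacobian = J,
    fingerprint = .data_fingerprint(y, sub$time_days),
    multistart = multistart), class = "tk_fit")
  # CI failure (singular normal matrix at the optimum) degrades the fit to
  # NA intervals rather than aborting; asymptotic_ci() itself still errors
  # when called directly on such a fit
  fit <- tryCatch(asymptotic_ci(fit), error = function(e) {
    warning(conditionMessage(e), call. = FALSE)
    fit$se <- setNames(rep(NA_real_, p), pnames)
    fit$ci95 <- matrix(NA_real_, p, 2,
                       dimnames = list(pnames, c("low", "high")))
    fit
  })
  fit$adjusted_r2 <- adjusted_r2(fit)
  # a perfect (zero-residual) fit has a degenerate Gaussian likelihood;
  # keep the fit usable and let aic() itself error if called directly
  fit$aic <- if (fit$rss > 0) aic(fit) else NA_real_
  fit
}

#' @export
print.tk_fit <- function(x, ...) {
  cat(sprintf("Toxicokinetic fit: %s phase, %s model (n = %d, p = %d)\n",
              x$phase, x$grouping, x$n_obs, x$n_params))
  est <- unlist(x$estimates)
  tab <- data.frame(estimate = signif(est, 4),
                    se = signif(x$se, 4),
                    ci_low = signif(x$ci95[, 1], 4),
                    ci_high = signif(x$ci95[, 2], 4))
  print(tab)
  cat(sprintf("RSS = %.4g, adjusted R2 = %.3f, AIC = %.2f (%sconverged in %d iter)\n",
              x$rss, x$adjusted_r2, x$aic,
              if (x$converged) "" else "NOT ", x$n_iterations))
  if (!is.null(x$anchor))
    cat("Decontamination anchor (C_ItC): ", x$anchor$type, " [",
        paste(sprintf("%s = %.3f", names(x$anchor$values),
                      x$anchor$values), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Asymptotic confidence intervals for a fitted phase model
#'
#' Standard errors come from the diagonal of `s^2 (J'J)^-1` with the
#' Jacobian evaluated at the optimum and `s^2 = RSS / (n - p)`; the interval
#' is `estimate +/- q * SE` with `q` a Student-t quantile on `n - p` df
#' (default) or a normal quantile.
#'
#' @param fit a `tk_fit`.
#' @param level confidence level, default 0.95.
#' @param quantile `"t"` (default) or `"z"`.
#' @return The fit with `se` and `ci95` filled in.
#' @export
asymptotic_ci <- function(fit, level = 0.95, quantile = c("t", "z")) {
  stopifnot(inherits(fit, "tk_fit"), level > 0, level < 1)
  quantile <- match.arg(quantile)
  J <- fit$jacobian
  p <- fit$n_params
  qrJ <- qr(crossprod(J))
  if (qrJ$rank < p) {
    bad <- fit$param_names[qrJ$pivot[(qrJ$rank + 1):p]]
    stop("asymptotic_ci: singular normal matrix; parameter(s) not ",
         "identifiable: ", paste(bad, collapse = ", "))
  }
  df <- fit$n_obs - p
  s2 <- fit$rss / df
  covm <- s2 * solve(qrJ)
  se <- sqrt(pmax(diag(covm), 0))
  q <- if (quantile == "t") stats::qt(1 - (1 - level) / 2, df)
       else stats::qnorm(1 - (1 - level) / 2)
  est <- unlist(fit$estimates)
  ci <- cbind(low = est - q * se, high = est + q * se)
  rownames(ci) <- fit$param_names
  fit$se <- setNames(se, fit$param_names)
  fit$ci95 <- ci
  fit$cov <- covm
  fit$ci_level <- level
  fit$ci_quantile <- quantile
  fit
}

#' Adjusted coefficient of determination
#'
#' `1 - (RSS / (n - p)) / (TSS / (n - 1))`, with the total sum of squares
#' about the mean of the phase observations.  May be negative for fits worse
#' than the mean.
#'
#' @param fit a `tk_fit`.
#' @param data optional observation table; when given, RSS and TSS are
#'   recomputed on its phase subset instead of the stored residuals.
#' @return Adjusted R-squared (unitless).
#' @export
adjusted_r2 <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "tk_fit"))
  if (is.null(data)) {
    rss <- fit$rss; tss <- fit$tss; n <- fit$n_obs
  } else {
    .check_obs_cols(data)
    t_C <- fit$schedule$t_C
    keep <- if (fit$phase == "contamination")
      data$time_days > 0 & data$time_days <= t_C else data$time_days > t_C
    y <- data$concentration[keep]
    mdl_pred <- .refit_predict(fit, data[keep, , drop = FALSE])
    rss <- sum((y - mdl_pred)^2)
    tss <- sum((y - mean(y))^2)
    n <- length(y)
  }
  p <- fit$n_params
  if (n <= p) stop("adjusted_r2: n <= p")
  1 - (rss / (n - p)) / (tss / (n - 1))
}

# predict a fitted phase model on new phase rows
.refit_predict <- function(fit, rows) {
  sch <- fit$schedule
  if (fit$phase == "contamination") {
    tt <- rows$time_days
    ce <- sch$C_Eu
    c0 <- rep(sch$C_I0, nrow(rows))
  } else {
    tt <- rows$time_days - sch$t_C
    ce <- sch$C_Ed
    c0 <- unname(fit$anchor$values[as.character(rows$habitat)])
  }
  if (fit$grouping == "pooled") {
    .onecomp(tt, c0, ce, fit$estimates$kA, fit$estimates$kE)
  } else {
    vapply(seq_len(nrow(rows)), function(i) {
      h <- as.character(rows$habitat[i])
      .onecomp(tt[i], c0[i], ce,
               fit$estimates[[paste0("kA_", h)]],
               fit$estimates[[paste0("kE_", h)]])
    }, numeric(1))
  }
}

#' Gaussian-likelihood AIC of a fitted phase model
#'
#' `n log(2 pi RSS / n) + n + 2 (p + 1)`: the maximum-likelihood residual
#' variance counts as an estimated parameter, matching `stats::AIC` on
#' `nls`/`lm` fits.
#'
#' @param fit a `tk_fit`.
#' @return AIC (unitless).
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "tk_fit"))
  if (fit$rss <= 0)
    stop("aic: zero residual sum of squares gives a degenerate likelihood")
  n <- fit$n_obs
  n * log(2 * pi * fit$rss / n) + n + 2 * (fit$n_params + 1)
}

#' Compare nested pooled and habitat-indexed fits
#'
#' Extra-sum-of-squares F-test plus AIC comparison between a null (pooled)
#' fit and an alternative (habitat-indexed) fit of the same phase on the
#' same observations:
#' `F = ((RSS0 - RSS1) / (p1 - p0)) / (RSS1 / (n - p1))`, upper-tail
#' p-value.  The preferred model follows the two-step logic of first
#' checking AIC, with the F-test p-value reported alongside.
#'
#' @param null_fit,alt_fit `tk_fit` objects, null nested in alternative.
#' @return A `tk_model_comparison`: `f_stat`, `df_num`, `df_den`,
#'   `p_value`, `aic_null`, `aic_alt`, `delta_aic`, `preferred`.
#' @export
compare_nested <- function(null_fit, alt_fit) {
  stopifnot(inherits(null_fit, "tk_fit"), inherits(alt_fit, "tk_fit"))
  if (null_fit$phase != alt_fit$phase)
    stop("compare_nested: fits are from different phases")
  if (!isTRUE(all.equal(null_fit$fingerprint, alt_fit$fingerprint)))
    stop("compare_nested: fits were not computed on the same observations")
  df_num <- alt_fit$n_params - null_fit$n_params
  if (df_num < 0)
    stop("compare_nested: alternative has fewer parameters than null")
  df_den <- alt_fit$n_obs - alt_fit$n_params
  if (df_num == 0) {
    if (abs(null_fit$rss - alt_fit$rss) >
        1e-8 * max(null_fit$rss, alt_fit$rss))
      stop("compare_nested: equal parameter counts but different RSS; ",
           "models are not nested")
    f_stat <- 0; p_value <- 1
  } else {
    f_stat <- max(0, (null_fit$rss - alt_fit$rss) / df_num /
                    (alt_fit$rss / df_den))
    p_value <- stats::pf(f_stat, df_num, df_den, lower.tail = FALSE)
  }
  a0 <- null_fit$aic; a1 <- alt_fit$aic
  structure(list(f_stat = f_stat, df_num = df_num, df_den = df_den,
                 p_value = p_value, aic_null = a0, aic_alt = a1,
                 delta_aic = a1 - a0,
                 preferred = if (a1 < a0) alt_fit$grouping
                             else null_fit$grouping,
                 phase = null_fit$phase),
            class = "tk_model_comparison")
}

#' @export
print.tk_model_comparison <- function(x, ...) {
  cat(sprintf("Nested model comparison (%s phase):\n", x$phase))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g\n",
              x$df_num, x$df_den, x$f_stat, x$p_value))
  cat(sprintf("  AIC null = %.2f, AIC alternative = %.2f (delta = %.2f)\n",
              x$aic_null, x$aic_alt, x$delta_aic))
  cat("  preferred:", x$preferred, "\n")
  invisible(x)
}
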