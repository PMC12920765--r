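# Endpoint contrast: internal Cd at the start (t = 0) versus the end
# (t = 42) of the experiment, with habitat and its interaction, fitted by
# ordinary least squares and tested by explicit nested-model F comparisons
# (each term's F comes from dropping it from the relevant model).

.endpoint_subset <- function(data, days) {
  .check_obs_cols(data)
  sub <- data[data$time_days %in% days, , drop = FALSE]
  sub$time_point <- factor(ifelse(sub$time_days == days[1], "t0", "t42"),
                           levels = c("t0", "t42"))
  sub$habitat <- factor(tolower(as.character(sub$habitat)))
  tab <- table(sub$time_point, sub$habitat)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)
    stop("fit_endpoint_model: empty design cell(s): ",
         paste(sprintf("%s x %s", rownames(tab)[empty[, 1]],
                       colnames(tab)[empty[, 2]]), collapse = ", "))
  }
  sub
}

#' Linear model for the start-versus-end concentration contrast
#'
#' Ordinary least squares of internal concentration on time point (t = 0 vs
#' t = 42), habitat, and their interaction, with treatment coding and
#' alphabetically-first reference levels (recorded in the output).
#'
#' @param data observation table (any phase; only the two endpoint days are
#'   used).
#' @param days the two endpoint days, default `c(0, 42)`.
#' @return An `endpoint_fit`: the underlying `lm`, the endpoint subset, a
#'   time-point-by-habitat table of group means/SD/n, and the reference
#'   levels used.
#' @examples
#' sim <- generate_dataset(simulation_config(seed = 1))
#' fit_endpoint_model(sim$observations)
#' @export
fit_endpoint_model <- function(data, days = c(0, 42)) {
  stopifnot(length(days) == 2)
  sub <- .endpoint_subset(data, days)
  model <- stats::lm(concentration ~ time_point + habitat +
                       time_point:habitat, data = sub)
  agg <- stats::aggregate(concentration ~ time_point + habitat, sub,
                          function(z) c(mean = mean(z), sd = stats::sd(z),
                                        n = length(z)))
  means <- data.frame(time_point = agg$time_point, habitat = agg$habitat,
                      mean = agg$concentration[, "mean"],
                      sd = agg$concentration[, "sd"],
                      n = agg$concentration[, "n"])
  structure(list(model = model, data = sub, group_means = means,
                 reference = c(time_point = levels(sub$time_point)[1],
                               habitat = levels(sub$habitat)[1]),
                 days = days),
            class = "endpoint_fit")
}

#' @export
print.endpoint_fit <- function(x, ...) {
  cat("Endpoint linear model: concentration ~ time_point * habitat\n")
  cat(sprintf("  reference levels: time_point = %s, habitat = %s\n",
              x$reference["time_point"], x$reference["habitat"]))
  print(signif(stats::coef(x$model), 4))
  cat("Group means (mg/kg):\n")
  print(x$group_means, row.names = FALSE)
  invisible(x)
}

#' Test one term of the endpoint model by nested-model comparison
#'
#' The interaction is tested by comparing the full model against the
#' additive model; each main effect is tested (after dropping the
#' interaction) by comparing the additive model against the model without
#' that main effect.  Degrees of freedom are whatever the two compared
#' models imply.
#'
#' @param data observation table.
#' @param term one of `"time_point"`, `"habitat"`, `"interaction"`.
#' @param days the two endpoint days, default `c(0, 42)`.
#' @return A `term_test`: `term`, `f_stat`, `df_num`, `df_den`, `p_value`.
#' @export
test_term <- function(data, term, days = c(0, 42)) {
  if (!term %in% c("time_point", "habitat", "interaction"))
    stop("test_term: unknown term '", term,
         "' (expected time_point, habitat or interaction)")
  sub <- .endpoint_subset(data, days)
  full <- stats::lm(concentration ~ time_point * habitat, data = sub)
  additive <- stats::lm(concentration ~ time_point + habitat, data = sub)
  cmp <- switch(term,
    interaction = stats::anova(additive, full),
    time_point  = stats::anova(stats::lm(concentration ~ habitat,
                                         data = sub), additive),
    habitat     = stats::anova(stats::lm(concentration ~ time_point,
                                         data = sub), additive))
  structure(list(term = term,
                 f_stat = cmp$F[2],
                 df_num = cmp$Df[2],
                 df_den = cmp$Res.Df[2],
                 p_value = cmp$`Pr(>F)`[2]),
            class = "term_test")
}

#' @export
print.term_test <- function(x, ...) {
  cat(sprintf("%s: F(%d, %d) = %.3f, p = %.4g\n",
              x$term, x$df_num, x$df_den, x$f_stat, x$p_value))
  invisible(x)
}

#' Quantitative residual diagnostics for the endpoint model
#'
#' Numerical stand-ins for the conventional visual checks: the Shapiro-Wilk
#' statistic on the residuals, the max/min ratio of per-cell residual
#' variances, and a residual-versus-fitted table suitable for plotting.
#'
#' @param fit an `endpoint_fit`.
#' @return A list: `shapiro_stat`, `shapiro_p`, `variance_ratio`,
#'   `cell_variances`, `resid_vs_fitted` (data frame).
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "endpoint_fit"))
  r <- stats::residuals(fit$model)
  if (length(r) < 4)
    stop("residual_diagnostics: need at least 4 observations")
  sw <- stats::shapiro.test(r)
  cell <- interaction(fit$data$time_point, fit$data$habitat, drop = TRUE)
  v <- tapply(r, cell, stats::var)
  v <- v[is.finite(v) & v > 0]
  list(shapiro_stat = unname(sw$statistic),
       shapiro_p = sw$p.value,
       variance_ratio = if (length(v)) max(v) / min(v) else NA_real_,
       cell_variances = v,
       resid_vs_fitted = data.frame(fitted = stats::fitted(fit$model),
                                    residual = unname(r),
                                    time_point = fit$data$time_point,
                                    habitat = fit$data$habitat))
}
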