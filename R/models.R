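## Species-level attractiveness models: LG dimorphism ratio, linear models
## with sequential (Type-I) ANOVA and backward-AIC reduction, Tukey group
## contrasts, and the LOWESS human-likeness curve.

#' Lovich-Gibbons sexual size dimorphism ratio
#'
#' `(body weight of the larger sex / body weight of the smaller sex) - 1`,
#' negative by convention when males are the larger sex, positive when
#' females are larger, and 0 when the sexes weigh the same.
#'
#' @param male_weight,female_weight positive body masses (vectorised).
#' @return numeric LG ratios.
#' @examples
#' lg_ratio(10, 5)  # -1: males twice as heavy
#' @export
lg_ratio <- function(male_weight, female_weight) {
  if (any(male_weight <= 0) || any(female_weight <= 0))
    stopf("body weights must be positive")
  mag <- pmax(male_weight, female_weight) / pmin(male_weight, female_weight) - 1
  ifelse(male_weight > female_weight, -mag, mag)
}

#' Fit a species-level linear model
#'
#' Least-squares fit with treatment contrasts, sequential (Type-I) ANOVA
#' respecting the order of the terms in the formula, coefficient t tests and
#' Gaussian AIC. If a `group` factor is present its reference level can be
#' declared (default "catarrhine", so coefficients are reported for the
#' other groups against it).
#'
#' @param formula model formula, e.g. `mean_beauty ~ group + factor2_inner +
#'   lg + human_likeness + bluish_t`.
#' @param data species table (one row per species).
#' @param reference_group reference level for the `group` factor, if present.
#' @return object of class `attract_lm`: the `lm` fit plus `anova` (Type I),
#'   `coefficients` table, `r_squared`, `adj_r_squared`, `aic`,
#'   `log_likelihood`, `n`.
#' @export
fit_lm <- function(formula, data, reference_group = "catarrhine") {
  data <- as.data.frame(data)
  vars <- all.vars(formula)
  if ("group" %in% vars && !is.null(reference_group)) {
    data$group <- factor(data$group)
    if (reference_group %in% levels(data$group))
      data$group <- relevel(data$group, ref = reference_group)
  }
  ## inline the data into the call so drop1()/update() refits are
  ## self-contained wherever they are evaluated
  fit <- eval(bquote(stats::lm(.(formula), data = .(data))))
  if (anyNA(coef(fit)))
    stopf("aliased term(s): %s",
          paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  if (df.residual(fit) <= 0) stopf("no residual degrees of freedom")
  sm <- summary(fit)
  structure(list(
    lm = fit, formula = formula, data = data,
    anova = anova(fit),
    coefficients = sm$coefficients,
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    aic = AIC(fit), log_likelihood = as.numeric(logLik(fit)),
    n = nobs(fit)
  ), class = "attract_lm")
}

#' @export
print.attract_lm <- function(x, digits = 4, ...) {
  cat("Linear model:", deparse(x$formula), "\n")
  cat(sprintf("n = %d, r^2 = %.4f, AIC = %.2f\n", x$n, x$r_squared, x$aic))
  cat("\nSequential (Type I) ANOVA:\n")
  print(x$anova, signif.stars = FALSE)
  cat("\nCoefficients:\n")
  printCoefmat(x$coefficients, digits = digits, signif.stars = FALSE)
  invisible(x)
}

#' @export
coef.attract_lm <- function(object, ...) coef(object$lm)
#' @export
predict.attract_lm <- function(object, ...) predict(object$lm, ...)
#' @export
residuals.attract_lm <- function(object, ...) residuals(object$lm)
#' @export
summary.attract_lm <- function(object, ...) summary(object$lm, ...)

#' Backward AIC reduction with a likelihood-ratio guard against the full model
#'
#' Repeatedly drops the single term whose removal lowers AIC the most. Before
#' accepting a drop, the candidate reduced model is compared with the
#' *original full* model by a likelihood-ratio test; reduction stops when no
#' drop lowers AIC or when that test becomes significant at `alpha` (the
#' offending drop is not applied). The elimination trace is recorded.
#'
#' @param fit an `attract_lm` (the full model).
#' @param alpha level of the likelihood-ratio stop rule (default 0.05).
#' @return the reduced `attract_lm`, with elements `trace` (data.frame of
#'   steps) and `dropped` (terms removed, in order).
#' @export
reduce_aic <- function(fit, alpha = 0.05) {
  if (!inherits(fit, "attract_lm")) stopf("fit must come from fit_lm()")
  full <- fit$lm
  ll_full <- logLik(full)
  cur <- full
  dropped <- character(0)
  trace <- data.frame(step = 0L, dropped = NA_character_, aic = AIC(full),
                      log_lik = as.numeric(ll_full), lrt_p = NA_real_,
                      stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    labs <- attr(terms(cur), "term.labels")
    if (!length(labs)) break
    d1 <- drop1(cur)
    cand <- rownames(d1)[-1]
    aics <- d1$AIC[-1]
    if (!length(cand) || min(aics) >= AIC(cur) - 1e-10) break
    drop_term <- cand[which.min(aics)]
    red <- update(cur, as.formula(paste(". ~ . -", drop_term)))
    ll_red <- logLik(red)
    df_diff <- attr(ll_full, "df") - attr(ll_red, "df")
    lrt_p <- pchisq(2 * (as.numeric(ll_full) - as.numeric(ll_red)),
                    df = df_diff, lower.tail = FALSE)
    if (lrt_p < alpha) break  # reduced model now significantly worse than full
    step_i <- step_i + 1L
    cur <- red
    dropped <- c(dropped, drop_term)
    trace <- rbind(trace, data.frame(step = step_i, dropped = drop_term,
                                     aic = AIC(cur),
                                     log_lik = as.numeric(ll_red),
                                     lrt_p = lrt_p, stringsAsFactors = FALSE))
  }
  out <- fit_lm(formula(cur), fit$data, reference_group = NULL)
  out$trace <- trace
  out$dropped <- dropped
  out$full_formula <- fit$formula
  out
}

#' Tukey honest-significant-difference group comparison
#'
#' Studentised-range pairwise comparisons of group means (Tukey-Kramer for
#' unbalanced sizes).
#'
#' @param values numeric response per item.
#' @param groups group labels (>= 2 groups, each with >= 2 items).
#' @param conf_level confidence level of the intervals.
#' @return data.frame with `pair`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups, conf_level = 0.95) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  if (any(table(groups) < 2))
    stopf("insufficient replication: group(s) with a single item: %s",
          paste(names(table(groups))[table(groups) < 2], collapse = ", "))
  tk <- TukeyHSD(aov(values ~ groups), conf.level = conf_level)$groups
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' LOWESS curve
#'
#' Locally weighted scatterplot smoothing with tricube weights and
#' robustness iterations, evaluated at the input x in input order. Spans too
#' small to hold a local neighbourhood of at least two points are widened
#' with a warning.
#'
#' @param x,y numeric vectors (>= 5 points).
#' @param span smoother span in (0, 1] (default 2/3).
#' @param iters robustness iterations (default 3).
#' @return numeric vector of fitted values aligned with the input.
#' @export
lowess_curve <- function(x, y, span = 2/3, iters = 3) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 5) stopf("need at least 5 points")
  if (span <= 0 || span > 1) stopf("span must lie in (0, 1]")
  if (span * length(x) < 2) {
    span <- 2 / length(x)
    warnf("span too small for a local neighbourhood; widened to %.3f", span)
  }
  sm <- lowess(x, y, f = span, iter = iters)
  fitted <- numeric(length(x))
  fitted[order(x)] <- sm$y
  fitted
}
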