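## Rater-agreement statistics for complete Likert rating matrices:
## consistency ICC, Spearman-Brown, scale inversion, Mann-Whitney gender
## screen with Bonferroni correction, Wilks MANOVA, nested variance
## components and Spearman correlation screens.

#' Construct a rating matrix
#'
#' A complete raters x stimuli matrix of integer Likert scores in 1-7, with
#' per-rater gender and age metadata.
#'
#' @param scores raters x stimuli integer matrix (complete, values 1-7).
#' @param rater_meta optional data.frame with `rater_id`, `gender`
#'   ("male"/"female") and `age`.
#' @param stimulus_ids optional stimulus ids (default: column names).
#' @return object of class `rating_matrix`.
#' @export
rating_matrix <- function(scores, rater_meta = NULL, stimulus_ids = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2 || ncol(scores) < 2)
    stopf("rating matrix needs >= 2 raters and >= 2 stimuli")
  if (anyNA(scores)) stopf("rating matrix must be complete (no missing cells)")
  if (any(scores != round(scores)) || any(scores < 1 | scores > 7))
    stopf("ratings must be integers in 1..7")
  storage.mode(scores) <- "integer"
  if (is.null(stimulus_ids))
    stimulus_ids <- colnames(scores) %||% paste0("stim", seq_len(ncol(scores)))
  colnames(scores) <- stimulus_ids
  if (is.null(rownames(scores))) rownames(scores) <- paste0("rater", seq_len(nrow(scores)))
  if (is.null(rater_meta))
    rater_meta <- data.frame(rater_id = rownames(scores),
                             gender = NA_character_, age = NA_real_,
                             stringsAsFactors = FALSE)
  if (is.null(rater_meta$rater_id)) rater_meta$rater_id <- rownames(scores)
  if (nrow(rater_meta) != nrow(scores))
    stopf("rater_meta must have one row per rater")
  structure(list(scores = scores, rater_meta = rater_meta,
                 stimulus_ids = stimulus_ids),
            class = "rating_matrix")
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat("Rating matrix:", nrow(x$scores), "raters x", ncol(x$scores),
      "stimuli (Likert 1-7)\n")
  if (!all(is.na(x$rater_meta$gender)))
    print(table(x$rater_meta$gender))
  invisible(x)
}

as_scores <- function(m) if (inherits(m, "rating_matrix")) m$scores else as.matrix(m)

#' Two-way consistency intraclass correlation
#'
#' Stimuli are the objects (rows of the ANOVA), raters the judges. From the
#' two-way ANOVA without interaction, with k raters:
#' single-measure ICC = (MS_rows - MS_err) / (MS_rows + (k-1) MS_err);
#' average-measure ICC = (MS_rows - MS_err) / MS_rows. The consistency form
#' ignores rater main effects, so adding a constant per rater leaves it
#' unchanged, and the average measure equals the Spearman-Brown step-up of
#' the single measure algebraically.
#'
#' @param m a `rating_matrix` or numeric raters x stimuli matrix.
#' @return object of class `icc`: `icc_single`, `icc_average`, `ms_rows`,
#'   `ms_error`, `n_stimuli`, `n_raters`, `f_value`, `df1`, `df2`, `p_value`.
#' @export
icc_consistency <- function(m) {
  x <- t(as_scores(m))  # stimuli x raters
  n <- nrow(x); k <- ncol(x)
  mu <- mean(x)
  ss_rows <- k * sum((rowMeans(x) - mu)^2)
  ss_cols <- n * sum((colMeans(x) - mu)^2)
  ss_tot <- sum((x - mu)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr == 0 && mse == 0)
    stopf("undefined ICC: no row variance and zero error mean square")
  single <- (msr - mse) / (msr + (k - 1) * mse)
  average <- (msr - mse) / msr
  f <- if (mse > 0) msr / mse else Inf
  structure(list(
    icc_single = single, icc_average = average,
    ms_rows = msr, ms_error = mse, n_stimuli = n, n_raters = k,
    f_value = f, df1 = n - 1, df2 = (n - 1) * (k - 1),
    p_value = pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  ), class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf(
    "Two-way consistency ICC (%d stimuli, %d raters)\n  single %.3f | average %.3f | F(%d,%d) = %.2f, p = %.3g\n",
    x$n_stimuli, x$n_raters, x$icc_single, x$icc_average, x$df1, x$df2,
    x$f_value, x$p_value))
  invisible(x)
}

#' Spearman-Brown step-up of a single-measure reliability
#'
#' Reliability of the mean of k raters given the single-rater reliability:
#' `k * s / (1 + (k - 1) * s)`.
#'
#' @param icc_single single-measure ICC in (-1, 1).
#' @param k number of raters averaged (positive integer).
#' @return average-measure reliability.
#' @examples
#' spearman_brown(0.182, 286)  # ~0.985
#' @export
spearman_brown <- function(icc_single, k) {
  if (any(k < 1) || any(k != round(k))) stopf("k must be a positive integer")
  den <- 1 + (k - 1) * icc_single
  if (any(den <= 0)) stopf("nonpositive Spearman-Brown denominator")
  k * icc_single / den
}

#' Invert a 1-7 Likert scale
#'
#' Maps every score x to 8 - x so that the higher value corresponds to higher
#' attractiveness; applying it twice restores the input.
#'
#' @param m a `rating_matrix` or integer matrix.
#' @return same type as the input.
#' @export
invert_scale <- function(m) {
  if (inherits(m, "rating_matrix")) {
    m$scores <- 8L - m$scores
    m
  } else 8L - m
}

## Mann-Whitney U with normal approximation, tie correction and continuity
## correction (two-sided). Returns c(u, p).
mw_u_approx <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) return(c(u = u, p = 1))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
  c(u = u, p = min(1, 2 * pnorm(-abs(z))))
}

#' Per-stimulus Mann-Whitney gender screen with Bonferroni correction
#'
#' Compares male and female raters' raw scores of each stimulus with a
#' two-sided Mann-Whitney U test (normal approximation with tie and
#' continuity correction; exact enumeration when both groups have <= 8 raters
#' and no ties). Significance is declared at `alpha / n_stimuli`.
#'
#' @param m a `rating_matrix` with gender metadata.
#' @param alpha family-wise level (default 0.05).
#' @return data.frame with `stimulus_id`, `u`, `p`, `p_bonferroni`,
#'   `significant`.
#' @export
gender_screen <- function(m, alpha = 0.05) {
  if (!inherits(m, "rating_matrix")) stopf("m must be a rating_matrix")
  g <- m$rater_meta$gender
  if (sum(g == "male", na.rm = TRUE) < 2 || sum(g == "female", na.rm = TRUE) < 2)
    stopf("need at least 2 raters of each gender")
  male <- m$scores[g == "male", , drop = FALSE]
  female <- m$scores[g == "female", , drop = FALSE]
  n_stim <- ncol(m$scores)
  res <- vapply(seq_len(n_stim), function(j) {
    x <- male[, j]; y <- female[, j]
    if (length(x) <= 8 && length(y) <= 8 && !any(duplicated(c(x, y)))) {
      wt <- wilcox.test(x, y, exact = TRUE)
      c(u = unname(wt$statistic), p = wt$p.value)
    } else mw_u_approx(x, y)
  }, c(u = 0, p = 0))
  data.frame(stimulus_id = m$stimulus_ids, u = res["u", ], p = res["p", ],
             p_bonferroni = pmin(1, res["p", ] * n_stim),
             significant = res["p", ] < alpha / n_stim,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' MANOVA with Wilks' lambda per term
#'
#' Multivariate analysis of variance of a response matrix on a design
#' formula, reporting Wilks' lambda, Rao's approximate F and its p-value for
#' each sequential term. When the response has too many columns for the
#' error matrix to be nonsingular (items <= responses + design df), the
#' responses are first reduced by PCA retaining `var_retained` of the
#' variance, with a warning; a single-column response reduces to the
#' univariate ANOVA.
#'
#' @param responses items x q numeric matrix.
#' @param design data.frame of predictors.
#' @param formula right-hand-side formula over `design` columns (default: all
#'   main effects).
#' @param var_retained PCA variance retained when reduction is needed.
#' @return data.frame with `term`, `wilks`, `f`, `df1`, `df2`, `p`,
#'   plus attribute `reduced_to` (number of response columns used).
#' @export
manova_wilks <- function(responses, design, formula = NULL,
                         var_retained = 0.95) {
  Y <- as.matrix(responses)
  design <- as.data.frame(design)
  if (is.null(formula))
    formula <- as.formula(paste("~", paste(names(design), collapse = " + ")))
  mm <- model.matrix(formula, design)
  n <- nrow(Y)
  if (ncol(Y) > 1 && n <= ncol(Y) + ncol(mm)) {
    keep <- max(1, min(n - ncol(mm) - 2, ncol(Y)))
    pr <- prcomp(Y, center = TRUE, scale. = FALSE)
    cum <- cumsum(pr$sdev^2) / sum(pr$sdev^2)
    k <- min(keep, max(1, which(cum >= var_retained)[1]))
    warnf("responses reduced by PCA from %d to %d columns (%.0f%% variance retained)",
          ncol(Y), k, 100 * cum[k])
    Y <- pr$x[, seq_len(k), drop = FALSE]
  }
  f2 <- update(formula, Y ~ .)
  env <- list2env(design)
  assign("Y", Y, envir = env)
  environment(f2) <- env
  if (ncol(Y) == 1) {
    fit <- lm(f2)
    an <- anova(fit)
    terms <- rownames(an)[rownames(an) != "Residuals"]
    ss_e <- an["Residuals", "Sum Sq"]
    out <- data.frame(term = terms,
                      wilks = ss_e / (ss_e + an[terms, "Sum Sq"]),
                      f = an[terms, "F value"], df1 = an[terms, "Df"],
                      df2 = an["Residuals", "Df"], p = an[terms, "Pr(>F)"],
                      stringsAsFactors = FALSE)
  } else {
    fit <- manova(f2)
    sm <- summary(fit, test = "Wilks")$stats
    terms <- rownames(sm)[rownames(sm) != "Residuals"]
    out <- data.frame(term = terms, wilks = sm[terms, "Wilks"],
                      f = sm[terms, "approx F"], df1 = sm[terms, "num Df"],
                      df2 = sm[terms, "den Df"], p = sm[terms, "Pr(>F)"],
                      stringsAsFactors = FALSE)
  }
  attr(out, "reduced_to") <- ncol(Y)
  rownames(out) <- NULL
  out
}

#' Nested variance components by method of moments
#'
#' Hierarchical ANOVA estimates for a balanced nested design
#' group > genus > species > individual (residual): expected mean squares are
#' equated to the sequential ANOVA mean squares and solved top-down. Negative
#' solutions are truncated at zero and flagged. Labels must nest (each
#' species in exactly one genus, each genus in one group).
#'
#' @param data data.frame with columns `group`, `genus`, `species` and the
#'   response named by `score`.
#' @param score response column name (default "score").
#' @return object of class `variance_components`: named vector `estimates`
#'   (group, genus, species, residual), `truncated` flags, `mean_squares`.
#' @export
nested_variance_components <- function(data, score = "score") {
  need <- c("group", "genus", "species", score)
  if (!all(need %in% names(data)))
    stopf("data needs columns %s", paste(need, collapse = ", "))
  ## nesting consistency
  if (any(tapply(data$genus, data$species, function(g) length(unique(g))) > 1))
    stopf("nesting violation: a species appears in more than one genus")
  if (any(tapply(data$group, data$genus, function(g) length(unique(g))) > 1))
    stopf("nesting violation: a genus appears in more than one group")
  y <- data[[score]]
  G <- factor(data$group); gn <- factor(data$genus); sp <- factor(data$species)
  ## levels are globally unique, so sequential fitting of the plain factors
  ## yields the nested ANOVA (aliased columns are dropped by lm)
  an <- anova(lm(y ~ G + gn + sp))
  ms <- an[, "Mean Sq"]
  names(ms) <- c("group", "genus", "species", "residual")
  ## balanced multipliers
  n_ind <- mean(table(sp))
  n_sp_per_genus <- mean(tapply(sp, gn, function(s) length(unique(s))))
  n_gn_per_group <- mean(tapply(gn, G, function(s) length(unique(s))))
  if (length(unique(table(sp))) > 1 ||
      length(unique(tapply(sp, gn, function(s) length(unique(s))))) > 1)
    warnf("design is unbalanced; method-of-moments estimates use average multipliers")
  mse <- ms[["residual"]]
  v_sp <- (ms[["species"]] - mse) / n_ind
  v_gn <- (ms[["genus"]] - ms[["species"]]) / (n_ind * n_sp_per_genus)
  v_gr <- (ms[["group"]] - ms[["genus"]]) / (n_ind * n_sp_per_genus * n_gn_per_group)
  est <- c(group = v_gr, genus = v_gn, species = v_sp, residual = mse)
  truncated <- est < 0
  est[truncated] <- 0
  structure(list(estimates = est, truncated = truncated, mean_squares = ms),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Nested variance components (method of moments)\n")
  print(round(x$estimates, 5))
  if (any(x$truncated))
    cat("note: negative estimate(s) truncated at 0:",
        paste(names(x$estimates)[x$truncated], collapse = ", "), "\n")
  invisible(x)
}

#' Spearman correlation screen
#'
#' Spearman's rho of `x` against each column of `Y`, with the tie-corrected
#' t approximation for the p-value. Constant vectors yield an NA correlation
#' with a flag instead of an error.
#'
#' @param x numeric vector.
#' @param Y numeric matrix or data.frame of candidate variables.
#' @param alpha significance level.
#' @return data.frame with `variable`, `rho`, `p`, `significant`, `degenerate`.
#' @export
spearman_screen <- function(x, Y, alpha = 0.05) {
  Y <- as.data.frame(Y)
  if (length(x) < 4) stopf("need at least 4 paired observations")
  rows <- lapply(names(Y), function(v) {
    y <- Y[[v]]
    if (length(y) != length(x)) stopf("length mismatch for %s", v)
    if (sd(x) == 0 || sd(y) == 0)
      return(data.frame(variable = v, rho = NA_real_, p = NA_real_,
                        significant = FALSE, degenerate = TRUE))
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    data.frame(variable = v, rho = unname(ct$estimate), p = ct$p.value,
               significant = ct$p.value < alpha, degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
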