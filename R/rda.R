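## Redundancy analysis (constrained ordination) of the rating response on
## species-level explanatory variables, with sequential permutation tests and
## forward model building. Fitting and permutation machinery are delegated to
## vegan; this layer fixes the response/constraint conventions used in the
## pipeline and exposes the quantities downstream code consumes.

#' Fit a redundancy analysis
#'
#' Multivariate least squares of a (column-centred) response matrix on a set
#' of constraints; constrained axes are the PCA of the fitted values and
#' unconstrained axes the PCA of the residuals, so the constrained and
#' unconstrained eigenvalues always sum to the total variance of the centred
#' response.
#'
#' @param Y items x q numeric response matrix (e.g. species x raters scores).
#' @param X data.frame (or matrix) of constraints; all columns are used.
#' @param scale scale response columns to unit variance (default FALSE).
#' @return object of class `rda_fit`: `constrained_eig`, `unconstrained_eig`,
#'   `total_variance`, `proportion_constrained`, `site_scores`,
#'   `biplot_scores` (scaling 2), `aliased`, and the underlying vegan
#'   ordination as `ord`.
#' @export
rda_fit <- function(Y, X, scale = FALSE) {
  Y <- as.matrix(Y)
  Xdf <- as.data.frame(X)
  if (nrow(Y) != nrow(Xdf)) stopf("Y and X must have the same number of rows")
  if (nrow(Y) <= ncol(Xdf)) stopf("need more items than constraints")
  dat <- list2env(list(Y = Y, Xdf = Xdf))
  fml <- as.formula(paste("Y ~", paste(names(Xdf), collapse = " + ")))
  ord <- vegan::rda(fml, data = Xdf, scale = scale)
  aliased <- if (!is.null(ord$CCA$alias)) ord$CCA$alias else character(0)
  ce <- ord$CCA$eig %||% numeric(0)
  ue <- ord$CA$eig %||% numeric(0)
  k <- length(ce)
  structure(list(
    constrained_eig = ce, unconstrained_eig = ue,
    total_variance = ord$tot.chi,
    proportion_constrained = sum(ce) / ord$tot.chi,
    site_scores = if (k)
      vegan::scores(ord, display = "sites", scaling = 2,
                    choices = seq_len(k)) else NULL,
    biplot_scores = if (k)
      vegan::scores(ord, display = "bp", scaling = 2,
                    choices = seq_len(k)) else NULL,
    aliased = aliased, terms = names(Xdf), ord = ord, n = nrow(Y)
  ), class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("Redundancy analysis:", x$n, "items,", length(x$terms), "constraint(s)\n")
  cat(sprintf("constrained axes explain %.2f%% of total variance\n",
              100 * x$proportion_constrained))
  if (length(x$aliased))
    cat("aliased constraints dropped:", paste(x$aliased, collapse = ", "), "\n")
  invisible(x)
}

#' Sequential permutation tests of RDA terms
#'
#' Tests each constraint with the terms before it as conditioning set
#' ("Type I" sequential tests), permuting residuals of the reduced model;
#' p = (exceedances + 1) / (n_perm + 1). Seeded and reproducible.
#'
#' @param Y,X as in [rda_fit()] (term order in `X` is the testing order).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return data.frame with `term`, `df`, `variance`, `f`, `p` and attribute
#'   `n_perm`.
#' @export
rda_permutation_terms <- function(Y, X, n_perm = 999, seed = 1) {
  if (n_perm < 99) stopf("n_perm must be >= 99")
  fit <- rda_fit(Y, X)
  an <- with_seed(seed,
    vegan::anova.cca(fit$ord, by = "terms", permutations = n_perm))
  terms <- rownames(an)[rownames(an) != "Residual"]
  out <- data.frame(term = terms, df = an[terms, "Df"],
                    variance = an[terms, "Variance"], f = an[terms, "F"],
                    p = an[terms, "Pr(>F)"], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  out
}

#' Forward RDA model building on permutation p-values
#'
#' At each step every remaining candidate is added last to the current
#' constraint set and assessed by its sequential permutation test; the
#' candidate with the smallest p (ties broken by the larger gain in
#' constrained variance) enters if p <= alpha, otherwise selection stops.
#' An AIC-like criterion (`n * log(RSS/n) + 2 * npar` from the residual
#' variance) is tracked as an advisory second criterion and its agreement
#' reported.
#'
#' @param Y response matrix.
#' @param candidates data.frame of candidate constraints.
#' @param n_perm permutations per test.
#' @param alpha entry threshold on the permutation p-value.
#' @param seed integer seed.
#' @return list: `selected` term names, `fit` (final [rda_fit()], NULL if
#'   empty), `path` (data.frame of evaluated steps), `aic_agrees`.
#' @export
rda_model_build <- function(Y, candidates, n_perm = 499, alpha = 0.05, seed = 1) {
  candidates <- as.data.frame(candidates)
  if (!ncol(candidates)) stopf("need at least one candidate")
  Y <- as.matrix(Y)
  n <- nrow(Y)
  rss0 <- sum(scale(Y, scale = FALSE)^2)
  aic_of <- function(fit, npar)
    n * log((fit$total_variance * (1 - fit$proportion_constrained)) *
              (n - 1) / n + 1e-300) + 2 * npar
  selected <- character(0)
  path <- NULL
  cur_aic <- n * log(rss0 / n / 1) + 2  # intercept-only analogue (scaled)
  cur_prop <- 0
  step_i <- 0L
  seeds <- derive_seeds(seed, ncol(candidates) * (ncol(candidates) + 1))
  si <- 0L
  aic_agrees <- TRUE
  repeat {
    remaining <- setdiff(names(candidates), selected)
    if (!length(remaining)) break
    step_i <- step_i + 1L
    stats <- lapply(remaining, function(cand) {
      si <<- si + 1L
      Xc <- candidates[, c(selected, cand), drop = FALSE]
      pt <- rda_permutation_terms(Y, Xc, n_perm = n_perm, seed = seeds[si])
      last <- nrow(pt)
      ft <- rda_fit(Y, Xc)
      data.frame(step = step_i, term = cand, p = pt$p[last], f = pt$f[last],
                 gain = ft$proportion_constrained - cur_prop,
                 prop = ft$proportion_constrained,
                 aic = aic_of(ft, length(selected) + 2),
                 stringsAsFactors = FALSE)
    })
    stats <- do.call(rbind, stats)
    path <- rbind(path, stats)
    best <- stats[order(stats$p, -stats$gain), ][1, ]
    if (best$p > alpha) break
    if (best$aic >= cur_aic) aic_agrees <- FALSE
    cur_aic <- best$aic
    cur_prop <- best$prop
    selected <- c(selected, best$term)
  }
  fit <- if (length(selected))
    rda_fit(Y, candidates[, selected, drop = FALSE]) else NULL
  list(selected = selected, fit = fit, path = path, aic_agrees = aic_agrees)
}
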