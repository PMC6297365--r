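## Landmark-based morphometrics: the 14 interlandmark distance traits, their
## maximum-likelihood factor summary, canonical variate analysis of the
## groups, and PCA.

edist <- function(m, p, q) sqrt(sum((m[p, ] - m[q, ])^2))

#' Derive the 14 morphometric traits from 19 facial landmarks
#'
#' Each trait is a Euclidean interlandmark distance (or the mean of two):
#' face height A-D, face width B-C, forehead height A-F, eye size
#' (mean of E1-E2 and G1-G2), nose length F-I, nose width H-J, mouth width
#' K-M, side hair (mean of O1-B and C-O2), top hair N-A, beard D-P,
#' interocular E2-G2, eyes-to-mouth F-L, philtrum I-L, chin L-D. Traits are
#' in pixels and invariant under rigid motion.
#'
#' The printed trait definitions pair nose length with F-I and nose width
#' with H-J; `nose_convention = "geometric"` instead uses the geometrically
#' natural F-J (length) and H-I (width).
#'
#' @param lm 19 x 2 named landmark matrix (see [load_landmarks()]).
#' @param nose_convention "as_printed" (default) or "geometric".
#' @return named numeric vector of the 14 traits.
#' @examples
#' lm <- generate_species_panel(2, seed = 1)[[1]]$landmark_template
#' derive_traits(lm)
#' @export
derive_traits <- function(lm, nose_convention = c("as_printed", "geometric")) {
  nose_convention <- match.arg(nose_convention)
  if (is.null(rownames(lm)))
    stopf("incomplete landmarks: matrix has no point names")
  miss <- setdiff(LANDMARK_NAMES, rownames(lm))
  if (length(miss))
    stopf("incomplete landmarks: missing point(s) %s", paste(miss, collapse = ", "))
  lm <- lm[LANDMARK_NAMES, , drop = FALSE]
  nose <- if (nose_convention == "as_printed")
    c(nose_length = edist(lm, "F", "I"), nose_width = edist(lm, "H", "J"))
  else
    c(nose_length = edist(lm, "F", "J"), nose_width = edist(lm, "H", "I"))
  out <- c(
    face_height = edist(lm, "A", "D"),
    face_width = edist(lm, "B", "C"),
    forehead_height = edist(lm, "A", "F"),
    eye_size = mean(c(edist(lm, "E1", "E2"), edist(lm, "G1", "G2"))),
    nose,
    mouth_width = edist(lm, "K", "M"),
    side_hair = mean(c(edist(lm, "O1", "B"), edist(lm, "C", "O2"))),
    top_hair = edist(lm, "N", "A"),
    beard = edist(lm, "D", "P"),
    interocular = edist(lm, "E2", "G2"),
    eyes_to_mouth = edist(lm, "F", "L"),
    philtrum = edist(lm, "I", "L"),
    chin = edist(lm, "L", "D"))
  out[TRAIT_NAMES]
}

#' Trait matrix for a set of landmark configurations
#'
#' @param landmarks named list of 19 x 2 landmark matrices.
#' @param ... passed to [derive_traits()].
#' @return items x 14 matrix with the landmark ids as row names.
#' @export
traits_table <- function(landmarks, ...) {
  t(vapply(landmarks, derive_traits, numeric(14), ...))
}

#' Maximum-likelihood factor analysis of the morphometric traits
#'
#' Standardises the trait columns, extracts `n_factors` maximum-likelihood
#' factors and rotates them by varimax with Kaiser row normalisation.
#' Factor scores use the regression method. Each factor is oriented so its
#' largest-|loading| trait loads positively, making the output reproducible.
#' Heywood cases (uniqueness at the optimisation floor) are flagged with a
#' warning.
#'
#' @param traits items x p numeric matrix (p >= 3 recommended).
#' @param n_factors number of factors (default 2).
#' @return An object of class `face_factors`: `loadings` (p x m),
#'   `uniquenesses`, `communalities`, `variance_explained` (percent per
#'   factor), `scores` (items x m), `converged`, `heywood`.
#' @export
fit_factors <- function(traits, n_factors = 2) {
  traits <- as.matrix(traits)
  if (nrow(traits) <= n_factors)
    stopf("need more items (%d) than factors (%d)", nrow(traits), n_factors)
  z <- scale(traits)
  if (any(!is.finite(z)))
    stopf("constant trait column(s): %s",
          paste(colnames(traits)[apply(traits, 2, sd) == 0], collapse = ", "))
  lower <- 1e-3
  fa <- tryCatch(
    factanal(x = z, factors = n_factors, rotation = "varimax",
             scores = "regression", control = list(lower = lower)),
    error = function(e) stopf("factor analysis did not converge: %s",
                              conditionMessage(e)))
  L <- unclass(fa$loadings)
  sc <- fa$scores
  ## sign convention: dominant trait of each factor loads positively
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) {
      L[, j] <- -L[, j]
      sc[, j] <- -sc[, j]
    }
  }
  heywood <- any(fa$uniquenesses <= lower + 1e-8)
  if (heywood)
    warnf("Heywood case: uniqueness floored at %g for %s", lower,
          paste(names(fa$uniquenesses)[fa$uniquenesses <= lower + 1e-8],
                collapse = ", "))
  structure(list(
    loadings = L,
    uniquenesses = fa$uniquenesses,
    communalities = 1 - fa$uniquenesses,
    variance_explained = 100 * colSums(L^2) / nrow(L),
    scores = sc,
    n = nrow(traits),
    converged = fa$converged %||% TRUE,
    heywood = heywood,
    stat = c(statistic = unname(fa$STATISTIC %||% NA_real_),
             p_value = unname(fa$PVAL %||% NA_real_))
  ), class = "face_factors")
}

#' @export
print.face_factors <- function(x, digits = 3, ...) {
  cat("Maximum-likelihood factors (varimax, Kaiser-normalised)\n")
  cat("Variance explained (%):",
      paste(sprintf("%.1f", x$variance_explained), collapse = ", "), "\n")
  print(round(x$loadings, digits))
  invisible(x)
}

## Factor summary that degrades gracefully: ML factor analysis needs clearly
## more items than traits, so small panels fall back to a PCA-based summary
## with the same fields (flagged by method = "pca"), with a warning.
morpho_factors <- function(traits, n_factors = 2) {
  if (nrow(traits) > ncol(traits) + n_factors) {
    fm <- tryCatch(suppressWarnings(fit_factors(traits, n_factors)),
                   error = function(e) NULL)
    if (!is.null(fm)) {
      fm$method <- "ml"
      return(fm)
    }
  }
  warnf("too few items for ML factor analysis (%d items, %d traits); using a PCA summary",
        nrow(traits), ncol(traits))
  pr <- prcomp(traits, center = TRUE, scale. = TRUE)
  k <- seq_len(n_factors)
  L <- pr$rotation[, k, drop = FALSE] %*% diag(pr$sdev[k], n_factors)
  sc <- scale(pr$x[, k, drop = FALSE])
  for (j in k) {
    if (L[which.max(abs(L[, j])), j] < 0) {
      L[, j] <- -L[, j]; sc[, j] <- -sc[, j]
    }
  }
  comm <- pmin(rowSums(L^2), 1)
  structure(list(loadings = L, uniquenesses = 1 - comm, communalities = comm,
                 variance_explained = 100 * pr$sdev[k]^2 / sum(pr$sdev^2),
                 scores = sc, n = nrow(traits), converged = TRUE,
                 heywood = FALSE, stat = c(statistic = NA_real_,
                                           p_value = NA_real_),
                 method = "pca"),
            class = "face_factors")
}

#' Canonical variate analysis
#'
#' Ordination that best separates a priori groups: the canonical axes are
#' eigenvectors of \eqn{W^{-1}B}, with W the unbiased pooled within-group
#' covariance (divisor n - g) and B the between-group covariance of group
#' means (divisor g - 1, weighted by group size). Axes are scaled so the
#' within-group variance of the scores is 1. Items are reassigned to the
#' nearest group centroid in canonical space.
#'
#' @param x items x p numeric matrix.
#' @param groups group labels (>= 2 groups with >= 2 items each).
#' @param ridge optional ridge added to W as `ridge * mean(diag(W))` when W
#'   is singular (default 0: a singular W is an error suggesting the ridge).
#' @return An object of class `cva_fit`: `axes` (p x s), `eigenvalues`,
#'   `centroids`, `scores`, `reassigned`, `accuracy`, `groups`, `means`.
#' @export
cva <- function(x, groups, ridge = 0) {
  x <- as.matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  if (any(table(groups) < 2)) stopf("each group needs at least 2 items")
  n <- nrow(x); g <- nlevels(groups); p <- ncol(x)
  means <- rowsum(x, groups) / as.vector(table(groups))
  grand <- colMeans(x)
  centered <- x - means[groups, , drop = FALSE]
  W <- crossprod(centered) / (n - g)
  ng <- as.vector(table(groups))
  md <- sweep(means, 2, grand)
  B <- crossprod(md * sqrt(ng)) / (g - 1)
  if (ridge > 0) W <- W + ridge * mean(diag(W)) * diag(p)
  Winv <- tryCatch(solve(W), error = function(e)
    stopf("within-group scatter is singular; retry with ridge > 0 (e.g. 1e-8)"))
  ee <- eigen(Winv %*% B)
  s <- min(g - 1, p)
  ord <- order(Re(ee$values), decreasing = TRUE)[seq_len(s)]
  lambda <- pmax(Re(ee$values)[ord], 0)
  A <- Re(ee$vectors)[, ord, drop = FALSE]
  ## scale axes so a' W a = 1 (unit within-group variance of scores)
  for (j in seq_len(s)) {
    nrm <- sqrt(drop(t(A[, j]) %*% W %*% A[, j]))
    if (nrm > 0) A[, j] <- A[, j] / nrm
    if (A[which.max(abs(A[, j])), j] < 0) A[, j] <- -A[, j]
  }
  rownames(A) <- colnames(x)
  colnames(A) <- paste0("CV", seq_len(s))
  scores <- sweep(x, 2, grand) %*% A
  centroids <- sweep(means, 2, grand) %*% A
  d2 <- vapply(seq_len(g), function(k)
    rowSums(sweep(scores, 2, centroids[k, ])^2), numeric(n))
  reassigned <- factor(levels(groups)[max.col(-d2)], levels = levels(groups))
  structure(list(
    axes = A, eigenvalues = lambda, centroids = centroids, scores = scores,
    reassigned = reassigned, groups = groups,
    accuracy = mean(reassigned == groups),
    means = means, grand_mean = grand, W = W
  ), class = "cva_fit")
}

#' @export
print.cva_fit <- function(x, ...) {
  cat("Canonical variate analysis:", nlevels(x$groups), "groups,",
      length(x$eigenvalues), "axes\n")
  cat("eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = ", "), "\n")
  cat(sprintf("reassignment accuracy: %.1f%%\n", 100 * x$accuracy))
  invisible(x)
}

#' Predict group membership for new items from a CVA fit
#'
#' @param object a `cva_fit`.
#' @param newdata items x p matrix on the same traits.
#' @param ... unused.
#' @return factor of assigned groups with canonical scores as an attribute.
#' @export
predict.cva_fit <- function(object, newdata, ...) {
  scores <- sweep(as.matrix(newdata), 2, object$grand_mean) %*% object$axes
  d2 <- vapply(seq_len(nrow(object$centroids)), function(k)
    rowSums(sweep(scores, 2, object$centroids[k, ])^2), numeric(nrow(scores)))
  d2 <- matrix(d2, nrow = nrow(scores))
  out <- factor(levels(object$groups)[max.col(-d2)], levels = levels(object$groups))
  attr(out, "scores") <- scores
  out
}

#' Leave-one-out reassignment accuracy of a CVA
#'
#' Refits the CVA without each item in turn and classifies the held-out item
#' by nearest centroid.
#'
#' @inheritParams cva
#' @return list with `predicted` labels and `accuracy`.
#' @export
cva_loo <- function(x, groups, ridge = 0) {
  x <- as.matrix(x)
  groups <- factor(groups)
  pred <- vapply(seq_len(nrow(x)), function(i) {
    fit <- cva(x[-i, , drop = FALSE], groups[-i], ridge = ridge)
    as.character(predict(fit, x[i, , drop = FALSE]))
  }, character(1))
  pred <- factor(pred, levels = levels(groups))
  list(predicted = pred, accuracy = mean(pred == groups))
}

#' Principal component analysis of a trait or covariate matrix
#'
#' Centred PCA by singular value decomposition, on the correlation matrix by
#' default (the traits have heterogeneous scales).
#'
#' @param x items x p matrix (>= 2 items and variables).
#' @param scale. standardise columns (default TRUE).
#' @return list with `scores`, `loadings`, `variance_fraction`, `sdev`.
#' @export
pca <- function(x, scale. = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stopf("need at least 2 items and 2 variables")
  sds <- apply(x, 2, sd)
  if (all(sds == 0)) stopf("degenerate input: constant matrix")
  if (scale. && any(sds == 0))
    stopf("degenerate input: constant column(s) %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
  pr <- prcomp(x, center = TRUE, scale. = scale.)
  list(scores = pr$x, loadings = pr$rotation,
       variance_fraction = pr$sdev^2 / sum(pr$sdev^2), sdev = pr$sdev)
}
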