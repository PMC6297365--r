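## Shared helpers: independent oracles and small fixture builders.

## Tucker congruence between two loading matrices after greedy column
## matching (sign-free).
tucker_congruence <- function(A, B) {
  stopifnot(dim(A) == dim(B))
  phi <- abs(crossprod(A, B)) /
    sqrt(outer(colSums(A^2), colSums(B^2)))
  ## greedy match columns
  used <- integer(0)
  vals <- numeric(ncol(A))
  for (j in seq_len(ncol(A))) {
    cand <- setdiff(seq_len(ncol(B)), used)
    k <- cand[which.max(phi[j, cand])]
    used <- c(used, k)
    vals[j] <- phi[j, k]
  }
  min(vals)
}

## Brute-force per-pixel classifier loop (independent of classify_pixels'
## vectorised path): one pixel at a time, explicit if-chains.
brute_force_profile <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  counts <- setNames(numeric(8), primface:::COLOR_CLASSES)
  n <- 0; lsum <- 0; ssum <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (img[i, j, 4] < 0.5) next
    r <- img[i, j, 1]; g <- img[i, j, 2]; b <- img[i, j, 3]
    mx <- max(r, g, b); mn <- min(r, g, b)
    L <- (mx + mn) / 2
    S <- if (mx == mn) 0 else (mx - mn) / (1 - abs(2 * L - 1))
    H <- if (mx == mn) 0 else {
      hh <- if (mx == r) ((g - b) / (mx - mn)) %% 6
      else if (mx == g) (b - r) / (mx - mn) + 2
      else (r - g) / (mx - mn) + 4
      (hh * 60) %% 360
    }
    cls <- if (L < 0.20) "black"
    else if (L > 0.71) "white"
    else if (S < 0.15) "gray"
    else if (H >= 350 || H < 18) "red"
    else if (H < 45) "orange"
    else if (H < 75) "yellow"
    else if (H >= 170 && H < 270) "bluish"
    else "unclassified"
    counts[cls] <- counts[cls] + 1
    n <- n + 1; lsum <- lsum + L; ssum <- ssum + S
  }
  list(fractions = counts / n, mean_lightness = lsum / n,
       mean_saturation = ssum / n, n_opaque = n)
}

## Random RGBA test image with a transparent border.
random_rgba <- function(h = 16, w = 16, p_transparent = 0.2) {
  img <- array(runif(h * w * 4), c(h, w, 4))
  img[, , 4] <- ifelse(matrix(runif(h * w), h, w) < p_transparent, 0, 1)
  if (all(img[, , 4] < 0.5)) img[1, 1, 4] <- 1
  img
}

## Uniform opaque square of a single RGB colour.
solid_image <- function(rgb, h = 10, w = 10) {
  img <- array(0, c(h, w, 4))
  img[, , 1] <- rgb[1]; img[, , 2] <- rgb[2]; img[, , 3] <- rgb[3]
  img[, , 4] <- 1
  img
}

## Random integer rating matrix (not from the simulator).
random_rating_matrix <- function(n_raters, n_stimuli, seed) {
  withr::with_seed(seed, {
    scores <- matrix(sample(1:7, n_raters * n_stimuli, replace = TRUE),
                     n_raters, n_stimuli)
    rating_matrix(scores)
  })
}

rigid_rotate <- function(lm, angle_deg, center = c(0, 0)) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- sweep(lm, 2, center)
  out <- out %*% R
  sweep(out, 2, center, `+`)
}
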