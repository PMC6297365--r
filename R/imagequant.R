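## Colour / pattern quantification of face stimuli.
##
## Stimuli are RGBA rasters in which alpha = 0 marks the cut-out background;
## only opaque pixels enter any statistic. Pixels are converted to HSL and
## classified into hue bins (red wraps around 360), with achromatic gates
## applied first: black (L < 0.20), then white (L > 0.71), then gray
## (S < 0.15). Hues outside every bin form an explicit "unclassified" class
## so the classes partition the opaque pixels exactly.

#' Convert RGB to HSL
#'
#' Standard hue/saturation/lightness conversion. Hue is in degrees
#' \code{[0, 360)} and is 0 by convention for achromatic pixels (S = 0).
#'
#' @param rgb numeric vector of length 3, or an n x 3 matrix, channels in
#'   \code{[0, 1]}.
#' @return A vector \code{c(h, s, l)} or an n x 3 matrix with columns
#'   \code{h}, \code{s}, \code{l}.
#' @examples
#' rgb_to_hsl(c(1, 0, 0))   # pure red: 0, 1, 0.5
#' @export
rgb_to_hsl <- function(rgb) {
  vec <- is.null(dim(rgb))
  m <- if (vec) matrix(rgb, ncol = 3) else as.matrix(rgb)
  if (ncol(m) != 3) stopf("rgb must have 3 channels")
  if (any(m < -1e-12) || any(m > 1 + 1e-12))
    stopf("rgb channels must lie in [0, 1]")
  m <- pmin(pmax(m, 0), 1)
  r <- m[, 1]; g <- m[, 2]; b <- m[, 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  l <- (mx + mn) / 2
  d <- mx - mn
  s <- ifelse(d == 0, 0, d / (1 - abs(2 * l - 1)))
  h <- numeric(length(r))
  i <- d > 0 & mx == r
  h[i] <- ((g[i] - b[i]) / d[i]) %% 6
  i <- d > 0 & mx == g & mx != r
  h[i] <- (b[i] - r[i]) / d[i] + 2
  i <- d > 0 & mx == b & mx != r & mx != g
  h[i] <- (r[i] - g[i]) / d[i] + 4
  h <- (h * 60) %% 360
  out <- cbind(h = h, s = s, l = l)
  if (vec) out[1, ] else out
}

#' Convert HSL to RGB
#'
#' Inverse of [rgb_to_hsl()]; used by the stimulus renderer.
#'
#' @param h hue in degrees, `s`, `l` in \code{[0, 1]}; vectors are recycled.
#' @param s,l saturation and lightness.
#' @return n x 3 matrix of RGB channels in \code{[0, 1]}.
#' @export
hsl_to_rgb <- function(h, s, l) {
  n <- max(length(h), length(s), length(l))
  h <- rep_len(h %% 360, n); s <- rep_len(s, n); l <- rep_len(l, n)
  c0 <- (1 - abs(2 * l - 1)) * s
  x <- c0 * (1 - abs((h / 60) %% 2 - 1))
  m <- l - c0 / 2
  sector <- floor(h / 60) %% 6
  r <- ifelse(sector == 0 | sector == 5, c0, ifelse(sector == 1 | sector == 4, x, 0))
  g <- ifelse(sector == 1 | sector == 2, c0, ifelse(sector == 0 | sector == 3, x, 0))
  b <- ifelse(sector == 3 | sector == 4, c0, ifelse(sector == 2 | sector == 5, x, 0))
  cbind(r = r + m, g = g + m, b = b + m)
}

#' Classify pixels into colour classes
#'
#' Applies the classification used for the face stimuli: pixels whose alpha is
#' below the opacity threshold are excluded; the remaining pixels pass through
#' the achromatic gates black (L < 0.20), white (L > 0.71), gray (S < 0.15),
#' in that order, and only then through the hue bins red
#' \code{[350, 360) U [0, 18)}, orange \code{[18, 45)}, yellow \code{[45, 75)}
#' and bluish \code{[170, 270)} (lower bound inclusive, upper exclusive).
#' Hues in no bin are "unclassified". Exactly one label is returned per pixel.
#'
#' @param h hue in degrees \code{[0, 360)}.
#' @param s,l saturation and lightness in \code{[0, 1]}.
#' @param alpha opacity in \code{[0, 1]} (default 1).
#' @param opacity_threshold pixels with alpha below this are "excluded".
#' @return character vector of labels among the colour classes or "excluded".
#' @examples
#' classify_pixels(c(10, 355, 200, 100), 0.6, 0.5)
#' @export
classify_pixels <- function(h, s, l, alpha = 1, opacity_threshold = 0.5) {
  n <- max(length(h), length(s), length(l), length(alpha))
  h <- rep_len(h, n); s <- rep_len(s, n); l <- rep_len(l, n)
  alpha <- rep_len(alpha, n)
  if (any(h < 0 | h >= 360)) stopf("hue must lie in [0, 360)")
  if (any(s < 0 | s > 1 | l < 0 | l > 1))
    stopf("saturation and lightness must lie in [0, 1]")
  out <- rep("unclassified", n)
  hue_red <- h >= 350 | h < 18
  out[hue_red] <- "red"
  out[h >= 18 & h < 45] <- "orange"
  out[h >= 45 & h < 75] <- "yellow"
  out[h >= 170 & h < 270] <- "bluish"
  out[s < 0.15] <- "gray"
  out[l > 0.71] <- "white"
  out[l < 0.20] <- "black"
  out[alpha < opacity_threshold] <- "excluded"
  out
}

#' Arcsine square-root transform of a proportion
#'
#' Variance-stabilising transform applied to colour-class fractions before
#' they enter linear models; strictly increasing from 0 to pi/2.
#'
#' @param p proportions in \code{[0, 1]}.
#' @return \code{asin(sqrt(p))} in radians.
#' @export
transform_fraction <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

## Coerce to an h x w x 4 RGBA array in [0,1] (png::readPNG layout).
as_stimulus_image <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
  if (length(dim(img)) != 3) stopf("image must be an array with channels")
  if (dim(img)[3] == 3)
    img <- array(c(img, rep(1, prod(dim(img)[1:2]))), c(dim(img)[1:2], 4))
  if (dim(img)[3] != 4) stopf("image must have 3 or 4 channels")
  img
}

#' Colour profile of a face stimulus
#'
#' Classifies every opaque pixel (see [classify_pixels()]) and returns the
#' per-class fractions, their arcsine-square-root transforms, the mean
#' lightness and saturation over opaque pixels, the Sobel pattern score and
#' the opaque pixel count. An optional exclusion mask removes pixels (e.g.
#' specific facial regions) from all statistics; fractions are renormalised
#' over the remaining pixels.
#'
#' @param image RGBA array (h x w x 4, channels in \code{[0, 1]}), as returned
#'   by [read_stimulus()] or [render_stimulus()].
#' @param mask optional logical matrix (h x w); `TRUE` pixels are excluded.
#' @param opacity_threshold alpha cutoff for opacity (default 0.5).
#' @param edge_threshold gradient threshold passed to [pattern_score()].
#' @return An object of class `color_profile`: list with `fractions`,
#'   `transformed_fractions`, `mean_lightness`, `mean_saturation`, `pattern`,
#'   `n_opaque`.
#' @export
color_profile <- function(image, mask = NULL, opacity_threshold = 0.5,
                          edge_threshold = 0.1) {
  img <- as_stimulus_image(image)
  h <- dim(img)[1]; w <- dim(img)[2]
  alpha <- img[, , 4]
  keep <- alpha >= opacity_threshold
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(alpha))) stopf("mask dimensions must match image")
    keep <- keep & !mask
  }
  n_opaque <- sum(keep)
  if (n_opaque == 0) stopf("empty image: no opaque unmasked pixels")
  rgb <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))[as.vector(keep), , drop = FALSE]
  hsl <- rgb_to_hsl(rgb)
  cls <- classify_pixels(hsl[, 1], hsl[, 2], hsl[, 3])
  counts <- table(factor(cls, levels = COLOR_CLASSES))
  fractions <- as.numeric(counts) / n_opaque
  names(fractions) <- COLOR_CLASSES
  structure(list(
    fractions = fractions,
    transformed_fractions = transform_fraction(fractions),
    mean_lightness = mean(hsl[, 3]),
    mean_saturation = mean(hsl[, 2]),
    pattern = pattern_score(img, threshold = edge_threshold, mask = mask,
                            opacity_threshold = opacity_threshold),
    n_opaque = n_opaque
  ), class = "color_profile")
}

#' @export
print.color_profile <- function(x, ...) {
  cat("Colour profile of a face stimulus (", x$n_opaque, " opaque pixels)\n", sep = "")
  print(round(x$fractions, 4))
  cat(sprintf("mean lightness %.3f, mean saturation %.3f, pattern %.3f\n",
              x$mean_lightness, x$mean_saturation, x$pattern))
  invisible(x)
}

#' Fur-pattern score from Sobel edge detection
#'
#' Computes the lightness gradient with the 3x3 Sobel operator (magnitude
#' normalised by 4, so a unit lightness step across an edge scores 1) and
#' returns the fraction of eligible pixels whose gradient magnitude exceeds
#' `threshold`. A pixel is eligible only if its whole 3x3 neighbourhood is
#' opaque (and unmasked), so the face outline against the transparent
#' background never counts as pattern. High values correspond to
#' high-frequency fur texture such as agouti coloration.
#'
#' Unlike the colour fractions, this score depends on pixel arrangement, not
#' just the pixel multiset: permuting pixels changes it.
#'
#' @inheritParams color_profile
#' @param threshold gradient cutoff on the \code{[0, 1]} lightness scale
#'   (default 0.1).
#' @return score in \code{[0, 1]} (0 when no pixel is eligible).
#' @export
pattern_score <- function(image, threshold = 0.1, mask = NULL,
                          opacity_threshold = 0.5) {
  img <- as_stimulus_image(image)
  h <- dim(img)[1]; w <- dim(img)[2]
  alpha <- img[, , 4]
  op <- alpha >= opacity_threshold
  if (!is.null(mask)) op <- op & !mask
  if (!any(op)) stopf("empty image: no opaque pixels")
  if (h < 3 || w < 3) return(0)
  mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
  mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
  L <- (mx + mn) / 2
  ri <- 2:(h - 1); ci <- 2:(w - 1)
  gx <- (L[ri - 1, ci + 1] + 2 * L[ri, ci + 1] + L[ri + 1, ci + 1]) -
        (L[ri - 1, ci - 1] + 2 * L[ri, ci - 1] + L[ri + 1, ci - 1])
  gy <- (L[ri + 1, ci - 1] + 2 * L[ri + 1, ci] + L[ri + 1, ci + 1]) -
        (L[ri - 1, ci - 1] + 2 * L[ri - 1, ci] + L[ri - 1, ci + 1])
  mag <- sqrt(gx^2 + gy^2) / 4
  ## eligibility: all 9 neighbours opaque
  elig <- op[ri, ci]
  for (dr in -1:1) for (dc in -1:1)
    elig <- elig & op[ri + dr, ci + dc]
  if (!any(elig)) return(0)
  mean(mag[elig] > threshold)
}

#' Read a stimulus image (PNG or TIFF) as an RGBA array
#'
#' @param path file path; format chosen by extension.
#' @return h x w x 4 array in \code{[0, 1]}.
#' @export
read_stimulus <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stopf("the 'tiff' package is required to read TIFF stimuli")
      tiff::readTIFF(path)
    },
    stopf("unsupported image format: %s", ext))
  as_stimulus_image(img)
}

#' Write a stimulus image as PNG with alpha channel
#'
#' @param image RGBA array.
#' @param path output file.
#' @export
write_stimulus <- function(image, path) {
  png::writePNG(as_stimulus_image(image), path)
  invisible(path)
}

#' Quantify a set of stimulus images
#'
#' Runs [color_profile()] over image files and returns one row per image with
#' all fractions, transforms, means and the pattern score.
#'
#' @param paths character vector of image files, or a directory containing
#'   PNG/TIFF stimuli.
#' @param mask_dir optional directory of single-channel mask images named like
#'   the stimuli; pixels with value > 0.5 are excluded.
#' @param edge_threshold passed to [pattern_score()].
#' @return data.frame keyed by `image_id` (file name without extension).
#' @export
quantify_images <- function(paths, mask_dir = NULL, edge_threshold = 0.1) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
  rows <- lapply(paths, function(p) {
    id <- tools::file_path_sans_ext(basename(p))
    mask <- NULL
    if (!is.null(mask_dir)) {
      mf <- list.files(mask_dir, pattern = paste0("^", id, "\\."), full.names = TRUE)
      if (length(mf)) {
        m <- read_stimulus(mf[1])
        mask <- m[, , 1] > 0.5
      }
    }
    pr <- color_profile(read_stimulus(p), mask = mask, edge_threshold = edge_threshold)
    data.frame(image_id = id, t(pr$fractions),
               t(stats::setNames(pr$transformed_fractions,
                                 paste0(COLOR_CLASSES, "_t"))),
               mean_lightness = pr$mean_lightness,
               mean_saturation = pr$mean_saturation,
               pattern = pr$pattern, n_opaque = pr$n_opaque,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
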