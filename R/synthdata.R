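## Synthetic study generator.
##
## Stands in for the photographic stimuli and the survey respondents: builds a
## species panel across the three morphological primate groups, renders flat
## elliptical face stimuli whose colour-class pixel counts are constructed
## exactly, digitises noisy landmarks from group templates, and simulates
## complete 1-7 Likert rating matrices from a linear latent model discretised
## through fixed cutpoints.

## ---- landmark templates ----------------------------------------------------

## Three group templates in pixel coordinates (origin top-left, y downward),
## chosen so that the derived traits are linearly separable between groups:
## catarrhines have a long nose and moderate eyes; platyrrhines a short face,
## short nose, long top hair; prosimians very large eyes, long side hair and
## beard. Differences are tens of pixels against a few pixels of digitising
## noise.
group_template <- function(group) {
  pts <- switch(group,
    catarrhine = c(
      A = c(150,  40), N = c(150,  15),
      B = c(255, 200), C = c( 45, 200), O1 = c(285, 200), O2 = c(15, 200),
      D = c(150, 370), P = c(150, 395),
      E1 = c(215, 150), E2 = c(175, 150), G2 = c(125, 150), G1 = c(85, 150),
      F = c(150, 150),
      H = c(172, 235), I = c(128, 235), J = c(150, 252),
      K = c(112, 300), L = c(150, 300), M = c(188, 300)),
    platyrrhine = c(
      A = c(150,  60), N = c(150,  15),
      B = c(230, 200), C = c( 70, 200), O1 = c(250, 200), O2 = c(50, 200),
      D = c(150, 350), P = c(150, 362),
      E1 = c(228, 150), E2 = c(168, 150), G2 = c(132, 150), G1 = c(72, 150),
      F = c(150, 150),
      H = c(166, 205), I = c(134, 205), J = c(150, 216),
      K = c(122, 285), L = c(150, 285), M = c(178, 285)),
    prosimian = c(
      A = c(150,  30), N = c(150,   8),
      B = c(250, 200), C = c( 50, 200), O1 = c(298, 200), O2 = c(2, 200),
      D = c(150, 385), P = c(150, 418),
      E1 = c(240, 140), E2 = c(170, 140), G2 = c(130, 140), G1 = c(60, 140),
      F = c(150, 140),
      H = c(168, 250), I = c(132, 250), J = c(150, 268),
      K = c(118, 310), L = c(150, 310), M = c(182, 310)),
    stopf("unknown group: %s", group))
  m <- matrix(pts, ncol = 2, byrow = TRUE)
  ## c(A = c(x, y), ...) names elements "A1","A2",...: strip the position digit
  rownames(m) <- sub("[0-9]$", "", names(pts)[seq(1, length(pts), by = 2)])
  colnames(m) <- c("x", "y")
  m[LANDMARK_NAMES, , drop = FALSE]
}

## Dirichlet-style colour-weight draw via normalised gammas.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  setNames(g / sum(g), names(alpha))
}

GROUP_COLOR_ALPHA <- list(
  catarrhine  = c(red = 8, orange = 3, yellow = 2, bluish = 0.6,
                  black = 4, white = 1, gray = 2, unclassified = 0.4),
  platyrrhine = c(red = 2, orange = 6, yellow = 8, bluish = 0.6,
                  black = 2, white = 1, gray = 2, unclassified = 0.4),
  prosimian   = c(red = 1, orange = 2, yellow = 2, bluish = 0.8,
                  black = 8, white = 3, gray = 5, unclassified = 0.4))

## ---- species panel ---------------------------------------------------------

#' Generate a synthetic species panel
#'
#' Draws species specifications for the three morphological primate groups.
#' Each species records its group, genus, latent beauty, true human-likeness
#' (1 = most human-like, 7 = least), Lovich-Gibbons dimorphism ratio, colour
#' weights over the eight colour classes, fur-pattern level, and a landmark
#' template (the group template plus species-level jitter and scale). All
#' generating parameters are returned, so downstream estimates can be checked
#' against truth.
#'
#' @param n_per_group species per group; a positive scalar, or a length-3
#'   vector named by group (catarrhine, platyrrhine, prosimian) for an
#'   unbalanced panel.
#' @param seed integer seed; the same seed reproduces the panel exactly.
#' @param species_template_sd pixel SD of species-level landmark jitter.
#' @param scale_range species-level uniform size-scaling range.
#' @return An object of class `species_panel`: a list of species specs.
#' @examples
#' panel <- generate_species_panel(2, seed = 1)
#' length(panel)  # 6
#' @export
generate_species_panel <- function(n_per_group, seed = 1,
                                   species_template_sd = 8,
                                   scale_range = c(0.85, 1.15)) {
  if (length(n_per_group) == 1) {
    n_per_group <- rep(n_per_group, 3)
    names(n_per_group) <- PRIMATE_GROUPS
  }
  if (is.null(names(n_per_group))) names(n_per_group) <- PRIMATE_GROUPS
  n_per_group <- n_per_group[PRIMATE_GROUPS]
  if (any(is.na(n_per_group)) || any(n_per_group < 2) ||
      any(n_per_group != round(n_per_group)))
    stopf("n_per_group must be integer(s) >= 2 for each of the three groups")
  hl_range <- list(catarrhine = c(1.5, 3.5), platyrrhine = c(3.0, 5.0),
                   prosimian = c(4.5, 6.5))
  lg_par <- list(catarrhine  = c(mean = -0.60, sd = 0.35, lo = -1.40, hi = 0.10),
                 platyrrhine = c(mean = -0.15, sd = 0.25, lo = -0.75, hi = 0.31),
                 prosimian   = c(mean =  0.00, sd = 0.12, lo = -0.30, hi = 0.30))
  pat_par <- list(catarrhine = c(2, 6), platyrrhine = c(2, 4), prosimian = c(5, 3))
  panel <- with_seed(seed, {
    out <- list()
    for (grp in PRIMATE_GROUPS) {
      ng <- n_per_group[[grp]]
      tmpl <- group_template(grp)
      for (i in seq_len(ng)) {
        id <- sprintf("%s_%02d", substr(grp, 1, 4), i)
        lg <- lg_par[[grp]]
        lg_val <- min(max(rnorm(1, lg["mean"], lg["sd"]), lg["lo"]), lg["hi"])
        ## species-level template: shared eye-line jitter keeps the eyes on a
        ## common horizontal line, then per-point jitter and size scale
        eye_dy <- rnorm(1, 0, species_template_sd)
        jit <- matrix(rnorm(38, 0, species_template_sd), ncol = 2)
        eye_pts <- c("E1", "E2", "G1", "G2", "F")
        jit[match(eye_pts, LANDMARK_NAMES), 2] <- eye_dy
        lm <- tmpl + jit
        sc <- runif(1, scale_range[1], scale_range[2])
        ctr <- colMeans(lm)
        lm <- sweep(sweep(lm, 2, ctr) * sc, 2, ctr, `+`)
        out[[id]] <- structure(list(
          species_id = id,
          genus_id = sprintf("%s_g%02d", substr(grp, 1, 4), ceiling(i / 2)),
          group = grp,
          latent_beauty = rnorm(1),
          human_likeness_true = runif(1, hl_range[[grp]][1], hl_range[[grp]][2]),
          lg_true = lg_val,
          color_weights = rdirichlet1(GROUP_COLOR_ALPHA[[grp]]),
          pattern_level = rbeta(1, pat_par[[grp]][1], pat_par[[grp]][2]),
          landmark_template = lm
        ), class = "species_spec")
      }
    }
    out
  })
  structure(panel, class = "species_panel",
            seed = seed, n_per_group = n_per_group)
}

#' @export
print.species_panel <- function(x, ...) {
  grp <- vapply(x, `[[`, "", "group")
  cat("Synthetic species panel:", length(x), "species\n")
  print(table(grp))
  invisible(x)
}

#' Species-level covariate table of a panel
#'
#' Flattens the generating parameters of a [generate_species_panel()] panel
#' into a data.frame: group, latent beauty, human-likeness, LG ratio, pattern
#' level, colour weights and their arcsine-square-root transforms (suffix
#' `_t`), plus treatment-coded group dummies (catarrhine reference).
#'
#' @param panel a `species_panel`.
#' @return data.frame with one row per species.
#' @export
spec_covariates <- function(panel) {
  rows <- lapply(panel, function(s) {
    cw <- s$color_weights
    data.frame(species_id = s$species_id, genus_id = s$genus_id,
               group = s$group, latent_beauty = s$latent_beauty,
               human_likeness = s$human_likeness_true, lg = s$lg_true,
               pattern = s$pattern_level, t(cw),
               t(setNames(transform_fraction(cw), paste0(names(cw), "_t"))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$group_platyrrhine <- as.numeric(out$group == "platyrrhine")
  out$group_prosimian <- as.numeric(out$group == "prosimian")
  rownames(out) <- NULL
  out
}

## ---- stimulus rendering ----------------------------------------------------

## Base HSL per colour class; every entry classifies back to its own class.
CLASS_HSL <- list(
  red          = c(h = 0,   s = 0.60, l = 0.50),
  orange       = c(h = 30,  s = 0.60, l = 0.50),
  yellow       = c(h = 60,  s = 0.60, l = 0.50),
  bluish       = c(h = 220, s = 0.60, l = 0.50),
  black        = c(h = 0,   s = 0.50, l = 0.10),
  white        = c(h = 0,   s = 0.50, l = 0.85),
  gray         = c(h = 0,   s = 0.05, l = 0.50),
  unclassified = c(h = 120, s = 0.60, l = 0.50))

## Lightness variants used for the pattern texture; both stay inside the
## class's own gates, so texture never changes class membership.
CLASS_L_VARIANTS <- list(
  red = c(0.35, 0.65), orange = c(0.35, 0.65), yellow = c(0.35, 0.65),
  bluish = c(0.35, 0.65), black = c(0.06, 0.16), white = c(0.78, 0.95),
  gray = c(0.35, 0.65), unclassified = c(0.35, 0.65))

#' Render a synthetic face stimulus
#'
#' Draws an opaque axis-aligned elliptical face on a fully transparent
#' background. Opaque pixels are partitioned into the eight colour classes as
#' contiguous angular sectors with *exact* integer pixel counts (largest-
#' remainder apportionment of the species' colour weights), so the fractions
#' recovered by [color_profile()] equal the returned truth map exactly. The
#' species' `pattern_level` sets the fraction of opaque pixels carrying a
#' high-spatial-frequency lightness alternation (a parity texture within each
#' class's own lightness gate), which drives the Sobel pattern score without
#' touching the class counts.
#'
#' @param spec a `species_spec` (or any list with `color_weights` and
#'   `pattern_level`).
#' @param width,height raster size in pixels (both >= 32).
#' @param seed integer seed for the texture placement.
#' @return list with `image` (h x w x 4 RGBA array) and `truth` (named exact
#'   colour-class fractions).
#' @export
render_stimulus <- function(spec, width = 120, height = 160, seed = 1) {
  if (width < 32 || height < 32) stopf("width and height must be >= 32")
  w8 <- spec$color_weights[COLOR_CLASSES]
  if (any(is.na(w8)) || any(w8 < 0) ||
      abs(sum(w8) - 1) > 1e-8)
    stopf("color_weights must cover all classes, be nonnegative and sum to 1")
  cx <- (width + 1) / 2; cy <- (height + 1) / 2
  a <- 0.42 * width; b <- 0.45 * height
  xs <- matrix(rep(seq_len(width), each = height), nrow = height)
  ys <- matrix(rep(seq_len(height), width), nrow = height)
  inside <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
  idx <- which(inside)
  n <- length(idx)
  ang <- atan2(ys[idx] - cy, xs[idx] - cx)
  rr <- (xs[idx] - cx)^2 + (ys[idx] - cy)^2
  ord <- order(ang, rr)
  counts <- largest_remainder(w8, n)
  cls <- rep(COLOR_CLASSES, counts)[order(ord)]  # map back to idx order
  base <- do.call(rbind, CLASS_HSL)[cls, , drop = FALSE]
  lvar <- do.call(rbind, CLASS_L_VARIANTS)[cls, , drop = FALSE]
  lvals <- base[, "l"]
  n_pat <- round(spec$pattern_level * n)
  if (n_pat > 0) {
    pat <- with_seed(seed, sample(n, n_pat))
    parity <- (xs[idx[pat]] + ys[idx[pat]]) %% 2 + 1
    lvals[pat] <- lvar[cbind(pat, parity)]
  }
  rgb <- hsl_to_rgb(base[, "h"], base[, "s"], lvals)
  img <- array(0, c(height, width, 4))
  img[, , 1] <- 1; img[, , 2] <- 1; img[, , 3] <- 1  # white, but transparent
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[idx] <- rgb[, ch]
    img[, , ch] <- plane
  }
  aplane <- img[, , 4]
  aplane[idx] <- 1
  img[, , 4] <- aplane
  truth <- counts / n
  names(truth) <- COLOR_CLASSES
  list(image = img, truth = truth, counts = setNames(as.integer(counts), COLOR_CLASSES))
}

## ---- landmark digitisation -------------------------------------------------

#' Sample noisy landmarks for a species
#'
#' Adds isotropic Gaussian digitising noise to the species' landmark template.
#' The vertical noise of the four eye corners (and the reference-cross centre,
#' which lies on the eye line) is shared, mirroring stimuli standardised so
#' the eyes intersect a common horizontal line.
#'
#' @param spec a `species_spec`.
#' @param noise_sd pixel SD of the digitising noise (>= 0).
#' @param seed integer seed.
#' @return 19 x 2 matrix of named landmark coordinates (origin top-left).
#' @export
sample_landmarks <- function(spec, noise_sd = 2, seed = 1) {
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  tmpl <- spec$landmark_template
  if (noise_sd == 0) return(tmpl)
  with_seed(seed, {
    noise <- matrix(rnorm(38, 0, noise_sd), ncol = 2)
    eye_pts <- match(c("E1", "E2", "G1", "G2", "F"), LANDMARK_NAMES)
    noise[eye_pts, 2] <- rnorm(1, 0, noise_sd)
    tmpl + noise
  })
}

## ---- rating simulation -----------------------------------------------------

## Attenuation of a correlation caused by discretising standard-normal
## latents through fixed cutpoints into integer category scores. For a
## bivariate normal pair with correlation r, the covariance of the two
## categorised scores is sum_{i,j} int_0^r phi2(c_i, c_j; t) dt (phi2 the
## bivariate normal density), so the observed correlation can be computed
## exactly and inverted numerically. To first order the attenuation factor
## is (sum(dnorm(cutpoints)) / sd(scores))^2, about 0.922 for 7
## equal-probability categories.
likert_observed_cor <- function(r, cutpoints, n_grid = 200) {
  if (r == 0) return(0)
  p <- diff(c(0, pnorm(cutpoints), 1))
  k <- seq_along(p)
  v_cat <- sum(p * (k - sum(k * p))^2)
  t <- seq(0, r, length.out = n_grid + 1)
  cv <- 0
  for (ci in cutpoints) for (cj in cutpoints) {
    f <- exp(-(ci^2 - 2 * t * ci * cj + cj^2) / (2 * (1 - t^2))) /
      (2 * pi * sqrt(1 - t^2))
    cv <- cv + (r / n_grid) * (sum(f) - (f[1] + f[n_grid + 1]) / 2)
  }
  cv / v_cat
}

## Latent correlation needed so the categorised scores show `target`.
likert_deattenuate <- function(target, cutpoints) {
  if (target <= 0) return(target)
  hi <- 1 - 1e-6
  if (likert_observed_cor(hi, cutpoints) < target)
    stopf("target_single_icc too high to reach after discretisation")
  uniroot(function(r) likert_observed_cor(r, cutpoints) - target,
          c(1e-9, hi), tol = 1e-8)$root
}

#' Simulate a complete Likert rating matrix
#'
#' Latent score of rater r for species s:
#' `lp(s) + b_r + offset(r, s) + e_rs`, with species signal
#' `lp(s) = sum_j weight_j * covariate_j(s)`, rater intercepts
#' `b_r ~ N(0, rater_sd^2)` and residual noise `e ~ N(0, resid_sd^2)`. The
#' latent is standardised by its total SD and discretised through fixed
#' cutpoints (default: equal probability under the standard normal) into
#' integers 1-7. Every rater scores every species.
#'
#' When `target_single_icc` is given, the species signal is rescaled so that
#' the *observed* single-measure consistency ICC of the discrete scores hits
#' the target: discretisation attenuates a latent correlation by a known
#' factor (about 0.922 for 7 equal-probability categories), so the latent
#' species variance is inflated accordingly. See the methods vignette.
#'
#' An optional gender effect adds `male_offset` to male raters' latents for
#' the species listed in `rater_model$male_pref_species` (negative offset =
#' preferred by men on a 1-is-best scale).
#'
#' @param covariates a `species_panel`, or a data.frame with `species_id` and
#'   numeric covariate columns.
#' @param n_raters number of raters (>= 2).
#' @param rater_sd SD of rater intercepts (consistency ICC ignores them).
#' @param species_signal named numeric vector: covariate -> weight.
#' @param likert_cutpoints 6 strictly increasing cutpoints on the
#'   standardised latent scale.
#' @param resid_sd residual SD (> 0 unless a degenerate matrix is wanted).
#' @param target_single_icc optional target for the observed single-measure
#'   consistency ICC; rescales the species signal.
#' @param rater_model list: `p_female`, `age_range`, `male_pref_species`,
#'   `male_offset`.
#' @param seed integer seed.
#' @return An object of class `rating_matrix`: `scores` (raters x stimuli
#'   integer matrix), `rater_meta` (gender, age), `stimulus_ids`.
#' @export
simulate_ratings <- function(covariates, n_raters, rater_sd = 0.3,
                             species_signal = c(latent_beauty = 0.5),
                             likert_cutpoints = qnorm((1:6) / 7),
                             resid_sd = 1, target_single_icc = NULL,
                             rater_model = list(), seed = 1) {
  if (inherits(covariates, "species_panel")) covariates <- spec_covariates(covariates)
  if (n_raters < 2) stopf("n_raters must be >= 2")
  if (any(diff(likert_cutpoints) <= 0))
    stopf("likert_cutpoints must be strictly increasing")
  rm0 <- list(p_female = 199 / 286, age_range = c(15, 69),
              male_pref_species = character(0), male_offset = 0)
  rater_model <- modifyList(rm0, rater_model)
  miss <- setdiff(names(species_signal), names(covariates))
  if (length(miss)) stopf("unknown covariates in species_signal: %s",
                          paste(miss, collapse = ", "))
  X <- as.matrix(covariates[, names(species_signal), drop = FALSE])
  lp <- drop(X %*% species_signal)
  n_s <- nrow(covariates)
  if (!is.null(target_single_icc)) {
    tau_lat <- likert_deattenuate(target_single_icc, likert_cutpoints)
    if (tau_lat >= 1) stopf("target_single_icc too high to reach after discretisation")
    v <- tau_lat / (1 - tau_lat) * resid_sd^2
    if (sd(lp) == 0) stopf("species signal is constant; cannot rescale to a positive ICC")
    lp <- (lp - mean(lp)) / sd(lp) * sqrt(v)
  }
  v_lp <- mean((lp - mean(lp))^2)
  tot_sd <- sqrt(v_lp + rater_sd^2 + resid_sd^2)
  if (tot_sd == 0) tot_sd <- 1
  ids <- covariates$species_id %||% paste0("sp", seq_len(n_s))
  with_seed(seed, {
    gender <- ifelse(runif(n_raters) < rater_model$p_female, "female", "male")
    age <- round(runif(n_raters, rater_model$age_range[1], rater_model$age_range[2]))
    b <- rnorm(n_raters, 0, rater_sd)
    latent <- outer(b, lp, `+`) +
      matrix(rnorm(n_raters * n_s, 0, resid_sd), n_raters, n_s)
    if (length(rater_model$male_pref_species) && rater_model$male_offset != 0) {
      cols <- match(rater_model$male_pref_species, ids)
      if (anyNA(cols)) stopf("male_pref_species not found in panel")
      latent[gender == "male", cols] <- latent[gender == "male", cols] +
        rater_model$male_offset
    }
    z <- latent / tot_sd
    scores <- matrix(findInterval(z, likert_cutpoints) + 1L, n_raters, n_s,
                     dimnames = list(paste0("rater", seq_len(n_raters)), ids))
    rating_matrix(scores,
                  rater_meta = data.frame(rater_id = rownames(scores),
                                          gender = gender, age = age,
                                          stringsAsFactors = FALSE))
  })
}

## ---- whole study -----------------------------------------------------------

#' Generate a full synthetic rating study
#'
#' Builds the complete bundle the analysis pipeline consumes: a species panel
#' (default 50 catarrhines, 24 platyrrhines, 33 prosimians = 107 species),
#' rendered stimuli, digitised landmarks, morphometric factor scores, and two
#' complete rating matrices - "beauty" (default 286 raters, observed
#' single-measure consistency ICC calibrated to ~0.18) and human-likeness
#' (default 60 raters, single ICC ~0.553). The beauty signal is a linear
#' combination of the inner-facial factor, human-likeness, LG ratio, bluish
#' tint, pattern, latent beauty and group offsets, with signs following the
#' raw 1-is-beautiful scale; all generating parameters are stored in `truth`.
#'
#' @param n_species length-3 named vector of species counts per group.
#' @param n_beauty_raters,n_humanlikeness_raters rater counts.
#' @param width,height stimulus raster size.
#' @param noise_sd landmark digitising noise (pixels).
#' @param beauty_icc,humanlikeness_icc target observed single-measure ICCs.
#' @param beauty_signal named weights of the beauty latent (before the ICC
#'   rescaling); `factor2_inner`/`factor1_outer` refer to morphometric factor
#'   scores computed from the sampled landmarks.
#' @param n_male_pref number of species given a male-preference offset.
#' @param male_offset latent offset added for male raters on those species.
#' @param render_images set `FALSE` to skip rendering (landmarks/ratings only).
#' @param seed master integer seed; all stage seeds derive from it.
#' @return An object of class `synthetic_study`: `panel`, `images`,
#'   `image_truth`, `landmarks`, `covariates` (with factor scores),
#'   `beauty_ratings`, `humanlikeness_ratings`, `truth`, `seed`.
#' @export
synth_study <- function(n_species = c(catarrhine = 50, platyrrhine = 24,
                                      prosimian = 33),
                        n_beauty_raters = 286, n_humanlikeness_raters = 60,
                        width = 120, height = 160, noise_sd = 2,
                        beauty_icc = 0.18, humanlikeness_icc = 0.553,
                        beauty_signal = c(factor2_inner = 0.35,
                                          human_likeness = 0.21,
                                          lg = -0.51, bluish_t = -1.6,
                                          pattern = 0.4, latent_beauty = 0.6,
                                          group_platyrrhine = 0.29,
                                          group_prosimian = -1.0),
                        n_male_pref = 5, male_offset = -1,
                        render_images = TRUE, seed = 1) {
  seeds <- derive_seeds(seed, 6)
  panel <- generate_species_panel(n_species, seed = seeds[1])
  ids <- names(panel)
  lm_seeds <- derive_seeds(seeds[2], length(ids))
  landmarks <- Map(function(s, sd1) sample_landmarks(s, noise_sd, sd1),
                   panel, lm_seeds)
  images <- NULL; image_truth <- NULL
  if (render_images) {
    im_seeds <- derive_seeds(seeds[3], length(ids))
    rend <- Map(function(s, sd1) render_stimulus(s, width, height, sd1),
                panel, im_seeds)
    images <- lapply(rend, `[[`, "image")
    image_truth <- lapply(rend, `[[`, "truth")
  }
  covs <- spec_covariates(panel)
  traits <- traits_table(landmarks)
  fac <- morpho_factors(traits, n_factors = 2)
  covs$factor1_outer <- fac$scores[, 1]
  covs$factor2_inner <- fac$scores[, 2]
  male_pref <- with_seed(seeds[4], sample(ids, min(n_male_pref, length(ids))))
  beauty <- simulate_ratings(covs, n_beauty_raters,
                             species_signal = beauty_signal,
                             target_single_icc = beauty_icc,
                             rater_model = list(male_pref_species = male_pref,
                                                male_offset = male_offset),
                             seed = seeds[5])
  humanlike <- simulate_ratings(covs, n_humanlikeness_raters,
                                species_signal = c(human_likeness = 1),
                                target_single_icc = humanlikeness_icc,
                                rater_model = list(p_female = 0.5),
                                seed = seeds[6])
  structure(list(
    panel = panel, images = images, image_truth = image_truth,
    landmarks = landmarks, covariates = covs, factor_model = fac,
    beauty_ratings = beauty, humanlikeness_ratings = humanlike,
    truth = list(beauty_signal = beauty_signal, beauty_icc = beauty_icc,
                 humanlikeness_icc = humanlikeness_icc,
                 male_pref_species = male_pref, male_offset = male_offset,
                 noise_sd = noise_sd, n_species = n_species),
    seed = seed
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic face-rating study (seed ", x$seed, ")\n", sep = "")
  cat("  species:", length(x$panel),
      "| beauty raters:", nrow(x$beauty_ratings$scores),
      "| human-likeness raters:", nrow(x$humanlikeness_ratings$scores), "\n")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Serialises the bundle as plain files: stimuli as PNG with alpha, landmarks
#' as TPS (`LM=19` records) and CSV, both rating matrices as CSV (rows =
#' raters, plus gender and age columns), the species covariate table as CSV
#' and the generating truth as JSON.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @param tps_height canvas height used for the TPS y-flip.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, tps_height = 540) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_dir <- file.path(dir, "images")
  if (!is.null(study$images)) {
    dir.create(img_dir, showWarnings = FALSE)
    for (id in names(study$images))
      write_stimulus(study$images[[id]], file.path(img_dir, paste0(id, ".png")))
  }
  write_landmarks_tps(study$landmarks, file.path(dir, "landmarks.tps"),
                      height = tps_height)
  write_landmarks_csv(study$landmarks, file.path(dir, "landmarks.csv"))
  write_ratings_csv(study$beauty_ratings, file.path(dir, "beauty_ratings.csv"))
  write_ratings_csv(study$humanlikeness_ratings,
                    file.path(dir, "humanlikeness_ratings.csv"))
  write.csv(study$covariates, file.path(dir, "species.csv"), row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
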