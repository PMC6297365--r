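test_that("species panels have the requested structure and are seed-deterministic", {
  panel <- generate_species_panel(2, seed = 1)
  expect_length(panel, 6)
  grp <- vapply(panel, `[[`, "", "group")
  expect_equal(unname(table(grp)[primface:::PRIMATE_GROUPS]), rep(2L, 3),
               ignore_attr = TRUE)
  expect_identical(panel, generate_species_panel(2, seed = 1))
  expect_false(identical(panel, generate_species_panel(2, seed = 2)))
  expect_error(generate_species_panel(0), "n_per_group")
  expect_error(generate_species_panel(-3), "n_per_group")
  ## invariants on every spec
  for (s in panel) {
    expect_equal(sum(s$color_weights), 1, tolerance = 1e-12)
    expect_true(all(s$color_weights >= 0))
    expect_true(s$lg_true >= -2 && s$lg_true <= 2)
    expect_true(s$human_likeness_true >= 1 && s$human_likeness_true <= 7)
    expect_true(s$pattern_level >= 0 && s$pattern_level <= 1)
  }
})

test_that("groups generated by the panel are separable by CVA with >= 95% leave-one-out accuracy", {
  panel <- generate_species_panel(36, seed = 7)
  lms <- lapply(seq_along(panel), function(i)
    sample_landmarks(panel[[i]], noise_sd = 2, seed = 100 + i))
  names(lms) <- names(panel)
  traits <- traits_table(lms)
  grp <- vapply(panel, `[[`, "", "group")
  loo <- cva_loo(traits, grp)
  expect_gte(loo$accuracy, 0.95)
})

test_that("rendered stimuli recover their colour composition exactly", {
  spec1 <- list(color_weights = setNames(c(0, 0, 0, 0, 1, 0, 0, 0),
                                         primface:::COLOR_CLASSES),
                pattern_level = 0)
  r1 <- render_stimulus(spec1, 48, 48, seed = 1)
  expect_equal(unname(r1$truth["black"]), 1)
  expect_equal(color_profile(r1$image)$fractions, r1$truth)
  spec2 <- list(color_weights = setNames(c(0.3, 0, 0.7, 0, 0, 0, 0, 0),
                                         primface:::COLOR_CLASSES),
                pattern_level = 0.5)
  r2 <- render_stimulus(spec2, 80, 100, seed = 2)
  expect_equal(color_profile(r2$image)$fractions, r2$truth)
  expect_equal(sum(r2$counts), color_profile(r2$image)$n_opaque)
  ## transparent background never contributes
  expect_equal(unname(r2$truth["red"] + r2$truth["yellow"]), 1)
  bad <- list(color_weights = setNames(rep(0.2, 8), primface:::COLOR_CLASSES),
              pattern_level = 0)
  expect_error(render_stimulus(bad, 48, 48), "sum to 1")
  expect_error(render_stimulus(spec1, 16, 48), ">= 32")
})

test_that("pattern level raises the Sobel pattern score", {
  w <- setNames(c(1, 0, 0, 0, 0, 0, 0, 0), primface:::COLOR_CLASSES)
  flat <- render_stimulus(list(color_weights = w, pattern_level = 0), 80, 80, seed = 1)
  tex <- render_stimulus(list(color_weights = w, pattern_level = 0.8), 80, 80, seed = 1)
  expect_gt(pattern_score(tex$image), pattern_score(flat$image))
  ## texture must not disturb the exact class counts
  expect_equal(color_profile(tex$image)$fractions, tex$truth)
})

test_that("sampled landmarks add calibrated noise and keep the eyes on one line", {
  panel <- generate_species_panel(2, seed = 5)
  s <- panel[[1]]
  expect_identical(sample_landmarks(s, 0, seed = 1), s$landmark_template)
  expect_identical(sample_landmarks(s, 2, seed = 9), sample_landmarks(s, 2, seed = 9))
  noise_sd <- 2
  reps <- vapply(1:100, function(i) sample_landmarks(s, noise_sd, seed = i)["A", "x"],
                 numeric(1))
  expect_gt(sd(reps), 1.5)
  expect_lt(sd(reps), 2.5)
  for (i in 1:20) {
    lm <- sample_landmarks(s, noise_sd, seed = 200 + i)
    eye_y <- lm[c("E1", "E2", "G1", "G2"), "y"]
    expect_lt(max(eye_y) - min(eye_y), 3 * noise_sd)
  }
})

test_that("rating simulation is deterministic, complete and seed-sensitive", {
  covs <- spec_covariates(generate_species_panel(3, seed = 2))
  a <- simulate_ratings(covs, 20, seed = 4)
  b <- simulate_ratings(covs, 20, seed = 4)
  expect_identical(a$scores, b$scores)
  c2 <- simulate_ratings(covs, 20, seed = 5)
  expect_gt(sum(a$scores != c2$scores), 0)
  expect_false(anyNA(a$scores))
  expect_true(all(a$scores %in% 1:7))
  expect_equal(dim(a$scores), c(20, 9))
  expect_error(simulate_ratings(covs, 20, likert_cutpoints = c(1, 1, 2, 3, 4, 5)),
               "increasing")
  expect_error(simulate_ratings(covs, 20, species_signal = c(nope = 1)), "unknown")
})

test_that("degenerate rating simulations behave as the latent model predicts", {
  covs <- spec_covariates(generate_species_panel(3, seed = 2))
  ## no rater effects, no residual noise: every rater identical, ICC = 1
  m <- simulate_ratings(covs, 10, rater_sd = 0, resid_sd = 0,
                        species_signal = c(latent_beauty = 1), seed = 1)
  expect_true(all(apply(m$scores, 2, function(x) length(unique(x)) == 1)))
  ic <- icc_consistency(m)
  expect_equal(ic$icc_single, 1)
  expect_equal(ic$icc_average, 1)
  ## equal species latents, noise > 0: ICC near zero
  covs0 <- covs
  covs0$latent_beauty <- 0
  big <- spec_covariates(generate_species_panel(34, seed = 3))
  big$latent_beauty <- 0
  m0 <- simulate_ratings(big, 100, species_signal = c(latent_beauty = 1), seed = 2)
  expect_lt(abs(icc_consistency(m0)$icc_single), 0.05)
})

test_that("the ICC calibration hits the study's agreement regime", {
  covs <- spec_covariates(generate_species_panel(c(catarrhine = 50,
                                                   platyrrhine = 24,
                                                   prosimian = 33), seed = 8))
  m <- simulate_ratings(covs, 286, species_signal = c(latent_beauty = 1),
                        target_single_icc = 0.18, seed = 3)
  ic <- icc_consistency(m)
  expect_equal(ic$icc_average, 0.985, tolerance = 0.005)
  expect_equal(ic$icc_average, spearman_brown(ic$icc_single, 286),
               tolerance = 1e-10)
})

test_that("species mean scores recover the generating signal weights within 2 SE", {
  ## n = 300 species. The expected mean score of a species with linear
  ## predictor lp is computable in closed form (probit steps over the
  ## cutpoints), so the regression of observed species means on the
  ## covariates must agree, coefficient by coefficient, with the same
  ## regression of the exact expectations.
  covs <- spec_covariates(generate_species_panel(100, seed = 12))
  w <- c(latent_beauty = 0.4, lg = -0.5, pattern = 0.6)
  rater_sd <- 0.3; resid_sd <- 1
  m <- simulate_ratings(covs, 300, rater_sd = rater_sd, resid_sd = resid_sd,
                        species_signal = w, seed = 13)
  lp <- drop(as.matrix(covs[, names(w)]) %*% w)
  tot_sd <- sqrt(mean((lp - mean(lp))^2) + rater_sd^2 + resid_sd^2)
  noise_sd <- sqrt(rater_sd^2 + resid_sd^2)
  cutp <- qnorm((1:6) / 7)
  mu <- 1 + vapply(lp, function(l)
    sum(1 - pnorm((cutp * tot_sd - l) / noise_sd)), numeric(1))
  est <- coef(summary(lm(colMeans(m$scores) ~ latent_beauty + lg + pattern,
                         data = covs)))
  oracle <- coef(lm(mu ~ latent_beauty + lg + pattern, data = covs))
  for (nm in names(w)) {
    expect_lt(abs(est[nm, "Estimate"] - oracle[nm]),
              2 * est[nm, "Std. Error"] + 1e-8)
  }
  ## and every generated weight shows through with its own sign
  for (nm in names(w))
    expect_equal(sign(est[nm, "Estimate"]), sign(w[[nm]]))
})

test_that("the gender screen flags the male-preferred species with high power", {
  hits <- 0; false_pos <- 0; n_rep <- 10
  for (i in seq_len(n_rep)) {
    st <- synth_study(n_species = c(catarrhine = 20, platyrrhine = 10,
                                    prosimian = 12),
                      n_beauty_raters = 286, n_humanlikeness_raters = 10,
                      render_images = FALSE, seed = 400 + i)
    gs <- gender_screen(st$beauty_ratings)
    flagged <- gs$stimulus_id[gs$significant]
    hits <- hits + length(intersect(flagged, st$truth$male_pref_species))
    false_pos <- false_pos + length(setdiff(flagged, st$truth$male_pref_species))
  }
  expect_gte(hits / (5 * n_rep), 0.8)           # per-species power
  expect_lte(false_pos / n_rep, 0.5)            # Bonferroni keeps false flags rare
})

test_that("a study bundle writes to plain files and reads back consistently", {
  st <- synth_study(n_species = c(catarrhine = 3, platyrrhine = 3, prosimian = 3),
                    n_beauty_raters = 12, n_humanlikeness_raters = 8,
                    width = 48, height = 48, seed = 6)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "landmarks.tps")))
  back <- read_ratings_csv(file.path(dir, "beauty_ratings.csv"))
  expect_equal(back$scores, st$beauty_ratings$scores, ignore_attr = TRUE)
  expect_equal(back$rater_meta$gender, st$beauty_ratings$rater_meta$gender)
  lms <- load_landmarks(file.path(dir, "landmarks.csv"))
  expect_equal(lms, st$landmarks, tolerance = 1e-12)
  img <- read_stimulus(file.path(dir, "images", paste0(names(st$panel)[1], ".png")))
  expect_equal(color_profile(img)$fractions, st$image_truth[[1]], tolerance = 1e-12)
})
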