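test_that("consistency ICC is 1 for identical raters and ignores rater offsets", {
  base <- sample(1:5, 12, replace = TRUE) + 1L
  m <- rating_matrix(rbind(base, base, base))
  ic <- icc_consistency(m)
  expect_equal(ic$icc_single, 1)
  expect_equal(ic$icc_average, 1)
  ## distinct per-rater constants: consistency unaffected
  m2 <- rating_matrix(rbind(base - 1L, base, base + 1L))
  ic2 <- icc_consistency(m2)
  expect_equal(ic2$icc_single, 1)
  expect_equal(ic2$icc_average, 1)
})

test_that("independent raters give near-zero single-measure ICC", {
  for (s in 1:20) {
    m <- random_rating_matrix(50, 100, seed = 500 + s)
    expect_lt(abs(icc_consistency(m)$icc_single), 0.05)
  }
})

test_that("a constant rating matrix has no defined ICC", {
  expect_error(icc_consistency(matrix(4L, 5, 6)), "undefined ICC")
})

test_that("Spearman-Brown has its closed-form identities", {
  expect_equal(spearman_brown(0.3, 1), 0.3)
  s <- runif(5, -0.1, 0.9)
  expect_equal(spearman_brown(s, 1), s)
  expect_error(spearman_brown(-0.5, 3), "denominator")
  expect_error(spearman_brown(0.2, 2.5), "positive integer")
})

test_that("scale inversion is an involution that reverses rank order and keeps ICC", {
  m <- random_rating_matrix(10, 8, seed = 42)
  inv <- invert_scale(m)
  expect_true(all(inv$scores == 8L - m$scores))
  expect_identical(invert_scale(inv)$scores, m$scores)
  expect_equal(rank(colMeans(inv$scores)), rank(-colMeans(m$scores)))
  expect_equal(icc_consistency(inv)$icc_single, icc_consistency(m)$icc_single,
               tolerance = 1e-12)
})

test_that("the Mann-Whitney screen matches wilcox.test and handles identical samples", {
  set.seed(51)
  x <- sample(1:7, 40, replace = TRUE)
  y <- sample(1:7, 60, replace = TRUE)
  ours <- primface:::mw_u_approx(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE, exact = FALSE))
  expect_equal(unname(ours["u"]), unname(ref$statistic))
  expect_equal(unname(ours["p"]), ref$p.value, tolerance = 1e-10)
  ## identical samples: central U, p ~ 1
  z <- rep(1:5, 4)
  res <- primface:::mw_u_approx(z, z)
  expect_equal(unname(res["u"]), length(z)^2 / 2)
  expect_gt(unname(res["p"]), 0.95)
})

test_that("the gender screen requires both genders and uses the Bonferroni threshold", {
  scores <- matrix(sample(1:7, 60, replace = TRUE), 6, 10)
  meta <- data.frame(rater_id = paste0("r", 1:6),
                     gender = c("male", "male", "male", "female", "female", "female"),
                     age = 20:25)
  m <- rating_matrix(scores, meta)
  out <- gender_screen(m, alpha = 0.05)
  expect_equal(nrow(out), 10)
  expect_equal(out$significant, out$p < 0.05 / 10)
  meta$gender <- "male"
  expect_error(gender_screen(rating_matrix(scores, meta)), "each gender")
})

test_that("single-response MANOVA reduces to the univariate ANOVA", {
  set.seed(52)
  d <- data.frame(g = rep(c("a", "b"), each = 15), x = rnorm(30))
  y <- rnorm(30) + (d$g == "b")
  out <- manova_wilks(matrix(y, ncol = 1), d, formula = ~ g + x)
  ref <- anova(lm(y ~ g + x, data = d))
  expect_equal(out$f, ref$`F value`[1:2], tolerance = 1e-9)
  expect_equal(out$p, ref$`Pr(>F)`[1:2], tolerance = 1e-9)
})

test_that("Wilks lambda is 1 when balanced group means are equal", {
  set.seed(57)
  block <- matrix(rnorm(12), 4, 3)
  y <- rbind(block, block)  # identical blocks, so group means are equal
  d <- data.frame(g = rep(c("a", "b"), each = 4))
  out <- manova_wilks(y, d, formula = ~ g)
  expect_equal(out$wilks, 1, tolerance = 1e-9)
})

test_that("MANOVA p-values are uniform under the null", {
  set.seed(53)
  ps <- replicate(300, {
    y <- matrix(rnorm(30 * 3), 30, 3)
    d <- data.frame(g = factor(rep(c("a", "b", "c"), each = 10)))
    manova_wilks(y, d, formula = ~ g)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("high-dimensional responses are PCA-reduced with a warning", {
  set.seed(54)
  y <- matrix(rnorm(20 * 40), 20, 40)
  d <- data.frame(g = rep(c("a", "b"), each = 10))
  expect_warning(out <- manova_wilks(y, d, formula = ~ g), "reduced by PCA")
  expect_lt(attr(out, "reduced_to"), 20)
})

test_that("nested variance components recover the generating variances", {
  ## balanced design near the study's regime: 30 groups x 4 genera x
  ## 3 species x 2 individuals; truth (0.07, 0.10, 0.24, 0.05)
  truth <- c(group = 0.07, genus = 0.10, species = 0.24, residual = 0.05)
  gen <- function(seed) {
    withr::with_seed(seed, {
      a <- 30; b <- 4; c3 <- 3; n <- 2
      grp <- rep(seq_len(a), each = b * c3 * n)
      gnu <- rep(seq_len(a * b), each = c3 * n)
      spp <- rep(seq_len(a * b * c3), each = n)
      y <- rnorm(a, 0, sqrt(truth["group"]))[grp] +
        rnorm(a * b, 0, sqrt(truth["genus"]))[gnu] +
        rnorm(a * b * c3, 0, sqrt(truth["species"]))[spp] +
        rnorm(a * b * c3 * n, 0, sqrt(truth["residual"]))
      data.frame(group = paste0("G", grp), genus = paste0("g", gnu),
                 species = paste0("s", spp), score = y)
    })
  }
  est <- rowMeans(vapply(1:8, function(s)
    nested_variance_components(gen(s))$estimates, numeric(4)))
  expect_true(all(abs(est - truth) / truth < 0.20))
})

test_that("degenerate nesting layouts are detected and residual-only data yields zeros above", {
  d <- data.frame(group = c("A", "A", "B", "B"), genus = c("g1", "g1", "g1", "g1"),
                  species = c("s1", "s2", "s3", "s4"), score = rnorm(4))
  expect_error(nested_variance_components(d), "nesting violation")
  set.seed(55)
  a <- 10; b <- 2; c3 <- 2; n <- 4
  grp <- rep(seq_len(a), each = b * c3 * n)
  gnu <- rep(seq_len(a * b), each = c3 * n)
  spp <- rep(seq_len(a * b * c3), each = n)
  d2 <- data.frame(group = paste0("G", grp), genus = paste0("g", gnu),
                   species = paste0("s", spp), score = rnorm(length(grp)))
  vc <- nested_variance_components(d2)
  expect_lt(sum(vc$estimates[c("group", "genus", "species")]), 0.2)
  ## variance scaling: doubling deviations quadruples every component
  d4 <- d2
  d4$score <- 2 * d2$score
  vc4 <- nested_variance_components(d4)
  expect_equal(vc4$mean_squares, 4 * vc$mean_squares, tolerance = 1e-9)
})

test_that("the Spearman screen reports perfect, inverse and degenerate correlations", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  out <- spearman_screen(x, data.frame(same = x, neg = -x, flat = rep(2, 8)))
  expect_equal(out$rho[1], 1)
  expect_equal(out$rho[2], -1)
  expect_true(is.na(out$rho[3]) && out$degenerate[3])
})

test_that("the Spearman screen holds its nominal size", {
  set.seed(56)
  rej <- mean(replicate(1000, {
    spearman_screen(rnorm(100), data.frame(y = rnorm(100)))$significant
  }))
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 1000)
  expect_gt(rej, ci[1])
  expect_lt(rej, ci[2])
})

test_that("ICC identity and recovery under simulated agreement regimes", {
  ## identity on arbitrary matrices is checked in the acceptance suite; here
  ## the recovery of a target single-measure ICC through discretisation
  covs <- spec_covariates(generate_species_panel(c(catarrhine = 50,
                                                   platyrrhine = 24,
                                                   prosimian = 33), seed = 9))
  for (tau in c(0.1, 0.2, 0.5)) {
    obs <- mean(vapply(1:4, function(i)
      icc_consistency(simulate_ratings(covs, 286,
                                       species_signal = c(latent_beauty = 1),
                                       target_single_icc = tau,
                                       seed = 700 + i))$icc_single, numeric(1)))
    expect_lt(abs(obs - tau), 0.03)
  }
})
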