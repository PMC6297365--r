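## Hand-constructed landmark set with easy distances.
toy_landmarks <- function() {
  m <- matrix(0, 19, 2, dimnames = list(primface:::LANDMARK_NAMES, c("x", "y")))
  m["A", ] <- c(50, 0);    m["D", ] <- c(50, 100)
  m["B", ] <- c(90, 50);   m["C", ] <- c(10, 50)
  m["E1", ] <- c(10, 40);  m["E2", ] <- c(20, 40)
  m["G1", ] <- c(60, 40);  m["G2", ] <- c(46, 40)
  m["F", ] <- c(50, 40)
  m["H", ] <- c(58, 60);   m["I", ] <- c(42, 60);  m["J", ] <- c(50, 66)
  m["K", ] <- c(35, 80);   m["L", ] <- c(50, 80);  m["M", ] <- c(65, 80)
  m["N", ] <- c(50, -10);  m["O1", ] <- c(95, 50); m["O2", ] <- c(5, 50)
  m["P", ] <- c(50, 110)
  m
}

test_that("traits equal hand-computed interlandmark distances", {
  tr <- derive_traits(toy_landmarks())
  expect_equal(unname(tr["face_height"]), 100)
  expect_equal(unname(tr["face_width"]), 80)
  expect_equal(unname(tr["eye_size"]), mean(c(10, 14)))  # E1E2 = 10, G1G2 = 14
  expect_equal(unname(tr["mouth_width"]), 30)
  expect_equal(unname(tr["top_hair"]), 10)
  expect_equal(unname(tr["beard"]), 10)
  expect_equal(unname(tr["interocular"]), 26)
  expect_equal(unname(tr["eyes_to_mouth"]), 40)
  expect_equal(unname(tr["chin"]), 20)
  expect_equal(unname(tr["side_hair"]), 5)
  expect_equal(unname(tr["nose_length"]), sqrt(8^2 + 20^2))   # F-I
  expect_equal(unname(tr["nose_width"]), sqrt(8^2 + 6^2))     # H-J
  expect_equal(unname(tr["philtrum"]), sqrt(8^2 + 20^2))      # I-L
  expect_true(all(tr >= 0))
})

test_that("the nose convention switch changes only the nose measurements", {
  m <- toy_landmarks()
  a <- derive_traits(m, nose_convention = "as_printed")
  g <- derive_traits(m, nose_convention = "geometric")
  expect_equal(unname(g["nose_length"]), 26)  # F-J vertical
  expect_equal(unname(g["nose_width"]), 16)   # H-I horizontal
  diff_names <- names(a)[a != g]
  expect_setequal(diff_names, c("nose_length", "nose_width"))
})

test_that("traits are invariant under rigid motion and equivariant under scaling", {
  m <- toy_landmarks()
  tr <- derive_traits(m)
  expect_equal(derive_traits(m + rep(c(5, 7), each = 19)), tr)
  rot <- rigid_rotate(m, 30, center = c(13, -4))
  rownames(rot) <- rownames(m)
  expect_equal(derive_traits(rot), tr, tolerance = 1e-9)
  expect_equal(derive_traits(m * 2.5), tr * 2.5, tolerance = 1e-12)
})

test_that("missing landmarks are reported by name", {
  m <- toy_landmarks()
  expect_error(derive_traits(m[rownames(m) != "G2", ]), "G2")
})

test_that("TPS and CSV encodings of the same configuration give identical traits", {
  panel <- generate_species_panel(2, seed = 4)
  lms <- lapply(panel, function(s) s$landmark_template)
  tps <- withr::local_tempfile(fileext = ".tps")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_landmarks_tps(lms, tps, height = 540)
  write_landmarks_csv(lms, csv)
  from_tps <- load_landmarks(tps, height = 540)
  from_csv <- load_landmarks(csv)
  expect_equal(names(from_tps), names(lms))
  ## TPS stores 6 decimal places, so traits agree to that precision
  expect_equal(traits_table(from_tps), traits_table(from_csv), tolerance = 1e-5)
  expect_equal(from_csv, lms, tolerance = 1e-12)  # CSV round trip
})

test_that("malformed landmark files are rejected with the offending record named", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=18", sprintf("%d %d", 1:18, 1:18), "ID=shortface"), f)
  expect_error(load_landmarks(f), "LM=18")
  expect_error(load_landmarks(f), "shortface")
  g <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(image_id = "x", point_name = primface:::LANDMARK_NAMES[1:18],
                   x = 1:18, y = 1:18)
  write.csv(df, g, row.names = FALSE)
  expect_error(load_landmarks(g), "18")
})

test_that("ML factor analysis recovers a two-factor block structure", {
  set.seed(31)
  n <- 500
  L_true <- matrix(0, 14, 2)
  L_true[1:7, 1] <- 0.8
  L_true[8:14, 2] <- 0.8
  scores <- matrix(rnorm(n * 2), n, 2)
  X <- scores %*% t(L_true) + matrix(rnorm(n * 14, 0, sqrt(1 - 0.64)), n, 14)
  colnames(X) <- primface:::TRAIT_NAMES
  fm <- fit_factors(X, 2)
  expect_gte(tucker_congruence(fm$loadings, L_true), 0.95)
  expect_true(all(fm$communalities >= 0 & fm$communalities <= 1))
  expect_true(all(fm$variance_explained > 0))
  expect_lte(sum(fm$variance_explained), 100)
  ## sign convention: dominant trait of each factor loads positively
  for (j in 1:2) expect_gt(fm$loadings[which.max(abs(fm$loadings[, j])), j], 0)
})

test_that("varimax rotation preserves total communality", {
  set.seed(32)
  X <- matrix(rnorm(200 * 6), 200, 6) %*% matrix(runif(36, -1, 1), 6, 6)
  colnames(X) <- paste0("t", 1:6)
  fm <- suppressWarnings(fit_factors(X, 2))
  un <- factanal(scale(X), 2, rotation = "none", control = list(lower = 1e-3))
  expect_equal(sum(fm$loadings^2), sum(unclass(un$loadings)^2), tolerance = 1e-6)
})

test_that("no factor dominates on uncorrelated noise", {
  set.seed(33)
  max_ve <- replicate(50, {
    X <- matrix(rnorm(60 * 14), 60, 14)
    colnames(X) <- primface:::TRAIT_NAMES
    fm <- suppressWarnings(fit_factors(X, 2))
    max(fm$variance_explained) / 100
  })
  ## each factor should hover near 1/14 of the variance
  expect_lt(mean(max_ve), 1 / 14 + 3 * sd(max_ve))
})

test_that("CVA finds the separating direction and matches the generalized eigen oracle", {
  ## enough items that the sampling noise of W stays well below the 5-degree
  ## tolerance on the recovered axis
  set.seed(34)
  n1 <- 300
  x <- rbind(matrix(rnorm(2 * n1), n1, 2),
             sweep(matrix(rnorm(2 * n1), n1, 2), 2, c(10, 0), `+`))
  g <- rep(c("a", "b"), each = n1)
  fit <- cva(x, g)
  ax <- fit$axes[, 1] / sqrt(sum(fit$axes[, 1]^2))
  angle <- acos(abs(sum(ax * c(1, 0)))) * 180 / pi
  expect_lt(angle, 5)
  expect_gte(fit$accuracy, 0.99)
  ## eigen oracle on a 3-group, 6-trait instance: whitening route
  y <- matrix(rnorm(90 * 6), 90, 6)
  gy <- rep(letters[1:3], each = 30)
  y[gy == "b", 1] <- y[gy == "b", 1] + 2
  y[gy == "c", 3] <- y[gy == "c", 3] + 3
  f2 <- cva(y, gy)
  means <- rowsum(y, gy) / 30
  B <- crossprod(sweep(means, 2, colMeans(y)) * sqrt(30)) / 2
  Ri <- solve(chol(f2$W))
  ev <- eigen(t(Ri) %*% B %*% Ri, symmetric = TRUE)$values[1:2]
  expect_equal(f2$eigenvalues, ev, tolerance = 1e-8)
})

test_that("CVA eigenvalues vanish when group labels are uninformative", {
  set.seed(35)
  x <- matrix(rnorm(60 * 4), 60, 4)
  g <- rep(c("a", "b", "c"), each = 20)
  obs <- cva(x, g)$eigenvalues[1]
  null_first <- replicate(99, cva(x, sample(g))$eigenvalues[1])
  expect_lt(obs, quantile(null_first, 0.95))
})

test_that("CVA input validation and the ridge path work", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(cva(x, rep("a", 10)), "2 groups")
  expect_error(cva(x, c("a", rep("b", 9))), "2 items")
  ## singular W: duplicated column
  xs <- cbind(x[, 1], x[, 1])
  expect_error(cva(xs, rep(c("a", "b"), 5)), "ridge")
  fit <- cva(xs, rep(c("a", "b"), 5), ridge = 1e-8)
  expect_true(all(is.finite(fit$eigenvalues)))
})

test_that("PCA behaves as an orthogonal decomposition", {
  set.seed(36)
  z <- rnorm(30)
  coll <- cbind(z, 3 * z + 1)
  p1 <- pca(coll, scale. = FALSE)
  expect_equal(p1$variance_fraction[1], 1, tolerance = 1e-9)
  x <- matrix(rnorm(40 * 5), 40, 5)
  p2 <- pca(x)
  expect_equal(sum(p2$variance_fraction), 1, tolerance = 1e-12)
  recon <- p2$scores %*% t(p2$loadings)
  expect_equal(recon, scale(x), tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(pca(matrix(1, 10, 3)), "degenerate")
})
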