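test_that("analytic eigenstructure: duplicated marker plus an orthogonal one", {
  set.seed(1)
  x <- rnorm(60)
  y <- residuals(lm(rnorm(60) ~ x))      # exactly uncorrelated in-sample
  sm <- as_sm(cbind(a = x, b = x, c = y))
  m <- fit_axes(sm)
  expect_equal(m$eigenvalues, c(2, 1, 0), tolerance = 1e-8)
  expect_equal(m$var_fraction[1], 2 / 3, tolerance = 1e-8)
})

test_that("fit_axes matches the explicit correlation eigendecomposition oracle", {
  set.seed(7)
  for (i in 1:5) {
    p <- sample(3:8, 1); n <- sample(50:300, 1)
    X <- matrix(rnorm(n * p), n, p) %*% matrix(rnorm(p * p), p, p)
    m <- fit_axes(as_sm(X))
    eo <- eigen(cor(X), symmetric = TRUE)
    expect_equal(m$eigenvalues, eo$values, tolerance = 1e-8)
    for (k in seq_len(p)) {
      d <- min(max(abs(m$loadings[, k] - eo$vectors[, k])),
               max(abs(m$loadings[, k] + eo$vectors[, k])))
      expect_lt(d, 1e-8)
    }
    expect_equal(sum(m$var_fraction), 1, tolerance = 1e-10)
    # orthonormality
    G <- crossprod(m$loadings)
    expect_lt(max(abs(G - diag(p))), 1e-10)
  }
})

test_that("fit_axes rejects degenerate input by marker name", {
  X <- cbind(a = rnorm(20), b = rep(1, 20))
  expect_error(fit_axes(as_sm(X)), "b")
  expect_error(fit_axes(as_sm(matrix(rnorm(4), 2, 2))), "3 rows")
  X2 <- cbind(a = rnorm(20), b = rnorm(20)); X2[3, 1] <- NA
  expect_error(fit_axes(as_sm(X2)), "missing")
})

test_that("projection identities: self-projection, linearity, score variance", {
  set.seed(11)
  X <- matrix(rnorm(200 * 5), 200, 5)
  sm <- as_sm(X)
  m <- fit_axes(sm)
  s1 <- project(m, sm, 1L)
  s1b <- project(m, sm, 1L)
  expect_identical(s1$score, s1b$score)                 # exact reproducibility
  expect_equal(var(s1$score), m$eigenvalues[1], tolerance = 1e-8)
  flipped <- m; flipped$loadings[, 1] <- -flipped$loadings[, 1]
  expect_equal(project(flipped, sm, 1L)$score, -s1$score, tolerance = 1e-14)
  # marker-name mismatch reports the symmetric difference
  sm2 <- as_sm(X[, 1:4])
  expect_error(project(m, sm2, 1L), "m05")
})

test_that("orient_axis flips with age, is idempotent, and falls back to the sign rule", {
  set.seed(12)
  age <- runif(300, 60, 90)
  X <- cbind(a = -age + rnorm(300, 0, 8), b = -age + rnorm(300, 0, 8),
             c = rnorm(300))
  sm <- as_sm(X, ages = age)
  m <- fit_axes(sm)
  s <- project(m, sm, 1L)
  r0 <- cor(s$score, age)
  m2 <- orient_axis(m, s, age)
  s2 <- project(m2, sm, 1L)
  expect_gte(cor(s2$score, age), abs(r0) - 1e-12)
  m3 <- orient_axis(m2, s2, age)
  expect_identical(m3$loadings, m2$loadings)            # idempotent
  # age-free fallback: top |loading| marker becomes positive
  m4 <- m2; m4$loadings[, 1] <- -m4$loadings[, 1]
  m5 <- orient_axis(m4)
  top <- which.max(abs(m5$loadings[, 1]))
  expect_gt(m5$loadings[top, 1], 0)
})

test_that("importance weights are |loading|-normalized, ordered, and sum to 1", {
  set.seed(13)
  m <- fit_axes(as_sm(matrix(rnorm(100 * 4), 100, 4)))
  # hand-arithmetic oracle on a constructed loading vector
  m$loadings[, 1] <- c(0.8, 0.6, 0, 0)
  w <- importance(m, 1L)
  expect_equal(as.numeric(w[c("m01", "m02")]), c(0.8, 0.6) / 1.4, tolerance = 1e-12)
  expect_equal(as.numeric(w["m03"]), 0)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(diff(as.numeric(w)) <= 0))
  # equal-magnitude loadings: every weight 1/p
  m$loadings[, 1] <- c(0.5, -0.5, 0.5, -0.5)
  expect_equal(as.numeric(importance(m, 1L)), rep(0.25, 4), tolerance = 1e-12)
  expect_error(importance(m, 9L), "axis")
})

test_that("scale invariance: native rescaling of a marker leaves axes unchanged", {
  gp <- generate_panel(small_config(n_subjects = 300, p = 5, seed = 14))
  mk <- sprintf("m%02d", 1:5)
  sm1 <- standardize(gp$panel, fit_transform_spec(gp$panel, markers = mk))
  pan2 <- gp$panel; pan2$m02 <- pan2$m02 * 37
  sm2 <- standardize(pan2, fit_transform_spec(pan2, markers = mk))
  m1 <- fit_axes(sm1); m2 <- fit_axes(sm2)
  expect_equal(m1$loadings, m2$loadings, tolerance = 1e-8)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-8)
})

test_that("anemia subaxis summarizes the red-cell cluster", {
  set.seed(15)
  # single marker: scores equal the (re-centered) marker up to sign
  X <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "hemoglobin"))
  sm <- as_sm(X)
  s <- anemia_subaxis(sm, markers = "hemoglobin")
  z <- (X[, 1] - mean(X[, 1])) / sd(X[, 1])
  expect_true(min(max(abs(s$score - z)), max(abs(s$score + z))) < 1e-10)
  # two perfectly correlated markers: score proportional to their mean
  X2 <- cbind(hemoglobin = z, hematocrit = z)
  s2 <- anemia_subaxis(as_sm(X2), markers = c("hemoglobin", "hematocrit"))
  expect_gt(abs(cor(s2$score, (z + z) / 2)), 1 - 1e-10)
  expect_error(anemia_subaxis(sm, markers = character()), "empty")
})

test_that("anemia subaxis recovers F1 on the default synthetic config", {
  fx <- shared_fixture()
  s <- anemia_subaxis(fx$sm)
  keep <- complete.cases(fx$sm$values[, intersect(anemia_markers(), fx$sm$markers)])
  expect_gte(abs(cor(s$score, fx$truth$F1[keep])), 0.8)
})

test_that("reduce_axis: no elimination gives r = 1; orthogonal zero-loading marker is free", {
  set.seed(16)
  f <- rnorm(300)
  X <- sapply(1:4, function(i) 0.8 * f + rnorm(300, 0, 0.6))
  w <- residuals(lm(rnorm(300) ~ X))     # exactly orthogonal to the block
  Xw <- cbind(X, w)
  colnames(Xw) <- sprintf("m%02d", 1:5)
  sm <- as_sm(Xw)
  m <- fit_axes(sm)
  full <- reduce_axis(m, sm, target_size = 5L)
  expect_equal(full$r, 1, tolerance = 1e-12)
  red <- reduce_axis(m, sm, target_size = 4L)
  expect_equal(red$path, "m05")          # the orthogonal marker goes first
  expect_equal(red$r, 1, tolerance = 1e-10)
  expect_error(reduce_axis(m, sm, required = c("m01"), forbidden = c("m01")), "overlap")
  expect_error(reduce_axis(m, sm, required = sprintf("m%02d", 1:3), target_size = 2L), "target")
})

test_that("clinical scoring equals projection and demands all reference markers", {
  fx <- shared_fixture()
  ref <- clinical_reference(fx$panel)
  # all measurements at stored centers -> score 0 (identity-family inversion)
  tab <- ref$spec$table
  centers <- setNames(numeric(length(ref$markers)), ref$markers)
  for (mk in ref$markers) {
    row <- tab[tab$marker == mk, ][1, ]
    centers[mk] <- switch(row$family,
      identity = row$center,
      log = exp(row$center) - row$shift,
      sqrt = row$center^2 - row$shift)
  }
  s0 <- clinical_score(centers, ref)
  expect_lt(abs(s0), 1e-8)
  # one marker at center + 1 SD on the transformed scale: score = its loading
  mk1 <- ref$markers[1]
  row <- tab[tab$marker == mk1, ][1, ]
  plus1 <- centers
  plus1[mk1] <- switch(row$family,
    identity = row$center + row$scale,
    log = exp(row$center + row$scale) - row$shift,
    sqrt = (row$center + row$scale)^2 - row$shift)
  s1 <- clinical_score(plus1, ref)
  expect_equal(s1, unname(ref$model$loadings[mk1, 1]), tolerance = 1e-6)
  # batch of 3 equals stacking and projecting
  batch <- as.data.frame(rbind(centers, plus1, centers))
  expect_equal(clinical_score(batch, ref),
               c(clinical_score(centers, ref), clinical_score(plus1, ref),
                 clinical_score(centers, ref)),
               tolerance = 1e-12)
  # missing markers are reported by name, no partial scores
  expect_error(clinical_score(centers[-(1:2)], ref), ref$markers[1])
  nav <- centers; nav[3] <- NA
  expect_error(clinical_score(nav, ref), ref$markers[3])
})
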