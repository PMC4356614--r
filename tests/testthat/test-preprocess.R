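test_that("choose_transform minimizes absolute skewness among the candidates", {
  # symmetric, evenly spaced values: already skewless, identity wins
  expect_equal(choose_transform(seq(1, 50))$family, "identity")

  skew_of <- function(x) {  # direct-formula oracle
    m <- mean(x); m2 <- mean((x - m)^2)
    mean((x - m)^3) / m2^1.5
  }
  set.seed(42)
  x <- exp(rnorm(2000))
  cand <- c(identity = abs(skew_of(x)), sqrt = abs(skew_of(sqrt(x))),
            log = abs(skew_of(log(x))))
  expect_equal(names(which.min(cand)), "log")
  expect_equal(choose_transform(x)$family, "log")

  y <- rnorm(2000)^2                      # sqrt restores near-normal magnitude
  expect_lt(abs(skew_of(sqrt(y))), abs(skew_of(y)))
  expect_true(choose_transform(y)$family %in% c("sqrt", "log"))
  expect_false(choose_transform(y)$family == "identity")
})

test_that("choose_transform guards degenerate input and non-positive values", {
  expect_error(choose_transform(rep(5, 50)), "constant")
  expect_error(choose_transform(c(1, 2, 3)), "at least 10")
  # negative minimum: shift must make values strictly positive before log
  set.seed(1)
  x <- exp(rnorm(500)) - 2
  tr <- choose_transform(x)
  if (tr$family != "identity") expect_true(all(x + tr$shift > 0))
})

test_that("standardization round-trips to mean 0 / SD 1 per cohort and marker", {
  gp <- generate_panel(small_config(n_subjects = 200, p = 4, seed = 8))
  pan <- gp$panel
  pan2 <- pan; pan2$cohort <- "c2"; pan2$m01 <- pan2$m01 * 100  # different native scale
  both <- rbind(pan, pan2)
  spec <- fit_transform_spec(both, markers = sprintf("m%02d", 1:4))
  sm <- standardize(both, spec)
  for (co in c("c1", "c2")) {
    sel <- sm$meta$cohort == co
    expect_lt(max(abs(colMeans(sm$values[sel, ]))), 1e-10)
    expect_lt(max(abs(apply(sm$values[sel, ], 2, sd) - 1)), 1e-10)
  }
  # per-cohort contract: distinct centers for the rescaled marker
  tab <- spec$table
  c1 <- tab$center[tab$cohort == "c1" & tab$marker == "m01"]
  c2 <- tab$center[tab$cohort == "c2" & tab$marker == "m01"]
  expect_false(isTRUE(all.equal(c1, c2)))
})

test_that("sex-stratified markers are centered within each sex", {
  gp <- generate_panel(small_config(n_subjects = 400, p = 3, seed = 9))
  pan <- gp$panel
  pan$m03 <- pan$m03 + ifelse(pan$sex == "female", 5, 0)   # estradiol-like offset
  spec <- fit_transform_spec(pan, markers = c("m01", "m02", "m03"),
                             sex_stratified = "m03")
  sm <- standardize(pan, spec)
  for (sx in c("female", "male")) {
    z <- sm$values[sm$meta$sex == sx, "m03"]
    expect_lt(abs(mean(z)), 1e-10)
    expect_lt(abs(sd(z) - 1), 1e-10)
  }
  # marker with identical distribution in both sexes: near-equal strata params
  spec2 <- fit_transform_spec(pan, markers = c("m01"), sex_stratified = "m01")
  t2 <- spec2$table
  expect_lt(abs(diff(t2$center)), 0.2)
  expect_lt(abs(diff(t2$scale)), 0.2)
})

test_that("stored specs reproduce hand-computed standardization on new data", {
  gp <- generate_panel(small_config(n_subjects = 100, p = 2, seed = 10))
  spec <- fit_transform_spec(gp$panel, markers = c("m01", "m02"))
  new_pan <- gp$panel[1:3, ]
  new_pan$m01 <- c(8.5, 10.2, 12.9)
  sm <- standardize(new_pan, spec)
  row <- spec$table[spec$table$marker == "m01", ]
  f <- function(x) switch(row$family, identity = x, log = log(x + row$shift),
                          sqrt = sqrt(x + row$shift))
  expect_equal(sm$values[, "m01"], (f(new_pan$m01) - row$center) / row$scale,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("standardize errors on markers absent or out of transform domain", {
  gp <- generate_panel(small_config(n_subjects = 100, p = 2, seed = 12))
  expect_error(fit_transform_spec(gp$panel, markers = c("m01", "nope")), "nope")
  spec <- fit_transform_spec(gp$panel, markers = c("m01", "m02"))
  spec$table$family[spec$table$marker == "m01"] <- "log"
  spec$table$shift[spec$table$marker == "m01"] <- 0
  bad <- gp$panel[1:2, ]; bad$m01 <- c(-5, 1)
  expect_error(standardize(bad, spec), "m01")
})

test_that("standardizing already-standardized data with a refit spec is idempotent", {
  gp <- generate_panel(small_config(n_subjects = 300, p = 4, seed = 13))
  spec <- fit_transform_spec(gp$panel, markers = sprintf("m%02d", 1:4))
  sm <- standardize(gp$panel, spec)
  pan2 <- cbind(sm$meta, as.data.frame(sm$values))
  spec2 <- fit_transform_spec(pan2, markers = sprintf("m%02d", 1:4))
  sm2 <- standardize(pan2, spec2)
  expect_lt(max(abs(sm2$values - sm$values)), 1e-10)
})

test_that("row permutation permutes but does not change transformed values", {
  gp <- generate_panel(small_config(n_subjects = 150, p = 3, seed = 14))
  spec <- fit_transform_spec(gp$panel, markers = sprintf("m%02d", 1:3))
  sm <- standardize(gp$panel, spec)
  set.seed(2); perm <- sample(nrow(gp$panel))
  sm_p <- standardize(gp$panel[perm, ], spec)
  expect_equal(sm_p$values, sm$values[perm, ], tolerance = 1e-14)
})

test_that("complete_cases matches a brute-force row scan and reports counts", {
  gp <- generate_panel(small_config(n_subjects = 400, p = 4, visits = 2L,
                                    missingness = 0.1, seed = 15))
  spec <- fit_transform_spec(gp$panel, markers = sprintf("m%02d", 1:4))
  sm <- standardize(gp$panel, spec)
  cc <- complete_cases(sm)
  brute <- sum(apply(gp$panel[, sprintf("m%02d", 1:4)], 1,
                     function(r) all(!is.na(r))))
  expect_equal(nrow(cc$matrix$values), brute)
  expect_equal(sum(cc$counts$visits), brute)
  expect_false(anyNA(cc$matrix$values))
  # no missing data: identity
  gp2 <- generate_panel(small_config(n_subjects = 50, p = 3, seed = 16))
  sm2 <- standardize(gp2$panel, fit_transform_spec(gp2$panel, markers = sprintf("m%02d", 1:3)))
  cc2 <- complete_cases(sm2)
  expect_equal(cc2$matrix$values, sm2$values)
  # empty result is an explicit error
  pan3 <- gp2$panel; pan3$m01 <- NA_real_
  sm3 <- standardize(pan3, fit_transform_spec(gp2$panel, markers = sprintf("m%02d", 1:3)))
  expect_error(complete_cases(sm3), "complete")
})

test_that("small rows retained count example: 5 rows with 1 missing keeps 4", {
  X <- matrix(rnorm(10), 5, 2)
  X[3, 2] <- NA
  expect_equal(nrow(complete_cases(as_sm(X))$matrix$values), 4L)
})
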