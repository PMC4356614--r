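test_that("demographic subsets partition rows; ages band at <65, 65-80, 80+", {
  meta <- data.frame(cohort = "c1", subject = sprintf("s%02d", 1:6),
                     sex = rep(c("female", "male"), 3),
                     age = c(50, 70, 90, 64.9, 65, 80))
  sch <- demographic_subsets(meta, "sex")
  expect_setequal(names(sch$sizes), c("female", "male"))
  expect_equal(sum(sch$sizes), 6)
  sch_age <- demographic_subsets(meta[1:3, ], "age")
  expect_setequal(names(sch_age$sizes), c("<65", "65-80", "80+"))
  expect_true(all(sch_age$sizes == 1))
  # band edges: 64.9 -> <65, 65 -> 65-80, 80 -> 80+
  sch2 <- demographic_subsets(meta, "age")
  expect_equal(sch2$labels[4:6], c("<65", "65-80", "80+"))
  expect_error(demographic_subsets(meta, "village"), "village")
})

test_that("random exclusive subsets are balanced, exhaustive, and seed-stable", {
  sch <- random_exclusive_subsets(3200, 10, seed = 4)
  expect_equal(unname(sch$sizes), rep(320L, 10))
  sch2 <- random_exclusive_subsets(10, 3, seed = 4)
  expect_equal(sort(unname(sch2$sizes), decreasing = TRUE), c(4L, 3L, 3L))
  expect_identical(random_exclusive_subsets(100, 7, seed = 9)$labels,
                   random_exclusive_subsets(100, 7, seed = 9)$labels)
  expect_error(random_exclusive_subsets(5, 6), "exceeds")
  expect_error(random_exclusive_subsets(5, 1), ">= 2")
  # partition law over assorted (n, k)
  for (i in 1:10) {
    n <- sample(20:200, 1); k <- sample(2:8, 1)
    s <- random_exclusive_subsets(n, k, seed = i)
    expect_equal(length(s$labels), n)
    expect_equal(sort(unique(s$labels)), sort(names(s$sizes)))
    expect_equal(unname(table(s$labels)[names(s$sizes)]), unname(s$sizes),
                 ignore_attr = TRUE)
    expect_lte(diff(range(s$sizes)), 1)
  }
})

test_that("replicate_axes reproduces the global axis from a whole-data subset", {
  set.seed(21)
  X <- matrix(rnorm(300 * 5), 300, 5)
  sm <- as_sm(X, ages = runif(300, 60, 90))
  sch <- structure(list(name = "one", labels = rep("all", 300),
                        sizes = c(all = 300L), kind = "demographic",
                        seed = NA_integer_, warnings = character()),
                   class = "subset_scheme")
  ra <- replicate_axes(sm, sch)
  glob <- principal_axis(sm)
  expect_lt(max(abs(ra$scores$all$score - glob$scores$score)), 1e-10)
})

test_that("identical half-copies give pairwise r = 1; tiny subsets are skipped", {
  set.seed(22)
  X <- matrix(rnorm(150 * 4), 150, 4)
  XX <- rbind(X, X)
  sm <- as_sm(XX, ages = rep(runif(150, 60, 90), 2))
  sch <- structure(list(name = "halves", labels = rep(c("h1", "h2"), each = 150),
                        sizes = c(h1 = 150L, h2 = 150L), kind = "demographic",
                        seed = NA_integer_, warnings = character()),
                   class = "subset_scheme")
  ra <- replicate_axes(sm, sch)
  rp <- pairwise_axis_correlations(ra$scores)
  expect_equal(unname(rp$matrix["h1", "h2"]), 1, tolerance = 1e-10)
  # a subset smaller than markers + 1 is skipped with a reason, not an error
  sch$labels[1:3] <- "tiny"; sch$sizes <- c(h1 = 147L, h2 = 150L, tiny = 3L)
  ra2 <- replicate_axes(sm, sch)
  expect_true("tiny" %in% names(ra2$skipped))
  expect_error(replicate_axes(as_sm(X[1:3, ]), sch), "align")
})

test_that("pairwise correlation report: counts, self-correlation, null scale", {
  set.seed(23)
  vs <- lapply(1:10, function(i) rnorm(500))
  rp <- pairwise_axis_correlations(vs)
  expect_equal(rp$n_pairs, choose(10, 2))   # 10 versions -> 45 coefficients
  expect_equal(rp$n_pairs, 45L)
  expect_true(all(abs(diag(rp$matrix) - 1) < 1e-12))
  expect_equal(rp$matrix, t(rp$matrix))
  # duplicated version correlates at exactly 1
  rp2 <- pairwise_axis_correlations(list(a = vs[[1]], b = vs[[1]]))
  expect_equal(unname(rp2$matrix["a", "b"]), 1, tolerance = 1e-12)
  # independent noise versions: correlations on the 1/sqrt(n) scale
  x <- rnorm(1000); y <- rnorm(1000)
  rp3 <- pairwise_axis_correlations(list(x = x, y = y))
  expect_lt(abs(rp3$summary$mean), 0.1)
  expect_error(pairwise_axis_correlations(list(rnorm(5), rnorm(6))), "length")
})

test_that("same_axis verdict respects the threshold", {
  M <- matrix(0.95, 3, 3); diag(M) <- 1
  rep_ok <- structure(list(matrix = M, summary = list(), n_pairs = 3,
                           threshold = 0.9, sizes = NULL), class = "stability_report")
  expect_true(same_axis(rep_ok))
  M2 <- M; M2[1, 2] <- M2[2, 1] <- 0.85
  rep_bad <- rep_ok; rep_bad$matrix <- M2
  expect_false(same_axis(rep_bad, threshold = 0.9))
  expect_true(same_axis(rep_bad, threshold = 0))
})

test_that("null distribution is reproducible and degenerates correctly at k = 2, reps = 1", {
  set.seed(24)
  sm <- as_sm(matrix(rnorm(200 * 4), 200, 4), ages = runif(200, 60, 90))
  nd <- null_distribution(sm, k = 2, reps = 1, seed = 5)
  expect_equal(nd$mean_of_means, nd$mean_of_minima)
  expect_equal(nrow(nd$per_replicate), 1L)
  nd2 <- null_distribution(sm, k = 3, reps = 4, seed = 6)
  nd3 <- null_distribution(sm, k = 3, reps = 4, seed = 6)
  expect_equal(nd2, nd3)
})

test_that("stability decreases (never increases) with marker residual noise", {
  # a small linear age trend keeps subset orientations consistent, as in the
  # intended use where the leading axis correlates with age
  mean_stab <- function(res_sd, seed) {
    lam <- sqrt(pmax(0, 1 - res_sd^2))
    cfg <- small_config(n_subjects = 1200, p = 8, lambda = lam,
                        residual_sd = rep(res_sd, 8), seed = seed,
                        trend = c(-1.5, 0.02, 0),
                        mortality = list(h0 = 0, log_hr = 0, followup_years = 8))
    gp <- generate_panel(cfg)
    sm <- standardize(gp$panel, fit_transform_spec(gp$panel, markers = cfg$markers$marker))
    mean(sapply(1:10, function(r)
      null_distribution(sm, k = 4, reps = 1, seed = 100 * seed + r)$mean_of_means))
  }
  s_lo <- mean_stab(0.5, 1)
  s_mid <- mean_stab(0.8, 2)
  s_hi <- mean_stab(0.95, 3)
  expect_gte(s_lo, s_mid - 0.02)
  expect_gte(s_mid, s_hi - 0.02)
})

test_that("importance stability: identical, reversed, and noise profiles", {
  w <- sort(runif(6), decreasing = TRUE); w <- w / sum(w)
  p1 <- structure(setNames(w, sprintf("m%d", 1:6)), class = c("importance_profile", "numeric"))
  expect_equal(importance_stability(list(p1, p1)), list(mean_abs_diff = 0, mean_rank_cor = 1))
  p2 <- structure(setNames(rev(w), names(p1)), class = class(p1))
  expect_equal(importance_stability(list(p1, p2))$mean_rank_cor, -1)
  # independent noise axes: rank correlation near 0 on average
  set.seed(25)
  profs <- lapply(1:12, function(i) {
    v <- abs(rnorm(43)); v <- v / sum(v)
    structure(setNames(v, sprintf("b%02d", 1:43)), class = class(p1))
  })
  expect_lt(abs(importance_stability(profs)$mean_rank_cor), 0.2)
  bad <- p1; names(bad)[1] <- "other"
  expect_error(importance_stability(list(p1, bad)), "marker")
})
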