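test_that("normal rank transform uses mid-ranks and RankIt", {
  expect_equal(normal_rank_transform(c(5, 9)),
               c(43.2551, 56.7449), tolerance = 1e-4)
  expect_equal(normal_rank_transform(c(4, 4, 4)), rep(50, 3))
  out <- normal_rank_transform(c(3, 1, 2))
  expect_equal(out[2], min(out))           # output order matches input
  expect_equal(out[order(c(3, 1, 2))], sort(out))
  # an untied median in an odd group sits exactly at T = 50
  expect_equal(normal_rank_transform(c(10, 20, 30))[2], 50)
  expect_error(normal_rank_transform(7), "at least 2")
})

test_that("design matrix enumerates all powers but the intercept", {
  g <- poly_term_grid(4)
  expect_equal(nrow(g), 24)
  expect_false(any(g$s == 0 & g$t == 0))
  X1 <- build_design(2, 3, k = 1)
  expect_equal(ncol(X1), 3)
  expect_equal(sort(as.numeric(X1)), sort(c(2, 3, 6)))  # l, a, l*a
  X4 <- build_design(c(0, 2), c(5, 5), k = 4)
  expect_equal(ncol(X4), 24)
  g4 <- poly_term_grid(4)
  expect_true(all(X4[1, g4$s >= 1] == 0))               # l = 0 zeroes l-terms
})

test_that("best-subset fit recovers an exact sparse polynomial", {
  grid <- expand.grid(l = seq(30, 70, by = 5), a = 1:7)
  y <- 2 + 0.5 * grid$l + 0.1 * grid$l * grid$a
  X <- build_design(grid$l, grid$a, k = 4)
  fit <- best_subset_fit(X, y, 2)
  expect_equal(fit$terms$s, c(1, 1))
  expect_equal(fit$terms$t, c(0, 1))
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients), c(0.5, 0.1), tolerance = 1e-8)
  expect_equal(fit$intercept, 2, tolerance = 1e-6)
})

test_that("degenerate constant response yields a zero-R2 intercept model", {
  grid <- expand.grid(l = seq(30, 70, by = 10), a = 1:7)
  X <- build_design(grid$l, grid$a, k = 4)
  fit <- best_subset_fit(X, rep(7, nrow(X)), 3)
  expect_equal(fit$r2, 0)
  expect_equal(fit$intercept, 7)
  expect_length(fit$coefficients, 0)
})

test_that("R2 is monotone in the number of selected terms", {
  r <- fixture_ranked()
  X <- build_design(r$l, r$age_mid, k = 4)
  r2_4 <- best_subset_fit(X, r$raw, 4)$r2
  r2_24 <- best_subset_fit(X, r$raw, 24)$r2
  expect_gte(r2_24, r2_4 - 1e-12)
})

test_that("best-subset search equals brute-force enumeration", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 60
    l <- runif(n, 25, 75); a <- sample(1:7, n, replace = TRUE)
    X <- build_design(l, a, k = 2)            # 8 predictors
    y <- 0.3 * l + 0.02 * l * a + rnorm(n, 0, 3)
    for (m in c(2, 3)) {
      fit <- best_subset_fit(X, y, m)
      oracle <- oracle_best_subset(X, y, m)
      expect_equal(fit$r2, oracle$r2, tolerance = 1e-9)
      expect_equal(fit$term_idx, sort(oracle$idx))
    }
  }
})

test_that("branch-and-bound path agrees with exhaustive enumeration", {
  set.seed(99)
  n <- 80
  l <- runif(n, 25, 75); a <- sample(1:7, n, replace = TRUE)
  X <- build_design(l, a, k = 2)
  y <- 0.3 * l - 0.01 * l^2 + 0.05 * a^2 + rnorm(n)
  sds <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
  ys <- y - mean(y)
  C <- crossprod(cbind(Xs, ys)) / (n - 1)
  exh <- normsim:::best_subset_indices(C, 3, exhaustive_limit = 1e6)
  bb <- normsim:::best_subset_indices(C, 3, exhaustive_limit = 1)
  expect_equal(sort(exh), sort(bb))
})

test_that("monotonicity checks distinguish rising, flat and falling surfaces", {
  rising <- toy_model(s = 1, t = 0, coefs = 1)            # raw = l
  expect_true(check_monotonicity(rising, strict = TRUE)$monotone)
  expect_true(check_monotonicity(rising)$monotone)

  falling <- toy_model(s = 1, t = 0, coefs = -1, intercept = 100,
                       raw_range = c(25, 75))
  strict_fall <- check_monotonicity(falling, strict = TRUE)
  expect_false(strict_fall$monotone)
  expect_gt(nrow(strict_fall$violations), 0)
  expect_false(check_monotonicity(falling)$monotone)

  # no dependence on l at all: strict test demands an increase
  flat <- toy_model(s = 0, t = 1, coefs = 1)
  expect_false(check_monotonicity(flat, strict = TRUE)$monotone)
})

test_that("model selection defaults to four terms on well-behaved data", {
  m <- select_model(fixture_ranked())
  expect_s3_class(m, "semiparam_model")
  expect_true(m$monotone)
  expect_true(m$n_terms %in% 3:4)
  expect_gt(m$r2, 0.95)
})

test_that("predicted raw scores are plain polynomial evaluations", {
  const <- toy_model(intercept = 11.5)
  expect_equal(predict_raw(const, c(20, 50, 80), c(1, 4, 7)), rep(11.5, 3))
  double_l <- toy_model(s = 1, t = 0, coefs = 2)
  expect_equal(predict_raw(double_l, 50, 3), 100)
  # continuity in l
  m <- select_model(fixture_ranked())
  eps <- 1e-6
  expect_lt(abs(predict_raw(m, 50 + eps, 3) - predict_raw(m, 50, 3)), 1e-3)
})

test_that("norm-score inversion round-trips and clamps", {
  double_l <- toy_model(s = 1, t = 0, coefs = 2)
  expect_equal(predict_norm(double_l, 100, 3), 50, tolerance = 1e-6)
  expect_equal(predict_norm(double_l, -1000, 3), 20)   # below window floor
  expect_equal(predict_norm(double_l, 1e6, 3), 80)

  m <- select_model(fixture_ranked())
  for (a in c(1, 4, 7)) {
    # probe the interior of the observed window, clear of the saturated
    # edges where the surface is allowed sub-resolution flatness
    lr <- m$data_range$l_by_group[[a]]
    ls <- seq(lr[1] + 0.1 * diff(lr), lr[2] - 0.1 * diff(lr),
              length.out = 15)
    raws <- predict_raw(m, ls, a)
    back <- predict_norm(m, raws, a)
    expect_true(all(abs(back - ls) <= 0.011))
  }
})

test_that("norm assignment is monotone in the raw score", {
  m <- select_model(fixture_ranked())
  tab <- norm_assignment(m)
  for (a in unique(tab$age)) {
    Ts <- tab$T[tab$age == a]
    expect_true(all(diff(Ts) >= 0))
  }
  expect_true(all(tab$T >= 20 & tab$T <= 80))
})

test_that("semi-parametric models survive JSON serialization", {
  path <- withr::local_tempfile(fileext = ".json")
  m <- select_model(fixture_ranked())
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$n_terms, m$n_terms)
  expect_equal(back$intercept, m$intercept)
  ls <- seq(30, 70, by = 10)
  expect_equal(predict_raw(back, ls, 4), predict_raw(m, ls, 4))
})

test_that("norm tables are exported with the expected columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  m <- select_model(fixture_ranked())
  norm_table(m, ages = c(2, 5), path = path)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(tab, c("age", "raw", "T"))
  expect_setequal(unique(tab$age), c(2, 5))
})

test_that("tidy and glance expose the fitted terms", {
  m <- select_model(fixture_ranked())
  td <- tidy(m)
  expect_equal(nrow(td), m$n_terms + 1)
  expect_equal(td$term[1], "(Intercept)")
  gl <- glance(m)
  expect_equal(gl$n_terms, m$n_terms)
  expect_true(gl$monotone)
})
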