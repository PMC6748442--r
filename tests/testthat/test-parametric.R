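make_group_persons <- function(values_by_group) {
  tibble::tibble(
    group = rep(seq_along(values_by_group),
                times = lengths(values_by_group)),
    raw = unlist(values_by_group))
}

test_that("identical group moments give a flat normal-family model", {
  persons <- make_group_persons(rep(list(c(8, 10, 12)), 7))
  m <- fit_no(persons)
  ages <- 1:7
  expect_equal(normsim:::eval_poly(m$mean_curve, ages), rep(10, 7),
               tolerance = 1e-8)
  expect_equal(normsim:::eval_poly(m$sd_curve, ages), rep(2, 7),
               tolerance = 1e-8)
})

test_that("group means lying on a cubic are recovered exactly", {
  cubic <- function(a) 5 + 2 * a - 0.3 * a^2 + 0.02 * a^3
  persons <- make_group_persons(lapply(1:7, function(g)
    cubic(g) + c(-1.5, 0, 1.5)))
  m <- fit_no(persons)
  expect_equal(normsim:::eval_poly(m$mean_curve, 1:7), cubic(1:7),
               tolerance = 1e-6)
})

test_that("fitted mean curve increases with age on simulated data", {
  s <- draw_normative_sample(300, seed = 21) |>
    simulate_raw_scores(make_scale("medium"), seed = 22)
  m <- fit_no(s)
  mu <- normsim:::eval_poly(m$mean_curve, seq(1, 7, by = 0.5))
  expect_true(all(diff(mu) > 0))
  sg <- normsim:::eval_poly(m$sd_curve, seq(0.5, 7.45, by = 0.05))
  expect_true(all(sg > 0))
})

test_that("normal-family norm scores follow the z formula with clamping", {
  m <- structure(list(mean_curve = c(10), sd_curve = c(2), converged = TRUE),
                 class = "no_model")
  expect_equal(predict_norm_no(m, 10, 3), 50)
  expect_equal(predict_norm_no(m, 12, 3), 60)
  expect_equal(predict_norm_no(m, 10 - 8, 3), 20)   # mean - 4 SD clamps
  raws <- seq(4, 16, by = 0.5)
  expect_true(all(diff(predict_norm_no(m, raws, 5)) >= 0))
})

test_that("Box-Cox transform has the correct lambda limits", {
  y <- c(5, 10, 20)
  expect_equal(normsim:::bccg_z(y, 10, 0.2, 1), (y / 10 - 1) / 0.2)
  expect_lt(max(abs(normsim:::bccg_z(y, 10, 0.2, 1e-8) -
                      normsim:::bccg_z(y, 10, 0.2, 0))), 1e-6)
  # first-order behaviour of the lambda -> 0 limit
  expect_lt(max(abs(normsim:::bccg_z(y, 10, 0.2, 1e-4) -
                      normsim:::bccg_z(y, 10, 0.2, 0))), 1e-3)
  expect_equal(normsim:::bccg_z(10, 10, 0.2, 0.7), 0)
})

test_that("BCCG fitting recovers constant generating parameters", {
  y <- rbccg(5000, mu = 10, sigma = 0.2, lambda = 1, seed = 31)
  persons <- tibble::tibble(group = rep(1:7, length.out = 5000),
                            raw = y - 1)          # undo the internal +1 shift
  m <- fit_bccg(persons, degrees = c(0, 0, 0), n_starts = 3)
  expect_true(m$converged)
  expect_equal(m$mu_curve[1], 10, tolerance = 0.05 * 10)
  expect_equal(m$sigma_curve[1], 0.2, tolerance = 0.05 * 0.2 + 0.01)
  expect_lt(abs(m$lambda_curve[1] - 1), 0.5)
})

test_that("BCCG norm scores honour the shifted transformation", {
  m <- structure(list(mu_curve = 10, sigma_curve = 0.2, lambda_curve = 1,
                      degrees = c(0, 0, 0), shift = 1, loglik = 0,
                      converged = TRUE),
                 class = "bccg_model")
  expect_equal(predict_norm_bccg(m, 9, 3), 50)        # raw + 1 = mu
  expect_equal(predict_norm_bccg(m, 10 * 1.2 - 1, 3), 60)  # mu (1 + sigma)
  raws <- seq(0, 20, by = 0.5)
  expect_true(all(diff(predict_norm_bccg(m, raws, 4)) >= 0))
  expect_error(predict_norm_bccg(m, -2, 3))
})

test_that("the fitted BCCG likelihood dominates the embedded normal fit", {
  s <- draw_normative_sample(150, seed = 41) |>
    simulate_raw_scores(make_scale("medium"), seed = 42)
  bc <- normsim:::with_seed_if(43, fit_bccg(s))
  expect_true(bc$converged)
  y <- s$raw + 1
  age <- as.numeric(s$group)
  s_shift <- s; s_shift$raw <- s_shift$raw + 1
  no <- fit_no(s_shift)
  mu0 <- normsim:::eval_poly(no$mean_curve, age)
  sg0 <- normsim:::eval_poly(no$sd_curve, age) / mu0   # sigma is a CV
  ll_no <- normsim:::bccg_loglik(y, mu0, sg0, rep(1, length(y)))
  p <- normsim:::bccg_unpack(c(bc$mu_curve, bc$sigma_curve, bc$lambda_curve),
                             bc$degrees, age)
  ll_bc <- normsim:::bccg_loglik(y, p$mu, p$sigma, p$lambda)
  expect_gte(ll_bc, ll_no - 1e-6)
})

test_that("parametric models serialize to JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  persons <- make_group_persons(rep(list(c(8, 10, 12, 9, 11)), 7))
  m <- fit_no(persons)
  write_parametric(m, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$family, "NO")
  expect_true(obj$converged)
})
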