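fake_crossval <- function(T_ideal, raw = NULL, age = 4) {
  n <- length(T_ideal)
  tibble::tibble(id = seq_len(n), age = rep_len(age, n),
                 group = as.integer(rep_len(age, n)),
                 raw = if (is.null(raw)) T_ideal else raw,
                 T_ideal = T_ideal)
}

# a normal-family model that predicts T = 50 + raw, handy for exact checks
identity_no <- structure(list(mean_curve = 0, sd_curve = 10, converged = TRUE),
                         class = "no_model")

test_that("ideal norms use the group-wise rank transform", {
  cv <- build_crossval_sample(500) |>
    simulate_raw_scores(make_scale("medium"), seed = 1) |>
    ideal_norms()
  for (g in c(1, 7)) {
    sub <- cv[cv$group == g, ]
    expect_equal(sub$T_ideal, normal_rank_transform(sub$raw))
    # tied raw scores share one ideal norm
    t_by_raw <- tapply(sub$T_ideal, sub$raw, function(x) length(unique(x)))
    expect_true(all(t_by_raw == 1))
  }
  expect_equal(sort(unique(normal_rank_transform(c(1, 2, 3, 4)))),
               50 + 10 * qnorm(c(0.125, 0.375, 0.625, 0.875)))
})

test_that("rmse and msd follow their definitions", {
  perfect <- score_model(identity_no, fake_crossval(seq(30, 70), raw = seq(-20, 20)))
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$msd, 0)
  offset <- score_model(identity_no, fake_crossval(seq(30, 70) - 2,
                                                   raw = seq(-20, 20)))
  expect_equal(offset$rmse, 2)
  expect_equal(offset$msd, 2)
  mixed <- score_model(identity_no, fake_crossval(c(49, 53), raw = c(0, 2)))
  expect_equal(mixed$rmse, 1)   # errors +1 and -1
  expect_equal(mixed$msd, 0)
  expect_true(perfect$included)
})

test_that("rmse dominates the absolute msd", {
  for (seed in 1:5) {
    set.seed(seed)
    ti <- runif(200, 30, 70)
    res <- score_model(identity_no, fake_crossval(ti + rnorm(200), raw = ti - 50))
    expect_gte(res$rmse, abs(res$msd))
  }
})

test_that("band errors partition T_ideal between 20 and 80", {
  ti <- c(10, seq(22.5, 77.5, by = 5), 85)   # one subject per band + extremes
  res <- score_model(identity_no, fake_crossval(ti - 1, raw = ti - 50))
  bands <- res$band_rmse[[1]]
  expect_length(bands, 12)
  expect_equal(bands, rep(1, 12))   # constant error of 1 inside every band
})

test_that("failed parametric fits are excluded from scoring", {
  failed <- structure(list(converged = FALSE), class = "bccg_model")
  res <- score_model(failed, fake_crossval(seq(40, 60)))
  expect_false(res$included)
  expect_true(is.na(res$rmse))
})

test_that("best parametric method is the lowest-RMSE converged one", {
  results <- tibble::tibble(
    method = c("semiparam", "no", "bccg"),
    rmse = c(1.0, 2.0, 1.5),
    converged = c(NA, TRUE, TRUE))
  expect_equal(pick_best_parametric(results), "bccg")
  results$rmse <- c(1.0, 1.5, 1.5)
  expect_equal(pick_best_parametric(results), "no")    # tie -> canonical order
  only_no <- results[results$method == "no", ]
  expect_equal(pick_best_parametric(only_no), "no")
  none <- results[results$method == "semiparam", ]
  expect_true(is.na(pick_best_parametric(none)))
})

test_that("win counts and chi-squared match hand computation", {
  w <- c(rep("a", 75), rep("b", 75))
  out <- win_counts_chi2(w)
  expect_equal(out$chi2, 0)
  expect_false(out$significant)
  out <- win_counts_chi2(c(rep("a", 90), rep("b", 10)))
  expect_equal(out$chi2, 64)
  expect_equal(out$df, 1)
  expect_true(out$significant)
  out <- win_counts_chi2(rep("a", 150), methods = c("a", "b", "c", "d"))
  expect_equal(out$chi2, 450)
  expect_equal(out$df, 3)
  expect_error(win_counts_chi2(character(0)), "no cycles")
})

test_that("cleaning drops poor parametric fits but keeps semi-parametric", {
  results <- tibble::tibble(
    method = c("no", "no", "bccg", "semiparam"),
    rmse = c(12.3, 9.99, 3, 3),
    converged = c(TRUE, TRUE, FALSE, NA),
    included = rmse < 10)
  out <- clean_results(results)
  expect_equal(nrow(out), 2)
  expect_setequal(out$method, c("no", "semiparam"))
  expect_equal(out$rmse[out$method == "no"], 9.99)
})
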