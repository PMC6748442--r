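# Shared fixtures, built in code at test time.

# A hand-made semi-parametric model: raw = intercept + sum(coef * l^s * a^t),
# with just enough metadata for prediction and monotonicity checks.
toy_model <- function(s = integer(0), t = integer(0), coefs = numeric(0),
                      intercept = 0, l_range = c(25, 75), age_range = c(1, 7),
                      raw_range = c(0, 20)) {
  groups <- seq(age_range[1], age_range[2])
  structure(
    list(k = 4, n_terms = length(s),
         terms = tibble::tibble(s = as.integer(s), t = as.integer(t)),
         intercept = intercept,
         coefficients = if (length(coefs))
           stats::setNames(coefs, paste0("l", s, "a", t)) else numeric(0),
         r2 = NA_real_, monotone = NA, rank_deficient = FALSE,
         data_range = list(l = l_range, age = age_range, raw = raw_range,
                           groups = groups,
                           l_by_group = rep(list(l_range), length(groups))),
         n = 0L),
    class = "semiparam_model")
}

# A ranked normative sample on the medium scale, reused across tests.
fixture_ranked <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- draw_normative_sample(100, seed = 42)
      s <- simulate_raw_scores(s, make_scale("medium"), seed = 43)
      cache <<- rank_sample(s)
    }
    cache
  }
})

# Brute-force best-subset oracle: enumerate every subset with lm().
oracle_best_subset <- function(X, y, m) {
  combos <- utils::combn(ncol(X), m)
  best <- -Inf; bi <- NULL
  syy <- sum((y - mean(y))^2)
  for (j in seq_len(ncol(combos))) {
    id <- combos[, j]
    f <- stats::lm.fit(cbind(1, X[, id, drop = FALSE]), y)
    r2 <- 1 - sum(f$residuals^2) / syy
    if (r2 > best + 1e-12) { best <- r2; bi <- id }
  }
  list(idx = bi, r2 = best)
}
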