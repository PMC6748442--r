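#' Construct a 20-item Rasch test scale
#'
#' Item locations match a perfect normal distribution: the normal quantiles at
#' probability points `(i - 0.5) / 20`, rescaled so their sample SD is exactly
#' 1.0, then shifted to the scale's mean location (-1 easy, 0 medium,
#' +1 difficult). The medium scale covers the modelled ability range well;
#' shifting the mean difficulty induces ceiling (easy) or floor (difficult)
#' effects in the resulting raw-score distributions.
#'
#' @param label One of `"easy"`, `"medium"`, `"difficult"`.
#' @return An object of class `rasch_scale`: a list with `label`, `deltas`
#'   (20 item locations in logits), `mean_delta`, `sd_delta`.
#' @export
#' @examples
#' sc <- make_scale("medium")
#' mean(sc$deltas)  # 0
#' sd(sc$deltas)    # 1
make_scale <- function(label = c("easy", "medium", "difficult")) {
  label <- match.arg(label)
  mean_delta <- c(easy = -1, medium = 0, difficult = 1)[[label]]
  q <- stats::qnorm((1:20 - 0.5) / 20)
  q <- q / stats::sd(q)
  structure(
    list(label = label, deltas = mean_delta + q,
         mean_delta = mean_delta, sd_delta = 1),
    class = "rasch_scale")
}

#' @export
print.rasch_scale <- function(x, ...) {
  cat("<rasch_scale>", x$label, "\n")
  cat("  20 items, mean location", x$mean_delta, ", SD", x$sd_delta, "\n")
  cat("  range:", signif(min(x$deltas), 4), "to", signif(max(x$deltas), 4),
      "logits\n")
  invisible(x)
}

#' Rasch solution probability
#'
#' One-parameter logistic model: `P(correct) = 1 / (1 + exp(-(theta - delta)))`.
#'
#' @param theta_pop Person ability (population z-score), vectorized.
#' @param delta Item location in logits, vectorized.
#' @return Probabilities in (0, 1).
#' @export
response_prob <- function(theta_pop, delta) {
  stopifnot(all(is.finite(delta)))
  stats::plogis(theta_pop - delta)
}

#' Simulate raw scores for a person table
#'
#' Each person answers every item of the scale by an independent Bernoulli
#' draw with Rasch probability [response_prob()]; the responses are summed to
#' a raw score between 0 and 20.
#'
#' @param persons A person tibble (needs `theta_pop`).
#' @param scale A [make_scale()] object.
#' @param seed Optional seed for reproducible draws.
#' @return The person tibble with the `raw` column filled.
#' @export
simulate_raw_scores <- function(persons, scale, seed = NULL) {
  stopifnot(inherits(scale, "rasch_scale"), "theta_pop" %in% names(persons))
  n <- nrow(persons)
  k <- length(scale$deltas)
  with_seed_if(seed, {
    p <- stats::plogis(outer(persons$theta_pop, scale$deltas, "-"))
    persons$raw <- as.integer(rowSums(matrix(stats::runif(n * k), n, k) < p))
  })
  persons
}

#' Expected raw score given ability
#'
#' Analytic expectation `sum_i P(correct on item i)`; strictly increasing in
#' ability. Serves as the oracle for the Monte-Carlo raw-score mean.
#'
#' @inheritParams response_prob
#' @param scale A [make_scale()] object.
#' @return Expected raw score (continuous).
#' @export
expected_raw <- function(theta_pop, scale) {
  stopifnot(inherits(scale, "rasch_scale"))
  rowSums(stats::plogis(outer(theta_pop, scale$deltas, "-")))
}

#' Average raw-score skewness of a scale under the population model
#'
#' Simulates `n_per_group` subjects per age group, computes the moment-ratio
#' skewness of the raw scores within each group and returns the unweighted
#' mean over the seven groups. Degenerate groups (zero raw-score variance)
#' are excluded with a warning.
#'
#' @param scale A [make_scale()] object.
#' @param pop A [population_model()].
#' @param n_per_group Subjects per group; at least 10^4 recommended.
#' @param seed Optional seed.
#' @return Average per-group skewness `g_m`.
#' @export
scale_skewness <- function(scale, pop = population_model(),
                           n_per_group = 1e5, seed = NULL) {
  persons <- draw_normative_sample(n_per_group, pop, seed = seed)
  persons <- simulate_raw_scores(persons, scale,
                                 seed = if (is.null(seed)) NULL else seed + 1)
  g <- vapply(split(persons$raw, persons$group), moment_skewness, numeric(1))
  if (anyNA(g)) {
    warning("degenerate age group with zero raw-score variance excluded")
    g <- g[!is.na(g)]
  }
  mean(g)
}

#' Read or write a test scale
#'
#' CSV with columns `item_index`, `delta`; the label and moments are carried
#' in the first comment line.
#'
#' @param scale A [make_scale()] object.
#' @param path File path.
#' @export
write_scale <- function(scale, path) {
  df <- tibble::tibble(item_index = seq_along(scale$deltas),
                       delta = scale$deltas,
                       label = scale$label)
  readr::write_csv(df, path)
  invisible(scale)
}

#' @rdname write_scale
#' @export
read_scale <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  structure(
    list(label = df$label[1], deltas = df$delta,
         mean_delta = round(mean(df$delta), 10),
         sd_delta = round(stats::sd(df$delta), 10)),
    class = "rasch_scale")
}
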