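#' Developmental population model
#'
#' Defines the fictitious population from which all simulated samples are
#' drawn: a latent ability that grows non-linearly over seven one-year age
#' groups. The unstandardized ability of a person with within-age z-score
#' `theta_age` at age `a` is `theta_age * sd_ability(a) + mean_ability(a)`;
#' z-standardizing that quantity across the whole population with the fixed
#' constants `pop_mu` and `pop_sigma` yields the population-wide ability
#' `theta_pop` that drives the Rasch item responses.
#'
#' The default mean and SD trajectories are
#' \deqn{M(a) = 1.5 a - 0.05 a^2 + 0.0001 a^4}
#' \deqn{SD(a) = 1 + 0.3 a - 0.01 a^2 + 0.00002 a^4}
#' with standardization constants 5.097 and 3.128. The constants are part of
#' the model definition and are taken as given rather than recomputed (an
#' analytic recomputation under uniform age mixing gives a slightly different
#' mean, about 5.06).
#'
#' @param mean_coeffs Coefficients of the mean-ability polynomial in age,
#'   ordered by increasing power starting at the constant term.
#' @param sd_coeffs Same layout for the ability SD polynomial.
#' @param pop_mu,pop_sigma Population standardization constants.
#' @return An object of class `norm_population`.
#' @export
#' @examples
#' pop <- population_model()
#' eval_mean_ability(1, pop)     # 1.4501
#' to_theta_pop(0, 1, pop)       # about -1.166
population_model <- function(mean_coeffs = c(0, 1.5, -0.05, 0, 0.0001),
                             sd_coeffs = c(1, 0.3, -0.01, 0, 0.00002),
                             pop_mu = 5.097, pop_sigma = 3.128) {
  stopifnot(pop_sigma > 0, length(mean_coeffs) >= 1, length(sd_coeffs) >= 1)
  pop <- structure(
    list(mean_coeffs = mean_coeffs, sd_coeffs = sd_coeffs,
         pop_mu = pop_mu, pop_sigma = pop_sigma,
         age_groups = tibble::tibble(group = 1:7,
                                     lower = 1:7 - 0.5, upper = 1:7 + 0.5)),
    class = "norm_population")
  ages <- seq(0.5, 7.5, by = 0.01)
  if (any(eval_sd_ability(ages, pop) <= 0))
    stop("sd_ability must be positive over the age range [0.5, 7.5)")
  if (any(diff(eval_mean_ability(ages, pop)) <= 0))
    stop("mean_ability must be strictly increasing over [0.5, 7.5)")
  pop
}

#' @export
print.norm_population <- function(x, ...) {
  cat("<norm_population>\n")
  cat("  mean ability:", paste(signif(x$mean_coeffs, 4), collapse = " "),
      "(coefficients by power of age)\n")
  cat("  sd ability:  ", paste(signif(x$sd_coeffs, 4), collapse = " "), "\n")
  cat("  standardization: mu =", x$pop_mu, " sigma =", x$pop_sigma, "\n")
  cat("  7 age groups covering [0.5, 7.5)\n")
  invisible(x)
}

eval_poly <- function(coeffs, x) {
  out <- numeric(length(x))
  for (i in seq_along(coeffs)) out <- out + coeffs[i] * x^(i - 1)
  out
}

#' Mean and SD of the latent ability at a given age
#'
#' @param age Age in years (vectorized). Values outside `[0.5, 7.5)` are
#'   permitted for diagnostics.
#' @param pop A [population_model()].
#' @return Ability units (dimensionless).
#' @export
eval_mean_ability <- function(age, pop = population_model()) {
  stopifnot(all(age >= 0))
  eval_poly(pop$mean_coeffs, age)
}

#' @rdname eval_mean_ability
#' @export
eval_sd_ability <- function(age, pop = population_model()) {
  stopifnot(all(age >= 0))
  eval_poly(pop$sd_coeffs, age)
}

#' Convert within-age ability to population-standardized ability
#'
#' Affine and strictly increasing in `theta_age` at every fixed age
#' (slope `sd_ability(age) / pop_sigma > 0`).
#'
#' @param theta_age Within-age z-score (vectorized).
#' @param age Age in years.
#' @inheritParams eval_mean_ability
#' @return Population-wide z-score `theta_pop`.
#' @export
to_theta_pop <- function(theta_age, age, pop = population_model()) {
  stopifnot(all(is.finite(theta_age)), all(is.finite(age)))
  (theta_age * eval_sd_ability(age, pop) + eval_mean_ability(age, pop) -
     pop$pop_mu) / pop$pop_sigma
}

age_group_of <- function(age) {
  grp <- as.integer(floor(age + 0.5))
  if (any(grp < 1L | grp > 7L)) stop("age outside the modelled range [0.5, 7.5)")
  grp
}

#' Draw a random normative sample
#'
#' Within each of the seven age groups, age is uniform over the group interval
#' and the within-age ability `theta_age` is standard normal; `theta_pop` is
#' derived deterministically. Raw scores are absent until a test scale is
#' simulated with [simulate_raw_scores()].
#'
#' @param n_per_group Persons per age group (>= 2).
#' @param pop A [population_model()].
#' @param seed Optional integer seed; the same seed reproduces the sample
#'   exactly and the caller's RNG state is left untouched.
#' @return A tibble with columns `id`, `age`, `group`, `theta_age`,
#'   `theta_pop`, `raw` (NA).
#' @export
#' @examples
#' s <- draw_normative_sample(50, seed = 1)
#' nrow(s)            # 350
#' range(s$age)       # inside [0.5, 7.5)
draw_normative_sample <- function(n_per_group, pop = population_model(),
                                  seed = NULL) {
  if (!is.numeric(n_per_group) || length(n_per_group) != 1L || n_per_group < 2)
    stop("n_per_group must be a single count >= 2")
  n_per_group <- as.integer(n_per_group)
  with_seed_if(seed, {
    group <- rep(1:7, each = n_per_group)
    age <- stats::runif(length(group), group - 0.5, group + 0.5)
    theta_age <- stats::rnorm(length(group))
    tibble::tibble(
      id = seq_along(group),
      age = age,
      group = group,
      theta_age = theta_age,
      theta_pop = to_theta_pop(theta_age, age, pop),
      raw = NA_integer_)
  })
}

#' Build the deterministic cross-validation sample
#'
#' Seven discrete age levels (1.0 ... 7.0) with `n_per_level` subjects each.
#' The within-age abilities are not sampled: at every level they are set to
#' the normal quantiles at probability points `(i - 0.5) / n`, so the sample
#' matches a perfect normal distribution (mean 0, skewness 0) at each level
#' and two builds are bit-identical.
#'
#' @param n_per_level Subjects per age level (>= 100).
#' @param pop A [population_model()].
#' @return A tibble in the same layout as [draw_normative_sample()].
#' @export
#' @examples
#' cv <- build_crossval_sample(100)
#' nrow(cv)   # 700
build_crossval_sample <- function(n_per_level = 10000,
                                  pop = population_model()) {
  if (!is.numeric(n_per_level) || length(n_per_level) != 1L)
    stop("n_per_level must be a single count")
  n_per_level <- as.integer(n_per_level)
  if (n_per_level < 3L) stop("n_per_level too small")
  level <- rep(1:7, each = n_per_level)
  theta_age <- rep(stats::qnorm((seq_len(n_per_level) - 0.5) / n_per_level), 7)
  tibble::tibble(
    id = seq_along(level),
    age = as.numeric(level),
    group = level,
    theta_age = theta_age,
    theta_pop = to_theta_pop(theta_age, as.numeric(level), pop),
    raw = NA_integer_)
}

#' Read or write person-level tables
#'
#' CSV with header `id, age, group, theta_age, theta_pop, raw`; decimal
#' point, UTF-8. `raw` may be empty for not-yet-simulated persons. User data
#' for norming only needs `age`, `group` and `raw`.
#'
#' @param persons A person tibble.
#' @param path File path.
#' @return `read_persons()` returns a tibble; `write_persons()` its input,
#'   invisibly.
#' @export
write_persons <- function(persons, path) {
  readr::write_csv(persons, path)
  invisible(persons)
}

#' @rdname write_persons
#' @export
read_persons <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
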