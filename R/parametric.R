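#' Normal-family parametric norming
#'
#' The classic two-parameter continuous-norming procedure: raw-score mean and
#' SD are computed separately per age group, each group summary is placed at
#' the group's midpoint age, and a polynomial in age is fitted to the seven
#' summaries (degree chosen by minimal AIC among 1..4). Norm scores then
#' follow from the normality assumption at any age.
#'
#' @param persons Person tibble with `raw` and `group`.
#' @param max_degree Largest polynomial degree considered.
#' @return An object of class `no_model` with `mean_curve`, `sd_curve`
#'   (polynomial coefficient vectors by increasing power), the per-group
#'   summary table, and `converged`.
#' @export
fit_no <- function(persons, max_degree = 4) {
  stopifnot(all(c("raw", "group") %in% names(persons)), !anyNA(persons$raw))
  grp <- persons |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(age = as.numeric(.data$group[1]),
                     m = mean(.data$raw),
                     s = stats::sd(.data$raw),
                     n = dplyr::n(), .groups = "drop")
  if (nrow(grp) < 2 || any(grp$n < 2))
    stop("fit_no needs at least 2 groups with at least 2 subjects each")
  fit_curve <- function(y) {
    degs <- seq_len(max(1, min(max_degree, nrow(grp) - 2)))
    fits <- lapply(degs, function(d)
      stats::lm(y ~ stats::poly(age, d, raw = TRUE), data = grp))
    fits[[which.min(vapply(fits, stats::AIC, numeric(1)))]]
  }
  mean_fit <- fit_curve(grp$m)
  # reduce the SD curve's degree until it stays positive over the age range
  ages <- seq(0.5, 7.5, by = 0.01)
  sd_coefs <- NULL
  sd_fit <- fit_curve(grp$s)
  d <- length(stats::coef(sd_fit)) - 1
  repeat {
    cand <- stats::lm(s ~ stats::poly(age, d, raw = TRUE), data = grp)
    cf <- unname(stats::coef(cand))
    if (all(eval_poly(cf, ages) > 0)) { sd_coefs <- cf; break }
    d <- d - 1
    if (d < 1) stop("no positive SD curve found; normal-family fit failed")
  }
  structure(
    list(mean_curve = unname(stats::coef(mean_fit)),
         sd_curve = sd_coefs,
         groups = grp,
         converged = TRUE),
    class = "no_model")
}

#' @export
print.no_model <- function(x, ...) {
  cat("<no_model> mean degree", length(x$mean_curve) - 1,
      ", sd degree", length(x$sd_curve) - 1, "\n")
  invisible(x)
}

#' Norm score under the normal-family model
#'
#' `z = (raw - mean(age)) / sd(age)`, `T = 50 + 10 z`, clamped to `[20, 80]`
#' for evaluation parity with the ability-band analysis.
#'
#' @param model A [fit_no()] model.
#' @param raw Raw scores, vectorized.
#' @param age Ages, vectorized (recycled).
#' @return T-scores in `[20, 80]`.
#' @export
predict_norm_no <- function(model, raw, age) {
  stopifnot(inherits(model, "no_model"))
  mu <- eval_poly(model$mean_curve, age)
  sg <- eval_poly(model$sd_curve, age)
  pmin(pmax(50 + 10 * (raw - mu) / sg, 20), 80)
}

# Box-Cox Cole-Green machinery -------------------------------------------

bccg_z <- function(y, mu, sigma, lambda) {
  n <- max(length(y), length(mu), length(sigma), length(lambda))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); lambda <- rep_len(lambda, n)
  ifelse(abs(lambda) < 1e-10,
         log(y / mu) / sigma,
         ((y / mu)^lambda - 1) / (lambda * sigma))
}

# least-squares age polynomial allowing degree zero (a constant)
polyfit_age <- function(x, y, degree) {
  if (degree == 0) return(mean(y))
  unname(stats::coef(stats::lm(y ~ stats::poly(x, degree, raw = TRUE))))
}

# log-likelihood of shifted scores under BCCG with pointwise parameters
bccg_loglik <- function(y, mu, sigma, lambda) {
  if (any(mu <= 0) || any(sigma <= 0)) return(-Inf)
  z <- bccg_z(y, mu, sigma, lambda)
  sum(stats::dnorm(z, log = TRUE) + (lambda - 1) * log(y / mu) -
        log(mu * sigma))
}

bccg_unpack <- function(par, degrees, age) {
  i1 <- degrees[1] + 1; i2 <- i1 + degrees[2] + 1; i3 <- i2 + degrees[3] + 1
  list(mu = eval_poly(par[1:i1], age),
       sigma = eval_poly(par[(i1 + 1):i2], age),
       lambda = eval_poly(par[(i2 + 1):i3], age))
}

#' Box-Cox Cole-Green parametric norming
#'
#' Fits the three-parameter Box-Cox (Cole-Green / LMS-type) family with
#' age-polynomial parameter curves mu(a), sigma(a), lambda(a) by joint
#' maximum likelihood. Because the family requires strictly positive scores,
#' one point is added to every raw score before fitting (an "icebreaker item"
#' that carries no information); the shift is internal and removed again when
#' norm scores are assigned.
#'
#' The likelihood uses the Cole-Green transformation
#' `z = ((y/mu)^lambda - 1) / (lambda sigma)` (log form at `lambda = 0`)
#' with the standard-normal density and Jacobian `(lambda - 1) log(y/mu) -
#' log(mu sigma)`. Optimization is multi-start quasi-Newton (BFGS) from
#' moment-based initial values.
#'
#' @param persons Person tibble with `raw` and `group`.
#' @param degrees Polynomial degrees of the mu, sigma, lambda curves.
#' @param shift Added to every raw score before fitting (default +1).
#' @param n_starts Number of optimizer starts.
#' @param max_iter Iteration cap per start.
#' @return An object of class `bccg_model` with curve coefficients, the
#'   shift, `loglik` and `converged`.
#' @export
fit_bccg <- function(persons, degrees = c(3, 2, 1), shift = 1,
                     n_starts = 5, max_iter = 500) {
  stopifnot(all(c("raw", "group") %in% names(persons)), !anyNA(persons$raw),
            length(degrees) == 3)
  y <- persons$raw + shift
  if (any(y <= 0)) stop("shifted raw scores must be strictly positive")
  age <- as.numeric(persons$group)
  grp <- persons |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(age = as.numeric(.data$group[1]),
                     m = mean(.data$raw + shift),
                     cv = stats::sd(.data$raw + shift) /
                       max(mean(.data$raw + shift), 1e-6),
                     .groups = "drop")
  # moment-based starting curves: mu from group means, sigma from group CVs,
  # lambda constant 1 (the normal-family corner of the Box-Cox family)
  mu0 <- polyfit_age(grp$age, grp$m, degrees[1])
  s0 <- polyfit_age(grp$age, grp$cv, degrees[2])
  l0 <- c(1, rep(0, degrees[3]))
  base <- c(mu0, s0, l0)
  nll <- function(par) {
    p <- bccg_unpack(par, degrees, age)
    ll <- bccg_loglik(y, p$mu, p$sigma, p$lambda)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  best <- NULL
  jitter_sd <- c(abs(base) * 0.1 + 0.01)
  for (s in seq_len(n_starts)) {
    start <- if (s == 1) base else base + stats::rnorm(length(base), 0, jitter_sd)
    opt <- tryCatch(
      stats::optim(start, nll, method = "BFGS",
                   control = list(maxit = max_iter, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) &&
        (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best) || best$value >= 1e12) {
    return(structure(
      list(mu_curve = NA, sigma_curve = NA, lambda_curve = NA,
           degrees = degrees, shift = shift, loglik = NA_real_,
           converged = FALSE),
      class = "bccg_model"))
  }
  i1 <- degrees[1] + 1; i2 <- i1 + degrees[2] + 1
  p <- best$par
  structure(
    list(mu_curve = p[1:i1],
         sigma_curve = p[(i1 + 1):i2],
         lambda_curve = p[(i2 + 1):length(p)],
         degrees = degrees, shift = shift,
         loglik = -best$value,
         converged = best$convergence == 0),
    class = "bccg_model")
}

#' @export
print.bccg_model <- function(x, ...) {
  cat("<bccg_model> degrees", paste(x$degrees, collapse = "/"),
      " shift +", x$shift, "\n", sep = "")
  cat("  loglik:", x$loglik, " converged:", x$converged, "\n")
  invisible(x)
}

#' Norm score under the Box-Cox Cole-Green model
#'
#' The internal shift is applied to the raw score, the fitted transformation
#' maps it to a standard-normal deviate, and `T = 50 + 10 z`, clamped to
#' `[20, 80]`.
#'
#' @param model A [fit_bccg()] model.
#' @param raw Raw scores, vectorized.
#' @param age Ages, vectorized (recycled).
#' @return T-scores in `[20, 80]`.
#' @export
predict_norm_bccg <- function(model, raw, age) {
  stopifnot(inherits(model, "bccg_model"))
  if (!isTRUE(model$converged)) stop("model did not converge")
  y <- raw + model$shift
  if (any(y <= 0)) stop("raw + shift must be strictly positive")
  mu <- eval_poly(model$mu_curve, age)
  sg <- eval_poly(model$sigma_curve, age)
  lb <- eval_poly(model$lambda_curve, age)
  z <- bccg_z(y, mu, sg, lb)
  pmin(pmax(50 + 10 * z, 20), 80)
}

#' Simulate scores from a BCCG distribution
#'
#' Inverse transformation `y = mu (1 + lambda sigma z)^(1/lambda)` applied to
#' standard-normal draws (log form at `lambda = 0`); draws whose transformed
#' argument would be non-positive are redrawn. Used for parameter-recovery
#' checks.
#'
#' @param n Number of draws.
#' @param mu,sigma,lambda BCCG parameters (scalars).
#' @param seed Optional seed.
#' @return Numeric vector of positive scores.
#' @export
rbccg <- function(n, mu, sigma, lambda, seed = NULL) {
  stopifnot(mu > 0, sigma > 0)
  with_seed_if(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      z <- stats::rnorm(n)
      y <- if (abs(lambda) < 1e-10) mu * exp(sigma * z)
           else {
             arg <- 1 + lambda * sigma * z
             ifelse(arg > 0, mu * arg^(1 / lambda), NA_real_)
           }
      out <- c(out, y[is.finite(y)])
    }
    out[seq_len(n)]
  })
}

#' Serialize parametric models to JSON
#'
#' @param model A `no_model` or `bccg_model`.
#' @param path JSON file path.
#' @export
write_parametric <- function(model, path) {
  obj <- if (inherits(model, "no_model")) {
    list(family = "NO", mean_curve = model$mean_curve,
         sd_curve = model$sd_curve, converged = model$converged)
  } else if (inherits(model, "bccg_model")) {
    list(family = "BCCG", mu_curve = model$mu_curve,
         sigma_curve = model$sigma_curve, lambda_curve = model$lambda_curve,
         degrees = model$degrees, shift = model$shift,
         loglik = model$loglik, converged = model$converged)
  } else stop("not a parametric model")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}
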