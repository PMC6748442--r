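#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a semi-parametric norming model
#'
#' @param x A `semiparam_model`.
#' @param ... Unused.
#' @return Tibble with one row per regression term: `term`, `s`, `t`,
#'   `estimate` (the intercept is the first row with `s = t = 0`).
#' @export
tidy.semiparam_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", paste0("l", x$terms$s, "a", x$terms$t)),
    s = c(0L, x$terms$s),
    t = c(0L, x$terms$t),
    estimate = c(x$intercept, unname(x$coefficients)))
}

#' @rdname tidy.semiparam_model
#' @export
glance.semiparam_model <- function(x, ...) {
  tibble::tibble(r2 = x$r2, n_terms = x$n_terms, k = x$k,
                 monotone = x$monotone, n = x$n)
}

#' Tidy a normal-family norming model
#'
#' @param x A `no_model`.
#' @param ... Unused.
#' @return Tibble with one row per curve coefficient.
#' @export
tidy.no_model <- function(x, ...) {
  tibble::tibble(
    curve = c(rep("mean", length(x$mean_curve)),
              rep("sd", length(x$sd_curve))),
    power = c(seq_along(x$mean_curve), seq_along(x$sd_curve)) - 1L,
    estimate = c(x$mean_curve, x$sd_curve))
}

#' @rdname tidy.no_model
#' @export
glance.no_model <- function(x, ...) {
  tibble::tibble(mean_degree = length(x$mean_curve) - 1L,
                 sd_degree = length(x$sd_curve) - 1L,
                 converged = x$converged)
}

#' Tidy a Box-Cox Cole-Green norming model
#'
#' @param x A `bccg_model`.
#' @param ... Unused.
#' @return Tibble with one row per curve coefficient.
#' @export
tidy.bccg_model <- function(x, ...) {
  tibble::tibble(
    curve = c(rep("mu", length(x$mu_curve)),
              rep("sigma", length(x$sigma_curve)),
              rep("lambda", length(x$lambda_curve))),
    power = c(seq_along(x$mu_curve), seq_along(x$sigma_curve),
              seq_along(x$lambda_curve)) - 1L,
    estimate = c(x$mu_curve, x$sigma_curve, x$lambda_curve))
}

#' @rdname tidy.bccg_model
#' @export
glance.bccg_model <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, shift = x$shift,
                 converged = x$converged)
}
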