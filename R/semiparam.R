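#' Normal rank transformation to T-scores
#'
#' Conventional norming within one group: mid-ranks for ties, percentile
#' `p = (rank - 0.5) / n` (the RankIt plotting position), then
#' `T = 50 + 10 * qnorm(p)`. Output order matches input order.
#'
#' @param values Raw scores of one group (length >= 2).
#' @return T-scores, same length and order as `values`.
#' @export
#' @examples
#' normal_rank_transform(c(3, 1, 2))       # 56.7, 43.3, 50
normal_rank_transform <- function(values) {
  n <- length(values)
  if (n < 2L) stop("normal_rank_transform needs at least 2 values per group")
  r <- rank(values, ties.method = "average")
  50 + 10 * stats::qnorm((r - 0.5) / n)
}

#' Attach observed locations to a person table
#'
#' Applies [normal_rank_transform()] to the raw scores within each age group
#' and stores the result as the observed location `l` (a T-score). The group
#' midpoint age is attached as `age_mid`: the location is a group-level rank
#' statistic, so it is paired with the group's age value in the regression.
#'
#' @param persons Person tibble with `raw` and `group`.
#' @return The tibble with columns `l` and `age_mid` added.
#' @export
rank_sample <- function(persons) {
  stopifnot(all(c("raw", "group") %in% names(persons)),
            !anyNA(persons$raw))
  persons |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(l = normal_rank_transform(.data$raw)) |>
    dplyr::ungroup() |>
    dplyr::mutate(age_mid = as.numeric(.data$group))
}

#' Polynomial term grid
#'
#' All powers `(s, t)` with `0 <= s, t <= k`, excluding `(0, 0)` (the
#' intercept is handled separately), in canonical order: increasing `s`,
#' then increasing `t`. Length `k^2 + 2k` (24 for `k = 4`).
#'
#' @param k Maximum power of location and age.
#' @return Tibble with columns `s` (power of location) and `t` (power of age).
#' @export
poly_term_grid <- function(k = 4) {
  stopifnot(k >= 1)
  g <- expand.grid(t = 0:k, s = 0:k)[, c("s", "t")]
  g <- g[!(g$s == 0 & g$t == 0), ]
  g <- g[order(g$s, g$t), ]
  tibble::as_tibble(g)
}

#' Build the polynomial design matrix
#'
#' Column `j` holds `l^s * age^t` for the j-th term of [poly_term_grid()].
#'
#' @param l Observed locations (T-scores).
#' @param age Ages (group midpoints in the standard workflow).
#' @param k Maximum power.
#' @return Numeric matrix with `k^2 + 2k` named columns (`l{s}a{t}`).
#' @export
build_design <- function(l, age, k = 4) {
  g <- poly_term_grid(k)
  X <- mapply(function(s, t) l^s * age^t, g$s, g$t)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  colnames(X) <- paste0("l", g$s, "a", g$t)
  X
}

# Exact best-subset search on precomputed correlation cross-products.
# Returns indices of the R^2-maximal subset of exactly m predictors.
# Exhaustive enumeration when feasible, otherwise a branch-and-bound with
# the bound R^2(partial set + all remaining candidates); both are exact and
# both enumerate candidates in canonical order, so ties keep the first
# (canonically smallest) subset.
subset_r2 <- function(C, id, p1) {
  b <- tryCatch(solve(C[id, id, drop = FALSE], C[id, p1]),
                error = function(e) NULL)
  if (is.null(b)) return(-Inf)
  sum(b * C[id, p1]) / C[p1, p1]
}

best_subset_indices <- function(C, m, exhaustive_limit = 3e5) {
  p <- nrow(C) - 1L
  p1 <- p + 1L
  if (m >= p) return(seq_len(p))
  if (choose(p, m) <= exhaustive_limit) {
    combos <- utils::combn(p, m)
    best <- -Inf; bi <- combos[, 1]
    for (j in seq_len(ncol(combos))) {
      r2 <- subset_r2(C, combos[, j], p1)
      if (r2 > best) { best <- r2; bi <- combos[, j] }
    }
    return(bi)
  }
  # branch and bound, depth-first in lexicographic order
  best <- -Inf; bi <- seq_len(m)
  rec <- function(chosen, nxt) {
    need <- m - length(chosen)
    if (need == 0L) {
      r2 <- subset_r2(C, chosen, p1)
      if (r2 > best) { best <<- r2; bi <<- chosen }
      return(invisible())
    }
    if (p - nxt + 1L < need) return(invisible())
    pool <- c(chosen, nxt:p)
    if (subset_r2(C, pool, p1) <= best) return(invisible())
    for (j in nxt:(p - need + 1L)) {
      rec(c(chosen, j), j + 1L)
    }
    invisible()
  }
  rec(integer(0), 1L)
  bi
}

#' Best-subset polynomial fit
#'
#' Among all subsets of exactly `n_terms` predictors, returns the ordinary
#' least-squares fit (intercept always included) with maximal coefficient of
#' determination. The search is exact; candidate subsets are enumerated in
#' canonical term order, so ties keep the canonically first subset. The
#' search runs on standardized cross-products for numerical stability; the
#' returned coefficients are refit on the original scale.
#'
#' @param X Design matrix from [build_design()].
#' @param y Raw-score vector.
#' @param n_terms Number of predictors to select.
#' @return A list with `term_idx`, `terms` (rows of [poly_term_grid()]),
#'   `intercept`, `coefficients`, `r2`, `rank_deficient`.
#' @export
best_subset_fit <- function(X, y, n_terms) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  p <- ncol(X)
  if (n_terms < 1 || n_terms > p) stop("n_terms must be between 1 and ncol(X)")
  if (nrow(X) < n_terms + 1) stop("need at least n_terms + 1 observations")
  syy <- sum((y - mean(y))^2)
  if (syy == 0) {
    return(list(term_idx = integer(0),
                terms = poly_term_grid(max(1, round(sqrt(p + 1)) - 1))[0, ],
                intercept = mean(y),
                coefficients = stats::setNames(numeric(0), character(0)),
                r2 = 0, rank_deficient = FALSE))
  }
  sds <- apply(X, 2, stats::sd)
  keep_sd <- ifelse(sds > 0, sds, 1)
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, keep_sd, "/")
  ys <- y - mean(y)
  C <- crossprod(cbind(Xs, ys)) / (length(y) - 1)
  bi <- sort(best_subset_indices(C, n_terms))
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, bi, drop = FALSE]), y)
  cf <- fit$coefficients
  rank_def <- anyNA(cf) || fit$rank < n_terms + 1
  if (rank_def) {
    warning("rank-deficient subset; missing coefficients set to zero")
    cf[is.na(cf)] <- 0
  }
  r2 <- 1 - sum(fit$residuals^2) / syy
  k <- round(sqrt(p + 1)) - 1
  list(term_idx = bi,
       terms = poly_term_grid(k)[bi, ],
       intercept = unname(cf[1]),
       coefficients = cf[-1],
       r2 = r2,
       rank_deficient = rank_def)
}

new_semiparam_model <- function(fit, k, ranked) {
  lr <- tapply(ranked$l, ranked$group, range)
  structure(
    list(k = k,
         n_terms = length(fit$term_idx),
         terms = fit$terms,
         intercept = fit$intercept,
         coefficients = fit$coefficients,
         r2 = fit$r2,
         monotone = NA,
         rank_deficient = fit$rank_deficient,
         data_range = list(
           l = range(ranked$l),
           age = range(ranked$age_mid),
           raw = range(ranked$raw),
           groups = sort(unique(ranked$age_mid)),
           l_by_group = lr),
         n = nrow(ranked)),
    class = "semiparam_model")
}

#' Predicted raw score of a semi-parametric model
#'
#' Plain polynomial evaluation `intercept + sum c_st l^s age^t`; no clamping.
#'
#' @param model A `semiparam_model`.
#' @param l Locations (T-scores), vectorized.
#' @param age Ages, vectorized (recycled against `l`).
#' @return Continuous expected raw scores.
#' @export
predict_raw <- function(model, l, age) {
  stopifnot(inherits(model, "semiparam_model"))
  n <- max(length(l), length(age))
  l <- rep_len(l, n); age <- rep_len(age, n)
  out <- rep(model$intercept, n)
  tm <- model$terms
  cf <- unname(model$coefficients)
  for (j in seq_len(nrow(tm)))
    out <- out + cf[j] * l^tm$s[j] * age^tm$t[j]
  out
}

#' Check a fitted norming surface for monotonicity violations
#'
#' Percentile curves must not cross: at every age, the predicted raw score
#' has to grow with the location `l`. Two notions are offered.
#'
#' With `strict = TRUE`, predictions on a fine location grid must strictly
#' increase at every evaluated age (a flat, location-free model fails).
#'
#' The default (`strict = FALSE`) is the criterion used during model
#' selection: within each age group's observed location range, predictions
#' clamped to the observed score range must cross each achievable integer raw
#' score at most once, i.e. the model must assign a unique location to every
#' achievable score. Sub-score-resolution wiggle in saturated floor/ceiling
#' regions, where the curve is necessarily flat, does not count as a
#' violation, while genuinely crossing percentile curves do.
#'
#' @param model A `semiparam_model`.
#' @param strict Use the strict increasing-grid criterion?
#' @param grid_points Grid resolution along the location axis.
#' @return A list with `monotone` (logical) and `violations` (tibble with
#'   `age` and the location at which the first violation occurs).
#' @export
check_monotonicity <- function(model, strict = FALSE, grid_points = 200) {
  stopifnot(inherits(model, "semiparam_model"))
  ages <- model$data_range$groups
  viol <- list()
  if (strict) {
    lg <- seq(model$data_range$l[1], model$data_range$l[2],
              length.out = grid_points)
    for (a in ages) {
      d <- diff(predict_raw(model, lg, a))
      if (any(d <= 0))
        viol[[length(viol) + 1]] <- tibble::tibble(age = a,
                                                   l = lg[which(d <= 0)[1]])
    }
  } else {
    rr <- model$data_range$raw
    levels <- seq(ceiling(rr[1]), floor(rr[2]))
    for (i in seq_along(ages)) {
      lr <- model$data_range$l_by_group[[i]]
      lg <- seq(lr[1], lr[2], length.out = grid_points)
      p_raw <- predict_raw(model, lg, ages[i])
      if (p_raw[length(p_raw)] <= p_raw[1]) {  # no net increase over the range
        viol[[length(viol) + 1]] <- tibble::tibble(age = ages[i], l = lr[1],
                                                   raw_level = NA_real_)
        next
      }
      p <- pmin(pmax(p_raw, rr[1]), rr[2])
      for (r in levels) {
        sg <- sign(p - r); sg <- sg[sg != 0]
        if (length(sg) > 1 && sum(diff(sg) != 0) > 1) {
          viol[[length(viol) + 1]] <- tibble::tibble(age = ages[i], l = NA_real_,
                                                     raw_level = r)
          break
        }
      }
    }
  }
  list(monotone = length(viol) == 0,
       violations = if (length(viol)) dplyr::bind_rows(viol)
                    else tibble::tibble(age = numeric(0), l = numeric(0)))
}

#' Fit a semi-parametric continuous norming model
#'
#' The selection rule: fit the best 4-term model; if it violates
#' monotonicity (see [check_monotonicity()]), try 3 terms, then 5, 6, ... up
#' to the full `k^2 + 2k` terms, returning the first monotone model. If no
#' term count yields a monotone model, the full model is returned with
#' `monotone = FALSE`.
#'
#' @param ranked Output of [rank_sample()] (needs `l`, `age_mid`, `raw`).
#' @param k Maximum polynomial power (smoothing degree), default 4.
#' @param default_terms Term count tried first, default 4.
#' @return A `semiparam_model` with `n_terms` and `monotone` recorded.
#' @export
#' @examples
#' s <- draw_normative_sample(100, seed = 7) |>
#'   simulate_raw_scores(make_scale("medium"), seed = 8) |>
#'   rank_sample()
#' m <- select_model(s)
#' m$n_terms
select_model <- function(ranked, k = 4, default_terms = 4) {
  stopifnot(all(c("l", "age_mid", "raw") %in% names(ranked)))
  X <- build_design(ranked$l, ranked$age_mid, k)
  max_terms <- ncol(X)
  counts <- unique(c(default_terms, default_terms - 1, setdiff(
    seq(default_terms + 1, max_terms), default_terms)))
  counts <- counts[counts >= 1 & counts <= max_terms]
  last <- NULL
  for (m in counts) {
    fit <- best_subset_fit(X, ranked$raw, m)
    mod <- new_semiparam_model(fit, k, ranked)
    chk <- check_monotonicity(mod)
    mod$monotone <- chk$monotone
    if (chk$monotone) return(mod)
    last <- mod
  }
  last
}

#' Convert a raw score into a norm score by inverting the model
#'
#' Searches the T-window `[20, 80]` on a 0.01 grid for the location whose
#' predicted raw score equals the target, with linear interpolation between
#' bracketing grid points. A raw score below (above) the window's predicted
#' range returns the window bound 20 (80). For a model that is not monotone
#' over the window, the smallest bracketing location is returned and the
#' attribute `"warning"` is set on the result.
#'
#' This continuous inversion round-trips with [predict_raw()] on monotone
#' models. For scoring integer raw scores against rank-based norms use
#' [norm_assignment()], which respects the mid-rank tie convention.
#'
#' @param model A `semiparam_model`.
#' @param raw Raw scores (continuous allowed), vectorized.
#' @param age Ages, vectorized (recycled).
#' @param window Search window in T-scores.
#' @param step Grid step.
#' @return Norm scores (T), with attribute `warning = TRUE` if a non-monotone
#'   window was encountered.
#' @export
predict_norm <- function(model, raw, age, window = c(20, 80), step = 0.01) {
  stopifnot(inherits(model, "semiparam_model"), all(is.finite(raw)))
  n <- max(length(raw), length(age))
  raw <- rep_len(raw, n); age <- rep_len(age, n)
  lg <- seq(window[1], window[2], by = step)
  out <- numeric(n)
  warn <- FALSE
  for (a in unique(age)) {
    i <- age == a
    p <- predict_raw(model, lg, a)
    if (any(diff(p) < 0)) { warn <- TRUE; p <- cummax(p) }
    out[i] <- stats::approx(p, lg, xout = raw[i], ties = min, rule = 2)$y
  }
  if (warn) attr(out, "warning") <- TRUE
  out
}

#' Model-implied norm assignment for integer raw scores
#'
#' Builds the raw-to-norm table the model implies at given ages, using the
#' same tie convention as conventional norming: the model's percentile
#' curves define, for every achievable score `r`, the location thresholds at
#' the half-scores `r - 0.5` and `r + 0.5`; the cumulative proportions at
#' those thresholds (under the T-score metric, `Phi((l - 50)/10)`) delimit
#' the probability block of `r`, and `r` is assigned the T-score of the
#' block's midpoint, `50 + 10 * qnorm((F(r-1) + F(r)) / 2)`. This is the
#' model analogue of assigning mid-rank percentiles to tied scores and is
#' the convention under which fitted norms are comparable to rank-based
#' (ideal) norms. Results are clamped to T in `[20, 80]`.
#'
#' @param model A `semiparam_model`.
#' @param ages Ages at which to tabulate (default: the fitted group ages).
#' @param score_range Integer score range to tabulate (default: the observed
#'   raw range of the normative sample).
#' @param window Location window searched for thresholds.
#' @return A tibble with columns `age`, `raw`, `T`.
#' @export
norm_assignment <- function(model, ages = NULL, score_range = NULL,
                            window = c(20, 80)) {
  stopifnot(inherits(model, "semiparam_model"))
  if (is.null(ages)) ages <- model$data_range$groups
  if (is.null(score_range)) score_range <- model$data_range$raw
  mn <- ceiling(score_range[1]); mx <- floor(score_range[2])
  lg <- seq(window[1], window[2], by = 0.1)
  rows <- vector("list", length(ages))
  for (j in seq_along(ages)) {
    p <- cummax(pmin(pmax(predict_raw(model, lg, ages[j]), mn), mx))
    thr <- stats::approx(p, lg, xout = seq(mn, mx - 1) + 0.5,
                         ties = min, rule = 2)$y
    Fh <- c(stats::pnorm((thr - 50) / 10), 1)
    Flo <- c(0, Fh[-length(Fh)])
    Tm <- 50 + 10 * stats::qnorm((Flo + Fh) / 2)
    rows[[j]] <- tibble::tibble(age = ages[j], raw = mn:mx,
                                T = pmin(pmax(Tm, window[1]), window[2]))
  }
  dplyr::bind_rows(rows)
}

#' Export a norm table
#'
#' Tabulates [norm_assignment()] over a user grid of ages and writes it as
#' CSV with columns `age`, `raw`, `T`.
#'
#' @inheritParams norm_assignment
#' @param path Optional CSV path; when `NULL` the table is only returned.
#' @return The norm-table tibble, invisibly when written.
#' @export
norm_table <- function(model, ages = NULL, score_range = NULL, path = NULL) {
  tab <- norm_assignment(model, ages, score_range)
  if (!is.null(path)) {
    readr::write_csv(tab, path)
    return(invisible(tab))
  }
  tab
}

#' @export
print.semiparam_model <- function(x, ...) {
  cat("<semiparam_model> k =", x$k, "\n")
  cat("  terms:", paste0("l^", x$terms$s, " a^", x$terms$t, collapse = ", "),
      "\n")
  cat("  n_terms =", x$n_terms, " R^2 =", signif(x$r2, 5),
      " monotone =", x$monotone, "\n")
  invisible(x)
}

#' Serialize a semi-parametric model to JSON
#'
#' @param model A `semiparam_model`.
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "semiparam_model"))
  obj <- list(k = model$k, n_terms = model$n_terms,
              s = model$terms$s, t = model$terms$t,
              intercept = model$intercept,
              coefficients = unname(model$coefficients),
              r2 = model$r2, monotone = model$monotone,
              rank_deficient = model$rank_deficient,
              data_range = list(l = model$data_range$l,
                                age = model$data_range$age,
                                raw = model$data_range$raw,
                                groups = model$data_range$groups,
                                l_by_group = unname(lapply(
                                  model$data_range$l_by_group, as.numeric))),
              n = model$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(k = obj$k, n_terms = obj$n_terms,
         terms = tibble::tibble(s = obj$s, t = obj$t),
         intercept = obj$intercept,
         coefficients = obj$coefficients,
         r2 = obj$r2, monotone = obj$monotone,
         rank_deficient = obj$rank_deficient,
         data_range = list(l = obj$data_range$l,
                           age = obj$data_range$age,
                           raw = obj$data_range$raw,
                           groups = obj$data_range$groups,
                           l_by_group = lapply(seq_len(nrow(obj$data_range$l_by_group)),
                                               function(i) obj$data_range$l_by_group[i, ])),
         n = obj$n),
    class = "semiparam_model")
}
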