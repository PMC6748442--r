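#' Configuration of a simulation study
#'
#' Full design of the Monte-Carlo comparison: sample sizes per age group,
#' scale difficulties, cycles per condition, cross-validation size, methods
#' and master seed. The published design uses 150 cycles per condition;
#' the default here is a desk-scale 20.
#'
#' @param sample_sizes Per-group sample sizes.
#' @param difficulties Scale labels.
#' @param cycles_per_condition Simulation cycles per (size, difficulty) cell.
#' @param crossval_n_per_level Cross-validation subjects per age level.
#' @param methods Subset of `c("semiparam", "no", "bccg")`.
#' @param master_seed Integer master seed; every per-cycle seed derives from
#'   it deterministically.
#' @param k Polynomial degree of the semi-parametric model.
#' @param restart_on_failure Restart a cycle (with a fresh derived seed) when
#'   a parametric fit fails? Off by default: failures are recorded instead.
#' @return A `study_config` list.
#' @export
study_config <- function(sample_sizes = c(50, 75, 100, 150, 250, 500, 1000),
                         difficulties = c("easy", "medium", "difficult"),
                         cycles_per_condition = 20,
                         crossval_n_per_level = 10000,
                         methods = c("semiparam", "no", "bccg"),
                         master_seed = 1,
                         k = 4,
                         restart_on_failure = FALSE) {
  stopifnot(cycles_per_condition >= 1, all(sample_sizes >= 10))
  methods <- match.arg(methods, c("semiparam", "no", "bccg"),
                       several.ok = TRUE)
  structure(
    list(sample_sizes = sample_sizes, difficulties = difficulties,
         cycles_per_condition = cycles_per_condition,
         crossval_n_per_level = crossval_n_per_level,
         methods = methods, master_seed = master_seed, k = k,
         restart_on_failure = restart_on_failure),
    class = "study_config")
}

#' Cross-validation sample with ideal norms for one scale
#'
#' Deterministic subjects via [build_crossval_sample()]; their raw scores are
#' simulated once per scale from a seed derived from the master seed, and
#' ideal norms attached. Cached by [run_study()] and reused across cycles
#' (results do not depend on the caching because the sample is a pure
#' function of scale and seed).
#'
#' @param scale A [make_scale()] object.
#' @param n_per_level Subjects per age level.
#' @param seed Seed for the raw-score simulation.
#' @param pop A [population_model()].
#' @return Cross-validation tibble with `raw` and `T_ideal`.
#' @export
crossval_for_scale <- function(scale, n_per_level = 10000, seed = 1,
                               pop = population_model()) {
  build_crossval_sample(n_per_level, pop) |>
    simulate_raw_scores(scale, seed = seed) |>
    ideal_norms()
}

#' Run one simulation cycle
#'
#' Draws a normative sample for the condition, simulates raw scores, fits
#' every configured method and scores each against the supplied
#' cross-validation sample. Deterministic given the seed. A parametric fit
#' failure is recorded in the results rather than silently restarted.
#'
#' @param scale A [make_scale()] object.
#' @param n_per_group Normative sample size per age group.
#' @param crossval Output of [crossval_for_scale()] for the same scale.
#' @param seed Cycle seed.
#' @param methods Methods to fit.
#' @param k Semi-parametric polynomial degree.
#' @param pop A [population_model()].
#' @return Tibble with one [score_model()] row per method, annotated with
#'   `scale`, `n_per_group`, `seed`.
#' @export
run_cycle <- function(scale, n_per_group, crossval, seed,
                      methods = c("semiparam", "no", "bccg"), k = 4,
                      pop = population_model()) {
  sample <- draw_normative_sample(n_per_group, pop, seed = seed) |>
    simulate_raw_scores(scale, seed = seed + 1)
  rows <- list()
  if ("semiparam" %in% methods) {
    ranked <- rank_sample(sample)
    mod <- select_model(ranked, k = k)
    rows$semiparam <- score_model(mod, crossval)
  }
  if ("no" %in% methods) {
    m <- tryCatch(fit_no(sample), error = function(e) NULL)
    rows$no <- if (is.null(m)) {
      tibble::tibble(method = "no", rmse = NA_real_, msd = NA_real_,
                     included = FALSE, n_terms = NA_integer_, r2 = NA_real_,
                     converged = FALSE, band_rmse = list(rep(NA_real_, 12)))
    } else score_model(m, crossval)
  }
  if ("bccg" %in% methods) {
    m <- with_seed_if(seed + 2, fit_bccg(sample))
    rows$bccg <- score_model(m, crossval)
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(scale = scale$label, n_per_group = n_per_group,
                  seed = seed, .before = 1)
}

#' Run the full simulation study
#'
#' Iterates every (difficulty, sample size) condition for the configured
#' number of cycles, with per-cycle seeds derived from the master seed. The
#' cross-validation sample of each scale is generated once and reused.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, per-cycle results
#'   (`cycles.csv`) and the aggregate table (`table.csv`) are written there
#'   incrementally.
#' @param progress Emit one progress line per condition to stderr?
#' @return A `study_results` list with `cycles` (per-cycle tibble),
#'   `table` (Table-2-style aggregate) and the config.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      progress = TRUE) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  n_cond <- length(config$difficulties) * length(config$sample_sizes)
  seeds <- derive_seeds(config$master_seed,
                        n_cond * config$cycles_per_condition + n_cond + 10)
  cv_seeds <- seeds[seq_along(config$difficulties)]
  cycle_seeds <- seeds[-seq_len(length(config$difficulties))]
  all_rows <- list()
  idx <- 0L
  for (d in seq_along(config$difficulties)) {
    scale <- make_scale(config$difficulties[d])
    cv <- crossval_for_scale(scale, config$crossval_n_per_level,
                             seed = cv_seeds[d])
    for (n in config$sample_sizes) {
      t0 <- Sys.time()
      for (cyc in seq_len(config$cycles_per_condition)) {
        idx <- idx + 1L
        res <- run_cycle(scale, n, cv, seed = cycle_seeds[idx],
                         methods = config$methods, k = config$k)
        if (config$restart_on_failure) {
          tries <- 0L
          while (any(!res$converged %in% c(TRUE, NA)) && tries < 10L) {
            tries <- tries + 1L
            res <- run_cycle(scale, n, cv,
                             seed = cycle_seeds[idx] + 1000L * tries,
                             methods = config$methods, k = config$k)
          }
        }
        res$cycle <- cyc
        all_rows[[idx]] <- res
      }
      if (progress)
        message(sprintf("condition %s n=%d: %d cycles in %.1fs",
                        scale$label, n, config$cycles_per_condition,
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
      if (!is.null(out_dir))
        readr::write_csv(flatten_cycles(dplyr::bind_rows(all_rows)),
                         file.path(out_dir, "cycles.csv"))
    }
  }
  cycles <- dplyr::bind_rows(all_rows)
  tab <- study_table(cycles)
  if (!is.null(out_dir))
    readr::write_csv(tab, file.path(out_dir, "table.csv"))
  structure(list(cycles = cycles, table = tab, config = config),
            class = "study_results")
}

flatten_cycles <- function(cycles) {
  bands <- do.call(rbind, cycles$band_rmse)
  colnames(bands) <- sprintf("band_%02d", 1:12)
  dplyr::bind_cols(dplyr::select(cycles, -"band_rmse"),
                   tibble::as_tibble(bands))
}

#' Aggregate per-cycle results into the summary table
#'
#' Cleaned (RMSE < 10, converged) per-condition means of RMSE and MSD per
#' method, in a wide layout: one row per (scale, method, metric), one column
#' per sample size, plus an `overall` column holding the unweighted mean of
#' the per-size cells, and an inclusion row in percent.
#'
#' @param cycles Per-cycle tibble from [run_study()].
#' @return A tibble mirroring the published table layout.
#' @export
study_table <- function(cycles) {
  cleaned <- clean_results(cycles)
  base <- cycles |>
    dplyr::distinct(.data$scale, .data$method, .data$n_per_group) |>
    dplyr::left_join(
      cleaned |>
        dplyr::group_by(.data$scale, .data$method, .data$n_per_group) |>
        dplyr::summarise(RMSE = mean(.data$rmse), MSD = mean(.data$msd),
                         .groups = "drop"),
      by = c("scale", "method", "n_per_group")) |>
    dplyr::left_join(
      cycles |>
        dplyr::group_by(.data$scale, .data$method, .data$n_per_group) |>
        dplyr::summarise(Included = 100 * mean(.data$included),
                         .groups = "drop"),
      by = c("scale", "method", "n_per_group"))
  long <- base |>
    tidyr::pivot_longer(c("Included", "RMSE", "MSD"), names_to = "metric") |>
    tidyr::pivot_wider(names_from = "n_per_group", values_from = "value",
                       names_prefix = "n")
  size_cols <- grep("^n\\d+$", names(long), value = TRUE)
  long$overall <- rowMeans(long[size_cols])
  long |>
    dplyr::arrange(.data$scale,
                   match(.data$method, c("semiparam", "no", "bccg")),
                   match(.data$metric, c("Included", "RMSE", "MSD")))
}

#' Distribution of selected term counts
#'
#' Fraction of semi-parametric cycles per selected term count, with the
#' cumulative shares of the parsimonious (3 or 4 terms) and the fallback
#' (full model) outcomes.
#'
#' @param cycles Per-cycle tibble from [run_study()] (or a `study_results`).
#' @return A list with `distribution` (tibble of `n_terms`, `share`),
#'   `share_3_4` and `share_max`.
#' @export
summarize_terms <- function(cycles) {
  if (inherits(cycles, "study_results")) cycles <- cycles$cycles
  semi <- cycles[cycles$method == "semiparam" & !is.na(cycles$n_terms), ]
  if (nrow(semi) == 0) stop("no semi-parametric results present")
  tab <- semi |>
    dplyr::count(.data$n_terms) |>
    dplyr::mutate(share = .data$n / sum(.data$n))
  kmax <- max(24, max(semi$n_terms))
  list(distribution = tab,
       share_3_4 = sum(tab$share[tab$n_terms %in% c(3, 4)]),
       share_max = sum(tab$share[tab$n_terms >= kmax]))
}

#' Band-wise RMSE profile
#'
#' Mean RMSE per five-point band of `T_ideal` across cycles, per method and
#' scale: the ability-resolved error profile (U-shaped for the
#' semi-parametric method).
#'
#' @param cycles Per-cycle tibble or `study_results`.
#' @return Tibble with `scale`, `method`, `band` (1-12), `band_mid`, `rmse`.
#' @export
band_profile <- function(cycles) {
  if (inherits(cycles, "study_results")) cycles <- cycles$cycles
  cleaned <- clean_results(cycles)
  bands <- do.call(rbind, cleaned$band_rmse)
  out <- list()
  for (sc in unique(cleaned$scale)) {
    for (m in unique(cleaned$method)) {
      i <- cleaned$scale == sc & cleaned$method == m
      if (!any(i)) next
      bm <- colMeans(bands[i, , drop = FALSE], na.rm = TRUE)
      out[[length(out) + 1]] <- tibble::tibble(
        scale = sc, method = m, band = 1:12,
        band_mid = band_breaks[-13] + 2.5, rmse = bm)
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.study_results <- function(x, ...) {
  cat("<study_results>", nrow(x$cycles), "method-cycles,",
      length(x$config$sample_sizes) * length(x$config$difficulties),
      "conditions\n")
  print(x$table, n = 20)
  invisible(x)
}
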