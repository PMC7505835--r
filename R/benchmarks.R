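#' Normalized unique-to-unlogged richness curve
#'
#' The fraction of the observed unique-to-unlogged richness expected to be
#' maintained when a proportion `p` of the disturbed area is retained
#' unlogged: `unique_unlogged_curve(p * T1) / unique_unlogged_curve(T1)`.
#' Runs from 0 at `p = 0` to 1 at `p = 1`. Undefined (NA, with status handled
#' by [compute_benchmarks()]) when the dataset has no unique-to-unlogged
#' species.
#'
#' @param paired A [pair_datasets()] object.
#' @param p Retention proportion(s) in [0, 1].
#' @return Fraction(s) in [0, 1], or NA if the unique class is empty.
#' @export
normalized_unique_curve <- function(paired, p) {
  stopifnot(inherits(paired, "paired_dataset"))
  if (any(p < 0) || any(p > 1)) stop("p must lie in [0, 1].")
  T1 <- n_plots_unlogged(paired)
  denom <- unique_unlogged_curve(paired, T1)
  if (denom == 0) return(rep(NA_real_, length(p)))
  unique_unlogged_curve(paired, p * T1) / denom
}

#' Retention proportion needed for a target fraction of unique richness
#'
#' Inverts the normalized unique-richness curve: the smallest retention
#' proportion p* with `normalized_unique_curve(p*) >= q`, found by bisection
#' on the continuous curve (grid-free, so p* does not depend on any plotting
#' grid). The curve is continuous and strictly increasing from 0 to 1, so the
#' root exists and is unique for any q in (0, 1).
#'
#' @param paired A [pair_datasets()] object.
#' @param q Target fraction in (0, 1); default 0.90.
#' @param tol Tolerance on the fraction scale: the result satisfies
#'   `|normalized_unique_curve(p*) - q| <= tol` (default 1e-6).
#' @return p* in [0, 1], or NA when the unique class is empty.
#' @export
retention_for_fraction <- function(paired, q = 0.9, tol = 1e-6) {
  if (q <= 0 || q >= 1) stop("q must lie strictly inside (0, 1).")
  f <- function(p) normalized_unique_curve(paired, p) - q
  f0 <- f(0)
  if (is.na(f0)) return(NA_real_)
  lo <- 0; hi <- 1
  flo <- f0
  # bisection with a bound on the function residual, not just the bracket
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol * 0.5) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    if (hi - lo < .Machine$double.eps * 4) break
  }
  (lo + hi) / 2
}

#' Fraction of unique richness maintained at a given retention level
#'
#' Companion statistic to [retention_for_fraction()]: the normalized
#' unique-to-unlogged curve evaluated at retention `p` (default 0.5, i.e.
#' salvage logging half of the disturbed area).
#'
#' @param paired A [pair_datasets()] object.
#' @param p Retention proportion; default 0.5.
#' @return Fraction in [0, 1], or NA when the unique class is empty.
#' @export
unique_fraction_at_retention <- function(paired, p = 0.5) {
  normalized_unique_curve(paired, p)
}

#' Benchmarks for one paired dataset
#'
#' @param paired A [pair_datasets()] object.
#' @param q Target fraction for the retention benchmark (default 0.90).
#' @param p_eval Retention level for the companion fraction (default 0.5).
#' @param tol Bisection tolerance, see [retention_for_fraction()].
#' @return A one-row tibble: `dataset_id, p_star, frac_at_half, n_unique,
#'   T_unlogged, T_logged, status` (`ok` or `undefined_no_unique_species`).
#' @export
compute_benchmarks <- function(paired, q = 0.9, p_eval = 0.5, tol = 1e-6) {
  part <- partition_species(paired)
  n_unique <- sum(part$class == "unique_unlogged")
  if (n_unique == 0L) {
    return(tibble::tibble(
      dataset_id = paired$meta$dataset_id, p_star = NA_real_,
      frac_at_half = NA_real_, n_unique = 0L,
      T_unlogged = n_plots_unlogged(paired),
      T_logged = n_plots_logged(paired),
      status = "undefined_no_unique_species"
    ))
  }
  tibble::tibble(
    dataset_id = paired$meta$dataset_id,
    p_star = retention_for_fraction(paired, q = q, tol = tol),
    frac_at_half = unique_fraction_at_retention(paired, p = p_eval),
    n_unique = n_unique,
    T_unlogged = n_plots_unlogged(paired),
    T_logged = n_plots_logged(paired),
    status = "ok"
  )
}

#' Summarize benchmarks across datasets by a grouping variable
#'
#' Unweighted mean and sample standard deviation (n - 1 denominator) of each
#' benchmark across datasets within each level of the grouping variable; each
#' species matrix contributes one equally weighted value. Datasets with an
#' undefined benchmark are excluded (their count is reported via message).
#'
#' @param benchmarks Tibble from [compute_benchmarks()] rows.
#' @param metadata Tibble of [study_metadata()] rows (one per dataset).
#' @param grouping One of `"all"`, `"disturbance_type"`, `"saproxylic"`,
#'   `"taxon_group"`, `"year"` (integer years since disturbance).
#' @param weight_by_study When TRUE, datasets are first averaged within
#'   `study_id` so each study (not each matrix) contributes one value per
#'   level; off by default.
#' @return A tibble with columns `grouping, level, statistic, n, mean, sd`;
#'   `sd` is NA for single-dataset levels.
#' @export
summarize_benchmarks <- function(benchmarks, metadata,
                                 grouping = c("all", "disturbance_type",
                                              "saproxylic", "taxon_group",
                                              "year"),
                                 weight_by_study = FALSE) {
  grouping <- match.arg(grouping)
  df <- dplyr::inner_join(benchmarks, metadata, by = "dataset_id")
  n_undef <- sum(df$status != "ok")
  if (n_undef > 0)
    message(n_undef, " dataset(s) with undefined benchmarks excluded from summaries.")
  df <- dplyr::filter(df, .data$status == "ok")
  if (!nrow(df)) {
    warning("No datasets with defined benchmarks; empty summary.")
    return(tibble::tibble(grouping = character(), level = character(),
                          statistic = character(), n = integer(),
                          mean = double(), sd = double()))
  }
  df$level <- switch(grouping,
    all = "all",
    disturbance_type = df$disturbance_type,
    saproxylic = ifelse(df$saproxylic, "saproxylic", "non_saproxylic"),
    taxon_group = df$taxon_group,
    year = as.character(as.integer(round(df$years_since_disturbance)))
  )
  long <- df |>
    tidyr::pivot_longer(c("p_star", "frac_at_half"),
                        names_to = "statistic", values_to = "value")
  if (weight_by_study) {
    long <- long |>
      dplyr::group_by(.data$level, .data$statistic, .data$study_id) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  long |>
    dplyr::group_by(.data$level, .data$statistic) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(grouping = grouping, .before = 1) |>
    dplyr::arrange(.data$statistic, .data$level)
}

#' Run the full benchmark pipeline on a collection of paired datasets
#'
#' For every dataset: mixture decomposition, retention benchmark p* at target
#' `q`, fraction of unique richness maintained at retention `p_eval`; then
#' group summaries over all grouping variables and (when enough datasets have
#' defined benchmarks) beta regressions of both benchmarks on years since
#' disturbance. Deterministic given inputs and config. When `out_dir` is
#' given, writes `benchmarks.csv`, `summaries.csv`, `curves.csv`,
#' `regression.json`-style report (as CSV of coefficients plus a text
#' summary) and `run.log`.
#'
#' @param collection Named list of [pair_datasets()] objects.
#' @param config List of options: `q_target` (0.9), `p_eval` (0.5), `n_grid`
#'   (201), `bisect_tol` (1e-6), `extrapolation_policy` ("unique_logged"),
#'   `weight_by_study` (FALSE; when TRUE group means weight each study
#'   equally instead of each dataset), `regression_covariates` (character;
#'   default `c("disturbance_type", "saproxylic")`), `df_smooth` (4).
#' @param out_dir Optional output directory.
#' @return List with `benchmarks`, `summaries`, `curves`, `regressions`
#'   (list of `beta_gam` fits or NULL), `log` (character).
#' @export
run_pipeline <- function(collection, config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(list(
    q_target = 0.9, p_eval = 0.5, n_grid = 201L, bisect_tol = 1e-6,
    extrapolation_policy = "unique_logged", weight_by_study = FALSE,
    regression_covariates = c("disturbance_type", "saproxylic"),
    df_smooth = 4L
  ), config)
  if (!length(collection)) stop("Empty dataset collection.")
  logs <- character()
  note <- function(...) logs <<- c(logs, sprintf(...))

  metadata <- purrr::map_dfr(collection, ~ .x$meta)
  benchmarks <- purrr::map_dfr(
    collection, compute_benchmarks,
    q = cfg$q_target, p_eval = cfg$p_eval, tol = cfg$bisect_tol
  )
  purrr::walk2(benchmarks$dataset_id, benchmarks$status,
               ~ note("dataset %s: %s", .x, .y))
  if (all(benchmarks$status != "ok"))
    stop("All datasets invalid/undefined: ",
         paste(unique(benchmarks$status), collapse = ", "))

  curves <- purrr::map_dfr(collection, function(pd) {
    dec <- compute_mixture_decomposition(
      pd, n_grid = cfg$n_grid, extrapolation_policy = cfg$extrapolation_policy)
    dplyr::mutate(tibble::as_tibble(dec), dataset_id = pd$meta$dataset_id,
                  .before = 1)
  })

  groupings <- c("all", "disturbance_type", "saproxylic", "taxon_group", "year")
  summaries <- purrr::map_dfr(
    groupings,
    ~ suppressMessages(summarize_benchmarks(
        benchmarks, metadata, grouping = .x,
        weight_by_study = cfg$weight_by_study))
  )

  reg_data <- dplyr::inner_join(benchmarks, metadata, by = "dataset_id") |>
    dplyr::filter(.data$status == "ok")
  regressions <- NULL
  if (nrow(reg_data) >= 10) {
    regressions <- purrr::map(
      c(p_star = "p_star", frac_at_half = "frac_at_half"),
      function(resp) {
        tryCatch(
          fit_beta_gam(reg_data, response = resp,
                       years_col = "years_since_disturbance",
                       covariates = cfg$regression_covariates,
                       df_smooth = cfg$df_smooth),
          error = function(e) {
            note("regression on %s failed: %s", resp, conditionMessage(e))
            NULL
          })
      })
  } else {
    note("fewer than 10 datasets with defined benchmarks; regression skipped")
  }

  out <- list(benchmarks = benchmarks, summaries = summaries, curves = curves,
              regressions = regressions, log = logs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(benchmarks, file.path(out_dir, "benchmarks.csv"))
    readr::write_csv(summaries, file.path(out_dir, "summaries.csv"))
    readr::write_csv(curves, file.path(out_dir, "curves.csv"))
    if (!is.null(regressions)) {
      reg_tbl <- purrr::imap_dfr(regressions, function(fit, nm) {
        if (is.null(fit)) return(tibble::tibble())
        dplyr::mutate(glance(fit), response = nm, .before = 1)
      })
      readr::write_csv(reg_tbl, file.path(out_dir, "regression.csv"))
    }
    writeLines(logs, file.path(out_dir, "run.log"))
  }
  out
}
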