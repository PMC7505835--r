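#' Partition pooled species into unique and shared classes
#'
#' Classification is at the reference-sample level: a species is unique to
#' the unlogged habitat when it was detected in at least one unlogged plot
#' and in no logged plot, and vice versa; species detected in both are
#' shared. The classes stay fixed while mixture curves track how much of each
#' class a mixed subsample is expected to detect, so at full retention the
#' unique-to-unlogged curve equals the observed count of unique species.
#'
#' @param paired A [pair_datasets()] object.
#' @return A tibble with columns `species`, `q_unlogged`, `q_logged`, `class`
#'   (factor: `unique_unlogged`, `unique_logged`, `shared`).
#' @export
partition_species <- function(paired) {
  stopifnot(inherits(paired, "paired_dataset"))
  dplyr::mutate(
    paired$incidence,
    class = factor(
      dplyr::case_when(
        .data$q_logged == 0L ~ "unique_unlogged",
        .data$q_unlogged == 0L ~ "unique_logged",
        TRUE ~ "shared"
      ),
      levels = c("unique_unlogged", "unique_logged", "shared")
    )
  )
}

#' Expected richness of species unique to the unlogged habitat
#'
#' Rarefaction of the unique-to-unlogged class only: the expected number of
#' observed unique species detected in `t1` plots drawn from the T1 unlogged
#' reference plots. This is the headline curve — it never requires
#' extrapolation because `t1 <= T1` by construction, rises from 0 at
#' `t1 = 0` to the observed unique count at `t1 = T1`, and is strictly
#' increasing whenever the class is non-empty.
#'
#' @param paired A [pair_datasets()] object.
#' @param t1 Real number of retained unlogged plots in [0, T1]; vectorized.
#' @return Expected unique-to-unlogged richness, one value per `t1`.
#' @export
unique_unlogged_curve <- function(paired, t1) {
  stopifnot(inherits(paired, "paired_dataset"))
  T1 <- n_plots_unlogged(paired)
  if (any(t1 < 0) || any(t1 > T1)) stop("t1 must lie in [0, T1].")
  part <- partition_species(paired)
  q <- part$q_unlogged[part$class == "unique_unlogged"]
  if (!length(q)) return(rep(0, length(t1)))
  vapply(t1, function(tt) sum(1 - miss_probability(T1, q, tt)), numeric(1))
}

#' Mixture components at one retention level
#'
#' The mixture keeps the total sample size fixed at T1: retaining `t1`
#' unlogged plots means the remaining `t2 = T1 - t1` plots are replaced by
#' plots drawn from the logged habitat. Expected richness decomposes over the
#' fixed species classes, with detection independent between habitats:
#' \itemize{
#'   \item unique_unlogged: `sum over class of 1 - mU(i, t1)`
#'   \item unique_logged:   `sum over class of 1 - mL(i, t2)`
#'   \item shared:          `sum over class of 1 - mU(i, t1) * mL(i, t2)`
#' }
#' where `mU`/`mL` are [miss_probability()] in each habitat. In unbalanced
#' designs with `t2 > T2` the logged sample must be extrapolated: components
#' are evaluated at `t2 = T2` and the Chao2 increment of the logged curve,
#' `extrapolated_richness(logged, t2 - T2) - S_obs(logged)`, is added. Under
#' the default `extrapolation_policy = "unique_logged"` the increment goes
#' wholly to the unique-to-logged component (species of the other classes are
#' already accounted for by their unlogged-sample detection terms); the
#' policy switch isolates this choice. The retention benchmarks depend only
#' on [unique_unlogged_curve()], which never extrapolates.
#'
#' @param paired A [pair_datasets()] object.
#' @param t1 Retained unlogged plots in [0, T1]; vectorized.
#' @param extrapolation_policy Where the extrapolated logged-habitat
#'   increment is allocated: `"unique_logged"` (default) or `"total_only"`
#'   (added to the total but to no component; leaves the additivity identity
#'   to the user).
#' @return A tibble with one row per `t1` and columns `t1, t2,
#'   unique_unlogged, unique_logged, shared, total, extrapolated`.
#' @export
mixture_components <- function(paired, t1,
                               extrapolation_policy = c("unique_logged",
                                                        "total_only")) {
  stopifnot(inherits(paired, "paired_dataset"))
  extrapolation_policy <- match.arg(extrapolation_policy)
  T1 <- n_plots_unlogged(paired)
  T2 <- n_plots_logged(paired)
  if (any(t1 < 0) || any(t1 > T1)) stop("t1 must lie in [0, T1].")
  part <- partition_species(paired)
  qU_uu <- part$q_unlogged[part$class == "unique_unlogged"]
  qL_ul <- part$q_logged[part$class == "unique_logged"]
  qU_sh <- part$q_unlogged[part$class == "shared"]
  qL_sh <- part$q_logged[part$class == "shared"]
  il <- to_incidence(paired$logged)

  t2 <- T1 - t1
  extrapolated <- t2 > T2
  t2_eff <- pmin(t2, T2)

  one <- function(tt1, tt2, extra_t) {
    uu <- if (length(qU_uu)) sum(1 - miss_probability(T1, qU_uu, tt1)) else 0
    ul <- if (length(qL_ul)) sum(1 - miss_probability(T2, qL_ul, tt2)) else 0
    sh <- if (length(qU_sh)) {
      sum(1 - miss_probability(T1, qU_sh, tt1) *
            miss_probability(T2, qL_sh, tt2))
    } else 0
    inc <- if (extra_t > 0) {
      extrapolated_richness(il, extra_t) - il$S_obs
    } else 0
    if (extrapolation_policy == "unique_logged") ul <- ul + inc
    c(unique_unlogged = uu, unique_logged = ul, shared = sh,
      total = uu + ul + sh +
        if (extrapolation_policy == "total_only") inc else 0)
  }
  comps <- purrr::pmap(
    list(t1, t2_eff, pmax(t2 - T2, 0)),
    function(a, b, e) one(a, b, e)
  )
  dplyr::bind_cols(
    tibble::tibble(t1 = t1, t2 = t2),
    dplyr::bind_rows(purrr::map(comps, ~ tibble::as_tibble(as.list(.x)))),
    tibble::tibble(extrapolated = extrapolated)
  )
}

#' Full mixture decomposition over a retention-proportion grid
#'
#' Evaluates [mixture_components()] on a uniform grid of retention
#' proportions p = t1 / T1 in [0, 1] and returns the long-format
#' decomposition used for plotting and export.
#'
#' @param paired A [pair_datasets()] object.
#' @param n_grid Number of grid points (default 201, i.e. steps of 0.005).
#' @param extrapolation_policy Passed to [mixture_components()].
#' @return A tibble of class `mixture_decomposition` with columns
#'   `p, t1, t2, component, value, extrapolated`; components are
#'   `unique_unlogged`, `unique_logged`, `shared`, `total`.
#' @export
compute_mixture_decomposition <- function(paired, n_grid = 201L,
                                          extrapolation_policy = "unique_logged") {
  stopifnot(n_grid >= 2L)
  T1 <- n_plots_unlogged(paired)
  p <- seq(0, 1, length.out = n_grid)
  wide <- mixture_components(paired, p * T1,
                             extrapolation_policy = extrapolation_policy)
  out <- dplyr::mutate(wide, p = p, .before = 1) |>
    tidyr::pivot_longer(c("unique_unlogged", "unique_logged", "shared", "total"),
                        names_to = "component", values_to = "value")
  attr(out, "dataset_id") <- paired$meta$dataset_id
  attr(out, "T1") <- T1
  attr(out, "T2") <- n_plots_logged(paired)
  class(out) <- c("mixture_decomposition", class(out))
  out
}

#' @rdname compute_mixture_decomposition
#' @param object A `mixture_decomposition`.
#' @param ... Unused.
#' @export
autoplot.mixture_decomposition <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$p, .data$value,
                                       colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Proportion of area retained unlogged (p)",
                  y = "Expected species richness", colour = NULL,
                  title = attr(object, "dataset_id")) +
    ggplot2::theme_minimal()
}
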