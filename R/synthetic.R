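#' Generate a two-habitat community model
#'
#' Defines the generating truth for a synthetic paired dataset: three species
#' classes (unique to unlogged, unique to logged, shared) and a per-species
#' per-plot detection probability in each habitat. Unique-class species have
#' probability exactly zero in the other habitat; shared species get
#' independent draws for the two habitats. Probabilities are drawn from a
#' log-normal on the odds scale (median 0.15, log-sd 1.0 by default), which
#' yields the long tail of rare species — incidence frequencies of 1-2 —
#' typical of field matrices, so the Chao2 branches are exercised.
#'
#' @param n_unique_unlogged,n_unique_logged,n_shared Class sizes (>= 0, not
#'   all zero).
#' @param T1,T2 Plots per habitat (>= 2).
#' @param p_median Median detection probability (default 0.15).
#' @param p_sdlog Log-sd of the odds (default 1.0).
#' @param seed Integer seed; the model is reproducible given the seed.
#' @return Object of class `community_model`: a tibble `species` with columns
#'   `species, class, p_unlogged, p_logged`, plus `T1`, `T2`, `seed`.
#' @export
generate_community <- function(n_unique_unlogged = 20L, n_unique_logged = 10L,
                               n_shared = 40L, T1 = 15L, T2 = 15L,
                               p_median = 0.15, p_sdlog = 1.0, seed = 1L) {
  if (n_unique_unlogged < 0 || n_unique_logged < 0 || n_shared < 0 ||
      (n_unique_unlogged + n_unique_logged + n_shared) == 0)
    stop("Class sizes must be non-negative and not all zero.")
  if (T1 < 2 || T2 < 2) stop("T1 and T2 must be at least 2.")
  set.seed(seed)
  draw_p <- function(n) {
    odds <- exp(rnorm(n, mean = log(p_median / (1 - p_median)), sd = p_sdlog))
    odds / (1 + odds)
  }
  cls <- rep(c("unique_unlogged", "unique_logged", "shared"),
             c(n_unique_unlogged, n_unique_logged, n_shared))
  n <- length(cls)
  species <- tibble::tibble(
    species = sprintf("%s_%03d", c(unique_unlogged = "uu", unique_logged = "ul",
                                   shared = "sh")[cls],
                      stats::ave(seq_len(n), cls, FUN = seq_along)),
    class = cls,
    p_unlogged = ifelse(cls == "unique_logged", 0, draw_p(n)),
    p_logged = ifelse(cls == "unique_unlogged", 0, draw_p(n))
  )
  structure(list(species = species, T1 = as.integer(T1), T2 = as.integer(T2),
                 seed = as.integer(seed)),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf("<community_model> %d species (%s), T1 = %d, T2 = %d, seed = %d\n",
              nrow(x$species),
              paste(table(x$species$class), collapse = "/"), x$T1, x$T2,
              x$seed))
  invisible(x)
}

#' Simulate a paired incidence dataset from a community model
#'
#' Every species x plot cell is an independent Bernoulli draw with the
#' species' habitat-specific detection probability (occupancy without spatial
#' clustering, so the expected curves are available in closed form).
#'
#' @param model A [generate_community()] model.
#' @param seed Integer seed for the draws.
#' @param meta Optional [study_metadata()] row; a generic one is filled in
#'   when omitted.
#' @return A [pair_datasets()] object. Species never detected in a habitat
#'   simply have zero rows there; species ids encode the true class (`uu_`,
#'   `ul_`, `sh_` prefixes) for test introspection.
#' @export
simulate_incidence <- function(model, seed = model$seed + 1L, meta = NULL) {
  stopifnot(inherits(model, "community_model"))
  set.seed(seed)
  sp <- model$species
  n <- nrow(sp)
  mu <- matrix(rbinom(n * model$T1, 1L, rep(sp$p_unlogged, model$T1)),
               nrow = n, dimnames = list(sp$species,
                                         paste0("u", seq_len(model$T1))))
  ml <- matrix(rbinom(n * model$T2, 1L, rep(sp$p_logged, model$T2)),
               nrow = n, dimnames = list(sp$species,
                                         paste0("l", seq_len(model$T2))))
  if (is.null(meta))
    meta <- study_metadata(paste0("sim", seed), "sim_study", "sim_taxon",
                           FALSE, "fire", 1)
  suppressWarnings(pair_datasets(
    species_plot_matrix(mu, habitat_label = "unlogged"),
    species_plot_matrix(ml, habitat_label = "logged"),
    meta
  ))
}

#' Analytic expected unique-to-unlogged richness under the generating model
#'
#' Truth oracle for parameter recovery: for the species truly unique to the
#' unlogged habitat, the expected number detected in `t1` independent plots
#' is `sum(1 - (1 - p_i)^t1)`, continuous in `t1`.
#'
#' @param model A [generate_community()] model.
#' @param t1 Real number of plots in [0, T1]; vectorized.
#' @return Expected richness per `t1`.
#' @export
true_unique_curve <- function(model, t1) {
  stopifnot(inherits(model, "community_model"))
  if (any(t1 < 0) || any(t1 > model$T1)) stop("t1 must lie in [0, T1].")
  p <- model$species$p_unlogged[model$species$class == "unique_unlogged"]
  vapply(t1, function(tt) sum(1 - (1 - p)^tt), numeric(1))
}

#' True retention benchmark under the generating model
#'
#' Inverts the normalized [true_unique_curve()] (relative to its value at the
#' reference sample size T1) to the smallest retention proportion reaching
#' target fraction `q`.
#'
#' @param model A [generate_community()] model.
#' @param q Target fraction in (0, 1).
#' @return True p* in (0, 1).
#' @export
true_retention <- function(model, q = 0.9) {
  denom <- true_unique_curve(model, model$T1)
  if (denom == 0) return(NA_real_)
  f <- function(p) true_unique_curve(model, p * model$T1) / denom - q
  uniroot(f, c(0, 1), tol = 1e-10)$root
}

#' Exact subsampling oracle for mixture components
#'
#' Brute-force verification of [mixture_components()]: enumerates all
#' C(T1, t1) * C(T2, t2) subset pairs, pools the selected plots, and averages
#' the detected richness of each reference-level species class. Only feasible
#' for small designs.
#'
#' @param paired A [pair_datasets()] object.
#' @param t1,t2 Integer subsample sizes per habitat.
#' @param max_pairs Combinatorial budget (default 1e6 subset pairs).
#' @return One-row tibble: `unique_unlogged, unique_logged, shared, total`.
#' @export
subsample_oracle_exact <- function(paired, t1, t2, max_pairs = 1e6) {
  stopifnot(inherits(paired, "paired_dataset"),
            t1 == round(t1), t2 == round(t2))
  T1 <- n_plots_unlogged(paired)
  T2 <- n_plots_logged(paired)
  n_pairs <- choose(T1, t1) * choose(T2, t2)
  if (n_pairs > max_pairs)
    stop("Enumeration over ", n_pairs, " subset pairs exceeds the budget; ",
         "use subsample_oracle_mc().")
  sub_u <- if (t1 > 0) combn(T1, t1, simplify = FALSE) else list(integer())
  sub_l <- if (t2 > 0) combn(T2, t2, simplify = FALSE) else list(integer())
  acc <- c(unique_unlogged = 0, unique_logged = 0, shared = 0, total = 0)
  cls <- component_class_matrices(paired)
  for (su in sub_u) {
    det_u <- if (length(su)) rowSums(cls$mat_u[, su, drop = FALSE]) > 0 else
      rep(FALSE, nrow(cls$mat_u))
    for (sl in sub_l) {
      det_l <- if (length(sl)) rowSums(cls$mat_l[, sl, drop = FALSE]) > 0 else
        rep(FALSE, nrow(cls$mat_l))
      acc <- acc + count_components(det_u | det_l, cls$class)
    }
  }
  tibble::as_tibble(as.list(acc / (length(sub_u) * length(sub_l))))
}

# Shared plumbing for the oracles: pooled-universe detection matrices aligned
# on the same species order, plus the reference-level class of each species.
component_class_matrices <- function(paired) {
  part <- partition_species(paired)
  species <- part$species
  mat0 <- function(m) {
    out <- matrix(FALSE, length(species), ncol(m),
                  dimnames = list(species, colnames(m)))
    hit <- intersect(rownames(m), species)
    out[hit, ] <- m[hit, , drop = FALSE] > 0
    out
  }
  list(mat_u = mat0(paired$unlogged$counts),
       mat_l = mat0(paired$logged$counts),
       class = part$class)
}

count_components <- function(detected, class) {
  uu <- sum(detected & class == "unique_unlogged")
  ul <- sum(detected & class == "unique_logged")
  sh <- sum(detected & class == "shared")
  c(unique_unlogged = uu, unique_logged = ul, shared = sh, total = uu + ul + sh)
}

#' Monte-Carlo subsampling oracle for mixture components
#'
#' As [subsample_oracle_exact()] but averaging over `reps` random subset
#' pairs (plots drawn without replacement within each habitat), with standard
#' errors of the means. Reproducible given `seed`.
#'
#' @param paired A [pair_datasets()] object.
#' @param t1,t2 Integer subsample sizes.
#' @param reps Number of replicates (>= 100).
#' @param seed Integer seed.
#' @return Tibble with columns `component, mean, se`.
#' @export
subsample_oracle_mc <- function(paired, t1, t2, reps = 2000L, seed = 1L) {
  stopifnot(inherits(paired, "paired_dataset"), reps >= 100)
  T1 <- n_plots_unlogged(paired)
  T2 <- n_plots_logged(paired)
  stopifnot(t1 >= 0, t1 <= T1, t2 >= 0, t2 <= T2)
  cls <- component_class_matrices(paired)
  set.seed(seed)
  draws <- matrix(0, reps, 4,
                  dimnames = list(NULL, c("unique_unlogged", "unique_logged",
                                          "shared", "total")))
  for (r in seq_len(reps)) {
    det_u <- if (t1 > 0)
      rowSums(cls$mat_u[, sample.int(T1, t1), drop = FALSE]) > 0 else
      rep(FALSE, nrow(cls$mat_u))
    det_l <- if (t2 > 0)
      rowSums(cls$mat_l[, sample.int(T2, t2), drop = FALSE]) > 0 else
      rep(FALSE, nrow(cls$mat_l))
    draws[r, ] <- count_components(det_u | det_l, cls$class)
  }
  tibble::tibble(
    component = colnames(draws),
    mean = colMeans(draws),
    se = apply(draws, 2, stats::sd) / sqrt(reps)
  )
}

#' The packaged synthetic collection
#'
#' A fixed 24-dataset collection used in examples and end-to-end tests:
#' 3 disturbance types x saproxylic / non-saproxylic x 4 taxon-like labels,
#' with deterministic per-dataset seeds derived from `seed`. Plot counts,
#' class sizes and years since disturbance vary across datasets within the
#' ranges typical of field studies (5-30 plots, tens to a few hundred
#' species, surveys within a few years of the disturbance).
#'
#' @param seed Integer base seed (default 20240501).
#' @return Named list of 24 [pair_datasets()] objects with attribute
#'   `models` (the generating [generate_community()] models, for truth
#'   checks).
#' @export
synthetic_collection <- function(seed = 20240501L) {
  grid <- tidyr::expand_grid(
    disturbance_type = c("fire", "windstorm", "insect_outbreak"),
    saproxylic = c(TRUE, FALSE),
    taxon = c("beetles", "fungi", "plants", "birds")
  )
  set.seed(seed)
  grid$T1 <- sample(8:25, nrow(grid), replace = TRUE)
  grid$T2 <- sample(8:25, nrow(grid), replace = TRUE)
  grid$n_uu <- sample(10:35, nrow(grid), replace = TRUE)
  grid$n_ul <- sample(5:20, nrow(grid), replace = TRUE)
  grid$n_sh <- sample(25:80, nrow(grid), replace = TRUE)
  grid$years <- sample(1:10, nrow(grid), replace = TRUE)
  grid$study_id <- paste0("study", rep(1:8, each = 3)[seq_len(nrow(grid))])
  grid$seed <- seed + seq_len(nrow(grid))

  models <- vector("list", nrow(grid))
  collection <- vector("list", nrow(grid))
  ids <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ids[i] <- sprintf("%s_%s_%s", substr(g$disturbance_type, 1, 4), g$taxon,
                      if (g$saproxylic) "sapro" else "nonsapro")
    models[[i]] <- generate_community(
      n_unique_unlogged = g$n_uu, n_unique_logged = g$n_ul, n_shared = g$n_sh,
      T1 = g$T1, T2 = g$T2, seed = g$seed
    )
    meta <- study_metadata(ids[i], g$study_id, g$taxon, g$saproxylic,
                           g$disturbance_type, g$years)
    collection[[i]] <- simulate_incidence(models[[i]], seed = g$seed + 1000L,
                                          meta = meta)
  }
  names(collection) <- ids
  names(models) <- ids
  attr(collection, "models") <- models
  collection
}

#' Write a synthetic collection to disk in the package's CSV formats
#'
#' Produces per-dataset wide CSV matrices, a metadata table, and `truth.csv`
#' with the generating model's analytic benchmarks.
#'
#' @param collection Output of [synthetic_collection()] (or compatible).
#' @param out_dir Output directory (created if needed).
#' @param q Target fraction for the true benchmark column.
#' @return `out_dir`, invisibly.
#' @export
write_collection <- function(collection, out_dir, q = 0.9) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  models <- attr(collection, "models")
  meta <- purrr::imap_dfr(collection, function(pd, id) {
    uf <- paste0(id, "_unlogged.csv")
    lf <- paste0(id, "_logged.csv")
    write_species_matrix(pd$unlogged, file.path(out_dir, uf))
    write_species_matrix(pd$logged, file.path(out_dir, lf))
    dplyr::mutate(pd$meta, unlogged_file = uf, logged_file = lf)
  })
  readr::write_csv(meta, file.path(out_dir, "metadata.csv"))
  if (!is.null(models)) {
    truth <- purrr::imap_dfr(models, function(m, id) {
      tibble::tibble(
        dataset_id = id,
        true_p_star = true_retention(m, q = q),
        true_frac_at_half =
          true_unique_curve(m, 0.5 * m$T1) / true_unique_curve(m, m$T1)
      )
    })
    readr::write_csv(truth, file.path(out_dir, "truth.csv"))
  }
  invisible(out_dir)
}
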