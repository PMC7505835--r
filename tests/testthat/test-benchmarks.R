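test_that("a single unique species seen once gives a linear curve, so p* = q", {
  pd <- linear_pair(T1 = 10)
  p <- c(0, 0.25, 0.5, 0.9, 1)
  expect_equal(normalized_unique_curve(pd, p), p, tolerance = 1e-12)
  expect_equal(retention_for_fraction(pd, q = 0.9), 0.9, tolerance = 1e-6)
  expect_equal(retention_for_fraction(pd, q = 0.5), 0.5, tolerance = 1e-6)
  expect_equal(unique_fraction_at_retention(pd, 0.5), 0.5, tolerance = 1e-12)
})

test_that("high-frequency unique species give a concave curve and small p*", {
  # all unique species present in every plot: detection saturates fast
  T1 <- 4
  mu <- matrix(1L, 3, T1, dimnames = list(c("a", "b", "c"), paste0("u", 1:T1)))
  ml <- matrix(1L, 1, 4, dimnames = list("a", paste0("l", 1:4)))
  pd <- pair_datasets(species_plot_matrix(mu, habitat_label = "unlogged"),
                      species_plot_matrix(ml, habitat_label = "logged"),
                      meta_fixture())
  expect_gt(unique_fraction_at_retention(pd, 0.5), 0.5)
  p_star <- retention_for_fraction(pd, q = 0.9)
  expect_lt(p_star, 0.9)
  # brute-force grid scan agrees with the bisection to grid resolution
  grid <- seq(0, 1, by = 1e-4)
  scan <- grid[which(normalized_unique_curve(pd, grid) >= 0.9)[1]]
  expect_lt(abs(p_star - scan), 2e-4)
})

test_that("inversion residual is bounded and p* is monotone in q", {
  for (seed in c(2, 9, 21)) {
    pd <- random_small_pair(seed + 400)
    if (sum(partition_species(pd)$class == "unique_unlogged") == 0) next
    qs <- c(0.1, 0.3, 0.5, 0.7, 0.9, 0.99)
    ps <- vapply(qs, function(q) retention_for_fraction(pd, q), numeric(1))
    expect_true(all(diff(ps) > 0))
    for (i in seq_along(qs)) {
      expect_lt(abs(normalized_unique_curve(pd, ps[i]) - qs[i]), 1e-6)
      expect_gte(unique_fraction_at_retention(pd, ps[i]), qs[i] - 1e-6)
    }
  }
  expect_error(retention_for_fraction(tiny_pair(), q = 1), "strictly inside")
})

test_that("datasets without unique species get an undefined status", {
  mu <- species_plot_matrix(matrix(1L, 1, 2, dimnames = list("a", c("u1", "u2"))),
                            habitat_label = "unlogged")
  ml <- species_plot_matrix(matrix(1L, 1, 2, dimnames = list("a", c("l1", "l2"))),
                            habitat_label = "logged")
  pd <- suppressWarnings(pair_datasets(mu, ml, meta_fixture("nouniq")))
  b <- compute_benchmarks(pd)
  expect_equal(b$status, "undefined_no_unique_species")
  expect_true(is.na(b$p_star))
  expect_equal(b$n_unique, 0L)
})

test_that("group summaries are unweighted means with sample SD", {
  benchmarks <- tibble::tibble(
    dataset_id = c("d1", "d2", "d3"),
    p_star = c(0.7, 0.8, 0.6), frac_at_half = c(0.5, 0.7, 0.9),
    n_unique = 5L, T_unlogged = 10L, T_logged = 10L,
    status = c("ok", "ok", "undefined_no_unique_species"))
  benchmarks$p_star[3] <- NA
  benchmarks$frac_at_half[3] <- NA
  metadata <- dplyr::bind_rows(
    study_metadata("d1", "s1", "beetles", TRUE, "fire", 2),
    study_metadata("d2", "s1", "fungi", FALSE, "fire", 3),
    study_metadata("d3", "s2", "birds", FALSE, "windstorm", 2))

  expect_message(
    s <- summarize_benchmarks(benchmarks, metadata, grouping = "all"),
    "excluded")
  row <- dplyr::filter(s, statistic == "p_star")
  expect_equal(row$n, 2L)
  expect_equal(row$mean, 0.75)
  expect_equal(row$sd, sd(c(0.7, 0.8)), tolerance = 1e-12)

  # single-dataset level reports NA sd; mean equals the value
  s2 <- suppressMessages(
    summarize_benchmarks(benchmarks, metadata, grouping = "taxon_group"))
  b_row <- dplyr::filter(s2, level == "beetles", statistic == "p_star")
  expect_equal(b_row$mean, 0.7)
  expect_true(is.na(b_row$sd))

  # pooled mean equals an independent accumulation in another order
  expect_equal(row$mean, sum(rev(c(0.7, 0.8))) / 2, tolerance = 1e-12)
})

test_that("the pipeline is deterministic and complete on the packaged collection", {
  coll <- synthetic_collection(seed = 555)
  res <- run_pipeline(coll)
  expect_equal(nrow(res$benchmarks), 24L)
  expect_true(all(res$benchmarks$status == "ok"))
  expect_true(all(res$benchmarks$p_star >= 0 & res$benchmarks$p_star <= 1))
  expect_s3_class(res$regressions$p_star, "beta_gam")

  # re-running writes byte-identical outputs
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_pipeline(coll, out_dir = d1)
  run_pipeline(synthetic_collection(seed = 555), out_dir = d2)
  for (f in c("benchmarks.csv", "summaries.csv", "curves.csv", "regression.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }

  # dropping one dataset changes only that row of the benchmark table
  res2 <- run_pipeline(coll[-1])
  expect_equal(res2$benchmarks, res$benchmarks[-1, ])
})
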