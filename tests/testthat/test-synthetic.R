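test_that("community generation is reproducible and class-structured", {
  m1 <- generate_community(seed = 10)
  m2 <- generate_community(seed = 10)
  expect_identical(m1, m2)
  sp <- m1$species
  expect_true(all(sp$p_logged[sp$class == "unique_unlogged"] == 0))
  expect_true(all(sp$p_unlogged[sp$class == "unique_logged"] == 0))
  expect_true(all(sp$p_unlogged >= 0 & sp$p_unlogged <= 1))
  expect_error(generate_community(n_unique_unlogged = 0, n_unique_logged = 0,
                                  n_shared = 0), "not all zero")
})

test_that("default parameters produce rare species (uniques and duplicates)", {
  # with median detection 0.15, species seen in <= 2 of 15 plots are common
  counts <- vapply(1:20, function(seed) {
    pd <- simulate_incidence(generate_community(seed = seed))
    f <- to_incidence(pd$unlogged)
    c(f$Q1, f$Q2)
  }, numeric(2))
  expect_gt(mean(counts[1, ] > 0), 0.9)
  expect_gt(mean(counts[2, ] > 0), 0.9)
})

test_that("incidence simulation follows the Bernoulli-per-plot model", {
  model <- generate_community(n_unique_unlogged = 2, n_unique_logged = 2,
                              n_shared = 2, T1 = 10, T2 = 10, seed = 4)
  model$species$p_unlogged[1] <- 1  # certain detection
  pd <- simulate_incidence(model, seed = 5)
  f <- to_incidence(pd$unlogged)
  expect_equal(unname(f$Q[model$species$species[1]]), 10L)

  # mean incidence over replicates matches T1 * p within 3 binomial SEs
  target <- model$species$species[5]   # a shared species
  p <- model$species$p_unlogged[5]
  qs <- vapply(1:400, function(s) {
    pdk <- simulate_incidence(model, seed = 1000 + s)
    q <- pdk$incidence$q_unlogged[pdk$incidence$species == target]
    if (length(q)) q else 0L
  }, numeric(1))
  se <- sqrt(10 * p * (1 - p) / 400)
  expect_lt(abs(mean(qs) - 10 * p), 3 * se)
})

test_that("the analytic truth curve has the closed-form values", {
  model <- generate_community(n_unique_unlogged = 1, n_unique_logged = 1,
                              n_shared = 1, T1 = 10, T2 = 10, seed = 2)
  model$species$p_unlogged[model$species$class == "unique_unlogged"] <- 0.5
  expect_equal(true_unique_curve(model, 0), 0)
  expect_equal(true_unique_curve(model, 2), 0.75, tolerance = 1e-12)
  model$species$p_unlogged[model$species$class == "unique_unlogged"] <- 1
  expect_equal(true_unique_curve(model, 1), 1)
  expect_equal(true_unique_curve(model, 7.5), 1)
})

test_that("exact and Monte-Carlo oracles agree with each other", {
  pd <- random_small_pair(77)
  T1 <- ncol(pd$unlogged$counts); T2 <- ncol(pd$logged$counts)
  t1 <- max(1, T1 - 2); t2 <- max(1, T2 - 2)
  oe <- subsample_oracle_exact(pd, t1, t2)
  mc <- subsample_oracle_mc(pd, t1, t2, reps = 3000, seed = 5)
  for (i in seq_len(nrow(mc))) {
    expect_lt(abs(mc$mean[i] - oe[[mc$component[i]]]),
              3 * max(mc$se[i], 1e-3))
  }
  # degenerate full-sample subsets have zero variance
  mc_full <- subsample_oracle_mc(pd, T1, T2, reps = 200, seed = 6)
  expect_true(all(mc_full$se == 0))
  # budget guard
  big <- simulate_incidence(generate_community(T1 = 30, T2 = 30, seed = 1))
  expect_error(subsample_oracle_exact(big, 15, 15), "budget")
})

test_that("Monte-Carlo standard error shrinks like 1/sqrt(reps)", {
  pd <- simulate_incidence(generate_community(T1 = 12, T2 = 12, seed = 31),
                           seed = 32)
  se1 <- mean(subsample_oracle_mc(pd, 6, 6, reps = 500, seed = 1)$se[1:3])
  se2 <- mean(subsample_oracle_mc(pd, 6, 6, reps = 2000, seed = 1)$se[1:3])
  expect_lt(abs(se2 / se1 - 0.5), 0.15)
})

test_that("synthetic datasets round-trip through the CSV formats", {
  coll <- synthetic_collection(seed = 777)[1:3]
  attr(coll, "models") <- attr(synthetic_collection(seed = 777), "models")[1:3]
  dir <- withr::local_tempdir()
  write_collection(coll, dir)
  md <- read_metadata(file.path(dir, "metadata.csv"))
  reread <- load_collection(md, data_dir = dir)
  expect_equal(names(reread), names(coll))
  for (id in names(coll)) {
    expect_identical(reread[[id]]$unlogged$counts, coll[[id]]$unlogged$counts)
    expect_identical(reread[[id]]$logged$counts, coll[[id]]$logged$counts)
    expect_equal(reread[[id]]$incidence, coll[[id]]$incidence)
  }
  truth <- readr::read_csv(file.path(dir, "truth.csv"), show_col_types = FALSE)
  expect_equal(nrow(truth), 3L)
  expect_true(all(truth$true_p_star > 0 & truth$true_p_star < 1))
})

test_that("estimated curves converge to the truth as sampling effort grows", {
  # same community, increasing numbers of plots: the normalized estimated
  # unique curve approaches the normalized analytic truth
  dev_at <- function(T1, seed) {
    model <- generate_community(n_unique_unlogged = 30, n_unique_logged = 10,
                                n_shared = 40, T1 = T1, T2 = T1, seed = 17)
    pd <- simulate_incidence(model, seed = seed)
    ps <- seq(0.1, 0.9, by = 0.1)
    est <- normalized_unique_curve(pd, ps)
    tru <- true_unique_curve(model, ps * T1) / true_unique_curve(model, T1)
    max(abs(est - tru))
  }
  devs_small <- vapply(1:6, function(s) dev_at(10, 100 + s), numeric(1))
  devs_large <- vapply(1:6, function(s) dev_at(150, 200 + s), numeric(1))
  expect_lt(mean(devs_large), mean(devs_small))
  expect_lt(mean(devs_large), 0.05)
})
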