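# Fixture builders shared across tests. Everything is generated in code; no
# files ship with the tests except what a test writes to tempdir() itself.

meta_fixture <- function(id = "d1", study = "s1") {
  study_metadata(id, study, "beetles", FALSE, "fire", 2)
}

# The two-species reference fixture used in several hand-worked examples:
# unlogged T1 = 2 with a in both plots and b in one; logged T2 = 2 with a in
# one plot only.
tiny_pair <- function() {
  mu <- matrix(c(1, 1, 1, 0), nrow = 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("u1", "u2")))
  ml <- matrix(c(1, 0), nrow = 1, dimnames = list("a", c("l1", "l2")))
  pair_datasets(species_plot_matrix(mu, habitat_label = "unlogged"),
                species_plot_matrix(ml, habitat_label = "logged"),
                meta_fixture())
}

# Random small paired dataset for enumeration oracles: T1, T2 <= 6 and at
# most 12 pooled species, guaranteed at least one species detected in the
# unlogged habitat.
random_small_pair <- function(seed) {
  set.seed(seed)
  T1 <- sample(2:6, 1)
  T2 <- sample(2:6, 1)
  n_sp <- sample(3:12, 1)
  sp <- paste0("s", seq_len(n_sp))
  repeat {
    mu <- matrix(rbinom(n_sp * T1, 1, runif(1, 0.2, 0.7)), n_sp,
                 dimnames = list(sp, paste0("u", 1:T1)))
    ml <- matrix(rbinom(n_sp * T2, 1, runif(1, 0.2, 0.7)), n_sp,
                 dimnames = list(sp, paste0("l", 1:T2)))
    if (any(rowSums(mu) > 0)) break
  }
  suppressWarnings(pair_datasets(
    species_plot_matrix(mu, habitat_label = "unlogged"),
    species_plot_matrix(ml, habitat_label = "logged"),
    meta_fixture(paste0("rnd", seed))
  ))
}

# A paired dataset whose unique-to-unlogged class is exactly one species seen
# in a single plot: its normalized unique curve is linear in p, so the
# retention benchmark has the closed form p* = q.
linear_pair <- function(T1 = 10) {
  mu <- matrix(0L, 2, T1, dimnames = list(c("a", "b"), paste0("u", 1:T1)))
  mu["a", ] <- 1L            # shared species, everywhere
  mu["b", 1] <- 1L           # unique species, exactly one plot
  ml <- matrix(1L, 1, 4, dimnames = list("a", paste0("l", 1:4)))
  pair_datasets(species_plot_matrix(mu, habitat_label = "unlogged"),
                species_plot_matrix(ml, habitat_label = "logged"),
                meta_fixture("lin"))
}

make_incidence <- function(T, Q) retbench:::incidence_freq(T, Q)

# Exhaustive within-habitat rarefaction oracle: mean richness over all
# C(T, t) subsets of the plots of one matrix.
enumerate_rarefaction <- function(counts, t) {
  Tn <- ncol(counts)
  subs <- combn(Tn, t, simplify = FALSE)
  mean(vapply(subs, function(s) {
    sum(rowSums(counts[, s, drop = FALSE] > 0) > 0)
  }, numeric(1)))
}
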