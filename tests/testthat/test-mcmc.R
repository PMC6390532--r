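test_that("count-based conditional probabilities follow the (eta + 1) rule", {
  # K = 1: the only component is chosen with probability 1
  st <- allocation_state(rep(1L, 5), 1L)
  out <- gibbs_allocation_sweep(st, matrix(-3, 5, 1))
  expect_identical(out$z, rep(1L, 5))
  expect_identical(out$eta, 5L)

  # equal likelihoods, post-decrement counts (3, 1) -> (2/3, 1/3)
  p <- mutselpip:::.gibbs_site_probs(c(3, 1), c(-7, -7))
  expect_equal(p, c(2 / 3, 1 / 3), tolerance = 1e-12)
  # likelihood ratio 3 with counts (0, 0) -> (3/4, 1/4)
  p <- mutselpip:::.gibbs_site_probs(c(0, 0), log(c(3, 1)) - 5)
  expect_equal(p, c(0.75, 0.25), tolerance = 1e-12)

  expect_error(gibbs_allocation_sweep(list(z = c(1L, 1L), eta = c(0L, 2L),
                                           K = 2L), matrix(0, 2, 2)),
               "counts inconsistent")
})

test_that("weight-conditional sweep matches its closed-form allocation law", {
  # degenerate weights send every site to component 1
  st <- weighted_allocation_sweep(matrix(-2, 50, 3), c(1, 0, 0))
  expect_identical(st$z, rep(1L, 50))
  expect_identical(st$eta, c(50L, 0L, 0L))

  # w = (0.25, 0.75) with likelihood ratio 3 -> allocation (0.5, 0.5)
  set.seed(42)
  logliks <- matrix(rep(log(c(3, 1)) - 4, each = 4000), 4000, 2)
  st <- weighted_allocation_sweep(logliks, c(0.25, 0.75))
  expect_equal(mean(st$z == 1), 0.5, tolerance = 3 * sqrt(0.25 / 4000) / 0.5)

  # uniform weights, equal likelihoods -> 1/K each
  set.seed(43)
  st <- weighted_allocation_sweep(matrix(-1, 8000, 4), rep(0.25, 4))
  freq <- tabulate(st$z, 4) / 8000
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 8000)))
})

test_that("weight draws follow the Dirichlet(1 + eta) conditional", {
  set.seed(7)
  eta <- c(100L, 0L)
  draws <- t(replicate(20000, update_weights(eta)))
  se <- sqrt(apply(draws, 2, var) / nrow(draws))
  # Dirichlet(101, 1) mean: (1 + eta_1) / (K + N) = 101 / 102
  expect_lt(abs(mean(draws[, 1]) - 101 / 102), 3 * se[1])
  # flat prior when all counts are zero
  draws <- t(replicate(20000, update_weights(c(0L, 0L, 0L))))
  se <- sqrt(apply(draws, 2, var) / nrow(draws))
  expect_true(all(abs(colMeans(draws) - 1 / 3) < 3 * se))
})

test_that("both samplers reproduce the enumerated two-site posterior", {
  # enumerable fixture: 2 sites, 2 components, asymmetric likelihoods
  logliks <- rbind(c(log(0.7), log(0.3)) - 3,
                   c(log(0.4), log(0.6)) - 5)
  exact <- enumerate_allocation_posterior(logliks)$site_marginals

  n_sweeps <- 20000L
  set.seed(11)
  st <- allocation_state(c(1L, 1L), 2L)
  acc_g <- matrix(0, 2, 2)
  for (s in seq_len(n_sweeps)) {
    st <- gibbs_allocation_sweep(st, logliks)
    acc_g[cbind(1:2, st$z)] <- acc_g[cbind(1:2, st$z)] + 1
  }
  expect_equal(acc_g / n_sweeps, exact, tolerance = 0.02,
               ignore_attr = TRUE)

  set.seed(12)
  w <- c(0.5, 0.5)
  acc_w <- matrix(0, 2, 2)
  for (s in seq_len(n_sweeps)) {
    st <- weighted_allocation_sweep(logliks, w)
    w <- update_weights(st$eta)
    acc_w[cbind(1:2, st$z)] <- acc_w[cbind(1:2, st$z)] + 1
  }
  expect_equal(acc_w / n_sweeps, exact, tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("parameter moves preserve their priors under a flat likelihood", {
  # all-missing alignment: every component likelihood is 1, so the chain
  # samples the priors of the free blocks
  tr <- tree4()
  aln <- codon_alignment(matrix(NA_integer_, 4, 2,
                                dimnames = list(tr$tip.label)))
  profiles <- mutselpip:::.new_profile_set(list(rep(1 / 20, 20)))
  cfg <- chain_config(sweeps = 4000, burnin = 500, thin = 2, seed = 3,
                      update_mut = TRUE, update_bl = TRUE,
                      step_rho = 1, step_phi = 1, step_bl = 2)
  trace <- run_chain(aln, tr, profiles, cfg)
  # flat Dirichlet marginals: E[rho_i] = 1/6, E[phi_a] = 1/4
  expect_equal(unname(colMeans(trace$rho)), rep(1 / 6, 6),
               tolerance = 0.04)
  expect_equal(unname(colMeans(trace$phi)), rep(1 / 4, 4),
               tolerance = 0.05)
  # branch lengths drift towards the exponential(mean 0.1) prior
  expect_lt(mean(trace$branch_lengths), 1)

  # identity proposals (step 0) leave the state unchanged and accept
  res <- mutselpip:::.simplex_mh(rep(1 / 6, 6), 0, function(x) 0)
  expect_true(res$accepted)
  expect_identical(res$value, rep(1 / 6, 6))
  res <- mutselpip:::.scalar_mult_mh(0.2, 0, 10, function(x) 0)
  expect_true(res$accepted)
  expect_identical(res$value, 0.2)
})

test_that("run_chain is reproducible and respects fixed blocks", {
  set.seed(9)
  tr <- tree5()
  aln <- random_alignment(tr$tip.label, 12)
  profiles <- mutsel_bc(0.9)
  cfg <- chain_config(sweeps = 200, seed = 17)
  t1 <- run_chain(aln, tr, profiles, cfg)
  t2 <- run_chain(aln, tr, profiles, cfg)
  expect_identical(t1$z, t2$z)
  expect_identical(t1$loglik, t2$loglik)
  expect_identical(t1$weights, t2$weights)
  # theta blocks fixed by default
  expect_true(all(apply(t1$rho, 2, function(x) diff(range(x)) == 0)))
  expect_identical(t1$branch_lengths, tr$edge.length)

  # K = 1 with fixed theta: constant allocations
  one <- load_profile_table(save_profile_table(
    structure(list(profiles = matrix(1 / 20, 1, 20,
                                     dimnames = list("C1", AMINO_ACIDS)),
                   weights = NULL, peakedness = NULL, source = "file"),
              class = "profile_set"),
    withr::local_tempfile(fileext = ".profiles")))
  tk1 <- run_chain(aln, tr, one, chain_config(sweeps = 50, seed = 2))
  expect_true(all(tk1$z == 1L))
  expect_error(chain_config(sweeps = 100, burnin = 100), "burn-in")
})

test_that("count conservation holds across sweeps", {
  set.seed(23)
  logliks <- matrix(rnorm(30 * 4), 30, 4)
  st <- allocation_state(sample.int(4, 30, TRUE), 4L)
  for (s in 1:50) {
    st <- gibbs_allocation_sweep(st, logliks)
    expect_identical(st$eta, tabulate(st$z, 4L))
    expect_identical(sum(st$eta), 30L)
  }
})

test_that("allocation recovery is strong under highly peaked profiles", {
  set.seed(31)
  rt <- random_tree(16, 0.35, 6)
  profiles <- mutsel_bc(0.9)
  alloc <- draw_allocations(100, 8)
  mut <- mutation_params()
  des <- simulation_design(rt$tree, character(0), profiles, alloc,
                           mut = mut)
  sim <- simulate_alignment(des, seed = 32)
  trace <- run_chain(sim$alignment, rt$tree, profiles,
                     chain_config(sweeps = 1500, seed = 33, mut = mut))
  probs <- allocation_probability(trace)
  p_true <- probs$table[cbind(seq_along(alloc), alloc)]
  expect_gte(mean(p_true > 0.9), 0.8)
})
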