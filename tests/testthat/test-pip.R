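point_mass <- function(k, K) { p <- numeric(K); p[k] <- 1; p }

test_that("allocation probabilities are draw proportions", {
  z <- rbind(c(1L, 2L), c(1L, 2L), c(2L, 2L), c(3L, 2L))
  probs <- allocation_probability(z, K = 3)
  expect_equal(probs$table[1, ], c(0.5, 0.25, 0.25), tolerance = 1e-12)
  expect_equal(probs$table[2, ], c(0, 1, 0), tolerance = 1e-12)
  expect_equal(rowSums(probs$table), c(1, 1), tolerance = 1e-12)
  expect_identical(probs$M, 4L)
  expect_error(allocation_probability(matrix(integer(0), 0, 2), K = 2),
               "no draws")
})

test_that("PIP identities hold exactly", {
  K <- 8
  expect_identical(pip(point_mass(3, K), point_mass(3, K)), 1)
  expect_identical(pip(point_mass(1, K), point_mass(2, K)), 0)
  half <- c(0.5, 0.5, rep(0, K - 2))
  expect_identical(pip(half, half), 0.5)
  u60 <- rep(1 / 60, 60)
  expect_equal(pip(u60, u60), 1 / 60, tolerance = 1e-12)
  expect_error(pip(point_mass(1, 4), point_mass(1, 5)), "length")
})

test_that("PIP is symmetric, label-permutation invariant and Cauchy-Schwarz bounded", {
  set.seed(13)
  for (r in 1:25) {
    K <- sample(2:60, 1)
    a <- rgamma(K, 0.5); a <- a / sum(a)
    b <- rgamma(K, 0.5); b <- b / sum(b)
    expect_equal(pip(a, b), pip(b, a), tolerance = 1e-12)
    perm <- sample.int(K)
    expect_equal(pip(a[perm], b[perm]), pip(a, b), tolerance = 1e-12)
    expect_lte(pip(a, b), sqrt(pip(a, a) * pip(b, b)) + 1e-12)
    expect_lte(pip(a, b), 1)
    expect_gte(pip(a, b), 0)
  }
})

test_that("allocation entropy matches closed forms", {
  expect_identical(allocation_entropy(point_mass(2, 10)), 0)
  expect_equal(allocation_entropy(rep(1 / 8, 8)), log(8), tolerance = 1e-12)
  expect_equal(allocation_entropy(c(0.5, 0.5, 0, 0)), log(2),
               tolerance = 1e-12)
})

test_that("site classification applies the inclusive threshold and entropy filter", {
  K <- 4
  mk <- function(rows) structure(list(table = rows, M = 100L, K = K,
                                      partition_label = NA),
                                 class = "allocation_probabilities")
  # PIP vector (0, 0.04, 0.05, 0.051, 1) at threshold 0.05 -> sites 1:3
  A <- rbind(point_mass(1, K), c(0.04, 0.96, 0, 0), c(0.05, 0.95, 0, 0),
             c(0.051, 0.949, 0, 0), point_mass(1, K))
  B <- rbind(point_mass(2, K), point_mass(1, K), point_mass(1, K),
             point_mass(1, K), point_mass(1, K))
  rep_ <- classify_sites(mk(A), mk(B), threshold = 0.05)
  expect_equal(rep_$pip, c(0, 0.04, 0.05, 0.051, 1), tolerance = 1e-12)
  expect_identical(which(rep_$shift), 1:3)
  # threshold 0: only exact zeros flagged
  expect_identical(which(classify_sites(mk(A), mk(B),
                                        threshold = 0)$shift), 1L)
  # self-comparison with concentrated allocation flags nothing
  self <- classify_sites(mk(B), mk(B), threshold = 0.05)
  expect_false(any(self$shift))
  # entropy filter suppresses weak-allocation calls
  weak <- rbind(rep(1 / 4, 4))
  disj <- rbind(c(0.25, 0.25, 0.25, 0.25))
  r2 <- classify_sites(mk(weak), mk(disj), threshold = 0.3)
  expect_true(r2$shift[1])  # PIP = 0.25, flagged without the filter
  r3 <- classify_sites(mk(weak), mk(disj), threshold = 0.3,
                       entropy_max = 0.5)
  expect_false(r3$shift[1])
  expect_error(classify_sites(mk(A), mk(B[, 1:3])), "disagree")
})

test_that("confusion metrics mirror the headline design arithmetic", {
  # 759 sites, 80 true shifts, 70 detected plus 14 false calls
  truth <- 1:80
  calls <- c(1:70, 101:114)
  m <- confusion_metrics(calls, truth, n_sites = 759)
  expect_equal(m$TPR, 0.875, tolerance = 1e-12)
  expect_equal(m$FPR, 14 / 679, tolerance = 1e-12)
  expect_equal(m$precision, 70 / 84, tolerance = 1e-12)
  # perfect and empty call sets
  expect_identical(confusion_metrics(truth, truth, n_sites = 759)$TPR, 1)
  expect_identical(confusion_metrics(truth, truth, n_sites = 759)$FPR, 0)
  none <- confusion_metrics(integer(0), truth, n_sites = 759)
  expect_identical(none$TPR, 0)
  expect_identical(none$FPR, 0)
  expect_identical(none$precision, 0)
  expect_true(is.na(confusion_metrics(1:3, integer(0),
                                      n_sites = 10)$TPR))
})

test_that("precision-recall sweep is monotone in recall", {
  pr <- precision_recall_curve(c(0.01, 0.9), truth = 1)
  expect_equal(pr$recall[pr$threshold >= 0.01], rep(1, sum(pr$threshold >= 0.01)))
  expect_equal(pr$precision[pr$threshold >= 0.01 & pr$threshold < 0.9],
               rep(1, sum(pr$threshold >= 0.01 & pr$threshold < 0.9)))
  expect_true(all(abs(pr$precision[pr$threshold >= 0.9] - 0.5) < 1e-12))

  set.seed(3)
  pips <- runif(40)
  truth <- sample.int(40, 10)
  pr <- precision_recall_curve(pips, truth)
  expect_true(all(diff(pr$recall) >= 0))
  # truth = all sites: precision 1 wherever anything is called
  pr_all <- precision_recall_curve(pips, 1:40)
  called <- pr_all$threshold >= min(pips)
  expect_equal(pr_all$precision[called], rep(1, sum(called)))
})
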