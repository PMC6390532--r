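test_that("allocation draws are uniform and reproducible", {
  set.seed(1)
  expect_identical(draw_allocations(10, 1), rep(1L, 10))
  z <- draw_allocations(8000, 8)
  freq <- tabulate(z, 8) / 8000
  expect_true(all(abs(freq - 1 / 8) < 3 * sqrt((1 / 8) * (7 / 8) / 8000)))
  set.seed(99); a <- draw_allocations(50, 4)
  set.seed(99); b <- draw_allocations(50, 4)
  expect_identical(a, b)
})

test_that("embedded shifts touch exactly the truth set", {
  set.seed(2)
  alloc <- draw_allocations(759, 8)
  out <- embed_shifts(alloc, 80, 8)
  expect_length(out$truth, 80L)
  expect_identical(which(out$allocation_sub != alloc), out$truth)
  expect_true(all(out$allocation_sub[out$truth] != alloc[out$truth]))
  expect_true(all(out$allocation_sub %in% 1:8))

  none <- embed_shifts(alloc, 0, 8)
  expect_identical(none$allocation_sub, alloc)
  expect_length(none$truth, 0L)
  expect_error(embed_shifts(rep(1L, 5), 2, 1), "single component")
})

test_that("zero-length branches copy the root codon everywhere", {
  set.seed(3)
  rt <- random_tree(6, 0.2, 2)
  tr0 <- scale_branches(rt$tree, 1)
  tr0$edge.length[] <- 0
  des <- simulation_design(tr0, rt$subclade, mutsel_bc(0.75),
                           draw_allocations(10, 8))
  sim <- simulate_alignment(des, seed = 4)
  expect_true(all(apply(sim$alignment$codons, 2,
                        function(col) length(unique(col)) == 1L)))
})

test_that("long-branch star simulation reaches the component's stationary law", {
  set.seed(5)
  n <- 300
  nwk <- paste0("(", paste0("t", 1:n, ":20", collapse = ","), ");")
  tr <- ape::read.tree(text = nwk)
  profiles <- mutsel_bc(0.9)
  mut <- mutation_params()
  des <- simulation_design(tr, character(0), profiles, 3L, mut = mut)
  sim <- simulate_alignment(des, seed = 6)
  gen <- build_generator(mut, profiles$profiles[3, ])
  obs <- tabulate(sim$alignment$codons[, 1], 61) / n
  se <- sqrt(gen$pi * (1 - gen$pi) / n)
  expect_true(all(abs(obs - gen$pi) <= 3 * se + 1e-9))
})

test_that("no-shift simulations give exchangeable partitions", {
  set.seed(7)
  rt <- random_tree(20, 1.0, 8)  # long branches: near-independent leaves
  profiles <- mutsel_bc(0.9)
  alloc <- draw_allocations(60, 8)
  des <- simulation_design(rt$tree, rt$subclade, profiles, alloc)
  sim <- simulate_alignment(des, seed = 8)
  gc <- universal_code()
  in_sub <- sim$alignment$taxa %in% rt$subclade
  # per-site dominant amino acid agrees between partitions at well above
  # chance rate: each partition samples the same stationary distribution
  dominant <- function(rows, n) {
    aa <- gc$aa_index[sim$alignment$codons[rows, n]]
    as.integer(names(which.max(table(aa))))
  }
  agree <- vapply(1:60, function(n)
    dominant(which(in_sub), n) == dominant(which(!in_sub), n), logical(1))
  expect_gte(mean(agree), 0.6)
})

test_that("branch scaling is exact and invertible", {
  set.seed(9)
  rt <- random_tree(10, 0.3, 0)
  tr <- rt$tree
  expect_identical(scale_branches(tr, 1)$edge.length, tr$edge.length)
  expect_equal(sum(scale_branches(tr, 10)$edge.length),
               10 * sum(tr$edge.length), tolerance = 1e-12)
  back <- scale_branches(scale_branches(tr, 10), 0.1)
  expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-12)
  expect_error(scale_branches(tr, 0), "positive")
})

test_that("random trees are binary, rooted, seeded and carry the sub-clade", {
  set.seed(10)
  two <- random_tree(2, 0.1, 0)
  expect_identical(ape::Ntip(two$tree), 2L)
  rt <- random_tree(16, 0.2, 6)
  expect_identical(ape::Ntip(rt$tree), 16L)
  expect_identical(nrow(rt$tree$edge), 30L)  # 2n - 2 edges, rooted binary
  expect_identical(rt$tree$Nnode, 15L)
  expect_true(ape::is.rooted(rt$tree))
  expect_length(rt$subclade, 6L)
  expect_true(ape::is.monophyletic(rt$tree, rt$subclade))
  set.seed(77); a <- random_tree(12, 0.2, 4)
  set.seed(77); b <- random_tree(12, 0.2, 4)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
})

test_that("profile ambiguity inflates no-shift PIP sensitivity to the analysis set", {
  # two near-identical components (same dominant group, different
  # weighting) split the allocation between them; a grouped set with one
  # component per biochemical class keeps the allocation together, so the
  # no-shift PIP is higher under the grouped analysis
  set.seed(15)
  base <- mutsel_bc(0.9)$profiles
  confusable <- rbind(base["small_nonpolar", ],
                      0.7 * base["small_nonpolar", ] +
                        0.3 * rep(1 / 20, 20),
                      base["aromatic", ], base["polar_positive", ])
  confusable <- confusable / rowSums(confusable)
  path <- withr::local_tempfile(fileext = ".profiles")
  writeLines(apply(confusable, 1, paste, collapse = " "), path)
  conf_set <- load_profile_table(path)

  rt <- random_tree(16, 0.35, 6)
  alloc <- rep(1L, 60)  # all sites in the shared dominant group, no shift
  mut <- mutation_params()
  des <- simulation_design(rt$tree, rt$subclade, conf_set, alloc,
                           mut = mut)
  sim <- simulate_alignment(des, seed = 16)
  cfg <- chain_config(sweeps = 1500, seed = 17, mut = mut)
  res_conf <- detect_shifts(sim$alignment, rt$tree, rt$subclade, conf_set,
                            cfg)
  res_bc <- detect_shifts(sim$alignment, rt$tree, rt$subclade,
                          mutsel_bc(0.9), cfg)
  expect_gt(mean(res_bc$report$pip), mean(res_conf$report$pip))
})
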