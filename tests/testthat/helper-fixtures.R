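# Shared fixtures and independent oracles for the test suite.

# Brute-force site likelihood by exhaustive enumeration over internal-node
# states.  Deliberately independent of the pruning implementation: it
# multiplies edge transition probabilities over an explicit state grid.
# Only usable for trees with <= 3 internal nodes (61^3 combinations).
brute_force_site_loglik <- function(obs, tree, gen) {
  ed <- tree$edge
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  stopifnot(nint <= 3L)
  P <- lapply(tree$edge.length,
              function(t) transition_probabilities(gen, t))
  grid <- as.matrix(expand.grid(rep(list(1:61), nint)))
  pr <- gen$pi[grid[, 1]]  # ape convention: root node is ntip + 1
  for (e in seq_len(nrow(ed))) {
    par_state <- grid[, ed[e, 1] - ntip]
    child <- ed[e, 2]
    if (child <= ntip) {
      o <- obs[tree$tip.label[child]]
      if (is.na(o)) next  # missing leaf: sum_y P[x, y] = 1
      pr <- pr * P[[e]][cbind(par_state, o)]
    } else {
      pr <- pr * P[[e]][cbind(par_state, grid[, child - ntip])]
    }
  }
  log(sum(pr))
}

# small random codon alignment over given taxa
random_alignment <- function(taxa, n_sites, missing_frac = 0) {
  m <- matrix(sample.int(61L, length(taxa) * n_sites, replace = TRUE),
              length(taxa), n_sites, dimnames = list(taxa, NULL))
  if (missing_frac > 0) {
    drop <- runif(length(m)) < missing_frac
    m[drop] <- NA_integer_
  }
  codon_alignment(m)
}

# fixed 4-taxon balanced rooted tree (3 internal nodes)
tree4 <- function() {
  ape::read.tree(text = "((A:0.2,B:0.3):0.1,(C:0.15,D:0.25):0.2);")
}

# 5-taxon tree with a multifurcation, still 3 internal nodes
tree5 <- function() {
  ape::read.tree(text = "((A:0.2,B:0.3,C:0.1):0.15,(D:0.25,E:0.1):0.2);")
}

# exact joint posterior over allocations for a tiny mixture fixture with
# the weights integrated out under a flat Dirichlet (Polya urn):
# p(z) propto prod_k Gamma(1 + eta_k) * prod_n L[n, z_n]
enumerate_allocation_posterior <- function(logliks) {
  N <- nrow(logliks); K <- ncol(logliks)
  combos <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  logp <- apply(combos, 1, function(z) {
    eta <- tabulate(z, nbins = K)
    sum(lgamma(1 + eta)) + sum(logliks[cbind(seq_len(N), z)])
  })
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  list(combos = combos, prob = p,
       site_marginals = t(vapply(seq_len(N), function(n) {
         vapply(seq_len(K), function(k) sum(p[combos[, n] == k]),
                numeric(1))
       }, numeric(K))))
}

# matched-seed simulation + two-partition analysis; returns TPR/FPR at
# the given PIP threshold.  theta is held fixed at the simulation truth.
run_shift_study <- function(peakedness, branch_scale = 1, seed = 11,
                            n_taxa = 16, clade_size = 6, n_sites = 200,
                            n_shift = 20, mean_branch = 0.35,
                            sweeps = 2000, threshold = 0.05) {
  set.seed(seed)
  rt <- random_tree(n_taxa, mean_branch, clade_size)
  alloc <- draw_allocations(n_sites, 8)
  shifts <- embed_shifts(alloc, n_shift, 8)
  mut <- mutation_params()
  profiles <- mutsel_bc(peakedness)
  tree <- scale_branches(rt$tree, branch_scale)
  des <- simulation_design(tree, rt$subclade, profiles, alloc,
                           shifts$allocation_sub, mut)
  sim <- simulate_alignment(des, seed = seed + 1)
  res <- detect_shifts(sim$alignment, tree, rt$subclade, profiles,
                       chain_config(sweeps = sweeps, seed = 99, mut = mut),
                       threshold = threshold)
  m <- confusion_metrics(res$report, sim$truth)
  list(TPR = m$TPR, FPR = m$FPR, report = res$report, truth = sim$truth)
}
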