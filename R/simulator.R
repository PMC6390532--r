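# Simulation of codon alignments under the mixture model on a fixed
# rooted tree, with optional sub-clade profile shifts: the synthetic-data
# generator behind all simulation studies in the package.
#
# Each site evolves under the generator of its allocated component; at
# shifted sites, every branch from the designated sub-clade's stem
# downward uses the alternative component instead (the regime change is
# placed on the stem, i.e. before the sub-clade's MRCA).  States are
# sampled branch-wise from exp(Qt), which is equivalent in distribution
# to event-level simulation and simpler to verify.

#' Uniform i.i.d. site-to-component allocations
#'
#' @param N Number of codon sites.
#' @param K Number of mixture components.
#' @return Length-N integer vector of components drawn uniformly from
#'   1..K.
#' @export
draw_allocations <- function(N, K) {
  if (N < 1L || K < 1L) stop("N and K must be >= 1")
  sample.int(K, N, replace = TRUE)
}

#' Embed sub-clade profile shifts into an allocation vector
#'
#' Picks \code{n_shift} sites uniformly without replacement; at each, the
#' sub-clade allocation is redrawn uniformly from the K - 1 components
#' different from the main allocation.  All other sites keep the main
#' allocation.
#'
#' @param allocation_main Length-N main-tree allocation vector.
#' @param n_shift Number of shifted sites.
#' @param K Number of components.
#' @return List with \code{allocation_sub} (length N) and \code{truth}
#'   (sorted integer vector of the shifted sites).
#' @export
embed_shifts <- function(allocation_main, n_shift, K) {
  N <- length(allocation_main)
  if (n_shift > N) stop("n_shift exceeds the number of sites")
  if (n_shift > 0 && K < 2L)
    stop("cannot embed shifts with a single component")
  allocation_sub <- allocation_main
  truth <- integer(0)
  if (n_shift > 0) {
    truth <- sort(sample.int(N, n_shift))
    for (s in truth) {
      alternatives <- setdiff(seq_len(K), allocation_main[s])
      allocation_sub[s] <- if (length(alternatives) == 1L) alternatives else
        sample(alternatives, 1L)
    }
  }
  list(allocation_sub = allocation_sub, truth = truth)
}

#' Multiply all branch lengths by a factor
#'
#' Used for the information-content studies: scaling all branch lengths
#' by 0.1 mimics a low-signal alignment, by 10 a high-signal one.
#'
#' @param tree A \code{phylo}.
#' @param factor Positive scale factor.
#' @return The tree with every branch length multiplied by \code{factor}.
#' @export
scale_branches <- function(tree, factor) {
  .check_tree(tree)
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("factor must be a single positive number")
  tree$edge.length <- tree$edge.length * factor
  tree
}

# random sequential-join topology over labels, exponential branch lengths
.random_join_newick <- function(labels, mean_branch) {
  groups <- as.list(labels)
  while (length(groups) > 1L) {
    pick <- sample.int(length(groups), 2L)
    bl <- stats::rexp(2, rate = 1 / mean_branch)
    merged <- sprintf("(%s:%.10f,%s:%.10f)",
                      groups[[pick[1]]], bl[1], groups[[pick[2]]], bl[2])
    groups <- c(groups[-pick], merged)
  }
  groups[[1]]
}

#' Random rooted binary tree with a designated sub-clade
#'
#' Generates a random bifurcating topology by uniform sequential joins,
#' with i.i.d. exponential branch lengths, and (optionally) a designated
#' monophyletic sub-clade of a requested size for shift experiments.
#' Sub-clade tips are labelled \code{sub1..subk}, the remainder
#' \code{out1..}.
#'
#' @param n_taxa Total number of tips (>= 2).
#' @param mean_branch Mean of the exponential branch-length distribution
#'   (expected substitutions/site).
#' @param clade_size Size of the designated sub-clade (0 for none; must
#'   leave at least 2 taxa outside).
#' @return List with \code{tree} (rooted \code{phylo}) and
#'   \code{subclade} (character vector of sub-clade tip labels, possibly
#'   empty).
#' @export
random_tree <- function(n_taxa, mean_branch = 0.1, clade_size = 0L) {
  if (n_taxa < 2L) stop("need at least 2 taxa")
  if (clade_size >= n_taxa - 1L && clade_size > 0L)
    stop("clade size must leave at least 2 taxa outside the sub-clade")
  if (clade_size > 0L) {
    sub_labels <- paste0("sub", seq_len(clade_size))
    out_labels <- paste0("out", seq_len(n_taxa - clade_size))
    sub_nwk <- if (clade_size == 1L) sub_labels else
      .random_join_newick(sub_labels, mean_branch)
    out_nwk <- .random_join_newick(out_labels, mean_branch)
    bl <- stats::rexp(2, rate = 1 / mean_branch)
    nwk <- sprintf("(%s:%.10f,%s:%.10f);", out_nwk, bl[1], sub_nwk, bl[2])
  } else {
    sub_labels <- character(0)
    nwk <- paste0(.random_join_newick(paste0("t", seq_len(n_taxa)),
                                      mean_branch), ";")
  }
  tree <- ape::read.tree(text = nwk)
  list(tree = tree, subclade = sub_labels)
}

# edge indices whose child lies in (or is) the clade rooted at the MRCA of
# `subclade`, including the stem edge leading to the MRCA
.subclade_edges <- function(tree, subclade) {
  if (length(subclade) == 0L) return(integer(0))
  tips <- match(subclade, tree$tip.label)
  if (anyNA(tips)) stop("sub-clade taxa missing from tree")
  if (length(tips) == 1L) return(which(tree$edge[, 2] == tips))
  if (!ape::is.monophyletic(tree, subclade))
    stop("sub-clade is not monophyletic in the tree")
  mrca <- ape::getMRCA(tree, tips)
  in_clade <- logical(max(tree$edge))
  in_clade[mrca] <- TRUE
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(pre)))
    if (in_clade[pre[e, 1]]) in_clade[pre[e, 2]] <- TRUE
  which(in_clade[tree$edge[, 2]] | tree$edge[, 2] == mrca)
}

#' Simulation design constructor
#'
#' Bundles everything [simulate_alignment()] needs: the tree, the
#' designated sub-clade, the profile set, the main-tree and sub-clade
#' allocation vectors, and the mutation parameters.
#'
#' @param tree Rooted \code{phylo} with branch lengths.
#' @param subclade Character vector of sub-clade tip labels (may be
#'   empty when no shift regime is wanted).
#' @param profiles A \code{profile_set}.
#' @param allocation_main Length-N component indices governing the whole
#'   tree (outside the sub-clade).
#' @param allocation_sub Length-N component indices governing the
#'   sub-clade (defaults to \code{allocation_main}: no shifts).
#' @param mut A \code{mutation_params}.
#' @return A \code{simulation_design} list; \code{truth} holds the sites
#'   where the two allocation vectors differ.
#' @export
simulation_design <- function(tree, subclade, profiles, allocation_main,
                              allocation_sub = allocation_main,
                              mut = mutation_params()) {
  .check_tree(tree)
  stopifnot(inherits(profiles, "profile_set"))
  K <- n_components(profiles)
  if (length(allocation_main) != length(allocation_sub))
    stop("allocation vectors differ in length")
  if (any(c(allocation_main, allocation_sub) < 1L) ||
      any(c(allocation_main, allocation_sub) > K))
    stop("allocations out of range 1..K")
  if (length(subclade) > 1L && !ape::is.monophyletic(tree, subclade))
    stop("sub-clade is not monophyletic in the tree")
  truth <- which(allocation_main != allocation_sub)
  if (length(truth) && length(subclade) == 0L)
    stop("shifted sites given but no sub-clade designated")
  structure(list(tree = tree, subclade = subclade, profiles = profiles,
                 allocation_main = as.integer(allocation_main),
                 allocation_sub = as.integer(allocation_sub),
                 mut = mut, truth = truth),
            class = "simulation_design")
}

#' Simulate a codon alignment under a design
#'
#' Per site, the root codon is drawn from the stationary distribution of
#' the site's main-allocation component; states then evolve down each
#' branch by sampling from the branch's transition matrix.  On every
#' branch from the sub-clade's stem downward, shifted sites use the
#' sub-allocation component's generator instead.
#'
#' @param design A [simulation_design()].
#' @param seed Optional integer seed for reproducibility.
#' @return List with \code{alignment} (a \code{codon_alignment} over the
#'   tree's tips) and \code{truth} (shifted site indices).
#' @export
simulate_alignment <- function(design, seed = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  if (!is.null(seed)) set.seed(seed)
  tree <- design$tree
  N <- length(design$allocation_main)
  K <- n_components(design$profiles)
  ntip <- length(tree$tip.label)

  gens <- lapply(seq_len(K), function(k)
    build_generator(design$mut, design$profiles$profiles[k, ]))

  shifted_edges <- .subclade_edges(tree, design$subclade)
  pre <- ape::reorder.phylo(tree, "cladewise")
  edge_order <- match(paste(pre$edge[, 1], pre$edge[, 2]),
                      paste(tree$edge[, 1], tree$edge[, 2]))

  states <- matrix(NA_integer_, max(tree$edge), N)
  root <- ntip + 1L
  for (k in unique(design$allocation_main)) {
    idx <- which(design$allocation_main == k)
    states[root, idx] <- sample.int(61L, length(idx), replace = TRUE,
                                    prob = gens[[k]]$pi)
  }

  Pcache <- new.env(parent = emptyenv())
  getP <- function(k, len) {
    key <- paste0(k, "_", format(len, digits = 17))
    P <- Pcache[[key]]
    if (is.null(P)) {
      P <- transition_probabilities(gens[[k]], len)
      Pcache[[key]] <- P
    }
    P
  }

  for (e in edge_order) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    len <- tree$edge.length[e]
    alloc <- if (e %in% shifted_edges) design$allocation_sub else
      design$allocation_main
    for (k in unique(alloc)) {
      idx <- which(alloc == k)
      P <- getP(k, len)
      for (p_state in unique(states[parent, idx])) {
        sub <- idx[states[parent, idx] == p_state]
        states[child, sub] <- sample.int(61L, length(sub), replace = TRUE,
                                         prob = P[p_state, ])
      }
    }
  }

  codons <- states[seq_len(ntip), , drop = FALSE]
  rownames(codons) <- tree$tip.label
  list(alignment = codon_alignment(codons), truth = design$truth)
}
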