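# Per-site, per-component phylogenetic likelihoods by Felsenstein pruning
# on a fixed rooted tree, and the weighted-sum mixture likelihood.
#
# Trees are ape "phylo" objects with branch lengths in expected
# substitutions per codon site (the generator normalisation).  The root
# state prior is the component's stationary distribution, as forced by
# reversibility and the equilibrium assumption of the model.

#' Construct a codon alignment
#'
#' @param codons Integer matrix, taxa x sites; entries are sense-codon
#'   indices (1..61) or NA for missing data.  Row names are taxon labels.
#' @return An object of class \code{codon_alignment}.
#' @seealso [read_alignment()] for building one from FASTA/PHYLIP.
#' @export
codon_alignment <- function(codons) {
  codons <- as.matrix(codons)
  if (is.null(rownames(codons))) stop("codon matrix must have taxon row names")
  if (anyDuplicated(rownames(codons))) stop("duplicate taxon names")
  storage.mode(codons) <- "integer"
  ok <- is.na(codons) | (codons >= 1L & codons <= 61L)
  if (!all(ok)) stop("codon indices must be in 1..61 or NA")
  structure(list(taxa = rownames(codons), codons = codons,
                 n_sites = ncol(codons)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("Codon alignment: %d taxa x %d sites (%.1f%% missing)\n",
              length(x$taxa), x$n_sites, 100 * mean(is.na(x$codons))))
  invisible(x)
}

.check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(is.na(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be non-negative and present on every edge")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  invisible(tree)
}

.match_taxa <- function(aln, tree) {
  m <- match(tree$tip.label, aln$taxa)
  if (anyNA(m))
    stop("taxa in tree but not in alignment: ",
         paste(tree$tip.label[is.na(m)], collapse = ", "))
  extra <- setdiff(aln$taxa, tree$tip.label)
  if (length(extra))
    stop("taxa in alignment but not in tree: ", paste(extra, collapse = ", "))
  m
}

# Pruning for one component: returns length-N vector of per-site
# log-likelihoods.  P matrices are precomputed per unique branch length.
.prune_component <- function(codons_by_tip, tree, gen) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  nsite <- ncol(codons_by_tip)
  post <- ape::reorder.phylo(tree, "postorder")
  edges <- post$edge
  elen <- post$edge.length

  Pcache <- new.env(parent = emptyenv())
  getP <- function(t) {
    key <- format(t, digits = 17)
    P <- Pcache[[key]]
    if (is.null(P)) {
      P <- transition_probabilities(gen, t)
      Pcache[[key]] <- P
    }
    P
  }

  partials <- vector("list", ntip + nnode)
  logscale <- matrix(0, 1, nsite)
  # leaf partials: indicator columns; missing -> all ones
  for (tip in seq_len(ntip)) {
    M <- matrix(0, 61, nsite)
    obs <- codons_by_tip[tip, ]
    miss <- is.na(obs)
    if (any(!miss)) M[cbind(obs[!miss], which(!miss))] <- 1
    if (any(miss)) M[, miss] <- 1
    partials[[tip]] <- M
  }
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1]; child <- edges[e, 2]
    # rows of P index the parent state: contribution to parent state x is
    # sum_y P[x, y] * partial_child[y]
    contrib <- getP(elen[e]) %*% partials[[child]]
    if (is.null(partials[[parent]])) {
      partials[[parent]] <- contrib
    } else {
      partials[[parent]] <- partials[[parent]] * contrib
    }
    # rescale to guard against underflow on deep trees
    cmax <- apply(partials[[parent]], 2, max)
    cmax[cmax == 0] <- 1
    partials[[parent]] <- sweep(partials[[parent]], 2, cmax, "/")
    logscale <- logscale + log(cmax)
  }
  root <- ntip + 1L
  lik <- colSums(gen$pi * partials[[root]])
  as.numeric(log(lik) + logscale)
}

# build one generator per mixture component
.component_generators <- function(mut, profiles, code = universal_code()) {
  lapply(seq_len(n_components(profiles)), function(k)
    build_generator(mut, profiles$profiles[k, ], code))
}

# N x K log-likelihood table from prebuilt generators; codons_by_tip rows
# must already be ordered like tree$tip.label
.logliks_from_gens <- function(codons_by_tip, tree, gens) {
  out <- matrix(NA_real_, ncol(codons_by_tip), length(gens))
  for (k in seq_along(gens))
    out[, k] <- .prune_component(codons_by_tip, tree, gens[[k]])
  out
}

#' Per-site log-likelihoods for every mixture component
#'
#' Runs the pruning algorithm once per component and returns the N x K
#' table of site log-likelihoods \eqn{\log p(D_n \mid \theta, \psi^{(k)})}
#' that both allocation samplers consume.  Missing leaves contribute
#' all-ones partials; an all-missing column has likelihood 1 (log 0).
#'
#' @param aln A \code{codon_alignment}.
#' @param tree Rooted \code{phylo} with branch lengths; tip labels must
#'   match the alignment taxa exactly.
#' @param mut A \code{mutation_params}.
#' @param profiles A \code{profile_set}.
#' @param code A \code{genetic_code}.
#' @return N x K numeric matrix of log-likelihoods.
#' @export
all_site_component_likelihoods <- function(aln, tree, mut, profiles,
                                           code = universal_code()) {
  stopifnot(inherits(aln, "codon_alignment"),
            inherits(profiles, "profile_set"))
  .check_tree(tree)
  m <- .match_taxa(aln, tree)
  codons_by_tip <- aln$codons[m, , drop = FALSE]
  out <- .logliks_from_gens(codons_by_tip, tree,
                            .component_generators(mut, profiles, code))
  colnames(out) <- rownames(profiles$profiles)
  out
}

#' Pruning log-likelihood of one site under one component
#'
#' @inheritParams all_site_component_likelihoods
#' @param psi Length-20 amino acid profile for the component.
#' @param n Site index (1-based).
#' @return The site log-likelihood \eqn{\log p(D_n \mid \theta, \psi)}.
#' @export
site_component_likelihood <- function(aln, tree, mut, psi, n,
                                      code = universal_code()) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (n < 1L || n > aln$n_sites) stop("site index out of range")
  .check_tree(tree)
  m <- .match_taxa(aln, tree)
  gen <- build_generator(mut, psi, code)
  .prune_component(aln$codons[m, n, drop = FALSE], tree, gen)
}

#' Weighted-sum mixture likelihood of a site
#'
#' \eqn{\log p(D_n \mid \theta) = \log \sum_k w_k\, p(D_n \mid \theta,
#' \psi^{(k)})}, computed by log-sum-exp so that component likelihoods
#' spanning hundreds of log units are handled stably.
#'
#' @param logliks Length-K vector of component log-likelihoods for the
#'   site (or an N x K matrix, in which case a length-N vector is
#'   returned).
#' @param w Length-K weight vector summing to 1.
#' @return Log mixture likelihood(s).
#' @export
mixture_site_likelihood <- function(logliks, w) {
  if (is.matrix(logliks)) {
    if (ncol(logliks) != length(w)) stop("weight/component length mismatch")
    lw <- sweep(logliks, 2, log(w), "+")
    mx <- apply(lw, 1, max)
    return(mx + log(rowSums(exp(lw - mx))))
  }
  if (length(logliks) != length(w)) stop("weight/component length mismatch")
  if (abs(sum(w) - 1) > 1e-6) stop("weights must sum to 1")
  lw <- logliks + log(w)
  mx <- max(lw)
  mx + log(sum(exp(lw - mx)))
}
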