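# Mutation-selection codon generator per mixture component.
#
# The infinitesimal rate from sense codon i to sense codon j (single
# nucleotide change a -> b at position c, j not a stop) is
#
#   Q_ij = rho_ab * phi_b * S_ij / (1 - exp(-S_ij)),
#
# where rho are symmetric nucleotide exchangeabilities, phi nucleotide
# propensities, and S_ij = ln psi_f(j) - ln psi_f(i) the scaled selection
# coefficient from the amino acid fitness profile psi.  The stationary
# distribution has the closed form pi_i ~ phi_i1 phi_i2 phi_i3 psi_f(i),
# and the chain is reversible with respect to it.

.RHO_PAIRS <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' Nucleotide-level mutation parameters
#'
#' Bundles the six symmetric nucleotide exchangeabilities (unordered pairs
#' AC, AG, AT, CG, CT, GT; constrained to sum to 1) and the four nucleotide
#' propensities (A, C, G, T; sum 1) composing the mutation rate
#' \eqn{\mu_{ij} = \rho_{ab}\,\varphi_b}.
#'
#' The defaults are transition-rich, A-biased values typical of posterior
#' means for RNA-virus protein-coding genes, and are the simulation defaults
#' used throughout the package.
#'
#' @param rho Numeric vector of 6 non-negative exchangeabilities, order
#'   AC, AG, AT, CG, CT, GT; normalised to sum 1.
#' @param phi Numeric vector of 4 positive propensities (A, C, G, T);
#'   normalised to sum 1.
#' @return An object of class \code{mutation_params}.
#' @export
mutation_params <- function(rho = c(0.05, 0.30, 0.05, 0.05, 0.45, 0.10),
                            phi = c(0.35, 0.18, 0.23, 0.24)) {
  rho <- as.numeric(rho); phi <- as.numeric(phi)
  if (length(rho) != 6L || any(rho < 0) || sum(rho) <= 0)
    stop("rho must be 6 non-negative exchangeabilities")
  if (length(phi) != 4L || any(phi <= 0))
    stop("phi must be 4 strictly positive propensities")
  rho <- rho / sum(rho)
  phi <- phi / sum(phi)
  names(rho) <- .RHO_PAIRS
  names(phi) <- NUCLEOTIDES
  structure(list(rho = rho, phi = phi), class = "mutation_params")
}

# symmetric lookup rho[a, b] as a 4x4 matrix
.rho_matrix <- function(mut) {
  m <- matrix(0, 4, 4, dimnames = list(NUCLEOTIDES, NUCLEOTIDES))
  m["A", "C"] <- m["C", "A"] <- mut$rho["AC"]
  m["A", "G"] <- m["G", "A"] <- mut$rho["AG"]
  m["A", "T"] <- m["T", "A"] <- mut$rho["AT"]
  m["C", "G"] <- m["G", "C"] <- mut$rho["CG"]
  m["C", "T"] <- m["T", "C"] <- mut$rho["CT"]
  m["G", "T"] <- m["T", "G"] <- mut$rho["GT"]
  m
}

#' Scaled selection coefficient between two codons
#'
#' \eqn{S_{ij} = \ln\psi_{f(j)} - \ln\psi_{f(i)}}: the log fitness
#' difference between the amino acids encoded by codons \code{j} and
#' \code{i} under profile \code{psi}.  Zero for synonymous pairs and
#' antisymmetric in (i, j).
#'
#' @param psi Length-20 positive profile vector (amino-acid order as in
#'   \code{AMINO_ACIDS}).
#' @param i,j Sense codon indices (1..61).
#' @param code A \code{genetic_code}.
#' @return The selection coefficient (dimensionless, scaled by population
#'   size).
#' @export
selection_coefficient <- function(psi, i, j, code = universal_code()) {
  if (any(c(i, j) < 1L) || any(c(i, j) > 61L))
    stop("codon index out of range 1..61")
  log(psi[code$aa_index[j]]) - log(psi[code$aa_index[i]])
}

#' Fixation factor S / (1 - exp(-S))
#'
#' The population-genetic fixation factor scaling a mutation rate by the
#' probability of fixation of the new allele, relative to neutral.
#' Continuous at S = 0 with value 1 (a second-order series is used for
#' |S| < 1e-8), and satisfies \eqn{h(S) = e^S h(-S)}.
#'
#' @param S Selection coefficient(s); vectorised.
#' @return Fixation factor(s), strictly positive.
#' @export
fixation_factor <- function(S) {
  out <- ifelse(abs(S) < 1e-8, 1 + S / 2, S / (1 - exp(-S)))
  as.numeric(out)
}

#' Build the mutation-selection generator for one mixture component
#'
#' Assembles the 61 x 61 infinitesimal rate matrix for a single amino acid
#' fitness profile: for codon pairs differing at exactly one nucleotide
#' (and not producing a stop codon),
#' \eqn{Q_{ij} = \rho_{ab}\varphi_b \, S_{ij}/(1 - e^{-S_{ij}})};
#' all other off-diagonal entries are zero; diagonals are negative row
#' sums.
#'
#' By default the generator is rescaled so the expected substitution rate
#' at its own stationary distribution is 1 (\eqn{-\sum_i \pi_i Q_{ii} = 1}),
#' making branch lengths interpretable as expected substitutions per codon
#' site; pass \code{normalize = FALSE} for the raw matrix when
#' cross-checking against other software.
#'
#' @param mut A \code{mutation_params} object.
#' @param psi Length-20 positive amino acid profile.
#' @param code A \code{genetic_code}.
#' @param normalize Rescale to unit expected rate at stationarity
#'   (default TRUE).
#' @return An object of class \code{component_generator}: list with
#'   \code{Q} (61 x 61), \code{pi} (stationary distribution), \code{scale}
#'   (the factor Q was divided by), and a cached symmetric
#'   eigendecomposition used by [transition_probabilities()].
#' @export
build_generator <- function(mut, psi, code = universal_code(),
                            normalize = TRUE) {
  stopifnot(inherits(mut, "mutation_params"))
  psi <- as.numeric(psi)
  if (length(psi) != 20L || any(psi <= 0))
    stop("psi must be a length-20 strictly positive profile")
  psi <- psi / sum(psi)
  rho_m <- .rho_matrix(mut)
  logpsi <- log(psi)

  Q <- matrix(0, 61, 61, dimnames = list(code$codons, code$codons))
  for (i in 1:61) {
    nb <- code$neighbors[[i]]
    S <- logpsi[code$aa_index[nb[, "j"]]] - logpsi[code$aa_index[i]]
    Q[i, nb[, "j"]] <- rho_m[cbind(nb[, "from"], nb[, "to"])] *
      mut$phi[nb[, "to"]] * fixation_factor(S)
  }
  diag(Q) <- -rowSums(Q)

  pi <- stationary_closed_form(mut, psi, code)
  scale <- 1
  if (normalize) {
    scale <- -sum(pi * diag(Q))
    Q <- Q / scale
  }

  # symmetric eigendecomposition of B = D^{1/2} Q D^{-1/2} (reversibility)
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)

  structure(list(Q = Q, pi = pi, scale = scale, psi = psi, mut = mut,
                 eig = list(values = eig$values, vectors = eig$vectors,
                            sq = sq)),
            class = "component_generator")
}

#' Closed-form stationary distribution of a mutation-selection generator
#'
#' \eqn{\pi_i \propto \varphi_{i_1}\varphi_{i_2}\varphi_{i_3}\psi_{f(i)}}
#' over the 61 sense codons.
#'
#' @inheritParams build_generator
#' @return Length-61 probability vector named by codon.
#' @export
stationary_closed_form <- function(mut, psi, code = universal_code()) {
  psi <- psi / sum(psi)
  pi <- mut$phi[code$nuc_index[, 1]] * mut$phi[code$nuc_index[, 2]] *
    mut$phi[code$nuc_index[, 3]] * psi[code$aa_index]
  pi <- pi / sum(pi)
  names(pi) <- code$codons
  pi
}

#' Stationary distribution of a built generator
#'
#' @param gen A \code{component_generator}.
#' @return Length-61 probability vector (the closed form cached at build
#'   time, which agrees with the numerical left null vector of Q).
#' @export
stationary_distribution <- function(gen) {
  stopifnot(inherits(gen, "component_generator"))
  gen$pi
}

#' Transition probability matrix exp(Qt)
#'
#' Computes the codon transition probabilities over a branch of length
#' \code{t} (expected substitutions per codon site under the default
#' normalisation) via the generator's reversible symmetric
#' eigendecomposition.  Tiny negative entries from floating-point rounding
#' are clamped to zero and rows renormalised.
#'
#' @param gen A \code{component_generator}.
#' @param t Branch length, >= 0.
#' @return 61 x 61 row-stochastic matrix.
#' @export
transition_probabilities <- function(gen, t) {
  stopifnot(inherits(gen, "component_generator"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("branch length t must be a single value >= 0")
  if (t == 0) {
    P <- diag(61)
    dimnames(P) <- dimnames(gen$Q)
    return(P)
  }
  V <- gen$eig$vectors
  e <- exp(gen$eig$values * t)
  sq <- gen$eig$sq
  P <- (V %*% (e * t(V)))
  P <- P * ((1 / sq) %o% sq)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(gen$Q)
  P
}

#' Expected non-synonymous substitution rate at stationarity
#'
#' Flux through codon pairs encoding different amino acids, under the
#' generator's own stationary distribution.  With a peaked profile this
#' rate is much lower than with a flat profile: the fixation factor
#' suppresses mutations away from the high-fitness group.
#'
#' @param gen A \code{component_generator}.
#' @param code A \code{genetic_code}.
#' @return Non-negative scalar.
#' @export
nonsynonymous_rate <- function(gen, code = universal_code()) {
  syn <- outer(code$aa_index, code$aa_index, "==")
  Qoff <- gen$Q
  diag(Qoff) <- 0
  sum(gen$pi * rowSums(Qoff * !syn))
}
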