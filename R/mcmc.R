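# MCMC over site-to-component allocations z, mixture weights w, nucleotide
# mutation parameters and branch lengths.
#
# Two allocation samplers are provided.  The count-based Gibbs sampler
# resamples one site at a time with probability proportional to
# (eta_k + 1) p(D_n | theta, psi^(k)), where eta_k counts the sites
# currently affiliated to component k after removing site n; this
# implicitly integrates the weights under a flat Dirichlet (Polya urn).
# The weight-demarginalised sampler draws all sites independently with
# probability proportional to w_k p(D_n | theta, psi^(k)) and then
# refreshes w from its Dirichlet(1 + eta) conditional; it targets the same
# marginal posterior over z and is order-independent, hence
# parallelisable.  The weighted sampler is the default.

#' Allocation state constructor
#'
#' @param z Length-N integer vector of component indices in 1..K.
#' @param K Number of mixture components.
#' @return List with \code{z} and the occupancy counts \code{eta}
#'   (\eqn{\eta_k = |\{n : z_n = k\}|}).
#' @export
allocation_state <- function(z, K) {
  z <- as.integer(z)
  if (any(z < 1L | z > K)) stop("allocations out of range 1..K")
  eta <- tabulate(z, nbins = K)
  list(z = z, eta = eta, K = K)
}

# conditional allocation probabilities of one site under the Polya urn,
# given post-decrement counts and the site's component log-likelihoods
.gibbs_site_probs <- function(eta_minus, loglik_row) {
  lp <- log(eta_minus + 1) + loglik_row
  p <- exp(lp - max(lp))
  p / sum(p)
}

#' One count-based Gibbs sweep over site allocations
#'
#' Sequentially resamples each site's allocation: the site's current
#' component count is decremented, a new component is drawn with
#' probability proportional to \eqn{(\eta_k + 1)\, p(D_n \mid \theta,
#' \psi^{(k)})} under the current counts, and the chosen count is
#' incremented.  The sequential dependence between sites is what
#' integrates the mixture weights out (flat Dirichlet prior).
#'
#' @param state An allocation state from [allocation_state()].
#' @param logliks N x K matrix of site/component log-likelihoods.
#' @return Updated allocation state.
#' @export
gibbs_allocation_sweep <- function(state, logliks) {
  z <- state$z; eta <- state$eta; K <- state$K
  if (length(z) != nrow(logliks) || K != ncol(logliks))
    stop("log-likelihood table does not match allocation state")
  if (!identical(tabulate(z, nbins = K), as.integer(eta)))
    stop("internal state error: counts inconsistent with allocations")
  for (n in seq_along(z)) {
    eta[z[n]] <- eta[z[n]] - 1L
    p <- .gibbs_site_probs(eta, logliks[n, ])
    k <- sample.int(K, 1L, prob = p)
    z[n] <- k
    eta[k] <- eta[k] + 1L
  }
  list(z = z, eta = eta, K = K)
}

#' One weight-conditional allocation sweep
#'
#' Draws every site's allocation independently with probability
#' proportional to \eqn{w_k\, p(D_n \mid \theta, \psi^{(k)})}.  The result
#' does not depend on the order sites are processed, which is what makes
#' this sampler parallelisable.  Sampling uses the Gumbel-max trick so the
#' whole sweep is one vectorised draw.
#'
#' @param logliks N x K matrix of site/component log-likelihoods.
#' @param w Length-K weight vector (summing to 1).
#' @return Allocation state (see [allocation_state()]).
#' @export
weighted_allocation_sweep <- function(logliks, w) {
  K <- ncol(logliks)
  if (length(w) != K) stop("weights do not match number of components")
  if (any(w < 0) || sum(w) <= 0) stop("invalid weights")
  lp <- sweep(logliks, 2, log(w), "+")
  g <- -log(-log(matrix(stats::runif(length(lp)), nrow(lp), K)))
  z <- max.col(lp + g, ties.method = "first")
  allocation_state(z, K)
}

#' Conjugate weight update
#'
#' Draws the mixture weights from their full conditional under a flat
#' Dirichlet prior: \eqn{w \mid z \sim \mathrm{Dirichlet}(1 + \eta_1,
#' \dots, 1 + \eta_K)}.  Alternating this draw with
#' [weighted_allocation_sweep()] targets the same marginal law over z as
#' the count-based sampler.
#'
#' @param eta Length-K occupancy counts.
#' @return Length-K weight vector.
#' @export
update_weights <- function(eta) {
  g <- stats::rgamma(length(eta), shape = 1 + eta, rate = 1)
  g / sum(g)
}

# log density of Dirichlet(alpha) at x (both length-d, x on the simplex)
.ldirichlet <- function(x, alpha) {
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

# Dirichlet proposal centred at the current simplex value with
# concentration 1/step (plus 1 per coordinate for properness); returns the
# proposed value and the Hastings log-ratio log q(x|y) - log q(y|x).
# step = 0 degenerates to the identity proposal (returned as NULL).
.simplex_propose <- function(current, step) {
  if (step <= 0) return(NULL)
  conc <- 1 / step
  a_fwd <- conc * current + 1
  prop <- stats::rgamma(length(current), shape = a_fwd, rate = 1)
  if (all(prop == 0)) return(NULL)
  prop <- prop / sum(prop)
  prop[prop < 1e-12] <- 1e-12
  prop <- prop / sum(prop)
  a_rev <- conc * prop + 1
  list(value = prop,
       log_hastings = .ldirichlet(current, a_rev) -
         .ldirichlet(prop, a_fwd))
}

# Metropolis-Hastings step for a simplex-valued parameter with a flat
# Dirichlet prior; step = 0 is the identity proposal, always accepted.
.simplex_mh <- function(current, step, logtarget) {
  if (step <= 0) return(list(value = current, accepted = TRUE))
  prop <- .simplex_propose(current, step)
  if (is.null(prop)) return(list(value = current, accepted = FALSE))
  logr <- logtarget(prop$value) - logtarget(current) + prop$log_hastings
  accepted <- log(stats::runif(1)) < logr
  list(value = if (accepted) prop$value else current, accepted = accepted)
}

# multiplicative MH step for one positive scalar with exponential(rate)
# prior; proposal x' = x * exp(step * (U - 0.5)), Hastings log(x'/x)
.scalar_mult_mh <- function(current, step, rate, logtarget) {
  if (step <= 0) return(list(value = current, accepted = TRUE))
  prop <- current * exp(step * (stats::runif(1) - 0.5))
  logr <- logtarget(prop) - logtarget(current) +
    stats::dexp(prop, rate, log = TRUE) -
    stats::dexp(current, rate, log = TRUE) +
    log(prop / current)
  accepted <- log(stats::runif(1)) < logr
  list(value = if (accepted) prop else current, accepted = accepted)
}

# data log-likelihood given current allocations
.alloc_loglik <- function(logliks, z) sum(logliks[cbind(seq_along(z), z)])

#' Chain configuration
#'
#' @param sampler Allocation sampler: \code{"weighted"} (default;
#'   parallelisable, weights drawn explicitly) or \code{"gibbs"}
#'   (count-based, weights integrated out).
#' @param sweeps Total number of sweeps.
#' @param burnin Number of initial sweeps discarded; default 20\% of
#'   \code{sweeps}.
#' @param thin Thinning interval; default keeps at most 2000 draws.
#' @param seed Integer RNG seed; every run is fully reproducible from it.
#' @param update_mut,update_bl Whether nucleotide parameters and branch
#'   lengths are resampled (Metropolis-Hastings) or held fixed at their
#'   initial values.
#' @param mut Initial \code{mutation_params}.
#' @param step_rho,step_phi,step_bl Initial proposal step sizes; adapted
#'   towards ~25\% acceptance during burn-in only, then frozen.
#' @param bl_prior_mean Mean of the i.i.d. exponential branch-length
#'   prior (expected substitutions/site).
#' @return A \code{chain_config} list.
#' @export
chain_config <- function(sampler = c("weighted", "gibbs"),
                         sweeps = 2000L, burnin = NULL, thin = NULL,
                         seed = 1L,
                         update_mut = FALSE, update_bl = FALSE,
                         mut = mutation_params(),
                         step_rho = 0.02, step_phi = 0.02, step_bl = 0.5,
                         bl_prior_mean = 0.1) {
  sampler <- match.arg(sampler)
  sweeps <- as.integer(sweeps)
  if (sweeps < 1L) stop("sweeps must be >= 1")
  if (is.null(burnin)) burnin <- as.integer(floor(0.2 * sweeps))
  burnin <- as.integer(burnin)
  if (burnin >= sweeps) stop("chain shorter than burn-in")
  if (is.null(thin)) thin <- max(1L, as.integer(ceiling((sweeps - burnin) / 2000)))
  structure(list(sampler = sampler, sweeps = sweeps, burnin = burnin,
                 thin = as.integer(thin), seed = as.integer(seed),
                 update_mut = update_mut, update_bl = update_bl,
                 mut = mut, step_rho = step_rho, step_phi = step_phi,
                 step_bl = step_bl, bl_prior_mean = bl_prior_mean),
            class = "chain_config")
}

#' Run an allocation MCMC chain
#'
#' Alternates allocation sweeps with (optional) Metropolis-Hastings
#' updates of the nucleotide exchangeabilities, propensities and branch
#' lengths, and records thinned post-burn-in draws.  The N x K
#' log-likelihood table is recomputed only when \eqn{\theta} changes;
#' allocation sweeps reuse it, which is exact since z does not enter the
#' table.  Proposal step sizes adapt during burn-in only.
#'
#' @param aln A \code{codon_alignment}.
#' @param tree Rooted \code{phylo} with branch lengths.
#' @param profiles A \code{profile_set} (profiles are fixed throughout).
#' @param config A [chain_config()].
#' @param code A \code{genetic_code}.
#' @return An object of class \code{mcmc_trace}: list with \code{z}
#'   (draws x N allocation matrix), \code{weights} (draws x K, weighted
#'   sampler only), \code{rho}, \code{phi}, \code{branch_lengths} (final),
#'   \code{loglik} (per-sweep data log-likelihood given allocations),
#'   \code{K}, and \code{meta} (sampler, sweeps, burn-in, thinning, seed).
#' @export
run_chain <- function(aln, tree, profiles, config = chain_config(),
                      code = universal_code()) {
  stopifnot(inherits(config, "chain_config"))
  .check_tree(tree)
  set.seed(config$seed)
  K <- n_components(profiles)
  if (K < 1L) stop("profile set must have at least one component")
  N <- aln$n_sites
  mut <- config$mut
  bl_rate <- 1 / config$bl_prior_mean

  m <- .match_taxa(aln, tree)
  codons_by_tip <- aln$codons[m, , drop = FALSE]
  gens <- .component_generators(mut, profiles, code)
  tab <- .logliks_from_gens(codons_by_tip, tree, gens)
  state <- allocation_state(sample.int(K, N, replace = TRUE), K)
  w <- rep(1 / K, K)

  keep <- seq(config$burnin + config$thin, config$sweeps, by = config$thin)
  if (length(keep) == 0L) keep <- config$sweeps
  zdraws <- matrix(NA_integer_, length(keep), N)
  wdraws <- matrix(NA_real_, length(keep), K)
  rhodraws <- matrix(NA_real_, length(keep), 6L)
  phidraws <- matrix(NA_real_, length(keep), 4L)
  lltrace <- numeric(config$sweeps)
  step_rho <- config$step_rho; step_phi <- config$step_phi
  step_bl <- config$step_bl
  acc <- c(rho = 0, phi = 0, bl = 0); try_n <- c(rho = 0, phi = 0, bl = 0)
  stored <- 0L

  cur_ll <- .alloc_loglik(tab, state$z)

  for (s in seq_len(config$sweeps)) {
    if (config$update_mut) {
      for (block in c("rho", "phi")) {
        step <- if (block == "rho") step_rho else step_phi
        prop <- .simplex_propose(unname(mut[[block]]), step)
        try_n[block] <- try_n[block] + 1
        if (is.null(prop)) {  # identity proposal
          acc[block] <- acc[block] + 1
        } else {
          mut2 <- if (block == "rho")
            mutation_params(rho = prop$value, phi = mut$phi) else
            mutation_params(rho = mut$rho, phi = prop$value)
          gens2 <- .component_generators(mut2, profiles, code)
          tab2 <- .logliks_from_gens(codons_by_tip, tree, gens2)
          ll2 <- .alloc_loglik(tab2, state$z)
          if (log(stats::runif(1)) < ll2 - cur_ll + prop$log_hastings) {
            mut <- mut2; gens <- gens2; tab <- tab2; cur_ll <- ll2
            acc[block] <- acc[block] + 1
          }
        }
      }
    }
    if (config$update_bl) {
      for (e in seq_along(tree$edge.length)) {
        l <- tree$edge.length[e]
        try_n["bl"] <- try_n["bl"] + 1
        if (step_bl <= 0) { acc["bl"] <- acc["bl"] + 1; next }
        l2 <- l * exp(step_bl * (stats::runif(1) - 0.5))
        tree2 <- tree; tree2$edge.length[e] <- l2
        tab2 <- .logliks_from_gens(codons_by_tip, tree2, gens)
        ll2 <- .alloc_loglik(tab2, state$z)
        logr <- ll2 - cur_ll +
          stats::dexp(l2, bl_rate, log = TRUE) -
          stats::dexp(l, bl_rate, log = TRUE) + log(l2 / l)
        if (log(stats::runif(1)) < logr) {
          tree <- tree2; tab <- tab2; cur_ll <- ll2
          acc["bl"] <- acc["bl"] + 1
        }
      }
    }

    if (config$sampler == "gibbs") {
      state <- gibbs_allocation_sweep(state, tab)
    } else {
      state <- weighted_allocation_sweep(tab, w)
      w <- update_weights(state$eta)
    }
    cur_ll <- .alloc_loglik(tab, state$z)
    lltrace[s] <- cur_ll

    # step-size adaptation, burn-in only, towards ~0.25 acceptance
    if (s <= config$burnin && s %% 50L == 0L) {
      adapt <- function(step, a, t) {
        if (t == 0) return(step)
        r <- a / t
        step * exp(0.5 * (r - 0.25))
      }
      step_rho <- adapt(step_rho, acc["rho"], try_n["rho"])
      step_phi <- adapt(step_phi, acc["phi"], try_n["phi"])
      step_bl <- adapt(step_bl, acc["bl"], try_n["bl"])
      acc[] <- 0; try_n[] <- 0
    }

    hit <- match(s, keep)
    if (!is.na(hit)) {
      zdraws[hit, ] <- state$z
      wdraws[hit, ] <- w
      rhodraws[hit, ] <- mut$rho
      phidraws[hit, ] <- mut$phi
      stored <- stored + 1L
    }
  }

  structure(list(z = zdraws, weights = wdraws, rho = rhodraws,
                 phi = phidraws, branch_lengths = tree$edge.length,
                 loglik = lltrace, K = K,
                 meta = list(sampler = config$sampler,
                             sweeps = config$sweeps,
                             burnin = config$burnin, thin = config$thin,
                             seed = config$seed, n_sites = N,
                             n_draws = stored, sweep_index = keep)),
            class = "mcmc_trace")
}

#' @export
print.mcmc_trace <- function(x, ...) {
  cat(sprintf(
    "MCMC trace: %d stored draws (%s sampler), %d sites, K = %d\n",
    x$meta$n_draws, x$meta$sampler, x$meta$n_sites, x$K))
  invisible(x)
}
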