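# Allocation-probability summaries of MCMC traces, the probability of
# identical profiles (PIP) across two taxa partitions, entropy filtering,
# thresholded shift calls and evaluation metrics.

#' Posterior allocation probabilities from a trace
#'
#' \eqn{p^{(n)}(k) = \frac{1}{M}\sum_m \delta_{mnk}}: the proportion of
#' stored posterior draws in which site n is allocated to component k.
#'
#' @param trace An \code{mcmc_trace} (or an M x N integer matrix of
#'   allocation draws).
#' @param K Number of components (taken from the trace when available).
#' @param partition_label Optional label recording which taxa partition
#'   the chain covered (e.g. \code{"human"}, \code{"avian"}).
#' @return An object of class \code{allocation_probabilities}: list with
#'   \code{table} (N x K matrix, rows summing to 1), \code{M} (number of
#'   draws) and \code{partition_label}.
#' @export
allocation_probability <- function(trace, K = NULL, partition_label = NA) {
  if (inherits(trace, "mcmc_trace")) {
    zd <- trace$z
    K <- trace$K
  } else {
    zd <- as.matrix(trace)
    if (is.null(K)) K <- max(zd)
  }
  M <- nrow(zd)
  if (is.null(M) || M < 1L) stop("trace contains no draws")
  N <- ncol(zd)
  tab <- matrix(0, N, K)
  for (k in seq_len(K)) tab[, k] <- colMeans(zd == k)
  structure(list(table = tab, M = M, K = K,
                 partition_label = partition_label),
            class = "allocation_probabilities")
}

#' @export
print.allocation_probabilities <- function(x, ...) {
  cat(sprintf(
    "Allocation probabilities: %d sites x %d components (M = %d draws%s)\n",
    nrow(x$table), x$K, x$M,
    if (is.na(x$partition_label)) "" else paste0(", ", x$partition_label)))
  invisible(x)
}

.prob_vector <- function(p) {
  p <- as.numeric(p)
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-6)
    stop("not a probability vector")
  pmax(p, 0)
}

#' Probability of identical profiles at a site
#'
#' Given the posterior allocation-probability vectors of the same site in
#' two taxa partitions, \eqn{\mathrm{PIP} = \sum_k p_A(k)\, p_B(k)}: the
#' posterior probability that both partitions were governed by the same
#' mixture component.  Equals 1 when both partitions allocate fully to
#' one identical component, 0 when the supports are disjoint.  A low PIP
#' flags a candidate shift in amino acid preference.
#'
#' @param p_a,p_b Length-K probability vectors over the same component
#'   set.
#' @return PIP in [0, 1].
#' @export
pip <- function(p_a, p_b) {
  if (length(p_a) != length(p_b))
    stop("allocation vectors differ in length")
  sum(.prob_vector(p_a) * .prob_vector(p_b))
}

#' Shannon entropy of an allocation vector
#'
#' \eqn{-\sum_k p(k)\ln p(k)} in nats, with \eqn{0 \ln 0 = 0}.  Low
#' entropy means strong allocation (a well-constrained site); high
#' entropy means the data barely discriminate among components, in which
#' case a low PIP reflects uncertainty rather than a clear shift.
#'
#' @param p Probability vector.
#' @return Entropy in nats, >= 0.
#' @export
allocation_entropy <- function(p) {
  p <- .prob_vector(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-site PIP report and shift calls for two partitions
#'
#' Computes, for every site, the PIP between the two partitions'
#' allocation vectors, each partition's allocation entropy and top
#' component, and a shift flag: sites with \code{PIP <= threshold} are
#' flagged (boundary inclusive).  If \code{entropy_max} is given, a
#' flagged site must additionally have both entropies at or below it;
#' this guards against calls driven by weak allocation on both sides
#' rather than a genuine preference shift.  The filter is off by
#' default.
#'
#' @param probs_a,probs_b \code{allocation_probabilities} for the two
#'   partitions (matching N and K).
#' @param threshold PIP call threshold (default 0.05).
#' @param entropy_max Optional entropy ceiling (nats) for calls.
#' @return An object of class \code{pip_report}: data frame with columns
#'   \code{site}, \code{pip}, \code{entropy_a}, \code{entropy_b},
#'   \code{top_a}, \code{top_prob_a}, \code{top_b}, \code{top_prob_b},
#'   \code{shift}.
#' @export
classify_sites <- function(probs_a, probs_b, threshold = 0.05,
                           entropy_max = NULL) {
  stopifnot(inherits(probs_a, "allocation_probabilities"),
            inherits(probs_b, "allocation_probabilities"))
  A <- probs_a$table; B <- probs_b$table
  if (!identical(dim(A), dim(B)))
    stop("partitions disagree in number of sites or components")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  N <- nrow(A)
  pip_n <- rowSums(A * B)
  ent_a <- apply(A, 1, allocation_entropy)
  ent_b <- apply(B, 1, allocation_entropy)
  top_a <- max.col(A, ties.method = "first")
  top_b <- max.col(B, ties.method = "first")
  shift <- pip_n <= threshold
  if (!is.null(entropy_max))
    shift <- shift & ent_a <= entropy_max & ent_b <= entropy_max
  out <- data.frame(site = seq_len(N), pip = pip_n,
                    entropy_a = ent_a, entropy_b = ent_b,
                    top_a = top_a,
                    top_prob_a = A[cbind(seq_len(N), top_a)],
                    top_b = top_b,
                    top_prob_b = B[cbind(seq_len(N), top_b)],
                    shift = shift)
  class(out) <- c("pip_report", "data.frame")
  attr(out, "threshold") <- threshold
  attr(out, "entropy_max") <- entropy_max
  out
}

#' Detection metrics against a known truth set
#'
#' @param calls Integer vector of called (flagged) site indices, or a
#'   \code{pip_report} (its flagged sites are used).
#' @param truth Integer vector of truly shifted site indices.
#' @param n_sites Total number of sites N (taken from the report when one
#'   is supplied).
#' @return List with \code{TP}, \code{FP}, \code{TPR} (= recall),
#'   \code{FPR}, \code{precision}.  TPR is NA when the truth set is
#'   empty; precision is 0 when nothing is called.
#' @export
confusion_metrics <- function(calls, truth, n_sites = NULL) {
  if (inherits(calls, "pip_report")) {
    if (is.null(n_sites)) n_sites <- nrow(calls)
    calls <- calls$site[calls$shift]
  }
  if (is.null(n_sites)) stop("n_sites required when calls is a plain vector")
  calls <- unique(as.integer(calls)); truth <- unique(as.integer(truth))
  if (length(setdiff(truth, seq_len(n_sites))))
    stop("truth contains sites outside 1..n_sites")
  TP <- length(intersect(calls, truth))
  FP <- length(setdiff(calls, truth))
  n_null <- n_sites - length(truth)
  list(TP = TP, FP = FP,
       TPR = if (length(truth)) TP / length(truth) else NA_real_,
       FPR = if (n_null) FP / n_null else NA_real_,
       precision = if (TP + FP > 0) TP / (TP + FP) else 0)
}

#' Precision-recall curve over PIP thresholds
#'
#' Sweeps the call threshold over the sorted unique PIP values (plus 0
#' and 1); at each threshold, sites with \code{PIP <= threshold} are
#' called.  Recall is non-decreasing in the threshold.
#'
#' @param pip_values Length-N numeric vector of per-site PIP values.
#' @param truth Integer vector of truly shifted site indices.
#' @return Data frame with columns \code{threshold}, \code{precision},
#'   \code{recall}.
#' @export
precision_recall_curve <- function(pip_values, truth) {
  N <- length(pip_values)
  truth <- unique(as.integer(truth))
  if (length(setdiff(truth, seq_len(N))))
    stop("truth contains sites outside 1..N")
  thresholds <- sort(unique(c(0, pip_values, 1)))
  rows <- lapply(thresholds, function(th) {
    m <- confusion_metrics(which(pip_values <= th), truth, n_sites = N)
    data.frame(threshold = th, precision = m$precision,
               recall = if (is.na(m$TPR)) NA_real_ else m$TPR)
  })
  do.call(rbind, rows)
}
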