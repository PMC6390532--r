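# Amino acid fitness profile sets: the biochemically grouped MutSelBC
# constructor with controllable peakedness, and plain-text profile tables in
# the layout used for published empirical finite-mixture sets (C10..C60).

# The eight biochemical groups, in their canonical order.  Dominant groups
# are pairwise disjoint so a component change is always a clear biochemical
# shift.
MUTSEL_BC_GROUPS <- list(
  small_nonpolar    = c("A", "G", "S", "T"),
  aromatic          = c("F", "W", "Y"),
  nonpolar_aliphatic = c("I", "L", "V", "M"),
  polar_positive    = c("H", "K", "R"),
  polar_negative    = c("D", "E"),
  polar_neutral     = c("N", "Q"),
  proline           = "P",
  cysteine          = "C"
)

PROFILE_FLOOR <- 1e-10

.floor_profile <- function(psi) {
  psi[psi < PROFILE_FLOOR] <- PROFILE_FLOOR
  psi / sum(psi)
}

.new_profile_set <- function(profiles, weights = NULL, peakedness = NULL,
                             source = "file", labels = NULL) {
  mat <- do.call(rbind, profiles)
  colnames(mat) <- AMINO_ACIDS
  rownames(mat) <- labels %||% paste0("C", seq_len(nrow(mat)))
  structure(list(profiles = mat, weights = weights,
                 peakedness = peakedness, source = source),
            class = "profile_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of components in a profile set
#' @param set A \code{profile_set}.
#' @export
n_components <- function(set) nrow(set$profiles)

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("Profile set (%s): %d components over 20 amino acids\n",
              x$source, n_components(x)))
  if (!is.null(x$peakedness))
    cat(sprintf("  peakedness: %g\n", x$peakedness))
  if (!is.null(x$weights))
    cat("  component weights present\n")
  invisible(x)
}

#' Biochemically grouped profile set with controllable peakedness
#'
#' Constructs the eight-component profile set in which each component
#' concentrates a total probability mass \code{peakedness} equally on the
#' members of one biochemical group of amino acids, with the complement
#' \code{1 - peakedness} spread equally over the remaining residues.  The
#' eight groups (in component order) are: small nonpolar (A, G, S, T);
#' aromatic (F, W, Y); nonpolar aliphatic (I, L, V, M); polar positive
#' (H, K, R); polar negative (D, E); polar neutral (N, Q); proline; and
#' cysteine.  The dominant groups are pairwise disjoint, so any component
#' change represents an unambiguous biochemical shift.
#'
#' At \code{peakedness = 1} the off-group entries would be exactly zero;
#' they are floored at \code{1e-10} and the profile renormalised so that
#' log-fitnesses stay finite.
#'
#' @param peakedness Probability mass in (0, 1] shared equally by a
#'   component's dominant group.
#' @return A \code{profile_set} with 8 components; rows are profiles over
#'   the 20 amino acids in alphabetical single-letter order, each summing
#'   to 1.
#' @examples
#' ps <- mutsel_bc(0.5)
#' sum(ps$profiles["nonpolar_aliphatic", c("V", "M", "L", "I")])  # 0.5
#' @export
mutsel_bc <- function(peakedness) {
  if (!is.numeric(peakedness) || length(peakedness) != 1L ||
      is.na(peakedness) || peakedness <= 0 || peakedness > 1)
    stop("peakedness must be a single value in (0, 1]")
  profiles <- lapply(MUTSEL_BC_GROUPS, function(group) {
    psi <- rep((1 - peakedness) / (20 - length(group)), 20)
    names(psi) <- AMINO_ACIDS
    psi[group] <- peakedness / length(group)
    .floor_profile(psi)
  })
  .new_profile_set(profiles, peakedness = peakedness, source = "mutsel_bc",
                   labels = names(MUTSEL_BC_GROUPS))
}

#' Read a profile table file
#'
#' Reads a whitespace-delimited finite-mixture profile table: one row per
#' component with 20 amino-acid frequencies (columns in alphabetical
#' single-letter order A, C, D, ..., Y), or 21 fields where the first is a
#' component weight.  Lines starting with \code{#} are comments.  This is
#' the de facto layout of published empirical mixture sets such as
#' C10--C60.
#'
#' Rows whose sum deviates from 1 by at most \code{1e-4} are renormalised;
#' larger deviations are format errors.  Entries below \code{1e-10} are
#' floored and the row renormalised so log-fitnesses stay finite.
#'
#' @param path Path to the table file.
#' @return A \code{profile_set} (with \code{weights} if the file carried a
#'   leading weight column, normalised to sum 1).
#' @seealso [save_profile_table()], [mutsel_bc()]
#' @export
load_profile_table <- function(path) {
  if (!file.exists(path)) stop("profile table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("profile table is empty: ", path)
  rows <- lapply(keep, function(ln) {
    fields <- suppressWarnings(
      as.numeric(strsplit(trimws(lines[ln]), "\\s+")[[1]]))
    if (anyNA(fields))
      stop("line ", ln, ": non-numeric field in profile table")
    if (!length(fields) %in% c(20L, 21L))
      stop("line ", ln, ": expected 20 or 21 fields, found ", length(fields))
    if (any(fields < 0))
      stop("line ", ln, ": negative entry in profile table")
    fields
  })
  nf <- lengths(rows)
  if (length(unique(nf)) != 1L)
    stop("inconsistent field counts across profile rows")
  has_weights <- nf[1] == 21L
  weights <- if (has_weights) vapply(rows, `[`, numeric(1), 1L) else NULL
  profiles <- lapply(seq_along(rows), function(r) {
    psi <- if (has_weights) rows[[r]][-1L] else rows[[r]]
    s <- sum(psi)
    if (abs(s - 1) > 1e-4)
      stop("line ", keep[r], ": profile sums to ", format(s),
           " (tolerance 1e-4)")
    .floor_profile(psi / s)
  })
  if (has_weights) {
    if (sum(weights) <= 0) stop("profile weights sum to zero")
    weights <- weights / sum(weights)
  }
  .new_profile_set(profiles, weights = weights, source = "file")
}

#' Write a profile table file
#'
#' Emits the whitespace-delimited format accepted by
#' [load_profile_table()], at full double precision, with a comment header
#' recording the amino-acid column order.  If the set carries weights they
#' are written as a leading first column (21 fields per row).
#'
#' @param set A \code{profile_set}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
save_profile_table <- function(set, path) {
  stopifnot(inherits(set, "profile_set"))
  header <- paste0("# amino acid columns: ",
                   paste(AMINO_ACIDS, collapse = " "))
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  body <- vapply(seq_len(n_components(set)), function(k) {
    fields <- fmt(set$profiles[k, ])
    if (!is.null(set$weights)) fields <- c(fmt(set$weights[k]), fields)
    paste(fields, collapse = " ")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
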