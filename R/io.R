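# Readers and writers for the standard formats: FASTA / PHYLIP codon
# alignments, Newick trees, taxon lists, MCMC trace files (TSV + JSON
# sidecar) and PIP report tables.  Sites are reported 1-based everywhere.

.chars_to_codons <- function(chars, taxa) {
  L <- ncol(chars)
  if (L %% 3L != 0L)
    stop("alignment length ", L, " is not divisible by 3 (frame violation)")
  if (anyDuplicated(taxa)) stop("duplicate taxon names in alignment")
  N <- L %/% 3L
  code <- universal_code()
  chars <- toupper(chars)
  chars[chars == "U"] <- "T"
  codons <- matrix(NA_integer_, length(taxa), N,
                   dimnames = list(taxa, NULL))
  for (n in seq_len(N)) {
    triplet <- chars[, (3 * n - 2):(3 * n), drop = FALSE]
    valid <- rowSums(matrix(triplet %in% NUCLEOTIDES, ncol = 3)) == 3L
    if (any(valid)) {
      strs <- paste0(triplet[valid, 1], triplet[valid, 2], triplet[valid, 3])
      if (any(strs %in% STOP_CODONS)) {
        bad <- which(valid)[which(strs %in% STOP_CODONS)[1]]
        stop("in-frame stop codon at site ", n, " in taxon '",
             taxa[bad], "'")
      }
      codons[valid, n] <- match(strs, code$codons)
    }
  }
  codon_alignment(codons)
}

#' Read an in-frame protein-coding alignment
#'
#' Reads FASTA or PHYLIP (sequential or interleaved) nucleotide
#' alignments and converts them to codon states.  Sequence length must
#' be divisible by 3 and equal across taxa.  Any codon containing a
#' non-ACGT/U character (gaps, Ns, ambiguity codes) is treated as
#' missing data; an in-frame stop codon is an error naming the taxon and
#' site.
#'
#' @param path Path to the alignment file.
#' @param format \code{"fasta"} (default), \code{"sequential"} or
#'   \code{"interleaved"}.
#' @return A \code{codon_alignment}.
#' @export
read_alignment <- function(path, format = c("fasta", "sequential",
                                            "interleaved")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  dna <- ape::read.dna(path, format = format, as.character = TRUE,
                       as.matrix = TRUE)
  .chars_to_codons(unname(dna), rownames(dna))
}

#' Write a codon alignment as FASTA
#'
#' @param aln A \code{codon_alignment}.
#' @param path Output path.  Missing codons are written as \code{---}.
#' @return Invisibly, \code{path}.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  code <- universal_code()
  lines <- character(2L * length(aln$taxa))
  for (t in seq_along(aln$taxa)) {
    cd <- aln$codons[t, ]
    seqs <- ifelse(is.na(cd), "---", code$codons[cd])
    lines[2 * t - 1] <- paste0(">", aln$taxa[t])
    lines[2 * t] <- paste(seqs, collapse = "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a rooted Newick tree with branch lengths
#'
#' @param path Path to a Newick file.
#' @return A rooted \code{phylo}; errors if branch lengths are missing.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick tree: ", path)
  .check_tree(tree)
  tree
}

#' Read a taxon list (one label per line)
#'
#' @param path Path to the file; blank lines and \code{#} comments are
#'   ignored.
#' @return Character vector of taxon labels.
#' @export
read_taxon_set <- function(path) {
  if (!file.exists(path)) stop("taxon list not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[!grepl("^(#|$)", x)]
  if (anyDuplicated(x)) stop("duplicate labels in taxon list")
  x
}

#' Split an alignment and tree by a monophyletic sub-clade
#'
#' Partitions the taxa into the designated sub-clade and its complement,
#' each with its induced subtree.  The stem branch leading to each
#' partition's root is dropped, so the two partitions are analysed as
#' fully independent trees (the infinite-stem assumption behind the
#' two-partition PIP comparison).  Site indexing is preserved in both
#' partitions.
#'
#' @param aln A \code{codon_alignment}.
#' @param tree Rooted \code{phylo} whose tips match the alignment taxa.
#' @param subclade Character vector of sub-clade tip labels; must be
#'   monophyletic in \code{tree}, and both partitions must keep at least
#'   2 taxa.
#' @return List of two lists, \code{sub} and \code{rest}, each with
#'   elements \code{alignment} and \code{tree}.
#' @export
split_by_subclade <- function(aln, tree, subclade) {
  stopifnot(inherits(aln, "codon_alignment"))
  .check_tree(tree)
  .match_taxa(aln, tree)
  if (!all(subclade %in% tree$tip.label))
    stop("sub-clade taxa missing from tree: ",
         paste(setdiff(subclade, tree$tip.label), collapse = ", "))
  rest <- setdiff(tree$tip.label, subclade)
  if (length(subclade) < 2L || length(rest) < 2L)
    stop("both partitions need at least 2 taxa")
  if (!ape::is.monophyletic(tree, subclade))
    stop("sub-clade is not monophyletic in the tree")
  take <- function(keep) {
    subtree <- ape::keep.tip(tree, keep)
    sub_aln <- codon_alignment(aln$codons[keep, , drop = FALSE])
    list(alignment = sub_aln, tree = subtree)
  }
  list(sub = take(subclade), rest = take(rest))
}

# --- trace files ----------------------------------------------------------

.rle_encode <- function(z) {
  r <- rle(as.integer(z))
  paste(paste0(r$values, "x", r$lengths), collapse = ",")
}

.rle_decode <- function(s) {
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "x", fixed = TRUE)
  unlist(lapply(parts, function(p)
    rep(as.integer(p[1]), as.integer(p[2]))))
}

#' Write an MCMC trace to disk
#'
#' Emits \code{<prefix>.trace.tsv} (one row per stored draw: sweep index,
#' data log-likelihood, nucleotide parameters, weights, and the
#' run-length-encoded allocation vector) and \code{<prefix>.meta.json}
#' (sampler, chain settings, seed).
#'
#' @param trace An \code{mcmc_trace}.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_trace <- function(trace, prefix) {
  stopifnot(inherits(trace, "mcmc_trace"))
  keep <- trace$meta$sweep_index
  df <- data.frame(sweep = keep, loglik = trace$loglik[keep])
  rho <- trace$rho; colnames(rho) <- paste0("rho_", .RHO_PAIRS)
  phi <- trace$phi; colnames(phi) <- paste0("phi_", NUCLEOTIDES)
  w <- trace$weights; colnames(w) <- paste0("w_", seq_len(trace$K))
  df <- cbind(df, rho, phi, w)
  df$z <- apply(trace$z, 1, .rle_encode)
  tsv <- paste0(prefix, ".trace.tsv")
  meta <- paste0(prefix, ".meta.json")
  utils::write.table(format(df, digits = 17, trim = TRUE), tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(trace$meta[setdiff(names(trace$meta),
                                            "sweep_index")],
                         list(K = trace$K,
                              branch_lengths = trace$branch_lengths)),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, meta))
}

#' Read back a trace written by [write_trace()]
#'
#' @param prefix The path prefix used at write time.
#' @return An \code{mcmc_trace} (the full per-sweep log-likelihood trace
#'   is restored only at the stored sweeps).
#' @export
read_trace <- function(prefix) {
  tsv <- paste0(prefix, ".trace.tsv")
  metaf <- paste0(prefix, ".meta.json")
  if (!file.exists(tsv) || !file.exists(metaf))
    stop("trace files not found for prefix: ", prefix)
  df <- utils::read.table(tsv, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(metaf, simplifyVector = TRUE)
  K <- meta$K
  z <- t(vapply(df$z, .rle_decode, integer(meta$n_sites)))
  dimnames(z) <- NULL
  loglik <- numeric(meta$sweeps)
  loglik[df$sweep] <- df$loglik
  structure(list(z = z,
                 weights = as.matrix(df[paste0("w_", seq_len(K))]),
                 rho = as.matrix(df[paste0("rho_", .RHO_PAIRS)]),
                 phi = as.matrix(df[paste0("phi_", NUCLEOTIDES)]),
                 branch_lengths = meta$branch_lengths,
                 loglik = loglik, K = K,
                 meta = list(sampler = meta$sampler, sweeps = meta$sweeps,
                             burnin = meta$burnin, thin = meta$thin,
                             seed = meta$seed, n_sites = meta$n_sites,
                             n_draws = meta$n_draws,
                             sweep_index = df$sweep)),
            class = "mcmc_trace")
}

#' Write a PIP report as TSV
#'
#' @param report A \code{pip_report} from [classify_sites()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_pip_report <- function(report, path) {
  stopifnot(inherits(report, "pip_report"))
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "site" &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a full N x K allocation-probability table as TSV
#'
#' Intended as the data export for logoplot rendering by external tools.
#'
#' @param probs An \code{allocation_probabilities}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_allocation_table <- function(probs, path) {
  stopifnot(inherits(probs, "allocation_probabilities"))
  df <- as.data.frame(probs$table)
  names(df) <- paste0("p_", seq_len(probs$K))
  df <- cbind(site = seq_len(nrow(df)), df)
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
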