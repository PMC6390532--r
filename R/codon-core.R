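# Universal genetic code tables, codon indexing and single-nucleotide
# neighbour enumeration.  All state indexing in the package (generator rows,
# alignment columns, simulator states) refers to the fixed codon ordering
# defined here.

NUCLEOTIDES <- c("A", "C", "G", "T")

# Single-letter amino acid codes in alphabetical order; amino-acid index
# 1..20 throughout the package refers to this ordering.
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Universal code as codon -> single-letter amino acid (stops excluded below).
.codon_aa_table <- function() {
  base <- expand.grid(p3 = NUCLEOTIDES, p2 = NUCLEOTIDES, p1 = NUCLEOTIDES,
                      stringsAsFactors = FALSE)
  codons <- paste0(base$p1, base$p2, base$p3)
  codons <- sort(codons)  # lexicographic over A < C < G < T
  aa <- vapply(codons, function(cd) {
    # standard code, written out by first base
    switch(cd,
      AAA = "K", AAC = "N", AAG = "K", AAT = "N",
      ACA = "T", ACC = "T", ACG = "T", ACT = "T",
      AGA = "R", AGC = "S", AGG = "R", AGT = "S",
      ATA = "I", ATC = "I", ATG = "M", ATT = "I",
      CAA = "Q", CAC = "H", CAG = "Q", CAT = "H",
      CCA = "P", CCC = "P", CCG = "P", CCT = "P",
      CGA = "R", CGC = "R", CGG = "R", CGT = "R",
      CTA = "L", CTC = "L", CTG = "L", CTT = "L",
      GAA = "E", GAC = "D", GAG = "E", GAT = "D",
      GCA = "A", GCC = "A", GCG = "A", GCT = "A",
      GGA = "G", GGC = "G", GGG = "G", GGT = "G",
      GTA = "V", GTC = "V", GTG = "V", GTT = "V",
      TAA = "*", TAC = "Y", TAG = "*", TAT = "Y",
      TCA = "S", TCC = "S", TCG = "S", TCT = "S",
      TGA = "*", TGC = "C", TGG = "W", TGT = "C",
      TTA = "L", TTC = "F", TTG = "L", TTT = "F")
  }, character(1))
  names(aa) <- codons
  aa
}

#' The universal genetic code over the 61 sense codons
#'
#' Builds the fixed codon-state table used throughout the package: the 61
#' sense codons of the universal genetic code in lexicographic order over the
#' alphabet A < C < G < T (stop codons TAA, TAG, TGA excluded), the
#' codon-to-amino-acid map, and per-position nucleotide indices.
#'
#' @return An object of class \code{genetic_code}: a list with
#'   \describe{
#'     \item{codons}{character vector of the 61 sense codons, in the fixed
#'       ordering; codon index 1..61 refers to this vector.}
#'     \item{aa}{character vector of length 61, the encoded amino acid
#'       (single-letter) per codon.}
#'     \item{aa_index}{integer vector of length 61 mapping each codon to an
#'       amino-acid index 1..20 (alphabetical single-letter order, see
#'       \code{AMINO_ACIDS}).}
#'     \item{nuc_index}{61 x 3 integer matrix; entry (i, c) is the index
#'       1..4 (A, C, G, T) of the nucleotide at position c of codon i.}
#'     \item{neighbors}{list of length 61; element i is an integer matrix
#'       with columns \code{j}, \code{pos}, \code{from}, \code{to} listing
#'       every sense codon j reachable from i by a single nucleotide change,
#'       the changing position, and the from/to nucleotide indices.}
#'   }
#' @examples
#' gc <- genetic_code()
#' gc$codons[1]                # "AAA"
#' table(gc$aa)["L"]           # leucine has six codons
#' @export
genetic_code <- function() {
  tab <- .codon_aa_table()
  sense <- tab[tab != "*"]
  codons <- names(sense)
  stopifnot(length(codons) == 61L)
  aa_index <- match(unname(sense), AMINO_ACIDS)
  nuc_index <- t(vapply(strsplit(codons, ""),
                        function(x) match(x, NUCLEOTIDES), integer(3)))
  dimnames(nuc_index) <- list(codons, NULL)

  # single-nucleotide sense neighbours
  idx <- seq_along(codons)
  names(idx) <- codons
  neighbors <- vector("list", 61L)
  for (i in idx) {
    rows <- NULL
    chars <- strsplit(codons[i], "")[[1]]
    for (pos in 1:3) {
      for (b in seq_along(NUCLEOTIDES)) {
        if (NUCLEOTIDES[b] == chars[pos]) next
        cand <- chars
        cand[pos] <- NUCLEOTIDES[b]
        cand <- paste(cand, collapse = "")
        j <- idx[cand]
        if (!is.na(j)) {  # stop-codon neighbours are dropped
          rows <- rbind(rows, c(j = unname(j), pos = pos,
                                from = match(chars[pos], NUCLEOTIDES),
                                to = b))
        }
      }
    }
    neighbors[[i]] <- rows
  }

  structure(list(codons = codons, aa = unname(sense), aa_index = aa_index,
                 nuc_index = nuc_index, neighbors = neighbors),
            class = "genetic_code")
}

# cached singleton; the table is immutable
.code_cache <- new.env(parent = emptyenv())

#' @rdname genetic_code
#' @export
universal_code <- function() {
  if (is.null(.code_cache$gc)) .code_cache$gc <- genetic_code()
  .code_cache$gc
}

#' Map a codon string to its state index
#'
#' @param codon A 3-letter nucleotide string (A/C/G/T; U is accepted and
#'   mapped to T).  Case-insensitive.
#' @param code A \code{genetic_code} object.
#' @return Integer index in 1..61 of the codon in the fixed sense-codon
#'   ordering.
#' @examples
#' codon_index("AAA")  # 1
#' codon_index("uuu")  # Phe codon TTT
#' @export
codon_index <- function(codon, code = universal_code()) {
  codon <- toupper(codon)
  codon <- gsub("U", "T", codon, fixed = TRUE)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("invalid codon '", codon, "': expected 3 characters from A/C/G/T/U")
  if (codon %in% STOP_CODONS)
    stop("stop codon '", codon, "' has no sense-codon index")
  match(codon, code$codons)
}

#' Translate a sense codon index to its amino acid
#'
#' @param i Codon index (1..61), possibly vectorised.
#' @param code A \code{genetic_code} object.
#' @return Single-letter amino acid code(s).
#' @export
translate_codon <- function(i, code = universal_code()) {
  if (any(i < 1L | i > 61L)) stop("codon index out of range 1..61")
  code$aa[i]
}

#' Single-nucleotide sense neighbours of a codon
#'
#' Lists every sense codon reachable from codon \code{i} by changing exactly
#' one nucleotide; changes producing a stop codon are excluded.
#'
#' @param i Codon index (1..61).
#' @param code A \code{genetic_code} object.
#' @return Integer matrix with one row per neighbour and columns \code{j}
#'   (neighbour codon index), \code{pos} (changing position 1..3),
#'   \code{from} and \code{to} (nucleotide indices 1..4).
#' @export
single_nt_neighbors <- function(i, code = universal_code()) {
  if (length(i) != 1L || is.na(i) || i < 1L || i > 61L)
    stop("codon index out of range 1..61")
  code$neighbors[[i]]
}
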