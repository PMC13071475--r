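# Precomputed structure of the standard genetic code over the 61 sense codons.
# Stop codons (TAA, TAG, TGA) are excluded from the state space, matching the
# convention of codon-substitution software.

.codonsel_cache <- new.env(parent = emptyenv())

#' Standard-genetic-code codon table
#'
#' Returns the precomputed structure of the standard genetic code used by the
#' simulation and likelihood engines: the 61 sense codons, their amino acids,
#' and pairwise relations (single-nucleotide neighbour, transition vs
#' transversion, synonymous vs nonsynonymous).
#'
#' @return A list with elements \code{codons} (character, length 61),
#'   \code{aa} (amino acid per codon), \code{index} (named lookup codon ->
#'   state index), and 61 x 61 logical matrices \code{single}, \code{ts},
#'   \code{syn}.
#' @export
codon_table <- function() {
  if (!is.null(.codonsel_cache$codon_tab)) return(.codonsel_cache$codon_tab)
  gc_map <- Biostrings::GENETIC_CODE
  codons <- names(gc_map)[gc_map != "*"]
  aa <- unname(gc_map[match(codons, names(gc_map))])
  n <- length(codons)
  stopifnot(n == 61L)
  cm <- do.call(rbind, strsplit(codons, ""))
  purine <- cm %in% c("A", "G")
  dim(purine) <- dim(cm)
  ndiff <- matrix(0L, n, n)
  ts <- matrix(FALSE, n, n)
  for (k in 1:3) {
    d <- outer(cm[, k], cm[, k], "!=")
    ndiff <- ndiff + d
    # same purine/pyrimidine class but different base => transition at pos k
    ts <- ts | (d & outer(purine[, k], purine[, k], "=="))
  }
  single <- ndiff == 1L
  ts <- ts & single
  syn <- outer(aa, aa, "==")
  tab <- list(
    codons = codons, aa = aa,
    index = stats::setNames(seq_len(n), codons),
    single = single, ts = ts, syn = syn
  )
  .codonsel_cache$codon_tab <- tab
  tab
}

#' Translate a vector of codons to amino acids
#'
#' Codons containing N (or other ambiguity codes) translate to \code{"X"};
#' the all-gap codon \code{"---"} translates to \code{"-"}. Stop codons
#' translate to \code{"*"}.
#'
#' @param codons Character vector of 3-letter codon strings.
#' @return Character vector of single-letter amino acids.
#' @export
translate_codons <- function(codons) {
  gc_map <- Biostrings::GENETIC_CODE
  out <- unname(gc_map[codons])
  out[codons == "---"] <- "-"
  out[is.na(out)] <- "X"
  out
}

# Split an in-frame DNA string into codons.
split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# Map codon strings to state indices 1..61; gaps/ambiguities/stops -> NA
# (treated as missing data by the pruning engine).
codon_state_indices <- function(codons) {
  tab <- codon_table()
  unname(tab$index[codons])
}
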