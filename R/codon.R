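## Codon-level primitives shared by the simulator and the divergence
## estimator: genetic code access, NG86-style site fractions, codon splitting.

.BASES <- c("A", "C", "G", "T")

# standard genetic code as a named vector, codon -> amino acid ("*" = stop)
genetic_code <- function() Biostrings::GENETIC_CODE

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

# split a nucleotide string into its codon vector
seq_codons <- function(seq) {
  L <- nchar(seq)
  if (L %% 3L != 0L) stop("sequence length not divisible by 3")
  if (L == 0L) return(character(0))
  substring(seq, seq(1L, L, 3L), seq(3L, L, 3L))
}

# TRUE where the base pair (b1, b2) is a transition (A<->G, C<->T); vectorized
is_transition <- function(b1, b2) {
  pur <- c("A", "G")
  (b1 %in% pur) == (b2 %in% pur) & b1 != b2
}

#' Synonymous and non-synonymous site fractions of a codon
#'
#' For each of the three codon positions, the fraction of the three possible
#' single-base changes that are synonymous under the standard genetic code.
#' Changes creating stop codons are excluded from the per-position
#' denominator, so the synonymous and non-synonymous fractions of every
#' position still sum to one and `S + N = 3` for every sense codon.
#'
#' @param codon A single sense codon (3 characters over ACGT, not a stop).
#' @return Named numeric vector with elements `S` and `N` summing to 3.
#' @examples
#' ng86_sites("TTT") # S = 1/3: only the third-position T->C change is silent
#' @export
ng86_sites <- function(codon) {
  gc <- genetic_code()
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L)
    stop("'codon' must be a single 3-letter string")
  b <- strsplit(codon, "")[[1L]]
  if (!all(b %in% .BASES))
    stop("codon contains a non-ACGT base (mask first): ", codon)
  aa0 <- gc[[codon]]
  if (aa0 == "*") stop("stop codon has no site decomposition: ", codon)
  s_tot <- 0
  for (pos in 1:3) {
    syn <- 0L
    valid <- 0L
    for (a in .BASES[.BASES != b[pos]]) {
      nb <- b
      nb[pos] <- a
      aa <- gc[[paste(nb, collapse = "")]]
      if (aa == "*") next
      valid <- valid + 1L
      if (aa == aa0) syn <- syn + 1L
    }
    if (valid > 0L) s_tot <- s_tot + syn / valid
  }
  c(S = s_tot, N = 3 - s_tot)
}

.codon_cache <- new.env(parent = emptyenv())

# memoized 61 x 2 matrix of NG86 site fractions, rownames = sense codons
ng86_table <- function() {
  if (is.null(.codon_cache$tab)) {
    cods <- sense_codons()
    .codon_cache$tab <- t(vapply(cods, ng86_sites, c(S = 0, N = 0)))
  }
  .codon_cache$tab
}
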