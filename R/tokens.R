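# SMILES tokenization shared by descriptor counting and the VAE vocabulary.

#' Split a SMILES string into grammar tokens
#'
#' Bracket atoms (`[nH]`, `[Na+]`, ...) and the two-character organic-subset
#' atoms `Cl` and `Br` are single tokens; every other character (atoms, bonds,
#' branches, ring-closure digits, `%nn` ring labels) is one token.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A list of character vectors, one per input string.
#' @examples
#' smiles_tokens("CC(Cl)Br")
#' @export
smiles_tokens <- function(smiles) {
  stopifnot(is.character(smiles))
  pat <- "\\[[^\\]]*\\]|Br|Cl|%[0-9]{2}|."
  m <- gregexpr(pat, smiles, perl = TRUE)
  regmatches(smiles, m)
}

# Token classification helpers -------------------------------------------

.atom_upper <- c("B", "C", "N", "O", "S", "P", "F", "I")
.atom_lower <- c("b", "c", "n", "o", "s", "p")

.is_atom_token <- function(tok) {
  startsWith(tok, "[") | tok %in% c(.atom_upper, .atom_lower, "Cl", "Br")
}

# heavy = any atom token that is not bare hydrogen
.is_heavy_token <- function(tok) {
  .is_atom_token(tok) & !grepl("^\\[[0-9]*H[0-9]*\\]$", tok)
}

.is_carbon_token <- function(tok) {
  tok %in% c("C", "c") | grepl("^\\[[0-9]*[Cc][H0-9@+\\-]*\\]$", tok)
}

.is_aromatic_token <- function(tok) {
  tok %in% .atom_lower | grepl("^\\[[0-9]*[bcnops]", tok)
}

.is_ring_token <- function(tok) {
  grepl("^[0-9]$|^%[0-9]{2}$", tok)
}

# Counts used by the syntax-derived descriptors. Ring counts are derived from
# ring-closure labels of the canonical SMILES (each label opens and closes
# exactly once in a valid string), aromaticity from lower-case atom symbols.
.token_counts <- function(tokens) {
  heavy <- .is_heavy_token(tokens)
  ring <- .is_ring_token(tokens)
  n_ring <- sum(ring) / 2
  # an aromatic ring is counted when its closure label is opened at an
  # aromatic atom: scan labels and remember the opening atom's flavour
  arom_rings <- 0L
  if (any(ring)) {
    open <- list()
    last_arom <- FALSE
    for (i in seq_along(tokens)) {
      tok <- tokens[[i]]
      if (.is_atom_token(tok)) {
        last_arom <- .is_aromatic_token(tok)
      } else if (.is_ring_token(tok)) {
        if (is.null(open[[tok]])) {
          open[[tok]] <- last_arom
        } else {
          if (isTRUE(open[[tok]])) arom_rings <- arom_rings + 1L
          open[[tok]] <- NULL
        }
      }
    }
  }
  c(
    HeavyAtomCount = sum(heavy),
    NumHeteroatoms = sum(heavy & !.is_carbon_token(tokens)),
    RingCount = n_ring,
    NumAromaticRings = arom_rings
  )
}
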