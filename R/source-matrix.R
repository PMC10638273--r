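## Synthetic stand-in for the published 178-eukaryote source-data table.
## The real per-species table is a supplementary download; this constructor
## builds a deterministic matrix that satisfies every count the study
## prints, so that the downstream pipeline can be exercised at full scale
## without network access. The joint structure of the unresolved species
## is under-determined by those counts and is fixed here by a single
## deterministic coherence packing (chosen once, from the counts alone).

#' Synthetic reconstruction of the 178-species source profile matrix
#'
#' Builds a deterministic 178 x 6 three-state matrix whose marginal
#' structure matches the published study exactly: 69/67/94/91/87/178
#' species with high-confidence RING1/PCGF/EZH/EED/SUZ12/RBBP orthologs,
#' 15 putative RING1 and 10 putative PCGF calls, and five-way category
#' counts 40 BOTH, 12 PRC1-only, 17 PRC2-only, 52 neither, 57 unclear.
#' Cells of the 57 unresolved species are laid out by a fixed coherence
#' packing; pairwise co-occurrence values computed from this matrix are
#' therefore indicative, not reproductions of the published ones. The
#' matrix is synthetic: species identifiers encode their category, not
#' real taxa.
#'
#' @return a \linkS4class{PresenceMatrix} (178 species x 6 subunits).
#' @export
#' @examples
#' m <- syntheticSourceMatrix()
#' table(categorizeSpecies(m))
syntheticSourceMatrix <- function() {
  subs <- coreSubunits()
  rows <- list()
  addRows <- function(prefix, n, template) {
    for (i in seq_len(n)) {
      rows[[sprintf("%s%02d", prefix, i)]] <<- template
    }
  }
  one <- function(r1, pg, ez, ed, sz) {
    structure(c(r1, pg, ez, ed, sz, PRESENT), names = subs)
  }
  addRows("both", 40, one("1", "1", "1", "1", "1"))
  addRows("prc1only", 12, one("1", "1", "0", "0", "0"))
  addRows("prc2only", 17, one("0", "0", "1", "1", "1"))
  addRows("neither", 52, one("0", "0", "0", "0", "0"))
  ## 57 unresolved species: putative PRC1 evidence, partial complexes.
  unclear <- rbind(
    do.call(rbind, replicate(15, one("P", "0", "1", "1", "1"), simplify = FALSE)), # u01-u15
    one("0", "P", "1", "1", "1"),                                                  # u16
    do.call(rbind, replicate(7,  one("0", "P", "1", "1", "0"), simplify = FALSE)), # u17-u23
    do.call(rbind, replicate(2,  one("0", "P", "1", "1", "0"), simplify = FALSE)), # u24-u25
    do.call(rbind, replicate(7,  one("1", "1", "1", "1", "0"), simplify = FALSE)), # u26-u32
    do.call(rbind, replicate(5,  one("0", "1", "1", "0", "1"), simplify = FALSE)), # u33-u37
    do.call(rbind, replicate(2,  one("1", "0", "0", "1", "1"), simplify = FALSE)), # u38-u39
    do.call(rbind, replicate(8,  one("1", "0", "0", "0", "0"), simplify = FALSE)), # u40-u47
    do.call(rbind, replicate(3,  one("0", "1", "0", "0", "0"), simplify = FALSE)), # u48-u50
    do.call(rbind, replicate(7,  one("0", "0", "0", "0", "1"), simplify = FALSE))  # u51-u57
  )
  rownames(unclear) <- sprintf("unclear%02d", seq_len(nrow(unclear)))
  m <- rbind(do.call(rbind, rows), unclear)
  colnames(m) <- subs
  PresenceMatrix(m)
}

#' High-confidence presence counts per subunit
#'
#' Number of species called high-confidence ("1") for each subunit of a
#' presence matrix.
#'
#' @param x a \linkS4class{PresenceMatrix}.
#' @return named integer vector.
#' @export
presenceCounts <- function(x) {
  m <- presenceStates(x)
  vapply(colnames(m), function(su) sum(m[, su] == PRESENT), integer(1))
}
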