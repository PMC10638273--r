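## S4 classes for the profiling pipeline. Validity methods enforce the
## structural invariants; accessors live in AllGenerics.R / the module files.

#' PresenceMatrix: species-by-subunit three-state profile matrix
#'
#' A complete species x subunit matrix of ortholog calls with cells
#' \code{"1"} (high-confidence present), \code{"0"} (absent) and \code{"P"}
#' (putative: partially supported, e.g. a zf-RING protein lacking a
#' recognizable RAWUL domain). Rows are species, columns subunits.
#'
#' @slot states character matrix with dimnames; cells in \{"1","0","P"\}.
#' @export
setClass("PresenceMatrix", representation(states = "matrix"))

setValidity("PresenceMatrix", function(object) {
  m <- object@states
  if (!is.character(m)) return("states must be a character matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("states must have species rownames and subunit colnames")
  if (anyDuplicated(rownames(m))) return("duplicate species rows")
  if (anyDuplicated(colnames(m))) return("duplicate subunit columns")
  bad <- !(m %in% validStates)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    return(sprintf("invalid cell state '%s' at species '%s', subunit '%s'",
                   m[idx[1L], idx[2L]], rownames(m)[idx[1L]], colnames(m)[idx[2L]]))
  }
  TRUE
})

#' SpeciesMap: species to major-group to root-side assignment
#'
#' Maps each species identifier to one major eukaryotic group, and each
#' group to one of the two sides of an assumed root of the species tree.
#' Presence on both sides (plus sufficiently many groups) is the evidence
#' used to place a gene in the last common ancestor.
#'
#' @slot groupOf named character vector: species -> group.
#' @slot sideOf named character vector: group -> root side.
#' @export
setClass("SpeciesMap", representation(groupOf = "character", sideOf = "character"))

setValidity("SpeciesMap", function(object) {
  if (anyDuplicated(names(object@groupOf)))
    return("a species is assigned to more than one group")
  if (anyDuplicated(names(object@sideOf)))
    return("a group is assigned to more than one root side")
  orphan <- setdiff(unique(object@groupOf), names(object@sideOf))
  if (length(orphan))
    return(sprintf("group(s) without a root side: %s", paste(orphan, collapse = ", ")))
  TRUE
})

#' LabeledGeneTree: gene tree with duplication/speciation node labels
#'
#' A rooted gene tree (an \code{ape} \code{phylo}, binary after
#' deterministic multifurcation resolution) in which every internal node
#' carries a species-overlap score |S_L intersect S_R| / |S_L union S_R|
#' and an event label: \code{"duplication"} when the score exceeds the
#' overlap threshold, else \code{"speciation"}.
#'
#' @slot tree a rooted binary \code{phylo}.
#' @slot events character vector over internal nodes (in phylo node order).
#' @slot overlap numeric vector of species-overlap scores, same order.
#' @slot meta data.frame of leaf metadata (leaf, species, protein,
#'   architecture, functionLabel).
#' @export
setClass("LabeledGeneTree",
         representation(tree = "ANY", events = "character",
                        overlap = "numeric", meta = "data.frame"))

setValidity("LabeledGeneTree", function(object) {
  tr <- object@tree
  if (!inherits(tr, "phylo")) return("tree must be a phylo object")
  if (length(object@events) != tr$Nnode) return("one event label per internal node required")
  if (length(object@overlap) != tr$Nnode) return("one overlap score per internal node required")
  if (!all(object@events %in% c("duplication", "speciation")))
    return("event labels must be 'duplication' or 'speciation'")
  if (any(object@overlap < 0 | object@overlap > 1)) return("overlap scores must lie in [0,1]")
  TRUE
})

#' ComplexStatusReport: per-species category with summary statistics
#'
#' Five-way categorization of species by the completeness of the two
#' complexes, with counts, nearest-integer percentages of the total, and
#' the uncoupled fraction (single-complex species among the
#' resolved-complete species BOTH + PRC1_ONLY + PRC2_ONLY).
#'
#' @slot categories named character vector: species -> category.
#' @slot counts named integer vector over the five categories.
#' @slot percentages named numeric vector (nearest-integer, of total).
#' @slot uncoupledPercent numeric; NA when no species is resolved complete.
#' @slot total integer number of species.
#' @export
setClass("ComplexStatusReport",
         representation(categories = "character", counts = "integer",
                        percentages = "numeric", uncoupledPercent = "numeric",
                        total = "integer"))

categoryLevels <- function() c("BOTH", "PRC1_ONLY", "PRC2_ONLY", "NEITHER", "UNCLEAR")

setValidity("ComplexStatusReport", function(object) {
  if (!identical(names(object@counts), categoryLevels()))
    return("counts must be named by the five categories in canonical order")
  if (sum(object@counts) != object@total) return("category counts must sum to total")
  if (!all(object@categories %in% categoryLevels()))
    return("unknown category label")
  TRUE
})

#' CooccurrenceResult: pairwise phi matrix with group averages
#'
#' Symmetric matrix of phi coefficients between subunit presence/absence
#' profiles (putative cells excluded pairwise or listwise), per-pair
#' effective sample sizes, intra/inter-complex averages, and the
#' average-linkage clustering of the subunits on d = 1 - phi.
#'
#' @slot phi symmetric numeric matrix (NA where undefined).
#' @slot n integer matrix of per-pair effective sample sizes.
#' @slot averages named numeric vector (intraPRC1, intraPRC2, inter).
#' @slot linkage an \code{hclust} object, or NULL when fewer than two
#'   subunits are clusterable.
#' @slot order character vector: dendrogram leaf order.
#' @export
setClass("CooccurrenceResult",
         representation(phi = "matrix", n = "matrix", averages = "numeric",
                        linkage = "ANY", order = "character"))

setValidity("CooccurrenceResult", function(object) {
  p <- object@phi
  if (!isTRUE(all.equal(p, t(p)))) return("phi matrix must be symmetric")
  offdiag <- p[row(p) != col(p)]
  if (any(!is.na(offdiag) & (offdiag < -1 - 1e-12 | offdiag > 1 + 1e-12)))
    return("phi values must lie in [-1, 1]")
  TRUE
})

#' LossModelParams: parameters of the coupled Dollo loss simulator
#'
#' @slot lambda per-complex loss rate (events per unit branch length).
#' @slot rho probability that a loss event removes both complexes at once.
#' @slot delta per-subunit degradation rate given the complex is retained.
#' @slot pi probability a present call is downgraded to putative.
#' @slot seed integer random seed.
#' @export
setClass("LossModelParams",
         representation(lambda = "numeric", rho = "numeric", delta = "numeric",
                        pi = "numeric", seed = "integer"))

setValidity("LossModelParams", function(object) {
  if (object@lambda < 0 || object@delta < 0) return("rates must be >= 0")
  if (object@rho < 0 || object@rho > 1) return("rho must lie in [0,1]")
  if (any(object@pi < 0 | object@pi > 1)) return("pi must lie in [0,1]")
  TRUE
})
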