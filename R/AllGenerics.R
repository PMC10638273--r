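#' @rdname PresenceMatrix-class
#' @param object,x a package object.
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname PresenceMatrix-class
#' @export
setGeneric("subunitNames", function(x) standardGeneric("subunitNames"))

#' @rdname PresenceMatrix-class
#' @export
setGeneric("presenceStates", function(x) standardGeneric("presenceStates"))

#' @rdname PresenceMatrix-class
#' @export
setGeneric("binaryProfiles", function(x) standardGeneric("binaryProfiles"))

#' @export
#' @rdname ComplexStatusReport-class
setGeneric("categories", function(x) standardGeneric("categories"))

#' @export
#' @rdname ComplexStatusReport-class
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))

#' @export
#' @rdname ComplexStatusReport-class
setGeneric("categoryPercentages", function(x) standardGeneric("categoryPercentages"))

#' @export
#' @rdname ComplexStatusReport-class
setGeneric("uncoupledPercent", function(x) standardGeneric("uncoupledPercent"))

#' @export
#' @rdname CooccurrenceResult-class
setGeneric("phiMatrix", function(x) standardGeneric("phiMatrix"))

#' @export
#' @rdname CooccurrenceResult-class
setGeneric("effectiveN", function(x) standardGeneric("effectiveN"))

#' @export
#' @rdname SpeciesMap-class
setGeneric("groupOf", function(x, species) standardGeneric("groupOf"))

#' @export
#' @rdname SpeciesMap-class
setGeneric("rootSideOf", function(x, group) standardGeneric("rootSideOf"))

setMethod("speciesNames", "PresenceMatrix", function(x) rownames(x@states))
setMethod("subunitNames", "PresenceMatrix", function(x) colnames(x@states))
setMethod("presenceStates", "PresenceMatrix", function(x) x@states)

## Binary view: 1 for present, 0 for absent, NA for putative — the encoding
## in which "putative orthologs contribute neither presences nor absences".
setMethod("binaryProfiles", "PresenceMatrix", function(x) {
  m <- matrix(NA_real_, nrow(x@states), ncol(x@states), dimnames = dimnames(x@states))
  m[x@states == PRESENT] <- 1
  m[x@states == ABSENT] <- 0
  m
})

setMethod("speciesNames", "SpeciesMap", function(x) names(x@groupOf))
setMethod("groupOf", "SpeciesMap", function(x, species) {
  missing <- setdiff(species, names(x@groupOf))
  if (length(missing))
    stop("species absent from the species map: ", paste(missing, collapse = ", "))
  unname(x@groupOf[species])
})
setMethod("rootSideOf", "SpeciesMap", function(x, group) {
  missing <- setdiff(group, names(x@sideOf))
  if (length(missing))
    stop("group(s) without root side: ", paste(missing, collapse = ", "))
  unname(x@sideOf[group])
})

setMethod("categories", "ComplexStatusReport", function(x) x@categories)
setMethod("categoryCounts", "ComplexStatusReport", function(x) x@counts)
setMethod("categoryPercentages", "ComplexStatusReport", function(x) x@percentages)
setMethod("uncoupledPercent", "ComplexStatusReport", function(x) x@uncoupledPercent)

setMethod("phiMatrix", "CooccurrenceResult", function(x) x@phi)
setMethod("effectiveN", "CooccurrenceResult", function(x) x@n)

setMethod("show", "PresenceMatrix", function(object) {
  cat(sprintf("PresenceMatrix: %d species x %d subunits\n",
              nrow(object@states), ncol(object@states)))
  tab <- table(factor(object@states, levels = validStates))
  cat(sprintf("  cells: %d present, %d absent, %d putative\n",
              tab[[PRESENT]], tab[[ABSENT]], tab[[PUTATIVE]]))
})

setMethod("show", "SpeciesMap", function(object) {
  cat(sprintf("SpeciesMap: %d species in %d groups on %d root side(s)\n",
              length(object@groupOf), length(object@sideOf),
              length(unique(object@sideOf))))
})

setMethod("show", "ComplexStatusReport", function(object) {
  cat(sprintf("ComplexStatusReport over %d species\n", object@total))
  for (cl in categoryLevels()) {
    cat(sprintf("  %-10s %4d (%d%%)\n", cl, object@counts[[cl]], object@percentages[[cl]]))
  }
  if (is.na(object@uncoupledPercent)) {
    cat("  uncoupled fraction: undefined (no resolved-complete species)\n")
  } else {
    cat(sprintf("  uncoupled fraction among resolved-complete species: %d%%\n",
                object@uncoupledPercent))
  }
})

setMethod("show", "CooccurrenceResult", function(object) {
  cat(sprintf("CooccurrenceResult over %d subunits\n", nrow(object@phi)))
  cat(sprintf("  intra-PRC1 %.3f, intra-PRC2 %.3f, inter %.3f\n",
              object@averages[["intraPRC1"]], object@averages[["intraPRC2"]],
              object@averages[["inter"]]))
})

setMethod("show", "LabeledGeneTree", function(object) {
  cat(sprintf("LabeledGeneTree: %d leaves, %d duplication / %d speciation nodes\n",
              length(object@tree$tip.label),
              sum(object@events == "duplication"),
              sum(object@events == "speciation")))
})

setMethod("show", "LossModelParams", function(object) {
  cat(sprintf("LossModelParams: lambda=%.3g rho=%.3g delta=%.3g pi=%s seed=%d\n",
              object@lambda, object@rho, object@delta,
              paste(signif(object@pi, 3), collapse = "/"), object@seed))
})
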