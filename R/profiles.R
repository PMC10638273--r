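## Profiles stage: assemble the species x subunit three-state matrix, score
## complex completeness, categorize species, summarize.

#' Default complex definitions
#'
#' The defining core subunit sets: PRC1 = \{RING1, PCGF\}, PRC2 = \{EZH,
#' EED, SUZ12\}. RBBP is carried in profile matrices but never used for
#' completeness, because its ubiquity (it participates in several other
#' chromatin assemblies) makes it uninformative about PRC2 presence.
#'
#' @return named list of character vectors of core subunits.
#' @export
defaultComplexDefinitions <- function() {
  list(PRC1 = c("RING1", "PCGF"), PRC2 = c("EZH", "EED", "SUZ12"))
}

#' Assemble a three-state presence matrix from ortholog calls
#'
#' Cells without a call default to absent; duplicate calls for one
#' (species, subunit) pair are an error.
#'
#' @param calls data.frame with columns species, subunit, status
#'   (high_confidence / putative / absent), e.g. from [callOrthologs()].
#' @param speciesUniverse ordered species list (default: species in calls).
#' @param subunits ordered subunit list (default [coreSubunits()]).
#' @return a \linkS4class{PresenceMatrix}.
#' @export
assembleMatrix <- function(calls, speciesUniverse = NULL,
                           subunits = coreSubunits()) {
  if (is.null(speciesUniverse)) speciesUniverse <- unique(calls$species)
  key <- paste(calls$species, calls$subunit, sep = "\r")
  if (anyDuplicated(key)) {
    d <- calls[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate call for species '%s', subunit '%s'", d$species, d$subunit))
  }
  m <- matrix(ABSENT, length(speciesUniverse), length(subunits),
              dimnames = list(speciesUniverse, subunits))
  inScope <- calls$species %in% speciesUniverse & calls$subunit %in% subunits
  for (i in which(inScope)) {
    m[calls$species[i], calls$subunit[i]] <- switch(calls$status[i],
      high_confidence = PRESENT, putative = PUTATIVE, absent = ABSENT,
      stop("unknown call status: ", calls$status[i]))
  }
  PresenceMatrix(m)
}

#' Score the completeness state of one complex in one species
#'
#' \code{complete} iff every core subunit is present ("1"); \code{absent}
#' iff every core subunit is absent ("0"); \code{putative_only} iff no
#' core subunit is present but at least one is putative; \code{partial}
#' otherwise (a mixture of present with absent/putative).
#'
#' @param row named character vector of cell states for one species.
#' @param core character vector of the complex's core subunits.
#' @return one of "complete", "partial", "putative_only", "absent".
#' @export
#' @examples
#' complexState(c(RING1 = "1", PCGF = "1"), c("RING1", "PCGF"))  # complete
#' complexState(c(RING1 = "P", PCGF = "0"), c("RING1", "PCGF"))  # putative_only
complexState <- function(row, core) {
  missing <- setdiff(core, names(row))
  if (length(missing))
    stop("schema error: core subunit column(s) missing: ",
         paste(missing, collapse = ", "))
  s <- row[core]
  if (all(s == PRESENT)) return("complete")
  if (all(s == ABSENT)) return("absent")
  if (!any(s == PRESENT)) return("putative_only")
  "partial"
}

#' Categorize every species by the completeness of both complexes
#'
#' BOTH iff both complexes are complete; PRC1_ONLY iff PRC1 is complete
#' and PRC2 fully absent (PRC2_ONLY symmetric); NEITHER iff both fully
#' absent; UNCLEAR otherwise — i.e. whenever either complex is partial or
#' supported only by putative calls. A species with one complete complex
#' and the other merely partial is therefore UNCLEAR, not *_ONLY: partial
#' complexes leave the status unresolved.
#'
#' @param x a \linkS4class{PresenceMatrix}.
#' @param definitions complex definitions (default
#'   [defaultComplexDefinitions()]).
#' @return named character vector: species -> category.
#' @export
categorizeSpecies <- function(x, definitions = defaultComplexDefinitions()) {
  m <- presenceStates(x)
  vapply(rownames(m), function(sp) {
    s1 <- complexState(m[sp, ], definitions$PRC1)
    s2 <- complexState(m[sp, ], definitions$PRC2)
    if (s1 == "complete" && s2 == "complete") "BOTH"
    else if (s1 == "complete" && s2 == "absent") "PRC1_ONLY"
    else if (s2 == "complete" && s1 == "absent") "PRC2_ONLY"
    else if (s1 == "absent" && s2 == "absent") "NEITHER"
    else "UNCLEAR"
  }, character(1))
}

#' Summarize species categories into a status report
#'
#' Computes category counts, nearest-integer percentages of the total
#' (halves rounded away from zero), and the uncoupled fraction: the
#' percentage of single-complex species among the resolved-complete
#' species (BOTH + PRC1_ONLY + PRC2_ONLY). With no resolved-complete
#' species the uncoupled fraction is undefined (NA), not 0.
#'
#' @param cats named character vector of per-species categories.
#' @return a \linkS4class{ComplexStatusReport}.
#' @export
#' @examples
#' cats <- rep(c("BOTH","PRC1_ONLY","PRC2_ONLY","NEITHER"), c(2, 1, 1, 3))
#' names(cats) <- paste0("s", 1:7)
#' uncoupledPercent(summarizeCategories(cats))  # 100 * 2/4 = 50
summarizeCategories <- function(cats) {
  if (!length(cats)) stop("contract error: empty category assignment")
  bad <- setdiff(unique(cats), categoryLevels())
  if (length(bad)) stop("unknown category label(s): ", paste(bad, collapse = ", "))
  counts <- vapply(categoryLevels(), function(cl) sum(cats == cl), integer(1))
  total <- length(cats)
  pct <- roundHalfUp(100 * counts / total)
  resolved <- counts[["BOTH"]] + counts[["PRC1_ONLY"]] + counts[["PRC2_ONLY"]]
  unc <- if (resolved == 0L) NA_real_ else
    roundHalfUp(100 * (counts[["PRC1_ONLY"]] + counts[["PRC2_ONLY"]]) / resolved)
  new("ComplexStatusReport", categories = cats, counts = counts,
      percentages = pct, uncoupledPercent = unc, total = total)
}

#' Single-complex percentage of the total
#'
#' Convenience accessor: the nearest-integer percentage of all species
#' that retained exactly one complete complex (PRC1_ONLY + PRC2_ONLY).
#'
#' @param report a \linkS4class{ComplexStatusReport}.
#' @return numeric percentage.
#' @export
singleComplexPercent <- function(report) {
  counts <- categoryCounts(report)
  roundHalfUp(100 * (counts[["PRC1_ONLY"]] + counts[["PRC2_ONLY"]]) / report@total)
}
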