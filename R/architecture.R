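## Domain-architecture stage: raw hits -> accepted per-protein architectures
## -> per-(species, subunit) ortholog confidence calls.

#' Filter domain hits by significance and resolve envelope overlaps
#'
#' Per protein, hits with independent E-value above \code{threshold} are
#' discarded; among the significant hits, overlapping envelopes are
#' resolved whole-hit greedily: hits are ranked by descending bit score
#' (ties: ascending E-value, then ascending start), and a hit is accepted
#' only if its envelope is disjoint from every previously accepted hit of
#' the same protein. The global ranking makes the result independent of
#' input order, and the operation is idempotent.
#'
#' @param hits data.frame as returned by [parseDomtblout()].
#' @param threshold per-domain E-value cutoff (default 1e-5).
#' @return data.frame of accepted hits, ordered by protein then start.
#' @export
#' @examples
#' h <- data.frame(protein = "P1", species = "S1",
#'                 domain = c("zf-RING", "RAWUL"),
#'                 start = c(10, 40), end = c(55, 120),
#'                 evalue = c(1e-12, 1e-8), bits = c(40, 25))
#' filterHits(h)  # overlap 40-55: the higher-scoring zf-RING hit wins
filterHits <- function(hits, threshold = 1e-5) {
  if (!is.numeric(threshold) || threshold <= 0) stop("E-value threshold must be > 0")
  if (nrow(hits) == 0L) return(hits)
  before <- nrow(hits)
  hits <- hits[hits$evalue <= threshold, , drop = FALSE]
  logCounts("filterHits/evalue", before, nrow(hits))
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$protein, -hits$bits, hits$evalue, hits$start)
  hits <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(hits))
  for (p in unique(hits$protein)) {
    idx <- which(hits$protein == p)
    accepted <- integer(0)
    for (i in idx) {
      clash <- any(hits$start[i] <= hits$end[accepted] &
                   hits$end[i] >= hits$start[accepted])
      if (!clash) {
        keep[i] <- TRUE
        accepted <- c(accepted, i)
      }
    }
  }
  logCounts("filterHits/overlap", nrow(hits), sum(keep))
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$protein, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the domain architecture of one protein
#'
#' Orders the accepted, non-overlapping hits of a single protein N- to
#' C-terminally (ascending envelope start) and returns the architecture as
#' a comma-joined domain string, e.g. \code{"zf-RING,RAWUL"}.
#'
#' @param hits data.frame of accepted hits for one protein.
#' @return list with elements \code{protein}, \code{species},
#'   \code{domains} (character vector, N->C) and \code{architecture}
#'   (the comma-joined string; \code{""} for a protein with no hits).
#' @export
architectureOf <- function(hits) {
  if (nrow(hits) == 0L)
    return(list(protein = NA_character_, species = NA_character_,
                domains = character(0), architecture = ""))
  if (length(unique(hits$protein)) != 1L)
    stop("architectureOf expects hits of a single protein")
  ord <- order(hits$start)
  hits <- hits[ord, , drop = FALSE]
  if (nrow(hits) > 1L && any(hits$start[-1] <= hits$end[-nrow(hits)]))
    stop("contract violation: overlapping hits passed to architectureOf; run filterHits first")
  list(protein = hits$protein[1], species = hits$species[1],
       domains = hits$domain, architecture = paste(hits$domain, collapse = ","))
}

#' Default subunit domain rules
#'
#' The domain requirements that define high-confidence and putative
#' ortholog calls for each subunit. RING1 and PCGF require an N-terminal
#' zf-RING followed by a C-terminal RAWUL; a zf-RING without a
#' recognizable RAWUL yields only a putative call. EZH is recognized by
#' its catalytic SET domain, EED and RBBP by WD40 repeats, SUZ12 by the
#' VEFS box, RYBP by zf-RanBP followed by the C-terminal beta-hairpin
#' (zf-RanBP alone is putative), CBX by chromo plus beta-hairpin (chromo
#' alone putative), and the PHC/SCM family by the SAM domain (no order
#' constraint: SAM/MBT orders are reversed in some unicellular lineages).
#'
#' @return data.frame with columns subunit, required, putative, ordered —
#'   required/putative are comma-joined domain sets; ordered marks rules
#'   whose required domains must appear in the given N->C order.
#' @export
defaultSubunitRules <- function() {
  data.frame(
    subunit  = c("RING1", "PCGF", "EZH", "EED", "SUZ12", "RBBP", "RYBP", "CBX", "PHC_SCM"),
    required = c("zf-RING,RAWUL", "zf-RING,RAWUL", "SET", "WD40", "VEFS", "WD40",
                 "zf-RanBP,beta-HP", "chromo,beta-HP", "SAM"),
    putative = c("zf-RING", "zf-RING", "", "", "", "", "zf-RanBP", "chromo", ""),
    ordered  = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

splitDomains <- function(s) {
  if (!nzchar(s)) character(0) else strsplit(s, ",", fixed = TRUE)[[1]]
}

## Does an architecture (domains N->C) satisfy a domain set, optionally in
## the stated order? Order satisfaction = some increasing subsequence of
## positions realises the required sequence.
satisfiesRule <- function(domains, requiredSet, ordered) {
  if (length(requiredSet) == 0L) return(FALSE)
  if (!all(requiredSet %in% domains)) return(FALSE)
  if (!ordered) return(TRUE)
  pos <- 0L
  for (d in requiredSet) {
    nxt <- which(domains == d & seq_along(domains) > pos)
    if (!length(nxt)) return(FALSE)
    pos <- min(nxt)
  }
  TRUE
}

#' Classify a species' candidate proteins for one subunit
#'
#' A species is called \code{high_confidence} for a subunit if any
#' candidate protein architecture satisfies the subunit's full required
#' domain set (respecting the N->C order constraint where the rule
#' declares one); otherwise \code{putative} if any candidate satisfies the
#' putative set; otherwise \code{absent}. Evidence proteins are those
#' satisfying the rule that fired.
#'
#' @param species species identifier.
#' @param architectures list of architectures (from [architectureOf()])
#'   for this species' candidate proteins; may be empty.
#' @param subunit subunit name, looked up in \code{rules}.
#' @param rules rule table (default [defaultSubunitRules()]).
#' @return list with species, subunit, status, proteins (evidence).
#' @export
classifySubunit <- function(species, architectures, subunit,
                            rules = defaultSubunitRules()) {
  row <- rules[rules$subunit == subunit, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown subunit rule: ", subunit)
  for (a in architectures) {
    if (!is.na(a$species) && !identical(a$species, species))
      stop(sprintf("architecture of protein '%s' belongs to species '%s', not '%s'",
                   a$protein, a$species, species))
  }
  req <- splitDomains(row$required)
  put <- splitDomains(row$putative)
  highHit <- vapply(architectures, function(a)
    satisfiesRule(a$domains, req, row$ordered), logical(1))
  if (any(highHit)) {
    return(list(species = species, subunit = subunit, status = "high_confidence",
                proteins = vapply(architectures[highHit], `[[`, character(1), "protein")))
  }
  putHit <- vapply(architectures, function(a)
    satisfiesRule(a$domains, put, FALSE), logical(1))
  if (any(putHit)) {
    return(list(species = species, subunit = subunit, status = "putative",
                proteins = vapply(architectures[putHit], `[[`, character(1), "protein")))
  }
  list(species = species, subunit = subunit, status = "absent", proteins = character(0))
}

#' Call ortholog confidence for every (species, subunit) pair
#'
#' Convenience driver: filters raw hits, builds per-protein architectures,
#' and classifies each species against each subunit rule.
#'
#' @param hits raw domain hits (see [parseDomtblout()]).
#' @param speciesUniverse species to call (default: those seen in hits).
#' @param subunits subunits to call (default: all rules).
#' @param rules rule table.
#' @param threshold per-domain E-value cutoff.
#' @return data.frame with columns species, subunit, status, proteins
#'   (comma-joined evidence identifiers).
#' @export
callOrthologs <- function(hits, speciesUniverse = NULL,
                          subunits = NULL, rules = defaultSubunitRules(),
                          threshold = 1e-5) {
  accepted <- filterHits(hits, threshold)
  if (is.null(speciesUniverse))
    speciesUniverse <- sort(unique(accepted$species))
  if (is.null(subunits)) subunits <- rules$subunit
  archBySpecies <- lapply(speciesUniverse, function(sp) {
    sub <- accepted[!is.na(accepted$species) & accepted$species == sp, , drop = FALSE]
    lapply(split(sub, sub$protein), architectureOf)
  })
  names(archBySpecies) <- speciesUniverse
  out <- list()
  for (sp in speciesUniverse) {
    for (su in subunits) {
      call <- classifySubunit(sp, archBySpecies[[sp]], su, rules)
      out[[length(out) + 1L]] <- data.frame(
        species = sp, subunit = su, status = call$status,
        proteins = paste(call$proteins, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(species = character(), subunit = character(),
                      status = character(), proteins = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
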