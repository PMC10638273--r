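## Co-occurrence stage: phi coefficients between binary presence profiles,
## intra/inter-complex averages, average-linkage clustering.

#' Phi coefficient of two binary vectors
#'
#' Pearson correlation specialised to binary data, computed from the 2x2
#' contingency counts after pairwise deletion of positions where either
#' vector is NA (putative calls): phi = (n11 n00 - n10 n01) /
#' sqrt((n11+n10)(n01+n00)(n11+n01)(n10+n00)). When any marginal is zero
#' (a constant vector) the value is undefined and NA is returned — never
#' 0.
#'
#' @param x,y numeric vectors of 0/1 with NA for excluded positions.
#' @return phi in [-1, 1], or NA when undefined.
#' @export
#' @examples
#' phiCoefficient(c(1,1,1,1,0,0,0,0), c(1,1,1,0,1,0,0,0))  # 0.5
phiCoefficient <- function(x, y) {
  if (length(x) != length(y)) stop("contract error: length mismatch")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n11 <- sum(x == 1 & y == 1)
  n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1)
  n00 <- sum(x == 0 & y == 0)
  denom2 <- (n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00)
  if (denom2 == 0) return(NA_real_)
  (n11 * n00 - n10 * n01) / sqrt(denom2)
}

## Effective pairwise n after deletion.
pairN <- function(x, y) sum(!is.na(x) & !is.na(y))

#' Pairwise phi co-occurrence of subunit profiles
#'
#' Computes phi for every unordered subunit pair of a presence matrix.
#' Putative cells contribute neither presences nor absences: under
#' \code{"pairwise"} handling (default) a species is dropped for a pair
#' iff either subunit is putative there; under \code{"listwise"} any
#' species with a putative call in any requested subunit is dropped from
#' all pairs. Zero-variance profiles yield NA (flagged in a warning) and
#' are excluded from averages and clustering.
#'
#' @param x a \linkS4class{PresenceMatrix}.
#' @param subunits subunits to correlate (default: all columns).
#' @param putativeHandling "pairwise" or "listwise".
#' @param prc1,prc2 core subunit sets used for the intra/inter averages.
#' @return a \linkS4class{CooccurrenceResult}.
#' @export
cooccurrence <- function(x, subunits = subunitNames(x),
                         putativeHandling = c("pairwise", "listwise"),
                         prc1 = c("RING1", "PCGF"),
                         prc2 = c("EZH", "EED", "SUZ12")) {
  putativeHandling <- match.arg(putativeHandling)
  missing <- setdiff(subunits, subunitNames(x))
  if (length(missing))
    stop("schema error: subunit(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  b <- binaryProfiles(x)[, subunits, drop = FALSE]
  if (putativeHandling == "listwise") {
    b <- b[stats::complete.cases(b), , drop = FALSE]
  }
  k <- length(subunits)
  phi <- matrix(NA_real_, k, k, dimnames = list(subunits, subunits))
  n <- matrix(0L, k, k, dimnames = list(subunits, subunits))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j < i) next
      phi[i, j] <- phi[j, i] <- phiCoefficient(b[, i], b[, j])
      n[i, j] <- n[j, i] <- pairN(b[, i], b[, j])
    }
  }
  undef <- subunits[vapply(seq_len(k), function(i) anyNA(phi[i, -i]), logical(1))]
  if (length(undef))
    warning("undefined (zero-variance or empty) phi involving: ",
            paste(undef, collapse = ", "))
  res <- new("CooccurrenceResult", phi = phi, n = n,
             averages = c(intraPRC1 = NA_real_, intraPRC2 = NA_real_, inter = NA_real_),
             linkage = NULL, order = character(0))
  if (all(c(prc1, prc2) %in% subunits)) {
    res@averages <- unlist(groupAverages(res, prc1, prc2))
  }
  cl <- averageLinkage(res)
  res@linkage <- cl$hclust
  res@order <- cl$order
  res
}

#' Intra- and inter-complex average phi
#'
#' Intra averages are taken over the unordered within-set pairs, the
#' inter average over all cross pairs of the two core sets (2 x 3 = 6
#' pairs for the defaults); RBBP belongs to neither set and is excluded.
#' Undefined pairs are dropped from the mean with a warning; when every
#' contributing pair is undefined the average is NA.
#'
#' @param result a \linkS4class{CooccurrenceResult}.
#' @param prc1,prc2 core subunit sets.
#' @return list with intraPRC1, intraPRC2, inter.
#' @export
groupAverages <- function(result, prc1 = c("RING1", "PCGF"),
                          prc2 = c("EZH", "EED", "SUZ12")) {
  p <- phiMatrix(result)
  need <- setdiff(c(prc1, prc2), rownames(p))
  if (length(need))
    stop("schema error: subunit(s) absent from result: ", paste(need, collapse = ", "))
  pairVals <- function(a, b = NULL) {
    if (is.null(b)) {
      if (length(a) < 2L) return(numeric(0))
      cmb <- utils::combn(a, 2)
      vapply(seq_len(ncol(cmb)), function(i) p[cmb[1, i], cmb[2, i]], numeric(1))
    } else {
      as.vector(p[a, b, drop = FALSE])
    }
  }
  avg <- function(v) {
    if (!length(v)) return(NA_real_)
    if (anyNA(v)) warning("undefined phi pair(s) excluded from average")
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    mean(v)
  }
  list(intraPRC1 = avg(pairVals(prc1)),
       intraPRC2 = avg(pairVals(prc2)),
       inter = avg(pairVals(prc1, prc2)))
}

#' Average-linkage clustering of subunits on phi distance
#'
#' Agglomerative average-linkage clustering on d = 1 - phi. Subunits with
#' any undefined pairwise value are reported and excluded; the remaining
#' subunits are presented to the clustering in lexicographic order so
#' that equal-distance merges resolve to the lexicographically smallest
#' pair.
#'
#' @param result a \linkS4class{CooccurrenceResult}.
#' @return list with \code{hclust} (an \code{hclust} object or NULL),
#'   \code{order} (ordered leaf names) and \code{excluded}.
#' @export
averageLinkage <- function(result) {
  p <- phiMatrix(result)
  subunits <- rownames(p)
  ## minimal exclusion: repeatedly drop the subunit with the most undefined
  ## pairs (ties: lexicographically last) until all kept pairs are defined
  keep <- sort(subunits, method = "radix")
  repeat {
    sub <- p[keep, keep, drop = FALSE]
    naCount <- vapply(seq_along(keep), function(i) sum(is.na(sub[i, -i])), integer(1))
    if (!any(naCount > 0L) || length(keep) == 0L) break
    worst <- keep[which(naCount == max(naCount))]
    keep <- setdiff(keep, worst[length(worst)])
  }
  bad <- setdiff(subunits, keep)
  if (length(keep) < 2L)
    return(list(hclust = NULL, order = keep, excluded = bad))
  d <- as.dist(1 - p[keep, keep])
  hc <- hclust(d, method = "average")
  list(hclust = hc, order = hc$labels[hc$order], excluded = bad)
}
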