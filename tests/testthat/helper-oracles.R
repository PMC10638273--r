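## Independent oracles used by the unit and property tests. These are kept
## deliberately naive and separate from the package's implementations.

## Phi from explicit 2x2 contingency counts (pairwise NA deletion).
phiOracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  d <- (n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00)
  if (d == 0) return(NA_real_)
  (n11 * n00 - n10 * n01) / sqrt(d)
}

## Truth-table species categorizer written as direct boolean logic.
categorizeOracle <- function(r1, pg, ez, ed, sz) {
  p1c <- r1 == "1" && pg == "1"
  p1a <- r1 == "0" && pg == "0"
  p2c <- ez == "1" && ed == "1" && sz == "1"
  p2a <- ez == "0" && ed == "0" && sz == "0"
  if (p1c && p2c) "BOTH"
  else if (p1c && p2a) "PRC1_ONLY"
  else if (p2c && p1a) "PRC2_ONLY"
  else if (p1a && p2a) "NEITHER"
  else "UNCLEAR"
}

## --- rooted binary tree enumeration over a small species alphabet -------

## All rooted binary topologies on the leaf index set idx (first index
## anchored to the left subtree to avoid mirror duplicates).
allTopologies <- function(idx) {
  if (length(idx) == 1L) return(list(idx))
  rest <- idx[-1]
  out <- list()
  for (k in 0:(length(rest) - 1)) {
    if (k == 0) {
      lefts <- list(idx[1])
      rights <- list(rest)
    } else {
      sel <- utils::combn(rest, k, simplify = FALSE)
      lefts <- lapply(sel, function(s) c(idx[1], s))
      rights <- lapply(sel, function(s) setdiff(rest, s))
    }
    for (i in seq_along(lefts)) {
      for (L in allTopologies(lefts[[i]])) {
        for (R in allTopologies(rights[[i]])) {
          out[[length(out) + 1L]] <- list(L, R)
        }
      }
    }
  }
  out
}

## A uniform-ish random topology by recursive random splits.
randomTopology <- function(idx) {
  if (length(idx) == 1L) return(idx)
  k <- sample(seq_len(length(idx) - 1L), 1L)
  left <- sample(idx, k)
  list(randomTopology(sort(left)), randomTopology(sort(setdiff(idx, left))))
}

## Leaf label for leaf index i under species assignment sp.
leafLabel <- function(sp, i) paste0(sp[i], "_", i)

topologyToNewick <- function(top, sp) {
  fmt <- function(t) {
    if (!is.list(t)) paste0(leafLabel(sp, t), ":1")
    else paste0("(", fmt(t[[1]]), ",", fmt(t[[2]]), "):1")
  }
  paste0(fmt(top), ";")
}

## Brute-force species-overlap labelling on the nested topology: returns a
## named list clade-key -> event, where the key is the sorted leaf labels.
overlapOracle <- function(top, sp, threshold = 0) {
  events <- list()
  walk <- function(t) {
    if (!is.list(t)) {
      return(list(leaves = leafLabel(sp, t), species = sp[t]))
    }
    L <- walk(t[[1]]); R <- walk(t[[2]])
    score <- length(intersect(L$species, R$species)) /
      length(union(L$species, R$species))
    leaves <- sort(c(L$leaves, R$leaves))
    key <- paste(leaves, collapse = "|")
    events[[key]] <<- if (score > threshold) "duplication" else "speciation"
    list(leaves = leaves, species = union(L$species, R$species))
  }
  walk(top)
  events
}

## Clade leaf sets per internal node of a phylo (named by node id).
cladeLeafSets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  repeat {
    done <- TRUE
    for (k in seq_len(nrow(tree$edge))) {
      p <- tree$edge[k, 1]
      kids <- tree$edge[tree$edge[, 1] == p, 2]
      if (is.null(sets[[p]]) && all(!vapply(sets[kids], is.null, logical(1)))) {
        sets[[p]] <- sort(unlist(sets[kids]))
        done <- FALSE
      }
    }
    if (done) break
  }
  sets
}

## Compare labelEvents against the brute-force oracle on one tree.
eventsAgreeWithOracle <- function(top, sp, threshold = 0) {
  nwk <- topologyToNewick(top, sp)
  tree <- readNewickTree(nwk)
  n <- length(tree$tip.label)
  meta <- data.frame(leaf = vapply(seq_along(sp), function(i) leafLabel(sp, i),
                                   character(1)),
                     species = sp, stringsAsFactors = FALSE)
  labeled <- labelEvents(tree, meta, threshold)
  oracle <- overlapOracle(top, sp, threshold)
  sets <- cladeLeafSets(labeled@tree)
  for (node in (n + 1L):(n + labeled@tree$Nnode)) {
    key <- paste(sets[[node]], collapse = "|")
    if (!identical(labeled@events[node - n], oracle[[key]])) return(FALSE)
  }
  TRUE
}

## All species assignments of n leaves over the alphabet, as a matrix.
allAssignments <- function(n, alphabet = c("X", "Y", "Z")) {
  as.matrix(expand.grid(rep(list(alphabet), n), stringsAsFactors = FALSE))
}

## Small presence matrix builder for tests.
pmat <- function(..., subunits = c("RING1", "PCGF", "EZH", "EED", "SUZ12", "RBBP")) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- subunits[seq_len(ncol(m))]
  rownames(m) <- sprintf("sp%02d", seq_len(nrow(m)))
  PresenceMatrix(m)
}
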