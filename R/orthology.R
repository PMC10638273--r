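## Gene-tree orthology stage: species-overlap duplication labelling,
## orthologous-group extraction, delineation criteria, LECA inference.

## --- internal tree helpers (on ape phylo) ---------------------------------

childrenOf <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

rootNode <- function(tree) length(tree$tip.label) + 1L

## Nested-list view of a phylo: list(label, length, children). Used for the
## deterministic multifurcation resolution.
phyloToNested <- function(tree, node = rootNode(tree)) {
  ntip <- length(tree$tip.label)
  edgeLen <- function(child) {
    if (is.null(tree$edge.length)) return(0)
    i <- which(tree$edge[, 2] == child)
    if (length(i)) tree$edge.length[i] else 0
  }
  build <- function(node) {
    if (node <= ntip) {
      return(list(label = tree$tip.label[node], length = edgeLen(node),
                  children = list()))
    }
    lab <- if (!is.null(tree$node.label)) tree$node.label[node - ntip] else ""
    if (is.na(lab)) lab <- ""
    kids <- lapply(childrenOf(tree, node), build)
    list(label = lab, length = edgeLen(node), children = kids)
  }
  build(node)
}

minLeafLabel <- function(nested) {
  if (!length(nested$children)) return(nested$label)
  min(vapply(nested$children, minLeafLabel, character(1)))
}

## Resolve every multifurcation into a left-leaning binary caterpillar with
## children taken in lexicographic order of their smallest leaf label; new
## internal nodes get zero-length branches and no support.
binarizeNested <- function(nested) {
  if (!length(nested$children)) return(nested)
  kids <- lapply(nested$children, binarizeNested)
  kids <- kids[order(vapply(kids, minLeafLabel, character(1)), method = "radix")]
  while (length(kids) > 2L) {
    merged <- list(label = "", length = 0,
                   children = kids[1:2])
    kids <- c(list(merged), kids[-(1:2)])
  }
  nested$children <- kids
  nested
}

nestedToNewick <- function(nested) {
  fmt <- function(x) {
    if (!length(x$children)) {
      sprintf("%s:%.6f", x$label, x$length)
    } else {
      sprintf("(%s)%s:%.6f",
              paste(vapply(x$children, fmt, character(1)), collapse = ","),
              x$label, x$length)
    }
  }
  paste0(fmt(nested), ";")
}

#' Resolve multifurcations deterministically
#'
#' Any node with more than two children is replaced by a left-leaning
#' binary caterpillar whose children are attached in lexicographic order
#' of their smallest descendant leaf label. The resolution is therefore a
#' pure function of the tree, independent of input rotation.
#'
#' @param tree a rooted \code{phylo}.
#' @return a rooted binary \code{phylo}.
#' @export
resolveMultifurcations <- function(tree) {
  if (ape::is.binary.phylo(tree)) return(tree)
  readNewickTree(nestedToNewick(binarizeNested(phyloToNested(tree))))
}

## Species sets per node, post-order; returns list indexed by node id.
nodeSpeciesSets <- function(tree, speciesOfLeaf) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- speciesOfLeaf[[tree$tip.label[i]]]
  for (node in postorderNodes(tree)) {
    kids <- childrenOf(tree, node)
    sets[[node]] <- sort(unique(unlist(sets[kids])))
  }
  sets
}

## Internal nodes in an order guaranteeing children before parents.
postorderNodes <- function(tree) {
  ntip <- length(tree$tip.label)
  acc <- new.env()
  acc$res <- integer(0)
  walk <- function(node) {
    if (node > ntip) {
      for (k in childrenOf(tree, node)) walk(k)
      acc$res <- c(acc$res, node)
    }
  }
  walk(rootNode(tree))
  acc$res
}

#' Label gene-tree nodes as duplication or speciation by species overlap
#'
#' For every internal node of a rooted binary gene tree, the species sets
#' of its two child clades are compared; the node's species-overlap score
#' is |S_L intersect S_R| / |S_L union S_R| and the node is labelled a
#' duplication when the score exceeds \code{overlapThreshold} (default 0:
#' any shared species implies a duplication), else a speciation.
#' Multifurcating input is first resolved with
#' [resolveMultifurcations()].
#'
#' @param tree rooted \code{phylo} gene tree.
#' @param meta data.frame with columns \code{leaf}, \code{species} (and
#'   optionally \code{protein}, \code{architecture}, \code{functionLabel})
#'   covering every leaf.
#' @param overlapThreshold duplication threshold on the overlap score.
#' @return a \linkS4class{LabeledGeneTree}.
#' @export
#' @examples
#' tr <- readNewickTree("((A_1:1,B_1:1):1,(A_2:1,C_1:1):1);")
#' meta <- data.frame(leaf = c("A_1","B_1","A_2","C_1"),
#'                    species = c("A","B","A","C"))
#' labelEvents(tr, meta)  # root shares species A: duplication
labelEvents <- function(tree, meta, overlapThreshold = 0) {
  if (overlapThreshold < 0 || overlapThreshold > 1)
    stop("overlapThreshold must lie in [0,1]")
  tree <- resolveMultifurcations(tree)
  missing <- setdiff(tree$tip.label, meta$leaf)
  if (length(missing))
    stop("leaf without species metadata: ", paste(missing, collapse = ", "))
  speciesOfLeaf <- as.list(structure(meta$species, names = meta$leaf))
  ntip <- length(tree$tip.label)
  sets <- nodeSpeciesSets(tree, speciesOfLeaf)
  events <- character(tree$Nnode)
  overlap <- numeric(tree$Nnode)
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    kids <- childrenOf(tree, node)
    sL <- sets[[kids[1]]]
    sR <- sets[[kids[2]]]
    score <- length(intersect(sL, sR)) / length(union(sL, sR))
    overlap[node - ntip] <- score
    events[node - ntip] <- if (score > overlapThreshold) "duplication" else "speciation"
  }
  keep <- intersect(c("leaf", "species", "protein", "architecture", "functionLabel"),
                    names(meta))
  new("LabeledGeneTree", tree = tree, events = events, overlap = overlap,
      meta = meta[meta$leaf %in% tree$tip.label, keep, drop = FALSE])
}

#' Extract orthologous groups from a labelled gene tree
#'
#' Removes every duplication node from the tree graph; each remaining
#' connected component — leaves linked exclusively through speciation
#' nodes — is one orthologous group. The groups always partition the leaf
#' set. Each group records its defining node (the component's node closest
#' to the root) and that node's support value where one exists.
#'
#' @param labeled a \linkS4class{LabeledGeneTree}.
#' @return list of groups; each is a list with \code{members} (leaf
#'   labels), \code{species}, \code{support} (integer or NA), and
#'   \code{definingNode} (internal phylo node id, or the leaf id for
#'   singleton groups).
#' @export
orthologousGroups <- function(labeled) {
  tree <- labeled@tree
  ntip <- length(tree$tip.label)
  nAll <- ntip + tree$Nnode
  alive <- rep(TRUE, nAll)
  dup <- which(labeled@events == "duplication") + ntip
  alive[dup] <- FALSE

  parent <- seq_len(nAll)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]
    if (alive[a] && alive[b]) parent[find(a)] <- find(b)
  }

  depth <- rep(0L, nAll)
  pre <- rev(postorderNodes(tree))
  for (node in pre) {
    for (k in childrenOf(tree, node)) depth[k] <- depth[node] + 1L
  }

  sup <- nodeSupports(tree)
  speciesOfLeaf <- structure(labeled@meta$species, names = labeled@meta$leaf)
  comp <- vapply(seq_len(nAll), find, integer(1))
  groups <- list()
  for (cid in unique(comp[seq_len(ntip)])) {
    nodes <- which(comp == cid & alive)
    leaves <- nodes[nodes <= ntip]
    topNode <- nodes[which.min(depth[nodes])]
    members <- tree$tip.label[leaves]
    groups[[length(groups) + 1L]] <- list(
      members = members,
      species = sort(unique(unname(speciesOfLeaf[members]))),
      support = if (topNode > ntip) sup[topNode - ntip] else NA_integer_,
      definingNode = topNode)
  }
  groups
}

#' Apply the orthologous-group delineation criteria
#'
#' A group passes when (i) its defining-node support exceeds
#' \code{supportThreshold} (a missing support fails with reason
#' \code{"no support"}); (ii) at least \code{consistencyFraction} of its
#' members share the modal domain-architecture string; and (iii) at least
#' \code{consistencyFraction} share the modal independent function label.
#' Members with no function label are excluded from criterion (iii)'s
#' denominator; a group in which no member has a label passes (iii)
#' vacuously.
#'
#' @param group one group from [orthologousGroups()].
#' @param meta leaf metadata data.frame with columns \code{leaf},
#'   \code{architecture}, \code{functionLabel}.
#' @param supportThreshold integer support cutoff (default 90, strict).
#' @param consistencyFraction required modal share (default 0.8).
#' @return list with \code{pass} (logical) and \code{failed} (character
#'   vector among "support", "architecture", "function", possibly with a
#'   "no support" annotation).
#' @export
delineationVerdict <- function(group, meta, supportThreshold = 90,
                               consistencyFraction = 0.8) {
  if (!length(group$members)) stop("contract error: empty orthologous group")
  failed <- character(0)
  if (is.na(group$support)) {
    failed <- c(failed, "support (no support)")
  } else if (!(group$support > supportThreshold)) {
    failed <- c(failed, "support")
  }
  rows <- meta[match(group$members, meta$leaf), , drop = FALSE]
  modalShare <- function(x) {
    x <- x[!is.na(x) & nzchar(x)]
    if (!length(x)) return(NA_real_)
    max(table(x)) / length(x)
  }
  archShare <- if ("architecture" %in% names(rows)) modalShare(rows$architecture) else NA_real_
  if (!is.na(archShare) && archShare < consistencyFraction)
    failed <- c(failed, "architecture")
  funShare <- if ("functionLabel" %in% names(rows)) modalShare(rows$functionLabel) else NA_real_
  if (!is.na(funShare) && funShare < consistencyFraction)
    failed <- c(failed, "function")
  list(pass = length(failed) == 0L, failed = failed,
       architectureShare = archShare, functionShare = funShare)
}

#' Infer presence in the last eukaryotic common ancestor (LECA)
#'
#' A group's gene is attributed to LECA when its member species cover both
#' sides of the assumed eukaryotic root and span at least
#' \code{minGroups} distinct major groups — the operational reading of a
#' deep speciation node whose descendants populate all major lineages.
#'
#' @param group one group from [orthologousGroups()].
#' @param speciesMap a \linkS4class{SpeciesMap}.
#' @param minGroups minimum number of distinct major groups (default 3).
#' @return list with \code{leca} (logical) and \code{evidence}: the major
#'   groups found on each root side.
#' @export
inferLeca <- function(group, speciesMap, minGroups = 3L) {
  if (!length(speciesMap@groupOf))
    stop("precondition error: empty species map for LECA inference")
  if (length(unique(speciesMap@sideOf)) < 2L)
    stop("precondition error: LECA inference needs groups on both root sides")
  gps <- unique(groupOf(speciesMap, group$species))
  sides <- rootSideOf(speciesMap, gps)
  evidence <- split(gps, sides)
  leca <- length(unique(sides)) == 2L && length(gps) >= minGroups
  list(leca = leca, evidence = evidence)
}
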