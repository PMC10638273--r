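## Synthetic-data stage: species trees, coupled Dollo subunit loss with
## putative noise, gene trees with root duplications, fixture bundles.

#' Construct loss-model parameters
#'
#' Defaults describe a eukaryote-scale scenario: on a species tree scaled
#' to unit root-to-tip height, each complex experiences loss events at
#' rate \code{lambda} per unit branch length (irreversible, Dollo); a
#' loss event spreads to the partner complex with probability
#' \code{rho}, otherwise it removes only its own complex; retained complexes
#' additionally lose individual subunits at rate \code{delta}; and each
#' surviving present call is downgraded to putative with probability
#' \code{pi} (scalar, or one value per core subunit to mimic
#' hard-to-detect subunits).
#'
#' @param lambda per-complex loss rate (default 0.9).
#' @param rho both-complex coupling probability (default 0.3).
#' @param delta per-subunit degradation rate (default 0.05).
#' @param pi putative-conversion probability (default 0.05).
#' @param seed integer seed.
#' @return a \linkS4class{LossModelParams}.
#' @export
lossModelParams <- function(lambda = 0.9, rho = 0.3, delta = 0.05,
                            pi = 0.05, seed = 1L) {
  new("LossModelParams", lambda = as.numeric(lambda), rho = as.numeric(rho),
      delta = as.numeric(delta), pi = as.numeric(pi), seed = as.integer(seed))
}

#' Simulate an ultrametric species tree with a major-group map
#'
#' A Yule (pure-birth) tree rescaled to unit root-to-tip height, with
#' leaves assigned round-robin to \code{nGroups} synthetic major groups
#' split evenly across two root sides.
#'
#' @param nSpecies number of leaves (>= 1).
#' @param seed integer seed.
#' @param nGroups number of major groups (default 6).
#' @return list with \code{tree} (phylo) and \code{map}
#'   (\linkS4class{SpeciesMap}).
#' @export
simulateSpeciesTree <- function(nSpecies, seed = 1L, nGroups = 6L) {
  if (nSpecies < 1) stop("parameter error: nSpecies must be >= 1")
  labels <- sprintf("s%03d", seq_len(nSpecies))
  if (nSpecies == 1L) {
    tree <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                           edge.length = 1, tip.label = labels,
                           Nnode = 1L), class = "phylo")
  } else {
    tree <- withSeed(seed, ape::rphylo(nSpecies, birth = 1, death = 0))
    tree$tip.label <- labels
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
  }
  groups <- sprintf("G%d", ((seq_len(nSpecies) - 1L) %% nGroups) + 1L)
  sides <- ifelse(as.integer(sub("^G", "", groups)) <= ceiling(nGroups / 2), "A", "B")
  list(tree = tree, map = SpeciesMap(labels, groups, sides))
}

## Per-branch stochastic kernel of the Dollo model; state is a list with
## logical complex flags and per-subunit retention.
prc1Subunits <- function() c("RING1", "PCGF")
prc2Subunits <- function() c("EZH", "EED", "SUZ12")

#' Simulate coupled Dollo loss of two complexes along a species tree
#'
#' Both complexes are present at the root. Each complex carries its own
#' loss-event process: on each branch of length t an event fires with
#' probability 1 - exp(-lambda t); with probability rho the event spreads
#' to the partner complex (removing both), else it removes only its own
#' complex (a no-op for a complex already lost). At rho = 0 the two
#' complexes are therefore lost independently; at rho = 1 their profiles
#' are identical. Losses are irreversible. On
#' branches where a complex is retained, each of its subunits drops
#' independently with probability 1 - exp(-delta t). Finally every
#' present tip cell is downgraded to putative with probability pi. The
#' truth (pre-noise subunit states, complex retention flags, true
#' category, per-branch events) is recorded before noise is applied.
#'
#' @param tree species tree (phylo).
#' @param map a \linkS4class{SpeciesMap} (carried into the truth record).
#' @param params a \linkS4class{LossModelParams}.
#' @param includeRbbp append a constant present RBBP column (default TRUE),
#'   mirroring its ubiquity in real profiles.
#' @return list with \code{matrix} (\linkS4class{PresenceMatrix}) and
#'   \code{truth} (list: complexStates data.frame, trueCategory, events
#'   data.frame, trueStates matrix).
#' @export
simulateProfiles <- function(tree, map, params = lossModelParams(),
                             includeRbbp = TRUE) {
  validObject(params)
  subs <- c(prc1Subunits(), prc2Subunits())
  piVec <- params@pi
  if (length(piVec) == 1L) piVec <- rep(piVec, length(subs))
  if (length(piVec) != length(subs))
    stop("parameter error: pi must be scalar or one value per core subunit")
  ntip <- length(tree$tip.label)
  nAll <- ntip + tree$Nnode
  withSeed(params@seed, {
    state <- vector("list", nAll)
    root <- ntip + 1L
    state[[root]] <- list(c1 = TRUE, c2 = TRUE,
                          sub = structure(rep(TRUE, length(subs)), names = subs))
    events <- list()
    edgeOrder <- preorderEdges(tree)
    for (k in edgeOrder) {
      p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
      t <- if (is.null(tree$edge.length)) 1 else tree$edge.length[k]
      st <- state[[p]]
      ## one loss-event process per complex (rate lambda each); an event
      ## spreads to the partner complex with probability rho
      pEvent <- 1 - exp(-params@lambda * t)
      for (cx in c("PRC1", "PRC2")) {
        if (stats::runif(1) < pEvent) {
          target <- if (stats::runif(1) < params@rho) "both" else cx
          if (target %in% c("both", "PRC1")) st$c1 <- FALSE
          if (target %in% c("both", "PRC2")) st$c2 <- FALSE
          events[[length(events) + 1L]] <- data.frame(edge = k, target = target)
        }
      }
      if (!st$c1) st$sub[prc1Subunits()] <- FALSE
      if (!st$c2) st$sub[prc2Subunits()] <- FALSE
      pDrop <- 1 - exp(-params@delta * t)
      if (st$c1) {
        drop <- stats::runif(2) < pDrop
        st$sub[prc1Subunits()] <- st$sub[prc1Subunits()] & !drop
      }
      if (st$c2) {
        drop <- stats::runif(3) < pDrop
        st$sub[prc2Subunits()] <- st$sub[prc2Subunits()] & !drop
      }
      state[[ch]] <- st
    }
    trueStates <- t(vapply(seq_len(ntip), function(i) state[[i]]$sub, logical(length(subs))))
    rownames(trueStates) <- tree$tip.label
    c1 <- vapply(seq_len(ntip), function(i) state[[i]]$c1, logical(1))
    c2 <- vapply(seq_len(ntip), function(i) state[[i]]$c2, logical(1))
    obs <- matrix(ifelse(trueStates, PRESENT, ABSENT), nrow(trueStates),
                  ncol(trueStates), dimnames = list(tree$tip.label, subs))
    for (j in seq_along(subs)) {
      hit <- obs[, j] == PRESENT & stats::runif(ntip) < piVec[j]
      obs[hit, j] <- PUTATIVE
    }
    if (includeRbbp) obs <- cbind(obs, RBBP = PRESENT)
    trueCategory <- ifelse(c1 & c2, "BOTH",
                    ifelse(c1, "PRC1_ONLY", ifelse(c2, "PRC2_ONLY", "NEITHER")))
    names(trueCategory) <- tree$tip.label
    list(matrix = PresenceMatrix(obs),
         truth = list(
           complexStates = data.frame(species = tree$tip.label,
                                      PRC1 = c1, PRC2 = c2,
                                      stringsAsFactors = FALSE),
           trueCategory = trueCategory,
           trueStates = trueStates,
           events = if (length(events)) do.call(rbind, events) else
             data.frame(edge = integer(), target = character())))
  })
}

## Edge indices in parent-before-child order.
preorderEdges <- function(tree) {
  ntip <- length(tree$tip.label)
  acc <- new.env(); acc$res <- integer(0)
  walk <- function(node) {
    ks <- which(tree$edge[, 1] == node)
    for (k in ks) {
      acc$res <- c(acc$res, k)
      walk(tree$edge[k, 2])
    }
  }
  walk(ntip + 1L)
  acc$res
}

#' Simulate a gene tree with root duplications and lineage loss
#'
#' The gene lineage is duplicated \code{nRootDuplications} times above the
#' species-tree root; each resulting copy then evolves inside the species
#' tree with per-branch loss probability 1 - exp(-lossRate t). The gene
#' tree is the caterpillar of surviving copy subtrees; every internal node
#' within a copy is given the constant \code{support} label. Leaf metadata
#' and the true duplication count / per-copy LECA status are returned
#' alongside.
#'
#' @param speciesTree phylo species tree.
#' @param map a \linkS4class{SpeciesMap}.
#' @param nRootDuplications number of duplications above the root (>= 0).
#' @param lossRate per-branch loss rate (>= 0).
#' @param seed integer seed.
#' @param support integer support written on internal nodes.
#' @param subunit subunit identity used for architecture/function labels.
#' @param minGroups LECA rule threshold carried into the truth record.
#' @return list with \code{tree} (phylo), \code{meta} (leaf metadata
#'   data.frame) and \code{truth} (nDuplications, copies: per-copy
#'   survivors and LECA flag).
#' @export
simulateGeneTree <- function(speciesTree, map, nRootDuplications = 1L,
                             lossRate = 0.3, seed = 1L, support = 95L,
                             subunit = "PCGF", minGroups = 3L) {
  if (nRootDuplications < 0) stop("parameter error: nRootDuplications must be >= 0")
  if (lossRate < 0) stop("parameter error: lossRate must be >= 0")
  nCopies <- nRootDuplications + 1L
  rules <- defaultSubunitRules()
  arch <- rules$required[rules$subunit == subunit]
  if (!length(arch)) stop("unknown subunit: ", subunit)
  withSeed(seed, {
    copies <- vector("list", nCopies)
    for (cp in seq_len(nCopies)) {
      surviving <- simulateSurvival(speciesTree, lossRate)
      copies[[cp]] <- surviving
    }
    subtrees <- character(0)
    copyInfo <- list()
    for (cp in seq_len(nCopies)) {
      sv <- copies[[cp]]
      if (!length(sv)) next
      nwk <- copySubtreeNewick(speciesTree, sv, cp, support)
      subtrees <- c(subtrees, nwk)
      sides <- unique(rootSideOf(map, unique(groupOf(map, sv))))
      gps <- unique(groupOf(map, sv))
      copyInfo[[length(copyInfo) + 1L]] <- list(
        copy = cp, species = sv,
        leca = length(sides) == 2L && length(gps) >= minGroups)
    }
    if (!length(subtrees))
      stop("all gene copies went extinct; lower lossRate")
    combined <- subtrees[1]
    if (length(subtrees) > 1L) {
      for (i in 2:length(subtrees)) {
        combined <- sprintf("(%s,%s)100:0.100000", combined, subtrees[i])
      }
    }
    tree <- readNewickTree(paste0(combined, ";"))
    meta <- data.frame(leaf = tree$tip.label,
                       species = sub("_c\\d+$", "", tree$tip.label),
                       protein = tree$tip.label,
                       architecture = arch,
                       functionLabel = subunit,
                       stringsAsFactors = FALSE)
    list(tree = tree, meta = meta,
         truth = list(nDuplications = length(subtrees) - 1L,
                      copies = copyInfo))
  })
}

## Which species retain the gene, given per-branch loss.
simulateSurvival <- function(tree, lossRate) {
  ntip <- length(tree$tip.label)
  if (ntip == 1L) {
    t <- if (is.null(tree$edge.length)) 1 else tree$edge.length[1]
    keep <- stats::runif(1) >= 1 - exp(-lossRate * t)
    return(if (keep) tree$tip.label else character(0))
  }
  nAll <- ntip + tree$Nnode
  present <- rep(FALSE, nAll)
  present[ntip + 1L] <- TRUE
  for (k in preorderEdges(tree)) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    t <- if (is.null(tree$edge.length)) 1 else tree$edge.length[k]
    present[ch] <- present[p] && stats::runif(1) >= 1 - exp(-lossRate * t)
  }
  tree$tip.label[present[seq_len(ntip)]]
}

## Newick of the species tree pruned to the surviving species, tips renamed
## "<species>_c<copy>", internal nodes labelled with the support value.
copySubtreeNewick <- function(tree, surviving, copy, support) {
  if (length(surviving) == 1L) {
    return(sprintf("%s_c%d:1.000000", surviving, copy))
  }
  sub <- ape::keep.tip(tree, surviving)
  sub$tip.label <- sprintf("%s_c%d", sub$tip.label, copy)
  sub$node.label <- rep(as.character(support), sub$Nnode)
  sub(";\\s*$", "", writeNewickTree(sub))
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits a species tree (Newick), species map (TSV), presence matrix
#' (TSV), gene tree (Newick), leaf metadata (TSV), a domtblout-style hit
#' table regenerating the PRC1/PRC2 calls of the presence matrix, and a
#' truth JSON. Every file re-parses through the package's readers;
#' identical seeds give byte-identical bundles.
#'
#' @param outDir writable output directory (created if needed).
#' @param scenario "coupled" (rho = 0.9), "uncoupled" (rho = 0) or
#'   "custom" (use \code{params} as given).
#' @param nSpecies number of species (default 178).
#' @param seed integer seed.
#' @param params \linkS4class{LossModelParams} for scenario "custom".
#' @return invisible named vector of file paths.
#' @export
emitFixtures <- function(outDir, scenario = c("coupled", "uncoupled", "custom"),
                         nSpecies = 178L, seed = 1L, params = NULL) {
  scenario <- match.arg(scenario)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  if (is.null(params)) {
    rho <- switch(scenario, coupled = 0.9, uncoupled = 0, custom =
                    stop("scenario 'custom' needs params"))
    params <- lossModelParams(rho = rho, seed = seed)
  } else {
    params@seed <- as.integer(seed)
  }
  st <- simulateSpeciesTree(nSpecies, seed = seed)
  prof <- simulateProfiles(st$tree, st$map, params)
  gt <- simulateGeneTree(st$tree, st$map, nRootDuplications = 1L,
                         lossRate = 0.3, seed = seed)
  paths <- c(species_tree = file.path(outDir, "species_tree.nwk"),
             species_map = file.path(outDir, "species_map.tsv"),
             presence_matrix = file.path(outDir, "presence_matrix.tsv"),
             gene_tree = file.path(outDir, "gene_tree.nwk"),
             leaf_meta = file.path(outDir, "leaf_meta.tsv"),
             hits = file.path(outDir, "hits.domtblout"),
             truth = file.path(outDir, "truth.json"))
  writeNewickTree(st$tree, paths[["species_tree"]])
  writeSpeciesMap(st$map, paths[["species_map"]])
  writePresenceMatrix(prof$matrix, paths[["presence_matrix"]])
  writeNewickTree(gt$tree, paths[["gene_tree"]])
  write.table(gt$meta, paths[["leaf_meta"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(domtbloutFromMatrix(prof$matrix), paths[["hits"]])
  truth <- list(scenario = scenario, seed = seed,
                params = list(lambda = params@lambda, rho = params@rho,
                              delta = params@delta, pi = params@pi),
                trueCategory = as.list(prof$truth$trueCategory),
                complexStates = prof$truth$complexStates,
                geneTree = gt$truth)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

## Synthesize domtblout lines consistent with a presence matrix: for each
## high-confidence cell the full domain complement, for putative cells the
## putative subset only.
domtbloutFromMatrix <- function(x) {
  rules <- defaultSubunitRules()
  domainSpans <- list("zf-RING" = c(10L, 55L), RAWUL = c(200L, 300L),
                      SET = c(400L, 520L), WD40 = c(30L, 70L),
                      VEFS = c(350L, 480L))
  m <- presenceStates(x)
  lines <- c("#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
             "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target")
  for (sp in rownames(m)) {
    for (su in intersect(colnames(m), rules$subunit)) {
      state <- m[sp, su]
      if (state == ABSENT) next
      row <- rules[rules$subunit == su, ]
      doms <- splitDomains(if (state == PRESENT) row$required else row$putative)
      if (!length(doms)) next
      protein <- sprintf("%s|%s_%s", sp, sp, su)
      for (i in seq_along(doms)) {
        span <- domainSpans[[doms[i]]]
        if (is.null(span)) span <- c(10L + 100L * (i - 1L), 80L + 100L * (i - 1L))
        lines <- c(lines, sprintf(
          "%-20s -  600 %-20s -  120   1e-30  100.0   0.0   %d  %d   1e-28     1e-25   50.0   0.0     1   120   %d   %d   %d   %d 0.95 synthetic hit",
          protein, doms[i], i, length(doms), span[1], span[2], span[1], span[2]))
      }
    }
  }
  lines
}
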