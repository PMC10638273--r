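test_that("species tree simulation is seeded, ultrametric and group-balanced", {
  st <- simulateSpeciesTree(30, seed = 7)
  expect_equal(length(st$tree$tip.label), 30)
  depths <- ape::node.depth.edgelength(st$tree)[1:30]
  expect_true(all(abs(depths - 1) < 1e-8))
  expect_setequal(unique(unname(st$tree$tip.label)), speciesNames(st$map))
  expect_equal(sort(unique(unname(rootSideOf(st$map, unique(st$map@groupOf))))),
               c("A", "B"))

  st2 <- simulateSpeciesTree(30, seed = 7)
  expect_identical(writeNewickTree(st$tree), writeNewickTree(st2$tree))
  st3 <- simulateSpeciesTree(30, seed = 8)
  expect_false(identical(writeNewickTree(st$tree), writeNewickTree(st3$tree)))

  one <- simulateSpeciesTree(1, seed = 1)
  expect_equal(length(one$tree$tip.label), 1)
  expect_error(simulateSpeciesTree(0), "nSpecies")
})

test_that("profile simulation respects its limiting parameter regimes", {
  st <- simulateSpeciesTree(40, seed = 2)
  ## no events: everything present, every species BOTH
  p0 <- simulateProfiles(st$tree, st$map,
                         lossModelParams(lambda = 0, delta = 0, pi = 0, seed = 1))
  expect_true(all(presenceStates(p0$matrix) == "1"))
  expect_true(all(p0$truth$trueCategory == "BOTH"))

  ## saturation: enormous loss rate wipes both complexes everywhere
  pBig <- simulateProfiles(st$tree, st$map,
                           lossModelParams(lambda = 1e3, delta = 0, pi = 0, seed = 1))
  expect_true(all(pBig$truth$trueCategory == "NEITHER"))

  ## perfect coupling without noise: PRC1 and PRC2 profiles identical
  p1 <- simulateProfiles(st$tree, st$map,
                         lossModelParams(lambda = 1, rho = 1, delta = 0, pi = 0,
                                         seed = 5))
  s <- presenceStates(p1$matrix)
  expect_identical(unname(s[, "RING1"]), unname(s[, "EZH"]))
  expect_identical(unname(s[, "PCGF"]), unname(s[, "SUZ12"]))

  expect_error(simulateProfiles(st$tree, st$map,
                                lossModelParams(rho = 1.5)), "rho")
})

test_that("losses are Dollo: no lineage regains a lost complex", {
  st <- simulateSpeciesTree(25, seed = 9)
  tr <- st$tree
  for (seed in 1:10) {
    p <- simulateProfiles(tr, st$map, lossModelParams(lambda = 1.2, seed = seed))
    ev <- p$truth$events
    if (!nrow(ev)) next
    ## a species below a both-complex loss edge must have lost both
    for (i in seq_len(nrow(ev))) {
      node <- tr$edge[ev$edge[i], 2]
      tips <- if (node <= length(tr$tip.label)) tr$tip.label[node] else
        ape::extract.clade(tr, node)$tip.label
      cs <- p$truth$complexStates
      below <- cs[cs$species %in% tips, ]
      if (ev$target[i] %in% c("both", "PRC1")) expect_true(all(!below$PRC1))
      if (ev$target[i] %in% c("both", "PRC2")) expect_true(all(!below$PRC2))
    }
  }
})

test_that("without noise the observed categories equal the simulated truth", {
  st <- simulateSpeciesTree(60, seed = 4)
  for (seed in 1:5) {
    p <- simulateProfiles(st$tree, st$map,
                          lossModelParams(lambda = 1, delta = 0, pi = 0, seed = seed))
    obs <- categorizeSpecies(p$matrix)
    expect_identical(unname(obs[names(p$truth$trueCategory)]),
                     unname(p$truth$trueCategory))
  }
})

test_that("gene tree simulation produces detectable root duplications", {
  st <- simulateSpeciesTree(20, seed = 3)
  ## no duplication, no loss: gene tree congruent with the species tree
  g0 <- simulateGeneTree(st$tree, st$map, nRootDuplications = 0, lossRate = 0,
                         seed = 1)
  expect_equal(sort(sub("_c1$", "", g0$tree$tip.label)), sort(st$tree$tip.label))
  lab0 <- labelEvents(g0$tree, g0$meta)
  expect_true(all(lab0@events == "speciation"))
  expect_equal(g0$truth$nDuplications, 0)

  ## one root duplication, no loss: exactly one duplication node, overlap 1
  g1 <- simulateGeneTree(st$tree, st$map, nRootDuplications = 1, lossRate = 0,
                         seed = 1)
  lab1 <- labelEvents(g1$tree, g1$meta)
  expect_equal(sum(lab1@events == "duplication"), 1)
  expect_equal(max(lab1@overlap), 1)
  expect_equal(g1$truth$nDuplications, 1)
  expect_true(all(vapply(g1$truth$copies, `[[`, logical(1), "leca")))

  ## determinism under the seed
  g1b <- simulateGeneTree(st$tree, st$map, nRootDuplications = 1, lossRate = 0,
                          seed = 1)
  expect_identical(writeNewickTree(g1$tree), writeNewickTree(g1b$tree))

  expect_error(simulateGeneTree(st$tree, st$map, nRootDuplications = -1),
               "nRootDuplications")
})

test_that("fixture bundles are deterministic and re-parse losslessly", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emitFixtures(d1, "coupled", nSpecies = 25, seed = 13)
  emitFixtures(d2, "coupled", nSpecies = 25, seed = 13)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }

  m <- readPresenceMatrix(file.path(d1, "presence_matrix.tsv"))
  sm <- readSpeciesMap(file.path(d1, "species_map.tsv"))
  tr <- readNewickTree(file = file.path(d1, "species_tree.nwk"))
  expect_setequal(speciesNames(m), tr$tip.label)
  expect_setequal(speciesNames(m), speciesNames(sm))

  ## matrix -> TSV -> matrix round trip
  f <- file.path(d1, "roundtrip.tsv")
  writePresenceMatrix(m, f)
  expect_identical(presenceStates(readPresenceMatrix(f)), presenceStates(m))

  ## the domtblout regenerates the unambiguous subunit columns (for EZH and
  ## SUZ12 a putative call has no domain-level representation, so only
  ## non-putative cells are recoverable there)
  hits <- parseDomtblout(file = file.path(d1, "hits.domtblout"))
  calls <- callOrthologs(hits, speciesUniverse = speciesNames(m))
  m2 <- assembleMatrix(calls, speciesUniverse = speciesNames(m))
  for (su in c("RING1", "PCGF")) {
    expect_identical(presenceStates(m2)[, su], presenceStates(m)[, su], info = su)
  }
  for (su in c("EZH", "SUZ12")) {
    keep <- presenceStates(m)[, su] != "P"
    expect_identical(presenceStates(m2)[keep, su], presenceStates(m)[keep, su],
                     info = su)
  }

  ## uncoupled truth marks no coupled loss events
  d3 <- withr::local_tempdir()
  emitFixtures(d3, "uncoupled", nSpecies = 25, seed = 13)
  truth <- jsonlite::read_json(file.path(d3, "truth.json"))
  expect_equal(truth$params$rho, 0)
})
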