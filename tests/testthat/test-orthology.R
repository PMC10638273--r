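metaFor <- function(labels) {
  data.frame(leaf = labels, species = sub("_.*$", "", labels),
             stringsAsFactors = FALSE)
}

test_that("species overlap separates duplication from speciation nodes", {
  tr <- readNewickTree("((A_1:1,B_1:1):1,(A_2:1,C_1:1):1);")
  lab <- labelEvents(tr, metaFor(tr$tip.label))
  n <- length(tr$tip.label)
  sets <- cladeLeafSets(lab@tree)
  rootIdx <- which(vapply((n + 1):(n + lab@tree$Nnode),
                          function(nd) length(sets[[nd]]) == n, logical(1)))
  expect_equal(lab@events[rootIdx], "duplication")
  expect_equal(lab@overlap[rootIdx], 1 / 3)

  tr2 <- readNewickTree("((A_1:1,B_1:1):1,(C_1:1,D_1:1):1);")
  lab2 <- labelEvents(tr2, metaFor(tr2$tip.label))
  expect_true(all(lab2@events == "speciation"))

  cherry <- readNewickTree("(A_1:1,A_2:1);")
  lab3 <- labelEvents(cherry, metaFor(cherry$tip.label))
  expect_equal(lab3@events, "duplication")
  expect_equal(lab3@overlap, 1)

  expect_error(labelEvents(tr, metaFor("A_1")), "without species metadata")
})

test_that("raising the overlap threshold never creates new duplications", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    sp <- sample(c("X", "Y", "Z"), n, replace = TRUE)
    top <- randomTopology(seq_len(n))
    tr <- readNewickTree(topologyToNewick(top, sp))
    meta <- data.frame(leaf = tr$tip.label, species = sub("_.*$", "", tr$tip.label))
    prev <- NULL
    for (th in c(0, 0.25, 0.5, 0.75)) {
      dup <- labelEvents(tr, meta, th)@events == "duplication"
      if (!is.null(prev)) expect_true(all(dup <= prev))
      prev <- dup
    }
  }
})

test_that("orthologous groups are cut at duplication nodes and partition leaves", {
  tr <- readNewickTree("((A_1:1,B_1:1):1,(A_2:1,C_1:1):1);")
  gr <- orthologousGroups(labelEvents(tr, metaFor(tr$tip.label)))
  expect_equal(length(gr), 2)
  expect_setequal(lapply(gr, `[[`, "members"),
                  list(c("A_1", "B_1"), c("A_2", "C_1")))

  ## no duplications: a single group
  tr2 <- readNewickTree("((A_1:1,B_1:1):1,(C_1:1,D_1:1):1);")
  gr2 <- orthologousGroups(labelEvents(tr2, metaFor(tr2$tip.label)))
  expect_equal(length(gr2), 1)
  expect_setequal(gr2[[1]]$members, tr2$tip.label)

  ## a paralog ladder of one species: all singletons
  tr3 <- readNewickTree("(((A_1:1,A_2:1):1,A_3:1):1,A_4:1);")
  gr3 <- orthologousGroups(labelEvents(tr3, metaFor(tr3$tip.label)))
  expect_equal(length(gr3), 4)
  expect_true(all(lengths(lapply(gr3, `[[`, "members")) == 1))
})

test_that("extracted groups partition the leaves of random trees", {
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(3:12, 1)
    sp <- sample(c("X", "Y", "Z", "W"), n, replace = TRUE)
    tr <- readNewickTree(topologyToNewick(randomTopology(seq_len(n)), sp))
    gr <- orthologousGroups(labelEvents(tr, metaFor(tr$tip.label)))
    members <- unlist(lapply(gr, `[[`, "members"))
    expect_setequal(members, tr$tip.label)
    expect_equal(length(members), length(unique(members)))
  }
})

test_that("multifurcations resolve deterministically before labelling", {
  tr <- readNewickTree("(C_1:1,A_1:1,B_1:1,A_2:1);")
  lab1 <- labelEvents(tr, metaFor(c("A_1", "A_2", "B_1", "C_1")))
  ## rotated input resolves to the same binary topology
  tr2 <- readNewickTree("(A_2:1,B_1:1,C_1:1,A_1:1);")
  lab2 <- labelEvents(tr2, metaFor(c("A_1", "A_2", "B_1", "C_1")))
  expect_identical(writeNewickTree(lab1@tree), writeNewickTree(lab2@tree))
  expect_identical(lab1@events, lab2@events)
  expect_true(ape::is.binary.phylo(lab1@tree))
})

test_that("delineation criteria check support and consistency fractions", {
  gr <- list(members = paste0("m", 1:5), species = paste0("s", 1:5),
             support = 95L, definingNode = 1L)
  meta <- data.frame(leaf = paste0("m", 1:5),
                     architecture = rep("zf-RING,RAWUL", 5),
                     functionLabel = rep("PCGF", 5))
  expect_true(delineationVerdict(gr, meta)$pass)

  ## support exactly at the threshold fails (strict >)
  gr90 <- gr; gr90$support <- 90L
  expect_equal(delineationVerdict(gr90, meta)$failed, "support")
  gr85 <- gr; gr85$support <- 85L
  expect_false(delineationVerdict(gr85, meta)$pass)

  ## missing support fails with its own reason
  grNA <- gr; grNA$support <- NA_integer_
  expect_match(delineationVerdict(grNA, meta)$failed, "no support")

  ## 3 of 5 share the modal architecture: 0.6 < 0.8
  meta2 <- meta
  meta2$architecture <- c(rep("zf-RING,RAWUL", 3), rep("zf-RING", 2))
  v <- delineationVerdict(gr, meta2)
  expect_false(v$pass)
  expect_true("architecture" %in% v$failed)
  expect_equal(v$architectureShare, 0.6)
  expect_true(delineationVerdict(gr, meta2, consistencyFraction = 0.5)$pass)

  ## members without function labels leave criterion (iii)'s denominator
  meta3 <- meta
  meta3$functionLabel <- c("PCGF", "PCGF", "PCGF", "PCGF", NA)
  expect_true(delineationVerdict(gr, meta3)$pass)

  expect_error(delineationVerdict(list(members = character(0)), meta), "empty")
})

test_that("LECA inference requires both root sides and enough major groups", {
  sm <- SpeciesMap(c("Hsap", "Scer", "Tbru", "Atha"),
                   c("Metazoa", "Fungi", "Discoba", "Chloroplastida"),
                   c("A", "A", "B", "B"))
  gBoth <- list(members = "x", species = c("Hsap", "Scer", "Tbru"))
  r <- inferLeca(gBoth, sm)
  expect_true(r$leca)
  expect_setequal(r$evidence$A, c("Metazoa", "Fungi"))
  expect_equal(r$evidence$B, "Discoba")

  gOne <- list(members = "x", species = "Hsap")
  expect_false(inferLeca(gOne, sm)$leca)

  ## two sides but only two groups: still not attributable
  gTwo <- list(members = "x", species = c("Hsap", "Tbru"))
  expect_false(inferLeca(gTwo, sm)$leca)

  empty <- SpeciesMap(character(0), character(0), character(0))
  expect_error(inferLeca(gBoth, empty), "empty species map")
  oneSide <- SpeciesMap(c("Hsap", "Scer"), c("Metazoa", "Fungi"), c("A", "A"))
  expect_error(inferLeca(gBoth, oneSide), "both root sides")
})

test_that("adding a species to a group never revokes a LECA verdict", {
  sm <- SpeciesMap(sprintf("s%d", 1:8),
                   rep(c("G1", "G2", "G3", "G4"), 2),
                   rep(c("A", "A", "B", "B"), 2))
  set.seed(3)
  for (rep in 1:20) {
    base <- sample(sprintf("s%d", 1:8), sample(2:6, 1))
    g <- list(members = base, species = base)
    before <- inferLeca(g, sm)$leca
    extra <- sample(setdiff(sprintf("s%d", 1:8), base), 1)
    g2 <- list(members = c(base, extra), species = c(base, extra))
    after <- inferLeca(g2, sm)$leca
    expect_true(after >= before)
  }
})

test_that("event labelling matches brute force on exhaustive small trees", {
  ## every rooted binary topology with 2-4 leaves x every 3-species assignment
  for (n in 2:4) {
    tops <- allTopologies(seq_len(n))
    assigns <- allAssignments(n)
    for (top in tops) {
      for (i in seq_len(nrow(assigns))) {
        ok <- eventsAgreeWithOracle(top, assigns[i, ])
        if (!ok) expect_true(ok, info = topologyToNewick(top, assigns[i, ]))
      }
    }
    expect_true(TRUE)
  }
})
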