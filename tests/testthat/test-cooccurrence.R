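test_that("phi handles identical, complementary and hand-computed vectors", {
  expect_equal(phiCoefficient(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(phiCoefficient(c(1, 1, 0, 0), c(0, 0, 1, 1)), -1)
  expect_equal(phiCoefficient(c(1, 1, 1, 1, 0, 0, 0, 0),
                              c(1, 1, 1, 0, 1, 0, 0, 0)), 0.5)
  ## zero-variance marginals: undefined, not zero
  expect_true(is.na(phiCoefficient(c(1, 1, 1), c(1, 0, 1))))
  expect_error(phiCoefficient(c(1, 0), c(1, 0, 1)), "length mismatch")
})

test_that("phi equals Pearson correlation on random binary pairs", {
  set.seed(99)
  for (rep in 1:300) {
    n <- sample(8:60, 1)
    x <- stats::rbinom(n, 1, runif(1, 0.2, 0.8))
    y <- stats::rbinom(n, 1, runif(1, 0.2, 0.8))
    p <- phiCoefficient(x, y)
    r <- suppressWarnings(cor(x, y))
    if (is.na(p)) {
      expect_true(is.na(r))
    } else {
      expect_equal(p, r, tolerance = 1e-12)
      expect_equal(p, phiOracle(x, y), tolerance = 1e-15)
      expect_equal(p, phiCoefficient(y, x))
      expect_true(p >= -1 - 1e-12 && p <= 1 + 1e-12)
    }
  }
})

test_that("putative positions are deleted pairwise and restoration is exact", {
  set.seed(17)
  for (rep in 1:30) {
    n <- 40
    x <- stats::rbinom(n, 1, 0.5)
    y <- stats::rbinom(n, 1, 0.5)
    base <- phiCoefficient(x, y)
    xm <- x; ym <- y
    xm[sample(n, 5)] <- NA
    ym[sample(n, 5)] <- NA
    masked <- phiCoefficient(xm, ym)
    keep <- !is.na(xm) & !is.na(ym)
    expect_equal(masked, phiOracle(x[keep], y[keep]))
    ## restoring the masked values reproduces the original value
    expect_equal(phiCoefficient(x, y), base)
  }
})

test_that("the pairwise matrix is symmetric with unit diagonal and flags constants", {
  m <- pmat(c("1", "1", "1", "0", "0", "1"),
            c("1", "1", "0", "1", "0", "1"),
            c("0", "0", "1", "1", "1", "1"),
            c("0", "1", "0", "0", "1", "1"))
  co <- suppressWarnings(cooccurrence(m))
  p <- phiMatrix(co)
  expect_equal(p, t(p))
  expect_equal(unname(diag(p)[1:5]), rep(1, 5))
  ## RBBP is constant 1: undefined against everything, flagged by warning
  expect_true(all(is.na(p["RBBP", setdiff(colnames(p), "RBBP")])))
  expect_warning(cooccurrence(m), "RBBP")
})

test_that("pairwise deletion drops species per pair and records effective n", {
  m <- pmat(c("1", "P", "1", "1", "1", "1"),
            c("1", "1", "1", "1", "0", "1"),
            c("0", "0", "0", "0", "1", "1"),
            c("0", "1", "0", "1", "0", "1"))
  co <- suppressWarnings(cooccurrence(m, subunits = c("RING1", "PCGF", "EZH")))
  n <- effectiveN(co)
  expect_equal(n["RING1", "PCGF"], 3L)   # sp01 has PCGF = P
  expect_equal(n["PCGF", "EZH"], 3L)
  expect_equal(n["RING1", "EZH"], 4L)

  ## listwise: any putative row is dropped everywhere
  col <- suppressWarnings(cooccurrence(m, subunits = c("RING1", "PCGF", "EZH"),
                                       putativeHandling = "listwise"))
  expect_true(all(effectiveN(col)[upper.tri(effectiveN(col))] == 3L))
})

test_that("group averages take within- and cross-set means excluding RBBP", {
  phi <- matrix(NA_real_, 6, 6,
                dimnames = list(coreSub <- c("RING1", "PCGF", "EZH", "EED", "SUZ12", "RBBP"),
                                coreSub))
  diag(phi) <- 1
  phi["RING1", "PCGF"] <- phi["PCGF", "RING1"] <- 0.65
  phi["EZH", "EED"] <- phi["EED", "EZH"] <- 0.8
  phi["EZH", "SUZ12"] <- phi["SUZ12", "EZH"] <- 0.7
  phi["EED", "SUZ12"] <- phi["SUZ12", "EED"] <- 0.6
  for (a in c("RING1", "PCGF")) for (b in c("EZH", "EED", "SUZ12")) {
    phi[a, b] <- phi[b, a] <- 0.3
  }
  res <- new("CooccurrenceResult", phi = phi,
             n = matrix(10L, 6, 6, dimnames = dimnames(phi)),
             averages = c(intraPRC1 = NA_real_, intraPRC2 = NA_real_, inter = NA_real_),
             linkage = NULL, order = character(0))
  avg <- groupAverages(res)
  expect_equal(avg$intraPRC1, 0.65)  # mean of the single core pair
  expect_equal(avg$intraPRC2, 0.7)
  expect_equal(avg$inter, 0.3)       # mean over the 6 cross pairs
  expect_error(groupAverages(res, prc1 = c("RING1", "NOPE")), "schema error")
})

test_that("average linkage merges closest pairs first with lexicographic ties", {
  phi <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(phi) <- 1
  phi["A", "B"] <- phi["B", "A"] <- 0.9
  res <- new("CooccurrenceResult", phi = phi,
             n = matrix(5L, 3, 3, dimnames = dimnames(phi)),
             averages = c(intraPRC1 = NA_real_, intraPRC2 = NA_real_, inter = NA_real_),
             linkage = NULL, order = character(0))
  cl <- averageLinkage(res)
  first <- cl$hclust$labels[-cl$hclust$merge[1, ]]
  expect_setequal(first, c("A", "B"))
  expect_true(all(diff(cl$hclust$height) >= -1e-12))

  ## equal distances: the lexicographically smallest pair merges first
  phiEq <- matrix(0.5, 3, 3, dimnames = dimnames(phi))
  diag(phiEq) <- 1
  resEq <- res; resEq@phi <- phiEq
  clEq <- averageLinkage(resEq)
  expect_setequal(clEq$hclust$labels[-clEq$hclust$merge[1, ]], c("A", "B"))

  ## a subunit with undefined distances is excluded, clustering proceeds
  phiNA <- phi
  phiNA["C", c("A", "B")] <- NA
  phiNA[c("A", "B"), "C"] <- NA
  resNA <- res; resNA@phi <- phiNA
  clNA <- averageLinkage(resNA)
  expect_equal(clNA$excluded, "C")
  expect_setequal(clNA$order, c("A", "B"))
})

test_that("merge heights are non-decreasing on random phi matrices", {
  set.seed(23)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    b <- matrix(stats::rbinom(40 * k, 1, 0.5), 40, k)
    colnames(b) <- sprintf("u%d", seq_len(k))
    states <- matrix(as.character(b), 40, k, dimnames = list(sprintf("s%d", 1:40),
                                                             colnames(b)))
    co <- suppressWarnings(cooccurrence(PresenceMatrix(states),
                                        prc1 = colnames(b)[1:2],
                                        prc2 = colnames(b)[-(1:2)]))
    if (!is.null(co@linkage)) expect_true(all(diff(co@linkage$height) >= -1e-12))
  }
})
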