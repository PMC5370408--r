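# Distances, neighbor joining, bootstrap, clade assignment, congruence.

test_that("Poisson distances match the closed form", {
  # 3 rows, pair (a, b) differing at 10% of 100 columns
  a <- chars(randAa(100))
  b <- a; b[1:10] <- vapply(b[1:10], function(x)
    setdiff(AA20, x)[1], "")
  mat <- rbind(a = a, b = b, c = a)
  D <- distanceMatrix(mat)
  expect_equal(D["a", "b"], -log(0.9), tolerance = 1e-12)
  expect_equal(D["a", "c"], 0)
  expect_identical(diag(D), c(a = 0, b = 0, c = 0))
  expect_identical(D, t(D))
})

test_that("distance preconditions: sparse pairs error, saturated pairs
          cap with a warning", {
  set.seed(110)
  mat <- rbind(a = chars(randAa(40)), b = chars(randAa(40)),
               c = chars(randAa(40)))
  mat["b", 1:25] <- "-"
  expect_error(distanceMatrix(mat), "\\(a, b\\)")
  m2 <- rbind(a = rep("A", 40), b = rep("C", 40),
              c = rep(c("A", "C"), 20))
  expect_warning(D <- distanceMatrix(m2), "saturated")
  expect_equal(D["a", "b"], -log(1 - 0.95))
  expect_equal(D["a", "c"], -log(0.5))
})

test_that("three taxa resolve with exact closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- njTree(D)
  expect_identical(ape::Ntip(tr), 3L)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el[c("x", "y", "z")]), c(1, 2, 3))
})

test_that("NJ recovers the generating topology from additive distances", {
  skip_if_not_installed("phangorn")
  set.seed(120)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n)
    D <- cophenetic(tr)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), njTree(D)), 0)
  }
})

test_that("NJ quartets agree with the least-squares-best topology on
          noisy distances", {
  set.seed(121)
  agree <- 0L; trials <- 200L
  for (i in seq_len(trials)) {
    tr <- ape::rtree(4)
    tr$tip.label <- paste0("t", 1:4)
    D <- cophenetic(tr)[paste0("t", 1:4), paste0("t", 1:4)]
    # near-additive regime: 5% multiplicative perturbation
    noise <- matrix(runif(16, 0.95, 1.05), 4)
    noise <- (noise + t(noise)) / 2
    Dn <- D * noise; diag(Dn) <- 0
    split <- njQuartetSplit(njTree(Dn))
    if (is.null(split)) next
    if (identical(split, as.integer(sort(oracleLsQuartet(Dn)))))
      agree <- agree + 1L
  }
  expect_gte(agree / trials, 0.95)
})

test_that("bootstrap supports are reproducible and order-invariant", {
  skip_if_not_installed("phangorn")
  fam <- generateProteinFamily(8, rootLength = 250, subsPerSite = 0.1,
                               seed = 130)
  mat <- aaRScreen:::.msaMatrix(alignProgressive(
    as.character(fam$sequences)))
  b1 <- bootstrapSupport(mat, 50, seed = 5)
  b2 <- bootstrapSupport(mat, 50, seed = 5)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  # permuting the row order preserves topology and the support multiset
  perm <- mat[sample(nrow(mat)), , drop = FALSE]
  b3 <- bootstrapSupport(perm, 50, seed = 5)
  expect_equal(phangorn::RF.dist(b1, b3), 0)
  expect_identical(sort(b1$node.label), sort(b3$node.label))
})

test_that("zero-divergence alignments come back unresolved", {
  set.seed(150)
  row <- chars(randAa(60))
  mat <- do.call(rbind, replicate(5, row, simplify = FALSE))
  rownames(mat) <- sprintf("s%d", 1:5)
  tr <- bootstrapSupport(mat, 20, seed = 1)
  expect_true(isTRUE(attr(tr, "unresolved")))
  expect_gt(tr$Nnode, 0)
})

test_that("strong phylogenetic signal earns high supports for the true
          bipartitions", {
  ct <- ape::read.tree(text = paste0(
    "(((((((L01,L02),L03),L04),L05),L06),L07),L08);"))
  ct$edge.length <- rep(0.1, nrow(ct$edge))
  fam <- generateProteinFamily(8, tree = ct, rootLength = 300, seed = 131)
  tr <- bootstrapSupport(aaRScreen:::.msaMatrix(
    alignProgressive(as.character(fam$sequences))), 100, seed = 7)
  leafOrder <- sort(ct$tip.label)
  trueKeys <- aaRScreen:::.splitKeys(ape::unroot(ct), leafOrder)
  gotKeys <- aaRScreen:::.splitKeys(tr, leafOrder)
  sup <- as.numeric(tr$node.label[tr$node.label != ""])
  covered <- mean(trueKeys %in% gotKeys)
  expect_gte(covered, 0.8)
  expect_gte(mean(sup >= 70), 0.8)
})

test_that("clade assignment follows the smallest pure side and reports
          ties honestly", {
  tr <- ape::read.tree(text = paste0(
    "(((q:0.1,x1:0.1):0.1,x2:0.1):0.5,((y1:0.1,y2:0.1):0.1,",
    "(y3:0.1,y4:0.1):0.1):0.5);"))
  labels <- c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y", y3 = "Y", y4 = "Y")
  res <- assignClade(tr, labels, "q")
  expect_identical(res$label, "X")
  expect_identical(res$rule, "monophyletic")
  # query on the central edge between two equal groups: a tie
  tie <- ape::read.tree(text =
    "((a1:1,a2:1):1,q:1,(b1:1,b2:1):1);")
  res2 <- assignClade(tie, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"), "q")
  expect_identical(res2$rule, "tie")
  expect_true(is.na(res2$label))
  expect_error(assignClade(tr, labels, "nope"), "not in tree")
})

test_that("clade assignment recovers truth on evolved families", {
  tpl <- paste0("(((q:%1$f,x1:%1$f):%1$f,(x2:%1$f,x3:%1$f):%1$f):%2$f,",
                "((y1:%1$f,y2:%1$f):%1$f,(y3:%1$f,y4:%1$f):%1$f):%2$f);")
  tr <- ape::read.tree(text = sprintf(tpl, 0.05, 0.3))
  labels <- c(x1 = "X", x2 = "X", x3 = "X",
              y1 = "Y", y2 = "Y", y3 = "Y", y4 = "Y")
  for (seed in 1:5) {
    fam <- generateProteinFamily(8, tree = tr, rootLength = 300,
                                 subsPerSite = 0.2, seed = seed)
    est <- njTree(distanceMatrix(alignProgressive(
      as.character(fam$sequences))))
    expect_identical(assignClade(est, labels, "q")$label, "X")
  }
})

test_that("congruence of a tree with itself is maximal and the RF agrees
          with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(140)
  t1 <- ape::rtree(10)
  res <- congruenceTest(t1, t1, nPerm = 999, seed = 2)
  expect_identical(rfDistance(res), 0L)
  expect_equal(pValue(res), 1 / 1000)
  for (i in 1:10) {
    a <- ape::rtree(sample(6:14, 1)); b <- ape::rtree(ape::Ntip(a))
    b$tip.label <- a$tip.label
    res <- congruenceTest(a, b, nPerm = 9, seed = i)
    expect_identical(rfDistance(res),
                     as.integer(phangorn::RF.dist(ape::unroot(a),
                                                  ape::unroot(b))))
    expect_equal(res@normalizedRF,
                 rfDistance(res) / (2 * (ape::Ntip(a) - 3)))
  }
  small <- ape::rtree(3)
  expect_error(congruenceTest(small, small), "share")
})

test_that("co-evolved family pairs give small congruence p-values", {
  famA <- generateProteinFamily(12, rootLength = 300, subsPerSite = 0.1,
                                seed = 141)
  famB <- generateProteinFamily(12, tree = famA$tree, subsPerSite = 0.1,
                                seed = 142)
  tA <- njTree(distanceMatrix(alignProgressive(
    as.character(famA$sequences))))
  tB <- njTree(distanceMatrix(alignProgressive(
    as.character(famB$sequences))))
  res <- congruenceTest(tA, tB, nPerm = 999, seed = 3)
  expect_lte(pValue(res), 0.01)
})
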