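# Cloverleaf folding, identity profiles, and the identity rule table.

test_that("a zero-noise tRNA folds onto the generator's template spans", {
  g <- generateTrna("Tyr", pair = "G-C", n73 = "A", vArmLen = 0, seed = 1)
  cl <- foldCloverleaf(g$sequence)
  expect_true(foldable(cl))
  seg <- segmentTable(cl)
  expect_identical(seg$start[seg$segment == "variable"], 44L)
  expect_identical(seg$end[seg$segment == "variable"], 48L)
  expect_identical(seg$start[seg$segment == "acceptor_stem_5p"], 1L)
  expect_identical(seg$end[seg$segment == "discriminator"], 73L)
  expect_identical(which(canonicalMap(cl) == 73L), 73L)
  # with a 13-nt V-arm every downstream span shifts by 8
  g2 <- generateTrna("Tyr", pair = "G-C", n73 = "A", vArmLen = 13,
                     seed = 1)
  cl2 <- foldCloverleaf(g2$sequence)
  seg2 <- segmentTable(cl2)
  expect_identical(seg2$end[seg2$segment == "variable"] -
                   seg2$start[seg2$segment == "variable"] + 1L, 13L)
  expect_identical(which(canonicalMap(cl2) == 73L), 81L)
})

test_that("deleting the variable region empties the V-arm span only", {
  g <- generateTrna("Trp", pair = "G-C", n73 = "A", vArmLen = 0, seed = 3)
  ch <- strsplit(g$sequence, "")[[1]]
  noVar <- paste(ch[-(44:48)], collapse = "")
  cl <- foldCloverleaf(noVar)
  expect_true(foldable(cl))
  seg <- segmentTable(cl)
  v <- seg[seg$segment == "variable", ]
  expect_true(v$start > v$end)           # empty span
  expect_identical(seg$end[seg$segment == "anticodon_arm"], 43L)
  expect_identical(which(canonicalMap(cl) == 73L), 68L)
})

test_that("fold preconditions and unfoldable inputs are handled", {
  expect_error(foldCloverleaf(strrep("A", 50)), "length")
  expect_error(foldCloverleaf(strrep("A", 120)), "length")
  expect_error(foldCloverleaf(paste0(strrep("A", 75), "Z")), "alphabet")
  un <- foldCloverleaf(strrep("A", 76))   # acceptor stem cannot pair
  expect_s4_class(un, "Cloverleaf")
  expect_false(foldable(un))
  expect_match(un@reason, "acceptor stem")
  expect_error(extractIdentityProfile(un), "unfoldable")
})

test_that("identity profiles read the planted elements exactly", {
  bactTyr <- generateTrna("Tyr", pair = "G-C", n73 = "A", vArmLen = 13,
                          seed = 5)
  p <- extractIdentityProfile(foldCloverleaf(bactTyr$sequence))
  expect_identical(paste0(p@pair1, "-", p@pair72), "G-C")
  expect_true(p@vArmPresent)

  archTyr <- generateTrna("Tyr", pair = "C-G", n73 = "A", vArmLen = 0,
                          seed = 6)
  p <- extractIdentityProfile(foldCloverleaf(archTyr$sequence))
  expect_identical(paste0(p@pair1, "-", p@pair72), "C-G")
  expect_false(p@vArmPresent)
  expect_identical(p@isotypeHint, "Tyr")

  archTrp <- generateTrna("Trp", pair = "G-C", n73 = "A", vArmLen = 0,
                          seed = 7)
  p <- extractIdentityProfile(foldCloverleaf(archTrp$sequence))
  expect_identical(p@n73, "A")
  expect_identical(paste0(p@pair1, "-", p@pair72), "G-C")
  expect_identical(p@isotypeHint, "Trp")
})

test_that("classification is total and matches the rule table on every
          pair/discriminator/V-arm combination", {
  for (iso in c("Tyr", "Trp")) {
    anticodon <- if (iso == "Tyr") "GTA" else "CCA"
    for (p1 in c("A", "C", "G", "T")) for (p72 in c("A", "C", "G", "T"))
      for (n73 in c("A", "C", "G", "T")) for (varm in c(TRUE, FALSE)) {
        prof <- new("IdentityProfile", pair1 = p1, pair72 = p72,
                    n73 = n73, vArmPresent = varm,
                    vArmLen = if (varm) 13L else 0L,
                    anticodon = anticodon, isotypeHint = iso)
        call <- classifyIdentity(prof)
        expect_identical(domainType(call),
                         oracleIdentityRule(iso, p1, p72, n73, varm))
        expect_gte(nrow(evidence(call)), 1)
        if (domainType(call) == "ambiguous")
          expect_true("conflict" %in% evidence(call)$element)
      }
  }
})

test_that("non-Tyr/Trp anticodons are rejected as unclassifiable", {
  prof <- new("IdentityProfile", pair1 = "G", pair72 = "C", n73 = "A",
              vArmPresent = FALSE, vArmLen = 0L, anticodon = "AAA",
              isotypeHint = "other")
  expect_error(classifyIdentity(prof), "not classifiable")
})

test_that("noisy but foldable tRNAs keep the correct discriminator and
          classify to truth", {
  types <- list(list("Tyr", "G-C", "A", 13L), list("Tyr", "C-G", "A", 0L),
                list("Tyr", "C-G", "A", 13L), list("Trp", "A-T", "G", 0L),
                list("Trp", "G-C", "A", 0L))
  folded <- 0L; good <- 0L
  for (i in 1:500) {
    t <- types[[(i %% length(types)) + 1L]]
    g <- generateTrna(t[[1]], pair = t[[2]], n73 = t[[3]],
                      vArmLen = t[[4]], mutationRate = 0.1, seed = i)
    cl <- foldCloverleaf(g$sequence)
    if (!foldable(cl)) next
    folded <- folded + 1L
    prof <- extractIdentityProfile(cl)
    okDisc <- prof@n73 == t[[3]]
    okCall <- domainType(classifyIdentity(prof)) == g$truth$domain_type
    if (okDisc && okCall) good <- good + 1L
  }
  expect_gt(folded, 300)
  expect_gte(good / folded, 0.99)
})
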