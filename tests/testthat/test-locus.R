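# Feature loading, ORF1 calling, operon detection, genome summaries.

roleFromTemplate <- function(template) {
  switch(template,
         trna_trp_A73 = "trna_trp_A73", orf1 = "orf1",
         trprs_a1 = "trprs_a1", trprs_a2 = "trprs_a2",
         trprs_a_like = "trprs_a_like", trprs_bacterial = "trprs_bacterial",
         trp_repressor = "trpR", "other")
}

test_that("loading a generated contig set recovers the truth table", {
  sc <- generateContigs(list(
    contigSpec(c("trna_trp_A73", "orf1", "trprs_a1"), seed = 41,
               contig = "cA"),
    contigSpec(c("filler", "trna_tyr"), seed = 42, contig = "cB",
               strand = "-")))
  f <- loadFeatures(sc$features, sc$contigs)
  tr <- sc$truth$features
  mc <- S4Vectors::mcols(f)
  m <- match(tr$id, mc$ID)
  expect_false(anyNA(m))
  expect_identical(BiocGenerics::start(f)[m], tr$start)
  expect_identical(BiocGenerics::end(f)[m], tr$end)
  expect_identical(as.character(BiocGenerics::strand(f))[m], tr$strand)
})

test_that("dangling contigs and out-of-range spans are parse errors", {
  sc <- generateContigs(contigSpec("filler", seed = 43, contig = "c1"))
  gr <- sc$features
  GenomeInfoDb::seqlevels(gr) <- c("c1", "ghost")
  bad <- gr
  GenomicRanges::seqnames(bad) <- factor("ghost", levels = c("c1", "ghost"))
  expect_error(loadFeatures(bad, sc$contigs), "ghost")
  over <- GenomicRanges::GRanges("c1", IRanges::IRanges(
    1, nchar(as.character(sc$contigs[[1]])) + 10), strand = "+")
  S4Vectors::mcols(over)$type <- "CDS"
  S4Vectors::mcols(over)$ID <- "oops"
  expect_error(loadFeatures(over, sc$contigs), "oops")
})

test_that("GFF3 write -> read round-trips the feature list", {
  sc <- generateContigs(contigSpec(c("trna_trp_A73", "orf1", "trprs_a1",
                                     "trprs_bacterial"), seed = 44))
  d <- tempfile()
  p <- writeContigSet(sc, d)
  f1 <- loadFeatures(sc$features, sc$contigs)
  f2 <- loadFeatures(p[["gff3"]], p[["fasta"]])
  for (col in c("ID", "type", "label", "sequence")) {
    expect_identical(as.character(S4Vectors::mcols(f1)[[col]]),
                     as.character(S4Vectors::mcols(f2)[[col]]))
  }
  expect_identical(BiocGenerics::start(f1), BiocGenerics::start(f2))
  expect_identical(as.character(BiocGenerics::strand(f1)),
                   as.character(BiocGenerics::strand(f2)))
})

annotated <- function(specs) {
  sc <- generateContigs(specs)
  f <- annotateFeatures(loadFeatures(sc$features, sc$contigs))
  list(sc = sc, f = callOrf1Candidates(f))
}

test_that("ORF1 calling is the conjunction of its three conditions", {
  # planted ORF1 in the canonical operon context is flagged
  base <- annotated(contigSpec(c("trna_trp_A73", "orf1", "trprs_a1"),
                               seed = 51))
  mc <- S4Vectors::mcols(base$f)
  expect_true(mc$orf1_like[mc$label == "orf1"])
  # (a) ablated: same protein with no tRNA/TrpRS-A context
  ctx <- annotated(contigSpec(c("filler", "orf1", "filler"), seed = 52))
  expect_false(any(S4Vectors::mcols(ctx$f)$orf1_like))
  # (b) ablated: the middle CDS classifies as a TrpRS, so it cannot be
  # ORF1 even in a perfect operon context
  conf <- annotated(contigSpec(c("trna_trp_A73", "trprs_a1", "trprs_a1"),
                               seed = 53))
  expect_false(any(S4Vectors::mcols(conf$f)$orf1_like))
  # (c) ablated: motif-free ORF1 variant is not flagged
  nom <- annotated(contigSpec(c("trna_trp_A73", "orf1_no_motifs",
                                "trprs_a1"), seed = 54))
  expect_false(any(S4Vectors::mcols(nom$f)$orf1_like))
  # archaeal cluster context also satisfies (a)
  arch <- annotated(contigSpec(c("trna_trp_A73", "orf1", "trprs_a2"),
                               seed = 55))
  mc <- S4Vectors::mcols(arch$f)
  expect_true(mc$orf1_like[mc$label == "orf1"])
})

test_that("operon patterns are found exactly and split at wide gaps", {
  a <- annotated(contigSpec(c("trna_trp_A73", "orf1", "trprs_a1",
                              "trprs_bacterial"), seed = 56))
  ops <- detectOperons(a$f)
  expect_setequal(ops$pattern,
                  c("tRNA_ORF1_TrpRSA1",
                    "tRNA_ORF1_TrpRSA1_plus_bacterialTrpRS"))
  # one gap beyond the maximum breaks the chain
  scWide <- generateContigs(contigSpec(
    c("trna_trp_A73", "orf1", "trprs_a1", "trprs_bacterial"),
    intergenicGap = 151, seed = 56))
  annWide <- annotateFeatures(loadFeatures(scWide$features,
                                           scWide$contigs))
  expect_identical(nrow(detectOperons(
    callOrf1Candidates(annWide, maxGap = 150))), 0L)
  expect_gt(nrow(detectOperons(
    callOrf1Candidates(annWide, maxGap = 200), maxGap = 200)), 0)
})

test_that("operon calls never span two strands", {
  a <- annotated(contigSpec(c("trna_trp_A73", "orf1", "trprs_a1"),
                            seed = 57))
  f <- a$f
  BiocGenerics::strand(f)[2] <- "-"       # flip the ORF1 feature
  expect_identical(nrow(detectOperons(f)), 0L)
})

test_that("detected operons equal the exhaustive window oracle on random
          layouts", {
  pool <- c("trna_trp_A73", "orf1", "trprs_a1", "trprs_a2",
            "trprs_bacterial", "trp_repressor", "filler", "trna_tyr")
  set.seed(60)
  specs <- lapply(1:40, function(i) {
    # half purely random layouts, half seeded with the canonical operon
    # block plus random decoration, so positives and negatives both occur
    layout <- if (i %% 2 == 0)
      sample(pool, sample(2:5, 1), replace = TRUE)
    else c(sample(pool, sample(0:1, 1)),
           c("trna_trp_A73", "orf1",
             sample(c("trprs_a1", "trprs_a2"), 1)),
           sample(pool, sample(0:2, 1)))
    contigSpec(layout, strand = sample(c("+", "-"), 1), seed = 6000 + i,
               contig = sprintf("r%02d", i))
  })
  a <- annotated(specs)
  got <- detectOperons(a$f)
  gotKeys <- sort(paste(got$pattern, got$members))
  tr <- a$sc$truth$features
  chains <- lapply(split(tr, tr$contig), function(x) {
    x <- x[if (x$strand[1] == "+") order(x$start) else order(-x$start), ]
    list(roles = vapply(x$template, roleFromTemplate, ""), ids = x$id)
  })
  expect_identical(gotKeys, oracleOperons(chains))
})

test_that("genome summaries count identities and flag dual identity", {
  sc <- generateContigs(list(
    contigSpec(c("trna_trp_G73", "filler"), seed = 61, contig = "d1",
               genome = "G"),
    contigSpec(c("trna_trp_A73", "orf1", "trprs_a1"), seed = 62,
               contig = "d2", genome = "G"),
    contigSpec(c("trna_tyr", "filler"), seed = 63, contig = "d3",
               genome = "H")))
  f <- callOrf1Candidates(annotateFeatures(
    loadFeatures(sc$features, sc$contigs)))
  s <- summarizeGenome(f)
  g <- s[s$genome == "G", ]
  expect_identical(g$n_Trp_bacterial, 1L)
  expect_identical(g$n_Trp_archaeal_eukaryal, 1L)
  expect_true(g$dual_identity)
  h <- s[s$genome == "H", ]
  expect_identical(h$n_Tyr_bacterial, 1L)
  expect_false(h$dual_identity)
  # additivity: per-contig counts sum to the genome counts
  perContig <- summarizeGenome(f, genomeOf = setNames(
    c("d1", "d2", "d3"), c("d1", "d2", "d3")))
  numeric_cols <- grep("^n_", names(s), value = TRUE)
  expect_identical(colSums(perContig[perContig$genome %in% c("d1", "d2"),
                                     numeric_cols]),
                   colSums(g[, numeric_cols]))
})
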