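# End-to-end orchestration and report writing.

#' Configuration for an end-to-end screen
#'
#' @param classifier a [classifierConfig()].
#' @param maxGap maximum intergenic gap (nt) for operon chains.
#' @param orf1LengthBounds protein length bounds for ORF1 candidates.
#' @param seed integer seed recorded in provenance and used by any
#'   stochastic stage.
#' @return list of class `screenConfig`.
#' @export
screenConfig <- function(classifier = classifierConfig(), maxGap = 150L,
                         orf1LengthBounds = c(120L, 450L), seed = 1L) {
  structure(list(classifier = classifier, maxGap = as.integer(maxGap),
                 orf1LengthBounds = as.integer(orf1LengthBounds),
                 seed = as.integer(seed)),
            class = "screenConfig")
}

#' Run the full identity/aaRS screen on annotated contigs
#'
#' Runs the stages in order: feature loading (GFF3 + FASTA), cloverleaf
#' folding and identity typing of tRNA genes, motif scanning and
#' nearest-reference lineage typing of CDS features, ORF1 candidate
#' calling, operon detection and per-genome identity summaries.
#' Per-record failures are recorded in the report's `note` column and
#' never abort the batch.
#'
#' @param gff GFF3 path or `GRanges`.
#' @param fasta FASTA path or `DNAStringSet`.
#' @param refs labeled aaRS reference set ([lineageReferences()] by
#'   default).
#' @param config a [screenConfig()].
#' @return A [ScreenReport-class] object.
#' @examples
#' sc <- generateContigs(contigSpec(c("trna_trp_A73", "orf1", "trprs_a1"),
#'                                  seed = 11))
#' runScreen(sc$features, sc$contigs)
#' @export
runScreen <- function(gff, fasta, refs = lineageReferences(),
                      config = screenConfig()) {
  features <- loadFeatures(gff, fasta)
  features <- annotateFeatures(features, refs, config$classifier)
  features <- callOrf1Candidates(features, maxGap = config$maxGap,
                                 lengthBounds = config$orf1LengthBounds)
  operons <- detectOperons(features, maxGap = config$maxGap)
  genomes <- summarizeGenome(features)
  mc <- as.data.frame(mcols(features))
  base <- data.frame(
    contig = as.character(GenomicRanges::seqnames(features)),
    id = mc$ID,
    start = BiocGenerics::start(features),
    end = BiocGenerics::end(features),
    strand = as.character(BiocGenerics::strand(features)),
    stringsAsFactors = FALSE)
  trna <- cbind(base, mc[, c("isotype", "domain_type", "n73", "v_arm_len",
                             "note")])[mc$type == "tRNA", , drop = FALSE]
  prot <- cbind(base, mc[, c("family", "lineage", "similarity", "n_high",
                             "n_kmsks", "n_fes", "trp_free", "orf1_like",
                             "note")])[mc$type == "CDS", , drop = FALSE]
  rownames(trna) <- rownames(prot) <- NULL
  new("ScreenReport", trna = trna, proteins = prot, operons = operons,
      genomes = genomes,
      provenance = list(
        package = "aaRScreen",
        version = as.character(utils::packageVersion("aaRScreen")),
        similarity_threshold = config$classifier$similarityThreshold,
        max_gap = config$maxGap,
        orf1_length_bounds = config$orf1LengthBounds,
        seed = config$seed))
}

#' Write a screen report as TSV tables + JSON provenance
#'
#' @param report a [ScreenReport-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
writeScreenReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(trna = file.path(dir, "trna_identity.tsv"),
             proteins = file.path(dir, "protein_types.tsv"),
             operons = file.path(dir, "operons.tsv"),
             genomes = file.path(dir, "genome_summary.tsv"),
             provenance = file.path(dir, "provenance.json"))
  write.table(report@trna, paths[["trna"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report@proteins, paths[["proteins"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report@operons, paths[["operons"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report@genomes, paths[["genomes"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report@provenance, paths[["provenance"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read and write trees in Newick with supports as internal labels
#'
#' Thin wrappers over the ape readers/writers, kept so that all pipeline
#' I/O goes through one surface.
#'
#' @param tree an `ape::phylo` (for writing).
#' @param path file path.
#' @return `readNewick` returns an `ape::phylo`; `writeNewick` returns
#'   the path invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) {
  ape::read.tree(path)
}
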