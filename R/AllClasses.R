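#' Cloverleaf fold of a tRNA gene
#'
#' Result of [foldCloverleaf()]: canonical segment spans, the mapping from
#' sequence index to canonical tRNA numbering (1..76; variable-arm positions
#' are flagged with `NA` in the map and carried in the `variable` segment),
#' and whether an admissible fold was found at all. An unfoldable input is
#' represented with `foldable = FALSE` and a human-readable `reason`, never
#' an error, so batch screens can record the failure per gene.
#'
#' @slot sequence character(1), the input coding-strand DNA.
#' @slot foldable logical(1).
#' @slot reason character(1), empty when foldable.
#' @slot segments data.frame with columns `segment`, `start`, `end`
#'   (1-based inclusive sequence coordinates; empty segments have
#'   `start > end`).
#' @slot canonicalMap integer vector, one entry per base: the canonical
#'   position number, or `NA` for variable-arm bases.
#' @slot variableLen integer(1), raw length of the variable region.
#'
#' @aliases Cloverleaf-class
#' @exportClass Cloverleaf
setClass("Cloverleaf",
  representation(
    sequence     = "character",
    foldable     = "logical",
    reason       = "character",
    segments     = "data.frame",
    canonicalMap = "integer",
    variableLen  = "integer"
  )
)

setValidity("Cloverleaf", function(object) {
  if (length(object@foldable) != 1L) return("'foldable' must be length 1")
  if (!object@foldable) return(TRUE)
  seg <- object@segments
  need <- c("segment", "start", "end")
  if (!all(need %in% names(seg))) return("segments need segment/start/end")
  n <- nchar(object@sequence)
  covered <- unlist(lapply(seq_len(nrow(seg)), function(i) {
    if (seg$start[i] > seg$end[i]) integer(0) else seg$start[i]:seg$end[i]
  }))
  if (length(covered) != n || anyDuplicated(covered) ||
      !identical(sort(covered), seq_len(n)))
    return("segments must tile the sequence without overlap")
  if (length(object@canonicalMap) != n)
    return("canonicalMap length must equal sequence length")
  TRUE
})

#' Identity-element profile of a folded tRNA
#'
#' The elements read off a [Cloverleaf-class] object that the Tyr/Trp
#' identity rules consume: the ordered 1-72 base pair, the discriminator
#' base N73, variable-arm presence/length and the anticodon. The isotype
#' hint comes from the anticodon alone (GTA = Tyr, CCA = Trp in gene
#' coordinates).
#'
#' @slot pair1 character(1), base at canonical position 1.
#' @slot pair72 character(1), base at canonical position 72.
#' @slot n73 character(1), discriminator base.
#' @slot vArmPresent logical(1).
#' @slot vArmLen integer(1), 0 when absent, >= 10 when present.
#' @slot anticodon character(1), three bases.
#' @slot isotypeHint character(1), one of "Tyr", "Trp", "other".
#'
#' @aliases IdentityProfile-class
#' @exportClass IdentityProfile
setClass("IdentityProfile",
  representation(
    pair1 = "character", pair72 = "character", n73 = "character",
    vArmPresent = "logical", vArmLen = "integer",
    anticodon = "character", isotypeHint = "character"
  )
)

setValidity("IdentityProfile", function(object) {
  if (xor(object@vArmPresent, object@vArmLen >= 10L))
    return("vArmPresent must hold exactly when vArmLen >= 10")
  if (nchar(object@anticodon) != 3L) return("anticodon must be 3 nt")
  if (!object@isotypeHint %in% c("Tyr", "Trp", "other"))
    return("isotypeHint must be Tyr, Trp or other")
  TRUE
})

#' Identity-domain classification of a tRNA
#'
#' The bacterial / archaeal-eukaryal / chimeric typing of a tRNA gene under
#' the Tyr and Trp identity-element rule tables, with per-element evidence.
#'
#' @slot isotype character(1), "Tyr" or "Trp".
#' @slot domainType character(1): one of `bacterial`, `archaeal_eukaryal`,
#'   `chimeric_C1G72_with_Varm`, `ambiguous`.
#' @slot evidence data.frame with columns `element`, `observed`,
#'   `expected`; ambiguous calls enumerate the conflicting elements.
#'
#' @aliases IdentityCall-class
#' @exportClass IdentityCall
setClass("IdentityCall",
  representation(isotype = "character", domainType = "character",
                 evidence = "data.frame")
)

setValidity("IdentityCall", function(object) {
  ok <- c("bacterial", "archaeal_eukaryal", "chimeric_C1G72_with_Varm",
          "ambiguous")
  if (!object@domainType %in% ok) return("unknown domainType")
  if (nrow(object@evidence) < 1L)
    return("every call must carry at least one evidence entry")
  TRUE
})

#' Family and lineage typing of an aaRS protein
#'
#' Nearest-reference classification of a candidate class Ic aaRS:
#' family (TyrRS/TrpRS), lineage clade, the winning reference and its
#' similarity, plus the top references as evidence.
#'
#' @slot family character(1): "TyrRS", "TrpRS" or "unknown".
#' @slot lineage character(1): one of `bacteria_type`,
#'   `archaea_eukarya_type`, `TrpRS_A1`, `TrpRS_A2`, `TrpRS_A_like`,
#'   `ORF1_like`, `unassigned`.
#' @slot bestReference character(1).
#' @slot similarity numeric(1), positives fraction in `[0, 1]`.
#' @slot evidence data.frame of top references (`reference`, `family`,
#'   `lineage`, `similarity`) plus any notes.
#' @slot threshold numeric(1), the similarity threshold used.
#'
#' @aliases AarsTypeCall-class
#' @exportClass AarsTypeCall
setClass("AarsTypeCall",
  representation(family = "character", lineage = "character",
                 bestReference = "character", similarity = "numeric",
                 evidence = "data.frame", threshold = "numeric")
)

setValidity("AarsTypeCall", function(object) {
  lin <- c("bacteria_type", "archaea_eukarya_type", "TrpRS_A1", "TrpRS_A2",
           "TrpRS_A_like", "ORF1_like", "unassigned")
  if (!object@lineage %in% lin) return("unknown lineage")
  if (object@similarity < 0 || object@similarity > 1)
    return("similarity must lie in [0, 1]")
  TRUE
})

#' Domain architecture of a class Ic aaRS protein
#'
#' Ordered N-to-C segmentation: optional B2 domain and linker, catalytic
#' core (HIGH..KMSKS), anticodon-binding domain, optional S4-like
#' C-terminal domain. Absent segments are simply omitted.
#'
#' @slot segments data.frame with columns `segment`, `start`, `end`,
#'   `evidence` (1-based inclusive residue coordinates).
#' @slot warning logical(1), set when no HIGH hit anchors the core.
#'
#' @aliases DomainArchitecture-class
#' @exportClass DomainArchitecture
setClass("DomainArchitecture",
  representation(segments = "data.frame", warning = "logical")
)

setValidity("DomainArchitecture", function(object) {
  seg <- object@segments
  if (nrow(seg) > 1L) {
    if (is.unsorted(seg$start)) return("segments must be ordered N to C")
    if (any(seg$start[-1L] <= seg$end[-nrow(seg)]))
      return("segments must not overlap")
  }
  TRUE
})

#' Sliding-window identity track and recombination breakpoints
#'
#' Produced by [detectBreakpoints()]: per-window identity between two
#' globally aligned sequences and the alignment columns where the track
#' crosses from a high-identity plateau to a low one (or back).
#'
#' @slot track data.frame with columns `start`, `end`, `center`
#'   (alignment columns) and `identity`.
#' @slot breakpoints numeric vector of alignment columns.
#' @slot window,step integer(1).
#' @slot highThreshold,lowThreshold numeric(1).
#'
#' @aliases BreakpointReport-class
#' @exportClass BreakpointReport
setClass("BreakpointReport",
  representation(track = "data.frame", breakpoints = "numeric",
                 window = "integer", step = "integer",
                 highThreshold = "numeric", lowThreshold = "numeric")
)

setValidity("BreakpointReport", function(object) {
  if (nrow(object@track) &&
      (min(object@track$identity) < 0 || max(object@track$identity) > 1))
    return("identity values must lie in [0, 1]")
  if (length(object@breakpoints) && nrow(object@track) &&
      (min(object@breakpoints) < min(object@track$start) ||
       max(object@breakpoints) > max(object@track$end)))
    return("breakpoints must lie inside the aligned region")
  TRUE
})

#' Paired-tree congruence statistic
#'
#' Robinson-Foulds distance between two trees restricted to their shared
#' leaves, with a leaf-label permutation p-value.
#'
#' @slot rfDistance integer(1), even for binary trees.
#' @slot normalizedRF numeric(1), `rf / (2 * (n - 3))`.
#' @slot pValue numeric(1), `(1 + #{perm RF <= observed}) / (nPerm + 1)`.
#' @slot nPermutations integer(1).
#' @slot nShared integer(1), number of shared leaves.
#' @slot seed integer(1), RNG seed used for the permutations.
#'
#' @aliases CongruenceResult-class
#' @exportClass CongruenceResult
setClass("CongruenceResult",
  representation(rfDistance = "integer", normalizedRF = "numeric",
                 pValue = "numeric", nPermutations = "integer",
                 nShared = "integer", seed = "integer")
)

setValidity("CongruenceResult", function(object) {
  if (object@normalizedRF < 0 || object@normalizedRF > 1)
    return("normalizedRF must lie in [0, 1]")
  if (object@pValue <= 0 || object@pValue > 1)
    return("pValue must lie in (0, 1]")
  TRUE
})

#' End-to-end screen report
#'
#' The combined output of [runScreen()]: one table per analysis stage plus
#' a provenance block recording the configuration and seeds actually used.
#'
#' @slot trna data.frame, per-tRNA identity table.
#' @slot proteins data.frame, per-protein motif/type table.
#' @slot operons data.frame, detected gene-cluster instances.
#' @slot genomes data.frame, per-genome identity summaries.
#' @slot provenance list (package version, configuration, seeds).
#'
#' @aliases ScreenReport-class
#' @exportClass ScreenReport
setClass("ScreenReport",
  representation(trna = "data.frame", proteins = "data.frame",
                 operons = "data.frame", genomes = "data.frame",
                 provenance = "list")
)
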