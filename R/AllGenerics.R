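#' Accessors for aaRScreen result objects
#'
#' Small read-only accessors so downstream code never touches slots
#' directly.
#'
#' @param x an aaRScreen S4 object.
#' @return The slot value; see the class documentation for details.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("foldable", function(x) standardGeneric("foldable"))
#' @rdname accessors
#' @export
setGeneric("canonicalMap", function(x) standardGeneric("canonicalMap"))
#' @rdname accessors
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))
#' @rdname accessors
#' @export
setGeneric("domainType", function(x) standardGeneric("domainType"))
#' @rdname accessors
#' @export
setGeneric("evidence", function(x) standardGeneric("evidence"))
#' @rdname accessors
#' @export
setGeneric("aarsFamily", function(x) standardGeneric("aarsFamily"))
#' @rdname accessors
#' @export
setGeneric("lineage", function(x) standardGeneric("lineage"))
#' @rdname accessors
#' @export
setGeneric("similarity", function(x) standardGeneric("similarity"))
#' @rdname accessors
#' @export
setGeneric("breakpoints", function(x) standardGeneric("breakpoints"))
#' @rdname accessors
#' @export
setGeneric("identityTrack", function(x) standardGeneric("identityTrack"))
#' @rdname accessors
#' @export
setGeneric("rfDistance", function(x) standardGeneric("rfDistance"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setMethod("foldable", "Cloverleaf", function(x) x@foldable)
#' @rdname accessors
#' @export
setMethod("canonicalMap", "Cloverleaf", function(x) x@canonicalMap)
#' @rdname accessors
#' @export
setMethod("segmentTable", "Cloverleaf", function(x) x@segments)
#' @rdname accessors
#' @export
setMethod("segmentTable", "DomainArchitecture", function(x) x@segments)
#' @rdname accessors
#' @export
setMethod("domainType", "IdentityCall", function(x) x@domainType)
#' @rdname accessors
#' @export
setMethod("evidence", "IdentityCall", function(x) x@evidence)
#' @rdname accessors
#' @export
setMethod("evidence", "AarsTypeCall", function(x) x@evidence)
#' @rdname accessors
#' @export
setMethod("aarsFamily", "AarsTypeCall", function(x) x@family)
#' @rdname accessors
#' @export
setMethod("lineage", "AarsTypeCall", function(x) x@lineage)
#' @rdname accessors
#' @export
setMethod("similarity", "AarsTypeCall", function(x) x@similarity)
#' @rdname accessors
#' @export
setMethod("breakpoints", "BreakpointReport", function(x) x@breakpoints)
#' @rdname accessors
#' @export
setMethod("identityTrack", "BreakpointReport", function(x) x@track)
#' @rdname accessors
#' @export
setMethod("rfDistance", "CongruenceResult", function(x) x@rfDistance)
#' @rdname accessors
#' @export
setMethod("pValue", "CongruenceResult", function(x) x@pValue)

setMethod("show", "Cloverleaf", function(object) {
  if (!object@foldable) {
    cat("Cloverleaf (unfoldable):", object@reason, "\n")
    return(invisible(NULL))
  }
  cat(sprintf("Cloverleaf of %d nt (variable region %d nt)\n",
              nchar(object@sequence), object@variableLen))
  seg <- object@segments
  for (i in seq_len(nrow(seg)))
    cat(sprintf("  %-18s %4d-%-4d\n", seg$segment[i], seg$start[i],
                seg$end[i]))
  invisible(NULL)
})

setMethod("show", "IdentityProfile", function(object) {
  cat(sprintf(
    "IdentityProfile: %s%s pair 1-72 %s-%s, N73 %s, V-arm %s (%d nt)\n",
    object@isotypeHint,
    sprintf(" (anticodon %s)", object@anticodon),
    object@pair1, object@pair72, object@n73,
    if (object@vArmPresent) "present" else "absent", object@vArmLen))
  invisible(NULL)
})

setMethod("show", "IdentityCall", function(object) {
  cat(sprintf("IdentityCall: tRNA-%s -> %s\n", object@isotype,
              object@domainType))
  ev <- object@evidence
  for (i in seq_len(nrow(ev)))
    cat(sprintf("  %-10s observed %-6s expected %s\n", ev$element[i],
                ev$observed[i], ev$expected[i]))
  invisible(NULL)
})

setMethod("show", "AarsTypeCall", function(object) {
  cat(sprintf("AarsTypeCall: family %s, lineage %s (best %s, similarity %.3f)\n",
              object@family, object@lineage, object@bestReference,
              object@similarity))
  invisible(NULL)
})

setMethod("show", "DomainArchitecture", function(object) {
  cat("DomainArchitecture",
      if (object@warning) "(warning: no catalytic-core anchor)" else "",
      "\n")
  seg <- object@segments
  for (i in seq_len(nrow(seg)))
    cat(sprintf("  %-16s %4d-%-4d %s\n", seg$segment[i], seg$start[i],
                seg$end[i], seg$evidence[i]))
  invisible(NULL)
})

setMethod("show", "BreakpointReport", function(object) {
  cat(sprintf(
    "BreakpointReport: %d window(s), %d breakpoint(s) at [%s]\n",
    nrow(object@track), length(object@breakpoints),
    paste(round(object@breakpoints), collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "CongruenceResult", function(object) {
  cat(sprintf(
    "CongruenceResult: RF = %d (normalized %.3f) over %d shared leaves; p = %.4g (%d permutations, seed %d)\n",
    object@rfDistance, object@normalizedRF, object@nShared, object@pValue,
    object@nPermutations, object@seed))
  invisible(NULL)
})

setMethod("show", "ScreenReport", function(object) {
  cat(sprintf(
    "ScreenReport: %d tRNA call(s), %d protein call(s), %d operon call(s), %d genome(s)\n",
    nrow(object@trna), nrow(object@proteins), nrow(object@operons),
    nrow(object@genomes)))
  invisible(NULL)
})
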