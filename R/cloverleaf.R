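# Cloverleaf folding, identity-element extraction and identity typing.
#
# The fold is an anchored mapping onto the canonical tRNA architecture:
# every segment of the cloverleaf except the variable region has a fixed
# canonical length (acceptor stem 7+7, D-arm 16 with its two-base
# connector, anticodon arm 17, T-arm 17, discriminator, CCA), so for a
# coding-strand gene without introns the only free parameter is the
# variable-region length, recovered from the total length. The mapping is
# then validated against the acceptor-stem pairing requirement. This keeps
# canonical numbering exact and fully deterministic, which is what the
# identity rules need; it is not a thermodynamic folder.

.WC <- c(A = "T", C = "G", G = "C", T = "A")

.isPaired <- function(a, b) {
  # Watson-Crick or G.U wobble (in DNA lettering, G.T)
  (!is.na(.WC[a]) && .WC[[a]] == b) ||
    (a == "G" && b == "T") || (a == "T" && b == "G")
}

# Segment lengths 5' -> 3' for the canonical 76-position cloverleaf with a
# variable region of length V (V = 5 in the type I consensus).
.cloverleafSpans <- function(V) {
  lens <- c(acceptor_stem_5p = 7L, connector_8_9 = 2L, d_arm = 16L,
            connector_26 = 1L, anticodon_arm = 17L, variable = V,
            t_arm = 17L, acceptor_stem_3p = 7L, discriminator = 1L,
            cca = 3L)
  ends <- cumsum(lens)
  data.frame(segment = names(lens),
             start = ends - lens + 1L, end = ends,
             row.names = NULL, stringsAsFactors = FALSE)
}

.unfoldable <- function(seq, reason) {
  new("Cloverleaf", sequence = seq, foldable = FALSE, reason = reason,
      segments = data.frame(), canonicalMap = integer(0),
      variableLen = NA_integer_)
}

#' Fold a tRNA gene into the cloverleaf
#'
#' Maps a coding-strand (5'->3') tRNA gene onto canonical cloverleaf
#' numbering 1..76. All canonical segments have fixed lengths, so the
#' variable-region length is recovered from the total gene length and the
#' mapping is validated against the acceptor stem: at least 6 of its 7
#' base pairs must be Watson-Crick or G.U. Sequences failing that check
#' (or whose length admits no canonical layout) come back as a structured
#' unfoldable result rather than an error.
#'
#' @param seq character(1) DNA over `A,C,G,T,N`, between 60 and 110 nt.
#' @param minAcceptorPairs integer(1), minimum paired positions (of 7)
#'   required in the acceptor stem; default 6 tolerates one mismatch.
#' @return A [Cloverleaf-class] object; check [foldable()].
#' @examples
#' tr <- generateTrna("Tyr", pair = "G-C", n73 = "A", vArmLen = 13, seed = 1)
#' foldCloverleaf(tr$sequence)
#' @export
foldCloverleaf <- function(seq, minAcceptorPairs = 6L) {
  seq <- toupper(as.character(seq)[1L])
  n <- nchar(seq)
  if (n < 60L || n > 110L)
    stop("sequence length must be between 60 and 110 nt, got ", n)
  ch <- .chars(seq)
  if (!all(ch %in% c(.DNA, "N")))
    stop("sequence alphabet must be A,C,G,T,N")
  V <- n - 71L
  if (V < 0L)
    return(.unfoldable(seq, "too short for the canonical cloverleaf"))
  # acceptor stem: canonical i pairs canonical 73 - i
  paired <- 0L
  for (i in 1:7) {
    j <- 68L + V - i                 # sequence index of canonical 73 - i
    if (.isPaired(ch[i], ch[j])) paired <- paired + 1L
  }
  if (paired < minAcceptorPairs)
    return(.unfoldable(seq, sprintf(
      "acceptor stem pairing below threshold (%d/7 paired)", paired)))
  cmap <- rep(NA_integer_, n)
  cmap[1:43] <- 1:43
  cmap[(44L + V):n] <- 49:76
  new("Cloverleaf", sequence = seq, foldable = TRUE, reason = "",
      segments = .cloverleafSpans(V), canonicalMap = cmap,
      variableLen = V)
}

#' Extract the Tyr/Trp identity elements from a folded tRNA
#'
#' Reads the ordered 1-72 base pair, the discriminator N73, the anticodon
#' and the variable-arm status off a foldable [Cloverleaf-class]. A
#' variable region of at least 10 nt counts as a V-arm (the type II
#' convention); shorter variable loops are reported as absent with length
#' zero. The isotype hint comes from the anticodon in gene coordinates
#' (GTA = Tyr, CCA = Trp, anything else = other).
#'
#' @param cl a foldable [Cloverleaf-class] object.
#' @return An [IdentityProfile-class] object.
#' @export
extractIdentityProfile <- function(cl) {
  stopifnot(is(cl, "Cloverleaf"))
  if (!cl@foldable)
    stop("cannot extract an identity profile from an unfoldable sequence: ",
         cl@reason)
  ch <- .chars(cl@sequence)
  idx <- function(canon) which(cl@canonicalMap == canon)
  V <- cl@variableLen
  vlen <- if (V >= 10L) V else 0L
  anticodon <- paste(ch[c(idx(34L), idx(35L), idx(36L))], collapse = "")
  hint <- switch(anticodon, GTA = "Tyr", CCA = "Trp", "other")
  new("IdentityProfile",
      pair1 = ch[idx(1L)], pair72 = ch[idx(72L)], n73 = ch[idx(73L)],
      vArmPresent = vlen >= 10L, vArmLen = vlen,
      anticodon = anticodon, isotypeHint = hint)
}

#' Classify a tRNA identity profile as bacterial, archaeal/eukaryal or
#' chimeric
#'
#' Applies the Tyr/Trp identity-element rule tables. For tRNA-Tyr:
#' G1-C72 with a V-arm is the bacterial identity; C1-G72 without a V-arm
#' is archaeal/eukaryal; C1-G72 *with* a V-arm is the chimeric
#' configuration seen in CPR bacteria; every other combination is
#' ambiguous. For tRNA-Trp: G73 is bacterial regardless of the 1-72 pair;
#' A73 together with G1-C72 is archaeal/eukaryal; anything else is
#' ambiguous. Each call carries per-element evidence, and ambiguous calls
#' enumerate the conflicting elements.
#'
#' @param profile an [IdentityProfile-class] with isotype hint Tyr or Trp.
#' @return An [IdentityCall-class] object.
#' @examples
#' tr <- generateTrna("Tyr", pair = "C-G", n73 = "A", vArmLen = 13, seed = 1)
#' classifyIdentity(extractIdentityProfile(foldCloverleaf(tr$sequence)))
#' @export
classifyIdentity <- function(profile) {
  stopifnot(is(profile, "IdentityProfile"))
  iso <- profile@isotypeHint
  if (iso == "other")
    stop("not classifiable: anticodon ", profile@anticodon,
         " is neither Tyr (GTA) nor Trp (CCA)")
  pair <- paste0(profile@pair1, "-", profile@pair72)
  varm <- profile@vArmPresent
  ev <- function(element, observed, expected)
    data.frame(element = element, observed = observed, expected = expected,
               stringsAsFactors = FALSE)
  if (iso == "Tyr") {
    evidence <- rbind(
      ev("pair_1_72", pair, "bacterial G-C / archaeal-eukaryal C-G"),
      ev("v_arm", if (varm) sprintf("present (%d nt)", profile@vArmLen)
                  else "absent",
         "bacterial present / archaeal-eukaryal absent"))
    type <-
      if (pair == "G-C" && varm) "bacterial"
      else if (pair == "C-G" && !varm) "archaeal_eukaryal"
      else if (pair == "C-G" && varm) "chimeric_C1G72_with_Varm"
      else "ambiguous"
    if (type == "ambiguous")
      evidence <- rbind(evidence, ev(
        "conflict", sprintf("pair %s with V-arm %s", pair,
                            if (varm) "present" else "absent"),
        "no Tyr rule matches this combination"))
  } else {
    evidence <- rbind(
      ev("n73", profile@n73, "bacterial G / archaeal-eukaryal A"),
      ev("pair_1_72", pair, "archaeal-eukaryal requires G-C"))
    type <-
      if (profile@n73 == "G") "bacterial"
      else if (profile@n73 == "A" && pair == "G-C") "archaeal_eukaryal"
      else "ambiguous"
    if (type == "ambiguous")
      evidence <- rbind(evidence, ev(
        "conflict", sprintf("N73 %s with pair %s", profile@n73, pair),
        "no Trp rule matches this combination"))
  }
  new("IdentityCall", isotype = iso, domainType = type, evidence = evidence)
}

#' Fold, profile and classify a batch of tRNA genes
#'
#' Convenience wrapper running [foldCloverleaf()],
#' [extractIdentityProfile()] and [classifyIdentity()] over a set of
#' sequences, returning one row per gene. Unfoldable or unclassifiable
#' genes are reported in place with the failure reason instead of
#' aborting the batch.
#'
#' @param seqs named character vector or `DNAStringSet` of coding-strand
#'   tRNA genes.
#' @return data.frame with columns `id`, `foldable`, `pos1`, `pos72`,
#'   `n73`, `anticodon`, `v_arm_len`, `isotype`, `domain_type`,
#'   `evidence`.
#' @export
classifyTrnaSet <- function(seqs) {
  seqs <- as.character(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("trna%03d", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    out <- data.frame(id = ids[i], foldable = FALSE, pos1 = NA_character_,
                      pos72 = NA_character_, n73 = NA_character_,
                      anticodon = NA_character_, v_arm_len = NA_integer_,
                      isotype = NA_character_, domain_type = NA_character_,
                      evidence = "", stringsAsFactors = FALSE)
    cl <- foldCloverleaf(seqs[[i]])
    if (!cl@foldable) {
      out$evidence <- cl@reason
      return(out)
    }
    prof <- extractIdentityProfile(cl)
    out$foldable <- TRUE
    out$pos1 <- prof@pair1; out$pos72 <- prof@pair72; out$n73 <- prof@n73
    out$anticodon <- prof@anticodon; out$v_arm_len <- prof@vArmLen
    out$isotype <- prof@isotypeHint
    call <- tryCatch(classifyIdentity(prof), error = function(e) NULL)
    if (is.null(call)) {
      out$domain_type <- NA_character_
      out$evidence <- "anticodon matches neither Tyr nor Trp"
    } else {
      out$domain_type <- call@domainType
      out$evidence <- paste(sprintf("%s=%s", call@evidence$element,
                                    call@evidence$observed),
                            collapse = "; ")
    }
    out
  })
  do.call(rbind, rows)
}
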