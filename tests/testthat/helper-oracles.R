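# Independent oracles used by the tests. These deliberately avoid the
# package's implementation paths: plain position-by-position scans,
# quadratic dynamic programming, exhaustive window enumeration.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

randAa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# --- motif scanning oracle (no regex, no vectorized trickery) --------
oracleScanStarts <- function(seq, pattern) {
  ch <- chars(seq)
  m <- length(pattern)
  starts <- integer(0)
  i <- 1L
  while (i + m - 1L <= length(ch)) {
    ok <- TRUE
    for (k in seq_len(m)) {
      if (!(ch[i + k - 1L] %in% pattern[[k]])) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, i)
    i <- i + 1L
  }
  starts
}

oracleGreedy <- function(starts, len) {
  keep <- integer(0); last <- -len
  for (s in starts) if (s >= last + len) { keep <- c(keep, s); last <- s }
  keep
}

ORACLE_HIGH <- list(c("H", "N", "Q"), c("I", "L", "V", "M", "A", "F", "G"),
                    "G", c("H", "N"))
ORACLE_KMSKS <- list(c("K", "R"), c("M", "L", "I", "V", "F"), "S",
                     c("K", "S"), c("S", "G"))
ORACLE_FES <- c(list("C"), rep(list(AA20), 22), list("C"),
                rep(list(AA20), 6), list("C"), rep(list(AA20), 2),
                list("C"))

# --- identity rule-table oracle (direct transcription of the rules) --
oracleIdentityRule <- function(isotype, p1, p72, n73, varm) {
  pair <- paste0(p1, "-", p72)
  if (isotype == "Tyr") {
    if (pair == "G-C" && varm) return("bacterial")
    if (pair == "C-G" && !varm) return("archaeal_eukaryal")
    if (pair == "C-G" && varm) return("chimeric_C1G72_with_Varm")
    return("ambiguous")
  }
  if (n73 == "G") return("bacterial")
  if (n73 == "A" && pair == "G-C") return("archaeal_eukaryal")
  "ambiguous"
}

# --- quadratic-time global affine alignment score oracle -------------
# Gap of length L costs open + ext * L (the pairwiseAlignment convention).
oracleGlobalScore <- function(a, b, open = 10, ext = 0.5) {
  B <- get(utils::data("BLOSUM62", package = "Biostrings",
                       envir = environment()), envir = environment())
  A <- chars(a); Bc <- chars(b)
  n <- length(A); m <- length(Bc)
  NEG <- -1e30
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (a advances)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
      B[A[i - 1], Bc[j - 1]]
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- exhaustive operon-window oracle ---------------------------------
# Enumerates every contiguous window of every strand-ordered chain and
# tests the role templates literally.
oracleOperons <- function(roleChains) {
  templates <- list(
    tRNA_ORF1_TrpRSA1 = c("trna_trp_A73", "orf1", "trprs_a1"),
    tRNA_ORF1_TrpRSA1_plus_bacterialTrpRS =
      c("trna_trp_A73", "orf1", "trprs_a1", "trprs_bacterial"),
    trpR_headed = c("trpR", "trna_trp_A73", "orf1", "trprs_a1"))
  out <- list()
  for (chain in roleChains) {
    roles <- chain$roles; ids <- chain$ids
    n <- length(roles)
    for (nm in names(templates)) {
      tpl <- templates[[nm]]
      k <- length(tpl)
      if (n < k) next
      for (i in seq_len(n - k + 1L))
        if (all(roles[i:(i + k - 1L)] == tpl))
          out[[length(out) + 1L]] <- paste(nm,
            paste(ids[i:(i + k - 1L)], collapse = ","))
    }
    if (any(roles %in% c("trprs_a2", "trprs_a_like")) &&
        any(roles == "trna_trp_A73") && any(roles == "orf1"))
      out[[length(out) + 1L]] <- paste("archaeal_cluster_A2",
        paste(ids[roles %in% c("trna_trp_A73", "orf1", "trprs_a2",
                               "trprs_a_like")], collapse = ","))
  }
  out <- unlist(out)
  if (is.null(out)) character(0) else sort(out)
}

# --- least-squares best topology for 4 taxa --------------------------
# Branch-length LS fit for each of the 3 unrooted quartet topologies;
# returns the split (as a sorted pair of tip indices grouped together)
# with minimal residual sum of squares.
oracleLsQuartet <- function(D) {
  pairs <- list(c(1, 2), c(1, 3), c(1, 4))
  rss <- sapply(pairs, function(pr) {
    grp1 <- pr; grp2 <- setdiff(1:4, pr)
    # path incidence over edges e1..e4 (pendant) + e5 (internal)
    rows <- list(); y <- numeric(0)
    for (i in 1:3) for (j in (i + 1):4) {
      inc <- numeric(5); inc[i] <- 1; inc[j] <- 1
      sameSide <- (i %in% grp1) == (j %in% grp1)
      if (!sameSide) inc[5] <- 1
      rows[[length(rows) + 1L]] <- inc
      y <- c(y, D[i, j])
    }
    Xm <- do.call(rbind, rows)
    fit <- lm.fit(Xm, y)
    sum(fit$residuals^2)
  })
  pairs[[which.min(rss)]]
}

# Split of tips 1,2 vs 3,4 implied by an NJ quartet tree (tip names
# "t1".."t4"): returns the pair grouped with t1.
njQuartetSplit <- function(tree) {
  memb <- aaRScreen:::.splitMembership(tree, paste0("t", 1:4))
  if (!nrow(memb)) return(NULL)           # star (ties)
  side <- memb[1L, ]                      # canonical: excludes t1
  sort(c(1L, which(!side)[which(!side) != 1L]))
}
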