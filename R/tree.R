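# Distance phylogenetics: Poisson-corrected distances, canonical
# neighbor-joining, bootstrap supports, clade assignment, and the
# Robinson-Foulds permutation test of paired-tree congruence.

.msaMatrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  rows <- as.character(msa)
  m <- do.call(rbind, lapply(rows, .chars))
  rownames(m) <- names(msa)
  m
}

#' Poisson-corrected distance matrix from an alignment
#'
#' For each pair of rows, computes the mismatch fraction `p` over the
#' mutually ungapped columns and corrects it as `d = -ln(1 - p)`
#' (Poisson model, uniform rates across sites). Mismatch fractions at or
#' above the saturation cap are truncated there with a warning.
#'
#' @param msa `AAStringSet` (gapped, equal width) or character matrix
#'   with >= 3 rows.
#' @param minUngapped minimum mutually ungapped columns per pair.
#' @param cap saturation cap on `p` (default 0.95).
#' @return symmetric numeric matrix with zero diagonal.
#' @examples
#' msa <- alignProgressive(c(a = "MKTAYIAK", b = "MKTAYIAK",
#'                           c = "MKTAYRAK"))
#' distanceMatrix(msa)
#' @export
distanceMatrix <- function(msa, minUngapped = 20L, cap = 0.95) {
  mat <- .msaMatrix(msa)
  n <- nrow(mat)
  if (n < 3L) stop("need at least 3 aligned rows")
  ids <- rownames(mat)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    if (sum(ok) < minUngapped)
      stop("pair (", ids[i], ", ", ids[j], ") shares only ", sum(ok),
           " ungapped columns (need ", minUngapped, ")")
    p <- mean(mat[i, ok] != mat[j, ok])
    if (p >= cap) {
      warning("pair (", ids[i], ", ", ids[j], ") is saturated (p = ",
              round(p, 3), "); capped at ", cap)
      p <- cap
    }
    d[i, j] <- d[j, i] <- -log(1 - p)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining (Saitou-Nei, Studier-Keppler Q-matrix).
#' Ties in the Q-matrix are broken by the smallest `(i, j)` index pair
#' in row-major order, so the construction is deterministic. Negative
#' branch-length estimates are clamped at zero. The result is unrooted
#' (a trifurcating root node in the `phylo` encoding). On additive
#' distances the generating topology is recovered exactly.
#'
#' @param D symmetric distance matrix with row/column names, `n >= 3`.
#' @return an `ape::phylo` tree.
#' @export
njTree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <-
      sprintf("t%d", seq_len(n))
  labels <- rownames(D)
  nodes <- labels                     # newick fragment per active node
  dm <- D
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(dm)
    Q <- (m - 2) * dm - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest (i, j), i < j, row-major on ties
    best <- c(NA_integer_, NA_integer_); bestQ <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
      if (Q[i, j] < bestQ - 1e-12) { bestQ <- Q[i, j]; best <- c(i, j) }
    i <- best[1L]; j <- best[2L]
    li <- dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dm[i, j] - li
    li <- max(0, li); lj <- max(0, lj)
    newick <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], li, nodes[j], lj)
    dnew <- (dm[i, ] + dm[j, ] - dm[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nodes <- c(nodes[keep], newick)
    rownames(dm) <- colnames(dm) <- NULL
  }
  la <- (dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2
  lb <- (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2
  lc <- (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", nodes[1], max(0, la),
                 nodes[2], max(0, lb), nodes[3], max(0, lc))
  ape::read.tree(text = txt)
}

# Nontrivial bipartitions of an unrooted tree as packed numeric keys
# over `leafOrder`; each split is canonicalized to the side NOT
# containing the first leaf of leafOrder.
.splitKeys <- function(tree, leafOrder) {
  memb <- .splitMembership(tree, leafOrder)
  if (!nrow(memb)) return(numeric(0))
  .packSplits(memb)
}

.splitMembership <- function(tree, leafOrder) {
  n <- length(leafOrder)
  pp <- ape::prop.part(tree)
  tipIdx <- match(tree$tip.label, leafOrder)
  rows <- list()
  for (k in seq_along(pp)) {
    side <- rep(FALSE, n)
    side[tipIdx[pp[[k]]]] <- TRUE
    sz <- sum(side)
    if (sz <= 1L || sz >= n - 1L) next
    if (side[1L]) side <- !side
    rows[[length(rows) + 1L]] <- side
  }
  if (!length(rows))
    return(matrix(logical(0), ncol = n))
  unique(do.call(rbind, rows))
}

.packSplits <- function(memb) {
  # n <= 52 keeps keys exact in doubles
  as.vector(memb %*% 2^(seq_len(ncol(memb)) - 1))
}

.rfFromKeys <- function(ka, kb) {
  length(ka) + length(kb) - 2L * length(intersect(ka, kb))
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the tree from the full alignment, then resamples alignment
#' columns with replacement `nReplicates` times, rebuilding distances
#' and the NJ tree each time; the support of each internal edge is the
#' percentage of replicates whose tree contains the same bipartition.
#' Supports are written into `node.label`. A zero-divergence alignment
#' (all rows identical) has no signal at all: the operation then returns
#' an unresolved star tree flagged with `attr(, "unresolved")`.
#'
#' @param msa `AAStringSet` or character matrix with >= 4 rows.
#' @param nReplicates number of bootstrap replicates (default 100).
#' @param seed integer seed; identical seeds give identical supports.
#' @return an `ape::phylo` with supports (percent) in `node.label`;
#'   the number of successful replicates is in `attr(, "nReplicates")`.
#' @export
bootstrapSupport <- function(msa, nReplicates = 100L, seed = 1L) {
  mat <- .msaMatrix(msa)
  if (nrow(mat) < 4L) stop("need at least 4 rows")
  D <- distanceMatrix(mat)
  if (max(D) == 0) {
    star <- ape::read.tree(text = paste0(
      "(", paste(rownames(mat), ":0", collapse = ","), ");"))
    attr(star, "unresolved") <- TRUE
    return(star)
  }
  tree <- njTree(D)
  leafOrder <- sort(rownames(mat))
  keys <- .splitKeys(tree, leafOrder)
  counts <- setNames(rep(0L, length(keys)), sprintf("%.0f", keys))
  nOk <- 0L
  .withSeed(seed, {
    for (b in seq_len(nReplicates)) {
      cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      Db <- tryCatch(suppressWarnings(distanceMatrix(mat[, cols,
                                                         drop = FALSE])),
                     error = function(e) NULL)
      if (is.null(Db)) next
      nOk <- nOk + 1L
      kb <- .splitKeys(njTree(Db), leafOrder)
      hit <- sprintf("%.0f", keys[keys %in% kb])
      counts[hit] <- counts[hit] + 1L
    }
  })
  support <- if (nOk > 0L) 100 * counts / nOk else counts * NA_real_
  # map supports onto internal nodes via each node's clade bipartition
  nt <- ape::Ntip(tree)
  pp <- ape::prop.part(tree)
  labs <- character(tree$Nnode)
  n <- length(leafOrder)
  tipIdx <- match(tree$tip.label, leafOrder)
  for (k in seq_along(pp)) {
    side <- rep(FALSE, n)
    side[tipIdx[pp[[k]]]] <- TRUE
    sz <- sum(side)
    if (sz <= 1L || sz >= n - 1L) { labs[k] <- ""; next }
    if (side[1L]) side <- !side
    key <- sprintf("%.0f", .packSplits(matrix(side, nrow = 1L)))
    labs[k] <- if (key %in% names(support))
      sprintf("%.0f", support[[key]]) else ""
  }
  tree$node.label <- labs
  attr(tree, "nReplicates") <- nOk
  tree
}

#' Assign a query leaf to a labeled clade
#'
#' Finds the smallest bipartition side that contains the query together
#' with references of exactly one label, and returns that label. When no
#' such side exists (the query sits among mixed labels), it falls back
#' to the label of the nearest labeled leaf by path length. Equidistant
#' or equally-sized conflicting alternatives are reported as a tie, not
#' silently resolved.
#'
#' @param tree an `ape::phylo`.
#' @param labels named character vector: reference leaf -> clade label.
#' @param query leaf id to place.
#' @return list with `label` (NA on a tie), `rule` ("monophyletic",
#'   "nearest", or "tie") and `detail`.
#' @export
assignClade <- function(tree, labels, query) {
  if (!query %in% tree$tip.label) stop("query leaf not in tree: ", query)
  labels <- labels[names(labels) %in% tree$tip.label &
                   names(labels) != query]
  if (length(unique(labels)) < 2L)
    stop("need at least 2 distinct reference labels among the leaves")
  leafOrder <- tree$tip.label
  memb <- .splitMembership(tree, leafOrder)
  qi <- match(query, leafOrder)
  ri <- match(names(labels), leafOrder)
  best <- NULL; bestSize <- Inf
  candidates <- list()
  for (k in seq_len(nrow(memb))) {
    for (side in list(memb[k, ], !memb[k, ])) {
      if (!side[qi]) next
      inside <- labels[side[ri]]
      if (!length(inside) || length(unique(inside)) != 1L) next
      candidates[[length(candidates) + 1L]] <-
        list(label = unique(inside), size = sum(side))
    }
  }
  if (length(candidates)) {
    sizes <- vapply(candidates, `[[`, 0, "size")
    labs <- vapply(candidates, `[[`, "", "label")
    minLabs <- unique(labs[sizes == min(sizes)])
    if (length(minLabs) == 1L)
      return(list(label = minLabs, rule = "monophyletic",
                  detail = sprintf("smallest pure side has %d leaves",
                                   as.integer(min(sizes)))))
    return(list(label = NA_character_, rule = "tie",
                detail = paste("equally small pure sides with labels:",
                               paste(minLabs, collapse = ", "))))
  }
  dm <- cophenetic(tree)
  dq <- dm[query, names(labels)]
  nearLabs <- unique(labels[dq == min(dq)])
  if (length(nearLabs) == 1L)
    return(list(label = unname(nearLabs), rule = "nearest",
                detail = sprintf("nearest labeled leaf at distance %.4g",
                                 min(dq))))
  list(label = NA_character_, rule = "tie",
       detail = paste("equidistant labels:",
                      paste(nearLabs, collapse = ", ")))
}

#' Permutation test of congruence between two trees
#'
#' Restricts both trees to their shared leaves, computes the
#' Robinson-Foulds bipartition distance, and compares it against a null
#' distribution obtained by permuting the leaf labels of the second
#' tree: `p = (1 + #{perm RF <= observed}) / (nPerm + 1)`. A small p
#' indicates the two gene trees are more congruent than label-shuffled
#' trees, the signature of co-evolving gene pairs.
#'
#' @param treeA,treeB `ape::phylo` trees sharing >= 4 leaf ids.
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed.
#' @return A [CongruenceResult-class] object.
#' @export
congruenceTest <- function(treeA, treeB, nPerm = 999L, seed = 1L) {
  shared <- intersect(treeA$tip.label, treeB$tip.label)
  if (length(shared) < 4L)
    stop("trees share only ", length(shared), " leaves (need >= 4)")
  tA <- ape::keep.tip(treeA, shared)
  tB <- ape::keep.tip(treeB, shared)
  leafOrder <- sort(shared)
  n <- length(shared)
  mA <- .splitMembership(tA, leafOrder)
  mB <- .splitMembership(tB, leafOrder)
  kA <- .packSplits(mA)
  rf <- .rfFromKeys(kA, .packSplits(mB))
  pow <- 2^(seq_len(n) - 1)
  count <- 0L
  .withSeed(seed, {
    for (b in seq_len(nPerm)) {
      perm <- sample.int(n)
      mp <- mB[, perm, drop = FALSE]
      flip <- mp[, 1L]
      mp[flip, ] <- !mp[flip, , drop = FALSE]
      kp <- as.vector(mp %*% pow)
      rfp <- .rfFromKeys(kA, kp)
      if (rfp <= rf) count <- count + 1L
    }
  })
  new("CongruenceResult", rfDistance = as.integer(rf),
      normalizedRF = rf / (2 * (n - 3)),
      pValue = (1 + count) / (nPerm + 1),
      nPermutations = as.integer(nPerm), nShared = as.integer(n),
      seed = as.integer(seed))
}
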