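# Independent brute-force oracles used to freeze expected values.

# Exhaustive small-parsimony: enumerate every internal labeling (vectorized
# over labelings). Supports a gain-count constraint, a fixed root state and an
# arbitrary 2x2 cost matrix. Independent of the package's DP code path.
bruteMinChanges <- function(tree, states, n_gains = NULL, root_state = NULL,
                            cost = NULL) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  internals <- seq(n_tip + 1L, n_node)
  k <- length(internals)
  st <- as.integer(states[tree$tip.label])
  n_lab <- 2L^k
  L <- matrix(0L, nrow = n_lab, ncol = n_node)
  L[, seq_len(n_tip)] <- matrix(st, nrow = n_lab, ncol = n_tip, byrow = TRUE)
  for (i in seq_len(k)) {
    L[, internals[i]] <- bitwAnd(bitwShiftR(seq_len(n_lab) - 1L, i - 1L), 1L)
  }
  keep <- rep(TRUE, n_lab)
  if (!is.null(root_state)) keep <- keep & L[, n_tip + 1L] == root_state
  P <- L[, tree$edge[, 1], drop = FALSE]
  C <- L[, tree$edge[, 2], drop = FALSE]
  if (!is.null(n_gains)) {
    keep <- keep & rowSums(P == 0L & C == 1L) == n_gains
  }
  if (!any(keep)) return(Inf)
  ch <- if (is.null(cost)) {
    rowSums(P != C)
  } else {
    rowSums(matrix(cost[cbind(as.vector(P) + 1L, as.vector(C) + 1L)],
                   nrow = n_lab))
  }
  min(ch[keep])
}

# Exhaustive 6-frame ORF scan written independently of longestOrf: for each
# frame, split into codons with substring arithmetic, break open stretches on
# stops using cumsum segmentation, and collect candidates per the rule
# "first start codon after a stop (or frame edge) through the next stop".
bruteLongestOrfLength <- function(seq, require_start = TRUE) {
  stops <- c("TAA", "TAG", "TGA")
  revcomp <- function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  best <- 0L
  for (strand_seq in c(seq, revcomp(seq))) {
    for (off in 0:2) {
      n_cod <- (nchar(strand_seq) - off) %/% 3
      if (n_cod < 1) next
      pos <- off + seq(1, by = 3, length.out = n_cod)
      codons <- substring(strand_seq, pos, pos + 2)
      seg <- cumsum(codons %in% stops)
      open <- !(codons %in% stops)
      for (segment in split(seq_along(codons)[open], seg[open])) {
        if (!length(segment)) next
        from <- if (require_start) {
          w <- which(codons[segment] == "ATG")
          if (!length(w)) next
          segment[w[1]]
        } else {
          segment[1]
        }
        best <- max(best, segment[length(segment)] - from + 1L)
      }
    }
  }
  best
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# Random rooted binary tree with binary tip states; occasionally collapsed to
# a multifurcating tree to exercise the generalized (polytomy) code path.
randomTreeStates <- function(n_tip, polytomy = FALSE) {
  tr <- ape::rtree(n_tip, rooted = TRUE)
  if (polytomy && n_tip > 3) {
    tr$edge.length[sample(length(tr$edge.length), 2)] <- 0
    tr <- ape::di2multi(tr, tol = 1e-8)
  }
  tr$edge.length <- NULL
  states <- stats::setNames(sample(0:1, n_tip, TRUE), tr$tip.label)
  list(tree = tr, states = states)
}
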