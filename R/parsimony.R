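# Small-parsimony routines for a binary C3 (0) / C4 (1) character on a fixed
# topology. Trees are ape "phylo" objects; tip states are named 0/1 vectors.

# children list indexed by node number (ape numbering: tips 1..n, root n+1)
childrenList <- function(tree) {
  n_node <- max(tree$edge)
  ch <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[i, 2])
  }
  ch
}

# post-order (children before parents) of internal+tip nodes
postorderNodes <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  ch <- childrenList(tree)
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(v, out)
    stack <- c(stack, ch[[v]])
  }
  out
}

checkStates <- function(tree, states) {
  if (is.null(names(states))) stop("states must be named by leaf label")
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing)) {
    stop("leaf missing from states: ", paste(missing, collapse = ", "))
  }
  st <- as.integer(states[tree$tip.label])
  if (!all(st %in% c(0L, 1L))) stop("states must be binary 0 (C3) / 1 (C4)")
  stats::setNames(st, tree$tip.label)
}

#' Minimum character changes by Fitch parsimony
#'
#' Computes the minimum number of C3/C4 state changes on the tree (generalized
#' Fitch, so multifurcations are handled without resolving them) plus one
#' optimal internal labeling with its gain (C3 to C4) / loss decomposition.
#' The witness root state is chosen to minimize changes; on a tie the C3 root
#' is taken and `root_tie` flagged. The change count itself is invariant to
#' rooting; the gain/loss split is only meaningful on a rooted tree.
#'
#' @param tree An [ape::phylo] tree.
#' @param states Named vector (leaf label -> 0/1), 1 = C4.
#' @return Named list: `min_changes`, `n_gains`, `n_losses`, `labeling`
#'   (named 0/1 vector over all nodes; internal nodes labeled
#'   `node<k>` unless the tree has node labels), `root_tie`.
#' @examples
#' tr <- readNewick("((A,B),(C,D));")
#' fitchMinChanges(tr, c(A = 1, B = 1, C = 0, D = 0))
#' @export
fitchMinChanges <- function(tree, states) {
  st <- checkStates(tree, states)
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  ch <- childrenList(tree)
  po <- postorderNodes(tree)
  # Sankoff-style DP with unit costs gives generalized Fitch on polytomies
  cost <- matrix(Inf, nrow = n_node, ncol = 2)
  for (v in po) {
    if (v <= n_tip) {
      cost[v, ] <- c(Inf, Inf)
      cost[v, st[v] + 1L] <- 0
    } else {
      for (s in 0:1) {
        tot <- 0
        for (c in ch[[v]]) {
          tot <- tot + min(cost[c, 1] + (s != 0L), cost[c, 2] + (s != 1L))
        }
        cost[v, s + 1L] <- tot
      }
    }
  }
  root <- n_tip + 1L
  min_changes <- min(cost[root, ])
  root_tie <- cost[root, 1] == cost[root, 2]
  # traceback: prefer C3 (0) on ties
  lab <- integer(n_node)
  pre <- rev(po)
  lab[root] <- if (cost[root, 1] <= cost[root, 2]) 0L else 1L
  for (v in pre) {
    if (v == root) next
    # parent already labeled when we reach v (preorder)
    p <- tree$edge[match(v, tree$edge[, 2]), 1]
    ps <- lab[p]
    pick <- c(cost[v, 1] + (ps != 0L), cost[v, 2] + (ps != 1L))
    lab[v] <- if (pick[1] <= pick[2]) 0L else 1L
  }
  node_names <- c(tree$tip.label,
                  if (!is.null(tree$node.label) &&
                      length(tree$node.label) == n_node - n_tip &&
                      all(nzchar(tree$node.label))) tree$node.label
                  else paste0("node", seq_len(n_node - n_tip) + n_tip))
  names(lab) <- node_names
  parent_state <- lab[tree$edge[, 1]]
  child_state <- lab[tree$edge[, 2]]
  n_gains <- sum(parent_state == 0L & child_state == 1L)
  n_losses <- sum(parent_state == 1L & child_state == 0L)
  list(min_changes = as.integer(min_changes), n_gains = n_gains,
       n_losses = n_losses, labeling = lab, root_tie = root_tie)
}

#' Minimum changes constrained to a fixed number of gains
#'
#' Minimum total state changes among internal labelings whose number of
#' C3-to-C4 edges (gains) equals `n_gains`, by dynamic programming over
#' (node, state, gains-used). Reproduces scenario comparisons such as "one
#' origin plus reversions" (n_gains = 1) against independent origins.
#'
#' @inheritParams fitchMinChanges
#' @param n_gains Required number of 0 to 1 edges.
#' @param root_state Ancestral state at the root: 0 (default, the C3
#'   ancestral condition — so with any C4 tip, `n_gains = 0` is infeasible),
#'   1, or `NULL` to leave the root free.
#' @return Named list: `feasible`, `min_changes`, `n_gains`, `n_losses`,
#'   `labeling` (NULL when infeasible).
#' @examples
#' tr <- readNewick("((A,B),(C,D));")
#' constrainedMinChanges(tr, c(A = 1, B = 1, C = 0, D = 0), n_gains = 1)
#' @export
constrainedMinChanges <- function(tree, states, n_gains, root_state = 0) {
  if (n_gains < 0) stop("n_gains must be non-negative")
  st <- checkStates(tree, states)
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  ch <- childrenList(tree)
  po <- postorderNodes(tree)
  gmax <- n_gains
  # cost[[v]][s+1, g+1]: min changes in subtree of v given v has state s and
  # the subtree (edges below v) contains exactly g gains
  cost <- vector("list", n_node)
  for (v in po) {
    m <- matrix(Inf, nrow = 2, ncol = gmax + 1L)
    if (v <= n_tip) {
      m[st[v] + 1L, 1L] <- 0
    } else {
      for (s in 0:1) {
        # convolve children over gain budget
        acc <- c(0, rep(Inf, gmax))    # acc[g+1]: best over processed children
        for (c in ch[[v]]) {
          # edge cost and gain contribution for child state t under parent s
          opt <- matrix(Inf, nrow = 2, ncol = gmax + 1L)  # t, gains in child branch+subtree
          for (t in 0:1) {
            dg <- as.integer(s == 0L && t == 1L)
            chg <- as.integer(s != t)
            for (g in 0:gmax) {
              if (g + dg <= gmax) {
                opt[t + 1L, g + dg + 1L] <- min(opt[t + 1L, g + dg + 1L],
                                                cost[[c]][t + 1L, g + 1L] + chg)
              }
            }
          }
          best_child <- apply(opt, 2, min)   # over child state t
          newacc <- rep(Inf, gmax + 1L)
          for (g1 in 0:gmax) {
            if (!is.finite(acc[g1 + 1L])) next
            for (g2 in 0:(gmax - g1)) {
              if (!is.finite(best_child[g2 + 1L])) next
              newacc[g1 + g2 + 1L] <- min(newacc[g1 + g2 + 1L],
                                          acc[g1 + 1L] + best_child[g2 + 1L])
            }
          }
          acc <- newacc
        }
        m[s + 1L, ] <- acc
      }
    }
    cost[[v]] <- m
  }
  root <- n_tip + 1L
  best <- if (is.null(root_state)) {
    min(cost[[root]][, gmax + 1L])
  } else {
    cost[[root]][root_state + 1L, gmax + 1L]
  }
  if (!is.finite(best)) {
    return(list(feasible = FALSE, min_changes = NA_integer_,
                n_gains = n_gains, n_losses = NA_integer_, labeling = NULL))
  }
  list(feasible = TRUE, min_changes = as.integer(best), n_gains = n_gains,
       n_losses = as.integer(best) - n_gains, labeling = NULL)
}

#' Sankoff small parsimony under an arbitrary cost matrix
#'
#' Standard dynamic program over the tree: the cost of labeling node v with
#' state s is the sum over children of the minimum of (child cost + transition
#' cost). With unit off-diagonal costs this equals the Fitch change count.
#'
#' @inheritParams fitchMinChanges
#' @param cost_matrix Square non-negative matrix, `cost_matrix[i, j]` = cost
#'   of an i-1 to j-1 state change along an edge (2 x 2 for the binary
#'   C3/C4 character).
#' @return Minimum total cost (numeric).
#' @export
sankoffMinCost <- function(tree, states, cost_matrix) {
  if (!is.matrix(cost_matrix) || nrow(cost_matrix) != ncol(cost_matrix)) {
    stop("cost matrix must be square")
  }
  if (any(cost_matrix < 0)) stop("cost matrix must be non-negative")
  st <- checkStates(tree, states)
  k <- nrow(cost_matrix)
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  ch <- childrenList(tree)
  po <- postorderNodes(tree)
  cost <- matrix(Inf, nrow = n_node, ncol = k)
  for (v in po) {
    if (v <= n_tip) {
      cost[v, ] <- Inf
      cost[v, st[v] + 1L] <- 0
    } else {
      for (s in seq_len(k)) {
        tot <- 0
        for (c in ch[[v]]) {
          tot <- tot + min(cost[c, ] + cost_matrix[s, ])
        }
        cost[v, s] <- tot
      }
    }
  }
  min(cost[n_tip + 1L, ])
}
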