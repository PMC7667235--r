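#' Read a newick tree
#'
#' Wraps [ape::read.tree()] with validation: unbalanced parentheses, trailing
#' garbage and duplicate leaf labels are errors rather than silently accepted.
#' Both rooted trees and unrooted trees (basal multifurcation) are supported;
#' branch lengths are optional.
#'
#' @param x Path to a newick file, or a newick string (detected by the
#'   presence of `(` or `;`).
#' @return An [ape::phylo] tree.
#' @examples
#' tr <- readNewick("((A,B),C);")
#' tr$tip.label
#' @export
readNewick <- function(x) {
  txt <- if (grepl("[(;]", x[1])) paste(x, collapse = "") else {
    if (!file.exists(x)) stop("file not found: ", x)
    paste(readLines(x, warn = FALSE), collapse = "")
  }
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) stop("unbalanced parentheses in newick string")
  if (grepl(",\\s*[),]", txt) || grepl("\\(\\s*[,)]", txt)) {
    stop("malformed newick: empty clade element")
  }
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup)) stop("duplicate leaf label(s): ", paste(unique(dup), collapse = ", "))
  tr
}

#' Write a tree as newick
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path; if `NULL` the newick string is returned.
#' @return The path (invisibly) or the newick string.
#' @export
writeNewick <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(path)
}
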