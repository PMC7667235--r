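#' @import methods
#' @importFrom stats lm coef sd rnorm runif qnorm pnorm rpois t.test aov setNames
#' @importFrom utils read.delim write.table head
NULL

#' Partitioned supermatrix of concatenated gene alignments
#'
#' A `PartitionedMatrix` bundles an alignment (all rows the same width) with an
#' ordered set of contiguous, non-overlapping column partitions that cover the
#' matrix exactly. One partition per concatenated gene is the typical use.
#' Partition coordinates are 1-based inclusive, the convention of the partition
#' files consumed by maximum-likelihood tree software; internal column
#' arithmetic is done 0-based half-open and converted only at the boundary.
#'
#' @slot alignment An [Biostrings::XStringSet] in which every sequence has the
#'   same width (the aligned supermatrix rows, one per taxon).
#' @slot partitions A `data.frame` with columns `name`, `start`, `end`,
#'   `datatype`, one row per partition in matrix order.
#'
#' @seealso [concatenateAlignments()], [writeSupermatrix()]
#' @export
setClass("PartitionedMatrix",
  representation(alignment = "XStringSet", partitions = "data.frame")
)

setValidity("PartitionedMatrix", function(object) {
  aln <- object@alignment
  pt <- object@partitions
  msgs <- character(0)
  w <- unique(Biostrings::width(aln))
  if (length(w) > 1) {
    return("all alignment rows must have identical width")
  }
  ncol <- if (length(w)) w else 0L
  need <- c("name", "start", "end", "datatype")
  if (!all(need %in% names(pt))) {
    return(sprintf("partitions must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(pt) == 0L) {
    if (ncol > 0) msgs <- c(msgs, "non-empty alignment requires partitions")
  } else {
    if (pt$start[1] != 1L) msgs <- c(msgs, "first partition must start at column 1")
    if (pt$end[nrow(pt)] != ncol) {
      msgs <- c(msgs, sprintf("partitions must cover all %d columns", ncol))
    }
    if (any(pt$end < pt$start)) msgs <- c(msgs, "partition end < start")
    if (nrow(pt) > 1L && !all(pt$start[-1] == pt$end[-nrow(pt)] + 1L)) {
      msgs <- c(msgs, "partitions must be contiguous and non-overlapping")
    }
  }
  if (anyDuplicated(names(aln))) msgs <- c(msgs, "duplicate taxon names")
  if (length(msgs)) msgs else TRUE
})

#' CO2-response (A/Ci) curve for one leaf
#'
#' Stepped gas-exchange measurements: at each ambient CO2 (`ca`) step the
#' intercellular CO2 (`ci`), net assimilation rate (`a`) and stomatal
#' conductance (`gs`) recorded at steady state. Units follow gas-exchange
#' convention: `ca`, `ci` in umol mol-1; `a` in umol m-2 s-1; `gs` in
#' mol m-2 s-1.
#'
#' @slot steps `data.frame` with columns `ca`, `ci`, `a`, `gs`, one row per
#'   CO2 step, in measurement order.
#' @slot leafT Leaf temperature, degrees C.
#' @slot pfd Photon flux density, umol m-2 s-1.
#'
#' @seealso [aciCurve()], [fitInitialSlope()], [pointMetrics()]
#' @export
setClass("AciCurve",
  representation(steps = "data.frame", leafT = "numeric", pfd = "numeric")
)

setValidity("AciCurve", function(object) {
  st <- object@steps
  msgs <- character(0)
  need <- c("ca", "ci", "a", "gs")
  if (!all(need %in% names(st))) {
    return(sprintf("steps must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(st) < 4L) msgs <- c(msgs, "need at least 4 CO2 steps")
  if (any(st$ci >= st$ca)) msgs <- c(msgs, "ci must be < ca at every step")
  if (length(msgs)) msgs else TRUE
})

#' Orthogroup: per-species sequence membership with optional alignment
#'
#' @slot ogId Orthogroup identifier.
#' @slot members Named list, species -> character vector of sequence ids
#'   (possibly empty).
#' @slot alignment An [Biostrings::AAStringSet] protein alignment whose names
#'   are sequence ids, or an empty set until attached.
#'
#' @seealso [readOrthogroupTable()], [filterOrthogroups()]
#' @export
setClass("Orthogroup",
  representation(ogId = "character", members = "list", alignment = "AAStringSet")
)

setValidity("Orthogroup", function(object) {
  msgs <- character(0)
  if (length(object@ogId) != 1L) msgs <- c(msgs, "ogId must be a single string")
  if (is.null(names(object@members)) && length(object@members)) {
    msgs <- c(msgs, "members must be named by species")
  }
  if (length(object@alignment)) {
    ids <- unlist(object@members, use.names = FALSE)
    bad <- setdiff(names(object@alignment), ids)
    if (length(bad)) {
      msgs <- c(msgs, sprintf("aligned sequence(s) not in members: %s",
                              paste(head(bad, 3), collapse = ", ")))
    }
    if (length(unique(Biostrings::width(object@alignment))) > 1) {
      msgs <- c(msgs, "alignment rows must have equal width")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn PartitionedMatrix-class Construct a partitioned matrix.
#' @param alignment Equal-width [Biostrings::XStringSet].
#' @param partitions `data.frame` with `name`, `start`, `end`, `datatype`.
#' @export
PartitionedMatrix <- function(alignment, partitions) {
  partitions$start <- as.integer(partitions$start)
  partitions$end <- as.integer(partitions$end)
  if (is.null(partitions$datatype)) partitions$datatype <- "DNA"
  new("PartitionedMatrix", alignment = alignment,
      partitions = as.data.frame(partitions, stringsAsFactors = FALSE))
}

#' Construct an A/Ci curve
#'
#' @param ca,ci,a,gs Numeric vectors of equal length: ambient CO2, intercellular
#'   CO2 (umol mol-1), net assimilation (umol m-2 s-1), stomatal conductance
#'   (mol m-2 s-1).
#' @param leafT Leaf temperature (degrees C).
#' @param pfd Photon flux density (umol m-2 s-1).
#' @return An [AciCurve-class] object.
#' @examples
#' crv <- aciCurve(ca = c(50, 100, 400, 1200), ci = c(20, 40, 130, 400),
#'                 a = c(1, 3, 22, 31), gs = c(0.1, 0.1, 0.12, 0.06))
#' aciSteps(crv)
#' @export
aciCurve <- function(ca, ci, a, gs = 1.6 * pmax(a, 0.01) / (ca - ci),
                     leafT = 30, pfd = 1800) {
  new("AciCurve",
      steps = data.frame(ca = ca, ci = ci, a = a, gs = gs),
      leafT = leafT, pfd = pfd)
}

#' @describeIn Orthogroup-class Construct an orthogroup.
#' @param ogId Orthogroup id.
#' @param members Named list species -> character vector of sequence ids.
#' @param alignment Optional protein alignment ([Biostrings::AAStringSet]).
#' @export
Orthogroup <- function(ogId, members, alignment = Biostrings::AAStringSet()) {
  new("Orthogroup", ogId = ogId, members = members, alignment = alignment)
}

# ---- accessors ----

#' @rdname PartitionedMatrix-class
#' @param object,x A `PartitionedMatrix`.
#' @export
setGeneric("partitions", function(x) standardGeneric("partitions"))

#' @rdname PartitionedMatrix-class
#' @export
setMethod("partitions", "PartitionedMatrix", function(x) x@partitions)

#' @rdname PartitionedMatrix-class
#' @export
setGeneric("alignment", function(x) standardGeneric("alignment"))

#' @rdname PartitionedMatrix-class
#' @export
setMethod("alignment", "PartitionedMatrix", function(x) x@alignment)

#' @rdname Orthogroup-class
#' @export
setMethod("alignment", "Orthogroup", function(x) x@alignment)

#' @rdname AciCurve-class
#' @param x An `AciCurve`.
#' @export
setGeneric("aciSteps", function(x) standardGeneric("aciSteps"))

#' @rdname AciCurve-class
#' @export
setMethod("aciSteps", "AciCurve", function(x) x@steps)

#' @rdname Orthogroup-class
#' @param x An `Orthogroup`.
#' @export
setGeneric("ogId", function(x) standardGeneric("ogId"))

#' @rdname Orthogroup-class
#' @export
setMethod("ogId", "Orthogroup", function(x) x@ogId)

#' @rdname Orthogroup-class
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname Orthogroup-class
#' @export
setMethod("members", "Orthogroup", function(x) x@members)

#' Attach or replace an orthogroup's protein alignment
#'
#' @param x An `Orthogroup`.
#' @param value An [Biostrings::AAStringSet] whose names are member sequence ids.
#' @rdname Orthogroup-class
#' @export
setGeneric("alignment<-", function(x, value) standardGeneric("alignment<-"))

#' @rdname Orthogroup-class
#' @export
setMethod("alignment<-", "Orthogroup", function(x, value) {
  x@alignment <- value
  validObject(x)
  x
})

setMethod("show", "PartitionedMatrix", function(object) {
  w <- if (length(object@alignment)) Biostrings::width(object@alignment)[1] else 0L
  cat(sprintf("PartitionedMatrix: %d taxa x %d columns, %d partition(s)\n",
              length(object@alignment), w, nrow(object@partitions)))
  if (nrow(object@partitions)) {
    p <- object@partitions
    cat(sprintf("  %s [%d-%d]%s\n", head(p$name, 5), head(p$start, 5),
                head(p$end, 5), ""), sep = "")
    if (nrow(p) > 5) cat(sprintf("  ... and %d more\n", nrow(p) - 5L))
  }
})

setMethod("show", "AciCurve", function(object) {
  st <- object@steps
  cat(sprintf("AciCurve: %d steps, Ca %g-%g umol mol-1, leaf %g C, PFD %g\n",
              nrow(st), min(st$ca), max(st$ca), object@leafT, object@pfd))
})

setMethod("show", "Orthogroup", function(object) {
  n_sp <- sum(lengths(object@members) > 0)
  cat(sprintf("Orthogroup %s: %d species present, %d sequences%s\n",
              object@ogId, n_sp, sum(lengths(object@members)),
              if (length(object@alignment))
                sprintf(", aligned (%d cols)", Biostrings::width(object@alignment)[1])
              else ""))
})
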