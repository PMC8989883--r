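#' @include AllClasses.R
NULL

#' Accessors for pipeline containers
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x a paleoshuffle S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
#' @rdname accessors
#' @export
setMethod("geneTable", "GenomeLayout", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))
#' @rdname accessors
#' @export
setMethod("speciesId", "GenomeLayout", function(x) x@speciesId)

#' @rdname accessors
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))
#' @rdname accessors
#' @export
setMethod("chromNames", "GenomeLayout", function(x) unique(x@genes$chrom))
#' @rdname accessors
#' @export
setMethod("chromNames", "SegmentPainting", function(x) names(x@chromLengths))

#' @rdname accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))
#' @rdname accessors
#' @export
setMethod("nGenes", "GenomeLayout", function(x) nrow(x@genes))

#' @rdname accessors
#' @export
setGeneric("blockTable", function(x) standardGeneric("blockTable"))
#' @rdname accessors
#' @export
setMethod("blockTable", "CollinearBlockSet", function(x) x@blocks)

#' @rdname accessors
#' @export
setGeneric("anchorTable", function(x) standardGeneric("anchorTable"))
#' @rdname accessors
#' @export
setMethod("anchorTable", "CollinearBlockSet", function(x) x@anchors)

#' @rdname accessors
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))
#' @rdname accessors
#' @export
setMethod("segmentTable", "SegmentPainting", function(x) x@segments)

#' @rdname accessors
#' @export
setGeneric("binTable", function(x) standardGeneric("binTable"))
#' @rdname accessors
#' @export
setMethod("binTable", "ContactMatrix", function(x) x@bins)

#' @rdname accessors
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))
#' @rdname accessors
#' @export
setMethod("contactCounts", "ContactMatrix", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("resolutionBp", function(x) standardGeneric("resolutionBp"))
#' @rdname accessors
#' @export
setMethod("resolutionBp", "ContactMatrix", function(x) x@resolution)

#' @rdname accessors
#' @export
setGeneric("isBalanced", function(x) standardGeneric("isBalanced"))
#' @rdname accessors
#' @export
setMethod("isBalanced", "ContactMatrix", function(x) x@balanced)

#' @rdname accessors
#' @export
setGeneric("biasVector", function(x) standardGeneric("biasVector"))
#' @rdname accessors
#' @export
setMethod("biasVector", "ContactMatrix", function(x) x@bias)

#' @rdname accessors
#' @export
setGeneric("mixtureComponents", function(x) standardGeneric("mixtureComponents"))
#' @rdname accessors
#' @export
setMethod("mixtureComponents", "KsMixture", function(x) x@components)

#' @rdname accessors
#' @export
setGeneric("lineageTruth", function(x) standardGeneric("lineageTruth"))
#' @rdname accessors
#' @export
setMethod("lineageTruth", "TruthSet", function(x) x@lineage)

#' @rdname accessors
#' @export
setGeneric("junctionTruth", function(x) standardGeneric("junctionTruth"))
#' @rdname accessors
#' @export
setMethod("junctionTruth", "TruthSet", function(x) x@junctions)

#' @rdname accessors
#' @export
setGeneric("retentionTruth", function(x) standardGeneric("retentionTruth"))
#' @rdname accessors
#' @export
setMethod("retentionTruth", "TruthSet", function(x) x@retention)

#' Number of chromosomes in a layout
#' @param x a GenomeLayout.
#' @return integer chromosome count.
#' @export
nChromosomes <- function(x) length(chromNames(x))

setMethod("show", "GenomeLayout", function(object) {
  g <- object@genes
  cat("GenomeLayout", object@speciesId,
      if (!is.na(object@subgenome)) paste0("(subgenome ", object@subgenome, ")") else "",
      "\n  ", length(unique(g$chrom)), "chromosomes,", nrow(g), "genes\n")
})

setMethod("show", "CollinearBlockSet", function(object) {
  cat("CollinearBlockSet:", nrow(object@blocks), "blocks,",
      nrow(object@anchors), "anchors\n")
})

setMethod("show", "SegmentPainting", function(object) {
  cat("SegmentPainting:", nrow(object@segments), "segments on",
      length(object@chromLengths), "chromosomes\n")
})

setMethod("show", "ContactMatrix", function(object) {
  cat("ContactMatrix:", nrow(object@counts), "x", ncol(object@counts),
      "bins at", object@resolution, "bp;",
      if (object@balanced) "balanced" else "raw", "\n")
})

setMethod("show", "KsMixture", function(object) {
  cat("KsMixture: k =", object@k, " BIC =", round(object@bic, 2), "\n")
  print(round(object@components, 4))
})

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:", nrow(object@lineage), "gene lineage labels,",
      nrow(object@junctions), "junctions,",
      nrow(object@retention), "retained copies\n")
})
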