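#' @import methods
NULL

#' GenomeLayout: ordered gene models for one (sub)genome
#'
#' The coordinate substrate of all pipeline stages. Genes are stored as a
#' data.frame sorted by (chrom, start); the 0-based \code{rank} of a gene
#' along its chromosome is the unit of all collinearity and gap
#' computations, base pairs appear only at I/O boundaries.
#'
#' @slot speciesId single character identifier.
#' @slot subgenome optional subgenome label ("A", "B" or NA).
#' @slot genes data.frame with columns gene_id, chrom, start, end, strand,
#'   family_id, rank. Coordinates are 1-based inclusive.
#' @export
setClass("GenomeLayout",
  representation(speciesId = "character", subgenome = "character",
                 genes = "data.frame"),
  prototype(speciesId = "genome", subgenome = NA_character_))

setValidity("GenomeLayout", function(object) {
  g <- object@genes
  need <- c("gene_id", "chrom", "start", "end", "strand", "family_id", "rank")
  if (!all(need %in% names(g)))
    return(paste("genes table must have columns:", paste(need, collapse = ", ")))
  if (nrow(g) == 0L) return(TRUE)
  if (anyDuplicated(g$gene_id)) return("duplicate gene_id in layout")
  if (any(g$start > g$end)) return("gene with start > end")
  if (!all(g$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  for (ch in unique(g$chrom)) {
    r <- g$rank[g$chrom == ch]
    if (!identical(sort(r), seq_along(r) - 1L))
      return(sprintf("ranks on chromosome %s are not consecutive 0..n-1", ch))
    s <- g$start[g$chrom == ch]
    if (is.unsorted(s[order(r)])) return(sprintf("ranks on %s not ordered by start", ch))
  }
  TRUE
})

#' CollinearBlockSet: chained anchor pairs between chromosomes
#'
#' Container for collinear blocks detected between two layouts. Each block
#' is a maximal monotone chain of anchor gene pairs obeying the rank-gap
#' constraint on both genomes.
#'
#' @slot blocks data.frame: block_id, chrom_a, chrom_b, orientation,
#'   n_anchors, start_a, end_a, start_b, end_b (0-based inclusive rank
#'   bounds), median_ks.
#' @slot anchors data.frame: block_id, gene_a, gene_b, chrom_a, chrom_b,
#'   rank_a, rank_b, similarity.
#' @export
setClass("CollinearBlockSet",
  representation(blocks = "data.frame", anchors = "data.frame"))

setValidity("CollinearBlockSet", function(object) {
  b <- object@blocks; a <- object@anchors
  if (nrow(b) && anyDuplicated(b$block_id)) return("duplicate block_id")
  if (nrow(a) && !all(a$block_id %in% b$block_id))
    return("anchor references unknown block_id")
  # monotonicity + gap invariants are asserted at construction time
  TRUE
})

#' SegmentPainting: extant chromosomes decomposed into ancestral segments
#'
#' @slot segments data.frame: segment_id, chrom, start_rank, end_rank
#'   (0-based half-open gene-rank span on the extant chromosome), origin
#'   (ancestral chromosome), orient, anc_start, anc_end (half-open ancestral
#'   rank span), n_genes, block_id, and optionally unit (beta-pair unit id),
#'   gamma_class, side and class label once copy labels are resolved.
#' @slot chromLengths named integer vector: genes per extant chromosome.
#' @export
setClass("SegmentPainting",
  representation(segments = "data.frame", chromLengths = "integer"))

setValidity("SegmentPainting", function(object) {
  s <- object@segments
  if (nrow(s) == 0L) return(TRUE)
  if (any(s$start_rank >= s$end_rank)) return("empty or inverted segment span")
  for (ch in unique(s$chrom)) {
    x <- s[s$chrom == ch, , drop = FALSE]
    x <- x[order(x$start_rank), , drop = FALSE]
    if (nrow(x) > 1L && any(x$start_rank[-1L] < x$end_rank[-nrow(x)]))
      return(sprintf("overlapping segments on chromosome %s", ch))
  }
  TRUE
})

#' ContactMatrix: binned symmetric Hi-C interaction matrix
#'
#' @slot counts symmetric numeric matrix (raw or balanced contact counts;
#'   masked bins are NA after balancing).
#' @slot resolution bin size in bp.
#' @slot bins data.frame: chrom, start, end (0-based half-open genomic
#'   windows), one row per matrix row.
#' @slot balanced logical flag.
#' @slot bias per-bin multiplicative bias vector (length 0 until balanced).
#' @export
setClass("ContactMatrix",
  representation(counts = "matrix", resolution = "numeric",
                 bins = "data.frame", balanced = "logical",
                 bias = "numeric"),
  prototype(balanced = FALSE, bias = numeric(0)))

setValidity("ContactMatrix", function(object) {
  m <- object@counts
  if (nrow(m) != ncol(m)) return("counts must be square")
  if (nrow(object@bins) != nrow(m)) return("bins table does not match matrix dimension")
  if (!all(c("chrom", "start", "end") %in% names(object@bins)))
    return("bins needs chrom, start, end")
  d <- max(abs(m - t(m)), na.rm = TRUE)
  if (is.finite(d) && d > 1e-9 * max(1, max(abs(m), na.rm = TRUE)))
    return("counts matrix is not symmetric")
  TRUE
})

#' KsMixture: Gaussian mixture fitted to a Ks distribution
#'
#' @slot components data.frame with columns weight, mean, sd (ordered by
#'   mean).
#' @slot k number of components.
#' @slot bic BIC of the selected model.
#' @slot logLik log-likelihood at convergence.
#' @slot range numeric(2), the Ks fit range.
#' @export
setClass("KsMixture",
  representation(components = "data.frame", k = "integer", bic = "numeric",
                 logLik = "numeric", range = "numeric"))

setValidity("KsMixture", function(object) {
  cmp <- object@components
  if (!all(c("weight", "mean", "sd") %in% names(cmp)))
    return("components needs weight, mean, sd")
  if (abs(sum(cmp$weight) - 1) > 1e-6) return("weights must sum to 1")
  if (any(cmp$sd <= 0)) return("component sd must be positive")
  if (is.unsorted(cmp$mean)) return("components must be ordered by mean")
  TRUE
})

#' TruthSet: generator-side ground truth
#'
#' Every quantity the synthetic-data generator implants, against which the
#' analysis modules are scored.
#'
#' @slot lineage data.frame: gene_id, locus, eu (ancestral chromosome),
#'   gamma (A/B/C), beta (a/b), chrom, rank.
#' @slot junctions data.frame: layer, chrom, pos (rank of the first gene
#'   right of the junction), left, right (origin class labels).
#' @slot retention data.frame: locus, class (e.g. "Eu2:Ba"), gene_id —
#'   one row per retained copy.
#' @slot ksExpected named numeric: expected observed median Ks per WGD
#'   layer in the final dataset.
#' @slot events list of rearrangement/event records.
#' @slot extra list: triad truth, compartment truth, TAD truth,
#'   methylation truth, intermediate layouts, etc.
#' @export
setClass("TruthSet",
  representation(lineage = "data.frame", junctions = "data.frame",
                 retention = "data.frame", ksExpected = "numeric",
                 events = "list", extra = "list"),
  prototype(ksExpected = numeric(0), events = list(), extra = list()))
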