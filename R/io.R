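## Readers/writers for all external formats. Coordinate contract: 1-based
## inclusive in GFF3, 0-based half-open in BED and in all internal bin
## indices.

#' Read gene models from GFF3 into a GenomeLayout
#'
#' @param path GFF3 file.
#' @param feature feature type to keep (default "gene").
#' @param speciesId species identifier for the layout.
#' @return a \linkS4class{GenomeLayout} with genes sorted by (chrom, start)
#'   and 0-based ranks assigned; 1-based inclusive coordinates preserved.
#' @export
readGeneModels <- function(path, feature = "gene", speciesId = "genome") {
  if (file.size(path) == 0) {
    warning("empty GFF3 file ", path, "; empty layout")
    psLog("read_gene_models", file = basename(path), genes = 0)
    return(newGenomeLayout(data.frame(), speciesId = speciesId))
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  gr <- gr[gr$type == feature]
  if (length(gr) == 0L) {
    psLog("read_gene_models", file = basename(path), genes = 0)
    warning("no '", feature, "' features in ", path, "; empty layout")
    return(newGenomeLayout(data.frame(), speciesId = speciesId))
  }
  ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
  if (is.null(ids) || anyNA(ids)) stop("GFF3 features lack ID attributes")
  if (anyDuplicated(ids)) stop("duplicate gene_id in ", path, ": ",
                               ids[duplicated(ids)][1])
  fam <- if (!is.null(gr$family_id)) gr$family_id else ids
  genes <- data.frame(gene_id = as.character(ids),
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
                      family_id = as.character(fam),
                      stringsAsFactors = FALSE)
  out <- newGenomeLayout(genes, speciesId = speciesId)
  psLog("read_gene_models", file = basename(path), genes = nrow(genes))
  out
}

#' Write a GenomeLayout as GFF3
#'
#' @param layout a GenomeLayout.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGeneModels <- function(layout, path) {
  g <- geneTable(layout)
  gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                               strand = g$strand)
  gr$type <- "gene"
  gr$source <- "paleoshuffle"
  gr$ID <- g$gene_id
  gr$family_id <- g$family_id
  rtracklayer::export(gr, path, format = "gff3")
  psLog("write_gene_models", file = basename(path), genes = nrow(g))
  invisible(path)
}

#' Read a 12-column (BLAST outfmt 6 dialect) homology table
#'
#' Columns: query, subject, pct_identity, aln_len, mismatches, gapopen,
#' qstart, qend, sstart, send, evalue, bitscore. Extra columns are ignored
#' with a warning. Records with evalue above \code{max_evalue} are dropped
#' and the dropped count logged.
#'
#' @param path tab/whitespace-delimited file.
#' @param max_evalue e-value cutoff (default 1e-5).
#' @return data.frame: query, subject, pct_identity, evalue, bitscore.
#' @export
readHomologyTable <- function(path, max_evalue = 1e-5) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(raw) < 12) stop("homology table has ", ncol(raw),
                           " columns; 12 (outfmt 6) required")
  if (ncol(raw) > 12) warning("homology table has extra columns; ignoring them")
  ev <- suppressWarnings(as.numeric(raw[[11]]))
  if (anyNA(ev)) stop("non-numeric evalue at data row ", which(is.na(ev))[1])
  rec <- data.frame(query = as.character(raw[[1]]),
                    subject = as.character(raw[[2]]),
                    pct_identity = as.numeric(raw[[3]]),
                    evalue = ev,
                    bitscore = as.numeric(raw[[12]]),
                    stringsAsFactors = FALSE)
  keep <- rec$evalue <= max_evalue
  psLog("read_homology_table", file = basename(path), kept = sum(keep),
        dropped = sum(!keep))
  rec[keep, , drop = FALSE]
}

#' Write homology records as a 12-column outfmt-6 style table
#'
#' @param records data.frame with query, subject, pct_identity, evalue,
#'   bitscore (other outfmt-6 columns are filled with placeholders).
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeHomologyTable <- function(records, path) {
  n <- nrow(records)
  tab <- data.frame(records$query, records$subject,
                    formatC(records$pct_identity, format = "f", digits = 2),
                    300L, 0L, 0L, 1L, 300L, 1L, 300L,
                    formatC(records$evalue, format = "e", digits = 2),
                    formatC(records$bitscore, format = "f", digits = 1))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  psLog("write_homology_table", file = basename(path), records = n)
  invisible(path)
}

# Build the bin table for a chromosome-size map at a given resolution.
makeBins <- function(chrom_sizes, resolution) {
  do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    n <- ceiling(chrom_sizes[[ch]] / resolution)
    st <- (seq_len(n) - 1L) * resolution
    data.frame(chrom = ch, start = st,
               end = pmin(st + resolution, chrom_sizes[[ch]]),
               stringsAsFactors = FALSE)
  }))
}

#' Read a contact matrix (dense TSV or COO triplet text)
#'
#' Dense input must be square and symmetric within 1e-9 (relative); COO
#' triplets (bin_i, bin_j, count; 0-based bins) are symmetrized. The bin
#' index is built from \code{chrom_sizes} and \code{resolution} as 0-based
#' half-open genomic windows.
#'
#' @param path input file.
#' @param resolution bin size in bp.
#' @param chrom_sizes named vector of chromosome lengths in bp.
#' @param format "dense" or "coo" (guessed from column count when NULL).
#' @return a \linkS4class{ContactMatrix}.
#' @export
readContactMatrix <- function(path, resolution, chrom_sizes, format = NULL) {
  bins <- makeBins(chrom_sizes, resolution)
  nb <- nrow(bins)
  raw <- utils::read.table(path, header = FALSE)
  if (is.null(format)) format <- if (ncol(raw) == 3 && nrow(raw) != 3) "coo" else
    if (ncol(raw) == nb) "dense" else "coo"
  if (format == "dense") {
    m <- as.matrix(raw)
    dimnames(m) <- NULL
    if (nrow(m) != ncol(m)) stop("dense contact matrix is not square")
    if (nrow(m) != nb) stop("matrix dimension ", nrow(m),
                            " does not match bin count ", nb)
    if (max(abs(m - t(m))) > 1e-9 * max(1, max(abs(m))))
      stop("dense contact matrix asymmetric beyond tolerance 1e-9")
  } else {
    i <- raw[[1]] + 1L; j <- raw[[2]] + 1L; v <- raw[[3]]
    if (any(i < 1L | i > nb | j < 1L | j > nb))
      stop("COO bin index out of range (", nb, " bins)")
    m <- matrix(0, nb, nb)
    m[cbind(i, j)] <- v
    m[cbind(j, i)] <- v
  }
  psLog("read_contact_matrix", file = basename(path), bins = nb,
        total = sum(m))
  new("ContactMatrix", counts = m, resolution = resolution, bins = bins,
      balanced = FALSE, bias = numeric(0))
}

#' Write a contact matrix as dense TSV or COO triplets
#'
#' @param cm a ContactMatrix.
#' @param path output file.
#' @param format "dense" or "coo".
#' @return invisibly, the path.
#' @export
writeContactMatrix <- function(cm, path, format = c("dense", "coo")) {
  format <- match.arg(format)
  m <- contactCounts(cm)
  if (format == "dense") {
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    utils::write.table(data.frame(idx[, 1] - 1L, idx[, 2] - 1L,
                                  m[idx]),
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  psLog("write_contact_matrix", file = basename(path), format = format)
  invisible(path)
}

#' Write a segment painting as BED6
#'
#' BED is 0-based half-open in bp. The name column is the resolved region
#' class label "Eu{c}:{gamma}{beta}" (or the origin chromosome when copy
#' labels are unresolved); the strand column carries segment orientation.
#' Gene-rank spans are converted to bp via the layout.
#'
#' @param painting a SegmentPainting.
#' @param layout the GenomeLayout the painting indexes (for bp lookup).
#' @param path output file.
#' @return invisibly, the path.
#' @export
writePaintingBed <- function(painting, layout, path) {
  s <- segmentTable(painting)
  if (nrow(s) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  g <- geneTable(layout)
  key <- paste(g$chrom, g$rank)
  startBp <- g$start[match(paste(s$chrom, s$start_rank), key)]
  endBp <- g$end[match(paste(s$chrom, s$end_rank - 1L), key)]
  name <- if (!is.null(s$class)) s$class else s$origin
  bed <- data.frame(s$chrom, startBp - 1L, endBp, name,
                    s$n_genes, s$orient)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  psLog("write_painting_bed", file = basename(path), segments = nrow(s))
  invisible(path)
}

#' Read a painting BED back into segment form
#'
#' Inverse of \code{\link{writePaintingBed}} up to the rank/bp conversion.
#'
#' @param path BED file.
#' @param layout the GenomeLayout used when writing.
#' @return a \linkS4class{SegmentPainting} (class labels in \code{class}).
#' @export
readPaintingBed <- function(path, layout) {
  if (file.size(path) == 0)
    return(new("SegmentPainting",
               segments = data.frame(segment_id = integer(0), chrom = character(0),
                                     start_rank = integer(0), end_rank = integer(0),
                                     class = character(0), orient = character(0),
                                     n_genes = integer(0)),
               chromLengths = chromGeneCounts(layout)))
  bed <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  g <- geneTable(layout)
  seg <- do.call(rbind, lapply(seq_len(nrow(bed)), function(i) {
    on <- g$chrom == bed[i, 1] & g$start >= bed[i, 2] + 1L & g$end <= bed[i, 3]
    r <- g$rank[on]
    data.frame(segment_id = i, chrom = bed[i, 1],
               start_rank = min(r), end_rank = max(r) + 1L,
               class = as.character(bed[i, 4]), orient = bed[i, 6],
               n_genes = sum(on), stringsAsFactors = FALSE)
  }))
  new("SegmentPainting", segments = seg, chromLengths = chromGeneCounts(layout))
}

#' Read/write gene x tissue expression records
#'
#' TSV with columns gene_id, tissue, replicate, tpm.
#'
#' @param path file path.
#' @return data.frame of expression records.
#' @export
readExpressionTable <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "tissue", "replicate", "tpm")
  if (!all(need %in% names(x))) stop("expression table needs columns ",
                                     paste(need, collapse = ", "))
  if (any(!is.finite(x$tpm)) || any(x$tpm < 0)) stop("tpm must be finite and non-negative")
  x
}

#' @rdname readExpressionTable
#' @param records expression record data.frame.
#' @export
writeExpressionTable <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write per-gene methylation levels
#'
#' TSV with columns gene_id, mC (fraction in [0, 1]).
#'
#' @param path file path.
#' @return data.frame with gene_id, mC.
#' @export
readMethylationTable <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("gene_id", "mC") %in% names(x)))
    stop("methylation table needs gene_id, mC")
  if (any(x$mC < 0 | x$mC > 1)) stop("mC outside [0, 1]")
  x
}

#' @rdname readMethylationTable
#' @param records methylation record data.frame.
#' @export
writeMethylationTable <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write coding sequences as FASTA
#'
#' @param cds named character vector of nucleotide sequences.
#' @param path output FASTA.
#' @return invisibly, the path.
#' @export
writeCds <- function(cds, path) {
  x <- Biostrings::DNAStringSet(cds)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read coding sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
readCds <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
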