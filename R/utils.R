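#' Structured one-line stage logging
#'
#' Emits one message per pipeline stage with input/output counts. Silenced
#' with \code{options(paleoshuffle.verbose = FALSE)}.
#'
#' @param stage short stage name.
#' @param ... named count/value fields appended as key=value.
#' @return invisibly, the formatted line.
#' @keywords internal
psLog <- function(stage, ...) {
  fields <- list(...)
  kv <- if (length(fields))
    paste(names(fields), vapply(fields, function(x) paste(format(x), collapse = ","),
                                character(1)), sep = "=", collapse = " ")
  else ""
  line <- sprintf("[paleoshuffle] %s %s", stage, kv)
  if (isTRUE(getOption("paleoshuffle.verbose", TRUE))) message(line)
  invisible(line)
}

# Evaluate expr under a local RNG seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a parent seed and a stream label, staying < 2^31.
childSeed <- function(seed, what) {
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

#' Build a GenomeLayout from a gene table
#'
#' Sorts genes by (chrom, start), assigns 0-based ranks per chromosome and
#' validates the layout invariants.
#'
#' @param genes data.frame with at least gene_id, chrom, start, end,
#'   strand; family_id optional (defaults to gene_id).
#' @param speciesId species identifier.
#' @param subgenome optional subgenome label.
#' @param chromOrder optional explicit chromosome ordering.
#' @return a \linkS4class{GenomeLayout}.
#' @export
newGenomeLayout <- function(genes, speciesId = "genome",
                            subgenome = NA_character_, chromOrder = NULL) {
  if (nrow(genes) == 0L) {
    g <- data.frame(gene_id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0),
                    strand = character(0), family_id = character(0),
                    rank = integer(0), stringsAsFactors = FALSE)
    return(new("GenomeLayout", speciesId = speciesId, subgenome = subgenome,
               genes = g))
  }
  if (is.null(genes$family_id)) genes$family_id <- genes$gene_id
  if (is.null(chromOrder)) chromOrder <- unique(genes$chrom)
  genes$chrom <- as.character(genes$chrom)
  o <- order(match(genes$chrom, chromOrder), genes$start)
  genes <- genes[o, , drop = FALSE]
  genes$rank <- as.integer(stats::ave(seq_len(nrow(genes)), genes$chrom,
                                      FUN = seq_along)) - 1L
  rownames(genes) <- NULL
  keep <- c("gene_id", "chrom", "start", "end", "strand", "family_id", "rank")
  extra <- setdiff(names(genes), keep)
  genes <- genes[, c(keep, extra), drop = FALSE]
  genes$start <- as.integer(genes$start); genes$end <- as.integer(genes$end)
  genes$rank <- as.integer(genes$rank)
  new("GenomeLayout", speciesId = speciesId, subgenome = subgenome, genes = genes)
}

# Genes-per-chromosome lengths of a layout, as a named integer vector.
chromGeneCounts <- function(layout) {
  g <- geneTable(layout)
  tab <- table(factor(g$chrom, levels = unique(g$chrom)))
  stats::setNames(as.integer(tab), names(tab))
}
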