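## Targeted retention implants: small scenario generators that place an
## explicit retention configuration on a duplicated genome so the
## fractionation statistics can be scored against exact truth.

# Build a fully duplicated (gamma x beta) genome skeleton without
# sequences: every locus present in all 6 copy classes.
makeDuplicatedSkeleton <- function(genes_per_chrom, n_chrom = length(genes_per_chrom),
                                   gammas = c("A", "B", "C"), betas = c("a", "b")) {
  rows <- list()
  for (e in seq_len(n_chrom)) {
    n <- genes_per_chrom[e]
    locus <- sprintf("Eu%d_%05d", e, seq_len(n))
    for (g in gammas) for (b in betas) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = paste0("g", locus, "_", g, b),
        chrom = sprintf("Eu%d_%s_%s", e, g, b),
        start = (seq_len(n) - 1L) * .GENE_BP + 1L,
        end = (seq_len(n) - 1L) * .GENE_BP + .GENE_LEN,
        strand = "+", family_id = locus, locus = locus,
        eu = e, gamma = g, beta = b, anc_rank = seq_len(n) - 1L,
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, rows)
  newGenomeLayout(genes, speciesId = "implant")
}

#' Region classes straight from generator truth labels
#'
#' The generator-side counterpart of \code{\link{enumerateRegionClasses}}:
#' classes are read off the implanted (eu, gamma, beta) labels instead of
#' being recovered by painting. Used to feed retention statistics in
#' implant scenarios where the copy configuration is the input.
#'
#' @param layout a generator GenomeLayout carrying truth columns.
#' @return list(classes, genes, n) as for enumerateRegionClasses.
#' @export
regionClassesFromTruth <- function(layout) {
  g <- geneTable(layout)
  cls <- paste0("Eu", g$eu, ":", g$gamma, g$beta)
  genes <- split(g$gene_id, cls)
  classes <- sort(names(genes))
  list(classes = classes, genes = genes[classes], n = length(classes))
}

#' Simulate a duplicated segment pair with an explicit retention implant
#'
#' One beta-derived pair of homologous segments carrying \code{n_both} loci
#' retained in both copies, \code{n_only1} retained only on copy 1 and
#' \code{n_only2} only on copy 2 (defaults: the 69/98/112 configuration of
#' a 279-locus segment pair). Which locus falls in which class is a seeded
#' permutation.
#'
#' @param n_both,n_only1,n_only2 locus counts per retention class.
#' @param seed RNG seed.
#' @return list(genome, retention, region_classes, gene_locus, classes =
#'   the two class labels).
#' @export
simulateSegmentPairImplant <- function(n_both = 69, n_only1 = 98,
                                       n_only2 = 112, seed = 1) {
  n <- n_both + n_only1 + n_only2
  skel <- makeDuplicatedSkeleton(n, n_chrom = 1, gammas = "C")
  g <- geneTable(skel)
  loci <- unique(g$locus)
  lab <- withSeed(childSeed(seed, "c6b"),
                  sample(rep(c("both", "only1", "only2"),
                             c(n_both, n_only1, n_only2))))
  implant <- stats::setNames(lapply(lab, function(l)
    switch(l, both = c("Ca", "Cb"), only1 = "Ca", only2 = "Cb")), loci)
  fr <- applyFractionation(list(layout = skel,
                                seqs = matrix(integer(0), 0, 0)),
                           list(implant = implant),
                           seed = childSeed(seed, "frac"))
  rc <- regionClassesFromTruth(fr$layout)
  gl <- stats::setNames(geneTable(fr$layout)$locus, geneTable(fr$layout)$gene_id)
  list(genome = fr$layout, retention = fr$retention, region_classes = rc,
       gene_locus = gl, classes = c("Eu1:Ca", "Eu1:Cb"),
       truth_labels = stats::setNames(lab, loci))
}

#' Simulate a genome-wide high-retention implant
#'
#' A diploid genome with \code{n_loci} ancestral loci across 7 duplicated
#' ancestral chromosomes, of which exactly \code{n_high} retain more than
#' \code{threshold} of their 6 copy classes; the rest retain
#' \code{threshold} or fewer. Copy-number distributions within each group
#' are seeded draws.
#'
#' @param n_loci total ancestral loci (default 14821).
#' @param n_high high-retention loci (default 993).
#' @param threshold copy-number threshold (default 3).
#' @param seed RNG seed.
#' @return list(genome, retention, region_classes, gene_locus,
#'   truth_high = character vector of high-retention loci).
#' @export
simulateRetentionImplant <- function(n_loci = 14821, n_high = 993,
                                     threshold = 3, seed = 1) {
  per <- rep(n_loci %/% 7L, 7L)
  per[7] <- per[7] + n_loci - sum(per)
  skel <- makeDuplicatedSkeleton(per)
  g <- geneTable(skel)
  loci <- unique(g$locus)
  allCls <- as.vector(outer(c("A", "B", "C"), c("a", "b"), paste0))
  withSeed(childSeed(seed, "retention"), {
    high <- sample(loci, n_high)
    copyN <- stats::setNames(integer(length(loci)), loci)
    copyN[high] <- sample((threshold + 1):6, n_high, replace = TRUE,
                          prob = c(0.6, 0.3, 0.1))
    low <- setdiff(loci, high)
    copyN[low] <- sample(seq_len(threshold), length(low), replace = TRUE,
                         prob = c(0.4, 0.35, 0.25))
    implant <- lapply(copyN, function(k) sample(allCls, k))
    names(implant) <- loci
    fr <- applyFractionation(list(layout = skel,
                                  seqs = matrix(integer(0), 0, 0)),
                             list(implant = implant),
                             seed = childSeed(seed, "frac"))
    rc <- regionClassesFromTruth(fr$layout)
    gl <- stats::setNames(geneTable(fr$layout)$locus,
                          geneTable(fr$layout)$gene_id)
    list(genome = fr$layout, retention = fr$retention, region_classes = rc,
         gene_locus = gl, truth_high = high)
  })
}
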