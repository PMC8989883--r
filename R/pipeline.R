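## End-to-end reconstruction pipeline over a replay dataset: collinearity
## against the ancestor, painting, Ks-based copy-label resolution, junction
## counting per WGD layer, karyotype reconstruction, region-class
## enumeration and rearrangement detection.

#' Run the full karyotype-reconstruction pipeline on a replay dataset
#'
#' @param replay result of \code{\link{fig1Replay}}.
#' @param max_gap,min_anchors,min_segment_genes collinearity/painting
#'   parameters (defaults 50/5/5).
#' @param seed analysis-side seed (anchor sampling, mixture restarts).
#' @return list with blocks, paintings, labelled painting (primary
#'   species), mixture, junction counts, region classes, karyotype
#'   reconstructions and rearrangement events.
#' @export
runKaryotypePipeline <- function(replay, max_gap = 50, min_anchors = 5,
                                 min_segment_genes = 5, seed = 1) {
  anc <- replay$ancestor
  sp1 <- replay$species$sp1
  sp2 <- replay$species$sp2

  paintOne <- function(genome, pairs) {
    pairs <- filterLargeFamilies(pairs)
    b <- detectCollinearBlocks(genome$layout, anc$layout, pairs,
                               max_gap = max_gap, min_anchors = min_anchors)
    list(blocks = b,
         painting = paintGenome(genome$layout, anc$layout, b,
                                min_segment_genes = min_segment_genes,
                                max_gap = max_gap))
  }
  a1 <- paintOne(sp1, replay$homology$sp1_vs_ancestor)
  a2 <- paintOne(sp2, replay$homology$sp2_vs_ancestor)

  selfBlocks <- detectCollinearBlocks(sp1$layout, sp1$layout,
                                      replay$homology$sp1_self,
                                      max_gap = max_gap,
                                      min_anchors = min_anchors, self = TRUE)
  # measure every self anchor: the sparsest beta pairs (low retention on
  # both copies) only carry a handful of anchors per segment pair
  selfKs <- blockAnchorKs(selfBlocks, sp1$seqs, sp1$seqs,
                          max_per_block = Inf,
                          seed = childSeed(seed, "selfks"))
  lab <- resolveCopyLabels(a1$painting, selfKs$blockset, selfKs$anchor_ks,
                           sp1$layout, seed = childSeed(seed, "mix"))

  events <- detectRearrangements(a1$painting, a2$painting)
  junctions <- countFusionJunctions(lab$painting, extant_events = events,
                                    tol = min_segment_genes)
  classes <- enumerateRegionClasses(lab$painting, sp1$layout)
  karyoExtant <- reconstructKaryotype(lab$painting, "extant")
  karyoPreBeta <- reconstructKaryotype(lab$painting, "pre_beta", junctions)

  # the post-triplication intermediate, painted the same way
  pg <- paintOne(replay$postGamma, replay$homology$post_gamma_vs_ancestor)
  karyoPostGamma <- reconstructKaryotype(pg$painting, "extant")

  list(blocks = list(sp1 = a1$blocks, sp2 = a2$blocks, self = selfKs$blockset),
       paintings = list(sp1 = a1$painting, sp2 = a2$painting,
                        post_gamma = pg$painting),
       labelled = lab$painting, mixture = lab$mixture,
       pair_table = lab$pair_table, self_anchor_ks = selfKs$anchor_ks,
       events = events, junctions = junctions, region_classes = classes,
       karyotype = list(extant = karyoExtant, pre_beta = karyoPreBeta,
                        post_gamma = karyoPostGamma))
}

#' Gene-to-locus map from a homology table against the ancestor
#'
#' Each extant gene is mapped to the ancestral locus (family) of its best
#' ancestor hit; used to index the retention matrix.
#'
#' @param pairs homology records extant-vs-ancestor.
#' @param ancestor the ancestor GenomeLayout.
#' @return named character vector gene_id -> locus.
#' @export
geneLocusMap <- function(pairs, ancestor) {
  g <- geneTable(ancestor)
  o <- order(-pairs$bitscore)
  p <- pairs[o, , drop = FALSE]
  p <- p[!duplicated(p$query), , drop = FALSE]
  stats::setNames(g$family_id[match(p$subject, g$gene_id)], p$query)
}

#' Simulate an allotetraploid with a diploid relative
#'
#' One subgenome (B) diverges from the diploid relative more recently than
#' the other (A): branch-specific divergence is implanted so that
#' Ks(A, diploid) > Ks(B, diploid). Used to exercise
#' \code{\link{assignSubgenomes}}.
#'
#' @param seed RNG seed.
#' @param n_chrom,genes_per_chrom,codons_per_gene ancestor dimensions.
#' @param ks_a,ks_b divergence of subgenomes A and B from the diploid.
#' @return list(tetraploid = list(layout, seqs), diploid = list(layout,
#'   seqs), homology, truth = named character chrom -> subgenome).
#' @export
simulateAllotetraploid <- function(seed = 1, n_chrom = 4,
                                   genes_per_chrom = 60,
                                   codons_per_gene = 100,
                                   ks_a = 0.6, ks_b = 0.2) {
  anc <- simulateAncestralGenome(n_chrom, genes_per_chrom, codons_per_gene,
                                 seed = childSeed(seed, "tetra-anc"))
  mkCopy <- function(suffix, target, stream) {
    m <- calibrateMutationRounds(anc$seqs, target,
                                 seed = childSeed(seed, paste0("cal", stream)))
    g <- geneTable(anc$layout)
    g$gene_id <- paste0(g$gene_id, "_", suffix)
    g$chrom <- paste0(g$chrom, "_", suffix)
    s <- withSeed(childSeed(seed, stream), mutateCodonMatrix(anc$seqs, m))
    rownames(s) <- g$gene_id
    list(genes = g, seqs = s)
  }
  # diploid keeps the ancestral sequences; subgenomes diverge by ks_a/ks_b
  cA <- mkCopy("A", ks_a, "subA")
  cB <- mkCopy("B", ks_b, "subB")
  genes <- rbind(cA$genes, cB$genes)
  tetra <- list(layout = newGenomeLayout(rebuildBp(genes), speciesId = "tetraploid"),
                seqs = rbind(cA$seqs, cB$seqs))
  dip <- list(layout = anc$layout, seqs = anc$seqs)
  hom <- truthHomology(tetra, dip)
  truth <- stats::setNames(rep(c("A", "B"), each = n_chrom),
                           c(unique(cA$genes$chrom), unique(cB$genes$chrom)))
  list(tetraploid = tetra, diploid = dip, homology = hom, truth = truth)
}
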