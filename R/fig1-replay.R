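## The canonical replay scenario: a 7-chromosome ancestor subjected to a
## triplication (gamma), a 26-junction fusion plan collapsing 21
## chromosomes (34 segments) into 8, a duplication (beta), four further
## fusions (16 -> 12 chromosomes), shared biased fractionation, and three
## species-specific rearrangements (two inversions + one reciprocal
## translocation) across two extant species. The internal composition of
## each fused chromosome is one consistent realization; the layer-wise
## junction and chromosome counts are the identifiable quantities.

# Fusion plan: 21 post-gamma chromosomes cut into 34 segments (13 split in
# half, 8 whole) and concatenated into 8 chromosomes = 26 heterologous
# junctions. No two same-ancestor segments share a chromosome and all 26
# junction class-types are pairwise distinct.
fig1FusionPlanGamma <- function(genes_per_chrom) {
  h <- genes_per_chrom %/% 2L
  seg <- function(eu, g, part) {
    ch <- sprintf("Eu%d_%s", eu, g)
    switch(part,
           h = list(chrom = ch, from = 0L, to = h),
           t = list(chrom = ch, from = h),
           w = list(chrom = ch))
  }
  list(
    Ar1 = list(seg(1, "A", "h"), seg(2, "B", "h"), seg(3, "C", "h"),
               seg(4, "A", "h"), seg(5, "C", "w")),
    Ar2 = list(seg(1, "B", "h"), seg(2, "C", "h"), seg(3, "A", "h"),
               seg(4, "B", "h"), seg(5, "A", "w")),
    Ar3 = list(seg(1, "C", "h"), seg(2, "A", "h"), seg(3, "B", "h"),
               seg(4, "C", "h"), seg(6, "A", "w")),
    Ar4 = list(seg(1, "A", "t"), seg(2, "C", "t"), seg(3, "B", "t"),
               seg(4, "B", "t"), seg(6, "B", "w")),
    Ar5 = list(seg(1, "B", "t"), seg(2, "A", "t"), seg(4, "C", "t"),
               seg(6, "C", "w")),
    Ar6 = list(seg(1, "C", "t"), seg(2, "B", "t"), seg(4, "A", "t"),
               seg(7, "A", "w")),
    Ar7 = list(seg(3, "C", "t"), seg(5, "B", "h"), seg(7, "B", "w")),
    Ar8 = list(seg(3, "A", "t"), seg(5, "B", "t"), seg(7, "C", "w")))
}

# Post-beta plan: four whole-chromosome fusions, 16 -> 12. The fused
# combinations differ between the two beta copies so each of the four
# junctions arises once.
fig1FusionPlanBeta <- function() {
  list(Pa1 = list(list(chrom = "Ar1_a"), list(chrom = "Ar2_a")),
       Pa2 = list(list(chrom = "Ar3_a"), list(chrom = "Ar4_a")),
       Pa3 = list(list(chrom = "Ar5_a")),
       Pa4 = list(list(chrom = "Ar6_a")),
       Pa5 = list(list(chrom = "Ar7_a")),
       Pa6 = list(list(chrom = "Ar8_a")),
       Pa7 = list(list(chrom = "Ar1_b"), list(chrom = "Ar3_b")),
       Pa8 = list(list(chrom = "Ar2_b"), list(chrom = "Ar4_b")),
       Pa9 = list(list(chrom = "Ar5_b")),
       Pa10 = list(list(chrom = "Ar6_b")),
       Pa11 = list(list(chrom = "Ar7_b")),
       Pa12 = list(list(chrom = "Ar8_b")))
}

# Homology records from generator truth: one record per gene pair sharing
# an ancestral locus, with percent identity measured from the sequences.
truthHomology <- function(genomeQ, genomeS, self = FALSE) {
  gq <- geneTable(genomeQ$layout); gs <- geneTable(genomeS$layout)
  bylocus <- split(seq_len(nrow(gs)), gs$locus)
  qi <- rep(seq_len(nrow(gq)), times = vapply(bylocus[gq$locus], length, integer(1)))
  si <- unlist(bylocus[gq$locus], use.names = FALSE)
  if (self) {
    keep <- gq$gene_id[qi] < gs$gene_id[si]
    qi <- qi[keep]; si <- si[keep]
  }
  M <- codonBaseMatches()
  L <- ncol(genomeQ$seqs)
  rowQ <- match(gq$gene_id, rownames(genomeQ$seqs))
  rowS <- match(gs$gene_id, rownames(genomeS$seqs))
  idFrac <- vapply(seq_along(qi), function(k) {
    sum(M[cbind(genomeQ$seqs[rowQ[qi[k]], ],
                genomeS$seqs[rowS[si[k]], ])]) / (3 * L)
  }, numeric(1))
  data.frame(query = gq$gene_id[qi], subject = gs$gene_id[si],
             pct_identity = round(100 * idFrac, 2),
             evalue = 1e-180,
             bitscore = round(1800 * idFrac, 1),
             stringsAsFactors = FALSE)
}

# Middle-portion rank span of the genes with a given truth origin on one
# chromosome (used to place within-segment rearrangement breakpoints).
originSpan <- function(layout, chrom, eu, gamma, mid_frac = 0.5) {
  g <- geneTable(layout)
  r <- sort(g$rank[g$chrom == chrom & g$eu == eu & g$gamma == gamma])
  n <- length(r)
  pad <- max(3L, floor(n * (1 - mid_frac) / 2))
  c(from = r[1] + pad, to = r[n] - pad + 1L)
}

#' Run the packaged fig1 replay scenario
#'
#' Generates the full synthetic dataset: ancestor, triplicated/duplicated
#' and fused genomes, shared biased fractionation, two extant species with
#' three rearrangements between them, truth-derived homology tables,
#' expression, methylation and a Hi-C contact matrix, plus the complete
#' \linkS4class{TruthSet}.
#'
#' @param seed RNG seed; the whole dataset is a deterministic function of
#'   it.
#' @param genes_per_chrom ancestral genes per chromosome (default 120).
#' @param codons_per_gene codons per gene (default 100).
#' @param gamma_ks,beta_ks per-event target Ks at application time.
#'   Defaults 0.8 and 0.4 so that the final observed layer medians sit near
#'   1.2 (gamma pairs accumulate the beta-era divergence on top) and 0.4.
#' @param fractionate apply the biased fractionation stage (default TRUE).
#' @param retention_probs per-copy-class retention probabilities used when
#'   \code{fractionate} (names Aa..Cb).
#' @param out optional directory; when given, all io_formats files plus
#'   truth.json are written there.
#' @return list with ancestor, postGamma, species (sp1 = primary, sp2),
#'   homology tables, expression, methylation, contacts, hic truth and the
#'   TruthSet.
#' @export
fig1Replay <- function(seed = 42, genes_per_chrom = 120, codons_per_gene = 100,
                       gamma_ks = 0.8, beta_ks = 0.4, fractionate = TRUE,
                       retention_probs = c(Aa = 0.85, Ab = 0.6, Ba = 0.55,
                                           Bb = 0.4, Ca = 0.45, Cb = 0.3),
                       out = NULL) {
  anc <- simulateAncestralGenome(7, genes_per_chrom, codons_per_gene,
                                 seed = childSeed(seed, "anc"))
  g3 <- applyWGD(anc, 3L, "gamma", gamma_ks, seed = childSeed(seed, "gamma"))
  postGamma <- g3
  ar <- applyFusionPlan(g3, fig1FusionPlanGamma(genes_per_chrom), "post-gamma")
  g6 <- applyWGD(list(layout = ar$layout, seqs = ar$seqs), 2L, "beta",
                 beta_ks, seed = childSeed(seed, "beta"))
  pa <- applyFusionPlan(g6, fig1FusionPlanBeta(), "post-beta")
  paGenome <- list(layout = pa$layout, seqs = pa$seqs)
  retention <- NULL
  if (fractionate) {
    fr <- applyFractionation(paGenome, list(probs = retention_probs),
                             seed = childSeed(seed, "frac"))
    paGenome <- list(layout = fr$layout, seqs = fr$seqs)
    retention <- fr$retention
  } else {
    g <- geneTable(paGenome$layout)
    retention <- data.frame(locus = g$locus,
                            class = paste0(g$gamma, g$beta),
                            gene_id = g$gene_id, stringsAsFactors = FALSE)
  }

  # speciation: sp1 (primary) carries one within-segment inversion; sp2
  # carries one inversion and the reciprocal translocation (three
  # rearrangements between the two extant species)
  sp1 <- paGenome
  inv1 <- originSpan(sp1$layout, "Pa4", eu = 4, gamma = "A")
  r1 <- applyRearrangement(sp1, "inversion",
                           list(chrom = "Pa4", from = inv1[["from"]],
                                to = inv1[["to"]]))
  sp1 <- list(layout = r1$layout, seqs = r1$seqs)
  sp1$layout@speciesId <- "sim_sp1"
  events <- list(c(species = "sim_sp1", r1$event))

  sp2 <- paGenome
  inv2 <- originSpan(sp2$layout, "Pa6", eu = 7, gamma = "C")
  r2 <- applyRearrangement(sp2, "inversion",
                           list(chrom = "Pa6", from = inv2[["from"]],
                                to = inv2[["to"]]))
  sp2 <- list(layout = r2$layout, seqs = r2$seqs)
  g <- geneTable(sp2$layout)
  # reciprocal translocation between non-homoeologous terminal segments
  # (Pa8 ends in an Eu6 copy, Pa10 in an Eu7 copy), cut inside the segments
  tailA <- sort(g$rank[g$chrom == "Pa8" & g$eu == 6])
  tailB <- sort(g$rank[g$chrom == "Pa10" & g$eu == 7])
  r3 <- applyRearrangement(sp2, "translocation",
                           list(chrom_a = "Pa8",
                                from_a = tailA[1] + length(tailA) %/% 3L,
                                chrom_b = "Pa10",
                                from_b = tailB[1] + 2L * (length(tailB) %/% 3L)))
  sp2 <- list(layout = r3$layout, seqs = r3$seqs)
  sp2$layout@speciesId <- "sim_sp2"
  events <- c(events, list(c(species = "sim_sp2", r2$event)),
              list(c(species = "sim_sp2", r3$event)))

  # layer attribution keys for junction truth: class types at the
  # (Eu, gamma) level
  stripBeta <- function(x) sub("([ABC])[ab]?$", "\\1", x)
  typeKey <- function(l, r) {
    l <- stripBeta(l); r <- stripBeta(r)
    paste(pmin(l, r), pmax(l, r), sep = "|")
  }
  gammaTypes <- typeKey(ar$junctions$left, ar$junctions$right)
  betaTypes <- typeKey(pa$junctions$left, pa$junctions$right)
  junctionsFor <- function(layout) {
    j <- truthJunctions(layout)
    if (!nrow(j)) return(cbind(j, layer = character(0)))
    key <- typeKey(j$left, j$right)
    j$layer <- ifelse(key %in% gammaTypes, "post-gamma",
                      ifelse(key %in% betaTypes, "post-beta", "extant"))
    j
  }
  j1 <- junctionsFor(sp1$layout); j1$species <- "sim_sp1"
  j2 <- junctionsFor(sp2$layout); j2$species <- "sim_sp2"

  lin <- function(genome, sp) {
    g <- geneTable(genome$layout)
    data.frame(species = sp, gene_id = g$gene_id, locus = g$locus,
               eu = g$eu, gamma = g$gamma, beta = g$beta, chrom = g$chrom,
               rank = g$rank, stringsAsFactors = FALSE)
  }

  # omics layers on the primary species
  chromSizes <- chromGeneCounts(sp1$layout) * .GENE_BP
  hicRes <- 10000L
  hicTruth <- withSeed(childSeed(seed, "hictruth"), {
    bins <- makeBins(chromSizes, hicRes)
    comp <- unlist(lapply(unique(bins$chrom), function(ch) {
      n <- sum(bins$chrom == ch)
      lab <- character(0); cur <- sample(c("A", "B"), 1)
      while (length(lab) < n) {
        lab <- c(lab, rep(cur, sample(8:15, 1))); cur <- setdiff(c("A", "B"), cur)
      }
      lab[seq_len(n)]
    }))
    tads <- do.call(rbind, lapply(unique(bins$chrom), function(ch) {
      n <- sum(bins$chrom == ch)
      cuts <- 0L
      while (cuts[length(cuts)] < n)
        cuts <- c(cuts, min(n, cuts[length(cuts)] + sample(5:9, 1)))
      data.frame(chrom = ch, start_bin = cuts[-length(cuts)],
                 end_bin = cuts[-1], stringsAsFactors = FALSE)
    }))
    list(compartments = comp, tads = tads, bins = bins)
  })
  contacts <- simulateContactMatrix(chromSizes, hicRes,
                                    compartments = hicTruth$compartments,
                                    tads = hicTruth$tads,
                                    decay_exponent = 1, depth = 2e6,
                                    seed = childSeed(seed, "hic"))
  tadsBp <- data.frame(chrom = hicTruth$tads$chrom,
                       start = hicTruth$tads$start_bin * hicRes,
                       end = hicTruth$tads$end_bin * hicRes)
  expr <- simulateExpression(sp1$layout, seed = childSeed(seed, "expr"))
  meth <- simulateMethylation(sp1$layout, tads = tadsBp,
                              seed = childSeed(seed, "meth"))

  homology <- list(
    sp1_vs_ancestor = truthHomology(sp1, anc),
    sp2_vs_ancestor = truthHomology(sp2, anc),
    post_gamma_vs_ancestor = truthHomology(postGamma, anc),
    sp1_self = truthHomology(sp1, sp1, self = TRUE),
    sp2_self = truthHomology(sp2, sp2, self = TRUE))

  truth <- new("TruthSet",
               lineage = rbind(lin(sp1, "sim_sp1"), lin(sp2, "sim_sp2")),
               junctions = rbind(j1, j2),
               retention = retention,
               ksExpected = c(beta = beta_ks, gamma = gamma_ks + beta_ks),
               events = events,
               extra = list(gamma_junction_types = gammaTypes,
                            beta_junction_types = betaTypes,
                            triads = expr$truth,
                            methylation = meth$truth,
                            compartments = hicTruth$compartments,
                            tads = hicTruth$tads,
                            hic_bins = hicTruth$bins,
                            n_region_classes = 42L))

  res <- list(ancestor = anc, postGamma = postGamma,
              arGenome = list(layout = ar$layout, seqs = ar$seqs),
              species = list(sp1 = sp1, sp2 = sp2),
              homology = homology, expression = expr$records,
              methylation = meth$records, contacts = contacts,
              truth = truth, seed = seed)

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    writeGeneModels(anc$layout, file.path(out, "ancestor.gff3"))
    writeGeneModels(sp1$layout, file.path(out, "sp1.gff3"))
    writeGeneModels(sp2$layout, file.path(out, "sp2.gff3"))
    writeCds(stats::setNames(apply(sp1$seqs, 1, codonStringFromInts), rownames(sp1$seqs)),
             file.path(out, "sp1_cds.fa"))
    writeHomologyTable(homology$sp1_vs_ancestor, file.path(out, "sp1_vs_ancestor.blast6"))
    writeHomologyTable(homology$sp1_self, file.path(out, "sp1_self.blast6"))
    writeExpressionTable(expr$records, file.path(out, "expression.tsv"))
    writeMethylationTable(meth$records, file.path(out, "methylation.tsv"))
    writeContactMatrix(contacts, file.path(out, "contacts.coo.tsv"), "coo")
    jsonlite::write_json(list(seed = seed,
                              chromosomes = length(chromNames(sp1$layout)),
                              junction_layers = table(j1$layer),
                              ks_expected = truth@ksExpected),
                         file.path(out, "truth.json"), auto_unbox = TRUE)
  }
  psLog("fig1_replay", seed = seed,
        sp1_chroms = length(chromNames(sp1$layout)),
        genes = nGenes(sp1$layout))
  res
}
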