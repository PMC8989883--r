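# Synthetic-genome generator: structure, determinism, event semantics and
# implanted truth bookkeeping.

test_that("ancestral genome has the requested shape and valid ORFs", {
  anc <- simulateAncestralGenome(7, 120, 100, seed = 1)
  expect_equal(nChromosomes(anc$layout), 7L)
  expect_equal(nGenes(anc$layout), 840L)
  expect_equal(ncol(anc$seqs), 100L)
  # no in-frame stop codon anywhere (scan via translation)
  stops <- which(Biostrings::GENETIC_CODE[paleoshuffle:::codonAlphabet()] == "*")
  expect_false(any(anc$seqs %in% stops))
  # determinism
  anc2 <- simulateAncestralGenome(7, 120, 100, seed = 1)
  expect_identical(anc$seqs, anc2$seqs)
  expect_identical(geneTable(anc$layout), geneTable(anc2$layout))
})

test_that("WGD multiplies chromosomes and calibrates pairwise Ks", {
  anc <- simulateAncestralGenome(7, 30, 100, seed = 2)
  g3 <- applyWGD(anc, 3L, "gamma", 0.6, seed = 3)
  expect_equal(nChromosomes(g3$layout), 21L)
  anc8 <- simulateAncestralGenome(8, 20, 100, seed = 2)
  expect_equal(nChromosomes(applyWGD(anc8, 2L, "beta", 0.3, seed = 3)$layout), 16L)
  expect_error(applyWGD(anc, 2L, "beta", -1, seed = 1), "positive")

  # median pairwise Ks within +/- 0.05 of target (>= 100 gene pairs)
  anc <- simulateAncestralGenome(2, 60, 100, seed = 5)
  g2 <- applyWGD(anc, 2L, "beta", 0.6, seed = 6)
  g <- geneTable(g2$layout)
  ks <- vapply(unique(g$locus), function(lc) {
    x <- g$gene_id[g$locus == lc]
    paleoshuffle:::ksNG86Int(g2$seqs[x[1], ], g2$seqs[x[2], ])$Ks
  }, numeric(1))
  expect_gte(length(ks), 100L)
  expect_lt(abs(median(ks, na.rm = TRUE) - 0.6), 0.05)
})

test_that("fusion plans concatenate segments and record junctions", {
  anc <- simulateAncestralGenome(2, 20, 10, seed = 4)
  plan <- list(fused = list(list(chrom = "Eu1"), list(chrom = "Eu2")))
  out <- applyFusionPlan(anc, plan, "test")
  expect_equal(nChromosomes(out$layout), 1L)
  expect_equal(nrow(out$junctions), 1L)
  expect_equal(out$junctions$pos, 20L)

  # junctions = segments - chromosomes when all junctions heterologous
  anc6 <- simulateAncestralGenome(6, 10, 10, seed = 4)
  plan2 <- list(
    n1 = list(list(chrom = "Eu1", from = 0L, to = 5L), list(chrom = "Eu2")),
    n2 = list(list(chrom = "Eu1", from = 5L), list(chrom = "Eu3"),
              list(chrom = "Eu4", from = 0L, to = 4L)),
    n3 = list(list(chrom = "Eu4", from = 4L), list(chrom = "Eu5"),
              list(chrom = "Eu6")))
  out2 <- applyFusionPlan(anc6, plan2, "test")
  expect_equal(nrow(out2$junctions), 8L - 3L)

  # omission and reuse are rejected
  expect_error(applyFusionPlan(anc, list(x = list(list(chrom = "Eu1"))), "t"),
               "omits")
  expect_error(applyFusionPlan(anc, list(
    x = list(list(chrom = "Eu1"), list(chrom = "Eu1")),
    y = list(list(chrom = "Eu2"))), "t"), "reuses")
})

test_that("fractionation honours probabilities, implants and conservation", {
  anc <- simulateAncestralGenome(2, 30, 10, seed = 6)
  g2 <- applyWGD(anc, 2L, "beta", 0.2, seed = 7)

  # loss probability 0 -> identity
  keepAll <- applyFractionation(g2, list(probs = c(a = 1, b = 1)), seed = 1)
  expect_equal(nGenes(keepAll$layout), nGenes(g2$layout))

  # explicit implant
  lc <- geneTable(g2$layout)$locus[1]
  imp <- applyFractionation(g2, list(implant = stats::setNames(list("a"), lc)),
                            seed = 1)
  expect_equal(sum(geneTable(imp$layout)$locus == lc), 1L)

  # conservation: retained genes equal retention truth rows, every locus kept
  fr <- applyFractionation(g2, list(probs = c(a = 0.7, b = 0.3)), seed = 2)
  expect_equal(nGenes(fr$layout), nrow(fr$retention))
  expect_setequal(unique(fr$retention$locus), unique(geneTable(g2$layout)$locus))

  expect_error(applyFractionation(g2, list(probs = c(a = 1.2, b = 0.5))),
               "\\[0, 1\\]")
})

test_that("rearrangements invert, translocate and split as specified", {
  anc <- simulateAncestralGenome(2, 30, 10, seed = 8)
  inv <- applyRearrangement(anc, "inversion",
                            list(chrom = "Eu1", from = 10L, to = 20L))
  g0 <- geneTable(anc$layout); g1 <- geneTable(inv$layout)
  id_at <- function(g, ch, r) g$gene_id[g$chrom == ch & g$rank == r]
  expect_equal(id_at(g1, "Eu1", 10L), id_at(g0, "Eu1", 19L))
  expect_equal(g1$strand[g1$chrom == "Eu1" & g1$rank == 10L], "-")

  # double inversion restores the original order and strands
  inv2 <- applyRearrangement(inv, "inversion",
                             list(chrom = "Eu1", from = 10L, to = 20L))
  expect_equal(geneTable(inv2$layout)$gene_id, g0$gene_id)
  expect_equal(geneTable(inv2$layout)$strand, g0$strand)

  # reciprocal translocation preserves chromosome lengths as a multiset
  tr <- applyRearrangement(anc, "translocation",
                           list(chrom_a = "Eu1", from_a = 10L,
                                chrom_b = "Eu2", from_b = 22L))
  expect_setequal(unname(paleoshuffle:::chromGeneCounts(tr$layout)),
                  c(10 + 8, 22 + 20))

  fis <- applyRearrangement(anc, "fission", list(chrom = "Eu1", at = 12L))
  expect_equal(nChromosomes(fis$layout), 3L)
  expect_error(applyRearrangement(anc, "inversion",
                                  list(chrom = "Eu1", from = 25L, to = 40L)),
               "range")
})

test_that("expression generator never emits all-zero triads and validates input", {
  anc <- simulateAncestralGenome(1, 50, 10, seed = 9)
  ex <- simulateExpression(anc$layout, seed = 10)
  tot <- tapply(ex$records$tpm, ex$records$gene_id, sum)
  expect_true(all(tot > 0))
  expect_error(simulateExpression(anc$layout,
                                  archetype_fracs = c(Balanced = 0.5)),
               "sum to 1")
  # noiseless Dirichlet limit: huge concentration pins fractions to the
  # archetype up to the replicate measurement noise
  ex2 <- simulateExpression(anc$layout,
                            archetype_fracs = c(Balanced = 1),
                            concentration = 1e7, seed = 11)
  tt <- triadTable(ex2$records)
  expect_true(all(abs(tt$frac_leaf - 1 / 3) < 0.1))
  expect_equal(mean(tt$frac_leaf), 1 / 3, tolerance = 0.02)
})

test_that("contact matrix generator implants decay, TADs and symmetry", {
  sizes <- c(c1 = 2e6)
  cm <- simulateContactMatrix(sizes, 20000, decay_exponent = 1, depth = 5e5,
                              seed = 12)
  m <- contactCounts(cm)
  expect_true(all(m >= 0))
  expect_identical(m, t(m))
  # pure decay: mean counts fall with distance
  d1 <- mean(m[row(m) == col(m) - 1])
  d10 <- mean(m[row(m) == col(m) - 10])
  expect_gt(d1, d10)

  # implanted TADs enrich within-domain contacts at equal distance
  tads <- data.frame(chrom = "c1", start_bin = c(10L, 40L), end_bin = c(30L, 60L))
  cmT <- simulateContactMatrix(sizes, 20000, tads = tads, tad_boost = 2,
                               depth = 2e6, seed = 13)
  mt <- contactCounts(cmT)
  within <- mean(mt[cbind(12:25, 12:25 + 4)])
  between <- mean(mt[cbind(28:34, 28:34 + 4)])
  expect_gt(within, between)
})

test_that("fig1 replay reproduces the implanted event bookkeeping", {
  rep <- getReplay(42)
  expect_equal(nChromosomes(rep$species$sp1$layout), 12L)
  expect_equal(nChromosomes(rep$postGamma$layout), 21L)
  expect_equal(nChromosomes(rep$arGenome$layout), 8L)

  jt <- junctionTruth(rep$truth)
  j1 <- jt[jt$species == "sim_sp1", ]
  expect_equal(sum(j1$layer == "post-gamma"), 52L)  # 26 junctions x 2 copies
  expect_equal(sum(j1$layer == "post-beta"), 4L)
  expect_equal(length(unique(rep$truth@extra$gamma_junction_types)), 26L)
  expect_equal(length(unique(rep$truth@extra$beta_junction_types)), 4L)

  # 42 distinct implanted region classes
  lin <- lineageTruth(rep$truth)
  lin1 <- lin[lin$species == "sim_sp1", ]
  expect_equal(length(unique(paste(lin1$eu, lin1$gamma, lin1$beta))), 42L)

  # three implanted rearrangements across the two species
  expect_equal(length(rep$truth@events), 3L)
})

test_that("the replay is a deterministic function of its seed", {
  a <- fig1Replay(seed = 27, genes_per_chrom = 40, codons_per_gene = 60)
  b <- fig1Replay(seed = 27, genes_per_chrom = 40, codons_per_gene = 60)
  expect_identical(geneTable(a$species$sp1$layout), geneTable(b$species$sp1$layout))
  expect_identical(a$species$sp1$seqs, b$species$sp1$seqs)
  expect_identical(a$expression, b$expression)
  expect_identical(a$methylation, b$methylation)
  expect_identical(contactCounts(a$contacts), contactCounts(b$contacts))
  expect_identical(retentionTruth(a$truth), retentionTruth(b$truth))
})
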