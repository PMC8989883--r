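# Painting, copy-label resolution, junction counting, karyotype
# reconstruction, rearrangement detection and subgenome assignment.

test_that("an unrearranged duplicated genome paints as one segment per chromosome", {
  anc <- simulateAncestralGenome(3, 40, 20, seed = 51)
  g2 <- applyWGD(anc, 2L, "beta", 0.2, seed = 52)
  hom <- paleoshuffle:::truthHomology(g2, anc)
  bs <- detectCollinearBlocks(g2$layout, anc$layout, hom)
  p <- paintGenome(g2$layout, anc$layout, bs)
  s <- segmentTable(p)
  expect_equal(nrow(s), 6L)
  expect_equal(sort(unique(s$chrom)), sort(chromNames(g2$layout)))
})

test_that("a head+tail fusion paints as two ordered segments", {
  anc <- simulateAncestralGenome(2, 40, 20, seed = 53)
  plan <- list(neo = list(list(chrom = "Eu1", from = 0L, to = 20L),
                          list(chrom = "Eu2", from = 20L, to = 40L)),
               rest1 = list(list(chrom = "Eu1", from = 20L)),
               rest2 = list(list(chrom = "Eu2", from = 0L, to = 20L)))
  fused <- applyFusionPlan(anc, plan, "t")
  hom <- paleoshuffle:::truthHomology(list(layout = fused$layout, seqs = fused$seqs),
                                      anc)
  bs <- detectCollinearBlocks(fused$layout, anc$layout, hom)
  p <- paintGenome(fused$layout, anc$layout, bs)
  s <- segmentTable(p)
  neo <- s[s$chrom == "neo", ]
  expect_equal(nrow(neo), 2L)
  expect_equal(neo$origin[order(neo$start_rank)], c("Eu1", "Eu2"))
})

test_that("junction-count identity holds: junctions = segments - chromosomes", {
  pipe <- getPipeline(42)
  s <- segmentTable(pipe$labelled)
  j <- pipe$junctions$junctions
  # the replay's only homologous adjacencies are inversion flanks, which are
  # same-class and therefore not junctions; collapse same-class neighbours
  keys <- paste(s$chrom, paleoshuffle:::pairKey(s))
  s2 <- s[order(s$chrom, s$start_rank), ]
  k2 <- paste(s2$chrom, paleoshuffle:::pairKey(s2))
  runs <- sum(k2[-1] != k2[-length(k2)] |
                s2$chrom[-1] != s2$chrom[-length(s2$chrom)]) + 1L
  expect_equal(nrow(j), runs - length(unique(s2$chrom)))
})

test_that("fusion junctions are recovered per layer on the replay", {
  pipe <- getPipeline(42)
  expect_equal(pipe$junctions$post_gamma, 26L)
  expect_equal(pipe$junctions$post_beta, 4L)
  # junction positions sit within tolerance of the implanted truth
  rep <- getReplay(42)
  jt <- junctionTruth(rep$truth)
  jt <- jt[jt$species == "sim_sp1", ]
  called <- pipe$junctions$junctions
  hits <- vapply(seq_len(nrow(called)), function(i)
    any(jt$chrom == called$chrom[i] & abs(jt$pos - called$pos[i]) <= 5),
    logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the junction counter separates extant translocation breakpoints", {
  rep <- getReplay(42)
  pipe <- getPipeline(42)
  # second species carries the translocation: with event exclusion its
  # layer counts match the implanted history
  anc <- rep$ancestor
  sp2 <- rep$species$sp2
  b2 <- detectCollinearBlocks(sp2$layout, anc$layout,
                              filterLargeFamilies(rep$homology$sp2_vs_ancestor))
  p2 <- paintGenome(sp2$layout, anc$layout, b2)
  self2 <- detectCollinearBlocks(sp2$layout, sp2$layout, rep$homology$sp2_self,
                                 self = TRUE)
  ks2 <- blockAnchorKs(self2, sp2$seqs, sp2$seqs, max_per_block = Inf)
  lab2 <- resolveCopyLabels(p2, ks2$blockset, ks2$anchor_ks, sp2$layout, seed = 9)
  jx <- countFusionJunctions(lab2$painting, extant_events = pipe$events)
  expect_equal(jx$post_gamma, 26L)
  expect_equal(jx$post_beta, 4L)
  expect_gte(jx$extant, 2L)
})

test_that("karyotype reconstruction recovers the intermediate chromosome counts", {
  pipe <- getPipeline(42)
  expect_equal(pipe$karyotype$extant$n_chromosomes, 12L)
  expect_equal(pipe$karyotype$pre_beta$n_chromosomes, 8L)
  expect_equal(pipe$karyotype$post_gamma$n_chromosomes, 21L)
})

test_that("an unduplicated genome reconstructs to its own chromosome number", {
  anc <- simulateAncestralGenome(5, 30, 20, seed = 54)
  hom <- paleoshuffle:::truthHomology(anc, anc)
  bs <- detectCollinearBlocks(anc$layout, anc$layout, hom)
  p <- paintGenome(anc$layout, anc$layout, bs)
  expect_equal(reconstructKaryotype(p, "extant")$n_chromosomes, 5L)
})

test_that("region classes enumerate the full gamma x beta complement", {
  pipe <- getPipeline(42)
  expect_equal(pipe$region_classes$n, 42L)
  # each ancestor contributes six classes
  eus <- sub(":.*", "", pipe$region_classes$classes)
  expect_true(all(table(eus) == 6L))
  # class gene lists are disjoint
  allGenes <- unlist(pipe$region_classes$genes)
  expect_equal(anyDuplicated(allGenes), 0L)
})

test_that("a gamma-only genome yields 21 region classes", {
  rep <- getReplay(42)
  anc <- rep$ancestor
  pg <- rep$postGamma
  b <- detectCollinearBlocks(pg$layout, anc$layout,
                             filterLargeFamilies(rep$homology$post_gamma_vs_ancestor))
  p <- paintGenome(pg$layout, anc$layout, b)
  selfHom <- paleoshuffle:::truthHomology(pg, pg, self = TRUE)
  sb <- detectCollinearBlocks(pg$layout, pg$layout, selfHom, self = TRUE)
  ks <- blockAnchorKs(sb, pg$seqs, pg$seqs, max_per_block = Inf)
  lab <- resolveCopyLabels(p, ks$blockset, ks$anchor_ks, pg$layout, seed = 3)
  cl <- enumerateRegionClasses(lab$painting, pg$layout)
  # single-layer history: 21 chromosome copies, one side each
  expect_equal(length(unique(sub("[ab]$", "", cl$classes))), 21L)
})

test_that("self-comparison of a painting yields no rearrangement events", {
  pipe <- getPipeline(42)
  expect_equal(length(detectRearrangements(pipe$paintings$sp1,
                                           pipe$paintings$sp1)), 0L)
})

test_that("the replay's three rearrangements are recovered between species", {
  pipe <- getPipeline(42)
  kinds <- sort(vapply(pipe$events, `[[`, character(1), "kind"))
  expect_equal(kinds, c("inversion", "inversion", "reciprocal_translocation"))
  # the implanted inversion span is recovered within tolerance
  rep <- getReplay(42)
  tru <- Filter(function(e) e$kind == "inversion" && e$species == "sim_sp1",
                rep$truth@events)[[1]]
  det <- Filter(function(e) e$kind == "inversion" && e$chrom == tru$chrom,
                pipe$events)
  expect_equal(length(det), 1L)
  expect_lte(abs(det[[1]]$from - tru$from), 5)
  expect_lte(abs(det[[1]]$to - tru$to), 5)
})

test_that("subgenomes are assigned by Ks proximity to the diploid relative", {
  sim <- simulateAllotetraploid(seed = 61)
  hom <- filterLargeFamilies(sim$homology)
  bs <- detectCollinearBlocks(sim$tetraploid$layout, sim$diploid$layout, hom)
  ks <- blockAnchorKs(bs, sim$tetraploid$seqs, sim$diploid$seqs,
                      max_per_block = Inf)
  asg <- assignSubgenomes(sim$tetraploid$layout, sim$diploid$layout,
                          ks$blockset)
  expect_identical(asg[names(sim$truth)], sim$truth)

  # diploid input: no second covered partner
  bsd <- detectCollinearBlocks(sim$diploid$layout, sim$diploid$layout,
                               paleoshuffle:::truthHomology(sim$diploid, sim$diploid))
  expect_error(assignSubgenomes(sim$diploid$layout, sim$diploid$layout, bsd),
               "no homoeologous pairs")
})
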