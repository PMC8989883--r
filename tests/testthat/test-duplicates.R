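# Retention statistics, triad normalization/classification, methylation
# classes and expression diversity/specificity.

test_that("retention matrix indexes loci by class with exact bookkeeping", {
  rc <- list(classes = c("Eu1:Aa", "Eu1:Ab"),
             genes = list(`Eu1:Aa` = c("g1_Aa", "g2_Aa"),
                          `Eu1:Ab` = c("g1_Ab")))
  gl <- c(g1_Aa = "L1", g2_Aa = "L2", g1_Ab = "L1")
  m <- buildRetentionMatrix(rc, gl)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(rowSums(m)), c(2, 1))
  # empty class column stays all FALSE
  rc$classes <- c(rc$classes, "Eu1:Ba"); rc$genes$`Eu1:Ba` <- character(0)
  m2 <- buildRetentionMatrix(rc, gl)
  expect_false(any(m2[, "Eu1:Ba"]))
  # a gene list mapping one locus twice into a class is a painting bug
  rc3 <- list(classes = "Eu1:Aa",
              genes = list(`Eu1:Aa` = c("g1_Aa", "g1_dup")))
  expect_error(buildRetentionMatrix(rc3, c(g1_Aa = "L1", g1_dup = "L1")),
               "twice")
})

test_that("retention summary counts high-retention loci", {
  m <- matrix(FALSE, 10, 6)
  m[1, 1:4] <- TRUE; m[2, 1:5] <- TRUE
  m[3:10, 1] <- TRUE
  rownames(m) <- paste0("L", 1:10); colnames(m) <- paste0("c", 1:6)
  s <- retentionSummary(m, threshold_more_than = 3)
  expect_equal(s$high_retention_count, 2L)
  expect_equal(s$high_retention_pct, 20)
  expect_equal(unname(s$copy_number_table["1"]), 8L)
})

test_that("segment-pair retention classes match an explicit implant exactly", {
  sim <- simulateSegmentPairImplant(n_both = 69, n_only1 = 98, n_only2 = 112,
                                    seed = 5)
  m <- buildRetentionMatrix(sim$region_classes, sim$gene_locus)
  pr <- pairRetentionClasses(m, sim$classes[1], sim$classes[2])
  expect_equal(pr$both, 69L)
  expect_equal(pr$singleton_copy1, 98L)
  expect_equal(pr$singleton_copy2, 112L)
  expect_equal(unname(round(pr$pct, 1)), c(24.7, 35.1, 40.1))

  # all-both implant
  sim2 <- simulateSegmentPairImplant(50, 0, 0, seed = 6)
  m2 <- buildRetentionMatrix(sim2$region_classes, sim2$gene_locus)
  pr2 <- pairRetentionClasses(m2, sim2$classes[1], sim2$classes[2])
  expect_equal(unname(pr2$pct), c(100, 0, 0))

  # random implants across seeds reproduce truth exactly
  set.seed(7)
  for (i in 1:10) {
    nb <- sample(10:60, 1); n1 <- sample(10:60, 1); n2 <- sample(10:60, 1)
    s3 <- simulateSegmentPairImplant(nb, n1, n2, seed = i)
    m3 <- buildRetentionMatrix(s3$region_classes, s3$gene_locus)
    p3 <- pairRetentionClasses(m3, s3$classes[1], s3$classes[2])
    expect_equal(c(p3$both, p3$singleton_copy1, p3$singleton_copy2),
                 c(nb, n1, n2))
  }
  expect_error(pairRetentionClasses(m, "Eu1:Ca", "nope"), "not found")
})

test_that("genome-wide retention implant is recovered exactly", {
  sim <- simulateRetentionImplant(n_loci = 2000, n_high = 150, seed = 8)
  m <- buildRetentionMatrix(sim$region_classes, sim$gene_locus)
  s <- retentionSummary(m, threshold_more_than = 3)
  expect_equal(s$n_loci, 2000L)
  expect_equal(s$high_retention_count, 150L)
  expect_setequal(rownames(m)[rowSums(m) > 3], sim$truth_high)
})

test_that("replay retention matrix matches generator truth per locus", {
  rep <- getReplay(42)
  pipe <- getPipeline(42)
  gl <- geneLocusMap(rep$homology$sp1_vs_ancestor, rep$ancestor$layout)
  m <- buildRetentionMatrix(pipe$region_classes, gl)
  tru <- retentionTruth(rep$truth)
  truCount <- table(tru$locus)
  common <- intersect(rownames(m), names(truCount))
  # painted classes cover nearly every retained copy; per-locus copy
  # numbers agree exactly on the covered loci (copy-class NAMES are only
  # identifiable up to a relabelling convention)
  expect_gte(length(common) / length(truCount), 0.99)
  agree <- rowSums(m)[common] == as.integer(truCount[common])
  expect_gte(mean(agree), 0.98)
  # every matrix cell points at a distinct real gene
  gid <- attr(m, "gene_ids")
  expect_equal(anyDuplicated(gid[!is.na(gid)]), 0L)
  expect_true(all(gid[!is.na(gid)] %in% tru$gene_id))
})

test_that("triad normalization follows the TPM-share definition", {
  fr <- triadNormalize(10, 30, 60)
  expect_equal(unlist(fr[, 1:3], use.names = FALSE), c(0.1, 0.3, 0.6))
  expect_equal(unlist(triadNormalize(5, 5, 5)[, 1:3], use.names = FALSE),
               rep(1 / 3, 3))
  expect_equal(unlist(triadNormalize(0, 0, 7)[, 1:3], use.names = FALSE),
               c(0, 0, 1))
  z <- triadNormalize(0, 0, 0)
  expect_false(z$expressed)
  expect_true(is.na(z$frac_leaf))
  expect_error(triadNormalize(-1, 2, 3), "non-negative")
})

test_that("triads classify to the nearest of the seven archetypes", {
  expect_equal(classifyTriad(1 / 3, 1 / 3, 1 / 3), "Balanced")
  expect_equal(classifyTriad(0.9, 0.05, 0.05), "Leaf-dominant")
  expect_equal(classifyTriad(0.02, 0.49, 0.49), "Leaf-suppressed")
  expect_equal(classifyTriad(0.49, 0.02, 0.49), "Root-suppressed")
  expect_equal(classifyTriad(0.05, 0.9, 0.05), "Root-dominant")
  expect_error(classifyTriad(0.5, 0.1, 0.1), "sum to 1")
})

test_that("every classified triad has fractions summing to one", {
  rep <- getReplay(42)
  tt <- triadTable(rep$expression)
  ok <- tt$expressed
  expect_true(all(abs(tt$frac_leaf[ok] + tt$frac_root[ok] + tt$frac_stem[ok] - 1)
                  < 1e-9))
})

test_that("methylation classes follow the thresholds with inclusive bounds", {
  expect_equal(classifyMethylation(0.1), "hypo")
  expect_equal(classifyMethylation(0.3), "hypo")
  expect_equal(classifyMethylation(0.7), "hyper")
  expect_equal(classifyMethylation(0.5), "intermediate")
  expect_error(classifyMethylation(1.2), "\\[0, 1\\]")
})

test_that("methylation class proportions match a beta-mixture truth", {
  set.seed(9)
  n <- 6000
  grp <- sample(c("lo", "hi"), n, TRUE, prob = c(0.5, 0.5))
  mC <- ifelse(grp == "lo", rbeta(n, 2, 8), rbeta(n, 8, 2))
  truthProp <- c(hypo = mean(mC <= 0.3), hyper = mean(mC >= 0.7),
                 intermediate = mean(mC > 0.3 & mC < 0.7))
  cls <- classifyMethylation(mC)
  got <- prop.table(table(cls))
  for (k in names(truthProp))
    expect_equal(unname(got[k]), unname(truthProp[k]), tolerance = 0.02)
})

test_that("Dj/Sj behave at the degenerate corners and respond to divergence", {
  # identical profiles: Dj = 0
  tri <- data.frame(gene_id = paste0("g", 1:4),
                    frac_leaf = 0.5, frac_root = 0.3, frac_stem = 0.2,
                    expressed = TRUE, region_class = "r1")
  ds <- expressionDiversitySpecificity(tri)
  expect_equal(ds$Dj, 0)
  # one-tissue-only expression: tau = 1
  tri2 <- data.frame(gene_id = "g1", frac_leaf = 1, frac_root = 0,
                     frac_stem = 0, expressed = TRUE, region_class = "r2")
  ds2 <- expressionDiversitySpecificity(tri2)
  expect_equal(ds2$Sj, 1)
  expect_true(is.na(ds2$Dj))  # single gene: diversity undefined

  # lower Dirichlet concentration (more divergent profiles) raises Dj
  lay <- tinyLayout(300)
  mkDj <- function(conc) {
    ex <- simulateExpression(lay, archetype_fracs = c(Balanced = 1),
                             concentration = conc, seed = 10)
    tt <- triadTable(ex$records)
    tt$region_class <- "r"
    expressionDiversitySpecificity(tt)$Dj
  }
  expect_gt(mkDj(3), mkDj(100))
})
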