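# ICE balancing, O/E normalization, compartment and TAD calling, topology
# comparison and TAD profiles.

simpleCM <- function(m, resolution = 1000, chrom = "c1") {
  sizes <- stats::setNames(nrow(m) * resolution, chrom)
  new("ContactMatrix", counts = m, resolution = resolution,
      bins = paleoshuffle:::makeBins(sizes, resolution), balanced = FALSE,
      bias = numeric(0))
}

test_that("ICE equalizes row sums and reconstructs the raw matrix", {
  set.seed(3)
  n <- 60
  base <- outer(1:n, 1:n, function(i, j) 1 / (abs(i - j) + 1))
  bias <- runif(n, 0.5, 2)
  raw <- round(base * outer(bias, bias) * 400)
  cm <- simpleCM(raw)
  bal <- iceBalance(cm)
  w <- contactCounts(bal)
  rs <- rowSums(w, na.rm = TRUE); rs <- rs[rs > 0]
  expect_lt(sd(rs) / mean(rs), 1e-5)
  # reconstruction identity raw ~= b_i b_j balanced on unmasked bins
  b <- biasVector(bal)
  rec <- outer(b, b) * w
  ok <- !is.na(w)
  expect_lt(max(abs(rec[ok] - raw[ok])) / max(raw), 1e-6)
  expect_true(isBalanced(bal))

  # already-balanced input is a fixed point (returned unchanged within tol)
  bal2 <- iceBalance(bal)
  w2 <- contactCounts(bal2)
  expect_equal(w2[ok & !is.na(w2)], w[ok & !is.na(w2)], tolerance = 1e-3)

  expect_error(iceBalance(simpleCM(matrix(0, 4, 4))), "all-zero")
})

test_that("observed/expected self-normalizes a pure decay matrix", {
  n <- 80
  m <- outer(1:n, 1:n, function(i, j) 100 / (abs(i - j) + 1))
  cm <- simpleCM(m)
  cm@balanced <- TRUE
  oe <- observedOverExpected(cm)
  expect_equal(mean(oe, na.rm = TRUE), 1, tolerance = 0.05)
  expect_lt(max(abs(oe - 1), na.rm = TRUE), 0.25)

  # checkerboard modulation survives O/E
  lab <- rep(c(1, -1), each = 10, length.out = n)
  chk <- m * exp(0.4 * outer(lab, lab))
  oe2 <- observedOverExpected(simpleCM(chk))
  same <- outer(lab, lab) > 0
  off <- abs(row(oe2) - col(oe2)) > 2
  expect_gt(mean(oe2[same & off], na.rm = TRUE),
            mean(oe2[!same & off], na.rm = TRUE))
})

test_that("expected counts decrease with distance for power-law input", {
  set.seed(4)
  n <- 70
  m <- outer(1:n, 1:n, function(i, j) 200 * (abs(i - j) + 1)^-1.2)
  m <- m + matrix(rnorm(n^2, 0, 0.5), n, n); m <- (m + t(m)) / 2
  cm <- simpleCM(m); cm@balanced <- TRUE
  oe <- observedOverExpected(cm)
  dmean <- vapply(0:(n - 1), function(d) {
    v <- m[col(m) - row(m) == d] / oe[col(oe) - row(oe) == d]
    mean(v, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(dmean[1:40]) < 1e-8))
})

test_that("compartment labels are sign-orientation invariant and handle degeneracy", {
  set.seed(5)
  nb <- 100
  comp <- rep(rep(c("A", "B"), 5), each = 10)
  cm <- simulateContactMatrix(c(c1 = nb * 20000), 20000, compartments = comp,
                              depth = 8e5, seed = 6)
  bal <- iceBalance(cm)
  oe <- observedOverExpected(bal)
  gd <- ifelse(comp == "A", 3, 1)
  cc <- callCompartments(oe, binTable(bal), gd)
  acc <- mean(cc$label == comp, na.rm = TRUE)
  expect_gte(acc, 0.95)
  # inverting the gene-density track flips the A/B orientation
  cc2 <- callCompartments(oe, binTable(bal), -gd)
  ok <- !is.na(cc$label)
  expect_true(all(cc$label[ok] != cc2$label[ok]))

  # constant (structureless) matrix: all NA with a warning
  n1 <- 40
  flat <- matrix(1, n1, n1)
  cmf <- simpleCM(flat); cmf@balanced <- TRUE
  oef <- observedOverExpected(cmf)
  expect_warning(ccf <- callCompartments(oef, binTable(cmf), rep(1, n1)),
                 "constant|few")
  expect_true(all(is.na(ccf$label)))
})

test_that("insulation score is flat on uniform input and dips at a block junction", {
  n <- 60
  uni <- simpleCM(matrix(5, n, n)); uni@balanced <- TRUE
  ins <- insulationScore(uni, window = 5000)
  expect_true(all(abs(ins$score[!is.na(ins$score)]) < 1e-12))
  expect_equal(sum(is.na(ins$score)), 2 * 5)  # w bins at each end

  blocky <- matrix(1, n, n)
  blocky[1:30, 1:30] <- 6; blocky[31:60, 31:60] <- 6
  bm <- simpleCM(blocky); bm@balanced <- TRUE
  ins2 <- insulationScore(bm, window = 5000)
  expect_equal(which.min(ins2$score), 30, tolerance = 1)
  expect_error(insulationScore(uni, window = 1000), "at least 2")
})

test_that("TAD calling tiles chromosomes and degrades to one domain", {
  n <- 50
  uni <- simpleCM(matrix(5, n, n)); uni@balanced <- TRUE
  ins <- insulationScore(uni, window = 5000)
  td <- callTads(ins, 1000)
  expect_equal(nrow(td), 1L)
  expect_equal(td$start_bin, 0L)
  expect_equal(td$end_bin, n)

  # implanted domains: sorted non-overlapping tiling
  cm <- simulateContactMatrix(c(c1 = 2e6), 20000,
                              tads = data.frame(chrom = "c1",
                                                start_bin = c(0L, 40L, 70L),
                                                end_bin = c(40L, 70L, 100L)),
                              depth = 2e6, seed = 8)
  bal <- iceBalance(cm)
  ins2 <- insulationScore(bal, window = 100000)
  td2 <- callTads(ins2, 20000, delta_span = 100000)
  expect_true(all(diff(td2$start_bin) > 0))
  expect_equal(td2$start_bin[-1], td2$end_bin[-nrow(td2)])
  expect_equal(td2$end_bin[nrow(td2)], 100L)
})

test_that("region topology contrast finds implanted homoeologous enrichment", {
  sizes <- c(c1 = 4e6, c2 = 4e6, c3 = 4e6)
  regions <- data.frame(chrom = rep(c("c1", "c2", "c3"), each = 2),
                        start = rep(c(0, 2e6), 3), end = rep(c(2e6, 4e6), 3),
                        class = paste0("r", 1:6),
                        ancestor = rep(c("Eu1", "Eu2"), 3))
  cm <- simulateContactMatrix(sizes, 100000, depth = 2e6,
                              region_classes = regions, homolog_boost = 1.6,
                              seed = 9)
  ct <- compareRegionTopology(iceBalance(cm), regions)
  expect_gt(ct$within_mean, ct$between_mean)
  expect_lt(ct$t_test$p.value, 0.01)
  # no intra-chromosomal or self pairs in scope
  expect_false(any(ct$pair_table$class1 == ct$pair_table$class2))
})

test_that("TAD profiles separate interior from border genes", {
  lay <- tinyLayout(200)  # genes every 1 kb over 200 kb
  tads <- data.frame(chrom = "chr1", start = c(0, 1e5), end = c(1e5, 2e5))
  set.seed(10)
  g <- geneTable(lay)
  mid <- (g$start + g$end) / 2
  interior <- (mid > 2e4 & mid < 8e4) | (mid > 1.2e5 & mid < 1.8e5)
  mC <- stats::setNames(ifelse(interior, rbeta(200, 8, 3), rbeta(200, 3, 8)),
                        g$gene_id)
  tpm <- stats::setNames(ifelse(interior, rlnorm(200, 1), rlnorm(200, 2)),
                         g$gene_id)
  pr <- profileOverTads(tads, lay, mC, tpm, resolution = 20000)
  zm <- pr$zone_means
  expect_gt(zm$mC[zm$zone == "interior"], zm$mC[zm$zone == "border"])
  expect_lt(zm$tpm[zm$zone == "interior"], zm$tpm[zm$zone == "border"])
  # partition: every gene in exactly one zone
  expect_equal(nrow(pr$zone_table), 200L)
  expect_true(all(pr$zone_table$zone %in% c("interior", "border")))
})

test_that("replay methylation shows the implanted TAD-interior enrichment", {
  rep <- getReplay(42)
  tads <- rep$truth@extra$tads
  tadsBp <- data.frame(chrom = tads$chrom, start = tads$start_bin * 10000,
                       end = tads$end_bin * 10000)
  mC <- stats::setNames(rep$methylation$mC, rep$methylation$gene_id)
  tt <- triadTable(rep$expression)
  tpm <- stats::setNames(tt$tpm_leaf + tt$tpm_root + tt$tpm_stem, tt$gene_id)
  pr <- profileOverTads(tadsBp, rep$species$sp1$layout, mC, tpm,
                        resolution = 10000)
  zm <- pr$zone_means
  expect_gt(zm$mC[zm$zone == "interior"], zm$mC[zm$zone == "border"])
})
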