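# Family filtering, DP anchor chaining against a brute-force oracle,
# ancestral-gene calling and paralog depth classes.

test_that("families above the size threshold are removed", {
  # a 31-member clique family plus one small pair
  big <- t(combn(paste0("f", 1:31), 2))
  pairs <- data.frame(query = c(big[, 1], "x1"),
                      subject = c(big[, 2], "x2"),
                      stringsAsFactors = FALSE)
  out <- filterLargeFamilies(pairs, max_family_size = 30)
  expect_equal(nrow(out), 1L)
  expect_equal(out$query, "x1")
  expect_identical(filterLargeFamilies(pairs, Inf), pairs)
})

test_that("remaining families after filtering are all within the limit", {
  set.seed(21)
  # random sparse graph over disjoint 15-gene pools: a mix of small
  # components and a few above the limit
  pools <- split(paste0("g", 1:150), rep(1:10, each = 15))
  pairs <- do.call(rbind, lapply(pools, function(p) {
    n <- sample(5:20, 1)
    data.frame(query = sample(p, n, TRUE), subject = sample(p, n, TRUE),
               stringsAsFactors = FALSE)
  }))
  pairs <- pairs[pairs$query != pairs$subject, ]
  out <- filterLargeFamilies(pairs, max_family_size = 8)
  expect_gt(nrow(out), 0)
  expect_lt(nrow(out), nrow(pairs))
  # recount: connected components of the remaining graph
  g <- unique(c(out$query, out$subject))
  comp <- seq_along(g); names(comp) <- g
  for (k in seq_len(nrow(out))) {
    r1 <- comp[out$query[k]]; r2 <- comp[out$subject[k]]
    comp[comp == r1] <- r2
  }
  expect_true(all(table(comp) <= 8))
})

test_that("perfectly collinear anchors chain into one oriented block", {
  la <- tinyLayout(30, prefix = "a"); lb <- tinyLayout(30, prefix = "b")
  anc <- linkAnchors(la, lb, "a1", "b1", 0:9, 10:19)
  bs <- detectCollinearBlocks(la, lb, anc)
  expect_equal(nrow(blockTable(bs)), 1L)
  expect_equal(blockTable(bs)$n_anchors, 10L)
  expect_equal(blockTable(bs)$orientation, "+")

  # mirrored ranks in genome b give one "-" block
  anc2 <- linkAnchors(la, lb, "a1", "b1", 0:9, 19:10)
  bs2 <- detectCollinearBlocks(la, lb, anc2)
  expect_equal(nrow(blockTable(bs2)), 1L)
  expect_equal(blockTable(bs2)$orientation, "-")
})

test_that("a gap above the limit splits runs into two blocks", {
  la <- tinyLayout(150, prefix = "a"); lb <- tinyLayout(150, prefix = "b")
  anc <- rbind(linkAnchors(la, lb, "a1", "b1", 0:5, 0:5),
               linkAnchors(la, lb, "a1", "b1", 66:71, 66:71))
  bs <- detectCollinearBlocks(la, lb, anc, max_gap = 50, min_anchors = 5)
  expect_equal(nrow(blockTable(bs)), 2L)
  expect_true(all(blockTable(bs)$n_anchors == 6L))
})

test_that("DP chaining matches the exhaustive oracle on small instances", {
  set.seed(31)
  for (case in 1:30) {
    n <- sample(6:12, 1)
    ra <- sample(0:40, n)
    rb <- sample(0:40, n)
    gap <- sample(c(5, 10, 50), 1)
    best <- max(oracleMaxChain(ra, rb, gap, "+"),
                oracleMaxChain(ra, rb, gap, "-"))
    chain <- max(length(paleoshuffle:::chainDP(ra, rb, gap)),
                 length(paleoshuffle:::chainDP(ra, -rb, gap)))
    expect_equal(chain, best)
  }
})

test_that("block invariants hold on pipeline output", {
  pipe <- getPipeline(42)
  bs <- pipe$blocks$sp1
  expect_silent(paleoshuffle:::assertBlockInvariants(blockTable(bs),
                                                     anchorTable(bs), 50))
})

test_that("ancestral genes need anchors in at least two subgenomes", {
  mk <- function(genes) {
    new("CollinearBlockSet",
        blocks = data.frame(block_id = 1L, chrom_a = "x", chrom_b = "r",
                            orientation = "+", n_anchors = length(genes),
                            start_a = 0L, end_a = 1L, start_b = 0L, end_b = 1L,
                            median_ks = NA_real_),
        anchors = data.frame(block_id = 1L, gene_a = paste0("q", seq_along(genes)),
                             gene_b = genes, chrom_a = "x", chrom_b = "r",
                             rank_a = seq_along(genes), rank_b = seq_along(genes),
                             similarity = 100))
  }
  bl <- list(s1 = mk(c("r1", "r2")), s2 = mk(c("r1", "r3")), s3 = mk("r1"))
  out <- callAncestralGenes(bl, min_subgenomes = 2)
  expect_setequal(out, "r1")
  expect_setequal(callAncestralGenes(bl, min_subgenomes = 1), c("r1", "r2", "r3"))
})

test_that("ancestral-gene calling recovers multi-copy loci on the replay", {
  rep <- getReplay(42)
  pipe <- getPipeline(42)
  # the two species act as the independent genomes anchored to the ancestor
  called <- callAncestralGenes(list(sp1 = pipe$blocks$sp1,
                                    sp2 = pipe$blocks$sp2),
                               min_subgenomes = 2)
  g <- geneTable(rep$ancestor$layout)
  called_loci <- g$family_id[match(called, g$gene_id)]
  ret <- retentionTruth(rep$truth)
  multi <- names(which(table(ret$locus) >= 2))
  expect_gte(mean(multi %in% called_loci), 0.95)
})

test_that("paralog depth takes the top two homologs as in-paralogous", {
  h <- data.frame(gene_id = paste0("h", 1:6),
                  similarity = c(90, 95, 80, 70, 60, 50))
  out <- classifyParalogDepth(h)
  expect_setequal(out$in_paralog, c("h1", "h2"))
  expect_equal(length(out$out_paralog), 4L)
  one <- classifyParalogDepth(data.frame(gene_id = "h1", similarity = 99))
  expect_equal(one$in_paralog, "h1")
  expect_equal(length(one$out_paralog), 0L)
  none <- classifyParalogDepth(data.frame(gene_id = character(0),
                                          similarity = numeric(0)))
  expect_equal(length(none$in_paralog), 0L)
})

test_that("in-paralog pairs are younger than out-paralog pairs on the replay", {
  rep <- getReplay(42)
  g <- geneTable(rep$species$sp1$layout)
  hom <- rep$homology$sp1_self
  set.seed(5)
  loci <- sample(names(which(table(g$locus) >= 4)), 25)
  ksIn <- c(); ksOut <- c()
  for (lc in loci) {
    ids <- g$gene_id[g$locus == lc]
    ref <- ids[1]
    hits <- hom[hom$query == ref | hom$subject == ref, ]
    other <- ifelse(hits$query == ref, hits$subject, hits$query)
    cls <- classifyParalogDepth(data.frame(gene_id = other,
                                           similarity = hits$bitscore))
    for (x in cls$in_paralog)
      ksIn <- c(ksIn, paleoshuffle:::ksNG86Int(rep$species$sp1$seqs[ref, ],
                                               rep$species$sp1$seqs[x, ])$Ks)
    for (x in cls$out_paralog)
      ksOut <- c(ksOut, paleoshuffle:::ksNG86Int(rep$species$sp1$seqs[ref, ],
                                                 rep$species$sp1$seqs[x, ])$Ks)
  }
  expect_lt(median(ksIn, na.rm = TRUE), median(ksOut, na.rm = TRUE))
})

test_that("block anchor statistics report mean and normal CI", {
  b <- data.frame(n_anchors = c(10L, 10L, 10L))
  st <- blockAnchorStats(b)
  expect_equal(st$mean, 10)
  expect_equal(diff(st$ci), 0)
  st2 <- blockAnchorStats(data.frame(n_anchors = c(5L, 15L)))
  expect_equal(st2$mean, 10)
  expect_equal(st2$se, 5)
  expect_error(blockAnchorStats(data.frame(n_anchors = 7L)), "at least 2")
})

test_that("anchor-count CI covers a known mean at the nominal rate", {
  set.seed(41)
  cover <- vapply(1:200, function(i) {
    n <- rpois(30, 17)
    st <- blockAnchorStats(data.frame(n_anchors = n))
    st$ci[1] <= 17 && 17 <= st$ci[2]
  }, logical(1))
  expect_gt(mean(cover), 0.88)  # normal approximation of a 95% CI
})
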