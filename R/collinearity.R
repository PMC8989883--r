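## Collinear block detection: anchor chaining by sparse dynamic programming
## under the rank-gap rule, gene-family size filtering, ancestral-gene
## calling and paralog depth classing.

#' Remove homology pairs touching large gene families
#'
#' Gene families are connected components of the homology graph; every
#' pair with an endpoint in a family of more than \code{max_family_size}
#' members is removed.
#'
#' @param pairs data.frame with query, subject columns (homology records).
#' @param max_family_size maximum family size kept (default 30).
#' @return the filtered pairs.
#' @export
filterLargeFamilies <- function(pairs, max_family_size = 30) {
  if (nrow(pairs) == 0L || is.infinite(max_family_size)) return(pairs)
  genes <- unique(c(pairs$query, pairs$subject))
  comp <- seq_along(genes)
  names(comp) <- genes
  # union-find with path compression
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  qi <- match(pairs$query, genes); si <- match(pairs$subject, genes)
  for (k in seq_len(nrow(pairs))) {
    a <- find(qi[k]); b <- find(si[k])
    if (a != b) comp[a] <- b
  }
  root <- vapply(seq_along(genes), find, integer(1))
  famSize <- table(root)
  big <- as.integer(names(famSize))[famSize > max_family_size]
  drop <- root[qi] %in% big | root[si] %in% big
  psLog("filter_large_families", input = nrow(pairs), removed = sum(drop),
        families_removed = length(big))
  pairs[!drop, , drop = FALSE]
}

# Longest chain (max anchor count) in one orientation by O(n^2) DP under
# the both-genome gap rule; returns indices of the best chain.
chainDP <- function(ra, rb, max_gap) {
  n <- length(ra)
  o <- order(ra, rb)
  ra <- ra[o]; rb <- rb[o]
  len <- rep(1L, n); pred <- rep(0L, n)
  for (i in seq_len(n)[-1]) {
    j <- seq_len(i - 1L)
    ok <- ra[j] < ra[i] & rb[j] < rb[i] &
      ra[i] - ra[j] - 1L <= max_gap & rb[i] - rb[j] - 1L <= max_gap
    if (any(ok)) {
      lj <- len[j]; lj[!ok] <- 0L
      jbest <- which.max(lj)
      if (lj[jbest] + 1L > len[i]) { len[i] <- lj[jbest] + 1L; pred[i] <- jbest }
    }
  }
  # best chain; ties resolved toward the leftmost start in genome a
  best <- which(len == max(len))
  starts <- vapply(best, function(i) { while (pred[i] > 0L) i <- pred[i]; ra[i] },
                   integer(1))
  i <- best[order(starts, best)][1]
  chain <- integer(0)
  while (i > 0L) { chain <- c(i, chain); i <- pred[i] }
  o[chain]
}

#' Detect collinear blocks between two layouts
#'
#' Anchors (homologous gene pairs present in both layouts) are chained per
#' chromosome pair and orientation by dynamic programming maximizing the
#' anchor count, subject to strict rank monotonicity and a maximal rank gap
#' of \code{max_gap} intervening genes on both genomes. Chains are
#' extracted greedily by score (ties to the leftmost start in the first
#' layout), each anchor joins at most one block, and chains with fewer
#' than \code{min_anchors} anchors are discarded.
#'
#' @param layout_a,layout_b GenomeLayouts.
#' @param anchors homology records (query in a, subject in b), ideally
#'   family-filtered.
#' @param max_gap maximal intervening-gene gap (default 50).
#' @param min_anchors minimal anchors per block (default 5).
#' @param self logical: layouts are the same genome (mirror-duplicate
#'   anchors are collapsed).
#' @return a \linkS4class{CollinearBlockSet}.
#' @export
detectCollinearBlocks <- function(layout_a, layout_b, anchors, max_gap = 50,
                                  min_anchors = 5, self = FALSE) {
  ga <- geneTable(layout_a); gb <- geneTable(layout_b)
  ia <- match(anchors$query, ga$gene_id)
  ib <- match(anchors$subject, gb$gene_id)
  ok <- !is.na(ia) & !is.na(ib)
  an <- data.frame(gene_a = anchors$query[ok], gene_b = anchors$subject[ok],
                   chrom_a = ga$chrom[ia[ok]], chrom_b = gb$chrom[ib[ok]],
                   rank_a = ga$rank[ia[ok]], rank_b = gb$rank[ib[ok]],
                   similarity = if (!is.null(anchors$bitscore)) anchors$bitscore[ok] else
                     anchors$pct_identity[ok],
                   stringsAsFactors = FALSE)
  if (self) {
    # orient each pair canonically and drop self-hits
    flip <- an$chrom_a > an$chrom_b |
      (an$chrom_a == an$chrom_b & an$rank_a > an$rank_b)
    an[flip, c("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b")] <-
      an[flip, c("gene_b", "gene_a", "chrom_b", "chrom_a", "rank_b", "rank_a")]
    an <- an[!(an$gene_a == an$gene_b), , drop = FALSE]
    an <- an[!duplicated(an[, c("gene_a", "gene_b")]), , drop = FALSE]
  }
  blocks <- list(); anchorRows <- list(); bid <- 0L
  for (key in unique(paste(an$chrom_a, an$chrom_b, sep = "\r"))) {
    sub <- an[paste(an$chrom_a, an$chrom_b, sep = "\r") == key, , drop = FALSE]
    avail <- rep(TRUE, nrow(sub))
    repeat {
      if (sum(avail) < min_anchors) break
      ra <- sub$rank_a[avail]; rb <- sub$rank_b[avail]
      fwd <- chainDP(ra, rb, max_gap)
      rev_ <- chainDP(ra, -rb, max_gap)
      use <- if (length(fwd) >= length(rev_)) list(idx = fwd, orient = "+") else
        list(idx = rev_, orient = "-")
      if (length(use$idx) < min_anchors) break
      rows <- which(avail)[use$idx]
      bid <- bid + 1L
      ch <- sub[rows, , drop = FALSE]
      blocks[[bid]] <- data.frame(
        block_id = bid, chrom_a = ch$chrom_a[1], chrom_b = ch$chrom_b[1],
        orientation = use$orient, n_anchors = nrow(ch),
        start_a = min(ch$rank_a), end_a = max(ch$rank_a),
        start_b = min(ch$rank_b), end_b = max(ch$rank_b),
        median_ks = NA_real_, stringsAsFactors = FALSE)
      anchorRows[[bid]] <- cbind(block_id = bid, ch)
      avail[rows] <- FALSE
    }
  }
  bs <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block_id = integer(0), chrom_a = character(0),
               chrom_b = character(0), orientation = character(0),
               n_anchors = integer(0), start_a = integer(0), end_a = integer(0),
               start_b = integer(0), end_b = integer(0), median_ks = numeric(0))
  as <- if (length(anchorRows)) do.call(rbind, anchorRows) else
    data.frame(block_id = integer(0), gene_a = character(0), gene_b = character(0),
               chrom_a = character(0), chrom_b = character(0),
               rank_a = integer(0), rank_b = integer(0), similarity = numeric(0))
  rownames(bs) <- rownames(as) <- NULL
  assertBlockInvariants(bs, as, max_gap)
  psLog("detect_collinear_blocks", anchors_in = nrow(an), blocks = nrow(bs),
        anchors_chained = nrow(as))
  new("CollinearBlockSet", blocks = bs, anchors = as)
}

# Structural invariants asserted on every block set: strict monotonicity in
# both genomes (direction per orientation) and the gap rule.
assertBlockInvariants <- function(blocks, anchors, max_gap) {
  for (b in blocks$block_id) {
    a <- anchors[anchors$block_id == b, , drop = FALSE]
    a <- a[order(a$rank_a), , drop = FALSE]
    if (is.unsorted(a$rank_a, strictly = TRUE))
      stop("block ", b, ": rank_a not strictly increasing")
    db <- diff(a$rank_b)
    ori <- blocks$orientation[blocks$block_id == b]
    if (ori == "+" && any(db <= 0)) stop("block ", b, ": rank_b not increasing")
    if (ori == "-" && any(db >= 0)) stop("block ", b, ": rank_b not decreasing")
    if (any(diff(a$rank_a) - 1L > max_gap) || any(abs(db) - 1L > max_gap))
      stop("block ", b, ": gap rule violated")
  }
  invisible(TRUE)
}

#' Call ancestral genes from blocks against a common reference
#'
#' A reference gene is called ancestral when it appears as a block anchor
#' in at least \code{min_subgenomes} distinct subgenomes/species.
#'
#' @param blocks_by_subgenome named list of CollinearBlockSets, each
#'   computed subgenome-vs-reference with the reference as genome b.
#' @param min_subgenomes minimum distinct subgenomes (default 2).
#' @return character vector of ancestral reference gene ids.
#' @export
callAncestralGenes <- function(blocks_by_subgenome, min_subgenomes = 2) {
  hits <- lapply(blocks_by_subgenome, function(bs) unique(anchorTable(bs)$gene_b))
  tab <- table(unlist(hits))
  out <- names(tab)[tab >= min_subgenomes]
  psLog("call_ancestral_genes", subgenomes = length(blocks_by_subgenome),
        ancestral = length(out))
  out
}

#' Classify homologs of a reference gene by paralog depth
#'
#' The top two homologs by similarity are in-paralogous (the most recent
#' duplication layer), the rest out-paralogous. Ties are broken by
#' lexicographic gene id (logged).
#'
#' @param homologs data.frame with gene_id and similarity for the homologs
#'   of one reference gene.
#' @return list(in_paralog = character, out_paralog = character).
#' @export
classifyParalogDepth <- function(homologs) {
  if (nrow(homologs) == 0L) return(list(in_paralog = character(0),
                                        out_paralog = character(0)))
  o <- order(-homologs$similarity, homologs$gene_id)
  if (nrow(homologs) > 2L &&
      homologs$similarity[o[2]] == homologs$similarity[o[3]])
    psLog("classify_paralog_depth", tie_broken = "lexicographic")
  top <- homologs$gene_id[o][seq_len(min(2L, nrow(homologs)))]
  list(in_paralog = top, out_paralog = setdiff(homologs$gene_id[o], top))
}

#' Mean anchors per block with a normal-approximation 95% CI
#'
#' @param blocks a CollinearBlockSet (or its block table).
#' @return list(mean, se, ci = c(lower, upper), n_blocks).
#' @export
blockAnchorStats <- function(blocks) {
  b <- if (is(blocks, "CollinearBlockSet")) blockTable(blocks) else blocks
  n <- b$n_anchors
  if (length(n) < 2L) stop("need at least 2 blocks for a CI")
  m <- mean(n); se <- stats::sd(n) / sqrt(length(n))
  list(mean = m, se = se, ci = c(m - 1.96 * se, m + 1.96 * se),
       n_blocks = length(n))
}
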