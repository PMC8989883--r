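## Ancestral-origin painting of extant chromosomes, gamma/beta copy-label
## resolution from Ks layers, fusion-junction counting per WGD layer,
## intermediate karyotype reconstruction, rearrangement detection and
## subgenome assignment.

#' Paint an extant genome by ancestral origin
#'
#' Projects each extant-vs-ancestor collinear block to a segment, merges
#' adjacent segments of the same origin and orientation separated by less
#' than \code{max_gap} genes on both coordinate systems, and drops segments
#' shorter than \code{min_segment_genes}.
#'
#' @param extant,ancestor GenomeLayouts.
#' @param blocks a CollinearBlockSet with the extant genome as side a.
#' @param min_segment_genes minimal genes per reported segment (default 5).
#' @param max_gap merge gap (default 50).
#' @return a \linkS4class{SegmentPainting}.
#' @export
paintGenome <- function(extant, ancestor, blocks, min_segment_genes = 5,
                        max_gap = 50) {
  bt <- blockTable(blocks)
  if (nrow(bt) == 0L) {
    warning("no blocks; empty painting")
    return(new("SegmentPainting",
               segments = emptySegments(), chromLengths = chromGeneCounts(extant)))
  }
  at <- anchorTable(blocks)
  # one working segment per block, carrying its anchors; a chain can span a
  # short foreign insertion (e.g. an inverted span bridged by the forward
  # chain), so overlapping spans are resolved by splitting the bracketing
  # segment at the intruder's boundaries
  trimRaided <- function(anch, jump = 20L, max_trim = 3L) {
    # a chain bridging a short foreign span (e.g. an inversion) can raid
    # a stray anchor from inside it; such anchors show as a large
    # ancestral-rank jump at the chain ends and are dropped
    anch <- anch[order(anch$rank_a), , drop = FALSE]
    for (k in seq_len(max_trim)) {
      n <- nrow(anch)
      if (n < 3) break
      if (abs(anch$rank_b[n] - anch$rank_b[n - 1]) > jump)
        anch <- anch[-n, , drop = FALSE]
      else if (abs(anch$rank_b[2] - anch$rank_b[1]) > jump)
        anch <- anch[-1, , drop = FALSE]
      else break
    }
    anch
  }
  mkseg <- function(anch, tmpl) {
    ra <- sort(anch$rank_a)
    rb <- range(anch$rank_b)
    data.frame(chrom = tmpl$chrom, start_rank = ra[1],
               end_rank = ra[length(ra)] + 1L, origin = tmpl$origin,
               orient = tmpl$orient, anc_start = rb[1], anc_end = rb[2] + 1L,
               n_genes = nrow(anch), block_id = tmpl$block_id,
               stringsAsFactors = FALSE)
  }
  worklist <- lapply(seq_len(nrow(bt)), function(i) {
    anch <- trimRaided(at[at$block_id == bt$block_id[i], c("rank_a", "rank_b")])
    tmpl <- data.frame(chrom = bt$chrom_a[i], origin = bt$chrom_b[i],
                       orient = bt$orientation[i], block_id = bt$block_id[i],
                       stringsAsFactors = FALSE)
    list(seg = mkseg(anch, tmpl), anch = anch, tmpl = tmpl)
  })
  for (pass in 1:10) {
    segdf <- do.call(rbind, lapply(worklist, `[[`, "seg"))
    clash <- NULL
    for (i in seq_along(worklist)) {
      s1 <- worklist[[i]]$seg
      ov <- which(segdf$chrom == s1$chrom & segdf$start_rank < s1$end_rank &
                    segdf$end_rank > s1$start_rank &
                    segdf$start_rank > s1$start_rank)
      ov <- setdiff(ov, i)
      if (length(ov)) { clash <- c(i, ov[1]); break }
    }
    if (is.null(clash)) break
    w <- worklist[[clash[1]]]; s2 <- worklist[[clash[2]]]$seg
    parts <- list(w$anch[w$anch$rank_a < s2$start_rank, , drop = FALSE],
                  w$anch[w$anch$rank_a >= s2$start_rank &
                           w$anch$rank_a < s2$end_rank, , drop = FALSE],
                  w$anch[w$anch$rank_a >= s2$end_rank, , drop = FALSE])
    parts <- lapply(parts[vapply(parts, nrow, integer(1)) > 0], trimRaided)
    worklist <- c(worklist[-clash[1]],
                  lapply(parts, function(p) list(seg = mkseg(p, w$tmpl),
                                                 anch = p, tmpl = w$tmpl)))
  }
  seg <- do.call(rbind, lapply(worklist, `[[`, "seg"))
  seg <- seg[order(seg$chrom, seg$start_rank), , drop = FALSE]
  # merge same-origin, same-orientation neighbours within the gap rule
  merged <- list()
  for (ch in unique(seg$chrom)) {
    x <- seg[seg$chrom == ch, , drop = FALSE]
    cur <- x[1, ]
    addRow <- function(acc, row) { acc[[length(acc) + 1L]] <- row; acc }
    for (i in seq_len(nrow(x))[-1]) {
      nxt <- x[i, ]
      gapExt <- nxt$start_rank - cur$end_rank
      gapAnc <- if (cur$orient == "+") nxt$anc_start - cur$anc_end else
        cur$anc_start - nxt$anc_end
      # a true continuation loses the same genes on both coordinate
      # systems; a large ancestral jump over a tiny extant gap marks a
      # real junction between different copies of the same ancestor
      if (nxt$origin == cur$origin && nxt$orient == cur$orient &&
          gapExt >= 0 && gapExt < max_gap && gapAnc > -3 && gapAnc < max_gap &&
          gapAnc - gapExt <= 10) {
        cur$end_rank <- nxt$end_rank
        cur$anc_start <- min(cur$anc_start, nxt$anc_start)
        cur$anc_end <- max(cur$anc_end, nxt$anc_end)
        cur$n_genes <- cur$n_genes + nxt$n_genes
      } else {
        merged <- addRow(merged, cur); cur <- nxt
      }
    }
    merged <- addRow(merged, cur)
  }
  seg <- do.call(rbind, merged)
  seg <- seg[seg$n_genes >= min_segment_genes, , drop = FALSE]
  seg <- seg[order(seg$chrom, seg$start_rank), , drop = FALSE]
  # blunt clip of any residual overlap (distinct origins competing for a
  # boundary gene)
  if (nrow(seg) > 1) for (i in seq_len(nrow(seg))[-1]) {
    if (seg$chrom[i] == seg$chrom[i - 1] &&
        seg$start_rank[i] < seg$end_rank[i - 1])
      seg$end_rank[i - 1] <- seg$start_rank[i]
  }
  seg <- seg[seg$end_rank > seg$start_rank, , drop = FALSE]
  seg$segment_id <- seq_len(nrow(seg))
  rownames(seg) <- NULL
  psLog("paint_genome", blocks = nrow(bt), segments = nrow(seg))
  new("SegmentPainting", segments = seg,
      chromLengths = chromGeneCounts(extant))
}

emptySegments <- function() {
  data.frame(chrom = character(0), start_rank = integer(0),
             end_rank = integer(0), origin = character(0),
             orient = character(0), anc_start = integer(0),
             anc_end = integer(0), n_genes = integer(0),
             block_id = integer(0), segment_id = integer(0))
}

# Map positions (chrom, rank) to containing painting segment ids (NA when
# unpainted).
segmentAt <- function(painting, chrom, rank) {
  s <- segmentTable(painting)
  out <- rep(NA_integer_, length(chrom))
  for (i in seq_along(chrom)) {
    hit <- which(s$chrom == chrom[i] & s$start_rank <= rank[i] &
                   s$end_rank > rank[i])
    if (length(hit)) out[i] <- s$segment_id[hit[1]]
  }
  out
}

#' Resolve gamma/beta copy labels of a painting from Ks layers
#'
#' Self-comparison anchors are grouped by the physical pair of painted
#' segments they connect; the median Ks per segment pair is assigned to a
#' WGD layer via a fitted Gaussian mixture (lowest-mean component = the
#' youngest duplication, beta). Beta-layer links group segments into
#' beta-pair units; units of each ancestral chromosome are then clustered
#' into gamma copy classes by interval colouring (ancestral-span overlap or
#' a gamma-layer link = different copy), and sides within each unit are
#' separated by two-colouring the beta links.
#'
#' @param painting a SegmentPainting (from \code{\link{paintGenome}}).
#' @param self_blocks CollinearBlockSet of the extant genome against
#'   itself.
#' @param self_anchor_ks data.frame(gene_a, gene_b, ks) for (a sample of)
#'   the self anchors, as from \code{\link{blockAnchorKs}}.
#' @param layout the extant GenomeLayout (to place anchors on segments).
#' @param mixture optional pre-fitted \linkS4class{KsMixture}; fitted from
#'   the segment-pair medians when NULL.
#' @param min_link_anchors minimal measured anchors for a usable
#'   segment-pair link (default 2).
#' @param seed seed for the mixture fit.
#' @return list(painting = labelled SegmentPainting, mixture, pair_table).
#' @export
resolveCopyLabels <- function(painting, self_blocks, self_anchor_ks, layout,
                              mixture = NULL, min_link_anchors = 2, seed = 1) {
  s <- segmentTable(painting)
  g <- geneTable(layout)
  ak <- self_anchor_ks
  ra <- match(ak$gene_a, g$gene_id); rb <- match(ak$gene_b, g$gene_id)
  segA <- segmentAt(painting, g$chrom[ra], g$rank[ra])
  segB <- segmentAt(painting, g$chrom[rb], g$rank[rb])
  ok <- !is.na(segA) & !is.na(segB) & segA != segB & !is.na(ak$ks)
  key <- paste(pmin(segA[ok], segB[ok]), pmax(segA[ok], segB[ok]))
  med <- tapply(ak$ks[ok], key, stats::median)
  cnt <- tapply(ak$ks[ok], key, length)
  pairs <- do.call(rbind, strsplit(names(med), " "))
  pt <- data.frame(seg1 = as.integer(pairs[, 1]), seg2 = as.integer(pairs[, 2]),
                   median_ks = as.numeric(med), n_anchors = as.integer(cnt))
  pt <- pt[pt$n_anchors >= min_link_anchors, , drop = FALSE]
  # links only make sense between segments of the same ancestral origin
  pt <- pt[s$origin[match(pt$seg1, s$segment_id)] ==
             s$origin[match(pt$seg2, s$segment_id)], , drop = FALSE]
  if (is.null(mixture)) {
    if (nrow(pt) >= 50) {
      mixture <- fitKsMixture(pt$median_ks, k_range = 1:3, seed = seed)
    } else {
      # too few pairs for a mixture: a single-layer history
      mixture <- new("KsMixture",
                     components = data.frame(weight = 1,
                                             mean = mean(pt$median_ks),
                                             sd = max(stats::sd(pt$median_ks), 1e-3)),
                     k = 1L, bic = NA_real_, logLik = NA_real_,
                     range = range(pt$median_ks))
    }
  }
  asg <- assignBlocksToEvents(pt$median_ks, mixture)
  # with a single fitted layer every link joins homoeologous copies of one
  # duplication: a conflict (gamma-type) link, not a beta pairing
  pt$layer <- ifelse(asg$component == 1 & mixture@k > 1, "beta", "gamma")

  # ---- beta-pair units: connected components of beta links ----
  nseg <- nrow(s)
  unit <- seq_len(nseg)
  find <- function(i) { while (unit[i] != i) { unit[i] <<- unit[unit[i]]; i <- unit[i] }; i }
  betaLinks <- pt[pt$layer == "beta", , drop = FALSE]
  gammaLinks <- pt[pt$layer == "gamma", , drop = FALSE]
  for (k in seq_len(nrow(betaLinks))) {
    a <- find(betaLinks$seg1[k]); b <- find(betaLinks$seg2[k])
    if (a != b) unit[a] <- b
  }
  # rescue pass: a segment with no usable beta link (the sparsest copy
  # classes can share only a couple of retained loci) is paired with the
  # unique same-origin, span-overlapping unit it has NO gamma link to —
  # homoeologs of a different gamma copy are always gamma-linked
  noBeta <- setdiff(seq_len(nseg), c(betaLinks$seg1, betaLinks$seg2))
  gConf <- function(i, members) {
    any((gammaLinks$seg1 == i & gammaLinks$seg2 %in% members) |
          (gammaLinks$seg2 == i & gammaLinks$seg1 %in% members))
  }
  for (i in noBeta) {
    ui <- find(i)
    others <- setdiff(which(s$origin == s$origin[i]), i)
    cand <- unique(vapply(others, find, integer(1)))
    cand <- setdiff(cand, ui)
    ok <- vapply(cand, function(u) {
      members <- which(vapply(seq_len(nseg), find, integer(1)) == u)
      overl <- any(pmin(s$anc_end[members], s$anc_end[i]) -
                     pmax(s$anc_start[members], s$anc_start[i]) >= 3)
      overl && !gConf(i, members) &&
        !any(vapply(members, function(mm) gConf(mm, which(vapply(seq_len(nseg), find, integer(1)) == ui)), logical(1)))
    }, logical(1))
    if (sum(ok) == 1L) {
      unit[find(i)] <- find(cand[ok])
      psLog("resolve_copy_labels", rescued_segment = s$segment_id[i])
    }
  }
  s$unit <- vapply(seq_len(nseg), find, integer(1))

  # ---- gamma classes per ancestral chromosome: interval colouring ----
  s$gamma_class <- NA_character_
  gammaConf <- unique(rbind(
    data.frame(u1 = s$unit[match(pt$seg1[pt$layer == "gamma"], s$segment_id)],
               u2 = s$unit[match(pt$seg2[pt$layer == "gamma"], s$segment_id)])))
  for (orig in unique(s$origin)) {
    us <- unique(s$unit[s$origin == orig])
    spans <- t(vapply(us, function(u) {
      ix <- s$unit == u
      c(min(s$anc_start[ix]), max(s$anc_end[ix]))
    }, numeric(2)))
    o <- order(spans[, 1], us)
    colors <- integer(length(us))
    assigned <- list()
    for (i in o) {
      placed <- FALSE
      for (cl in seq_along(assigned)) {
        members <- assigned[[cl]]
        overlap <- any(pmin(spans[members, 2], spans[i, 2]) -
                         pmax(spans[members, 1], spans[i, 1]) >= 3)
        gconf <- any((gammaConf$u1 == us[i] & gammaConf$u2 %in% us[members]) |
                       (gammaConf$u2 == us[i] & gammaConf$u1 %in% us[members]))
        if (!overlap && !gconf) {
          assigned[[cl]] <- c(members, i); colors[i] <- cl; placed <- TRUE
          break
        }
      }
      if (!placed) { assigned[[length(assigned) + 1L]] <- i; colors[i] <- length(assigned) }
    }
    lab <- c(LETTERS[1:26])[colors]
    s$gamma_class[s$origin == orig] <- lab[match(s$unit[s$origin == orig], us)]
  }

  # ---- beta sides: two-colour each unit's beta links ----
  s$side <- NA_character_
  for (u in unique(s$unit)) {
    segs <- s$segment_id[s$unit == u]
    side <- stats::setNames(rep(NA_integer_, length(segs)), segs)
    lk <- betaLinks[s$unit[match(betaLinks$seg1, s$segment_id)] == u, , drop = FALSE]
    anchor <- segs[order(s$chrom[match(segs, s$segment_id)],
                         s$start_rank[match(segs, s$segment_id)])][1]
    side[as.character(anchor)] <- 0L
    repeat {
      changed <- FALSE
      for (k in seq_len(nrow(lk))) {
        a <- as.character(lk$seg1[k]); b <- as.character(lk$seg2[k])
        if (!is.na(side[a]) && is.na(side[b])) { side[b] <- 1L - side[a]; changed <- TRUE }
        if (!is.na(side[b]) && is.na(side[a])) { side[a] <- 1L - side[b]; changed <- TRUE }
      }
      if (!changed) break
    }
    side[is.na(side)] <- 0L  # singletons (lost beta partner)
    s$side[s$unit == u] <- c("a", "b")[side[as.character(s$segment_id[s$unit == u])] + 1L]
  }
  s$class <- paste0(s$origin, ":", s$gamma_class, s$side)
  out <- new("SegmentPainting", segments = s,
             chromLengths = painting@chromLengths)
  psLog("resolve_copy_labels", segment_pairs = nrow(pt),
        k = mixture@k, units = length(unique(s$unit)))
  list(painting = out, mixture = mixture, pair_table = pt)
}

# Pair-level (origin + gamma copy, side-blind) key of each segment.
pairKey <- function(s) paste0(s$origin, ":", s$gamma_class)

#' Count fusion junctions per WGD layer
#'
#' A junction is an adjacency between painted segments of different
#' (ancestor, gamma-copy) origin on one chromosome. A junction type seen in
#' both beta copies of the genome is one post-gamma (pre-duplication)
#' fusion; a single-occurrence type is post-beta. Junction instances lying
#' within \code{tol} genes of a supplied extant rearrangement breakpoint
#' are attributed to the "extant" layer first.
#'
#' @param painting a labelled SegmentPainting (see
#'   \code{\link{resolveCopyLabels}}).
#' @param extant_events optional list of rearrangement events (as returned
#'   by \code{\link{detectRearrangements}} or the generator) whose
#'   breakpoints are excluded.
#' @param tol breakpoint matching tolerance in genes (default 5).
#' @return list(post_gamma, post_beta, extant, unassigned, junctions =
#'   data.frame(chrom, pos, left, right, type, layer)).
#' @export
countFusionJunctions <- function(painting, extant_events = NULL, tol = 5) {
  s <- segmentTable(painting)
  if (is.null(s$gamma_class)) stop("painting has no copy labels; run resolveCopyLabels")
  jx <- list()
  for (ch in unique(s$chrom)) {
    x <- s[s$chrom == ch, , drop = FALSE]
    x <- x[order(x$start_rank), , drop = FALSE]
    if (nrow(x) < 2) next
    keys <- pairKey(x)
    for (k in seq_len(nrow(x))[-1]) {
      if (keys[k] != keys[k - 1]) {
        jx[[length(jx) + 1L]] <- data.frame(
          chrom = ch, pos = x$start_rank[k],
          left = x$class[k - 1], right = x$class[k],
          type = paste(pmin(keys[k - 1], keys[k]),
                       pmax(keys[k - 1], keys[k]), sep = "|"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(jx))
    return(list(post_gamma = 0L, post_beta = 0L, extant = 0L, unassigned = 0L,
                junctions = data.frame()))
  j <- do.call(rbind, jx)
  j$layer <- NA_character_
  if (!is.null(extant_events)) {
    bps <- eventBreakpoints(extant_events)
    for (i in seq_len(nrow(j))) {
      if (any(bps$chrom == j$chrom[i] & abs(bps$pos - j$pos[i]) <= tol))
        j$layer[i] <- "extant"
    }
  }
  open <- is.na(j$layer)
  for (tp in unique(j$type[open])) {
    ix <- which(open & j$type == tp)
    n <- length(ix)
    lay <- c(rep("post-gamma", 2L * (n %/% 2L)), rep("post-beta", n %% 2L))
    j$layer[ix] <- lay
    if (n > 2) psLog("count_fusion_junctions", ambiguous_type = tp, n = n)
  }
  res <- list(post_gamma = sum(j$layer == "post-gamma") %/% 2L,
              post_beta = sum(j$layer == "post-beta"),
              extant = sum(j$layer == "extant"),
              unassigned = sum(is.na(j$layer)),
              junctions = j)
  psLog("count_fusion_junctions", post_gamma = res$post_gamma,
        post_beta = res$post_beta, extant = res$extant)
  res
}

# Breakpoint table (chrom, pos) from rearrangement event records.
eventBreakpoints <- function(events) {
  rows <- lapply(events, function(e) {
    if (e$kind == "inversion")
      data.frame(chrom = e$chrom, pos = c(e$from, e$to))
    else if (e$kind %in% c("reciprocal_translocation", "translocation"))
      data.frame(chrom = c(e$chrom_a, e$chrom_b), pos = c(e$from_a, e$from_b))
    else if (e$kind == "fission")
      data.frame(chrom = e$chrom, pos = e$at)
    else data.frame(chrom = character(0), pos = integer(0))
  })
  do.call(rbind, rows)
}

#' Reconstruct an intermediate karyotype from a labelled painting
#'
#' Layer "extant" reports the painted chromosome complement as-is. Layer
#' "pre_beta" splits chromosomes at post-beta junctions and collapses the
#' resulting pieces pairwise by identical (orientation-canonical) origin
#' composition: the chromosome complement before the beta duplication.
#'
#' @param painting labelled SegmentPainting.
#' @param layer "extant" or "pre_beta".
#' @param junctions optional precomputed \code{\link{countFusionJunctions}}
#'   result (computed when NULL and needed).
#' @return list(n_chromosomes, composition = named character of collapsed
#'   pair-key compositions).
#' @export
reconstructKaryotype <- function(painting, layer = c("extant", "pre_beta"),
                                 junctions = NULL) {
  layer <- match.arg(layer)
  s <- segmentTable(painting)
  compOf <- function(x) {
    k <- pairKey(x[order(x$start_rank), , drop = FALSE])
    k <- k[c(TRUE, k[-1] != k[-length(k)])]
    paste(k, collapse = ">")
  }
  if (layer == "extant") {
    comp <- vapply(split(s, s$chrom), compOf, character(1))
    return(list(n_chromosomes = length(chromNames(painting)),
                composition = comp))
  }
  if (is.null(s$gamma_class)) stop("painting has no copy labels; run resolveCopyLabels")
  if (is.null(junctions)) junctions <- countFusionJunctions(painting)
  j <- junctions$junctions
  pieces <- list()
  for (ch in unique(s$chrom)) {
    x <- s[s$chrom == ch, , drop = FALSE]
    x <- x[order(x$start_rank), , drop = FALSE]
    cuts <- sort(j$pos[j$chrom == ch & j$layer == "post-beta"])
    grp <- findInterval(x$start_rank, c(-Inf, cuts))
    for (p in unique(grp)) pieces[[length(pieces) + 1L]] <- x[grp == p, , drop = FALSE]
  }
  canon <- vapply(pieces, function(x) {
    k <- pairKey(x[order(x$start_rank), , drop = FALSE])
    k <- k[c(TRUE, k[-1] != k[-length(k)])]
    fwd <- paste(k, collapse = ">"); rev_ <- paste(rev(k), collapse = ">")
    min(fwd, rev_)
  }, character(1))
  tab <- table(canon)
  bad <- names(tab)[tab != 2]
  if (length(bad))
    stop("inconsistent beta pairing for composition(s): ",
         paste(bad, collapse = "; "))
  list(n_chromosomes = length(tab), composition = names(tab))
}

#' Enumerate duplicated region classes
#'
#' Distinct resolved (ancestor, gamma copy, beta side) classes of a
#' labelled painting, with the member gene list per class.
#'
#' @param painting labelled SegmentPainting.
#' @param layout the extant GenomeLayout (for gene membership).
#' @return list(classes = character, genes = named list of gene id
#'   vectors, n = class count).
#' @export
enumerateRegionClasses <- function(painting, layout) {
  s <- segmentTable(painting)
  if (is.null(s$class)) stop("painting has no copy labels; run resolveCopyLabels")
  g <- geneTable(layout)
  genes <- list()
  for (i in seq_len(nrow(s))) {
    ids <- g$gene_id[g$chrom == s$chrom[i] & g$rank >= s$start_rank[i] &
                       g$rank < s$end_rank[i]]
    cl <- s$class[i]
    genes[[cl]] <- c(genes[[cl]], ids)
  }
  classes <- sort(names(genes))
  psLog("enumerate_region_classes", n_classes = length(classes))
  list(classes = classes, genes = genes[classes], n = length(classes))
}

# ---- rearrangement detection ----

# Refine one chromosome's segment list at the ancestral breakpoints of the
# other painting (same origin), interpolating extant ranks proportionally,
# so both paintings become comparable segment-by-segment.
refineSegments <- function(x, cutsByOrigin, tol = 3) {
  out <- list()
  for (i in seq_len(nrow(x))) {
    row <- x[i, ]
    cuts <- cutsByOrigin[[row$origin]]
    cuts <- sort(unique(cuts[cuts > row$anc_start + tol & cuts < row$anc_end - tol]))
    if (!length(cuts)) { out[[length(out) + 1L]] <- row; next }
    bounds <- c(row$anc_start, cuts, row$anc_end)
    L <- row$anc_end - row$anc_start
    for (k in seq_len(length(bounds) - 1L)) {
      piece <- row
      piece$anc_start <- bounds[k]; piece$anc_end <- bounds[k + 1L]
      fr <- (bounds[k] - row$anc_start) / L
      to <- (bounds[k + 1L] - row$anc_start) / L
      if (row$orient == "+") {
        piece$start_rank <- row$start_rank + round(fr * (row$end_rank - row$start_rank))
        piece$end_rank <- row$start_rank + round(to * (row$end_rank - row$start_rank))
      } else {
        piece$start_rank <- row$start_rank + round((1 - to) * (row$end_rank - row$start_rank))
        piece$end_rank <- row$start_rank + round((1 - fr) * (row$end_rank - row$start_rank))
      }
      piece$n_genes <- piece$end_rank - piece$start_rank
      out[[length(out) + 1L]] <- piece
    }
  }
  res <- do.call(rbind, out)
  res[order(res$start_rank), , drop = FALSE]
}

segEqual <- function(a, b, tol = 5) {
  a$origin == b$origin & a$orient == b$orient &
    abs(a$anc_start - b$anc_start) <= tol & abs(a$anc_end - b$anc_end) <= tol
}

#' Detect rearrangements between two paintings of a common reference
#'
#' Inversions are maximal runs of segments whose orientation (and segment
#' order) is flipped between the two paintings at the same origin locus;
#' reciprocal translocations are chromosome pairs whose terminal
#' origin-segment runs are exchanged. Self-comparison yields no events.
#'
#' @param painting_a,painting_b SegmentPaintings against the same ancestor.
#' @param tol ancestral-rank matching tolerance in genes (default 5).
#' @return list of KaryotypeEvent-style records (kind, chrom(s), spans).
#' @export
detectRearrangements <- function(painting_a, painting_b, tol = 5) {
  sa <- segmentTable(painting_a); sb <- segmentTable(painting_b)
  # cluster near-identical cut positions (fractionation shifts a breakpoint
  # by a few unretained loci between the two paintings)
  clusterCuts <- function(x, tol) {
    x <- sort(unique(x))
    if (length(x) < 2) return(x)
    x[c(TRUE, diff(x) > tol)]
  }
  events <- list()
  chroms <- intersect(unique(sa$chrom), unique(sb$chrom))
  tails <- list()
  for (ch in chroms) {
    xa <- sa[sa$chrom == ch, , drop = FALSE]
    xb <- sb[sb$chrom == ch, , drop = FALSE]
    # refinement cuts from this chromosome's segments only: boundaries of
    # other copies elsewhere in the genome are irrelevant here
    both <- rbind(xa, xb)
    cuts <- lapply(split(c(both$anc_start, both$anc_end),
                         c(both$origin, both$origin)),
                   clusterCuts, tol = tol)
    A <- refineSegments(xa, cuts, tol)
    B <- refineSegments(xb, cuts, tol)
    nA <- nrow(A); nB <- nrow(B)
    i <- 1L
    while (i <= min(nA, nB) && segEqual(A[i, ], B[i, ], tol)) i <- i + 1L
    if (i > max(nA, nB)) next  # identical
    jA <- nA; jB <- nB
    while (jA >= i && jB >= i && segEqual(A[jA, ], B[jB, ], tol)) {
      jA <- jA - 1L; jB <- jB - 1L
    }
    winA <- A[seq(i, jA), , drop = FALSE]
    winB <- B[seq(i, jB), , drop = FALSE]
    # inversion: A window equals the reversed, orientation-flipped B window
    if (nrow(winA) == nrow(winB)) {
      flipped <- winB[rev(seq_len(nrow(winB))), , drop = FALSE]
      flipped$orient <- ifelse(flipped$orient == "+", "-", "+")
      if (all(segEqual(winA, flipped, tol))) {
        events[[length(events) + 1L]] <- list(
          kind = "inversion", chrom = ch,
          from = min(winA$start_rank), to = max(winA$end_rank))
        next
      }
    }
    # fallback: single-origin windows covering the same ancestral span
    # with flipped orientation content (boundary-anchor noise tolerant)
    if (length(unique(winA$origin)) == 1L &&
        identical(unique(winA$origin), unique(winB$origin)) &&
        abs(min(winA$anc_start) - min(winB$anc_start)) <= 3 * tol &&
        abs(max(winA$anc_end) - max(winB$anc_end)) <= 3 * tol &&
        sum(winA$orient == "-") != sum(winB$orient == "-")) {
      events[[length(events) + 1L]] <- list(
        kind = "inversion", chrom = ch,
        from = min(winA$start_rank), to = max(winA$end_rank))
      next
    }
    # otherwise remember the differing suffix for translocation pairing,
    # collapsed to maximal same-origin runs so piece counts are comparable
    # across chromosomes refined with different cut sets
    collapse <- function(w) {
      w <- w[order(w$start_rank), , drop = FALSE]
      grp <- cumsum(c(TRUE, w$origin[-1] != w$origin[-nrow(w)] |
                        w$orient[-1] != w$orient[-nrow(w)]))
      do.call(rbind, lapply(split(w, grp), function(p) {
        p$anc_start[1] <- min(p$anc_start); p$anc_end[1] <- max(p$anc_end)
        p$end_rank[1] <- max(p$end_rank)
        p[1, , drop = FALSE]
      }))
    }
    tails[[ch]] <- list(A = collapse(winA), B = collapse(winB))
  }
  chs <- names(tails)
  if (length(chs) >= 2) {
    used <- character(0)
    for (u in chs) for (v in chs) {
      if (u >= v || u %in% used || v %in% used) next
      exch <- nrow(tails[[u]]$A) == nrow(tails[[v]]$B) &&
        nrow(tails[[v]]$A) == nrow(tails[[u]]$B) &&
        all(segEqual(tails[[u]]$A, tails[[v]]$B, tol)) &&
        all(segEqual(tails[[v]]$A, tails[[u]]$B, tol))
      if (exch) {
        events[[length(events) + 1L]] <- list(
          kind = "reciprocal_translocation",
          chrom_a = u, from_a = min(tails[[u]]$A$start_rank),
          chrom_b = v, from_b = min(tails[[v]]$A$start_rank))
        used <- c(used, u, v)
      }
    }
    for (ch in setdiff(chs, used))
      events[[length(events) + 1L]] <- list(kind = "unclassified", chrom = ch)
  }
  psLog("detect_rearrangements", events = length(events))
  events
}

#' Assign tetraploid chromosomes to subgenomes via a diploid relative
#'
#' Homoeologous chromosome pairs are identified by best block coverage
#' against the diploid relative (the two tetraploid chromosomes sharing a
#' diploid best partner). Within each pair, the chromosome with the lower
#' median block Ks to the diploid clusters with it and is labelled
#' subgenome "B"; its partner "A". Ties go to the higher anchor count
#' (logged).
#'
#' @param tetraploid,diploid GenomeLayouts.
#' @param blocks CollinearBlockSet tetraploid-vs-diploid with
#'   \code{median_ks} filled (see \code{\link{blockAnchorKs}}).
#' @return named character vector: tetraploid chromosome -> "A"/"B".
#' @export
assignSubgenomes <- function(tetraploid, diploid, blocks) {
  bt <- blockTable(blocks)
  cov <- tapply(bt$n_anchors, list(bt$chrom_a, bt$chrom_b), sum)
  cov[is.na(cov)] <- 0
  pairs <- list()
  for (d in colnames(cov)) {
    o <- order(-cov[, d])
    top <- rownames(cov)[o[1:2]]
    if (cov[o[2], d] == 0)
      stop("no homoeologous pairs: diploid chromosome ", d,
           " has fewer than 2 covered partners")
    pairs[[d]] <- top
  }
  out <- character(0)
  for (d in names(pairs)) {
    p <- pairs[[d]]
    ksOf <- function(tc) stats::median(bt$median_ks[bt$chrom_a == tc & bt$chrom_b == d],
                                       na.rm = TRUE)
    k1 <- ksOf(p[1]); k2 <- ksOf(p[2])
    if (isTRUE(all.equal(k1, k2))) {
      psLog("assign_subgenomes", tie = d, rule = "anchor_count")
      b <- p[order(-c(cov[p[1], d], cov[p[2], d]), p)][1]
    } else b <- p[which.min(c(k1, k2))]
    out[b] <- "B"; out[setdiff(p, b)] <- "A"
  }
  missing <- setdiff(chromNames(tetraploid), names(out))
  if (length(missing)) stop("unpaired tetraploid chromosome(s): ",
                            paste(missing, collapse = ", "))
  psLog("assign_subgenomes", pairs = length(pairs))
  out[chromNames(tetraploid)]
}
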