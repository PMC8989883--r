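## Hi-C contact-matrix balancing (ICE), observed/expected normalization,
## A/B compartment calling, insulation-score TAD calling and topology
## comparison across duplicated region classes. Masked bins propagate NA,
## never zero-fill.

#' Iterative correction (ICE) of a contact matrix
#'
#' Bins below the \code{min_bin_coverage} quantile of nonzero row sums are
#' masked (NA). Rows are iteratively rescaled until the coefficient of
#' variation of the unmasked row sums drops below \code{tol} (or
#' \code{max_iter}). The returned bias vector reconstructs the raw matrix:
#' raw = b_i * b_j * balanced.
#'
#' @param cm a raw \linkS4class{ContactMatrix}.
#' @param max_iter maximum iterations (default 200).
#' @param tol row-sum CV tolerance (default 1e-5).
#' @param min_bin_coverage coverage quantile below which bins are masked
#'   (default 0.02).
#' @return a balanced ContactMatrix (bias in \code{biasVector}).
#' @export
iceBalance <- function(cm, max_iter = 200, tol = 1e-5,
                       min_bin_coverage = 0.02) {
  m <- contactCounts(cm)
  if (sum(m, na.rm = TRUE) == 0) stop("all-zero contact matrix")
  n <- nrow(m)
  rs <- rowSums(m, na.rm = TRUE)
  cut <- stats::quantile(rs[rs > 0], min_bin_coverage)
  # strict-with-margin: when coverage is already uniform (e.g. on a
  # balanced matrix) the quantile equals the common row sum up to the
  # convergence tolerance, and those bins must not be masked
  mask <- rs < cut * (1 - 1e-3) | rs == 0
  w <- m
  w[mask, ] <- NA; w[, mask] <- NA
  bias <- rep(1, n)
  for (it in seq_len(max_iter)) {
    s <- rowSums(w, na.rm = TRUE)
    s[mask] <- NA
    mu <- mean(s, na.rm = TRUE)
    cv <- stats::sd(s, na.rm = TRUE) / mu
    if (is.finite(cv) && cv < tol) break
    d <- s / mu
    d[!is.finite(d) | d == 0] <- 1
    w <- w / outer(d, d)
    bias <- bias * d
  }
  psLog("ice_balance", iters = it, cv = signif(cv, 3), masked = sum(mask))
  new("ContactMatrix", counts = w, resolution = resolutionBp(cm),
      bins = binTable(cm), balanced = TRUE, bias = bias)
}

#' Observed-over-expected normalization per chromosome
#'
#' Expected counts at each bin distance are the lowess-smoothed mean of the
#' balanced counts at that distance (plain diagonal means for chromosomes
#' under \code{min_bins_lowess} bins); O/E = observed / expected.
#' Inter-chromosomal entries and masked bins are NA.
#'
#' @param cm a balanced ContactMatrix.
#' @param min_bins_lowess smoothing threshold (default 10).
#' @return matrix of O/E values (NA outside intra-chromosomal scope).
#' @export
observedOverExpected <- function(cm, min_bins_lowess = 10) {
  m <- contactCounts(cm)
  bins <- binTable(cm)
  oe <- matrix(NA_real_, nrow(m), ncol(m))
  for (ch in unique(bins$chrom)) {
    ix <- which(bins$chrom == ch)
    sub <- m[ix, ix, drop = FALSE]
    nb <- length(ix)
    dmean <- vapply(0:(nb - 1), function(d) {
      v <- sub[col(sub) - row(sub) == d]
      mean(v, na.rm = TRUE)
    }, numeric(1))
    if (nb >= min_bins_lowess) {
      # smooth in log-log space: power-law decay is linear there, so the
      # fit is faithful at both the diagonal and the far tail
      dok <- which(is.finite(dmean) & dmean > 0)
      lw <- stats::lowess(log(dok), log(dmean[dok]), f = 0.3)
      sm <- rep(NA_real_, nb)
      sm[dok] <- exp(stats::approx(lw$x, lw$y, xout = log(dok), rule = 2)$y)
      expd <- sm
    } else expd <- dmean
    E <- matrix(expd[abs(col(sub) - row(sub)) + 1L], nb, nb)
    oe[ix, ix] <- sub / E
  }
  oe
}

#' Call A/B compartments from an O/E matrix
#'
#' Per chromosome, the first eigenvector of the Pearson correlation matrix
#' of the O/E columns; the sign is oriented so that the positive (A) set
#' has the higher mean gene density, and bins are labelled by sign. Masked
#' bins stay NA.
#'
#' @param oe O/E matrix (from \code{\link{observedOverExpected}}).
#' @param bins bin table of the matrix.
#' @param gene_density per-bin gene counts (for sign orientation).
#' @return data.frame(chrom, start, end, eigen, label).
#' @export
callCompartments <- function(oe, bins, gene_density) {
  out <- bins
  out$eigen <- NA_real_; out$label <- NA_character_
  for (ch in unique(bins$chrom)) {
    ix <- which(bins$chrom == ch)
    sub <- oe[ix, ix, drop = FALSE]
    ok <- which(colSums(is.finite(sub)) > 2)
    if (length(ok) < 3) { warning("chromosome ", ch, ": too few usable bins"); next }
    cc <- suppressWarnings(stats::cor(sub[ok, ok], use = "pairwise.complete.obs"))
    cc[!is.finite(cc)] <- 0
    if (max(abs(cc - cc[1, 1])) < 1e-12) { warning("constant matrix on ", ch); next }
    ev <- eigen(cc, symmetric = TRUE)
    e1 <- ev$vectors[, 1]
    gd <- gene_density[ix][ok]
    mA <- mean(gd[e1 > 0]); mB <- mean(gd[e1 < 0])
    if (is.finite(mA) && is.finite(mB) && mB > mA) e1 <- -e1
    if (all(e1 >= 0) || all(e1 <= 0)) e1 <- abs(e1)  # single-compartment: all A
    out$eigen[ix[ok]] <- e1
    out$label[ix[ok]] <- ifelse(e1 > 0, "A", "B")
  }
  psLog("call_compartments", A = sum(out$label == "A", na.rm = TRUE),
        B = sum(out$label == "B", na.rm = TRUE))
  out
}

#' Insulation score along the diagonal
#'
#' Mean balanced counts in a square window sliding along the diagonal
#' (bins i-w..i-1 x i+1..i+w), log2-normalized by the chromosome mean; NA
#' within w bins of chromosome ends.
#'
#' @param cm balanced ContactMatrix.
#' @param window window size in bp (default 500 kb); must be a multiple of
#'   the resolution and at least 2 bins.
#' @return data.frame(chrom, start, end, score).
#' @export
insulationScore <- function(cm, window = 500000) {
  res <- resolutionBp(cm)
  w <- as.integer(round(window / res))
  if (w < 2) stop("window must span at least 2 bins")
  m <- contactCounts(cm)
  bins <- binTable(cm)
  out <- bins; out$score <- NA_real_
  for (ch in unique(bins$chrom)) {
    ix <- which(bins$chrom == ch)
    sub <- m[ix, ix, drop = FALSE]
    nb <- length(ix)
    raw <- rep(NA_real_, nb)
    if (nb > 2 * w) {
      for (i in (w + 1):(nb - w))
        raw[i] <- mean(sub[(i - w):(i - 1), (i + 1):(i + w)], na.rm = TRUE)
    }
    mu <- mean(raw, na.rm = TRUE)
    out$score[ix] <- log2(raw / mu)
  }
  out
}

#' Call TAD-like domains from an insulation track
#'
#' Boundaries are local minima of the insulation score where the delta
#' vector (mean score over \code{delta_span} left of the bin minus right of
#' it) crosses zero with amplitude at least \code{boundary_strength_min};
#' domains are the intervals between successive boundaries. An optional
#' two-state Viterbi smoothing of discretized scores can refine boundary
#' bins (off by default).
#'
#' @param track insulation data.frame (from \code{\link{insulationScore}}).
#' @param resolution bin size in bp.
#' @param delta_span averaging span for the delta vector (default 100 kb).
#' @param boundary_strength_min minimal delta amplitude (default 0.1).
#' @param hmm apply the optional HMM smoothing (default FALSE).
#' @return data.frame(chrom, start_bin, end_bin, start, end,
#'   boundary_strength): non-overlapping domains tiling each chromosome.
#' @export
callTads <- function(track, resolution, delta_span = 100000,
                     boundary_strength_min = 0.1, hmm = FALSE) {
  dw <- max(1L, as.integer(round(delta_span / resolution)))
  out <- list()
  for (ch in unique(track$chrom)) {
    x <- track[track$chrom == ch, , drop = FALSE]
    sc <- x$score
    nb <- length(sc)
    delta <- rep(NA_real_, nb)
    for (i in seq_len(nb)) {
      l <- sc[max(1, i - dw):max(1, i - 1)]
      r <- sc[min(nb, i + 1):min(nb, i + dw)]
      if (i > 1 && i < nb) delta[i] <- mean(l, na.rm = TRUE) - mean(r, na.rm = TRUE)
    }
    isMin <- rep(FALSE, nb)
    for (i in 2:(nb - 1))
      isMin[i] <- is.finite(sc[i]) && is.finite(sc[i - 1]) && is.finite(sc[i + 1]) &&
        sc[i] <= sc[i - 1] && sc[i] <= sc[i + 1]
    # delta crosses zero downward at a boundary: positive left, negative right
    strength <- rep(NA_real_, nb)
    for (i in which(isMin)) {
      lv <- delta[max(1, i - 2):i]; rv <- delta[i:min(nb, i + 2)]
      lmax <- suppressWarnings(max(lv, na.rm = TRUE))
      rmin <- suppressWarnings(min(rv, na.rm = TRUE))
      if (is.finite(lmax) && is.finite(rmin) && lmax > 0 && rmin < 0)
        strength[i] <- lmax - rmin
    }
    bd <- which(is.finite(strength) & strength >= boundary_strength_min)
    if (hmm && length(bd)) bd <- refineBoundariesHmm(sc, bd)
    # suppress near-duplicate boundaries (jitter around one dip), keeping
    # the deepest insulation minimum; the window stays below the smallest
    # resolvable domain so true neighbours survive
    sep <- max(2L, dw %/% 2L + 1L)
    if (length(bd) > 1) {
      repeat {
        gaps <- diff(bd)
        k <- which(gaps < sep)
        if (!length(k)) break
        k <- k[1]
        drop <- if (sc[bd[k]] <= sc[bd[k + 1]]) k + 1L else k
        bd <- bd[-drop]
      }
    }
    edges <- c(0L, bd, nb)
    for (k in seq_len(length(edges) - 1L)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bin = edges[k], end_bin = edges[k + 1L],
        start = x$start[edges[k] + 1L], end = x$end[edges[k + 1L]],
        boundary_strength = if (k < length(edges) - 1L) strength[edges[k + 1L]] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  psLog("call_tads", domains = nrow(res))
  res
}

# Optional 2-state (interior/boundary) Viterbi smoothing over discretized
# insulation scores; returns refined boundary bins near the proposals.
refineBoundariesHmm <- function(sc, proposals) {
  z <- sc; z[!is.finite(z)] <- 0
  q <- stats::quantile(z, c(0.1, 0.9))
  obs <- findInterval(z, c(q[1], q[2])) + 1L  # 1 low, 2 mid, 3 high
  emis <- rbind(interior = c(0.1, 0.3, 0.6), boundary = c(0.7, 0.25, 0.05))
  trans <- rbind(c(0.95, 0.05), c(0.5, 0.5))
  n <- length(obs)
  v <- matrix(-Inf, 2, n); ptr <- matrix(0L, 2, n)
  v[, 1] <- log(c(0.9, 0.1)) + log(emis[, obs[1]])
  for (t in 2:n) for (s in 1:2) {
    cand <- v[, t - 1] + log(trans[, s])
    ptr[s, t] <- which.max(cand)
    v[s, t] <- max(cand) + log(emis[s, obs[t]])
  }
  path <- integer(n); path[n] <- which.max(v[, n])
  for (t in (n - 1):1) path[t] <- ptr[path[t + 1], t + 1]
  hmmBd <- which(path == 2)
  vapply(proposals, function(b) {
    near <- hmmBd[abs(hmmBd - b) <= 2]
    if (length(near)) near[which.min(abs(near - b))] else b
  }, integer(1))
}

#' Compare chromatin topology across duplicated region classes
#'
#' For every pair of region classes: the mean log2 normalized contact
#' frequency between their bins; a within-ancestor vs between-ancestor
#' contrast (two-sample t test on inter-chromosomal pair means); and the
#' fraction of region-junction sites coinciding (within 1 bin) with an A/B
#' compartment switch.
#'
#' @param cm balanced ContactMatrix.
#' @param regions data.frame(chrom, start, end in bp, class, ancestor).
#' @param compartments optional compartment track (for junction/switch
#'   overlap).
#' @return list(pair_table, within_mean, between_mean, t_test,
#'   switch_overlap).
#' @export
compareRegionTopology <- function(cm, regions, compartments = NULL) {
  m <- contactCounts(cm)
  tot <- sum(m, na.rm = TRUE)
  bins <- binTable(cm)
  mids <- (bins$start + bins$end) / 2
  binsOf <- function(i) which(bins$chrom == regions$chrom[i] &
                                mids >= regions$start[i] & mids < regions$end[i])
  reg <- lapply(seq_len(nrow(regions)), binsOf)
  small <- vapply(reg, length, integer(1)) < 2
  if (any(small)) warning(sum(small), " region(s) smaller than 2 bins skipped")
  pairs <- list()
  for (i in seq_len(nrow(regions))) for (j in seq_len(nrow(regions))) {
    if (i >= j || small[i] || small[j]) next
    if (regions$chrom[i] == regions$chrom[j]) next  # inter-chromosomal scope
    v <- m[reg[[i]], reg[[j]]]
    pairs[[length(pairs) + 1L]] <- data.frame(
      class1 = regions$class[i], class2 = regions$class[j],
      same_ancestor = regions$ancestor[i] == regions$ancestor[j],
      mean_log2 = log2(mean(v, na.rm = TRUE) / tot),
      stringsAsFactors = FALSE)
  }
  pt <- do.call(rbind, pairs)
  wi <- pt$mean_log2[pt$same_ancestor]; be <- pt$mean_log2[!pt$same_ancestor]
  tt <- if (length(wi) > 1 && length(be) > 1) stats::t.test(wi, be) else NULL
  sw <- NA_real_
  if (!is.null(compartments)) {
    lab <- compartments$label
    switchBins <- which(bins$chrom[-1] == bins$chrom[-nrow(bins)] &
                          lab[-1] != lab[-length(lab)])
    jxBins <- unlist(lapply(unique(regions$chrom), function(ch) {
      r <- regions[regions$chrom == ch, , drop = FALSE]
      r <- r[order(r$start), , drop = FALSE]
      if (nrow(r) < 2) return(integer(0))
      vapply(r$start[-1], function(bp)
        which(bins$chrom == ch & bins$start <= bp & bins$end > bp)[1], integer(1))
    }))
    if (length(jxBins))
      sw <- mean(vapply(jxBins, function(b)
        any(abs(switchBins - b) <= 1), logical(1)))
  }
  psLog("compare_region_topology", pairs = nrow(pt),
        within = round(mean(wi), 3), between = round(mean(be), 3))
  list(pair_table = pt, within_mean = mean(wi), between_mean = mean(be),
       t_test = tt, switch_overlap = sw)
}

#' Methylation/expression profiles over TAD interiors vs borders
#'
#' Genes are assigned to the border zone when they overlap a boundary bin
#' +/- 1 bin, else to the interior of their domain; reports zone means and
#' a rescaled meta-profile over interior quantile bins plus flanks.
#'
#' @param tads TAD table from \code{\link{callTads}}.
#' @param layout GenomeLayout (gene positions).
#' @param mC named numeric: gene_id -> methylation level.
#' @param tpm named numeric: gene_id -> expression (e.g. mean TPM).
#' @param resolution bin size in bp.
#' @param n_meta interior meta-profile bins (default 20).
#' @return list(zone_table, zone_means, meta_profile).
#' @export
profileOverTads <- function(tads, layout, mC, tpm, resolution,
                            n_meta = 20) {
  g <- geneTable(layout)
  if (nrow(g) == 0L) stop("no genes in scope")
  mid <- (g$start + g$end) / 2
  zone <- rep(NA_character_, nrow(g))
  rel <- rep(NA_real_, nrow(g))
  for (i in seq_len(nrow(tads))) {
    hit <- g$chrom == tads$chrom[i] & mid >= tads$start[i] & mid < tads$end[i]
    if (!any(hit)) next
    nearStart <- mid < tads$start[i] + resolution
    nearEnd <- mid >= tads$end[i] - resolution
    zone[hit & (nearStart | nearEnd)] <- "border"
    zone[hit & !(nearStart | nearEnd)] <- "interior"
    rel[hit] <- (mid[hit] - tads$start[i]) / (tads$end[i] - tads$start[i])
  }
  zone[is.na(zone)] <- "border"  # genes outside any domain sit at edges
  zt <- data.frame(gene_id = g$gene_id, zone = zone, rel_pos = rel,
                   mC = unname(mC[g$gene_id]), tpm = unname(tpm[g$gene_id]),
                   stringsAsFactors = FALSE)
  zm <- stats::aggregate(cbind(mC, tpm) ~ zone, zt, mean, na.rm = TRUE)
  inb <- zt[zt$zone == "interior" & !is.na(zt$rel_pos), , drop = FALSE]
  inb$meta_bin <- pmin(n_meta, findInterval(inb$rel_pos,
                                            seq(0, 1, length.out = n_meta + 1),
                                            rightmost.closed = TRUE))
  mp <- stats::aggregate(cbind(mC, tpm) ~ meta_bin, inb, mean, na.rm = TRUE)
  psLog("profile_over_tads", interior = sum(zone == "interior"),
        border = sum(zone == "border"))
  list(zone_table = zt, zone_means = zm, meta_profile = mp)
}
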