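## Generators for tissue expression, per-gene methylation and binned Hi-C
## contact matrices with implanted truth.

.TISSUES <- c("leaf", "root", "stem")

#' Expression triad archetypes
#'
#' The seven canonical tissue-fraction profiles: Balanced (1/3, 1/3, 1/3),
#' one dominant vertex per tissue, and one suppressed profile per tissue
#' (0 for the suppressed tissue, 1/2 for the other two).
#'
#' @return 7 x 3 numeric matrix, rownames = category names, colnames =
#'   tissues.
#' @export
triadArchetypes <- function() {
  a <- rbind(
    Balanced = c(1, 1, 1) / 3,
    `Leaf-dominant` = c(1, 0, 0),
    `Root-dominant` = c(0, 1, 0),
    `Stem-dominant` = c(0, 0, 1),
    `Leaf-suppressed` = c(0, 1, 1) / 2,
    `Root-suppressed` = c(1, 0, 1) / 2,
    `Stem-suppressed` = c(1, 1, 0) / 2)
  colnames(a) <- .TISSUES
  a
}

# Dirichlet sampler via gamma draws; alpha is an n x k matrix.
rdirichletMat <- function(alpha) {
  x <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow = nrow(alpha))
  x / pmax(rowSums(x), .Machine$double.eps)
}

#' Simulate tissue expression with implanted triad categories
#'
#' Each gene draws a triad category; tissue TPM triples are sampled around
#' the category archetype with Dirichlet fraction noise (concentration
#' \code{concentration}; archetype zeros are softened by +0.5 pseudo-alpha)
#' scaled by a log-normal magnitude. All-zero triples are never emitted.
#'
#' @param layout a GenomeLayout (genes to simulate).
#' @param archetype_fracs named numeric, probabilities of the 7 categories
#'   (must sum to 1).
#' @param concentration Dirichlet concentration (default 50).
#' @param n_replicates replicates per gene x tissue (default 2).
#' @param magnitude_meanlog,magnitude_sdlog log-normal TPM magnitude.
#' @param seed RNG seed.
#' @return list(records = data.frame(gene_id, tissue, replicate, tpm),
#'   truth = data.frame(gene_id, category)).
#' @export
simulateExpression <- function(layout, archetype_fracs = NULL,
                               concentration = 50, n_replicates = 2,
                               magnitude_meanlog = 3, magnitude_sdlog = 1,
                               seed = 1) {
  arch <- triadArchetypes()
  if (is.null(archetype_fracs))
    archetype_fracs <- c(Balanced = 0.4, `Leaf-dominant` = 0.12,
                         `Root-dominant` = 0.12, `Stem-dominant` = 0.12,
                         `Leaf-suppressed` = 0.08, `Root-suppressed` = 0.08,
                         `Stem-suppressed` = 0.08)
  if (abs(sum(archetype_fracs) - 1) > 1e-8)
    stop("archetype fractions must sum to 1")
  if (!all(names(archetype_fracs) %in% rownames(arch)))
    stop("unknown archetype names")
  ids <- geneTable(layout)$gene_id
  n <- length(ids)
  withSeed(childSeed(seed, "expression"), {
    cat_i <- sample(names(archetype_fracs), n, replace = TRUE,
                    prob = archetype_fracs)
    alpha <- concentration * arch[cat_i, , drop = FALSE] + 0.5
    fr <- rdirichletMat(alpha)
    mag <- stats::rlnorm(n, magnitude_meanlog, magnitude_sdlog)
    base <- fr * mag
    recs <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      noise <- matrix(stats::rlnorm(n * 3, 0, 0.1), n, 3)
      data.frame(gene_id = rep(ids, 3),
                 tissue = rep(.TISSUES, each = n),
                 replicate = r,
                 tpm = as.vector(base * noise),
                 stringsAsFactors = FALSE)
    }))
    psLog("simulate_expression", genes = n, concentration = concentration,
          seed = seed)
    list(records = recs,
         truth = data.frame(gene_id = ids, category = cat_i,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate per-gene methylation with TAD-interior enrichment
#'
#' Genes inside TAD interiors draw from a hypermethylated Beta
#' distribution, genes at TAD borders (or with no TAD annotation) from a
#' hypomethylated one.
#'
#' @param layout a GenomeLayout.
#' @param tads optional data.frame (chrom, start, end in bp, 0-based
#'   half-open); border zone = within \code{border_bp} of a boundary.
#' @param border_bp border half-width in bp (default 20000).
#' @param shape_interior,shape_border Beta shape pairs.
#' @param seed RNG seed.
#' @return list(records = data.frame(gene_id, mC), truth =
#'   data.frame(gene_id, zone)).
#' @export
simulateMethylation <- function(layout, tads = NULL, border_bp = 20000,
                                shape_interior = c(8, 4),
                                shape_border = c(3, 7), seed = 1) {
  g <- geneTable(layout)
  mid <- (g$start + g$end) / 2
  zone <- rep("border", nrow(g))
  if (!is.null(tads) && nrow(tads)) {
    for (i in seq_len(nrow(tads))) {
      inTad <- g$chrom == tads$chrom[i] & mid >= tads$start[i] & mid < tads$end[i]
      interior <- inTad & mid >= tads$start[i] + border_bp &
        mid < tads$end[i] - border_bp
      zone[interior] <- "interior"
    }
  }
  withSeed(childSeed(seed, "methylation"), {
    mC <- ifelse(zone == "interior",
                 stats::rbeta(nrow(g), shape_interior[1], shape_interior[2]),
                 stats::rbeta(nrow(g), shape_border[1], shape_border[2]))
    psLog("simulate_methylation", genes = nrow(g),
          interior = sum(zone == "interior"))
    list(records = data.frame(gene_id = g$gene_id, mC = mC,
                              stringsAsFactors = FALSE),
         truth = data.frame(gene_id = g$gene_id, zone = zone,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a binned Hi-C contact matrix with implanted structure
#'
#' Expected intra-chromosomal counts follow a power-law distance decay
#' \code{(d + 1)^-decay_exponent} modulated by a compartment checkerboard
#' factor (same-label bins enriched) and a within-TAD enrichment factor;
#' inter-chromosomal pairs get a flat background, optionally boosted for
#' bins in duplicated regions of shared ancestral origin. Counts are
#' Poisson at the stated sequencing depth and the matrix is symmetric.
#'
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param resolution bin size (bp); a trailing short bin is kept.
#' @param compartments optional per-bin labels ("A"/"B"), length = total
#'   bins, or NULL.
#' @param tads optional data.frame (chrom, start_bin, end_bin; 0-based
#'   half-open, per chromosome).
#' @param decay_exponent power-law decay exponent (default 1).
#' @param depth total expected contact count (default 1e6).
#' @param comp_strength log-scale compartment modulation (default 0.5:
#'   same-label pairs x exp(+0.5/2), opposite x exp(-0.5/2)).
#' @param tad_boost within-TAD multiplicative enrichment (default 2).
#' @param inter_base inter-chromosomal background relative to the
#'   long-range intra level (default 0.05).
#' @param region_classes optional data.frame (chrom, start, end in bp,
#'   ancestor) marking duplicated regions; same-ancestor region pairs on
#'   different chromosomes are boosted by \code{homolog_boost}.
#' @param homolog_boost multiplicative boost (default 1 = off).
#' @param seed RNG seed.
#' @return a \linkS4class{ContactMatrix} (raw counts).
#' @export
simulateContactMatrix <- function(chrom_sizes, resolution,
                                  compartments = NULL, tads = NULL,
                                  decay_exponent = 1, depth = 1e6,
                                  comp_strength = 0.5, tad_boost = 2,
                                  inter_base = 0.05,
                                  region_classes = NULL, homolog_boost = 1,
                                  seed = 1) {
  bins <- makeBins(chrom_sizes, resolution)
  nb <- nrow(bins)
  lam <- matrix(0, nb, nb)
  binChrom <- bins$chrom
  for (ch in unique(binChrom)) {
    ix <- which(binChrom == ch)
    d <- abs(outer(seq_along(ix), seq_along(ix), "-"))
    lam[ix, ix] <- (d + 1)^(-decay_exponent)
  }
  interLevel <- inter_base * (max(table(binChrom)))^(-decay_exponent)
  inter <- outer(binChrom, binChrom, "!=")
  lam[inter] <- interLevel
  if (!is.null(compartments)) {
    stopifnot(length(compartments) == nb)
    same <- outer(compartments, compartments, "==")
    mod <- ifelse(same, exp(comp_strength / 2), exp(-comp_strength / 2))
    intra <- !inter
    lam[intra] <- lam[intra] * mod[intra]
  }
  if (!is.null(tads) && nrow(tads)) {
    for (i in seq_len(nrow(tads))) {
      ix <- which(binChrom == tads$chrom[i])
      span <- ix[seq.int(tads$start_bin[i] + 1L, tads$end_bin[i])]
      lam[span, span] <- lam[span, span] * tad_boost
    }
  }
  if (!is.null(region_classes) && homolog_boost != 1) {
    mids <- (bins$start + bins$end) / 2
    anc <- rep(NA_character_, nb)
    for (i in seq_len(nrow(region_classes))) {
      hit <- binChrom == region_classes$chrom[i] &
        mids >= region_classes$start[i] & mids < region_classes$end[i]
      anc[hit] <- region_classes$ancestor[i]
    }
    sameAnc <- outer(anc, anc, "==") & inter
    sameAnc[is.na(sameAnc)] <- FALSE
    lam[sameAnc] <- lam[sameAnc] * homolog_boost
  }
  lam <- (lam + t(lam)) / 2
  lam <- lam * depth / sum(lam)
  withSeed(childSeed(seed, "hic"), {
    up <- upper.tri(lam, diag = TRUE)
    counts <- matrix(0, nb, nb)
    counts[up] <- stats::rpois(sum(up), lam[up])
    counts <- counts + t(counts) - diag(diag(counts))
    psLog("simulate_contact_matrix", bins = nb, depth = depth, seed = seed)
    new("ContactMatrix", counts = counts, resolution = resolution,
        bins = bins, balanced = FALSE, bias = numeric(0))
  })
}
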