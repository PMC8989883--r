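## Synthetic multi-species genome generator with implanted polyploidy
## history. A "genome" in this module is a list(layout = GenomeLayout,
## seqs = integer codon matrix with rownames = gene_id). Generator truth
## (locus, eu, gamma, beta labels) rides along as extra columns of the gene
## table; analysis modules only ever use the standard layout columns.

.GENE_BP <- 1000L   # synthetic gene spacing in bp
.GENE_LEN <- 900L   # synthetic gene length in bp

# Recompute synthetic bp coordinates from ranks.
rebuildBp <- function(genes) {
  genes$start <- genes$rank * .GENE_BP + 1L
  genes$end <- genes$start + .GENE_LEN - 1L
  genes
}

#' Simulate an ancestral genome with random coding sequences
#'
#' Builds the pre-polyploidy ancestor: \code{n_anc_chrom} chromosomes with
#' \code{genes_per_chrom} genes each, every gene carrying a random in-frame
#' codon sequence free of internal stop codons. Each ancestral locus gets a
#' unique family identifier.
#'
#' @param n_anc_chrom number of ancestral chromosomes (default 7).
#' @param genes_per_chrom genes per chromosome; scalar or a vector of
#'   length \code{n_anc_chrom}.
#' @param codons_per_gene codons per gene (default 100).
#' @param seed RNG seed; identical seeds give identical output.
#' @return list with \code{layout} (GenomeLayout; extra truth columns
#'   locus, eu, gamma, beta, anc_rank) and \code{seqs} (integer codon
#'   matrix, rownames = gene_id).
#' @export
simulateAncestralGenome <- function(n_anc_chrom = 7, genes_per_chrom = 120,
                                    codons_per_gene = 100, seed = 1) {
  stopifnot(n_anc_chrom >= 1)
  npc <- rep_len(genes_per_chrom, n_anc_chrom)
  withSeed(childSeed(seed, "ancestor"), {
    sense <- which(!isStopCodon())
    genes <- do.call(rbind, lapply(seq_len(n_anc_chrom), function(e) {
      n <- npc[e]
      data.frame(gene_id = sprintf("gEu%d_%04d", e, seq_len(n)),
                 chrom = sprintf("Eu%d", e),
                 start = (seq_len(n) - 1L) * .GENE_BP + 1L,
                 end = (seq_len(n) - 1L) * .GENE_BP + .GENE_LEN,
                 strand = "+",
                 family_id = sprintf("Eu%d_%04d", e, seq_len(n)),
                 locus = sprintf("Eu%d_%04d", e, seq_len(n)),
                 eu = e, gamma = NA_character_, beta = NA_character_,
                 anc_rank = seq_len(n) - 1L,
                 stringsAsFactors = FALSE)
    }))
    seqs <- matrix(sample(sense, nrow(genes) * codons_per_gene, replace = TRUE),
                   nrow = nrow(genes))
    rownames(seqs) <- genes$gene_id
    layout <- newGenomeLayout(genes, speciesId = "ancestor")
    psLog("simulate_ancestral_genome", chroms = n_anc_chrom,
          genes = nrow(genes), codons = codons_per_gene, seed = seed)
    list(layout = layout, seqs = seqs)
  })
}

# Apply m single-codon mutation rounds to every row of an integer codon
# matrix (synonymous-biased, stop-free), in place semantics via return.
mutateCodonMatrix <- function(seqs, m, synBias = 5) {
  if (m <= 0 || nrow(seqs) == 0L) return(seqs)
  cdf <- codonMutationCdf(synBias)
  n <- nrow(seqs); L <- ncol(seqs)
  for (k in seq_len(m)) {
    pos <- sample.int(L, n, replace = TRUE)
    cur <- seqs[cbind(seq_len(n), pos)]
    u <- stats::runif(n)
    nxt <- max.col(cdf[cur, , drop = FALSE] >= u, ties.method = "first")
    seqs[cbind(seq_len(n), pos)] <- nxt
  }
  seqs
}

# Find the per-copy mutation-round count m such that the median NG86 Ks
# between two independently m-mutated copies hits the target. Monotone in
# m, so plain bisection against the package's own estimator.
calibrateMutationRounds <- function(seqs, target_ks, synBias = 5, seed = 1,
                                    sample_genes = 40) {
  idx <- withSeed(childSeed(seed, "calib-sample"),
                  sample(nrow(seqs), min(sample_genes, nrow(seqs))))
  probe <- seqs[idx, , drop = FALSE]
  medKs <- function(m) {
    a <- withSeed(childSeed(seed, paste0("calibA", m)),
                  mutateCodonMatrix(probe, m, synBias))
    b <- withSeed(childSeed(seed, paste0("calibB", m)),
                  mutateCodonMatrix(probe, m, synBias))
    ks <- vapply(seq_len(nrow(a)),
                 function(i) ksNG86Int(a[i, ], b[i, ])$Ks, numeric(1))
    stats::median(ks, na.rm = TRUE)
  }
  lo <- 0L; hi <- 2L * ncol(seqs)
  while (medKs(hi) < target_ks && hi < 20L * ncol(seqs)) hi <- hi * 2L
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (medKs(mid) < target_ks) lo <- mid else hi <- mid
  }
  hi
}

#' Apply a whole-genome duplication or triplication
#'
#' Every chromosome is copied \code{multiplicity} times. Each copy's
#' sequences are evolved by a synonymous-biased per-site substitution
#' process calibrated (by bisection against the package's NG86 estimator)
#' so that the median pairwise Ks between copies at application time is
#' \code{target_ks}. Copy labels: gamma layer A/B/C, beta layer a/b.
#'
#' @param genome list(layout, seqs) as from
#'   \code{\link{simulateAncestralGenome}}.
#' @param multiplicity 2 or 3.
#' @param layer_label label recorded in the truth ("gamma", "beta", ...).
#' @param target_ks target median pairwise Ks between copies (> 0).
#' @param seed RNG seed.
#' @return list(layout, seqs) with copy labels set, plus attribute
#'   \code{mutation_rounds}.
#' @export
applyWGD <- function(genome, multiplicity, layer_label, target_ks, seed = 1) {
  stopifnot(multiplicity %in% c(2L, 3L))
  if (target_ks <= 0) stop("target_ks must be positive")
  labels <- if (layer_label == "beta") c("a", "b") else c("A", "B", "C")[seq_len(multiplicity)]
  labels <- labels[seq_len(multiplicity)]
  # the calibration measures the pairwise Ks of two independently m-mutated
  # copies, exactly the configuration applied below
  m <- calibrateMutationRounds(genome$seqs, target_ks, seed = childSeed(seed, "calib"))
  g <- geneTable(genome$layout)
  base <- genome$seqs[g$gene_id, , drop = FALSE]
  copies <- lapply(seq_along(labels), function(i) {
    lab <- labels[i]
    gi <- g
    gi$gene_id <- paste0(g$gene_id, "_", lab)
    gi$chrom <- paste0(g$chrom, "_", lab)
    if (lab %in% c("A", "B", "C")) gi$gamma <- lab else gi$beta <- lab
    si <- withSeed(childSeed(seed, paste0("wgd", lab)),
                   mutateCodonMatrix(base, m))
    rownames(si) <- gi$gene_id
    list(genes = gi, seqs = si)
  })
  genes <- do.call(rbind, lapply(copies, `[[`, "genes"))
  seqs <- do.call(rbind, lapply(copies, `[[`, "seqs"))
  layout <- newGenomeLayout(rebuildBp(genes), speciesId = speciesId(genome$layout))
  psLog("apply_wgd", layer = layer_label, multiplicity = multiplicity,
        target_ks = target_ks, rounds_per_copy = m,
        chroms = length(chromNames(layout)))
  out <- list(layout = layout, seqs = seqs)
  attr(out, "mutation_rounds") <- m
  out
}

#' Apply a chromosome fusion plan
#'
#' The plan partitions the current chromosomes into gene-rank segments and
#' concatenates them into new chromosomes; every segment must be used
#' exactly once. Junction truth records every adjacency between segments
#' from different source chromosomes.
#'
#' @param genome list(layout, seqs).
#' @param plan named list; each element is the recipe for one new
#'   chromosome: a list of segments \code{list(chrom =, from =, to =)}
#'   with 0-based half-open rank bounds (\code{from}/\code{to} may be
#'   omitted for a whole chromosome).
#' @param layer_label layer recorded on the junction truth.
#' @return list(layout, seqs, junctions) where junctions is a data.frame
#'   (layer, chrom, pos, left, right).
#' @export
applyFusionPlan <- function(genome, plan, layer_label) {
  g <- geneTable(genome$layout)
  used <- rep(FALSE, nrow(g))
  rows <- list(); junctions <- list()
  for (newChrom in names(plan)) {
    parts <- plan[[newChrom]]
    segRows <- lapply(parts, function(p) {
      onChrom <- g$chrom == p$chrom
      if (!any(onChrom)) stop("fusion plan references unknown chromosome ", p$chrom)
      nmax <- sum(onChrom)
      from <- if (is.null(p$from)) 0L else p$from
      to <- if (is.null(p$to)) nmax else p$to
      if (from < 0 || to > nmax || from >= to)
        stop("fusion plan span out of range on ", p$chrom)
      which(onChrom & g$rank >= from & g$rank < to)
    })
    idx <- unlist(segRows)
    if (any(used[idx]) || anyDuplicated(idx)) stop("fusion plan reuses a segment")
    used[idx] <- TRUE
    gi <- g[idx, , drop = FALSE]
    gi$chrom <- newChrom
    gi$rank <- seq_len(nrow(gi)) - 1L
    rows[[newChrom]] <- gi
    # junctions between consecutive segments of different source chromosome
    srcOfSeg <- vapply(seq_along(parts), function(k) parts[[k]]$chrom, character(1))
    pos <- cumsum(vapply(segRows, length, integer(1)))
    for (k in seq_along(parts)[-1]) {
      if (srcOfSeg[k] != srcOfSeg[k - 1]) {
        lg <- g[segRows[[k - 1]][length(segRows[[k - 1]])], ]
        rg <- g[segRows[[k]][1], ]
        junctions[[length(junctions) + 1L]] <- data.frame(
          layer = layer_label, chrom = newChrom, pos = pos[k - 1],
          left = originClassLabel(lg), right = originClassLabel(rg),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!all(used)) stop("fusion plan omits ", sum(!used), " genes")
  genes <- do.call(rbind, rows)
  genes <- rebuildBp(genes)
  # ranks were assigned manually; rebuild layout preserving plan order
  layout <- newGenomeLayout(genes, speciesId = speciesId(genome$layout),
                            chromOrder = names(plan))
  jt <- if (length(junctions)) do.call(rbind, junctions) else
    data.frame(layer = character(0), chrom = character(0), pos = integer(0),
               left = character(0), right = character(0))
  psLog("apply_fusion_plan", layer = layer_label,
        chroms = length(plan), junctions = nrow(jt))
  list(layout = layout, seqs = genome$seqs, junctions = jt)
}

# Origin class label of a gene from its truth columns: "Eu{e}:{gamma}{beta}".
originClassLabel <- function(generow) {
  paste0("Eu", generow$eu, ":",
         ifelse(is.na(generow$gamma), "", generow$gamma),
         ifelse(is.na(generow$beta), "", generow$beta))
}

#' Apply (biased) gene fractionation
#'
#' Deletes gene copies either by per-copy-class retention probabilities or
#' by an explicit locus-to-retained-copy-set implant. Unless
#' \code{allow_full_loss}, at least one copy of every ancestral locus is
#' kept (a uniformly chosen survivor when all copies would be lost).
#'
#' @param genome list(layout, seqs).
#' @param retention_spec either \code{list(probs = c(Aa = 0.8, ...))} with
#'   per-class retention probabilities (class key = paste0(gamma, beta)),
#'   or \code{list(implant = list(locus1 = c("Aa", "Bb"), ...))} naming the
#'   copy classes retained per locus (loci not named keep all copies).
#' @param seed RNG seed.
#' @param allow_full_loss allow loci to lose every copy (default FALSE).
#' @return list(layout, seqs, retention) where retention is a data.frame
#'   (locus, class, gene_id) of retained copies.
#' @export
applyFractionation <- function(genome, retention_spec, seed = 1,
                               allow_full_loss = FALSE) {
  g <- geneTable(genome$layout)
  cls <- paste0(ifelse(is.na(g$gamma), "", g$gamma),
                ifelse(is.na(g$beta), "", g$beta))
  keep <- rep(TRUE, nrow(g))
  if (!is.null(retention_spec$probs)) {
    p <- retention_spec$probs
    if (any(p < 0 | p > 1)) stop("retention probabilities outside [0, 1]")
    pg <- p[cls]
    pg[is.na(pg)] <- 1
    keep <- withSeed(childSeed(seed, "fractionation"),
                     stats::runif(nrow(g)) < pg)
  } else if (!is.null(retention_spec$implant)) {
    imp <- retention_spec$implant
    hit <- g$locus %in% names(imp)
    keep[hit] <- mapply(function(lc, cl) cl %in% imp[[lc]],
                        g$locus[hit], cls[hit])
  } else stop("retention_spec needs $probs or $implant")
  if (!allow_full_loss) {
    lost <- setdiff(unique(g$locus), unique(g$locus[keep]))
    if (length(lost)) {
      rescue <- withSeed(childSeed(seed, "rescue"), vapply(lost, function(lc) {
        cand <- which(g$locus == lc)
        cand[sample.int(length(cand), 1)]
      }, integer(1)))
      keep[rescue] <- TRUE
    }
  }
  g2 <- g[keep, , drop = FALSE]
  g2 <- g2[order(match(g2$chrom, unique(g$chrom)), g2$rank), , drop = FALSE]
  g2$rank <- as.integer(stats::ave(seq_len(nrow(g2)), g2$chrom, FUN = seq_along)) - 1L
  g2 <- rebuildBp(g2)
  layout <- newGenomeLayout(g2, speciesId = speciesId(genome$layout),
                            chromOrder = unique(g$chrom))
  retention <- data.frame(locus = g2$locus,
                          class = paste0(ifelse(is.na(g2$gamma), "", g2$gamma),
                                         ifelse(is.na(g2$beta), "", g2$beta)),
                          gene_id = g2$gene_id, stringsAsFactors = FALSE)
  psLog("apply_fractionation", kept = nrow(g2), dropped = nrow(g) - nrow(g2))
  seqs <- if (nrow(genome$seqs)) genome$seqs[g2$gene_id, , drop = FALSE] else
    genome$seqs
  list(layout = layout, seqs = seqs, retention = retention)
}

#' Apply an inversion, reciprocal translocation or fission
#'
#' Inversion reverses gene order and flips strands within a rank span;
#' reciprocal translocation swaps terminal segments of two chromosomes;
#' fission splits one chromosome in two.
#'
#' @param genome list(layout, seqs).
#' @param kind "inversion", "translocation" or "fission".
#' @param params inversion: list(chrom, from, to) 0-based half-open rank
#'   span; translocation: list(chrom_a, from_a, chrom_b, from_b) with tails
#'   starting at the given ranks; fission: list(chrom, at, new_names).
#' @param layer_label layer recorded on the event truth.
#' @return list(layout, seqs, event).
#' @export
applyRearrangement <- function(genome, kind, params, layer_label = "extant") {
  g <- geneTable(genome$layout)
  chromOrder <- unique(g$chrom)
  if (kind == "inversion") {
    on <- g$chrom == params$chrom
    n <- sum(on)
    if (params$from < 0 || params$to > n || params$from >= params$to)
      stop("inversion span out of range")
    sel <- which(on & g$rank >= params$from & g$rank < params$to)
    sel <- sel[order(g$rank[sel])]
    inv <- rev(sel)
    g[sel, ] <- g[inv, ]
    g$strand[sel] <- ifelse(g$strand[sel] == "+", "-", "+")
    g$rank[sel] <- params$from:(params$to - 1L)
    event <- list(kind = "inversion", layer = layer_label,
                  chrom = params$chrom, from = params$from, to = params$to)
  } else if (kind == "translocation") {
    onA <- g$chrom == params$chrom_a; onB <- g$chrom == params$chrom_b
    nA <- sum(onA); nB <- sum(onB)
    if (params$from_a >= nA || params$from_b >= nB ||
        params$from_a < 1 || params$from_b < 1)
      stop("translocation span out of range")
    tailA <- which(onA & g$rank >= params$from_a)
    tailB <- which(onB & g$rank >= params$from_b)
    g$chrom[tailA] <- params$chrom_b
    g$chrom[tailB] <- params$chrom_a
    g$rank[tailA] <- params$from_b + seq_along(tailA) - 1L
    g$rank[tailB] <- params$from_a + seq_along(tailB) - 1L
    event <- list(kind = "reciprocal_translocation", layer = layer_label,
                  chrom_a = params$chrom_a, from_a = params$from_a,
                  chrom_b = params$chrom_b, from_b = params$from_b)
  } else if (kind == "fission") {
    on <- g$chrom == params$chrom
    n <- sum(on)
    if (params$at <= 0 || params$at >= n) stop("fission point out of range")
    nm <- if (!is.null(params$new_names)) params$new_names else
      paste0(params$chrom, c("_p", "_q"))
    sel2 <- which(on & g$rank >= params$at)
    sel1 <- which(on & g$rank < params$at)
    g$chrom[sel1] <- nm[1]; g$chrom[sel2] <- nm[2]
    g$rank[sel2] <- g$rank[sel2] - params$at
    chromOrder <- as.vector(unlist(lapply(chromOrder, function(ch)
      if (ch == params$chrom) nm else ch)))
    event <- list(kind = "fission", layer = layer_label,
                  chrom = params$chrom, at = params$at, new_names = nm)
  } else stop("unknown rearrangement kind: ", kind)
  g <- g[order(match(g$chrom, chromOrder), g$rank), , drop = FALSE]
  g <- rebuildBp(g)
  layout <- newGenomeLayout(g, speciesId = speciesId(genome$layout),
                            chromOrder = chromOrder)
  psLog("apply_rearrangement", kind = kind, layer = layer_label)
  list(layout = layout, seqs = genome$seqs, event = event)
}

# Derive truth segments (runs of constant origin class, contiguous in
# ancestral rank and orientation) from generator gene metadata.
truthSegments <- function(layout, max_gap = 50) {
  g <- geneTable(layout)
  cls <- paste0("Eu", g$eu, ":", ifelse(is.na(g$gamma), "", g$gamma),
                ifelse(is.na(g$beta), "", g$beta))
  out <- list()
  for (ch in unique(g$chrom)) {
    x <- g[g$chrom == ch, , drop = FALSE]
    x <- x[order(x$rank), , drop = FALSE]
    cl <- cls[g$chrom == ch][order(g$rank[g$chrom == ch])]
    dir <- ifelse(x$strand == "+", 1L, -1L)
    brk <- c(TRUE, cl[-1] != cl[-length(cl)] |
               dir[-1] != dir[-length(dir)] |
               abs(diff(x$anc_rank)) > max_gap)
    id <- cumsum(brk)
    for (s in unique(id)) {
      ix <- which(id == s)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_rank = x$rank[ix[1]],
        end_rank = x$rank[ix[length(ix)]] + 1L,
        class = cl[ix[1]],
        orient = if (dir[ix[1]] > 0) "+" else "-",
        anc_start = min(x$anc_rank[ix]), anc_end = max(x$anc_rank[ix]) + 1L,
        n_genes = length(ix), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Derive truth junctions (adjacent truth segments of different origin
# class) from generator metadata.
truthJunctions <- function(layout, max_gap = 50) {
  seg <- truthSegments(layout, max_gap)
  out <- list()
  for (ch in unique(seg$chrom)) {
    x <- seg[seg$chrom == ch, , drop = FALSE]
    x <- x[order(x$start_rank), , drop = FALSE]
    if (nrow(x) < 2) next
    for (k in 2:nrow(x)) {
      if (x$class[k] != x$class[k - 1]) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, pos = x$start_rank[k],
          left = x$class[k - 1], right = x$class[k],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), pos = integer(0),
               left = character(0), right = character(0))
}
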