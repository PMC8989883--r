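## Retention/fractionation statistics over duplicated region classes,
## homoeolog expression triad normalization and seven-category
## classification, and methylation classing.

#' Build the locus x region-class retention matrix
#'
#' @param region_classes list as from \code{\link{enumerateRegionClasses}}
#'   (classes + per-class gene lists).
#' @param gene_locus named character: gene_id -> ancestral locus id (from
#'   the homology/painting pipeline; the generator's homology tables give
#'   this mapping directly).
#' @param loci optional restriction to these loci (e.g. called ancestral
#'   genes); default all loci seen.
#' @return logical matrix loci x classes with attribute "gene_ids"
#'   (character matrix of the retained gene per cell, NA when absent).
#' @export
buildRetentionMatrix <- function(region_classes, gene_locus, loci = NULL) {
  cls <- region_classes$classes
  pairs <- do.call(rbind, lapply(cls, function(cl) {
    ids <- region_classes$genes[[cl]]
    if (length(ids) == 0L) return(NULL)
    lc <- gene_locus[ids]
    data.frame(locus = unname(lc), class = cl, gene_id = ids,
               stringsAsFactors = FALSE)
  }))
  pairs <- pairs[!is.na(pairs$locus), , drop = FALSE]
  if (anyDuplicated(pairs[, c("locus", "class")])) {
    d <- pairs[duplicated(pairs[, c("locus", "class")]), ]
    stop("gene(s) mapped to one class twice (painting bug), e.g. locus ",
         d$locus[1], " class ", d$class[1])
  }
  if (is.null(loci)) loci <- sort(unique(pairs$locus))
  dropped <- sum(!pairs$locus %in% loci)
  pairs <- pairs[pairs$locus %in% loci, , drop = FALSE]
  m <- matrix(FALSE, length(loci), length(cls),
              dimnames = list(loci, cls))
  gid <- matrix(NA_character_, length(loci), length(cls),
                dimnames = list(loci, cls))
  m[cbind(pairs$locus, pairs$class)] <- TRUE
  gid[cbind(pairs$locus, pairs$class)] <- pairs$gene_id
  attr(m, "gene_ids") <- gid
  psLog("build_retention_matrix", loci = nrow(m), classes = ncol(m),
        dropped = dropped)
  m
}

#' Summarize retention across region classes
#'
#' @param matrix retention matrix from \code{\link{buildRetentionMatrix}}.
#' @param threshold_more_than loci retaining MORE THAN this many copies are
#'   the high-retention class (default 3, i.e. more than half of 6).
#' @return list(n_loci, high_retention_count, high_retention_pct,
#'   per_class_rate, copy_number_table).
#' @export
retentionSummary <- function(matrix, threshold_more_than = 3) {
  rs <- rowSums(matrix)
  high <- sum(rs > threshold_more_than)
  out <- list(n_loci = nrow(matrix),
              high_retention_count = high,
              high_retention_pct = 100 * high / nrow(matrix),
              per_class_rate = colMeans(matrix),
              copy_number_table = table(factor(rs, levels = 0:ncol(matrix))))
  psLog("retention_summary", loci = out$n_loci, high = high,
        pct = round(out$high_retention_pct, 1))
  out
}

#' Classify loci of one duplicated segment pair by retention
#'
#' For two homologous region classes derived from one duplication event,
#' classifies every locus present in at least one copy as retained in both,
#' singleton on copy 1, or singleton on copy 2; percentages are over the
#' present loci.
#'
#' @param matrix retention matrix.
#' @param class1,class2 the two region-class column names of the pair.
#' @return list(both, singleton_copy1, singleton_copy2, absent, pct =
#'   named percentages over present loci).
#' @export
pairRetentionClasses <- function(matrix, class1, class2) {
  if (!all(c(class1, class2) %in% colnames(matrix)))
    stop("classes not found in the retention matrix: ",
         class1, ", ", class2, " (not a duplicated pair?)")
  c1 <- matrix[, class1]; c2 <- matrix[, class2]
  both <- sum(c1 & c2); s1 <- sum(c1 & !c2); s2 <- sum(!c1 & c2)
  absent <- sum(!c1 & !c2)
  present <- both + s1 + s2
  pct <- 100 * c(both = both, singleton_copy1 = s1, singleton_copy2 = s2) /
    max(present, 1L)
  psLog("pair_retention_classes", both = both, s1 = s1, s2 = s2)
  list(both = both, singleton_copy1 = s1, singleton_copy2 = s2,
       absent = absent, pct = pct)
}

#' Normalize an expression triple to tissue fractions
#'
#' \code{frac_x = tpm_x / (tpm_leaf + tpm_root + tpm_stem)}. All-zero
#' triples are flagged not expressed (fractions NA).
#'
#' @param tpm_leaf,tpm_root,tpm_stem TPM values (vectorized).
#' @return data.frame(frac_leaf, frac_root, frac_stem, expressed).
#' @export
triadNormalize <- function(tpm_leaf, tpm_root, tpm_stem) {
  if (any(c(tpm_leaf, tpm_root, tpm_stem) < 0, na.rm = TRUE))
    stop("TPM must be non-negative")
  tot <- tpm_leaf + tpm_root + tpm_stem
  expressed <- tot > 0
  f <- cbind(tpm_leaf, tpm_root, tpm_stem) / ifelse(tot > 0, tot, NA)
  data.frame(frac_leaf = f[, 1], frac_root = f[, 2], frac_stem = f[, 3],
             expressed = expressed)
}

#' Classify a triad by its nearest archetype
#'
#' Euclidean distance in the fraction simplex to the seven archetypes
#' (balanced, three dominant, three suppressed); exact ties go to Balanced
#' (logged).
#'
#' @param frac_leaf,frac_root,frac_stem fractions summing to 1
#'   (vectorized).
#' @return character vector of categories.
#' @export
classifyTriad <- function(frac_leaf, frac_root, frac_stem) {
  fr <- cbind(frac_leaf, frac_root, frac_stem)
  if (any(abs(rowSums(fr) - 1) > 1e-6, na.rm = TRUE))
    stop("fractions must sum to 1")
  arch <- triadArchetypes()
  d2 <- sapply(seq_len(nrow(arch)), function(j)
    rowSums((fr - rep(arch[j, ], each = nrow(fr)))^2))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  best <- apply(d2, 1, function(x) {
    w <- which(x == min(x))
    if (length(w) > 1) {
      if (1 %in% w) return(1L)  # ties -> Balanced
      return(w[1])
    }
    w
  })
  nties <- sum(apply(d2, 1, function(x) sum(x == min(x)) > 1))
  if (nties) psLog("classify_triad", ties_to_balanced = nties)
  rownames(arch)[best]
}

#' Build classified triad records from expression records
#'
#' Replicates are averaged to one TPM per gene and tissue before
#' normalization.
#'
#' @param records expression records (gene_id, tissue, replicate, tpm).
#' @return data.frame(gene_id, tpm_leaf, tpm_root, tpm_stem, frac_*,
#'   expressed, category).
#' @export
triadTable <- function(records) {
  agg <- stats::aggregate(tpm ~ gene_id + tissue, records, mean)
  wide <- stats::reshape(agg, idvar = "gene_id", timevar = "tissue",
                         direction = "wide")
  names(wide) <- sub("^tpm\\.", "tpm_", names(wide))
  for (t in c("tpm_leaf", "tpm_root", "tpm_stem"))
    if (is.null(wide[[t]])) wide[[t]] <- 0
  fr <- triadNormalize(wide$tpm_leaf, wide$tpm_root, wide$tpm_stem)
  out <- cbind(wide[, c("gene_id", "tpm_leaf", "tpm_root", "tpm_stem")], fr)
  out$category <- NA_character_
  ok <- out$expressed
  out$category[ok] <- classifyTriad(out$frac_leaf[ok], out$frac_root[ok],
                                    out$frac_stem[ok])
  psLog("triad_table", genes = nrow(out), not_expressed = sum(!ok))
  out
}

#' Classify methylation level
#'
#' @param mC methylation fraction(s) in [0, 1].
#' @param hypo_max hypomethylated when mC <= this (default 0.3).
#' @param hyper_min hypermethylated when mC >= this (default 0.7, boundary
#'   inclusive).
#' @return character vector: "hypo", "intermediate" or "hyper".
#' @export
classifyMethylation <- function(mC, hypo_max = 0.3, hyper_min = 0.7) {
  if (any(mC < 0 | mC > 1, na.rm = TRUE)) stop("mC outside [0, 1]")
  ifelse(mC <= hypo_max, "hypo", ifelse(mC >= hyper_min, "hyper",
                                        "intermediate"))
}

# Jensen-Shannon divergence (log2, in [0, 1]) between two discrete
# profiles.
jsd2 <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    ix <- a > 0
    sum(a[ix] * log2(a[ix] / b[ix]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Expression diversity and specificity per region class
#'
#' Dj is the mean pairwise Jensen-Shannon divergence (log2; in [0, 1]) of
#' tissue-fraction profiles among the genes of a region class; Sj is the
#' mean tau tissue-specificity \code{sum(1 - x/max(x)) / (n_tissues - 1)}.
#' Classes with a single expressed gene get Dj = NA (flagged).
#'
#' @param triads classified triad table (\code{\link{triadTable}}) with a
#'   \code{region_class} column.
#' @return data.frame(region_class, n_genes, Dj, Sj).
#' @export
expressionDiversitySpecificity <- function(triads) {
  if (is.null(triads$region_class)) stop("triads need a region_class column")
  x <- triads[triads$expressed, , drop = FALSE]
  out <- lapply(split(x, x$region_class), function(g) {
    fr <- as.matrix(g[, c("frac_leaf", "frac_root", "frac_stem")])
    tau <- mean(apply(fr, 1, function(v) sum(1 - v / max(v)) / (ncol(fr) - 1)))
    dj <- NA_real_
    if (nrow(fr) >= 2) {
      cmb <- utils::combn(nrow(fr), 2)
      dj <- mean(apply(cmb, 2, function(ij) jsd2(fr[ij[1], ], fr[ij[2], ])))
    }
    data.frame(region_class = g$region_class[1], n_genes = nrow(fr),
               Dj = dj, Sj = tau, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
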