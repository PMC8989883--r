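# Shared fixtures and independent oracles for the test suite. Oracles are
# written from first principles, independent of the package internals they
# check.

options(paleoshuffle.verbose = FALSE)

# ---- tiny layout builders ----

tinyLayout <- function(n_per_chrom, species = "toy", prefix = "chr") {
  rows <- list()
  for (i in seq_along(n_per_chrom)) {
    n <- n_per_chrom[i]
    rows[[i]] <- data.frame(
      gene_id = sprintf("%s%d_g%03d", prefix, i, seq_len(n)),
      chrom = paste0(prefix, i),
      start = (seq_len(n) - 1L) * 1000L + 1L,
      end = (seq_len(n) - 1L) * 1000L + 900L,
      strand = "+", stringsAsFactors = FALSE)
  }
  newGenomeLayout(do.call(rbind, rows), speciesId = species)
}

# homology records linking gene i of chrom_a to gene perm[i] of chrom_b
linkAnchors <- function(la, lb, chrom_a, chrom_b, ranks_a, ranks_b,
                        bitscore = 500) {
  ga <- geneTable(la); gb <- geneTable(lb)
  q <- ga$gene_id[match(paste(chrom_a, ranks_a), paste(ga$chrom, ga$rank))]
  s <- gb$gene_id[match(paste(chrom_b, ranks_b), paste(gb$chrom, gb$rank))]
  data.frame(query = q, subject = s, pct_identity = 90, evalue = 1e-50,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

# one cached fig1 replay + pipeline per session (several files use it)
.fixtureCache <- new.env()
getReplay <- function(seed = 42) {
  key <- paste0("replay", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- fig1Replay(seed = seed)
  .fixtureCache[[key]]
}
getPipeline <- function(seed = 42) {
  key <- paste0("pipe", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- runKaryotypePipeline(getReplay(seed), seed = 1)
  .fixtureCache[[key]]
}

# ---- independent NG86 oracle ----

.oBases <- c("T", "C", "A", "G")
.oCodons <- apply(expand.grid(p3 = .oBases, p2 = .oBases, p1 = .oBases)[, 3:1],
                  1, paste0, collapse = "")
.oAA <- unname(Biostrings::GENETIC_CODE[.oCodons])

oracleSynSites <- function(codon) {
  cs <- strsplit(codon, "")[[1]]
  aa <- Biostrings::GENETIC_CODE[[codon]]
  tot <- 0
  for (p in 1:3) for (b in setdiff(.oBases, cs[p])) {
    alt <- cs; alt[p] <- b
    aa2 <- Biostrings::GENETIC_CODE[[paste0(alt, collapse = "")]]
    if (aa2 != "*" && aa2 == aa) tot <- tot + 1
  }
  tot / 3
}

# pathway enumeration for one codon pair: all orders of the differing
# positions; pathways through stop codons excluded; if all are blocked,
# average over all pathways with stop-creating steps as nonsynonymous
oracleCodonDiff <- function(c1, c2) {
  s1 <- strsplit(c1, "")[[1]]; s2 <- strsplit(c2, "")[[1]]
  dpos <- which(s1 != s2)
  if (length(dpos) == 0) return(c(sd = 0, nd = 0))
  perms <- if (length(dpos) == 1) list(dpos) else {
    pm <- function(v) if (length(v) == 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(pm(v[-i]), function(r) c(v[i], r))))
    pm(dpos)
  }
  valid <- list(); all_sn <- list()
  for (p in perms) {
    cur <- s1; sC <- 0; nC <- 0; blocked <- FALSE
    sF <- 0; nF <- 0
    for (pos in p) {
      aaPrev <- Biostrings::GENETIC_CODE[[paste0(cur, collapse = "")]]
      cur[pos] <- s2[pos]
      aaNext <- Biostrings::GENETIC_CODE[[paste0(cur, collapse = "")]]
      if (aaNext == "*") { blocked <- TRUE; nF <- nF + 1 }
      else if (aaNext == aaPrev) { sC <- sC + 1; sF <- sF + 1 }
      else { nC <- nC + 1; nF <- nF + 1 }
    }
    all_sn[[length(all_sn) + 1]] <- c(sF, nF)
    if (!blocked) valid[[length(valid) + 1]] <- c(sC, nC)
  }
  use <- if (length(valid)) valid else all_sn
  m <- colMeans(do.call(rbind, use))
  c(sd = m[1], nd = m[2])
}

oracleNG86 <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  S <- (sum(vapply(ca, oracleSynSites, numeric(1))) +
          sum(vapply(cb, oracleSynSites, numeric(1)))) / 2
  d <- colSums(do.call(rbind, lapply(seq_along(ca), function(i)
    oracleCodonDiff(ca[i], cb[i]))))
  list(S = S, N = 3 * length(ca) - S, Sd = unname(d[1]), Nd = unname(d[2]))
}

randomSenseCodons <- function(n) {
  sense <- .oCodons[.oAA != "*"]
  paste0(sample(sense, n, replace = TRUE), collapse = "")
}

# ---- brute-force maximum-chain oracle (n <= 15 anchors) ----

oracleMaxChain <- function(ra, rb, max_gap, orientation = "+") {
  if (orientation == "-") rb <- -rb
  n <- length(ra)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) <= best) next
    o <- idx[order(ra[idx], rb[idx])]
    a <- ra[o]; b <- rb[o]
    ok <- TRUE
    if (length(o) > 1) {
      da <- diff(a); db <- diff(b)
      ok <- all(da > 0) && all(db > 0) &&
        all(da - 1 <= max_gap) && all(abs(db) - 1 <= max_gap)
    }
    if (ok) best <- max(best, length(idx))
  }
  best
}

# ---- K2P counting oracle ----

oracleK2P <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  pur <- c("A", "G")
  ts <- sum(va != vb & ((va %in% pur) == (vb %in% pur)))
  tv <- sum(va != vb) - ts
  P <- ts / length(va); Q <- tv / length(va)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}
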