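## Codon-level machinery shared by the Ks estimator and the sequence
## generator. All heavy per-pair work reduces to table lookups over a
## precomputed 64 x 64 pathway-averaged difference table (built once per
## session and cached).

.psCache <- new.env(parent = emptyenv())

.BASES <- c("T", "C", "A", "G")

# 64 codon strings in a fixed enumeration; integer codon codes index these.
codonAlphabet <- function() {
  if (!is.null(.psCache$codons)) return(.psCache$codons)
  cod <- apply(expand.grid(p3 = .BASES, p2 = .BASES, p1 = .BASES)[, 3:1], 1,
               paste0, collapse = "")
  .psCache$codons <- unname(cod)
  .psCache$codons
}

codonAA <- function() {
  if (!is.null(.psCache$aa)) return(.psCache$aa)
  gc <- Biostrings::GENETIC_CODE
  .psCache$aa <- unname(gc[codonAlphabet()])
  .psCache$aa
}

isStopCodon <- function() codonAA() == "*"

# Per-codon synonymous site count: at each position, (number of the 3
# alternative bases giving the same amino acid) / 3. Changes to stop codons
# count as nonsynonymous. Stop codons themselves get NA.
codonSynSites <- function() {
  if (!is.null(.psCache$synSites)) return(.psCache$synSites)
  cods <- codonAlphabet(); aa <- codonAA()
  s <- numeric(64)
  for (i in seq_len(64)) {
    if (aa[i] == "*") { s[i] <- NA_real_; next }
    cs <- strsplit(cods[i], "")[[1]]
    tot <- 0
    for (p in 1:3) for (b in setdiff(.BASES, cs[p])) {
      alt <- cs; alt[p] <- b
      j <- match(paste0(alt, collapse = ""), cods)
      if (aa[j] != "*" && aa[j] == aa[i]) tot <- tot + 1
    }
    s[i] <- tot / 3
  }
  .psCache$synSites <- s
  s
}

# Pathway-averaged synonymous/nonsynonymous difference counts between every
# pair of sense codons (Nei-Gojobori): enumerate all orders of the differing
# positions, drop pathways passing through a stop codon, average the
# per-step synonymous / nonsynonymous tallies over the remaining pathways.
# In the (rare) case where every pathway is blocked by a stop, fall back to
# averaging over all pathways with stop-creating steps counted as
# nonsynonymous.
codonDiffTables <- function() {
  if (!is.null(.psCache$SdMat)) return(list(Sd = .psCache$SdMat, Nd = .psCache$NdMat))
  cods <- codonAlphabet(); aa <- codonAA()
  codChars <- do.call(rbind, strsplit(cods, ""))
  Sd <- matrix(NA_real_, 64, 64); Nd <- matrix(NA_real_, 64, 64)
  perms <- list(`1` = list(1L),
                `2` = list(1:2, 2:1),
                `3` = list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                           c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L)))
  for (i in seq_len(64)) {
    if (aa[i] == "*") next
    for (j in seq_len(64)) {
      if (aa[j] == "*") next
      dpos <- which(codChars[i, ] != codChars[j, ])
      nd <- length(dpos)
      if (nd == 0L) { Sd[i, j] <- 0; Nd[i, j] <- 0; next }
      paths <- perms[[as.character(nd)]]
      sTot <- nTot <- 0; nValid <- 0
      sAll <- nAll <- 0   # fallback accumulators (stops = nonsynonymous)
      for (p in paths) {
        cur <- codChars[i, ]; sCnt <- nCnt <- 0; blocked <- FALSE
        sF <- nF <- 0
        for (step in p) {
          prevAA <- aa[match(paste0(cur, collapse = ""), cods)]
          cur[dpos[step]] <- codChars[j, dpos[step]]
          nxt <- match(paste0(cur, collapse = ""), cods)
          if (aa[nxt] == "*") { blocked <- TRUE; nF <- nF + 1 }
          else if (aa[nxt] == prevAA) { sCnt <- sCnt + 1; sF <- sF + 1 }
          else { nCnt <- nCnt + 1; nF <- nF + 1 }
        }
        sAll <- sAll + sF; nAll <- nAll + nF
        if (!blocked) { sTot <- sTot + sCnt; nTot <- nTot + nCnt; nValid <- nValid + 1 }
      }
      if (nValid > 0) { Sd[i, j] <- sTot / nValid; Nd[i, j] <- nTot / nValid }
      else { Sd[i, j] <- sAll / length(paths); Nd[i, j] <- nAll / length(paths) }
    }
  }
  .psCache$SdMat <- Sd; .psCache$NdMat <- Nd
  list(Sd = Sd, Nd = Nd)
}

# Single-base mutation transition distribution over codons, with synonymous
# changes weighted 5x relative to nonsynonymous and stop-creating changes
# forbidden. Returned as a 64 x 64 row-cumulative probability matrix for
# fast inverse-CDF sampling.
codonMutationCdf <- function(synBias = 5) {
  key <- paste0("mutCdf", synBias)
  if (!is.null(.psCache[[key]])) return(.psCache[[key]])
  cods <- codonAlphabet(); aa <- codonAA()
  codChars <- do.call(rbind, strsplit(cods, ""))
  W <- matrix(0, 64, 64)
  for (i in seq_len(64)) {
    if (aa[i] == "*") next
    for (p in 1:3) for (b in setdiff(.BASES, codChars[i, p])) {
      alt <- codChars[i, ]; alt[p] <- b
      j <- match(paste0(alt, collapse = ""), cods)
      if (aa[j] == "*") next
      W[i, j] <- W[i, j] + if (aa[j] == aa[i]) synBias else 1
    }
  }
  P <- W / pmax(rowSums(W), 1e-12)
  cdf <- t(apply(P, 1, cumsum))
  cdf[rowSums(W) > 0, 64] <- 1  # guard against float undershoot in sampling
  .psCache[[key]] <- cdf
  cdf
}

# Number of matching bases (0..3) between every codon pair; used to derive
# percent identity for emitted homology tables.
codonBaseMatches <- function() {
  if (!is.null(.psCache$baseMatch)) return(.psCache$baseMatch)
  codChars <- do.call(rbind, strsplit(codonAlphabet(), ""))
  M <- matrix(0L, 64, 64)
  for (p in 1:3) M <- M + outer(codChars[, p], codChars[, p], "==")
  .psCache$baseMatch <- M
  M
}

# ---- conversions ----

codonIntsFromString <- function(seq) {
  seq <- toupper(gsub("U", "T", seq))
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length not divisible by 3")
  codons <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  idx <- match(codons, codonAlphabet())
  if (anyNA(idx)) stop("sequence contains non-ACGT characters")
  idx
}

codonStringFromInts <- function(ints) paste0(codonAlphabet()[ints], collapse = "")

#' Nei-Gojobori (NG86) synonymous/nonsynonymous rate estimate
#'
#' Counts synonymous (S) and nonsynonymous (N) sites averaged over both
#' sequences, tallies pathway-averaged synonymous/nonsynonymous differences
#' per codon (all substitution orders enumerated, pathways through stop
#' codons excluded), and applies the Jukes-Cantor correction
#' \code{Ks = -3/4 log(1 - 4/3 ps)}. Proportions \code{ps >= 3/4} are
#' flagged saturated with \code{Ks = NA} (likewise for Ka).
#'
#' @param seq_a,seq_b equal-length in-frame nucleotide strings (or integer
#'   codon vectors) with no internal stop codons.
#' @return list with S, N, Sd, Nd, ps, pn, Ks, Ka, saturated_s,
#'   saturated_n.
#' @export
ksNG86 <- function(seq_a, seq_b) {
  a <- if (is.character(seq_a)) codonIntsFromString(seq_a) else as.integer(seq_a)
  b <- if (is.character(seq_b)) codonIntsFromString(seq_b) else as.integer(seq_b)
  if (length(a) != length(b)) stop("sequences must be equal length")
  stops <- isStopCodon()
  if (any(stops[a]) || any(stops[b])) stop("internal stop codon in alignment")
  ksNG86Int(a, b)
}

# Fast path on integer codon vectors (no validation).
ksNG86Int <- function(a, b) {
  syn <- codonSynSites()
  tabs <- codonDiffTables()
  S <- (sum(syn[a]) + sum(syn[b])) / 2
  N <- 3 * length(a) - S
  idx <- cbind(a, b)
  Sd <- sum(tabs$Sd[idx]); Nd <- sum(tabs$Nd[idx])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  satS <- ps >= 3 / 4; satN <- pn >= 3 / 4
  Ks <- if (satS) NA_real_ else -3 / 4 * log(1 - 4 / 3 * ps)
  Ka <- if (satN) NA_real_ else -3 / 4 * log(1 - 4 / 3 * pn)
  list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn, Ks = Ks, Ka = Ka,
       saturated_s = satS, saturated_n = satN)
}

#' Kimura two-parameter distance
#'
#' \code{K = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q))} with P and Q the observed
#' transition and transversion proportions. Returns NA (flagged saturated)
#' when the logarithm argument is non-positive.
#'
#' @param seq_a,seq_b equal-length gap-free nucleotide strings.
#' @return list with P, Q, K, saturated.
#' @export
k2pDistance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be equal length")
  purine <- c("A", "G")
  diff <- a != b
  ts <- sum(diff & ((a %in% purine) == (b %in% purine)))
  tv <- sum(diff) - ts
  P <- ts / length(a); Q <- tv / length(a)
  arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0)
    return(list(P = P, Q = Q, K = NA_real_, saturated = TRUE))
  list(P = P, Q = Q, K = -0.5 * log(arg1 * sqrt(arg2)), saturated = FALSE)
}

#' LTR insertion age from a K2P distance
#'
#' \code{age = K / (2 r)} years, with r the per-site per-year mutation
#' rate.
#'
#' @param K Kimura two-parameter distance (>= 0).
#' @param r mutation rate per site per year (default 1.3e-8).
#' @return age in years.
#' @export
ltrAge <- function(K, r = 1.3e-8) {
  if (any(r <= 0)) stop("mutation rate r must be positive")
  if (any(K < 0)) stop("K must be non-negative")
  K / (2 * r)
}
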