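## Ks distribution summaries: block medians, kernel density, Gaussian
## mixture fitting by EM (KDE-mode initialization + seeded restarts, BIC
## model selection) and block-to-event assignment.

#' Compute NG86 Ks for anchor pairs of a block set
#'
#' For each block, up to \code{max_per_block} anchors are sampled
#' (deterministically, by seed) and their Ks computed from the codon
#' matrices; the block table's \code{median_ks} is filled with the median
#' of unsaturated anchor values.
#'
#' @param blockset a CollinearBlockSet.
#' @param seqs_a,seqs_b integer codon matrices (rownames = gene ids) for
#'   the two genomes.
#' @param max_per_block anchor sample size per block (default 60); anchors
#'   are taken evenly spaced along the chain so every part of a long block
#'   is measured.
#' @param seed reserved for API stability (sampling is deterministic).
#' @return list(blockset = updated CollinearBlockSet, anchor_ks =
#'   data.frame(block_id, gene_a, gene_b, ks)).
#' @export
blockAnchorKs <- function(blockset, seqs_a, seqs_b, max_per_block = 60,
                          seed = 1) {
  an <- anchorTable(blockset)
  bt <- blockTable(blockset)
  pick <- unlist(lapply(split(seq_len(nrow(an)), an$block_id), function(ix) {
    ix <- ix[order(an$rank_a[ix])]
    if (length(ix) <= max_per_block) ix else
      ix[unique(round(seq(1, length(ix), length.out = max_per_block)))]
  }), use.names = FALSE)
  sub <- an[pick, , drop = FALSE]
  ra <- match(sub$gene_a, rownames(seqs_a))
  rb <- match(sub$gene_b, rownames(seqs_b))
  ks <- vapply(seq_len(nrow(sub)), function(k)
    ksNG86Int(seqs_a[ra[k], ], seqs_b[rb[k], ])$Ks, numeric(1))
  med <- vapply(bt$block_id, function(b)
    stats::median(ks[sub$block_id == b], na.rm = TRUE), numeric(1))
  bt$median_ks <- med
  psLog("block_anchor_ks", blocks = nrow(bt), anchors_measured = nrow(sub),
        saturated = sum(is.na(ks)))
  list(blockset = new("CollinearBlockSet", blocks = bt, anchors = an),
       anchor_ks = data.frame(block_id = sub$block_id, gene_a = sub$gene_a,
                              gene_b = sub$gene_b, ks = ks,
                              stringsAsFactors = FALSE))
}

#' Median Ks of a block
#'
#' Median of the unsaturated anchor Ks values (mean of the central two for
#' even counts). All-saturated blocks are flagged undefined.
#'
#' @param ks_values anchor Ks values of one block (NA = saturated).
#' @return list(median, n_used, all_saturated).
#' @export
blockMedianKs <- function(ks_values) {
  v <- ks_values[!is.na(ks_values)]
  if (length(v) == 0L)
    return(list(median = NA_real_, n_used = 0L, all_saturated = TRUE))
  list(median = stats::median(v), n_used = length(v), all_saturated = FALSE)
}

#' Gaussian kernel density of a Ks sample on a fixed grid
#'
#' Evaluated on the grid \code{seq(0, ks_max, by = 0.005)} with Silverman's
#' rule-of-thumb bandwidth by default; the returned density is normalized
#' to integrate to 1 over the grid.
#'
#' @param values Ks values (NA dropped).
#' @param bandwidth kernel bandwidth; default Silverman.
#' @param ks_max grid upper end (default 3).
#' @return data.frame(ks, density).
#' @export
ksDensity <- function(values, bandwidth = NULL, ks_max = 3) {
  v <- values[!is.na(values) & values <= ks_max & values >= 0]
  if (length(v) < 2L) stop("need at least 2 Ks values in range")
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(v)
  grid <- seq(0, ks_max, by = 0.005)
  dens <- vapply(grid, function(x) mean(stats::dnorm(x, v, bandwidth)),
                 numeric(1))
  area <- sum(dens) * 0.005
  data.frame(ks = grid, density = dens / area)
}

# log-sum-exp across mixture components (rows = obs, cols = components)
logRowSums <- function(lp) {
  m <- apply(lp, 1, max)
  m + log(rowSums(exp(lp - m)))
}

emFit <- function(x, w, mu, sd0, max_iter = 500, tol = 1e-8, var_floor = 1e-6) {
  n <- length(x); k <- length(mu)
  ll_old <- -Inf; trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lp <- sapply(seq_len(k), function(j)
      log(w[j]) + stats::dnorm(x, mu[j], pmax(sqrt(var_floor), sd0[j]), log = TRUE))
    if (k == 1L) lp <- matrix(lp, ncol = 1)
    lse <- logRowSums(lp)
    ll <- sum(lse)
    # EM guarantees a non-decreasing likelihood (the variance floor can
    # nick it by float noise); stop rather than record a decrease
    if (ll < ll_old - 1e-6 * (1 + abs(ll_old))) break
    trace <- c(trace, ll)
    converged <- abs(ll - ll_old) < tol * (1 + abs(ll))
    ll_old <- ll
    if (converged) break
    r <- exp(lp - lse)
    nk <- colSums(r)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(r * x) / nk
    sd0 <- sqrt(pmax(colSums(r * (x - rep(mu, each = n))^2) / nk, var_floor))
  }
  list(w = w, mu = mu, sd = sd0, logLik = ll_old, trace = trace)
}

#' Fit a Gaussian mixture to a Ks distribution
#'
#' EM over k in \code{k_range}, each k initialized from the top-k KDE modes
#' plus \code{n_restarts} seeded random restarts; the best k is chosen by
#' BIC (or AIC). Deterministic for a given seed.
#'
#' @param values Ks values.
#' @param k_range candidate component counts (default 1:5).
#' @param fit_range Ks window used for fitting (default c(0.05, 3)).
#' @param n_restarts random restarts per k (default 5).
#' @param criterion "BIC" (default) or "AIC".
#' @param seed RNG seed.
#' @return a \linkS4class{KsMixture}.
#' @export
fitKsMixture <- function(values, k_range = 1:5, fit_range = c(0.05, 3),
                         n_restarts = 5, criterion = c("BIC", "AIC"),
                         seed = 1) {
  criterion <- match.arg(criterion)
  x <- values[!is.na(values) & values >= fit_range[1] & values <= fit_range[2]]
  if (length(x) < 50L)
    stop("need at least 50 Ks values in the fit range (have ", length(x), ")")
  kde <- ksDensity(x, ks_max = fit_range[2])
  d <- kde$density
  isMode <- c(FALSE, d[-c(1, length(d))] > d[-c(length(d) - 1, length(d))] &
                d[-c(1, length(d))] >= d[-(1:2)], FALSE)
  modes <- kde$ks[isMode][order(-d[isMode])]
  n <- length(x)
  best <- NULL
  for (k in k_range) {
    if (k > n / 10) next
    inits <- list()
    mu0 <- if (length(modes) >= k) modes[seq_len(k)] else
      stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    inits[[1]] <- list(w = rep(1 / k, k), mu = sort(mu0),
                       sd = rep(stats::sd(x) / k + 1e-3, k))
    rst <- withSeed(childSeed(seed, paste0("mixk", k)), lapply(seq_len(n_restarts), function(r)
      list(w = rep(1 / k, k), mu = sort(sample(x, k)),
           sd = rep(stats::sd(x) / k + 1e-3, k))))
    inits <- c(inits, rst)
    fitK <- NULL
    for (ini in inits) {
      f <- emFit(x, ini$w, ini$mu, ini$sd)
      if (!is.null(f) && (is.null(fitK) || f$logLik > fitK$logLik)) fitK <- f
    }
    if (is.null(fitK)) next
    p <- 3 * k - 1
    score <- if (criterion == "BIC") -2 * fitK$logLik + p * log(n) else
      -2 * fitK$logLik + 2 * p
    if (is.null(best) || score < best$score)
      best <- list(score = score, k = k, fit = fitK)
  }
  o <- order(best$fit$mu)
  cmp <- data.frame(weight = best$fit$w[o], mean = best$fit$mu[o],
                    sd = best$fit$sd[o])
  psLog("fit_ks_mixture", n = n, k = best$k, criterion = criterion,
        score = round(best$score, 2))
  new("KsMixture", components = cmp, k = as.integer(best$k),
      bic = if (criterion == "BIC") best$score else NA_real_,
      logLik = best$fit$logLik, range = fit_range)
}

#' Assign blocks (or any Ks medians) to mixture components
#'
#' Maximum posterior responsibility at each median; exact posterior ties go
#' to the lower-mean component (logged).
#'
#' @param medians numeric vector of block median Ks values.
#' @param mixture a KsMixture.
#' @return data.frame(median_ks, component, posterior); component indexes
#'   the mean-ordered components of the mixture.
#' @export
assignBlocksToEvents <- function(medians, mixture) {
  cmp <- mixtureComponents(mixture)
  post <- sapply(seq_len(nrow(cmp)), function(j)
    cmp$weight[j] * stats::dnorm(medians, cmp$mean[j], cmp$sd[j]))
  if (is.null(dim(post))) post <- matrix(post, nrow = 1)
  tot <- rowSums(post)
  post <- post / ifelse(tot > 0, tot, 1)
  comp <- max.col(post, ties.method = "first")  # first = lower mean on ties
  nties <- sum(apply(post, 1, function(p) sum(p == max(p)) > 1))
  if (nties > 0) psLog("assign_blocks_to_events", ties_to_lower_mean = nties)
  data.frame(median_ks = medians, component = comp,
             posterior = post[cbind(seq_along(medians), comp)])
}
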