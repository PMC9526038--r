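#' Pool gene records into a single evolutionary unit
#'
#' Element-wise sum of the nonsynonymous and synonymous spectra and of the
#' divergence and site counts across genes. All records must share the
#' same sample size and folded flag. Pooling increases the polymorphism
#' available to an estimator, but heterogeneous genes can combine into a
#' table whose association reverses the per-gene signal (Simpson's
#' paradox), so pooled and per-gene conclusions are not interchangeable.
#'
#' @param records a [GeneVariation-class] or list thereof.
#' @param geneId identifier for the pooled record; the default tags the
#'   number of pooled genes.
#' @return A single [GeneVariation-class].
#' @export
poolRecords <- function(records, geneId = NULL) {
  records <- asRecordList(records)
  if (length(records) == 0L) stop("no records to pool")
  if (length(records) == 1L) return(records[[1L]])
  n <- records[[1L]]@sfsN@sampleSize
  folded <- records[[1L]]@sfsN@folded
  for (g in records) {
    if (g@sfsN@sampleSize != n)
      stop("cannot pool records with mixed sample sizes")
    if (g@sfsN@folded != folded)
      stop("cannot pool folded with unfolded records")
  }
  if (is.null(geneId))
    geneId <- sprintf("pool_of_%d", length(records))
  cn <- Reduce(`+`, lapply(records, function(g) g@sfsN@counts))
  cs <- Reduce(`+`, lapply(records, function(g) g@sfsS@counts))
  GeneVariation(geneId,
                SFS(cn, sampleSize = n, folded = folded),
                SFS(cs, sampleSize = n, folded = folded),
                dN = sum(vapply(records, function(g) g@dN, numeric(1))),
                dS = sum(vapply(records, function(g) g@dS, numeric(1))),
                mN = sum(vapply(records, function(g) g@mN, numeric(1))),
                mS = sum(vapply(records, function(g) g@mS, numeric(1))))
}

#' Bootstrap gene pools of increasing size
#'
#' For each pool size, draws genes with replacement from the record list,
#' pools them, applies the configured test, and aggregates the alpha
#' estimates over replicates: mean, empirical 2.5/97.5 percentiles (linear
#' interpolation) and the fraction of replicates that were analyzable
#' (unanalyzable replicates are counted but excluded from the mean and
#' percentiles). The procedure probes the minimum amount of data each
#' estimator needs.
#'
#' Reproducibility: every (pool size, replicate) pair uses its own RNG
#' stream derived deterministically from \code{seed}, so identical seeds
#' give bit-identical output regardless of evaluation order.
#'
#' @param records list of [GeneVariation-class] objects.
#' @param poolSizes integer pool sizes (default the 1-to-1000 grid used in
#'   gene pooling studies).
#' @param replicates resamples per pool size (default 1000).
#' @param seed master seed.
#' @param method one of \code{c("mkt", "fww", "emkt", "imp", "imp_high")}.
#' @param cutoff frequency cutoff for cutoff-based methods.
#' @param high upper cutoff for \code{"imp_high"}.
#' @return A data.frame with one row per pool size: \code{pool_size},
#'   \code{alpha_mean}, \code{alpha_p2_5}, \code{alpha_p97_5},
#'   \code{fraction_analyzable}, \code{mean_pn}, \code{mean_ps}.
#' @export
bootstrapPools <- function(records,
                           poolSizes = c(1, 2, 5, 10, 25, 50, 75, 100,
                                         250, 500, 750, 1000),
                           replicates = 1000L, seed = 1L, method = "imp",
                           cutoff = 0.15, high = 0.85) {
  records <- asRecordList(records)
  if (length(records) == 0L) stop("empty record list")
  if (any(poolSizes < 1L)) stop("pool sizes must be positive")
  if (replicates < 1L) stop("replicates must be >= 1")
  method <- match.arg(method,
                      c("mkt", "fww", "emkt", "imp", "imp_high"))
  testFun <- switch(method,
    mkt = function(g) standardMKT(g),
    fww = function(g) fwwMKT(g, cutoff),
    emkt = function(g) eMKT(g, cutoff),
    imp = function(g) impMKT(g, cutoff),
    imp_high = function(g) impMKTHigh(g, cutoff, high))
  old <- globalenv()$.Random.seed
  on.exit(restoreRNG(old), add = TRUE)
  out <- vector("list", length(poolSizes))
  for (si in seq_along(poolSizes)) {
    size <- poolSizes[si]
    alphas <- numeric(replicates)
    ok <- logical(replicates)
    pns <- numeric(replicates)
    pss <- numeric(replicates)
    for (r in seq_len(replicates)) {
      set.seed(poolStreamSeed(seed, si, r))
      idx <- sample.int(length(records), size, replace = TRUE)
      pooled <- poolRecords(records[idx],
                            geneId = sprintf("pool_%d_%d", size, r))
      res <- testFun(pooled)
      ok[r] <- res@analyzable
      alphas[r] <- res@alpha
      pns[r] <- sum(pooled@sfsN@counts)
      pss[r] <- sum(pooled@sfsS@counts)
    }
    a <- alphas[ok]
    q <- if (length(a))
      unname(stats::quantile(a, c(0.025, 0.975), type = 7))
      else c(NA_real_, NA_real_)
    out[[si]] <- data.frame(
      pool_size = size,
      alpha_mean = if (length(a)) mean(a) else NA_real_,
      alpha_p2_5 = q[1], alpha_p97_5 = q[2],
      fraction_analyzable = mean(ok),
      mean_pn = mean(pns), mean_ps = mean(pss))
  }
  do.call(rbind, out)
}

# deterministic sub-seed per (pool size index, replicate); kept well
# below 2^31
poolStreamSeed <- function(seed, sizeIndex, replicate) {
  ((abs(seed) %% 100000L) * 1009L + sizeIndex * 99991L + replicate) %%
    2147483647L
}
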