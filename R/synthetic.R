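## Poisson Random Field generator of synthetic gene variation records.
## Sites evolve independently; the segregating-frequency density under
## genic selection with scaled coefficient gamma = 2*Ne*s is
##   f(q; gamma) = (1 - exp(-gamma (1 - q))) / (q (1 - q) (1 - exp(-gamma)))
## whose neutral limit is 1/q, and the expected sampled class i carries
##   G(i; gamma, n) = integral f(q; gamma) Binom(i; n, q) dq
## (G(i; 0, n) = 1/i exactly). Fixations accrue relative to neutral at
##   u(gamma) = gamma / (1 - exp(-gamma)).

# selection kernel H(q) = q(1-q) f(q); overflow-safe on both tails
selectionKernel <- function(q, gamma) {
  if (abs(gamma) < 1e-8) return(1 - q)
  if (gamma < 0) {
    (exp(gamma) - exp(gamma * q)) / expm1(gamma)
  } else {
    -expm1(gamma * (q - 1)) / -expm1(-gamma)
  }
}

# relative fixation rate vs neutral
relativeFixationRate <- function(gamma) {
  ifelse(abs(gamma) < 1e-8, 1, gamma / (-expm1(-gamma)))
}

#' Expected sampled spectrum under selection
#'
#' Expected relative density of segregating sites per derived-allele-count
#' class for a sample of \code{n} haploid sequences, under the diffusion
#' (Poisson Random Field) stationary density for scaled selection
#' coefficient \code{gamma} = 2 Ne s. The result is scaled so that the
#' neutral case (\code{gamma = 0}) gives exactly \code{1/i}; multiplying
#' by the locus mutation rate theta * L gives expected counts. Mass
#' monomorphic in the sample (classes 0 and n) is dropped.
#'
#' @param gamma scaled selection coefficient (negative = deleterious;
#'   0 = neutral, returned analytically).
#' @param n sample size (haploid sequences).
#' @return Numeric vector of length \code{n - 1}.
#' @examples
#' expectedSfsSelected(0, 10)        # 1, 1/2, ..., 1/9
#' expectedSfsSelected(-2000, 20)    # mass piled onto singletons
#' @export
expectedSfsSelected <- function(gamma, n) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2")
  i <- seq_len(n - 1L)
  if (abs(gamma) < 1e-12) return(1 / i)
  breaks <- sort(unique(c(0, 10^seq(-7, 0, length.out = 15), 1)))
  vapply(i, function(ii) {
    fn <- function(q)
      vapply(q, function(qq)
        selectionKernel(qq, gamma) * stats::dbinom(ii, n, qq) /
          (qq * (1 - qq)), numeric(1))
    tot <- 0
    for (k in seq_len(length(breaks) - 1L)) {
      tot <- tot + stats::integrate(fn, breaks[k], breaks[k + 1L],
                                    rel.tol = 1e-8, subdivisions = 200L,
                                    stop.on.error = FALSE)$value
    }
    tot
  }, numeric(1))
}

#' Build a synthetic-data configuration
#'
#' Returns a [SyntheticConfig-class] whose defaults are the baseline
#' scenario of the benchmarking setup (see the class documentation);
#' \code{preset} switches individual parameters to the named alternative
#' scenario. Available presets: \code{"baseline"},
#' \code{"gammaBen500"}, \code{"gammaBen100"}, \code{"gammaDel1000"},
#' \code{"gammaDel500"}, \code{"beta0.1"}, \code{"beta0.2"},
#' \code{"genes28000"}, \code{"genes2000"}, \code{"rho0.01"},
#' \code{"rho0.0001"}, \code{"theta0.01"}, \code{"theta0.0001"},
#' \code{"alpha0.1"}, \code{"alpha0.7"}.
#'
#' @param preset scenario name.
#' @param ... individual parameter overrides (names as in
#'   [SyntheticConfig-class], e.g. \code{nGenes = 500}, \code{seed = 7}).
#' @return A [SyntheticConfig-class] object.
#' @examples
#' syntheticConfig(nGenes = 100, seed = 3)
#' syntheticConfig("beta0.1", nGenes = 100)
#' @export
syntheticConfig <- function(preset = "baseline", ...) {
  base <- list(theta = 0.001, rho = 0.001, gammaDel = -2000, beta = 0.3,
               gammaBen = 250, pA = 0.00021, alphaTarget = 0.4,
               alphaWeakFraction = 0, sampleSize = 20L, nGenes = 14000L,
               mnPerGene = 1125, msPerGene = 375,
               divergenceTimeScale = 4, seed = 1L)
  presets <- list(
    baseline = list(),
    gammaBen500 = list(gammaBen = 500, pA = 0.00012),
    gammaBen100 = list(gammaBen = 100, pA = 0.00048),
    gammaDel1000 = list(gammaDel = -1000),
    gammaDel500 = list(gammaDel = -500),
    `beta0.1` = list(beta = 0.1, pA = 0.00115),
    `beta0.2` = list(beta = 0.2, pA = 0.00048),
    genes28000 = list(nGenes = 28000L),
    genes2000 = list(nGenes = 2000L),
    `rho0.01` = list(rho = 0.01),
    `rho0.0001` = list(rho = 0.0001),
    `theta0.01` = list(theta = 0.01),
    `theta0.0001` = list(theta = 0.0001),
    `alpha0.1` = list(alphaTarget = 0.1, pA = 0.000036),
    `alpha0.7` = list(alphaTarget = 0.7, pA = 0.00075,
                      alphaWeakFraction = 0))
  if (!preset %in% names(presets))
    stop("unknown preset '", preset, "'; available: ",
         paste(names(presets), collapse = ", "))
  pars <- utils::modifyList(base, presets[[preset]])
  pars <- utils::modifyList(pars, list(...))
  new("SyntheticConfig", theta = pars$theta, rho = pars$rho,
      gammaDel = pars$gammaDel, beta = pars$beta, gammaBen = pars$gammaBen,
      pA = pars$pA, alphaTarget = pars$alphaTarget,
      alphaWeakFraction = pars$alphaWeakFraction,
      sampleSize = as.integer(pars$sampleSize),
      nGenes = as.integer(pars$nGenes), mnPerGene = pars$mnPerGene,
      msPerGene = pars$msPerGene,
      divergenceTimeScale = pars$divergenceTimeScale,
      seed = as.integer(pars$seed))
}

# session cache for the quadrature-heavy expectations (keyed on the
# parameters that determine them)
.sfsCache <- new.env(parent = emptyenv())

cachedSfs <- function(key, compute) {
  if (is.null(.sfsCache[[key]])) .sfsCache[[key]] <- compute()
  .sfsCache[[key]]
}

# per-class expected intensities for one gene under a config; the gamma
# DFE is discretized into K quantile midpoints
syntheticIntensities <- function(config, K = 64L) {
  n <- config@sampleSize
  gNeutral <- expectedSfsSelected(0, n)
  if (config@gammaDel == 0) {
    gDel <- gNeutral
    eU <- 1
  } else {
    x <- stats::qgamma((seq_len(K) - 0.5) / K, shape = config@beta,
                       scale = abs(config@gammaDel) / config@beta)
    key <- sprintf("del_%g_%g_%d_%d", config@gammaDel, config@beta, n, K)
    gDel <- cachedSfs(key, function()
      rowMeans(vapply(x, function(xx) expectedSfsSelected(-xx, n),
                      numeric(n - 1L))))
    eU <- mean(relativeFixationRate(-x))
  }
  gBen <- if (config@pA > 0)
    cachedSfs(sprintf("ben_%g_%d", config@gammaBen, n),
              function() expectedSfsSelected(config@gammaBen, n))
  else numeric(n - 1L)
  thN <- config@theta * config@mnPerGene
  thS <- config@theta * config@msPerGene
  lamPn <- thN * (config@pA * gBen + (1 - config@pA) * gDel)
  lamPs <- thS * gNeutral
  lamDs <- thS * config@divergenceTimeScale
  lamDnNon <- thN * config@divergenceTimeScale * (1 - config@pA) * eU
  lamDnBen <- if (config@alphaTarget > 0)
    config@alphaTarget / (1 - config@alphaTarget) * lamDnNon else 0
  list(lamPn = lamPn, lamPs = lamPs, lamDs = lamDs,
       lamDnNon = lamDnNon, lamDnBen = lamDnBen,
       delSfs = thN * (1 - config@pA) * gDel, neutralSfs = gNeutral)
}

#' Generate a synthetic dataset with known true alpha
#'
#' Draws per-gene variation records from the Poisson Random Field model:
#' synonymous spectra are Poisson around the neutral expectation
#' \code{theta m_S / i}; nonsynonymous spectra mix a gamma-distributed
#' deleterious class (discretized into 64 quantile points) with a
#' beneficial point mass of mutational weight \code{pA}; synonymous
#' divergence is Poisson around
#' \code{theta m_S divergenceTimeScale}; nonsynonymous divergence is the
#' sum of a non-adaptive component (neutral-plus-deleterious fixation
#' leak, rate scaled by the mean relative fixation rate of the DFE) and a
#' beneficial component whose expected share is \code{alphaTarget}. The
#' class of every fixation is recorded, so the realized adaptive fraction
#' in the truth object is exact by construction. Fully reproducible from
#' \code{config@seed}.
#'
#' @param config a [SyntheticConfig-class] object.
#' @return A list with elements \code{records} (list of
#'   [GeneVariation-class]) and \code{truth} ([SyntheticTruth-class]).
#' @examples
#' sim <- simulateDataset(syntheticConfig(nGenes = 5, seed = 42))
#' realizedAlpha(sim$truth)
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  lam <- syntheticIntensities(config)
  n <- config@sampleSize
  G <- config@nGenes
  nc <- n - 1L
  old <- globalenv()$.Random.seed
  on.exit(restoreRNG(old), add = TRUE)
  set.seed(config@seed)
  pnMat <- matrix(stats::rpois(G * nc, rep(lam$lamPn, each = G)), G, nc)
  psMat <- matrix(stats::rpois(G * nc, rep(lam$lamPs, each = G)), G, nc)
  dsVec <- stats::rpois(G, lam$lamDs)
  dnNon <- stats::rpois(G, lam$lamDnNon)
  dnBen <- stats::rpois(G, lam$lamDnBen)
  ids <- sprintf("gene_%05d", seq_len(G))
  records <- lapply(seq_len(G), function(k) {
    GeneVariation(ids[k],
                  SFS(pnMat[k, ], sampleSize = n),
                  SFS(psMat[k, ], sampleSize = n),
                  dN = dnNon[k] + dnBen[k], dS = dsVec[k],
                  mN = config@mnPerGene, mS = config@msPerGene)
  })
  totalDn <- sum(dnNon) + sum(dnBen)
  truth <- new("SyntheticTruth",
               realizedAlpha = if (totalDn > 0) sum(dnBen) / totalDn
                               else NA_real_,
               perGene = data.frame(gene_id = ids, dn_adaptive = dnBen,
                                    dn_nonadaptive = dnNon,
                                    stringsAsFactors = FALSE),
               expectedDelSfs = lam$delSfs,
               expectedNeutralSfs = lam$neutralSfs,
               config = config)
  list(records = records, truth = truth)
}

#' @rdname accessors
#' @export
setMethod("realizedAlpha", "SyntheticTruth", function(x) x@realizedAlpha)

#' Expected deleterious polymorphism below a cutoff
#'
#' Expected number of deleterious-origin segregating sites per gene with
#' derived-allele frequency strictly below the cutoff, read off the
#' generating intensities of a synthetic dataset. This is the
#' ground-truth counterpart of the count the imputation estimates.
#'
#' @param truth a [SyntheticTruth-class] object.
#' @param cutoff frequency cutoff in (0, 1).
#' @return Expected count per gene (a single number).
#' @rdname expectedPwdBelowCutoff
#' @export
setMethod("expectedPwdBelowCutoff", "SyntheticTruth",
  function(truth, cutoff) {
    n <- truth@config@sampleSize
    fr <- seq_len(n - 1L) / n
    sum(truth@expectedDelSfs[fr < cutoff])
  })

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    paste0("SyntheticConfig: theta = %g, gammaDel = %g (beta = %g), ",
           "gammaBen = %g, pA = %g,\n  alphaTarget = %g, n = %d, ",
           "genes = %d (mN = %g, mS = %g), T = %g, seed = %d\n"),
    object@theta, object@gammaDel, object@beta, object@gammaBen,
    object@pA, object@alphaTarget, object@sampleSize, object@nGenes,
    object@mnPerGene, object@msPerGene, object@divergenceTimeScale,
    object@seed))
  if (object@rho != 0 || object@alphaWeakFraction != 0)
    cat("  (rho and alphaWeakFraction are recorded metadata only)\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth over %d genes: realized alpha = %.4f\n",
              nrow(object@perGene), object@realizedAlpha))
})
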