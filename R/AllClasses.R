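#' @import methods
NULL

#' Site frequency spectrum
#'
#' Counts of segregating sites per allele-frequency class at a fixed sample
#' size of \code{n} haploid sequences. Unfolded spectra are indexed by
#' derived-allele count \code{i = 1..n-1}; folded spectra by minor-allele
#' count \code{i = 1..floor(n/2)}. Counts may be real-valued (e.g. after
#' hypergeometric projection); raw data are integers.
#'
#' @slot counts numeric vector of per-class counts, all \code{>= 0}.
#' @slot sampleSize integer, the number of sampled haploid sequences.
#' @slot folded logical, whether classes index minor-allele counts.
#'
#' @seealso [SFS()], [sfsTotal()], [foldSFS()], [projectSFS()]
#' @export
setClass("SFS",
  representation(counts = "numeric", sampleSize = "integer",
                 folded = "logical"))

setValidity("SFS", function(object) {
  n <- object@sampleSize
  msg <- character()
  if (length(n) != 1L || is.na(n) || n < 2L)
    msg <- c(msg, "sampleSize must be a single integer >= 2")
  expected <- if (isTRUE(object@folded)) n %/% 2L else n - 1L
  if (length(msg) == 0L && length(object@counts) != expected)
    msg <- c(msg, sprintf("counts must have length %d for %s SFS at n = %d",
                          expected,
                          if (object@folded) "a folded" else "an unfolded", n))
  if (anyNA(object@counts) || any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative and non-missing")
  if (length(object@folded) != 1L || is.na(object@folded))
    msg <- c(msg, "folded must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Per-gene variation record
#'
#' One gene's paired nonsynonymous/synonymous site frequency spectra,
#' fixed-difference counts and analyzed site counts. The polymorphism
#' totals P_N and P_S are always derived from the spectra, never stored.
#'
#' @slot geneId character gene identifier.
#' @slot sfsN,sfsS [SFS-class] objects for nonsynonymous and synonymous
#'   segregating sites; must share sample size and folded flag.
#' @slot dN,dS numeric fixed-difference counts (nonsynonymous, synonymous).
#' @slot mN,mS numeric counts of analyzed nonsynonymous/synonymous sites.
#'
#' @seealso [GeneVariation()], [pN()], [pS()], [standardMKT()]
#' @export
setClass("GeneVariation",
  representation(geneId = "character", sfsN = "SFS", sfsS = "SFS",
                 dN = "numeric", dS = "numeric",
                 mN = "numeric", mS = "numeric"))

setValidity("GeneVariation", function(object) {
  msg <- character()
  if (length(object@geneId) != 1L || is.na(object@geneId))
    msg <- c(msg, "geneId must be a single string")
  if (object@sfsN@sampleSize != object@sfsS@sampleSize)
    msg <- c(msg, "sfsN and sfsS must share the same sample size")
  if (object@sfsN@folded != object@sfsS@folded)
    msg <- c(msg, "sfsN and sfsS must share the same folded flag")
  for (s in c("dN", "dS")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0)
      msg <- c(msg, sprintf("%s must be a single non-negative number", s))
  }
  for (s in c("mN", "mS")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", s))
  }
  if (length(msg)) msg else TRUE
})

#' Frequency-band polymorphism counts
#'
#' Counts of nonsynonymous and synonymous segregating sites below versus
#' at-or-above a frequency cutoff, as used by the cutoff-based tests and
#' by the imputation of slightly deleterious variants. For folded spectra
#' the band is defined on minor-allele frequency, so the "below" band
#' collects both low- and high-frequency derived alleles.
#'
#' @slot pnLow,pnHigh,psLow,psHigh numeric band counts.
#' @slot cutoff numeric frequency cutoff in (0, 1).
#'
#' @seealso [bandCounts()], [imputePwd()]
#' @export
setClass("BandCounts",
  representation(pnLow = "numeric", pnHigh = "numeric",
                 psLow = "numeric", psHigh = "numeric", cutoff = "numeric"))

setValidity("BandCounts", function(object) {
  msg <- character()
  v <- c(object@pnLow, object@pnHigh, object@psLow, object@psHigh)
  if (length(v) != 4L || anyNA(v) || any(v < 0))
    msg <- c(msg, "band counts must be single non-negative numbers")
  if (length(object@cutoff) != 1L || is.na(object@cutoff) ||
      object@cutoff <= 0 || object@cutoff >= 1)
    msg <- c(msg, "cutoff must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Result of a McDonald-Kreitman style test
#'
#' Outcome of one 2x2 polymorphism/divergence test on a gene (or pooled
#' gene set): the integer contingency table actually tested, the alpha
#' estimate computed from unrounded quantities, the two-sided Fisher exact
#' P-value and the imputation bookkeeping.
#'
#' @slot method character: one of \code{"mkt"}, \code{"fww"}, \code{"emkt"},
#'   \code{"imp"}, \code{"imp_high"}.
#' @slot cutoff numeric cutoff(s); length 2 (low, high) for
#'   \code{"imp_high"}, length 0 for \code{"mkt"}.
#' @slot table 2x2 numeric matrix (integer-valued cells) with polymorphism
#'   in the first column, divergence in the second; rows nonsynonymous,
#'   synonymous.
#' @slot alpha numeric estimate of the adaptive substitution fraction
#'   (at most 1; may be negative).
#' @slot pValue two-sided Fisher exact P-value.
#' @slot pwd imputed count of slightly deleterious nonsynonymous
#'   polymorphisms (methods \code{"imp"}/\code{"imp_high"}; NA otherwise),
#'   after clamping to [0, P_N(below cutoff)].
#' @slot pwdUnclamped the raw imputed value before clamping.
#' @slot pneut P_N minus the (clamped, unrounded) imputed count.
#' @slot fNeutral neutral fraction estimated from the synonymous class
#'   (method \code{"emkt"} only).
#' @slot excludedFraction share of all polymorphic sites dropped from the
#'   test, with total polymorphism P_N + P_S as the denominator.
#' @slot analyzable logical; FALSE when a margin required by the method is
#'   zero, in which case alpha and pValue are NA.
#' @slot clamped logical; TRUE when the imputation was clamped.
#' @slot note character diagnostic (e.g. reason a gene was skipped).
#'
#' @seealso [standardMKT()], [impMKT()], [classifyGene()]
#' @export
setClass("MKTResult",
  representation(method = "character", cutoff = "numeric", table = "matrix",
                 alpha = "numeric", pValue = "numeric",
                 pwd = "numeric", pwdUnclamped = "numeric", pneut = "numeric",
                 fNeutral = "numeric", excludedFraction = "numeric",
                 analyzable = "logical", clamped = "logical",
                 note = "character"))

setValidity("MKTResult", function(object) {
  msg <- character()
  if (!object@method %in% c("mkt", "fww", "emkt", "imp", "imp_high"))
    msg <- c(msg, "unknown method")
  if (!all(dim(object@table) == c(2L, 2L)))
    msg <- c(msg, "table must be 2x2")
  if (any(object@table < 0, na.rm = TRUE))
    msg <- c(msg, "table cells must be non-negative")
  if (!is.na(object@alpha) && object@alpha > 1 + 1e-12)
    msg <- c(msg, "alpha cannot exceed 1")
  if (!is.na(object@pValue) &&
      (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Per-frequency alpha function
#'
#' alpha estimated in derived-allele-frequency bins of the pooled spectra,
#' the input of the asymptotic extrapolation. Bins with zero synonymous
#' polymorphism are masked.
#'
#' @slot x numeric frequency grid (i/n), strictly increasing within (0,1).
#' @slot alphaX numeric per-bin alpha estimates (NA where masked).
#' @slot usable logical mask of informative bins.
#' @slot dN,dS numeric pooled divergence counts used.
#' @slot cumulative logical; TRUE when alpha(x) accumulates classes up to x.
#'
#' @seealso [alphaFunction()], [fitAsymptotic()]
#' @export
setClass("AlphaFunction",
  representation(x = "numeric", alphaX = "numeric", usable = "logical",
                 dN = "numeric", dS = "numeric", cumulative = "logical"))

setValidity("AlphaFunction", function(object) {
  msg <- character()
  if (length(object@x) != length(object@alphaX) ||
      length(object@x) != length(object@usable))
    msg <- c(msg, "x, alphaX and usable must have equal length")
  if (any(diff(object@x) <= 0) || any(object@x <= 0) || any(object@x >= 1))
    msg <- c(msg, "x must be strictly increasing within (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Asymptotic exponential fit of alpha(x)
#'
#' Parameters of the exponential model alpha(x) = a + b * exp(-c * x)
#' fitted to a per-frequency alpha function, its extrapolation
#' alpha(1) = a + b * exp(-c), and a bootstrap confidence interval
#' obtained by resampling frequency bins.
#'
#' @slot a,b,c numeric fit parameters (for the linear fallback, the slope
#'   is stored in \code{b} and \code{c} is NA).
#' @slot alphaInf numeric alpha extrapolated to x = 1.
#' @slot ciLow,ciHigh numeric percentile bootstrap bounds for alphaInf.
#' @slot converged logical; FALSE when neither model could be fitted.
#' @slot model character, \code{"exponential"} or \code{"linear"}.
#' @slot nPoints integer number of bins entering the fit.
#'
#' @seealso [fitAsymptotic()]
#' @export
setClass("AsymptoticFit",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alphaInf = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 converged = "logical", model = "character",
                 nPoints = "integer"))

#' Configuration of the synthetic-data generator
#'
#' Parameters of the Poisson Random Field generator of per-gene variation
#' records with known true alpha. Defaults mirror the baseline forward
#' simulation scenario (theta = 0.001 per site, gamma distributed
#' deleterious selection with shape 0.3 and mean scaled strength -2000, a
#' beneficial point mass at 2Ns = 250 entering the spectrum with mutational
#' weight p_a = 0.00021, total adaptation rate 0.4, samples of 20 haploid
#' sequences, genes of five 300-bp exons split 0.75/0.25 into
#' nonsynonymous/synonymous sites).
#'
#' \code{rho} and \code{alphaWeakFraction} are recorded for scenario parity
#' but do not alter the generated data: sites are unlinked by construction,
#' and the mapping from a weak-adaptive fixation share to mutational
#' proportions would require an external fixation-probability solver, which
#' the truth-by-construction design deliberately sidesteps.
#'
#' @slot theta per-site population-scaled mutation rate (4 Ne mu).
#' @slot rho per-site population-scaled recombination rate (metadata only).
#' @slot gammaDel scaled selection strength 2Ns of deleterious mutations
#'   (negative; mean of the gamma DFE). 0 disables the deleterious class.
#' @slot beta gamma shape of the deleterious DFE.
#' @slot gammaBen scaled strength of the beneficial point mass (positive).
#' @slot pA proportion of new nonsynonymous mutations that are beneficial.
#' @slot alphaTarget expected fraction of adaptive nonsynonymous fixations.
#' @slot alphaWeakFraction recorded share of alpha attributed to weak
#'   adaptation (metadata only).
#' @slot sampleSize number of sampled haploid sequences.
#' @slot nGenes number of genes to generate.
#' @slot mnPerGene,msPerGene nonsynonymous/synonymous sites per gene.
#' @slot divergenceTimeScale expected neutral substitutions per site, in
#'   units of theta (controls the divergence column of the tables).
#' @slot seed integer random seed.
#'
#' @seealso [syntheticConfig()], [simulateDataset()]
#' @export
setClass("SyntheticConfig",
  representation(theta = "numeric", rho = "numeric", gammaDel = "numeric",
                 beta = "numeric", gammaBen = "numeric", pA = "numeric",
                 alphaTarget = "numeric", alphaWeakFraction = "numeric",
                 sampleSize = "integer", nGenes = "integer",
                 mnPerGene = "numeric", msPerGene = "numeric",
                 divergenceTimeScale = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@theta <= 0) msg <- c(msg, "theta must be positive")
  if (object@beta <= 0) msg <- c(msg, "beta must be positive")
  if (object@gammaDel > 0)
    msg <- c(msg, "gammaDel is a deleterious strength and cannot be positive")
  if (object@pA < 0 || object@pA > 1) msg <- c(msg, "pA must lie in [0, 1]")
  if (object@alphaTarget < 0 || object@alphaTarget >= 1)
    msg <- c(msg, "alphaTarget must lie in [0, 1)")
  if (object@alphaWeakFraction < 0 || object@alphaWeakFraction > 1)
    msg <- c(msg, "alphaWeakFraction must lie in [0, 1]")
  if (object@sampleSize < 4L) msg <- c(msg, "sampleSize must be >= 4")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@mnPerGene <= 0 || object@msPerGene <= 0)
    msg <- c(msg, "site counts must be positive")
  if (object@divergenceTimeScale <= 0)
    msg <- c(msg, "divergenceTimeScale must be positive")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic dataset
#'
#' Bookkeeping recorded while generating a synthetic dataset: the class of
#' every nonsynonymous fixation (so the realized adaptive fraction is exact
#' by construction) and the expected per-class deleterious polymorphism,
#' from which the expected number of slightly deleterious variants below
#' any cutoff can be read off.
#'
#' @slot realizedAlpha fraction of nonsynonymous fixations drawn from the
#'   beneficial class, over the whole dataset.
#' @slot perGene data.frame with columns \code{gene_id},
#'   \code{dn_adaptive}, \code{dn_nonadaptive}.
#' @slot expectedDelSfs numeric expected deleterious-origin counts per
#'   frequency class for one gene.
#' @slot expectedNeutralSfs numeric expected neutral-shape counts per class
#'   for one synonymous-site-equivalent unit (for reference).
#' @slot config the generating [SyntheticConfig-class].
#'
#' @seealso [simulateDataset()], [expectedPwdBelowCutoff()]
#' @export
setClass("SyntheticTruth",
  representation(realizedAlpha = "numeric", perGene = "data.frame",
                 expectedDelSfs = "numeric", expectedNeutralSfs = "numeric",
                 config = "SyntheticConfig"))
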