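#' Construct a site frequency spectrum
#'
#' @param counts numeric vector of per-class counts: derived-allele classes
#'   \code{1..n-1} (unfolded) or minor-allele classes \code{1..floor(n/2)}
#'   (folded).
#' @param sampleSize number of sampled haploid sequences; defaults to the
#'   value implied by \code{length(counts)} for an unfolded spectrum.
#' @param folded logical flag.
#'
#' @return An [SFS-class] object.
#' @examples
#' SFS(c(5, 2, 1))            # unfolded, n = 4
#' SFS(c(6, 2), sampleSize = 4, folded = TRUE)
#' @export
SFS <- function(counts, sampleSize = length(counts) + 1L, folded = FALSE) {
  new("SFS", counts = as.numeric(counts),
      sampleSize = as.integer(sampleSize), folded = isTRUE(folded))
}

#' Construct a per-gene variation record
#'
#' @param geneId gene identifier.
#' @param sfsN,sfsS nonsynonymous and synonymous [SFS-class] objects (or
#'   bare count vectors, which are taken as unfolded spectra).
#' @param dN,dS nonsynonymous/synonymous fixed-difference counts.
#' @param mN,mS numbers of analyzed nonsynonymous/synonymous sites.
#'
#' @return A [GeneVariation-class] object.
#' @examples
#' g <- GeneVariation("g1", SFS(c(3, 2, 1)), SFS(c(2, 2, 2)),
#'                    dN = 4, dS = 3, mN = 300, mS = 100)
#' pN(g); pS(g)
#' @export
GeneVariation <- function(geneId, sfsN, sfsS, dN, dS, mN, mS) {
  if (!is(sfsN, "SFS")) sfsN <- SFS(sfsN)
  if (!is(sfsS, "SFS")) sfsS <- SFS(sfsS)
  new("GeneVariation", geneId = as.character(geneId), sfsN = sfsN,
      sfsS = sfsS, dN = as.numeric(dN), dS = as.numeric(dS),
      mN = as.numeric(mN), mS = as.numeric(mS))
}

#' Total polymorphism count of a spectrum
#'
#' Sum of all frequency-class counts; preserved exactly by folding.
#'
#' @param x an [SFS-class] object.
#' @return A single number.
#' @examples
#' sfsTotal(SFS(c(3, 2, 1)))  # 6
#' @rdname sfsTotal
#' @export
setMethod("sfsTotal", "SFS", function(x) sum(x@counts))

#' Fold an unfolded spectrum
#'
#' Collapses derived-allele classes to minor-allele classes:
#' \code{f'(i) = f(i) + f(n - i)} for \code{i < n/2}, and
#' \code{f'(n/2) = f(n/2)} when \code{n} is even. The total count is
#' preserved exactly. Folding an already folded spectrum is a contract
#' violation and signals an error.
#'
#' @param x an unfolded [SFS-class] object.
#' @return A folded [SFS-class] object.
#' @examples
#' foldSFS(SFS(c(5, 2, 1)))   # counts 6, 2 at n = 4
#' @rdname foldSFS
#' @export
setMethod("foldSFS", "SFS", function(x) {
  if (x@folded)
    stop("cannot fold an already folded SFS")
  n <- x@sampleSize
  half <- n %/% 2L
  out <- numeric(half)
  for (i in seq_len(half)) {
    j <- n - i
    out[i] <- if (j == i) x@counts[i] else x@counts[i] + x@counts[j]
  }
  new("SFS", counts = out, sampleSize = n, folded = TRUE)
})

#' Hypergeometric projection to a smaller sample size
#'
#' Expected spectrum after downsampling from \code{n} to \code{m} haploid
#' sequences: \code{f_m(j) = sum_i f_n(i) P(j | i)} with \code{P(j | i)}
#' the hypergeometric probability of drawing \code{j} derived alleles in
#' \code{m} draws without replacement from \code{i} derived among \code{n}.
#' Mass that becomes monomorphic after downsampling (j = 0 or j = m) is
#' discarded, mirroring observable data. Counts are returned as
#' expectations (real numbers); \code{rounding = "stochastic"} instead
#' draws integer counts whose expectation equals the projection, under the
#' given seed.
#'
#' @param x an unfolded [SFS-class] object.
#' @param m target sample size, \code{2 <= m <= sampleSize(x)}.
#' @param rounding \code{"none"} (default) or \code{"stochastic"}.
#' @param seed seed for stochastic rounding.
#' @return An [SFS-class] at sample size \code{m}.
#' @examples
#' projectSFS(SFS(c(3, 2, 1)), 3)
#' @rdname projectSFS
#' @export
setMethod("projectSFS", "SFS",
  function(x, m, rounding = c("none", "stochastic"), seed = NULL) {
    rounding <- match.arg(rounding)
    if (x@folded)
      stop("projection is defined on unfolded spectra")
    n <- x@sampleSize
    m <- as.integer(m)
    if (m > n) stop("cannot project to a larger sample size (m > n)")
    if (m < 2L) stop("target sample size must be at least 2")
    if (m == n) return(x)
    out <- numeric(m - 1L)
    for (j in seq_len(m - 1L)) {
      # dhyper(j; i, n - i, m) over source classes i
      i <- seq_len(n - 1L)
      out[j] <- sum(x@counts * stats::dhyper(j, i, n - i, m))
    }
    if (rounding == "stochastic") {
      if (!is.null(seed)) {
        old <- globalenv()$.Random.seed
        on.exit(restoreRNG(old), add = TRUE)
        set.seed(seed)
      }
      frac <- out - floor(out)
      out <- floor(out) + (stats::runif(length(out)) < frac)
    }
    new("SFS", counts = out, sampleSize = m, folded = FALSE)
  })

# restore (or remove) a saved .Random.seed
restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# frequency grid of an SFS: class i has frequency i/n (derived-allele
# frequency when unfolded, minor-allele frequency when folded)
sfsFrequencies <- function(x) {
  seq_along(x@counts) / x@sampleSize
}

#' Split polymorphism counts at a frequency cutoff
#'
#' Partitions the nonsynonymous and synonymous polymorphism of a gene into
#' counts strictly below versus at-or-above a frequency cutoff. A class at
#' frequency \code{i/n} is "below" iff \code{i/n < cutoff} (ties go to the
#' upper band). For folded spectra the comparison uses minor-allele
#' frequency, so removing the lower band removes both rare derived and
#' rare ancestral variants.
#'
#' @param x a [GeneVariation-class] record.
#' @param cutoff frequency in (0, 1).
#' @return A [BandCounts-class] object.
#' @examples
#' g <- GeneVariation("g", SFS(c(3, 2, 1)), SFS(c(2, 2, 2)), 4, 3, 300, 100)
#' bandCounts(g, 0.5)
#' @rdname bandCounts
#' @export
setMethod("bandCounts", "GeneVariation", function(x, cutoff) {
  if (length(cutoff) != 1L || is.na(cutoff) || cutoff <= 0 || cutoff >= 1)
    stop("cutoff must lie in (0, 1)")
  fr <- sfsFrequencies(x@sfsN)
  low <- fr < cutoff
  new("BandCounts",
      pnLow = sum(x@sfsN@counts[low]), pnHigh = sum(x@sfsN@counts[!low]),
      psLow = sum(x@sfsS@counts[low]), psHigh = sum(x@sfsS@counts[!low]),
      cutoff = cutoff)
})

## Accessors -----------------------------------------------------------------

#' Accessors for spectra and gene records
#'
#' @param x an [SFS-class], [GeneVariation-class] or [SyntheticTruth-class]
#'   object as appropriate.
#' @return The corresponding slot or derived value; \code{pN()}/\code{pS()}
#'   are the totals of the nonsynonymous/synonymous spectra.
#' @name accessors
#' @examples
#' g <- GeneVariation("g", SFS(c(3, 2, 1)), SFS(c(2, 2, 2)), 4, 3, 300, 100)
#' sampleSize(g); pN(g); dS(g)
NULL

#' @rdname accessors
#' @export
setMethod("sampleSize", "SFS", function(x) x@sampleSize)
#' @rdname accessors
#' @export
setMethod("sampleSize", "GeneVariation", function(x) x@sfsN@sampleSize)
#' @rdname accessors
#' @export
setMethod("isFolded", "SFS", function(x) x@folded)
#' @rdname accessors
#' @export
setMethod("isFolded", "GeneVariation", function(x) x@sfsN@folded)
#' @rdname accessors
#' @export
setMethod("sfsCounts", "SFS", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("geneId", "GeneVariation", function(x) x@geneId)
#' @rdname accessors
#' @export
setMethod("sfsN", "GeneVariation", function(x) x@sfsN)
#' @rdname accessors
#' @export
setMethod("sfsS", "GeneVariation", function(x) x@sfsS)
#' @rdname accessors
#' @export
setMethod("pN", "GeneVariation", function(x) sum(x@sfsN@counts))
#' @rdname accessors
#' @export
setMethod("pS", "GeneVariation", function(x) sum(x@sfsS@counts))
#' @rdname accessors
#' @export
setMethod("dN", "GeneVariation", function(x) x@dN)
#' @rdname accessors
#' @export
setMethod("dS", "GeneVariation", function(x) x@dS)
#' @rdname accessors
#' @export
setMethod("mN", "GeneVariation", function(x) x@mN)
#' @rdname accessors
#' @export
setMethod("mS", "GeneVariation", function(x) x@mS)

## show methods --------------------------------------------------------------

setMethod("show", "SFS", function(object) {
  cat(sprintf("%s SFS, n = %d, total = %g\n",
              if (object@folded) "folded" else "unfolded",
              object@sampleSize, sum(object@counts)))
  cat("counts:", paste(signif(object@counts, 4), collapse = " "), "\n")
})

setMethod("show", "GeneVariation", function(object) {
  cat(sprintf(
    "GeneVariation '%s' (n = %d%s): P_N = %g, P_S = %g, D_N = %g, D_S = %g, m_N = %g, m_S = %g\n",
    object@geneId, object@sfsN@sampleSize,
    if (object@sfsN@folded) ", folded" else "",
    sum(object@sfsN@counts), sum(object@sfsS@counts),
    object@dN, object@dS, object@mN, object@mS))
})

setMethod("show", "BandCounts", function(object) {
  cat(sprintf(
    "BandCounts at cutoff %g: P_N %g | %g, P_S %g | %g (below | at-or-above)\n",
    object@cutoff, object@pnLow, object@pnHigh, object@psLow, object@psHigh))
})
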