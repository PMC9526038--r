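## The 2x2 MKT family. All alpha estimates use unrounded imputed
## quantities; rounding (half away from zero) happens only when counts
## enter the Fisher contingency table.

# shared analyzability screen: zero synonymous polymorphism, zero
# divergence in either class, or no polymorphism at all
screenRecord <- function(g) {
  if (sum(g@sfsS@counts) == 0) return("P_S = 0")
  if (g@dN == 0) return("D_N = 0")
  if (g@dS == 0) return("D_S = 0")
  if (sum(g@sfsN@counts) + sum(g@sfsS@counts) == 0)
    return("no polymorphism")
  NULL
}

#' Standard McDonald-Kreitman test
#'
#' The classical 2x2 test contrasting the nonsynonymous/synonymous ratio
#' of polymorphism with that of divergence, with
#' \code{alpha = 1 - (P_N / P_S) (D_S / D_N)}. Genes with zero synonymous
#' polymorphism or zero divergence in either class are not analyzable.
#'
#' @param record a [GeneVariation-class] object.
#' @param alternative sidedness of the Fisher exact test.
#' @return An [MKTResult-class] object.
#' @examples
#' g <- GeneVariation("g", SFS(c(5, 2, 2, 1, 1, rep(0, 14)), 20),
#'                    SFS(c(4, 2, 3, 2, 2, 1, 1, 1, rep(0, 6), 1, rep(0, 4)), 20),
#'                    dN = 15, dS = 8, mN = 500, mS = 200)
#' standardMKT(g)
#' @seealso [fwwMKT()], [eMKT()], [impMKT()]
#' @export
standardMKT <- function(record, alternative = "two.sided") {
  bad <- screenRecord(record)
  if (!is.null(bad)) return(naMKTResult("mkt", numeric(0), bad))
  pn <- sum(record@sfsN@counts); ps <- sum(record@sfsS@counts)
  alpha <- 1 - (pn / ps) * (record@dS / record@dN)
  newMKTResult("mkt", numeric(0), pn, ps, record@dN, record@dS, alpha,
               excludedFraction = 0, alternative = alternative)
}

#' Frequency-cutoff (FWW) McDonald-Kreitman test
#'
#' Removes every polymorphic site, nonsynonymous and synonymous, below the
#' derived-allele-frequency cutoff before testing, on the assumption that
#' slightly deleterious variants segregate at low frequency.
#'
#' @inheritParams standardMKT
#' @param cutoff frequency cutoff in (0, 1); classes at exactly the cutoff
#'   frequency are retained.
#' @return An [MKTResult-class]; \code{excludedFraction} is the share of
#'   all polymorphic sites removed.
#' @export
fwwMKT <- function(record, cutoff = 0.15, alternative = "two.sided") {
  bad <- screenRecord(record)
  if (!is.null(bad)) return(naMKTResult("fww", cutoff, bad))
  b <- bandCounts(record, cutoff)
  if (b@psHigh == 0)
    return(naMKTResult("fww", cutoff, "P_S at-or-above cutoff is 0"))
  pn <- b@pnLow + b@pnHigh; ps <- b@psLow + b@psHigh
  alpha <- 1 - (b@pnHigh / b@psHigh) * (record@dS / record@dN)
  newMKTResult("fww", cutoff, b@pnHigh, b@psHigh, record@dN, record@dS,
               alpha,
               excludedFraction = (b@pnLow + b@psLow) / (pn + ps),
               alternative = alternative)
}

#' Extended McDonald-Kreitman test (eMKT)
#'
#' Decomposes the nonsynonymous polymorphism into effectively neutral and
#' weakly deleterious parts, estimating the neutral fraction below the
#' cutoff from the synonymous class:
#' \code{f_neutral = P_S(below) / P_S}, then
#' \code{P_N_neutral = P_N * f_neutral + P_N(at-or-above)}. The test uses
#' the rounded neutral count against the full synonymous polymorphism.
#'
#' The published definition multiplies the total \code{P_N} by
#' \code{f_neutral}; set \code{pnBelowOnly = TRUE} for the alternative
#' reading that applies the fraction to the below-cutoff count only.
#'
#' @inheritParams fwwMKT
#' @param pnBelowOnly use \code{P_N(below) * f_neutral} for the neutral
#'   part below the cutoff instead of \code{P_N * f_neutral}.
#' @return An [MKTResult-class] with \code{fNeutral} filled in.
#' @export
eMKT <- function(record, cutoff = 0.15, pnBelowOnly = FALSE,
                 alternative = "two.sided") {
  bad <- screenRecord(record)
  if (!is.null(bad)) return(naMKTResult("emkt", cutoff, bad))
  b <- bandCounts(record, cutoff)
  pn <- b@pnLow + b@pnHigh; ps <- b@psLow + b@psHigh
  fNeutral <- b@psLow / ps
  base <- if (pnBelowOnly) b@pnLow else pn
  pnNeutral <- base * fNeutral + b@pnHigh
  alpha <- 1 - (pnNeutral / ps) * (record@dS / record@dN)
  newMKTResult("emkt", cutoff, pnNeutral, ps, record@dN, record@dS, alpha,
               pneut = pnNeutral, fNeutral = fNeutral,
               excludedFraction = (pn - pnNeutral) / (pn + ps),
               alternative = alternative)
}

#' Impute the number of slightly deleterious variants below a cutoff
#'
#' Assuming variants at or above the cutoff are effectively neutral, the
#' expected neutral nonsynonymous/synonymous ratio is
#' \code{P_N(high) / P_S(high)}; the below-cutoff nonsynonymous excess over
#' that ratio is attributed to slightly deleterious mutations:
#' \deqn{P_{wd} = P_N(low) - P_N(high) \, P_S(low) / P_S(high).}
#' The value is clamped to \code{[0, P_N(low)]}; a negative raw imputation
#' (more constraint below the cutoff than above) is reported as 0 with the
#' clamp flag set.
#'
#' @param bands a [BandCounts-class] object (or a [GeneVariation-class]
#'   plus \code{cutoff}).
#' @param cutoff frequency cutoff, used when \code{bands} is a record.
#' @return A list with \code{pwd} (clamped), \code{unclamped} and
#'   \code{clamped} (logical).
#' @examples
#' b <- new("BandCounts", pnLow = 7, pnHigh = 4, psLow = 6, psHigh = 11,
#'          cutoff = 0.15)
#' imputePwd(b)$pwd   # 4.818...
#' @export
imputePwd <- function(bands, cutoff = 0.15) {
  if (is(bands, "GeneVariation")) bands <- bandCounts(bands, cutoff)
  if (!is(bands, "BandCounts")) stop("expected BandCounts or GeneVariation")
  if (bands@psHigh == 0)
    stop("P_S at-or-above the cutoff is 0; the neutral ratio is undefined")
  raw <- bands@pnLow - bands@pnHigh * bands@psLow / bands@psHigh
  pwd <- min(max(raw, 0), bands@pnLow)
  list(pwd = pwd, unclamped = raw, clamped = (pwd != raw))
}

#' Imputed McDonald-Kreitman test (impMKT)
#'
#' Imputes the number of slightly deleterious nonsynonymous variants below
#' the frequency cutoff (see [imputePwd()]) and removes only those from
#' the nonsynonymous polymorphism cell; the synonymous polymorphism is not
#' reduced. The adaptive fraction uses the unrounded imputation:
#' \code{alpha = 1 - ((P_N - P_wd) / P_S) (D_S / D_N)}; the contingency
#' table uses the rounded count.
#'
#' @inheritParams fwwMKT
#' @return An [MKTResult-class] with imputation bookkeeping
#'   (\code{pwd}, \code{pwdUnclamped}, \code{clamped});
#'   \code{excludedFraction} is the rounded removed count over total
#'   polymorphism.
#' @examples
#' g <- GeneVariation("g", SFS(c(5, 2, 2, 1, 1, rep(0, 14)), 20),
#'                    SFS(c(4, 2, 3, 2, 2, 1, 1, 1, rep(0, 6), 1, rep(0, 4)), 20),
#'                    dN = 15, dS = 8, mN = 500, mS = 200)
#' impMKT(g, 0.15)
#' @export
impMKT <- function(record, cutoff = 0.15, alternative = "two.sided") {
  bad <- screenRecord(record)
  if (!is.null(bad)) return(naMKTResult("imp", cutoff, bad))
  b <- bandCounts(record, cutoff)
  if (b@psHigh == 0)
    return(naMKTResult("imp", cutoff, "P_S at-or-above cutoff is 0"))
  imp <- imputePwd(b)
  pn <- b@pnLow + b@pnHigh; ps <- b@psLow + b@psHigh
  alpha <- 1 - ((pn - imp$pwd) / ps) * (record@dS / record@dN)
  newMKTResult("imp", cutoff, pn - imp$pwd, ps, record@dN, record@dS,
               alpha, pwd = imp$pwd, pwdUnclamped = imp$unclamped,
               pneut = pn - imp$pwd, clamped = imp$clamped,
               excludedFraction = roundHalfAway(imp$pwd) / (pn + ps),
               alternative = alternative)
}

#' Imputed MKT with a high-frequency correction
#'
#' Extension of [impMKT()] for data where weakly selected variants also
#' accumulate at high frequencies (e.g. under linked selection). The
#' neutral nonsynonymous/synonymous ratio is estimated from the mid band
#' \code{low <= i/n < high}; the below-\code{low} excess is imputed and
#' removed as in [impMKT()], while the at-or-above-\code{high} excess
#' \code{X = max(0, P_N(high band) - r P_S(high band))} is moved from the
#' nonsynonymous polymorphism to the nonsynonymous divergence cell rather
#' than dropped.
#'
#' @inheritParams standardMKT
#' @param low,high frequency cutoffs with \code{low < high}.
#' @return An [MKTResult-class]; \code{cutoff} holds \code{c(low, high)}.
#' @export
impMKTHigh <- function(record, low = 0.15, high = 0.85,
                       alternative = "two.sided") {
  if (!(low < high)) stop("low cutoff must be smaller than high cutoff")
  bad <- screenRecord(record)
  if (!is.null(bad)) return(naMKTResult("imp_high", c(low, high), bad))
  fr <- sfsFrequencies(record@sfsN)
  lo <- fr < low
  mid <- fr >= low & fr < high
  hi <- fr >= high
  psMid <- sum(record@sfsS@counts[mid])
  if (psMid == 0)
    return(naMKTResult("imp_high", c(low, high),
                       "no synonymous polymorphism in the mid band"))
  r <- sum(record@sfsN@counts[mid]) / psMid
  pnLow <- sum(record@sfsN@counts[lo])
  rawPwd <- pnLow - r * sum(record@sfsS@counts[lo])
  pwd <- min(max(rawPwd, 0), pnLow)
  xHigh <- max(0, sum(record@sfsN@counts[hi]) -
                  r * sum(record@sfsS@counts[hi]))
  pn <- sum(record@sfsN@counts); ps <- sum(record@sfsS@counts)
  pnAdj <- pn - pwd - xHigh
  dnAdj <- record@dN + xHigh
  alpha <- 1 - (pnAdj / ps) * (record@dS / dnAdj)
  newMKTResult("imp_high", c(low, high), pnAdj, ps, dnAdj, record@dS,
               alpha, pwd = pwd, pwdUnclamped = rawPwd, pneut = pnAdj,
               clamped = (pwd != rawPwd),
               excludedFraction = roundHalfAway(pwd) / (pn + ps),
               alternative = alternative)
}

#' Purifying-selection fractions d, d_w, d_0
#'
#' Heuristic decomposition of new nonsynonymous mutations into strongly
#' deleterious (\code{d}, the missing fraction of segregating sites),
#' weakly deleterious (\code{d_w}, from the imputed below-cutoff count)
#' and effectively neutral (\code{d_0}, the remainder):
#' \deqn{d = 1 - (P_N / P_S)(m_S / m_N), \quad
#'       d_w = (P_{wd} / P_S)(m_S / m_N), \quad d_0 = 1 - d - d_w.}
#' The unrounded imputation is used, so the three fractions sum to one
#' exactly.
#'
#' @inheritParams fwwMKT
#' @return A list with components \code{d}, \code{dw}, \code{d0}.
#' @export
dStats <- function(record, cutoff = 0.15) {
  ps <- sum(record@sfsS@counts)
  if (ps == 0) stop("P_S = 0; d statistics undefined")
  b <- bandCounts(record, cutoff)
  imp <- imputePwd(b)
  pn <- sum(record@sfsN@counts)
  ratio <- record@mS / record@mN
  d <- 1 - (pn / ps) * ratio
  dw <- (imp$pwd / ps) * ratio
  list(d = d, dw = dw, d0 = 1 - d - dw)
}

#' Classify a gene from its test result
#'
#' A gene is under positive selection when the test is significant with a
#' positive alpha, under negative selection when significant with a
#' negative alpha; otherwise non-significant. Non-analyzable results stay
#' non-analyzable regardless of the P-value.
#'
#' @param result an [MKTResult-class].
#' @param significance significance level (default 0.05).
#' @return One of \code{"positive"}, \code{"negative"},
#'   \code{"non-significant"}, \code{"non-analyzable"}.
#' @export
classifyGene <- function(result, significance = 0.05) {
  if (!result@analyzable) return("non-analyzable")
  if (!is.na(result@pValue) && result@pValue < significance) {
    if (result@alpha > 0) return("positive")
    if (result@alpha < 0) return("negative")
  }
  "non-significant"
}

#' Run a battery of MKT variants over many genes
#'
#' Batch driver: applies the requested method(s) and cutoff(s) to each
#' record and collects one result row per gene per method.
#'
#' @param records list of [GeneVariation-class] objects (or one record).
#' @param methods character subset of
#'   \code{c("mkt", "fww", "emkt", "imp", "imp_high")}.
#' @param cutoff frequency cutoff for the cutoff-based methods.
#' @param high upper cutoff for \code{"imp_high"}.
#' @param significance significance level for the class column.
#' @param bh add a Benjamini-Hochberg adjusted P-value column, computed
#'   per method over the analyzable genes (off by default).
#' @return A data.frame with columns \code{gene_id}, \code{method},
#'   \code{cutoff}, \code{pn_cell}, \code{ps_cell}, \code{dn}, \code{ds},
#'   \code{pwd}, \code{alpha}, \code{p_value}, \code{class} (and
#'   \code{p_bh} when requested).
#' @export
runMKT <- function(records, methods = "imp", cutoff = 0.15, high = 0.85,
                   significance = 0.05, bh = FALSE) {
  records <- asRecordList(records)
  methods <- match.arg(methods,
                       c("mkt", "fww", "emkt", "imp", "imp_high"),
                       several.ok = TRUE)
  rows <- list()
  for (m in methods) {
    for (g in records) {
      res <- switch(m,
        mkt = standardMKT(g),
        fww = fwwMKT(g, cutoff),
        emkt = eMKT(g, cutoff),
        imp = impMKT(g, cutoff),
        imp_high = impMKTHigh(g, cutoff, high))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g@geneId, method = m,
        cutoff = if (m == "mkt") NA_real_ else cutoff,
        pn_cell = res@table[1, 1], ps_cell = res@table[2, 1],
        dn = res@table[1, 2], ds = res@table[2, 2],
        pwd = res@pwd, alpha = res@alpha, p_value = res@pValue,
        class = classifyGene(res, significance),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (bh) {
    out$p_bh <- NA_real_
    for (m in unique(out$method)) {
      sel <- out$method == m & !is.na(out$p_value)
      out$p_bh[sel] <- stats::p.adjust(out$p_value[sel], method = "BH")
    }
  }
  out
}

## Result accessors ----------------------------------------------------------

#' Accessors for test results
#'
#' @param x an [MKTResult-class] object.
#' @return The corresponding slot.
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
setMethod("alphaEstimate", "MKTResult", function(x) x@alpha)
#' @rdname result-accessors
#' @export
setMethod("pValue", "MKTResult", function(x) x@pValue)
#' @rdname result-accessors
#' @export
setMethod("contingencyTable", "MKTResult", function(x) x@table)
#' @rdname result-accessors
#' @export
setMethod("pwdEstimate", "MKTResult", function(x) x@pwd)
#' @rdname result-accessors
#' @export
setMethod("isAnalyzable", "MKTResult", function(x) x@analyzable)
#' @rdname result-accessors
#' @export
setMethod("excludedFraction", "MKTResult", function(x) x@excludedFraction)

setMethod("show", "MKTResult", function(object) {
  lab <- c(mkt = "standard MKT", fww = "FWW MKT", emkt = "extended MKT",
           imp = "imputed MKT", imp_high = "imputed MKT (high-frequency)")
  cat(lab[[object@method]])
  if (length(object@cutoff))
    cat(sprintf(" [cutoff %s]", paste(object@cutoff, collapse = ", ")))
  cat("\n")
  if (!object@analyzable) {
    cat("not analyzable:", object@note, "\n")
    return(invisible(NULL))
  }
  print(object@table)
  cat(sprintf("alpha = %.4f, two-sided Fisher exact P = %.4g\n",
              object@alpha, object@pValue))
  if (!is.na(object@pwd))
    cat(sprintf("imputed P_wd = %.4g%s\n", object@pwd,
                if (object@clamped) " (clamped)" else ""))
  if (!is.na(object@excludedFraction))
    cat(sprintf("excluded fraction of polymorphism = %.3f\n",
                object@excludedFraction))
  invisible(NULL)
})
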