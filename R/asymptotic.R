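#' Per-frequency alpha function of pooled data
#'
#' Computes alpha in derived-allele-frequency bins of the pooled spectra:
#' \code{alpha(x_i) = 1 - (D_S / D_N) (P_N(i) / P_S(i))} with
#' \code{x_i = i / n}, either per bin (default) or cumulatively over
#' classes up to \code{i}. Bins with zero synonymous polymorphism are
#' masked as unusable.
#'
#' @param records a [GeneVariation-class] or list thereof (pooled
#'   automatically); spectra must be unfolded.
#' @param cumulative compute cumulative rather than per-bin alpha.
#' @return An [AlphaFunction-class] object.
#' @seealso [fitAsymptotic()]
#' @export
alphaFunction <- function(records, cumulative = FALSE) {
  g <- poolRecords(records)
  if (g@sfsN@folded)
    stop("the alpha function requires unfolded spectra")
  if (g@dN == 0 || g@dS == 0)
    stop("pooled divergence counts must be positive")
  pn <- g@sfsN@counts
  ps <- g@sfsS@counts
  if (cumulative) {
    pn <- cumsum(pn)
    ps <- cumsum(ps)
  }
  usable <- ps > 0
  ax <- rep(NA_real_, length(pn))
  ax[usable] <- 1 - (g@dS / g@dN) * (pn[usable] / ps[usable])
  if (!any(usable))
    stop("all frequency bins are masked (no synonymous polymorphism)")
  new("AlphaFunction", x = sfsFrequencies(g@sfsN), alphaX = ax,
      usable = usable, dN = g@dN, dS = g@dS, cumulative = cumulative)
}

#' Asymptotic extrapolation of alpha(x)
#'
#' Fits the exponential model \code{alpha(x) = a + b exp(-c x)} to the
#' usable bins inside the trim interval by bounded Levenberg-Marquardt
#' least squares (multi-start over three initial decay rates,
#' \code{c} constrained to (0, 100]), and reports
#' \code{alpha(1) = a + b exp(-c)}, the estimate of the adaptive fraction
#' once slightly deleterious variants have decayed out of the spectrum.
#' When the exponential cannot be fitted, a linear fit \code{a + b x} is
#' used instead and flagged. The confidence interval is a percentile
#' bootstrap over resampled frequency bins.
#'
#' The default trim interval [0.1, 0.9] drops the lowest-frequency bins
#' (dominated by weakly deleterious variants) and the highest (prone to
#' polarization error).
#'
#' @param alphaFn an [AlphaFunction-class] object.
#' @param trim numeric interval of frequencies used for fitting.
#' @param bootstrap number of bin-resampling replicates (0 disables).
#' @param seed seed for the bootstrap.
#' @return An [AsymptoticFit-class] object.
#' @examples
#' af <- new("AlphaFunction", x = (1:19) / 20,
#'           alphaX = 0.6 - 0.4 * exp(-5 * (1:19) / 20),
#'           usable = rep(TRUE, 19), dN = 100, dS = 100,
#'           cumulative = FALSE)
#' fitAsymptotic(af, bootstrap = 0)
#' @export
fitAsymptotic <- function(alphaFn, trim = c(0.1, 0.9), bootstrap = 500L,
                          seed = 1L) {
  stopifnot(is(alphaFn, "AlphaFunction"), length(trim) == 2L)
  sel <- alphaFn@usable & !is.na(alphaFn@alphaX) &
    alphaFn@x >= trim[1] & alphaFn@x <= trim[2]
  x <- alphaFn@x[sel]
  y <- alphaFn@alphaX[sel]
  if (length(x) < 3L)
    stop("need at least 3 usable frequency bins inside the trim interval")
  fit <- fitAlphaCurve(x, y)
  if (!fit$converged)
    return(new("AsymptoticFit", a = NA_real_, b = NA_real_, c = NA_real_,
               alphaInf = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
               converged = FALSE, model = "none",
               nPoints = length(x)))
  ci <- c(NA_real_, NA_real_)
  if (bootstrap > 0L) {
    old <- globalenv()$.Random.seed
    on.exit(restoreRNG(old), add = TRUE)
    set.seed(seed)
    reps <- vapply(seq_len(bootstrap), function(k) {
      idx <- sample.int(length(x), replace = TRUE)
      f <- fitAlphaCurve(x[idx], y[idx])
      if (f$converged) f$alphaInf else NA_real_
    }, numeric(1))
    ci <- unname(stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE,
                                 type = 7))
  }
  new("AsymptoticFit", a = fit$a, b = fit$b, c = fit$c,
      alphaInf = fit$alphaInf, ciLow = ci[1], ciHigh = ci[2],
      converged = TRUE, model = fit$model, nPoints = length(x))
}

# exponential fit with multi-start and linear fallback
fitAlphaCurve <- function(x, y) {
  best <- NULL
  yl <- y[which.max(x)]
  yf <- y[which.min(x)]
  for (c0 in c(1, 5, 25)) {
    f <- tryCatch({
      m <- minpack.lm::nlsLM(y ~ a + b * exp(-cc * x),
        data = data.frame(x = x, y = y),
        start = list(a = yl, b = yf - yl, cc = c0),
        lower = c(-Inf, -Inf, 1e-3), upper = c(Inf, Inf, 100),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      list(rss = sum(stats::residuals(m)^2), co = stats::coef(m))
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(f) && (is.null(best) || f$rss < best$rss)) best <- f
  }
  if (!is.null(best)) {
    co <- best$co
    return(list(a = unname(co["a"]), b = unname(co["b"]),
                c = unname(co["cc"]),
                alphaInf = unname(co["a"] + co["b"] * exp(-co["cc"])),
                model = "exponential", converged = TRUE))
  }
  lf <- tryCatch(stats::lm(y ~ x), error = function(e) NULL)
  if (!is.null(lf)) {
    co <- stats::coef(lf)
    return(list(a = unname(co[1]), b = unname(co[2]), c = NA_real_,
                alphaInf = unname(co[1] + co[2]), model = "linear",
                converged = TRUE))
  }
  list(converged = FALSE)
}

#' @rdname fitAsymptotic
#' @param x an [AsymptoticFit-class] object.
#' @export
setMethod("alphaInf", "AsymptoticFit", function(x) x@alphaInf)

setMethod("show", "AsymptoticFit", function(object) {
  if (!object@converged) {
    cat("asymptotic fit did not converge\n")
    return(invisible(NULL))
  }
  cat(sprintf("asymptotic alpha fit (%s, %d bins)\n", object@model,
              object@nPoints))
  if (object@model == "exponential")
    cat(sprintf("  a = %.4f, b = %.4f, c = %.4f\n", object@a, object@b,
                object@c))
  else
    cat(sprintf("  intercept = %.4f, slope = %.4f\n", object@a, object@b))
  cat(sprintf("  alpha(1) = %.4f [%.4f, %.4f]\n", object@alphaInf,
              object@ciLow, object@ciHigh))
  invisible(NULL)
})

setMethod("show", "AlphaFunction", function(object) {
  cat(sprintf("alpha(x) over %d bins (%s), %d usable; D_N = %g, D_S = %g\n",
              length(object@x),
              if (object@cumulative) "cumulative" else "per-bin",
              sum(object@usable), object@dN, object@dS))
})

#' Plot a per-frequency alpha function and optional fit
#'
#' @param x an [AlphaFunction-class] object.
#' @param fit optional [AsymptoticFit-class] to overlay.
#' @param ... passed to [plot()].
#' @return Invisibly, \code{NULL}.
#' @export
plotAlphaFunction <- function(x, fit = NULL, ...) {
  plot(x@x[x@usable], x@alphaX[x@usable], xlab = "derived allele frequency",
       ylab = expression(alpha(x)), pch = 19, ...)
  if (!is.null(fit) && fit@converged) {
    xx <- seq(min(x@x), 1, length.out = 200)
    yy <- if (fit@model == "exponential")
      fit@a + fit@b * exp(-fit@c * xx) else fit@a + fit@b * xx
    graphics::lines(xx, yy, col = "firebrick")
    graphics::abline(h = fit@alphaInf, lty = 2, col = "grey40")
  }
  invisible(NULL)
}
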