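#' Two-sided Fisher exact test for an MKT contingency table
#'
#' Two-sided Fisher exact P-value for a 2x2 table (sum of the
#' probabilities of all tables with the same margins that are no more
#' probable than the observed one), computed by [stats::fisher.test()].
#' A table with an empty row or column carries no information about
#' association: the P-value is 1 and the result is flagged.
#'
#' @param tab 2x2 matrix of integer-valued counts (polymorphism column
#'   first, nonsynonymous row first), or a numeric vector
#'   \code{c(pn, ps, dn, ds)}.
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"}.
#' @return A list with elements \code{p} and \code{degenerate} (TRUE when
#'   a margin was zero).
#' @examples
#' mktFisher(c(11, 17, 15, 8))$p  # 0.093
#' @export
mktFisher <- function(tab, alternative = "two.sided") {
  if (!is.matrix(tab)) {
    if (length(tab) != 4L) stop("expected a 2x2 table")
    tab <- matrix(tab, 2L, 2L)
  }
  if (any(tab < 0) || anyNA(tab)) stop("table cells must be non-negative")
  if (any(abs(tab - round(tab)) > 1e-8))
    stop("table cells must be integers; round imputed quantities first")
  tab <- round(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p = 1, degenerate = TRUE))
  list(p = stats::fisher.test(tab, alternative = alternative)$p.value,
       degenerate = FALSE)
}

# round half away from zero (4.5 -> 5, -4.5 -> -5); contingency cells only
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# assemble an MKTResult; pn/dn cells may arrive unrounded
newMKTResult <- function(method, cutoff, pnCell, psCell, dnCell, dsCell,
                         alpha, pwd = NA_real_, pwdUnclamped = NA_real_,
                         pneut = NA_real_, fNeutral = NA_real_,
                         excludedFraction = NA_real_, clamped = FALSE,
                         alternative = "two.sided") {
  tab <- matrix(roundHalfAway(c(pnCell, psCell, dnCell, dsCell)), 2L, 2L,
                dimnames = list(c("nonsynonymous", "synonymous"),
                                c("polymorphism", "divergence")))
  ft <- mktFisher(tab, alternative = alternative)
  new("MKTResult", method = method, cutoff = cutoff, table = tab,
      alpha = alpha, pValue = ft$p, pwd = pwd,
      pwdUnclamped = pwdUnclamped, pneut = pneut, fNeutral = fNeutral,
      excludedFraction = excludedFraction, analyzable = TRUE,
      clamped = clamped,
      note = if (ft$degenerate) "degenerate table (empty margin)" else "")
}

# a non-analyzable placeholder result
naMKTResult <- function(method, cutoff, reason) {
  new("MKTResult", method = method, cutoff = cutoff,
      table = matrix(NA_real_, 2L, 2L,
                     dimnames = list(c("nonsynonymous", "synonymous"),
                                     c("polymorphism", "divergence"))),
      alpha = NA_real_, pValue = NA_real_, pwd = NA_real_,
      pwdUnclamped = NA_real_, pneut = NA_real_, fNeutral = NA_real_,
      excludedFraction = NA_real_, analyzable = FALSE, clamped = FALSE,
      note = reason)
}
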