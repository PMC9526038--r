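#' @rdname sfsTotal
#' @export
setGeneric("sfsTotal", function(x) standardGeneric("sfsTotal"))

#' @rdname foldSFS
#' @export
setGeneric("foldSFS", function(x) standardGeneric("foldSFS"))

#' @rdname projectSFS
#' @export
setGeneric("projectSFS",
  function(x, m, rounding = c("none", "stochastic"), seed = NULL)
    standardGeneric("projectSFS"))

#' @rdname bandCounts
#' @export
setGeneric("bandCounts", function(x, cutoff) standardGeneric("bandCounts"))

#' @rdname accessors
#' @export
setGeneric("sampleSize", function(x) standardGeneric("sampleSize"))

#' @rdname accessors
#' @export
setGeneric("isFolded", function(x) standardGeneric("isFolded"))

#' @rdname accessors
#' @export
setGeneric("sfsCounts", function(x) standardGeneric("sfsCounts"))

#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname accessors
#' @export
setGeneric("sfsN", function(x) standardGeneric("sfsN"))

#' @rdname accessors
#' @export
setGeneric("sfsS", function(x) standardGeneric("sfsS"))

#' @rdname accessors
#' @export
setGeneric("pN", function(x) standardGeneric("pN"))

#' @rdname accessors
#' @export
setGeneric("pS", function(x) standardGeneric("pS"))

#' @rdname accessors
#' @export
setGeneric("dN", function(x) standardGeneric("dN"))

#' @rdname accessors
#' @export
setGeneric("dS", function(x) standardGeneric("dS"))

#' @rdname accessors
#' @export
setGeneric("mN", function(x) standardGeneric("mN"))

#' @rdname accessors
#' @export
setGeneric("mS", function(x) standardGeneric("mS"))

#' @rdname result-accessors
#' @export
setGeneric("alphaEstimate", function(x) standardGeneric("alphaEstimate"))

#' @rdname result-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname result-accessors
#' @export
setGeneric("contingencyTable",
  function(x) standardGeneric("contingencyTable"))

#' @rdname result-accessors
#' @export
setGeneric("pwdEstimate", function(x) standardGeneric("pwdEstimate"))

#' @rdname result-accessors
#' @export
setGeneric("isAnalyzable", function(x) standardGeneric("isAnalyzable"))

#' @rdname result-accessors
#' @export
setGeneric("excludedFraction",
  function(x) standardGeneric("excludedFraction"))

#' @rdname fitAsymptotic
#' @export
setGeneric("alphaInf", function(x) standardGeneric("alphaInf"))

#' @rdname expectedPwdBelowCutoff
#' @export
setGeneric("expectedPwdBelowCutoff",
  function(truth, cutoff) standardGeneric("expectedPwdBelowCutoff"))

#' @rdname accessors
#' @export
setGeneric("realizedAlpha", function(x) standardGeneric("realizedAlpha"))
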