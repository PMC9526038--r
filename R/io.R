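#' Read a gene table
#'
#' Reads the tab-separated gene-table format: one row per gene with header
#' \code{gene_id n folded sfs_n sfs_s dn ds mn ms}, where \code{sfs_n} and
#' \code{sfs_s} are comma-separated per-class counts of length \code{n - 1}
#' (unfolded) or \code{floor(n / 2)} (folded). Malformed rows are reported
#' with their line numbers.
#'
#' @param path file path.
#' @return A list of [GeneVariation-class] records (empty, with a warning,
#'   for an empty file).
#' @seealso [writeGeneTable()], [readDafDiv()]
#' @export
readGeneTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("gene_id", "n", "folded", "sfs_n", "sfs_s",
                "dn", "ds", "mn", "ms")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("gene table is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(tab) == 0L) {
    warning("empty gene table: ", path)
    return(list())
  }
  out <- vector("list", nrow(tab))
  for (k in seq_len(nrow(tab))) {
    line <- k + 1L  # header is line 1
    row <- tab[k, ]
    parsed <- tryCatch({
      n <- as.integer(row$n)
      folded <- as.logical(row$folded)
      cn <- parseCounts(row$sfs_n, "sfs_n")
      cs <- parseCounts(row$sfs_s, "sfs_s")
      num <- function(col) {
        v <- suppressWarnings(as.numeric(row[[col]]))
        if (is.na(v)) stop("column '", col, "' is not numeric")
        if (v < 0) stop("column '", col, "' is negative")
        v
      }
      GeneVariation(row$gene_id,
                    SFS(cn, sampleSize = n, folded = folded),
                    SFS(cs, sampleSize = n, folded = folded),
                    dN = num("dn"), dS = num("ds"),
                    mN = num("mn"), mS = num("ms"))
    }, error = function(e) {
      stop(sprintf("malformed gene table row at line %d (gene '%s'): %s",
                   line, row$gene_id, conditionMessage(e)), call. = FALSE)
    })
    out[[k]] <- parsed
  }
  out
}

parseCounts <- function(field, what) {
  v <- suppressWarnings(as.numeric(strsplit(field, ",", fixed = TRUE)[[1]]))
  if (length(v) == 0L || anyNA(v))
    stop("column '", what, "' does not parse as comma-separated counts")
  if (any(v < 0)) stop("column '", what, "' contains negative counts")
  v
}

#' Write a gene table
#'
#' Writes records in the format read by [readGeneTable()]; integer counts
#' round-trip bit-exactly.
#'
#' @param records list of [GeneVariation-class] objects (or a single one).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGeneTable <- function(records, path) {
  records <- asRecordList(records)
  rows <- vapply(records, function(g) {
    paste(g@geneId, g@sfsN@sampleSize, g@sfsN@folded,
          paste(formatCount(g@sfsN@counts), collapse = ","),
          paste(formatCount(g@sfsS@counts), collapse = ","),
          formatCount(g@dN), formatCount(g@dS),
          formatCount(g@mN), formatCount(g@mS), sep = "\t")
  }, character(1))
  writeLines(c(paste(c("gene_id", "n", "folded", "sfs_n", "sfs_s",
                       "dn", "ds", "mn", "ms"), collapse = "\t"), rows),
             path)
  invisible(path)
}

formatCount <- function(x) {
  ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
         format(signif(x, 6), scientific = FALSE, trim = TRUE))
}

#' Read the two-file DAF/DIV dialect
#'
#' Reads the web-server style pair of files: a DAF file with header
#' \code{daf Pi P0} giving, per derived-allele-frequency bin, the bin
#' frequency and the nonsynonymous (\code{Pi}) and synonymous (\code{P0})
#' counts; and a DIV file with header \code{mi Di m0 D0} giving
#' nonsynonymous sites and fixed differences and their synonymous
#' counterparts. Either file may carry a leading \code{gene_id} column for
#' several concatenated genes; without it, a single gene named
#' \code{"gene"} is returned. The sample size is inferred from the number
#' of frequency bins per gene (\code{n = bins + 1}); bin frequencies must
#' match \code{i/n}.
#'
#' @param dafPath,divPath file paths.
#' @return A list of [GeneVariation-class] records.
#' @seealso [readGeneTable()]
#' @export
readDafDiv <- function(dafPath, divPath) {
  daf <- utils::read.delim(dafPath, stringsAsFactors = FALSE)
  div <- utils::read.delim(divPath, stringsAsFactors = FALSE)
  if (!all(c("daf", "Pi", "P0") %in% names(daf)))
    stop("DAF file must have columns daf, Pi, P0")
  if (!all(c("mi", "Di", "m0", "D0") %in% names(div)))
    stop("DIV file must have columns mi, Di, m0, D0")
  if (!"gene_id" %in% names(daf)) daf$gene_id <- "gene"
  if (!"gene_id" %in% names(div)) div$gene_id <- "gene"
  ids <- unique(daf$gene_id)
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    d <- daf[daf$gene_id == id, ]
    v <- div[div$gene_id == id, ]
    if (nrow(v) != 1L)
      stop("DIV file must have exactly one row for gene '", id, "'")
    d <- d[order(d$daf), ]
    n <- nrow(d) + 1L
    if (max(abs(d$daf - seq_len(n - 1L) / n)) > 1e-6)
      stop("DAF bins for gene '", id, "' are not the grid i/n (n = ",
           n, ")")
    if (any(d$Pi < 0) || any(d$P0 < 0))
      stop("negative counts in DAF file for gene '", id, "'")
    out[[k]] <- GeneVariation(id,
      SFS(d$Pi, sampleSize = n), SFS(d$P0, sampleSize = n),
      dN = v$Di, dS = v$D0, mN = v$mi, mS = v$m0)
  }
  out
}

#' Write the two-file DAF/DIV dialect
#'
#' @param records list of unfolded [GeneVariation-class] records.
#' @param dafPath,divPath output paths.
#' @return \code{c(dafPath, divPath)}, invisibly.
#' @export
writeDafDiv <- function(records, dafPath, divPath) {
  records <- asRecordList(records)
  dafRows <- character(0)
  divRows <- character(0)
  for (g in records) {
    if (g@sfsN@folded) stop("DAF/DIV output is defined for unfolded spectra")
    n <- g@sfsN@sampleSize
    fr <- seq_len(n - 1L) / n
    dafRows <- c(dafRows, paste(g@geneId, formatCount(signif(fr, 6)),
                                formatCount(g@sfsN@counts),
                                formatCount(g@sfsS@counts), sep = "\t"))
    divRows <- c(divRows, paste(g@geneId, formatCount(g@mN),
                                formatCount(g@dN), formatCount(g@mS),
                                formatCount(g@dS), sep = "\t"))
  }
  writeLines(c("gene_id\tdaf\tPi\tP0", dafRows), dafPath)
  writeLines(c("gene_id\tmi\tDi\tm0\tD0", divRows), divPath)
  invisible(c(dafPath, divPath))
}

#' Write a result table
#'
#' Writes a data.frame of test results as TSV with a stable column order
#' and floating-point values at 6 significant digits.
#'
#' @param results data.frame, e.g. from [runMKT()] or [bootstrapPools()].
#' @param path output file path ("" for standard output).
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(results, path) {
  out <- results
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# normalize single record / list input
asRecordList <- function(records) {
  if (is(records, "GeneVariation")) return(list(records))
  if (!is.list(records) || !all(vapply(records, is, logical(1),
                                       "GeneVariation")))
    stop("expected a GeneVariation or a list of GeneVariation objects")
  records
}
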