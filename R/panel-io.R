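# Delimited-table input/output. Tables are probes-in-rows,
# samples-in-columns, matching exported minfi-style intensity matrices.
# "NA" is the sole missing token on output; "NA", "NaN" and empty cells are
# accepted on input. Invalid cells are masked on read, not fatal: the
# screening pipeline excludes such entries from every denominator.

.sepFor <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.readMatrixFile <- function(path, role) {
  if (!file.exists(path))
    stop(sprintf("file for role '%s' not found: %s", role, path))
  df <- utils::read.delim(path, sep = .sepFor(path), header = TRUE,
                          row.names = 1, check.names = FALSE,
                          colClasses = "character", comment.char = "#",
                          na.strings = c("NA", "NaN", ""))
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(df)), nrow(df), ncol(df),
           dimnames = list(rownames(df), colnames(df))))
  m
}

#' Read a paired BS/oxBS intensity panel from four delimited tables
#'
#' Each file is a TSV or CSV (auto-detected from the extension) with a
#' header row of sample ids and the probe id in the first column. The four
#' tables must agree exactly in probe and sample ids (order included);
#' a mismatch is a fatal error naming the offending roles. Negative or
#' non-numeric cells are masked (with a warning giving counts), never
#' silently dropped: the output always has one row per input probe.
#'
#' @param paths named character vector or list with entries \code{M_bs},
#'   \code{U_bs}, \code{M_oxbs}, \code{U_oxbs} giving the file paths.
#' @param tissue tissue label for the panel.
#' @return an \linkS4class{HmcPanel}.
#' @export
readPanel <- function(paths, tissue = c("unspecified", "healthy", "cancer")) {
  tissue <- match.arg(tissue)
  roles <- c("M_bs", "U_bs", "M_oxbs", "U_oxbs")
  paths <- as.list(paths)
  if (!all(roles %in% names(paths)))
    stop("paths must name all four roles: ", paste(roles, collapse = ", "))
  mats <- lapply(roles, function(r) .readMatrixFile(paths[[r]], r))
  names(mats) <- roles
  ref <- mats[[1]]
  bad_roles <- character()
  for (r in roles[-1]) {
    if (!identical(dim(mats[[r]]), dim(ref)) ||
        !identical(rownames(mats[[r]]), rownames(ref)) ||
        !identical(colnames(mats[[r]]), colnames(ref)))
      bad_roles <- c(bad_roles, r)
  }
  if (length(bad_roles))
    stop("probe/sample ids do not align with M_bs for role(s): ",
         paste(bad_roles, collapse = ", "))
  n_nonnum <- sum(vapply(mats, function(m) sum(is.na(m)), numeric(1)))
  n_neg <- sum(vapply(mats, function(m) sum(m < 0, na.rm = TRUE), numeric(1)))
  if (n_nonnum + n_neg > 0)
    warning(sprintf("masked %d missing/non-numeric and %d negative cell(s)",
                    n_nonnum, n_neg))
  mask <- Reduce(`|`, lapply(mats, function(m) is.na(m) | m < 0))
  mask[is.na(mask)] <- TRUE
  HmcPanel(mats$M_bs, mats$U_bs, mats$M_oxbs, mats$U_oxbs,
           tissue = tissue, mask = mask)
}

#' Write a panel's four intensity matrices
#'
#' Writes \code{M_bs.tsv}, \code{U_bs.tsv}, \code{M_oxbs.tsv},
#' \code{U_oxbs.tsv} under \code{dir}; masked entries are written as
#' \code{NA}.
#'
#' @param panel an \linkS4class{HmcPanel}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writePanel <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mask <- assay(panel, "mask")
  out <- c(M_bs = NA, U_bs = NA, M_oxbs = NA, U_oxbs = NA)
  for (r in names(out)) {
    m <- assay(panel, r)
    m[mask] <- NA
    p <- file.path(dir, paste0(r, ".tsv"))
    .writeMatrix(m, p)
    out[r] <- p
  }
  invisible(out)
}

.fmtNum <- function(x) {
  out <- formatC(x, digits = 15, format = "g")
  out[is.na(x)] <- "NA"
  out
}

.writeMatrix <- function(m, path, header_lines = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  writeLines(paste(c("probe_id", colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], .fmtNum(m[i, ])), collapse = "\t"), character(1))
  writeLines(body, con)
}

#' Write a result object as a delimited text table
#'
#' Serialises result objects with a stable column order; masked or undefined
#' entries are written as \code{NA}. Numeric values are written with 15
#' significant digits and round-trip through the matching reader to at least
#' 12 significant digits; metadata (measure name, offset, threshold, axis,
#' statistic) travel in \code{#}-prefixed header lines.
#'
#' @param result a \linkS4class{MeasureMatrix}, \linkS4class{CallMatrix},
#'   \linkS4class{ConcordanceTable} or \linkS4class{PrevalenceSummary}.
#' @param path output file path (unwritable paths are fatal).
#' @return invisibly, \code{path}.
#' @seealso \code{\link{readMeasureTable}}, \code{\link{readCallTable}},
#'   \code{\link{readConcordanceTable}}
#' @export
setGeneric("writeTable", function(result, path) standardGeneric("writeTable"))

#' @rdname writeTable
#' @export
setMethod("writeTable", "MeasureMatrix", function(result, path) {
  hdr <- c(sprintf("# measure: %s", result@measure),
           if (length(result@alpha)) sprintf("# alpha: %s",
                                             .fmtNum(result@alpha)))
  v <- result@values
  v[result@mask] <- NA
  .writeMatrix(v, path, hdr)
  invisible(path)
})

#' @rdname writeTable
#' @export
setMethod("writeTable", "CallMatrix", function(result, path) {
  hdr <- c(sprintf("# measure: %s", result@measure),
           sprintf("# threshold: %s", .fmtNum(result@threshold)))
  v <- matrix(ifelse(result@calls, "TRUE", "FALSE"),
              nrow(result@calls), dimnames = dimnames(result@calls))
  v[result@mask] <- NA
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("probe_id", colnames(v)), collapse = "\t"), con)
  v[is.na(v)] <- "NA"
  body <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], v[i, ]), collapse = "\t"), character(1))
  writeLines(body, con)
  invisible(path)
})

#' @rdname writeTable
#' @export
setMethod("writeTable", "ConcordanceTable", function(result, path) {
  df <- data.frame(statistic = result@statistic,
                   measure1 = result@pair[1], measure2 = result@pair[2],
                   tissue = result@tissue, axis = result@axis,
                   unit = names(result@values),
                   value = .fmtNum(result@values),
                   degenerate = result@degenerate,
                   expectation = .fmtNum(result@expectation),
                   expectation_method = result@expectationMethod)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
})

#' @rdname writeTable
#' @export
setMethod("writeTable", "PrevalenceSummary", function(result, path) {
  df <- data.frame(measure = result@measure, axis = result@axis,
                   unit = names(result@proportions),
                   proportion = .fmtNum(result@proportions),
                   denominator = result@denominators)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
})

.readHeaderMeta <- function(path) {
  lines <- readLines(path, n = 10)
  meta <- lines[startsWith(lines, "# ")]
  kv <- strsplit(sub("^# ", "", meta), ": ", fixed = TRUE)
  out <- lapply(kv, `[`, 2)
  names(out) <- vapply(kv, `[`, character(1), 1)
  out
}

#' Read a MeasureMatrix written by writeTable
#'
#' @param path file path.
#' @return a \linkS4class{MeasureMatrix}; \code{NA} cells become masked.
#' @export
readMeasureTable <- function(path) {
  meta <- .readHeaderMeta(path)
  m <- .readMatrixFile(path, "measure")
  mask <- is.na(m)
  alpha <- if (!is.null(meta$alpha)) as.numeric(meta$alpha) else numeric(0)
  noise <- NULL
  if (identical(meta$measure, "delta_h"))
    noise <- !mask & m < 0
  .MeasureMatrix(meta$measure, m, mask, alpha = alpha, noise = noise)
}

#' Read a CallMatrix written by writeTable
#'
#' @param path file path.
#' @return a \linkS4class{CallMatrix}; \code{NA} cells become masked.
#' @export
readCallTable <- function(path) {
  meta <- .readHeaderMeta(path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "#",
                          na.strings = c("NA", "NaN", ""))
  m <- as.matrix(df) == "TRUE"
  mask <- is.na(m)
  m[mask] <- FALSE
  new("CallMatrix", measure = meta$measure,
      threshold = as.numeric(meta$threshold), calls = m, mask = mask)
}

#' Read a ConcordanceTable written by writeTable
#'
#' @param path file path.
#' @return a \linkS4class{ConcordanceTable}.
#' @export
readConcordanceTable <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE,
                          na.strings = c("NA", "NaN", ""))
  v <- as.numeric(df$value)
  names(v) <- as.character(df$unit)
  new("ConcordanceTable",
      pair = c(as.character(df$measure1[1]), as.character(df$measure2[1])),
      tissue = as.character(df$tissue[1]), axis = as.character(df$axis[1]),
      statistic = as.character(df$statistic[1]), values = v,
      expectation = as.numeric(df$expectation[1]),
      expectationMethod = as.character(df$expectation_method[1]),
      degenerate = as.logical(df$degenerate))
}
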