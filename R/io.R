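#' @title Tabular and gene-set input/output
#' @description Readers and writers for the three tabular containers the
#'   pipeline moves between -- expression matrices (genes x samples),
#'   flow-cytometry panels (samples x phenotypes) and score matrices
#'   (signatures x samples) -- plus the GMT gene-set format. All readers
#'   enforce the schema strictly: deconvolution is numerically sensitive to
#'   silent coercion, so a malformed cell is an error, never an NA.
#' @name immunomix-io
NULL

# delimiter by extension, falling back to a sniff of the first data line
.guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return(",")
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) return("\t")
  line <- readLines(path, n = 20L)
  line <- line[!startsWith(line, "#")][1]
  if (is.na(line)) stop("empty file: ", path)
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t" else ","
}

.read_table_checked <- function(path, sep, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          comment.char = "#", quote = "\"",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2)
    stop(what, ": expected a header row plus at least one data column in ", path)
  df
}

# coerce the value block to numeric, reporting the first bad cell by coordinates
.numeric_block <- function(df, path, offset = 1L) {
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals) & nzchar(trimws(vals)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("parse error in %s: non-numeric value '%s' at row %d, column %d",
                 path, vals[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2] + offset))
  if (anyNA(num))
    stop("missing values are not permitted in ", path,
         " (impute or filter upstream)")
  dimnames(num) <- list(df[[1]], colnames(df)[-1])
  num
}

#' Read a gene expression matrix
#'
#' Reads a genes x samples table (TSV or CSV; first column gene symbols,
#' header row sample identifiers) into a numeric matrix on the linear
#' intensity scale. Duplicate gene symbols are collapsed, and data that look
#' log-transformed (global maximum below `log_max`) trigger a warning and,
#' by default, are returned to the linear scale as `2^x`.
#'
#' @param path file path (TSV/CSV, RFC-4180 quoting; `#` lines are comments).
#' @param collapse_rule how to collapse duplicate gene symbols:
#'   `"max-mean"` keeps the row with the largest mean (common microarray
#'   practice), `"mean"` averages the rows, `"first"` keeps the first.
#' @param anti_log if `TRUE` (default) and the matrix looks log2-scaled,
#'   exponentiate back to the linear scale.
#' @param log_max global-maximum threshold below which data are deemed
#'   log-scaled; microarray linear intensities run into the thousands while
#'   log2 values rarely exceed ~20, so the default of 50 separates them.
#' @return numeric matrix, genes in rows (unique symbols), samples in columns.
#' @export
read_expression <- function(path, collapse_rule = c("max-mean", "mean", "first"),
                            anti_log = TRUE, log_max = 50) {
  collapse_rule <- match.arg(collapse_rule)
  sep <- .guess_sep(path)
  df <- .read_table_checked(path, sep, "expression")
  hdr <- colnames(df)[-1]
  if (all(!is.na(suppressWarnings(as.numeric(hdr)))))
    stop("schema error: header row of sample ids missing in ", path)
  mat <- .numeric_block(df, path)
  if (any(mat < 0))
    stop("expression values must be non-negative (linear scale); found ",
         min(mat), " in ", path)
  mat <- collapse_duplicates(mat, collapse_rule)
  if (max(mat) < log_max) {
    warning("expression maximum is ", signif(max(mat), 4), " (< ", log_max,
            "): data appear log2-scaled",
            if (anti_log) "; anti-logging with base 2" else "")
    if (anti_log) mat <- 2^mat
  }
  mat
}

#' Collapse duplicate gene rows
#'
#' @param mat numeric matrix with gene symbols as rownames.
#' @param rule `"max-mean"`, `"mean"` or `"first"` (see [read_expression()]).
#' @return matrix with unique rownames, in first-appearance order.
#' @export
collapse_duplicates <- function(mat, rule = c("max-mean", "mean", "first")) {
  rule <- match.arg(rule)
  genes <- rownames(mat)
  if (!anyDuplicated(genes)) return(mat)
  keep_order <- unique(genes)
  rows <- switch(rule,
    "max-mean" = vapply(keep_order, function(g) {
      idx <- which(genes == g)
      mat[idx[which.max(rowMeans(mat[idx, , drop = FALSE]))], ]
    }, numeric(ncol(mat))),
    "mean" = vapply(keep_order, function(g) {
      colMeans(mat[genes == g, , drop = FALSE])
    }, numeric(ncol(mat))),
    "first" = vapply(keep_order, function(g) {
      mat[which(genes == g)[1], ]
    }, numeric(ncol(mat))))
  out <- t(rows)
  dimnames(out) <- list(keep_order, colnames(mat))
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene symbols; descriptions are
#'   kept in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[`, character(1), 1L)
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0)
    stop("duplicate gene-set name(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  empty <- lengths(sets) == 0
  if (any(empty))
    stop("gene set(s) with zero genes in ", path, ": ",
         paste(nm[empty], collapse = ", "))
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1)), nm)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flow-cytometry percentage panel
#'
#' Samples x phenotypes CSV/TSV of percent-of-parent values; every value must
#' lie in \[0, 100\].
#'
#' @param path file path.
#' @return numeric matrix, samples in rows, phenotypes in columns.
#' @export
read_flow <- function(path) {
  sep <- .guess_sep(path)
  df <- .read_table_checked(path, sep, "flow panel")
  phen <- colnames(df)[-1]
  dup <- phen[duplicated(phen)]
  if (length(dup) > 0)
    stop("duplicate flow phenotype name(s): ", paste(unique(dup), collapse = ", "))
  mat <- .numeric_block(df, path)
  if (any(mat < 0 | mat > 100))
    stop(sprintf("range error in %s: flow percentages must be in [0, 100], found %s",
                 path, format(mat[which.max(abs(mat - 50))])))
  mat
}

#' Read a deconvolution score matrix
#'
#' @param path file path written by [write_scores()] (signatures x samples).
#' @return numeric matrix with a `"method_tag"` attribute (`"svr"`,
#'   `"ssgsea"` or `NA` if the header comment is absent).
#' @export
read_scores <- function(path) {
  sep <- .guess_sep(path)
  hdr <- readLines(path, n = 5L)
  tag <- regmatches(hdr, regexpr("method=[a-z]+", hdr))
  df <- .read_table_checked(path, sep, "score matrix")
  mat <- .numeric_block(df, path)
  attr(mat, "method_tag") <-
    if (length(tag) > 0) sub("method=", "", tag[1]) else NA_character_
  mat
}

.version_header <- function(extra = "") {
  ver <- tryCatch(as.character(utils::packageVersion("immunomix")),
                  error = function(e) "dev")
  paste0("# immunomix ", ver, if (nzchar(extra)) paste0("; ", extra))
}

#' Write a score matrix (or any named numeric matrix) as TSV
#'
#' The file starts with a comment line carrying the package version and the
#' method tag, so scores round-trip through [read_scores()] with provenance.
#'
#' @param mat numeric matrix, signatures/cell types in rows.
#' @param path output path.
#' @param method_tag `"svr"`, `"ssgsea"`, or `NULL` to omit.
#' @param id_col name for the first (rowname) column.
#' @export
write_scores <- function(mat, path, method_tag = attr(mat, "method_tag"),
                         id_col = "signature_id") {
  extra <- if (!is.null(method_tag) && !is.na(method_tag))
    paste0("method=", method_tag) else ""
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.version_header(extra), con)
  df <- data.frame(rownames(mat), format(mat, digits = 15, trim = TRUE,
                                         scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(mat))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' @param mat genes x samples numeric matrix.
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  write_scores(mat, path, method_tag = NULL, id_col = "gene")
}

#' Write a flow panel as CSV
#'
#' @param panel samples x phenotypes matrix of percentages.
#' @param path output path.
#' @export
write_flow <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.version_header(), con)
  df <- data.frame(sample_id = rownames(panel),
                   format(panel, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
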