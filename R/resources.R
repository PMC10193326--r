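#' @title Reference assets: cell-type inventories, exclusion list, mappings
#' @description The scoring side of the pipeline works against fixed
#'   reference assets: the 22-type LM22-layout inventory used by the
#'   SVR method, the 64-type inventory used by the ssGSEA method together
#'   with the 20-name non-blood exclusion list applied before whole-blood
#'   scoring, and the signature-to-flow-phenotype mapping tables that anchor
#'   validation. Inventories and mappings ship as plain-text fixtures under
#'   `inst/extdata`; the LM22 matrix itself is a third-party asset and is
#'   loaded from a user-supplied file (see [validate_signature_matrix()]),
#'   while tests use synthetic signature matrices from
#'   [make_signature_matrix()].
#' @name immunomix-resources
NULL

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "immunomix")
  if (!nzchar(path)) stop("bundled fixture not found: ", file)
  path
}

.read_name_list <- function(file) {
  x <- readLines(.extdata(file))
  x[nzchar(trimws(x)) & !startsWith(x, "#")]
}

#' Cell-type inventories
#'
#' `xcell_cell_types()` returns the 64-type inventory of the ssGSEA method
#' (dot-normalized names); `cibersort_cell_types()` the 22 LM22 cell types;
#' `blood_exclusion_list()` the 20 non-blood cell types (chondrocytes,
#' osteoblasts, fibroblasts, ...) removed before scoring whole blood.
#'
#' @return character vector of cell-type names.
#' @export
xcell_cell_types <- function() .read_name_list("xcell_cell_types.txt")

#' @rdname xcell_cell_types
#' @export
cibersort_cell_types <- function() .read_name_list("cibersort_cell_types.txt")

#' @rdname xcell_cell_types
#' @export
blood_exclusion_list <- function() .read_name_list("xcell_blood_exclusion.txt")

#' Remove excluded cell types from a signature collection
#'
#' Drops the named cell types from a gene-signature collection (or from a
#' plain inventory of cell-type names). Applied to the full 64-type
#' inventory with the bundled 20-name non-blood list this retains the 44
#' cell types scored in whole blood.
#'
#' @param signatures either a named list (cell type -> list of gene sets)
#'   or a character vector of cell-type names.
#' @param exclusion character vector of cell-type names to remove; defaults
#'   to [blood_exclusion_list()].
#' @param strict if `TRUE` (default), an exclusion name absent from
#'   `signatures` is an error; if `FALSE`, a warning.
#' @return object of the same shape as `signatures`, minus the exclusions.
#' @export
apply_exclusion <- function(signatures, exclusion = blood_exclusion_list(),
                            strict = TRUE) {
  nm <- if (is.character(signatures)) signatures else names(signatures)
  if (is.null(nm)) stop("signature collection must be named")
  missing <- setdiff(exclusion, nm)
  if (length(missing) > 0) {
    msg <- paste0("exclusion name(s) not present in the collection: ",
                  paste(missing, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  keep <- !(nm %in% exclusion)
  if (is.character(signatures)) signatures[keep] else signatures[keep]
}

.mapping_files <- c(
  gse93777_cibersort = "mapping_gse93777_cibersort.tsv",
  gse93777_xcell     = "mapping_gse93777_xcell.tsv",
  clarity            = "mapping_clarity_reconstructed.tsv")

.mapping_rows <- c(gse93777_cibersort = 14L, gse93777_xcell = 25L,
                   clarity = 26L)

#' Load a bundled signature/flow mapping table
#'
#' Three mappings ship with the package: the 14-pair and 25-pair tables used
#' for the GSE93777-style validation of the SVR and ssGSEA methods, and a
#' 26-pair (9 SVR + 17 ssGSEA) reconstruction of the trial-cohort mapping in
#' which each of nine flow phenotypes is mapped to all related signatures.
#' Loading verifies the expected shape, so a corrupted fixture fails loudly.
#'
#' @param which `"gse93777_cibersort"`, `"gse93777_xcell"` or `"clarity"`.
#' @return data.frame with columns `signature_id`, `flow_phenotype`.
#' @export
load_mapping <- function(which = c("gse93777_cibersort", "gse93777_xcell",
                                   "clarity")) {
  which <- match.arg(which)
  df <- utils::read.table(.extdata(.mapping_files[[which]]), sep = "\t",
                          header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!identical(colnames(df), c("signature_id", "flow_phenotype")) ||
      nrow(df) != .mapping_rows[[which]])
    stop("mapping fixture '", which, "' is corrupted: expected ",
         .mapping_rows[[which]], " (signature_id, flow_phenotype) rows")
  if (anyDuplicated(df))
    stop("mapping fixture '", which, "' contains duplicate pairs")
  df
}

#' Load a bundled published correlation table
#'
#' The pairwise validation tables for the GSE93777 cohort as printed
#' (Spearman r, p, FDR and the published assessment label) for the 14
#' SVR-method pairs and the 25 ssGSEA-method pairs. These are inputs for the
#' classification stage: feeding the printed `(r, FDR)` values through
#' [classify_correlation()] reproduces the published category counts.
#'
#' @param which `"gse93777_cibersort"` or `"gse93777_xcell"`.
#' @return data.frame with columns `signature_id`, `flow_phenotype`, `r`
#'   (numeric), `p` (character, as printed -- may be `"<0.001"`), `fdr`
#'   (numeric), `assessment` (character, as printed).
#' @export
load_correlation_table <- function(which = c("gse93777_cibersort",
                                             "gse93777_xcell")) {
  which <- match.arg(which)
  file <- sub("^mapping_", "",
              sub("\\.tsv$", "_correlations.tsv", .mapping_files[[which]]))
  df <- utils::read.table(.extdata(file), sep = "\t", header = TRUE,
                          comment.char = "#", colClasses = "character",
                          stringsAsFactors = FALSE)
  df$r <- as.numeric(df$r)
  df$fdr <- as.numeric(df$fdr)
  expected <- .mapping_rows[[which]]
  if (nrow(df) != expected || anyNA(df$r) || anyNA(df$fdr))
    stop("correlation table fixture '", which, "' is corrupted")
  df
}

#' Validate a signature matrix
#'
#' Checks the structural invariants a reference matrix must satisfy before
#' deconvolution: unique genes, at least two cell types, non-negative
#' values, and no constant column (a zero-variance profile cannot be
#' distinguished from the intercept). Also reports the condition number of
#' the column space as a collinearity diagnostic.
#'
#' @param B numeric matrix, genes x cell types, with dimnames.
#' @return list with `n_genes`, `n_cell_types`, `condition_number`,
#'   `constant_columns` (character vector, possibly empty) and `ok`.
#' @export
validate_signature_matrix <- function(B) {
  if (is.null(rownames(B)) || is.null(colnames(B)))
    stop("signature matrix must carry gene rownames and cell-type colnames")
  dup <- rownames(B)[duplicated(rownames(B))]
  if (length(dup) > 0)
    stop("duplicate gene(s) in signature matrix: ",
         paste(unique(dup), collapse = ", "))
  if (ncol(B) < 2) stop("signature matrix needs at least 2 cell types")
  if (any(B < 0)) stop("signature matrix values must be non-negative")
  sds <- apply(B, 2, stats::sd)
  constant <- colnames(B)[sds == 0]
  if (length(constant) > 0)
    warning("constant (zero-variance) column(s): ",
            paste(constant, collapse = ", "))
  list(n_genes = nrow(B), n_cell_types = ncol(B),
       condition_number = kappa(B, exact = FALSE),
       constant_columns = constant,
       ok = length(constant) == 0)
}

#' Read a signature matrix from TSV/CSV
#'
#' LM22 layout: first column gene symbols, one column per cell type.
#'
#' @param path file path.
#' @param prefix optional method prefix (e.g. `"cibersort"`) prepended to
#'   column names as `prefix.CellType`.
#' @return genes x cell-types numeric matrix, validated.
#' @export
read_signature_matrix <- function(path, prefix = NULL) {
  sep <- .guess_sep(path)
  df <- .read_table_checked(path, sep, "signature matrix")
  B <- .numeric_block(df, path)
  if (!is.null(prefix)) colnames(B) <- paste(prefix, colnames(B), sep = ".")
  validate_signature_matrix(B)
  B
}
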