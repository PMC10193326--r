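#' @title Flow-cytometry concordance validation
#' @description Deconvolution output is validated against matched
#'   flow-cytometry percentages: for every mapped (signature, phenotype)
#'   pair a Spearman rank correlation is computed across shared samples,
#'   p-values are adjusted across the tested family (BH false discovery
#'   rate or Bonferroni), and each pair is assessed on a four-level scale
#'   -- strong (r > 0.5), moderate (0.3 < r <= 0.5), weak (r <= 0.3 with
#'   FDR < 0.1) or none (FDR > 0.1, or any non-positive r).
#' @name immunomix-validation
NULL

#' Spearman correlation for one matched pair
#'
#' Tie-corrected (average-rank) Spearman correlation with a two-sided
#' p-value from the t approximation `t = r * sqrt((n-2)/(1-r^2))` on
#' `n - 2` degrees of freedom. For small samples without need of speed an
#' exact permutation p-value (full enumeration) is available for `n <= 7`.
#' A constant vector leaves r undefined: the pair is returned with `r = NA`
#' and `flag = "constant input"` rather than an error, so one degenerate
#' signature does not abort a validation run.
#'
#' @param x,y matched numeric vectors (already joined by sample).
#' @param exact use exact permutation p (only honoured for n <= 7).
#' @return list with `r`, `p`, `n`, `flag` (`NA` or a reason string).
#' @export
spearman_pair <- function(x, y, exact = FALSE) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4)
    return(list(r = NA_real_, p = NA_real_, n = n, flag = "fewer than 4 samples"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, flag = "constant input"))
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  if (exact && n <= 7) {
    perms <- .permutations(n)
    r_null <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(r_null) >= abs(r) - 1e-12)
  } else {
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(r = r, p = p, n = n, flag = NA_character_)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Adjust p-values for multiple testing
#'
#' BH step-up (with the usual monotonicity enforcement, capped at 1) or
#' Bonferroni `min(1, m * p)`.
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` passed through).
#' @param method `"bh"` or `"bonferroni"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)   # NA entries (untestable pairs) stay out of the family
  out[ok] <- stats::p.adjust(p[ok],
                             method = c(bh = "BH",
                                        bonferroni = "bonferroni")[method])
  out
}

#' Assess a correlation by the four-level rule
#'
#' Applies, in order: non-positive r -> `"none"` (negative correlations are
#' never counted as validation, whatever their significance); adjusted
#' p > 0.1 -> `"none"`; r > 0.5 -> `"strong"`; r > 0.3 -> `"moderate"`;
#' otherwise `"weak"`. The published rule leaves the boundary values
#' unassigned ("0.3 < r < 0.5" vs "r > 0.5"); the strict inequalities are
#' kept, so r = 0.5 is moderate and r = 0.3 is weak. `NA` in either input
#' yields `NA`.
#'
#' @param r Spearman correlation(s) in \[-1, 1\].
#' @param fdr adjusted p-value(s) in \[0, 1\].
#' @return character vector: `"strong"`, `"moderate"`, `"weak"` or `"none"`.
#' @export
classify_correlation <- function(r, fdr) {
  if (length(fdr) == 1) fdr <- rep(fdr, length(r))
  stopifnot(length(r) == length(fdr))
  if (any(r < -1 | r > 1, na.rm = TRUE)) stop("r must lie in [-1, 1]")
  if (any(fdr < 0 | fdr > 1, na.rm = TRUE)) stop("fdr must lie in [0, 1]")
  ifelse(is.na(r) | is.na(fdr), NA_character_,
    ifelse(r <= 0, "none",
      ifelse(fdr > 0.1, "none",
        ifelse(r > 0.5, "strong",
          ifelse(r > 0.3, "moderate", "weak")))))
}

#' Tabulate assessment categories
#'
#' @param category character vector from [classify_correlation()].
#' @return named integer vector over `strong`, `moderate`, `weak`, `none`
#'   plus `untested` (`NA` entries).
#' @export
summarize_categories <- function(category) {
  levels <- c("strong", "moderate", "weak", "none")
  counts <- vapply(levels, function(l) sum(category == l, na.rm = TRUE),
                   integer(1))
  c(counts, untested = sum(is.na(category)))
}

#' Validate a score matrix against a flow panel
#'
#' Joins scores and flow percentages by sample id, computes the Spearman
#' correlation for every mapped (signature, phenotype) pair, adjusts
#' p-values across exactly the tested pairs, and assesses each pair with
#' [classify_correlation()]. Pairs whose signature or phenotype is missing
#' from the inputs are reported in the result (category `NA`, with a flag),
#' never silently dropped.
#'
#' @param scores signatures x samples score matrix.
#' @param flow samples x phenotypes percentage matrix.
#' @param mapping data.frame with columns `signature_id`, `flow_phenotype`
#'   (see [load_mapping()]).
#' @param method `"bh"` (FDR; the GSE93777-style default) or
#'   `"bonferroni"` (the trial-cohort default).
#' @param exact passed to [spearman_pair()].
#' @return list with `results` (one row per mapped pair: `signature_id`,
#'   `flow_phenotype`, `n`, `r`, `p`, `adjusted`, `category`, `flag`) and
#'   `summary` (category counts, `total` tested, `untested`,
#'   `n_samples_matched`).
#' @export
validate_scores <- function(scores, flow, mapping,
                            method = c("bh", "bonferroni"), exact = FALSE) {
  method <- match.arg(method)
  stopifnot(all(c("signature_id", "flow_phenotype") %in% colnames(mapping)))
  ids <- intersect(colnames(scores), rownames(flow))
  if (length(ids) < 4)
    stop("fewer than 4 samples shared between scores and flow panel")
  res <- mapping[, c("signature_id", "flow_phenotype")]
  res$n <- NA_integer_; res$r <- NA_real_; res$p <- NA_real_
  res$flag <- NA_character_
  for (i in seq_len(nrow(res))) {
    sig <- res$signature_id[i]; phen <- res$flow_phenotype[i]
    if (!sig %in% rownames(scores)) {
      res$flag[i] <- "signature not in score matrix"; next
    }
    if (!phen %in% colnames(flow)) {
      res$flag[i] <- "phenotype not in flow panel"; next
    }
    sp <- spearman_pair(scores[sig, ids], flow[ids, phen], exact = exact)
    res$n[i] <- sp$n; res$r[i] <- sp$r; res$p[i] <- sp$p
    res$flag[i] <- sp$flag
  }
  tested <- !is.na(res$p)
  res$adjusted <- NA_real_
  res$adjusted[tested] <- adjust(res$p[tested], method)
  res$category <- classify_correlation(res$r, res$adjusted)
  summary <- as.list(summarize_categories(res$category))
  summary$total <- sum(tested)
  summary$n_samples_matched <- length(ids)
  list(results = res, summary = summary)
}

#' Write a static validation report
#'
#' Plain-markdown replacement for an interactive viewer: the per-pair table
#' and the category summary, plus provenance (package version, adjustment
#' method).
#'
#' @param validation list returned by [validate_scores()].
#' @param path output path (markdown).
#' @param title report heading.
#' @export
write_validation_report <- function(validation, path,
                                    title = "Deconvolution vs flow cytometry") {
  res <- validation$results
  s <- validation$summary
  fmt <- function(x, d = 3) ifelse(is.na(x), "--", formatC(x, digits = d, format = "f"))
  lines <- c(
    paste("#", title), "",
    .version_header(), "",
    sprintf("Tested pairs: %d (samples matched: %d); untested: %d",
            s$total, s$n_samples_matched, s$untested), "",
    sprintf("Summary: strong %d / moderate %d / weak %d / none %d",
            s$strong, s$moderate, s$weak, s$none), "",
    "| signature | phenotype | n | r | p | adjusted | category |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s | %s | %s | %s |",
            res$signature_id, res$flow_phenotype,
            ifelse(is.na(res$n), "--", res$n),
            fmt(res$r), fmt(res$p, 4), fmt(res$adjusted, 4),
            ifelse(is.na(res$category), paste0("untested (", res$flag, ")"),
                   res$category)))
  writeLines(lines, path)
  invisible(path)
}
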