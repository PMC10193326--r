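#' @title Per-cell-type treatment-effect testing
#' @description The cohort stage: deconvolution scores for a three-arm
#'   trial (placebo / low dose / high dose) are screened for zero
#'   inflation, then each retained signature is tested for a treatment
#'   effect with a multivariate linear model (`score ~ treatment + age +
#'   gender`) alongside a treatment-only model. P-values are adjusted
#'   across signatures within each contrast and p-type family, and a
#'   signature is called significant only when both the adjusted treatment
#'   coefficient p and the adjusted overall F-test p fall below 0.1 -- the
#'   dual rule that screens out apparent effects explained by age or
#'   gender.
#' @name immunomix-treatment
NULL

#' Filter zero-inflated signatures
#'
#' Deconvolution fractions of rare cell types can be estimated at exactly
#' zero in almost every sample; such signatures carry no usable variation
#' and are removed before modelling. A signature is dropped when its
#' fraction of zero values exceeds `threshold` (strictly greater, so 198
#' zeros out of 200 at the 0.99 default is retained and 199 is dropped).
#'
#' @param scores signatures x samples matrix.
#' @param threshold zero-fraction cutoff; default 0.99.
#' @return list with `retained` (sub-matrix) and `dropped` (names).
#' @export
zero_filter <- function(scores, threshold = 0.99) {
  zero_frac <- rowMeans(scores == 0)
  drop <- zero_frac > threshold
  list(retained = scores[!drop, , drop = FALSE],
       dropped = rownames(scores)[drop])
}

.contrasts <- c("low_vs_placebo", "high_vs_placebo", "combined_vs_placebo")

.contrast_subset <- function(cohort, contrast) {
  arm <- as.character(cohort$arm)
  keep <- switch(contrast,
    low_vs_placebo      = arm %in% c("placebo", "low_dose"),
    high_vs_placebo     = arm %in% c("placebo", "high_dose"),
    combined_vs_placebo = arm %in% c("placebo", "low_dose", "high_dose"),
    stop("unknown contrast: ", contrast))
  d <- cohort[keep, , drop = FALSE]
  d$treated <- factor(ifelse(d$arm == "placebo", "placebo", "treated"),
                      levels = c("placebo", "treated"))
  if (any(table(d$treated) == 0))
    stop("contrast ", contrast, " has an empty arm")
  d
}

#' Fit the treatment models for one signature
#'
#' Fits `score ~ treated + age + gender` (gender coded with F as reference,
#' placebo as the reference arm) and the treatment-only model
#' `score ~ treated` on the samples entering `contrast`; the combined
#' contrast pools both dose arms into one treated level. Returns the
#' unadjusted quantities the cohort stage adjusts across signatures.
#'
#' @param cohort data.frame with columns `sample_id`, `arm` (`placebo`,
#'   `low_dose`, `high_dose`), `age`, `gender` (`F`/`M`) and one numeric
#'   column per signature.
#' @param signature_id column to model.
#' @param contrast one of `"low_vs_placebo"`, `"high_vs_placebo"`,
#'   `"combined_vs_placebo"`.
#' @return list with `beta_treatment`, `p_treatment`, `p_ftest` (overall
#'   F of the covariate model), `p_simple` (treatment p from the
#'   treatment-only model), `n`, `flag`.
#' @export
fit_cell_type <- function(cohort, signature_id, contrast) {
  stopifnot(all(c("arm", "age", "gender") %in% colnames(cohort)))
  if (!signature_id %in% colnames(cohort))
    stop("signature column not found: ", signature_id)
  if (any(cohort$age <= 0)) stop("age must be positive")
  d <- .contrast_subset(cohort, contrast)
  d$gender <- factor(as.character(d$gender), levels = c("F", "M"))
  y <- d[[signature_id]]
  if (stats::sd(y) == 0)
    return(list(beta_treatment = NA_real_, p_treatment = NA_real_,
                p_ftest = NA_real_, p_simple = NA_real_, n = nrow(d),
                flag = "constant score"))
  n_params <- 4L  # intercept + treated + age + gender
  if (nrow(d) <= n_params)
    stop("fewer samples (", nrow(d), ") than model parameters")
  fit <- stats::lm(y ~ treated + age + gender, data = d)
  sm <- summary(fit)
  fs <- sm$fstatistic
  simple <- summary(stats::lm(y ~ treated, data = d))
  list(beta_treatment = sm$coefficients["treatedtreated", "Estimate"],
       p_treatment = sm$coefficients["treatedtreated", "Pr(>|t|)"],
       p_ftest = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
       p_simple = simple$coefficients["treatedtreated", "Pr(>|t|)"],
       n = nrow(d), flag = NA_character_)
}

#' Treatment-effect analysis across all signatures
#'
#' Applies [zero_filter()] to the score columns, fits [fit_cell_type()] for
#' every retained signature and contrast, adjusts p-values across
#' signatures separately per contrast and per p-type (treatment
#' coefficient, overall F-test, treatment-only model), and flags a
#' signature significant when both `p_treatment_adj < 0.1` and
#' `p_ftest_adj < 0.1` (strictly). Signatures flagged constant are excluded
#' from the adjustment family.
#'
#' @param cohort data.frame as for [fit_cell_type()].
#' @param signatures character vector of score column names; default: all
#'   numeric columns besides `sample_id`, `arm`, `age`, `gender`.
#' @param contrasts subset of the three contrasts; default all.
#' @param adjust_method `"bh"` (default) or `"bonferroni"`.
#' @param zero_threshold passed to [zero_filter()].
#' @param alpha significance threshold on both adjusted p-values; default 0.1.
#' @return data.frame with one row per (signature, contrast):
#'   `signature_id`, `contrast`, `n`, `beta_treatment`, `p_treatment`,
#'   `p_treatment_adj`, `p_ftest`, `p_ftest_adj`, `p_simple`,
#'   `p_simple_adj`, `significant`, `flag`; dropped signature names in
#'   `attr(, "dropped")`.
#' @export
analyze_cohort <- function(cohort, signatures = NULL,
                           contrasts = .contrasts,
                           adjust_method = c("bh", "bonferroni"),
                           zero_threshold = 0.99, alpha = 0.1) {
  adjust_method <- match.arg(adjust_method)
  contrasts <- match.arg(contrasts, .contrasts, several.ok = TRUE)
  meta <- c("sample_id", "arm", "age", "gender")
  if (is.null(signatures))
    signatures <- setdiff(colnames(cohort)[vapply(cohort, is.numeric,
                                                  logical(1))],
                          meta)
  scores <- t(as.matrix(cohort[, signatures, drop = FALSE]))
  colnames(scores) <- cohort$sample_id
  zf <- zero_filter(scores, zero_threshold)
  retained <- rownames(zf$retained)
  rows <- list()
  for (ctr in contrasts) {
    fits <- lapply(retained, function(sig) fit_cell_type(cohort, sig, ctr))
    df <- data.frame(
      signature_id = retained, contrast = ctr,
      n = vapply(fits, `[[`, numeric(1), "n"),
      beta_treatment = vapply(fits, `[[`, numeric(1), "beta_treatment"),
      p_treatment = vapply(fits, `[[`, numeric(1), "p_treatment"),
      p_ftest = vapply(fits, `[[`, numeric(1), "p_ftest"),
      p_simple = vapply(fits, `[[`, numeric(1), "p_simple"),
      flag = vapply(fits, `[[`, character(1), "flag"),
      stringsAsFactors = FALSE)
    df$p_treatment_adj <- adjust(df$p_treatment, adjust_method)
    df$p_ftest_adj <- adjust(df$p_ftest, adjust_method)
    df$p_simple_adj <- adjust(df$p_simple, adjust_method)
    df$significant <- !is.na(df$p_treatment_adj) & !is.na(df$p_ftest_adj) &
      df$p_treatment_adj < alpha & df$p_ftest_adj < alpha
    rows[[ctr]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[, c("signature_id", "contrast", "n", "beta_treatment",
                 "p_treatment", "p_treatment_adj", "p_ftest", "p_ftest_adj",
                 "p_simple", "p_simple_adj", "significant", "flag")]
  attr(out, "dropped") <- zf$dropped
  out
}
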