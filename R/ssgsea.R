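#' @title Signature scoring by single-sample gene-set enrichment
#' @description Rank-based scoring of gene signatures in individual
#'   samples, aggregation of signature scores to cell types, a monotone
#'   calibration step, and spillover compensation that sharpens closely
#'   related cell types by subtracting a weighted share of their
#'   neighbours' scores (the analogue of fluorescence compensation in flow
#'   cytometry).
#' @name immunomix-ssgsea
NULL

#' Single-sample enrichment score for one gene set
#'
#' Genes are ordered by descending expression (ties broken by the stable
#' gene order of the input vector). Walking down the ranked list, each
#' signature gene contributes a hit increment proportional to
#' `rank_weight^alpha_w`, where `rank_weight = G - position + 1` (so the
#' top-ranked gene carries the largest weight) and hit increments are
#' normalized to sum to 1 over the signature; each non-signature gene
#' contributes a miss decrement of `1/(G - k)`. The score is the integral
#' of the running sum over all `G` positions, so it is maximal when the
#' signature occupies the top ranks and symmetric around 0 for random
#' placements at `alpha_w = 0`.
#'
#' @param expr named numeric expression vector for one sample.
#' @param sig character vector of signature genes.
#' @param alpha_w rank-weight exponent; default 0.25.
#' @param tie_warn_frac warn when more than this fraction of genes are
#'   involved in expression ties (ranking then leans on the tie rule);
#'   default 0.1.
#' @return scalar enrichment score.
#' @export
ssgsea_es <- function(expr, sig, alpha_w = 0.25, tie_warn_frac = 0.1) {
  if (is.null(names(expr))) stop("expression vector must carry gene names")
  G <- length(expr)
  hits_genes <- intersect(names(expr), sig)
  if (length(hits_genes) == 0)
    stop("no signature gene present in the expression universe")
  tied <- sum(duplicated(expr) | duplicated(expr, fromLast = TRUE))
  if (tied / G > tie_warn_frac)
    warning(sprintf("%.0f%% of genes have tied expression; ranking falls back ",
                    100 * tied / G),
            "to the stable input gene order")
  ord <- order(-expr)                      # stable: ties keep input order
  is_hit <- names(expr)[ord] %in% sig
  k <- sum(is_hit)
  w <- (G - seq_len(G) + 1)^alpha_w
  incr <- ifelse(is_hit, w / sum(w[is_hit]),
                 if (k < G) -1 / (G - k) else 0)
  sum(cumsum(incr))
}

#' Score cell types across an expression matrix
#'
#' Computes [ssgsea_es()] for every signature of every cell type in every
#' sample and averages the enrichment scores over each cell type's
#' signatures. Cell types whose signatures share no genes with the
#' expression universe are dropped with a warning.
#'
#' @param mix genes x samples expression matrix.
#' @param sigs named list: cell type -> list (or single character vector)
#'   of gene-signature vectors; apply [apply_exclusion()] beforehand when
#'   scoring whole blood.
#' @param alpha_w rank-weight exponent passed to [ssgsea_es()].
#' @return cell-types x samples matrix of raw (uncalibrated) scores.
#' @export
score_cell_types <- function(mix, sigs, alpha_w = 0.25) {
  if (is.null(names(sigs))) stop("signature collection must be named")
  sigs <- lapply(sigs, function(s) if (is.character(s)) list(s) else s)
  universe <- rownames(mix)
  usable <- lapply(sigs, function(sets)
    Filter(function(s) length(intersect(s, universe)) > 0, sets))
  dropped <- names(usable)[lengths(usable) == 0]
  if (length(dropped) > 0) {
    warning("cell type(s) with no usable signature dropped: ",
            paste(dropped, collapse = ", "))
    usable <- usable[lengths(usable) > 0]
  }
  out <- matrix(NA_real_, nrow = length(usable), ncol = ncol(mix),
                dimnames = list(names(usable), colnames(mix)))
  for (j in seq_len(ncol(mix))) {
    expr <- mix[, j]
    for (ct in names(usable)) {
      es <- vapply(usable[[ct]], function(s)
        ssgsea_es(expr, s, alpha_w = alpha_w), numeric(1))
      out[ct, j] <- mean(es)
    }
  }
  out
}

#' Calibrate raw enrichment scores to a non-negative linear-like scale
#'
#' Per cell type, scores are shifted so the minimum across samples is zero
#' and then passed through a monotone power law
#' `(x + shift)^exponent / scale`. The default (identity) parameters
#' perform the min-shift only; because the map is strictly monotone for
#' positive parameters, sample rankings within a cell type are preserved
#' for any parameter choice.
#'
#' @param panel cell-types x samples raw score matrix.
#' @param params `NULL` for identity, or a data.frame with columns
#'   `cell_type`, `shift`, `scale`, `exponent` (scale and exponent > 0).
#' @return calibrated matrix, all entries >= 0.
#' @export
calibrate <- function(panel, params = NULL) {
  out <- panel - apply(panel, 1, min)
  if (is.null(params)) return(out)
  stopifnot(all(c("cell_type", "shift", "scale", "exponent") %in%
                  colnames(params)))
  if (any(params$scale <= 0) || any(params$exponent <= 0))
    stop("calibration scale and exponent must be positive")
  for (i in seq_len(nrow(params))) {
    ct <- params$cell_type[i]
    if (!ct %in% rownames(out)) next
    out[ct, ] <- (out[ct, ] + params$shift[i])^params$exponent[i] /
      params$scale[i]
  }
  out
}

#' Apply spillover compensation to a calibrated score panel
#'
#' For each sample, the compensated score of cell type i is
#' `max(0, t_i - alpha * sum_{j != i} K[i, j] * t_j)`: a weighted share of
#' related cell types' scores is subtracted, with the spillover matrix `K`
#' encoding how strongly type j's signal bleeds into type i's signatures.
#'
#' @param panel cell-types x samples calibrated score matrix.
#' @param K spillover matrix (cell types x cell types), diagonal exactly 1,
#'   off-diagonal in \[0, 1\]; must cover all rows of `panel`.
#' @param alpha compensation strength in \[0, 1\]; default 0.5.
#' @return compensated cell-types x samples matrix with
#'   `method_tag = "ssgsea"`; entries are non-negative.
#' @export
spillover_compensate <- function(panel, K, alpha = 0.5) {
  types <- rownames(panel)
  missing <- setdiff(types, rownames(K))
  if (length(missing) > 0)
    stop("spillover matrix is missing cell type(s): ",
         paste(missing, collapse = ", "))
  K <- K[types, types, drop = FALSE]
  if (any(abs(diag(K) - 1) > 1e-12))
    stop("spillover matrix diagonal must be exactly 1")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  K0 <- K
  diag(K0) <- 0
  out <- pmax(panel - alpha * (K0 %*% panel), 0)
  dimnames(out) <- dimnames(panel)
  attr(out, "method_tag") <- "ssgsea"
  out
}

#' Derive a spillover matrix from synthetic pure-type samples
#'
#' Scores every cell type on expression profiles that are pure in one cell
#' type at a time; `K[i, j]` is the mean (min-shifted) score of cell type i
#' on pure type-j samples, row-scaled so the diagonal is exactly 1 and
#' off-diagonal entries are clipped to \[0, 1\]. Large off-diagonal entries
#' reveal signature overlap between related cell types. A near-singular K
#' (reciprocal condition number below `rcond_tol`) is flagged with a
#' warning, as it indicates reference types too similar to separate.
#'
#' @param sigs named signature collection as for [score_cell_types()].
#' @param pure_maker function(cell_type, n) returning a genes x n
#'   expression matrix of pure samples of that type.
#' @param n_pure pure samples per type; default 5.
#' @param alpha_w rank-weight exponent for scoring.
#' @param rcond_tol reciprocal-condition-number threshold; default 1e-6.
#' @return spillover matrix K (cell types x cell types).
#' @export
derive_spillover <- function(sigs, pure_maker, n_pure = 5, alpha_w = 0.25,
                             rcond_tol = 1e-6) {
  types <- names(sigs)
  M <- matrix(0, length(types), length(types),
              dimnames = list(types, types))
  for (j in seq_along(types)) {
    pure <- pure_maker(types[j], n_pure)
    sc <- score_cell_types(pure, sigs, alpha_w = alpha_w)
    M[rownames(sc), j] <- rowMeans(sc)
  }
  M <- M - min(M)                          # scores to a common >= 0 origin
  if (any(diag(M) <= 0))
    stop("degenerate reference: a cell type scores at the panel minimum ",
         "on its own pure samples")
  K <- M / diag(M)                         # row-scale: K[i, ] / M[i, i]
  K[K > 1] <- 1
  K[K < 0] <- 0
  diag(K) <- 1
  if (rcond(K) < rcond_tol)
    warning("spillover matrix is near-singular (rcond = ",
            format(rcond(K), digits = 3),
            "): reference cell types may be indistinguishable")
  K
}
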