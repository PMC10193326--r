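#' @title Cell-fraction estimation by linear nu-support-vector regression
#' @description Solves the mixture model m = f x B per sample: m is the
#'   observed bulk expression vector over the signature genes, B the
#'   reference signature matrix (genes x cell types) and f the unknown
#'   vector of cell-type fractions. Each sample is regressed against the
#'   standardized signature matrix with a linear nu-SVR over a small nu
#'   grid; the primal coefficient vector is clipped at zero and renormalized
#'   onto the unit simplex, and the nu whose (clipped, unnormalized)
#'   reconstruction best matches the standardized mixture is kept.
#' @name immunomix-svr
NULL

#' Standardize a mixture vector and signature matrix to a common gene space
#'
#' Intersects the gene universes, then z-scores the signature matrix over
#' all of its entries (global mean/sd, the default) or per column, and the
#' mixture over the shared genes. Standardization makes the regression
#' scale-free: multiplying a mixture by a positive constant leaves the
#' standardized problem, and hence the estimated fractions, unchanged.
#'
#' @param m named numeric expression vector (one sample).
#' @param B genes x cell-types signature matrix.
#' @param scheme `"global"` (default) or `"per-column"` z-scoring of `B`.
#' @return list with `m` (standardized mixture), `B` (standardized
#'   signatures), `genes` (shared gene ids).
#' @export
standardize <- function(m, B, scheme = c("global", "per-column")) {
  scheme <- match.arg(scheme)
  if (is.null(names(m)) || is.null(rownames(B)))
    stop("mixture and signature matrix must carry gene names")
  genes <- intersect(names(m), rownames(B))
  if (length(genes) < 2)
    stop("fewer than 2 genes shared between mixture and signature matrix")
  m <- m[genes]
  B <- B[genes, , drop = FALSE]
  if (stats::sd(m) == 0) stop("mixture has zero variance over shared genes")
  m_star <- (m - mean(m)) / stats::sd(m)
  B_star <- if (scheme == "global") (B - mean(B)) / stats::sd(as.vector(B))
            else scale(B)
  list(m = m_star, B = B_star, genes = genes)
}

#' Estimate cell-type fractions for one sample
#'
#' Fits a linear nu-SVR of the standardized mixture on the standardized
#' signature matrix for each nu in `nu_grid`, extracts the primal weight
#' vector over cell types, clips negative weights to zero (fractions are
#' physical proportions), and selects the nu whose reconstruction
#' `B* %*% w_clipped` has the lowest RMSE against the standardized mixture.
#' The winning weights are renormalized to sum to exactly 1.
#'
#' @param m named numeric expression vector for one sample (linear scale).
#' @param B genes x cell-types signature matrix.
#' @param nu_grid candidate nu values; default `c(0.25, 0.5, 0.75)`.
#' @param cost SVR cost constant C; default 1.
#' @param scheme standardization scheme passed to [standardize()].
#' @return list with `fractions` (named, non-negative, summing to 1),
#'   `chosen_nu`, `rmse` and `pearson_r` of the winning reconstruction.
#' @export
fit_sample <- function(m, B, nu_grid = c(0.25, 0.5, 0.75), cost = 1,
                       scheme = "global") {
  std <- standardize(m, B, scheme)
  k <- ncol(B)
  fits <- lapply(nu_grid, function(nu) {
    fit <- tryCatch(
      e1071::svm(x = std$B, y = std$m, type = "nu-regression",
                 kernel = "linear", nu = nu, cost = cost, scale = FALSE),
      error = function(e) e)
    if (inherits(fit, "error")) return(fit)
    w <- drop(t(fit$coefs) %*% fit$SV)      # primal weights over cell types
    w <- pmax(w, 0)
    recon <- drop(std$B %*% w)
    list(nu = nu, w = w,
         rmse = sqrt(mean((recon - std$m)^2)),
         pearson_r = suppressWarnings(stats::cor(recon, std$m)))
  })
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok))
    stop("nu-SVR failed for every nu in the grid: ",
         paste(vapply(fits, conditionMessage, character(1)), collapse = "; "))
  fits <- fits[ok]
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rmse"))]]
  if (sum(best$w) <= 0)
    stop("all primal coefficients non-positive; mixture cannot be ",
         "represented as a non-negative combination of the signatures")
  f <- best$w / sum(best$w)
  names(f) <- colnames(B)
  list(fractions = f, chosen_nu = best$nu, rmse = best$rmse,
       pearson_r = best$pearson_r)
}

#' Deconvolve an expression matrix into cell-type fractions
#'
#' Applies [fit_sample()] to every column of the mixture matrix. Samples
#' are independent, so the result does not depend on column order; a sample
#' that fails is reported in the error log and its column filled with `NA`
#' rather than aborting the run.
#'
#' @param mix genes x samples expression matrix (linear scale).
#' @param B genes x cell-types signature matrix.
#' @param nu_grid,cost,scheme passed to [fit_sample()].
#' @param prefix optional signature-id prefix (e.g. `"cibersort"`) applied
#'   to the output rownames as `prefix.CellType`.
#' @return cell-types x samples fraction matrix with `method_tag = "svr"`;
#'   the per-sample QC table (`chosen_nu`, `rmse`, `pearson_r`) is attached
#'   as attribute `"qc"` and the per-sample error log (if any) as
#'   `"errors"`.
#' @export
deconvolve <- function(mix, B, nu_grid = c(0.25, 0.5, 0.75), cost = 1,
                       scheme = "global", prefix = NULL) {
  samples <- colnames(mix)
  if (is.null(samples)) stop("mixture matrix must carry sample colnames")
  out <- matrix(NA_real_, nrow = ncol(B), ncol = ncol(mix),
                dimnames = list(colnames(B), samples))
  qc <- data.frame(sample_id = samples, chosen_nu = NA_real_,
                   rmse = NA_real_, pearson_r = NA_real_,
                   stringsAsFactors = FALSE)
  errors <- character(0)
  for (j in seq_along(samples)) {
    fit <- tryCatch(fit_sample(mix[, j], B, nu_grid, cost, scheme),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      errors[samples[j]] <- conditionMessage(fit)
      next
    }
    out[, j] <- fit$fractions
    qc$chosen_nu[j] <- fit$chosen_nu
    qc$rmse[j] <- fit$rmse
    qc$pearson_r[j] <- fit$pearson_r
  }
  if (length(errors) > 0)
    warning(length(errors), " sample(s) failed deconvolution; see attr(,'errors')")
  if (!is.null(prefix)) rownames(out) <- paste(prefix, rownames(out), sep = ".")
  attr(out, "method_tag") <- "svr"
  attr(out, "qc") <- qc
  attr(out, "errors") <- errors
  out
}
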