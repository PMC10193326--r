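#' @title Synthetic data with known ground truth
#' @description Generators for every input the pipeline consumes: block-
#'   structured signature matrices, bulk mixtures built as `B %*% f` from
#'   Dirichlet fractions with multiplicative lognormal noise (the
#'   scale-dependent error regime of microarray intensities), matched
#'   pseudo-flow panels with multiplicative Gaussian measurement noise, and
#'   three-arm treatment cohorts with injected per-signature effects and
#'   age/gender covariates. Every generator is deterministic under its
#'   `seed` argument and records the seed in its ground-truth output.
#' @name immunomix-simulate
NULL

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  force(expr)
}

#' Generate a block-marker signature matrix
#'
#' Each cell type receives a contiguous window of high-expression marker
#' genes on a low lognormal background. Windows are placed at a stride of
#' `block * (1 - overlap)`, so adjacent cell types share a fraction
#' `overlap` of their marker genes -- the correlated, hard-to-separate
#' reference columns that closely related immune subtypes exhibit. The
#' matrix has full column rank for `overlap < 0.5`; the marker indices per
#' type are attached as attribute `"marker_blocks"`.
#'
#' @param n_genes number of genes (must be at least `5 * n_types`).
#' @param n_types number of cell types.
#' @param overlap fraction in \[0, 1) of each type's markers shared with
#'   the adjacent type; default 0.
#' @param marker_high mean marker intensity; default 500 (background ~ 50).
#' @param seed RNG seed.
#' @return genes x cell-types matrix (`g1..gN` x `type1..typeK`).
#' @export
make_signature_matrix <- function(n_genes, n_types, overlap = 0,
                                  marker_high = 500, seed = 1) {
  if (n_genes < 5 * n_types)
    stop("infeasible: need n_genes >= 5 * n_types (",
         n_genes, " < ", 5 * n_types, ")")
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  .with_seed(seed, {
    B <- matrix(stats::rlnorm(n_genes * n_types, log(50), 0.3),
                n_genes, n_types,
                dimnames = list(paste0("g", seq_len(n_genes)),
                                paste0("type", seq_len(n_types))))
    block <- floor(n_genes / n_types)
    stride <- max(1, round(block * (1 - overlap)))
    blocks <- lapply(seq_len(n_types), function(k) {
      start <- (k - 1) * stride + 1
      start:(start + block - 1)
    })
    for (k in seq_len(n_types))
      B[blocks[[k]], k] <- stats::rlnorm(block, log(marker_high), 0.2)
    attr(B, "marker_blocks") <- stats::setNames(blocks, colnames(B))
    B
  })
}

#' Simulate bulk mixtures from a signature matrix
#'
#' Fractions are drawn per sample from a symmetric Dirichlet (via
#' normalized gamma variates); the expression of sample s is
#' `B %*% f_s * scale`, perturbed by multiplicative lognormal noise
#' `exp(N(0, noise_sd))`.
#'
#' @param B genes x cell-types signature matrix.
#' @param n_samples number of mixture samples.
#' @param dirichlet_alpha scalar or per-type concentration; default 1
#'   (uniform on the simplex).
#' @param noise_sd sd of the log-noise; 0 for noiseless mixtures.
#' @param scale global intensity multiplier; default 1.
#' @param seed RNG seed.
#' @return list with `expr` (genes x samples), `truth` (list:
#'   `fractions` cell-types x samples on the unit simplex, `noise_sd`,
#'   `seed`).
#' @export
make_mixtures <- function(B, n_samples, dirichlet_alpha = 1, noise_sd = 0,
                          scale = 1, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  k <- ncol(B)
  alpha <- rep(dirichlet_alpha, length.out = k)
  .with_seed(seed, {
    F_mat <- vapply(seq_len(n_samples), function(s) {
      g <- stats::rgamma(k, shape = alpha, rate = 1)
      g / sum(g)
    }, numeric(k))
    dimnames(F_mat) <- list(colnames(B), paste0("s", seq_len(n_samples)))
    expr <- B %*% F_mat * scale
    if (noise_sd > 0)
      expr <- expr * exp(matrix(stats::rnorm(length(expr), 0, noise_sd),
                                nrow(expr)))
    list(expr = expr,
         truth = list(fractions = F_mat, noise_sd = noise_sd, seed = seed))
  })
}

#' Simulate a matched pseudo-flow panel from known fractions
#'
#' Percentages are `100 * fraction`, perturbed by multiplicative Gaussian
#' measurement noise with coefficient of variation `cv` and clipped to
#' \[0, 100\].
#'
#' @param truth ground-truth list from [make_mixtures()] (or any list with
#'   a `fractions` cell-types x samples matrix).
#' @param cv measurement coefficient of variation; 0 for exact percentages.
#' @param seed RNG seed.
#' @return samples x phenotypes percentage matrix; phenotype names are the
#'   cell-type names.
#' @export
make_flow <- function(truth, cv = 0, seed = 1) {
  if (cv < 0) stop("cv must be non-negative")
  f <- truth$fractions
  .with_seed(seed, {
    pct <- 100 * t(f)
    if (cv > 0)
      pct <- pct * matrix(1 + stats::rnorm(length(pct), 0, cv), nrow(pct))
    pmin(pmax(pct, 0), 100)
  })
}

#' Simulate a three-arm treatment cohort of deconvolution scores
#'
#' Samples are allocated to placebo / low-dose / high-dose arms with ages
#' uniform over `age_range` and genders drawn at `gender_balance` female.
#' Each signature's score is a Gaussian baseline plus optional age and
#' gender dependence plus the injected arm effects, enabling both
#' effect-recovery and confounding experiments. Default arm sizes
#' (57 / 62 / 70) mirror a realistic trial-subset design.
#'
#' @param n_per_arm named vector `c(placebo=, low_dose=, high_dose=)`,
#'   each at least 10.
#' @param signatures signature names (or a count, auto-named `sig1..`).
#' @param effects `NULL`, or a data.frame with columns `signature`, `arm`
#'   (`low_dose`/`high_dose`), `delta` (additive shift in score units).
#' @param baseline_mean,baseline_sd score baseline; defaults 1 and 0.2.
#' @param age_range,gender_balance covariate generators; defaults 18--65
#'   and 0.886 female.
#' @param age_slope,gender_shift optional per-signature named vectors of
#'   covariate dependence (score units per year; M-vs-F shift).
#' @param age_arm_bias optional named vector over arms of additive mean-age
#'   shifts (years), for constructing age-confounded designs.
#' @param seed RNG seed.
#' @return list with `cohort` (data.frame: `sample_id`, `arm`, `age`,
#'   `gender`, one column per signature) and `truth` (list: `effects`,
#'   `seed`).
#' @export
make_cohort <- function(n_per_arm = c(placebo = 57, low_dose = 62,
                                      high_dose = 70),
                        signatures = 10, effects = NULL,
                        baseline_mean = 1, baseline_sd = 0.2,
                        age_range = c(18, 65), gender_balance = 0.886,
                        age_slope = NULL, gender_shift = NULL,
                        age_arm_bias = NULL, seed = 1) {
  stopifnot(all(c("placebo", "low_dose", "high_dose") %in% names(n_per_arm)))
  if (any(n_per_arm < 10)) stop("each arm needs at least 10 samples")
  if (is.numeric(signatures) && length(signatures) == 1)
    signatures <- paste0("sig", seq_len(signatures))
  .with_seed(seed, {
    arm <- rep(names(n_per_arm), times = n_per_arm)
    n <- length(arm)
    age <- stats::runif(n, age_range[1], age_range[2])
    if (!is.null(age_arm_bias))
      age <- age + unname(age_arm_bias[arm])
    gender <- ifelse(stats::runif(n) < gender_balance, "F", "M")
    cohort <- data.frame(sample_id = sprintf("p%03d", seq_len(n)),
                         arm = arm, age = age, gender = gender,
                         stringsAsFactors = FALSE)
    for (sig in signatures) {
      y <- stats::rnorm(n, baseline_mean, baseline_sd)
      if (!is.null(age_slope) && sig %in% names(age_slope))
        y <- y + age_slope[[sig]] * (age - mean(age_range))
      if (!is.null(gender_shift) && sig %in% names(gender_shift))
        y <- y + gender_shift[[sig]] * (gender == "M")
      if (!is.null(effects)) {
        hits <- effects[effects$signature == sig, , drop = FALSE]
        for (i in seq_len(nrow(hits)))
          y <- y + hits$delta[i] * (arm == hits$arm[i])
      }
      cohort[[sig]] <- y
    }
    list(cohort = cohort,
         truth = list(effects = effects, seed = seed))
  })
}

#' Build pure-type expression samples from a signature matrix
#'
#' Convenience generator for [derive_spillover()]: returns a function that
#' produces `n` noisy pure samples of a requested cell type from `B`.
#'
#' @param B genes x cell-types signature matrix.
#' @param noise_sd multiplicative lognormal noise sd; default 0.05.
#' @param seed base seed; each (type, n) call derives its own substream.
#' @return function(cell_type, n) -> genes x n matrix.
#' @export
pure_sample_maker <- function(B, noise_sd = 0.05, seed = 1) {
  function(cell_type, n) {
    if (!cell_type %in% colnames(B)) stop("unknown cell type: ", cell_type)
    sub_seed <- (seed * 131 + match(cell_type, colnames(B))) %% .Machine$integer.max
    .with_seed(sub_seed, {
      base <- B[, cell_type]
      out <- vapply(seq_len(n), function(i)
        base * exp(stats::rnorm(length(base), 0, noise_sd)), numeric(nrow(B)))
      dimnames(out) <- list(rownames(B), paste0(cell_type, "_pure", seq_len(n)))
      out
    })
  }
}
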