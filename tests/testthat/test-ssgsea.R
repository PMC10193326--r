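test_that("enrichment scores match the naive oracle on every placement", {
  # all C(10,3) placements of a 3-gene signature in a 10-gene universe
  expr <- stats::setNames(seq(10, 1), paste0("g", 1:10))
  placements <- utils::combn(10, 3)
  es <- apply(placements, 2, function(idx) {
    sig <- paste0("g", idx)
    expect_equal(ssgsea_es(expr, sig), oracle_es(expr, sig))
    ssgsea_es(expr, sig)
  })
  # the top-rank placement attains the maximum over all placements
  top <- ssgsea_es(expr, paste0("g", 1:3))
  expect_equal(top, max(es))
})

test_that("a whole-universe signature collapses to the weight-forced value", {
  expr <- stats::setNames(c(9, 7, 5, 3, 1), paste0("g", 1:5))
  sig <- paste0("g", 1:5)
  # miss term vanishes; ES is the integral of cumulative normalized weights
  w <- (5:1)^0.25
  expected <- sum(cumsum(w / sum(w)))
  expect_equal(ssgsea_es(expr, sig), expected)
})

test_that("scores are rank-invariant and tie-aware", {
  expr <- stats::setNames(stats::runif(30, 1, 100), paste0("g", 1:30))
  sig <- paste0("g", c(2, 9, 17, 25))
  base <- ssgsea_es(expr, sig)
  expect_equal(ssgsea_es(log2(expr), sig), base)
  expect_equal(ssgsea_es(expr^3 + 5, sig), base)
  expect_equal(ssgsea_es(rank(expr), sig), base)

  tied <- stats::setNames(rep(c(1, 2), each = 10), paste0("g", 1:20))
  expect_warning(ssgsea_es(tied, paste0("g", 1:2)), "tied")
  expect_error(ssgsea_es(expr, c("absent1", "absent2")), "no signature gene")
})

test_that("cell-type aggregation averages signature scores per type", {
  set.seed(42)
  mix <- matrix(stats::rlnorm(40 * 3, log(50), 1), 40, 3,
                dimnames = list(paste0("g", 1:40), paste0("s", 1:3)))
  sigA1 <- paste0("g", 1:5); sigA2 <- paste0("g", 3:8)
  sigs <- list(A = list(sigA1, sigA2), B = list(paste0("g", 20:24)))
  panel <- score_cell_types(mix, sigs)
  expect_identical(rownames(panel), c("A", "B"))
  # mean of the two signature ES values, per sample
  for (j in 1:3) {
    esA <- mean(c(ssgsea_es(mix[, j], sigA1), ssgsea_es(mix[, j], sigA2)))
    expect_equal(panel["A", j], esA)
  }
  # single-signature type equals that signature's ES; duplicated signature
  # averages to the same value
  dup <- score_cell_types(mix, list(B = list(paste0("g", 20:24),
                                             paste0("g", 20:24))))
  expect_equal(dup["B", ], panel["B", ])
  # a type with no usable genes is dropped with a warning
  expect_warning(p2 <- score_cell_types(mix, c(sigs, list(C = list("nope")))),
                 "dropped: C")
  expect_identical(rownames(p2), c("A", "B"))
})

test_that("calibration min-shifts, scales, and preserves sample ranking", {
  panel <- matrix(c(-2, 1, 0, 4, -1, 2), 2, 3,
                  dimnames = list(c("A", "B"), paste0("s", 1:3)))
  ident <- calibrate(panel)
  expect_equal(unname(ident["A", ]), c(0, 2, 1))
  expect_true(all(ident >= 0))
  half <- calibrate(panel, data.frame(cell_type = c("A", "B"), shift = 0,
                                      scale = 2, exponent = 1))
  expect_equal(half, ident / 2)
  # any positive power law preserves within-type sample ranking
  set.seed(7)
  for (i in 1:20) {
    raw <- matrix(stats::rnorm(12), 3, 4,
                  dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
    params <- data.frame(cell_type = c("A", "B", "C"),
                         shift = stats::runif(3, 0, 1),
                         scale = stats::runif(3, 0.5, 3),
                         exponent = stats::runif(3, 0.2, 3))
    cal <- calibrate(raw, params)
    for (ct in rownames(raw))
      expect_identical(order(cal[ct, ]), order(raw[ct, ]))
  }
})

test_that("spillover compensation matches the closed-form two-type case", {
  panel <- matrix(c(1.0, 0.4), 2, 1, dimnames = list(c("A", "B"), "s1"))
  K <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  out <- spillover_compensate(panel, K, alpha = 0.5)
  expect_equal(unname(out[, 1]), c(1.0 - 0.5 * 0.5 * 0.4, 0.4 - 0.5 * 0.5 * 1.0))
  expect_equal(unname(out[, 1]), c(0.9, 0.15))

  # identity K is a no-op; outputs are clipped at zero
  K_id <- diag(2)
  dimnames(K_id) <- list(c("A", "B"), c("A", "B"))
  expect_equal(spillover_compensate(panel, K_id, 0.5)[, 1], panel[, 1])
  hot <- matrix(c(0.1, 2), 2, 1, dimnames = list(c("A", "B"), "s1"))
  expect_true(all(spillover_compensate(hot, K, 1) >= 0))
  expect_error(spillover_compensate(panel, K[1, 1, drop = FALSE]), "missing")
})

test_that("derived spillover reflects signature overlap", {
  # orthogonal references and disjoint signatures: K near identity
  B <- make_signature_matrix(60, 3, overlap = 0, seed = 13)
  sigs <- list(type1 = list(paste0("g", 1:10)),
               type2 = list(paste0("g", 21:30)),
               type3 = list(paste0("g", 41:50)))
  K <- derive_spillover(sigs, pure_sample_maker(B, seed = 14))
  expect_equal(unname(diag(K)), rep(1, 3))
  expect_true(all(K >= 0 & K <= 1))

  # adjacent types sharing half their signature genes (marker windows
  # overlap at 0.5: blocks 1-20 / 11-30 / 21-40) show strong cross-talk
  sigs_ov <- list(type1 = list(paste0("g", 8:17)),
                  type2 = list(paste0("g", 13:22)),
                  type3 = list(paste0("g", 31:40)))
  B_ov <- make_signature_matrix(60, 3, overlap = 0.5, seed = 13)
  K_ov <- derive_spillover(sigs_ov, pure_sample_maker(B_ov, seed = 14))
  expect_gt(K_ov["type2", "type1"], 0.2)
  expect_gt(K_ov["type1", "type2"], 0.2)
})

test_that("spillover compensation reduces cross-type confusion", {
  set.seed(99)
  # marker windows at overlap 0.4: blocks 1-20 / 13-32 / 25-44; each
  # signature sits inside its own block with a few genes in the shared zone
  B <- make_signature_matrix(60, 3, overlap = 0.4, seed = 23)
  sigs <- list(type1 = list(paste0("g", 5:16)),
               type2 = list(paste0("g", 17:28)),
               type3 = list(paste0("g", 33:44)))
  maker <- pure_sample_maker(B, seed = 24)
  pure <- cbind(maker("type1", 5), maker("type2", 5), maker("type3", 5))
  panel <- calibrate(score_cell_types(pure, sigs))
  K <- derive_spillover(sigs, maker)
  comp <- spillover_compensate(panel, K)
  truth <- rep(c("type1", "type2", "type3"), each = 5)
  off_mass <- function(p) {
    mean(vapply(seq_len(ncol(p)), function(j) {
      tot <- sum(p[, j])
      if (tot == 0) 0 else sum(p[setdiff(rownames(p), truth[j]), j]) / tot
    }, numeric(1)))
  }
  expect_lt(off_mass(comp), off_mass(panel))
  # the true type attains the top compensated score on pure samples
  top_hit <- vapply(seq_len(ncol(comp)), function(j)
    rownames(comp)[which.max(comp[, j])] == truth[j], logical(1))
  expect_gte(mean(top_hit), 0.95)
})
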