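make_features <- function(n, p = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  X
}

test_that("a single informative feature dominates the fitted weights", {
  X <- make_features(200)
  y <- 0.5 + 0.1 * X[, 3] + rnorm(200, sd = 1e-3)
  fit <- fit_detection_regression(X, y, n_replicates = 3)
  w <- coef(fit)[-1]
  expect_equal(names(which.max(abs(w))), "f3")
  expect_gt(fit$r_squared, 0.99)
  # against the closed-form OLS oracle (ridge 1e-3 is negligible here)
  ols <- lm(y ~ X)
  expect_equal(unname(w["f3"] / sd(X[, 3])), unname(coef(ols)["Xf3"]),
               tolerance = 1e-2)
})

test_that("degenerate targets and too few replicates are refused", {
  X <- make_features(50)
  expect_error(fit_detection_regression(X, rep(0, 50), n_replicates = 3),
               "constant")
  expect_error(fit_detection_regression(X, runif(50), n_replicates = 2),
               "three or more")
})

test_that("duplicated feature columns stay finite and preserve predictions", {
  X <- make_features(100, p = 3)
  y <- 0.2 + 0.3 * X[, 1] + rnorm(100, sd = 0.05)
  fit1 <- fit_detection_regression(X, y, n_replicates = 3)
  Xd <- cbind(X, f1_copy = X[, 1])
  fit2 <- fit_detection_regression(Xd, y, n_replicates = 3)
  expect_true(all(is.finite(coef(fit2))))
  expect_equal(predict(fit2, Xd), predict(fit1, X), tolerance = 1e-3)
})

test_that("scores are the intercept plus the weighted standardized features", {
  X <- make_features(80)
  y <- 0.4 + 0.2 * X[, 2] + rnorm(80, sd = 0.01)
  fit <- fit_detection_regression(X, y, n_replicates = 3)
  # all-mean feature row scores at the intercept
  x0 <- matrix(fit$center, 1, dimnames = list(NULL, colnames(X)))
  expect_equal(predict(fit, x0), unname(coef(fit)[1]))
  # +1 sd on feature j moves the score by w_j
  x1 <- x0; x1[1, 2] <- x1[1, 2] + fit$scale[2]
  expect_equal(predict(fit, x1) - predict(fit, x0), unname(coef(fit)["f2"]))
  # hand-computed dot product on three rows
  X3 <- X[1:3, , drop = FALSE]
  Xs <- sweep(sweep(X3, 2, fit$center), 2, fit$scale, `/`)
  expect_equal(score_candidates(fit, X3),
               as.numeric(Xs %*% coef(fit)[-1]) + coef(fit)[1])
})

test_that("scores are invariant to affine rescaling of a raw feature", {
  X <- make_features(120)
  y <- 0.3 + 0.15 * X[, 4] + rnorm(120, sd = 0.02)
  fit1 <- fit_detection_regression(X, y, n_replicates = 3)
  X2 <- X; X2[, 4] <- 100 * X[, 4] + 7
  fit2 <- fit_detection_regression(X2, y, n_replicates = 3)
  expect_equal(score_candidates(fit1, X), score_candidates(fit2, X2),
               tolerance = 1e-6)
})

test_that("the ridge solution agrees with glmnet at matched penalty", {
  skip_if_not_installed("glmnet")
  X <- make_features(150, p = 6, seed = 4)
  y <- 0.5 + 0.1 * X[, 1] - 0.05 * X[, 5] + rnorm(150, sd = 0.05)
  ridge <- 1e-3
  fit <- fit_detection_regression(X, y, n_replicates = 3, ridge = ridge)
  Xs <- scale(X)
  # glmnet minimizes 1/(2n)RSS + lambda/2 ||b||^2 for alpha=0: lambda = ridge/n
  gn <- glmnet::glmnet(Xs, y, alpha = 0, lambda = ridge / length(y),
                       standardize = FALSE, intercept = TRUE,
                       thresh = 1e-12)
  expect_equal(unname(coef(fit)[-1]), as.numeric(coef(gn))[-1],
               tolerance = 1e-3)
})

test_that("leader permutation preserves per-leader totals and leaves mORFs alone", {
  gd <- list(g1 = toy_gene_data(
    cands = data.frame(gene_id = "g1", start_pos = 0L, stop_pos = 8L,
                       start_codon = "ATG", length_nt = 9L,
                       overlaps_morf = FALSE),
    tracks = list(c(rpois(30, 2), rpois(30, 5)),
                  c(rpois(30, 2), rpois(30, 5)),
                  c(rpois(30, 2), rpois(30, 5))),
    leader_len = 30L))
  X <- compute_features(gd$g1$cands, Reduce(`+`, gd$g1$tracks), gd$g1$rna, 30L)
  y <- c(0.5)
  # need >1 candidate to fit; use a canned linear model instead
  perm <- uorfseqr:::.permute_leader(gd$g1$tracks[[1]], 30L)
  expect_equal(sum(perm[1:30]), sum(gd$g1$tracks[[1]][1:30]))
  expect_equal(perm[31:60], gd$g1$tracks[[1]][31:60])
})

test_that("null scores equal real scores for leaders without P-sites", {
  set.seed(21)
  cands <- data.frame(gene_id = "g1", start_pos = c(0L, 12L),
                      stop_pos = c(8L, 23L), start_codon = "ATG",
                      length_nt = c(9L, 12L), overlaps_morf = FALSE)
  empty_leader <- c(integer(30), rpois(30, 5))
  gd <- list(g1 = toy_gene_data(cands,
                                list(empty_leader, empty_leader, empty_leader),
                                leader_len = 30L))
  X <- compute_features(cands, Reduce(`+`, gd$g1$tracks), gd$g1$rna, 30L)
  # synthetic fitted model with arbitrary finite weights
  y <- c(0.2, 0.8)
  fake <- structure(list(
    coefficients = c(`(intercept)` = 0.1,
                     stats::setNames(rep(0.05, ncol(X)), colnames(X))),
    center = rep(0, ncol(X)), scale = rep(1, ncol(X))),
    class = "uorf_regression")
  real <- score_candidates(fake, X)
  nulls <- build_null_scores(gd, fake, n_permutations = 3, seed = 7)
  expect_equal(as.numeric(nulls), rep(real, 3))
})

test_that("empirical q-values match the stated formula by brute force", {
  set.seed(31)
  real <- rnorm(50)
  nulls <- rnorm(500, mean = -0.5)
  q <- empirical_qvalues(real, nulls)
  # brute-force double loop over thresholds
  q_oracle <- vapply(real, function(x) {
    thr <- real[real <= x]
    fdrs <- vapply(thr, function(s) {
      ((1 + sum(nulls >= s)) / length(nulls)) /
        (max(1, sum(real >= s)) / length(real))
    }, numeric(1))
    min(c(fdrs, 1), 1)
  }, numeric(1))
  q_oracle <- pmin(q_oracle, 1)
  expect_equal(q, q_oracle)
  # monotone non-increasing in score
  o <- order(real)
  expect_true(all(diff(q[o]) <= 1e-12))
})

test_that("q-value limit cases behave", {
  # every real score above every null: the pointwise FDR at the top score is
  # (1/N_null)/(1/N_real) = 0.1, but the q-value minimizes over all
  # rejection regions containing the candidate, and the full set has
  # FDR (1/1000)/(100/100) = 0.001
  real <- seq_len(100) / 100
  nulls <- rep(-1, 1000)
  fdr_top <- ((1 + sum(nulls >= 1)) / 1000) / (max(1, sum(real >= 1)) / 100)
  expect_equal(fdr_top, 0.1)
  q <- empirical_qvalues(real, nulls)
  expect_equal(unique(q), 0.001)
  # real scores drawn from the null: q near 1
  set.seed(12)
  r2 <- rnorm(200); n2 <- rnorm(2000)
  expect_gte(median(empirical_qvalues(r2, n2)), 0.8)
  # all real below all null: q = 1 everywhere
  expect_equal(empirical_qvalues(c(0, 0.1), c(5, 6, 7)), c(1, 1))
  expect_error(empirical_qvalues(1, numeric(0)), "empty")
})

test_that("call_significant applies the FDR cut and overlap resolution", {
  calls <- data.frame(gene_id = "g", start_pos = c(0L, 3L, 30L),
                      stop_pos = c(20L, 11L, 40L), start_codon = "ATG",
                      length_nt = c(21L, 9L, 11L), overlaps_morf = FALSE,
                      score = c(5, 3, 1), q_value = c(0.01, 0.049, 0.051))
  out <- call_significant(calls, beta = 0.05)
  # 2 pass the cut; the nested pair resolves to its higher-scoring member
  expect_equal(nrow(out), 1L)
  expect_equal(out$score, 5)
  expect_equal(nrow(call_significant(calls, beta = 0)), 0L)
})
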