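#' Fit the detection regression
#'
#' Fits a ridge-regularized linear regression of the per-candidate detection
#' fraction (share of biological replicates in which the candidate passes the
#' heuristic detector) on the 18 standardized features.  At least three
#' biological replicates are required; with fewer, the detection fraction is
#' too coarse to train against.  The feature weights are estimated
#' independently for each experiment (species x condition).
#'
#' @param features Numeric matrix (candidates x features), e.g. stacked
#'   [compute_features()] output.
#' @param y Detection fractions in `[0, 1]`, one per candidate.
#' @param n_replicates Number of biological replicates behind `y`; must be
#'   >= 3.
#' @param ridge Ridge penalty on the standardized coefficients (default
#'   `1e-3`; the features are collinear by construction, so a small penalty
#'   keeps the weights finite without changing predictions materially).
#' @return An object of class `"uorf_regression"` with components
#'   `coefficients` (intercept first), `center`, `scale`, `fitted`, `y`,
#'   `r_squared`, `n`, `ridge`.
#' @seealso [predict.uorf_regression()], [score_candidates()]
#' @export
fit_detection_regression <- function(features, y, n_replicates, ridge = 1e-3) {
  features <- as.matrix(features)
  if (n_replicates < 3) {
    stop("uORF calling requires three or more biological replicates (got ",
         n_replicates, ")")
  }
  if (nrow(features) != length(y)) stop("features/y length mismatch")
  if (stats::var(y) == 0) {
    stop("degenerate training target: detection fraction is constant (",
         y[1], ") across all candidates")
  }
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  scl[scl == 0] <- 1               # constant columns contribute nothing
  Xs <- sweep(sweep(features, 2, ctr), 2, scl, `/`)
  yc <- y - mean(y)
  p <- ncol(Xs)
  beta <- solve(crossprod(Xs) + diag(ridge, p), crossprod(Xs, yc))
  fitted <- as.numeric(Xs %*% beta) + mean(y)
  r2 <- 1 - sum((y - fitted)^2) / sum(yc^2)
  cf <- c(`(intercept)` = mean(y), stats::setNames(as.numeric(beta), colnames(features)))
  structure(list(coefficients = cf, center = ctr, scale = scl,
                 fitted = fitted, y = y, r_squared = r2,
                 n = length(y), ridge = ridge),
            class = "uorf_regression")
}

#' @export
print.uorf_regression <- function(x, ...) {
  cat("uORF detection regression (ridge = ", format(x$ridge),
      ")\n  candidates: ", x$n, "   R-squared: ", round(x$r_squared, 4),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.uorf_regression <- function(object, ...) {
  w <- object$coefficients[-1]
  tab <- data.frame(feature = names(w), weight = as.numeric(w))
  tab <- tab[order(-abs(tab$weight)), ]
  rownames(tab) <- NULL
  out <- list(weights = tab, intercept = unname(object$coefficients[1]),
              r_squared = object$r_squared, n = object$n)
  class(out) <- "summary.uorf_regression"
  out
}

#' @export
print.summary.uorf_regression <- function(x, ...) {
  cat("uORF detection regression: n =", x$n,
      " R-squared =", round(x$r_squared, 4), "\n")
  cat("Intercept:", format(x$intercept, digits = 4), "\n")
  cat("Standardized feature weights (by magnitude):\n")
  print(utils::head(x$weights, 18), row.names = FALSE)
  invisible(x)
}

#' @export
coef.uorf_regression <- function(object, ...) object$coefficients

#' @export
residuals.uorf_regression <- function(object, ...) object$y - object$fitted

#' Predict scores for new candidates
#' @param object A fitted `"uorf_regression"`.
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @return Numeric score vector (intercept + weighted standardized features).
#' @export
predict.uorf_regression <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, names(object$coefficients)[-1], drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  as.numeric(Xs %*% object$coefficients[-1]) + unname(object$coefficients[1])
}

#' @export
plot.uorf_regression <- function(x, ...) {
  plot(x$fitted, x$y, xlab = "fitted score", ylab = "detection fraction",
       main = "uORF detection regression", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Score candidates with a fitted detection regression
#'
#' Thin wrapper over [predict.uorf_regression()]; scores are the weighted sum
#' of standardized features plus the intercept.
#'
#' @inheritParams predict.uorf_regression
#' @param features Feature matrix.
#' @param model A fitted `"uorf_regression"`.
#' @return Numeric score vector.
#' @export
score_candidates <- function(model, features) predict(model, features)

## -- randomized null --------------------------------------------------------

# uniformly re-position the P-sites within the leader portion of one track,
# preserving the per-leader total; the mORF portion is untouched
.permute_leader <- function(track, leader_len) {
  if (leader_len <= 0L) return(track)
  total <- sum(track[seq_len(leader_len)])
  out <- track
  out[seq_len(leader_len)] <- 0L
  if (total > 0L) {
    out[seq_len(leader_len)] <- tabulate(
      sample.int(leader_len, total, replace = TRUE), nbins = leader_len)
  }
  out
}

#' Build the randomized-null score sample
#'
#' For each permutation, the P-site counts within each transcript leader are
#' uniformly re-positioned (per replicate, preserving per-leader totals; the
#' mORF is untouched so gene expression level is preserved), features are
#' recomputed on the permuted pooled track, and the already-trained model is
#' applied.  All permutation scores are pooled into one null sample.
#'
#' @param gene_data Named list (by gene); each element a list with `cands`
#'   (candidate data frame), `tracks` (list of per-replicate P-site vectors),
#'   `rna` (coverage vector), `leader_len`.
#' @param model A fitted `"uorf_regression"`.
#' @param n_permutations Number of permutations (default 10).
#' @param seed Integer seed; recorded in the output attributes.
#' @return Numeric vector of pooled null scores with attribute `seed`.
#' @export
build_null_scores <- function(gene_data, model, n_permutations = 10L, seed = 1L) {
  stopifnot(n_permutations >= 1L)
  set.seed(seed)
  null_scores <- vector("list", n_permutations)
  for (p in seq_len(n_permutations)) {
    per_gene <- lapply(gene_data, function(g) {
      if (nrow(g$cands) == 0L) return(NULL)
      perm <- lapply(g$tracks, .permute_leader, leader_len = g$leader_len)
      pooled <- Reduce(`+`, perm)
      compute_features(g$cands, pooled, g$rna, g$leader_len)
    })
    X <- do.call(rbind, per_gene[!vapply(per_gene, is.null, logical(1))])
    null_scores[[p]] <- score_candidates(model, X)
  }
  out <- unlist(null_scores, use.names = FALSE)
  attr(out, "seed") <- seed
  out
}

#' Empirical q-values against a null score sample
#'
#' For a score threshold `s`, the estimated false discovery rate is
#' `FDR(s) = [(1 + #null >= s) / N_null] / [max(1, #real >= s) / N_real]`;
#' the q-value of a candidate is the minimum of `FDR(s)` over thresholds at
#' or below its score, clipped to `[0, 1]`.  The +1 pseudocount keeps every
#' q-value strictly positive.
#'
#' @param real_scores Scores of the observed candidates.
#' @param null_scores Pooled permutation scores (non-empty).
#' @return Numeric q-values, one per real score, monotone non-increasing in
#'   the score.
#' @export
empirical_qvalues <- function(real_scores, null_scores) {
  if (length(null_scores) == 0L) stop("empty null score sample")
  n_real <- length(real_scores)
  n_null <- length(null_scores)
  thr <- sort(unique(real_scores))
  null_sorted <- sort(null_scores)
  real_sorted <- sort(real_scores)
  n_null_ge <- vapply(thr, function(s) sum(null_sorted >= s), integer(1))
  n_real_ge <- vapply(thr, function(s) sum(real_sorted >= s), integer(1))
  fdr <- ((1 + n_null_ge) / n_null) / (pmax(1L, n_real_ge) / n_real)
  q_at_thr <- pmin(cummin(fdr), 1)      # running min over thresholds <= s
  q_at_thr[match(real_scores, thr)]
}

#' Final significant uORF calls
#'
#' Flags candidates with q-value at or below `beta`, resolves overlapping and
#' nested significant candidates ([resolve_overlaps()]), and sorts by gene
#' and position.
#'
#' @param calls Data frame of scored candidates with columns of
#'   [enumerate_candidates()] plus `score` and `q_value`.
#' @param beta FDR level (default 0.05).
#' @return The significant, overlap-resolved subset with a `significant`
#'   column (all `TRUE`).
#' @export
call_significant <- function(calls, beta = 0.05) {
  sig <- calls[calls$q_value <= beta, , drop = FALSE]
  if (nrow(sig) > 0L) sig <- resolve_overlaps(sig)
  sig$significant <- rep(TRUE, nrow(sig))
  rownames(sig) <- NULL
  sig
}
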