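# Canonical correlation analysis between per-task Cognitive Indices and
# scalar imaging burden measures, with Y-row permutation inference and
# back-projected loadings. The fit uses the SVD-whitening closed form: with
# X = Ux Dx Vx' and Y = Uy Dy Vy' (thin SVDs of the standardized blocks),
# the singular values of Ux' Uy are the canonical correlations and the
# weights are Vx Dx^-1 U and Vy Dy^-1 V.

#' Fit a canonical correlation analysis
#'
#' Finds, for each mode, the pair of linear combinations of the X block
#' (cognitive variables) and the Y block (imaging variables) with maximal
#' correlation, subject to orthogonality with earlier modes. Rows with any
#' missing value are dropped (listwise, with a message); columns are
#' standardized. Canonical variates have unit variance. Sign convention: each
#' block's variate is flipped so that its largest-|loading| variable loads
#' positively (the reported canonical correlations are the nonnegative
#' singular values and are unaffected).
#'
#' @param X numeric matrix, participants x cognitive variables.
#' @param Y numeric matrix, participants x imaging variables (same rows).
#' @return Object of class `cca_result`: `canonical_correlations` (length
#'   `min(p, q)`, non-increasing, in `[0, 1]`), `x_weights`, `y_weights`,
#'   `x_variates`, `y_variates`, `x_backprojected`, `y_backprojected`
#'   (correlations of each original variable with its own block's variates),
#'   `n` (complete rows used).
#' @export
fit_cca <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stopf("X and Y must have the same rows")
  complete <- stats::complete.cases(X) & stats::complete.cases(Y)
  if (any(!complete)) {
    message(sum(!complete), " incomplete row(s) dropped (listwise)")
  }
  X <- X[complete, , drop = FALSE]
  Y <- Y[complete, , drop = FALSE]
  n <- nrow(X)
  p <- ncol(X)
  q <- ncol(Y)
  if (n <= p + q) {
    stopf("need more complete rows (%d) than total variables (%d)", n, p + q)
  }
  Xs <- scale(X)
  Ys <- scale(Y)
  if (any(!is.finite(Xs)) || any(!is.finite(Ys))) {
    stopf("constant column present; remove it before fitting")
  }
  sx <- svd(Xs)
  sy <- svd(Ys)
  rtol <- max(dim(Xs), dim(Ys)) * .Machine$double.eps
  if (min(sx$d) < rtol * max(sx$d) || min(sy$d) < rtol * max(sy$d)) {
    stopf("rank-deficient block: remove linearly dependent columns before fitting")
  }
  K <- crossprod(sx$u, sy$u)
  sk <- svd(K)
  m <- min(p, q)
  rho <- clip01(sk$d[seq_len(m)])

  # weights on the standardized scale; variates scaled to unit variance
  a <- sx$v %*% (sk$u[, seq_len(m), drop = FALSE] / sx$d)
  b <- sy$v %*% (sk$v[, seq_len(m), drop = FALSE] / sy$d)
  U <- Xs %*% a
  V <- Ys %*% b
  U <- sweep(U, 2, apply(U, 2, stats::sd), "/")
  V <- sweep(V, 2, apply(V, 2, stats::sd), "/")
  a <- sweep(a, 2, apply(Xs %*% a, 2, stats::sd), "/")
  b <- sweep(b, 2, apply(Ys %*% b, 2, stats::sd), "/")

  xload <- stats::cor(Xs, U)
  yload <- stats::cor(Ys, V)
  for (k in seq_len(m)) {
    if (xload[which.max(abs(xload[, k])), k] < 0) {
      a[, k] <- -a[, k]; U[, k] <- -U[, k]; xload[, k] <- -xload[, k]
    }
    if (yload[which.max(abs(yload[, k])), k] < 0) {
      b[, k] <- -b[, k]; V[, k] <- -V[, k]; yload[, k] <- -yload[, k]
    }
  }
  rownames(a) <- rownames(xload) <- colnames(X)
  rownames(b) <- rownames(yload) <- colnames(Y)

  structure(list(
    canonical_correlations = rho,
    x_weights = a, y_weights = b,
    x_variates = U, y_variates = V,
    x_backprojected = xload, y_backprojected = yload,
    n = n, complete_rows = which(complete)
  ), class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result> %d mode(s), n = %d; canonical correlations: %s\n",
              length(x$canonical_correlations), x$n,
              paste(sprintf("%.3f", x$canonical_correlations), collapse = ", ")))
  invisible(x)
}

# bare canonical correlations for permutation resampling
cca_correlations <- function(Xs, Ys) {
  sx <- svd(Xs, nv = 0)
  sy <- svd(Ys, nv = 0)
  d <- svd(crossprod(sx$u, sy$u), nu = 0, nv = 0)$d
  clip01(d[seq_len(min(ncol(Xs), ncol(Ys)))])
}

#' Permutation test for canonical correlation modes
#'
#' Re-estimates every mode's canonical correlation under random permutations
#' of the Y rows (breaking the X-Y pairing while preserving each block's
#' internal structure) and reports the per-mode permutation p-value
#' `(1 + #(perm >= observed)) / (1 + n_perm)`.
#'
#' @param X,Y the matrices passed to [fit_cca()] (incomplete rows are dropped
#'   the same way).
#' @param n_perm number of permutations (at least 999).
#' @param seed integer seed; fixed seed gives identical p-values across runs.
#' @return list with `p` (per-mode p-values), `observed` (canonical
#'   correlations), `n_perm`, `seed`.
#' @export
cca_permutation_test <- function(X, Y, n_perm = 999L, seed = 1L) {
  if (n_perm < 999) stopf("use at least 999 permutations")
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  complete <- stats::complete.cases(X) & stats::complete.cases(Y)
  Xs <- scale(X[complete, , drop = FALSE])
  Ys <- scale(Y[complete, , drop = FALSE])
  obs <- cca_correlations(Xs, Ys)
  n <- nrow(Xs)
  with_seed(seed, {
    exceed <- integer(length(obs))
    for (b in seq_len(n_perm)) {
      perm <- cca_correlations(Xs, Ys[sample.int(n), , drop = FALSE])
      exceed <- exceed + (perm >= obs)
    }
    list(p = (1 + exceed) / (1 + n_perm), observed = obs,
         n_perm = as.integer(n_perm), seed = as.integer(seed))
  })
}

#' Back-projected loadings of a fitted CCA
#'
#' Pearson correlation of each original variable with each canonical variate
#' of its own block - the interpretable "which variables carry this mode"
#' summary (weights themselves are not interpretable under collinearity).
#'
#' @param result a [fit_cca()] object.
#' @param X,Y the matrices the result was fitted on.
#' @return list with `x` and `y` loading matrices (variables x modes).
#' @export
backproject <- function(result, X, Y) {
  X <- as.matrix(X)[result$complete_rows, , drop = FALSE]
  Y <- as.matrix(Y)[result$complete_rows, , drop = FALSE]
  if (nrow(X) != nrow(result$x_variates)) stopf("dimension mismatch with fitted result")
  if (ncol(X) != nrow(result$x_weights) || ncol(Y) != nrow(result$y_weights)) {
    stopf("dimension mismatch with fitted result")
  }
  list(x = stats::cor(X, result$x_variates),
       y = stats::cor(Y, result$y_variates))
}

#' Phase-wise CCA of Cognitive Indices against imaging burden
#'
#' Assembles, for one recovery phase, the participant x task Cognitive Index
#' matrix (missing cells completed with the phase's Bayesian-PCA posterior
#' means, so listwise deletion only removes participants without imaging) and
#' the lesion / white-matter burden matrix, then fits the CCA and its
#' permutation test.
#'
#' @param decomposition output of [decompose_all()].
#' @param meta participant-session metadata.
#' @param phase `"subacute"` or `"chronic"` (concurrent imaging exists from
#'   the subacute phase on).
#' @param n_perm,seed permutation settings.
#' @return list with the `fit` (`cca_result`), `permutation` test, `phase`,
#'   and the matrices used.
#' @export
cca_by_phase <- function(decomposition, meta, phase, n_perm = 9999L,
                         seed = 1L) {
  gf <- extract_g(decomposition, meta, phase, family = "cognitive_index")
  Xfull <- gf$fit$imputed  # standardized, missing cells completed
  ids <- names(gf$scores)
  sel <- select_phase_sessions(meta, phase)
  img <- sel[match(ids, sel$participant_id),
             c("lesion_volume", "wmh_volume"), drop = FALSE]
  Y <- as.matrix(img)
  rownames(Y) <- ids
  fit <- fit_cca(Xfull, Y)
  perm <- cca_permutation_test(Xfull, Y, n_perm = n_perm, seed = seed)
  list(phase = phase, fit = fit, permutation = perm, X = Xfull, Y = Y)
}
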