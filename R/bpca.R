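# Global-factor extraction over the participant x task matrix by an
# expectation-maximisation probabilistic PCA that tolerates missing entries,
# with an automatic-relevance-determination prior on the loadings (default
# hyperparameters are uninformative). Missing cells are handled in the
# E-step by conditioning each row's latent posterior on its observed entries
# only; no pre-imputation is ever done beyond the deterministic
# classical-PCA initialisation.

#' Fit an EM-based Bayesian PCA on a matrix with missing entries
#'
#' Fits the probabilistic PCA model `x = W z + e`, `z ~ N(0, I_q)`,
#' `e ~ N(0, sigma^2 I)` by expectation-maximisation, conditioning each row's
#' latent posterior on its observed entries, with a Bayesian
#' automatic-relevance-determination prior on the columns of `W`
#' (uninformative by default, so the fit coincides with maximum likelihood on
#' well-determined axes). Columns are standardised internally on their
#' observed values. Initialisation is deterministic: classical PCA of the
#' mean-imputed matrix, so repeated fits are identical without any seed.
#' Iteration stops when the largest absolute change in `W` falls below `tol`.
#'
#' Variance explained is model-based: component `k` accounts for
#' `(d_k^2 + sigma^2) / (sum_j d_j^2 + n_col * sigma^2)` of the total modelled
#' variance, where `d_k` are the singular values of the fitted `W`. On a
#' noiseless rank-1 matrix the first component therefore explains exactly 1.
#'
#' @param x numeric matrix (rows = participants, columns = variables), NAs
#'   allowed; at least 2 columns, each with at least 2 observed values.
#' @param n_components number of principal axes to estimate.
#' @param tol convergence tolerance on the loading matrix.
#' @param max_iter iteration cap; non-convergence is flagged on the result.
#' @param ard apply the automatic-relevance-determination update; disable to
#'   run plain maximum-likelihood probabilistic PCA.
#' @return Object of class `bpca_fit`: orthonormal `axes` (column space of
#'   `W`), `loadings` (axes scaled by component standard deviations, sign
#'   convention: mean loading positive per axis), `scores` (posterior-mean
#'   factor values per row), `variance_explained` per component, `sigma2`,
#'   `imputed` (completed standardised matrix), `center`/`scale`,
#'   `converged`, `n_iter`.
#' @export
fit_bpca <- function(x, n_components = 1L, tol = 1e-4, max_iter = 1000L,
                     ard = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stopf("at least 2 columns are required")
  obs <- !is.na(x)
  n_obs_col <- colSums(obs)
  if (any(n_obs_col == 0)) {
    bad <- colnames(x)[n_obs_col == 0] %||% which(n_obs_col == 0)
    stopf("column(s) with no observed values: %s", paste(bad, collapse = ", "))
  }
  if (any(n_obs_col < 2)) {
    bad <- colnames(x)[n_obs_col < 2] %||% which(n_obs_col < 2)
    stopf("column(s) with fewer than 2 observed values: %s",
          paste(bad, collapse = ", "))
  }
  all_na_row <- rowSums(obs) == 0
  if (any(all_na_row)) stopf("%d row(s) have no observed values", sum(all_na_row))

  n <- nrow(x)
  d <- ncol(x)
  q <- as.integer(n_components)
  if (q < 1 || q >= d) stopf("n_components must be in [1, ncol - 1]")

  ctr <- colMeans(x, na.rm = TRUE)
  scl <- apply(x, 2, stats::sd, na.rm = TRUE)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  x0 <- xs
  x0[!obs] <- 0

  # deterministic init: classical PCA on the mean-imputed (= zero-filled)
  # standardised matrix
  sv0 <- svd(x0, nu = 0, nv = q)
  ev <- (svd(x0, nu = 0, nv = 0)$d)^2 / max(1, n - 1)
  sigma2 <- if (length(ev) > q) mean(ev[(q + 1):length(ev)]) else 1e-4
  sigma2 <- max(sigma2, 1e-8)
  W <- sv0$v %*% diag(sqrt(pmax(ev[seq_len(q)] - sigma2, 1e-8)), q, q)

  n_total_obs <- sum(obs)
  Ez <- matrix(0, n, q)
  converged <- FALSE
  iter <- 0L
  alpha <- rep(0, q)
  for (it in seq_len(max_iter)) {
    iter <- it
    # E-step
    Cz <- vector("list", n)
    for (i in seq_len(n)) {
      o <- obs[i, ]
      Wo <- W[o, , drop = FALSE]
      Mi <- crossprod(Wo) + diag(sigma2, q)
      Mi_inv <- solve(Mi)
      Ez[i, ] <- Mi_inv %*% crossprod(Wo, xs[i, o])
      Cz[[i]] <- sigma2 * Mi_inv
    }
    if (ard) alpha <- d / (colSums(W^2) + 1e-10)
    # M-step (per variable, over rows where it is observed)
    W_new <- W
    for (j in seq_len(d)) {
      rows <- which(obs[, j])
      A <- diag(sigma2 * alpha, q, q)
      b <- numeric(q)
      for (i in rows) {
        A <- A + Cz[[i]] + tcrossprod(Ez[i, ])
        b <- b + xs[i, j] * Ez[i, ]
      }
      W_new[j, ] <- solve(A, b)
    }
    rss <- 0
    for (i in seq_len(n)) {
      o <- obs[i, ]
      Wo <- W_new[o, , drop = FALSE]
      pred <- as.numeric(Wo %*% Ez[i, ])
      rss <- rss + sum((xs[i, o] - pred)^2) +
        sum(diag(Wo %*% Cz[[i]] %*% t(Wo)))
    }
    sigma2_new <- max(rss / n_total_obs, 1e-10)
    delta <- max(abs(W_new - W))
    W <- W_new
    sigma2 <- sigma2_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("bpca did not converge; partial result returned")

  sw <- svd(W)
  axes <- sw$u
  comp_var <- sw$d^2 + sigma2
  total_var <- sum(sw$d^2) + d * sigma2
  scores <- (Ez %*% sw$v) %*% diag(sw$d, q, q)

  # sign convention: mean loading positive (ties broken by largest |loading|)
  for (k in seq_len(q)) {
    m <- mean(axes[, k])
    flip <- if (m != 0) m < 0 else axes[which.max(abs(axes[, k])), k] < 0
    if (flip) {
      axes[, k] <- -axes[, k]
      scores[, k] <- -scores[, k]
    }
  }
  loadings <- sweep(axes, 2, sqrt(comp_var), "*")
  rownames(axes) <- rownames(loadings) <- colnames(x)
  rownames(scores) <- rownames(x)

  imputed <- xs
  recon <- scores %*% t(axes)
  imputed[!obs] <- recon[!obs]

  structure(list(
    axes = axes, loadings = loadings, scores = scores,
    variance_explained = comp_var / total_var, sigma2 = sigma2,
    imputed = imputed, center = ctr, scale = scl,
    converged = converged, n_iter = iter, tol = tol
  ), class = "bpca_fit")
}

#' @export
print.bpca_fit <- function(x, ...) {
  cat(sprintf("<bpca_fit> %d components over %d variables; variance explained %s; %d EM iterations%s\n",
              ncol(x$axes), nrow(x$axes),
              paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
              x$n_iter, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

# Pick, per participant, the one session of `phase` closest to the phase's
# reference day; returns the meta rows selected.
select_phase_sessions <- function(meta, phase) {
  m <- meta[!is.na(meta$phase) & meta$phase == phase, , drop = FALSE]
  if (nrow(m) == 0) return(m)
  ref <- phase_reference_days[[phase]]
  m <- m[order(m$participant_id, abs(m$days_since_stroke - ref),
               m$session_index), , drop = FALSE]
  m[!duplicated(m$participant_id), , drop = FALSE]
}

#' Extract the global cognition factor for one recovery phase
#'
#' Assembles the participant x task matrix of a metric family for one
#' recovery phase (one session per participant: the session closest to the
#' phase's reference day of 4, 94 or 371 days post-stroke) and extracts its
#' first principal axis with [fit_bpca()]. Loadings follow the mean-positive
#' sign convention, so on well-formed batteries all tasks load positively and
#' higher scores mean better global cognition.
#'
#' @param metrics per-session metric table: the decomposition output (family
#'   `"cognitive_index"`) or the standard metrics (family
#'   `"standard_accuracy"`, scored as proportion correct).
#' @param meta participant-session metadata (for phase and day lookup).
#' @param phase `"acute"`, `"subacute"` or `"chronic"`.
#' @param family metric family to summarise.
#' @param min_rows refuse to fit below this many participants (an unstable
#'   factor is worse than none).
#' @return Object of class `global_factor`: `phase`, `metric_family`,
#'   named `loadings`, named participant `scores`, `variance_explained`,
#'   `n_participants`, `n_iter`, `converged`, plus the underlying `fit`.
#' @export
extract_g <- function(metrics, meta, phase,
                      family = c("cognitive_index", "standard_accuracy"),
                      min_rows = 10L) {
  family <- match.arg(family)
  sel <- select_phase_sessions(meta, phase)
  if (nrow(sel) < min_rows) {
    stopf("phase '%s' has %d participants with sessions; at least %d required",
          phase, nrow(sel), min_rows)
  }
  value <- if (family == "cognitive_index") {
    metrics$cognitive_index
  } else {
    metrics$accuracy_count / metrics$trial_count
  }
  key_sel <- paste(sel$participant_id, sel$session_index)
  key_met <- paste(metrics$participant_id, metrics$session_index)
  rows <- metrics[key_met %in% key_sel, , drop = FALSE]
  vals <- value[key_met %in% key_sel]

  tasks <- sort(unique(metrics$task_id))
  mat <- matrix(NA_real_, nrow(sel), length(tasks),
                dimnames = list(sel$participant_id, tasks))
  ri <- match(rows$participant_id, sel$participant_id)
  ci <- match(rows$task_id, tasks)
  mat[cbind(ri, ci)] <- vals

  keep <- rowSums(!is.na(mat)) > 0
  if (any(!keep)) {
    message(sum(!keep), " participant(s) with no task data dropped from ",
            phase, " factor")
    mat <- mat[keep, , drop = FALSE]
  }
  if (nrow(mat) < min_rows) {
    stopf("phase '%s' has %d usable rows; at least %d required",
          phase, nrow(mat), min_rows)
  }

  fit <- fit_bpca(mat, n_components = 1L)
  structure(list(
    phase = phase, metric_family = family,
    loadings = stats::setNames(fit$loadings[, 1], tasks),
    scores = stats::setNames(fit$scores[, 1], rownames(mat)),
    variance_explained = fit$variance_explained[1],
    n_participants = nrow(mat),
    n_iter = fit$n_iter, converged = fit$converged,
    fit = fit
  ), class = "global_factor")
}

#' @export
print.global_factor <- function(x, ...) {
  cat(sprintf("<global_factor> %s / %s: %d participants, variance explained %.1f%%\n",
              x$metric_family, x$phase, x$n_participants,
              100 * x$variance_explained))
  invisible(x)
}
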