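## Non-smooth non-negative matrix factorization (nsNMF) for mutational
## signature deconvolution.  The model is X ~ W S(theta) H, where the
## smoothing matrix S(theta) = (1-theta) I + (theta/k) J absorbs noise and
## drives both the basis (signatures) and the coefficients (exposures)
## towards sparseness.  Updates are the multiplicative Kullback-Leibler
## rules, applied with the smoothed partner matrix.

EPS_NMF <- 1e-12

#' Smoothing matrix of non-smooth NMF
#'
#' `S = (1 - theta) * I + (theta / k) * J` with `J` the all-ones matrix.
#' `theta = 0` gives the identity (classical NMF); `theta = 1` the uniform
#' averaging matrix. Rows (and columns) sum to 1 for every theta.
#'
#' @param k Number of signatures (matrix dimension).
#' @param theta Smoothing parameter in \[0, 1\].
#' @return A `k x k` matrix.
#' @export
smoothing_matrix <- function(k, theta) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) stop("k must be >= 1")
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 1) {
    stop("theta must lie in [0, 1]")
  }
  (1 - theta) * diag(k) + (theta / k) * matrix(1, k, k)
}

## Generalized KL divergence D(X || Y) = sum x log(x/y) - x + y.
kl_divergence <- function(X, Y) {
  Y <- pmax(Y, EPS_NMF)
  pos <- X > 0
  sum(X[pos] * log(X[pos] / Y[pos])) - sum(X) + sum(Y)
}

## One full multiplicative KL update sweep of (W, H) for X ~ W S H, with W
## kept column-stochastic throughout.  Because S is doubly stochastic,
## colSums(W) = 1 implies colSums(W S) = 1, so the constrained model is the
## probabilistic (PLSA-style) form of KL-NMF and each conditional update is
## an EM M-step: the divergence is non-increasing and the fitted W needs no
## post-hoc normalization.
nsnmf_update <- function(X, W, H, S) {
  ## update H against the smoothed basis W S (colSums(W S) = 1)
  WS <- W %*% S
  V <- X / pmax(WS %*% H, EPS_NMF)
  H <- H * crossprod(WS, V)
  ## update W against the smoothed coefficients S H, renormalizing columns
  SH <- S %*% H
  V <- X / pmax(W %*% SH, EPS_NMF)
  W <- W * (V %*% t(SH))
  W <- sweep(W, 2L, pmax(colSums(W), EPS_NMF), "/")
  list(W = W, H = H)
}

#' Fit a non-smooth NMF signature model
#'
#' Factorizes a nonnegative catalogue matrix `X` (96 context classes x
#' samples) as `W S(theta) H` by alternating multiplicative KL updates, with
#' the smoothing matrix interposed when updating each factor. The best of
#' `n_restarts` random initializations (by final divergence) is kept; the
#' basis columns are normalized to sum to 1 with a compensating rescale of
#' the exposures, which leaves the reconstruction `W S H` unchanged.
#'
#' @param X Nonnegative numeric matrix (contexts x samples).
#' @param k Number of signatures, `k < min(dim(X))`.
#' @param theta Smoothing parameter in \[0, 1\] (default 0.5).
#' @param n_restarts Random restarts (default 10).
#' @param max_iter Maximum update sweeps per restart (default 2000).
#' @param tol Relative divergence-change convergence threshold (default 1e-6).
#' @param seed Integer seed making the restarts reproducible.
#' @param init Optional list with `W` and `H` giving a fixed initialization
#'   (then `n_restarts` is ignored); used mainly for cross-checks.
#' @return An object of class `nsnmf_model`: list with `W` (96 x k, columns
#'   sum to 1), `H` (k x samples), `S`, `theta`, `k`, `divergence`,
#'   `history` (divergence per recorded sweep of the winning restart),
#'   `n_restarts`, `seed`, `converged`.
#' @export
nsnmf <- function(X, k, theta = 0.5, n_restarts = 10L, max_iter = 2000L,
                  tol = 1e-6, seed = 1L, init = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(X < 0)) stop("X must be finite and nonnegative")
  if (k >= min(dim(X))) stop("k must be smaller than both dimensions of X")
  S <- smoothing_matrix(k, theta)
  m <- nrow(X); n <- ncol(X)
  scale0 <- sum(X) / n

  run_one <- function(W, H) {
    hist <- numeric(0)
    d_prev <- kl_divergence(X, W %*% S %*% H)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      up <- nsnmf_update(X, W, H, S)
      W <- up$W; H <- up$H
      d <- kl_divergence(X, W %*% S %*% H)
      hist <- c(hist, d)
      if (d > d_prev + 1e-8 * (1 + abs(d_prev))) {
        warning("non-monotone divergence; stopping this restart")
        break
      }
      if (abs(d_prev - d) < tol * (1 + abs(d_prev))) {
        converged <- TRUE
        break
      }
      d_prev <- d
    }
    list(W = W, H = H, divergence = hist[length(hist)],
         history = hist, converged = converged)
  }

  norm_cols <- function(W) sweep(W, 2L, pmax(colSums(W), EPS_NMF), "/")
  best <- NULL
  if (!is.null(init)) {
    W0 <- as.matrix(init$W)
    best <- run_one(norm_cols(W0), as.matrix(init$H) * rep(colSums(W0), ncol(init$H)))
  } else {
    set.seed(seed)
    for (r in seq_len(n_restarts)) {
      W0 <- norm_cols(matrix(stats::runif(m * k, 0.1, 1), m, k))
      H0 <- matrix(stats::runif(k * n, 0.1, 1) * scale0 / k, k, n)
      fit <- run_one(W0, H0)
      if (is.null(best) || fit$divergence < best$divergence) best <- fit
    }
  }

  ## W is kept column-stochastic by the updates themselves; the reported
  ## normalization is therefore exact and leaves W S H untouched.
  Wn <- norm_cols(best$W)
  Hn <- best$H
  rownames(Wn) <- rownames(X)
  colnames(Hn) <- colnames(X)

  structure(list(W = Wn, H = Hn, S = S, theta = theta, k = k,
                 divergence = best$divergence, history = best$history,
                 n_restarts = if (is.null(init)) n_restarts else 1L,
                 seed = seed, converged = best$converged),
            class = "nsnmf_model")
}

#' @exportS3Method base::print
print.nsnmf_model <- function(x, ...) {
  cat(sprintf("Non-smooth NMF model: k = %d, theta = %.2f\n", x$k, x$theta))
  cat(sprintf("  %d contexts x %d samples, KL divergence %.4f (%s)\n",
              nrow(x$W), ncol(x$H), x$divergence,
              if (isTRUE(x$converged)) "converged" else "max_iter reached"))
  invisible(x)
}

#' Reconstruction of a fitted nsNMF model
#' @param model An `nsnmf_model`.
#' @return The fitted matrix `W S H`.
#' @export
nsnmf_reconstruction <- function(model) {
  model$W %*% model$S %*% model$H
}

#' Refit exposures of a catalogue against fixed signatures
#'
#' With the signature basis `W` held fixed (columns summing to 1), finds the
#' nonnegative mixture weights minimizing either the generalized KL
#' divergence or the squared error between the catalogue and `W h`, and
#' returns them as proportions summing to 1 — the fraction of the sample's
#' mutations attributable to each signature.
#'
#' @param W Signature matrix (96 x k, columns sum to 1).
#' @param catalog Numeric vector of 96 context counts (or a matrix with
#'   samples in columns, handled column-wise).
#' @param loss `"kl"` (default) or `"ls"`.
#' @param max_iter,tol Iteration controls of the multiplicative solver.
#' @return Numeric vector (or matrix) of exposure proportions; all-`NA` with
#'   a warning for a zero-count catalogue.
#' @export
fit_exposures <- function(W, catalog, loss = c("kl", "ls"),
                          max_iter = 5000L, tol = 1e-10) {
  loss <- match.arg(loss)
  W <- as.matrix(W)
  if (is.matrix(catalog) && ncol(catalog) > 1L) {
    return(apply(catalog, 2L, function(x)
      fit_exposures(W, x, loss = loss, max_iter = max_iter, tol = tol)))
  }
  x <- as.numeric(catalog)
  if (length(x) != nrow(W)) stop("catalog length must match nrow(W)")
  if (sum(x) == 0) {
    warning("zero-count catalogue: exposures undefined")
    return(stats::setNames(rep(NA_real_, ncol(W)), colnames(W)))
  }
  k <- ncol(W)
  h <- rep(sum(x) / k, k)
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    if (loss == "kl") {
      v <- x / pmax(as.numeric(W %*% h), EPS_NMF)
      h <- h * as.numeric(crossprod(W, v)) / pmax(colSums(W), EPS_NMF)
      obj <- kl_divergence(matrix(x), matrix(W %*% h))
    } else {
      wh <- pmax(as.numeric(W %*% h), EPS_NMF)
      h <- h * as.numeric(crossprod(W, x)) / pmax(as.numeric(crossprod(W, wh)), EPS_NMF)
      obj <- sum((x - as.numeric(W %*% h))^2)
    }
    if (abs(obj_prev - obj) < tol * (1 + abs(obj_prev))) break
    obj_prev <- obj
  }
  p <- h / sum(h)
  stats::setNames(p, colnames(W))
}

#' Hoyer sparseness of a nonnegative vector
#'
#' `(sqrt(n) - ||x||_1 / ||x||_2) / (sqrt(n) - 1)`: 1 for a one-hot vector,
#' 0 for a constant vector, `NA` for the zero vector (undefined).
#'
#' @param x Numeric vector.
#' @return Scalar in \[0, 1\] or `NA`.
#' @export
hoyer_sparseness <- function(x) {
  n <- length(x)
  l2 <- sqrt(sum(x^2))
  if (l2 == 0) return(NA_real_)
  (sqrt(n) - sum(abs(x)) / l2) / (sqrt(n) - 1)
}

#' Sparseness and orthogonality diagnostics of a fitted model
#'
#' @param model An `nsnmf_model`.
#' @return List with `W_sparseness` (per signature), `H_sparseness` (per
#'   exposure row), their means, and `mean_signature_correlation` (mean
#'   pairwise Pearson correlation between signature columns).
#' @export
sparseness_report <- function(model) {
  ws <- apply(model$W, 2L, hoyer_sparseness)
  hs <- apply(model$H, 1L, hoyer_sparseness)
  corr <- NA_real_
  if (model$k >= 2L) {
    cm <- stats::cor(model$W)
    corr <- mean(cm[upper.tri(cm)])
  }
  list(W_sparseness = ws, H_sparseness = hs,
       mean_W_sparseness = mean(ws, na.rm = TRUE),
       mean_H_sparseness = mean(hs, na.rm = TRUE),
       mean_signature_correlation = corr)
}

#' Greedy best cosine matching between two signature sets
#'
#' Matches estimated signature columns to reference columns by repeatedly
#' pairing the globally most-similar remaining pair (cosine similarity), a
#' maximum-weight matching adequate for the well-separated signatures used
#' in evaluation.
#'
#' @param W_est,W_ref Matrices with signatures in columns.
#' @return Data frame with `ref`, `est` (column indices) and `cosine`.
#' @export
match_signatures <- function(W_est, W_ref) {
  cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sim <- outer(seq_len(ncol(W_ref)), seq_len(ncol(W_est)),
               Vectorize(function(i, j) cs(W_ref[, i], W_est[, j])))
  out <- NULL
  while (any(is.finite(sim))) {
    ij <- arrayInd(which.max(sim), dim(sim))
    out <- rbind(out, data.frame(ref = ij[1L], est = ij[2L],
                                 cosine = sim[ij[1L], ij[2L]]))
    sim[ij[1L], ] <- -Inf
    sim[, ij[2L]] <- -Inf
  }
  out[order(out$ref), , drop = FALSE]
}
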