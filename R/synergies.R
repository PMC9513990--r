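# Muscle-synergy extraction by non-negative matrix factorization
# (multiplicative updates, Frobenius objective) with restarts and a
# variance-accounted-for rank selection.

nmf_mu <- function(V, k, max_iter = 500, tol = 1e-6) {
  m <- nrow(V); n <- ncol(V)
  eps <- .Machine$double.eps
  W <- matrix(stats::runif(m * k, 0.1, 1), m, k)
  H <- matrix(stats::runif(k * n, 0.1, 1), k, n)
  err_old <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10L == 0L) {
      err <- sum((V - W %*% H)^2)
      if (is.finite(err_old) && (err_old - err) <= tol * err_old) break
      err_old <- err
    }
  }
  list(W = W, H = H, sse = sum((V - W %*% H)^2))
}

#' Extract muscle synergies from EMG envelopes
#'
#' Non-negative matrix factorization `E ~ W H` of the envelope matrix
#' (muscles x samples) into spatial weights `W` (muscles x k) and temporal
#' activations `H` (k x samples), by multiplicative updates with restarts
#' (best of `n_restarts` by reconstruction error, deterministic under
#' `seed`). Reconstruction quality is the variance accounted for,
#' `VAF = 1 - SSE/SST` with `SST = ||E - mean(E)||_F^2` (grand-mean-centered
#' total sum of squares). When `vaf_target` is given instead of `k`, the rank
#' is the smallest k whose VAF reaches the target.
#'
#' @param envelopes Nonnegative envelope matrix, either muscles x samples or
#'   samples x muscles (muscle columns named; orientation detected from the
#'   muscle registry, otherwise columns are taken as muscles).
#' @param k Fixed synergy count; `NULL` selects the rank by `vaf_target`.
#' @param vaf_target VAF threshold for rank selection (default 0.90).
#' @param n_restarts Random restarts per rank.
#' @param seed RNG seed (restarts are seeded `seed + restart`).
#' @param max_iter,tol Multiplicative-update stopping rule (relative SSE
#'   change).
#' @return Object of class `ulb_synergies`: list with `W`, `H`, `k`, `vaf`,
#'   `vaf_by_k`.
#' @export
extract_synergies <- function(envelopes, k = NULL, vaf_target = 0.90,
                              n_restarts = 20, seed = 1, max_iter = 500,
                              tol = 1e-6) {
  E <- as.matrix(envelopes)
  if (any(E < 0)) stop("negative envelope values: conditioning bug upstream")
  # orient as muscles x samples
  if (!is.null(colnames(E)) && all(colnames(E) %in% target_muscles()))
    E <- t(E)
  else if (!is.null(rownames(E)) && all(rownames(E) %in% target_muscles())) {
    # already muscles x rows
  } else if (nrow(E) > ncol(E)) E <- t(E)
  m <- nrow(E)
  if (m < 2L) stop("need at least 2 muscles")
  sst <- sum((E - mean(E))^2)
  fit_rank <- function(kk) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- with_seed(seed + r, nmf_mu(E, kk, max_iter, tol))
      if (is.null(best) || fit$sse < best$sse) best <- fit
    }
    best
  }
  vaf_by_k <- numeric(0)
  if (!is.null(k)) {
    k <- as.integer(k)
    stopifnot(k >= 1L, k <= m)
    best <- fit_rank(k)
    vaf <- 1 - best$sse / sst
    vaf_by_k <- stats::setNames(vaf, k)
  } else {
    for (kk in seq_len(m)) {
      best <- fit_rank(kk)
      vaf <- 1 - best$sse / sst
      vaf_by_k <- c(vaf_by_k, stats::setNames(vaf, kk))
      k <- kk
      if (vaf >= vaf_target) break
    }
  }
  rownames(best$W) <- rownames(E)
  structure(list(W = best$W, H = best$H, k = k, vaf = vaf,
                 vaf_by_k = vaf_by_k), class = "ulb_synergies")
}

#' @export
print.ulb_synergies <- function(x, ...) {
  cat(sprintf("Muscle synergies: k = %d, VAF = %.3f (%d muscles x %d samples)\n",
              x$k, x$vaf, nrow(x$W), ncol(x$H)))
  invisible(x)
}

#' Match extracted synergy weights to a reference set
#'
#' Greedy best-match cosine similarity between columns of two spatial-weight
#' matrices (used for recovery checks against a known generator).
#'
#' @param W,W_ref muscles x k weight matrices.
#' @return numeric vector of matched cosine similarities (length k).
#' @export
synergy_cosine_match <- function(W, W_ref) {
  k <- ncol(W_ref)
  cosine <- function(a, b) sum(a * b) / (vnorm(a) * vnorm(b))
  sims <- outer(seq_len(ncol(W)), seq_len(k),
                Vectorize(function(i, j) cosine(W[, i], W_ref[, j])))
  out <- numeric(k)
  for (step in seq_len(k)) {
    best <- which(sims == max(sims), arr.ind = TRUE)[1, ]
    out[step] <- sims[best[1], best[2]]
    sims[best[1], ] <- -Inf
    sims[, best[2]] <- -Inf
  }
  out
}
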