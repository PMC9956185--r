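# Nonmetric multidimensional scaling by alternating isotonic regression
# (pool-adjacent-violators via stats::isoreg) and a Guttman/SMACOF
# configuration update, minimising Kruskal stress-1:
#   stress = sqrt( sum (dhat_ij - f(d_ij))^2 / sum dhat_ij^2 )
# where dhat are configuration distances and f the monotone disparities.

# stress-1 and disparities of a configuration X against dissimilarity order
nmds_stress_parts <- function(X, delta, ord, ut) {
  dd <- as.matrix(dist(X))[ut]
  dhat <- numeric(length(dd))
  dhat[ord] <- stats::isoreg(dd[ord])$yf
  ss_dd <- sum(dd^2)
  if (ss_dd <= 0) return(list(dd = dd, dhat = dhat, stress = 1))
  ss_dhat <- sum(dhat^2)
  if (ss_dhat > 0) dhat <- dhat * sqrt(ss_dd / ss_dhat)
  list(dd = dd, dhat = dhat, stress = sqrt(sum((dd - dhat)^2) / ss_dd))
}

#' Recompute Kruskal stress-1 from ordination coordinates
#'
#' @param coords samples-by-axes coordinate matrix.
#' @param d symmetric dissimilarity matrix (or `pairwise_matrix`) in the
#'   same sample order.
#' @return Stress-1 value.
#' @export
ordination_stress <- function(coords, d) {
  d <- as.matrix(d)
  ut <- upper.tri(d)
  delta <- d[ut]
  nmds_stress_parts(as.matrix(coords), delta, order(delta), ut)$stress
}

nmds_single <- function(X, delta, ord, ut, maxit, tol) {
  m <- nrow(X)
  prev <- Inf
  Xprev <- X
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    parts <- nmds_stress_parts(X, delta, ord, ut)
    if (parts$stress > prev + 1e-12) {    # safeguard: never accept an increase
      X <- Xprev
      break
    }
    trace <- c(trace, parts$stress)
    if (prev - parts$stress < tol) {
      converged <- TRUE
      break
    }
    prev <- parts$stress
    Xprev <- X
    # Guttman transform with current disparities
    w <- ifelse(parts$dd > 0, parts$dhat / parts$dd, 0)
    W <- matrix(0, m, m)
    W[ut] <- w
    W <- W + t(W)
    B <- diag(rowSums(W)) - W
    X <- B %*% X / m
    X <- scale(X, center = TRUE, scale = FALSE)
  }
  final <- nmds_stress_parts(X, delta, ord, ut)
  list(X = X, stress = final$stress, converged = converged, trace = trace)
}

#' Nonmetric multidimensional scaling
#'
#' Minimises Kruskal stress-1 with monotone (pool-adjacent-violators)
#' regression and iterative majorisation, over several restarts: the
#' first starts from the classical metric-MDS configuration, the rest
#' from seeded random configurations.  The best restart is returned.
#' Deterministic given `seed`.
#'
#' @param d symmetric dissimilarity matrix or `pairwise_matrix`.
#' @param k number of ordination axes (default 2).
#' @param restarts number of starts (default 50).
#' @param seed integer RNG seed.
#' @param maxit,tol iteration cap and stress-change convergence
#'   tolerance for each start.
#' @return An object of class `ordination`: list with centered `points`
#'   (samples x k), `stress`, `converged`, `seed`, and the per-iteration
#'   stress `trace` of the winning restart.
#' @export
nmds <- function(d, k = 2, restarts = 50, seed = 42, maxit = 500, tol = 1e-7) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12)
    stop("nmds needs a symmetric dissimilarity matrix", call. = FALSE)
  stopifnot(k >= 1, restarts >= 1)
  m <- nrow(d)
  ut <- upper.tri(d)
  delta <- d[ut]
  ord <- order(delta)
  scale0 <- max(delta)
  if (scale0 <= 0) scale0 <- 1
  best <- NULL
  for (r in seq_len(restarts)) {
    X0 <- if (r == 1) {
      cm <- suppressWarnings(stats::cmdscale(d, k = min(k, m - 1)))
      if (ncol(cm) < k) cm <- cbind(cm, matrix(0, m, k - ncol(cm)))
      cm + local_seed(derive_seed(seed, "jitter", r),
                      matrix(rnorm(m * k, sd = 1e-4 * scale0), m, k))
    } else {
      local_seed(derive_seed(seed, "restart", r),
                 matrix(runif(m * k, -scale0, scale0), m, k))
    }
    X0 <- scale(X0, center = TRUE, scale = FALSE)
    fit <- nmds_single(X0, delta, ord, ut, maxit, tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- scale(best$X, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  dimnames(pts) <- list(rownames(d), paste0("NMDS", seq_len(k)))
  structure(list(points = pts, stress = best$stress,
                 converged = best$converged, seed = seed,
                 trace = best$trace, restarts = restarts),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d samples, %d axes, stress = %.4f (%s)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
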