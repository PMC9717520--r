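#' SparCC basis correlations from compositional counts
#'
#' Infers correlations of (unobserved) basis abundances from compositional
#' count data via log-ratio variances. For each of `n_inner` iterations,
#' fractions are drawn from a Dirichlet posterior (pseudocount 1), the
#' variation matrix `T_ij = var(log(f_i / f_j))` is formed, basis variances
#' are solved from the sparsity-approximated linear system, and the most
#' strongly correlated pair above `exclusion_threshold` is iteratively
#' excluded from the system for `n_exclusion` rounds. The returned estimate
#' is the average over the inner iterations, clipped to \[-1, 1\] with a
#' unit diagonal.
#'
#' @param table a [count_table()] or samples x taxa count matrix.
#' @param n_inner Dirichlet resampling iterations (default 20).
#' @param n_exclusion strong-pair exclusion rounds (default 10).
#' @param exclusion_threshold |correlation| above which a pair may be
#'   excluded (default 0.1).
#' @param seed integer seed.
#' @return symmetric taxa x taxa correlation matrix.
#' @export
sparcc <- function(table, n_inner = 20, n_exclusion = 10,
                   exclusion_threshold = 0.1, seed = 1) {
  x <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  p <- ncol(x)
  if (p < 4L) stop("SparCC requires >=4 components")
  with_seed(seed, {
    acc <- matrix(0, p, p)
    for (it in seq_len(n_inner)) {
      # Dirichlet posterior draw of fractions, pseudocount 1
      g <- matrix(stats::rgamma(length(x), shape = x + 1), nrow(x), p)
      f <- g / rowSums(g)
      lf <- log(f)
      v <- stats::var(lf)
      d <- diag(v)
      tmat <- outer(d, d, `+`) - 2 * v    # variation matrix var(log f_i/f_j)
      acc <- acc + sparcc_basis(tmat, n_exclusion, exclusion_threshold)
    }
    r <- acc / n_inner
    r <- pmin(pmax((r + t(r)) / 2, -1), 1)
    diag(r) <- 1
    dimnames(r) <- list(colnames(x), colnames(x))
    r
  })
}

# Solve basis variances/correlations from a variation matrix with iterative
# exclusion of strongly correlated pairs (the SparCC sparsity heuristic).
sparcc_basis <- function(tmat, n_exclusion, exclusion_threshold) {
  p <- ncol(tmat)
  m <- matrix(1, p, p)
  diag(m) <- p - 1
  excluded <- matrix(FALSE, p, p)
  solve_rho <- function() {
    tvec <- rowSums(tmat * !excluded) - diag(tmat)
    omega <- tryCatch(solve(m, tvec), error = function(e) NULL)
    if (is.null(omega)) return(NULL)
    omega <- pmax(omega, 1e-10)
    rho <- (outer(omega, omega, `+`) - tmat) / (2 * sqrt(outer(omega, omega)))
    diag(rho) <- 1
    rho
  }
  rho <- solve_rho()
  if (is.null(rho)) return(diag(p))
  for (round in seq_len(n_exclusion)) {
    cand <- abs(rho)
    cand[excluded | upper.tri(cand, diag = TRUE)] <- 0
    worst <- which.max(cand)
    if (cand[worst] <= exclusion_threshold) break
    ij <- arrayInd(worst, dim(cand))
    i <- ij[1L]; j <- ij[2L]
    # never let a component's usable degree drop below 2
    deg <- rowSums(!excluded) - 1
    if (deg[i] <= 2 || deg[j] <= 2) break
    excluded[i, j] <- excluded[j, i] <- TRUE
    m[i, j] <- m[j, i] <- m[i, j] - 1
    m[i, i] <- m[i, i] - 1
    m[j, j] <- m[j, j] - 1
    new_rho <- solve_rho()
    if (is.null(new_rho)) break
    rho <- new_rho
  }
  rho
}

#' Bootstrap pseudo p-values for SparCC correlations
#'
#' The null distribution is generated by permuting each taxon's counts
#' across samples independently (breaking all associations while preserving
#' per-taxon margins) and rerunning [sparcc()]; the two-sided p-value uses
#' the add-one convention `p = (1 + #{|r_boot| >= |r_obs|}) / (n_boot + 1)`,
#' so the smallest attainable p is `1/(n_boot + 1)`.
#'
#' @inheritParams sparcc
#' @param n_boot bootstrap rounds (default 100).
#' @return list with `r` (observed correlation matrix), `p` (matrix of
#'   pseudo p-values), and `n_boot`.
#' @export
sparcc_bootstrap_p <- function(table, n_boot = 100, n_inner = 20,
                               n_exclusion = 10, exclusion_threshold = 0.1,
                               seed = 1) {
  x <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  r_obs <- sparcc(x, n_inner = n_inner, n_exclusion = n_exclusion,
                  exclusion_threshold = exclusion_threshold, seed = seed)
  count_ge <- matrix(0, ncol(x), ncol(x))
  with_seed(seed + 1L, {
    for (b in seq_len(n_boot)) {
      perm <- apply(x, 2L, sample)
      r_b <- sparcc(perm, n_inner = n_inner, n_exclusion = n_exclusion,
                    exclusion_threshold = exclusion_threshold,
                    seed = sample.int(.Machine$integer.max, 1L))
      count_ge <- count_ge + (abs(r_b) >= abs(r_obs))
    }
  })
  p <- (1 + count_ge) / (n_boot + 1)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(r_obs)
  list(r = r_obs, p = p, n_boot = n_boot)
}
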