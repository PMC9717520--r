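#' Co-inertia analysis of two sample-matched tables
#'
#' Maximizes the co-structure of two tables over the same samples. By
#' default each table is first replaced by its Bray-Curtis PCoA coordinates
#' (the route used for microbiota-vs-metabolome coupling); `via_pcoa =
#' FALSE` runs the analysis on the column-centered raw tables. The
#' cross-covariance SVD yields paired axes, and the overall similarity is
#' the RV coefficient
#' `trace(X'Y Y'X) / sqrt(trace((X'X)^2) trace((Y'Y)^2))` in \[0, 1\].
#'
#' @param x,y sample-matched tables (identical rownames in the same order);
#'   nonnegative abundances when `via_pcoa = TRUE`.
#' @param n_axes paired axes to return (default 2); PCoA coordinates are
#'   capped at the positive rank.
#' @param via_pcoa replace each table by Bray-Curtis PCoA coordinates first
#'   (default TRUE).
#' @return list with `rv`, `axes_x`, `axes_y` (paired sample scores),
#'   `singular_values`.
#' @export
coinertia <- function(x, y, n_axes = 2, via_pcoa = TRUE) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(rownames(x), rownames(y))) {
    bad <- union(setdiff(rownames(x), rownames(y)),
                 setdiff(rownames(y), rownames(x)))
    stop("sample mismatch between tables: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  prep <- function(m) {
    if (via_pcoa) {
      ord <- pcoa(bray_curtis(m), n_axes = max_pos_axes(m))
      m <- ord$coordinates
    }
    scale(m, center = TRUE, scale = FALSE)
  }
  xc <- prep(x); yc <- prep(y)
  rv <- rv_coefficient(xc, yc)
  sv <- svd(crossprod(xc, yc))
  k <- min(n_axes, length(sv$d))
  list(
    rv = rv,
    axes_x = xc %*% sv$u[, seq_len(k), drop = FALSE],
    axes_y = yc %*% sv$v[, seq_len(k), drop = FALSE],
    singular_values = sv$d
  )
}

max_pos_axes <- function(m) {
  d <- bray_curtis(m)
  ev <- pcoa(d, n_axes = 1)$eigenvalues
  max(1L, min(sum(ev > max(ev) * 1e-10), nrow(as.matrix(m)) - 1L))
}

rv_coefficient <- function(xc, yc) {
  xy <- crossprod(xc, yc)
  xx <- crossprod(xc)
  yy <- crossprod(yc)
  sum(xy^2) / sqrt(sum(xx^2) * sum(yy^2))
}

#' Monte Carlo test of co-inertia association
#'
#' Permutes the rows of `y` `n_permutations` times and recomputes the RV
#' coefficient; `p = (1 + #{rv_perm >= rv_obs}) / (n_permutations + 1)`.
#'
#' @inheritParams coinertia
#' @param n_permutations permutations (default 999).
#' @param seed integer seed.
#' @return list with `rv`, `p_value`, `n_permutations`.
#' @export
monte_carlo_test <- function(x, y, n_permutations = 999, seed = 1,
                             via_pcoa = TRUE) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(rownames(x), rownames(y))) stop("sample mismatch between tables")
  prep <- function(m) {
    if (via_pcoa) m <- pcoa(bray_curtis(m), n_axes = max_pos_axes(m))$coordinates
    scale(m, center = TRUE, scale = FALSE)
  }
  xc <- prep(x); yc <- prep(y)
  rv_obs <- rv_coefficient(xc, yc)
  n <- nrow(xc)
  count <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      rv_coefficient(xc, yc[sample(n), , drop = FALSE]) >= rv_obs
    }, logical(1)))
  })
  list(rv = rv_obs, p_value = (1 + count) / (n_permutations + 1),
       n_permutations = n_permutations)
}

#' Pairwise Spearman association between two feature tables
#'
#' Spearman rank correlations (mid-ranks on ties) between every feature of
#' `a` and every feature of `b`, with two-sided p-values from the
#' t-approximation and BH adjustment across the full matrix. Constant
#' features yield `NA` correlations. Significance stars use the
#' 0.05/0.01/0.001 thresholds on adjusted p.
#'
#' @param a,b samples x features matrices over matched samples.
#' @return list with matrices `rho`, `p`, `p_adjusted`, `stars`.
#' @export
spearman_association <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  n <- nrow(a)
  const_a <- apply(a, 2L, function(v) length(unique(v)) == 1L)
  const_b <- apply(b, 2L, function(v) length(unique(v)) == 1L)
  rho <- suppressWarnings(stats::cor(a, b, method = "spearman"))
  rho[const_a, ] <- NA_real_
  rho[, const_b] <- NA_real_
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1] <- 0
  p_adj <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p),
                  dimnames = dimnames(p))
  stars <- matrix("", nrow(p), ncol(p), dimnames = dimnames(p))
  stars[!is.na(p_adj) & p_adj < 0.05] <- "*"
  stars[!is.na(p_adj) & p_adj < 0.01] <- "**"
  stars[!is.na(p_adj) & p_adj < 0.001] <- "***"
  list(rho = rho, p = p, p_adjusted = p_adj, stars = stars)
}

#' Redundancy analysis of a genus-level table on constraints
#'
#' Thin wrapper over constrained ordination: the response table is regressed
#' on the (dummy-coded) constraints, the PCA of the fitted values gives the
#' constrained axes, and significance is assessed by permutation. Collinear
#' (aliased) constraints are dropped with a warning.
#'
#' @param y samples x genera relative-abundance matrix.
#' @param x data.frame of constraint variables (numeric or factors).
#' @param n_permutations permutations for the significance test
#'   (default 999).
#' @param seed integer seed.
#' @return list with `proportion_constrained`, `p_value`, `site_scores`,
#'   `fit` (the underlying `rda` object).
#' @export
rda_constrained <- function(y, x, n_permutations = 999, seed = 1) {
  y <- as.matrix(y)
  x <- as.data.frame(x)
  fit <- vegan::rda(y ~ ., data = x)
  # aliased (collinear) constraints are dropped by the fit; report them
  mm <- stats::model.matrix(~ ., data = x)[, -1, drop = FALSE]
  if (qr(mm)$rank < ncol(mm)) {
    warning("collinear constraint(s) dropped (model matrix rank ",
            qr(mm)$rank, " < ", ncol(mm), ")")
  }
  prop <- fit$CCA$tot.chi / fit$tot.chi
  pval <- with_seed(seed, {
    stats::anova(fit, permutations = n_permutations)$`Pr(>F)`[1L]
  })
  k <- min(2L, ncol(fit$CCA$u))
  list(
    proportion_constrained = prop,
    p_value = pval,
    site_scores = fit$CCA$u[, seq_len(k), drop = FALSE],
    fit = fit
  )
}
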