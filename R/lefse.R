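#' Kruskal-Wallis screen for differentially abundant features
#'
#' First stage of the LEfSe-style procedure: a per-feature two-sided
#' Kruskal-Wallis test (mid-rank tie correction) across groups. Constant
#' features get p = 1 and are retained with a warning.
#'
#' @param table a `relative_abundance` table (or samples x features matrix).
#' @param labels group factor over samples.
#' @param alpha screening level (default 0.05).
#' @return data.frame with `feature_id`, `kw_p`, `pass`.
#' @export
kruskal_screen <- function(table, labels, alpha = 0.05) {
  x <- abundance_matrix(table)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("need at least two groups")
  p <- apply(x, 2L, function(v) {
    if (length(unique(v)) == 1L) return(NA_real_)
    stats::kruskal.test(v, labels)$p.value
  })
  if (anyNA(p)) {
    warning(sum(is.na(p)), " constant feature(s) assigned p = 1")
    p[is.na(p)] <- 1
  }
  data.frame(feature_id = colnames(x), kw_p = unname(p),
             pass = unname(p < alpha), stringsAsFactors = FALSE)
}

# One LDA bootstrap round in the canonical LEfSe style: features are on the
# per-million scale; the per-feature effect size averages the feature's
# contribution along the (unit-norm) discriminant axis with its raw group
# mean difference.
lefse_lda_round <- function(x, labels) {
  lev <- levels(labels)
  mu <- rbind(colMeans(x[labels == lev[1L], , drop = FALSE]),
              colMeans(x[labels == lev[2L], , drop = FALSE]))
  raw_diff <- mu[1L, ] - mu[2L, ]
  w_unit <- tryCatch({
    # small jitter keeps the within-class covariance non-singular
    xj <- x + matrix(stats::rnorm(length(x), 0, 1e-6 * max(1, mean(abs(x)))),
                     nrow(x), ncol(x))
    fit <- suppressWarnings(MASS::lda(xj, grouping = labels, tol = 1e-10))
    w <- fit$scaling[, 1L]
    w / sqrt(sum(w^2))
  }, error = function(e) NULL)
  if (is.null(w_unit)) {
    coeff <- abs(raw_diff)
  } else {
    proj_gap <- abs(sum(w_unit * mu[1L, ]) - sum(w_unit * mu[2L, ]))
    coeff <- abs(w_unit * proj_gap)
  }
  (coeff + abs(raw_diff)) / 2
}

#' Bootstrap LDA effect sizes
#'
#' Second stage of the LEfSe-style procedure. Relative abundances are put on
#' the canonical per-million scale so that a 10^6-fold group contrast maps
#' near score 6; for each of `n_boot` bootstrap rounds a fraction
#' `subsample_frac` of each class is drawn, a one-axis linear discriminant is
#' fitted, and the per-feature effect size is the average of the
#' discriminant-axis contribution and the raw group-mean difference. The
#' final score is `log10(1 + mean bootstrap effect)`.
#'
#' @param table a `relative_abundance` table (or matrix on \[0, 1\] scale).
#' @param labels two-group factor (for more levels, use one-vs-all
#'   externally).
#' @param n_boot bootstrap rounds (default 30).
#' @param subsample_frac per-class subsampling fraction (default 2/3).
#' @param seed integer seed.
#' @return data.frame with `feature_id`, `lda_score`, `enriched_group`.
#' @export
lda_effect_size <- function(table, labels, n_boot = 30, subsample_frac = 2 / 3,
                            seed = 1) {
  x <- abundance_matrix(table) * 1e6
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("lda_effect_size expects exactly two groups")
  lev <- levels(labels)
  idx1 <- which(labels == lev[1L]); idx2 <- which(labels == lev[2L])
  k1 <- max(2L, ceiling(length(idx1) * subsample_frac))
  k2 <- max(2L, ceiling(length(idx2) * subsample_frac))
  effects <- with_seed(seed, {
    rounds <- matrix(NA_real_, n_boot, ncol(x))
    for (b in seq_len(n_boot)) {
      for (try in seq_len(10L)) {
        take <- c(sample(idx1, k1), sample(idx2, k2))
        sub <- x[take, , drop = FALSE]
        sub_lab <- droplevels(labels[take])
        if (nlevels(sub_lab) == 2L) break
        if (try == 10L) stop("could not draw a two-class bootstrap sample")
      }
      rounds[b, ] <- lefse_lda_round(sub, sub_lab)
    }
    colMeans(rounds)
  })
  mu1 <- colMeans(x[idx1, , drop = FALSE])
  mu2 <- colMeans(x[idx2, , drop = FALSE])
  data.frame(
    feature_id = colnames(x),
    lda_score = log10(1 + pmax(effects, 0)),
    enriched_group = ifelse(mu1 >= mu2, lev[1L], lev[2L]),
    stringsAsFactors = FALSE
  )
}

#' LEfSe-style differential abundance
#'
#' Composition of the Kruskal-Wallis screen and the bootstrap LDA effect
#' size; a feature passes iff `kw_p < p_cut` and `lda_score > lda_cut`
#' (defaults 0.05 and 2.0). Results are sorted by enriched group and
#' decreasing score.
#'
#' @inheritParams lda_effect_size
#' @param lda_cut LDA score threshold (default 2.0).
#' @param p_cut screening p threshold (default 0.05).
#' @return data.frame with `feature_id`, `kw_p`, `lda_score`,
#'   `enriched_group`, `passes`.
#' @export
run_lefse <- function(table, labels, lda_cut = 2.0, p_cut = 0.05,
                      n_boot = 30, subsample_frac = 2 / 3, seed = 1) {
  screen <- suppressWarnings(kruskal_screen(table, labels, alpha = p_cut))
  scores <- lda_effect_size(table, labels, n_boot = n_boot,
                            subsample_frac = subsample_frac, seed = seed)
  out <- merge(screen[, c("feature_id", "kw_p")], scores, by = "feature_id")
  out$passes <- out$kw_p < p_cut & out$lda_score > lda_cut
  out <- out[order(out$enriched_group, -out$lda_score), ]
  rownames(out) <- NULL
  out
}
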