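#' Construct a peak-intensity matrix
#'
#' Samples x peaks nonnegative intensities with explicit `NA` for missing
#' values and a per-sample QC flag (pooled quality-control injections are
#' kept apart from biological samples in every downstream rule).
#'
#' @param intensities numeric matrix, samples in rows, peaks in columns,
#'   with dimnames; `NA` marks a missing peak.
#' @param is_qc logical vector flagging QC samples; defaults to rownames
#'   starting with `"QC_"`.
#' @return an object of class `peak_matrix`.
#' @export
peak_matrix <- function(intensities, is_qc = NULL) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    stop("intensities must carry sample and peak names")
  }
  if (any(intensities < 0, na.rm = TRUE)) stop("negative intensities are not allowed")
  if (is.null(is_qc)) is_qc <- startsWith(rownames(intensities), "QC_")
  stopifnot(length(is_qc) == nrow(intensities))
  structure(list(intensities = intensities, is_qc = as.logical(is_qc)),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("peak_matrix: %d biological + %d QC samples x %d peaks (%.1f%% missing)\n",
              sum(!x$is_qc), sum(x$is_qc), ncol(x$intensities),
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' Filter peaks by missingness and impute remnants
#'
#' A peak is removed iff it is missing in more than `bio_missing_cut` of the
#' biological samples OR more than `qc_missing_cut` of the QC samples
#' (defaults 80% and 50%). Remaining missing values are imputed with half
#' the peak's minimum observed intensity, a common metabolomics default for
#' values below the detection limit.
#'
#' @param m a [peak_matrix()].
#' @param bio_missing_cut,qc_missing_cut missingness fractions in \[0, 1\].
#' @return the filtered, imputed [peak_matrix()] with attribute `"removed"`
#'   logging each removed peak, and `"imputed"` counting imputations per
#'   peak.
#' @export
filter_peaks <- function(m, bio_missing_cut = 0.80, qc_missing_cut = 0.50) {
  stopifnot(inherits(m, "peak_matrix"))
  if (bio_missing_cut < 0 || bio_missing_cut > 1 ||
      qc_missing_cut < 0 || qc_missing_cut > 1) stop("cuts must lie in [0, 1]")
  bio <- m$intensities[!m$is_qc, , drop = FALSE]
  qc <- m$intensities[m$is_qc, , drop = FALSE]
  bio_miss <- colMeans(is.na(bio))
  if (nrow(qc) == 0L) {
    warning("no QC samples; QC missingness rule skipped")
    qc_miss <- rep(0, ncol(m$intensities))
  } else {
    qc_miss <- colMeans(is.na(qc))
  }
  drop <- bio_miss > bio_missing_cut | qc_miss > qc_missing_cut
  kept <- m$intensities[, !drop, drop = FALSE]
  n_imputed <- colSums(is.na(kept))
  for (j in which(n_imputed > 0L)) {
    obs <- kept[, j]
    fill <- min(obs, na.rm = TRUE) / 2
    kept[is.na(obs), j] <- fill
  }
  out <- peak_matrix(kept, m$is_qc)
  attr(out, "removed") <- data.frame(
    peak_id = colnames(m$intensities)[drop],
    bio_missing = unname(bio_miss[drop]),
    qc_missing = unname(qc_miss[drop]),
    stringsAsFactors = FALSE
  )
  attr(out, "imputed") <- n_imputed
  out
}

#' Total-intensity normalization
#'
#' Scales every sample so its total peak intensity equals the cohort median
#' total, removing injection-amount differences while preserving within-
#' sample peak ratios. Run after [filter_peaks()] (no missing values
#' allowed).
#'
#' @param m a [peak_matrix()] without missing values.
#' @return the normalized [peak_matrix()].
#' @export
tic_normalize <- function(m) {
  stopifnot(inherits(m, "peak_matrix"))
  if (anyNA(m$intensities)) stop("run filter_peaks first: missing values present")
  totals <- rowSums(m$intensities)
  if (any(totals == 0)) {
    stop("zero-total sample(s): ",
         paste(rownames(m$intensities)[totals == 0], collapse = ", "))
  }
  target <- stats::median(totals)
  peak_matrix(m$intensities * (target / totals), m$is_qc)
}

#' OPLS-DA with VIP-based metabolite selection
#'
#' Orthogonal projection to latent structures discriminant analysis:
#' `n_orth` orthogonal components (orthogonal signal correction against the
#' class vector) are removed from the unit-variance-scaled data, a single
#' predictive PLS component is fitted, and VIP is computed on that
#' predictive component (so `mean(VIP^2) = 1` identically). Univariate
#' two-sided t-tests with BH adjustment complete the selection rule
#' `VIP > 1 & adjusted p < 0.05`.
#'
#' @param m a [peak_matrix()] (QC samples are ignored) or a samples x peaks
#'   matrix.
#' @param labels two-group factor over the biological samples.
#' @param n_orth number of orthogonal components to remove (default 1).
#' @return list with `selection` (data.frame: `peak_id`, `vip`, `t_p`,
#'   `t_p_adjusted`, `selected`), `scores` (per-sample predictive and first
#'   orthogonal score), and `r2y` (class variance explained by the
#'   predictive component).
#' @export
oplsda_vip <- function(m, labels, n_orth = 1) {
  x <- if (inherits(m, "peak_matrix")) {
    m$intensities[!m$is_qc, , drop = FALSE]
  } else {
    as.matrix(m)
  }
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("OPLS-DA requires exactly two groups")
  if (any(table(labels) < 3L)) stop("each group needs at least 3 samples")
  stopifnot(nrow(x) == length(labels))
  y <- ifelse(labels == levels(labels)[1L], 1, -1)
  y <- y - mean(y)
  sds <- apply(x, 2L, stats::sd)
  sds[sds == 0] <- 1
  xs <- scale(x, center = TRUE, scale = sds)
  t_orth <- matrix(0, nrow(x), 0)
  for (k in seq_len(n_orth)) {
    w <- drop(crossprod(xs, y)); w <- w / sqrt(sum(w^2))
    t_pred <- drop(xs %*% w)
    p <- drop(crossprod(xs, t_pred)) / sum(t_pred^2)
    w_o <- p - drop(crossprod(w, p)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) break
    w_o <- w_o / nw
    t_o <- drop(xs %*% w_o)
    p_o <- drop(crossprod(xs, t_o)) / sum(t_o^2)
    xs <- xs - tcrossprod(t_o, p_o)
    t_orth <- cbind(t_orth, t_o)
  }
  w <- drop(crossprod(xs, y)); w <- w / sqrt(sum(w^2))
  t_pred <- drop(xs %*% w)
  q <- sum(y * t_pred) / sum(t_pred^2)
  r2y <- (q^2 * sum(t_pred^2)) / sum(y^2)
  vip <- sqrt(ncol(x)) * abs(w)  # single predictive component: ||w|| = 1
  t_p <- apply(x, 2L, function(v) {
    if (stats::sd(v[labels == levels(labels)[1L]]) == 0 &&
        stats::sd(v[labels == levels(labels)[2L]]) == 0) return(1)
    tryCatch(stats::t.test(v ~ labels)$p.value, error = function(e) 1)
  })
  # BH across all peaks: adjusting only within the VIP > 1 subset would be
  # selection-biased (VIP correlates with the t statistic under the null)
  t_adj <- stats::p.adjust(t_p, method = "BH")
  list(
    selection = data.frame(
      peak_id = colnames(x), vip = unname(vip), t_p = unname(t_p),
      t_p_adjusted = unname(t_adj),
      selected = unname(vip > 1 & t_adj < 0.05),
      stringsAsFactors = FALSE
    ),
    scores = data.frame(
      sample_id = rownames(x), t_pred = t_pred,
      t_orth1 = if (ncol(t_orth) > 0) t_orth[, 1L] else 0,
      stringsAsFactors = FALSE
    ),
    r2y = r2y
  )
}

#' Biweight midcorrelation
#'
#' Robust correlation replacing means/SDs with medians and tricube weights
#' (robustness constant 9). Columns whose median absolute deviation is zero
#' fall back to Pearson correlation for the affected pairs.
#'
#' @param x samples x features matrix (or a vector with `y`).
#' @param y optional second vector/matrix.
#' @return correlation matrix (or scalar for two vectors).
#' @export
bicor <- function(x, y = NULL) {
  xm <- as.matrix(x)
  transform_cols <- function(m) {
    med <- apply(m, 2L, stats::median)
    mad_raw <- apply(abs(sweep(m, 2L, med)), 2L, stats::median)
    fallback <- mad_raw == 0
    out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
    for (j in seq_len(ncol(m))) {
      v <- m[, j] - med[j]
      if (fallback[j]) {
        v <- m[, j] - mean(m[, j])
        s <- sqrt(sum(v^2))
        out[, j] <- if (s > 0) v / s else 0
      } else {
        u <- v / (9 * mad_raw[j])
        w <- (1 - u^2)^2 * (abs(u) < 1)
        a <- v * w
        s <- sqrt(sum(a^2))
        out[, j] <- if (s > 0) a / s else 0
      }
    }
    out
  }
  xt <- transform_cols(xm)
  if (is.null(y)) {
    r <- crossprod(xt)
  } else {
    yt <- transform_cols(as.matrix(y))
    r <- crossprod(xt, yt)
  }
  pmin(pmax(r, -1), 1)
}

#' Detect coabundance modules (signed bicor/TOM clustering)
#'
#' Standardized peaks are correlated with [bicor()], turned into a signed
#' adjacency `((1 + r) / 2)^beta`, converted to topological overlap, and the
#' TOM dissimilarity tree (average linkage) is cut at a fixed height.
#' Clusters below `min_size` are relabeled `"grey"`; grey peaks are the
#' "not coexpressed with any module" set and are excluded from downstream
#' module tests. Each module gets a unit-norm eigenmetabolite (first
#' principal component of its standardized peaks), sign-oriented to
#' correlate positively with the module mean profile. Module labels are
#' `"M01"`, `"M02"`, ... by decreasing size.
#'
#' @param m a [peak_matrix()] (biological samples only are used) or a
#'   samples x peaks matrix.
#' @param beta soft-threshold power (default 8, the scale-free topology
#'   choice).
#' @param min_size minimum module size (default 5).
#' @param cut_height static tree-cut height on the TOM dissimilarity
#'   (default 0.75).
#' @return list with `assignment` (data.frame `peak_id`, `module`),
#'   `eigenmetabolites` (samples x modules matrix), `variance_explained`
#'   (per module), and the parameters used.
#' @export
coabundance_modules <- function(m, beta = 8, min_size = 5, cut_height = 0.75) {
  x <- if (inherits(m, "peak_matrix")) {
    m$intensities[!m$is_qc, , drop = FALSE]
  } else {
    as.matrix(m)
  }
  if (anyNA(x)) stop("missing values: run filter_peaks first")
  if (ncol(x) < min_size) stop("fewer peaks than min_size")
  constant <- apply(x, 2L, function(v) length(unique(v)) == 1L)
  if (any(constant)) {
    warning(sum(constant), " constant peak(s) assigned to grey")
  }
  work <- x[, !constant, drop = FALSE]
  r <- bicor(work)
  adj <- ((1 + r) / 2)^beta
  diag(adj) <- 1
  k <- colSums(adj) - 1
  num <- adj %*% adj - adj   # = sum_{k != i,j} a_ik a_kj + a_ij   (unit diagonal)
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- num / denom
  diag(tom) <- 1
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_size]
  module <- rep("grey", ncol(x))
  names(module) <- colnames(x)
  ord <- keep[order(-sizes[keep])]
  for (i in seq_along(ord)) {
    module[colnames(work)[cl == as.integer(ord[i])]] <- sprintf("M%02d", i)
  }
  mods <- sort(setdiff(unique(module), "grey"))
  eig <- matrix(NA_real_, nrow(x), length(mods),
                dimnames = list(rownames(x), mods))
  varex <- stats::setNames(numeric(length(mods)), mods)
  for (mod in mods) {
    sub <- scale(x[, module == mod, drop = FALSE])
    sv <- svd(sub, nu = 1, nv = 0)
    e <- sv$u[, 1L]
    if (stats::cor(e, rowMeans(sub)) < 0) e <- -e
    eig[, mod] <- e
    varex[mod] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  list(assignment = data.frame(peak_id = names(module), module = unname(module),
                               stringsAsFactors = FALSE),
       eigenmetabolites = eig, variance_explained = varex,
       beta = beta, min_size = min_size, cut_height = cut_height)
}

#' Compare module abundance between two groups
#'
#' Two-sided Wilcoxon rank-sum test on each module's eigenmetabolite values
#' between the two groups, BH-adjusted across modules. Grey (unassigned)
#' peaks are excluded by construction.
#'
#' @param modules result of [coabundance_modules()].
#' @param labels two-group factor over the biological samples.
#' @return data.frame with `module`, `p`, `p_adjusted`.
#' @export
compare_module_abundance <- function(modules, labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("need exactly two groups")
  eig <- modules$eigenmetabolites
  stopifnot(nrow(eig) == length(labels))
  p <- apply(eig, 2L, function(e) {
    suppressWarnings(stats::wilcox.test(e ~ labels)$p.value)
  })
  data.frame(module = colnames(eig), p = unname(p),
             p_adjusted = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}
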