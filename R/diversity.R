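#' Per-sample alpha diversity
#'
#' Richness (observed taxa), Shannon entropy in nats, and the Gini-Simpson
#' index `1 - sum(p^2)` (inverse Simpson `1/sum(p^2)` available via
#' `simpson_variant`), computed from a (preferably rarefied) count table.
#'
#' @param table a [count_table()].
#' @param simpson_variant `"gini"` (default, `1 - sum(p^2)`) or
#'   `"inverse"` (`1 / sum(p^2)`).
#' @return data.frame with columns `sample_id`, `richness`, `shannon`,
#'   `simpson`.
#' @export
alpha_diversity <- function(table, simpson_variant = c("gini", "inverse")) {
  stopifnot(inherits(table, "count_table"))
  simpson_variant <- match.arg(simpson_variant)
  ls <- library_sizes(table)
  if (any(ls == 0)) {
    stop("zero-sum sample(s): ", paste(names(ls)[ls == 0], collapse = ", "))
  }
  if (length(unique(ls)) > 1L) {
    warning("unequal library sizes; rarefy before comparing alpha diversity")
  }
  x <- table$counts
  data.frame(
    sample_id = rownames(x),
    richness = as.integer(rowSums(x > 0)),
    shannon = unname(vegan::diversity(x, index = "shannon")),
    simpson = unname(vegan::diversity(
      x, index = if (simpson_variant == "gini") "simpson" else "invsimpson")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Bray-Curtis distance matrix
#'
#' `d(a, b) = sum |a_i - b_i| / sum (a_i + b_i)` over taxa, on counts or
#' relative abundances.
#'
#' @param table a [count_table()], `relative_abundance`, or plain numeric
#'   matrix (samples x features).
#' @return a `dist` object with sample labels.
#' @export
bray_curtis <- function(table) {
  x <- abundance_matrix(table)
  if (nrow(x) < 2L) stop("need at least two samples")
  if (any(rowSums(x) == 0)) stop("all-zero sample(s) make Bray-Curtis undefined")
  vegan::vegdist(x, method = "bray")
}

abundance_matrix <- function(table) {
  if (inherits(table, "count_table")) return(table$counts)
  if (inherits(table, "relative_abundance")) return(table$values)
  as.matrix(table)
}

#' Principal coordinate analysis
#'
#' Classical metric scaling (Gower double-centering + eigendecomposition) of
#' a distance matrix. Negative eigenvalues are retained in the report but
#' excluded from the proportion-explained denominator; no Lingoes/Cailliez
#' correction is applied.
#'
#' @param d a `dist` object or square symmetric matrix.
#' @param n_axes number of axes to return (truncated to the positive rank
#'   with a warning when it exceeds it).
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   nonincreasing), and `proportion_explained` (per returned axis, relative
#'   to the sum of positive eigenvalues).
#' @export
pcoa <- function(d, n_axes = 2) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  g <- -0.5 * dm^2
  g <- sweep(g, 1L, rowMeans(g))
  g <- sweep(g, 2L, colMeans(g))
  g <- g + mean(-0.5 * dm^2)
  eig <- eigen(g, symmetric = TRUE)
  pos <- which(eig$values > max(eig$values) * 1e-10)
  if (n_axes > length(pos)) {
    warning("n_axes exceeds the positive rank; truncating to ", length(pos))
    n_axes <- length(pos)
  }
  take <- seq_len(n_axes)
  coords <- eig$vectors[, take, drop = FALSE] %*%
    diag(sqrt(eig$values[take]), n_axes, n_axes)
  dimnames(coords) <- list(rownames(dm), paste0("Axis", take))
  list(
    coordinates = coords,
    eigenvalues = eig$values,
    proportion_explained = eig$values[take] / sum(eig$values[pos])
  )
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate ANOVA (adonis-style partition of the distance
#' matrix's sum of squares) with the add-one permutation p-value
#' `p = (1 + #{F_perm >= F_obs}) / (n_permutations + 1)`. Permutations are
#' unrestricted by default; a `strata` factor restricts them within blocks
#' (e.g. litters).
#'
#' @param d a `dist` or square symmetric matrix.
#' @param labels group factor, one level per sample.
#' @param n_permutations number of permutations (default 999).
#' @param strata optional blocking factor for restricted permutation.
#' @param seed integer seed.
#' @return list with `pseudo_F`, `R2`, `p_value`, `n_permutations`.
#' @export
permanova <- function(d, labels, n_permutations = 999, strata = NULL, seed = 1) {
  d <- stats::as.dist(d)
  labels <- as.factor(labels)
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L)) {
    stop("group(s) of size 1: ", paste(names(tab)[tab < 2], collapse = ", "))
  }
  df <- data.frame(group = labels)
  ctrl <- permute::how(nperm = n_permutations)
  if (!is.null(strata)) {
    permute::setBlocks(ctrl) <- as.factor(strata)
  }
  fit <- with_seed(seed, vegan::adonis2(d ~ group, data = df, permutations = ctrl))
  list(
    pseudo_F = fit$F[1L],
    R2 = fit$R2[1L],
    p_value = fit$`Pr(>F)`[1L],
    n_permutations = n_permutations
  )
}

#' Within-group pairwise distances and a two-group contrast
#'
#' Extracts all intra-group pairwise distances per group (groups with fewer
#' than two samples are excluded with a warning) and, when exactly two
#' groups remain, compares them with a two-sided Wilcoxon rank-sum test.
#'
#' @param d a `dist` or square symmetric matrix with sample labels.
#' @param labels group factor over samples (in `d` order).
#' @return list with `distances` (named list of numeric vectors) and
#'   `wilcoxon_p` (two-group case, otherwise `NA`).
#' @export
within_group_distances <- function(d, labels) {
  dm <- as.matrix(d)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("need at least two groups")
  out <- list()
  for (g in levels(labels)) {
    idx <- which(labels == g)
    if (length(idx) < 2L) {
      warning("group '", g, "' has fewer than two samples; excluded")
      next
    }
    sub <- dm[idx, idx]
    out[[g]] <- sub[lower.tri(sub)]
  }
  wilcoxon_p <- NA_real_
  if (length(out) == 2L) {
    wilcoxon_p <- suppressWarnings(
      stats::wilcox.test(out[[1L]], out[[2L]], alternative = "two.sided")$p.value
    )
  }
  list(distances = out, wilcoxon_p = wilcoxon_p)
}

#' Scheirer-Ray-Hare rank test for a two-factor layout
#'
#' Nonparametric alternative to two-way ANOVA: mid-ranks of the pooled
#' response are pushed through the two-way sum-of-squares partition;
#' `H = SS_effect / MS_total`, tie-corrected, is referred to a chi-square
#' distribution with the effect's degrees of freedom. With a single-level
#' second factor the main-effect H reduces exactly to Kruskal-Wallis.
#'
#' @param values numeric response.
#' @param factor_a,factor_b crossed factors (every cell must be nonempty).
#' @return data.frame with one row per effect (`A`, `B`, `A:B`): `df`, `H`,
#'   `p_value`.
#' @export
scheirer_ray_hare <- function(values, factor_a, factor_b) {
  a <- droplevels(as.factor(factor_a))
  b <- droplevels(as.factor(factor_b))
  stopifnot(length(values) == length(a), length(values) == length(b))
  if (any(table(a, b) == 0L)) stop("every factor cell must be nonempty")
  r <- rank(values)
  n <- length(r)
  ms_total <- n * (n + 1) / 12
  ties <- table(values)
  tie_correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  ss <- c(A = 0, B = 0, `A:B` = 0)
  df <- c(A = nlevels(a) - 1L, B = nlevels(b) - 1L,
          `A:B` = (nlevels(a) - 1L) * (nlevels(b) - 1L))
  if (tie_correction > 0) {
    fit <- if (nlevels(a) > 1L && nlevels(b) > 1L) {
      stats::anova(stats::lm(r ~ a * b))
    } else if (nlevels(a) > 1L) {
      stats::anova(stats::lm(r ~ a))
    } else if (nlevels(b) > 1L) {
      stats::anova(stats::lm(r ~ b))
    } else {
      NULL
    }
    if (!is.null(fit)) {
      rn <- rownames(fit)
      for (term in c(a = "a", b = "b", ab = "a:b")) {
        key <- c(a = "A", b = "B", `a:b` = "A:B")[[term]]
        if (term %in% rn) ss[[key]] <- fit[term, "Sum Sq"]
      }
    }
  }
  h <- if (tie_correction > 0) ss / ms_total / tie_correction else ss * 0
  p <- rep(1, length(h))
  pos <- df > 0L & h > 0
  p[pos] <- stats::pchisq(h[pos], df[pos], lower.tail = FALSE)
  data.frame(effect = names(ss), df = unname(df), H = unname(h),
             p_value = unname(p), stringsAsFactors = FALSE, row.names = NULL)
}
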