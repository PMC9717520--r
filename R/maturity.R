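#' Select age-discriminatory taxa by cross-validated random forest
#'
#' Ranks taxa by random-forest importance for regressing chronological age
#' on the reference (control) group, then computes repeated k-fold
#' cross-validation error for nested taxon subsets in importance order. The
#' selected set size is the global minimum of the mean CV error curve
#' (a 1-SE rule is available via `one_se`).
#'
#' @param table a `relative_abundance` table (or samples x taxa matrix).
#' @param meta sample metadata with `sample_id`, `age_days`, `diet_group`,
#'   `oral_group`.
#' @param reference_group `"<diet>_<oral>"` label of the reference arm
#'   (default `"control_Nonoral"`: neither dietary supplementation nor oral
#'   dosing).
#' @param n_folds CV folds (default 10; reduced with a warning when the
#'   reference has fewer than `2 * n_folds` samples).
#' @param n_repeats CV repeats (default 5).
#' @param subset_sizes subset sizes to scan (default `1:min(30, n_taxa)`).
#' @param ntree_cv trees per CV fit (default 100; the final model uses 500).
#' @param one_se use the 1-SE rule instead of the global minimum.
#' @param seed integer seed.
#' @return list with `selected_taxa`, `ranking` (all taxa by importance),
#'   `cv_curve` (data.frame `size`, `cv_error`, `cv_se`).
#' @export
select_age_taxa <- function(table, meta, reference_group = "control_Nonoral",
                            n_folds = 10, n_repeats = 5, subset_sizes = NULL,
                            ntree_cv = 100, one_se = FALSE, seed = 1) {
  x <- abundance_matrix(table)
  info <- match_reference(x, meta, reference_group)
  xr <- info$x; age <- info$age
  if (length(unique(age)) < 3L) stop("reference group must span >=3 distinct ages")
  if (nrow(xr) < 2L * n_folds) {
    n_folds <- max(2L, nrow(xr) %/% 2L)
    warning("too few reference samples; folds reduced to ", n_folds)
  }
  subset_sizes <- subset_sizes %||% seq_len(min(30L, ncol(xr)))
  with_seed(seed, {
    rf <- randomForest::randomForest(xr, age, ntree = 500, importance = TRUE)
    imp <- randomForest::importance(rf, type = 1L)[, 1L]
    constant <- apply(xr, 2L, function(v) length(unique(v)) == 1L)
    imp[constant] <- -Inf
    ranking <- colnames(xr)[order(imp, decreasing = TRUE)]
    cv_err <- matrix(NA_real_, n_repeats, length(subset_sizes))
    for (rep_i in seq_len(n_repeats)) {
      folds <- sample(rep_len(seq_len(n_folds), nrow(xr)))
      for (si in seq_along(subset_sizes)) {
        feats <- ranking[seq_len(subset_sizes[si])]
        sq_err <- numeric(0)
        for (f in seq_len(n_folds)) {
          test <- folds == f
          fit <- randomForest::randomForest(xr[!test, feats, drop = FALSE],
                                            age[!test], ntree = ntree_cv)
          pred <- stats::predict(fit, xr[test, feats, drop = FALSE])
          sq_err <- c(sq_err, (pred - age[test])^2)
        }
        cv_err[rep_i, si] <- mean(sq_err)
      }
    }
    curve <- data.frame(
      size = subset_sizes,
      cv_error = colMeans(cv_err),
      cv_se = apply(cv_err, 2L, stats::sd) / sqrt(n_repeats)
    )
    best <- which.min(curve$cv_error)
    if (one_se) {
      thresh <- curve$cv_error[best] + curve$cv_se[best]
      best <- which(curve$cv_error <= thresh)[1L]
    }
    list(selected_taxa = ranking[seq_len(curve$size[best])],
         ranking = ranking, cv_curve = curve)
  })
}

match_reference <- function(x, meta, reference_group) {
  meta <- meta[match(rownames(x), meta$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata missing for some samples")
  grp <- paste(meta$diet_group, meta$oral_group, sep = "_")
  ref <- grp == reference_group
  if (!any(ref)) stop("reference group '", reference_group, "' absent")
  list(x = x[ref, , drop = FALSE], age = meta$age_days[ref], which = ref,
       group = grp, meta = meta)
}

#' Fit the microbiota-age model
#'
#' Refits a 500-tree random-forest regression of chronological age on the
#' selected taxa using reference-group samples only, reports out-of-bag
#' variance explained, and fits a cubic smoothing spline (smoothness by
#' generalized cross-validation) mapping chronological age to the expected
#' microbiota age of reference animals. With few distinct ages the spline
#' approaches interpolation of per-age means, which is the intended
#' behaviour.
#'
#' @inheritParams select_age_taxa
#' @param selected_taxa taxa from [select_age_taxa()].
#' @param ntree trees in the final forest (default 500).
#' @return a `maturity_model`: list with `forest`, `spline`,
#'   `selected_taxa`, `variance_explained` (percent, out-of-bag),
#'   `reference_group`, `age_range`.
#' @export
fit_maturity_model <- function(table, meta, selected_taxa,
                               reference_group = "control_Nonoral",
                               ntree = 500, seed = 1) {
  x <- abundance_matrix(table)
  missing <- setdiff(selected_taxa, colnames(x))
  if (length(missing)) stop("selected taxa absent from table: ",
                            paste(missing, collapse = ", "))
  info <- match_reference(x, meta, reference_group)
  xr <- info$x[, selected_taxa, drop = FALSE]
  age <- info$age
  with_seed(seed, {
    rf <- randomForest::randomForest(xr, age, ntree = ntree)
    pred <- stats::predict(rf, xr)
    sp <- stats::smooth.spline(age, pred, cv = FALSE)
    structure(list(
      forest = rf, spline = sp, selected_taxa = selected_taxa,
      variance_explained = 100 * rf$rsq[length(rf$rsq)],
      reference_group = reference_group,
      age_range = range(age)
    ), class = "maturity_model")
  })
}

#' @export
print.maturity_model <- function(x, ...) {
  cat(sprintf(
    "maturity_model: %d taxa, %.1f%% OOB variance explained, reference '%s'\n",
    length(x$selected_taxa), x$variance_explained, x$reference_group))
  invisible(x)
}

#' Score microbiota age and relative maturity
#'
#' `microbiota_age` is the random-forest prediction; `relative_maturity` is
#' the microbiota age minus the reference spline's expected microbiota age
#' at the sample's chronological age. Reference-group training samples are
#' mean-zero by construction of the spline. Ages outside the spline support
#' are extrapolated (natural cubic splines are linear beyond the boundary)
#' with a warning.
#'
#' @param model a `maturity_model`.
#' @param table abundance table containing the selected taxa (absent taxa
#'   are imputed as 0 with a warning).
#' @param meta metadata with `sample_id` and `age_days`.
#' @return data.frame with `sample_id`, `age_days`, `microbiota_age`,
#'   `relative_maturity`.
#' @export
score_maturity <- function(model, table, meta) {
  x <- abundance_matrix(table)
  missing <- setdiff(model$selected_taxa, colnames(x))
  if (length(missing)) {
    warning("absent taxa imputed as 0: ", paste(missing, collapse = ", "))
    pad <- matrix(0, nrow(x), length(missing),
                  dimnames = list(rownames(x), missing))
    x <- cbind(x, pad)
  }
  meta <- meta[match(rownames(x), meta$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata missing for some samples")
  if (any(meta$age_days < model$age_range[1L] |
          meta$age_days > model$age_range[2L])) {
    warning("chronological age outside spline support; linear extrapolation")
  }
  pred <- stats::predict(model$forest, x[, model$selected_taxa, drop = FALSE])
  expected <- stats::predict(model$spline, meta$age_days)$y
  data.frame(
    sample_id = rownames(x),
    age_days = meta$age_days,
    microbiota_age = unname(pred),
    relative_maturity = unname(pred - expected),
    stringsAsFactors = FALSE
  )
}

#' Compare maturity between groups
#'
#' Per-age two-group Wilcoxon rank-sum tests on relative maturity
#' (BH-adjusted across ages); age strata with fewer than `min_per_group`
#' samples in either group are skipped with a warning.
#'
#' @param scores output of [score_maturity()].
#' @param groups factor over the scored samples (two levels compared).
#' @param min_per_group minimum samples per group per age (default 3).
#' @return data.frame with `age_days`, `n_a`, `n_b`, `median_diff`
#'   (first level minus second), `p`, `p_adjusted`.
#' @export
compare_maturity <- function(scores, groups, min_per_group = 3) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("need exactly two groups")
  lev <- levels(groups)
  rows <- list()
  for (a in sort(unique(scores$age_days))) {
    sel <- scores$age_days == a
    va <- scores$relative_maturity[sel & groups == lev[1L]]
    vb <- scores$relative_maturity[sel & groups == lev[2L]]
    if (length(va) < min_per_group || length(vb) < min_per_group) {
      warning("age ", a, ": fewer than ", min_per_group, " per group; skipped")
      next
    }
    p <- suppressWarnings(stats::wilcox.test(va, vb)$p.value)
    rows[[as.character(a)]] <- data.frame(
      age_days = a, n_a = length(va), n_b = length(vb),
      median_diff = stats::median(va) - stats::median(vb), p = p,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
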