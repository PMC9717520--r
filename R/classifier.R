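#' Assign diarrhea labels to sampled time points
#'
#' A sample is labeled `"diarrhea"` iff diarrhea occurred on the sampling
#' day itself, or an episode of at least two consecutive diarrhea days
#' occurred in the interval since the previous sampling day (such episodes
#' are assigned forward to the next sampling day, e.g. diarrhea on days 15
#' and 16 with sampling days 14 and 21 labels the day-21 sample). Gaps in
#' the daily records that leave the rule undecidable yield `"unknown"`.
#'
#' @param daily_health data.frame with columns `piglet`, `day`, `status`
#'   (`"healthy"`/`"diarrhea"`).
#' @param sampling_days integer vector of sampling days.
#' @return data.frame with `piglet`, `sampling_day`, `health_label`.
#' @export
assign_diarrhea_labels <- function(daily_health, sampling_days) {
  need <- c("piglet", "day", "status")
  if (!all(need %in% names(daily_health))) {
    stop("daily_health needs columns: ", paste(need, collapse = ", "))
  }
  sampling_days <- sort(unique(as.integer(sampling_days)))
  rows <- list()
  for (pg in unique(daily_health$piglet)) {
    rec <- daily_health[daily_health$piglet == pg, ]
    status <- stats::setNames(rec$status, rec$day)
    for (i in seq_along(sampling_days)) {
      d <- sampling_days[i]
      prev <- if (i == 1L) -Inf else sampling_days[i - 1L]
      window <- (max(prev + 1, min(rec$day))):d
      window <- window[window >= prev + 1 & window <= d]
      st <- status[as.character(window)]
      label <- if (!is.na(status[as.character(d)]) &&
                   status[as.character(d)] == "diarrhea") {
        "diarrhea"
      } else {
        runs <- rle(ifelse(is.na(st), "gap", st))
        if (any(runs$values == "diarrhea" & runs$lengths >= 2L)) {
          "diarrhea"
        } else if (anyNA(st)) {
          "unknown"
        } else {
          "healthy"
        }
      }
      rows[[paste(pg, d)]] <- data.frame(piglet = pg, sampling_day = d,
                                         health_label = label,
                                         stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Diarrhea incidence percentage
#'
#' `incidence (%) = observations of diarrhea / (piglets x observational
#' days) x 100`.
#'
#' @param n_diarrhea_observations count of piglet-days with diarrhea.
#' @param n_piglets number of piglets observed.
#' @param n_days number of observational days.
#' @return percentage in \[0, 100\].
#' @export
diarrhea_incidence <- function(n_diarrhea_observations, n_piglets, n_days) {
  if (any(c(n_diarrhea_observations, n_piglets, n_days) < 0)) {
    stop("counts must be nonnegative")
  }
  if (n_piglets * n_days == 0) stop("zero denominator")
  n_diarrhea_observations / (n_piglets * n_days) * 100
}

# Mutual information (nats) of a discrete contingency table.
mutual_information <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
}

discretize_quantile <- function(v, n_bins) {
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2L) return(rep(1L, length(v)))
  cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' mRMR feature ranking
#'
#' Greedy minimal-redundancy maximal-relevance ordering: features are
#' quantile-discretized, the first pick maximizes mutual information with
#' the label, and each subsequent pick maximizes relevance minus mean
#' redundancy with the already-selected set (MID/difference criterion;
#' `"quotient"` divides instead). Deterministic: ties break by column
#' order, and constant features (zero MI) sort last.
#'
#' @param table a `relative_abundance` table or samples x features matrix.
#' @param labels binary labels.
#' @param n_bins quantile bins for discretization (default 3).
#' @param criterion `"difference"` (default) or `"quotient"`.
#' @return character vector: all features in mRMR order.
#' @export
mrmr_rank <- function(table, labels, n_bins = 3,
                      criterion = c("difference", "quotient")) {
  criterion <- match.arg(criterion)
  x <- abundance_matrix(table)
  if (ncol(x) < 2L) stop("need at least two features")
  y <- as.factor(labels)
  disc <- apply(x, 2L, discretize_quantile, n_bins = n_bins)
  relevance <- apply(disc, 2L, mutual_information, y = y)
  p <- ncol(x)
  # degenerate features (a single bin, hence zero MI with everything) are
  # excluded from the greedy search and appended last in column order
  degenerate <- which(apply(disc, 2L, function(b) length(unique(b)) == 1L))
  mi_cache <- matrix(NA_real_, p, p)
  selected <- integer(0)
  remaining <- setdiff(seq_len(p), degenerate)
  n_active <- length(remaining)
  for (step in seq_len(n_active)) {
    if (length(selected) == 0L) {
      score <- relevance[remaining]
    } else {
      red <- vapply(remaining, function(j) {
        mean(vapply(selected, function(s) {
          if (is.na(mi_cache[s, j])) {
            mi_cache[s, j] <<- mi_cache[j, s] <<-
              mutual_information(disc[, s], disc[, j])
          }
          mi_cache[s, j]
        }, numeric(1)))
      }, numeric(1))
      score <- if (criterion == "difference") {
        relevance[remaining] - red
      } else {
        relevance[remaining] / pmax(red, 1e-12)
      }
    }
    pick <- remaining[which.max(score)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  colnames(x)[c(selected, degenerate)]
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with the
#' standard convention that a zero factor in the denominator gives 0.
#'
#' @param tp,tn,fp,fn confusion-matrix counts.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(tp, tn, fp, fn) {
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

mcc_from_predictions <- function(truth, pred, positive) {
  mcc(tp = sum(truth == positive & pred == positive),
      tn = sum(truth != positive & pred != positive),
      fp = sum(truth != positive & pred == positive),
      fn = sum(truth == positive & pred != positive))
}

#' Incremental feature selection with SVM and LOOCV
#'
#' For each prefix size `k` of the mRMR ranking, trains a radial-basis SVM
#' (C = 1, library-default bandwidth; features standardized once) on the
#' top-k features under leave-one-out cross-validation and records the MCC
#' of the pooled LOOCV predictions. The chosen panel is the prefix with the
#' highest MCC (ties go to the smallest k).
#'
#' @param table a `relative_abundance` table or samples x features matrix.
#' @param labels binary labels.
#' @param ranking feature order from [mrmr_rank()].
#' @param max_size largest prefix to scan (default `min(100, #features)`).
#' @param kernel SVM kernel (default `"radial"`).
#' @param cost SVM cost parameter (default 1).
#' @param seed integer seed (SVM fitting is deterministic; the seed guards
#'   any internal randomness).
#' @return list with `curve` (data.frame `size`, `mcc`), `chosen_size`,
#'   `panel`.
#' @export
ifs_svm_loocv <- function(table, labels, ranking, max_size = NULL,
                          kernel = "radial", cost = 1, seed = 1) {
  x <- abundance_matrix(table)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2L) stop("labels must be binary")
  if (any(table(y) < 2L)) stop("each class needs at least 2 samples for LOOCV")
  max_size <- max_size %||% min(100L, length(ranking))
  if (max_size > length(ranking)) stop("max_size exceeds ranked features")
  positive <- levels(y)[2L]
  sds <- apply(x, 2L, stats::sd); sds[sds == 0] <- 1
  xs <- scale(x, scale = sds)
  n <- nrow(xs)
  curve <- with_seed(seed, {
    vapply(seq_len(max_size), function(k) {
      feats <- ranking[seq_len(k)]
      pred <- character(n)
      for (i in seq_len(n)) {
        fit <- e1071::svm(xs[-i, feats, drop = FALSE], y[-i],
                          kernel = kernel, cost = cost, scale = FALSE)
        pred[i] <- as.character(stats::predict(fit, xs[i, feats, drop = FALSE]))
      }
      mcc_from_predictions(as.character(y), pred, positive)
    }, numeric(1))
  })
  chosen <- which.max(curve)
  list(curve = data.frame(size = seq_len(max_size), mcc = curve),
       chosen_size = chosen, panel = ranking[seq_len(chosen)])
}

#' Train the final SVM on a chosen panel
#'
#' @inheritParams ifs_svm_loocv
#' @param panel feature panel (e.g. from [ifs_svm_loocv()]).
#' @return list with the fitted `svm` model, the panel, and the
#'   standardization parameters applied to inputs.
#' @export
train_svm_panel <- function(table, labels, panel, kernel = "radial", cost = 1) {
  x <- abundance_matrix(table)
  y <- droplevels(as.factor(labels))
  centers <- colMeans(x[, panel, drop = FALSE])
  sds <- apply(x[, panel, drop = FALSE], 2L, stats::sd); sds[sds == 0] <- 1
  xs <- scale(x[, panel, drop = FALSE], center = centers, scale = sds)
  fit <- e1071::svm(xs, y, kernel = kernel, cost = cost, scale = FALSE,
                    probability = TRUE)
  list(model = fit, panel = panel, centers = centers, sds = sds,
       levels = levels(y))
}

#' Evaluate a trained panel classifier with ROC/AUC
#'
#' Decision scores on the test set are summarized as an ROC curve (AUC by
#' trapezoidal integration, identical to the normalized Mann-Whitney U
#' statistic) with a percentile-bootstrap confidence interval over test
#' samples.
#'
#' @param model result of [train_svm_panel()].
#' @param test_table abundance table of test samples.
#' @param test_labels binary labels of test samples.
#' @param n_ci_boot bootstrap rounds for the CI (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with `auc`, `ci` (lower/upper), and `curve` (data.frame
#'   `fpr`, `tpr`, monotone nondecreasing).
#' @export
evaluate_roc <- function(model, test_table, test_labels, n_ci_boot = 2000,
                         conf = 0.95, seed = 1) {
  x <- abundance_matrix(test_table)
  y <- factor(as.character(test_labels), levels = model$levels)
  if (nlevels(droplevels(y)) < 2L) stop("test set must contain both classes")
  xs <- scale(x[, model$panel, drop = FALSE], center = model$centers,
              scale = model$sds)
  dv <- attr(stats::predict(model$model, xs, decision.values = TRUE),
             "decision.values")
  scores <- dv[, 1L]
  # decision values are oriented toward the first label of the "a/b" pair;
  # flip so larger always means the positive (second) class
  pos <- model$levels[2L]
  if (!startsWith(colnames(dv)[1L], paste0(pos, "/"))) scores <- -scores
  roc_with_auc(y == pos, scores, n_ci_boot = n_ci_boot, conf = conf,
               seed = seed)
}

#' ROC curve and AUC from scores
#'
#' @param truth logical (or 0/1) vector: positive class membership.
#' @param scores numeric decision scores (larger = more positive).
#' @param n_ci_boot percentile-bootstrap rounds for the CI (0 skips it).
#' @param conf confidence level.
#' @param seed integer seed.
#' @return list with `auc`, `ci`, `curve`.
#' @export
roc_with_auc <- function(truth, scores, n_ci_boot = 2000, conf = 0.95,
                         seed = 1) {
  truth <- as.logical(truth)
  r <- pROC::roc(response = truth, predictor = scores, quiet = TRUE,
                 direction = "<", levels = c(FALSE, TRUE))
  auc <- as.numeric(pROC::auc(r))
  curve <- data.frame(fpr = rev(1 - r$specificities),
                      tpr = rev(r$sensitivities))
  ci <- c(NA_real_, NA_real_)
  if (n_ci_boot > 0) {
    boot <- with_seed(seed, {
      vapply(seq_len(n_ci_boot), function(i) {
        idx <- sample(length(truth), replace = TRUE)
        if (length(unique(truth[idx])) < 2L) return(NA_real_)
        as.numeric(pROC::auc(pROC::roc(response = truth[idx],
                                       predictor = scores[idx], quiet = TRUE,
                                       direction = "<",
                                       levels = c(FALSE, TRUE))))
      }, numeric(1))
    })
    ci <- unname(stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                                 na.rm = TRUE))
  }
  list(auc = auc, ci = ci, curve = curve)
}
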