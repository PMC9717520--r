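test_that("diarrhea assignment follows the two-consecutive-day rule", {
  daily <- expand.grid(piglet = "p1", day = 0:28)
  daily$status <- "healthy"
  daily$status[daily$day %in% c(15, 16)] <- "diarrhea"
  lab <- assign_diarrhea_labels(daily, c(0, 3, 7, 14, 21, 28))
  expect_identical(lab$health_label[lab$sampling_day == 21], "diarrhea")
  expect_identical(lab$health_label[lab$sampling_day == 14], "healthy")
  expect_identical(lab$health_label[lab$sampling_day == 28], "healthy")

  # single-day episode between samplings stays healthy
  daily2 <- daily; daily2$status <- "healthy"
  daily2$status[daily2$day == 10] <- "diarrhea"
  lab2 <- assign_diarrhea_labels(daily2, c(7, 14))
  expect_true(all(lab2$health_label == "healthy"))

  # diarrhea on the sampling day itself
  daily3 <- daily; daily3$status <- "healthy"
  daily3$status[daily3$day == 7] <- "diarrhea"
  lab3 <- assign_diarrhea_labels(daily3, c(0, 7))
  expect_identical(lab3$health_label[lab3$sampling_day == 7], "diarrhea")

  # record gap -> unknown
  daily4 <- daily[daily$day != 10, ]; daily4$status <- "healthy"
  lab4 <- assign_diarrhea_labels(daily4, c(7, 14))
  expect_identical(lab4$health_label[lab4$sampling_day == 14], "unknown")
})

test_that("diarrhea incidence applies the exact formula", {
  expect_equal(diarrhea_incidence(0, 6, 21), 0)
  expect_equal(diarrhea_incidence(12, 6, 21), 12 / (6 * 21) * 100)
  expect_equal(diarrhea_incidence(6 * 21, 6, 21), 100)
  expect_error(diarrhea_incidence(1, 0, 21), "denominator")
})

test_that("mutual information ranking puts a label-determined feature first", {
  set.seed(71)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(runif(n * 10), n, 10)
  x[, 4] <- y + runif(n, 0, 0.01)            # perfectly label-determined
  colnames(x) <- sprintf("F%02d", 1:10)
  rownames(x) <- paste0("s", 1:n)
  rk <- mrmr_rank(x, y)
  expect_identical(rk[1], "F04")
  expect_identical(rk, mrmr_rank(x, y))       # deterministic
  # an exact duplicate of the top feature is demoted below an independent
  # weakly informative feature
  x2 <- cbind(x, DUP = x[, 4])
  x2[, 1] <- y * 0.5 + runif(n)               # weak independent signal
  rk2 <- mrmr_rank(x2, y)
  expect_lt(which(rk2 == "F01"), which(rk2 == "DUP"))
  # constant feature ranks last
  x3 <- cbind(x, ZZZ = rep(1, n))
  expect_identical(mrmr_rank(x3, y)[ncol(x3)], "ZZZ")
})

test_that("MCC matches hand arithmetic and conventions", {
  expect_equal(mcc(5, 5, 0, 0), 1)
  expect_equal(mcc(0, 0, 5, 5), -1)
  expect_equal(mcc(4, 3, 1, 2), 10 / sqrt(600))
  expect_equal(mcc(7, 0, 3, 0), 0)    # all predicted one class
  # symmetric under simultaneous class/prediction flip
  expect_equal(mcc(4, 3, 1, 2), mcc(3, 4, 2, 1))
})

test_that("IFS/SVM recovers an informative prefix and stays flat on noise", {
  fx <- classifier_fixture(cohort_seed = 72, label_seed = 2)
  rk <- mrmr_rank(fx$rel, fx$labels)
  ifs <- ifs_svm_loocv(fx$rel, fx$labels, rk, max_size = 10,
                       kernel = "linear", seed = 1)
  expect_identical(nrow(ifs$curve), 10L)
  expect_gte(max(ifs$curve$mcc), 0.9)
  expect_gte(sum(fx$panel %in% ifs$panel), 4)
  # panel is a prefix of the ranking
  expect_identical(ifs$panel, rk[seq_len(ifs$chosen_size)])
  # shuffled labels: no structure
  set.seed(3)
  shuf <- setNames(sample(fx$labels), names(fx$labels))
  rk0 <- mrmr_rank(fx$rel, shuf)
  ifs0 <- ifs_svm_loocv(fx$rel, shuf, rk0, max_size = 5,
                        kernel = "linear", seed = 1)
  expect_lt(max(abs(ifs0$curve$mcc)), 0.3)
})

test_that("ROC/AUC equals the normalized Mann-Whitney statistic", {
  set.seed(73)
  scores <- rnorm(400)
  truth <- rbinom(400, 1, 0.5) == 1
  res <- roc_with_auc(truth, scores, n_ci_boot = 0)
  u <- suppressWarnings(wilcox.test(scores[truth], scores[!truth])$statistic)
  expect_equal(res$auc, unname(u) / (sum(truth) * sum(!truth)),
               tolerance = 1e-9)
  expect_lt(abs(res$auc - 0.5), 0.1)
  # curve monotone, AUC consistent with trapezoidal integration
  curve <- res$curve
  expect_true(all(diff(curve$tpr) >= 0))
  trap <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  expect_equal(res$auc, trap, tolerance = 1e-9)
  # perfect scores
  expect_equal(roc_with_auc(c(rep(TRUE, 5), rep(FALSE, 5)),
                            c(6:10, 1:5), n_ci_boot = 0)$auc, 1)
})

test_that("a trained panel SVM evaluates with a bootstrap CI", {
  fx <- classifier_fixture(cohort_seed = 74, label_seed = 4)
  y <- factor(ifelse(fx$labels == 1, "diarrhea", "healthy"),
              levels = c("healthy", "diarrhea"))
  idx_train <- seq_len(120)
  idx_test <- setdiff(seq_along(y), idx_train)
  tr <- train_svm_panel(as_rel(fx$rel$values[idx_train, ]), y[idx_train],
                        panel = fx$panel, kernel = "linear")
  ev <- evaluate_roc(tr, as_rel(fx$rel$values[idx_test, ]), y[idx_test],
                     n_ci_boot = 200, seed = 5)
  expect_gt(ev$auc, 0.8)
  expect_true(ev$ci[1] <= ev$auc && ev$ci[2] >= ev$auc)
  expect_error(evaluate_roc(tr, as_rel(fx$rel$values[idx_test, ]),
                            rep("healthy", length(idx_test))), "both classes")
})
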