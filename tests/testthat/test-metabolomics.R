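make_pm <- function(values, n_qc = 0) {
  n <- nrow(values)
  rn <- c(sprintf("Bio%02d", seq_len(n - n_qc)),
          if (n_qc > 0) sprintf("QC_%02d", seq_len(n_qc)))
  dimnames(values) <- list(rn, sprintf("P%03d", seq_len(ncol(values))))
  peak_matrix(values)
}

test_that("peak filter applies the missingness OR-rule and imputes half-minimum", {
  set.seed(31)
  v <- matrix(runif(15 * 4, 100, 200), 15, 4)
  v[1:10, 1] <- NA       # 10/10 bio missing -> >80% -> removed
  v[11:13, 2] <- NA      # 3/5 QC missing -> >50% -> removed
  v[1:2, 3] <- NA        # 20% bio missing -> kept, imputed
  pm <- make_pm(v, n_qc = 5)
  out <- filter_peaks(pm)
  expect_identical(colnames(out$intensities), c("P003", "P004"))
  expect_setequal(attr(out, "removed")$peak_id, c("P001", "P002"))
  # imputation: half the observed minimum of the peak
  expect_equal(unname(out$intensities[1:2, "P003"]),
               rep(min(v[-(1:2), 3]) / 2, 2))
  # complete peak untouched
  expect_identical(out$intensities[, "P004"], pm$intensities[, "P004"])
  # idempotent
  again <- filter_peaks(out)
  expect_identical(again$intensities, out$intensities)
  expect_warning(filter_peaks(make_pm(v[1:10, ], n_qc = 0)), "QC")
})

test_that("TIC normalization equalizes totals and preserves profiles", {
  set.seed(32)
  v <- matrix(runif(5 * 10, 50, 150), 5, 10)
  v[2, ] <- v[2, ] * 10       # injection-amount artifact
  pm <- make_pm(v)
  out <- tic_normalize(pm)
  tot <- rowSums(out$intensities)
  expect_lt(max(abs(tot - tot[1])), 1e-9)
  # scaling a sample leaves its normalized profile unchanged
  v2 <- v; v2[3, ] <- v2[3, ] * 7
  out2 <- tic_normalize(make_pm(v2))
  expect_equal(out2$intensities[3, ] / sum(out2$intensities[3, ]),
               out$intensities[3, ] / sum(out$intensities[3, ]),
               tolerance = 1e-12)
  # rank order within a sample preserved
  expect_identical(order(out$intensities[1, ]), order(v[1, ]))
  expect_error(tic_normalize(make_pm(matrix(NA_real_, 2, 2))), "missing")
})

test_that("VIP identity holds on arbitrary inputs", {
  set.seed(33)
  for (i in 1:5) {
    x <- matrix(rnorm(20 * (20 + i * 13)), 20)
    dimnames(x) <- list(paste0("s", 1:20), paste0("p", seq_len(ncol(x))))
    v <- oplsda_vip(x, rep(c("a", "b"), each = 10))
    expect_equal(mean(v$selection$vip^2), 1, tolerance = 1e-6)
  }
  expect_error(oplsda_vip(x, rep(c("a", "b", "c"), length.out = 20)),
               "two groups")
  expect_error(oplsda_vip(x[1:5, ], c("a", "a", "a", "b", "b")), "3 samples")
})

test_that("OPLS-DA/VIP recovers planted class separation", {
  set.seed(34)
  tp <- fp <- numeric(5)
  for (s in 1:5) {
    x <- matrix(rnorm(26 * 205), 26, 205)
    grp <- rep(c("a", "b"), each = 13)
    x[grp == "b", 1:5] <- x[grp == "b", 1:5] + 2
    dimnames(x) <- list(paste0("s", 1:26), sprintf("P%03d", 1:205))
    v <- oplsda_vip(x, grp)
    sel <- v$selection$peak_id[v$selection$selected]
    tp[s] <- sum(sel %in% sprintf("P%03d", 1:5))
    fp[s] <- length(sel) - tp[s]
  }
  expect_gte(mean(tp), 4)
  expect_lte(mean(fp), 2)
})

test_that("bicor behaves like a correlation and is robust to sign", {
  set.seed(35)
  x <- rnorm(40)
  expect_equal(as.numeric(bicor(cbind(a = x, b = x))[1, 2]), 1)
  expect_equal(as.numeric(bicor(cbind(a = x, b = -x))[1, 2]), -1)
  m <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, letters[1:5]))
  r <- bicor(m)
  expect_true(all(abs(r) <= 1))
  expect_equal(unname(diag(r)), rep(1, 5))
  expect_equal(r, t(r), tolerance = 1e-12)
  # zero-MAD column falls back to Pearson
  m2 <- cbind(m, z = rep(c(0, 0, 0, 0, 1), 8))
  expect_true(all(is.finite(bicor(m2))))
})

test_that("coabundance modules recover planted blocks and grey out noise", {
  met <- simulate_metabolome(metabolome_spec(
    n_per_group = 13, n_peaks = 95, module_sizes = c(20, 15, 10),
    within_corr = 0.8, n_shifted_modules = 1,
    bio_missing_rate = 0, qc_missing_rate = 0, seed = 36
  ))
  logbio <- log(met$matrix$intensities[!met$matrix$is_qc, ])
  mods <- coabundance_modules(logbio)
  planted <- met$truth$module > 0
  ari <- adjusted_rand(met$truth$module[planted],
                       mods$assignment$module[planted])
  expect_gte(ari, 0.9)
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(ari, mclust::adjustedRandIndex(
      met$truth$module[planted], mods$assignment$module[planted]))
  }
  expect_gt(mean(mods$assignment$module[!planted] == "grey"), 0.8)
  # module labels ordered by decreasing size
  sizes <- table(mods$assignment$module)
  mods_only <- sizes[setdiff(names(sizes), "grey")]
  expect_true(all(diff(unname(mods_only)) <= 0))
})

test_that("eigenmetabolite of identical standardized peaks is the common profile", {
  set.seed(37)
  common <- rnorm(20)
  block <- sapply(1:6, function(i) 3 + i * common)   # same shape, scaled
  noise <- matrix(rnorm(20 * 5, sd = 0.01), 20, 5)
  x <- cbind(block, noise + rep(rnorm(5), each = 20))
  dimnames(x) <- list(paste0("s", 1:20), sprintf("P%02d", 1:11))
  mods <- coabundance_modules(x, min_size = 5)
  m1 <- mods$assignment$module[1:6]
  expect_true(all(m1 == m1[1]) && m1[1] != "grey")
  expect_equal(unname(mods$variance_explained[m1[1]]), 1, tolerance = 1e-9)
  e <- mods$eigenmetabolites[, m1[1]]
  expect_gt(abs(cor(e, common)), 0.9999)
  # constant peak goes grey with a warning
  x2 <- cbind(x, const = rep(1, 20))
  expect_warning(mods2 <- coabundance_modules(x2, min_size = 5), "constant")
  expect_identical(mods2$assignment$module[mods2$assignment$peak_id == "const"],
                   "grey")
})

test_that("module abundance contrast finds the shifted block", {
  met <- simulate_metabolome(metabolome_spec(
    n_per_group = 8, n_peaks = 40, module_sizes = c(12, 10),
    within_corr = 0.85, n_shifted_modules = 1, shift_sd = 2,
    bio_missing_rate = 0, qc_missing_rate = 0, seed = 38
  ))
  logbio <- log(met$matrix$intensities[!met$matrix$is_qc, ])
  mods <- coabundance_modules(logbio)
  cmp <- compare_module_abundance(mods, met$groups)
  # the module carrying peaks of the shifted block must reject
  shifted_peaks <- names(met$truth$module)[met$truth$module == 1]
  shifted_mod <- mods$assignment$module[
    mods$assignment$peak_id %in% shifted_peaks]
  shifted_mod <- names(sort(table(shifted_mod), decreasing = TRUE))[1]
  expect_lt(cmp$p_adjusted[cmp$module == shifted_mod], 0.05)
  # single-module edge case: BH equals raw p
  one <- list(eigenmetabolites = mods$eigenmetabolites[, 1, drop = FALSE])
  cmp1 <- compare_module_abundance(one, met$groups)
  expect_identical(cmp1$p, cmp1$p_adjusted)
})
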