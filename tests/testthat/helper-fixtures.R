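# Shared synthetic fixtures, all built in code at test time.

# adjusted Rand index between two labelings (Hubert & Arabie)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# small deterministic count table
tiny_counts <- function() {
  count_table(matrix(
    c(2, 2, 4,
      1, 0, 3,
      5, 5, 0),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("s1", "s2", "s3"), c("tA", "tB", "tC"))
  ))
}

# skewed rank-abundance community with 5 closure-balanced planted contrasts:
# features 1-3 shifted 10x up, 4-5 shifted 10x down in the treated group
lefse_fixture <- function(n_per = 8, cv = 0.05, n_feat = 100) {
  base <- exp(stats::rnorm(n_feat, 0, 2.5)); base <- base / sum(base)
  base[1:3] <- 0.004; base[4:5] <- 0.06
  base <- base / sum(base)
  x <- matrix(NA_real_, 2 * n_per, n_feat)
  for (i in seq_len(2 * n_per)) {
    b <- base
    if (i > n_per) {
      b[1:3] <- b[1:3] * 10
      b[4:5] <- b[4:5] / 10
    }
    v <- b * exp(stats::rnorm(n_feat, 0, cv))
    x[i, ] <- v / sum(v)
  }
  dimnames(x) <- list(paste0("s", seq_len(2 * n_per)),
                      sprintf("F%03d", seq_len(n_feat)))
  list(rel = structure(list(values = x), class = "relative_abundance"),
       labels = rep(c("ctrl", "trt"), each = n_per),
       truth = sprintf("F%03d", 1:5))
}

# independent lognormal basis abundances -> compositional counts (SparCC null);
# optionally a planted basis correlation between taxa 1 and 2
sparcc_counts <- function(n, p, depth = 10000, planted_rho = NULL) {
  logb <- matrix(stats::rnorm(n * p, 8, 1), n, p)
  if (!is.null(planted_rho)) {
    s <- diag(2); s[1, 2] <- s[2, 1] <- planted_rho
    logb[, 1:2] <- 8 + matrix(stats::rnorm(n * 2), n, 2) %*% chol(s)
  }
  fr <- exp(logb); fr <- fr / rowSums(fr)
  cnt <- t(apply(fr, 1L, function(f) stats::rmultinom(1, depth, f)))
  dimnames(cnt) <- list(paste0("s", seq_len(n)), paste0("t", seq_len(p)))
  cnt
}

# relative-abundance matrix wrapper
as_rel <- function(x) structure(list(values = x), class = "relative_abundance")

# cohort tuned for maturity tests: acceleration planted on the oral arm of
# the control diet so the age signal is not confounded with diet shifts
maturity_cohort <- function(seed, accel_days = 4) {
  simulate_cohort(cohort_spec(
    n_taxa = 100, n_age_taxa = 10, n_shift_taxa = 0,
    lib_meanlog = log(10000),
    maturity_shift_days = c(control_Oral = accel_days),
    seed = seed
  ))
}

# cohort + separable diarrhea labels for classifier tests
classifier_fixture <- function(cohort_seed = 5, label_seed = 1,
                               logit_scale = 200) {
  co <- simulate_cohort(cohort_spec(
    n_litters_per_group = 4, ages = c(7, 14, 21, 28), n_taxa = 60,
    n_age_taxa = 0, n_shift_taxa = 0, lib_meanlog = log(8000),
    seed = cohort_seed
  ))
  lab <- simulate_diarrhea_labels(co$table, panel_size = 5,
                                  logit_scale = logit_scale, seed = label_seed)
  list(table = co$table, rel = to_relative_abundance(co$table),
       labels = lab$labels, panel = names(lab$panel))
}
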