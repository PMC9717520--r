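#' Specify a synthetic longitudinal piglet cohort
#'
#' Defines the generative model used to emulate a 2x2 (maternal diet x oral
#' dosing) longitudinal design: per-litter log-composition offsets, logistic
#' age trajectories for a subset of taxa, diet-linked log-fold shifts, and
#' Dirichlet-multinomial counts with lognormal library sizes. Defaults mirror
#' the study design: four litters of three piglets per group, sampling at
#' days 0/3/7/14/21/28, and sequencing depths centred on ~43,600 reads.
#'
#' @param n_litters_per_group litters per diet x oral group (default 4).
#' @param n_piglets_per_litter piglets sampled per litter (default 3).
#' @param ages sampling ages in days (default `c(0, 3, 7, 14, 21, 28)`).
#' @param n_taxa number of taxa (default 100).
#' @param n_age_taxa number of age-linked taxa with logistic trajectories
#'   (default 10).
#' @param traj_amplitude log-scale amplitude of the age trajectories
#'   (default 3).
#' @param traj_slope logistic slope per day (default 0.35).
#' @param n_shift_taxa number of diet-shifted taxa (default 5).
#' @param shift_log_fold natural-log fold shift applied to shifted taxa in
#'   the I5007 diet groups (default 1.5).
#' @param maturity_shift_days named numeric: per-group shift (days) applied
#'   to the age entering the trajectories; positive values advance microbial
#'   development. Names are `<diet>_<oral>` combinations; unnamed groups get
#'   0.
#' @param litter_sd SD of per-litter log-composition offsets (default 0.3).
#' @param dm_concentration Dirichlet-multinomial concentration governing
#'   overdispersion (default 50).
#' @param lib_meanlog,lib_sdlog lognormal library-size parameters (defaults
#'   `log(43559)` and 0.18, matching a 43,559 +/- 7,824 read depth profile).
#' @param seed integer seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_litters_per_group = 4, n_piglets_per_litter = 3,
                        ages = c(0, 3, 7, 14, 21, 28),
                        n_taxa = 100, n_age_taxa = 10,
                        traj_amplitude = 3, traj_slope = 0.35,
                        n_shift_taxa = 5, shift_log_fold = 1.5,
                        maturity_shift_days = NULL,
                        litter_sd = 0.3, dm_concentration = 50,
                        lib_meanlog = log(43559), lib_sdlog = 0.18,
                        seed = 1) {
  if (n_age_taxa > n_taxa) stop("n_age_taxa cannot exceed n_taxa")
  if (is.unsorted(ages)) stop("ages must be sorted ascending")
  stopifnot(all(is.finite(c(traj_amplitude, traj_slope, shift_log_fold,
                            litter_sd, dm_concentration))))
  spec <- list(
    n_litters_per_group = n_litters_per_group,
    n_piglets_per_litter = n_piglets_per_litter,
    ages = ages, n_taxa = n_taxa, n_age_taxa = n_age_taxa,
    traj_amplitude = traj_amplitude, traj_slope = traj_slope,
    n_shift_taxa = n_shift_taxa, shift_log_fold = shift_log_fold,
    maturity_shift_days = maturity_shift_days,
    litter_sd = litter_sd, dm_concentration = dm_concentration,
    lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog, seed = seed
  )
  class(spec) <- "cohort_spec"
  spec
}

#' Simulate a longitudinal cohort with planted structure
#'
#' Draws counts sample-wise from a Dirichlet-multinomial whose composition is
#' `softmax(base + age trajectory + diet shift + litter offset)`. The truth
#' record lists the planted age-linked taxa, diet-shifted taxa, and litter
#' assignments so downstream recovery can be scored without inspecting
#' generator internals. The generator is a pure function of its spec (and
#' the spec's seed).
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `table` ([count_table()]), `metadata`
#'   (validated sample metadata data.frame), and `truth`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    groups <- expand.grid(diet = c("control", "I5007"),
                          oral = c("Nonoral", "Oral"),
                          stringsAsFactors = FALSE)
    taxa <- sprintf("OTU%03d", seq_len(spec$n_taxa))
    base <- stats::rnorm(spec$n_taxa, 0, 1.5)
    age_idx <- seq_len(spec$n_age_taxa)
    # age-linked taxa get moderate baselines so their trajectories are
    # observable at realistic depth and overdispersion: below ~0.5% relative
    # abundance a taxon's Dirichlet weight drops under 1 and its counts are
    # presence/absence noise
    base[age_idx] <- stats::rnorm(spec$n_age_taxa, 1, 0.35)
    direction <- rep_len(c(1, -1), spec$n_age_taxa)
    midpoints <- seq(2, max(spec$ages) - 2, length.out = max(spec$n_age_taxa, 1L))
    # slopes vary across taxa so each trajectory is informative in its own
    # age window (complementary, not redundant, age signal)
    slopes <- spec$traj_slope *
      rep_len(c(1, 2.5, 1.5, 3, 2), spec$n_age_taxa)
    shift_idx <- if (spec$n_shift_taxa > 0) {
      spec$n_age_taxa + seq_len(spec$n_shift_taxa)
    } else integer(0)
    if (length(shift_idx) && max(shift_idx) > spec$n_taxa) {
      stop("n_age_taxa + n_shift_taxa exceeds n_taxa")
    }

    rows <- list(); meta <- list(); litter_of <- character(0)
    litter_counter <- 0L
    for (g in seq_len(nrow(groups))) {
      gname <- paste(groups$diet[g], groups$oral[g], sep = "_")
      mshift <- 0
      if (!is.null(spec$maturity_shift_days) &&
          gname %in% names(spec$maturity_shift_days)) {
        mshift <- spec$maturity_shift_days[[gname]]
      }
      for (l in seq_len(spec$n_litters_per_group)) {
        litter_counter <- litter_counter + 1L
        litter_id <- sprintf("L%02d", litter_counter)
        litter_eff <- stats::rnorm(spec$n_taxa, 0, spec$litter_sd)
        for (p in seq_len(spec$n_piglets_per_litter)) {
          subject <- sprintf("P%02d_%d", litter_counter, p)
          for (a in spec$ages) {
            eta <- base + litter_eff
            if (spec$n_age_taxa > 0) {
              traj <- direction * spec$traj_amplitude *
                stats::plogis(slopes * ((a + mshift) - midpoints))
              eta[age_idx] <- eta[age_idx] + traj
            }
            if (groups$diet[g] == "I5007" && length(shift_idx)) {
              eta[shift_idx] <- eta[shift_idx] + spec$shift_log_fold
            }
            comp <- exp(eta - max(eta)); comp <- comp / sum(comp)
            gam <- stats::rgamma(spec$n_taxa, shape = spec$dm_concentration * comp)
            if (sum(gam) == 0) gam <- comp
            probs <- gam / sum(gam)
            libsize <- max(1L, round(stats::rlnorm(1, spec$lib_meanlog, spec$lib_sdlog)))
            cnt <- as.vector(stats::rmultinom(1, libsize, probs))
            sid <- sprintf("%s_%s_d%02d", gname, subject, a)
            rows[[sid]] <- cnt
            meta[[sid]] <- data.frame(
              sample_id = sid, subject_id = subject, litter_id = litter_id,
              age_days = as.integer(a), diet_group = groups$diet[g],
              oral_group = groups$oral[g], health_label = "unknown",
              stringsAsFactors = FALSE
            )
            litter_of[sid] <- litter_id
          }
        }
      }
    }
    counts <- do.call(rbind, rows)
    colnames(counts) <- taxa
    metadata <- do.call(rbind, meta)
    rownames(metadata) <- NULL
    list(
      table = count_table(counts),
      metadata = validate_sample_metadata(metadata),
      truth = list(
        age_taxa = taxa[age_idx],
        age_taxa_direction = stats::setNames(direction, taxa[age_idx]),
        shifted_taxa = taxa[shift_idx],
        litters = litter_of,
        maturity_shift_days = spec$maturity_shift_days,
        spec = spec
      )
    )
  })
}

#' Specify a synthetic untargeted-metabolome peak matrix
#'
#' Defaults emulate a serum matrix of the scale reported for umbilical cord
#' blood (1087 peaks after curation), with pooled-QC technical replicates
#' and block-correlated coabundance modules.
#'
#' @param n_per_group biological samples per treatment group (default 13).
#' @param n_qc pooled QC injections (default 5).
#' @param n_peaks total peaks (default 1087).
#' @param module_sizes integer vector of planted module sizes, each >= 5
#'   (default 25 modules of 20 peaks).
#' @param within_corr within-module correlation of log intensities
#'   (default 0.8).
#' @param n_shifted_modules leading modules whose latent factor is shifted
#'   in the treated group (default 3).
#' @param shift_sd size of that shift in factor SD units (default 2).
#' @param bio_missing_rate,qc_missing_rate independent missingness rates
#'   (defaults 0.05 and 0.02).
#' @param seed integer seed.
#' @return a `metabolome_spec` list.
#' @export
metabolome_spec <- function(n_per_group = 13, n_qc = 5, n_peaks = 1087,
                            module_sizes = rep(20L, 25),
                            within_corr = 0.8, n_shifted_modules = 3,
                            shift_sd = 2, bio_missing_rate = 0.05,
                            qc_missing_rate = 0.02, seed = 1) {
  if (sum(module_sizes) > n_peaks) stop("module sizes exceed n_peaks")
  if (within_corr <= 0 || within_corr >= 1) stop("within_corr must lie in (0, 1)")
  if (any(module_sizes < 5)) {
    warning("modules below size 5 are not expected to be detectable")
  }
  structure(list(n_per_group = n_per_group, n_qc = n_qc, n_peaks = n_peaks,
                 module_sizes = as.integer(module_sizes),
                 within_corr = within_corr,
                 n_shifted_modules = n_shifted_modules, shift_sd = shift_sd,
                 bio_missing_rate = bio_missing_rate,
                 qc_missing_rate = qc_missing_rate, seed = seed),
            class = "metabolome_spec")
}

#' Simulate a peak-intensity matrix with planted coabundance modules
#'
#' Log intensities follow a one-factor Gaussian model per module
#' (`z = sqrt(rho) f + sqrt(1 - rho) eps`), giving exchangeable within-module
#' correlation `rho`; off-module peaks are independent noise. QC samples are
#' technical replicates of the pooled biological mean plus small analytical
#' noise. Missing values are injected completely at random.
#'
#' @param spec a [metabolome_spec()].
#' @return list with `matrix` (a [peak_matrix()]), `groups` (treatment factor
#'   over biological samples), and `truth` (module membership, shifted
#'   modules).
#' @export
simulate_metabolome <- function(spec) {
  stopifnot(inherits(spec, "metabolome_spec"))
  with_seed(spec$seed, {
    n_bio <- 2L * spec$n_per_group
    groups <- rep(c("control", "I5007"), each = spec$n_per_group)
    module <- integer(spec$n_peaks)
    pos <- 1L
    for (m in seq_along(spec$module_sizes)) {
      module[pos:(pos + spec$module_sizes[m] - 1L)] <- m
      pos <- pos + spec$module_sizes[m]
    }
    rho <- spec$within_corr
    mu <- stats::runif(spec$n_peaks, 10, 16)
    sd_peak <- 0.5
    z <- matrix(stats::rnorm(n_bio * spec$n_peaks), n_bio, spec$n_peaks)
    for (m in seq_along(spec$module_sizes)) {
      f <- stats::rnorm(n_bio)
      if (m <= spec$n_shifted_modules) {
        f[groups == "I5007"] <- f[groups == "I5007"] + spec$shift_sd
      }
      idx <- which(module == m)
      z[, idx] <- sqrt(rho) * f + sqrt(1 - rho) * z[, idx]
    }
    logint <- sweep(sweep(z, 2L, sd_peak, `*`), 2L, mu, `+`)
    bio <- exp(logint)
    qc_log <- matrix(rep(colMeans(logint), each = spec$n_qc), spec$n_qc,
                     spec$n_peaks)
    qc <- exp(qc_log + matrix(stats::rnorm(spec$n_qc * spec$n_peaks, 0, 0.05),
                              spec$n_qc, spec$n_peaks))
    inten <- rbind(bio, qc)
    rownames(inten) <- c(sprintf("Bio%02d", seq_len(n_bio)),
                         sprintf("QC_%02d", seq_len(spec$n_qc)))
    colnames(inten) <- sprintf("RT%04d_mz%04d", seq_len(spec$n_peaks),
                               seq_len(spec$n_peaks))
    is_qc <- c(rep(FALSE, n_bio), rep(TRUE, spec$n_qc))
    miss_bio <- matrix(stats::runif(n_bio * spec$n_peaks) < spec$bio_missing_rate,
                       n_bio, spec$n_peaks)
    miss_qc <- matrix(stats::runif(spec$n_qc * spec$n_peaks) < spec$qc_missing_rate,
                      spec$n_qc, spec$n_peaks)
    inten[rbind(miss_bio, miss_qc)] <- NA_real_
    names(module) <- colnames(inten)
    list(
      matrix = peak_matrix(inten, is_qc),
      groups = stats::setNames(groups, rownames(inten)[!is_qc]),
      truth = list(module = module,
                   shifted_modules = seq_len(spec$n_shifted_modules),
                   spec = spec)
    )
  })
}

#' Simulate binary diarrhea labels driven by a hidden taxon panel
#'
#' Labels are Bernoulli with a logit linear in the standardized relative
#' abundances of a randomly chosen hidden panel; the panel is returned so
#' classifier recovery can be scored. A degenerate all-one/all-zero draw is
#' resampled once, then raises an error.
#'
#' @param table a [count_table()].
#' @param panel_size number of panel taxa.
#' @param logit_scale effect scale; 0 gives labels independent of the data.
#' @param seed integer seed.
#' @return list with `labels` (named 0/1 integer vector) and `panel`
#'   (taxon ids with their signed weights).
#' @export
simulate_diarrhea_labels <- function(table, panel_size, logit_scale, seed) {
  stopifnot(inherits(table, "count_table"))
  if (panel_size > ncol(table$counts)) stop("panel_size exceeds number of taxa")
  rel <- to_relative_abundance(table)$values
  # candidate panel taxa must be prevalent: a biomarker panel of mostly-absent
  # OTUs carries no recoverable signal
  prevalent <- colnames(rel)[colMeans(rel > 0) >= 0.5]
  if (length(prevalent) < panel_size) prevalent <- colnames(rel)
  with_seed(seed, {
    draw <- function() {
      panel <- sample(prevalent, panel_size)
      w <- rep_len(c(1, -1), panel_size)
      z <- scale(rel[, panel, drop = FALSE])
      z[is.nan(z)] <- 0
      eta <- as.vector(z %*% w) * logit_scale / sqrt(panel_size)
      labels <- stats::rbinom(nrow(rel), 1L, stats::plogis(eta))
      list(panel = stats::setNames(w, panel),
           labels = stats::setNames(labels, rownames(rel)))
    }
    res <- draw()
    if (length(unique(res$labels)) == 1L) {
      res <- draw()
      if (length(unique(res$labels)) == 1L) {
        stop("degenerate labels: all samples fell in one class twice")
      }
    }
    res
  })
}

#' Simulate a pair of sample-matched tables sharing latent factors
#'
#' `X` and `Y` are noisy linear images of the same latent factor scores;
#' `noise_sd` tunes the association strength (0 shared factors gives two
#' independent noise tables).
#'
#' @param n samples; `p`, `q` feature counts of the two tables.
#' @param shared_factors number of shared latent factors
#'   (`<= min(p, q)`).
#' @param noise_sd SD of additive Gaussian noise.
#' @param seed integer seed.
#' @return list with matrices `x` (n x p) and `y` (n x q).
#' @export
simulate_linked_tables <- function(n, p, q, shared_factors, noise_sd, seed) {
  if (shared_factors > min(p, q)) stop("shared_factors must be <= min(p, q)")
  with_seed(seed, {
    x <- matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
    y <- matrix(stats::rnorm(n * q, 0, noise_sd), n, q)
    if (shared_factors > 0) {
      s <- matrix(stats::rnorm(n * shared_factors), n, shared_factors)
      a <- matrix(stats::rnorm(p * shared_factors), p, shared_factors)
      b <- matrix(stats::rnorm(q * shared_factors), q, shared_factors)
      x <- s %*% t(a) + x
      y <- s %*% t(b) + y
    }
    dimnames(x) <- list(sprintf("S%03d", seq_len(n)), sprintf("X%03d", seq_len(p)))
    dimnames(y) <- list(sprintf("S%03d", seq_len(n)), sprintf("Y%03d", seq_len(q)))
    list(x = x, y = y)
  })
}
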