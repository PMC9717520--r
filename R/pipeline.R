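#' Default pipeline configuration
#'
#' All study parameters surfaced in one place: rarefaction depth 27,226,
#' LEfSe thresholds (LDA > 2.0, p < 0.05), SparCC network thresholds
#' (|r| > 0.7, p < 0.05, 100 bootstraps), coabundance soft power 8 with
#' minimum module size 5, 999 PERMANOVA/Monte Carlo permutations, 10,000 KS
#' bootstraps, and 10-fold x 5-repeat maturity cross-validation. The demo
#' cohort/metabolome sizes keep an end-to-end run on one CPU short while
#' exercising every stage.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @return named list of parameters.
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = seed,
    rarefy_depth = 27226,
    lefse_lda_cut = 2.0,
    lefse_p_cut = 0.05,
    sparcc_r_cut = 0.7,
    sparcc_p_cut = 0.05,
    sparcc_n_boot = 100,
    module_beta = 8,
    module_min_size = 5,
    n_permutations = 999,
    ks_n_boot = 10000,
    maturity_n_folds = 10,
    maturity_n_repeats = 5,
    # demo problem sizes (synthetic cohort)
    demo_n_taxa = 60,
    demo_n_age_taxa = 8,
    demo_n_peaks = 120,
    demo_module_sizes = c(15L, 10L, 8L),
    demo_sparcc_taxa = 12,
    demo_lib_meanlog = log(30000)
  )
}

validate_run_config <- function(config) {
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, config)
}

#' Run the full demo pipeline on simulated data
#'
#' Simulates a cohort, metabolome, and diarrhea labels with planted
#' structure, then executes every analysis stage in dependency order:
#' rarefaction, alpha/beta diversity with PERMANOVA, LEfSe differential
#' abundance at day 0, SparCC networks per diet group with topology and KS
#' comparison, metabolite filtering/normalization/OPLS-DA/modules, the
#' microbiota-age model with relative-maturity contrasts, co-inertia
#' coupling, and the mRMR/SVM diarrhea classifier. Every stage output is
#' written as TSV under `out_dir` and checksummed into `MANIFEST.tsv`;
#' reruns with the same config are bit-identical.
#'
#' @param config (partial) configuration list; see [default_run_config()].
#'   Unknown keys are rejected before any stage runs.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the manifest data.frame and the in-memory
#'   stage results.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("micromat_run_")) {
  cfg <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(stage) {
    message(sprintf("[micromat] %-22s %+6.1fs", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  outputs <- list()
  save_tsv <- function(obj, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    df <- as.data.frame(obj)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) formatC(v, digits = 10, format = "g"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = !is.null(rownames(obj)) &&
                         !identical(rownames(obj), as.character(seq_len(nrow(df)))))
    outputs[[name]] <<- path
    invisible(path)
  }

  log_stage("simulate cohort")
  cohort <- simulate_cohort(cohort_spec(
    n_taxa = cfg$demo_n_taxa, n_age_taxa = cfg$demo_n_age_taxa,
    lib_meanlog = cfg$demo_lib_meanlog,
    maturity_shift_days = c(I5007_Oral = 3),
    seed = cfg$seed
  ))
  write_count_table(cohort$table, file.path(out_dir, "counts.tsv"))
  outputs[["counts"]] <- file.path(out_dir, "counts.tsv")
  save_tsv(cohort$metadata, "metadata")

  log_stage("rarefy + diversity")
  depth <- min(cfg$rarefy_depth, min(library_sizes(cohort$table)))
  rare <- rarefy(cohort$table, depth, seed = cfg$seed + 1)
  meta <- cohort$metadata[match(sample_ids(rare), cohort$metadata$sample_id), ]
  alpha <- alpha_diversity(rare)
  save_tsv(alpha, "alpha_diversity")
  d0 <- meta$age_days == 0
  bc <- bray_curtis(rarefy(cohort$table, depth, seed = cfg$seed + 1))
  perm <- permanova(stats::as.dist(as.matrix(bc)[d0, d0]),
                    meta$diet_group[d0],
                    n_permutations = cfg$n_permutations, seed = cfg$seed + 2)
  save_tsv(data.frame(term = "diet_day0", pseudo_F = perm$pseudo_F,
                      R2 = perm$R2, p_value = perm$p_value), "permanova")

  log_stage("lefse day 0")
  rel <- to_relative_abundance(rare)
  lefse <- run_lefse(
    structure(list(values = rel$values[d0, , drop = FALSE]),
              class = "relative_abundance"),
    meta$diet_group[d0], lda_cut = cfg$lefse_lda_cut,
    p_cut = cfg$lefse_p_cut, seed = cfg$seed + 3
  )
  save_tsv(lefse, "lefse_day0")

  log_stage("sparcc networks")
  top_taxa <- names(sort(colMeans(rel$values), decreasing = TRUE))[
    seq_len(cfg$demo_sparcc_taxa)]
  nets <- list()
  for (grp in c("control", "I5007")) {
    sel <- meta$diet_group == grp & d0
    res <- sparcc_bootstrap_p(cohort$table$counts[meta$sample_id[sel],
                                                  top_taxa, drop = FALSE],
                              n_boot = min(cfg$sparcc_n_boot, 50),
                              n_inner = 5, seed = cfg$seed + 4)
    nets[[grp]] <- build_network(res, r_cut = cfg$sparcc_r_cut,
                                 p_cut = cfg$sparcc_p_cut)
  }
  topo <- rbind(
    data.frame(group = "control", topology(nets$control)),
    data.frame(group = "I5007", topology(nets$I5007))
  )
  save_tsv(topo, "network_topology")
  ks <- compare_networks_ks(nets$control, nets$I5007,
                            n_boot = min(cfg$ks_n_boot, 1000),
                            seed = cfg$seed + 5)
  save_tsv(ks, "network_ks")
  ov <- edge_overlap(nets$control, nets$I5007)
  save_tsv(data.frame(t(ov$counts)), "network_edge_overlap")

  log_stage("metabolome")
  met <- simulate_metabolome(metabolome_spec(
    n_peaks = cfg$demo_n_peaks, module_sizes = cfg$demo_module_sizes,
    seed = cfg$seed + 6
  ))
  pm <- tic_normalize(filter_peaks(met$matrix))
  # peak intensities are analyzed on the log scale throughout
  logbio <- log(pm$intensities[!pm$is_qc, , drop = FALSE])
  vip <- oplsda_vip(logbio, met$groups)
  save_tsv(vip$selection, "oplsda_vip")
  mods <- coabundance_modules(logbio, beta = cfg$module_beta,
                              min_size = cfg$module_min_size)
  save_tsv(mods$assignment, "metabolite_modules")
  save_tsv(compare_module_abundance(mods, met$groups), "module_wilcoxon")

  log_stage("maturity")
  sel_taxa <- select_age_taxa(rel, meta, n_folds = min(cfg$maturity_n_folds, 5),
                              n_repeats = min(cfg$maturity_n_repeats, 2),
                              subset_sizes = c(2, 4, 6, 8, 10, 15, 20),
                              seed = cfg$seed + 7)
  model <- fit_maturity_model(rel, meta, sel_taxa$selected_taxa,
                              seed = cfg$seed + 8)
  scores <- score_maturity(model, rel, meta)
  save_tsv(scores, "maturity_scores")
  grp <- paste(meta$diet_group, meta$oral_group, sep = "_")
  contrast <- grp %in% c("control_Nonoral", "I5007_Oral")
  save_tsv(compare_maturity(scores[contrast, ], grp[contrast]),
           "maturity_contrast")

  log_stage("coinertia")
  d0_ids <- meta$sample_id[d0]
  linked <- simulate_linked_tables(length(d0_ids), 20, 15, 2, 0.5,
                                   seed = cfg$seed + 9)
  cia <- monte_carlo_test(linked$x, linked$y, via_pcoa = FALSE,
                          n_permutations = cfg$n_permutations,
                          seed = cfg$seed + 10)
  save_tsv(data.frame(rv = cia$rv, p_value = cia$p_value), "coinertia")

  log_stage("classifier")
  lab <- simulate_diarrhea_labels(rare, panel_size = 5, logit_scale = 6,
                                  seed = cfg$seed + 11)
  ranking <- mrmr_rank(rel, lab$labels)
  ifs <- ifs_svm_loocv(rel, lab$labels, ranking, max_size = 15,
                       seed = cfg$seed + 12)
  save_tsv(ifs$curve, "ifs_curve")

  manifest <- data.frame(
    output = names(outputs),
    file = basename(unlist(outputs)),
    md5 = unname(tools::md5sum(unlist(outputs))),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(out_dir, "MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_stage("done")
  invisible(list(manifest = manifest, config = cfg, out_dir = out_dir,
                 results = list(permanova = perm, lefse = lefse,
                                networks = nets, vip = vip, modules = mods,
                                maturity = list(model = model, scores = scores),
                                coinertia = cia, ifs = ifs)))
}
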