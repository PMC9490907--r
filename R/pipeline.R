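#' Full pipeline run configuration
#'
#' Bundles the configuration of every stage: simulation, labeling, tiling and
#' feature extraction, MIL training and splitting, stain-quantification hue
#' bands, and the downstream statistics. Fully serialisable; it is echoed
#' into the run report for provenance, and every random draw in a run flows
#' from the seeds recorded here.
#'
#' @param sim A [sim_config()].
#' @param policy A [label_policy()].
#' @param tile_size,min_tissue Tiling parameters (see [tile()]).
#' @param feature_dim Dimension of the default tile feature extractor.
#' @param n_folds Monte Carlo cross-validation folds.
#' @param split_seed Seed for [make_splits()] and per-fold training.
#' @param mil Named list of [mil_train()] hyperparameters
#'   (`lr`, `max_epochs`, `patience`, `embed`, `attn_hidden`, `gated`,
#'   `instance_loss_weight`, `B`).
#' @param dark,light [hue_range()] band parameters for stain quantification.
#' @param top_k Number of top-attention tiles quantified per slide.
#' @param n_perm Permutations for differential correlation.
#' @param n_levels Quantile bins for conditional-independence tests.
#' @param permute_labels Permute the derived labels before training (null
#'   calibration runs).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(sim = sim_config(),
                            policy = label_policy(),
                            tile_size = 256, min_tissue = 0.5,
                            feature_dim = 64,
                            n_folds = 10, split_seed = sim$seed + 100L,
                            mil = list(),
                            dark = dark_blue_range(),
                            light = light_blue_range(),
                            top_k = 100, n_perm = 1000, n_levels = 3,
                            z_scope = c("slide", "cohort"),
                            permute_labels = FALSE) {
  z_scope <- match.arg(z_scope)
  mil_defaults <- list(lr = 2e-4, max_epochs = 200, patience = 10,
                       embed = 64, attn_hidden = 48, gated = TRUE,
                       instance_loss_weight = 0.3, B = 8)
  mil <- utils::modifyList(mil_defaults, mil)
  structure(list(sim = sim, policy = policy, tile_size = tile_size,
                 min_tissue = min_tissue, feature_dim = feature_dim,
                 n_folds = n_folds, split_seed = as.integer(split_seed),
                 mil = mil, dark = dark, light = light, top_k = top_k,
                 n_perm = n_perm, n_levels = n_levels, z_scope = z_scope,
                 permute_labels = permute_labels),
            class = "pipeline_config")
}

# simulate + segment + tile + featurize + count stains for one donor,
# retaining only tile-level data (images are discarded to bound memory)
process_slide <- function(donor, config, extractor) {
  sl <- generate_slide(donor, config$sim)
  mask <- segment_tissue(sl$image)
  if (isTRUE(attr(mask, "empty"))) return(NULL)
  grid <- tile(sl$image, mask, config$tile_size, config$min_tissue)
  if (nrow(grid) == 0L) return(NULL)
  bag <- extract_features(sl$image, grid, extractor, donor$donor_id)
  hsi <- rgb_to_hsi(sl$image)
  ts <- config$tile_size
  meta <- grid
  meta$donor_id <- donor$donor_id
  meta$dark_count <- meta$light_count <- integer(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    ys <- (grid$y0[k] + 1L):(grid$y0[k] + ts)
    xs <- (grid$x0[k] + 1L):(grid$x0[k] + ts)
    sub <- list(h = hsi$h[ys, xs], s = hsi$s[ys, xs], i = hsi$i[ys, xs])
    meta$dark_count[k] <- sum(positive_mask_hsi(sub$h, sub$s, sub$i, config$dark))
    meta$light_count[k] <- sum(positive_mask_hsi(sub$h, sub$s, sub$i, config$light))
  }
  cx <- grid$x0 + ts %/% 2L
  cy <- grid$y0 + ts %/% 2L
  meta$center_region <- sl$region_mask[cbind(cy + 1L, cx + 1L)]
  nrd <- nrow(sl$true_tile_density)
  meta$true_density <- sl$true_tile_density[cbind(grid$row + 1L, grid$col + 1L)]
  list(bag = bag, meta = meta, region_mask = sl$region_mask)
}

#' Run the full analysis pipeline
#'
#' Executes the stages simulate, label, featurize (tile + extract + stain
#' counts), split, train, evaluate, interpret, quantify and associate on
#' synthetic data, returning all stage outputs plus a compact report. With an
#' `outdir`, artifacts (cohort CSV, evaluation JSON, stain summaries,
#' report) are written to disk, and a completed run with an identical
#' configuration is reloaded instead of recomputed (hash check on the
#' serialised configuration).
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory for artifacts and caching.
#' @param keep_masks Keep region masks in memory for interpretation (default
#'   TRUE; masks are also needed by [region_attention()]).
#' @param verbose Print stage progress.
#' @return A `pipeline_result` list: `cohort` (with `label` and `p_ci`),
#'   `tile_meta`, `eval` (per-fold and aggregate), `region_attention`,
#'   `stain` (per-slide summaries and group tests), `assoc` (correlation
#'   table, differential correlation, conditional-independence tests), and
#'   `report` (flat named list of headline numbers).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         keep_masks = TRUE, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    hash <- config_hash(config)
    cache <- file.path(outdir, "result.rds")
    if (file.exists(cache)) {
      prev <- readRDS(cache)
      if (identical(attr(prev, "config_hash"), hash)) {
        say("configuration unchanged; reusing completed run in %s", outdir)
        return(prev)
      }
    }
  }

  say("stage simulate: %d donors", config$sim$n_donors)
  cohort <- generate_cohort(config$sim)
  say("stage label (%s policy)", config$policy$mode)
  cohort <- label_cohort(cohort, config$policy)
  if (config$permute_labels) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(config$split_seed + 1L)
    cohort$label <- sample(cohort$label)
  }

  say("stage featurize: tiling, features, stain counts")
  extractor <- default_extractor(config$feature_dim)
  bags <- list(); metas <- list(); masks <- list()
  for (i in seq_len(nrow(cohort))) {
    ps <- process_slide(cohort[i, ], config, extractor)
    if (is.null(ps)) { say("  slide %s skipped: no tissue", cohort$donor_id[i]); next }
    bags[[cohort$donor_id[i]]] <- ps$bag
    metas[[cohort$donor_id[i]]] <- ps$meta
    if (keep_masks) masks[[cohort$donor_id[i]]] <- ps$region_mask
  }
  tile_meta <- do.call(rbind, metas)
  rownames(tile_meta) <- NULL

  use <- cohort$label %in% c("CI", "NCI") & cohort$donor_id %in% names(bags)
  ids <- cohort$donor_id[use]
  ylab <- as.integer(cohort$label[use] == "CI")
  say("stage split: %d folds over %d labeled donors", config$n_folds, length(ids))
  splits <- make_splits(ids, ylab, config$n_folds, seed = config$split_seed)

  say("stage train/evaluate")
  names(ylab) <- ids
  fold_models <- list(); fold_results <- list()
  for (f in seq_len(config$n_folds)) {
    fold <- splits$folds[[f]]
    mdl <- mil_train(bags[fold$train], ylab[fold$train],
                     bags[fold$val], ylab[fold$val],
                     lr = config$mil$lr, max_epochs = config$mil$max_epochs,
                     patience = config$mil$patience, embed = config$mil$embed,
                     attn_hidden = config$mil$attn_hidden,
                     gated = config$mil$gated,
                     instance_loss_weight = config$mil$instance_loss_weight,
                     B = config$mil$B, seed = config$split_seed + f)
    fold_models[[f]] <- mdl
    fold_results[[f]] <- evaluate_fold(mdl, bags[fold$test], ylab[fold$test])
    say("  fold %d: AUC %.3f, balanced accuracy %.3f", f,
        fold_results[[f]]$auc, fold_results[[f]]$balanced_accuracy)
  }
  agg <- aggregate_folds(fold_results)
  best <- fold_models[[agg$best_fold]]
  say("  mean AUC %.3f (Wilcoxon p = %.2g), best fold %d",
      agg$mean_auc, agg$auc_wilcoxon$p.value, agg$best_fold)

  # slide-level probabilities from the best-fold model, for every slide
  cohort$p_ci <- NA_real_
  for (id in names(bags))
    cohort$p_ci[cohort$donor_id == id] <- predict_slide(bags[[id]], best)

  say("stage interpret: attention maps and region statistics")
  maps <- lapply(bags, attention_map, model = best)
  if (identical(config$z_scope, "cohort")) maps <- cohort_z_transform(maps)
  regatt <- if (keep_masks)
    region_attention(maps[names(masks)], masks) else NULL

  say("stage quantify: positive pixels in top-%d attention tiles", config$top_k)
  summaries <- list(); top_tiles <- list()
  for (id in names(bags)) {
    tk <- suppressWarnings(top_k_tiles(maps[[id]], config$top_k))
    top_tiles[[id]] <- data.frame(donor_id = id, rank = tk$rank,
                                  row = tk$row, col = tk$col)
    mm <- metas[[id]]
    key <- paste(tk$row, tk$col)
    sel <- mm[match(key, paste(mm$row, mm$col)), ]
    summaries[[id]] <- summarize_slide(sel, id)
  }
  top_tiles <- do.call(rbind, top_tiles)
  rownames(top_tiles) <- NULL
  stain_sum <- do.call(rbind, summaries)
  rownames(stain_sum) <- NULL
  sub <- merge(stain_sum, cohort, by = "donor_id")
  sub <- sub[sub$label %in% c("CI", "NCI") & !sub$missing, ]
  pred_group <- factor(ifelse(sub$p_ci >= 0.5, "pred_CI", "pred_NCI"),
                       levels = c("pred_CI", "pred_NCI"))
  stain_tests <- list(
    predicted = if (nlevels(droplevels(pred_group)) == 2L)
      compare_groups(sub, pred_group) else NULL,
    labeled = compare_groups(sub, factor(sub$label, levels = c("CI", "NCI")))
  )

  say("stage associate: correlations and conditional independence")
  lab01 <- ifelse(sub$label == "CI", 1, 0)
  cors <- rbind(
    assoc_row("p_ci", "age", sub$p_ci, sub$age),
    assoc_row("p_ci", "braak", sub$p_ci, sub$braak),
    assoc_row("p_ci", "artag", sub$p_ci, sub$artag),
    assoc_row("p_ci", "cvd", sub$p_ci, sub$cvd),
    assoc_row("p_ci", "label", sub$p_ci, lab01),
    assoc_row("median_dark", "p_ci", sub$median_dark, sub$p_ci),
    assoc_row("median_dark", "age", sub$median_dark, sub$age),
    assoc_row("median_dark", "label", sub$median_dark, lab01)
  )
  diffcorr <- tryCatch(
    differential_correlation(sub$age, sub$p_ci, sub$label,
                             n_perm = config$n_perm, seed = config$split_seed + 2L),
    error = function(e) NULL)
  ci_tests <- list(
    label_age_given_dark = tryCatch(
      conditional_independence(lab01, sub$age, sub$median_dark,
                               n_levels = config$n_levels),
      error = function(e) NULL),
    label_dark_given_age = tryCatch(
      conditional_independence(lab01, sub$median_dark, sub$age,
                               n_levels = config$n_levels),
      error = function(e) NULL)
  )

  report <- list(
    n_donors = nrow(cohort),
    n_labeled = length(ids),
    mean_auc = agg$mean_auc,
    mean_balanced_accuracy = agg$mean_balanced_accuracy,
    auc_wilcoxon_p = agg$auc_wilcoxon$p.value,
    best_fold = agg$best_fold,
    wm_attention_median_z = if (!is.null(regatt))
      stats::median(regatt$per_slide$wm_median, na.rm = TRUE) else NA,
    gm_attention_median_z = if (!is.null(regatt))
      stats::median(regatt$per_slide$gm_median, na.rm = TRUE) else NA,
    region_paired_t_p = if (!is.null(regatt)) regatt$p.value else NA,
    dark_welch_p_predicted = if (!is.null(stain_tests$predicted))
      stain_tests$predicted$p.value[1] else NA,
    ratio_welch_p_predicted = if (!is.null(stain_tests$predicted))
      stain_tests$predicted$p.value[2] else NA,
    rho_age_pci = cors$rho[cors$pair == "p_ci~age"],
    ci_G_label_age_given_dark = if (!is.null(ci_tests$label_age_given_dark))
      ci_tests$label_age_given_dark$G else NA,
    ci_G_label_dark_given_age = if (!is.null(ci_tests$label_dark_given_age))
      ci_tests$label_dark_given_age$G else NA
  )

  result <- structure(list(cohort = cohort, tile_meta = tile_meta,
                           eval = c(agg, list(folds = fold_results)),
                           best_model = best, maps = maps,
                           region_attention = regatt, top_tiles = top_tiles,
                           stain = list(summaries = stain_sum, tests = stain_tests),
                           assoc = list(correlations = cors, diffcorr = diffcorr,
                                        ci_tests = ci_tests),
                           report = report, config = config),
                      class = "pipeline_result")
  if (!is.null(outdir)) {
    attr(result, "config_hash") <- config_hash(config)
    write_cohort_csv(cohort, file.path(outdir, "cohort.csv"))
    utils::write.csv(stain_sum, file.path(outdir, "stain_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(top_tiles, file.path(outdir, "top_tiles.csv"),
                     row.names = FALSE)
    if (!is.null(regatt))
      utils::write.csv(regatt$per_slide,
                       file.path(outdir, "region_attention.csv"),
                       row.names = FALSE)
    write_mil_checkpoint(best, file.path(outdir, "best_model.json"))
    utils::write.csv(cors, file.path(outdir, "correlations.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    saveRDS(result, file.path(outdir, "result.rds"))
  }
  result
}

#' Run the pipeline up to a named stage
#'
#' Thin stage-addressable wrapper over [run_pipeline()]. Because every stage
#' is deterministic given the configuration and the full run is cached on
#' disk by configuration hash, requesting any stage executes (or reuses) the
#' run and returns that stage's artifacts; rerunning a completed stage with
#' an unchanged configuration is a no-op.
#'
#' @param stage One of `"simulate"`, `"label"`, `"featurize"`, `"split"`,
#'   `"train"`, `"evaluate"`, `"interpret"`, `"quantify"`, `"associate"`,
#'   `"report"`, `"all"`.
#' @param config A [pipeline_config()].
#' @param outdir Output/cache directory (strongly recommended).
#' @param verbose Print stage progress.
#' @return The artifacts of the requested stage (the full `pipeline_result`
#'   for `"all"`).
#' @export
run_stage <- function(stage = c("all", "simulate", "label", "featurize",
                                "split", "train", "evaluate", "interpret",
                                "quantify", "associate", "report"),
                      config = pipeline_config(), outdir = NULL,
                      verbose = TRUE) {
  stage <- match.arg(stage)
  res <- run_pipeline(config, outdir = outdir, verbose = verbose)
  switch(stage,
         all = res,
         simulate = res$cohort[, setdiff(names(res$cohort), c("label", "p_ci"))],
         label = res$cohort[, setdiff(names(res$cohort), "p_ci")],
         featurize = res$tile_meta,
         split = make_splits(res$cohort$donor_id[res$cohort$label %in% c("CI", "NCI")],
                             res$cohort$label[res$cohort$label %in% c("CI", "NCI")],
                             config$n_folds, seed = config$split_seed),
         train = res$best_model,
         evaluate = res$eval,
         interpret = list(maps = res$maps, region_attention = res$region_attention),
         quantify = res$stain,
         associate = res$assoc,
         report = res$report)
}

assoc_row <- function(a, b, x, y) {
  sp <- tryCatch(spearman_cor(x, y), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(sp))
    return(data.frame(pair = paste0(a, "~", b), rho = NA_real_,
                      p.value = NA_real_, n = sum(stats::complete.cases(x, y)),
                      method = "spearman"))
  data.frame(pair = paste0(a, "~", b), rho = sp$rho, p.value = sp$p.value,
             n = sp$n, method = "spearman")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2)
  unname(tools::md5sum(tmp))
}
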