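default_config <- function() {
  list(
    version = 1,
    seed = NULL,
    out_dir = NULL,
    distance = "bray",
    match = list(caliper_sd = 0.2),
    split = list(ratio = c(2, 1)),
    screen = list(abundance = 0.005, p_pre = 0.05, p_key = 0.01,
                  importance = 1e-4, n_trees = 1000),
    rfcv = list(folds = 5, repeats = 5, n_trees = 500, rule = "min"),
    model = list(n_trees = 1000, importance_floor = 0.001),
    pod = list(folds = 5, repeats = 5),
    sparcc = list(n_inner = 20, n_boot = 100,
                  indicators = c("ALB", "Pro24h", "SCr"), method = "sparcc"),
    nmds = list(restarts = 20, max_iter = 300),
    anosim = list(n_perm = 999))
}

config_error <- function(...) {
  stop(structure(class = c("gutpod_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Validate and normalise a pipeline configuration
#'
#' Merges user settings over the defaults and enforces the reproducibility
#' contract before any compute: a master seed must be present (every random
#' stage derives its own stream from it) and referenced input files must
#' exist.
#'
#' @param config named list (e.g. from [yaml::read_yaml]).
#' @return The normalised config.
#' @export
validate_config <- function(config) {
  cfg <- modifyList(default_config(), config)
  if (is.null(cfg$seed)) config_error("config must declare a seed")
  if (is.null(cfg$out_dir)) config_error("config must declare out_dir")
  if (!cfg$distance %in% c("bray", "unifrac-unweighted", "unifrac-weighted"))
    config_error("unknown distance: ", cfg$distance)
  if (is.null(cfg$input) == is.null(cfg$synthetic))
    config_error("exactly one of input/synthetic must be given")
  if (!is.null(cfg$input)) {
    for (f in c("otu_table", "metadata")) {
      if (is.null(cfg$input[[f]])) config_error("input$", f, " is required")
      if (!file.exists(cfg$input[[f]]))
        config_error("input file not found: ", cfg$input[[f]])
    }
    if (!is.null(cfg$input$tree) && !file.exists(cfg$input$tree))
      config_error("tree file not found: ", cfg$input$tree)
  }
  cfg
}

pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    sp_args <- cfg$synthetic
    sp_args$external_cohorts <- NULL; sp_args$batch_sigma_external <- NULL
    preset <- sp_args$preset; sp_args$preset <- NULL
    spec <- do.call(synthetic_spec, sp_args)
    n_ext <- cfg$synthetic$external_cohorts %||% 1
    if (n_ext > 0) {
      cohorts <- generate_multicohort(
        spec, n_cohorts = n_ext + 1,
        batch_sigma = cfg$synthetic$batch_sigma_external %||% 0.5,
        seed = cfg$seed)
    } else cohorts <- list(generate_cohort(spec, seed = cfg$seed))
    main <- cohorts[[1]]
    ext <- if (n_ext > 0) cohorts[-1] else list()
    list(table = main$table, metadata = main$metadata, tree = main$tree,
         taxonomy = main$taxonomy, truth = main$truth,
         external = lapply(ext, function(e)
           list(name = e$metadata$cohort[1], table = e$table,
                metadata = e$metadata)))
  } else {
    ext <- lapply(cfg$input$external %||% list(), function(e)
      list(name = e$name %||% basename(e$otu_table),
           table = read_otu_table(e$otu_table,
                                  format = e$format %||% "tsv",
                                  orientation = e$orientation %||% "otus-as-rows"),
           metadata = read_metadata(e$metadata)))
    list(table = read_otu_table(cfg$input$otu_table,
                                format = cfg$input$format %||% "tsv",
                                orientation = cfg$input$orientation %||% "otus-as-rows"),
         metadata = read_metadata(cfg$input$metadata),
         tree = if (!is.null(cfg$input$tree)) read_otu_tree(cfg$input$tree),
         taxonomy = if (!is.null(cfg$input$taxonomy))
           read_taxonomy(cfg$input$taxonomy),
         truth = NULL, external = ext)
  }
}

beta_distance <- function(tab, tree, distance) {
  switch(distance,
         "bray" = bray_curtis(tab),
         "unifrac-unweighted" = unifrac(tab, tree, weighted = FALSE),
         "unifrac-weighted" = unifrac(tab, tree, weighted = TRUE))
}

roc_summary <- function(roc) {
  list(auc = roc$auc, cutoff = roc$cutoff, sensitivity = roc$sensitivity,
       specificity = roc$specificity, n_case = roc$n_case,
       n_control = roc$n_control)
}

#' Run the full diagnostic-model workflow
#'
#' Executes the study pipeline in order: propensity matching, 2:1
#' discovery/validation split, discovery-cohort alpha/beta diversity with
#' ordination and ANOSIM, the three-criterion OTU screen, cross-validated
#' feature-count selection, final model training, leak-free discovery POD +
#' ROC, validation- and external-cohort ROC, and the panel x clinical
#' SparCC block. Every stage's output is persisted under `out_dir` and a
#' combined report is written as JSON and markdown. Identical config +
#' inputs give a byte-identical report.
#'
#' @param config a config list (see [validate_config]) or a path to a YAML
#'   file.
#' @return The report (list of class `study_report`), invisibly writing
#'   `report.json`, `report.md` and per-stage files into `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "gutpod_config_error")) stop(e)
      stop(structure(class = c("gutpod_stage_error", "error", "condition"),
                     list(message = paste0("stage '", name, "' failed: ",
                                           conditionMessage(e)),
                          call = NULL, stage = name)))
    })
  }

  inp <- stage("load", pipeline_inputs(cfg))
  tab <- inp$table; meta <- inp$metadata

  mc <- stage("match", propensity_match(meta, cfg$match$caliper_sd, seed))
  sp <- stage("split", split_discovery_validation(mc, cfg$split$ratio, seed))
  write.csv(mc$pairs, file.path(cfg$out_dir, "matched_pairs.csv"),
            row.names = FALSE)
  write.csv(data.frame(
    sample_id = c(sp$discovery_ids, sp$validation_ids),
    side = rep(c("discovery", "validation"),
               c(length(sp$discovery_ids), length(sp$validation_ids)))),
    file.path(cfg$out_dir, "cohort_split.csv"), row.names = FALSE)

  disc_tab <- tab[sp$discovery_ids, ]
  disc_lab <- meta$group[match(sp$discovery_ids, meta$sample_id)]
  val_tab <- tab[sp$validation_ids, ]
  val_lab <- meta$group[match(sp$validation_ids, meta$sample_id)]

  div <- stage("diversity", {
    alpha <- alpha_diversity(disc_tab, disc_lab)
    D <- beta_distance(disc_tab, inp$tree, cfg$distance)
    ord_p <- pcoa(D)
    ord_n <- nmds(D, restarts = cfg$nmds$restarts,
                  max_iter = cfg$nmds$max_iter, seed = seed)
    an <- anosim(D, disc_lab, n_perm = cfg$anosim$n_perm, seed = seed)
    write.csv(alpha$per_sample, file.path(cfg$out_dir, "alpha_diversity.csv"),
              row.names = FALSE)
    write_dist_matrix(D, file.path(cfg$out_dir, "beta_distance.tsv"))
    write.csv(data.frame(sample_id = rownames(ord_p$coords), ord_p$coords),
              file.path(cfg$out_dir, "pcoa_coords.csv"), row.names = FALSE)
    writeLines(jsonlite::toJSON(list(R = an$R, p = an$p,
                                     n_perm = an$n_perm),
                                auto_unbox = TRUE, digits = NA),
               file.path(cfg$out_dir, "anosim.json"))
    list(alpha = alpha, anosim = an, pcoa = ord_p, nmds = ord_n)
  })

  scr <- stage("screen", select_candidates(
    disc_tab, disc_lab, abundance = cfg$screen$abundance,
    p_pre = cfg$screen$p_pre, p_key = cfg$screen$p_key,
    importance = cfg$screen$importance, n_trees = cfg$screen$n_trees,
    seed = seed))
  write_screen_result(scr, file.path(cfg$out_dir, "screen.csv"))
  if (length(scr$candidates) < 2)
    stop(structure(class = c("gutpod_stage_error", "error", "condition"),
                   list(message = "stage 'screen' failed: fewer than 2 candidate OTUs survive the screen",
                        call = NULL, stage = "screen")))

  curve <- stage("rfcv", cv_error_curve(
    disc_tab, disc_lab, scr$candidates, folds = cfg$rfcv$folds,
    repeats = cfg$rfcv$repeats, n_trees = cfg$rfcv$n_trees, seed = seed,
    rule = cfg$rfcv$rule))
  panel <- head(scr$candidates, curve$chosen_k)
  model <- stage("train", train_final(
    disc_tab, disc_lab, panel, importance_floor = cfg$model$importance_floor,
    n_trees = cfg$model$n_trees, seed = seed))
  write_pod_model(model, file.path(cfg$out_dir, "model.json"))

  rocs <- stage("evaluate", {
    pod_disc <- compute_pod(model, disc_tab, disc_lab,
                            mode = "cross-validated", folds = cfg$pod$folds,
                            repeats = cfg$pod$repeats, seed = seed)
    out <- list(discovery = roc_analysis(pod_disc, disc_lab,
                                         case_level = model$case_level))
    out$validation <- validate_external(model, val_tab, val_lab)
    for (e in inp$external)
      out[[e$name]] <- validate_external(
        model, e$table, e$metadata$group[match(rownames(e$table),
                                               e$metadata$sample_id)])
    for (nm in names(out)) {
      write.csv(out[[nm]]$curve,
                file.path(cfg$out_dir, paste0("roc_", nm, ".csv")),
                row.names = FALSE)
    }
    out
  })

  assoc <- stage("sparcc", {
    case_level <- model$case_level
    case_ids <- meta$sample_id[meta$group == case_level]
    case_ids <- intersect(rownames(tab), case_ids)
    tryCatch({
      a <- clinical_association(tab[case_ids, ], meta, panel_ids = panel,
                                indicators = cfg$sparcc$indicators,
                                method = cfg$sparcc$method,
                                n_inner = cfg$sparcc$n_inner,
                                n_boot = cfg$sparcc$n_boot, seed = seed)
      write.csv(a$block, file.path(cfg$out_dir, "sparcc_block.csv"),
                row.names = FALSE)
      a
    }, error = function(e) {
      warning("clinical association skipped: ", conditionMessage(e))
      NULL
    })
  })

  report <- structure(list(
    package_version = as.character(packageVersion("gutpod")),
    config = cfg,
    matching = list(n_pairs = nrow(mc$pairs),
                    unmatched_cases = mc$unmatched_cases,
                    balance = as.list(mc$balance), caliper = mc$caliper),
    split = list(n_discovery = length(sp$discovery_ids),
                 n_validation = length(sp$validation_ids)),
    alpha = div$alpha$comparisons,
    anosim = list(R = div$anosim$R, p = div$anosim$p),
    pcoa_prop_explained = div$pcoa$prop_explained[1:2],
    nmds_stress = div$nmds$stress,
    screen = list(n_tested = nrow(scr$table),
                  n_candidates = length(scr$candidates),
                  candidates = scr$candidates),
    rfcv = list(k = curve$k, mean_error = unname(curve$mean_error),
                sd_error = unname(curve$sd_error),
                chosen_k = curve$chosen_k, rule = curve$rule),
    panel = panel,
    importance = model$importance,
    cohorts = lapply(rocs, roc_summary),
    sparcc = if (!is.null(assoc)) assoc$block,
    truth = if (!is.null(inp$truth))
      list(effect_otus = inp$truth$effect_otus)),
    class = "study_report")

  json <- jsonlite::toJSON(report, digits = NA, auto_unbox = TRUE,
                           force = TRUE, null = "null")
  writeLines(json, file.path(cfg$out_dir, "report.json"))
  writeLines(report_markdown(report), file.path(cfg$out_dir, "report.md"))
  invisible(report)
}

report_markdown <- function(rep) {
  fmt_roc <- function(nm, s) sprintf(
    "| %s | %.2f%% | %.4g | %.4g | %.4g | %d/%d |", nm, 100 * s$auc,
    s$cutoff, s$sensitivity, s$specificity, s$n_case, s$n_control)
  c(sprintf("# Diagnostic-model report (gutpod %s)", rep$package_version),
    "",
    sprintf("Matched pairs: %d (caliper %.3f); discovery n = %d, validation n = %d.",
            rep$matching$n_pairs, rep$matching$caliper,
            rep$split$n_discovery, rep$split$n_validation),
    "",
    "## Alpha diversity (discovery)",
    "",
    sprintf("- %s: statistic %.4g, p = %.4g (%s)", rep$alpha$index,
            rep$alpha$statistic, rep$alpha$p, rep$alpha$method),
    "",
    sprintf("ANOSIM R = %.4f (p = %.4g); NMDS stress = %.4f.",
            rep$anosim$R, rep$anosim$p, rep$nmds_stress),
    "",
    "## Screen and panel",
    "",
    sprintf("%d of %d OTUs passed the three-criterion screen; RFCV chose k = %d (%s rule).",
            rep$screen$n_candidates, rep$screen$n_tested,
            rep$rfcv$chosen_k, rep$rfcv$rule),
    sprintf("Panel: %s", paste(rep$panel, collapse = ", ")),
    "",
    "## Cohort performance",
    "",
    "| cohort | AUC | cut-off | sensitivity | specificity | case/control |",
    "|---|---|---|---|---|---|",
    vapply(names(rep$cohorts), function(nm)
      fmt_roc(nm, rep$cohorts[[nm]]), character(1)),
    "")
}
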