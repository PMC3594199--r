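#' Run the full grey-matter network pipeline
#'
#' Orchestrates simulate -> extract -> metrics -> smallworld -> regions ->
#' stats as one reproducible run. The configuration is a nested list (or a
#' path to a YAML file with the same structure):
#'
#' ```
#' out_dir: run1
#' seed: 1
#' simulate:            # optional; omit to use pre-existing volumes
#'   n_per_group: 5
#'   spec: {shape: [30, 30, 18], disease_fraction: 0.3}
#' network:
#'   target_spurious: 0.05
#'   n_null_pairs: 20000
#'   min_mask_voxels: 14
#'   n_reference: 20
#'   swaps_per_edge: 10
#' stages: [simulate, extract, metrics, smallworld, regions, stats]
#' overwrite: false
#' ```
#'
#' Without a `simulate` block the out_dir must already contain
#' `cohort.csv` plus `<id>_gm.nii.gz` (and optionally `<id>_labels.nii.gz`)
#' per subject. Completed stages are skipped when their outputs exist and
#' `overwrite` is false. A manifest (JSON) records the config, seeds,
#' per-subject thresholds/densities/node counts, package version and
#' timestamps; aggregation is ordered by subject id so reruns are
#' order-independent.
#'
#' @param config nested list or path to a YAML config file.
#' @return The run manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    out_dir = "gmnet_run", seed = 1L, overwrite = FALSE,
    stages = c("simulate", "extract", "metrics", "smallworld", "regions",
               "stats"),
    network = list())
  config <- utils::modifyList(defaults, config)
  net_defaults <- list(target_spurious = 0.05, n_null_pairs = 20000L,
                       min_mask_voxels = 14L, n_reference = 20L,
                       swaps_per_edge = 10L)
  net <- utils::modifyList(net_defaults, config$network)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  manifest <- list(config = config,
                   package_version = as.character(utils::packageVersion("gmnet")),
                   started = format(Sys.time(), usetz = TRUE),
                   stages_run = character(0), subjects = list())
  path_of <- function(id, what) file.path(out, paste0(id, "_", what))
  fresh <- function(p) config$overwrite || !all(file.exists(p))

  run_stage <- function(name, fn) {
    if (!(name %in% stages)) return(invisible(NULL))
    ok <- tryCatch({fn(); TRUE},
                   error = function(e) stop("pipeline stage '", name,
                                            "' failed: ",
                                            conditionMessage(e),
                                            call. = FALSE))
    manifest$stages_run <<- c(manifest$stages_run, name)
  }

  # -- simulate ------------------------------------------------------------
  run_stage("simulate", function() {
    if (is.null(config$simulate)) return()
    sim <- config$simulate
    spec <- do.call(synthetic_spec, if (is.null(sim$spec)) list() else
      sim$spec)
    n <- if (is.null(sim$n_per_group)) 5L else as.integer(sim$n_per_group)
    if (!fresh(file.path(out, "cohort.csv"))) return()
    coh <- generate_cohort(spec, n, seed = config$seed,
                           network = net)
    for (i in seq_along(coh$subjects)) {
      id <- coh$cohort$id[i]
      write_volume(coh$subjects[[i]]$volume, path_of(id, "gm.nii.gz"))
      write_labels(coh$subjects[[i]]$labels, path_of(id, "labels.nii.gz"),
                   voxel_size_mm = spec$voxel_size_mm)
    }
    write_cohort(coh$cohort, file.path(out, "cohort.csv"))
    jsonlite::write_json(
      list(score_model = coh$truth[c("score_intercept", "score_slope",
                                     "score_sd")],
           lambda = coh$truth$lambda, seed = coh$truth$seed,
           disease_fraction = coh$truth$disease_fraction),
      file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  })

  cohort <- read_cohort(file.path(out, "cohort.csv"))
  cohort <- cohort[order(cohort$id), , drop = FALSE]
  ids <- cohort$id

  # -- extract -------------------------------------------------------------
  run_stage("extract", function() {
    for (i in seq_along(ids)) {
      gpath <- path_of(ids[i], "graph.json")
      if (!fresh(gpath)) next
      vol <- read_volume(path_of(ids[i], "gm.nii.gz"))
      g <- extract_network(vol, target_spurious = net$target_spurious,
                           n_null_pairs = net$n_null_pairs,
                           seed = as.integer((as.numeric(config$seed) * 1000 + i) %% .Machine$integer.max),
                           min_mask_voxels = net$min_mask_voxels,
                           subject_id = ids[i])
      save_graph(g, gpath)
    }
  })

  # -- metrics -------------------------------------------------------------
  run_stage("metrics", function() {
    for (id in ids) {
      mpath <- path_of(id, "metrics.csv")
      if (!fresh(mpath)) next
      g <- load_graph(path_of(id, "graph.json"))
      rep_ <- graph_report(g)
      utils::write.csv(rep_$nodal, mpath, row.names = FALSE)
      jsonlite::write_json(rep_$global, path_of(id, "global.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  })

  # -- smallworld ----------------------------------------------------------
  run_stage("smallworld", function() {
    for (i in seq_along(ids)) {
      spath <- path_of(ids[i], "smallworld.json")
      if (!fresh(spath)) next
      g <- load_graph(path_of(ids[i], "graph.json"))
      sw <- suppressWarnings(
        small_world(g, n_reference = net$n_reference,
                    swaps_per_edge = net$swaps_per_edge,
                    seed = as.integer((as.numeric(config$seed) * 1000 + i) %% .Machine$integer.max)))
      jsonlite::write_json(unclass(sw), spath, auto_unbox = TRUE,
                           digits = NA)
    }
  })

  # -- regions -------------------------------------------------------------
  run_stage("regions", function() {
    for (id in ids) {
      rpath <- path_of(id, "regions.csv")
      if (!fresh(rpath)) next
      lpath <- path_of(id, "labels.nii.gz")
      if (!file.exists(lpath)) {
        warning("no label volume for subject ", id,
                "; regional stage skipped")
        next
      }
      vol <- read_volume(path_of(id, "gm.nii.gz"))
      labels <- read_labels(lpath)
      cubes <- extract_cubes(vol, min_mask_voxels = net$min_mask_voxels)
      g <- load_graph(path_of(id, "graph.json"))
      rep_ <- graph_report(g)
      assign <- assign_cubes_to_regions(cubes, labels)
      vols <- regional_volume(vol, labels)
      reg <- summarize_regions(rep_, assign, labels, vols)
      reg$subject <- id
      utils::write.csv(reg, rpath, row.names = FALSE)
    }
  })

  # -- stats ---------------------------------------------------------------
  run_stage("stats", function() {
    spath <- file.path(out, "group_stats.csv")
    if (!fresh(spath)) return()
    glob <- do.call(rbind, lapply(ids, function(id) {
      g <- jsonlite::read_json(path_of(id, "global.json"),
                               simplifyVector = TRUE)
      sw <- jsonlite::read_json(path_of(id, "smallworld.json"),
                                simplifyVector = TRUE)
      data.frame(id = id, size = g$size, density = g$density,
                 mean_degree = g$mean_degree,
                 mean_clustering = g$mean_clustering,
                 char_path_length = g$char_path_length,
                 mean_betweenness = g$mean_betweenness,
                 gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma)
    }))
    dat <- merge(cohort, glob, by = "id", sort = TRUE)
    covs <- data.frame(gm_volume = dat$global_gm_volume, age = dat$age,
                       sex = as.integer(factor(dat$sex)))
    props <- c("mean_clustering", "char_path_length", "gamma", "lambda",
               "sigma", "mean_betweenness")
    tests <- do.call(rbind, lapply(props, function(p) {
      a <- ancova_group(dat[[p]], dat$group, covs)
      lv <- levene_check(dat[[p]], dat$group)
      data.frame(property = p, F = a$F, df1 = a$df1, df2 = a$df2, p = a$p,
                 levene_p = lv$p, n = a$n)
    }))
    tests$p_fdr <- fdr_adjust(tests$p)
    utils::write.csv(tests, spath, row.names = FALSE)
    if (any(!is.na(dat$cognitive_score))) {
      cors <- do.call(rbind, lapply(c("char_path_length", "lambda"),
                                    function(p) {
        ct <- pearson_with_ci(rank_transform(dat$cognitive_score),
                              rank_transform(dat[[p]]))
        data.frame(property = p, r = ct$r, p = ct$p, ci_lo = ct$ci[1],
                   ci_hi = ct$ci[2], n = ct$n)
      }))
      cors$p_fdr <- fdr_adjust(cors$p)
      utils::write.csv(cors, file.path(out, "score_correlations.csv"),
                       row.names = FALSE)
    }
  })

  # -- manifest ------------------------------------------------------------
  manifest$subjects <- lapply(ids, function(id) {
    gpath <- path_of(id, "graph.json")
    if (!file.exists(gpath)) return(list(id = id))
    g <- load_graph(gpath)
    n <- igraph::vcount(g$graph)
    list(id = id, n_nodes = n, n_edges = igraph::ecount(g$graph),
         density = 2 * igraph::ecount(g$graph) / (n * (n - 1)),
         threshold = g$threshold,
         achieved_spurious = g$achieved_spurious)
  })
  manifest$finished <- format(Sys.time(), usetz = TRUE)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(manifest)
}
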