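#' Pipeline configuration
#'
#' Collects everything that determines a full analysis run: geometry,
#' cohort design, phases to simulate, permutation and model options, and
#' the output directory. A config round-trips losslessly through YAML via
#' [write_mwm_config()] / [read_mwm_config()].
#'
#' @param design An [mwm_design()].
#' @param geometry An [mwm_geometry()].
#' @param phases Phases to simulate and analyze.
#' @param B Number of permutations for both permutation tests (0 skips the
#'   permutation stage).
#' @param pairwise_session Session at which PC1 pairwise tests are run
#'   (default: the last acquisition session).
#' @param quad_order Gauss-Hermite order for the censored model.
#' @param bin_size Occupancy-grid cell size in cm.
#' @param seed Master seed for the run (defaults to the design's seed).
#' @param outdir Output directory, or `NULL` to skip writing files.
#' @param verbose Emit progress messages.
#' @return An object of class `mwm_config`.
#' @export
mwm_config <- function(design = mwm_design(),
                       geometry = mwm_geometry(),
                       phases = c("pretraining", "acquisition", "probe",
                                  "cued", "reversal"),
                       B = 10000,
                       pairwise_session = design$n_sessions,
                       quad_order = 16,
                       bin_size = 5,
                       seed = design$seed,
                       outdir = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(design, "mwm_design"), inherits(geometry, "mwm_geometry"))
  phases <- match.arg(phases, c("pretraining", "acquisition", "probe",
                                "cued", "reversal"), several.ok = TRUE)
  if (!"acquisition" %in% phases) {
    stop("The pipeline requires the acquisition phase.", call. = FALSE)
  }
  stopifnot(B >= 0, quad_order >= 1, bin_size > 0)
  structure(
    list(design = design, geometry = geometry, phases = phases, B = B,
         pairwise_session = pairwise_session, quad_order = quad_order,
         bin_size = bin_size, seed = as.integer(seed), outdir = outdir,
         verbose = isTRUE(verbose)),
    class = "mwm_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config An [mwm_config()].
#' @param path YAML file path.
#' @return `write_mwm_config()` returns `path` invisibly;
#'   `read_mwm_config()` returns the reconstructed `mwm_config`.
#' @export
write_mwm_config <- function(config, path) {
  stopifnot(inherits(config, "mwm_config"))
  d <- config$design
  g <- config$geometry
  lst <- list(
    design = list(
      groups = lapply(as.list(d$groups), unname),
      n_sessions = d$n_sessions,
      trials_per_session = d$trials_per_session,
      n_reversal_sessions = d$n_reversal_sessions,
      trial_cutoff = d$trial_cutoff,
      sample_rate = d$sample_rate,
      heading_sd = d$heading_sd,
      max_goal_bias = d$max_goal_bias,
      belief_error_scale = d$belief_error_scale,
      seed = d$seed
    ),
    geometry = list(
      pool_radius = g$pool_radius,
      platform_radius = g$platform_radius,
      platform_wall_distance = g$platform_wall_distance,
      platform_center = g$platform_center,
      target_quadrant = g$target_quadrant,
      periphery_band_width = g$periphery_band_width,
      corridor_half_width = g$corridor_half_width
    ),
    phases = config$phases,
    B = config$B,
    pairwise_session = config$pairwise_session,
    quad_order = config$quad_order,
    bin_size = config$bin_size,
    seed = config$seed,
    outdir = config$outdir,
    verbose = config$verbose
  )
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_mwm_config
#' @export
read_mwm_config <- function(path) {
  lst <- yaml::read_yaml(path)
  design <- mwm_design(
    groups = tibble::as_tibble(lst$design$groups),
    n_sessions = lst$design$n_sessions,
    trials_per_session = lst$design$trials_per_session,
    n_reversal_sessions = lst$design$n_reversal_sessions,
    trial_cutoff = lst$design$trial_cutoff,
    sample_rate = lst$design$sample_rate,
    heading_sd = lst$design$heading_sd,
    max_goal_bias = lst$design$max_goal_bias,
    belief_error_scale = lst$design$belief_error_scale,
    seed = lst$design$seed
  )
  geometry <- mwm_geometry(
    pool_radius = lst$geometry$pool_radius,
    platform_radius = lst$geometry$platform_radius,
    platform_wall_distance = lst$geometry$platform_wall_distance,
    platform_center = unlist(lst$geometry$platform_center),
    target_quadrant = lst$geometry$target_quadrant,
    periphery_band_width = lst$geometry$periphery_band_width,
    corridor_half_width = lst$geometry$corridor_half_width
  )
  mwm_config(design = design, geometry = geometry, phases = unlist(lst$phases),
             B = lst$B, pairwise_session = lst$pairwise_session,
             quad_order = lst$quad_order, bin_size = lst$bin_size,
             seed = lst$seed, outdir = lst$outdir, verbose = lst$verbose)
}

#' Run the full analysis pipeline
#'
#' Executes the analysis chain end to end: simulate (or ingest) tracking
#' records, compute per-trial metrics, apply the cued exclusion rule,
#' average trials into session records, build the group-median table, fit
#' the supervised PCA, project individuals as supplementary points,
#' decompose the variance, run the permutation tests, fit the censored
#' latency model (against both untreated reference groups) and uncensored
#' models for Gallagher index and thigmotaxis, run the repeated-measures
#' ANOVAs, and accumulate the group occupancy grids. When reversal
#' sessions are present the median-table/PCA/decomposition chain is
#' repeated on them. `(config, seed)` fully determines every numeric
#' output.
#'
#' If `config$outdir` is set, all result tables are written there together
#' with a `manifest.json` recording the seed, package version, per-file
#' MD5 checksums and any skipped stages.
#'
#' @param config An [mwm_config()].
#' @param tracking Optional pre-loaded tracking tibble (e.g. from
#'   [read_tracking()]); when `NULL` the cohort is simulated.
#' @return An object of class `mwm_run`: a list with elements `tracking`,
#'   `metrics`, `excluded`, `session_metrics`, `median_table`, `pca`,
#'   `supplementary`, `decomposition`, `perm_separation`, `perm_pairwise`,
#'   `latency_fit_wt`, `latency_fit_ts`, `gallagher_fit`,
#'   `thigmotaxis_fit`, `anovas`, `grids`, `reversal` (or `NULL` where a
#'   stage was skipped), and `manifest`.
#' @export
run_mwm_pipeline <- function(config, tracking = NULL) {
  stopifnot(inherits(config, "mwm_config"))
  design <- config$design
  geometry <- config$geometry
  say <- function(...) if (config$verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("Pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  set.seed(config$seed)
  if (is.null(tracking)) {
    say("Simulating cohort...")
    tracking <- stage("simulate",
                      simulate_cohort(design, geometry, phases = config$phases))
  }
  say("Computing trial metrics...")
  metrics <- stage("metrics", trial_metrics(tracking, geometry))
  excluded <- character(0)
  if ("cued" %in% unique(metrics$phase)) {
    excluded <- stage("cued_exclusion", cued_exclusions(metrics))
    say(sprintf("Cued exclusion removed %d subject(s).", length(excluded)))
  }
  kept <- dplyr::filter(metrics, !.data$subject_id %in% excluded)
  sm <- stage("session_means", session_metrics(kept))
  acq <- dplyr::filter(sm, .data$phase == "acquisition")

  say("Fitting supervised PCA...")
  med <- stage("median_table", group_median_table(acq))
  pca <- stage("pca", mwm_pca(med))
  supp <- stage("supplementary", project_supplementary(acq, pca))
  dec <- stage("decomposition", decompose_variance(pca, supp))

  perm_sep <- NULL
  perm_pairs <- NULL
  if (config$B > 0) {
    say(sprintf("Permutation tests (B = %d)...", config$B))
    perm_sep <- stage("permutation_separation",
                      separation_test(acq, B = config$B,
                                      seed = config$seed + 1L))
    perm_pairs <- stage("permutation_pairwise",
                        pc1_pairwise_test(acq,
                                          session = config$pairwise_session,
                                          B = config$B,
                                          seed = config$seed + 2L))
  }

  say("Fitting censored and mixed models...")
  refs <- intersect(c("WT-NT", "TS-NT"), unique(acq$group))
  lat_wt <- if (length(refs) >= 1) {
    stage("latency_model", fit_latency_model(acq, cutoff = design$trial_cutoff,
                                             reference = refs[1],
                                             quad_order = config$quad_order))
  }
  lat_ts <- if (length(refs) >= 2) {
    stage("latency_model_ts",
          fit_latency_model(acq, cutoff = design$trial_cutoff,
                            reference = refs[2],
                            quad_order = config$quad_order))
  }
  gal_fit <- stage("gallagher_model",
                   fit_metric_lmm(acq, "gallagher",
                                  reference = if (length(refs)) refs[1],
                                  quad_order = config$quad_order))
  thig_fit <- stage("thigmotaxis_model",
                    fit_metric_lmm(acq, "thigmotaxis",
                                   reference = if (length(refs)) refs[1],
                                   quad_order = config$quad_order))
  anovas <- lapply(
    stats::setNames(nm = c("latency", "gallagher", "thigmotaxis")),
    function(m) stage(paste0("anova_", m), rm_anova_posthoc(acq, m))
  )

  say("Accumulating occupancy grids...")
  acq_track <- dplyr::filter(tracking, .data$phase == "acquisition",
                             !.data$subject_id %in% excluded)
  grids <- lapply(split(acq_track, acq_track$group), occupancy_grid,
                  geometry = geometry, bin_size = config$bin_size,
                  dt = 1 / design$sample_rate)

  reversal <- NULL
  if ("reversal" %in% unique(sm$phase)) {
    say("Reversal-phase ordination...")
    rev_sm <- dplyr::filter(sm, .data$phase == "reversal")
    rev_med <- stage("reversal_median_table", group_median_table(rev_sm))
    rev_pca <- stage("reversal_pca", mwm_pca(rev_med))
    rev_supp <- stage("reversal_supplementary",
                      project_supplementary(rev_sm, rev_pca))
    reversal <- list(
      median_table = rev_med,
      pca = rev_pca,
      supplementary = rev_supp,
      decomposition = stage("reversal_decomposition",
                            decompose_variance(rev_pca, rev_supp))
    )
  }

  run <- structure(
    list(tracking = tracking, metrics = metrics, excluded = excluded,
         session_metrics = sm, median_table = med, pca = pca,
         supplementary = supp, decomposition = dec,
         perm_separation = perm_sep, perm_pairwise = perm_pairs,
         latency_fit_wt = lat_wt, latency_fit_ts = lat_ts,
         gallagher_fit = gal_fit, thigmotaxis_fit = thig_fit,
         anovas = anovas, grids = grids, reversal = reversal,
         config = config, manifest = NULL),
    class = "mwm_run"
  )
  if (!is.null(config$outdir)) {
    run$manifest <- write_run_outputs(run, config$outdir)
  }
  run
}

#' @export
print.mwm_run <- function(x, ...) {
  cat("<mwm_run>\n")
  cat(sprintf("  %d subjects (%d excluded at the cued stage)\n",
              dplyr::n_distinct(x$session_metrics$subject_id),
              length(x$excluded)))
  cat(sprintf("  PCA: PC1 %.1f%%, PC2 %.1f%% of between-group variance\n",
              x$pca$pct_var[1], x$pca$pct_var[2]))
  cat(sprintf("  decomposition: between %.1f%% (sessions %.1f%% + within %.1f%%)\n",
              x$decomposition$pct_between, x$decomposition$pct_between_session,
              x$decomposition$pct_within_session))
  if (!is.null(x$perm_separation)) {
    cat(sprintf("  separation test: p = %.4g (B = %d)\n",
                x$perm_separation$p_value, x$perm_separation$B))
  }
  invisible(x)
}

# Write all result files plus a manifest with checksums; returns the
# manifest (also written as manifest.json).
write_run_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(outdir, f)
  dropnull <- function(x) x[!vapply(x, is.null, logical(1))]

  readr::write_csv(run$metrics, path("metrics.csv"), progress = FALSE)
  readr::write_csv(run$session_metrics, path("session_metrics.csv"),
                   progress = FALSE)
  readr::write_csv(run$median_table, path("median_table.csv"), progress = FALSE)
  pca_json <- list(
    acquisition = pca_to_list(run$pca),
    reversal = if (!is.null(run$reversal)) pca_to_list(run$reversal$pca)
  )
  jsonlite::write_json(dropnull(pca_json), path("pca.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(run$supplementary, path("supplementary.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    dropnull(list(
      acquisition = unclass_decomp(run$decomposition),
      reversal = if (!is.null(run$reversal))
        unclass_decomp(run$reversal$decomposition)
    )),
    path("variance_decomposition.json"), auto_unbox = TRUE, digits = NA)
  perm_written <- !is.null(run$perm_separation)
  if (perm_written) {
    jsonlite::write_json(
      list(
        separation = list(
          statistic_kind = run$perm_separation$statistic_kind,
          observed = run$perm_separation$observed,
          B = run$perm_separation$B,
          p_value = run$perm_separation$p_value,
          seed = run$perm_separation$seed
        ),
        pc1_pairwise = as.data.frame(run$perm_pairwise)
      ),
      path("permutation.json"), auto_unbox = TRUE, digits = NA)
  }
  models <- dplyr::bind_rows(dropnull(list(
    `latency|WT-NT` = if (!is.null(run$latency_fit_wt)) tidy(run$latency_fit_wt),
    `latency|TS-NT` = if (!is.null(run$latency_fit_ts)) tidy(run$latency_fit_ts),
    gallagher = tidy(run$gallagher_fit),
    thigmotaxis = tidy(run$thigmotaxis_fit)
  )), .id = "model")
  readr::write_csv(models, path("censored_model.csv"), progress = FALSE)
  anova_tbl <- dplyr::bind_rows(lapply(run$anovas, function(a) {
    dplyr::bind_cols(glance(a)[rep(1, nrow(tidy(a))), ], tidy(a))
  }), .id = "metric")
  readr::write_csv(anova_tbl, path("anova.csv"), progress = FALSE)
  all_grid <- Reduce(`+`, lapply(run$grids, `[[`, "counts"))
  utils::write.table(all_grid, path("occupancy_grid.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  g1 <- run$grids[[1]]
  jsonlite::write_json(
    list(x_edges = g1$x_edges, y_edges = g1$y_edges, bin_size = g1$bin_size,
         groups = names(run$grids),
         dwell_total = sum(vapply(run$grids, `[[`, numeric(1), "dwell_total"))),
    path("occupancy_grid.json"), auto_unbox = TRUE, digits = NA)

  files <- setdiff(list.files(outdir), "manifest.json")
  manifest <- list(
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = run$config$seed,
    package_version = as.character(utils::packageVersion("mwmpca")),
    n_subjects = dplyr::n_distinct(run$session_metrics$subject_id),
    excluded_subjects = run$excluded,
    stages_skipped = if (!perm_written) "permutation" else character(0),
    artifacts = lapply(stats::setNames(nm = sort(files)), function(f) {
      list(md5 = unname(tools::md5sum(path(f))))
    })
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest
}

pca_to_list <- function(pca) {
  list(
    eigenvalues = pca$eigenvalues,
    pct_var = pca$pct_var,
    center = as.list(pca$center),
    scale = as.list(pca$scale),
    loadings = as.data.frame(pca$loadings),
    contributions = as.data.frame(pca$contributions),
    scores = as.data.frame(pca$scores)
  )
}

unclass_decomp <- function(d) unclass(d)[c(
  "v_total", "v_between", "v_between_session", "v_within_session",
  "pct_between", "pct_within_group", "pct_between_session",
  "pct_within_session", "n_vars", "n_groups", "n_sessions",
  "n_individual_points"
)]
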