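# Run configuration and the end-to-end orchestrator:
# features -> TICA -> microstates -> MSM -> CK -> PCCA+ -> dG -> TPT.

#' Assemble and validate a pipeline run configuration
#'
#' Either pass a YAML/JSON file path or named fields. Lags are in frames; an
#' optional `ns_per_frame` converts reported rates to physical time.
#'
#' @param file Optional YAML or JSON configuration file.
#' @param ... Fields overriding/completing the file: `input` (PDB paths or a
#'   feature table path), `lesion_resno`, `partner_resno`, `tica_lag`,
#'   `tica_dim` or `tica_var_frac`, `k`, `msm_lag`, `n_macrostates`,
#'   `temperature`, `source`, `sink`, `ck_factors`, `n_boot`, `seed`,
#'   `ns_per_frame`, `out_dir`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(file = NULL, ...) {
  cfg <- list()
  if (!is.null(file)) {
    .stop_if(!file.exists(file), "config file does not exist: %s", file)
    cfg <- if (grepl("\\.ya?ml$", file)) yaml::read_yaml(file)
           else jsonlite::read_json(file, simplifyVector = TRUE)
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  defaults <- list(tica_lag = 100L, tica_dim = NULL, tica_var_frac = 0.9,
                   k = 300L, msm_lag = 100L, n_macrostates = 5L,
                   temperature = 298, source = 1L, sink = NULL,
                   ck_factors = 1:5, n_boot = 100L, seed = 1L,
                   ns_per_frame = NULL, out_dir = NULL,
                   kmeans_fit_sample = 200000L)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[nm] <- list(defaults[[nm]])
  if (is.null(cfg$sink)) cfg$sink <- cfg$n_macrostates
  if (!is.null(cfg$input)) {
    missing <- cfg$input[!file.exists(cfg$input)]
    .stop_if(length(missing) > 0, "input path(s) not found: %s",
             paste(missing, collapse = ", "))
  }
  .stop_if(cfg$tica_lag < 1 || cfg$msm_lag < 1, "lags must be >= 1 frame")
  .stop_if(cfg$n_macrostates < 1, "n_macrostates must be >= 1")
  structure(cfg, class = "run_config")
}

.pipeline_log <- function(env, stage, ...) {
  msg <- sprintf(...)
  env$log <- c(env$log, sprintf("[%s] %s", stage, msg))
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full kinetic-analysis pipeline
#'
#' Executes, in order: featurization (lesion-partner pairwise distances when
#' trajectories are given; a precomputed [feature_series()] is used as-is),
#' TICA, k-means microstate clustering, reversible MSM estimation, implied
#' timescales, the Chapman-Kolmogorov test, PCCA+ macrostates with
#' stationary-weight free energies, and transition-path-theory flux from
#' `source` to `sink` macrostate. Every stage's artifact is returned and,
#' when `out_dir` is set, persisted (features/CVs as delimited text, models
#' and networks as JSON).
#'
#' @param config A [run_config()].
#' @param features Optional [feature_series()] bypassing trajectory input.
#' @return An object of class `flip_pipeline` with the stage artifacts
#'   (`features`, `tica`, `microstates`, `msm`, `its`, `cktest`, `pcca`,
#'   `tpt`, `pathways`, `macro_flux`), the structured `log` and a `summary`
#'   list.
#' @export
run_pipeline <- function(config, features = NULL) {
  stopifnot(inherits(config, "run_config"))
  env <- new.env(); env$log <- character(0)
  out <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.null(features)) {
    .stop_if(is.null(config$input), "config has no input and no features given")
    if (all(grepl("\\.pdb$", config$input, ignore.case = TRUE))) {
      traj <- stage("read", read_trajectory(config$input))
      .pipeline_log(env, "read", "%d frames, %d atoms, %d segment(s)",
                    n_frames(traj), n_atoms(traj), length(traj$boundaries))
      a <- traj$atoms
      ga <- which(a$resno == config$lesion_resno & a$elety != "P")
      gb <- which(a$resno == config$partner_resno & a$elety != "P")
      features <- stage("featurize", pairwise_distance_features(traj, ga, gb))
    } else {
      features <- stage("featurize", read_features(config$input))
    }
  }
  out$features <- features
  .pipeline_log(env, "featurize", "%d frames x %d features",
                nrow(features$values), ncol(features$values))

  out$tica <- stage("tica", tica(features, lag = config$tica_lag,
                                 dim = config$tica_dim,
                                 var_frac = config$tica_var_frac))
  .pipeline_log(env, "tica", "retained %d of %d dims; eigenvalues %s",
                out$tica$m, out$tica$d,
                paste(sprintf("%.3f", head(out$tica$values, 4)), collapse = " "))
  proj <- predict(out$tica, features)

  out$microstates <- stage("cluster",
    kmeans_cluster(proj, k = config$k, seed = config$seed,
                   fit_sample = config$kmeans_fit_sample))
  .pipeline_log(env, "cluster", "k = %d, inertia %.4g",
                config$k, out$microstates$inertia)

  out$msm <- stage("msm", markov_model(out$microstates, lag = config$msm_lag))
  .pipeline_log(env, "msm", "%d/%d states in active set",
                length(out$msm$active_set), config$k)
  n_out <- sum(!unlist(.as_dtraj_list(out$microstates)) %in% out$msm$active_set)
  if (n_out > 0)
    .pipeline_log(env, "msm", "%d frame(s) outside the active set dropped from macrostate statistics", n_out)

  its_lags <- unique(pmax(1L, round(config$msm_lag * c(0.25, 0.5, 1, 2))))
  out$its <- stage("its", withCallingHandlers(
    implied_timescales(out$microstates, its_lags),
    warning = function(w) {
      .pipeline_log(env, "its", "%s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }))

  out$pcca <- stage("pcca", pcca(out$msm, config$n_macrostates,
                                 temperature = config$temperature))
  .pipeline_log(env, "pcca", "macrostate dG (kcal/mol): %s",
                paste(sprintf("%.2f", out$pcca$free_energy), collapse = " "))

  if (config$n_macrostates > 1) {
    out$cktest <- stage("cktest",
      chapman_kolmogorov(out$msm, out$pcca, factors = config$ck_factors,
                         n_boot = config$n_boot, seed = config$seed))
    .pipeline_log(env, "cktest", "%s", if (out$cktest$pass) "PASS" else "FAIL")
    A <- which(out$pcca$crisp == config$source) - 1L
    B <- which(out$pcca$crisp == config$sink) - 1L
    out$tpt <- stage("tpt", tpt(out$msm, A, B))
    out$pathways <- stage("tpt", decompose_pathways(out$tpt, max_paths = 50))
    out$macro_flux <- stage("tpt",
      coarse_grain_flux(out$tpt, out$pcca, ns_per_frame = config$ns_per_frame))
    macro_paths <- stage("tpt",
      .macro_pathways(out$pathways, out$pcca$crisp))
    out$macro_pathways <- macro_paths
    .pipeline_log(env, "tpt", "total flux %.4g/lag; top path %s (%.1f%%)",
                  out$tpt$total_flux, macro_paths$path[1],
                  100 * macro_paths$fraction[1])
  } else {
    .pipeline_log(env, "pcca", "single macrostate: dG = 0, flux stage skipped")
  }

  out$log <- env$log
  out$summary <- list(
    tica_eigenvalues = head(out$tica$values, 10),
    tica_dims = out$tica$m,
    implied_timescales = out$its,
    ck_pass = if (!is.null(out$cktest)) out$cktest$pass else NA,
    free_energy = out$pcca$free_energy,
    pathways = if (!is.null(out$macro_pathways)) out$macro_pathways else NULL,
    seed = config$seed)
  class(out) <- "flip_pipeline"
  if (!is.null(config$out_dir)) .persist_pipeline(out, config$out_dir)
  out
}

# aggregate microstate pathways to macrostate-level paths and merge fractions
.macro_pathways <- function(pathways, crisp) {
  mp <- vapply(strsplit(pathways$path, "-"), function(s) {
    m <- crisp[as.integer(s) + 1L]
    paste(m[c(TRUE, diff(m) != 0)], collapse = "-")
  }, character(1))
  agg <- aggregate(cbind(flux, fraction) ~ path, data = transform(pathways, path = mp),
                   FUN = sum)
  agg[order(-agg$fraction), , drop = FALSE]
}

.persist_pipeline <- function(out, dir) {
  for (d in c("features", "tica", "cluster", "msm", "macrostates", "tpt"))
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  write_features(out$features, file.path(dir, "features", "features.tsv"))
  write_tica(out$tica, file.path(dir, "tica", "tica.json"))
  write.table(data.frame(state = out$microstates$labels),
              file.path(dir, "cluster", "dtraj.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write_msm(out$msm, file.path(dir, "msm", "msm.json"))
  jsonlite::write_json(out$pcca[c("crisp", "pi_macro", "free_energy")],
                       file.path(dir, "macrostates", "pcca.json"),
                       digits = NA, auto_unbox = TRUE)
  if (!is.null(out$tpt))
    write_tpt(out$tpt, file.path(dir, "tpt", "flux.json"), out$pathways)
  writeLines(out$log, file.path(dir, "run.log"))
  jsonlite::write_json(out$summary, file.path(dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(dir)
}

#' @export
print.flip_pipeline <- function(x, ...) {
  cat("Base-flipping kinetic analysis pipeline\n")
  cat(sprintf("  TICA: %d dims, eigenvalues %s\n", x$tica$m,
              paste(sprintf("%.3f", head(x$tica$values, 4)), collapse = " ")))
  cat(sprintf("  MSM: %d active microstates at lag %d\n",
              length(x$msm$active_set), x$msm$lag))
  if (!is.null(x$cktest))
    cat(sprintf("  CK test: %s\n", if (x$cktest$pass) "PASS" else "FAIL"))
  cat("  macrostate dG (kcal/mol):",
      paste(sprintf("%.2f", x$pcca$free_energy), collapse = " "), "\n")
  if (!is.null(x$macro_pathways)) {
    cat("  flux pathways:\n")
    for (i in seq_len(min(5, nrow(x$macro_pathways))))
      cat(sprintf("    %s  %.1f%%\n", x$macro_pathways$path[i],
                  100 * x$macro_pathways$fraction[i]))
  }
  invisible(x)
}
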