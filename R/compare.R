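#' Run the end-to-end algorithm comparison
#'
#' Simulates (or loads) sparse-angle projections of the built-in head
#' phantom and reconstructs them with every requested algorithm at a
#' matched outer-iteration budget, then scores each result against the
#' ground truth.  Writes, under `out_dir`: per-algorithm volumes
#' (`<alg>.mhd`), a metrics table (`metrics.csv`, columns RMSE/PSNR/SSIM),
#' central profile curves (`profile_<alg>.csv`), absolute-difference maps
#' (`diff_<alg>.mhd`), and a full run log (`run_log.yaml` with parameters,
#' seed and package version).  Rerunning with the same config and seed is
#' bitwise reproducible.
#'
#' @param config A [run_config()]; its `algorithm` field is ignored in
#'   favour of `algorithms`.
#' @param algorithms Character vector of reconstructors to run.
#' @param out_dir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @param budget Optional outer-iteration budget imposed on the SART-family
#'   methods (SART, SART-TV, ASD-POCS); `NULL` (default) keeps each
#'   algorithm's configured iteration count.  The TpV solver and the
#'   guided-filter outer loop always keep their own budgets (an ADM
#'   iteration and a filter pass have no view-subset structure to match).
#' @param projections Optional measured [projection_set()] overriding
#'   simulation; `reference` must then be given for scoring.
#' @param reference Optional ground-truth [ct_volume()].
#' @return Invisibly, a list with `metrics` (data frame), `volumes` (named
#'   list of [ct_volume()]), `reference` and `out_dir`.
#' @export
compare_algorithms <- function(config,
                               algorithms = c("sart", "asd-pocs", "sart-tv",
                                              "tpv", "tpv-gif"),
                               out_dir = NULL, budget = NULL,
                               projections = NULL, reference = NULL) {
  stopifnot(inherits(config, "run_config"))
  algorithms <- match.arg(algorithms,
                          c("sart", "asd-pocs", "sart-tv", "tpv", "tpv-gif"),
                          several.ok = TRUE)
  if (is.null(projections)) {
    sim <- simulate_projections(simulation_config(
      config$grid, config$geometry, noise = config$noise,
      photons_per_ray = config$photons_per_ray, seed = config$seed))
    projections <- sim$projections
    reference <- sim$ground_truth
  } else if (is.null(reference)) {
    stop("supply a reference volume when passing measured projections")
  }
  sart_c <- config$sart
  base_c <- config$baseline
  gif_c <- config$tpv_gif
  if (!is.null(budget)) {
    budget <- as.integer(budget)
    sart_c$n_iterations <- budget
    base_c$n_iterations <- budget
  }
  controls <- list("sart" = sart_c, "sart-tv" = base_c, "asd-pocs" = base_c,
                   "tpv" = config$tpv, "tpv-gif" = gif_c)
  volumes <- list()
  rows <- list()
  for (alg in algorithms) {
    if (alg == "tpv-gif" && !is.null(volumes[["tpv"]]) &&
        identical(gif_c$tpv, config$tpv)) {
      # the TpV run above used the same solver config; reuse it as I_initial
      vol <- tpv_gif_reconstruct(projections, config$grid, gif_c,
                                 initial_guidance = volumes[["tpv"]])
      volumes[[alg]] <- ct_volume(config$grid, vol$values)
    } else {
      fit <- ct_reconstruct(projections, config$grid, method = alg,
                            control = controls[[alg]])
      volumes[[alg]] <- fit$volume
    }
    rep <- metrics_report(volumes[[alg]], reference)
    rows[[alg]] <- data.frame(algorithm = alg, rmse = rep$rmse,
                              psnr = rep$psnr, ssim = rep$ssim)
  }
  metrics <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(format(metrics, digits = 17),
              file.path(out_dir, "metrics.csv"), row.names = FALSE,
              quote = FALSE)
    write_mhd(reference, file.path(out_dir, "reference.mhd"))
    mid <- ceiling(config$grid$shape[3] / 2)
    row_mid <- ceiling(config$grid$shape[2] / 2)
    ref_prof <- profile_line(reference, 3, mid, "row", row_mid)
    for (alg in algorithms) {
      tag <- gsub("-", "_", alg)
      write_mhd(volumes[[alg]], file.path(out_dir, paste0(tag, ".mhd")))
      write_mhd(abs_diff(volumes[[alg]], reference),
                file.path(out_dir, paste0("diff_", tag, ".mhd")))
      prof <- profile_line(volumes[[alg]], 3, mid, "row", row_mid)
      write.csv(data.frame(position = prof$position,
                           reference = ref_prof$value,
                           reconstruction = prof$value),
                file.path(out_dir, paste0("profile_", tag, ".csv")),
                row.names = FALSE, quote = FALSE)
    }
    log <- list(
      package_version = as.character(utils::packageVersion("cbctrec")),
      seed = config$seed,
      budget = if (is.null(budget)) "per-algorithm config" else budget,
      algorithms = algorithms,
      noise = config$noise,
      geometry = geometry_to_list(config$geometry),
      grid = list(shape = config$grid$shape,
                  voxel_size = config$grid$voxel_size,
                  origin = config$grid$origin),
      sart = unclass(sart_c), baseline = unclass(base_c),
      tpv = unclass(config$tpv),
      tpv_gif = list(n_outer = gif_c$n_outer, sart = unclass(gif_c$sart),
                     tpv = unclass(gif_c$tpv),
                     gif = if (is.null(gif_c$gif)) NULL
                       else unclass(gif_c$gif)))
    yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"), precision = 17)
  }
  invisible(list(metrics = metrics, volumes = volumes,
                 reference = reference, out_dir = out_dir))
}
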