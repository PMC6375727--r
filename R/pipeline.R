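# Orchestration: run configuration, provenance, and the synthetic demo.

stage_keys <- list(
  simulate = c("stage", "outdir", "kind", "seed", "params"),
  gc_quant = c("stage", "outdir", "fluor", "brightfield", "roi", "bg",
               "axis_deg", "near_sign", "seed"),
  turning = c("stage", "outdir", "table", "seed"),
  tract = c("stage", "outdir", "mask", "threshold", "landmarks",
            "control_mean_tpa", "seed"),
  arbor = c("stage", "outdir", "swc", "seed"),
  psilac = c("stage", "outdir", "table", "alpha", "adjust",
             "min_ratio_count", "seed"),
  demo = c("stage", "outdir", "seed")
)

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config) || is.null(config$stage)) {
    stop("config must be a list (or YAML/JSON file) with a 'stage' key")
  }
  if (!config$stage %in% names(stage_keys)) {
    stop("unknown stage '", config$stage, "'; one of: ",
         paste(names(stage_keys), collapse = ", "))
  }
  unknown <- setdiff(names(config), stage_keys[[config$stage]])
  if (length(unknown)) {
    stop("unknown config keys for stage ", config$stage, ": ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(config$outdir)) stop("config needs an 'outdir'")
  if (is.null(config$seed)) config$seed <- 1L
  config
}

write_provenance <- function(config, outdir) {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  prov <- list(
    stage = config$stage,
    config = config,
    config_md5 = unname(tools::md5sum(tmp)),
    seed = config$seed,
    package = "axoquant",
    version = as.character(utils::packageVersion("axoquant"))
  )
  unlink(tmp)
  jsonlite::write_json(
    prov, file.path(outdir, provenance_name(config)),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
}

provenance_name <- function(config) {
  tag <- if (config$stage == "simulate") {
    paste0(config$stage, "_", config$kind)
  } else {
    config$stage
  }
  paste0(tag, "_provenance.json")
}

#' Run one analysis stage from a configuration
#'
#' Dispatches on `config$stage` (`simulate`, `gc_quant`, `turning`,
#' `tract`, `arbor`, `psilac`, `demo`), validates that no unknown keys are
#' present, runs the stage, writes its TSV/JSON outputs into
#' `config$outdir` together with a machine-readable provenance record
#' (config hash, seed, package version). Reruns with the same config and
#' seed produce byte-identical output tables.
#'
#' @param config named list, or path to a YAML/JSON configuration file.
#' @return (invisibly) a character vector of the files written.
#' @export
run_stage <- function(config) {
  config <- load_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- switch(
    config$stage,
    simulate = stage_simulate(config),
    gc_quant = stage_gc_quant(config),
    turning = stage_turning(config),
    tract = stage_tract(config),
    arbor = stage_arbor(config),
    psilac = stage_psilac(config),
    demo = make_demo_dataset(outdir, seed = config$seed)
  )
  write_provenance(config, outdir)
  invisible(c(files, file.path(outdir, provenance_name(config))))
}

need_file <- function(path, what) {
  if (is.null(path)) stop("config is missing the '", what, "' input path")
  if (!file.exists(path)) stop("missing ", what, " input file: ", path)
  path
}

stage_simulate <- function(config) {
  kind <- config$kind
  if (is.null(kind)) stop("simulate stage needs 'kind'")
  params <- config$params
  if (is.null(params)) params <- list()
  params$seed <- config$seed
  out <- config$outdir
  gen <- switch(
    kind,
    growth_cone = do.call(make_growth_cone_image, params),
    tract = do.call(make_tract_image, params),
    arbor = do.call(make_arbor, params),
    psilac = do.call(make_psilac_table, params),
    stop("unknown simulate kind '", kind, "'")
  )
  files <- character(0)
  if (kind == "growth_cone") {
    files <- c(
      write_image_tiff(gen$fluorescence, file.path(out, "gc_fluor.tif")),
      write_image_tiff(gen$brightfield, file.path(out, "gc_brightfield.tif")),
      write_roi_csv(gen$gc_roi, file.path(out, "gc_roi.csv")),
      write_roi_csv(gen$bg_roi, file.path(out, "gc_bg_roi.csv"))
    )
  } else if (kind == "tract") {
    files <- c(
      write_image_tiff(gen$image, file.path(out, "tract.tif")),
      write_landmarks_csv(gen$landmarks, file.path(out, "landmarks.csv"))
    )
  } else if (kind == "arbor") {
    files <- write_swc(gen$tree, file.path(out, "arbor.swc"))
  } else {
    files <- write_psilac_tsv(gen$table, file.path(out, "psilac.tsv"))
  }
  gt_file <- file.path(out, paste0(kind, "_ground_truth.json"))
  write_ground_truth_json(gen$ground_truth, gt_file)
  c(files, gt_file)
}

stage_gc_quant <- function(config) {
  fluor <- read_image_tiff(need_file(config$fluor, "fluor"), "fluorescence")
  bf <- read_image_tiff(need_file(config$brightfield, "brightfield"),
                        "brightfield")
  roi <- read_roi_csv(need_file(config$roi, "roi"), label = "growth_cone")
  bg <- read_roi_csv(need_file(config$bg, "bg"), label = "background")
  if (is.null(config$axis_deg) || is.null(config$near_sign)) {
    stop("gc_quant needs 'axis_deg' and 'near_sign'")
  }
  mask <- roi_pixel_mask(fluor, roi)
  pts <- pixel_centers(fluor)
  anchor <- c(mean(pts[as.vector(mask), 1]), mean(pts[as.vector(mask), 2]))
  line <- bisection_line(anchor, unit_vector(config$axis_deg + 90),
                         config$near_sign)
  res <- quantify_growth_cone(fluor, bf, roi, bg, line, config$axis_deg)
  out_tsv <- file.path(config$outdir, "gc_quant.tsv")
  write_result_tsv(res, out_tsv)
  out_json <- file.path(config$outdir, "gc_quant_summary.json")
  jsonlite::write_json(as.list(res), out_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  c(out_tsv, out_json)
}

stage_turning <- function(config) {
  tab <- utils::read.csv(need_file(config$table, "table"))
  tab <- turning_angles_table(tab)
  summ <- turning_summary(tab$turning_angle_deg)
  out_tsv <- file.path(config$outdir, "turning_angles.tsv")
  write_result_tsv(tab, out_tsv)
  out_json <- file.path(config$outdir, "turning_summary.json")
  jsonlite::write_json(
    list(mean = summ$mean, sem = summ$sem, n = summ$n),
    out_json, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  c(out_tsv, out_json)
}

stage_tract <- function(config) {
  img <- read_image_tiff(need_file(config$mask, "mask"))
  landmarks <- read_landmarks_csv(need_file(config$landmarks, "landmarks"))
  threshold <- if (is.null(config$threshold)) 110 else config$threshold
  scene <- tract_scene(img, landmarks, threshold = threshold)
  res <- tract_metrics(scene)
  if (!is.null(config$control_mean_tpa)) {
    res$posterior_avoidance <- res$tpa_deg < config$control_mean_tpa
  }
  out_tsv <- file.path(config$outdir, "tract_metrics.tsv")
  write_result_tsv(res, out_tsv)
  out_tsv
}

stage_arbor <- function(config) {
  paths <- config$swc
  if (is.null(paths)) stop("arbor stage needs 'swc' (file(s) or directory)")
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.swc$", full.names = TRUE)
  }
  if (!length(paths)) stop("no SWC files found")
  res <- do.call(rbind, lapply(paths, function(p) {
    m <- arbor_metrics(read_swc(need_file(p, "swc")))
    cbind(data.frame(file = basename(p)), m)
  }))
  out_tsv <- file.path(config$outdir, "arbor_metrics.tsv")
  write_result_tsv(res, out_tsv)
  out_json <- file.path(config$outdir, "arbor_metadata.json")
  jsonlite::write_json(
    list(aci_definition = "count-weighted mean branch order over orders >= 1"),
    out_json, auto_unbox = TRUE, pretty = TRUE
  )
  c(out_tsv, out_json)
}

stage_psilac <- function(config) {
  tab <- read_psilac_tsv(need_file(config$table, "table"))
  if (is.null(config$adjust) || !config$adjust %in% c("bh", "raw")) {
    stop("psilac stage needs 'adjust' set to \"bh\" or \"raw\"",
         " (the significance threshold mode is an explicit choice)")
  }
  alpha <- if (is.null(config$alpha)) 0.10 else config$alpha
  min_count <- if (is.null(config$min_ratio_count)) 2 else
    config$min_ratio_count
  out <- psilac_pipeline(tab, min_count = min_count, alpha = alpha,
                         use_adjusted = config$adjust == "bh")
  out_tsv <- file.path(config$outdir, "psilac_results.tsv")
  write_result_tsv(out$results, out_tsv)
  out_json <- file.path(config$outdir, "psilac_model.json")
  jsonlite::write_json(
    c(out$model, list(offset = out$offset, alpha = alpha,
                      adjust = config$adjust)),
    out_json, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  c(out_tsv, out_json)
}

#' Generate the all-synthetic demo fixture bundle
#'
#' Emits one instance of each synthetic generator (growth-cone image pair,
#' tract image, arbor tree, pSILAC table) with ground-truth JSON sidecars,
#' sized so the full pipeline runs in well under a minute.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer base seed; each generator receives a distinct
#'   derived seed.
#' @return (invisibly) character vector of files written.
#' @export
make_demo_dataset <- function(outdir, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  files <- c(files, run_stage(list(
    stage = "simulate", kind = "growth_cone", outdir = outdir,
    seed = child_seed(seed, 1),
    params = list(gradient_strength = 0.5, noise_sd = 2)
  )))
  files <- c(files, run_stage(list(
    stage = "simulate", kind = "tract", outdir = outdir,
    seed = child_seed(seed, 2),
    params = list(oc = c(40, 160), tpb = c(180, 60), mdt_angle_deg = 50,
                  pre_width_px = 10, post_width_px = 12, tpa_deg = -9)
  )))
  files <- c(files, run_stage(list(
    stage = "simulate", kind = "arbor", outdir = outdir,
    seed = child_seed(seed, 3),
    params = list(n_primary = 4, n_secondary = 3, n_tertiary = 2)
  )))
  files <- c(files, run_stage(list(
    stage = "simulate", kind = "psilac", outdir = outdir,
    seed = child_seed(seed, 4),
    params = list(n_proteins = 500, global_offset = 0.3)
  )))
  invisible(files)
}
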