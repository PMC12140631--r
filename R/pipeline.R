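## End-to-end pipeline: tissue build -> band reconstruction -> mode
## decomposition, with a JSON manifest of everything written.

#' Read a pipeline run configuration
#'
#' Single YAML file with the scenario inputs and solver settings. Fields:
#' \code{seed}, \code{outdir}, \code{band} (two Hz values), \code{solver}
#' (\code{K}, \code{tol}, \code{method}), \code{decompose} (\code{n},
#' \code{threshold}, \code{radius}, \code{dense}), \code{tissue}
#' (\code{smoothing}, partial-volume sd in voxels, default 2 for label-map
#' inputs), and either \code{inputs}
#' (paths: \code{labels}, \code{tissueTable} optional, \code{electrodes},
#' \code{eeg}, \code{fs} optional, \code{atlas} optional) or \code{phantom}
#' (arguments of \code{\link{phantomScenario}}). All referenced paths must
#' exist at load time.
#'
#' @param path YAML file path
#' @return a list of class \code{RunConfig}
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$configPath <- path
  if (!is.null(cfg$inputs)) {
    for (p in intersect(names(cfg$inputs),
                        c("labels", "tissueTable", "electrodes", "eeg", "atlas")))
      if (!file.exists(cfg$inputs[[p]]))
        stop("configured path does not exist: ", cfg$inputs[[p]])
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$band)) cfg$band <- c(8, 12)
  structure(cfg, class = "RunConfig")
}

#' Run the full reconstruction pipeline
#'
#' Executes tissue build, band-limited inverse reconstruction and mode
#' decomposition, writing NIfTI/CSV outputs and a JSON manifest (package
#' version, seed, config hash, per-stage timings, per-bin iteration
#' diagnostics, output paths). Any stage error aborts with the stage name.
#'
#' @param config a \code{RunConfig} from \code{\link{readRunConfig}}, a YAML
#'   path, or an equivalent list
#' @return the manifest, invisibly
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  outdir <- config$outdir
  if (is.null(outdir)) stop("config needs an 'outdir'")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(config$seed))
  man <- new.env(parent = emptyenv())
  man$timings <- list()
  man$outputs <- list()
  man$extra <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    man$timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  ## --- tissue / scenario -------------------------------------------------
  env <- stage("tissue", {
    if (!is.null(config$phantom)) {
      args <- config$phantom
      args$seed <- as.integer(config$seed)
      sc <- do.call(phantomScenario, args)
      writeLabels(sc$grid, file.path(outdir, "labels.nii"))
      man$outputs$labels <- file.path(outdir, "labels.nii")
      writeEEG(sc$recording, file.path(outdir, "phantom_eeg.csv"))
      man$outputs$eeg <- file.path(outdir, "phantom_eeg.csv")
      list(grid = sc$grid, field = sc$field, sensors = sc$sensors,
           rec = sc$recording, truth = sc$sourceVoxels)
    } else {
      inp <- config$inputs
      if (is.null(inp$labels) || is.null(inp$electrodes) || is.null(inp$eeg))
        stop("inputs require labels, electrodes and eeg paths")
      grid <- readLabels(inp$labels)
      table <- if (!is.null(inp$tissueTable)) readTissueTable(inp$tissueTable)
               else defaultTissueTable()
      ## label maps carry hard jumps; resolve them for the spectral solver
      smoothing <- if (!is.null(config$tissue$smoothing))
        config$tissue$smoothing else 2
      field <- buildTensorField(grid, table, smoothing = smoothing)
      list(grid = grid, field = field, sensors = NULL, rec = NULL,
           truth = NULL)
    }
  })

  ## --- reconstruction ----------------------------------------------------
  recon <- stage("reconstruct", {
    if (is.null(env$sensors)) {
      env$sensors <- readElectrodes(config$inputs$electrodes, env$grid)
      env$rec <- readEEG(config$inputs$eeg, fs = config$inputs$fs)
    }
    s <- config$solver
    cfgInv <- inverseConfig(
      band = as.numeric(config$band),
      K = if (!is.null(s$K)) as.integer(s$K) else 20L,
      tol = if (!is.null(s$tol)) s$tol else 1e-6,
      method = if (!is.null(s$method)) s$method else "minnorm")
    out <- reconstructBand(env$rec, env$field, env$sensors, cfgInv)
    writeVolume(out@phiT, file.path(outdir, "phi_band.nii"), env$grid)
    man$outputs$phiT <- file.path(outdir, "phi_band.nii")
    binfo <- lapply(out@diagnostics, function(d)
      list(omega = d$omega, iterations = d$iterations,
           finalRelChange = if (length(d$relChange)) d$relChange[length(d$relChange)]
                            else NA_real_))
    man$extra$bins <- binfo
    for (b in seq_along(out@freqs)) {
      fr <- file.path(outdir, sprintf("phi_bin_%gHz_real.nii", out@freqs[b]))
      fi <- file.path(outdir, sprintf("phi_bin_%gHz_imag.nii", out@freqs[b]))
      writeVolume(Re(out@volumes[[b]]), fr, env$grid)
      writeVolume(Im(out@volumes[[b]]), fi, env$grid)
      man$outputs[[sprintf("bin_%g", out@freqs[b])]] <- c(fr, fi)
    }
    out
  })

  ## --- decomposition -----------------------------------------------------
  stage("decompose", {
    dcfg <- config$decompose
    n <- if (!is.null(dcfg$n)) dcfg$n else 10L
    tau <- if (!is.null(dcfg$threshold)) dcfg$threshold else 0.6
    radius <- if (!is.null(dcfg$radius)) dcfg$radius else 2
    dense <- isTRUE(dcfg$dense)
    mask <- labelVolume(env$grid) > 0L
    Q <- couplingMatrix(recon@phiT, mask = mask, radius = radius,
                        dense = dense)
    modes <- suppressWarnings(espDecompose(Q, recon@phiT, n))
    pw <- modePowerMap(modes)
    writeVolume(pw, file.path(outdir, "power_map.nii"), env$grid)
    writeVolume(thresholdMap(pw, tau), file.path(outdir, "power_map_thr.nii"),
                env$grid)
    utils::write.csv(
      data.frame(time = (seq_len(nrow(modes@timecourses)) - 1) / recon@fs,
                 modes@timecourses),
      file.path(outdir, "mode_timecourses.csv"), row.names = FALSE)
    man$outputs$powerMap <- file.path(outdir, "power_map.nii")
    man$outputs$powerMapThresholded <- file.path(outdir, "power_map_thr.nii")
    man$outputs$modeTimecourses <- file.path(outdir, "mode_timecourses.csv")
    man$extra$nModes <- length(modeAmplitudes(modes))
    if (!is.null(config$inputs$atlas)) {
      atlas <- readLabels(config$inputs$atlas)
      rp <- regionPower(pw, atlas)
      utils::write.csv(rp, file.path(outdir, "region_power.csv"),
                       row.names = FALSE)
      man$outputs$regionPower <- file.path(outdir, "region_power.csv")
    }
    NULL
  })

  manifest <- list(package = "spectre",
                   version = as.character(utils::packageVersion("spectre")),
                   seed = as.integer(config$seed),
                   configHash = if (!is.null(config$configPath))
                     unname(tools::md5sum(config$configPath)) else NA,
                   timings = man$timings,
                   outputs = man$outputs[!vapply(man$outputs, is.null,
                                                 logical(1))],
                   bins = man$extra$bins, nModes = man$extra$nModes)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
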