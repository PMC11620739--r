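# Run persistence and report assembly.  Arrays are stored as RDS, per-cell
# tables as CSV and reports as JSON; a manifest with checksums ties a run
# directory together.

#' Save a simulation run to a directory
#'
#' Writes `config.yaml`, `arrays.rds` (maps, weights, checkpoints),
#' `metrics.csv` (per-cell gridness/spacing plus one population row) and
#' `manifest.json` (file inventory with MD5 checksums).
#'
#' @param sim a [run_grid_sim()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_run <- function(sim, dir) {
  stopifnot(inherits(sim, "grid_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_config(sim$config, file.path(dir, "config.yaml"))
  saveRDS(sim[c("W_in", "W_rec", "maps", "occupancy", "checkpoints",
                "checkpoint_steps", "state")],
          file.path(dir, "arrays.rds"))
  write.csv(run_metrics(sim), file.path(dir, "metrics.csv"),
            row.names = FALSE)
  files <- c("config.yaml", "arrays.rds", "metrics.csv")
  manifest <- list(
    package = "flexattractor",
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = sim$config$seed,
    n_checkpoints = length(sim$checkpoints),
    files = lapply(files, function(f) list(
      name = f, md5 = unname(tools::md5sum(file.path(dir, f))))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a saved run
#' @param dir directory written by [save_run()].
#' @param verify check file checksums against the manifest.
#' @return a `grid_sim` object.
#' @export
load_run <- function(dir, verify = TRUE) {
  man_path <- file.path(dir, "manifest.json")
  if (verify && file.exists(man_path)) {
    man <- jsonlite::read_json(man_path)
    for (f in man$files) {
      p <- file.path(dir, f$name)
      if (!file.exists(p)) stop("missing run file: ", f$name)
      if (!identical(unname(tools::md5sum(p)), f$md5))
        stop("checksum mismatch for ", f$name, " (stale or corrupted run)")
    }
  }
  out <- readRDS(file.path(dir, "arrays.rds"))
  out$config <- load_config(file.path(dir, "config.yaml"))
  class(out) <- "grid_sim"
  out
}

# per-cell metrics table with a final population row
run_metrics <- function(sim) {
  sc <- population_grid_scores(sim$maps, sim$config$pixel_size)
  pop_ac <- population_autocorrelogram(sim$maps, sim$config$pixel_size)
  pop_sp <- estimate_spacing(pop_ac)
  pop <- data.frame(cell = NA_integer_,
                    gridness = compute_gridness(pop_ac, pop_sp),
                    spacing = as.numeric(pop_sp),
                    n_maxima = nrow(autocorr_maxima(pop_ac, pop_sp)),
                    flagged = isTRUE(attr(pop_sp, "flagged")))
  out <- rbind(sc, pop)
  out$scope <- c(rep("cell", nrow(sc)), "population")
  out
}

#' Topology report for a saved or in-memory run
#'
#' Builds the population (and optionally neuron) point cloud, runs the
#' closed-surface classification and returns a serialisable report.
#'
#' @param sim a `grid_sim` or a rate-map stack.
#' @param mode `"population"` or `"neurons"`.
#' @param field coefficient prime.
#' @param k_dim,k1,k2 local-analysis parameters (see [classify_surface()]).
#' @return a list ready for [jsonlite::write_json()].
#' @export
topology_report <- function(sim, mode = c("population", "neurons"),
                            field = 2, k_dim = 70, k1 = 50, k2 = 100) {
  mode <- match.arg(mode)
  maps <- if (inherits(sim, "grid_sim")) sim$maps else sim
  if (mode == "population") {
    cloud <- build_population_cloud(maps)
    rep <- classify_surface(cloud, k_dim = k_dim, k1 = k1, k2 = k2,
                            field = field)
    list(mode = mode, verdict = rep$verdict,
         betti = as.integer(rep$betti),
         frac_local_dim2 = rep$frac_dim2,
         frac_local_beta1_1 = rep$frac_beta1_1,
         orientable = rep$orientable)
  } else {
    cloud <- build_neuron_cloud(maps)
    ps <- rips_persistence(cloud, max_degree = 2, field = field)
    betti <- count_betti(ps, diagram_cutoffs(ps))
    list(mode = mode, betti = as.integer(betti),
         verdict = paste0("betti (", paste(betti, collapse = ","), ")"))
  }
}

#' Assemble a combined report from one or more run directories
#'
#' Merges `metrics.csv`, `topology.json` and `config_report.json` (when
#' present) from each run directory into a single JSON-ready structure
#' with per-run entries and, for multiple runs, a frequency table of Betti
#' patterns.  Missing components are reported as explicit gaps, and
#' re-running the assembly is idempotent.
#'
#' @param run_dirs character vector of run directories.
#' @param out optional path for the combined `report.json`.
#' @return the report list, invisibly when `out` is given.
#' @export
assemble_report <- function(run_dirs, out = NULL) {
  runs <- lapply(run_dirs, function(d) {
    entry <- list(dir = d)
    mp <- file.path(d, "metrics.csv")
    entry$metrics <- if (file.exists(mp)) {
      m <- read.csv(mp)
      cells <- m[m$scope == "cell", ]
      list(mean_gridness = mean(cells$gridness, na.rm = TRUE),
           mean_spacing = mean(cells$spacing, na.rm = TRUE),
           population_gridness = m$gridness[m$scope == "population"])
    } else "missing"
    tp <- file.path(d, "topology.json")
    entry$topology <- if (file.exists(tp)) jsonlite::read_json(tp)
                      else "missing"
    cp <- file.path(d, "config_report.json")
    entry$configuration <- if (file.exists(cp)) jsonlite::read_json(cp)
                           else "missing"
    entry
  })
  betti <- vapply(runs, function(r) {
    if (is.list(r$topology) && !is.null(r$topology$betti))
      paste(unlist(r$topology$betti), collapse = ",")
    else NA_character_
  }, character(1))
  report <- list(n_runs = length(runs), runs = runs)
  if (length(runs) > 1 && any(!is.na(betti)))
    report$betti_frequency <- as.list(table(betti[!is.na(betti)]))
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(report))
  }
  report
}
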