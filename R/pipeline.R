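## End-to-end orchestration: seeded synthetic runs through simulation,
## alignment, consensus and off-site statistics, with a manifest that
## suffices to reproduce any run.

#' Default pipeline configuration
#'
#' @param preset simulation preset, \code{"combed-fragment"} or
#'   \code{"plasmid"}.
#' @param n_molecules molecules to simulate.
#' @param seed master seed.
#' @return nested configuration list (simulation, alignment, consensus).
#' @export
pipeline_config <- function(preset = "combed-fragment", n_molecules = 180,
                            seed = 1) {
  list(
    seed = seed,
    map = list(name = "synthetic-amplicon", length = 5000, motif = "TCGA",
               positions = c(600, 700, 1500, 2100, 2950, 3050, 3700, 4300,
                             4800)),
    simulate = list(preset = preset, n_molecules = n_molecules,
                    p_second = 0),
    align = list(stretch = 1.6, stretch_tol = 0.1, match_width = 150),
    consensus = list(bin_width = 50, removal_window = 100,
                     apply_removal = TRUE)
  )
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes simulate -> align (both orientations) -> place -> dual-strand
#' removal -> consensus -> off-site statistics, writing all stage outputs
#' and a manifest (config echo + seed + package version) to \code{outdir}.
#' Runs are byte-identical for a fixed configuration.
#'
#' @param config a configuration list as from \code{\link{pipeline_config}},
#'   or the path to a YAML file holding one.
#' @param outdir output directory (created if needed), or \code{NULL} to
#'   skip writing files.
#' @return (invisibly) a list with the reference map, traces, truth,
#'   alignments, placed labels, consensus histogram and off-site stats.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config error: file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  base <- pipeline_config()
  config <- utils::modifyList(base, config)
  mp <- config$map
  refmap <- reference_map(mp$name, mp$length, mp$motif, mp$positions)
  cfg <- do.call(sim_config, c(config$simulate, list(seed = config$seed)))
  params <- do.call(alignment_params, config$align)

  sim <- simulate_molecules(refmap, cfg)
  alns <- lapply(sim$traces, align_best_orientation, refmap = refmap,
                 params = params)
  placed <- do.call(rbind, lapply(seq_along(alns), function(i) {
    p <- place_labels(alns[[i]], sim$traces[[i]], refmap)
    if (isTRUE(config$consensus$apply_removal))
      p <- remove_dual_strand(p, window = config$consensus$removal_window)
    p
  }))
  cons <- build_consensus(placed, refmap,
                          bin_width = config$consensus$bin_width)
  resid <- unlist(lapply(alns, alignment_residuals, refmap = refmap))
  stats <- offsite_stats(placed, refmap, n_molecules = cfg$n_molecules,
                         match_width = params$match_width,
                         residuals = resid)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(config = config,
                     package = "mtagmap",
                     version = as.character(utils::packageVersion("mtagmap")),
                     r_version = paste(R.version$major, R.version$minor,
                                       sep = "."))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_map(refmap, file.path(outdir, "sites.bed"))
    write_traces(sim$traces, file.path(outdir, "traces.csv"))
    write_alignments(alns, file.path(outdir, "alignments.jsonl"))
    write.csv(placed, file.path(outdir, "placed.csv"), row.names = FALSE)
    write.csv(data.frame(bin_start = head(cons$breaks, -1),
                         count = cons$counts),
              file.path(outdir, "consensus.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(stats)[c(
      "n_matched", "n_unmatched", "offsite_fraction", "offsite_density",
      "onsite_per_site", "efficiency", "offsite_fraction_corrected",
      "offsite_density_corrected", "uniformity_p")],
      file.path(outdir, "offsite.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(refmap = refmap, traces = sim$traces, truth = sim$truth,
                 alignments = alns, placed = placed, consensus = cons,
                 offsite = stats))
}
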