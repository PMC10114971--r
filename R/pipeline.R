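# End-to-end orchestration: seeded multi-replica simulation of a switch
# system, pooling into one combined trajectory, and the full analysis
# sequence (free-energy landscape with valleys, RMSF, radius of gyration,
# cross-correlation, PCA, contact occupancy), with every numeric table and
# a checksum manifest written to an output directory.

.config_sections <- list(
  system = c("n_beads", "bond_length", "bond_k", "angle_k", "switch_pair",
             "well_distances", "well_depths", "barrier", "mutation_bias",
             "well_width"),
  simulation = c("n_steps", "timestep", "temperature", "friction", "stride",
                 "stages", "refresh"),
  boost = c("mode", "sigma_0"),
  analysis = c("fel_bins", "depth_cutoff", "min_separation", "min_count",
               "fel_method", "rg_bin_width", "contact_cutoff"),
  top = c("system", "simulation", "boost", "analysis", "replicas", "seed",
          "label", "outdir")
)

#' Assemble and validate a pipeline run configuration
#'
#' Flat nested-list configuration with one section per stage.  Unknown keys
#' are hard errors (typo guard).  The seed is mandatory; every random draw
#' in the run derives from it, so a repeated run reproduces all numeric
#' tables bitwise.
#'
#' @param system switch-chain parameters (see [switch_chain_spec()])
#' @param simulation Langevin parameters (see [langevin_config()], minus
#'   the seed)
#' @param boost list with `mode` (`"lower_bound"`, `"upper_bound"` or
#'   `"none"`) and `sigma_0`
#' @param analysis list with `fel_bins`, `depth_cutoff`, `min_separation`,
#'   `fel_method`, `rg_bin_width`, `contact_cutoff`
#' @param replicas number of independent replicas pooled before analysis
#' @param seed master seed
#' @param label condition label (e.g. `"WT"`, `"mutant"`)
#' @param outdir output directory (created); NULL to skip file output
#' @export
run_config <- function(system = list(), simulation = list(n_steps = 20000),
                       boost = list(mode = "lower_bound", sigma_0 = 6),
                       analysis = list(), replicas = 4, seed,
                       label = "WT", outdir = NULL) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- list(system = system, simulation = simulation, boost = boost,
              analysis = analysis, replicas = as.integer(replicas),
              seed = as.integer(seed), label = label, outdir = outdir)
  for (sec in c("system", "simulation", "boost", "analysis")) {
    unknown <- setdiff(names(cfg[[sec]]), .config_sections[[sec]])
    if (length(unknown) > 0) {
      stop("unknown key(s) in config section '", sec, "': ",
           paste(unknown, collapse = ", "))
    }
  }
  defaults <- list(fel_bins = 24, depth_cutoff = 1.0, min_separation = 2,
                   min_count = 10, fel_method = "cumulant2",
                   rg_bin_width = 0.1, contact_cutoff = 15)
  cfg$analysis <- utils::modifyList(defaults, cfg$analysis)
  stopifnot(cfg$replicas >= 1)
  class(cfg) <- "run_config"
  cfg
}

write_table_with_units <- function(df, path, units) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", units), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on a switch-chain system
#'
#' Simulates `replicas` independent seeded (optionally boosted) Langevin
#' replicas, concatenates their production frames into a single combined
#' trajectory, and executes the analysis sequence on it: switch-distance
#' series, 2D free-energy landscape on (heavy-atom RMSD, switch distance)
#' with valley detection, RMSF, radius-of-gyration distribution,
#' cross-correlation map, PCA, and switch-contact occupancy.  All numeric
#' tables (plus a config echo and an md5 manifest) are written to
#' `config$outdir` when it is set.
#'
#' @param config a [run_config()]
#' @return (invisibly) a `pipeline_result` list with the trajectory, boost
#'   records, landscape, valleys and every analysis table
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  spec <- do.call(switch_chain_spec, config$system)
  sc <- make_switch_chain(spec)
  boost_mode <- config$boost$mode
  sigma_0 <- if (is.null(config$boost$sigma_0)) 6 else config$boost$sigma_0

  runs <- vector("list", config$replicas)
  for (r in seq_len(config$replicas)) {
    sim <- config$simulation
    sim$seed <- config$seed + 1000L * r
    cfg_r <- do.call(langevin_config, sim)
    runs[[r]] <- run_langevin(sc$system, cfg_r,
                              boost = if (boost_mode == "none") NULL else boost_mode,
                              sigma_0 = sigma_0)
  }
  trajs <- lapply(runs, run_trajectory, topology = sc$topology)
  sgt <- concatenate_trajectories(trajs)
  records <- do.call(rbind, lapply(runs, `[[`, "records"))

  an <- config$analysis
  pair <- spec$switch_pair
  dd <- distance_definition("switch_distance", pair[1], pair[2])
  dist_series <- distance_series(sgt, dd)
  fel <- build_fel(sgt, rc1 = list(kind = "rmsd", reference = 1,
                                   selection = selection("heavy")),
                   rc2 = dist_series,
                   records = if (boost_mode == "none") NULL else records,
                   method = an$fel_method, breaks = an$fel_bins,
                   temperature = if (is.null(config$simulation$temperature))
                     300 else config$simulation$temperature)
  valleys <- find_valleys(fel, depth_cutoff = an$depth_cutoff,
                          min_separation = an$min_separation,
                          min_count = an$min_count)
  rmsf_v <- rmsf(sgt, selection("calpha"))
  rg <- rg_series(sgt)
  rg_dist <- frequency_distribution(rg, an$rg_bin_width)
  cc <- dccm(sgt, selection("calpha"))
  pc <- pca(sgt, selection("calpha"))
  occ <- occupancy(sgt, "hbond", criteria = hbond_criteria(an$contact_cutoff, 1),
                   donors = cbind(pair[1], NA), acceptors = pair[2],
                   heavy_fallback = TRUE)

  valley_table <- if (length(valleys) == 0) {
    data.frame(valley = character(0), G_min = numeric(0),
               rc1_center = numeric(0), rc2_center = numeric(0),
               population = integer(0), fraction = numeric(0))
  } else {
    data.frame(
      valley = vapply(valleys, `[[`, "", "valley_id"),
      G_min = vapply(valleys, `[[`, 0, "G_min"),
      rc1_center = vapply(valleys, function(v) fel$centers[[1]][v$minimum_bin[1]], 0),
      rc2_center = vapply(valleys, function(v) fel$centers[[2]][v$minimum_bin[2]], 0),
      population = vapply(valleys, `[[`, 0, "population"),
      fraction = vapply(valleys, `[[`, 0, "fraction"))
  }

  result <- list(
    config = config, spec = spec, topology = sc$topology, trajectory = sgt,
    records = records, runs = runs, fel = fel, valleys = valleys,
    valley_table = valley_table, rmsf = rmsf_v, rg = rg, rg_dist = rg_dist,
    dccm = cc, pca = pc, occupancy = occ, distance = dist_series)
  class(result) <- "pipeline_result"

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outdir, f)
    cfg_echo <- config
    cfg_echo$outdir <- NULL
    yaml::write_yaml(unclass(cfg_echo), out("config.yaml"))
    write_table_with_units(data.frame(frame = seq_along(dist_series),
                                      distance = dist_series),
                           out("switch_distance.tsv"), "A")
    write_table_with_units(as.data.frame(fel), out("pmf.tsv"),
                           "rc1 A (rmsd), rc2 A (distance), G kcal/mol")
    write_table_with_units(valley_table, out("valleys.tsv"),
                           "G kcal/mol, rc A")
    write_table_with_units(data.frame(residue = as.integer(names(rmsf_v)),
                                      rmsf = rmsf_v),
                           out("rmsf.tsv"), "A")
    write_table_with_units(data.frame(frame = seq_along(rg), rg = rg),
                           out("rg.tsv"), "A")
    cc_df <- as.data.frame(unclass(cc))
    names(cc_df) <- paste0("res", colnames(cc))
    write_table_with_units(cc_df, out("dccm.tsv"), "dimensionless")
    write_table_with_units(
      data.frame(mode = seq_along(pc$values), eigenvalue = pc$values,
                 fraction = pc$fraction, cumulative = pc$cumulative),
      out("pca_eigenvalues.tsv"), "A^2")
    write_table_with_units(occ, out("occupancy.tsv"), "percent")
    write_boost_log(records, out("boost_log.tsv"))
    files <- setdiff(list.files(config$outdir), "manifest.tsv")
    manifest <- data.frame(
      file = files,
      md5 = as.vector(tools::md5sum(file.path(config$outdir, files))),
      stringsAsFactors = FALSE)
    utils::write.table(manifest, out("manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    result$manifest <- manifest
  }
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result [%s]: %d frames, %d valleys\n",
              x$config$label, n_frames(x$trajectory), length(x$valleys)))
  invisible(x)
}

#' Compare two pipeline runs (e.g. wild-type vs mutant)
#'
#' Emits the per-residue flexibility difference (variant minus reference),
#' valley populations per condition on each run's own landscape, an outer
#' join of the occupancy tables, and the interaction diff between the two
#' EV1 representative frames' contact sets.
#'
#' @param res_reference,res_variant `pipeline_result` objects over the
#'   same topology
#' @return list with `delta_rmsf`, `populations`, `occupancy`,
#'   `ev1_contact_diff`
#' @export
compare_conditions <- function(res_reference, res_variant) {
  stopifnot(inherits(res_reference, "pipeline_result"),
            inherits(res_variant, "pipeline_result"))
  if (n_atoms(res_reference$topology) != n_atoms(res_variant$topology)) {
    stop("runs use different topologies")
  }
  drmsf <- delta_rmsf(res_variant$rmsf, res_reference$rmsf)
  pops <- rbind(
    cbind(condition = res_reference$config$label, res_reference$valley_table),
    cbind(condition = res_variant$config$label, res_variant$valley_table))
  occ <- merge(res_reference$occupancy[c("key", "occupancy")],
               res_variant$occupancy[c("key", "occupancy")],
               by = "key", all = TRUE,
               suffixes = paste0(".", make.unique(c(
                 res_reference$config$label, res_variant$config$label))))
  contacts <- lapply(list(res_reference, res_variant), function(res) {
    if (length(res$valleys) == 0) return(character(0))
    f <- representative_frame(res$fel, res$valleys[[1]])
    pair <- res$spec$switch_pair
    detect_hbonds(frame_coords(res$trajectory, f), res$topology,
                  criteria = hbond_criteria(res$config$analysis$contact_cutoff, 1),
                  donors = cbind(pair[1], NA), acceptors = pair[2],
                  heavy_fallback = TRUE)$key
  })
  list(delta_rmsf = drmsf, populations = pops, occupancy = occ,
       ev1_contact_diff = network_diff(contacts[[1]], contacts[[2]]))
}
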