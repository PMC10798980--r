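#' Write a structure as extended XYZ with a JSON annotation sidecar
#'
#' The element column carries the one-letter residue code; the comment
#' line carries chain/residue metadata as JSON.  Annotations (index sets
#' and pair matrices) go to `<path>.json`.
#'
#' @param structure A [coarse_structure()].
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_structure_xyz <- function(structure, path) {
  meta <- jsonlite::toJSON(list(
    chain_id = structure$chain_id,
    residue_index = structure$residue_index,
    bead_kind = structure$bead_kind
  ), auto_unbox = FALSE)
  lines <- c(
    as.character(nrow(structure)),
    as.character(meta),
    sprintf("%s %.6f %.6f %.6f", structure$residue_name,
            structure$x, structure$y, structure$z)
  )
  writeLines(lines, path)
  ann <- structure_annotations(structure)
  if (length(ann) > 0) {
    jsonlite::write_json(ann, paste0(path, ".json"), auto_unbox = FALSE)
  }
  invisible(path)
}

#' Write a trajectory as multi-frame extended XYZ plus a TSV energy log
#'
#' @param traj A `dmd_trajectory`.
#' @param path Output XYZ path; the energy log goes to `<path>.energy.tsv`
#'   with columns time (ns), kinetic, potential and total (kcal/mol).
#' @return Invisibly `path`.
#' @export
write_trajectory_xyz <- function(traj, path) {
  n <- dim(traj$frames)[2]
  codes <- traj$topology$beads$code
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj$times)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("time_ns=%.6f", traj$times[f]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", codes,
                       traj$frames[f, , 1], traj$frames[f, , 2],
                       traj$frames[f, , 3]), con)
  }
  utils::write.table(traj$energy, paste0(path, ".energy.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

topology_to_list <- function(topology) {
  list(
    beads = as.data.frame(topology$beads),
    bonds = as.data.frame(topology$bonds),
    contacts = as.data.frame(topology$contacts),
    nonbonded = lapply(topology$nonbonded, function(sp) {
      list(radii = sp$radii, energies = sp$energies, bounded = sp$bounded)
    }),
    immobilized = topology$immobilized,
    pulled = topology$pulled,
    interface_contacts = as.data.frame(topology$interface_contacts),
    box_edge = topology$box_edge,
    options = topology$options
  )
}

#' Serialize a topology to JSON
#'
#' @param topology A `dmd_topology`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_topology_json <- function(topology, path) {
  jsonlite::write_json(topology_to_list(topology), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Export a step potential as a two-column table
#'
#' @param pot A [step_potential()].
#' @param path TSV output path (radius, energy).
#' @return Invisibly `path`.
#' @export
write_step_potential_tsv <- function(pot, path) {
  utils::write.table(tidy.step_potential(pot)[, c("r_outer", "energy")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write campaign outputs as tidy TSV tables plus a JSON report
#'
#' Every table the campaign produced is written to `dir` and listed in
#' the JSON manifest together with seeds, failures and the aggregate
#' simulated time.
#'
#' @param campaign A `binding_campaign` or `steered_campaign`.
#' @param dir Output directory (created if needed).
#' @return Invisibly the manifest (named file list).
#' @export
write_campaign_tables <- function(campaign, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (tab in campaign$report$tables) {
    x <- campaign[[tab]]
    if (is.null(x) || !is.data.frame(x) || nrow(x) == 0) next
    x <- dplyr::select(x, -dplyr::any_of("values"))
    f <- file.path(dir, paste0(tab, ".tsv"))
    utils::write.table(as.data.frame(x), f, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    manifest[[tab]] <- f
  }
  rep <- campaign$report
  rep$config <- unclass(rep$config)
  rep$config$ligand <- lapply(rep$config$ligand, unclass)
  rep$manifest <- unlist(manifest)
  f <- file.path(dir, "report.json")
  jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  manifest$report <- f
  invisible(manifest)
}

#' Read a simulation configuration from a YAML or JSON document
#'
#' The document holds any of the [sim_config()] arguments
#' (`duration_ns`, `sampling_ns`, `temperature`, `thermostat_rate`,
#' `seed`, `box_edge`).
#'
#' @param path File ending in `.json`, `.yaml` or `.yml`.
#' @return A [sim_config()].
#' @export
sim_config_from_file <- function(path) {
  args <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  do.call(sim_config, args)
}
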