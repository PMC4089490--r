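# End-to-end orchestration: run every analysis stage on a closed-state
# monomer and an open-state dimer, echo the exact configuration into the
# report, and write deterministic JSON/TSV outputs.

#' Build a validated run configuration
#'
#' @param closed_path PDB file of the closed-state structure.
#' @param open_path PDB file of the open-state dimer.
#' @param closed_chain chain id within the closed structure.
#' @param open_chains the two dimer chain ids.
#' @param alpha5_range,alpha6_range stem-helix residue ranges.
#' @param relay_anchors charge-relay anchor residue numbers.
#' @param core_residues hydrophobic-core residue numbers.
#' @param switch_residues switching-element residue numbers.
#' @param probe_radius probe radius, Angstrom (0.5 to 3).
#' @param n_points quadrature points per atom (16 to 10000).
#' @param saltbridge_cutoff salt-bridge N-O cutoff, Angstrom (2.5 to 6).
#' @param open_angle_max,closed_angle_min conformation-call thresholds,
#'   degrees.
#' @param seed integer seed (propagated to every stochastic stage).
#' @param out_dir output directory.
#' @return list of class `run_config`; every threshold is range-checked here
#'   so reports can never contain silently invalid settings.
#' @export
run_config <- function(closed_path, open_path, closed_chain = "A",
                       open_chains = c("A", "B"),
                       alpha5_range = c(70, 83), alpha6_range = c(84, 96),
                       relay_anchors = c(E = 26, central = 84, D = 86),
                       core_residues = .CORE_RESIDUES,
                       switch_residues = .SWITCH_RESIDUES,
                       probe_radius = 1.4, n_points = 960,
                       saltbridge_cutoff = 4.0,
                       open_angle_max = 35, closed_angle_min = 70,
                       seed = 1, out_dir = tempfile("pyrinswitch_run_")) {
  stopifnot(probe_radius >= 0.5, probe_radius <= 3,
            n_points >= 16, n_points <= 10000,
            saltbridge_cutoff >= 2.5, saltbridge_cutoff <= 6,
            open_angle_max > 0, closed_angle_min > open_angle_max,
            closed_angle_min <= 180, length(open_chains) == 2)
  structure(list(
    closed_path = closed_path, open_path = open_path,
    closed_chain = closed_chain, open_chains = open_chains,
    alpha5_range = alpha5_range, alpha6_range = alpha6_range,
    relay_anchors = relay_anchors, core_residues = core_residues,
    switch_residues = switch_residues,
    probe_radius = probe_radius, n_points = n_points,
    saltbridge_cutoff = saltbridge_cutoff,
    open_angle_max = open_angle_max, closed_angle_min = closed_angle_min,
    seed = as.integer(seed), out_dir = out_dir), class = "run_config")
}

#' Run the full conformational-switch analysis
#'
#' Executes, in order: interface burial of the open dimer, conformation
#' calls on all chains, charge-relay detection, hydrophobic-core burial of
#' the closed monomer, the switching-element report, salt bridges, the dimer
#' twofold axis and the interface charge summary; writes `summary.json` plus
#' TSV tables into `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return the report, invisibly (a list mirroring `summary.json`).
#' @details Outputs are deterministic: two runs with identical configuration
#'   and seed produce byte-identical JSON/TSV. The configuration (with every
#'   threshold) is echoed into the report.
#' @export
run_switch_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$closed_path, config$open_path)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  closed <- read_structure(config$closed_path)
  open_d <- read_structure(config$open_path)
  if (!all(config$open_chains %in% chain_ids(open_d)))
    stop("open dimer lacks chain(s): ",
         paste(setdiff(config$open_chains, chain_ids(open_d)), collapse = ", "))

  iface <- buried_interface_area(open_d, config$open_chains[1],
                                 config$open_chains[2],
                                 config$probe_radius, config$n_points)
  conf_closed <- call_conformation(closed, config$closed_chain,
                                   config$alpha5_range, config$alpha6_range,
                                   config$open_angle_max,
                                   config$closed_angle_min)
  conf_open <- lapply(config$open_chains, function(cc)
    call_conformation(open_d, cc, config$alpha5_range, config$alpha6_range,
                      config$open_angle_max, config$closed_angle_min))
  relay_closed <- detect_charge_relay(closed, config$closed_chain,
                                      config$relay_anchors,
                                      config$saltbridge_cutoff)
  relay_open <- detect_charge_relay(open_d, config$open_chains[1],
                                    config$relay_anchors,
                                    config$saltbridge_cutoff)
  core <- hydrophobic_core(closed, config$closed_chain,
                           config$core_residues,
                           config$probe_radius, config$n_points)
  switches <- switching_elements(closed, config$closed_chain, open_d,
                                 config$open_chains, config$switch_residues,
                                 probe_radius = config$probe_radius,
                                 n_points = config$n_points)
  bridges <- find_salt_bridges(open_d, config$saltbridge_cutoff)
  axis <- dimer_symmetry_axis(open_d, config$open_chains[1],
                              config$open_chains[2])
  charges <- interface_charge_summary(open_d, iface)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    tool = "pyrinswitch",
    version = as.character(utils::packageVersion("pyrinswitch")),
    config = unclass(config),
    interface = list(buried_area = iface$buried_area,
                     n_interface_residues = nrow(iface$interface_residues)),
    conformation = c(
      stats::setNames(list(list(state = conf_closed$state,
                                angle = conf_closed$inter_axis_angle)),
                      paste0("closed_", config$closed_chain)),
      stats::setNames(lapply(conf_open, function(x)
        list(state = x$state, angle = x$inter_axis_angle)),
        paste0("open_", config$open_chains))),
    charge_relay = list(
      closed = list(status = relay_closed$status,
                    d_E_central = relay_closed$d_E_central,
                    d_central_D = relay_closed$d_central_D),
      open = list(status = relay_open$status)),
    hydrophobic_core = list(contact_area = core$core_contact_area,
                            mean_burial_fraction =
                              mean(core$per_residue$burial_fraction)),
    switching_elements = switches,
    n_salt_bridges = nrow(bridges),
    dimer_axis = list(angle = axis$angle, twofold = axis$twofold),
    interface_charges = list(per_side = as.data.frame(charges$per_side),
                             total = as.list(charges$total))
  )
  jsonlite::write_json(report, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  utils::write.table(iface$per_residue,
                     file.path(config$out_dir, "interface_residues.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(switches,
                     file.path(config$out_dir, "switching_elements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bridges,
                     file.path(config$out_dir, "salt_bridges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(axis$distance_table,
                     file.path(config$out_dir, "axis_distances.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}

#' Fetch deposited structure fixtures (network-gated)
#'
#' Downloads PDB entries into a local cache with an md5 manifest. Offline
#' analyses never call this: cached files are reused and the function is
#' only invoked on explicit request.
#'
#' @param ids PDB accession codes (4 characters, e.g. `"4n1j"`).
#' @param dest cache directory.
#' @param base_url download root.
#' @return named character vector of file paths.
#' @export
fetch_fixtures <- function(ids, dest,
                           base_url = "https://files.rcsb.org/download") {
  bad <- !grepl("^[0-9][A-Za-z0-9]{3}$", ids)
  if (any(bad)) stop("malformed PDB id(s): ", paste(ids[bad], collapse = ", "))
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(dest, "MANIFEST.tsv")
  manifest <- if (file.exists(manifest_path))
    utils::read.table(manifest_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else data.frame(id = character(), file = character(), md5 = character(),
                  stringsAsFactors = FALSE)
  out <- character(0)
  for (id in tolower(ids)) {
    path <- file.path(dest, paste0(id, ".pdb"))
    hit <- manifest$id == id & file.exists(path)
    if (any(hit) && unname(tools::md5sum(path)) == manifest$md5[hit][1]) {
      out[id] <- path
      next
    }
    url <- sprintf("%s/%s.pdb", base_url, id)
    status <- tryCatch(utils::download.file(url, path, quiet = TRUE,
                                            mode = "wb"),
                       error = function(e) -1L, warning = function(w) -1L)
    if (!identical(status, 0L) || !file.exists(path)) {
      stop("download failed for '", id, "' from ", url)
    }
    manifest <- rbind(manifest[manifest$id != id, , drop = FALSE],
                      data.frame(id = id, file = basename(path),
                                 md5 = unname(tools::md5sum(path)),
                                 stringsAsFactors = FALSE))
    out[id] <- path
  }
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out
}
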