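# Per-cavity occupancy counting and species density maps.

# heavy-atom geometric centres of every molecule of a species, plus mol ids
molecule_centers <- function(xyz, topology, species) {
  rows <- heavy_atoms(topology, species)
  if (!length(rows)) return(list(centers = matrix(0, 0, 3), mol = integer()))
  mol <- topology$mol[rows]
  n <- rowsum(rep(1, length(rows)), mol)
  sums <- rowsum(xyz[rows, , drop = FALSE], mol)
  list(centers = sums / as.vector(n), mol = as.integer(rownames(sums)))
}

#' Is a molecule inside a cavity?
#'
#' A molecule occupies a cavity when its heavy-atom geometric centre lies
#' within `dist` (default 1.0 Angstrom) of any cavity voxel centre.
#'
#' @param mol_rows topology row indices of the molecule's atoms.
#' @param cavity a `chan_cavity`.
#' @param frame a `chan_frame`.
#' @param topology matching `chan_topology`.
#' @param dist membership distance, Angstrom.
#' @return logical.
#' @export
molecule_in_cavity <- function(mol_rows, cavity, frame, topology,
                               dist = 1.0) {
  hv <- mol_rows[toupper(topology$elem[mol_rows]) != "H"]
  if (!length(hv))
    stop("classification error: molecule has no heavy atoms")
  ctr <- colMeans(frame$xyz[hv, , drop = FALSE])
  as.logical(cavity_contains(cavity, matrix(ctr, 1, 3), mode = "dist",
                             dist = dist))
}

# per-frame cavity index (or NA) for every molecule of a species
assign_to_cavities <- function(xyz, topology, cavities, species,
                               dist = 1.0) {
  mc <- molecule_centers(xyz, topology, species)
  out <- rep(NA_integer_, nrow(mc$centers))
  if (!nrow(mc$centers)) return(list(assign = out, mol = mc$mol))
  for (ci in seq_along(cavities)) {
    inside <- cavity_contains(cavities[[ci]], mc$centers, mode = "dist",
                              dist = dist)
    out[is.na(out) & inside] <- ci
  }
  list(assign = out, mol = mc$mol)
}

#' Cavity assignment matrix for a species over a trajectory
#'
#' @param traj a `chan_trajectory` (frames in the laboratory frame of the
#'   cavities, i.e. aligned).
#' @param cavities list of `chan_cavity`.
#' @param species species class to track (default "ligand").
#' @param dist membership distance.
#' @return molecules x frames integer matrix of cavity indices (NA =
#'   unbound); rownames are molecule ids.
#' @export
cavity_assignments <- function(traj, cavities, species = "ligand",
                               dist = 1.0) {
  nf <- n_frames(traj)
  first <- assign_to_cavities(traj$coords[, , 1], traj$topology, cavities,
                              species, dist)
  out <- matrix(NA_integer_, length(first$mol), nf,
                dimnames = list(first$mol, NULL))
  out[, 1] <- first$assign
  if (nf > 1) for (f in 2:nf)
    out[, f] <- assign_to_cavities(traj$coords[, , f], traj$topology,
                                   cavities, species, dist)$assign
  out
}

#' Per-cavity occupancy time series
#'
#' Counts, per frame and cavity: ligand and water molecules (by heavy-atom
#' geometric centre membership) and lipid acyl-chain heavy atoms
#' (individually within `dist` of a cavity voxel centre).  The summary is
#' mean +/- SD over the trailing `window` fraction of frames (default the
#' second half, frames with t >= T/2).
#'
#' @param traj aligned `chan_trajectory`.
#' @param cavities list of `chan_cavity`.
#' @param dist membership distance, Angstrom.
#' @param window trailing fraction of frames for summaries (default 0.5).
#' @return object of class `chan_occupancy`: list of per-cavity data.frames
#'   (`time`, `n_ligand`, `n_water`, `n_lipid`) plus a `summary` data.frame.
#' @export
occupancy_series <- function(traj, cavities, dist = 1.0, window = 0.5) {
  top <- traj$topology
  nf <- n_frames(traj)
  ncav <- length(cavities)
  if (!ncav) stop("no cavities supplied")
  for (ci in seq_len(ncav)) if (!nrow(cavities[[ci]]$centers))
    warning("cavity ", cavities[[ci]]$id, " has an empty region; ",
            "series will be all zero")
  lig <- wat <- lip <- matrix(0L, nf, ncav)
  lip_rows <- lipid_chain_atoms(top)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f]
    la <- assign_to_cavities(xyz, top, cavities, "ligand", dist)$assign
    wa <- assign_to_cavities(xyz, top, cavities, "water", dist)$assign
    lig[f, ] <- tabulate(la, ncav)
    wat[f, ] <- tabulate(wa, ncav)
    if (length(lip_rows)) {
      pts <- xyz[lip_rows, , drop = FALSE]
      for (ci in seq_len(ncav))
        lip[f, ci] <- sum(cavity_contains(cavities[[ci]], pts,
                                          mode = "dist", dist = dist))
    }
  }
  wi <- window_frames(traj$times, window)
  ids <- vapply(cavities, function(x) x$id, "")
  series <- lapply(seq_len(ncav), function(ci)
    data.frame(time = traj$times, n_ligand = lig[, ci], n_water = wat[, ci],
               n_lipid = lip[, ci]))
  names(series) <- ids
  summ <- do.call(rbind, lapply(seq_len(ncav), function(ci) data.frame(
    cavity = ids[ci], class = cavities[[ci]]$class,
    ligand_mean = mean(lig[wi, ci]), ligand_sd = sd(lig[wi, ci]),
    water_mean = mean(wat[wi, ci]), water_sd = sd(wat[wi, ci]),
    lipid_mean = mean(lip[wi, ci]), lipid_sd = sd(lip[wi, ci]),
    stringsAsFactors = FALSE)))
  structure(list(series = series, summary = summ,
                 counts = list(ligand = lig, water = wat, lipid = lip),
                 times = traj$times, window_frames = wi),
            class = "chan_occupancy")
}

# frames belonging to the trailing window: t >= (1 - window) * T, inclusive
window_frames <- function(times, window = 0.5) {
  t_tot <- times[length(times)]
  which(times >= (1 - window) * t_tot - 1e-9)
}

# heavy atoms of lipid acyl chains: carbon atoms of lipid molecules, the
# glycerol carbons (C1-C3) and headgroup excluded
lipid_chain_atoms <- function(top) {
  rows <- heavy_atoms(top, "lipid")
  nm <- toupper(top$elety[rows])
  rows[toupper(top$elem[rows]) == "C" & !nm %in% c("C1", "C2", "C3")]
}

#' Species number-density map
#'
#' Each heavy atom of the species adds one count to its containing voxel per
#' frame; the map is the per-frame mean over the averaging window, so the
#' voxel sum equals the mean atom count inside the mapped box (conservation).
#'
#' @param traj aligned `chan_trajectory`.
#' @param species species class ("ligand", "water", "lipid", ...).
#' @param window trailing fraction of frames averaged (default 0.5, the
#'   second half).
#' @param resolution voxel edge, Angstrom (default 1).
#' @return a [chan_grid()] of mean counts per voxel per frame.
#' @export
density_map <- function(traj, species, window = 0.5, resolution = 1) {
  top <- traj$topology
  rows <- heavy_atoms(top, species)
  if (!length(rows)) stop("selection error: no atoms of species ", species)
  wi <- window_frames(traj$times, window)
  all_pts <- do.call(rbind, lapply(wi, function(f)
    traj$coords[rows, , f, drop = FALSE][, , 1]))
  lo <- floor(apply(all_pts, 2, min) / resolution) * resolution
  hi <- ceiling(apply(all_pts, 2, max) / resolution) * resolution
  dims <- pmax(1, round((hi - lo) / resolution)) + 1
  ijk <- round(sweep(all_pts, 2, lo) / resolution) + 1
  lin <- ijk[, 1] + (ijk[, 2] - 1) * dims[1] + (ijk[, 3] - 1) * dims[1] * dims[2]
  counts <- tabulate(lin, prod(dims)) / length(wi)
  chan_grid(array(counts, dim = dims), origin = lo, spacing = resolution)
}
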