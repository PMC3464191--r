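# Core data model: Topology, Frame, Trajectory.
#
# A topology is a data.frame with one row per atom and the columns
#   eleno  integer atom serial
#   elety  atom name (e.g. "CA", "OW")
#   resid  residue name (e.g. "ALA", "HOH", "ETH")
#   chain  chain identifier
#   resno  residue number
#   elem   chemical element symbol
#   vdw    van der Waals radius, Angstrom
#   species one of "protein", "water", "ligand", "lipid", "ion"
#   mol    integer molecule id (protein: one per chain; solvent/ligand/lipid:
#          one per residue)
# Units are Angstrom and nanoseconds throughout the package; conversion happens
# only at the I/O boundary.

SPECIES_LEVELS <- c("protein", "water", "ligand", "lipid", "ion")

#' Default residue-name to species classification rules
#'
#' Maps standard amino-acid residue names to `"protein"`, common water residue
#' names to `"water"`, ethanol-like residue names to `"ligand"`, phospholipid
#' residue names to `"lipid"` and monatomic ions to `"ion"`.  Pass a modified
#' copy to [read_structure()] for non-standard naming.
#'
#' @return named character vector, names are residue names.
#' @export
default_species_rules <- function() {
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "HSD", "HSE", "HSP", "HID", "HIE", "HIP",
          # pseudo-residues emitted by the synthetic channel generator
          "PWL", "PCG")
  wat <- c("HOH", "SOL", "WAT", "TIP", "TIP3", "SPC", "W")
  lig <- c("ETH", "EOH", "ETA", "ETO", "LIG")
  lip <- c("DOPC", "POPC", "DPPC", "DMPC", "LIP", "PC")
  ion <- c("NA", "CL", "K", "MG", "CA2", "ZN", "SOD", "CLA", "NA+", "CL-")
  c(setNames(rep("protein", length(aa)), aa),
    setNames(rep("water", length(wat)), wat),
    setNames(rep("ligand", length(lig)), lig),
    setNames(rep("lipid", length(lip)), lip),
    setNames(rep("ion", length(ion)), ion))
}

#' Van der Waals radii by element
#'
#' Bondi radii for the common biological elements, with hydrogen at 1.10
#' Angstrom.  Unknown elements fall back to `default_radius`.
#'
#' @param overrides optional named numeric vector of per-element overrides.
#' @param default_radius radius used for elements not in the table.
#' @return named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function(overrides = NULL, default_radius = 1.70) {
  r <- c(H = 1.10, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
         F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, NA. = 2.27, K = 2.75,
         MG = 1.73, ZN = 1.39, FE = 1.63)
  names(r)[names(r) == "NA."] <- "NA"
  if (!is.null(overrides)) r[names(overrides)] <- overrides
  attr(r, "default") <- default_radius
  r
}

lookup_vdw <- function(elem, radii = vdw_radii()) {
  out <- unname(radii[toupper(elem)])
  out[is.na(out)] <- attr(radii, "default") %||% 1.70
  out
}

#' Construct a topology
#'
#' Low-level constructor validating the atom table invariants: every atom has
#' exactly one species class, a positive van der Waals radius and a molecule
#' id.
#'
#' @param atoms data.frame with columns `eleno`, `elety`, `resid`, `chain`,
#'   `resno`, `elem`, `vdw`, `species`, `mol`.
#' @return object of class `chan_topology` (a data.frame).
#' @export
chan_topology <- function(atoms) {
  need <- c("eleno", "elety", "resid", "chain", "resno", "elem", "vdw",
            "species", "mol")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("topology missing columns: ", paste(miss, collapse = ", "))
  if (any(is.na(atoms$species)) || !all(atoms$species %in% SPECIES_LEVELS))
    stop("every atom must have exactly one species class among: ",
         paste(SPECIES_LEVELS, collapse = ", "))
  if (any(!is.finite(atoms$vdw)) || any(atoms$vdw <= 0))
    stop("van der Waals radii must be positive")
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  class(atoms) <- c("chan_topology", "data.frame")
  atoms
}

#' @export
print.chan_topology <- function(x, ...) {
  cat("chan_topology:", nrow(x), "atoms,",
      length(unique(x$mol)), "molecules,",
      length(protein_chains(x)), "protein chains\n")
  tab <- table(x$species)
  cat("  species:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Protein chain identifiers in file order
#' @param top a `chan_topology`.
#' @return character vector of chain ids.
#' @export
protein_chains <- function(top) {
  unique(top$chain[top$species == "protein"])
}

# heavy-atom row indices (optionally restricted to a species)
heavy_atoms <- function(top, species = NULL) {
  sel <- toupper(top$elem) != "H"
  if (!is.null(species)) sel <- sel & top$species %in% species
  which(sel)
}

#' Map M2 prime-notation positions to residue numbers
#'
#' For GLIC-like numbering the M2 pore-lining helix position p' corresponds to
#' residue 224 + p, e.g. 9' = 233, 14' = 238, 16' = 240.
#'
#' @param prime integer prime position(s).
#' @param offset residue number of position 0'; 224 for GLIC.
#' @return integer residue numbers.
#' @export
prime_to_resno <- function(prime, offset = 224L) offset + as.integer(prime)

#' Construct a single coordinate frame
#'
#' @param xyz n x 3 numeric matrix of coordinates in Angstrom.
#' @param time time stamp in ns.
#' @param box optional periodic box vectors (3-vector or 3x3 matrix), Angstrom.
#' @return object of class `chan_frame`.
#' @export
chan_frame <- function(xyz, time = 0, box = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must be an n x 3 matrix")
  if (time < 0) stop("frame time must be non-negative")
  structure(list(xyz = xyz, time = time, box = box), class = "chan_frame")
}

#' Construct a trajectory
#'
#' @param topology a `chan_topology`.
#' @param coords either a list of n x 3 matrices or an n x 3 x n_frames array.
#' @param times frame times in ns; must be strictly increasing and (within 1%)
#'   uniformly spaced.
#' @param dt frame spacing in ns; inferred from `times` when `NULL`.
#' @return object of class `chan_trajectory`.
#' @export
chan_trajectory <- function(topology, coords, times = NULL, dt = NULL) {
  if (is.list(coords)) {
    nf <- length(coords)
    coords <- array(unlist(coords), dim = c(nrow(coords[[1]]), 3, nf))
  }
  nf <- dim(coords)[3]
  if (nf < 2) stop("a trajectory needs at least 2 frames")
  if (dim(coords)[1] != nrow(topology))
    stop("coordinate count does not match topology atom count")
  if (is.null(times)) {
    if (is.null(dt)) dt <- 1
    times <- (seq_len(nf) - 1) * dt
  }
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  sp <- diff(times)
  if (is.null(dt)) dt <- stats::median(sp)
  if (any(abs(sp - dt) > 0.01 * dt))
    stop("frame spacing is not uniform within 1%")
  structure(list(topology = topology, coords = coords, times = times, dt = dt),
            class = "chan_trajectory")
}

#' @export
print.chan_trajectory <- function(x, ...) {
  cat("chan_trajectory:", dim(x$coords)[3], "frames x", dim(x$coords)[1],
      "atoms, dt =", x$dt, "ns\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `chan_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame of a trajectory
#' @param traj a `chan_trajectory`.
#' @param i frame index (1-based).
#' @return a `chan_frame`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  chan_frame(traj$coords[, , i], time = traj$times[i])
}
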