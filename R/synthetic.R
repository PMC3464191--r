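# Synthetic pentameric-channel generator with full ground truth.
#
# The generator emulates the statistical structure of a solvated
# channel/membrane simulation without any physics: a C5-symmetric pore wall
# with a prescribed radius profile r(z), five pore-lining M2-like helices with
# optional per-subunit kinks, ten caged cavities (five membrane-facing
# intra-subunit, five interface inter-subunit), ligand molecules hopping
# between bulk and cavities as a two-state Markov chain with exponential
# dwell times, cavity waters displaced by ligands, and lipid chains inserting
# into intra-subunit cavities with a per-frame probability reduced per
# resident ligand.
#
# Cage construction: every cavity is a rectangular box surrounded by planes of
# carbon pseudo-atoms at offsets (vdw + probe) = 3.1 A from each face, so the
# probe-free interior is *exactly* the declared box and the declared volume is
# exact ground truth.

WALL_VDW <- 1.7      # carbon pseudo-atoms everywhere
CLEAR <- WALL_VDW + 1.4   # cage plane offset: vdw + water probe

#' Specification of a synthetic pentameric channel
#'
#' Defaults describe the reference study system: a pore with its tightest
#' constriction of 2.25 A radius at the 9' level (z = 0), secondary
#' constrictions near 16' (z = +10), 2' (z = -10) and -2' (z = -18); five
#' 25-residue pore-lining helices (residues 221-245, hinge at 238); five
#' intra-subunit cavities (5 x 5 x 7 A boxes, 175 A^3, membrane-facing) and
#' five inter-subunit cavities (5 x 5 x 5 A boxes, 125 A^3, at the subunit
#' interfaces); ligand at roughly 1 mol-% of the bulk water count with 50 ns
#' mean bound dwell and 500 ns mean unbound dwell (dilute-bulk regime); one
#' 8-atom lipid chain per intra-subunit cavity; 300 bulk waters and 3 baseline
#' waters per inter-subunit cavity.
#'
#' @param pore_points two-column matrix (z, r) of the piecewise-linear target
#'   pore radius profile, Angstrom.
#' @param z_range axial extent of the transmembrane wall, Angstrom.
#' @param wall_spacing pseudo-atom spacing of the pore wall and cavity cages.
#' @param helix_radius radial distance of the M2-like helix axes from the pore
#'   axis.
#' @param kink per-subunit kink angle in degrees (length 5).
#' @param cavity_classes list of cavity class definitions, each a list with
#'   `class` ("intra"/"inter"), `size` (box edge lengths, A), `radius` (radial
#'   distance of the box centre), `angle` (angular offset of site 0, degrees)
#'   and `z` (axial centre).  Each definition is replicated five-fold by 72
#'   degree rotations.
#' @param ligand list: `count`, `tau_b` (mean bound dwell, ns), `tau_u` (mean
#'   unbound dwell, ns).
#' @param lipid list: `chains_per_intra`, `atoms_per_chain`, `p_insert`
#'   (per-frame insertion probability), `ligand_factor` (multiplicative
#'   reduction of `p_insert` per resident ligand).
#' @param water list: `bulk` count and `baseline` waters per inter-subunit
#'   cavity.
#' @param protein_jitter per-frame Gaussian positional noise of protein
#'   pseudo-atoms (A).
#' @param seed integer seed for [simulate_trajectory()].
#' @return object of class `chan_spec`.
#' @export
channel_spec <- function(pore_points = cbind(z = c(-20, -18, -10, 0, 5, 10, 15),
                                             r = c(3.5, 2.8, 2.6, 2.25, 3.0, 2.8, 3.5)),
                         z_range = c(-20, 15),
                         wall_spacing = 0.9,
                         helix_radius = 9,
                         kink = rep(0, 5),
                         cavity_classes = list(
                           list(class = "intra", size = c(5, 5, 7),
                                radius = 18, angle = 0, z = 7),
                           list(class = "inter", size = c(5, 5, 5),
                                radius = 18, angle = 36, z = -7)),
                         ligand = list(count = 20, tau_b = 50, tau_u = 500),
                         lipid = list(chains_per_intra = 1, atoms_per_chain = 8,
                                      p_insert = 0.7, ligand_factor = 0.5),
                         water = list(bulk = 300, baseline = 3),
                         protein_jitter = 0.05,
                         seed = 1) {
  if (any(pore_points[, 2] <= 0)) stop("pore radius must be positive everywhere")
  if (ligand$tau_b <= 0 || ligand$tau_u <= 0) stop("dwell means must be positive")
  if (length(kink) != 5) stop("kink must give one angle per subunit")
  max_wall <- max(pore_points[, 2]) + WALL_VDW
  for (cc in cavity_classes) {
    if (any(cc$size <= 0)) stop("cavity true volume must be positive")
    inner <- cc$radius - max(cc$size) / 2 - CLEAR
    if (inner < max_wall + 1)
      stop("cavity overlaps the pore lumen (inner edge ", round(inner, 1),
           " A vs wall ", round(max_wall, 1), " A)")
  }
  structure(list(pore_points = pore_points, z_range = z_range,
                 wall_spacing = wall_spacing, helix_radius = helix_radius,
                 kink = kink, cavity_classes = cavity_classes,
                 ligand = ligand, lipid = lipid, water = water,
                 protein_jitter = protein_jitter, seed = seed),
            class = "chan_spec")
}

#' Target pore radius of a spec at height z
#' @param spec a [channel_spec()].
#' @param z heights, Angstrom.
#' @return linear interpolation of the spec's pore profile (rule-2 clamped).
#' @export
spec_pore_radius <- function(spec, z) {
  stats::approx(spec$pore_points[, 1], spec$pore_points[, 2], xout = z,
                rule = 2)$y
}

#' Calpha trace of an ideal, optionally kinked alpha-helix
#'
#' Builds an ideal alpha-helix (1.5 A rise, 100 degree twist, 2.3 A radius)
#' along +z with residue `z0_resno` at z = 0, then rigidly rotates the part at
#' and above the hinge by `kink_deg` about the local +x axis through the hinge
#' point on the helix axis.
#'
#' @param resnos residue numbers (one Calpha each).
#' @param hinge_resno hinge residue (kept in both segments downstream).
#' @param kink_deg kink angle, degrees.
#' @param z0_resno residue whose axial position is z = 0.
#' @param rise,twist,radius helix geometry parameters.
#' @return length(resnos) x 3 coordinate matrix.
#' @export
build_kinked_helix <- function(resnos, hinge_resno = 238, kink_deg = 0,
                               z0_resno = 233, rise = 1.5, twist = 100,
                               radius = 2.3) {
  i <- as.numeric(resnos)
  th <- i * twist * pi / 180
  xyz <- cbind(radius * cos(th), radius * sin(th), (i - z0_resno) * rise)
  if (kink_deg != 0) {
    zh <- (hinge_resno - z0_resno) * rise
    R <- rotation_matrix(c(1, 0, 0), kink_deg)
    up <- i >= hinge_resno
    p <- sweep(xyz[up, , drop = FALSE], 2, c(0, 0, zh))
    xyz[up, ] <- sweep(p %*% t(R), 2, c(0, 0, zh), `+`)
  }
  xyz
}

# chain id from an angular position (sector k covers 72k +/- 36 degrees)
chain_of_angle <- function(theta_deg) {
  LETTERS[(floor(((theta_deg + 36) %% 360) / 72) %% 5) + 1]
}

# pseudo-atom plane: rectangular grid of points
plane_grid <- function(center, u, v, half_u, half_v, spacing) {
  su <- seq(-half_u, half_u, by = spacing)
  sv <- seq(-half_v, half_v, by = spacing)
  g <- expand.grid(su, sv)
  sweep(outer(g[, 1], u) + outer(g[, 2], v), 2, center, `+`)
}

# cage atoms for an axis-aligned box: planes at CLEAR (and CLEAR + 0.8)
# outside each face, extended `ext` beyond the face edges
cage_atoms <- function(center, size, spacing, ext = 1.5, shells = c(0, 0.8)) {
  h <- size / 2
  out <- list()
  axes <- diag(3)
  for (d in 1:3) {
    uo <- axes[, (d %% 3) + 1]; vo <- axes[, ((d + 1) %% 3) + 1]
    hu <- h[(d %% 3) + 1] + ext; hv <- h[((d + 1) %% 3) + 1] + ext
    for (s in c(-1, 1)) for (sh in shells) {
      c_ <- center + s * (h[d] + CLEAR + sh) * axes[, d]
      out[[length(out) + 1]] <- plane_grid(c_, uo, vo, hu, hv, spacing)
    }
  }
  do.call(rbind, out)
}

# resolved cavity sites: data.frame of id, class, site, center, size, angle
cavity_sites <- function(spec) {
  rows <- list()
  for (ci in seq_along(spec$cavity_classes)) {
    cc <- spec$cavity_classes[[ci]]
    for (k in 0:4) {
      th <- cc$angle + 72 * k
      ctr <- c(cc$radius * cos(th * pi / 180), cc$radius * sin(th * pi / 180),
               cc$z)
      rows[[length(rows) + 1]] <- data.frame(
        id = paste0(cc$class, k + 1), class = cc$class, site = k + 1,
        cx = ctr[1], cy = ctr[2], cz = ctr[3],
        sx = cc$size[1], sy = cc$size[2], sz = cc$size[3],
        angle = th, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Build the static pentamer: topology, coordinates and static ground truth
#'
#' @param spec a [channel_spec()].
#' @return list with `topology`, `frame`, and `truth` (static part: cavity
#'   table with exact volumes, per-subunit kink angles, the pore radius
#'   function, marker residue numbers).
#' @export
build_pentamer <- function(spec) {
  sites <- cavity_sites(spec)
  at <- list(); xyz <- list()
  add <- function(coords, elety, resid, chain, resno, elem, species) {
    n <- nrow(coords)
    at[[length(at) + 1]] <<- data.frame(
      elety = rep_len(elety, n), resid = rep_len(resid, n),
      chain = rep_len(chain, n), resno = rep_len(resno, n),
      elem = rep_len(elem, n), species = rep_len(species, n),
      stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1]] <<- coords
  }

  # M2-like helices: residues 221-245, one per subunit, marker residues at
  # prime positions 9' (233), 14' (238), 16' (240)
  resnos <- 221:245
  resid_of <- ifelse(resnos == 238, "PHE",
                     ifelse(resnos %in% c(233, 240), "ILE", "ALA"))
  # thin rods (0.01 A Calpha radius): the declared kink is then exact ground
  # truth under the inertia-axis convention, which carries an intrinsic
  # offset of several degrees for partial-turn segments of real-width helices
  for (k in 0:4) {
    local <- build_kinked_helix(resnos, kink_deg = spec$kink[k + 1],
                                radius = 0.01)
    th <- 72 * k
    lab <- rotate_z(local, th)
    lab[, 1] <- lab[, 1] + spec$helix_radius * cos(th * pi / 180)
    lab[, 2] <- lab[, 2] + spec$helix_radius * sin(th * pi / 180)
    add(lab, "CA", resid_of, LETTERS[k + 1], resnos, "C", "protein")
  }

  # pore wall: stacked rings of radius r(z) + vdw
  zs <- seq(spec$z_range[1], spec$z_range[2], by = 1)
  for (i in seq_along(zs)) {
    z <- zs[i]
    R <- spec_pore_radius(spec, z) + WALL_VDW
    n <- max(8, ceiling(2 * pi * R / spec$wall_spacing))
    th <- (seq_len(n) - 1) / n * 360 + i * 3.7   # stagger successive rings
    ring <- cbind(R * cos(th * pi / 180), R * sin(th * pi / 180), z)
    add(ring, "W", "PWL", chain_of_angle(th), 1000 + i, "C", "protein")
  }

  # cavity cages
  for (j in seq_len(nrow(sites))) {
    s <- sites[j, ]
    cg <- cage_atoms(c(s$cx, s$cy, s$cz), c(s$sx, s$sy, s$sz),
                     spec$wall_spacing)
    th <- atan2(cg[, 2] - s$cy, cg[, 1] - s$cx) * 180 / pi  # side of interface
    if (s$class == "intra") {
      ch <- LETTERS[s$site]
    } else {
      # interface cage: split atoms between the two flanking subunits by the
      # tangential side of the interface axis
      tang <- -sin(s$angle * pi / 180) * (cg[, 1] - s$cx) +
        cos(s$angle * pi / 180) * (cg[, 2] - s$cy)
      ch <- ifelse(tang < 0, LETTERS[s$site], LETTERS[(s$site %% 5) + 1])
    }
    add(cg, "CG", "PCG", ch, 2000 + j, "C", "protein")
  }

  # packing atoms: fill the interstitial protein body between wall, helices
  # and cavity cages so that only the declared cavities are enclosed voids
  r_out <- max(sqrt(sites$cx^2 + sites$cy^2)) +
    max(sites$sx, sites$sy) / 2 + CLEAR + 1.2
  g <- seq(-r_out, r_out, by = 2.6)
  zg <- seq(spec$z_range[1] - 1, spec$z_range[2] + 4, by = 2.6)
  pk <- as.matrix(expand.grid(g, g, zg))
  rad <- sqrt(pk[, 1]^2 + pk[, 2]^2)
  keep <- rad >= 7 & rad <= r_out
  # stay clear of every cavity box (cage clearance + margin)
  for (j in seq_len(nrow(sites))) {
    s <- sites[j, ]
    dx <- pmax(abs(pk[, 1] - s$cx) - s$sx / 2, 0)
    dy <- pmax(abs(pk[, 2] - s$cy) - s$sy / 2, 0)
    dz <- pmax(abs(pk[, 3] - s$cz) - s$sz / 2, 0)
    keep <- keep & sqrt(dx^2 + dy^2 + dz^2) >= CLEAR + 0.15
  }
  pk <- pk[keep, , drop = FALSE]
  th_pk <- atan2(pk[, 2], pk[, 1]) * 180 / pi
  add(pk, "PK", "PWL", chain_of_angle(th_pk), 5000, "C", "protein")

  atoms <- do.call(rbind, at)
  coords <- do.call(rbind, xyz)
  atoms$eleno <- seq_len(nrow(atoms))
  atoms$vdw <- rep(WALL_VDW, nrow(atoms))
  atoms$mol <- assign_molecules(atoms$chain, atoms$resno, atoms$resid,
                                atoms$species)
  top <- chan_topology(atoms)
  sites$volume <- sites$sx * sites$sy * sites$sz
  truth <- list(cavities = sites, kink = spec$kink,
                pore_points = spec$pore_points,
                markers = c(p9 = 233L, p14 = 238L, p16 = 240L))
  list(topology = top, frame = chan_frame(coords), truth = truth)
}

#' Two-state (bound/bulk) exchange traces with exponential dwell times
#'
#' Each molecule follows a continuous-time Markov chain between "bulk" and
#' "bound" with exponential dwell times of means `tau_u` and `tau_b`; on each
#' binding event a cavity is drawn uniformly.  States are sampled at the frame
#' times.
#'
#' @param n_mol number of molecules.
#' @param nf number of frames.
#' @param dt frame spacing, ns.
#' @param tau_b,tau_u mean bound / unbound dwell times, ns.
#' @param n_cav number of cavities to assign bound episodes to.
#' @param seed integer seed.
#' @return list with `traces` (n_mol x nf 0/1 matrix) and `assign` (n_mol x
#'   nf cavity index, NA when unbound).
#' @export
simulate_dwell_traces <- function(n_mol, nf, dt, tau_b, tau_u, n_cav = 1,
                                  seed = 1) {
  with_seed(seed, {
    traces <- matrix(0L, n_mol, nf)
    assign_ <- matrix(NA_integer_, n_mol, nf)
    t_end <- nf * dt
    p_bound <- tau_b / (tau_b + tau_u)
    for (m in seq_len(n_mol)) {
      t <- 0
      bound <- runif(1) < p_bound
      cav <- if (bound) sample.int(n_cav, 1) else NA_integer_
      while (t < t_end) {
        dwell <- rexp(1, rate = 1 / if (bound) tau_b else tau_u)
        f0 <- floor(t / dt) + 1
        f1 <- min(nf, ceiling((t + dwell) / dt))
        if (f0 <= nf && f1 >= f0 && bound) {
          traces[m, f0:f1] <- 1L
          assign_[m, f0:f1] <- cav
        }
        t <- t + dwell
        bound <- !bound
        if (bound) cav <- sample.int(n_cav, 1)
      }
    }
    list(traces = traces, assign = assign_)
  })
}

# uniform point in an axis-aligned box shrunk by `margin` from every face
runif_in_box <- function(n, center, size, margin = 1) {
  h <- pmax(size / 2 - margin, 0.05)
  sweep(cbind(runif(n, -h[1], h[1]), runif(n, -h[2], h[2]),
              runif(n, -h[3], h[3])), 2, center, `+`)
}

# uniform point in a cylindrical solvent shell (emulates "more than 8 A from
# the protein" bulk placement)
runif_in_shell <- function(n, r_in, r_out, z_lim) {
  r <- sqrt(runif(n, r_in^2, r_out^2))
  th <- runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th), runif(n, z_lim[1], z_lim[2]))
}

#' Simulate a synthetic channel trajectory with ground truth
#'
#' The protein scaffold is static apart from optional Gaussian jitter; ligands
#' follow two-state exchange dynamics ([simulate_dwell_traces()]), bound
#' ligands are placed uniformly strictly inside their assigned cavity box and
#' bulk ligands in a solvent shell 8-25 A outside the protein; cavity waters
#' are displaced one-for-one by resident ligands; lipid chains insert into
#' intra-subunit cavities with per-frame probability `p_insert *
#' ligand_factor^n_ligand`.  All randomness derives from `seed`.
#'
#' @param spec a [channel_spec()].
#' @param nf number of frames (>= 2).
#' @param dt frame spacing, ns.
#' @param seed integer seed; defaults to `spec$seed`.
#' @return list with `trajectory` (a [chan_trajectory()]) and `truth`
#'   (ground-truth list: cavity table with exact volumes, per-ligand bound
#'   traces and cavity assignments, per-cavity per-frame water counts and
#'   lipid atom counts, dwell means, theoretical bound fraction, kink angles,
#'   pore profile).
#' @export
simulate_trajectory <- function(spec, nf, dt = 1, seed = spec$seed) {
  if (nf < 2) stop("nf must be >= 2")
  base <- build_pentamer(spec)
  sites <- base$truth$cavities
  ncav <- nrow(sites)
  intra_idx <- which(sites$class == "intra")
  n_lig <- spec$ligand$count
  dyn <- simulate_dwell_traces(n_lig, nf, dt, spec$ligand$tau_b,
                               spec$ligand$tau_u, ncav, seed = seed)

  prot_xyz <- base$frame$xyz
  n_prot <- nrow(prot_xyz)
  shell_in <- max(sites$cx^2 + sites$cy^2)^0.5 + max(sites$sx) + CLEAR + 8
  shell_out <- shell_in + 17
  zlim <- spec$z_range + c(-5, 5)

  # fixed atom pool (constant topology): displaced cavity waters and
  # uninserted lipid chains park in the solvent / membrane shell
  n_wcav <- spec$water$baseline * length(which(sites$class == "inter"))
  n_wat <- spec$water$bulk + n_wcav
  n_chain <- spec$lipid$chains_per_intra * length(intra_idx)
  apc <- spec$lipid$atoms_per_chain

  top <- base$topology
  extra <- list(
    data.frame(elety = rep(c("C1", "C2", "O1"), n_lig),
               resid = "ETH", chain = "L",
               resno = rep(seq_len(n_lig), each = 3), elem = rep(c("C", "C", "O"), n_lig),
               species = "ligand", stringsAsFactors = FALSE),
    data.frame(elety = "OW", resid = "HOH", chain = "S",
               resno = seq_len(n_wat), elem = "O", species = "water",
               stringsAsFactors = FALSE),
    data.frame(elety = paste0("CH", rep(seq_len(apc), n_chain)),
               resid = "LIP", chain = "M",
               resno = rep(seq_len(n_chain), each = apc), elem = "C",
               species = "lipid", stringsAsFactors = FALSE))
  extra <- do.call(rbind, extra)
  extra$eleno <- n_prot + seq_len(nrow(extra))
  extra$vdw <- lookup_vdw(extra$elem)
  all_atoms <- rbind(top[, c("elety", "resid", "chain", "resno", "elem",
                             "species", "eleno", "vdw", "mol")][, ],
                     cbind(extra, mol = 0)[, c("elety", "resid", "chain",
                                               "resno", "elem", "species",
                                               "eleno", "vdw", "mol")])
  all_atoms$mol <- assign_molecules(all_atoms$chain, all_atoms$resno,
                                    all_atoms$resid, all_atoms$species)
  top_all <- chan_topology(all_atoms)

  lig_rows <- n_prot + seq_len(3 * n_lig)
  wat_rows <- max(lig_rows) + seq_len(n_wat)
  lip_rows <- max(wat_rows) + seq_len(n_chain * apc)

  # cavity each fixed water belongs to (inter cavities only), NA for bulk
  wat_cav <- c(rep(which(sites$class == "inter"),
                   each = spec$water$baseline), rep(NA, spec$water$bulk))
  chain_cav <- rep(intra_idx, each = spec$lipid$chains_per_intra)

  water_counts <- matrix(0L, nf, ncav)
  lipid_atoms <- matrix(0L, nf, ncav)
  coords <- array(0, dim = c(nrow(all_atoms), 3, nf))

  with_seed(seed + 1L, {
    # rigid 3-atom ligand body: heavy-atom geometric centre at the origin
    body <- rbind(c(0.7, 0, 0), c(-0.35, 0.6, 0), c(-0.35, -0.6, 0))
    for (f in seq_len(nf)) {
      fx <- prot_xyz
      if (spec$protein_jitter > 0)
        fx <- fx + matrix(rnorm(length(fx), 0, spec$protein_jitter),
                          ncol = 3)
      frame_xyz <- matrix(0, nrow(all_atoms), 3)
      frame_xyz[seq_len(n_prot), ] <- fx

      n_in_cav <- tabulate(dyn$assign[, f][dyn$traces[, f] == 1L], ncav)

      # ligands
      for (m in seq_len(n_lig)) {
        ctr <- if (dyn$traces[m, f] == 1L) {
          s <- sites[dyn$assign[m, f], ]
          runif_in_box(1, c(s$cx, s$cy, s$cz), c(s$sx, s$sy, s$sz))
        } else runif_in_shell(1, shell_in, shell_out, zlim)
        ax <- fibonacci_sphere(32)[sample.int(32, 1), ]
        R <- rotation_matrix(ax, runif(1, 0, 360))
        frame_xyz[lig_rows[(m - 1) * 3 + 1:3], ] <-
          sweep(body %*% t(R), 2, ctr, `+`)
      }

      # cavity waters: baseline minus resident ligands, never negative
      for (j in which(sites$class == "inter")) {
        rows_j <- wat_rows[which(wat_cav == j)]
        keep <- max(0L, length(rows_j) - n_in_cav[j])
        s <- sites[j, ]
        if (keep > 0)
          frame_xyz[rows_j[seq_len(keep)], ] <-
            runif_in_box(keep, c(s$cx, s$cy, s$cz), c(s$sx, s$sy, s$sz))
        if (keep < length(rows_j))
          frame_xyz[rows_j[(keep + 1):length(rows_j)], ] <-
            runif_in_shell(length(rows_j) - keep, shell_in, shell_out, zlim)
        water_counts[f, j] <- keep
      }
      bulk_w <- wat_rows[is.na(wat_cav)]
      frame_xyz[bulk_w, ] <- runif_in_shell(length(bulk_w), shell_in,
                                            shell_out, zlim)

      # lipid chains: per-frame insertion, suppressed by resident ligands
      for (ci in seq_len(n_chain)) {
        j <- chain_cav[ci]
        p <- spec$lipid$p_insert * spec$lipid$ligand_factor^n_in_cav[j]
        rows_c <- lip_rows[(ci - 1) * apc + seq_len(apc)]
        if (runif(1) < p) {
          s <- sites[j, ]
          z0 <- runif(1, s$cz - s$sz / 2 + 1.1,
                      s$cz + s$sz / 2 - 1.1 - 0.55 * (apc - 1))
          ctr <- runif_in_box(1, c(s$cx, s$cy, 0), c(s$sx, s$sy, 1), margin = 1.1)
          frame_xyz[rows_c, ] <- cbind(rep(ctr[1], apc), rep(ctr[2], apc),
                                       z0 + 0.55 * (seq_len(apc) - 1))
          lipid_atoms[f, j] <- apc
        } else {
          frame_xyz[rows_c, ] <- runif_in_shell(apc, shell_in, shell_out,
                                                c(-10, 10))
        }
      }
      coords[, , f] <- frame_xyz
    }
  })

  traj <- chan_trajectory(top_all, coords, dt = dt)
  truth <- base$truth
  truth$traces <- dyn$traces
  truth$assign <- dyn$assign
  truth$water_counts <- water_counts
  truth$lipid_atoms <- lipid_atoms
  truth$tau_b <- spec$ligand$tau_b
  truth$tau_u <- spec$ligand$tau_u
  truth$bound_fraction <- spec$ligand$tau_b /
    (spec$ligand$tau_b + spec$ligand$tau_u)
  list(trajectory = traj, truth = truth)
}
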