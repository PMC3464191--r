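# Void detection, consensus cavities, classification, five-fold
# symmetrization, Monte-Carlo volumes and cavity-lining polarity.

# scan directions for the burial test: 6 axial + 8 body-diagonal rays
burial_rays <- function() {
  ax <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  dg <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
  unname(rbind(ax, dg))
}

# error unless the frame's five-fold axis is (close to) +z
check_aligned <- function(frame, topology, tol_deg = 5) {
  ca <- which(topology$species == "protein" & topology$elety == "CA")
  if (length(ca) < 3) ca <- heavy_atoms(topology, "protein")
  e <- eigen(stats::cov(frame$xyz[ca, , drop = FALSE]), symmetric = TRUE)
  sep <- vapply(1:3, function(i) min(abs(e$values[i] - e$values[-i])),
                numeric(1))
  axis <- e$vectors[, which.max(sep)]
  ang <- acos(pmin(1, abs(axis[3]))) * 180 / pi
  if (ang > tol_deg)
    stop("precondition: frame is not aligned to the pore axis (",
         round(ang, 1), " degrees off +z); run align_to_pore_axis() first")
  invisible(TRUE)
}

#' A cavity region (set of lattice voxels, optionally rotated)
#'
#' Voxel centres live on a cubic lattice in a template frame; `rotation`
#' degrees about the +z pore axis take them to the laboratory frame (used by
#' [symmetrize_cavities()]; 0 for detected components).
#'
#' @param centers m x 3 matrix of voxel centres (template frame).
#' @param spacing lattice spacing, Angstrom.
#' @param id,class,site,chains metadata (class is "intra", "inter" or
#'   "ambiguous").
#' @param rotation degrees about +z taking template to laboratory frame.
#' @return object of class `chan_cavity`.
#' @export
chan_cavity <- function(centers, spacing = 1, id = "cav", class = NA,
                        site = NA, chains = NULL, rotation = 0) {
  structure(list(centers = as.matrix(centers), spacing = spacing, id = id,
                 class = class, site = site, chains = chains,
                 rotation = rotation), class = "chan_cavity")
}

#' @export
print.chan_cavity <- function(x, ...) {
  cat("chan_cavity", x$id, "(", x$class, "): ", nrow(x$centers),
      " voxels, rotation ", x$rotation, " deg\n", sep = "")
  invisible(x)
}

# voxel centres in the laboratory frame
cavity_centers_lab <- function(cav) {
  if (cav$rotation == 0) cav$centers else rotate_z(cav$centers, cav$rotation)
}

# grow the voxel set by n lattice steps (Chebyshev neighbourhood)
dilate_cavity <- function(cav, n = 1) {
  if (n <= 0) return(cav)
  off <- as.matrix(expand.grid(-n:n, -n:n, -n:n)) * cav$spacing
  pts <- do.call(rbind, lapply(seq_len(nrow(off)), function(i)
    sweep(cav$centers, 2, off[i, ], `+`)))
  cav$centers <- unique(round(pts, 6))
  cav
}

# TRUE for points inside the cavity: "cube" = inside the union of voxel
# cubes; "dist" = within `dist` of the nearest voxel centre (the occupancy
# membership rule)
cavity_contains <- function(cav, pts, mode = c("cube", "dist"), dist = 1.0) {
  mode <- match.arg(mode)
  pts <- matrix(pts, ncol = 3)
  if (cav$rotation != 0) pts <- rotate_z(pts, -cav$rotation)
  if (mode == "dist")
    return(cpp_min_dist(pts, cav$centers) <= dist)
  off <- cav$centers[1, ]
  key <- function(m) {
    i <- round(sweep(m, 2, off) / cav$spacing) + 1000
    (i[, 1] * 2001 + i[, 2]) * 2001 + i[, 3]
  }
  nearest <- sweep(round(sweep(pts, 2, off) / cav$spacing) * cav$spacing,
                   2, off, `+`)
  ok <- key(nearest) %in% key(cav$centers)
  # nearest lattice point membership == inside that voxel's cube
  ok & (apply(abs(pts - nearest), 1, max) <= cav$spacing / 2 + 1e-9)
}

#' Detect void voxels in one aligned frame
#'
#' A voxel on the 1 Angstrom lattice is void when its centre is at least
#' (vdw + probe) from every protein heavy atom, it is buried (at least
#' `min_hits` of 14 scan rays meet a protein heavy atom within `ray_len`),
#' and it does not lie in the pore lumen (radial distance to the axis not
#' more than the pore radius at its height).
#'
#' @param frame aligned `chan_frame`.
#' @param topology matching `chan_topology`.
#' @param probe probe radius, Angstrom (default 1.4, a water).
#' @param spacing voxel lattice spacing (default 1).
#' @param z_range axial span of the grid (default: protein extent).
#' @param grid optional `chan_grid` fixing origin/dimensions (for trajectory
#'   consensus); values are ignored.
#' @param ray_len,min_hits burial rule parameters.
#' @param pore optional data.frame (z, r) from [radius_profile()]; computed
#'   from the frame when `NULL`.
#' @return logical `chan_grid` (TRUE = void).
#' @export
detect_voids <- function(frame, topology, probe = 1.4, spacing = 1,
                         z_range = NULL, grid = NULL, ray_len = 8,
                         min_hits = 9, pore = NULL) {
  check_aligned(frame, topology)
  hv <- heavy_atoms(topology, "protein")
  pa <- frame$xyz[hv, , drop = FALSE]
  vdw <- topology$vdw[hv]
  if (is.null(grid)) {
    if (is.null(z_range)) z_range <- range(pa[, 3])
    lo <- c(floor(min(pa[, 1])), floor(min(pa[, 2])), max(floor(min(pa[, 3])), z_range[1]))
    hi <- c(ceiling(max(pa[, 1])), ceiling(max(pa[, 2])), min(ceiling(max(pa[, 3])), z_range[2]))
    dims <- pmax(1, floor((hi - lo) / spacing) + 1)
    grid <- chan_grid(array(0, dim = dims), origin = lo, spacing = spacing)
  }
  centers <- grid_centers(grid)
  code <- cpp_classify_voxels(centers, pa, vdw, probe, burial_rays(),
                              ray_len, min_hits)
  void <- code == 2L
  if (is.null(pore))
    pore <- radius_profile(frame, topology, z_range = range(centers[, 3]),
                           z_step = spacing)
  ok_p <- !is.na(pore$r)
  rz <- if (sum(ok_p) >= 2)
    stats::approx(pore$z[ok_p], pore$r[ok_p], xout = centers[, 3],
                  rule = 2)$y
  else if (sum(ok_p) == 1) rep(pore$r[ok_p], nrow(centers))
  else rep(NA_real_, nrow(centers))
  lumen <- !is.na(rz) & sqrt(centers[, 1]^2 + centers[, 2]^2) <= rz + probe
  void[lumen] <- FALSE
  chan_grid(array(void, dim = dim(grid$values)), grid$origin, grid$spacing)
}

# connected components (26-neighbourhood) of TRUE voxels in a logical grid
grid_components <- function(grid, min_voxels = 8) {
  d <- dim(grid$values)
  idx <- which(grid$values)
  if (!length(idx)) return(list())
  ii <- arrayInd(idx, d)
  key <- ii[, 1] + (ii[, 2] - 1) * d[1] + (ii[, 3] - 1) * d[1] * d[2]
  lookup <- new.env(hash = TRUE, size = length(key))
  for (j in seq_along(key)) assign(as.character(key[j]), j, envir = lookup)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  comp <- integer(length(idx))
  nc <- 0L
  for (j in seq_along(idx)) {
    if (comp[j]) next
    nc <- nc + 1L
    queue <- j; comp[j] <- nc
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nb <- sweep(off, 2, ii[cur, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      nbk <- nb[, 1] + (nb[, 2] - 1) * d[1] + (nb[, 3] - 1) * d[1] * d[2]
      for (k in nbk) {
        hit <- mget(as.character(k), envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(hit) && !comp[hit]) { comp[hit] <- nc; queue <- c(queue, hit) }
      }
    }
  }
  centers <- sweep((ii - 1) * grid$spacing, 2, grid$origin, `+`)
  comps <- lapply(seq_len(nc), function(c_)
    chan_cavity(centers[comp == c_, , drop = FALSE], grid$spacing,
                id = paste0("component", c_)))
  comps[vapply(comps, function(x) nrow(x$centers), 0L) >= min_voxels]
}

#' Consensus cavities over a trajectory
#'
#' Frames are sampled at `stride`, aligned, void-classified, and per-voxel
#' void frequencies accumulated; voxels void in at least `freq_threshold` of
#' the sampled frames form connected components (26-neighbourhood),
#' discarding components below `min_voxels`.
#'
#' @param traj a `chan_trajectory`.
#' @param stride frame stride for sampling (default 5, i.e. every 5 ns at
#'   1 ns spacing).
#' @param freq_threshold consensus frequency threshold (default 0.20).
#' @param min_voxels minimum component size.
#' @param ... passed to [detect_voids()].
#' @return list with `grid` (frequency `chan_grid`), `cavities` (list of
#'   `chan_cavity`), and `n_sampled`.
#' @export
consensus_cavities <- function(traj, stride = 5, freq_threshold = 0.20,
                               min_voxels = 8, ...) {
  if (stride > n_frames(traj))
    stop("sampling error: stride (", stride, ") exceeds trajectory length (",
         n_frames(traj), " frames)")
  idx <- seq(1, n_frames(traj), by = stride)
  top <- traj$topology
  acc <- NULL; grid <- NULL
  for (i in idx) {
    al <- align_to_pore_axis(get_frame(traj, i), top)
    vg <- detect_voids(al$frame, top, grid = grid, ...)
    if (is.null(grid)) {
      grid <- vg
      acc <- array(0, dim = dim(vg$values))
    }
    acc <- acc + vg$values
  }
  freq <- acc / length(idx)
  fgrid <- chan_grid(freq, grid$origin, grid$spacing)
  sel <- chan_grid(freq >= freq_threshold, grid$origin, grid$spacing)
  list(grid = fgrid, cavities = grid_components(sel, min_voxels),
       n_sampled = length(idx))
}

#' Classify cavities as intra- or inter-subunit
#'
#' Lining atoms are protein heavy atoms within `cutoff` of any cavity voxel.
#' A component is intra-subunit when at least 80% of lining atoms belong to
#' one chain, inter-subunit when two chains each contribute at least 20%
#' (assigned to that interface), otherwise flagged ambiguous (reported, not
#' dropped).
#'
#' @param cavities list of `chan_cavity` from [consensus_cavities()].
#' @param frame aligned `chan_frame` used for the lining.
#' @param topology matching `chan_topology`.
#' @param cutoff lining distance, Angstrom.
#' @return the cavities with `class`, `chains`, `site` and `lining` filled in.
#' @export
classify_cavities <- function(cavities, frame, topology, cutoff = 5) {
  hv <- heavy_atoms(topology, "protein")
  pa <- frame$xyz[hv, , drop = FALSE]
  lapply(cavities, function(cav) {
    d <- cpp_min_dist(pa, cavity_centers_lab(cav))
    lining <- hv[d <= cutoff]
    if (!length(lining)) { cav$class <- "ambiguous"; return(cav) }
    frac <- sort(table(topology$chain[lining]) / length(lining),
                 decreasing = TRUE)
    chains <- names(frac)
    if (frac[1] >= 0.80) {
      cav$class <- "intra"; cav$chains <- chains[1]
      cav$site <- match(chains[1], LETTERS)
    } else if (length(frac) >= 2 && frac[2] >= 0.20) {
      cav$class <- "inter"; cav$chains <- chains[1:2]
      ix <- sort(match(chains[1:2], LETTERS))
      # interface k sits between subunits k and k+1 (E-A wraps to site 5)
      cav$site <- if (identical(ix, c(1L, 5L))) 5L else ix[1]
    } else {
      cav$class <- "ambiguous"; cav$chains <- chains[1]
    }
    cav$lining <- lining
    cav
  })
}

#' Five-fold symmetrization of a cavity class
#'
#' The largest component of the class becomes the template; rotated copies at
#' k * 72 degrees (k = 0..4) about the pore axis define the per-site
#' integration regions, preserving per-site identity.
#'
#' @param cavities classified cavities.
#' @param class "intra" or "inter".
#' @param n_sym symmetry order (5).
#' @return list of `n_sym` `chan_cavity` regions (empty with a warning when
#'   the class is missing).
#' @export
symmetrize_cavities <- function(cavities, class, n_sym = 5) {
  cls <- Filter(function(x) identical(x$class, class), cavities)
  if (!length(cls)) {
    warning("no cavities of class '", class, "' to symmetrize")
    return(list())
  }
  sizes <- vapply(cls, function(x) nrow(x$centers), 0L)
  tmpl <- cls[[which.max(sizes)]]
  base_site <- if (is.na(tmpl$site)) 1L else tmpl$site
  lapply(0:(n_sym - 1), function(k) {
    cav <- tmpl
    cav$rotation <- tmpl$rotation + k * 360 / n_sym
    cav$site <- ((base_site - 1L + k) %% n_sym) + 1L
    cav$id <- paste0(class, cav$site)
    cav$chains <- NULL
    cav
  })
}

#' Monte-Carlo cavity volume
#'
#' Uniform samples in the bounding box of the region; a sample is a hit when
#' it falls inside the region's voxel cubes (after optional dilation) and at
#' least (vdw + probe) from every protein heavy atom.  Volume = box volume x
#' hit fraction, SE = box volume x sqrt(p (1 - p) / n).
#'
#' @param region a `chan_cavity`.
#' @param frame aligned `chan_frame` supplying the atoms (`NULL` for a pure
#'   region volume).
#' @param topology matching `chan_topology` (required with `frame`).
#' @param n number of Monte-Carlo samples (>= 100).
#' @param seed integer seed (deterministic volumes).
#' @param probe probe radius, Angstrom.
#' @param dilate lattice steps to grow the region before sampling; use 1 when
#'   the sharp cavity boundary should be defined by the atoms rather than by
#'   the detected voxel set (per-frame volumes inside a fixed consensus
#'   region).
#' @return numeric volume in Angstrom^3 with attributes `se` and `n`.
#' @export
mc_volume <- function(region, frame = NULL, topology = NULL, n = 10000,
                      seed = 1, probe = 1.4, dilate = 0) {
  if (n < 100) stop("precision error: n must be at least 100")
  if (nrow(region$centers) == 0)
    return(structure(0, se = 0, n = n))
  reg <- dilate_cavity(region, dilate)
  lab <- cavity_centers_lab(reg)
  half <- reg$spacing * sqrt(3) / 2
  lo <- apply(lab, 2, min) - half
  hi <- apply(lab, 2, max) + half
  vbox <- prod(hi - lo)
  with_seed(seed, {
    pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
                 runif(n, lo[3], hi[3]))
    hit <- cavity_contains(reg, pts, mode = "cube")
    if (!is.null(frame) && any(hit)) {
      hv <- heavy_atoms(topology, "protein")
      clash <- cpp_clash(pts[hit, , drop = FALSE],
                         frame$xyz[hv, , drop = FALSE], topology$vdw[hv],
                         probe)
      hit[hit] <- !clash
    }
    p <- mean(hit)
    structure(vbox * p, se = vbox * sqrt(p * (1 - p) / n), n = n)
  })
}

#' Polar fraction of the cavity-lining accessible surface
#'
#' Shrake-Rupley-style point sampling of the probe-accessible surface of the
#' cavity-lining atoms, restricted to surface points facing the cavity
#' (within `face_dist` of a cavity voxel centre); the polar fraction is the
#' area contributed by N/O/S atoms over the total.
#'
#' @param cavity a `chan_cavity`.
#' @param frame aligned `chan_frame`.
#' @param topology matching `chan_topology`.
#' @param probe probe radius (default 1.4).
#' @param n_points surface points per atom.
#' @param face_dist maximum distance from a surface point to the nearest
#'   cavity voxel centre.
#' @param cutoff lining selection distance.
#' @return fraction in \[0, 1\], or `NA` when the cavity-facing surface is
#'   empty; attribute `area` holds the total facing area.
#' @export
polar_surface_fraction <- function(cavity, frame, topology, probe = 1.4,
                                   n_points = 600, face_dist = 1.5,
                                   cutoff = 5) {
  hv <- heavy_atoms(topology, "protein")
  pa <- frame$xyz[hv, , drop = FALSE]
  vdw <- topology$vdw[hv]
  lab <- cavity_centers_lab(cavity)
  dmin <- cpp_min_dist(pa, lab)
  lining <- which(dmin <= cutoff)
  if (!length(lining)) return(structure(NA_real_, area = 0))
  sph <- fibonacci_sphere(n_points)
  polar <- toupper(topology$elem[hv]) %in% c("N", "O", "S")
  a_pol <- 0; a_tot <- 0
  for (li in lining) {
    r <- vdw[li] + probe
    pts <- sweep(sph * r, 2, pa[li, ], `+`)
    others <- setdiff(seq_len(nrow(pa)), li)
    # accessible: not inside any other atom's probe-expanded sphere
    near <- others[cpp_min_dist(matrix(pa[others, ], ncol = 3),
                                matrix(pa[li, ], nrow = 1)) <= r + max(vdw) + probe]
    acc <- if (length(near))
      !cpp_clash(pts, pa[near, , drop = FALSE], vdw[near], probe)
    else rep(TRUE, n_points)
    facing <- acc
    facing[acc] <- cpp_min_dist(pts[acc, , drop = FALSE], lab) <= face_dist
    area <- 4 * pi * r^2 * sum(facing) / n_points
    a_tot <- a_tot + area
    if (polar[li]) a_pol <- a_pol + area
  }
  if (a_tot == 0) return(structure(NA_real_, area = 0))
  structure(a_pol / a_tot, area = a_tot)
}
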