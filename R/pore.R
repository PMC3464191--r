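# Pore radius as a function of axial position and time.
#
# The pore radius at height z is the radius of the largest sphere centred in
# the plane z that touches no atom van der Waals sphere: r(z) = max over
# centres c of min over atoms i of (|c - x_i| - vdw_i), the classic
# HOLE-style definition.  The centre search is a 9-start Nelder-Mead within a
# disc around the pore axis.

#' Align a frame to the pore axis
#'
#' Rotates the pentamer so its five-fold axis (the non-degenerate principal
#' axis of the protein Calpha inertia tensor) points along +z with the
#' extracellular side (16' marker) up, and translates so the axis passes
#' through the origin with the mean 9' marker Calpha at z = 0.
#'
#' @param frame a `chan_frame`.
#' @param topology matching `chan_topology`.
#' @param marker_lower,marker_upper residue numbers of the z-origin anchor
#'   (9', default 233) and orientation marker (16', default 240).
#' @return list with `frame` (transformed), `R` (rotation), `shift`
#'   (translation applied after rotation).
#' @export
align_to_pore_axis <- function(frame, topology, marker_lower = 233,
                               marker_upper = 240) {
  xyz <- frame$xyz
  ca <- which(topology$species == "protein" & topology$elety == "CA")
  if (length(ca) < 3) ca <- heavy_atoms(topology, "protein")
  e <- eigen(stats::cov(xyz[ca, , drop = FALSE]), symmetric = TRUE)
  # the symmetry axis is the principal axis whose eigenvalue is most
  # separated from the two (nearly degenerate) perpendicular ones
  sep <- vapply(1:3, function(i) min(abs(e$values[i] - e$values[-i])),
                numeric(1))
  axis <- e$vectors[, which.max(sep)]
  # eigenvector sign is arbitrary: canonicalize toward +z so nearly-aligned
  # frames get a small rotation (never a 180-degree flip that would scramble
  # the azimuth across frames); the marker check below still flips a frame
  # that is genuinely upside down
  if (axis[3] < 0) axis <- -axis
  # rotation taking `axis` onto +z
  v <- c(axis[2], -axis[1], 0)   # axis x z
  if (sqrt(sum(v^2)) < 1e-9) {
    R <- if (axis[3] > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    ang <- acos(pmax(-1, pmin(1, axis[3]))) * 180 / pi
    R <- rotation_matrix(v, ang)
  }
  out <- xyz %*% t(R)

  lo <- which(topology$species == "protein" & topology$elety == "CA" &
                topology$resno == marker_lower)
  hi <- which(topology$species == "protein" & topology$elety == "CA" &
                topology$resno == marker_upper)
  if (!length(lo) || !length(hi)) {
    warning("missing 9'/16' marker residues; anchoring to the geometric centre")
    shift <- -colMeans(out[ca, , drop = FALSE])
  } else {
    if (mean(out[hi, 3]) < mean(out[lo, 3])) {   # flip extracellular side up
      R <- diag(c(1, -1, -1)) %*% R
      out <- xyz %*% t(R)
    }
    shift <- c(-colMeans(out[ca, 1:2, drop = FALSE]), -mean(out[lo, 3]))
  }
  out <- sweep(out, 2, -shift)
  list(frame = chan_frame(out, time = frame$time, box = frame$box),
       R = R, shift = shift)
}

#' Pore radius profile of a single (aligned) frame
#'
#' @param frame aligned `chan_frame`.
#' @param topology matching `chan_topology`.
#' @param z z grid; default `seq` over `z_range` at `z_step`.
#' @param z_range axial span; default the protein Calpha extent.
#' @param z_step grid step, Angstrom.
#' @param slab_half atoms within this distance of each z plane contribute.
#' @param max_off_axis radius of the disc searched for the sphere centre.
#' @param tol optimizer tolerance, Angstrom.
#' @return data.frame with columns `z` and `r`; `r` is `NA` (missing) where
#'   no atoms fall in the slab, and clamped at 0 from below.
#' @export
radius_profile <- function(frame, topology, z = NULL, z_range = NULL,
                           z_step = 0.5, slab_half = 6, max_off_axis = 5,
                           tol = 1e-3) {
  xyz <- if (inherits(frame, "chan_frame")) frame$xyz else as.matrix(frame)
  hv <- heavy_atoms(topology, "protein")
  pa <- xyz[hv, , drop = FALSE]
  vdw <- topology$vdw[hv]
  if (is.null(z)) {
    if (is.null(z_range)) {
      ca <- which(topology$species == "protein" & topology$elety == "CA")
      if (!length(ca)) ca <- hv
      z_range <- range(xyz[ca, 3])
    }
    z <- seq(z_range[1], z_range[2], by = z_step)
  }
  # deterministic coarse grid over the search disc; Nelder-Mead refinement
  # from the best few grid points (the objective is piecewise smooth, so
  # isolated starts can stall on ridges)
  gg <- as.matrix(expand.grid(seq(-max_off_axis, max_off_axis, by = 0.5),
                              seq(-max_off_axis, max_off_axis, by = 0.5)))
  gg <- gg[gg[, 1]^2 + gg[, 2]^2 <= max_off_axis^2, , drop = FALSE]
  r <- vapply(z, function(zi) {
    sel <- abs(pa[, 3] - zi) <= slab_half
    if (!any(sel)) return(NA_real_)
    A <- pa[sel, , drop = FALSE]; w <- vdw[sel]
    obj <- function(c2) {
      if (sum(c2^2) > max_off_axis^2) return(1e6)
      -min(sqrt((A[, 1] - c2[1])^2 + (A[, 2] - c2[2])^2 + (A[, 3] - zi)^2) - w)
    }
    coarse <- vapply(seq_len(nrow(gg)), function(i) obj(gg[i, ]), numeric(1))
    starts <- gg[order(coarse)[1:9], , drop = FALSE]
    best <- -min(coarse)
    for (s in seq_len(nrow(starts))) {
      o <- optim(starts[s, ], obj, method = "Nelder-Mead",
                 control = list(abstol = tol, reltol = 1e-8, maxit = 300))
      if (-o$value > best) best <- -o$value
    }
    max(best, 0)
  }, numeric(1))
  data.frame(z = z, r = r)
}

#' Pore radius heatmap r(z, t) over a trajectory
#'
#' Frames are aligned to the pore axis, profiled at the given stride, and the
#' per-frame mean z of the marker residues recorded for windowed-minimum
#' extraction.
#'
#' @param traj a `chan_trajectory`.
#' @param stride frame stride (1 profiles every frame, matching per-ns
#'   extraction at 1 ns spacing).
#' @param markers named integer vector of marker residue numbers.
#' @param window trailing fraction of profiled frames used for the summary.
#' @inheritParams radius_profile
#' @return object of class `chan_pore_profile`: list with `z`, `times`,
#'   `r` (length(z) x frames matrix), `marker_z` (frames x markers), and
#'   summary `mean`/`sd` matrices over the trailing window.
#' @export
profile_heatmap <- function(traj, stride = 1, z_range = NULL, z_step = 0.5,
                            markers = c(p9 = 233, p14 = 238, p16 = 240),
                            window = 0.5, ...) {
  idx <- seq(1, n_frames(traj), by = stride)
  top <- traj$topology
  zg <- NULL
  rmat <- NULL
  mz <- matrix(NA_real_, length(idx), length(markers),
               dimnames = list(NULL, names(markers)))
  for (i in seq_along(idx)) {
    al <- align_to_pore_axis(get_frame(traj, idx[i]), top)
    prof <- radius_profile(al$frame, top, z = zg, z_range = z_range,
                           z_step = z_step, ...)
    if (is.null(zg)) {
      zg <- prof$z
      rmat <- matrix(NA_real_, length(zg), length(idx))
    }
    rmat[, i] <- prof$r
    for (m in seq_along(markers)) {
      ca <- which(top$species == "protein" & top$elety == "CA" &
                    top$resno == markers[m])
      if (length(ca)) mz[i, m] <- mean(al$frame$xyz[ca, 3])
    }
  }
  wi <- seq.int(max(1L, length(idx) - ceiling(window * length(idx)) + 1L),
                length(idx))
  structure(list(z = zg, times = traj$times[idx], r = rmat, marker_z = mz,
                 window_mean = rowMeans(rmat[, wi, drop = FALSE]),
                 window_sd = apply(rmat[, wi, drop = FALSE], 1, sd)),
            class = "chan_pore_profile")
}

#' Windowed minimum pore radius at a marker residue
#'
#' Per frame, the minimum of r(z, t) over z within half a window of the
#' marker's mean z in that frame.
#'
#' @param profile a `chan_pore_profile` from [profile_heatmap()].
#' @param marker marker name (column of `profile$marker_z`, e.g. `"p9"`).
#' @param window full z-window width, Angstrom (default 5).
#' @return data.frame with columns `time` and `r_min` (`NA` where every value
#'   in the window is missing).
#' @export
min_radius_window <- function(profile, marker = "p9", window = 5) {
  if (!marker %in% colnames(profile$marker_z))
    stop("unknown marker: ", marker)
  rmin <- vapply(seq_along(profile$times), function(i) {
    z0 <- profile$marker_z[i, marker]
    sel <- abs(profile$z - z0) <= window / 2
    v <- profile$r[sel, i]
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  }, numeric(1))
  data.frame(time = profile$times, r_min = rmin)
}
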