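# Superposition, RMSD analyses and the M2 kink angle.

#' Domain definition by residue range
#'
#' @param name label, e.g. "TMD".
#' @param resno integer residue numbers in the domain (e.g. `196:315`).
#' @param chains chain ids in scope, or `NULL` for all protein chains.
#' @return object of class `chan_domain`.
#' @export
domain_definition <- function(name, resno, chains = NULL) {
  if (!length(resno)) stop("domain residue range must be non-empty")
  structure(list(name = name, resno = as.integer(resno), chains = chains),
            class = "chan_domain")
}

# row indices of the Calpha atoms of a domain, in topology order
domain_ca <- function(top, domain = NULL) {
  sel <- top$species == "protein" & top$elety == "CA"
  if (!is.null(domain)) {
    sel <- sel & top$resno %in% domain$resno
    if (!is.null(domain$chains)) sel <- sel & top$chain %in% domain$chains
  }
  idx <- which(sel)
  if (!length(idx)) stop("domain selects no Calpha atoms")
  idx
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimizing the RMSD between
#' selected atoms of a mobile and a reference frame, and applies it to all
#' mobile coordinates.
#'
#' @param mobile n x 3 matrix (or `chan_frame`) to move.
#' @param reference n x 3 matrix (or `chan_frame`) to fit onto.
#' @param sel indices of the atoms used for the fit (>= 3, mapped 1:1);
#'   default all.
#' @return list with `xyz` (all mobile coordinates, transformed), `R` (3x3
#'   rotation, det +1), `t` (translation), and `rmsd` (post-fit RMSD over
#'   `sel`, Angstrom).
#' @export
superpose <- function(mobile, reference, sel = NULL) {
  P <- if (inherits(mobile, "chan_frame")) mobile$xyz else as.matrix(mobile)
  Q <- if (inherits(reference, "chan_frame")) reference$xyz else as.matrix(reference)
  if (is.null(sel)) sel <- seq_len(nrow(P))
  if (length(sel) < 3) stop("degenerate selection: need at least 3 atoms")
  Ps <- P[sel, , drop = FALSE]; Qs <- Q[sel, , drop = FALSE]
  if (nrow(Ps) != nrow(Qs)) stop("selections must map 1:1 between frames")
  cp <- colMeans(Ps); cq <- colMeans(Qs)
  Pc <- sweep(Ps, 2, cp); Qc <- sweep(Qs, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  if (min(s$d) < 1e-10 && s$d[2] < 1e-10)
    stop("degenerate (collinear) selection")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_ <- cq - as.vector(R %*% cp)
  fit <- sweep(P %*% t(R), 2, t_, `+`)
  rmsd <- sqrt(mean(rowSums((fit[sel, , drop = FALSE] - Qs)^2)))
  list(xyz = fit, R = R, t = t_, rmsd = rmsd)
}

#' RMSD time series over a domain
#'
#' Each frame is least-squares fitted to the reference on the Calpha atoms of
#' `fit_domain`, then the Calpha RMSD is computed over `domain`.
#'
#' @param traj a `chan_trajectory`.
#' @param reference reference `chan_frame` (same topology).
#' @param domain `chan_domain` the RMSD is reported for (default: whole
#'   protein).
#' @param fit_domain `chan_domain` used for the superposition (default:
#'   `domain`).
#' @param window trailing fraction of frames for the summary statistics
#'   (default 0.1, i.e. last 10% of frames).
#' @return data.frame with columns `time` and `rmsd`; attributes
#'   `window_mean` and `window_sd`.
#' @export
rmsd_series <- function(traj, reference, domain = NULL, fit_domain = domain,
                        window = 0.1) {
  top <- traj$topology
  fit_idx <- domain_ca(top, fit_domain)
  dom_idx <- domain_ca(top, domain)
  ref <- if (inherits(reference, "chan_frame")) reference$xyz else as.matrix(reference)
  nf <- n_frames(traj)
  out <- vapply(seq_len(nf), function(i) {
    s <- superpose(traj$coords[, , i], ref, sel = fit_idx)
    sqrt(mean(rowSums((s$xyz[dom_idx, , drop = FALSE] -
                         ref[dom_idx, , drop = FALSE])^2)))
  }, numeric(1))
  res <- data.frame(time = traj$times, rmsd = out)
  wi <- seq.int(max(1L, nf - ceiling(window * nf) + 1L), nf)
  attr(res, "window_mean") <- mean(out[wi])
  attr(res, "window_sd") <- sd(out[wi])
  res
}

#' Per-residue mean Calpha RMSD
#'
#' After a global fit on `fit_domain`, the per-frame Calpha deviation of each
#' residue is averaged over frames and over the protein chains.
#'
#' @inheritParams rmsd_series
#' @return data.frame with columns `resno` and `rmsd` (Angstrom).
#' @export
rmsd_per_residue <- function(traj, reference, fit_domain = NULL) {
  top <- traj$topology
  fit_idx <- domain_ca(top, fit_domain)
  ca_idx <- domain_ca(top, NULL)
  ref <- if (inherits(reference, "chan_frame")) reference$xyz else as.matrix(reference)
  nf <- n_frames(traj)
  dev <- matrix(0, length(ca_idx), nf)
  for (i in seq_len(nf)) {
    s <- superpose(traj$coords[, , i], ref, sel = fit_idx)
    dev[, i] <- sqrt(rowSums((s$xyz[ca_idx, , drop = FALSE] -
                                ref[ca_idx, , drop = FALSE])^2))
  }
  per_atom <- rowMeans(dev)
  resno <- top$resno[ca_idx]
  agg <- tapply(per_atom, resno, mean)   # average over the 5 chains
  data.frame(resno = as.integer(names(agg)), rmsd = as.numeric(agg))
}

#' Kink segment definition
#'
#' Default segments follow the M2 convention: bottom 7'-14' (residues
#' 221-238), top 14'-21' (residues 238-245); the hinge residue belongs to
#' both.
#'
#' @param bottom residue numbers of the lower segment.
#' @param top residue numbers of the upper segment.
#' @return object of class `chan_kink_segments`.
#' @export
kink_segments <- function(bottom = 221:238, top = 238:245) {
  if (length(intersect(bottom, top)) != 1)
    stop("segments must share exactly the hinge residue")
  if (length(bottom) < 3 || length(top) < 3)
    stop("each segment needs at least 3 residues")
  structure(list(bottom = as.integer(bottom), top = as.integer(top)),
            class = "chan_kink_segments")
}

principal_axis <- function(xyz) {
  if (nrow(xyz) < 3) stop("degenerate segment: fewer than 3 atoms")
  e <- eigen(stats::cov(xyz), symmetric = TRUE)
  if (e$values[1] < 1e-12) stop("degenerate segment: zero extent")
  e$vectors[, 1]   # direction of maximal extent = first inertia axis (unit masses)
}

#' M2 helix kink angle
#'
#' Angle between the first principal axes of inertia (unit masses) of the
#' Calpha atoms of the bottom and top kink segments, folded into \[0, 90\]
#' degrees (principal axes are sign-ambiguous).
#'
#' @param frame a `chan_frame` or n x 3 matrix.
#' @param topology the matching `chan_topology`.
#' @param chain chain id; `NULL` returns the mean over all protein chains.
#' @param segments a [kink_segments()].
#' @return angle in degrees; with `chain = NULL` the per-chain mean, with
#'   attribute `per_chain`.
#' @export
kink_angle <- function(frame, topology, chain = NULL,
                       segments = kink_segments()) {
  xyz <- if (inherits(frame, "chan_frame")) frame$xyz else as.matrix(frame)
  chains <- if (is.null(chain)) protein_chains(topology) else chain
  ang <- vapply(chains, function(ch) {
    bi <- domain_ca(topology, domain_definition("bottom", segments$bottom, ch))
    ti <- domain_ca(topology, domain_definition("top", segments$top, ch))
    a <- principal_axis(xyz[bi, , drop = FALSE])
    b <- principal_axis(xyz[ti, , drop = FALSE])
    acos(pmin(1, abs(sum(a * b)))) * 180 / pi
  }, numeric(1))
  if (!is.null(chain) && length(chain) == 1) return(unname(ang))
  structure(mean(ang), per_chain = ang)
}

#' Kink angle over a trajectory
#'
#' @inheritParams kink_angle
#' @param traj a `chan_trajectory`.
#' @return list with `per_frame` (frames x chains matrix), `mean` and `sd`
#'   over frames and chains.
#' @export
kink_angle_series <- function(traj, chain = NULL, segments = kink_segments()) {
  chains <- if (is.null(chain)) protein_chains(traj$topology) else chain
  m <- t(vapply(seq_len(n_frames(traj)), function(i) {
    vapply(chains, function(ch)
      kink_angle(traj$coords[, , i], traj$topology, ch, segments), numeric(1))
  }, numeric(length(chains))))
  if (length(chains) == 1) m <- matrix(m, ncol = 1)
  colnames(m) <- chains
  list(per_frame = m, mean = mean(m), sd = sd(as.vector(m)))
}
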