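# void detection, consensus, classification, symmetrization, volumes, polarity

test_that("void classification matches a brute-force rule evaluation", {
  bp <- build_pentamer(small_spec())
  al <- align_to_pore_axis(bp$frame, bp$topology)
  top <- bp$topology
  # small sub-grid straddling one intra cavity
  s <- chancav:::cavity_sites(small_spec())[1, ]
  grid <- chan_grid(array(0, c(9, 9, 11)),
                    origin = round(c(s$cx, s$cy, s$cz)) - c(4, 4, 5))
  vg <- detect_voids(al$frame, top, grid = grid)
  # independent R re-evaluation of clash + burial + lumen at every point
  centers <- chancav:::grid_centers(grid)
  pa <- al$frame$xyz[chancav:::heavy_atoms(top, "protein"), ]
  vdw <- top$vdw[chancav:::heavy_atoms(top, "protein")]
  rays <- chancav:::burial_rays()
  pore <- radius_profile(al$frame, top, z_range = range(centers[, 3]),
                         z_step = 1)
  oracle <- vapply(seq_len(nrow(centers)), function(i) {
    p <- centers[i, ]
    d <- sqrt(colSums((t(pa) - p)^2))
    if (any(d < vdw + 1.4)) return(FALSE)
    hits <- 0
    for (r in seq_len(nrow(rays))) {
      u <- rays[r, ]
      rel <- sweep(pa, 2, p)
      proj <- rel %*% u
      perp2 <- rowSums(rel^2) - proj^2
      entry <- proj - sqrt(pmax(vdw^2 - perp2, 0))
      if (any(proj > 0 & perp2 <= vdw^2 & entry <= 8)) hits <- hits + 1
    }
    if (hits < 9) return(FALSE)
    rz <- approx(pore$z, pore$r, xout = p[3], rule = 2)$y
    sqrt(p[1]^2 + p[2]^2) > rz + 1.4
  }, logical(1))
  expect_identical(as.vector(vg$values), oracle)
  expect_gt(sum(oracle), 0)
})

test_that("exposed points are not void; enclosed box interiors are", {
  # a free point far from a slim atom column is exposed (burial fails)
  xyz <- cbind(0, 0, seq(-10, 10, 1))
  top <- cloud_topology(nrow(xyz))
  g <- chan_grid(array(0, c(1, 1, 1)), origin = c(20, 0, 0))
  vg <- detect_voids(chan_frame(xyz), top, grid = g,
                     pore = data.frame(z = 0, r = 0))
  expect_false(any(vg$values))

  # enclosed 5 x 5 x 7 box: centre voxel is void
  cg <- chancav:::cage_atoms(c(0, 0, 0), c(5, 5, 7), 0.9)
  topc <- cloud_topology(nrow(cg))
  g2 <- chan_grid(array(0, c(1, 1, 1)), origin = c(0, 0, 0))
  vg2 <- detect_voids(chan_frame(cg), topc, grid = g2,
                      pore = data.frame(z = 0, r = NA_real_))
  expect_true(all(vg2$values))
})

test_that("consensus frequencies equal per-frame boolean means exactly", {
  spec <- small_spec(protein_jitter = 0.3)   # breathing scaffold
  sim <- simulate_trajectory(spec, nf = 8, dt = 1, seed = 5)
  cons <- consensus_cavities(sim$trajectory, stride = 2)
  idx <- seq(1, 8, by = 2)
  acc <- NULL
  for (i in idx) {
    al <- align_to_pore_axis(get_frame(sim$trajectory, i),
                             sim$trajectory$topology)
    vg <- detect_voids(al$frame, sim$trajectory$topology,
                       grid = cons$grid)
    acc <- if (is.null(acc)) vg$values else acc + vg$values
  }
  expect_equal(cons$grid$values, acc / length(idx), tolerance = 1e-12)
  expect_error(consensus_cavities(sim$trajectory, stride = 100),
               "sampling error")
})

test_that("the ten declared cavities are recovered and classified", {
  sim <- fixture_sim()
  cons <- consensus_cavities(sim$trajectory, stride = 20)
  al <- align_to_pore_axis(get_frame(sim$trajectory, 1),
                           sim$trajectory$topology)
  cls <- classify_cavities(cons$cavities, al$frame, sim$trajectory$topology)
  classes <- vapply(cls, function(x) x$class, "")
  expect_equal(sum(classes == "intra"), 5)
  expect_equal(sum(classes == "inter"), 5)
  sites_intra <- sort(vapply(cls[classes == "intra"], function(x) x$site, 0L))
  expect_equal(sites_intra, 1:5)
  # consensus voxel sets cover the declared boxes; burial-marginal boundary
  # voxels under scaffold jitter may add a thin rind
  sizes <- vapply(cls, function(x) nrow(x$centers), 0L)
  expect_true(all(sizes[classes == "intra"] >= 175 &
                    sizes[classes == "intra"] <= 190))
  expect_true(all(sizes[classes == "inter"] >= 125 &
                    sizes[classes == "inter"] <= 140))
})

test_that("symmetrization rotates the template onto all five sites", {
  vox <- unname(as.matrix(expand.grid(14:18, -2:2, 0:4)))
  cav <- chan_cavity(vox, 1, id = "intra1", class = "intra", site = 1)
  sym <- symmetrize_cavities(list(cav), "intra")
  expect_length(sym, 5)
  expect_equal(vapply(sym, function(x) x$rotation, 0), 72 * (0:4))
  # 360 degrees is the identity
  full <- sym[[1]]; full$rotation <- 360
  expect_equal(chancav:::cavity_centers_lab(full), vox, tolerance = 1e-9)
  # rotating site k's lab centres back by -72k reproduces the template
  for (k in 2:5) {
    back <- chancav:::rotate_z(chancav:::cavity_centers_lab(sym[[k]]),
                               -(k - 1) * 72)
    expect_equal(back, vox, tolerance = 1e-9)
  }
  expect_warning(symmetrize_cavities(list(cav), "inter"), "no cavities")
})

test_that("MC volume is calibrated on boxes and spheres", {
  # full box, no atoms
  vox <- as.matrix(expand.grid(0:9, 0:9, 0:9))  # 10x10x10 A box
  cav <- chan_cavity(vox, 1)
  v <- mc_volume(cav, n = 10000, seed = 1)
  expect_lt(abs(v - 1000), 3 * attr(v, "se"))
  # empty region
  expect_equal(as.numeric(mc_volume(chan_cavity(matrix(0, 0, 3), 1))), 0)
  expect_error(mc_volume(cav, n = 50), "precision")

  # sphere-carved region vs fine-grid quadrature
  ctr <- c(4.5, 4.5, 4.5)
  atom <- matrix(ctr, 1)
  topa <- cloud_topology(1, vdw = 2.0)          # blocks a 3.4 A sphere
  vs <- mc_volume(cav, chan_frame(atom), topa, n = 40000, seed = 2)
  gq <- as.matrix(expand.grid(seq(-0.4, 9.4, 0.2), seq(-0.4, 9.4, 0.2),
                              seq(-0.4, 9.4, 0.2)))
  inside <- gq[, 1] >= -0.5 & gq[, 1] <= 9.5 &
    sqrt(colSums((t(gq) - ctr)^2)) >= 3.4
  oracle <- sum(inside) * 0.2^3
  expect_lt(abs(vs - oracle), 3 * attr(vs, "se") + 5)
})

test_that("MC volume is unbiased and its SE scales as n^(-1/2)", {
  vox <- as.matrix(expand.grid(0:6, 0:6, 0:6))   # 7x7x7 box, 343 A^3
  cav <- chan_cavity(vox, 1)
  vals <- vapply(1:50, function(s) as.numeric(mc_volume(cav, n = 10000,
                                                        seed = s)),
                 numeric(1))
  se_pooled <- attr(mc_volume(cav, n = 10000, seed = 1), "se") / sqrt(50)
  expect_lt(abs(mean(vals) - 343), 2 * se_pooled)
  se4 <- attr(mc_volume(cav, n = 1e4, seed = 3), "se")
  se6 <- attr(mc_volume(cav, n = 1e6, seed = 3), "se")
  expect_lt(abs(se4 / se6 - 10), 2)   # within 20% of the n^(-1/2) factor
})

test_that("declared volumes are recovered and enlargement is monotone", {
  sim <- fixture_sim()
  tr <- sim$trajectory
  cons <- consensus_cavities(tr, stride = 20)
  al <- align_to_pore_axis(get_frame(tr, 1), tr$topology)
  cls <- classify_cavities(cons$cavities, al$frame, tr$topology)
  for (class_ in c("intra", "inter")) {
    truthv <- sim$truth$cavities$volume[sim$truth$cavities$class == class_][1]
    sym <- symmetrize_cavities(cls, class_)
    for (rg in sym) {
      v <- mc_volume(rg, al$frame, tr$topology, n = 10000, seed = 11,
                     dilate = 1)
      expect_lt(abs(v - truthv), max(0.05 * truthv, 2))
    }
  }
  # enlarging the region never decreases the estimate beyond MC noise
  small <- cls[[which(vapply(cls, function(x)
    identical(x$class, "intra"), logical(1)))[1]]]
  shrunk <- small; shrunk$centers <- small$centers[
    small$centers[, 3] < mean(small$centers[, 3]), , drop = FALSE]
  v_small <- mc_volume(shrunk, al$frame, tr$topology, n = 20000, seed = 4)
  v_big <- mc_volume(small, al$frame, tr$topology, n = 20000, seed = 4)
  expect_gt(v_big, v_small - 3 * attr(v_big, "se"))
})

test_that("cavity-lining polarity spans carbon-only to oxygen-only linings", {
  mk <- function(elem) {
    cg <- chancav:::cage_atoms(c(0, 0, 0), c(5, 5, 5), 0.9)
    top <- cloud_topology(nrow(cg), elem = elem,
                          vdw = if (elem == "O") 1.52 else 1.7)
    cav <- chan_cavity(as.matrix(expand.grid(-2:2, -2:2, -2:2)), 1)
    polar_surface_fraction(cav, chan_frame(cg), top)
  }
  expect_equal(as.numeric(mk("C")), 0)
  expect_equal(as.numeric(mk("O")), 1)

  # mixed lining: fraction matches dense Shrake-Rupley-style counting
  cg <- chancav:::cage_atoms(c(0, 0, 0), c(5, 5, 5), 0.9)
  set.seed(9)
  elems <- sample(c("C", "O"), nrow(cg), replace = TRUE, prob = c(0.7, 0.3))
  # equal pseudo-atom radii so neither element shadows the other
  top <- chan_topology(data.frame(
    eleno = seq_len(nrow(cg)), elety = "X", resid = "PWL", chain = "A",
    resno = 1, elem = elems, vdw = 1.7, species = "protein", mol = 1))
  cav <- chan_cavity(as.matrix(expand.grid(-2:2, -2:2, -2:2)), 1)
  f1 <- polar_surface_fraction(cav, chan_frame(cg), top, n_points = 600)
  f2 <- polar_surface_fraction(cav, chan_frame(cg), top, n_points = 5000)
  expect_equal(as.numeric(f1), as.numeric(f2), tolerance = 0.03)
  expect_gt(as.numeric(f1), 0.05); expect_lt(as.numeric(f1), 0.95)
})
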