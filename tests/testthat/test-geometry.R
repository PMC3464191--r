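test_that("superposition is exact for identical and rigidly moved frames", {
  set.seed(1)
  P <- matrix(rnorm(60), 20)
  s0 <- superpose(P, P)
  expect_equal(s0$rmsd, 0, tolerance = 1e-12)
  expect_equal(s0$R, diag(3), tolerance = 1e-9)

  R <- chancav:::rotation_matrix(c(1, -2, 0.5), 37)
  Q <- sweep(P %*% t(R), 2, c(5, -3, 2), `+`)
  s <- superpose(Q, P)
  expect_lt(s$rmsd, 1e-6)
  expect_equal(det(s$R), 1, tolerance = 1e-9)
})

test_that("superposition rejects degenerate selections", {
  P <- matrix(rnorm(60), 20)
  expect_error(superpose(P, P, sel = 1:2), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 0.1), "collinear")
})

test_that("RMSD after fit matches brute-force minimization over rotations", {
  set.seed(7)
  P <- matrix(rnorm(36), 12)
  Q <- P
  Q[1, ] <- Q[1, ] + c(1, 0, 0)     # one atom displaced 1 A
  s <- superpose(Q, P)
  # refit can only reduce the naive sqrt(1/N) upper bound
  expect_lte(s$rmsd, sqrt(1 / 12) + 1e-9)
  # independent oracle: numeric optimization over Euler angles + translation
  obj <- function(p) {
    Rz <- chancav:::rotation_matrix(c(0, 0, 1), p[1])
    Ry <- chancav:::rotation_matrix(c(0, 1, 0), p[2])
    Rx <- chancav:::rotation_matrix(c(1, 0, 0), p[3])
    M <- sweep(Q %*% t(Rz %*% Ry %*% Rx), 2, p[4:6], `+`)
    sqrt(mean(rowSums((M - P)^2)))
  }
  o <- optim(rep(0, 6), obj, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 2000))
  expect_equal(s$rmsd, o$value, tolerance = 1e-5)
  # cross-check against the independent bio3d implementation
  fit <- suppressWarnings(bio3d::fit.xyz(as.vector(t(P)), as.vector(t(Q))))
  expect_equal(s$rmsd, bio3d::rmsd(as.vector(t(P)), fit), tolerance = 2e-3)
})

test_that("rmsd_series handles static, shifted and random trajectories", {
  sim <- fixture_sim()
  top <- sim$trajectory$topology
  ref <- get_frame(sim$trajectory, 1)
  # static trajectory -> all zero
  coords <- array(rep(ref$xyz, 4), c(nrow(ref$xyz), 3, 4))
  static <- chan_trajectory(top, coords, dt = 1)
  expect_equal(rmsd_series(static, ref)$rmsd, rep(0, 4), tolerance = 1e-9)

  # uniform 2 A shift of a domain after fitting on a disjoint domain
  dom <- domain_definition("top", 240:245)
  fitdom <- domain_definition("bottom", 221:232)
  ca_dom <- chancav:::domain_ca(top, dom)
  coords2 <- coords
  for (f in 1:4) coords2[ca_dom, 1, f] <- coords2[ca_dom, 1, f] + 2
  shifted <- chan_trajectory(top, coords2, dt = 1)
  rs <- rmsd_series(shifted, ref, domain = dom, fit_domain = fitdom)
  expect_equal(rs$rmsd, rep(2, 4), tolerance = 1e-6)

  # random trajectory equals an independent per-frame recomputation
  rs2 <- rmsd_series(sim$trajectory, ref)
  ca <- chancav:::domain_ca(top, NULL)
  oracle <- vapply(seq_len(n_frames(sim$trajectory)), function(f) {
    s <- superpose(sim$trajectory$coords[, , f], ref$xyz, sel = ca)
    s$rmsd
  }, numeric(1))
  expect_equal(rs2$rmsd, oracle, tolerance = 1e-12)
})

test_that("per-residue RMSD localizes a displaced residue", {
  sim <- fixture_sim()
  top <- sim$trajectory$topology
  ref <- get_frame(sim$trajectory, 1)
  coords <- array(rep(ref$xyz, 3), c(nrow(ref$xyz), 3, 3))
  static <- chan_trajectory(top, coords, dt = 1)
  pr <- rmsd_per_residue(static, ref)
  expect_equal(pr$rmsd, rep(0, nrow(pr)), tolerance = 1e-9)

  # displace residue 240 on one chain only in later frames
  idx <- which(top$elety == "CA" & top$resno == 240 & top$chain == "A")
  coords[idx, 2, 2:3] <- coords[idx, 2, 2:3] + 3
  moved <- chan_trajectory(top, coords, dt = 1)
  fitdom <- domain_definition("fit", 221:232)
  pr2 <- rmsd_per_residue(moved, ref, fit_domain = fitdom)
  expect_gt(pr2$rmsd[pr2$resno == 240], 0.3)
  expect_lt(max(pr2$rmsd[pr2$resno %in% 221:230]), 0.05)
})

test_that("kink angle is exact on rods and invariant to rigid motion", {
  # collinear rods -> 0
  rod <- function(n, start, dir)
    sweep(outer(seq_len(n) - 1, dir), 2, start, `+`)
  top2 <- chan_topology(data.frame(
    eleno = 1:25, elety = "CA", resid = "ALA", chain = "A", resno = 221:245,
    elem = "C", vdw = 1.7, species = "protein", mol = 1))
  hinge <- c(0, 0, 25.5)   # residue 238
  straight <- rbind(rod(18, c(0, 0, 0), c(0, 0, 1.5)),
                    rod(7, hinge + c(0, 0, 1.5), c(0, 0, 1.5)))
  expect_equal(kink_angle(straight, top2, chain = "A"), 0, tolerance = 1e-6)

  # rods meeting at the hinge at a constructed 30 degree angle
  d30 <- c(sin(30 * pi / 180), 0, cos(30 * pi / 180)) * 1.5
  bent <- rbind(rod(18, c(0, 0, 0), c(0, 0, 1.5)), rod(7, hinge + d30, d30))
  expect_equal(kink_angle(bent, top2, chain = "A"), 30, tolerance = 0.1)

  # invariance under global rotation and reflection; range [0, 90]
  R <- chancav:::rotation_matrix(c(2, 1, 1), 111)
  rotated <- bent %*% t(R)
  expect_equal(kink_angle(rotated, top2, chain = "A"), 30, tolerance = 1e-6)
  reflected <- bent %*% diag(c(-1, 1, 1))
  expect_equal(kink_angle(reflected, top2, chain = "A"), 30, tolerance = 1e-6)
  d170 <- c(sin(170 * pi / 180), 0, cos(170 * pi / 180)) * 1.5
  folded <- rbind(rod(18, c(0, 0, 0), c(0, 0, 1.5)),
                  rod(7, hinge + d170, d170))
  a <- kink_angle(folded, top2, chain = "A")
  expect_gte(a, 0); expect_lte(a, 90)
})

test_that("helix bending changes the inertia-axis angle by the bend", {
  # the inertia axis of a partial-turn helix segment is intrinsically tilted,
  # so the bent helix is compared against the straight baseline
  resnos <- 221:245
  top <- chan_topology(data.frame(
    eleno = seq_along(resnos), elety = "CA", resid = "ALA", chain = "A",
    resno = resnos, elem = "C", vdw = 1.7, species = "protein", mol = 1))
  a0 <- kink_angle(build_kinked_helix(resnos, kink_deg = 0), top, "A")
  a20 <- kink_angle(build_kinked_helix(resnos, kink_deg = 20), top, "A")
  expect_equal(a20 - a0, 20, tolerance = 1.5)
  # thin rods recover the bend itself
  a20r <- kink_angle(build_kinked_helix(resnos, kink_deg = 20, radius = 0.01),
                     top, "A")
  expect_equal(a20r, 20, tolerance = 0.1)
})

test_that("kink segment validation enforces the shared hinge", {
  expect_error(kink_segments(221:237, 239:245), "hinge")
  expect_error(kink_segments(237:238, 238:245), "at least 3")
})
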