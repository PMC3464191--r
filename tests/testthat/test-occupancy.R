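test_that("molecule membership follows the centre-distance rule", {
  cav <- chan_cavity(as.matrix(expand.grid(0:4, 0:4, 0:4)), 1)
  top <- chan_topology(data.frame(
    eleno = 1:3, elety = c("C1", "C2", "O1"), resid = "ETH", chain = "L",
    resno = 1, elem = c("C", "C", "O"), vdw = c(1.7, 1.7, 1.52),
    species = "ligand", mol = 1))
  body <- rbind(c(0.7, 0, 0), c(-0.35, 0.6, 0), c(-0.35, -0.6, 0))
  at_ctr <- function(ctr) chan_frame(sweep(body, 2, ctr, `+`))
  expect_true(molecule_in_cavity(1:3, cav, at_ctr(c(2, 2, 2)), top))
  expect_false(molecule_in_cavity(1:3, cav, at_ctr(c(14, 2, 2)), top))

  # boundary sweep equals brute-force distance evaluation
  for (x in seq(3.0, 6.5, 0.25)) {
    got <- molecule_in_cavity(1:3, cav, at_ctr(c(x, 2, 2)), top)
    dmin <- min(sqrt(colSums((t(cav$centers) - c(x, 2, 2))^2)))
    expect_identical(got, dmin <= 1.0)
  }

  toph <- top; toph$elem <- "H"
  expect_error(molecule_in_cavity(1:3, cav, at_ctr(c(0, 0, 0)), toph),
               "no heavy atoms")
})

test_that("occupancy series reproduce the generator ground truth exactly", {
  sim <- fixture_sim()
  regions <- truth_regions(sim$truth$cavities)
  occ <- occupancy_series(sim$trajectory, regions)
  sites <- sim$truth$cavities
  lig_true <- vapply(seq_len(nrow(sites)), function(j)
    colSums(sim$truth$assign == j & sim$truth$traces == 1L, na.rm = TRUE),
    numeric(n_frames(sim$trajectory)))
  expect_equal(unname(occ$counts$ligand), unname(lig_true),
               ignore_attr = TRUE)
  expect_equal(unname(occ$counts$water), unname(sim$truth$water_counts),
               ignore_attr = TRUE)
  expect_equal(unname(occ$counts$lipid), unname(sim$truth$lipid_atoms),
               ignore_attr = TRUE)
})

test_that("empty cavities give all-zero series with a warning", {
  sim <- fixture_sim()
  empty <- chan_cavity(matrix(numeric(0), 0, 3), 1, id = "void")
  expect_warning(occ <- occupancy_series(sim$trajectory, list(empty)),
                 "empty region")
  expect_true(all(occ$counts$ligand == 0))
})

test_that("summary windows cover the trailing half inclusively", {
  times <- 0:9
  expect_identical(chancav:::window_frames(times, 0.5), 6:10)
  expect_identical(chancav:::window_frames(times, 0.2), 9:10)
})

test_that("density maps place atoms in voxels and conserve mass", {
  top <- chan_topology(data.frame(
    eleno = 1, elety = "OW", resid = "HOH", chain = "S", resno = 1,
    elem = "O", vdw = 1.52, species = "water", mol = 1))
  # stationary atom: a single voxel with value 1
  coords <- array(rep(c(3.2, -1.1, 7.9), each = 1), c(1, 3, 4))
  for (f in 1:4) coords[1, , f] <- c(3.2, -1.1, 7.9)
  tr <- chan_trajectory(top, coords, dt = 1)
  dm <- density_map(tr, "water", window = 1)
  expect_equal(sum(dm$values), 1)
  expect_equal(max(dm$values), 1)

  # atom alternating between two voxels over an even window: 0.5 each
  for (f in 1:4) coords[1, , f] <- if (f %% 2) c(0, 0, 0) else c(4, 0, 0)
  tr2 <- chan_trajectory(top, coords, dt = 1)
  dm2 <- density_map(tr2, "water", window = 1)
  expect_equal(sort(dm2$values[dm2$values > 0]), c(0.5, 0.5))

  expect_error(density_map(tr, "ligand"), "selection error")
})

test_that("density-map mass equals the mean species atom count (exact)", {
  sim <- fixture_sim()
  for (sp in c("ligand", "water", "lipid")) {
    dm <- density_map(sim$trajectory, sp, window = 0.5)
    n_atoms <- length(chancav:::heavy_atoms(sim$trajectory$topology, sp))
    expect_equal(sum(dm$values), n_atoms, tolerance = 1e-9)
  }
})

test_that("generator ligand density concentrates in the cavity band", {
  sim <- fixture_sim()
  dm <- density_map(sim$trajectory, "ligand", window = 1)
  centers <- chancav:::grid_centers(dm)
  rad <- sqrt(centers[, 1]^2 + centers[, 2]^2)
  w <- as.vector(dm$values)
  # truth histogram: fraction of ligand-atom mass within the cavity radius
  # band (everything bound); bulk sits in the distant solvent shell
  frac_band <- sum(w[rad < 28]) / sum(w)
  truth_frac <- mean(sim$truth$traces)
  expect_equal(frac_band, truth_frac, tolerance = 1e-9)
})

test_that("occupancy counts are invariant under consistent rigid motion", {
  sim <- fixture_sim()
  regions <- truth_regions(sim$truth$cavities)
  f <- get_frame(sim$trajectory, 2)
  a1 <- chancav:::assign_to_cavities(f$xyz, sim$trajectory$topology,
                                     regions, "ligand")
  # rotate frame and regions about z by 72 degrees together
  moved <- chancav:::rotate_z(f$xyz, 72)
  regions_rot <- lapply(regions, function(r) { r$rotation <- 72; r })
  a2 <- chancav:::assign_to_cavities(moved, sim$trajectory$topology,
                                     regions_rot, "ligand")
  expect_identical(a1$assign, a2$assign)
})
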