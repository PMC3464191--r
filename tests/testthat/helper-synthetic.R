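# shared fixtures, built once per test run

# small channel spec for fast end-to-end tests
small_spec <- function(...) {
  channel_spec(ligand = list(count = 12, tau_b = 20, tau_u = 120),
               water = list(bulk = 60, baseline = 3), ...)
}

# cavity regions built directly from the generator's ground-truth site table
# (lattice points strictly inside each declared box)
truth_regions <- function(sites) {
  lapply(seq_len(nrow(sites)), function(j) {
    s <- sites[j, ]
    gx <- expand.grid(seq(ceiling(s$cx - s$sx / 2 + 0.01), floor(s$cx + s$sx / 2 - 0.01)),
                      seq(ceiling(s$cy - s$sy / 2 + 0.01), floor(s$cy + s$sy / 2 - 0.01)),
                      seq(ceiling(s$cz - s$sz / 2 + 0.01), floor(s$cz + s$sz / 2 - 0.01)))
    chan_cavity(as.matrix(gx), 1, id = s$id, class = s$class, site = s$site)
  })
}

# memoized medium simulation shared by occupancy/kinetics/synthetic tests
.fixture_env <- new.env()
fixture_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_trajectory(small_spec(), nf = 40, dt = 1,
                                            seed = 7)
  .fixture_env$sim
}

# minimal cylindrical "channel": stacked dense rings of radius wall_r
ring_stack <- function(wall_r = 5, zs = seq(-6, 6, 1), spacing = 0.25,
                       shift = NULL) {
  out <- list()
  for (z in zs) {
    n <- ceiling(2 * pi * wall_r / spacing)
    th <- 2 * pi * seq_len(n) / n
    ring <- cbind(wall_r * cos(th), wall_r * sin(th), z)
    if (!is.null(shift) && z == shift$z) ring[, 1] <- ring[, 1] + shift$dx
    out[[length(out) + 1]] <- ring
  }
  xyz <- do.call(rbind, out)
  top <- chan_topology(data.frame(
    eleno = seq_len(nrow(xyz)), elety = "CA", resid = "ALA",
    chain = rep(LETTERS[1:5], length.out = nrow(xyz)), resno = 1,
    elem = "C", vdw = 1.7, species = "protein", mol = 1))
  list(top = top, fr = chan_frame(xyz))
}

# topology for a bare point cloud of carbon pseudo-atoms
cloud_topology <- function(n, elem = "C", vdw = 1.7) {
  chan_topology(data.frame(
    eleno = seq_len(n), elety = "X", resid = "PWL", chain = "A", resno = 1,
    elem = elem, vdw = vdw, species = "protein", mol = 1))
}

# memoized end-to-end pipeline run (shared by pipeline + acceptance tests)
pipeline_config <- function(out_dir = NULL) {
  list(input = list(n_frames = 50, dt = 1, seed = 5,
                    spec = list(kink = rep(10, 5),
                                ligand = list(count = 12, tau_b = 20,
                                              tau_u = 120),
                                water = list(bulk = 60, baseline = 3))),
       cavities = list(stride = 10, volume_stride = 10),
       pore = list(stride = 10),
       kinetics = list(n_boot = 50),
       out_dir = out_dir)
}
fixture_report <- function() {
  if (is.null(.fixture_env$report)) {
    .fixture_env$out_dir <- tempfile("chancav_report_")
    .fixture_env$report <- suppressWarnings(
      run_pipeline(pipeline_config(.fixture_env$out_dir)))
  }
  .fixture_env$report
}

# comparable numeric core of a pipeline report (drops fitted-model objects)
report_digest <- function(rep) {
  list(rmsd = rep$rmsd$series$rmsd,
       kink = rep$kink$per_chain_mean,
       pore = rep$pore$heatmap$r,
       vol_i = rep$cavities$volume_mean$intra,
       vol_e = rep$cavities$volume_mean$inter,
       occ = rep$occupancy$counts,
       bf = rep$kinetics$bound_fraction,
       tau = lapply(rep$kinetics$fits, function(f)
         if (inherits(f, "chan_exchange_fit")) c(f$tau_s, f$tau_f, f$A_f)
         else f),
       lm = lapply(rep$stats$fits, function(f)
         if (inherits(f, "chan_linear_fit")) unclass(f) else f))
}
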