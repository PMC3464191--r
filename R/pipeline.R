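# End-to-end analysis pipeline: align -> rmsd/kink -> pore -> cavities ->
# occupancy -> kinetics -> stats.

#' Default pipeline configuration
#'
#' Every constant of the reference protocol is a named default: 5-frame
#' cavity stride (5 ns at 1 ns spacing), 20% consensus frequency threshold,
#' 10,000 Monte-Carlo volume iterations, 1 Angstrom density/void lattice,
#' 5 Angstrom constriction z-window, trailing-half averaging window.
#'
#' @return nested list; see the package vignette for the schema.
#' @export
default_config <- function() {
  list(
    input = list(type = "synthetic", n_frames = 100, dt = 1, seed = 1,
                 spec = list()),
    rmsd = list(window = 0.1),
    kink = list(bottom = c(221, 238), top = c(238, 245)),
    pore = list(stride = 5, z_step = 0.5, marker = "p9", window = 5),
    cavities = list(stride = 5, freq_threshold = 0.20, min_voxels = 8,
                    probe = 1.4, mc_n = 10000, mc_seed = 1, dilate = 1,
                    volume_stride = 5),
    occupancy = list(window = 0.5, dist = 1.0),
    kinetics = list(classes = c("intra", "inter"), n_boot = 100, seed = 1),
    stats = list(bin_width = 10),
    out_dir = NULL)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

# superpose every frame onto the aligned first frame (protein Calpha)
align_trajectory <- function(traj) {
  top <- traj$topology
  al1 <- align_to_pore_axis(get_frame(traj, 1), top)
  ca <- which(top$species == "protein" & top$elety == "CA")
  if (length(ca) < 3) ca <- heavy_atoms(top, "protein")
  coords <- traj$coords
  coords[, , 1] <- al1$frame$xyz
  for (f in seq_len(n_frames(traj))[-1]) {
    s <- superpose(traj$coords[, , f], al1$frame$xyz, sel = ca)
    coords[, , f] <- s$xyz
  }
  chan_trajectory(top, coords, times = traj$times, dt = traj$dt)
}

#' Run the full analysis pipeline
#'
#' Executes input -> align -> rmsd/kink -> pore -> cavities -> occupancy ->
#' kinetics -> stats with every seed, window, stride and threshold taken
#' from the configuration; any stage failure halts with the stage name and
#' cause (outputs already written to `out_dir` are retained).
#'
#' @param config nested configuration list (merged over
#'   [default_config()]), or the path to a YAML file of the same shape.
#' @return a `chan_report` list: configuration echo, per-stage results, and
#'   (for synthetic input) the generator ground truth.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  report <- list(config = cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  traj <- stage("input", {
    inp <- cfg$input
    if (identical(inp$type, "synthetic")) {
      spec <- do.call(channel_spec, inp$spec)
      sim <- simulate_trajectory(spec, nf = inp$n_frames, dt = inp$dt,
                                 seed = inp$seed)
      truth <- sim$truth
      sim$trajectory
    } else {
      st <- read_structure(inp$structure)
      read_trajectory(inp$trajectory, st$topology, dt = inp$dt %||% 1)
    }
  })
  report$truth <- truth

  atraj <- stage("align", align_trajectory(traj))
  ref <- get_frame(atraj, 1)
  top <- atraj$topology

  report$rmsd <- stage("rmsd", {
    rs <- rmsd_series(atraj, ref, window = cfg$rmsd$window)
    list(series = rs, window_mean = attr(rs, "window_mean"),
         window_sd = attr(rs, "window_sd"))
  })

  report$kink <- stage("kink", {
    seg <- kink_segments(cfg$kink$bottom[1]:cfg$kink$bottom[2],
                         cfg$kink$top[1]:cfg$kink$top[2])
    ks <- kink_angle_series(atraj, segments = seg)
    list(per_chain_mean = colMeans(ks$per_frame), mean = ks$mean,
         sd = ks$sd)
  })

  report$pore <- stage("pore", {
    hm <- profile_heatmap(atraj, stride = cfg$pore$stride,
                          z_step = cfg$pore$z_step)
    mrw <- min_radius_window(hm, marker = cfg$pore$marker,
                             window = cfg$pore$window)
    list(heatmap = hm, min_series = mrw,
         min_mean = mean(mrw$r_min, na.rm = TRUE))
  })

  report$cavities <- stage("cavities", {
    cc <- cfg$cavities
    cons <- consensus_cavities(atraj, stride = cc$stride,
                               freq_threshold = cc$freq_threshold,
                               min_voxels = cc$min_voxels, probe = cc$probe)
    cls <- classify_cavities(cons$cavities, ref, top)
    sym <- list(intra = symmetrize_cavities(cls, "intra"),
                inter = symmetrize_cavities(cls, "inter"))
    # per-frame volumes inside the fixed symmetrized regions, averaged over
    # the trailing half of the trajectory
    wi <- window_frames(atraj$times, 0.5)
    vi <- wi[seq(1, length(wi), by = cc$volume_stride)]
    vols <- lapply(sym, function(regions) {
      if (!length(regions)) return(NULL)
      per_frame <- vapply(regions, function(rg) {
        vapply(seq_along(vi), function(i)
          as.numeric(mc_volume(rg, get_frame(atraj, vi[i]), top,
                               n = cc$mc_n, seed = cc$mc_seed + vi[i],
                               probe = cc$probe, dilate = cc$dilate)),
          numeric(1))
      }, numeric(length(vi)))
      if (is.null(dim(per_frame))) per_frame <- matrix(per_frame, nrow = 1)
      per_frame   # frames x sites
    })
    list(consensus = cons, classified = cls, regions = sym,
         volume_frames = vi, volumes = vols,
         volume_mean = lapply(vols, function(v) if (!is.null(v)) colMeans(v)),
         volume_sd = lapply(vols, function(v) if (!is.null(v)) apply(v, 2, sd)))
  })

  regions <- c(report$cavities$regions$intra, report$cavities$regions$inter)
  report$occupancy <- stage("occupancy", {
    if (!length(regions)) stop("no cavity regions detected")
    occupancy_series(atraj, regions, dist = cfg$occupancy$dist,
                     window = cfg$occupancy$window)
  })

  report$kinetics <- stage("kinetics", {
    assign_ <- cavity_assignments(atraj, regions,
                                  dist = cfg$occupancy$dist)
    fits <- list()
    for (cl in cfg$kinetics$classes) {
      tr <- binary_traces(assign_, regions, class = cl, dt = atraj$dt)
      fits[[cl]] <- tryCatch({
        ac <- occupancy_autocorrelation(tr)
        fit_double_exponential(ac, n_boot = cfg$kinetics$n_boot,
                               seed = cfg$kinetics$seed)
      }, error = function(e) paste("not fitted:", conditionMessage(e)))
    }
    n_lig <- length(unique(top$mol[top$species == "ligand"]))
    bound_frac <- if (n_lig > 0) {
      per_mol <- rowMeans(!is.na(assign_))
      list(mean = sum(!is.na(assign_)) / (n_lig * ncol(assign_)),
           se = if (nrow(assign_) > 1)
             sd(c(per_mol, numeric(n_lig - nrow(assign_)))) / sqrt(n_lig)
           else NA)
    }
    list(assignments = assign_, fits = fits, bound_fraction = bound_frac)
  })

  report$stats <- stage("stats", {
    occ <- report$occupancy
    bw <- cfg$stats$bin_width
    intra_ids <- which(vapply(regions, function(r)
      identical(r$class, "intra"), logical(1)))
    inter_ids <- which(vapply(regions, function(r)
      identical(r$class, "inter"), logical(1)))
    pool <- function(ids, xcol, ycol) {
      do.call(rbind, lapply(ids, function(ci) bin_paired_occupancy(
        occ$counts[[xcol]][, ci], occ$counts[[ycol]][, ci],
        occ$times, bw)))
    }
    fits <- list()
    if (length(intra_ids)) {
      p <- pool(intra_ids, "ligand", "lipid")
      fits$lipid_vs_ligand_intra <- tryCatch(linear_fit(p),
        error = function(e) paste("not fitted:", conditionMessage(e)))
    }
    if (length(inter_ids)) {
      p <- pool(inter_ids, "ligand", "water")
      fits$water_vs_ligand_inter <- tryCatch(linear_fit(p),
        error = function(e) paste("not fitted:", conditionMessage(e)))
    }
    # cavity tables (volume over sampled frames; occupancies over the window)
    tabs <- list()
    for (cl in c("intra", "inter")) {
      ids <- if (cl == "intra") intra_ids else inter_ids
      if (!length(ids)) next
      q <- list(ligand = occ$counts$ligand[, ids, drop = FALSE],
                water = occ$counts$water[, ids, drop = FALSE],
                lipid = occ$counts$lipid[, ids, drop = FALSE])
      tabs[[cl]] <- cavity_table(q, window_frames = occ$window_frames)
    }
    list(fits = fits, tables = tabs)
  })

  if (!is.null(out_dir)) stage("write", write_report(report, out_dir))
  class(report) <- "chan_report"
  report
}

# serialize the main report components as CSV/JSON/DX
write_report <- function(report, out_dir) {
  write.csv(report$rmsd$series, file.path(out_dir, "rmsd.csv"),
            row.names = FALSE)
  hm <- report$pore$heatmap
  write.csv(cbind(z = hm$z, as.data.frame(hm$r)),
            file.path(out_dir, "pore_heatmap.csv"), row.names = FALSE)
  write.csv(report$pore$min_series, file.path(out_dir, "pore_min.csv"),
            row.names = FALSE)
  write_dx(report$cavities$consensus$grid,
           file.path(out_dir, "cavity_frequency.dx"))
  for (nm in names(report$occupancy$series))
    write.csv(report$occupancy$series[[nm]],
              file.path(out_dir, paste0("occupancy_", nm, ".csv")),
              row.names = FALSE)
  summ <- list(
    kink = report$kink, rmsd_window = report$rmsd[c("window_mean", "window_sd")],
    pore_min_mean = report$pore$min_mean,
    volumes = report$cavities[c("volume_mean", "volume_sd")],
    bound_fraction = report$kinetics$bound_fraction,
    kinetics = lapply(report$kinetics$fits, function(f)
      if (inherits(f, "chan_exchange_fit"))
        f[c("A_f", "tau_f", "tau_s", "se_tau_s", "degenerate")] else f),
    stats = lapply(report$stats$fits, function(f)
      if (inherits(f, "chan_linear_fit")) unclass(f) else f))
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
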