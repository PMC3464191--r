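# Trajectory reading: multi-model PDB and DCD.

#' Read a trajectory file
#'
#' Supports multi-model PDB and DCD.  XTC/TRR are not supported; convert such
#' trajectories to DCD or multi-model PDB upstream.
#'
#' @param path trajectory file.
#' @param topology `chan_topology` describing the atoms; the file's atom count
#'   must match.
#' @param dt frame spacing in ns used to populate times (PDB and DCD carry no
#'   reliable time stamps).
#' @return a [chan_trajectory()].
#' @export
read_trajectory <- function(path, topology, dt = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xtc", "trr"))
    stop("XTC/TRR reading is not supported; convert to DCD or multi-model PDB")
  if (ext == "dcd") {
    xyz <- tryCatch(bio3d::read.dcd(path, verbose = FALSE),
                    error = function(e) stop("unparseable DCD file: ", path))
    nat <- ncol(xyz) / 3
    if (nat != nrow(topology))
      stop("trajectory atom count (", nat, ") does not match topology (",
           nrow(topology), ")")
    nf <- nrow(xyz)
    coords <- array(0, dim = c(nat, 3, nf))
    for (i in seq_len(nf)) coords[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    return(chan_trajectory(topology, coords, dt = dt))
  }
  # multi-model PDB
  mm <- read_multimodel_pdb(path)
  if (ncol(mm$xyz[[1]]) != 3 || nrow(mm$xyz[[1]]) != nrow(topology))
    stop("trajectory atom count (", nrow(mm$xyz[[1]]),
         ") does not match topology (", nrow(topology), ")")
  chan_trajectory(topology, mm$xyz, dt = dt)
}

# fast fixed-width multi-model PDB coordinate reader; reports the last good
# frame on truncation
read_multimodel_pdb <- function(path) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  ends <- which(startsWith(lines, "ENDMDL"))
  starts <- which(startsWith(lines, "MODEL"))
  if (!length(starts)) { starts <- 1L; ends <- length(lines) }
  if (length(ends) < length(starts)) {
    warning("truncated trajectory: last complete frame is ", length(ends))
    starts <- starts[seq_along(ends)]
  }
  nat <- NULL
  xyz <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    idx <- which(is_atom & seq_along(lines) > starts[i] & seq_along(lines) < ends[i])
    at <- lines[idx]
    m <- cbind(as.numeric(substr(at, 31, 38)),
               as.numeric(substr(at, 39, 46)),
               as.numeric(substr(at, 47, 54)))
    if (anyNA(m)) stop("corrupt frame ", i, "; last good frame index is ", i - 1L)
    if (is.null(nat)) nat <- nrow(m)
    else if (nrow(m) != nat) stop("corrupt frame ", i,
                                  "; last good frame index is ", i - 1L)
    xyz[[i]] <- m
  }
  list(xyz = xyz)
}
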