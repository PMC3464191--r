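# OpenDX scalar-field grid I/O (the format used for density and cavity maps).

#' Construct a regular scalar grid
#'
#' @param values 3-D numeric array.
#' @param origin length-3 origin of the first voxel centre, Angstrom.
#' @param spacing scalar lattice spacing, Angstrom (grids are cubic-lattice).
#' @return object of class `chan_grid`.
#' @export
chan_grid <- function(values, origin, spacing = 1) {
  if (length(dim(values)) != 3) stop("grid values must be a 3-D array")
  if (length(spacing) != 1 || spacing <= 0)
    stop("unsupported grid: spacing must be a single positive value")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing)), class = "chan_grid")
}

#' @export
print.chan_grid <- function(x, ...) {
  cat("chan_grid:", paste(dim(x$values), collapse = " x "),
      "voxels, spacing", x$spacing, "A, origin",
      paste(sprintf("%.2f", x$origin), collapse = " "), "\n")
  invisible(x)
}

# centres of all voxels as an n x 3 matrix (x fastest)
grid_centers <- function(grid) {
  d <- dim(grid$values)
  ii <- as.matrix(expand.grid(seq_len(d[1]) - 1, seq_len(d[2]) - 1,
                              seq_len(d[3]) - 1))
  sweep(ii * grid$spacing, 2, grid$origin, `+`)
}

#' Write a scalar grid as an OpenDX file
#'
#' @param grid a [chan_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  if (!inherits(grid, "chan_grid")) stop("grid must be a chan_grid")
  d <- dim(grid$values)
  if (any(d < 1) || length(grid$values) == 0) stop("empty grid")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # DX order: z fastest
  v <- aperm(grid$values, c(3, 2, 1))
  vals <- sprintf("%.10g", as.vector(v))
  n <- length(vals)
  pad <- (3 - n %% 3) %% 3
  if (pad) vals <- c(vals, rep("", pad))
  writeLines(apply(matrix(vals, ncol = 3, byrow = TRUE), 1,
                   function(r) trimws(paste(r, collapse = " "))), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Read an OpenDX scalar grid
#'
#' @param path DX file written by [write_dx()] (or compatible).
#' @return a [chan_grid()].
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  cnt <- regmatches(lines[1], gregexpr("[0-9]+", lines[1]))[[1]]
  d <- as.integer(tail(cnt, 3))
  origin <- as.numeric(strsplit(trimws(sub("origin", "", lines[grep("^origin", lines)[1]])), "\\s+")[[1]])
  deltas <- lines[grep("^delta", lines)]
  dmat <- do.call(rbind, lapply(deltas, function(l)
    as.numeric(strsplit(trimws(sub("delta", "", l)), "\\s+")[[1]])))
  sp <- unique(round(diag(dmat), 9))
  if (length(sp) != 1 || any(abs(dmat - diag(rep(sp, 3))) > 1e-8))
    stop("unsupported grid: non-uniform or non-axis-aligned spacing")
  i0 <- grep("data follows", lines)[1]
  iend <- grep("^attribute", lines)
  iend <- if (length(iend)) min(iend) - 1 else length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(lines[(i0 + 1):iend]), "\\s+")))
  vals <- vals[seq_len(prod(d))]
  arr <- aperm(array(vals, dim = rev(d)), c(3, 2, 1))
  chan_grid(arr, origin, sp)
}
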