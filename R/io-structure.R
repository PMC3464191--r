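# Structure I/O: PDB (read/write, via bio3d for parsing), GRO (read).

guess_element <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    e <- toupper(trimws(elesy))
    ok <- !is.na(e) & nzchar(e)
    if (all(ok)) return(e)
  } else {
    e <- rep(NA_character_, length(elety))
    ok <- logical(length(elety))
  }
  # first alphabetic character of the atom name, two-letter halides aside
  nm <- toupper(trimws(elety[!ok]))
  first <- sub("^[0-9']*", "", nm)
  guess <- substr(first, 1, 1)
  guess[substr(first, 1, 2) %in% c("CL", "BR")] <- substr(first[substr(first, 1, 2) %in% c("CL", "BR")], 1, 2)
  e[!ok] <- guess
  e
}

classify_species <- function(resid, species_rules, default_species = NULL) {
  sp <- unname(species_rules[toupper(resid)])
  if (anyNA(sp)) {
    if (is.null(default_species)) {
      bad <- sort(unique(resid[is.na(sp)]))
      stop("no species rule for residue name(s): ", paste(bad, collapse = ", "),
           " (supply species_rules entries or default_species)")
    }
    sp[is.na(sp)] <- default_species
  }
  sp
}

# molecule ids: protein -> one molecule per chain; everything else -> one per
# residue (chain/resno/resid run)
assign_molecules <- function(chain, resno, resid, species) {
  key <- ifelse(species == "protein",
                paste0("P|", chain),
                paste0("R|", chain, "|", resno, "|", resid))
  match(key, unique(key))
}

#' Read a structure file into a topology and frame
#'
#' Reads a PDB (via bio3d) or GRO file, classifies every atom into a species
#' class using residue-name rules, assigns van der Waals radii from an element
#' table, and groups atoms into molecules.  Chains are preserved in file
#' order.
#'
#' @param path path to a `.pdb` or `.gro` file.
#' @param species_rules named character vector mapping residue names to species
#'   classes; see [default_species_rules()].
#' @param default_species class used for residue names absent from
#'   `species_rules`; when `NULL` (default) unknown names are an error.
#' @param radii vdW radius table from [vdw_radii()].
#' @return list with elements `topology` (a [chan_topology()]) and `frame`
#'   (a [chan_frame()], coordinates in Angstrom).
#' @export
read_structure <- function(path, species_rules = default_species_rules(),
                           default_species = NULL, radii = vdw_radii()) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") {
    raw <- read_gro_raw(path)
  } else {
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                    error = function(e) stop("unparseable PDB file: ", path,
                                             " (", conditionMessage(e), ")"))
    at <- pdb$atom
    raw <- list(eleno = at$eleno, elety = at$elety, resid = at$resid,
                chain = ifelse(is.na(at$chain), "A", at$chain),
                resno = at$resno,
                elesy = if ("elesy" %in% names(at)) at$elesy else NULL,
                xyz = cbind(at$x, at$y, at$z), box = NULL)
  }
  elem <- guess_element(raw$elety, raw$elesy)
  species <- classify_species(raw$resid, species_rules, default_species)
  mol <- assign_molecules(raw$chain, raw$resno, raw$resid, species)
  top <- chan_topology(data.frame(
    eleno = raw$eleno, elety = raw$elety, resid = toupper(raw$resid),
    chain = raw$chain, resno = raw$resno, elem = elem,
    vdw = lookup_vdw(elem, radii), species = species, mol = mol,
    stringsAsFactors = FALSE))
  list(topology = top, frame = chan_frame(raw$xyz, time = 0, box = raw$box))
}

# minimal GROMACS .gro reader (fixed-width, coordinates nm -> Angstrom)
read_gro_raw <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("unparseable GRO file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || length(lines) < n + 3) stop("unparseable GRO file: ", path)
  body <- lines[3:(2 + n)]
  resno <- as.integer(substr(body, 1, 5))
  resid <- trimws(substr(body, 6, 10))
  elety <- trimws(substr(body, 11, 15))
  eleno <- as.integer(substr(body, 16, 20))
  x <- as.numeric(substr(body, 21, 28)) * 10
  y <- as.numeric(substr(body, 29, 36)) * 10
  z <- as.numeric(substr(body, 37, 44)) * 10
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])) * 10
  # GRO has no chain column; start a new chain when resno decreases
  brk <- cumsum(c(1L, as.integer(diff(resno) < 0)))
  chain <- LETTERS[pmin(brk, 26L)]
  list(eleno = eleno, elety = elety, resid = resid, chain = chain,
       resno = resno, elesy = NULL, xyz = cbind(x, y, z), box = box[1:3])
}

format_pdb_atom <- function(i, elety, resid, chain, resno, xyz, elem) {
  nm <- ifelse(nchar(elety) < 4, sprintf(" %-3s", elety), sprintf("%-4s", elety))
  sprintf("ATOM  %5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i %% 100000, nm, substr(resid, 1, 3), substr(chain, 1, 1),
          resno %% 10000, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, substr(elem, 1, 2))
}

#' Write a topology + coordinates as a PDB file
#'
#' With a matrix, writes a single-model PDB; with a `chan_trajectory`, writes
#' a multi-model PDB (one MODEL per frame).
#'
#' @param top a `chan_topology`.
#' @param coords n x 3 matrix, `chan_frame`, or `chan_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(top, coords, path) {
  con <- file(path, "w")
  on.exit(close(con))
  one <- function(xyz) {
    lines <- format_pdb_atom(seq_len(nrow(top)), top$elety, top$resid,
                             top$chain, top$resno, xyz, top$elem)
    # TER between chains keeps readers from merging them
    writeLines(lines, con)
  }
  if (inherits(coords, "chan_trajectory")) {
    for (i in seq_len(n_frames(coords))) {
      writeLines(sprintf("MODEL     %4d", i), con)
      one(coords$coords[, , i])
      writeLines("ENDMDL", con)
    }
  } else {
    if (inherits(coords, "chan_frame")) coords <- coords$xyz
    one(as.matrix(coords))
  }
  writeLines("END", con)
  invisible(path)
}
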