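# File I/O: multi-MODEL PDB (parsing delegated to bio3d, with a light
# pre-scan supplying precise structural diagnostics), multi-frame XYZ, and a
# YAML sidecar for ground-truth beam specifications.

.chain_alphabet <- c(LETTERS, letters, 0:9)

#' Read a (multi-MODEL) PDB file as structure + trajectory
#'
#' One trajectory frame per MODEL record (a single frame if the file has
#' none). Chain identifiers map to `strand_index` (in order of first
#' appearance); `layer_index` is taken from segment identifiers of the form
#' `L<k>` when present, otherwise left NA.
#'
#' @param path PDB file path.
#' @param time_per_frame Sampling interval metadata, ps.
#' @return List with `structure` (first frame as [fibril_structure()]) and
#'   `trajectory` (a `fibril_trajectory`).
#' @export
read_pdb <- function(path, time_per_frame = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  # pre-scan: per-MODEL atom counts and malformed coordinate fields
  model_starts <- grep("^MODEL", lines)
  atom_lines <- which(is_atom)
  if (!length(atom_lines)) stop("no ATOM/HETATM records in ", path)
  for (ln in atom_lines) {
    fields <- c(substr(lines[ln], 31, 38), substr(lines[ln], 39, 46),
                substr(lines[ln], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(fields))))
      stop("malformed coordinate field at line ", ln, " of ", path)
  }
  if (length(model_starts) > 1) {
    model_of <- findInterval(atom_lines, model_starts)
    counts <- table(model_of[model_of > 0])
    if (length(unique(as.integer(counts))) > 1)
      stop("inconsistent atom count across MODELs in ", path, ": ",
           paste(as.integer(counts), collapse = ", "))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nmodel <- nrow(pdb$xyz)
  natom <- nrow(at)
  chain <- at$chain
  chain[is.na(chain)] <- "A"
  strand <- as.integer(factor(chain, levels = unique(chain)))
  layer <- rep(NA_integer_, natom)
  if (!is.null(at$segid)) {
    hit <- grepl("^L\\d+$", at$segid)
    layer[hit] <- as.integer(sub("^L", "", at$segid[hit]))
  }
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(at$elety), 1, 1)
  elem[is.na(elem) | elem == ""] <- substr(trimws(at$elety), 1, 1)[is.na(elem) | elem == ""]
  masses <- .atom_masses[ifelse(trimws(at$elety) == "CA", "CA", trimws(elem))]
  masses[is.na(masses)] <- 12.011
  atoms <- data.frame(element = trimws(elem), atom_name = trimws(at$elety),
                      residue_index = at$resno, strand_index = strand,
                      layer_index = layer, mass = unname(masses),
                      stringsAsFactors = FALSE)
  coords <- array(0, dim = c(natom, 3, nmodel))
  for (i in seq_len(nmodel)) coords[, , i] <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
  traj <- fibril_trajectory(coords, atoms, time_per_frame)
  list(structure = fibril_structure(atoms, coords[, , 1]), trajectory = traj)
}

#' Write a structure or trajectory as a (multi-MODEL) PDB file
#'
#' Strand index is written as the chain identifier and layer index as segment
#' id `L<k>`, so [read_pdb()] round-trips the topology. Coordinates are
#' written at the PDB's fixed 3-decimal precision.
#'
#' @param x A `fibril_structure` or `fibril_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "fibril_structure")) {
    frames <- list(x$coords); atoms <- x$atoms
  } else if (inherits(x, "fibril_trajectory")) {
    frames <- lapply(seq_len(n_frames(x)), function(i) frame_coords(x, i))
    atoms <- x$atoms
  } else stop("x must be a fibril_structure or fibril_trajectory")
  chain <- .chain_alphabet[((atoms$strand_index - 1) %% length(.chain_alphabet)) + 1]
  segid <- ifelse(is.na(atoms$layer_index), "",
                  sprintf("L%d", atoms$layer_index))
  multi <- length(frames) > 1
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    cc <- frames[[f]]
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
      seq_len(nrow(atoms)) %% 100000,
      ifelse(nchar(atoms$atom_name) < 4, paste0(" ", atoms$atom_name),
             atoms$atom_name),
      "GLY", chain, atoms$residue_index %% 10000,
      cc[, 1], cc[, 2], cc[, 3], 1, 0, segid, atoms$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ: per frame a count line, a comment line, then
#' `element x y z` rows. Element symbols are checked against `atom_table`
#' when supplied.
#'
#' @param path XYZ file path.
#' @param atom_table Optional topology table (as in [fibril_structure()]).
#' @param time_per_frame Sampling interval metadata, ps.
#' @return A `fibril_trajectory`.
#' @export
read_xyz_trajectory <- function(path, atom_table = NULL, time_per_frame = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  frames <- list(); elems <- NULL; i <- 1L; f <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) stop("bad atom-count line at line ", i, " of ", path)
    if (i + 1 + n > length(lines)) stop("truncated frame at line ", i, " of ", path)
    block <- lines[(i + 2):(i + 1 + n)]
    toks <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(toks, length, integer(1)) < 4)
    if (length(bad)) stop("malformed XYZ row at line ", i + 1 + bad[1], " of ", path)
    el <- vapply(toks, `[`, character(1), 1)
    cc <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (anyNA(cc)) stop("malformed coordinates in frame starting line ", i, " of ", path)
    f <- f + 1L
    if (is.null(elems)) elems <- el
    else if (!identical(el, elems)) stop("atom list changed in frame ", f)
    frames[[f]] <- cc
    i <- i + 2L + n
  }
  counts <- unique(vapply(frames, nrow, integer(1)))
  if (length(counts) != 1) stop("frames differ in atom count")
  if (is.null(atom_table)) {
    atom_table <- data.frame(element = elems, atom_name = "CA",
                             residue_index = seq_along(elems),
                             strand_index = 1L, layer_index = NA_integer_,
                             mass = 12.011, stringsAsFactors = FALSE)
  } else {
    if (nrow(atom_table) != counts) stop("atom_table does not match frame size")
    if (!all(toupper(atom_table$element) == toupper(elems)))
      stop("element symbols disagree with atom_table")
  }
  fibril_trajectory(frames, atom_table, time_per_frame)
}

#' Write a trajectory (or structure) as multi-frame XYZ
#'
#' @param x A `fibril_trajectory` or `fibril_structure`.
#' @param path Output path.
#' @param digits Printed decimal places (default 3).
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(x, path, digits = 3) {
  if (inherits(x, "fibril_structure")) {
    frames <- list(x$coords); atoms <- x$atoms
  } else {
    frames <- lapply(seq_len(n_frames(x)), function(i) frame_coords(x, i))
    atoms <- x$atoms
  }
  fmt <- sprintf("%%s %%.%df %%.%df %%.%df", digits, digits, digits)
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_along(frames)) {
    writeLines(as.character(nrow(atoms)), con)
    writeLines(sprintf("frame %d", f), con)
    cc <- frames[[f]]
    writeLines(sprintf(fmt, atoms$element, cc[, 1], cc[, 2], cc[, 3]), con)
  }
  invisible(path)
}

#' Write / read a beam specification sidecar (YAML)
#'
#' Serializes the ground-truth [beam_spec()] next to a generated trajectory.
#'
#' @param spec A [beam_spec()].
#' @param path YAML path.
#' @return `path` invisibly / the restored `beam_spec`.
#' @export
write_beam_spec <- function(spec, path) {
  stopifnot(inherits(spec, "beam_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_beam_spec
#' @export
read_beam_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(beam_spec, vals)
}
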