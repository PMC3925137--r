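# Steric-zipper polymorph taxonomy and an idealized cross-beta fibril builder.
#
# A steric-zipper polymorph is labelled by three binary choices: whether the
# two beta-sheets of the ladder are co-aligned or anti-aligned, whether the
# hydrogen bonding within each sheet is parallel or anti-parallel (strand
# direction constant vs alternating layer-to-layer), and whether the zipper
# interface packs identical (homo) or distinct (hetero) sheet faces. The
# eight combinations give the eight polymorph classes.

.zipper_table <- data.frame(
  class_id = 1:8,
  abbreviation = c("co-pho", "co-phe", "aa-pho", "aa-phe",
                   "co-apho", "co-aphe", "aa-apho", "aa-aphe"),
  ladder_alignment = c("co-aligned", "co-aligned", "anti-aligned", "anti-aligned",
                       "co-aligned", "co-aligned", "anti-aligned", "anti-aligned"),
  hbond_type = c("parallel", "parallel", "parallel", "parallel",
                 "anti-parallel", "anti-parallel", "anti-parallel", "anti-parallel"),
  zipper_type = c("homo", "hetero", "homo", "hetero",
                  "homo", "hetero", "homo", "hetero"),
  stringsAsFactors = FALSE
)

#' Enumerate the eight steric-zipper polymorph classes
#'
#' @return data.frame with columns `class_id`, `abbreviation`,
#'   `ladder_alignment`, `hbond_type`, `zipper_type`; one row per class.
#' @export
enumerate_zipper_classes <- function() .zipper_table

#' Look up a zipper class by id or abbreviation
#'
#' @param class_spec Integer class id (1-8) or abbreviation such as "aa-apho".
#' @return One-row data.frame describing the class.
#' @export
zipper_class <- function(class_spec) {
  tab <- .zipper_table
  row <- if (is.numeric(class_spec)) {
    tab[tab$class_id == class_spec, ]
  } else {
    tab[tab$abbreviation == class_spec, ]
  }
  if (nrow(row) != 1) stop("unknown zipper class: ", class_spec)
  row
}

#' Parameters for the idealized fibril builder
#'
#' Defaults emulate canonical cross-beta geometry: 4.8 A inter-layer rise,
#' 3.4 A C-alpha spacing along an extended beta strand, and a 10 A dry
#' zipper interface between the two sheets.
#'
#' @param n_layers Number of beta-sheet layers (>= 2).
#' @param strands_per_layer Strands per layer (one per sheet; default 2).
#' @param rise_per_layer Inter-layer rise along the fibril axis, A.
#' @param twist_per_layer Rotation between successive layers about the fibril
#'   axis, degrees, in \[0, 180).
#' @param residues_per_strand Residues per strand.
#' @param sheet_separation Distance between the two sheets, A.
#' @param include_backbone_atoms If TRUE each residue carries N, H, CA, C, O
#'   in idealized extended-strand geometry; otherwise C-alpha only.
#' @return List of validated build parameters.
#' @export
fibril_build_params <- function(n_layers = 6, strands_per_layer = 2,
                                rise_per_layer = 4.8, twist_per_layer = 0,
                                residues_per_strand = 9,
                                sheet_separation = 10.0,
                                include_backbone_atoms = FALSE) {
  stopifnot(n_layers >= 2, strands_per_layer >= 1, rise_per_layer > 0,
            twist_per_layer >= 0, twist_per_layer < 180,
            residues_per_strand >= 1, sheet_separation > 0)
  list(n_layers = n_layers, strands_per_layer = strands_per_layer,
       rise_per_layer = rise_per_layer, twist_per_layer = twist_per_layer,
       residues_per_strand = residues_per_strand,
       sheet_separation = sheet_separation,
       include_backbone_atoms = include_backbone_atoms)
}

# idealized per-residue backbone offsets (A), in the strand local frame with
# u = strand direction, z = fibril axis. Chosen so that in a stack with
# 4.8 A rise the N-H...O=C geometry is a clean hydrogen bond directed along
# the fibril axis (as in cross-beta architecture).
.backbone_offsets <- function(dir) {
  list(N  = c(-0.6 * dir, 0, 0),
       H  = c(-0.6 * dir, 0, -1.0),
       CA = c(0, 0, 0),
       C  = c(0.6 * dir, 0, 0),
       O  = c(0, 0, 1.4))
}

.atom_masses <- c(N = 14.007, H = 1.008, C = 12.011, O = 15.999, CA = 12.011)

#' Build an idealized steric-zipper fibril
#'
#' Places `n_layers` layers of `strands_per_layer` extended beta strands:
#' successive layers are related by a rise of `rise_per_layer` along the
#' fibril (z) axis and a rotation of `twist_per_layer` about it. Anti-aligned
#' classes reverse the strand direction of the second sheet; anti-parallel
#' hydrogen-bond classes alternate strand direction layer-to-layer within
#' each sheet; hetero zippers shift the second sheet half a residue along
#' the strand so the two packed faces are distinct.
#'
#' @param zipper Class id, abbreviation, or one-row result of
#'   [zipper_class()].
#' @param params Result of [fibril_build_params()].
#' @return A [fibril_structure()]; coordinates are deterministic functions of
#'   the inputs.
#' @export
build_zipper_fibril <- function(zipper, params = fibril_build_params()) {
  if (!is.data.frame(zipper)) zipper <- zipper_class(zipper)
  if (zipper$zipper_type == "hetero" && params$strands_per_layer != 2)
    stop("hetero zipper classes require exactly 2 strands per layer")
  nres <- params$residues_per_strand
  spacing <- 3.4  # C-alpha rise along an extended strand, A
  sheet_y <- (seq_len(params$strands_per_layer) -
                (params$strands_per_layer + 1) / 2) * params$sheet_separation
  rows <- list(); xyz <- list(); k <- 0L
  for (layer in seq_len(params$n_layers)) {
    # right-handed helix about +z: a positive twist reads as a positive
    # IUPAC inter-layer dihedral
    ang <- -(layer - 1) * params$twist_per_layer * pi / 180
    Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
    z0 <- (layer - 1) * params$rise_per_layer
    for (sheet in seq_len(params$strands_per_layer)) {
      dir <- 1
      if (zipper$ladder_alignment == "anti-aligned" && sheet %% 2 == 0) dir <- -dir
      if (zipper$hbond_type == "anti-parallel" && layer %% 2 == 0) dir <- -dir
      xshift <- if (zipper$zipper_type == "hetero" && sheet %% 2 == 0) spacing / 2 else 0
      strand_id <- (layer - 1) * params$strands_per_layer + sheet
      for (res in seq_len(nres)) {
        x <- (res - (nres + 1) / 2) * spacing * dir + xshift
        base <- c(x, sheet_y[sheet], 0)
        offs <- if (params$include_backbone_atoms) .backbone_offsets(dir)
                else list(CA = c(0, 0, 0))
        for (an in names(offs)) {
          k <- k + 1L
          p <- base + offs[[an]]
          xyz[[k]] <- as.numeric(Rz %*% p) + c(0, 0, z0)
          rows[[k]] <- data.frame(
            element = if (an == "CA") "C" else substr(an, 1, 1),
            atom_name = an, residue_index = as.integer(res),
            strand_index = as.integer(strand_id),
            layer_index = as.integer(layer), mass = unname(.atom_masses[an]),
            strand_direction = dir, stringsAsFactors = FALSE)
        }
      }
    }
  }
  atoms <- do.call(rbind, rows)
  coords <- do.call(rbind, xyz)
  fibril_structure(atoms, coords,
                   metadata = list(class_label = zipper$abbreviation,
                                   class_id = zipper$class_id,
                                   n_layers = params$n_layers,
                                   strands_per_layer = params$strands_per_layer,
                                   twist_per_layer = params$twist_per_layer,
                                   rise_per_layer = params$rise_per_layer))
}
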