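## Internal element tables -----------------------------------------------

# Bondi van der Waals radii (nm) for heavy atoms used in SASA.
.default_vdw_nm <- c(C = 0.170, N = 0.155, O = 0.152, S = 0.180)

# Standard atomic masses (u) used for mass-weighted Rg.
.atomic_mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008,
                  other = 0)

.known_elements <- c("C", "N", "O", "S", "H")

#' Infer the element of an atom from its PDB-style name
#'
#' Uses the leading element letter after stripping digits and the standard
#' two-character disambiguation (a name starting with a digit, e.g. "1HB",
#' is a hydrogen; two-letter names whose first letter is C/N/O/S/H are the
#' one-letter element unless they are a recognised two-letter element).
#'
#' @param atom_name character vector of atom names ("CA", "CE", "OXT", ...).
#' @return character vector over \{C,N,O,S,H,other\}.
#' @keywords internal
infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", trimws(atom_name)))
  first <- substr(nm, 1L, 1L)
  el <- ifelse(first %in% .known_elements, first, "other")
  el[nm == ""] <- "other"
  # Names like "FE", "MG", "ZN", "CL", "BR" are full element symbols; of
  # these only CL/CA-as-calcium collide with carbon names.  Protein atom
  # names never use calcium/chlorine, so the simple rule stands for the
  # standard residues this package targets.
  el
}

#' Construct a Topology
#'
#' A Topology is the static atom/residue metadata shared by every frame of
#' a trajectory: atom names, elements, residue membership and a chain id.
#'
#' @param atom_name character vector of PDB-convention atom names.
#' @param element character vector over \{C,N,O,S,H,other\}; inferred from
#'   `atom_name` when `NULL`.
#' @param residue_index integer vector (1-based) mapping each atom to its
#'   residue; must be non-decreasing.
#' @param residue_name character vector, one 3-letter code per residue.
#' @param serial integer atom serial numbers; defaults to `seq_along(atom_name)`.
#' @param chain_id single chain identifier string.
#' @return an object of class `"topology"` with elements `atoms`
#'   (data.frame: serial, atom_name, element, residue_index),
#'   `residues` (data.frame: residue_name, first, last), `chain_id`,
#'   `n_residues`.
#' @export
topology <- function(atom_name, element = NULL, residue_index, residue_name,
                     serial = seq_along(atom_name), chain_id = "A") {
  atom_name <- as.character(atom_name)
  n <- length(atom_name)
  if (n == 0L) stop("topology must contain at least one atom")
  residue_index <- as.integer(residue_index)
  if (length(residue_index) != n)
    stop("residue_index must have one entry per atom")
  if (is.unsorted(residue_index))
    stop("residue_index must be non-decreasing along the atom list")
  if (is.null(element)) element <- infer_element(atom_name)
  element <- as.character(element)
  bad <- !element %in% c(.known_elements, "other")
  if (any(bad)) stop("unknown element code: ", paste(unique(element[bad]),
                                                     collapse = ", "))
  uidx <- unique(residue_index)
  if (!identical(uidx, seq_along(uidx)))
    stop("residue_index must cover 1..n_residues without gaps")
  nres <- length(uidx)
  residue_name <- toupper(as.character(residue_name))
  if (length(residue_name) != nres)
    stop("need one residue_name per residue (", nres, ")")
  first <- match(uidx, residue_index)
  last <- vapply(uidx, function(i) max(which(residue_index == i)), integer(1))
  structure(list(
    atoms = data.frame(serial = as.integer(serial), atom_name = atom_name,
                       element = element, residue_index = residue_index,
                       stringsAsFactors = FALSE),
    residues = data.frame(residue_name = residue_name, first = first,
                          last = as.integer(last), stringsAsFactors = FALSE),
    chain_id = as.character(chain_id)[1],
    n_residues = nres
  ), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("Topology: ", nrow(x$atoms), " atoms, ", x$n_residues,
      " residues (chain ", x$chain_id, ")\n", sep = "")
  cat("  residues:", paste(utils::head(x$residues$residue_name, 8),
                           collapse = " "),
      if (x$n_residues > 8) "..." else "", "\n")
  invisible(x)
}

#' Indices of a residue's atoms
#' @param top a `topology`.
#' @param residue 1-based residue index.
#' @return integer vector of atom indices.
#' @keywords internal
residue_atoms <- function(top, residue) {
  r <- top$residues[residue, ]
  seq.int(r$first, r$last)
}

#' Find a named atom within a residue
#' @return atom index, or NA_integer_ if absent.
#' @keywords internal
find_atom <- function(top, residue, atom_name) {
  idx <- residue_atoms(top, residue)
  hit <- idx[top$atoms$atom_name[idx] == atom_name]
  if (length(hit) == 0L) NA_integer_ else hit[1]
}

#' Construct a coordinate Frame
#'
#' @param coords numeric n x 3 matrix of coordinates in nm.
#' @param time_ns non-negative frame time in ns.
#' @return object of class `"frame"`.
#' @export
frame <- function(coords, time_ns = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  if (!all(is.finite(coords))) stop("coordinates must all be finite")
  if (!is.finite(time_ns) || time_ns < 0) stop("time_ns must be >= 0")
  structure(list(time_ns = as.numeric(time_ns), coords = unname(coords)),
            class = "frame")
}

#' Construct a Trajectory
#'
#' @param topology a `topology`.
#' @param frames list of `frame` objects with strictly increasing times and
#'   coordinates matching the topology atom count.
#' @return object of class `"trajectory"`.
#' @export
trajectory <- function(topology, frames) {
  stopifnot(inherits(topology, "topology"))
  if (length(frames) < 1L) stop("trajectory needs at least one frame")
  nat <- nrow(topology$atoms)
  times <- vapply(frames, function(f) f$time_ns, numeric(1))
  ok <- vapply(frames, function(f) nrow(f$coords) == nat, logical(1))
  if (!all(ok))
    stop("frame atom count mismatch: frames ",
         paste(which(!ok), collapse = ", "), " do not have ", nat, " atoms")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  t <- frame_times(x)
  cat("Trajectory: ", length(x$frames), " frames, ",
      nrow(x$topology$atoms), " atoms, t = ",
      format(t[1]), " .. ", format(t[length(t)]), " ns\n", sep = "")
  invisible(x)
}

#' Frame times of a trajectory (ns)
#' @param traj a `trajectory`.
#' @return numeric vector.
#' @export
frame_times <- function(traj) {
  vapply(traj$frames, function(f) f$time_ns, numeric(1))
}

#' Indices of frames falling in a time window
#'
#' The window is closed: frames with `t0 <= time <= t1` are included.
#'
#' @param traj a `trajectory`.
#' @param window numeric length-2 `(t0, t1)` in ns; `NULL` means all frames.
#' @return integer vector of frame indices.
#' @export
frames_in_window <- function(traj, window = NULL) {
  t <- frame_times(traj)
  if (is.null(window)) return(seq_along(t))
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be (t0, t1) with t0 < t1")
  which(t >= window[1] & t <= window[2])
}

#' Select atoms by a named predicate
#'
#' @param top a `topology`.
#' @param selection one of `"calpha"` (CA atoms), `"heavy"` (non-hydrogen),
#'   `"all"`, or an integer vector of atom indices.
#' @return integer atom indices.
#' @export
select_atoms <- function(top, selection = "calpha") {
  if (is.numeric(selection)) return(as.integer(selection))
  switch(match.arg(selection, c("calpha", "heavy", "all")),
         calpha = which(top$atoms$atom_name == "CA"),
         heavy = which(top$atoms$element != "H"),
         all = seq_len(nrow(top$atoms)))
}
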