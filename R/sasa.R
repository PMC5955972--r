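## Solvent-accessible surface area by the Shrake-Rupley method on a
## deterministic golden-spiral point lattice, hydrophobic/hydrophilic
## partitioning by element (C,S vs N,O), windowed ensemble statistics and
## the hydrophobic transfer energy
##   dG_HP (kJ/mol) = 15.4 * dASA_nonpolar - 2.6 * dASA_polar
## with dASA in nm^2 (denatured minus native ensemble means).

.HP_COEF_NONPOLAR <- 15.4  # kJ mol^-1 nm^-2
.HP_COEF_POLAR <- 2.6      # kJ mol^-1 nm^-2

# quasi-uniform points on the unit sphere (golden spiral; no RNG)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the van der Waals surface: each heavy atom's
#' ASA is `4*pi*(r+probe)^2` times the fraction of lattice points on its
#' expanded sphere not inside any other atom's expanded sphere. Hydrogens
#' are excluded from both surface and occlusion by default (united-atom
#' view). Class totals partition heavy-atom ASA by element into
#' hydrophobic (C, S) and hydrophilic (N, O); other elements are summed
#' separately.
#'
#' @param fr a [frame()].
#' @param top the matching [topology()].
#' @param probe_nm probe radius in nm (0.14, water).
#' @param n_points lattice points per atom (960).
#' @param radii named vector of van der Waals radii in nm per element;
#'   default Bondi: C 0.170, N 0.155, O 0.152, S 0.180.
#' @param include_hydrogens include H atoms as spheres (needs an "H"
#'   radius in `radii`).
#' @return object of class `"asa_frame"`: list with `per_atom_asa_nm2`
#'   (NA for excluded atoms), `class_totals` (hydrophobic, hydrophilic,
#'   other), `time_ns`.
#' @export
#' @examples
#' top <- topology("C", residue_index = 1, residue_name = "ALA")
#' fr <- frame(matrix(0, 1, 3))
#' shrake_rupley(fr, top)$class_totals[["hydrophobic"]]  # 4*pi*0.31^2
shrake_rupley <- function(fr, top, probe_nm = 0.14, n_points = 960L,
                          radii = .default_vdw_nm,
                          include_hydrogens = FALSE) {
  el <- top$atoms$element
  use <- if (include_hydrogens) rep(TRUE, length(el)) else el != "H"
  el_use <- el[use]
  need <- setdiff(unique(el_use), c(names(radii)))
  need <- setdiff(need, "other")
  if (length(need) > 0)
    stop("no van der Waals radius for element(s): ",
         paste(need, collapse = ", "))
  if (any(el_use == "other") && !"other" %in% names(radii))
    stop("no van der Waals radius for element(s): other")
  co <- fr$coords[use, , drop = FALSE]
  R <- unname(radii[el_use]) + probe_nm
  n <- nrow(co)
  pts <- .sphere_points(n_points)
  asa <- numeric(n)
  # pairwise distances once; neighbor lists from them
  d2 <- as.matrix(stats::dist(co))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      asa[i] <- 4 * pi * R[i]^2
      next
    }
    p <- sweep(pts * R[i], 2, co[i, ], "+")          # n_points x 3
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dd <- (p[free, 1] - co[j, 1])^2 + (p[free, 2] - co[j, 2])^2 +
            (p[free, 3] - co[j, 3])^2
      free[free] <- dd >= R[j]^2
    }
    asa[i] <- 4 * pi * R[i]^2 * sum(free) / n_points
  }
  per_atom <- rep(NA_real_, length(el))
  per_atom[use] <- asa
  cls <- ifelse(el_use %in% c("C", "S"), "hydrophobic",
                ifelse(el_use %in% c("N", "O"), "hydrophilic", "other"))
  totals <- c(hydrophobic = sum(asa[cls == "hydrophobic"]),
              hydrophilic = sum(asa[cls == "hydrophilic"]),
              other = sum(asa[cls == "other"]))
  structure(list(per_atom_asa_nm2 = per_atom, class_totals = totals,
                 time_ns = fr$time_ns),
            class = "asa_frame")
}

#' ASA results for every frame of a trajectory
#'
#' @inheritParams shrake_rupley
#' @param traj a [trajectory()].
#' @return list of `asa_frame` objects, classed `"asa_series"`.
#' @export
asa_series <- function(traj, probe_nm = 0.14, n_points = 960L,
                       radii = .default_vdw_nm, include_hydrogens = FALSE) {
  out <- lapply(traj$frames, shrake_rupley, top = traj$topology,
                probe_nm = probe_nm, n_points = n_points, radii = radii,
                include_hydrogens = include_hydrogens)
  class(out) <- "asa_series"
  out
}

#' Windowed ensemble mean and SD of class-partitioned ASA
#'
#' Mean and population SD over the window's frames of the hydrophobic
#' (C, S) and hydrophilic (N, O) ASA totals, the quantities whose
#' native/denatured difference feeds the hydrophobic-energy estimate.
#'
#' @param series an `asa_series` (or list of `asa_frame`s).
#' @param window `(t0_ns, t1_ns)`, or `NULL` for all frames.
#' @return object of class `"asa_window_summary"`: list with `window`,
#'   `n_frames`, `mean_hydrophobic_nm2`, `sd_hydrophobic_nm2`,
#'   `mean_hydrophilic_nm2`, `sd_hydrophilic_nm2`.
#' @export
window_summary <- function(series, window = NULL) {
  t <- vapply(series, `[[`, numeric(1), "time_ns")
  keep <- if (is.null(window)) seq_along(t)
          else which(t >= window[1] & t <= window[2])
  if (length(keep) < 2L)
    stop("window must contain at least 2 frames (has ", length(keep), ")")
  hp <- vapply(series[keep], function(s) s$class_totals[["hydrophobic"]],
               numeric(1))
  hl <- vapply(series[keep], function(s) s$class_totals[["hydrophilic"]],
               numeric(1))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(list(window = if (is.null(window)) range(t) else window,
                 n_frames = length(keep),
                 mean_hydrophobic_nm2 = mean(hp),
                 sd_hydrophobic_nm2 = pop_sd(hp),
                 mean_hydrophilic_nm2 = mean(hl),
                 sd_hydrophilic_nm2 = pop_sd(hl)),
            class = "asa_window_summary")
}

#' @export
print.asa_window_summary <- function(x, ...) {
  cat(sprintf(
    "ASA window %s-%s ns (%d frames): hydrophobic %.2f +/- %.2f nm^2, hydrophilic %.2f +/- %.2f nm^2\n",
    format(x$window[1]), format(x$window[2]), x$n_frames,
    x$mean_hydrophobic_nm2, x$sd_hydrophobic_nm2,
    x$mean_hydrophilic_nm2, x$sd_hydrophilic_nm2))
  invisible(x)
}

#' Class-partitioned ASA difference between two ensembles
#'
#' Denatured minus native ensemble mean, per class.
#'
#' @param native,denatured `asa_window_summary` objects (or lists with
#'   `mean_hydrophobic_nm2` / `mean_hydrophilic_nm2`).
#' @return named numeric: `delta_nonpolar_nm2`, `delta_polar_nm2`.
#' @export
delta_asa <- function(native, denatured) {
  c(delta_nonpolar_nm2 =
      denatured$mean_hydrophobic_nm2 - native$mean_hydrophobic_nm2,
    delta_polar_nm2 =
      denatured$mean_hydrophilic_nm2 - native$mean_hydrophilic_nm2)
}

#' Hydrophobic transfer energy from ASA differences
#'
#' `dG_HP (kJ/mol) = 15.4 * dASA_nonpolar - 2.6 * dASA_polar`, with the
#' ASA differences in nm^2 taken between the denatured and native
#' ensemble means.
#'
#' @param delta_nonpolar_nm2 hydrophobic (C, S) ASA difference in nm^2.
#' @param delta_polar_nm2 hydrophilic (N, O) ASA difference in nm^2.
#' @param native_label,denatured_label optional ensemble labels.
#' @return object of class `"hydrophobic_energy"`: list with the inputs
#'   and `delta_g_hp_kj_mol`.
#' @export
#' @examples
#' hydrophobic_energy(11.53, 8.18)$delta_g_hp_kj_mol  # 156.29
hydrophobic_energy <- function(delta_nonpolar_nm2, delta_polar_nm2,
                               native_label = "native",
                               denatured_label = "denatured") {
  structure(list(
    delta_asa_nonpolar_nm2 = delta_nonpolar_nm2,
    delta_asa_polar_nm2 = delta_polar_nm2,
    delta_g_hp_kj_mol = .HP_COEF_NONPOLAR * delta_nonpolar_nm2 -
      .HP_COEF_POLAR * delta_polar_nm2,
    native_label = native_label, denatured_label = denatured_label
  ), class = "hydrophobic_energy")
}

#' @export
print.hydrophobic_energy <- function(x, ...) {
  cat(sprintf(
    "dG_HP(%s -> %s) = 15.4 * %.2f - 2.6 * %.2f = %.1f kJ/mol\n",
    x$native_label, x$denatured_label, x$delta_asa_nonpolar_nm2,
    x$delta_asa_polar_nm2, x$delta_g_hp_kj_mol))
  invisible(x)
}

#' Pairwise hydrophobic-energy differences between variants
#'
#' Given hydrophobic energies per variant, tabulates `ddG_HP` of each
#' variant against each baseline (variant minus baseline).
#'
#' @param results named list of `hydrophobic_energy` objects (or numbers).
#' @param baselines character vector of names in `results`.
#' @return data.frame `variant`, `baseline`, `ddg_hp_kj_mol`.
#' @export
energy_differences <- function(results, baselines) {
  miss <- setdiff(baselines, names(results))
  if (length(miss) > 0)
    stop("baseline(s) absent from results: ", paste(miss, collapse = ", "))
  val <- vapply(results, function(r)
    if (inherits(r, "hydrophobic_energy")) r$delta_g_hp_kj_mol
    else as.numeric(r), numeric(1))
  out <- expand.grid(variant = names(results), baseline = baselines,
                     stringsAsFactors = FALSE)
  out$ddg_hp_kj_mol <- val[out$variant] - val[out$baseline]
  out
}
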