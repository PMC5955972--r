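## Frame-level geometric observables: optimal rigid superposition (Kabsch),
## RMSD series against a fixed reference, and radius of gyration.

#' Optimal rigid superposition of two coordinate sets (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the
#' weighted RMS distance between `R %*% mobile + t` and `reference`.
#' A reflection in the SVD solution is corrected by sign-flipping the
#' smallest singular value so chirality is preserved.
#'
#' @param mobile,reference n x 3 coordinate matrices (nm), equal n >= 3.
#' @param weights per-atom non-negative weights; default equal.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3;
#'   the superposed mobile is `mobile %*% t(rotation) + translation`), and
#'   `rmsd_nm`, the minimized weighted RMSD.
#' @export
#' @examples
#' x <- matrix(rnorm(12), 4, 3)
#' superpose(x, x)$rmsd_nm  # 0
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (nrow(reference) != n) stop("coordinate sets must have equal atom counts")
  if (n < 3L) stop("superposition needs at least 3 atoms")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative with positive sum")
  w <- weights / sum(weights)
  mu_m <- colSums(mobile * w)
  mu_r <- colSums(reference * w)
  A <- sweep(mobile, 2, mu_m)
  B <- sweep(reference, 2, mu_r)
  H <- t(A * w) %*% B
  s <- svd(H)
  # degenerate (e.g. collinear) sets have no unique rotation
  if (s$d[2] < 1e-12 * max(s$d[1], 1e-300))
    stop("degenerate (collinear or coincident) coordinates")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(mu_r - R %*% mu_m),
       rmsd_nm = rmsd)
}

#' Per-frame superposed RMSD series
#'
#' Each frame is optimally superposed onto a fixed reference over the
#' selected atoms and the minimized RMSD recorded, the `gmx rms`
#' convention. Default selection is the C-alpha atoms, unweighted.
#'
#' @param traj a [trajectory()].
#' @param selection as in [select_atoms()]; default `"calpha"`.
#' @param reference a [frame()] or frame index; default the first frame.
#' @param weights optional per-selected-atom weights.
#' @return data.frame of class `"rmsd_series"`: `time_ns`, `rmsd_nm`.
#' @export
rmsd_series <- function(traj, selection = "calpha", reference = 1L,
                        weights = NULL) {
  idx <- select_atoms(traj$topology, selection)
  if (length(idx) == 0L) stop("empty atom selection")
  ref <- if (inherits(reference, "frame")) reference$coords
         else traj$frames[[reference]]$coords
  ref <- ref[idx, , drop = FALSE]
  out <- data.frame(
    time_ns = frame_times(traj),
    rmsd_nm = vapply(traj$frames, function(f)
      superpose(f$coords[idx, , drop = FALSE], ref, weights)$rmsd_nm,
      numeric(1)))
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' Radius of gyration of one frame
#'
#' `sqrt(sum(w_i * |r_i - rbar|^2) / sum(w_i))` with `rbar` the weighted
#' centroid. Mass-weighted with standard atomic masses by default (the
#' `gmx gyrate` convention); hydrogens carry their own mass when present.
#'
#' @param fr a [frame()].
#' @param top the matching [topology()].
#' @param selection as in [select_atoms()]; default `"all"`.
#' @param mass_weighted logical; `FALSE` gives the unweighted geometric Rg.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(fr, top, selection = "all",
                               mass_weighted = TRUE) {
  idx <- select_atoms(top, selection)
  if (length(idx) == 0L) stop("empty atom selection")
  co <- fr$coords[idx, , drop = FALSE]
  w <- if (mass_weighted) {
    m <- .atomic_mass[top$atoms$element[idx]]
    m[is.na(m) | m == 0] <- 12.011  # unknown elements counted as carbon
    m
  } else rep(1, length(idx))
  mu <- colSums(co * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(co, 2, mu)^2)) / sum(w))
}

#' Radius-of-gyration series over a trajectory
#'
#' @inheritParams radius_of_gyration
#' @param traj a [trajectory()].
#' @return data.frame of class `"rg_series"`: `time_ns`, `rg_nm`.
#' @export
rg_series <- function(traj, selection = "all", mass_weighted = TRUE) {
  out <- data.frame(
    time_ns = frame_times(traj),
    rg_nm = vapply(traj$frames, radius_of_gyration, numeric(1),
                   top = traj$topology, selection = selection,
                   mass_weighted = mass_weighted))
  class(out) <- c("rg_series", "data.frame")
  out
}
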