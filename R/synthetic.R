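## Seeded synthetic trajectories with known ground truth. These stand in
## for microsecond MD runs: every observable the analysis modules compute
## (per-pair salt-bridge occupancy, per-residue helicity, radius of
## gyration) is controlled by the generator and recorded, so parameter
## recovery can be tested without a force field. No physical realism is
## attempted beyond what the downstream operators consume.

#' Specification for a synthetic ensemble
#'
#' @param sequence character vector of 3-letter residue codes.
#' @param pair_targets data.frame with columns `donor` (positive residue
#'   index), `acceptor` (negative residue index), `occupancy` in [0, 1];
#'   or `NULL`.
#' @param helix_segments data.frame with columns `start`, `end`,
#'   `fraction` in [0, 1]; or `NULL`.
#' @param rg_start_nm,rg_end_nm radius-of-gyration profile endpoints (nm).
#' @param rg_noise_sd noise SD (nm) added to the Rg target per frame.
#' @param n_frames number of frames (>= 1).
#' @param dt_ns frame spacing in ns; default 0.4, the reporting
#'   granularity used throughout.
#' @param seed integer RNG seed.
#' @return object of class `"ensemble_spec"`.
#' @export
ensemble_spec <- function(sequence, pair_targets = NULL,
                          helix_segments = NULL,
                          rg_start_nm = 1.2, rg_end_nm = 1.2,
                          rg_noise_sd = 0, n_frames = 500L, dt_ns = 0.4,
                          seed = 1L) {
  sequence <- toupper(as.character(sequence))
  n <- length(sequence)
  if (n == 0L) stop("sequence must be non-empty")
  if (!is.null(pair_targets)) {
    pair_targets <- as.data.frame(pair_targets)
    stopifnot(all(c("donor", "acceptor", "occupancy") %in%
                    names(pair_targets)))
    if (any(pair_targets$occupancy < 0 | pair_targets$occupancy > 1))
      stop("occupancy targets must lie in [0, 1]")
    if (any(pair_targets$donor < 1 | pair_targets$donor > n |
            pair_targets$acceptor < 1 | pair_targets$acceptor > n))
      stop("pair residue indices outside the chain")
  }
  if (!is.null(helix_segments)) {
    helix_segments <- as.data.frame(helix_segments)
    stopifnot(all(c("start", "end", "fraction") %in% names(helix_segments)))
    if (any(helix_segments$start < 1 | helix_segments$end > n |
            helix_segments$start > helix_segments$end))
      stop("helix segments must lie within the chain")
    if (any(helix_segments$fraction < 0 | helix_segments$fraction > 1))
      stop("helicity fractions must lie in [0, 1]")
  }
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (dt_ns <= 0) stop("dt_ns must be positive")
  if (rg_start_nm <= 0 || rg_end_nm <= 0) stop("rg profile must be positive")
  structure(list(sequence = sequence, n_residues = n,
                 pair_targets = pair_targets,
                 helix_segments = helix_segments,
                 rg_start_nm = rg_start_nm, rg_end_nm = rg_end_nm,
                 rg_noise_sd = rg_noise_sd,
                 n_frames = as.integer(n_frames), dt_ns = dt_ns,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

# two-state Markov chain with stationary P(on) = p and dwell scale tau
# sampled steps (mean bonded dwell tau/(1-p)); occupancy, not kinetics,
# is the controlled quantity
.markov_states <- function(p, n, tau = 2.5) {
  q_off <- (1 - p) / tau   # on -> off
  q_on <- p / tau          # off -> on
  s <- logical(n)
  s[1] <- stats::runif(1) < p
  if (n > 1) {
    u <- stats::runif(n - 1)
    for (t in 2:n)
      s[t] <- if (s[t - 1]) u[t - 1] >= q_off else u[t - 1] < q_on
  }
  s
}

#' Generate a contact trajectory with prescribed salt-bridge occupancies
#'
#' Residues sit far apart on a planar grid (3 nm spacing, so untargeted
#' criterion atoms never come within 0.7 nm). For each targeted pair a
#' two-state Markov chain toggles the pair between a bonded geometry
#' (criterion-atom distance uniform in [0.35, 0.55] nm) and an unbonded
#' one (uniform in [0.8, 2.5] nm) with stationary bonded probability
#' equal to the target; the "mover" residue of each pair is displaced
#' along a pair-specific direction above the grid plane. The uniform
#' distance bands keep the 0.6 nm classification unambiguous away from
#' the boundary.
#'
#' @param spec an [ensemble_spec()] with `pair_targets`.
#' @return list with `trajectory` and `truth`; `truth$pairs` is a
#'   data.frame `donor`, `acceptor`, `target`, `realized` (realized
#'   bonded-state fraction), and `truth$states` the frames x pairs
#'   logical state matrix.
#' @export
generate_contact_trajectory <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  pt <- spec$pair_targets
  if (is.null(pt) || nrow(pt) == 0L)
    stop("spec carries no pair_occupancy targets")
  old <- .restore_seed(spec$seed); on.exit(old())
  n <- spec$n_residues
  # residue templates from the single-residue ideal builder
  tmpl <- lapply(unique(spec$sequence), function(code)
    build_chain(code, "extended"))
  names(tmpl) <- unique(spec$sequence)

  # assemble topology
  names_out <- character(0); el <- character(0); ridx <- integer(0)
  base_coord <- NULL
  m <- ceiling(sqrt(n))
  for (i in seq_len(n)) {
    tp <- tmpl[[spec$sequence[i]]]
    at <- tp$topology$atoms
    names_out <- c(names_out, at$atom_name)
    el <- c(el, at$element)
    ridx <- c(ridx, rep(i, nrow(at)))
    shift <- c(((i - 1) %% m) * 3, ((i - 1) %/% m) * 3, 0)
    base_coord <- rbind(base_coord, sweep(tp$frame$coords, 2, shift, "+"))
  }
  top <- topology(atom_name = names_out, element = el, residue_index = ridx,
                  residue_name = spec$sequence)
  map <- criterion_atom_map()

  # anchor/mover assignment: the acceptor moves unless already a mover
  np <- nrow(pt)
  mover <- integer(np); anchor <- integer(np)
  taken <- integer(0)
  for (k in seq_len(np)) {
    d <- pt$donor[k]; a <- pt$acceptor[k]
    role_d <- .residue_role(top, d, map); role_a <- .residue_role(top, a, map)
    if (!identical(role_d, "positive"))
      stop("pair ", k, ": donor residue ", d, " is not positive")
    if (!identical(role_a, "negative"))
      stop("pair ", k, ": acceptor residue ", a, " is not negative")
    if (!a %in% taken) { mover[k] <- a; anchor[k] <- d }
    else if (!d %in% taken) { mover[k] <- d; anchor[k] <- a }
    else stop("infeasible targets: residues of pair (", d, ", ", a,
              ") already move for other pairs")
    taken <- c(taken, mover[k])
  }
  # anchors that are themselves movers must be placed first
  ord <- order(match(anchor, mover, nomatch = 0L))
  if (any((dep <- match(anchor, mover, nomatch = 0L)) > 0)) {
    # reject cycles: repeatedly peel pairs whose anchor is not a mover
    left <- seq_len(np); ord <- integer(0)
    while (length(left) > 0) {
      free <- left[!anchor[left] %in% mover[left]]
      if (length(free) == 0L)
        stop("infeasible targets: cyclic anchor/mover dependencies")
      ord <- c(ord, free); left <- setdiff(left, free)
    }
  }

  crit_role <- vapply(seq_len(n), function(i) .residue_role(top, i, map),
                      character(1))
  crit_atom <- rep(NA_integer_, n)
  for (i in which(!is.na(crit_role)))
    crit_atom[i] <- criterion_atom(top, i, crit_role[i], map)

  # pair directions: tilted off the grid plane, spread in azimuth
  theta <- 30 * pi / 180
  uvec <- t(vapply(seq_len(np), function(k) {
    phi <- 2 * pi * (k - 1) / max(np, 1) + 0.3
    c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  }, numeric(3)))

  states <- vapply(seq_len(np), function(k)
    .markov_states(pt$occupancy[k], spec$n_frames),
    logical(spec$n_frames))
  states <- matrix(states, nrow = spec$n_frames)
  dists <- matrix(stats::runif(spec$n_frames * np), spec$n_frames, np)
  dists <- ifelse(states, 0.35 + dists * 0.20, 0.8 + dists * 1.7)

  res_rows <- split(seq_along(ridx), ridx)
  frames <- vector("list", spec$n_frames)
  for (t in seq_len(spec$n_frames)) {
    co <- base_coord
    for (k in ord) {
      i_anchor <- anchor[k]; i_mover <- mover[k]
      target_pos <- co[crit_atom[i_anchor], ] + dists[t, k] * uvec[k, ]
      offset <- target_pos - co[crit_atom[i_mover], ]
      rows <- res_rows[[i_mover]]
      co[rows, ] <- sweep(co[rows, , drop = FALSE], 2, offset, "+")
    }
    frames[[t]] <- frame(co, time_ns = (t - 1) * spec$dt_ns)
  }
  traj <- trajectory(top, frames)
  truth <- list(
    pairs = data.frame(donor = pt$donor, acceptor = pt$acceptor,
                       target = pt$occupancy,
                       realized = colMeans(states)),
    states = states)
  list(trajectory = traj, truth = truth)
}

#' Generate a radius-of-gyration trajectory
#'
#' Frames are isotropic Gaussian clouds (one pseudo-atom per residue,
#' carbon mass) rescaled so the exact Rg follows a linear interpolation
#' from `rg_start_nm` to `rg_end_nm`, plus seeded Gaussian noise of SD
#' `rg_noise_sd` on the per-frame target.
#'
#' @param spec an [ensemble_spec()].
#' @return list with `trajectory` and `truth` (`truth$rg_nm`: the exact
#'   per-frame Rg values).
#' @export
generate_rg_trajectory <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  old <- .restore_seed(spec$seed + 1L); on.exit(old())
  n <- spec$n_residues
  if (n < 2L) stop("rg generation needs at least 2 residues")
  nf <- spec$n_frames
  top <- topology(atom_name = rep("CA", n), element = rep("C", n),
                  residue_index = seq_len(n),
                  residue_name = spec$sequence)
  frac <- if (nf == 1L) 0 else (seq_len(nf) - 1) / (nf - 1)
  target <- spec$rg_start_nm + frac * (spec$rg_end_nm - spec$rg_start_nm)
  if (spec$rg_noise_sd > 0)
    target <- pmax(0.05, target + stats::rnorm(nf, 0, spec$rg_noise_sd))
  frames <- vector("list", nf)
  for (t in seq_len(nf)) {
    co <- matrix(stats::rnorm(3 * n), n, 3)
    co <- sweep(co, 2, colMeans(co))
    rg0 <- sqrt(mean(rowSums(co^2)))
    co <- co * (target[t] / rg0)
    frames[[t]] <- frame(co, time_ns = (t - 1) * spec$dt_ns)
  }
  list(trajectory = trajectory(top, frames),
       truth = list(rg_nm = target))
}

#' Generate a trajectory with prescribed per-residue helicity
#'
#' Each helix segment is toggled on/off by an independent two-state
#' Markov chain with stationary on-probability equal to its target
#' fraction. A frame's conformation is built with ideal-helix backbone
#' dihedrals (phi -57, psi -47) inside the segments that are on and
#' extended dihedrals elsewhere; conformations are cached per on/off
#' combination, so frames with the same segment states are identical.
#' Realized ground truth is the per-residue fraction of frames whose
#' enclosing segment was on (DSSP end effects at segment termini are the
#' analysis module's concern, not the generator's).
#'
#' @param spec an [ensemble_spec()] with `helix_segments`.
#' @return list with `trajectory` and `truth` (`truth$residue_fraction`:
#'   per-residue on-fraction; `truth$segment_states`: frames x segments).
#' @export
generate_helicity_trajectory <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  hs <- spec$helix_segments
  if (is.null(hs) || nrow(hs) == 0L)
    stop("spec carries no helix_segments")
  old <- .restore_seed(spec$seed + 2L); on.exit(old())
  n <- spec$n_residues; nf <- spec$n_frames
  ns <- nrow(hs)
  states <- matrix(vapply(seq_len(ns), function(k)
    .markov_states(hs$fraction[k], nf), logical(nf)), nrow = nf)
  cache <- new.env(parent = emptyenv())
  build_combo <- function(on) {
    key <- paste(as.integer(on), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    phi <- rep(-139, n); psi <- rep(135, n)
    for (k in which(on)) {
      idx <- hs$start[k]:hs$end[k]
      phi[idx] <- -57; psi[idx] <- -47
    }
    ch <- .build_chain_phipsi(spec$sequence, cbind(phi, psi))
    cache[[key]] <- ch
    ch
  }
  first <- build_combo(states[1, ])
  frames <- vector("list", nf)
  for (t in seq_len(nf)) {
    ch <- build_combo(states[t, ])
    frames[[t]] <- frame(ch$frame$coords, time_ns = (t - 1) * spec$dt_ns)
  }
  res_frac <- numeric(n)
  for (k in seq_len(ns)) {
    idx <- hs$start[k]:hs$end[k]
    res_frac[idx] <- pmax(res_frac[idx], mean(states[, k]))
  }
  list(trajectory = trajectory(first$topology, frames),
       truth = list(residue_fraction = res_frac, segment_states = states))
}
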