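## DSSP-style secondary structure from Kabsch-Sander backbone H-bond
## energies:
##   E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)  kcal/mol, r in A
## (bond iff E < -0.5). Categories: H (alpha-helix), E (beta-sheet),
## B (isolated beta-bridge), T (turn), C (other); the "structure"
## aggregate is H + E + B + T.

.KS_Q <- 0.084 * 332     # kcal/mol * Angstrom
.KS_CUTOFF <- -0.5       # kcal/mol

# backbone atom coordinates per residue (Angstrom); amide H placed
# geometrically when missing (N-H 1.00 A along the C(i-1)/CA bisector)
.backbone_coords <- function(fr, top) {
  n <- top$n_residues
  get <- function(i, nm) {
    a <- find_atom(top, i, nm)
    if (is.na(a)) rep(NA_real_, 3) else fr$coords[a, ] * 10
  }
  N <- t(vapply(seq_len(n), get, numeric(3), nm = "N"))
  CA <- t(vapply(seq_len(n), get, numeric(3), nm = "CA"))
  C <- t(vapply(seq_len(n), get, numeric(3), nm = "C"))
  O <- t(vapply(seq_len(n), get, numeric(3), nm = "O"))
  H <- t(vapply(seq_len(n), get, numeric(3), nm = "H"))
  for (i in seq_len(n)) {
    if (any(is.na(H[i, ])) && !any(is.na(N[i, ]))) {
      if (i > 1 && !any(is.na(C[i - 1, ])) && !any(is.na(CA[i, ]))) {
        u1 <- N[i, ] - C[i - 1, ]; u1 <- u1 / sqrt(sum(u1^2))
        u2 <- N[i, ] - CA[i, ]; u2 <- u2 / sqrt(sum(u2^2))
        h <- u1 + u2; h <- h / sqrt(sum(h^2))
        H[i, ] <- N[i, ] + 1.0 * h
      } else if (!any(is.na(CA[i, ]))) {
        u <- N[i, ] - CA[i, ]; u <- u / sqrt(sum(u^2))
        H[i, ] <- N[i, ] + 1.0 * u
      }
    }
  }
  list(N = N, CA = CA, C = C, O = O, H = H)
}

#' Kabsch-Sander hydrogen-bond energy for one donor/acceptor pair
#'
#' Electrostatic model of the backbone N-H...O=C hydrogen bond. The bond
#' is assigned when the energy is below -0.5 kcal/mol. Proline donors are
#' excluded (no amide H), as are pairs closer than |i-j| = 2 in sequence.
#'
#' @param fr a [frame()].
#' @param top the matching [topology()].
#' @param donor_i residue index donating the N-H.
#' @param acceptor_j residue index providing the C=O.
#' @return list `donor`, `acceptor`, `energy_kcal_mol`, `is_bond`;
#'   energy is `NA` (with a warning) when backbone atoms are missing.
#' @export
backbone_hbond_energy <- function(fr, top, donor_i, acceptor_j) {
  if (abs(donor_i - acceptor_j) < 2L)
    stop("Kabsch-Sander bonds are defined only for |i-j| >= 2")
  bb <- .backbone_coords(fr, top)
  e <- .ks_energy_one(bb, top, donor_i, acceptor_j)
  if (is.na(e))
    warning("missing backbone atoms for pair (", donor_i, ", ",
            acceptor_j, "); pair skipped")
  list(donor = donor_i, acceptor = acceptor_j, energy_kcal_mol = e,
       is_bond = isTRUE(e < .KS_CUTOFF))
}

.ks_energy_one <- function(bb, top, d, a) {
  if (top$residues$residue_name[d] == "PRO") return(NA_real_)
  v <- c(bb$N[d, ], bb$H[d, ], bb$C[a, ], bb$O[a, ])
  if (any(is.na(v))) return(NA_real_)
  rON <- sqrt(sum((bb$O[a, ] - bb$N[d, ])^2))
  rCH <- sqrt(sum((bb$C[a, ] - bb$H[d, ])^2))
  rOH <- sqrt(sum((bb$O[a, ] - bb$H[d, ])^2))
  rCN <- sqrt(sum((bb$C[a, ] - bb$N[d, ])^2))
  if (min(rON, rCH, rOH, rCN) < 0.5) return(-9.9)  # clash convention
  .KS_Q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

# full n x n H-bond energy/bond matrices; entry [d, a] = donor d -> acceptor a
.ks_hbond_matrix <- function(fr, top) {
  n <- top$n_residues
  bb <- .backbone_coords(fr, top)
  E <- matrix(NA_real_, n, n)
  for (d in seq_len(n)) {
    if (top$residues$residue_name[d] == "PRO") next
    if (any(is.na(bb$H[d, ])) || any(is.na(bb$N[d, ]))) next
    for (a in seq_len(n)) {
      if (abs(d - a) < 2L) next
      # cheap prefilter: CA-CA beyond 9 A cannot H-bond
      if (any(is.na(bb$CA[d, ])) || any(is.na(bb$CA[a, ]))) next
      if (sum((bb$CA[d, ] - bb$CA[a, ])^2) > 81) next
      E[d, a] <- .ks_energy_one(bb, top, d, a)
    }
  }
  bond <- !is.na(E) & E < .KS_CUTOFF
  list(energy = E, bond = bond)
}

#' Assign per-residue secondary structure for one frame
#'
#' Minimal DSSP-style rules on Kabsch-Sander bonds. An n-turn at residue
#' i is a bond from the N-H of residue i+n to the C=O of residue i
#' (n = 3, 4, 5). Helix (H): two consecutive 4-turns at i-1 and i mark
#' residues i+1..i+4 (folded to alpha only; 3-10/pi turns count as T).
#' Bridges follow the parallel/antiparallel Kabsch-Sander patterns;
#' ladders of >= 2 consecutive bridges give E, isolated bridges B, and
#' 3/4/5-turn residues not already H/E/B give T. Priority H > E > B > T.
#'
#' @param fr a [frame()].
#' @param top the matching [topology()].
#' @return character vector over \{"H","E","B","T","C"\}, one per residue,
#'   classed `"secstruct_frame"` with attribute `time_ns`.
#' @export
assign_frame <- function(fr, top) {
  n <- top$n_residues
  hb <- .ks_hbond_matrix(fr, top)$bond
  # turn_n[i] TRUE: bond N-H(i+n) -> C=O(i)
  turn <- function(len) {
    v <- rep(FALSE, n)
    idx <- seq_len(max(0, n - len))
    v[idx] <- hb[cbind(idx + len, idx)]
    v
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
  lab <- rep("C", n)
  # helix: consecutive 4-turns at i-1 and i -> residues i+1..i+4
  helix <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (i >= 2 && t4[i - 1] && t4[i])
      helix[(i + 1):min(n, i + 4)] <- TRUE
  }
  # bridges
  bridge <- matrix(FALSE, n, n)
  hbda <- function(d, a) {           # bond donor d -> acceptor a, guarded
    d >= 1 && a >= 1 && d <= n && a <= n && hb[d, a]
  }
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (abs(i - j) < 3) next
      par <- (hbda(i, j - 1) && hbda(j + 1, i)) ||
             (hbda(j, i - 1) && hbda(i + 1, j))
      anti <- (hbda(i, j) && hbda(j, i)) ||
              (hbda(i + 1, j - 1) && hbda(j + 1, i - 1))
      if (par || anti) bridge[i, j] <- TRUE
    }
  }
  has_bridge <- apply(bridge, 1, any)
  # ladders: two consecutive residues both bridged to consecutive partners
  sheet <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    if (!has_bridge[i] || !has_bridge[i + 1]) next
    ji <- which(bridge[i, ]); jn <- which(bridge[i + 1, ])
    if (any(abs(outer(ji, jn, "-")) == 1))
      sheet[c(i, i + 1)] <- TRUE
  }
  in_turn <- rep(FALSE, n)
  mark <- function(tv, len) {
    for (i in which(tv)) in_turn[(i + 1):min(n, i + len - 1)] <<- TRUE
  }
  mark(t3, 3); mark(t4, 4); mark(t5, 5)
  lab[in_turn] <- "T"
  lab[has_bridge & !sheet] <- "B"
  lab[sheet] <- "E"
  lab[helix] <- "H"
  structure(lab, class = "secstruct_frame", time_ns = fr$time_ns)
}

#' Assign secondary structure for every frame
#' @param traj a [trajectory()].
#' @return list of `secstruct_frame`s, classed `"secstruct_series"`.
#' @export
secstruct_series <- function(traj) {
  out <- lapply(traj$frames, assign_frame, top = traj$topology)
  class(out) <- "secstruct_series"
  out
}

.ss_times <- function(series) {
  vapply(series, function(s) attr(s, "time_ns"), numeric(1))
}

#' Windowed secondary-structure category counts
#'
#' Per-frame residue counts of alpha-helix (H), beta-sheet (E),
#' beta-bridge (B), turn (T) and their "structure" aggregate
#' (H + E + B + T), summarized as mean and population SD over the
#' window's frames.
#'
#' @param series a `secstruct_series` (or list of assignments).
#' @param window `(t0_ns, t1_ns)` or `NULL`.
#' @return data.frame of class `"secstruct_counts"`: `category`, `mean`,
#'   `sd`, with attribute `window` and `n_frames`.
#' @export
window_counts <- function(series, window = NULL) {
  t <- .ss_times(series)
  keep <- if (is.null(window)) seq_along(t)
          else which(t >= window[1] & t <= window[2])
  if (length(keep) < 2L)
    stop("window must contain at least 2 frames (has ", length(keep), ")")
  cats <- c("H", "E", "B", "T")
  per_frame <- t(vapply(series[keep], function(s)
    vapply(cats, function(k) sum(s == k), numeric(1)), numeric(4)))
  per_frame <- cbind(per_frame, structure = rowSums(per_frame))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- data.frame(
    category = c("alpha_helix", "beta_sheet", "beta_bridge", "turn",
                 "structure"),
    mean = apply(per_frame, 2, mean),
    sd = apply(per_frame, 2, pop_sd))
  rownames(out) <- NULL
  attr(out, "window") <- if (is.null(window)) range(t) else window
  attr(out, "n_frames") <- length(keep)
  class(out) <- c("secstruct_counts", "data.frame")
  out
}

#' Per-residue helicity profile over a window
#'
#' Fraction of window frames in which each residue is labelled H.
#'
#' @param series a `secstruct_series`.
#' @param window `(t0_ns, t1_ns)` or `NULL`.
#' @return data.frame of class `"helicity_profile"`: `residue`,
#'   `helicity` in [0, 1].
#' @export
helicity_profile <- function(series, window = NULL) {
  t <- .ss_times(series)
  keep <- if (is.null(window)) seq_along(t)
          else which(t >= window[1] & t <= window[2])
  if (length(keep) == 0L) stop("no frames in the requested window")
  m <- vapply(series[keep], function(s) s == "H",
              logical(length(series[[1]])))
  out <- data.frame(residue = seq_len(nrow(as.matrix(m))),
                    helicity = rowMeans(as.matrix(m)))
  class(out) <- c("helicity_profile", "data.frame")
  out
}

#' Flat-text dump of per-frame assignments
#'
#' One line per frame: time in ns, a tab, then the one-letter labels.
#'
#' @param series a `secstruct_series`.
#' @param path output file.
#' @export
write_secstruct <- function(series, path) {
  lines <- vapply(series, function(s)
    sprintf("%.4f\t%s", attr(s, "time_ns"), paste(s, collapse = "")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
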