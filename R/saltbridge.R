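## Salt-bridge detection by the side-chain carbon-carbon distance criterion:
## a positively charged residue (Lys CE, Arg CD) and a negatively charged
## residue (Glu CD, Asp CG) form a salt bridge in a frame when their
## criterion atoms are less than `cutoff_nm` apart (strict inequality).
## The C-terminal carboxylate participates as an extra negative site and,
## optionally, the free N-terminus as an extra positive site.

#' Criterion-atom map for salt-bridge detection
#'
#' @param cutoff_nm distance cutoff in nm (strict `<`); default 0.6.
#' @param arg_atom side-chain carbon used for arginine, `"CD"` (default)
#'   or `"CZ"`.
#' @param include_cterm treat the C-terminal carboxyl carbon (terminal
#'   residue backbone "C") as a negative site.
#' @param include_nterm treat the N-terminal backbone nitrogen as a
#'   positive site (off by default).
#' @return object of class `"criterion_map"`.
#' @export
criterion_atom_map <- function(cutoff_nm = 0.6, arg_atom = c("CD", "CZ"),
                               include_cterm = TRUE, include_nterm = FALSE) {
  arg_atom <- match.arg(arg_atom)
  if (!is.numeric(cutoff_nm) || cutoff_nm <= 0) stop("cutoff_nm must be > 0")
  structure(list(
    positive = c(LYS = "CE", ARG = arg_atom),
    negative = c(GLU = "CD", ASP = "CG"),
    cutoff_nm = cutoff_nm,
    include_cterm = include_cterm,
    include_nterm = include_nterm
  ), class = "criterion_map")
}

# role of residue i under the map: "positive", "negative" or NA
.residue_role <- function(top, i, map) {
  rn <- top$residues$residue_name[i]
  if (rn %in% names(map$positive)) return("positive")
  if (rn %in% names(map$negative)) return("negative")
  if (map$include_cterm && i == top$n_residues) return("negative")
  if (map$include_nterm && i == 1L) return("positive")
  NA_character_
}

#' Criterion atom of a residue
#'
#' Returns the atom index of the carbon (or terminal N) used by the
#' salt-bridge distance criterion for the given residue and role.
#'
#' @param top a [topology()].
#' @param residue 1-based residue index.
#' @param role `"positive"` or `"negative"`.
#' @param map a [criterion_atom_map()].
#' @return integer atom index.
#' @export
#' @examples
#' ch <- build_chain(c("ALA", "GLU", "LYS"), "extended")
#' criterion_atom(ch$topology, 3, "positive")  # index of Lys CE
criterion_atom <- function(top, residue, role = c("positive", "negative"),
                           map = criterion_atom_map()) {
  role <- match.arg(role)
  rn <- top$residues$residue_name[residue]
  tab <- map[[role]]
  if (rn %in% names(tab)) {
    nm <- tab[[rn]]
  } else if (role == "negative" && map$include_cterm &&
             residue == top$n_residues) {
    nm <- "C"   # C-terminal carboxyl carbon
  } else if (role == "positive" && map$include_nterm && residue == 1L) {
    nm <- "N"
  } else {
    stop("residue ", residue, " (", rn, ") is not ", role,
         " under the criterion map")
  }
  idx <- find_atom(top, residue, nm)
  if (is.na(idx))
    stop("residue ", residue, " (", rn, ") lacks criterion atom ", nm)
  idx
}

# all residues with the given role (including terminal extras)
.role_residues <- function(top, role, map) {
  tab <- map[[if (role == "positive") "positive" else "negative"]]
  hits <- which(top$residues$residue_name %in% names(tab))
  if (role == "negative" && map$include_cterm)
    hits <- sort(unique(c(hits, top$n_residues)))
  if (role == "positive" && map$include_nterm)
    hits <- sort(unique(c(hits, 1L)))
  hits
}

#' Distance series between the criterion atoms of an ion pair
#'
#' @param traj a [trajectory()].
#' @param donor residue index of the positively charged residue.
#' @param acceptor residue index of the negatively charged residue.
#' @param map a [criterion_atom_map()].
#' @return data.frame of class `"pair_distance_series"`: `donor`,
#'   `acceptor`, `time_ns`, `distance_nm`.
#' @export
pair_distances <- function(traj, donor, acceptor,
                           map = criterion_atom_map()) {
  top <- traj$topology
  ia <- criterion_atom(top, donor, "positive", map)
  ib <- criterion_atom(top, acceptor, "negative", map)
  d <- vapply(traj$frames, function(f)
    sqrt(sum((f$coords[ia, ] - f$coords[ib, ])^2)), numeric(1))
  out <- data.frame(donor = donor, acceptor = acceptor,
                    time_ns = frame_times(traj), distance_nm = d)
  class(out) <- c("pair_distance_series", "data.frame")
  out
}

# distance matrix (frames x pairs) between criterion atoms
.pair_distance_matrix <- function(traj, atom_i, atom_j) {
  out <- vapply(seq_along(atom_i), function(k) {
    vapply(traj$frames, function(f)
      sqrt(sum((f$coords[atom_i[k], ] - f$coords[atom_j[k], ])^2)),
      numeric(1))
  }, numeric(length(traj$frames)))
  matrix(out, nrow = length(traj$frames))
}

#' Salt-bridge occupancy report
#'
#' For each target residue, the percentage of window frames in which its
#' criterion-atom distance to each oppositely charged residue (including
#' the C-terminal carboxylate) is below the cutoff. The per-residue sum
#' over partners may exceed 100, indicating more than one simultaneous
#' salt bridge.
#'
#' @param traj a [trajectory()].
#' @param targets integer vector of target residue indices (must be
#'   charged under the map).
#' @param window `(t0_ns, t1_ns)` or `NULL` for the whole trajectory.
#' @param map a [criterion_atom_map()].
#' @param prefilter_nm if set, pairs whose minimum distance over the whole
#'   trajectory exceeds this value are omitted from the report (a
#'   reporting filter only; retained pairs' values are unaffected) --
#'   the `gmx saltbr -t` convention.
#' @param sampling_interval_ns frames are subsampled to (multiples of)
#'   this spacing before counting; `NULL` uses every frame in the window.
#' @return object of class `"occupancy_report"`: list with `pairs`
#'   (data.frame residue, partner, occupancy_pct), `per_residue`
#'   (data.frame residue, sum_pct), `window`, `sampling_interval_ns`,
#'   `n_frames`.
#' @export
occupancy <- function(traj, targets, window = NULL,
                      map = criterion_atom_map(), prefilter_nm = NULL,
                      sampling_interval_ns = NULL) {
  top <- traj$topology
  widx <- frames_in_window(traj, window)
  if (length(widx) == 0L) stop("no frames in the requested window")
  times <- frame_times(traj)
  if (!is.null(sampling_interval_ns)) {
    keep <- .subsample_times(times[widx], sampling_interval_ns)
    widx <- widx[keep]
    if (length(widx) == 0L) stop("sampling interval left no frames")
  }
  pairs <- NULL
  for (r in targets) {
    role <- .residue_role(top, r, map)
    if (is.na(role))
      stop("target residue ", r, " (", top$residues$residue_name[r],
           ") is not charged under the criterion map")
    partners <- .role_residues(top,
                               if (role == "positive") "negative"
                               else "positive", map)
    partners <- setdiff(partners, r)
    if (length(partners) > 0)
      pairs <- rbind(pairs, data.frame(residue = r, partner = partners,
                                       role = role))
  }
  if (is.null(pairs)) stop("no chargeable partners found for the targets")
  ai <- mapply(function(r, role) criterion_atom(top, r, role, map),
               pairs$residue, pairs$role)
  aj <- mapply(function(p, role) criterion_atom(
    top, p, if (role == "positive") "negative" else "positive", map),
    pairs$partner, pairs$role)
  dist_all <- .pair_distance_matrix(traj, ai, aj)     # all frames
  occ <- 100 * colMeans(dist_all[widx, , drop = FALSE] < map$cutoff_nm)
  keep <- rep(TRUE, nrow(pairs))
  if (!is.null(prefilter_nm))
    keep <- apply(dist_all, 2, min) <= prefilter_nm
  pair_df <- data.frame(residue = pairs$residue[keep],
                        partner = pairs$partner[keep],
                        occupancy_pct = occ[keep])
  if (nrow(pair_df) > 0) {
    per_res <- stats::aggregate(occupancy_pct ~ residue, pair_df, sum)
    names(per_res)[2] <- "sum_pct"
  } else {
    per_res <- data.frame(residue = integer(0), sum_pct = numeric(0))
  }
  structure(list(pairs = pair_df, per_residue = per_res,
                 window = if (is.null(window)) range(times[widx]) else window,
                 sampling_interval_ns = sampling_interval_ns,
                 n_frames = length(widx)),
            class = "occupancy_report")
}

# indices (into a sorted time vector) at/after multiples of the interval
.subsample_times <- function(times, interval_ns) {
  keep <- logical(length(times))
  next_t <- times[1]
  for (i in seq_along(times)) {
    if (times[i] >= next_t - 1e-9) {
      keep[i] <- TRUE
      next_t <- next_t + interval_ns
    }
  }
  keep
}

#' @export
print.occupancy_report <- function(x, ...) {
  cat("Salt-bridge occupancy (window ", x$window[1], "-", x$window[2],
      " ns, ", x$n_frames, " frames)\n", sep = "")
  print(format(x$pairs, digits = 4), row.names = FALSE)
  cat("per-residue sums:\n")
  print(format(x$per_residue, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Salt-bridge count series for one residue
#'
#' Partitions the trajectory into time bins and reports, per bin, the
#' mean over the bin's frames of the number of distinct partners within
#' the cutoff (the convention of per-residue salt-bridge count
#' trajectories sampled every 0.4 ns).
#'
#' @param traj a [trajectory()].
#' @param residue target residue index (charged under the map).
#' @param bin_ns bin width in ns; must be at least the frame spacing.
#' @param map a [criterion_atom_map()].
#' @return object of class `"count_series"`: data.frame `time_ns` (bin
#'   midpoints), `count` plus attributes `residue` and `mean_count`.
#' @export
count_series <- function(traj, residue, bin_ns = 0.4,
                         map = criterion_atom_map()) {
  top <- traj$topology
  times <- frame_times(traj)
  if (length(times) > 1 && bin_ns < min(diff(times)) - 1e-9)
    stop("bin_ns (", bin_ns, ") is smaller than the frame spacing")
  role <- .residue_role(top, residue, map)
  if (is.na(role)) stop("residue ", residue, " is not charged under the map")
  partners <- setdiff(
    .role_residues(top, if (role == "positive") "negative" else "positive",
                   map), residue)
  ai <- rep(criterion_atom(top, residue, role, map), length(partners))
  aj <- vapply(partners, function(p) criterion_atom(
    top, p, if (role == "positive") "negative" else "positive", map),
    integer(1))
  if (length(partners) == 0L) {
    counts_per_frame <- rep(0, length(times))
  } else {
    d <- .pair_distance_matrix(traj, ai, aj)
    counts_per_frame <- rowSums(d < map$cutoff_nm)
  }
  bin <- floor((times - times[1]) / bin_ns + 1e-9)
  agg <- tapply(counts_per_frame, bin, mean)
  mid <- times[1] + (as.numeric(names(agg)) + 0.5) * bin_ns
  out <- data.frame(time_ns = mid, count = as.numeric(agg))
  attr(out, "residue") <- residue
  attr(out, "mean_count") <- mean(counts_per_frame)
  class(out) <- c("count_series", "data.frame")
  out
}

#' Average reports across subunits
#'
#' Elementwise arithmetic mean of several occupancy reports or count
#' series (e.g. the three subunits of a trimer). Pairs missing from a
#' report are treated as 0 before averaging.
#'
#' @param reports list of `occupancy_report`s or `count_series` with
#'   matching residue numbering (and equal binning for count series).
#' @return an object of the same class as the inputs.
#' @export
aggregate_subunits <- function(reports) {
  if (length(reports) == 0L) stop("no reports to aggregate")
  if (inherits(reports[[1]], "occupancy_report")) {
    keys <- unique(do.call(rbind, lapply(reports, function(r)
      r$pairs[c("residue", "partner")])))
    keys <- keys[order(keys$residue, keys$partner), , drop = FALSE]
    acc <- rep(0, nrow(keys))
    for (r in reports) {
      m <- match(paste(keys$residue, keys$partner),
                 paste(r$pairs$residue, r$pairs$partner))
      v <- ifelse(is.na(m), 0, r$pairs$occupancy_pct[m])
      acc <- acc + v
    }
    pair_df <- data.frame(residue = keys$residue, partner = keys$partner,
                          occupancy_pct = acc / length(reports))
    per_res <- stats::aggregate(occupancy_pct ~ residue, pair_df, sum)
    names(per_res)[2] <- "sum_pct"
    return(structure(list(pairs = pair_df, per_residue = per_res,
                          window = reports[[1]]$window,
                          sampling_interval_ns =
                            reports[[1]]$sampling_interval_ns,
                          n_frames = reports[[1]]$n_frames),
                     class = "occupancy_report"))
  }
  if (inherits(reports[[1]], "count_series")) {
    n <- nrow(reports[[1]])
    same <- vapply(reports, function(r)
      nrow(r) == n && isTRUE(all.equal(r$time_ns, reports[[1]]$time_ns)),
      logical(1))
    if (!all(same)) stop("count series have mismatched time bins")
    cnt <- rowMeans(matrix(vapply(reports, function(r) r$count,
                                  numeric(n)), nrow = n))
    out <- data.frame(time_ns = reports[[1]]$time_ns, count = cnt)
    attr(out, "residue") <- attr(reports[[1]], "residue")
    attr(out, "mean_count") <- mean(vapply(reports, attr, numeric(1),
                                           "mean_count"))
    class(out) <- c("count_series", "data.frame")
    return(out)
  }
  stop("unsupported report type: ", class(reports[[1]])[1])
}

#' Tidy an occupancy report into a flat table
#' @param x an `occupancy_report`.
#' @return data.frame `residue`, `partner`, `occupancy_pct`.
#' @export
as.data.frame.occupancy_report <- function(x, ...) x$pairs
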