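## End-to-end orchestration: per-subunit geometry -> salt bridges -> SASA
## -> secondary structure, window selection, aggregation across subunits
## sharing a variant label, and report tables.

#' Analysis configuration
#'
#' @param inputs data.frame with columns `label` (variant label; inputs
#'   sharing a label are averaged as subunits), `topology` (path),
#'   `trajectory` (path) and optionally `format`
#'   (`"multi_model_pdb"`/`"gro_sequence"`). Alternatively a list of
#'   ready-made [trajectory()] objects named by label.
#' @param windows named list of `(t0_ns, t1_ns)` windows. Defaults follow
#'   the study design: `native` 50--400 ns (300 K run), `denatured`
#'   400--1400 ns (400/450 K runs), `late` 1000--1400 ns, `helix_window`
#'   1200--1400 ns. Windows are clipped to the available time span with
#'   a warning when a run is shorter.
#' @param target_residues residues for the occupancy/count reports.
#' @param cutoff_nm salt-bridge cutoff (0.6).
#' @param prefilter_nm occupancy reporting prefilter (`gmx saltbr -t`
#'   convention); `NULL` disables it.
#' @param probe_nm,n_points SASA parameters.
#' @param bin_ns count-series bin width.
#' @param seed integer seed echoed into reports.
#' @return object of class `"analysis_config"`.
#' @export
analysis_config <- function(inputs,
                            windows = list(native = c(50, 400),
                                           denatured = c(400, 1400),
                                           late = c(1000, 1400),
                                           helix_window = c(1200, 1400)),
                            target_residues = NULL,
                            cutoff_nm = 0.6, prefilter_nm = NULL,
                            probe_nm = 0.14, n_points = 960L,
                            bin_ns = 0.4, seed = 1L) {
  for (w in windows)
    if (length(w) != 2 || w[1] < 0 || w[1] >= w[2])
      stop("each window must be (t0, t1) with 0 <= t0 < t1")
  structure(list(inputs = inputs, windows = windows,
                 target_residues = target_residues,
                 cutoff_nm = cutoff_nm, prefilter_nm = prefilter_nm,
                 probe_nm = probe_nm, n_points = as.integer(n_points),
                 bin_ns = bin_ns, seed = as.integer(seed)),
            class = "analysis_config")
}

.clip_window <- function(window, times, what) {
  w <- c(max(window[1], times[1]), min(window[2], times[length(times)]))
  if (w[1] > window[1] || w[2] < window[2])
    warning(sprintf("window %s clipped to %g-%g ns (run spans %g-%g ns)",
                    what, w[1], w[2], times[1], times[length(times)]))
  if (w[1] >= w[2]) NULL else w
}

.load_inputs <- function(inputs) {
  if (is.list(inputs) && !is.data.frame(inputs)) {
    if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
      stop("in-memory inputs must be a named list of trajectories")
    return(mapply(function(tr, lb) list(label = lb, traj = tr),
                  inputs, names(inputs), SIMPLIFY = FALSE))
  }
  inputs <- as.data.frame(inputs)
  lapply(seq_len(nrow(inputs)), function(i) {
    fmt <- if ("format" %in% names(inputs)) inputs$format[i]
           else "multi_model_pdb"
    top <- read_topology(inputs$topology[i])
    list(label = inputs$label[i],
         traj = read_trajectory(top, inputs$trajectory[i], fmt))
  })
}

#' Run the full denatured-ensemble analysis
#'
#' Per input: C-alpha RMSD and Rg series, salt-bridge occupancy (in the
#' `denatured` window) and count series, windowed ASA summaries
#' (`native` and `denatured`), secondary-structure window counts and the
#' helicity profile (`helix_window`). Inputs sharing a label are averaged
#' as subunits in the occupancy and count reports. Deterministic given
#' the config.
#'
#' @param config an [analysis_config()].
#' @return object of class `"run_report"`: list with per-input `series`
#'   (rmsd, rg), `occupancy` (per label), `counts` (per label x residue),
#'   `asa` (per input), `hp_energy` (per label, when both windows are
#'   available), `secstruct` (per input), `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  items <- .load_inputs(config$inputs)
  map <- criterion_atom_map(cutoff_nm = config$cutoff_nm)
  stage <- function(what, label, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", what, "' failed for input '", label, "': ",
           conditionMessage(e), call. = FALSE))
  }
  series <- list(); occ <- list(); cnt <- list(); asa <- list()
  ss <- list(); labels <- vapply(items, `[[`, character(1), "label")
  for (i in seq_along(items)) {
    it <- items[[i]]; tr <- it$traj; lb <- it$label
    times <- frame_times(tr)
    w_nat <- .clip_window(config$windows$native, times, "native")
    w_den <- .clip_window(config$windows$denatured, times, "denatured")
    w_hel <- .clip_window(config$windows$helix_window, times,
                          "helix_window")
    series[[i]] <- stage("geometry", lb, list(
      rmsd = rmsd_series(tr),
      rg = rg_series(tr)))
    targets <- config$target_residues
    if (is.null(targets))
      targets <- which(!is.na(vapply(seq_len(tr$topology$n_residues),
                                     function(r) .residue_role(tr$topology,
                                                               r, map),
                                     character(1))))
    occ[[i]] <- stage("saltbridge", lb,
      occupancy(tr, targets, window = w_den, map = map,
                prefilter_nm = config$prefilter_nm))
    cnt[[i]] <- stage("saltbridge", lb, lapply(targets, function(r)
      count_series(tr, r, bin_ns = config$bin_ns, map = map)))
    names(cnt[[i]]) <- as.character(targets)
    asa_s <- stage("sasa", lb,
      asa_series(tr, probe_nm = config$probe_nm,
                 n_points = config$n_points))
    asa[[i]] <- list(
      native = if (!is.null(w_nat)) window_summary(asa_s, w_nat) else NULL,
      denatured = if (!is.null(w_den)) window_summary(asa_s, w_den)
                  else NULL)
    ss_s <- stage("secstruct", lb, secstruct_series(tr))
    ss[[i]] <- list(
      counts = if (!is.null(w_den)) window_counts(ss_s, w_den) else NULL,
      helicity = if (!is.null(w_hel)) helicity_profile(ss_s, w_hel)
                 else NULL)
  }
  # aggregate subunits per label
  occ_by_label <- lapply(split(occ, labels), aggregate_subunits)
  cnt_by_label <- lapply(split(cnt, labels), function(lst) {
    res <- names(lst[[1]])
    out <- lapply(res, function(r)
      aggregate_subunits(lapply(lst, `[[`, r)))
    names(out) <- res
    out
  })
  hp <- lapply(split(asa, labels), function(lst) {
    ok <- vapply(lst, function(a)
      !is.null(a$native) && !is.null(a$denatured), logical(1))
    if (!any(ok)) return(NULL)
    lst <- lst[ok]
    d <- rowMeans(vapply(lst, function(a)
      delta_asa(a$native, a$denatured), numeric(2)))
    hydrophobic_energy(d[["delta_nonpolar_nm2"]], d[["delta_polar_nm2"]])
  })
  structure(list(series = stats::setNames(series, labels),
                 occupancy = occ_by_label,
                 counts = cnt_by_label,
                 asa = stats::setNames(asa, labels),
                 hp_energy = hp,
                 secstruct = stats::setNames(ss, labels),
                 provenance = list(
                   n_inputs = length(items),
                   labels = labels,
                   windows = config$windows,
                   cutoff_nm = config$cutoff_nm,
                   probe_nm = config$probe_nm,
                   n_points = config$n_points,
                   seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("denatens")))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("denatens run report:", x$provenance$n_inputs, "input(s),",
      length(x$occupancy), "label(s)\n")
  for (lb in names(x$occupancy)) {
    cat("-- ", lb, ": per-residue occupancy sums (%)\n", sep = "")
    print(format(x$occupancy[[lb]]$per_residue, digits = 4),
          row.names = FALSE)
  }
  invisible(x)
}

#' Hydrophobic energies from ensemble-average ASA tables
#'
#' Reproduces the hydrophobic-energy bookkeeping end to end from tabular
#' input: each table carries per-variant class means (one row per variant
#' and class), the per-class differences (denatured minus native) feed
#' the energy equation, and pairwise variant differences are tabulated
#' against the given baselines.
#'
#' @param native_table,denatured_table data.frames with columns `label`,
#'   `class` (`"hydrophobic"`/`"hydrophilic"`), `mean_nm2`.
#' @param baselines labels to difference against (optional).
#' @return list with `energies` (data.frame `label`,
#'   `delta_nonpolar_nm2`, `delta_polar_nm2`, `dg_hp_kj_mol`) and
#'   `differences` (from [energy_differences()], or NULL).
#' @export
hpenergy_from_tables <- function(native_table, denatured_table,
                                 baselines = NULL) {
  need <- c("label", "class", "mean_nm2")
  for (tb in list(native_table, denatured_table))
    if (!all(need %in% names(tb)))
      stop("tables need columns: ", paste(need, collapse = ", "))
  get_mean <- function(tb, lb, cls) {
    v <- tb$mean_nm2[tb$label == lb & tb$class == cls]
    if (length(v) != 1L)
      stop("missing or duplicated ", cls, " entry for variant '", lb, "'")
    v
  }
  labs <- unique(native_table$label)
  if (!setequal(labs, unique(denatured_table$label)))
    stop("native and denatured tables list different variants")
  res <- lapply(labs, function(lb) {
    dn <- get_mean(denatured_table, lb, "hydrophobic") -
          get_mean(native_table, lb, "hydrophobic")
    dp <- get_mean(denatured_table, lb, "hydrophilic") -
          get_mean(native_table, lb, "hydrophilic")
    hydrophobic_energy(dn, dp)
  })
  names(res) <- labs
  energies <- data.frame(
    label = labs,
    delta_nonpolar_nm2 = vapply(res, `[[`, numeric(1),
                                "delta_asa_nonpolar_nm2"),
    delta_polar_nm2 = vapply(res, `[[`, numeric(1), "delta_asa_polar_nm2"),
    dg_hp_kj_mol = vapply(res, `[[`, numeric(1), "delta_g_hp_kj_mol"),
    row.names = NULL)
  diffs <- if (!is.null(baselines)) energy_differences(res, baselines)
           else NULL
  list(energies = energies, differences = diffs)
}

#' Reference ensemble-average ASA table for the CutA1 variants
#'
#' Loads the published ensemble-average ASA table for the three CutA1
#' variants (Ec0SH, Ec0VV, Ec0VV_6): class-partitioned means at 300 K
#' (native window, 50--400 ns) and 400/450 K (denatured window,
#' 400--1400 ns), in nm^2, shipped as plain CSV in `inst/extdata`.
#'
#' @return data.frame `label`, `temperature_k`, `class`, `mean_nm2`,
#'   `sd_nm2`.
#' @export
cuta1_asa_table <- function() {
  path <- system.file("extdata", "cuta1_asa_means.csv",
                      package = "denatens", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
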