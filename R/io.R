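## Trajectory and table I/O: PDB (single and multi-MODEL), GRO, CSV/TSV/JSON.
## PDB reading goes through bio3d; GRO is parsed here (fixed-width GROMACS
## dialect); coordinates are stored in nm internally (PDB Angstrom / 10).

.three_to_one_ok <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS",
                      "ILE","LEU","LYS","MET","PHE","PRO","SER","THR","TRP",
                      "TYR","VAL")

.topology_from_bio3d <- function(pdb) {
  at <- pdb$atom
  # keep altloc 'A' or blank only
  keep <- is.na(at$alt) | at$alt %in% c("", " ", "A")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms after altloc filtering")
  # residue boundaries by (chain, resno, insert)
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  ridx <- match(key, unique(key))
  el <- at$elesy
  miss <- is.na(el) | trimws(el) == ""
  if (any(miss)) el[miss] <- infer_element(at$elety[miss])
  el <- toupper(trimws(el))
  el[!el %in% .known_elements] <- "other"
  rn <- toupper(at$resid[match(unique(ridx), ridx)])
  unk <- setdiff(rn, .three_to_one_ok)
  if (length(unk) > 0)
    warning("unknown residue(s) kept with inferred elements: ",
            paste(unk, collapse = ", "))
  topology(atom_name = trimws(at$elety), element = el,
           residue_index = ridx, residue_name = rn,
           serial = at$eleno,
           chain_id = if (all(is.na(at$chain))) "A" else at$chain[1])
}

.read_gro_lines <- function(lines) {
  # One GRO frame: title, atom count, atom lines, box line.
  if (length(lines) < 3L) stop("GRO frame truncated")
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat)) stop("GRO parse error at line 2: bad atom count '",
                       trimws(lines[2]), "'")
  if (length(lines) < 2L + nat + 1L)
    stop("GRO frame truncated: expected ", nat, " atom lines")
  al <- lines[3:(2 + nat)]
  resno <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resnm <- toupper(trimws(substr(al, 6, 10)))
  atnm <- trimws(substr(al, 11, 15))
  serial <- suppressWarnings(as.integer(substr(al, 16, 20)))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0)
    stop("GRO parse error at line ", bad[1] + 2L, ": '", al[bad[1]], "'")
  list(resno = resno, resnm = resnm, atnm = atnm, serial = serial,
       coords = cbind(x, y, z), title = lines[1],
       n_lines = 2L + nat + 1L)
}

.gro_time_ns <- function(title) {
  # GROMACS writes "... t=  123.00000" in ps on the title line.
  m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  if (length(m) == 0) return(NA_real_)
  as.numeric(sub("t=\\s*", "", m)) / 1000
}

#' Read a topology from a PDB or GRO file
#'
#' Elements are taken from PDB columns 77--78 when present, otherwise
#' inferred from the atom name. Hydrogens are retained (flagged by
#' element "H"). Alternate locations other than 'A'/blank are dropped.
#'
#' @param path file path.
#' @param format `"pdb"` or `"gro"`; default guessed from the extension.
#' @return a [topology()].
#' @export
#' @examples
#' \dontrun{top <- read_topology("model.pdb")}
read_topology <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") {
    pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                    error = function(e) stop("PDB parse error in ", path,
                                             ": ", conditionMessage(e)))
    return(.topology_from_bio3d(pdb))
  }
  lines <- .read_text_lines(path)
  if (length(lines) < 3L) stop("GRO parse error: file too short (",
                               length(lines), " lines)")
  fr <- .read_gro_lines(lines)
  ridx <- match(fr$resno, unique(fr$resno))
  rn <- fr$resnm[match(unique(ridx), ridx)]
  unk <- setdiff(rn, .three_to_one_ok)
  if (length(unk) > 0)
    warning("unknown residue(s) kept with inferred elements: ",
            paste(unk, collapse = ", "))
  topology(atom_name = fr$atnm, residue_index = ridx, residue_name = rn,
           serial = fr$serial, chain_id = "A")
}

.read_text_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sub("\r$", "", lines)  # tolerate CRLF
}

#' Read a coordinate trajectory
#'
#' Frames are checked against the topology atom count and must be
#' time-ordered. Times come from file metadata when present (GRO title
#' `t=` fields, in ps); otherwise they are synthesized as
#' `(frame - 1) * stride_ns`.
#'
#' @param topology a [topology()] the frames must match.
#' @param path file path.
#' @param format `"multi_model_pdb"`, `"gro_sequence"` (concatenated GRO
#'   frames), or `"xtc"` (not supported; raises an error).
#' @param stride_ns time step used when the file carries no times.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(topology, path,
                            format = c("multi_model_pdb", "gro_sequence",
                                       "xtc"),
                            stride_ns = 0.4) {
  format <- match.arg(format)
  if (format == "xtc")
    stop("XTC reading is not supported; convert to multi-model PDB or a ",
         "GRO sequence (e.g. 'gmx trjconv -o traj.gro')")
  nat <- nrow(topology$atoms)
  if (format == "multi_model_pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    if (ncol(xyz) != 3L * nat)
      stop("atom-count mismatch: trajectory has ", ncol(xyz) / 3,
           " atoms per frame, topology has ", nat)
    frames <- lapply(seq_len(nrow(xyz)), function(i) {
      co <- matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10  # Angstrom -> nm
      frame(co, time_ns = (i - 1) * stride_ns)
    })
    return(trajectory(topology, frames))
  }
  # gro_sequence
  lines <- .read_text_lines(path)
  frames <- list(); pos <- 1L; i <- 0L
  while (pos + 2L <= length(lines) && any(nzchar(lines[pos:length(lines)]))) {
    fr <- .read_gro_lines(lines[pos:length(lines)])
    if (nrow(fr$coords) != nat)
      stop("atom-count mismatch in frame ", i + 1L, ": ", nrow(fr$coords),
           " atoms, topology has ", nat)
    i <- i + 1L
    t_ns <- .gro_time_ns(fr$title)
    if (is.na(t_ns)) t_ns <- (i - 1) * stride_ns
    frames[[i]] <- frame(fr$coords, time_ns = t_ns)
    pos <- pos + fr$n_lines
    while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  if (length(frames) == 0L) stop("no frames found in ", path)
  times <- vapply(frames, `[[`, numeric(1), "time_ns")
  if (any(diff(times) <= 0)) stop("non-monotonic frame times in ", path)
  trajectory(topology, frames)
}

.pdb_atom_line <- function(serial, name, resname, chain, resno, xyz_A, element) {
  nm <- ifelse(nchar(name) < 4, sprintf(" %-3s", name), sprintf("%-4s", name))
  sprintf("ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nm, resname, chain, resno %% 10000L,
          xyz_A[1], xyz_A[2], xyz_A[3], 1, 0,
          ifelse(element == "other", "", element))
}

#' Write a trajectory to multi-model PDB or a GRO sequence
#'
#' Coordinates are written at the format's native precision (0.001 nm);
#' GRO frames carry the time on the title line (`t=` in ps).
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @param format `"multi_model_pdb"` or `"gro_sequence"`.
#' @export
write_trajectory <- function(traj, path,
                             format = c("multi_model_pdb", "gro_sequence")) {
  format <- match.arg(format)
  top <- traj$topology
  at <- top$atoms
  resname <- top$residues$residue_name[at$residue_index]
  out <- character(0)
  if (format == "multi_model_pdb") {
    for (i in seq_along(traj$frames)) {
      f <- traj$frames[[i]]
      out <- c(out, sprintf("MODEL     %4d", i),
               vapply(seq_len(nrow(at)), function(j)
                 .pdb_atom_line(at$serial[j], at$atom_name[j], resname[j],
                                top$chain_id, at$residue_index[j],
                                f$coords[j, ] * 10, at$element[j]),
                 character(1)),
               "ENDMDL")
    }
    out <- c(out, "END")
  } else {
    for (i in seq_along(traj$frames)) {
      f <- traj$frames[[i]]
      head <- sprintf("frame %d t= %.5f", i, f$time_ns * 1000)
      body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                      at$residue_index %% 100000L, resname,
                      formatC(at$atom_name, width = 5),
                      at$serial %% 100000L,
                      f$coords[, 1], f$coords[, 2], f$coords[, 3])
      out <- c(out, head, sprintf("%5d", nrow(at)), body,
               "   10.00000   10.00000   10.00000")
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Write an analysis table to CSV, TSV or JSON
#'
#' Column order is preserved as given; numeric columns are written at a
#' fixed precision so reports are byte-stable.
#'
#' @param report a non-empty data.frame.
#' @param path output path.
#' @param format `"csv"`, `"tsv"` or `"json"`.
#' @param digits decimal digits for numeric columns.
#' @export
write_table <- function(report, path, format = c("csv", "tsv", "json"),
                        digits = 6) {
  format <- match.arg(format)
  report <- as.data.frame(report)
  if (nrow(report) == 0L) stop("refusing to write an empty report")
  num <- vapply(report, is.numeric, logical(1))
  fmt <- report
  fmt[num] <- lapply(report[num], function(x) round(x, digits))
  if (format == "json") {
    jsonlite::write_json(fmt, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    sep <- if (format == "csv") "," else "\t"
    utils::write.table(fmt, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
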