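## Ideal-geometry chain construction. Atoms are placed sequentially from
## internal coordinates (bond, angle, torsion) -- the standard NeRF scheme.
## Bond lengths/angles are Engh-Huber-style ideal values; coordinates are
## built in Angstrom and stored in nm.

# place point d given a-b-c, |cd| = bond, angle(b,c,d), torsion(a,b,c,d) (deg)
.place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# side-chain carbon path (beyond CB) needed for each charged residue's
# criterion atom; all other residues get backbone only
.sidechain_path <- list(
  LYS = c("CB", "CG", "CD", "CE"),
  ARG = c("CB", "CG", "CD"),
  GLU = c("CB", "CG", "CD"),
  ASP = c("CB", "CG")
)

#' Build an ideal-geometry peptide chain
#'
#' Places backbone atoms (N, CA, C, O and amide H) plus the side-chain
#' carbon path up to each charged residue's salt-bridge criterion atom
#' (CE for Lys; CD for Arg and Glu; CG for Asp) with ideal bond geometry.
#' `ideal_helix` uses phi = -57, psi = -47 degrees; `extended` uses
#' phi = -139, psi = 135; `coil` draws backbone dihedrals uniformly from
#' the broad beta/alpha region under the given seed.
#'
#' @param sequence character vector of 3-letter residue codes.
#' @param conformation `"ideal_helix"`, `"extended"` or `"coil"`.
#' @param seed integer seed (used by `"coil"` only; construction is
#'   otherwise deterministic).
#' @return list with elements `topology` and `frame`.
#' @export
#' @examples
#' ch <- build_chain(rep("ALA", 12), "ideal_helix")
#' ch$topology
build_chain <- function(sequence,
                        conformation = c("ideal_helix", "extended", "coil"),
                        seed = 1L) {
  conformation <- match.arg(conformation)
  sequence <- toupper(as.character(sequence))
  if (length(sequence) == 0L) stop("sequence must be non-empty")
  unk <- setdiff(sequence, .three_to_one_ok)
  if (length(unk) > 0)
    stop("unknown residue code(s): ", paste(unique(unk), collapse = ", "))
  n <- length(sequence)
  phi_psi <- switch(conformation,
    ideal_helix = cbind(rep(-57, n), rep(-47, n)),
    extended = cbind(rep(-139, n), rep(135, n)),
    coil = {
      old <- .restore_seed(seed)
      on.exit(old())
      cbind(stats::runif(n, -150, -60), stats::runif(n, -60, 160))
    })
  .build_chain_phipsi(sequence, phi_psi)
}

# core builder: per-residue (phi, psi) in degrees, one row per residue
.build_chain_phipsi <- function(sequence, phi_psi) {
  n <- length(sequence)
  names_out <- character(0); el_out <- character(0)
  ridx_out <- integer(0); coords <- NULL
  add <- function(nm, res_i, xyz, el = NULL) {
    names_out <<- c(names_out, nm)
    el_out <<- c(el_out, if (is.null(el)) infer_element(nm) else el)
    ridx_out <<- c(ridx_out, res_i)
    coords <<- rbind(coords, xyz)
  }

  # seed first three backbone atoms
  b <- list()  # per-residue backbone positions N, CA, C
  N1 <- c(0, 0, 0)
  CA1 <- c(1.458, 0, 0)
  C1 <- .place_atom(c(0, 1, 0), N1, CA1, 1.525, 111.2, phi_psi[1, 1])
  b[[1]] <- list(N = N1, CA = CA1, C = C1)
  if (n > 1) {
    for (i in 2:n) {
      p <- b[[i - 1]]
      Ni <- .place_atom(p$N, p$CA, p$C, 1.329, 116.2, phi_psi[i - 1, 2])
      CAi <- .place_atom(p$CA, p$C, Ni, 1.458, 121.7, 180)
      Ci <- .place_atom(p$C, Ni, CAi, 1.525, 111.2, phi_psi[i, 1])
      b[[i]] <- list(N = Ni, CA = CAi, C = Ci)
    }
  }
  for (i in seq_len(n)) {
    p <- b[[i]]
    add("N", i, p$N)
    # amide hydrogen: in-plane bisector of C(i-1)-N and CA-N, 1.00 A
    if (i == 1) {
      H <- p$N + 1.0 * (p$N - p$CA) / sqrt(sum((p$N - p$CA)^2))
    } else {
      u1 <- p$N - b[[i - 1]]$C; u1 <- u1 / sqrt(sum(u1^2))
      u2 <- p$N - p$CA; u2 <- u2 / sqrt(sum(u2^2))
      hdir <- u1 + u2; hdir <- hdir / sqrt(sum(hdir^2))
      H <- p$N + 1.0 * hdir
    }
    add("H", i, H)
    add("CA", i, p$CA)
    # carbonyl: O anti to the next N (torsion psi + 180 about CA-C)
    O <- .place_atom(p$N, p$CA, p$C, 1.231, 120.5, phi_psi[i, 2] + 180)
    sc <- .sidechain_path[[sequence[i]]]
    if (!is.null(sc)) {
      CB <- .place_atom(p$C, p$N, p$CA, 1.53, 110.5, 122.5)
      add("CB", i, CB)
      prev3 <- list(p$N, p$CA, CB)
      for (k in seq_along(sc)[-1]) {
        nxt <- .place_atom(prev3[[1]], prev3[[2]], prev3[[3]],
                           1.52, 112.0, 180)
        add(sc[k], i, nxt)
        prev3 <- list(prev3[[2]], prev3[[3]], nxt)
      }
    }
    add("C", i, p$C)
    add("O", i, O)
  }
  top <- topology(atom_name = names_out, element = el_out,
                  residue_index = ridx_out, residue_name = sequence)
  list(topology = top, frame = frame(coords / 10, time_ns = 0))
}

# run code under a local RNG state, restoring the caller's afterwards
.restore_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Build a two-strand antiparallel beta-sheet fixture
#'
#' Constructs one extended strand, then places a second, antiparallel
#' copy alongside it, choosing the inter-strand offset by a deterministic
#' grid search that maximizes the number of Kabsch-Sander backbone
#' hydrogen bonds between the strands. The two strands are returned as a
#' single 2n-residue topology (sequence positions n and n+1 are spatially
#' far apart; assignment operates on geometry only).
#'
#' @param n_per_strand residues per strand.
#' @return list with `topology` and `frame`.
#' @export
build_sheet <- function(n_per_strand = 8) {
  ch <- build_chain(rep("ALA", n_per_strand), "extended")
  co <- ch$frame$coords  # nm
  nat <- nrow(co)
  # strand axis: CA(1) -> CA(n); align to x for a clean search space
  ca <- which(ch$topology$atoms$atom_name == "CA")
  axis <- co[ca[length(ca)], ] - co[ca[1], ]
  axis <- axis / sqrt(sum(axis^2))
  # rotation taking axis -> +x
  rot_to_x <- .rotation_between(axis, c(1, 0, 0))
  co <- co %*% t(rot_to_x)
  # antiparallel copy: rotate 180 deg about y so it runs along -x, offset in y
  flip <- diag(c(-1, 1, -1))
  best <- NULL
  top2 <- topology(
    atom_name = rep(ch$topology$atoms$atom_name, 2),
    element = rep(ch$topology$atoms$element, 2),
    residue_index = c(ch$topology$atoms$residue_index,
                      ch$topology$atoms$residue_index + n_per_strand),
    residue_name = rep("ALA", 2 * n_per_strand))
  for (dy in seq(0.42, 0.56, by = 0.01)) {
    for (dx in seq(-0.5, 0.5, by = 0.025)) {
      co2 <- co %*% t(flip)
      co2[, 1] <- co2[, 1] + dx + (max(co[, 1]) + min(co[, 1]))
      co2[, 2] <- co2[, 2] + dy
      fr <- frame(rbind(co, co2))
      hb <- .ks_hbond_matrix(fr, top2)
      # count inter-strand bonds only
      nb <- sum(hb$bond[seq_len(n_per_strand),
                        n_per_strand + seq_len(n_per_strand)]) +
            sum(hb$bond[n_per_strand + seq_len(n_per_strand),
                        seq_len(n_per_strand)])
      if (is.null(best) || nb > best$nb)
        best <- list(nb = nb, fr = fr)
    }
  }
  list(topology = top2, frame = best$fr, n_interstrand_hbonds = best$nb)
}

# minimal rotation taking unit vector u onto unit vector v
.rotation_between <- function(u, v) {
  w <- .cross3(u, v)
  s <- sqrt(sum(w^2)); cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite: rotate pi about any perpendicular axis
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- .cross3(u, p); w <- w / sqrt(sum(w^2))
    return(2 * outer(w, w) - diag(3))
  }
  wx <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + wx + wx %*% wx * ((1 - cth) / s^2)
}
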