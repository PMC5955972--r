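# Shared fixtures, built in code at test time.

# Ala-Glu-Lys toy peptide: topology + one extended frame
toy_peptide <- function() build_chain(c("ALA", "GLU", "LYS"), "extended")

# a short 3-frame trajectory of the toy peptide (rigid shifts)
toy_trajectory <- function() {
  ch <- toy_peptide()
  trajectory(ch$topology, list(
    ch$frame,
    frame(ch$frame$coords + 0.1, time_ns = 1),
    frame(ch$frame$coords + 0.25, time_ns = 2)))
}

# 12-residue chain with three donor/acceptor pairs for contact synthesis
contact_sequence <- function() {
  s <- rep("ALA", 12)
  s[c(1, 5, 9)] <- c("LYS", "ARG", "LYS")
  s[c(3, 7, 11)] <- c("GLU", "ASP", "GLU")
  s
}

contact_spec <- function(occ = c(0.9, 0.6, 0.3), n_frames = 500, seed = 1) {
  ensemble_spec(contact_sequence(),
                pair_targets = data.frame(donor = c(1, 5, 9),
                                          acceptor = c(3, 7, 11),
                                          occupancy = occ),
                n_frames = n_frames, seed = seed)
}

# minimal n-atom all-carbon topology (one residue per atom)
carbon_topology <- function(n) {
  topology(rep("CA", n), element = rep("C", n), residue_index = seq_len(n),
           residue_name = rep("ALA", n))
}

# rigid transform: rotation about an axis + translation
rigid_transform <- function(coords, angle = 0.7, axis = c(0, 0, 1),
                            shift = c(1, -2, 3)) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + s_ * K + (1 - c_) * K %*% K
  sweep(coords %*% t(R), 2, shift, "+")
}

# independent RMSD oracle: numeric minimization over Euler angles from
# several deterministic starts (never calls superpose)
oracle_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  euler_rot <- function(p) {
    ca <- cos(p[1]); sa <- sin(p[1])
    cb <- cos(p[2]); sb <- sin(p[2])
    cg <- cos(p[3]); sg <- sin(p[3])
    Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
    Rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  f <- function(p) sqrt(mean(rowSums((A %*% t(euler_rot(p)) - B)^2)))
  starts <- as.matrix(expand.grid(a = seq(0, 2 * pi, length.out = 5)[-5],
                                  b = seq(0, pi, length.out = 4),
                                  g = seq(0, 2 * pi, length.out = 5)[-5]))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    r <- stats::optim(starts[i, ], f, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (r$value < best) best <- r$value
  }
  best
}

# exact two-sphere Shrake-Rupley oracle: spherical-cap closed form for the
# accessible area of sphere (cA, RA) occluded by sphere (cB, RB)
cap_asa <- function(RA, RB, d) {
  if (d >= RA + RB) return(4 * pi * RA^2)
  if (d + RA <= RB) return(0)
  # height of the cap of sphere A lying inside B
  h <- RA - (d^2 + RA^2 - RB^2) / (2 * d)
  4 * pi * RA^2 - 2 * pi * RA * h
}
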