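test_that("isolated and fully buried atoms hit their closed forms", {
  t1 <- topology("C", residue_index = 1, residue_name = "ALA")
  s <- shrake_rupley(frame(matrix(0, 1, 3)), t1)
  expect_equal(s$class_totals[["hydrophobic"]], 4 * pi * 0.31^2,
               tolerance = 5e-3)  # exact for the lattice, 0.5% contract
  expect_equal(s$per_atom_asa_nm2[1], 4 * pi * 0.31^2, tolerance = 1e-12)

  # atom at the center of a tight cage of 26 large atoms -> ASA 0
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  co <- rbind(c(0, 0, 0), dirs * 0.25)
  tc <- topology(c("C", rep("S", 26)), residue_index = rep(1, 27),
                 residue_name = "CYS")
  s2 <- shrake_rupley(frame(co), tc)
  expect_equal(s2$per_atom_asa_nm2[1], 0)

  expect_error(
    shrake_rupley(frame(matrix(0, 1, 3)),
                  topology("X1", element = "other", residue_index = 1,
                           residue_name = "ALA")),
    "radius")
})

test_that("dimer ASA matches the spherical-cap closed form and MC oracle", {
  rC <- 0.170; probe <- 0.14; R <- rC + probe
  tt <- topology(c("C", "C"), residue_index = c(1, 2),
                 residue_name = c("ALA", "ALA"))
  set.seed(99)
  mc_points <- matrix(rnorm(3e5), 1e5, 3)
  mc_points <- mc_points / sqrt(rowSums(mc_points^2))
  for (d in c(0.25, 0.40, 0.55)) {
    fr <- frame(rbind(c(0, 0, 0), c(d, 0, 0)))
    s <- shrake_rupley(fr, tt)
    exact <- cap_asa(R, R, d)
    expect_equal(s$per_atom_asa_nm2[1], exact, tolerance = 0.01)
    expect_equal(s$per_atom_asa_nm2[2], exact, tolerance = 0.01)
    # independent Monte-Carlo surface-point oracle
    p <- mc_points * R
    frac <- mean((p[, 1] - d)^2 + p[, 2]^2 + p[, 3]^2 >= R^2)
    expect_equal(s$per_atom_asa_nm2[1], 4 * pi * R^2 * frac,
                 tolerance = 0.01)
  }
})

test_that("lattice refinement converges within 1% on dimers", {
  tt <- topology(c("C", "O"), residue_index = c(1, 2),
                 residue_name = c("ALA", "ALA"))
  fr <- frame(rbind(c(0, 0, 0), c(0.3, 0, 0)))
  a960 <- shrake_rupley(fr, tt, n_points = 960L)$per_atom_asa_nm2
  a3840 <- shrake_rupley(fr, tt, n_points = 3840L)$per_atom_asa_nm2
  expect_true(all(abs(a960 - a3840) / a3840 <= 0.01))
})

test_that("removing an occluder never decreases any other atom's ASA", {
  ch <- build_chain(c("LYS", "GLU", "ASP"), "extended")
  full <- shrake_rupley(ch$frame, ch$topology)
  heavy <- which(ch$topology$atoms$element != "H")
  drop <- heavy[5]
  keep <- setdiff(seq_len(nrow(ch$topology$atoms)), drop)
  top2 <- topology(ch$topology$atoms$atom_name[keep],
                   element = ch$topology$atoms$element[keep],
                   residue_index = ch$topology$atoms$residue_index[keep],
                   residue_name = ch$topology$residues$residue_name)
  s2 <- shrake_rupley(frame(ch$frame$coords[keep, , drop = FALSE]), top2)
  old <- full$per_atom_asa_nm2[keep]
  expect_true(all(s2$per_atom_asa_nm2 >= old - 1e-12, na.rm = TRUE))
})

test_that("class totals partition heavy-atom ASA and ignore hydrogens", {
  ch <- build_chain(c("LYS", "GLU"), "ideal_helix")
  s <- shrake_rupley(ch$frame, ch$topology)
  heavy <- ch$topology$atoms$element != "H"
  expect_true(all(is.na(s$per_atom_asa_nm2[!heavy])))
  expect_equal(sum(s$class_totals),
               sum(s$per_atom_asa_nm2[heavy]), tolerance = 1e-9)
  cls <- ch$topology$atoms$element[heavy]
  expect_equal(s$class_totals[["hydrophobic"]],
               sum(s$per_atom_asa_nm2[heavy][cls %in% c("C", "S")]),
               tolerance = 1e-9)
})

test_that("ASA is rigid-invariant at the lattice's resolution", {
  # the point lattice is fixed in space, so rotation invariance is only
  # approximate; at 960 points the class totals move by well under the
  # 1% convergence contract
  ch <- build_chain(c("ALA", "GLU", "LYS"), "ideal_helix")
  s1 <- shrake_rupley(ch$frame, ch$topology)
  s2 <- shrake_rupley(frame(rigid_transform(ch$frame$coords)),
                      ch$topology)
  rel <- abs(s1$class_totals - s2$class_totals) / s1$class_totals
  expect_true(all(rel[1:2] <= 0.01))
  # pure translation is exact
  s3 <- shrake_rupley(frame(ch$frame$coords + 3.7), ch$topology)
  expect_equal(s1$class_totals, s3$class_totals, tolerance = 1e-9)
})

test_that("window summaries report the ensemble mean and population SD", {
  mk <- function(hp, hl, t) structure(
    list(per_atom_asa_nm2 = NA,
         class_totals = c(hydrophobic = hp, hydrophilic = hl, other = 0),
         time_ns = t), class = "asa_frame")
  series <- list(mk(10, 5, 0), mk(20, 5, 1))
  ws <- window_summary(series)
  expect_equal(ws$mean_hydrophobic_nm2, 15)
  expect_equal(ws$sd_hydrophobic_nm2, 5)    # population SD
  expect_equal(ws$sd_hydrophilic_nm2, 0)
  expect_error(window_summary(series, c(10, 20)), "at least 2")

  set.seed(6)
  vals <- rnorm(100, 30, 4)
  series2 <- lapply(seq_along(vals), function(i)
    mk(vals[i], 20, i - 1))
  ws2 <- window_summary(series2)
  expect_equal(ws2$mean_hydrophobic_nm2, mean(vals), tolerance = 1e-12)
  expect_equal(ws2$sd_hydrophobic_nm2,
               sqrt(mean((vals - mean(vals))^2)), tolerance = 1e-12)
})

test_that("delta_asa reproduces the published CutA1 bookkeeping", {
  tab <- cuta1_asa_table()
  get <- function(lb, temp, cls)
    list(mean_hydrophobic_nm2 = tab$mean_nm2[tab$label == lb &
           tab$temperature_k == temp & tab$class == "hydrophobic"],
         mean_hydrophilic_nm2 = tab$mean_nm2[tab$label == lb &
           tab$temperature_k == temp & tab$class == "hydrophilic"])
  d <- delta_asa(get("Ec0VV_6", 300), get("Ec0VV_6", 400))
  expect_identical(unname(d["delta_nonpolar_nm2"]), 33.41 - 21.88) # 11.53
  expect_equal(unname(d["delta_polar_nm2"]), 8.19, tolerance = 1e-9)

  same <- get("Ec0VV", 300)
  expect_equal(unname(delta_asa(same, same)), c(0, 0))
})

test_that("hydrophobic energy is the stated linear form", {
  h <- hydrophobic_energy(11.53, 8.18)
  expect_equal(h$delta_g_hp_kj_mol, 15.4 * 11.53 - 2.6 * 8.18,
               tolerance = 1e-9)
  expect_equal(h$delta_g_hp_kj_mol, 156.3, tolerance = 0.2)
  expect_equal(hydrophobic_energy(0, 0)$delta_g_hp_kj_mol, 0)
  expect_equal(hydrophobic_energy(12.54, 7.76)$delta_g_hp_kj_mol, 172.9,
               tolerance = 0.2)
  expect_equal(hydrophobic_energy(11.68, 7.90)$delta_g_hp_kj_mol, 159.4,
               tolerance = 0.2)
  # linearity and sign flip under ensemble swap
  a <- hydrophobic_energy(3, 1)$delta_g_hp_kj_mol
  b <- hydrophobic_energy(6, 2)$delta_g_hp_kj_mol
  expect_equal(b, 2 * a, tolerance = 1e-12)
  expect_equal(hydrophobic_energy(-3, -1)$delta_g_hp_kj_mol, -a,
               tolerance = 1e-12)
})

test_that("variant energy differences difference against baselines", {
  res <- list(Ec0VV = hydrophobic_energy(11.37, 7.76),
              Ec0SH = hydrophobic_energy(9.95, 7.33))
  d <- energy_differences(res, "Ec0SH")
  dd <- d$ddg_hp_kj_mol[d$variant == "Ec0VV"]
  expect_equal(dd, 20.8, tolerance = 0.2)
  expect_equal(d$ddg_hp_kj_mol[d$variant == "Ec0SH"], 0)
  expect_error(energy_differences(res, "nope"), "absent")
})
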