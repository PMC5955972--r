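test_that("ideal helix geometry places i -> i+4 hydrogen-bond partners", {
  ch <- build_chain(rep("ALA", 12), "ideal_helix")
  d <- vapply(1:8, function(i) {
    o <- denatens:::find_atom(ch$topology, i, "O")
    n <- denatens:::find_atom(ch$topology, i + 4, "N")
    sqrt(sum((ch$frame$coords[o, ] - ch$frame$coords[n, ])^2))
  }, numeric(1))
  expect_true(all(d < 0.35))
})

test_that("tiny chains build and construction is deterministic", {
  ch <- build_chain(c("ALA", "GLY"))
  expect_equal(ch$topology$n_residues, 2)
  expect_true(all(is.finite(ch$frame$coords)))
  a <- build_chain(rep("ALA", 6), "coil", seed = 42)
  b <- build_chain(rep("ALA", 6), "coil", seed = 42)
  expect_identical(a$frame$coords, b$frame$coords)
  expect_error(build_chain(c("ALA", "XXX")), "unknown residue")
})

test_that("contact generator hits degenerate occupancy targets exactly", {
  for (p in c(0, 1)) {
    sp <- ensemble_spec(contact_sequence(),
                        pair_targets = data.frame(donor = 1, acceptor = 3,
                                                  occupancy = p),
                        n_frames = 100, seed = 5)
    g <- generate_contact_trajectory(sp)
    expect_equal(g$truth$pairs$realized, p)
    rep <- occupancy(g$trajectory, targets = 1)
    occ13 <- rep$pairs$occupancy_pct[rep$pairs$partner == 3]
    expect_equal(occ13, 100 * p)
  }
})

test_that("contact generator concentrates near the target (seed 7 case)", {
  sp <- ensemble_spec(contact_sequence(),
                      pair_targets = data.frame(donor = 1, acceptor = 3,
                                                occupancy = 0.6),
                      n_frames = 2000, seed = 7)
  g <- generate_contact_trajectory(sp)
  expect_lt(abs(g$truth$pairs$realized - 0.6),
            3 * sqrt(0.6 * 0.4 / 2000))
})

test_that("measured occupancy equals the realized ground truth exactly", {
  # bonded band < 0.6 nm < unbonded band by construction, so the distance
  # classifier must reproduce the generator's state sequence verbatim
  g <- generate_contact_trajectory(contact_spec(n_frames = 400, seed = 9))
  rep <- occupancy(g$trajectory, targets = c(1, 5, 9))
  m <- merge(g$truth$pairs, rep$pairs,
             by.x = c("donor", "acceptor"), by.y = c("residue", "partner"))
  expect_equal(m$occupancy_pct / 100, m$realized, tolerance = 1e-12)
})

test_that("generated geometry keeps untargeted charged residues apart", {
  g <- generate_contact_trajectory(contact_spec(n_frames = 50, seed = 3))
  rep <- occupancy(g$trajectory, targets = c(1, 5, 9))
  untargeted <- rep$pairs[!(paste(rep$pairs$residue, rep$pairs$partner) %in%
                              c("1 3", "5 7", "9 11")), ]
  expect_true(all(untargeted$occupancy_pct == 0))
})

test_that("conflicting pair geometry is rejected with the conflict named", {
  sq <- contact_sequence()
  # a shared acceptor is feasible (it tracks its anchor), but four pairs
  # over two donors and two acceptors force a cyclic dependency
  sp <- ensemble_spec(sq,
                      pair_targets = data.frame(
                        donor = c(1, 5, 1, 5),
                        acceptor = c(3, 7, 7, 3),
                        occupancy = rep(0.5, 4)),
                      n_frames = 10, seed = 1)
  expect_error(generate_contact_trajectory(sp), "infeasible")
  expect_error(ensemble_spec(sq, pair_targets = data.frame(
    donor = 1, acceptor = 3, occupancy = 1.2)), "\\[0, 1\\]")
})

test_that("rg generator follows its profile exactly and reproducibly", {
  sp <- ensemble_spec(rep("ALA", 40), rg_start_nm = 1.2, rg_end_nm = 1.2,
                      rg_noise_sd = 0, n_frames = 20, seed = 2)
  g <- generate_rg_trajectory(sp)
  rg <- rg_series(g$trajectory)
  expect_equal(rg$rg_nm, rep(1.2, 20), tolerance = 1e-12)

  sp2 <- ensemble_spec(rep("ALA", 40), rg_start_nm = 1.5, rg_end_nm = 1.2,
                       rg_noise_sd = 0.02, n_frames = 100, seed = 2)
  g2 <- generate_rg_trajectory(sp2)
  rg2 <- rg_series(g2$trajectory)
  fit <- stats::lm(rg_nm ~ time_ns, rg2)
  expect_lt(stats::coef(fit)[2], 0)
  expect_equal(rg2$rg_nm, g2$truth$rg_nm, tolerance = 1e-12)

  g3 <- generate_rg_trajectory(sp2)
  expect_identical(g2$trajectory$frames[[50]]$coords,
                   g3$trajectory$frames[[50]]$coords)
})

test_that("helicity generator recovers segment on-fractions", {
  sp <- ensemble_spec(rep("ALA", 20),
                      helix_segments = data.frame(start = 5, end = 16,
                                                  fraction = 0.6),
                      n_frames = 300, seed = 11)
  g <- generate_helicity_trajectory(sp)
  ss <- secstruct_series(g$trajectory)
  hp <- helicity_profile(ss)
  interior <- 8:13
  target_realized <- mean(g$truth$segment_states[, 1])
  # interior residues are H exactly when the segment is on
  expect_equal(hp$helicity[interior],
               rep(target_realized, length(interior)))
  # realized fraction near target at the correlation-adjusted scale
  # (dwell ~5 steps inflates the binomial SE by ~2)
  expect_lt(abs(target_realized - 0.6),
            6 * sqrt(0.6 * 0.4 / 300))
})

test_that("generators are bitwise deterministic and leave the RNG alone", {
  set.seed(123); before <- .Random.seed
  g1 <- generate_contact_trajectory(contact_spec(n_frames = 20, seed = 4))
  expect_identical(.Random.seed, before)
  g2 <- generate_contact_trajectory(contact_spec(n_frames = 20, seed = 4))
  expect_identical(g1$trajectory$frames[[20]]$coords,
                   g2$trajectory$frames[[20]]$coords)
  expect_identical(g1$truth, g2$truth)
})
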