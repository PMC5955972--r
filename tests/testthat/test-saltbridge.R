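test_that("criterion atoms follow the Lys-CE / Arg-CD / Glu-CD / Asp-CG map", {
  ch <- build_chain(c("LYS", "ALA", "ASP", "ARG", "GLU"), "extended")
  top <- ch$topology
  expect_equal(top$atoms$atom_name[criterion_atom(top, 1, "positive")], "CE")
  expect_equal(top$atoms$atom_name[criterion_atom(top, 3, "negative")], "CG")
  expect_equal(top$atoms$atom_name[criterion_atom(top, 4, "positive")], "CD")
  expect_equal(top$atoms$atom_name[criterion_atom(top, 5, "negative")], "CD")
  expect_error(criterion_atom(top, 2, "positive"), "ALA")
  # C-terminal carboxylate is a negative site even for an uncharged residue
  ch2 <- build_chain(c("LYS", "GLU", "ALA"), "extended")
  expect_equal(
    ch2$topology$atoms$atom_name[criterion_atom(ch2$topology, 3,
                                                "negative")], "C")
  # arginine criterion atom is configurable (CZ not built -> named error)
  expect_error(criterion_atom(top, 4, "positive",
    criterion_atom_map(arg_atom = "CZ")), "CZ")
})

test_that("pair distances match a brute-force double loop", {
  g <- generate_contact_trajectory(contact_spec(n_frames = 40, seed = 6))
  tr <- g$trajectory
  pd <- pair_distances(tr, 1, 3)
  i <- criterion_atom(tr$topology, 1, "positive")
  j <- criterion_atom(tr$topology, 3, "negative")
  brute <- numeric(length(tr$frames))
  for (t in seq_along(tr$frames)) {
    s <- 0
    for (k in 1:3) s <- s + (tr$frames[[t]]$coords[i, k] -
                               tr$frames[[t]]$coords[j, k])^2
    brute[t] <- sqrt(s)
  }
  expect_equal(pd$distance_nm, brute, tolerance = 1e-14)
  # bonded-state frames sit inside the generator's bonded band
  bonded <- g$truth$states[, 1]
  expect_true(all(pd$distance_nm[bonded] >= 0.35 &
                    pd$distance_nm[bonded] <= 0.55))
  expect_true(all(pd$distance_nm[!bonded] >= 0.8))
})

test_that("occupancy counts strict sub-cutoff frames only", {
  # Lys-Glu pair at an exactly controlled criterion-atom distance; the
  # trailing Ala supplies a far-away C-terminal negative site
  ch <- build_chain(c("LYS", "GLU", "ALA"), "extended")
  top <- ch$topology
  i <- criterion_atom(top, 1, "positive")
  j <- criterion_atom(top, 2, "negative")
  place <- function(d, t) {
    co <- sweep(ch$frame$coords, 2, ch$frame$coords[i, ])  # atom i at origin
    rows <- denatens:::residue_atoms(top, 2)
    co[rows, ] <- sweep(co[rows, , drop = FALSE], 2, co[j, ])
    co[rows, 3] <- co[rows, 3] + d                         # atom j at (0,0,d)
    far <- denatens:::residue_atoms(top, 3)
    co[far, 1] <- co[far, 1] + 8
    frame(co, time_ns = t)
  }
  tr <- trajectory(top, list(place(0.3, 0), place(0.6, 1), place(0.9, 2)))
  rep <- occupancy(tr, targets = 1)
  occ <- rep$pairs$occupancy_pct[rep$pairs$partner == 2]
  expect_equal(occ, 100 / 3)  # 0.6 exactly does NOT count

  # permanently bonded pair reports 100; prefilter omits never-close pairs
  tr2 <- trajectory(top, list(place(0.4, 0), place(0.5, 1)))
  rep2 <- occupancy(tr2, targets = 1, prefilter_nm = 0.4)
  expect_equal(rep2$pairs$occupancy_pct[rep2$pairs$partner == 2], 100)
  expect_false(3 %in% rep2$pairs$partner)     # C-terminal site omitted
  rep3 <- occupancy(tr2, targets = 1)         # ... but reported as 0 without
  expect_equal(rep3$pairs$occupancy_pct[rep3$pairs$partner == 3], 0)
})

test_that("occupancy is invariant under frame reordering in the window", {
  g <- generate_contact_trajectory(contact_spec(n_frames = 60, seed = 8))
  tr <- g$trajectory
  perm <- sample(seq_along(tr$frames))
  frames2 <- lapply(seq_along(perm), function(k) {
    f <- tr$frames[[perm[k]]]
    frame(f$coords, time_ns = (k - 1) * 0.4)
  })
  tr2 <- trajectory(tr$topology, frames2)
  r1 <- occupancy(tr, targets = c(1, 5, 9))
  r2 <- occupancy(tr2, targets = c(1, 5, 9))
  expect_equal(r1$pairs$occupancy_pct, r2$pairs$occupancy_pct)
})

test_that("subsampling the window changes occupancy only by removal noise", {
  g <- generate_contact_trajectory(contact_spec(n_frames = 1000, seed = 12))
  full <- occupancy(g$trajectory, targets = 1)
  half <- occupancy(g$trajectory, targets = 1,
                    sampling_interval_ns = 0.8)
  o1 <- full$pairs$occupancy_pct[full$pairs$partner == 3] / 100
  o2 <- half$pairs$occupancy_pct[half$pairs$partner == 3] / 100
  expect_equal(half$n_frames, 500)
  expect_lt(abs(o1 - o2), 3 * sqrt(o1 * (1 - o1) / 500))
})

test_that("count series equals per-pair occupancy sums and handles bins", {
  g <- generate_contact_trajectory(contact_spec(n_frames = 500, seed = 10))
  rep <- occupancy(g$trajectory, targets = 1)
  cs <- count_series(g$trajectory, 1, bin_ns = 0.4)
  expect_equal(attr(cs, "mean_count"),
               sum(rep$pairs$occupancy_pct[rep$pairs$residue == 1]) / 100,
               tolerance = 1e-12)
  expect_true(all(cs$count >= 0))
  expect_error(count_series(g$trajectory, 1, bin_ns = 0.1),
               "frame spacing")
  # mean count of two independent pairs approximates p1 + p2
  cs5 <- count_series(g$trajectory, 5)
  expect_lt(abs(attr(cs5, "mean_count") -
                  g$truth$pairs$realized[2]), 1e-12)
})

test_that("aggregate_subunits averages elementwise with missing pairs as 0", {
  g <- generate_contact_trajectory(contact_spec(n_frames = 100, seed = 2))
  r <- occupancy(g$trajectory, targets = c(1, 5))
  same <- aggregate_subunits(list(r, r, r))
  expect_equal(same$pairs$occupancy_pct, r$pairs$occupancy_pct)

  mk <- function(v) {
    x <- r
    x$pairs$occupancy_pct[1] <- v
    x
  }
  avg <- aggregate_subunits(list(mk(30), mk(60), mk(90)))
  expect_equal(avg$pairs$occupancy_pct[1], 60)

  # a pair absent from one subunit is averaged as zero
  drop1 <- r
  drop1$pairs <- r$pairs[-1, ]
  avg2 <- aggregate_subunits(list(r, r, drop1))
  expect_equal(avg2$pairs$occupancy_pct[1],
               r$pairs$occupancy_pct[1] * 2 / 3)
})

test_that("subunit averaging equals pooled-frame computation", {
  runs <- lapply(1:3, function(s)
    generate_contact_trajectory(contact_spec(n_frames = 200, seed = s)))
  reps <- lapply(runs, function(g) occupancy(g$trajectory, targets = 1))
  avg <- aggregate_subunits(reps)
  # pooled: concatenate the three state sequences
  pooled <- mean(vapply(runs, function(g) mean(g$truth$states[, 1]),
                        numeric(1)))
  occ13 <- avg$pairs$occupancy_pct[avg$pairs$partner == 3] / 100
  expect_equal(occ13, pooled, tolerance = 1e-12)
})
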