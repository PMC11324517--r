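test_that("contact profile agrees with the brute-force pair-distance oracle", {
  set.seed(7)
  # random small complex: 1 three-atom ligand + 8 one-atom residues, 12 frames
  lig <- matrix(rnorm(9, sd = 2), 3, 3)
  res <- matrix(rnorm(24, sd = 5), 8, 3)
  top <- new_structure3d(rbind(
    atoms_df(1:3, c("C1", "C2", "C3"), "LIG", "L", 900L, lig, "C", het = TRUE),
    atoms_df(4:11, "CA", "GLY", "A", 1:8, res, "C")))
  frames <- lapply(1:12, function(f)
    rbind(lig + matrix(rnorm(9, sd = 1), 3, 3),
          res + matrix(rnorm(24, sd = 1), 8, 3)))
  tr <- new_trajectory3d(top, frames)
  p <- contact_profile(tr, selection(resname = "LIG"), cutoff = 4.0)
  oracle <- contact_oracle(tr, 1:3, cutoff = 4.0)
  expect_equal(p$contact_probability,
               unname(rowMeans(oracle)[paste(p$chain, p$resseq, sep = "|")]))
})

test_that("planted contact fractions are recovered exactly and bracketing the stable rule", {
  tr <- make_planted_contact_trajectory(
    100, c("10" = 0.5, "20" = 0.41, "30" = 0.40, "40" = 0), seed = 3)
  p <- contact_profile(tr, selection(resname = "LIG"))
  probs <- setNames(p$contact_probability, p$resseq)
  expect_equal(unname(probs[c("10", "20", "30", "40")]),
               c(0.50, 0.41, 0.40, 0))
  stable <- setNames(p$stable, p$resseq)
  expect_true(stable[["10"]])
  expect_true(stable[["20"]])     # 0.41 > 0.40, strictly more than 40%
  expect_false(stable[["30"]])    # exactly 0.40 is not "more than 40%"
  expect_false(stable[["40"]])
})

test_that("contact probabilities are invariant to frame permutation and duplication", {
  tr <- make_planted_contact_trajectory(50, c("10" = 0.4, "20" = 0.8), seed = 9)
  p1 <- contact_profile(tr, selection(resname = "LIG"))
  perm <- sample(n_frames(tr))
  tr2 <- tr; tr2$coords <- tr$coords[, , perm]
  p2 <- contact_profile(tr2, selection(resname = "LIG"))
  expect_equal(p2$contact_probability, p1$contact_probability)
  tr3 <- tr; tr3$coords <- tr$coords[, , rep(seq_len(n_frames(tr)), 2)]
  p3 <- contact_profile(tr3, selection(resname = "LIG"))
  expect_equal(p3$contact_probability, p1$contact_probability)
})

test_that("top coordinating residues rank by probability with documented tie-break", {
  p <- data.frame(chain = c("A", "A", "A", "B"), resseq = c(5L, 3L, 9L, 1L),
                  resname = "GLY",
                  contact_probability = c(0.7, 0.9, 0.7, 0.2),
                  stable = c(TRUE, TRUE, TRUE, FALSE))
  class(p) <- c("contact_profile", "data.frame")
  top <- top_coordinating_residues(p, k = 3)
  expect_equal(top$resseq, c(3L, 5L, 9L))   # tie 0.7/0.7 -> lower resseq first
  expect_equal(nrow(top_coordinating_residues(p, k = 99)), 4L)
})

test_that("ring geometry returns mass-weighted COM and least-squares normal", {
  th <- 2 * pi * (0:5) / 6
  hexa <- cbind(1.4 * cos(th), 1.4 * sin(th), 0)
  g <- ring_geometry(hexa, rep("C", 6))
  expect_equal(g$com, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(abs(g$normal[3]), 1, tolerance = 1e-12)

  tilt <- hexa %*% t(rotation_about("x", 30))
  g2 <- ring_geometry(tilt, rep("C", 6))
  expect_equal(acos(abs(g2$normal[3])) * 180 / pi, 30, tolerance = 1e-9)

  # mass weighting: one heavy substituent pulls the COM, not the centroid
  g3 <- ring_geometry(hexa, c("N", "C", "C", "C", "C", "C"))
  expect_gt(sum(g3$com * hexa[1, ]), 0)

  expect_error(ring_geometry(cbind(1:6, 0, 0), rep("C", 6)), "collinear")
  expect_error(ring_geometry(hexa[1:4, ], rep("C", 4)), "at least 5")
})

test_that("the 9-atom indole ring spec resolves on a tryptophan residue", {
  s <- trp_fixture(resseq = 84)
  idx <- bindsight:::resolve_ring(s, ring_spec(resseq = 84,
                                               atoms = indole_ring_atoms))
  expect_length(idx, 9L)
  expect_identical(s$atoms$name[idx], indole_ring_atoms)
  expect_length(adenine_ring_atoms, 9L)
})

test_that("stacking criterion applies both thresholds and the acute-angle convention", {
  ra <- ring_spec(resseq = 1, atoms = paste0("C", 1:6))
  rb <- ring_spec(resseq = 2, atoms = paste0("C", 1:6))
  near <- make_stacked_rings_trajectory(10, 1, distance_when_stacked = 3.5,
                                        seed = 1)
  expect_equal(occupancy(stacking_series(near, ra, rb)), 1.0)
  far <- make_stacked_rings_trajectory(10, 1, distance_when_stacked = 5.5,
                                       seed = 1)
  expect_equal(occupancy(stacking_series(far, ra, rb)), 0)
  tilted44 <- make_stacked_rings_trajectory(10, 1, distance_when_stacked = 4,
                                            angle_when_stacked = 44, seed = 1)
  expect_equal(occupancy(stacking_series(tilted44, ra, rb)), 1.0)
  tilted46 <- make_stacked_rings_trajectory(10, 1, distance_when_stacked = 4,
                                            angle_when_stacked = 46, seed = 1)
  expect_equal(occupancy(stacking_series(tilted46, ra, rb)), 0)

  # normal sign flip via reversed atom order leaves occupancy unchanged
  rb_rev <- ring_spec(resseq = 2, atoms = paste0("C", 6:1))
  mix <- make_stacked_rings_trajectory(40, 0.6, angle_when_stacked = 20,
                                       seed = 4)
  expect_equal(occupancy(stacking_series(mix, ra, rb_rev)),
               occupancy(stacking_series(mix, ra, rb)))
})

test_that("stacking occupancy matches the planted fraction and is rigid-motion invariant", {
  tr <- make_stacked_rings_trajectory(500, 0.99, seed = 8)
  ra <- ring_spec(resseq = 1, atoms = paste0("C", 1:6))
  rb <- ring_spec(resseq = 2, atoms = paste0("C", 1:6))
  s <- stacking_series(tr, ra, rb)
  expect_equal(occupancy(s), 0.99)
  expect_equal(occupancy(s), mean(s$stacked))

  R <- rotation_about("y", 50)
  tr2 <- tr
  for (f in seq_len(n_frames(tr2)))
    tr2$coords[, , f] <- frame_coords(tr, f) %*% t(R) +
      matrix(c(3, -7, 11), 12, 3, byrow = TRUE)
  expect_equal(occupancy(stacking_series(tr2, ra, rb)), 0.99)
})

test_that("hydrogen-bond criterion evaluates distance and D-H-A angle", {
  geom <- function(da, ang) {
    d <- c(0, 0, 0); h <- c(1, 0, 0)
    # acceptor placed so that D-H-A angle is `ang` and |DA| = da
    th <- (180 - ang) * pi / 180
    candidates <- function(r) h + r * c(cos(th), sin(th), 0)
    f <- function(r) sqrt(sum((candidates(r) - d)^2)) - da
    r <- uniroot(f, c(0.1, 10))$root
    rbind(d, h, candidates(r))
  }
  top <- new_structure3d(atoms_df(1:3, c("N", "H1", "O"),
                                  c("ASN", "ASN", "SER"), "A", c(1, 1, 2),
                                  geom(2.8, 175), c("N", "H", "O")))
  tr <- new_trajectory3d(top, list(geom(2.8, 175), geom(4.0, 175),
                                   geom(2.8, 100)))
  hs <- hbond_series(tr, donor = list(resseq = 1, name = "N"),
                     acceptor = list(resseq = 2, name = "O"),
                     hydrogen = list(resseq = 1, name = "H1"))
  expect_equal(hs$present, c(TRUE, FALSE, FALSE))
  expect_equal(hs$da_distance, c(2.8, 4.0, 2.8), tolerance = 1e-6)
  expect_equal(hs$dha_angle[1], 175, tolerance = 1e-6)

  # 70 of 100 frames satisfied -> occupancy 0.70
  frames <- c(lapply(1:70, function(i) geom(2.8, 175)),
              lapply(1:30, function(i) geom(4.0, 175)))
  tr2 <- new_trajectory3d(top, frames)
  hs2 <- hbond_series(tr2, donor = list(resseq = 1, name = "N"),
                      acceptor = list(resseq = 2, name = "O"),
                      hydrogen = list(resseq = 1, name = "H1"))
  expect_equal(occupancy(hs2), 0.70)

  # no-hydrogen topology: distance-only criterion, recorded as such
  hs3 <- hbond_series(tr, donor = list(resseq = 1, name = "N"),
                      acceptor = list(resseq = 2, name = "O"))
  expect_equal(hs3$present, c(TRUE, FALSE, TRUE))
  expect_false(attr(hs3, "angle_criterion"))
})

test_that("moiety RMSF averages per-atom RMSF within named groups", {
  anchors <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  probe <- rbind(c(5, 5, 5), c(2, 2, 2))
  top <- new_structure3d(rbind(
    atoms_df(1:4, "CA", "GLY", "A", 1:4, anchors, "C"),
    atoms_df(5:6, c("C1", "C2"), "LIG", "L", 10L,
             probe, "C", het = TRUE)))
  frozen <- new_trajectory3d(top, lapply(1:4, function(f) rbind(anchors, probe)))
  groups <- list(g1 = selection(names = "C1"), g2 = selection(names = "C2"))
  expect_equal(unname(moiety_rmsf(frozen, selection(names = "CA"), groups)),
               c(0, 0), tolerance = 1e-10)

  set.seed(5)
  frames <- lapply(1:400, function(f)
    rbind(anchors, probe[1, ] + rnorm(3, 0, 0.2), probe[2, ] + rnorm(3, 0, 0.6)))
  tr <- new_trajectory3d(top, frames)
  m <- moiety_rmsf(tr, selection(names = "CA"), groups)
  expect_lt(m["g1"], m["g2"])
  # single-atom moiety equals that atom's RMSF
  r <- rmsf_per_atom(tr, selection(names = "CA"), selection(names = "C1"))
  expect_equal(unname(m["g1"]), unname(r), tolerance = 1e-12)
  expect_error(moiety_rmsf(tr, selection(names = "CA"),
                           list(bad = selection(names = "ZZ"))), "empty")
})

test_that("ideal-gas RDF is flat at 1 and respects exclusion radii", {
  gas <- make_ideal_gas_box(20000, c(40, 40, 40), n_frames = 120, seed = 7)
  rdf <- radial_distribution(gas, selection(resname = "REF"),
                             selection(resname = "GAS"), r_max = 12, dr = 0.5)
  sel <- rdf$r >= 4 & rdf$r <= 10
  expect_lt(max(abs(rdf$g[sel] - 1)), 0.05)

  # integral recovers the expected neighbour count within 5%
  rho <- attr(rdf, "bulk_density")
  n_expected <- rho * 4 / 3 * pi * 12^3
  n_observed <- sum(attr(rdf, "counts")) / attr(rdf, "n_frames")
  expect_lt(abs(n_observed - n_expected) / n_expected, 0.05)

  excl <- make_ideal_gas_box(2000, c(30, 30, 30), n_frames = 10,
                             exclusion_radius = 2.5, seed = 2)
  rdf2 <- radial_distribution(excl, selection(resname = "REF"),
                              selection(resname = "GAS"), r_max = 10, dr = 0.25)
  expect_equal(max(rdf2$g[rdf2$r < 2.4]), 0)

  # doubling the density leaves g(r) unchanged within sampling error
  gas2 <- make_ideal_gas_box(4000, c(30, 30, 30), n_frames = 60, seed = 11)
  gas1 <- make_ideal_gas_box(2000, c(30, 30, 30), n_frames = 60, seed = 12)
  g2 <- radial_distribution(gas2, selection(resname = "REF"),
                            selection(resname = "GAS"), r_max = 10, dr = 1)
  g1 <- radial_distribution(gas1, selection(resname = "REF"),
                            selection(resname = "GAS"), r_max = 10, dr = 1)
  keep <- g1$r > 3
  expect_lt(max(abs(g2$g[keep] - g1$g[keep])), 0.15)
})

test_that("a planted solvent shell appears at the right radius", {
  # 300 probes pinned on a 3 A sphere around the reference + uniform rest
  set.seed(21)
  n_shell <- 300; n_bulk <- 1700; box <- c(30, 30, 30); ctr <- box / 2
  mk <- function() {
    u <- matrix(rnorm(n_shell * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    shell <- sweep(3 * u, 2, ctr, "+")
    bulk <- cbind(runif(n_bulk, 0, box[1]), runif(n_bulk, 0, box[2]),
                  runif(n_bulk, 0, box[3]))
    rbind(ctr, shell, bulk)
  }
  top <- new_structure3d(rbind(
    atoms_df(1L, "O", "REF", "A", 1L, matrix(ctr, 1), "O", het = TRUE),
    atoms_df(1L + seq_len(n_shell + n_bulk), "O", "GAS", "B",
             1L + seq_len(n_shell + n_bulk),
             matrix(0, n_shell + n_bulk, 3), "O", het = TRUE)))
  tr <- new_trajectory3d(top, lapply(1:5, function(f) mk()), box = box)
  rdf <- radial_distribution(tr, selection(resname = "REF"),
                             selection(resname = "GAS"), r_max = 10, dr = 0.25)
  expect_lt(abs(rdf$r[which.max(rdf$g)] - 3.0), 0.25)
})
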