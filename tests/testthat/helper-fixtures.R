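# shared fixtures and independent oracles (kept deliberately naive)

atoms_df <- bindsight:::atoms_df
new_structure3d <- bindsight:::new_structure3d
new_trajectory3d <- bindsight:::new_trajectory3d

merge_structures <- function(a, b) {
  at <- rbind(a$atoms, b$atoms)
  at$serial <- seq_len(nrow(at))
  new_structure3d(at)
}

# a tryptophan residue with backbone, the 9 indole heavy atoms and two
# hydrogens; coordinates are an arbitrary non-planar arrangement
trp_fixture <- function(resseq = 84, chain = "A") {
  nm <- c("N", "CA", "CB", "CG", "CD1", "NE1", "CE2", "CZ2", "CH2",
          "CZ3", "CE3", "CD2", "HB1", "HB2")
  el <- c("N", "C", "C", "C", "C", "N", "C", "C", "C", "C", "C", "C",
          "H", "H")
  set.seed(84)
  xyz <- matrix(rnorm(length(nm) * 3, sd = 2), ncol = 3)
  new_structure3d(atoms_df(seq_along(nm), nm, "TRP", chain, resseq, xyz, el))
}

# planar aromatic residue whose ring centroid sits at `center`
phe_fixture <- function(resseq, center, chain = "A") {
  ring <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  th <- 2 * pi * (0:5) / 6
  xyz <- cbind(1.39 * cos(th), 1.39 * sin(th), 0)
  xyz <- sweep(xyz, 2, center, "+")
  xyz <- rbind(xyz, matrix(center + c(0, 0, 2), 1, 3))  # CA off-plane
  new_structure3d(atoms_df(seq_len(7), c(ring, "CA"), "PHE", chain, resseq,
                           xyz, rep("C", 7)))
}

# brute-force per-frame contact oracle: residue in contact iff any
# heavy-heavy pair distance <= cutoff (triple loop, no vectorisation)
contact_oracle <- function(traj, ligand_idx, cutoff) {
  a <- traj$topology$atoms
  heavy <- which(a$element != "H")
  prot <- setdiff(heavy, ligand_idx)
  keys <- unique(paste(a$chain[prot], a$resseq[prot], sep = "|"))
  nf <- bindsight::n_frames(traj)
  hits <- matrix(FALSE, length(keys), nf, dimnames = list(keys, NULL))
  for (f in seq_len(nf)) {
    m <- bindsight::frame_coords(traj, f)
    for (i in prot) {
      key <- paste(a$chain[i], a$resseq[i], sep = "|")
      for (j in ligand_idx) {
        if (sqrt(sum((m[i, ] - m[j, ])^2)) <= cutoff) {
          hits[key, f] <- TRUE
          break
        }
      }
    }
  }
  hits
}

# brute-force rotation-grid superposition oracle: best RMSD over a 5-degree
# Euler-angle grid with optimal translation (centroid match)
grid_superpose_rmsd <- function(ref, mob, step = 5) {
  P <- sweep(mob, 2, colMeans(mob))
  Q <- sweep(ref, 2, colMeans(ref))
  const <- sum(P^2) + sum(Q^2)
  H <- crossprod(P, Q)
  ang <- seq(0, 355, by = step) * pi / 180
  best <- Inf
  for (a in ang) {
    Ra <- bindsight::rotation_about("z", a * 180 / pi)
    for (b in seq(0, 175, by = step) * pi / 180) {
      Rb <- bindsight::rotation_about("y", b * 180 / pi)
      for (c_ in ang) {
        R <- Ra %*% Rb %*% bindsight::rotation_about("z", c_ * 180 / pi)
        val <- const - 2 * sum(R * t(H))   # sum |R p - q|^2 = const - 2 tr(R H)
        if (val < best) best <- val
      }
    }
  }
  sqrt(max(best, 0) / nrow(ref))
}

deposited_dir <- function() {
  Sys.getenv("BINDSIGHT_DEPOSITED_DIR", "deposited-structures")
}
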