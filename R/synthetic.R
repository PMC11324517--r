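# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

atoms_df <- function(serial, name, resname, chain, resseq, xyz, element,
                     het = FALSE) {
  data.frame(serial = as.integer(serial), name = name, altloc = "",
             resname = resname, chain = chain, resseq = as.integer(resseq),
             icode = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             element = element, occupancy = 1, bfactor = 0, het = het,
             stringsAsFactors = FALSE)
}

#' Build an ideal alpha-helix CA trace
#'
#' CA_i = orientation . (radius cos(i twist), radius sin(i twist), i rise),
#' with the canonical alpha-helix defaults (1.5 A rise, 100 degree twist,
#' 2.3 A radius), so the true axis is the rotated z axis — ground truth for
#' helix-axis fitting and helix-comparison tests.
#'
#' @param n_res Number of residues, >= 4.
#' @param rise Rise per residue (Angstrom).
#' @param twist Twist per residue (degrees).
#' @param radius Helix radius (Angstrom).
#' @param orientation 3 x 3 rotation applied to the canonical helix.
#' @param translation Length-3 offset applied after rotation.
#' @param chain,start_resseq Residue labelling of the trace.
#' @return A \code{structure3d} of ALA CA atoms.
#' @export
build_ideal_helix <- function(n_res, rise = 1.5, twist = 100, radius = 2.3,
                              orientation = diag(3), translation = c(0, 0, 0),
                              chain = "A", start_resseq = 1L) {
  if (n_res < 4L) stop("an ideal helix needs at least 4 residues")
  i <- seq_len(n_res) - 1L
  th <- i * twist * pi / 180
  xyz <- cbind(radius * cos(th), radius * sin(th), i * rise)
  xyz <- xyz %*% t(orientation) +
    matrix(translation, n_res, 3, byrow = TRUE)
  new_structure3d(atoms_df(seq_len(n_res), "CA", "ALA", chain,
                           start_resseq + i, xyz, "C"),
                  id = sprintf("ideal_helix_%d", n_res))
}

#' Rotation matrix about a coordinate axis
#' @param axis "x", "y" or "z".
#' @param angle Angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  a <- angle * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = rbind(c(1, 0, 0), c(0, c_, -s_), c(0, s_, c_)),
    y = rbind(c(c_, 0, s_), c(0, 1, 0), c(-s_, 0, c_)),
    z = rbind(c(c_, -s_, 0), c(s_, c_, 0), c(0, 0, 1)))
}

#' Trajectory with planted per-residue ligand-contact fractions
#'
#' Topology: a one-atom ligand at the origin plus one heavy atom per scored
#' residue, each on its own radial direction. For residue r with fraction
#' f_r, exactly \code{round(f_r * n_frames)} seeded-random frames place its
#' atom at \code{cutoff - 1} A from the ligand and the remaining frames at
#' \code{cutoff + 2} A, so the contact rule recovers the planted fraction
#' exactly (constructions sit 1 A inside / 2 A outside the cutoff, never on
#' the boundary).
#'
#' @param n_frames Number of frames.
#' @param contact_fractions Named numeric vector in [0,1]; names are residue
#'   numbers.
#' @param cutoff Contact cutoff the plant is built around (Angstrom).
#' @param seed RNG seed.
#' @return A \code{trajectory3d}; ligand is residue LIG 900 on chain L.
#' @export
make_planted_contact_trajectory <- function(n_frames, contact_fractions,
                                            cutoff = 4.0, seed = 1L) {
  stopifnot(all(contact_fractions >= 0 & contact_fractions <= 1),
            !is.null(names(contact_fractions)))
  n_res <- length(contact_fractions)
  resseq <- as.integer(names(contact_fractions))
  # well-separated radial directions, one per residue
  phi <- 2 * pi * (seq_len(n_res) - 1L) / max(n_res, 2L)
  dirs <- cbind(cos(phi), sin(phi), 0)
  top_xyz <- rbind(c(0, 0, 0), dirs * (cutoff + 2))
  atoms <- rbind(
    atoms_df(1L, "C1", "LIG", "L", 900L,
             matrix(top_xyz[1, ], 1, 3), "C", het = TRUE),
    atoms_df(1L + seq_len(n_res), "CA", "GLY", "A", resseq,
             top_xyz[-1, , drop = FALSE], "C"))
  atoms$serial <- seq_len(nrow(atoms))
  top <- new_structure3d(atoms, id = "planted_contacts")
  with_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(f) top_xyz)
    for (r in seq_len(n_res)) {
      n_in <- round(contact_fractions[r] * n_frames)
      hot <- if (n_in > 0) sample(n_frames, n_in) else integer(0)
      for (f in hot) frames[[f]][r + 1L, ] <- dirs[r, ] * (cutoff - 1)
    }
    new_trajectory3d(top, frames)
  })
}

hexagon <- function(radius = 1.39) {
  th <- 2 * pi * (0:5) / 6
  cbind(radius * cos(th), radius * sin(th), 0)
}

#' Trajectory with a planted ring-stacking fraction
#'
#' Two six-membered carbon rings. In the planted "stacked" frames ring B is
#' tilted by \code{angle_when_stacked} about x and its center of mass sits
#' \code{distance_when_stacked} A above ring A; in the remaining frames ring
#' B is parallel but displaced to \code{unstacked_distance} A, violating the
#' distance criterion. Which frames are stacked is seeded-random.
#'
#' @param n_frames Number of frames.
#' @param stacked_fraction Fraction of frames with the planted stacked
#'   geometry.
#' @param distance_when_stacked,angle_when_stacked Planted COM distance
#'   (Angstrom) and inter-normal angle (degrees) in stacked frames.
#' @param unstacked_distance COM distance in non-stacked frames (Angstrom).
#' @param seed RNG seed.
#' @return A \code{trajectory3d}; rings are residues RGA 1 and RGB 2 with
#'   atoms C1..C6.
#' @export
make_stacked_rings_trajectory <- function(n_frames, stacked_fraction,
                                          distance_when_stacked = 3.5,
                                          angle_when_stacked = 0,
                                          unstacked_distance = 8.0,
                                          seed = 1L) {
  stopifnot(stacked_fraction >= 0, stacked_fraction <= 1)
  A <- hexagon()
  mk_b <- function(dist, ang) {
    B <- hexagon() %*% t(rotation_about("x", ang))
    sweep(B, 2, c(0, 0, dist), "+")
  }
  B_on <- mk_b(distance_when_stacked, angle_when_stacked)
  B_off <- mk_b(unstacked_distance, 0)
  atoms <- rbind(
    atoms_df(1:6, paste0("C", 1:6), "RGA", "A", 1L, A, "C", het = TRUE),
    atoms_df(7:12, paste0("C", 1:6), "RGB", "A", 2L, B_on, "C", het = TRUE))
  top <- new_structure3d(atoms, id = "stacked_rings")
  n_on <- round(stacked_fraction * n_frames)
  with_seed(seed, {
    hot <- if (n_on > 0) sample(n_frames, n_on) else integer(0)
    frames <- lapply(seq_len(n_frames), function(f)
      rbind(A, if (f %in% hot) B_on else B_off))
    new_trajectory3d(top, frames)
  })
}

#' Toy metal coordination site
#'
#' Ion at the origin with oxygen ligands at the vertices of an ideal
#' polyhedron, scaled to the requested distances, with optional isotropic
#' Gaussian jitter.
#'
#' @param geometry One of "tetrahedral", "octahedral", "square_planar",
#'   "trigonal_planar", "trigonal_bipyramidal".
#' @param distances Ligand distances (Angstrom), one per vertex.
#' @param jitter Per-coordinate Gaussian s.d. applied to ligand positions
#'   (Angstrom).
#' @param ion_element Ion element symbol (e.g. "ZN", "NA").
#' @param seed RNG seed (used only when jitter > 0).
#' @return A \code{structure3d}: the ion plus one single-oxygen ligand
#'   residue per vertex.
#' @export
make_metal_site <- function(geometry = c("tetrahedral", "octahedral",
                                         "square_planar", "trigonal_planar",
                                         "trigonal_bipyramidal"),
                            distances, jitter = 0, ion_element = "ZN",
                            seed = 1L) {
  geometry <- match.arg(geometry)
  tmpl <- c(coordination_templates(),
            list(square_planar = rbind(c(1, 0, 0), c(-1, 0, 0),
                                       c(0, 1, 0), c(0, -1, 0))))
  V <- tmpl[[geometry]]
  if (length(distances) != nrow(V))
    stop(geometry, " needs ", nrow(V), " distances, got ", length(distances))
  xyz <- V * distances
  if (jitter > 0)
    xyz <- with_seed(seed, xyz + matrix(rnorm(length(xyz), 0, jitter),
                                        nrow(xyz), 3))
  rn <- toupper(ion_element)
  atoms <- rbind(
    atoms_df(1L, rn, rn, "A", 500L, matrix(0, 1, 3), rn, het = TRUE),
    atoms_df(1L + seq_len(nrow(xyz)), "O1", "LIG", "A",
             500L + seq_len(nrow(xyz)), xyz, "O", het = TRUE))
  new_structure3d(atoms, id = paste0("metal_site_", geometry))
}

#' Ideal-gas solvent box (RDF null model)
#'
#' A single reference atom at the box center plus probe points drawn
#' uniformly in an orthorhombic periodic box, optionally excluded from a
#' sphere around the reference. For this trajectory g(r) = 1 (beyond any
#' exclusion radius) up to sampling error.
#'
#' @param n_points Number of probe points (>= 100).
#' @param box Length-3 box edge lengths (Angstrom).
#' @param n_frames Number of independent frames.
#' @param exclusion_radius Probes are resampled until outside this radius of
#'   the reference (Angstrom).
#' @param seed RNG seed.
#' @return A \code{trajectory3d} with \code{box} set; reference is residue
#'   REF 1, probes are residue GAS.
#' @export
make_ideal_gas_box <- function(n_points, box = c(40, 40, 40), n_frames = 10L,
                               exclusion_radius = 0, seed = 1L) {
  stopifnot(n_points >= 100L)
  if (min(box) <= 2 * exclusion_radius)
    stop("box smaller than twice the exclusion radius")
  ctr <- box / 2
  atoms <- rbind(
    atoms_df(1L, "O", "REF", "A", 1L, matrix(ctr, 1, 3), "O", het = TRUE),
    atoms_df(1L + seq_len(n_points), "O", "GAS", "B",
             1L + seq_len(n_points), matrix(0, n_points, 3), "O", het = TRUE))
  top <- new_structure3d(atoms, id = "ideal_gas_box")
  with_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(f) {
      P <- cbind(runif(n_points, 0, box[1]), runif(n_points, 0, box[2]),
                 runif(n_points, 0, box[3]))
      if (exclusion_radius > 0) {
        repeat {
          d <- sqrt(rowSums(sweep(P, 2, ctr)^2))
          bad <- which(d < exclusion_radius)
          if (!length(bad)) break
          P[bad, ] <- cbind(runif(length(bad), 0, box[1]),
                            runif(length(bad), 0, box[2]),
                            runif(length(bad), 0, box[3]))
        }
      }
      rbind(ctr, P)
    })
    new_trajectory3d(top, frames, box = box)
  })
}

#' Generator presets at the published assay parameters
#'
#' Named parameter sets for \code{\link{simulate_dose_response}} matching the
#' reported dopamine-uptake kinetics (Km 0.55 uM, Vmax 342.8 fmol/min/well
#' for the truncated construct; 0.56 uM / 190.9 for full-length) and the
#' radioligand saturation binding (Kd 6.5 nM). Bmax is not reported and is
#' set to a plausible assay-scale signal.
#'
#' @format Named list with elements \code{model}, \code{params}, \code{x},
#'   \code{unit}.
#' @export
dose_response_presets <- list(
  fig1a_delta_hDAT = list(model = "mm",
                          params = list(Km = 0.55, Vmax = 342.8),
                          x = c(0.0137, 0.0412, 0.123, 0.370, 1.11, 3.33,
                                10, 30),
                          unit = "uM"),
  fig1a_full_hDAT = list(model = "mm",
                         params = list(Km = 0.56, Vmax = 190.9),
                         x = c(0.0137, 0.0412, 0.123, 0.370, 1.11, 3.33,
                               10, 30),
                         unit = "uM"),
  fig1b_win35428 = list(model = "binding",
                        params = list(Kd = 6.5, Bmax = 2000),
                        x = c(1, 2.5, 5, 10, 25, 50, 100, 150),
                        unit = "nM")
)

#' Simulate a noisy dose-response dataset
#'
#' y = model(x) (1 + eps) + background, with eps ~ Normal(0, cv) i.i.d. per
#' replicate and background replicates at the stated mean (same constant-CV
#' noise). The constant-CV Gaussian noise model reflects assays reported as
#' mean +/- s.d.
#'
#' @param model "mm" (params Km, Vmax), "binding" (Kd, Bmax),
#'   "hill_normalized" (IC50, h) or "hill_variable" (IC50, h, top, bottom).
#' @param params Named parameter list for the model.
#' @param x Concentration grid.
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param n_replicates Replicates per concentration.
#' @param background_mean Mean background signal added to every well and
#'   issued as background replicates.
#' @param seed RNG seed.
#' @param unit Concentration unit tag.
#' @return A \code{dose_response} dataset.
#' @export
simulate_dose_response <- function(model = c("mm", "binding",
                                             "hill_normalized",
                                             "hill_variable"),
                                   params, x, cv = 0.05, n_replicates = 3L,
                                   background_mean = 0, seed = 1L,
                                   unit = "uM") {
  model <- match.arg(model)
  mu <- switch(model,
    mm = params$Vmax * x / (params$Km + x),
    binding = params$Bmax * x / (params$Kd + x),
    hill_normalized = 100 / (1 + (x / params$IC50)^params$h),
    hill_variable = params$bottom + (params$top - params$bottom) /
      (1 + (x / params$IC50)^params$h))
  if (any(!is.finite(mu))) stop("invalid parameters for model ", model)
  with_seed(seed, {
    eps <- matrix(rnorm(length(x) * n_replicates, 0, cv),
                  length(x), n_replicates)
    y <- mu * (1 + eps) + background_mean
    bg <- background_mean * (1 + rnorm(n_replicates, 0, cv))
    dose_response_dataset(x, y, background = bg, unit = unit,
                          condition = model)
  })
}
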