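# standard atomic masses, keyed by upper-case element symbol
ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                 P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
                 NA. = 22.990, K = 39.098, MG = 24.305, CA = 40.078,
                 ZN = 65.38, FE = 55.845, MN = 54.938, CU = 63.546)

element_mass <- function(element) {
  key <- ifelse(toupper(element) == "NA", "NA.", toupper(element))
  m <- ATOMIC_MASS[key]
  if (any(is.na(m))) stop("unknown element(s): ",
                          paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Per-residue ligand contact probabilities from a trajectory
#'
#' A residue is in contact in a frame if any of its heavy atoms lies within
#' \code{cutoff} of any ligand heavy atom. The contact probability is the
#' fraction of frames in contact, and a residue is flagged as a stable
#' contact when that probability exceeds \code{stable_threshold} strictly
#' (more than 40 percent of the time under the defaults).
#'
#' @param traj A \code{trajectory3d}.
#' @param ligand_sel \code{atom_selection} for the ligand (hydrogens are
#'   excluded automatically).
#' @param residues Optional data frame with columns \code{chain, resseq}
#'   restricting the protein residues scored; by default every residue not in
#'   the ligand selection.
#' @param cutoff Heavy-atom distance cutoff in Angstrom.
#' @param stable_threshold Strict stable-contact threshold (fraction).
#' @return A \code{contact_profile}: data frame with \code{chain, resseq,
#'   resname, contact_probability, stable}, plus attributes \code{n_frames},
#'   \code{cutoff}, \code{stable_threshold}.
#' @export
contact_profile <- function(traj, ligand_sel, residues = NULL, cutoff = 4.0,
                            stable_threshold = 0.40) {
  stopifnot(cutoff > 0)
  top <- traj$topology
  li <- select_atoms(top, ligand_sel)
  li <- li[top$atoms$element[li] != "H"]
  if (!length(li)) stop("empty ligand selection")
  nf <- n_frames(traj)
  if (nf < 1L) stop("zero frames")
  a <- top$atoms
  prot <- setdiff(which(a$element != "H"), li)
  key <- paste(a$chain[prot], a$resseq[prot], sep = "|")
  if (!is.null(residues)) {
    want <- paste(residues$chain, residues$resseq, sep = "|")
    sel <- key %in% want
    prot <- prot[sel]; key <- key[sel]
  }
  if (!length(prot)) stop("no protein residues to score")
  ukey <- unique(key)
  grp <- match(key, ukey)
  hits <- matrix(FALSE, length(ukey), nf)
  cut2 <- cutoff^2
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)
    d2 <- cross_dist2(m[prot, , drop = FALSE], m[li, , drop = FALSE])
    amin <- apply(d2, 1, min)
    hits[, f] <- tapply(amin, grp, min) <= cut2
  }
  prob <- rowMeans(hits)
  first <- match(ukey, key)
  out <- data.frame(
    chain = a$chain[prot[first]],
    resseq = a$resseq[prot[first]],
    resname = a$resname[prot[first]],
    contact_probability = as.numeric(prob),
    stable = as.numeric(prob) > stable_threshold,
    stringsAsFactors = FALSE
  )
  attr(out, "n_frames") <- nf
  attr(out, "cutoff") <- cutoff
  attr(out, "stable_threshold") <- stable_threshold
  class(out) <- c("contact_profile", "data.frame")
  out
}

#' Top coordinating residues from a contact profile
#'
#' Residues ranked by contact probability, descending; ties broken by
#' (chain, resseq) ascending.
#'
#' @param p A \code{contact_profile}.
#' @param k Number of residues to return (truncated to the profile length).
#' @return The first \code{k} rows of the ranked profile.
#' @export
top_coordinating_residues <- function(p, k = 15L) {
  stopifnot(k >= 1L)
  o <- order(-p$contact_probability, p$chain, p$resseq)
  out <- p[o, , drop = FALSE][seq_len(min(k, nrow(p))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ring specification
#'
#' Names the ordered heavy atoms that define an aromatic ring for the
#' stacking analysis (e.g. the 9 indole atoms of a tryptophan, or the 9
#' adenine-ring atoms of a bound nucleoside analogue).
#'
#' @param chain,resseq,resname Residue spec (resname optional).
#' @param atoms Ordered atom-name vector, length >= 5.
#' @return A \code{ring_spec}.
#' @export
ring_spec <- function(chain = NULL, resseq, atoms, resname = NULL) {
  if (length(atoms) < 5L) stop("a ring needs at least 5 atoms")
  obj <- list(chain = chain, resseq = resseq, resname = resname, atoms = atoms)
  class(obj) <- "ring_spec"
  obj
}

resolve_ring <- function(topology, ring) {
  idx <- integer(length(ring$atoms))
  for (k in seq_along(ring$atoms)) {
    i <- select_atoms(topology, selection(chain = ring$chain,
                                          resseq = ring$resseq,
                                          resname = ring$resname,
                                          names = ring$atoms[k]))
    if (!length(i)) stop("ring atom not found: ", ring$atoms[k],
                         " in residue ", ring$resseq)
    idx[k] <- i[1]
  }
  idx
}

#' Ring center of mass and plane normal
#'
#' COM is mass-weighted over the listed heavy atoms; the normal is the unit
#' normal of the least-squares plane (direction of smallest variance). The
#' normal's sign is arbitrary and is folded away by the acute-angle
#' convention in \code{\link{stacking_series}}.
#'
#' @param xyz n x 3 coordinates of the ring atoms.
#' @param elements Element symbols for mass lookup.
#' @return List with \code{com} (length 3) and unit \code{normal}.
#' @export
ring_geometry <- function(xyz, elements) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 5L) stop("a ring needs at least 5 atoms")
  w <- element_mass(elements)
  com <- colSums(xyz * w) / sum(w)
  X <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(X)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) stop("collinear ring atoms")
  list(com = com, normal = sv$v[, 3])
}

#' Ring pi-stacking time series and occupancy
#'
#' Two rings are stacked in a frame when the distance between their heavy-atom
#' centers of mass is at most \code{d_max} and the acute angle between their
#' least-squares plane normals is at most \code{a_max}. Occupancy is the
#' fraction of frames satisfying both criteria.
#'
#' @param traj A \code{trajectory3d}.
#' @param ringA,ringB \code{ring_spec} objects.
#' @param d_max COM distance threshold (Angstrom).
#' @param a_max Inter-normal angle threshold (degrees).
#' @return A \code{stacking_series}: data frame with per-frame
#'   \code{com_distance}, \code{normal_angle}, \code{stacked}; attribute
#'   \code{occupancy}.
#' @export
stacking_series <- function(traj, ringA, ringB, d_max = 5.0, a_max = 45.0) {
  ia <- resolve_ring(traj$topology, ringA)
  ib <- resolve_ring(traj$topology, ringB)
  ea <- traj$topology$atoms$element[ia]
  eb <- traj$topology$atoms$element[ib]
  nf <- n_frames(traj)
  dist <- ang <- numeric(nf)
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)
    ga <- ring_geometry(m[ia, , drop = FALSE], ea)
    gb <- ring_geometry(m[ib, , drop = FALSE], eb)
    dist[f] <- sqrt(sum((ga$com - gb$com)^2))
    ang[f] <- acos(pmin(1, abs(sum(ga$normal * gb$normal)))) * 180 / pi
  }
  stacked <- dist <= d_max & ang <= a_max
  out <- data.frame(frame = seq_len(nf), com_distance = dist,
                    normal_angle = ang, stacked = stacked)
  attr(out, "occupancy") <- mean(stacked)
  attr(out, "d_max") <- d_max
  attr(out, "a_max") <- a_max
  class(out) <- c("stacking_series", "data.frame")
  out
}

#' Stacking occupancy
#' @param x A \code{stacking_series} or \code{hbond_series}.
#' @return Fraction of frames in which the interaction criterion holds.
#' @export
occupancy <- function(x) attr(x, "occupancy")

#' Hydrogen-bond time series and occupancy
#'
#' Geometric criterion: donor-acceptor distance at most \code{d_cut} and
#' donor-hydrogen-acceptor angle at least \code{a_cut}. These cutoffs are a
#' common geometric convention, not a community standard fixed by any one
#' source; both are configurable. When the topology carries no hydrogens,
#' pass \code{hydrogen = NULL} to evaluate the distance criterion alone
#' (recorded in the result).
#'
#' @param traj A \code{trajectory3d}.
#' @param donor,acceptor Atom specs: lists with \code{chain, resseq, name}.
#' @param hydrogen Atom spec for the donor hydrogen, or NULL to disable the
#'   angle criterion.
#' @param d_cut Donor-acceptor distance cutoff (Angstrom).
#' @param a_cut D-H-A angle cutoff (degrees).
#' @return An \code{hbond_series}: per-frame \code{da_distance},
#'   \code{dha_angle} (NA when angle disabled), \code{present}; attribute
#'   \code{occupancy}.
#' @export
hbond_series <- function(traj, donor, acceptor, hydrogen = NULL,
                         d_cut = 3.5, a_cut = 120.0) {
  one <- function(spec) {
    i <- select_atoms(traj$topology,
                      selection(chain = spec$chain, resseq = spec$resseq,
                                names = spec$name))
    if (!length(i)) stop("atom not found: ", spec$name, " ", spec$resseq)
    i[1]
  }
  di <- one(donor); ai <- one(acceptor)
  hi <- if (!is.null(hydrogen)) one(hydrogen) else NA_integer_
  nf <- n_frames(traj)
  da <- numeric(nf); dha <- rep(NA_real_, nf)
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)
    da[f] <- sqrt(sum((m[di, ] - m[ai, ])^2))
    if (!is.na(hi)) {
      v1 <- m[di, ] - m[hi, ]; v2 <- m[ai, ] - m[hi, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      dha[f] <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
    }
  }
  present <- da <= d_cut & (is.na(hi) | dha >= a_cut)
  out <- data.frame(frame = seq_len(nf), da_distance = da, dha_angle = dha,
                    present = present)
  attr(out, "occupancy") <- mean(present)
  attr(out, "angle_criterion") <- !is.na(hi)
  class(out) <- c("hbond_series", "data.frame")
  out
}

#' Mean RMSF per named atom group (moiety)
#'
#' Averages per-atom RMSF (see \code{\link{rmsf_per_atom}}) within each named
#' group, e.g. the tropane / fluorophenyl / carbomethoxy moieties of a
#' tropane-class inhibitor.
#'
#' @param traj A \code{trajectory3d}.
#' @param fit_sel \code{atom_selection} used to superpose frames.
#' @param moieties Named list of \code{atom_selection} objects.
#' @return Named numeric vector of group-mean RMSF (Angstrom).
#' @export
moiety_rmsf <- function(traj, fit_sel, moieties) {
  stopifnot(length(moieties) >= 1L, !is.null(names(moieties)))
  vapply(moieties, function(sel) {
    i <- select_atoms(traj$topology, sel)
    if (!length(i)) stop("empty moiety group")
    mean(rmsf_per_atom(traj, fit_sel, sel))
  }, numeric(1))
}

#' Radial distribution function g(r)
#'
#' Histogram of reference-probe distances under the minimum-image convention
#' in an orthorhombic box, normalised by the spherical shell volume
#' 4 pi r^2 dr, the probe bulk density, the number of reference atoms and the
#' number of frames — so an ideal gas gives g(r) = 1 at all r beyond any
#' exclusion radius.
#'
#' @param traj A \code{trajectory3d} whose \code{box} is set (or pass
#'   \code{box}).
#' @param ref_sel,probe_sel \code{atom_selection} objects.
#' @param r_max Maximum distance (Angstrom); must not exceed half the
#'   shortest box edge.
#' @param dr Bin width (Angstrom).
#' @param box Optional length-3 box override.
#' @return An \code{rdf_result}: data frame with \code{r} (bin centers) and
#'   \code{g}; attributes \code{dr}, \code{n_frames}, \code{bulk_density}.
#' @export
radial_distribution <- function(traj, ref_sel, probe_sel, r_max, dr,
                                box = NULL) {
  stopifnot(r_max > dr, dr > 0)
  if (is.null(box)) box <- traj$box
  if (is.null(box)) stop("box dimensions required for RDF normalisation")
  if (r_max > min(box) / 2)
    stop("r_max exceeds half the shortest box edge")
  ri <- select_atoms(traj$topology, ref_sel)
  pi_ <- select_atoms(traj$topology, probe_sel)
  if (!length(ri)) stop("empty reference selection")
  if (!length(pi_)) stop("empty probe selection")
  nf <- n_frames(traj)
  breaks <- seq(0, r_max, by = dr)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  counts <- numeric(length(breaks) - 1L)
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)
    R <- m[ri, , drop = FALSE]; P <- m[pi_, , drop = FALSE]
    for (j in seq_len(nrow(R))) {
      d <- sweep(P, 2, R[j, ])
      for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
      r <- sqrt(rowSums(d^2))
      r <- r[r > 1e-9 & r < r_max]
      counts <- counts + tabulate(findInterval(r, breaks), length(counts))
    }
  }
  vol <- prod(box)
  rho <- length(pi_) / vol
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  shell <- 4 * pi * centers^2 * diff(breaks)
  g <- counts / (nf * length(ri) * shell * rho)
  out <- data.frame(r = centers, g = g)
  attr(out, "dr") <- dr
  attr(out, "n_frames") <- nf
  attr(out, "bulk_density") <- rho
  attr(out, "counts") <- counts
  class(out) <- c("rdf_result", "data.frame")
  out
}
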