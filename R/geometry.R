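#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired coordinate sets, by singular value decomposition of the covariance
#' matrix with the usual determinant correction (so reflections are never
#' returned). The transform maps \code{mob} onto \code{ref}:
#' \code{x' = R x + t}.
#'
#' @param ref,mob n x 3 coordinate matrices, n >= 3, in pairing order.
#' @return A \code{superposition} object: \code{rotation} (3 x 3),
#'   \code{translation} (length 3), \code{rmsd} (Angstrom), \code{n_pairs}.
#' @export
kabsch_superpose <- function(ref, mob) {
  ref <- as.matrix(ref); mob <- as.matrix(mob)
  if (!all(dim(ref) == dim(mob))) stop("coordinate sets differ in size")
  n <- nrow(ref)
  if (n < 3L) stop("need at least 3 paired points")
  cr <- colMeans(ref); cm <- colMeans(mob)
  P <- sweep(mob, 2, cm); Q <- sweep(ref, 2, cr)
  sv <- svd(crossprod(P, Q))           # H = P^T Q ; R = V D U^T
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate (collinear) point set; superposition ill-defined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- as.numeric(cr - R %*% cm)
  moved <- mob %*% t(R) + matrix(t_vec, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - ref)^2)))
  obj <- list(rotation = R, translation = t_vec, rmsd = rmsd, n_pairs = n)
  class(obj) <- "superposition"
  obj
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: %d pairs, rmsd %.3f A\n", x$n_pairs, x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param fit A \code{superposition} (or list with rotation/translation).
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, fit) {
  xyz <- as.matrix(xyz)
  xyz %*% t(fit$rotation) + matrix(fit$translation, nrow(xyz), 3, byrow = TRUE)
}

#' Pair alpha-carbons between two structures via a correspondence table
#'
#' Used to superpose structures whose residue numbering differs (orthologues).
#' Rows whose CA atom is missing on either side are dropped and counted.
#'
#' @param ref,target \code{structure3d} objects.
#' @param mapping Data frame with columns \code{ref_chain, ref_resseq,
#'   target_chain, target_resseq}.
#' @return List with \code{ref_idx}, \code{target_idx} (atom indices in
#'   mapping order), \code{n_pairs}, \code{n_dropped}.
#' @export
pair_calpha <- function(ref, target, mapping) {
  need <- c("ref_chain", "ref_resseq", "target_chain", "target_resseq")
  stopifnot(all(need %in% names(mapping)))
  find_ca <- function(s, chain, resseq) {
    i <- select_atoms(s, selection(chain = chain, resseq = resseq, names = "CA"))
    if (length(i)) i[1] else NA_integer_
  }
  ri <- mapply(find_ca, chain = mapping$ref_chain, resseq = mapping$ref_resseq,
               MoreArgs = list(s = ref))
  ti <- mapply(find_ca, chain = mapping$target_chain,
               resseq = mapping$target_resseq, MoreArgs = list(s = target))
  ok <- !is.na(ri) & !is.na(ti)
  if (!any(ok)) stop("no residue pairs with CA present on both sides")
  list(ref_idx = unname(ri[ok]), target_idx = unname(ti[ok]),
       n_pairs = sum(ok), n_dropped = sum(!ok))
}

#' Fit a helix axis through alpha-carbon positions
#'
#' The axis direction is the principal component of the CA trace after
#' smoothing with a sliding four-residue (about one helical turn) centroid,
#' which cancels the circular component of the helix so the fit is unbiased
#' even when the helix spans a non-integer number of turns. The sign is
#' fixed to point from the first toward the last residue, so directions are
#' comparable between helices. The centroid reported is that of the raw CA
#' positions.
#'
#' @param calpha n x 3 matrix of CA coordinates in sequence order, n >= 4.
#' @return A \code{helix_axis}: \code{centroid}, unit \code{direction},
#'   \code{n_calpha}.
#' @export
fit_helix_axis <- function(calpha) {
  calpha <- as.matrix(calpha)
  n <- nrow(calpha)
  if (n < 4L) stop("need at least 4 CA positions to fit a helix axis")
  ctr <- colMeans(calpha)
  w <- if (n >= 7L) 4L else 1L
  sm <- if (w > 1L) {
    t(vapply(seq_len(n - w + 1L),
             function(i) colMeans(calpha[i:(i + w - 1L), , drop = FALSE]),
             numeric(3)))
  } else calpha
  X <- sweep(sm, 2, colMeans(sm))
  sv <- svd(X)
  if (sv$d[1] < 1e-10) stop("zero-variance input")
  dir <- sv$v[, 1]
  span <- calpha[n, ] - calpha[1, ]
  if (sum(dir * span) < 0) dir <- -dir
  obj <- list(centroid = ctr, direction = dir / sqrt(sum(dir^2)), n_calpha = n)
  class(obj) <- "helix_axis"
  obj
}

#' Helix displacement and reorientation between two structures
#'
#' Superposes \code{target} onto \code{ref} using the CA atoms of an alignment
#' mapping (e.g. the scaffold helices TM3/TM8), then compares one helix
#' between the two structures in the common frame. Displacement is the
#' distance between the helix CA centroids after alignment; reorientation is
#' the acute angle between the fitted axis directions. Both are invariant to
#' any rigid motion applied to both inputs.
#'
#' @param ref,target \code{structure3d} objects.
#' @param align_map Mapping data frame (see \code{\link{pair_calpha}}) giving
#'   the residues used to fit the superposition.
#' @param helix_map Mapping data frame giving the helix residues to compare.
#' @return A \code{helix_comparison}: \code{displacement} (Angstrom),
#'   \code{reorientation} (degrees, 0-90), \code{alignment_rmsd},
#'   \code{n_align}, \code{n_helix}.
#' @export
compare_helix <- function(ref, target, align_map, helix_map) {
  ap <- pair_calpha(ref, target, align_map)
  if (ap$n_pairs < 3L) stop("alignment pairing has fewer than 3 pairs")
  fit <- kabsch_superpose(coords(ref, ap$ref_idx), coords(target, ap$target_idx))
  hp <- pair_calpha(ref, target, helix_map)
  if (hp$n_pairs < 4L) stop("helix selection has fewer than 4 CA atoms")
  ref_ca <- coords(ref, hp$ref_idx)
  tgt_ca <- apply_transform(coords(target, hp$target_idx), fit)
  ax_r <- fit_helix_axis(ref_ca)
  ax_t <- fit_helix_axis(tgt_ca)
  disp <- sqrt(sum((ax_r$centroid - ax_t$centroid)^2))
  cosang <- abs(sum(ax_r$direction * ax_t$direction))
  reori <- acos(pmin(1, cosang)) * 180 / pi
  obj <- list(displacement = disp, reorientation = reori,
              alignment_rmsd = fit$rmsd, n_align = ap$n_pairs,
              n_helix = hp$n_pairs)
  class(obj) <- "helix_comparison"
  obj
}

#' @export
print.helix_comparison <- function(x, ...) {
  cat(sprintf("helix comparison: displacement %.2f A, reorientation %.1f deg (alignment rmsd %.2f A, %d pairs)\n",
              x$displacement, x$reorientation, x$alignment_rmsd, x$n_align))
  invisible(x)
}

# side-chain ring atom sets for the ring-centroid distance rule
RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "NE1", "CE2", "CZ2", "CH2", "CZ3", "CE3", "CD2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

#' Distance between two residues under a stated atom rule
#'
#' Supported rules: a named atom (\code{rule = "atom"}, with \code{atom=}),
#' alpha-carbon (\code{"ca"}), side-chain aromatic ring centroid
#' (\code{"ring_centroid"}), or minimum heavy-atom distance
#' (\code{"min_heavy"}). The extracellular-gate measurement between aromatic
#' gate residues uses the ring-centroid rule.
#'
#' @param s A \code{structure3d}.
#' @param a,b Residue specs: lists with \code{chain} and \code{resseq}
#'   (optionally \code{resname}).
#' @param rule Distance rule (single rule applied to both residues).
#' @param atom Atom name when \code{rule = "atom"}.
#' @return Distance in Angstrom.
#' @export
residue_distance <- function(s, a, b,
                             rule = c("ca", "atom", "ring_centroid", "min_heavy"),
                             atom = NULL) {
  rule <- match.arg(rule)
  res_atoms <- function(spec) {
    i <- select_atoms(s, selection(chain = spec$chain, resseq = spec$resseq,
                                   resname = spec$resname))
    if (!length(i)) stop("residue not found: ", spec$chain, spec$resseq)
    i
  }
  point <- function(spec) {
    i <- res_atoms(spec)
    at <- s$atoms[i, ]
    switch(rule,
      ca = {
        j <- i[at$name == "CA"]
        if (!length(j)) stop("CA absent in residue ", spec$resseq)
        coords(s, j[1])[1, ]
      },
      atom = {
        if (is.null(atom)) stop("rule 'atom' needs an atom name")
        j <- i[at$name == atom]
        if (!length(j)) stop("atom ", atom, " absent in residue ", spec$resseq)
        coords(s, j[1])[1, ]
      },
      ring_centroid = {
        rn <- at$resname[1]
        ring <- RING_ATOMS[[rn]]
        if (is.null(ring)) stop("no ring definition for residue type ", rn)
        j <- i[at$name %in% ring]
        if (length(j) < 5L) stop("incomplete ring in residue ", spec$resseq)
        colMeans(coords(s, j))
      },
      min_heavy = NULL)
  }
  if (rule == "min_heavy") {
    ia <- res_atoms(a); ib <- res_atoms(b)
    ia <- ia[s$atoms$element[ia] != "H"]
    ib <- ib[s$atoms$element[ib] != "H"]
    d2 <- cross_dist2(coords(s, ia), coords(s, ib))
    return(sqrt(min(d2)))
  }
  sqrt(sum((point(a) - point(b))^2))
}

# squared distances between all row pairs of two coordinate matrices
cross_dist2 <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Per-atom root-mean-square fluctuation over a trajectory
#'
#' Each frame is superposed onto the first frame using the atoms of
#' \code{fit_sel}; RMSF of each measured atom is the root mean square of its
#' deviation from its time-averaged position in the aligned frames.
#'
#' @param traj A \code{trajectory3d} with at least 2 frames.
#' @param fit_sel \code{atom_selection} for the superposition (typically CA).
#' @param measure_sel \code{atom_selection} for the atoms to measure.
#' @return Numeric vector of RMSF values (Angstrom), one per measured atom,
#'   named by atom index.
#' @export
rmsf_per_atom <- function(traj, fit_sel, measure_sel) {
  if (n_frames(traj) < 2L) stop("need at least 2 frames")
  fi <- select_atoms(traj$topology, fit_sel)
  mi <- select_atoms(traj$topology, measure_sel)
  if (!length(fi)) stop("empty fit selection")
  if (!length(mi)) stop("empty measure selection")
  ref <- frame_coords(traj, 1)[fi, , drop = FALSE]
  nf <- n_frames(traj)
  aligned <- array(0, dim = c(length(mi), 3L, nf))
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)
    fit <- kabsch_superpose(ref, m[fi, , drop = FALSE])
    aligned[, , f] <- apply_transform(m[mi, , drop = FALSE], fit)
  }
  mean_pos <- apply(aligned, c(1, 2), mean)
  dev2 <- vapply(seq_len(nf), function(f)
    rowSums((aligned[, , f] - mean_pos)^2), numeric(length(mi)))
  dev2 <- matrix(dev2, nrow = length(mi))
  out <- sqrt(rowMeans(dev2))
  names(out) <- mi
  out
}
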