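#' Coordination-shell search configuration
#'
#' Element-specific distance windows for candidate coordinating atoms, and
#' the eligible donor elements. The default windows (Zn 1.9-2.6 A, Na
#' 2.2-2.9 A) bracket typical first-shell metal-donor distances in protein
#' structures with standard coordination-chemistry margins; both are
#' configurable.
#'
#' @param windows Named list of c(min, max) distance windows (Angstrom),
#'   keyed by upper-case ion element symbol.
#' @param donors Eligible donor element symbols.
#' @return A \code{coordination_config}.
#' @export
coordination_config <- function(windows = list(ZN = c(1.9, 2.6),
                                               `NA` = c(2.2, 2.9)),
                                donors = c("N", "O", "S")) {
  for (w in windows)
    if (length(w) != 2L || w[1] >= w[2]) stop("each window must be c(min, max) with min < max")
  obj <- list(windows = windows, donors = toupper(donors))
  class(obj) <- "coordination_config"
  obj
}

#' Find the coordination shell of a metal/ion atom
#'
#' Lists every eligible donor atom (N/O/S by default) whose distance to the
#' ion lies inside the element's window, sorted by distance. For histidine
#' residues with both imidazole nitrogens in the window, only the nearer of
#' ND1/NE2 is kept (the tautomer at the site is not assumed).
#'
#' @param s A \code{structure3d}.
#' @param ion Ion atom spec: list with any of \code{resname, chain, resseq,
#'   serial} identifying a single atom.
#' @param cfg A \code{coordination_config}.
#' @return A \code{coordination_site}: \code{ion} (element, position, residue),
#'   \code{ligands} data frame (atom identity, distance, coordinates),
#'   \code{coordination_number}, \code{mean_distance} (NA when the shell is
#'   empty, with a warning).
#' @export
find_coordination_shell <- function(s, ion, cfg = coordination_config()) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(ion$serial))  keep <- keep & a$serial %in% ion$serial
  if (!is.null(ion$resname)) keep <- keep & a$resname %in% ion$resname
  if (!is.null(ion$chain))   keep <- keep & a$chain %in% ion$chain
  if (!is.null(ion$resseq))  keep <- keep & a$resseq %in% ion$resseq
  ii <- which(keep)
  if (length(ii) == 0L) stop("ion atom not found")
  if (length(ii) > 1L) stop("ion spec matches ", length(ii), " atoms; be more specific")
  elem <- toupper(a$element[ii])
  win <- cfg$windows[[elem]]
  if (is.null(win)) stop("no distance window configured for element ", elem)
  pos <- c(a$x[ii], a$y[ii], a$z[ii])
  cand <- which(a$element %in% cfg$donors & seq_len(nrow(a)) != ii)
  d <- sqrt((a$x[cand] - pos[1])^2 + (a$y[cand] - pos[2])^2 +
            (a$z[cand] - pos[3])^2)
  inwin <- d >= win[1] & d <= win[2]
  lig_idx <- cand[inwin]
  lig_d <- d[inwin]
  o <- order(lig_d)
  lig_idx <- lig_idx[o]; lig_d <- lig_d[o]
  # histidine: keep only the nearer imidazole nitrogen
  if (length(lig_idx)) {
    la <- a[lig_idx, ]
    drop <- rep(FALSE, length(lig_idx))
    his <- la$resname == "HIS" & la$name %in% c("ND1", "NE2")
    if (any(his)) {
      rk <- paste(la$chain, la$resseq)
      for (r in unique(rk[his])) {
        j <- which(his & rk == r)
        if (length(j) > 1L) drop[j[-1]] <- TRUE  # already distance-sorted
      }
    }
    lig_idx <- lig_idx[!drop]; lig_d <- lig_d[!drop]
  }
  if (length(lig_idx) == 0L)
    warning("no coordinating atoms found within the ", elem, " window")
  la <- a[lig_idx, , drop = FALSE]
  ligands <- data.frame(serial = la$serial, name = la$name,
                        resname = la$resname, chain = la$chain,
                        resseq = la$resseq, distance = lig_d,
                        x = la$x, y = la$y, z = la$z,
                        stringsAsFactors = FALSE)
  rownames(ligands) <- NULL
  obj <- list(
    ion = list(element = elem, position = pos, resname = a$resname[ii],
               chain = a$chain[ii], resseq = a$resseq[ii]),
    ligands = ligands,
    coordination_number = nrow(ligands),
    mean_distance = if (nrow(ligands)) mean(lig_d) else NA_real_
  )
  class(obj) <- "coordination_site"
  obj
}

#' @export
print.coordination_site <- function(x, ...) {
  cat(sprintf("coordination site: %s, %d ligand(s), mean distance %.2f A\n",
              x$ion$element, x$coordination_number, x$mean_distance))
  if (x$coordination_number)
    print(x$ligands[, c("name", "resname", "chain", "resseq", "distance")])
  invisible(x)
}

#' Summarise a coordination site
#'
#' @param site A \code{coordination_site} with at least one ligand.
#' @return One-row data frame: ion identity, coordination number, mean/min/max
#'   distance (Angstrom) and the donor residue list.
#' @export
coordination_summary <- function(site) {
  if (site$coordination_number < 1L) stop("empty coordination shell")
  d <- site$ligands$distance
  donors <- paste(unique(paste0(site$ligands$resname, site$ligands$resseq,
                                ":", site$ligands$name)), collapse = ", ")
  data.frame(ion = site$ion$element, n = site$coordination_number,
             mean_distance = mean(d), min_distance = min(d),
             max_distance = max(d), donors = donors,
             stringsAsFactors = FALSE)
}

# unit vertex directions of the ideal coordination polyhedra
coordination_templates <- function() {
  s3 <- 1 / sqrt(3)
  list(
    trigonal_planar = rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0),
                            c(-0.5, -sqrt(3) / 2, 0)),
    tetrahedral = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                        c(-1, -1, 1)) * s3,
    trigonal_bipyramidal = rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0),
                                 c(-0.5, -sqrt(3) / 2, 0),
                                 c(0, 0, 1), c(0, 0, -1)),
    octahedral = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1))
  )
}

pair_angles <- function(U) {
  n <- nrow(U)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cosang <- rowSums(U[idx[, 1], , drop = FALSE] * U[idx[, 2], , drop = FALSE])
  list(idx = idx, angles = acos(pmax(-1, pmin(1, cosang))) * 180 / pi)
}

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

#' Deviation of a coordination shell from ideal geometry
#'
#' Compares the observed ligand-ion-ligand angle set against each ideal
#' template with the same vertex count (trigonal planar, tetrahedral,
#' trigonal bipyramidal, octahedral), minimising the angle RMS deviation over
#' all ligand-to-vertex assignments (exhaustive, at most 6! = 720). The
#' assignment search makes the result invariant to ligand input order.
#'
#' @param site A \code{coordination_site} with 3 to 6 ligands, or an n x 3
#'   matrix of ligand positions relative to the ion.
#' @return List with \code{geometry} (best-matching template label) and
#'   \code{angle_rms_deviation} (degrees), plus per-template deviations.
#' @export
geometry_deviation <- function(site) {
  if (inherits(site, "coordination_site")) {
    V <- as.matrix(site$ligands[, c("x", "y", "z")])
    V <- sweep(V, 2, site$ion$position)
  } else V <- as.matrix(site)
  n <- nrow(V)
  if (!(n %in% 3:6)) stop("unsupported coordination number: ", n)
  U <- V / sqrt(rowSums(V^2))
  obs <- pair_angles(U)
  tmpl <- coordination_templates()
  tmpl <- tmpl[vapply(tmpl, nrow, 1L) == n]
  perms <- all_perms(n)
  devs <- vapply(tmpl, function(Tm) {
    ta <- pair_angles(Tm)
    best <- Inf
    for (p in perms) {
      # template angle between assigned vertices p[i], p[j]
      key_t <- pmin(ta$idx[, 1], ta$idx[, 2]) * 10L +
               pmax(ta$idx[, 1], ta$idx[, 2])
      tmap <- numeric(max(key_t)); tmap[key_t] <- ta$angles
      key_o <- pmin(p[obs$idx[, 1]], p[obs$idx[, 2]]) * 10L +
               pmax(p[obs$idx[, 1]], p[obs$idx[, 2]])
      rms <- sqrt(mean((obs$angles - tmap[key_o])^2))
      if (rms < best) best <- rms
    }
    best
  }, numeric(1))
  k <- which.min(devs)
  list(geometry = names(devs)[k], angle_rms_deviation = unname(devs[k]),
       per_template = devs)
}
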