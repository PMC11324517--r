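#' Read a structure from a PDB file
#'
#' Parses all ATOM/HETATM records of a fixed-column PDB file into a
#' \code{structure3d} object. Heteroatoms (ions, ligands) are retained with
#' their deposited residue names, and residue numbers are kept exactly as in
#' the file (full-length numbering; no renumbering). Alternate locations other
#' than blank or \code{"A"} are dropped, so downstream analyses always see a
#' single conformer.
#'
#' @param path Path to a PDB file.
#' @param id Label for the structure; defaults to the file name.
#' @return A \code{structure3d} object: a list with \code{atoms} (data frame
#'   with columns \code{serial, name, altloc, resname, chain, resseq, icode,
#'   x, y, z, element, occupancy, bfactor, het}) and \code{id}.
#' @export
read_structure <- function(path, id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  a <- pdb$atom
  if (nrow(a) == 0L) stop("no ATOM/HETATM records parsed from ", path)
  atoms <- data.frame(
    serial    = a$eleno,
    name      = a$elety,
    altloc    = ifelse(is.na(a$alt), "", a$alt),
    resname   = a$resid,
    chain     = ifelse(is.na(a$chain), "", a$chain),
    resseq    = a$resno,
    icode     = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    element   = ifelse(is.na(a$elesy) | a$elesy == "", "", toupper(a$elesy)),
    occupancy = ifelse(is.na(a$o), 1, a$o),
    bfactor   = ifelse(is.na(a$b), 0, a$b),
    het       = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  # altloc policy: keep blank or 'A' only (single-conformer analyses)
  atoms <- atoms[atoms$altloc %in% c("", "A"), , drop = FALSE]
  blank <- atoms$element == ""
  if (any(blank)) {
    atoms$element[blank] <- infer_element(atoms$name[blank], atoms$resname[blank])
  }
  if (nrow(atoms) == 0L) stop("zero atoms retained from ", path)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)
  rownames(atoms) <- NULL
  new_structure3d(atoms, id = id)
}

new_structure3d <- function(atoms, id = "structure") {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  obj <- list(atoms = atoms, id = id)
  class(obj) <- "structure3d"
  obj
}

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atoms
  cat("structure3d:", x$id, "\n")
  cat(sprintf("  %d atoms (%d HETATM), chains: %s\n", nrow(a), sum(a$het),
              paste(unique(a$chain), collapse = " ")))
  het <- unique(a$resname[a$het])
  if (length(het)) cat("  hetero residues:", paste(het, collapse = " "), "\n")
  invisible(x)
}

# Element inference when the element column is absent/blank. Two-letter
# monatomic ions are recognised from the residue name; otherwise the first
# alphabetic character of the atom name (PDB convention) is used.
infer_element <- function(name, resname) {
  two <- c("ZN", "NA", "CL", "MG", "MN", "FE", "CU", "BR", "K", "CA", "NI", "CO")
  out <- character(length(name))
  nm <- toupper(trimws(name))
  rn <- toupper(trimws(resname))
  ion <- rn %in% two & nm == rn
  out[ion] <- rn[ion]
  rest <- !ion
  out[rest] <- vapply(nm[rest], function(s) {
    s <- gsub("[^A-Z]", "", s)
    if (nchar(s) == 0L) stop("cannot infer element from blank atom name")
    substr(s, 1L, 1L)
  }, character(1))
  out
}

#' Write a structure to a PDB file
#'
#' Fixed-column PDB output; coordinates survive a read/write round trip to
#' 0.001 Angstrom (the format's printed precision). Atom names longer than
#' four characters cannot be represented in the format and raise an error
#' rather than being silently truncated.
#'
#' @param s A \code{structure3d}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "structure3d"))
  a <- s$atoms
  if (nrow(a) == 0L) stop("empty structure")
  bad <- nchar(a$name) > 4L
  if (any(bad))
    stop("atom name(s) exceed the 4-character PDB field: ",
         paste(unique(a$name[bad]), collapse = ", "))
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = a$resseq, resid = a$resname, eleno = a$serial,
    elety = a$name, chain = ifelse(a$chain == "", NA, a$chain),
    insert = ifelse(a$icode == "", "", a$icode),
    alt = ifelse(a$altloc == "", NA, a$altloc),
    o = a$occupancy, b = a$bfactor, elesy = a$element
  )
  invisible(path)
}

#' Coordinate matrix of a structure
#'
#' @param s A \code{structure3d}.
#' @param idx Optional integer atom indices.
#' @return Numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(s, idx = NULL) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Atom selection
#'
#' A declarative atom selection resolved against a \code{structure3d} by
#' \code{\link{select_atoms}}. All filters are optional and combined with AND.
#'
#' @param chain Chain identifier(s).
#' @param resseq Residue numbers (full-length numbering); ranges may be given
#'   as any integer vector, e.g. \code{84} or \code{152:180}.
#' @param resname Residue name(s), e.g. \code{"TRP"} or a ligand code.
#' @param names Atom name(s), e.g. \code{c("CG","CD1","NE1")}.
#' @param heavy_only If TRUE, exclude element H.
#' @return An \code{atom_selection} object.
#' @export
selection <- function(chain = NULL, resseq = NULL, resname = NULL,
                      names = NULL, heavy_only = FALSE) {
  obj <- list(chain = chain, resseq = resseq, resname = resname,
              names = names, heavy_only = isTRUE(heavy_only))
  class(obj) <- "atom_selection"
  obj
}

#' Resolve an atom selection against a structure
#'
#' @param s A \code{structure3d}.
#' @param sel An \code{atom_selection} (see \code{\link{selection}}).
#' @return Integer indices of matching atoms in file order (possibly empty).
#' @export
select_atoms <- function(s, sel) {
  stopifnot(inherits(s, "structure3d"), inherits(sel, "atom_selection"))
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain))   keep <- keep & a$chain %in% sel$chain
  if (!is.null(sel$resseq))  keep <- keep & a$resseq %in% sel$resseq
  if (!is.null(sel$resname)) keep <- keep & a$resname %in% sel$resname
  if (!is.null(sel$names))   keep <- keep & a$name %in% sel$names
  if (sel$heavy_only)        keep <- keep & a$element != "H"
  which(keep)
}

new_trajectory3d <- function(topology, frames, box = NULL, frame_spacing = 1) {
  stopifnot(inherits(topology, "structure3d"))
  n_atoms <- nrow(topology$atoms)
  if (is.list(frames)) {
    for (i in seq_along(frames)) {
      f <- frames[[i]]
      if (!is.matrix(f) || nrow(f) != n_atoms || ncol(f) != 3L)
        stop("frame ", i, ": expected ", n_atoms, " x 3 coordinates, got ",
             nrow(f), " x ", ncol(f))
    }
    arr <- array(unlist(frames), dim = c(n_atoms, 3L, length(frames)))
  } else {
    arr <- frames
    stopifnot(length(dim(arr)) == 3L, dim(arr)[1] == n_atoms, dim(arr)[2] == 3L)
  }
  if (dim(arr)[3] < 1L) stop("trajectory must contain at least one frame")
  obj <- list(topology = topology, coords = arr, box = box,
              frame_spacing = frame_spacing)
  class(obj) <- "trajectory3d"
  obj
}

#' Number of frames in a trajectory
#' @param traj A \code{trajectory3d}.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one trajectory frame
#' @param traj A \code{trajectory3d}.
#' @param i Frame index (1-based).
#' @return n_atoms x 3 matrix.
#' @export
frame_coords <- function(traj, i) {
  m <- traj$coords[, , i, drop = TRUE]
  dim(m) <- c(dim(traj$coords)[1], 3L)
  m
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("trajectory3d: %d atoms x %d frames", dim(x$coords)[1],
              n_frames(x)))
  if (!is.null(x$box)) cat(sprintf(", box %.1f x %.1f x %.1f A",
                                   x$box[1], x$box[2], x$box[3]))
  cat("\n")
  invisible(x)
}

#' Read a coordinate trajectory
#'
#' Reads a multi-model PDB (MODEL/ENDMDL blocks) or a plain XYZ-frames file
#' (count line, comment line, then \code{element x y z} rows per frame) against
#' a fixed topology. Every frame must carry exactly as many atoms as the
#' topology; a mismatch is reported with the offending frame index.
#'
#' @param path Trajectory file; format chosen by extension (\code{.pdb} vs
#'   \code{.xyz}) unless \code{format} is given.
#' @param topology A \code{structure3d} defining atom identities.
#' @param stride Keep every \code{stride}-th frame starting from the first.
#' @param format \code{"auto"}, \code{"pdb"} or \code{"xyz"}.
#' @param box Optional orthorhombic box lengths (length-3, Angstrom) used by
#'   periodic analyses; taken from a CRYST1 record when present in a PDB.
#' @return A \code{trajectory3d}.
#' @export
read_trajectory <- function(path, topology, stride = 1L,
                            format = c("auto", "pdb", "xyz"), box = NULL) {
  format <- match.arg(format)
  stopifnot(file.exists(path), stride >= 1L)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  n_atoms <- nrow(topology$atoms)
  lines <- readLines(path)
  if (format == "pdb") {
    res <- parse_pdb_frames(lines, n_atoms)
    frames <- res$frames
    if (is.null(box)) box <- res$box
  } else {
    frames <- parse_xyz_frames(lines, n_atoms)
  }
  if (length(frames) == 0L) stop("zero frames read from ", path)
  keep <- seq(1L, length(frames), by = stride)
  new_trajectory3d(topology, frames[keep], box = box)
}

# Coordinate-only extraction from MODEL blocks; topology identity comes from
# the caller's structure3d, so only columns 31-54 are consumed here.
parse_pdb_frames <- function(lines, n_atoms) {
  box <- NULL
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr))
    box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                        substr(cr[1], 25, 33)))
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  frames <- list()
  if (length(model_starts) == 0L) {
    idx <- which(is_atom)
    frames[[1]] <- pdb_xyz(lines[idx])
  } else {
    bounds <- c(model_starts, length(lines) + 1L)
    for (k in seq_along(model_starts)) {
      span <- seq(bounds[k], bounds[k + 1L] - 1L)
      endm <- grep("^ENDMDL", lines[span])
      if (length(endm)) span <- span[seq_len(endm[1] - 1L)]
      idx <- span[is_atom[span]]
      frames[[k]] <- pdb_xyz(lines[idx])
    }
  }
  for (k in seq_along(frames))
    if (nrow(frames[[k]]) != n_atoms)
      stop("frame ", k, ": expected ", n_atoms, " atoms, found ",
           nrow(frames[[k]]))
  list(frames = frames, box = box)
}

pdb_xyz <- function(atom_lines) {
  m <- cbind(as.numeric(substr(atom_lines, 31, 38)),
             as.numeric(substr(atom_lines, 39, 46)),
             as.numeric(substr(atom_lines, 47, 54)))
  colnames(m) <- c("x", "y", "z")
  m
}

parse_xyz_frames <- function(lines, n_atoms) {
  frames <- list()
  i <- 1L; k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ count line at line ", i)
    k <- k + 1L
    if (n != n_atoms)
      stop("frame ", k, ": expected ", n_atoms, " atoms, found ", n)
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    m <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    colnames(m) <- c("x", "y", "z")
    frames[[k]] <- m
    i <- i + 2L + n
  }
  frames
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj A \code{trajectory3d}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory3d"))
  a <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(traj$box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       traj$box[1], traj$box[2], traj$box[3]), con)
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  # PDB atom-name justification: 1-3 char names start in column 14
  nm <- ifelse(nchar(a$name) < 4L, sprintf(" %-3s", a$name), a$name)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    m <- frame_coords(traj, f)
    writeLines(sprintf("%s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       rec, a$serial %% 100000L, nm, substr(paste0(a$altloc, " "), 1, 1),
                       a$resname, substr(paste0(a$chain, " "), 1, 1),
                       a$resseq, substr(paste0(a$icode, " "), 1, 1),
                       m[, 1], m[, 2], m[, 3], a$occupancy, a$bfactor,
                       a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
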