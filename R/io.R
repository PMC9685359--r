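#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) into the package's atom tibble,
#' resolving elements from columns 77-78 with an atom-name fallback and
#' attaching van der Waals radii from a configurable table.
#'
#' @param path Path to a PDB file.
#' @param radii_table Named numeric vector mapping element symbols to radii
#'   in Angstrom; must contain a `default` entry used (with a warning) for
#'   unknown elements.
#' @return Atom tibble (see [validate_structure()]) in file order, with
#'   `charge` initialised to 0.
#' @export
read_structure <- function(path, radii_table = default_vdw_radii()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  check_pdb_coords(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path))
  at <- pdb$atom
  if (nrow(at) == 0) abort(paste0("empty structure (zero atoms): ", path))
  element <- resolve_elements(at$elesy, at$elety)
  atoms <- tibble::tibble(
    serial = as.integer(at$eleno),
    name = at$elety,
    element = element,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = as.integer(at$resno),
    resname = at$resid,
    x = at$x, y = at$y, z = at$z,
    radius = radius_for(element, radii_table),
    charge = 0L
  )
  validate_structure(atoms)
  atoms
}

# Scan ATOM/HETATM coordinate fields so parse failures cite the line.
check_pdb_coords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      abort(paste0("PDB parse error at line ", i,
                   ": ATOM record too short for coordinates"))
    }
    flds <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    vals <- suppressWarnings(as.numeric(flds))
    if (any(is.na(vals))) {
      abort(paste0("PDB parse error at line ", i,
                   ": unreadable coordinate field '",
                   flds[which(is.na(vals))[1]], "'"))
    }
  }
  invisible(lines)
}

resolve_elements <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  # fallback: first alphabetic character of the atom name
  fb <- toupper(substr(gsub("[^A-Za-z].*", "", gsub("^[0-9]+", "", elety)), 1, 1))
  ifelse(el == "", fb, el)
}

radius_for <- function(element, radii_table) {
  if (!"default" %in% names(radii_table)) {
    abort("radii table must contain a 'default' entry")
  }
  r <- radii_table[element]
  unknown <- unique(element[is.na(r)])
  if (length(unknown) > 0) {
    warn(paste0("unknown element(s) ", paste(unknown, collapse = ", "),
                ": using default radius ", radii_table[["default"]], " A"))
    r[is.na(r)] <- radii_table[["default"]]
  }
  unname(r)
}

#' Write a structure to a PDB file
#'
#' @param atoms Atom tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  validate_structure(atoms)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(atom_coords(atoms))),
    type = rep("ATOM", nrow(atoms)),
    eleno = atoms$serial,
    elety = atoms$name,
    resid = atoms$resname,
    chain = atoms$chain,
    resno = atoms$resno,
    elesy = atoms$element
  )
  invisible(path)
}

#' Construct a trajectory ensemble
#'
#' A trajectory ensemble couples one topology (atom tibble) with an ordered
#' list of coordinate matrices, frame times in nanoseconds, a replica id and
#' a phase label (`bulk`, `vacuum` or `rehydration`).
#'
#' @param topology Atom tibble shared by all frames.
#' @param frames List of `n_atoms x 3` coordinate matrices (Angstrom).
#' @param times Numeric vector of frame times (ns), strictly increasing.
#' @param replica_id Replica identifier string.
#' @param phase One of `"bulk"`, `"vacuum"`, `"rehydration"`.
#' @return An object of class `traj_ensemble`.
#' @export
trajectory_ensemble <- function(topology, frames, times = seq_along(frames),
                                replica_id = "r1", phase = "bulk") {
  validate_structure(topology)
  phase <- match.arg(phase, c("bulk", "vacuum", "rehydration"))
  n <- nrow(topology)
  for (k in seq_along(frames)) {
    frames[[k]] <- unname(as.matrix(frames[[k]]))
    if (nrow(frames[[k]]) != n || ncol(frames[[k]]) != 3) {
      abort(paste0("frame ", k, " has ", nrow(frames[[k]]),
                   " atoms; topology has ", n))
    }
  }
  if (length(times) != length(frames) || any(diff(times) <= 0)) {
    abort("frame times must match frame count and be strictly increasing")
  }
  structure(
    list(topology = tibble::as_tibble(topology), frames = frames,
         times = as.numeric(times), replica_id = replica_id, phase = phase),
    class = "traj_ensemble"
  )
}

#' @export
print.traj_ensemble <- function(x, ...) {
  cat(sprintf("<traj_ensemble> %s phase '%s': %d frames x %d atoms (%.3g-%.3g ns)\n",
              x$replica_id, x$phase, length(x$frames), nrow(x$topology),
              min(x$times), max(x$times)))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

#' Read a trajectory from a multi-model PDB or XYZ file
#'
#' One frame per MODEL (PDB) or per block (XYZ). Frame times default to
#' `dt * (0:(n-1))` when the file carries none.
#'
#' @param path Path to a multi-model PDB or a plain XYZ file.
#' @param topology Atom tibble the frames must match in atom count/order.
#' @param dt Frame spacing in ns used to synthesise frame times.
#' @param replica_id,phase Passed to [trajectory_ensemble()].
#' @param format `"pdb"`, `"xyz"`, or `"auto"` (from the file extension).
#' @return A `traj_ensemble`.
#' @export
read_trajectory <- function(path, topology, dt = 1,
                            replica_id = "r1", phase = "bulk",
                            format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  n <- nrow(topology)
  if (format == "xyz") {
    frames <- read_xyz_frames(path, n)
  } else {
    lines <- readLines(path, warn = FALSE)
    starts <- grep("^MODEL", lines)
    if (length(starts) > 0) {
      ends <- grep("^ENDMDL", lines)
      if (length(ends) != length(starts)) abort("unbalanced MODEL/ENDMDL records")
      for (m in seq_along(starts)) {
        cnt <- sum(grepl("^(ATOM|HETATM)", lines[starts[m]:ends[m]]))
        if (cnt != n) {
          abort(paste0("model ", m, " has ", cnt, " atoms; topology has ", n))
        }
      }
    }
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE))
    xyz <- pdb$xyz
    if (ncol(xyz) != 3 * n) {
      abort(paste0("trajectory atom count ", ncol(xyz) / 3,
                   " does not match topology (", n, ")"))
    }
    frames <- lapply(seq_len(nrow(xyz)), function(i) {
      matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    })
  }
  trajectory_ensemble(topology, frames, times = dt * (seq_along(frames) - 1) + dt,
                      replica_id = replica_id, phase = phase)
}

read_xyz_frames <- function(path, n_atoms) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1
  m <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    cnt <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(cnt)) abort(paste0("XYZ parse error at line ", i, ": expected atom count"))
    m <- m + 1
    if (cnt != n_atoms) {
      abort(paste0("model ", m, " has ", cnt, " atoms; topology has ", n_atoms))
    }
    block <- lines[(i + 2):(i + 1 + cnt)]
    parts <- strsplit(trimws(block), "\\s+")
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(is.na(coords))) {
      abort(paste0("XYZ parse error in model ", m, ": unreadable coordinates"))
    }
    frames[[m]] <- coords
    i <- i + 2 + cnt
  }
  if (length(frames) == 0) abort("no frames in XYZ file")
  frames
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj A `traj_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    fr <- traj$frames[[k]]
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      top$serial, substr(top$name, 1, 4), top$resname, top$chain, top$resno,
      fr[, 1], fr[, 2], fr[, 3], top$element
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Bundle replicas sharing one topology and phase
#'
#' @param trajectories List of `traj_ensemble` objects with identical atom
#'   counts and phase labels.
#' @return Tibble with columns `replica_id`, `phase`, `n_frames` and a
#'   list-column `trajectory`; class `replica_set`.
#' @export
replica_set <- function(trajectories) {
  if (length(trajectories) == 0) abort("replica set needs at least one trajectory")
  n <- nrow(trajectories[[1]]$topology)
  ph <- trajectories[[1]]$phase
  for (tr in trajectories) {
    if (nrow(tr$topology) != n) abort("replicas must share one topology (atom count mismatch)")
    if (tr$phase != ph) abort("replicas must share one phase label")
  }
  out <- tibble::tibble(
    replica_id = vapply(trajectories, function(t) t$replica_id, character(1)),
    phase = ph,
    n_frames = vapply(trajectories, n_frames, integer(1)),
    trajectory = trajectories
  )
  class(out) <- c("replica_set", class(out))
  out
}

replica_topology <- function(replicas) replicas$trajectory[[1]]$topology

# All (replica, frame) coordinate matrices, optionally windowed per replica.
pooled_frames <- function(replicas, window = NULL) {
  out <- list()
  for (tr in replicas$trajectory) {
    idx <- seq_len(n_frames(tr))
    if (!is.null(window)) idx <- intersect(idx, window)
    out <- c(out, tr$frames[idx])
  }
  out
}
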