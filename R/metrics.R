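#' Kabsch least-squares superposition
#'
#' Finds the proper rotation (det = +1) and translation minimising the
#' least-squares deviation of `mobile` from `reference` over a selection,
#' via SVD of the covariance matrix.
#'
#' @param mobile `n x 3` coordinate matrix to fit.
#' @param reference `n x 3` reference coordinates.
#' @param sel Integer indices of atoms used for the fit (default all).
#' @return List with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom, over the selection after fitting), and `fitted` (all mobile
#'   coordinates after the transform).
#' @export
kabsch_superpose <- function(mobile, reference, sel = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(sel)) sel <- seq_len(nrow(mobile))
  if (length(sel) < 3) abort("superposition needs at least 3 selected atoms")
  A <- mobile[sel, , drop = FALSE]
  B <- reference[sel, , drop = FALSE]
  if (nrow(A) != nrow(B)) abort("selection sizes differ between mobile and reference")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(A0) %*% B0
  sv <- svd(H)
  if (min(sv$d) < 1e-10 && sum(sv$d > 1e-10) < 2) {
    abort("degenerate superposition: selected atoms are collinear or coincident")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- sweep(sweep(mobile, 2, ca) %*% t(R), 2, cb, "+")
  dev <- fitted[sel, , drop = FALSE] - B
  rmsd <- sqrt(mean(rowSums(dev^2)))
  list(rotation = R, translation = cb - as.vector(R %*% ca),
       rmsd = rmsd, fitted = fitted)
}

#' RMSD time series across replicas
#'
#' Per-frame superposed RMSD against a reference, computed per replica and
#' then averaged across replicas at each time point (mean +/- sd, the
#' convention for averages at specific time points).
#'
#' @param replicas A `replica_set`.
#' @param reference Atom tibble sharing the replicas' topology.
#' @param selection Selection string (default `"calpha"`).
#' @return Tibble of class `series_stat`: `time` (ns), `mean`, `spread`
#'   (sd across replicas), plus a `values` list-column of per-replica
#'   values; attribute `label`.
#' @export
rmsd_series <- function(replicas, reference, selection = "calpha") {
  top <- replica_topology(replicas)
  sel <- select_atoms(top, selection, require_n = 3)
  ref_xyz <- atom_coords(reference)
  times <- replicas$trajectory[[1]]$times
  for (tr in replicas$trajectory) {
    if (length(tr$times) != length(times) || any(abs(tr$times - times) > 1e-9)) {
      abort("replica frame times are misaligned")
    }
  }
  per_rep <- vapply(replicas$trajectory, function(tr) {
    vapply(tr$frames, function(fr) kabsch_superpose(fr, ref_xyz, sel)$rmsd,
           numeric(1))
  }, numeric(length(times)))
  per_rep <- matrix(per_rep, nrow = length(times))
  new_series(
    time = times,
    mean = rowMeans(per_rep),
    spread = apply(per_rep, 1, stats::sd),
    values = lapply(seq_along(times), function(i) per_rep[i, ]),
    label = paste0("RMSD [A], selection '", selection, "'")
  )
}

new_series <- function(time, mean, spread, values = NULL, label = "") {
  spread[is.na(spread)] <- 0
  out <- tibble::tibble(time = time, mean = mean, spread = spread)
  if (!is.null(values)) out$values <- values
  attr(out, "label") <- label
  class(out) <- c("series_stat", class(out))
  out
}

#' Iterative ensemble-average structure
#'
#' Superposes every frame of every replica onto a running mean structure,
#' recomputes the mean and repeats until the mean moves less than `tol`
#' (at least two passes).
#'
#' @param replicas A `replica_set`.
#' @param selection Selection string used for the superposition fit.
#' @param tol Convergence threshold on the mean shift (Angstrom).
#' @param max_iter Safety cap on iterations.
#' @return Atom tibble: the replicas' topology carrying mean coordinates.
#' @export
average_structure <- function(replicas, selection = "calpha", tol = 1e-6,
                              max_iter = 50) {
  top <- replica_topology(replicas)
  sel <- select_atoms(top, selection, require_n = 3)
  frames <- pooled_frames(replicas)
  mean_xyz <- frames[[1]]
  for (it in seq_len(max_iter)) {
    fitted <- lapply(frames, function(fr) kabsch_superpose(fr, mean_xyz, sel)$fitted)
    new_mean <- Reduce(`+`, fitted) / length(fitted)
    shift <- sqrt(max(rowSums((new_mean - mean_xyz)^2)))
    mean_xyz <- new_mean
    if (it >= 2 && shift < tol) break
  }
  set_atom_coords(top, mean_xyz)
}

#' Per-residue root-mean-square fluctuation
#'
#' Each pooled frame is superposed onto the average structure; the RMSF of
#' an atom is the root of the mean squared displacement from its average
#' position, reported per residue (the Cα atom under the default selection,
#' the mean over residue atoms otherwise). Pooling frames across replicas
#' implements the concatenated-trajectory convention.
#'
#' @param replicas A `replica_set`.
#' @param average Atom tibble from [average_structure()] (computed if
#'   omitted).
#' @param selection Selection string (default `"calpha"`).
#' @return Tibble `chain`, `resno`, `resname`, `rmsf` (Angstrom).
#' @export
rmsf_per_residue <- function(replicas, average = NULL, selection = "calpha") {
  top <- replica_topology(replicas)
  sel <- select_atoms(top, selection, require_n = 3)
  res <- residue_table(top)
  sel_res <- unique(top[sel, c("chain", "resno")])
  miss <- dplyr::anti_join(res[, c("chain", "resno")], sel_res,
                           by = c("chain", "resno"))
  if (nrow(miss) > 0) {
    abort(paste0("selection '", selection, "' misses residue(s): ",
                 paste(paste0(miss$chain, miss$resno), collapse = ", ")))
  }
  if (is.null(average)) average <- average_structure(replicas, selection)
  avg_xyz <- atom_coords(average)
  frames <- pooled_frames(replicas)
  msd <- numeric(nrow(top))
  for (fr in frames) {
    fitted <- kabsch_superpose(fr, avg_xyz, sel)$fitted
    msd <- msd + rowSums((fitted - avg_xyz)^2)
  }
  atom_rmsf <- sqrt(msd / length(frames))
  top$rmsf <- atom_rmsf
  top[sel, ] %>%
    dplyr::group_by(.data$chain, .data$resno, .data$resname) %>%
    dplyr::summarise(rmsf = mean(.data$rmsf), .groups = "drop") %>%
    dplyr::arrange(match(.data$chain, chain_ids(top)), .data$resno)
}

residue_index_map <- function(top) {
  res <- residue_table(top)
  key <- paste(res$chain, res$resno)
  stats::setNames(seq_len(nrow(res)), key)
}

#' Residue contact map of a single frame
#'
#' Two residues are in contact when their minimum heavy-atom distance is
#' within the cutoff. The matrix is symmetric with a true diagonal.
#'
#' @param coords `n_atoms x 3` frame coordinates.
#' @param topology Atom tibble describing the atoms.
#' @param cutoff Contact distance cutoff in Angstrom (default 3.5).
#' @return Logical `n_res x n_res` matrix, residue order as in
#'   [residue_table()]; attributes `chain_boundaries` and `cutoff`.
#' @export
contact_map <- function(coords, topology, cutoff = 3.5) {
  stopifnot(cutoff > 0)
  heavy <- select_atoms(topology, "heavy")
  coords <- as.matrix(coords)[heavy, , drop = FALSE]
  top <- topology[heavy, ]
  rmap <- residue_index_map(topology)
  ridx <- rmap[paste(top$chain, top$resno)]
  nres <- length(rmap)
  d <- as.matrix(stats::dist(coords))
  con <- matrix(FALSE, nres, nres)
  within <- d <= cutoff
  pair <- which(within, arr.ind = TRUE)
  con[cbind(ridx[pair[, 1]], ridx[pair[, 2]])] <- TRUE
  diag(con) <- TRUE
  res <- residue_table(topology)
  attr(con, "chain_boundaries") <- cumsum(table(factor(res$chain, levels = unique(res$chain))))
  attr(con, "cutoff") <- cutoff
  con
}

#' Contact occupancy over a replica set
#'
#' Fraction of (replica, frame-in-window) pairs in which each residue pair
#' is in contact; 0 means the contact never occurred in any replica.
#'
#' @param replicas A `replica_set`.
#' @param window Integer vector of frame indices (default: all frames).
#' @param cutoff Contact cutoff in Angstrom.
#' @return Numeric matrix in `[0,1]` of class `occupancy_matrix` with
#'   attributes `cutoff`, `window`, `n_replicas`, `chain_boundaries`,
#'   `residues`.
#' @export
contact_occupancy <- function(replicas, window = NULL, cutoff = 3.5) {
  top <- replica_topology(replicas)
  nf <- min(replicas$n_frames)
  if (is.null(window)) window <- seq_len(nf)
  if (length(window) == 0 || any(window < 1 | window > nf)) {
    abort("window must be a non-empty set of frame indices present in all replicas")
  }
  frames <- pooled_frames(replicas, window)
  acc <- NULL
  for (fr in frames) {
    cm <- contact_map(fr, top, cutoff)
    acc <- if (is.null(acc)) cm + 0 else acc + cm
  }
  occ <- acc / length(frames)
  res <- residue_table(top)
  structure(occ,
            cutoff = cutoff, window = range(window),
            n_replicas = nrow(replicas),
            chain_boundaries = attr(contact_map(frames[[1]], top, cutoff),
                                    "chain_boundaries"),
            residues = res,
            class = c("occupancy_matrix", "matrix", "array"))
}

#' Geometric hydrogen-bond count of a frame
#'
#' Counts donor-acceptor pairs (N/O donors carrying a hydrogen, N/O
#' acceptors, different residues) with donor-acceptor distance within
#' `d_cutoff` and H-D-A angle within `angle_cutoff`. Structures without
#' hydrogens are handled in a proxy mode that applies the distance
#' criterion between donor heavy atoms and acceptors only; the returned
#' value then carries attribute `proxy = TRUE`.
#'
#' @param coords `n_atoms x 3` frame coordinates.
#' @param topology Atom tibble.
#' @param d_cutoff Donor-acceptor distance cutoff (Angstrom, default 3.5).
#' @param angle_cutoff H-D-A angle cutoff (degrees, default 30).
#' @param bond_max Covalent D-H search distance (Angstrom, default 1.25).
#' @return Integer count with attribute `proxy`.
#' @export
hydrogen_bond_count <- function(coords, topology, d_cutoff = 3.5,
                                angle_cutoff = 30, bond_max = 1.25) {
  coords <- as.matrix(coords)
  el <- toupper(topology$element)
  is_no <- el %in% c("N", "O")
  if (!any(is_no)) {
    warn("no N/O atoms: hydrogen-bond count is 0")
    return(structure(0L, proxy = FALSE))
  }
  h_idx <- which(el == "H")
  proxy <- length(h_idx) == 0
  don_acc <- which(is_no)
  rid <- paste(topology$chain, topology$resno)
  count <- 0L
  if (proxy) {
    d <- as.matrix(stats::dist(coords[don_acc, , drop = FALSE]))
    for (i in seq_along(don_acc)) {
      for (j in seq_along(don_acc)) {
        if (i >= j) next
        if (rid[don_acc[i]] == rid[don_acc[j]]) next
        if (d[i, j] <= d_cutoff) count <- count + 1L
      }
    }
  } else {
    # attach hydrogens to their nearest covalent N/O donor
    donors <- list()
    for (h in h_idx) {
      dd <- sqrt(rowSums((coords[don_acc, , drop = FALSE] -
                            matrix(coords[h, ], length(don_acc), 3,
                                   byrow = TRUE))^2))
      j <- which.min(dd)
      if (dd[j] <= bond_max) {
        donors[[length(donors) + 1]] <- c(D = don_acc[j], H = h)
      }
    }
    for (dh in donors) {
      D <- dh[["D"]]; H <- dh[["H"]]
      for (A in don_acc) {
        if (A == D || rid[A] == rid[D]) next
        da <- coords[A, ] - coords[D, ]
        dist_da <- sqrt(sum(da^2))
        if (dist_da > d_cutoff) next
        dh_vec <- coords[H, ] - coords[D, ]
        cosang <- sum(da * dh_vec) / (dist_da * sqrt(sum(dh_vec^2)))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        if (ang <= angle_cutoff) count <- count + 1L
      }
    }
  }
  structure(as.integer(count), proxy = proxy)
}

#' Mean hydrogen-bond count over a window of a replica set
#'
#' @param replicas A `replica_set`.
#' @param window Frame indices (default all).
#' @param ... Passed to [hydrogen_bond_count()].
#' @return Numeric mean count, attribute `proxy`.
#' @export
hydrogen_bond_mean <- function(replicas, window = NULL, ...) {
  top <- replica_topology(replicas)
  nf <- min(replicas$n_frames)
  if (is.null(window)) window <- seq_len(nf)
  frames <- pooled_frames(replicas, window)
  counts <- vapply(frames, function(fr) {
    as.numeric(hydrogen_bond_count(fr, top, ...))
  }, numeric(1))
  proxy <- attr(hydrogen_bond_count(frames[[1]], top, ...), "proxy")
  structure(mean(counts), proxy = proxy)
}
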