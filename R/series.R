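#' Per-frame geometry series (CCS, SASA, volume) over a replica set
#'
#' Computes, for every frame of every replica, the projection-approximation
#' collision cross-section, the total solvent accessible surface area and
#' the van der Waals volume, and aggregates them per time point across
#' replicas (mean +/- sd, with the per-replica values retained for pooled
#' tail statistics).
#'
#' @param replicas A `replica_set`.
#' @param ccs_probe CCS probe radius in Angstrom (default 1.0).
#' @param sasa_probe SASA probe radius in Angstrom (default 1.4).
#' @param n_orientations Orientations per CCS evaluation (default 32; the
#'   per-frame Monte-Carlo error averages out across the frames and
#'   replicas entering any tail window).
#' @param seed Base seed; each (replica, frame) CCS call gets a distinct
#'   deterministic sub-seed.
#' @param pixel CCS rasterization pixel (Angstrom).
#' @param voxel Volume grid spacing (Angstrom).
#' @param sasa_points Sphere points per atom for SASA.
#' @param metrics Character subset of `c("ccs", "sasa", "volume")`.
#' @return Named list of `series_stat` tibbles, one per metric.
#' @export
frame_geometry_series <- function(replicas, ccs_probe = 1.0, sasa_probe = 1.4,
                                  n_orientations = 32, seed = 1, pixel = 0.5,
                                  voxel = 0.4, sasa_points = 240,
                                  metrics = c("ccs", "sasa", "volume")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  top <- replica_topology(replicas)
  radii <- top$radius
  times <- replicas$trajectory[[1]]$times
  nt <- length(times)
  nr <- nrow(replicas)
  vals <- lapply(metrics, function(m) matrix(NA_real_, nt, nr))
  names(vals) <- metrics
  for (r in seq_len(nr)) {
    tr <- replicas$trajectory[[r]]
    for (k in seq_len(nt)) {
      fr <- tr$frames[[k]]
      if ("ccs" %in% metrics) {
        sub_seed <- (seed + r * 6151L + k * 101L) %% .Machine$integer.max
        vals$ccs[k, r] <- ccs_projection_approximation(
          fr, radii, probe = ccs_probe, n_orientations = n_orientations,
          seed = sub_seed, pixel = pixel)$ccs
      }
      if ("sasa" %in% metrics) {
        vals$sasa[k, r] <- sum(shrake_rupley_sasa(fr, radii,
                                                  probe = sasa_probe,
                                                  n_points = sasa_points))
      }
      if ("volume" %in% metrics) {
        vals$volume[k, r] <- molecular_volume(fr, radii, voxel = voxel)
      }
    }
  }
  labels <- c(ccs = "PA CCS [A^2]", sasa = "SASA [A^2]", volume = "vdW volume [A^3]")
  out <- lapply(metrics, function(m) {
    v <- vals[[m]]
    new_series(
      time = times,
      mean = rowMeans(v),
      spread = apply(v, 1, stats::sd),
      values = lapply(seq_len(nt), function(i) v[i, ]),
      label = labels[[m]]
    )
  })
  names(out) <- metrics
  out
}
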