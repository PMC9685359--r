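#' Tail-window average of a metric series
#'
#' Averages the final fraction of a series (the relatively linear tail used
#' for phase-level estimates). When the series carries per-replica values
#' (a `values` list-column as produced by the series builders), the mean
#' and sem are computed over the pooled replica values in the tail;
#' otherwise over the tail means.
#'
#' @param series A `series_stat` tibble (columns `time`, `mean`, optional
#'   `values`).
#' @param tail_fraction Fraction of points, from the end, to average
#'   (default 0.1 — e.g. the last 50 ns of a 500 ns trajectory).
#' @return Tibble with one row: `mean`, `sem`, `n`, `t_start`, `t_end`.
#' @export
tail_average <- function(series, tail_fraction = 0.1) {
  if (nrow(series) == 0) abort("empty series")
  stopifnot(tail_fraction > 0, tail_fraction <= 1)
  n_tail <- max(1L, floor(nrow(series) * tail_fraction))
  idx <- seq(nrow(series) - n_tail + 1L, nrow(series))
  if ("values" %in% names(series)) {
    pool <- unlist(series$values[idx])
  } else {
    pool <- series$mean[idx]
  }
  sem <- if (length(pool) > 1) stats::sd(pool) / sqrt(length(pool)) else 0
  tibble::tibble(mean = mean(pool), sem = sem, n = length(pool),
                 t_start = series$time[idx[1]],
                 t_end = series$time[idx[length(idx)]])
}

#' Percent compaction of a vacuum tail average relative to a bulk reference
#'
#' `100 * (bulk_ref - vacuum_tail) / bulk_ref`; positive when the vacuum
#' structure is smaller than the solution reference.
#'
#' @param bulk_ref Bulk-phase reference value (> 0).
#' @param vacuum_tail Vacuum-phase tail-window average.
#' @return Percentage.
#' @export
compaction_percent <- function(bulk_ref, vacuum_tail) {
  stopifnot(bulk_ref > 0)
  100 * (bulk_ref - vacuum_tail) / bulk_ref
}

#' Solution-structure recovery percentage and gap
#'
#' The gap is `bulk_ref - rehydration_tail`; recovery is
#' `100 * (1 - |gap| / bulk_ref)`, so overshooting the reference also
#' lowers the score.
#'
#' @param bulk_ref Bulk-phase reference value (> 0).
#' @param rehydration_tail Rehydration-phase tail-window average.
#' @return Tibble with `recovery_pct` and `gap` (same units as the input).
#' @export
recovery_percent <- function(bulk_ref, rehydration_tail) {
  stopifnot(bulk_ref > 0)
  gap <- bulk_ref - rehydration_tail
  tibble::tibble(recovery_pct = 100 * (1 - abs(gap) / bulk_ref), gap = gap)
}

#' Contact-map recovery fractions
#'
#' Binarizes three occupancy matrices at a presence threshold and compares
#' the unordered off-diagonal contact sets: `restored_fraction` is the
#' share of bulk contacts present again after rehydration;
#' `persistent_vacuum_fraction` is the share of vacuum-only contacts (in
#' vacuum but not bulk) that survive rehydration.
#'
#' @param bulk_occ,vacuum_occ,rehydration_occ `occupancy_matrix` objects of
#'   identical dimensions.
#' @param presence_threshold Occupancy above which a contact counts as
#'   present (default 0.5).
#' @return Tibble with `restored_fraction`, `persistent_vacuum_fraction`,
#'   `n_bulk_contacts`, `n_vacuum_only`.
#' @export
contact_recovery <- function(bulk_occ, vacuum_occ, rehydration_occ,
                             presence_threshold = 0.5) {
  if (!all(dim(bulk_occ) == dim(vacuum_occ)) ||
      !all(dim(bulk_occ) == dim(rehydration_occ))) {
    abort("occupancy matrices must share dimensions")
  }
  ut <- upper.tri(bulk_occ)
  b <- bulk_occ > presence_threshold & ut
  v <- vacuum_occ > presence_threshold & ut
  r <- rehydration_occ > presence_threshold & ut
  nb <- sum(b)
  if (nb == 0) abort("empty bulk contact set: recovery fractions undefined")
  vac_only <- v & !b
  nv <- sum(vac_only)
  tibble::tibble(
    restored_fraction = sum(b & r) / nb,
    persistent_vacuum_fraction = if (nv > 0) sum(vac_only & r) / nv else NA_real_,
    n_bulk_contacts = nb,
    n_vacuum_only = nv
  )
}

#' Net-charge bookkeeping for chain-symmetric protonation
#'
#' @param solution_charge Net solution charge (e).
#' @param sites_per_chain Protonation sites accepted per chain.
#' @param n_chains Number of sequence-identical chains.
#' @return Resulting vacuum net charge (e).
#' @export
charge_bookkeeping <- function(solution_charge, sites_per_chain, n_chains) {
  stopifnot(sites_per_chain >= 0, n_chains >= 0)
  solution_charge + sites_per_chain * n_chains
}

#' Percent change of a fluctuation value between phases
#'
#' `100 * (value_rehydrated - value_vacuum) / value_vacuum`; negative when
#' the fluctuation decreases on rehydration.
#'
#' @param value_vacuum Vacuum-phase value (> 0).
#' @param value_rehydrated Rehydration-phase value.
#' @return Percentage.
#' @export
rmsf_change_percent <- function(value_vacuum, value_rehydrated) {
  stopifnot(value_vacuum > 0)
  100 * (value_rehydrated - value_vacuum) / value_vacuum
}

#' Assemble a recovery report from per-phase metric series
#'
#' Takes per-phase series of CCS, SASA and volume (as produced by
#' [frame_geometry_series()]), occupancy matrices and hydrogen-bond means,
#' and computes tail averages, per-metric compaction and recovery
#' percentages, the CCS gap and contact-recovery fractions.
#'
#' @param series Named list `bulk`, `vacuum`, `rehydration`; each a named
#'   list of `series_stat` tibbles for metrics `ccs`, `sasa`, `volume`.
#' @param occupancy Named list `bulk`, `vacuum`, `rehydration` of
#'   `occupancy_matrix` objects (optional, NULL to skip).
#' @param hbonds Named numeric vector/list of per-phase mean hydrogen-bond
#'   counts (optional).
#' @param tail_fraction Tail window as a fraction of frames (default 0.1).
#' @param presence_threshold Contact binarization threshold (default 0.5).
#' @return A `recovery_report` list.
#' @export
recovery_report <- function(series, occupancy = NULL, hbonds = NULL,
                            tail_fraction = 0.1, presence_threshold = 0.5) {
  metrics <- names(series$bulk)
  tails <- list()
  per_metric <- list()
  for (m in metrics) {
    bulk <- tail_average(series$bulk[[m]], tail_fraction)
    vac <- tail_average(series$vacuum[[m]], tail_fraction)
    reh <- tail_average(series$rehydration[[m]], tail_fraction)
    rec <- recovery_percent(bulk$mean, reh$mean)
    per_metric[[m]] <- tibble::tibble(
      metric = m,
      bulk_ref = bulk$mean, bulk_sem = bulk$sem,
      vacuum_tail = vac$mean, vacuum_sem = vac$sem,
      rehydration_tail = reh$mean, rehydration_sem = reh$sem,
      compaction_pct = compaction_percent(bulk$mean, vac$mean),
      recovery_pct = rec$recovery_pct,
      gap = rec$gap
    )
    tails[[m]] <- list(bulk = bulk, vacuum = vac, rehydration = reh)
  }
  summary <- dplyr::bind_rows(per_metric)
  contacts <- NULL
  if (!is.null(occupancy)) {
    contacts <- contact_recovery(occupancy$bulk, occupancy$vacuum,
                                 occupancy$rehydration, presence_threshold)
  }
  structure(
    list(summary = summary, tails = tails, contacts = contacts,
         hbonds = hbonds, tail_fraction = tail_fraction,
         presence_threshold = presence_threshold),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> tail fraction", x$tail_fraction, "\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %-7s bulk %10.2f  vacuum %10.2f (compaction %5.2f%%)  rehydrated %10.2f (recovery %6.2f%%, gap %8.2f)\n",
      s$metric[i], s$bulk_ref[i], s$vacuum_tail[i], s$compaction_pct[i],
      s$rehydration_tail[i], s$recovery_pct[i], s$gap[i]))
  }
  if (!is.null(x$contacts)) {
    cat(sprintf("  contacts: restored %.3f, persistent vacuum-only %.3f (of %d)\n",
                x$contacts$restored_fraction,
                x$contacts$persistent_vacuum_fraction,
                x$contacts$n_vacuum_only))
  }
  if (!is.null(x$hbonds)) {
    cat("  mean H-bonds:", paste(names(x$hbonds), round(unlist(x$hbonds), 1),
                                 collapse = ", "), "\n")
  }
  invisible(x)
}

#' Broom-style accessors for vacuform result objects
#'
#' `tidy()` returns per-site or per-metric detail rows; `glance()` returns
#' a one-row summary.
#'
#' @param x A `protonation_plan` or `recovery_report`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_vacuform
NULL

#' @rdname tidy_vacuform
#' @export
tidy.recovery_report <- function(x, ...) {
  x$summary
}

#' @rdname tidy_vacuform
#' @export
glance.recovery_report <- function(x, ...) {
  ccs <- x$summary[x$summary$metric == "ccs", ]
  out <- tibble::tibble(
    ccs_compaction_pct = ccs$compaction_pct,
    ccs_recovery_pct = ccs$recovery_pct,
    ccs_gap = ccs$gap,
    tail_fraction = x$tail_fraction
  )
  if (!is.null(x$contacts)) {
    out$restored_fraction <- x$contacts$restored_fraction
    out$persistent_vacuum_fraction <- x$contacts$persistent_vacuum_fraction
  }
  out
}
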