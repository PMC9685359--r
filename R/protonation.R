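#' Default gas-phase basicity table
#'
#' Relative gas-phase basicities (kJ/mol) for the six residue types
#' considered as vacuum protonation sites. The ordering (Arg > His > Lys >
#' Gln > Glu > Asp) follows the proton-affinity literature for amino-acid
#' side chains; absolute values only matter through their rank, and the
#' table is user-overridable.
#'
#' @return Named numeric vector (kJ/mol) for LYS, ARG, HIS, GLN, ASP, GLU.
#' @export
default_gpb_table <- function() {
  c(ARG = 1007, HIS = 958, LYS = 951, GLN = 937, GLU = 910, ASP = 885)
}

CANDIDATE_TYPES <- c("LYS", "ARG", "HIS", "GLN", "ASP", "GLU")

#' Per-residue mean solvent accessible surface area over a trajectory
#'
#' Computes Shrake-Rupley per-atom areas for every frame, sums them within
#' residues, and averages over frames (mean +/- sd across frames).
#'
#' @param trajectory A `traj_ensemble` (or a `replica_set`, whose frames
#'   are pooled).
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param restrict Optional character vector of residue types to report
#'   (e.g. the six protonation-candidate types); `NULL` keeps all.
#' @param n_points Sphere points per atom for the SASA kernel.
#' @return Tibble `chain`, `resno`, `resname`, `mean_sasa`, `sd_sasa`
#'   (Angstrom^2).
#' @export
per_residue_sasa <- function(trajectory, probe = 1.4, restrict = NULL,
                             n_points = 960) {
  if (inherits(trajectory, "replica_set")) {
    top <- replica_topology(trajectory)
    frames <- pooled_frames(trajectory)
  } else {
    top <- trajectory$topology
    frames <- trajectory$frames
  }
  if (length(frames) == 0) abort("trajectory has no frames")
  if (!is.null(restrict) && length(restrict) == 0) {
    abort("empty residue-type restriction set")
  }
  key <- paste(top$chain, top$resno)
  res <- residue_table(top)
  rkey <- paste(res$chain, res$resno)
  per_frame <- vapply(frames, function(fr) {
    a <- shrake_rupley_sasa(fr, top$radius, probe = probe, n_points = n_points)
    as.numeric(tapply(a, factor(key, levels = rkey), sum))
  }, numeric(nrow(res)))
  per_frame <- matrix(per_frame, nrow = nrow(res))
  out <- res
  out$mean_sasa <- rowMeans(per_frame)
  out$sd_sasa <- apply(per_frame, 1, stats::sd)
  out$sd_sasa[is.na(out$sd_sasa)] <- 0
  if (!is.null(restrict)) out <- out[out$resname %in% restrict, ]
  tibble::as_tibble(out)
}

#' Select protonation candidates by SASA threshold and GPB rank
#'
#' Restricts a per-residue SASA table to the six candidate residue types,
#' drops residues whose mean SASA is below the threshold (strictly smaller
#' areas are disregarded), and orders the survivors by gas-phase basicity
#' descending, ties broken by larger SASA, then lower residue number.
#'
#' @param sasa_table Output of [per_residue_sasa()].
#' @param gpb Named numeric GPB table (see [default_gpb_table()]).
#' @param threshold SASA threshold in Angstrom^2 (default 50).
#' @return Tibble of candidate sites: `chain`, `resno`, `resname`,
#'   `mean_sasa`, `sd_sasa`, `gpb`, `excluded`, `reason`, `selected`.
#' @export
select_candidates <- function(sasa_table, gpb = default_gpb_table(),
                              threshold = 50) {
  tab <- sasa_table[sasa_table$resname %in% CANDIDATE_TYPES, ]
  tab <- tab[tab$mean_sasa >= threshold, ]
  tab$gpb <- unname(gpb[tab$resname])
  if (any(is.na(tab$gpb))) {
    abort("GPB table lacks a value for a candidate residue type")
  }
  tab <- tab[order(-tab$gpb, -tab$mean_sasa, tab$resno), ]
  tab$excluded <- FALSE
  tab$reason <- ""
  tab$selected <- FALSE
  tibble::as_tibble(tab)
}

ONE_LETTER <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Mark candidates adjacent to positive charges as excluded
#'
#' Implements the Coulomb-repulsion skip: a candidate is excluded when a
#' residue already carrying formal charge +1 sits next to it. `sequence`
#' mode (default, parameter-free) looks at positions +/-1 in the same
#' chain; `spatial` mode excludes candidates whose side-chain centroid lies
#' within `spatial_cutoff` of any +1 residue's centroid.
#'
#' @param candidates Tibble from [select_candidates()].
#' @param structure Atom tibble with solution formal charges assigned.
#' @param mode `"sequence"` or `"spatial"`.
#' @param spatial_cutoff Centroid distance cutoff in Angstrom (required in
#'   spatial mode).
#' @return The candidates tibble with `excluded`/`reason` filled in.
#' @export
apply_neighbor_exclusion <- function(candidates, structure,
                                     mode = c("sequence", "spatial"),
                                     spatial_cutoff = NULL) {
  mode <- match.arg(mode)
  rc <- residue_charges(structure)
  pos <- rc[rc$charge > 0, ]
  # chain termini are never protonation sites: their exposure and charge
  # are dominated by the terminal amine/carboxylate groups
  term <- dplyr::bind_rows(lapply(split(rc, rc$chain), function(g) {
    g[c(which.min(g$resno), which.max(g$resno)), c("chain", "resno")]
  }))
  if (mode == "spatial" && is.null(spatial_cutoff)) {
    abort("spatial neighbor mode requires a spatial_cutoff")
  }
  cent <- NULL
  if (mode == "spatial") {
    xyz <- atom_coords(structure)
    key <- paste(structure$chain, structure$resno)
    cent <- rowsum(xyz, key) / as.vector(table(key)[unique(key)])
  }
  for (i in seq_len(nrow(candidates))) {
    ch <- candidates$chain[i]; rn <- candidates$resno[i]
    if (any(term$chain == ch & term$resno == rn)) {
      candidates$excluded[i] <- TRUE
      candidates$reason[i] <- "chain terminus"
      next
    }
    if (mode == "sequence") {
      nb <- pos[pos$chain == ch & abs(pos$resno - rn) == 1, ]
      if (nrow(nb) > 0) {
        off <- ifelse(nb$resno[1] > rn, "i+1", "i-1")
        code <- ONE_LETTER[nb$resname[1]]
        if (is.na(code)) code <- nb$resname[1]
        candidates$excluded[i] <- TRUE
        candidates$reason[i] <- paste0("positive neighbor ", code, " at ", off)
      }
    } else {
      ci <- cent[paste(ch, rn), ]
      for (j in seq_len(nrow(pos))) {
        cj <- cent[paste(pos$chain[j], pos$resno[j]), ]
        dd <- sqrt(sum((ci - cj)^2))
        if (dd <= spatial_cutoff) {
          candidates$excluded[i] <- TRUE
          candidates$reason[i] <- sprintf(
            "positive residue %s%d within %.1f A", pos$chain[j],
            pos$resno[j], dd)
          break
        }
      }
    }
  }
  candidates
}

#' Build a vacuum protonation plan to a target net charge
#'
#' Walks the GPB-ranked, non-excluded candidate list and accepts sites
#' until the target net charge is reached exactly. Each accepted
#' protonation adds +1 e: acidic sites (Asp/Glu) are neutralised (-1 to 0),
#' His/Gln gain +1; Lys and Arg, already protonated at pH 7, are visited
#' but skipped. In symmetric mode the sequence-identical chains are treated
#' as one: an accepted position is applied to every chain simultaneously
#' and must be eligible in all of them.
#'
#' @param structure Atom tibble with solution charges assigned.
#' @param candidates Tibble from [apply_neighbor_exclusion()].
#' @param target_charge Desired net charge in elementary charges.
#' @param symmetric Apply sites identically across chains (default TRUE).
#' @return A `protonation_plan`: list with `sites` (every visited site and
#'   its outcome), `target_charge`, `initial_charge`, `resulting_charge`,
#'   `selected` (accepted sites), `symmetric`.
#' @export
build_protonation_plan <- function(structure, candidates, target_charge,
                                   symmetric = TRUE) {
  initial <- net_charge(structure)
  if (target_charge < initial) {
    abort(paste0("target charge ", target_charge,
                 " below current net charge ", initial))
  }
  chains <- chain_ids(structure)
  n_chains <- length(chains)
  need <- target_charge - initial
  if (symmetric) {
    seqs <- chain_sequences(structure)
    if (length(unique(vapply(seqs, paste, character(1), collapse = ","))) != 1) {
      abort("symmetric mode requires sequence-identical chains")
    }
    if (need %% n_chains != 0) {
      abort(paste0("parity error: charge deficit ", need,
                   " not divisible by ", n_chains, " chains"))
    }
  }
  cand <- candidates
  cand$outcome <- ""
  got <- 0L
  if (symmetric) {
    # walk unique positions in ranked order; require eligibility in all chains
    for (i in seq_len(nrow(cand))) {
      if (cand$outcome[i] != "") next
      if (got >= need) { cand$outcome[i] <- "not needed"; next }
      rn <- cand$resno[i]
      rows <- which(cand$resno == rn)
      if (cand$resname[i] %in% c("LYS", "ARG")) {
        cand$outcome[rows] <- "skipped: already protonated at pH 7"
        next
      }
      if (length(rows) < n_chains || any(cand$excluded[rows])) {
        why <- if (any(cand$excluded[rows])) {
          paste0("excluded: ", cand$reason[rows][cand$excluded[rows]][1])
        } else "ineligible in at least one chain"
        cand$outcome[rows] <- why
        next
      }
      cand$selected[rows] <- TRUE
      cand$outcome[rows] <- "selected"
      got <- got + n_chains
    }
  } else {
    for (i in seq_len(nrow(cand))) {
      if (got >= need) { cand$outcome[i] <- "not needed"; next }
      if (cand$resname[i] %in% c("LYS", "ARG")) {
        cand$outcome[i] <- "skipped: already protonated at pH 7"
        next
      }
      if (cand$excluded[i]) {
        cand$outcome[i] <- paste0("excluded: ", cand$reason[i])
        next
      }
      cand$selected[i] <- TRUE
      cand$outcome[i] <- "selected"
      got <- got + 1L
    }
  }
  if (got < need) {
    abort(paste0("insufficient sites: need ", need, " protonation(s), found ",
                 got, " (shortfall ", need - got, ")"))
  }
  structure(
    list(sites = cand, target_charge = as.integer(target_charge),
         initial_charge = initial,
         resulting_charge = initial + got,
         selected = cand[cand$selected, ],
         symmetric = symmetric),
    class = "protonation_plan"
  )
}

#' @export
print.protonation_plan <- function(x, ...) {
  cat(sprintf("<protonation_plan> %+d e -> %+d e (target %+d e), %d site(s)%s\n",
              x$initial_charge, x$resulting_charge, x$target_charge,
              nrow(x$selected), if (x$symmetric) ", chain-symmetric" else ""))
  if (nrow(x$selected) > 0) {
    sel <- x$selected
    from <- ifelse(sel$resname %in% c("ASP", "GLU"), -1L, 0L)
    cat(sprintf("  %s%-4d %s  SASA %7.2f (+/-%.2f) A^2   %+d -> %+d\n",
                sel$chain, sel$resno, sel$resname, sel$mean_sasa,
                sel$sd_sasa, from, from + 1L), sep = "")
  }
  invisible(x)
}

#' Apply a protonation plan to a structure
#'
#' Acidic sites (Asp/Glu) go from -1 to 0; His/Gln sites from 0 to +1.
#' Re-applying a plan whose sites are already protonated is an error.
#'
#' @param structure Atom tibble with solution charges assigned.
#' @param plan A `protonation_plan`.
#' @return Atom tibble with updated formal charges; its [net_charge()]
#'   equals `plan$resulting_charge`.
#' @export
apply_plan <- function(structure, plan) {
  sel <- plan$selected
  if (nrow(sel) == 0) return(structure)
  rc <- residue_charges(structure)
  for (i in seq_len(nrow(sel))) {
    ch <- sel$chain[i]; rn <- sel$resno[i]; nm <- sel$resname[i]
    cur <- rc$charge[rc$chain == ch & rc$resno == rn]
    if (length(cur) != 1) abort(paste0("plan site ", ch, rn, " not in structure"))
    expected <- if (nm %in% c("ASP", "GLU")) -1L else 0L
    if (cur != expected) {
      abort(paste0("double protonation: ", ch, rn, " ", nm,
                   " already at charge ", cur))
    }
    rows <- which(structure$chain == ch & structure$resno == rn)
    structure$charge[rows[1]] <- structure$charge[rows[1]] + 1L
  }
  structure
}

#' @rdname tidy_vacuform
#' @export
tidy.protonation_plan <- function(x, ...) {
  sites <- tibble::as_tibble(x$sites)
  sites$solution_charge <- ifelse(sites$resname %in% c("ASP", "GLU"), -1L,
                                  ifelse(sites$resname %in% c("LYS", "ARG"), 1L, 0L))
  sites$vacuum_charge <- sites$solution_charge + as.integer(sites$selected)
  sites
}

#' @rdname tidy_vacuform
#' @export
glance.protonation_plan <- function(x, ...) {
  tibble::tibble(
    initial_charge = x$initial_charge,
    target_charge = x$target_charge,
    resulting_charge = x$resulting_charge,
    n_selected = nrow(x$selected),
    n_candidates = nrow(x$sites),
    symmetric = x$symmetric
  )
}
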