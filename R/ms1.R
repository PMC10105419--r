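# MS1 linking: enumerate modified peptide species from candidate cores and
# match them to observed high-resolution MS1 peaks within a ppm tolerance.

#' Define the modification space searched during MS1 linking
#'
#' Bounds on the anticipated post-translational modifications applied to a
#' predicted core peptide: dehydration (-H2O, on Ser/Thr), methylation
#' (+CH2) and dehydrogenation (-H2, e.g. a disulfide). The dehydration
#' bound `"auto"` resolves per core to its Ser+Thr count.
#'
#' @param max_dehydrations integer bound or `"auto"`.
#' @param allow_methylation,allow_dehydrogenation logical flags.
#' @param max_methylations,max_dehydrogenations count limits used when the
#'   corresponding flag is TRUE.
#' @param charge_states integer charge states assumed for peaks without a
#'   charge annotation.
#' @return object of class `modspace`.
#' @export
modification_space <- function(max_dehydrations = "auto",
                               allow_methylation = FALSE,
                               max_methylations = 1L,
                               allow_dehydrogenation = FALSE,
                               max_dehydrogenations = 1L,
                               charge_states = 1:3) {
  if (!identical(max_dehydrations, "auto")) {
    stopifnot(max_dehydrations >= 0)
  }
  stopifnot(max_methylations >= 0, max_dehydrogenations >= 0,
            all(charge_states >= 1))
  structure(list(
    max_dehydrations = max_dehydrations,
    allow_methylation = isTRUE(allow_methylation),
    max_methylations = as.integer(max_methylations),
    allow_dehydrogenation = isTRUE(allow_dehydrogenation),
    max_dehydrogenations = as.integer(max_dehydrogenations),
    charge_states = as.integer(charge_states)
  ), class = "modspace")
}

#' Resolve the dehydration bound of a space for a given core
#' @param core core peptide sequence.
#' @param space `modspace`.
#' @return integer bound (`"auto"` = number of Ser + Thr in the core).
#' @export
dehydration_bound <- function(core, space) {
  if (identical(space$max_dehydrations, "auto")) {
    sum(strsplit(core, "")[[1]] %in% c("S", "T"))
  } else {
    as.integer(space$max_dehydrations)
  }
}

#' Enumerate modified peptide species for a core peptide
#'
#' Cartesian product of modification counts within the space's bounds,
#' deduplicated by net molecular formula (isobaric count-vectors collapse to
#' one species; all generating count-vectors are retained in the
#' `provenance` attribute).
#'
#' @param core core peptide sequence.
#' @param space `modspace`.
#' @return data.frame with columns core, n_dehydration, n_methylation,
#'   n_dehydrogenation, n_mods, formula, mass; attribute `provenance` maps
#'   formula -> matrix of generating count vectors.
#' @export
enumerate_species <- function(core, space = modification_space()) {
  stopifnot(nchar(core) > 0)
  base <- peptide_formula(core)
  d_max <- dehydration_bound(core, space)
  m_max <- if (space$allow_methylation) space$max_methylations else 0L
  g_max <- if (space$allow_dehydrogenation) space$max_dehydrogenations else 0L
  grid <- expand.grid(n_dehydration = 0:d_max, n_methylation = 0:m_max,
                      n_dehydrogenation = 0:g_max)
  grid <- grid[order(grid$n_dehydration + grid$n_methylation +
                       grid$n_dehydrogenation), , drop = FALSE]
  keep <- list(); prov <- list()
  for (i in seq_len(nrow(grid))) {
    mods <- modification_set(grid$n_dehydration[i], grid$n_methylation[i],
                             grid$n_dehydrogenation[i])
    f <- tryCatch(apply_modifications(base, mods), error = function(e) NULL)
    if (is.null(f)) next  # infeasible (counts driven negative)
    key <- format_formula(f)
    cv <- c(grid$n_dehydration[i], grid$n_methylation[i],
            grid$n_dehydrogenation[i])
    if (is.null(prov[[key]])) {
      keep[[key]] <- data.frame(
        core = core,
        n_dehydration = cv[1], n_methylation = cv[2],
        n_dehydrogenation = cv[3], n_mods = sum(cv),
        formula = key, mass = monoisotopic_mass(f),
        stringsAsFactors = FALSE)
      prov[[key]] <- matrix(cv, nrow = 1,
                            dimnames = list(NULL, c("dehydration",
                                                    "methylation",
                                                    "dehydrogenation")))
    } else {
      prov[[key]] <- rbind(prov[[key]], cv)
    }
  }
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  attr(out, "provenance") <- prov
  out
}

#' Match MS1 peaks to enumerated peptide species
#'
#' For each peak and each (species, charge) pair — the peak's own charge if
#' annotated, otherwise every charge in `charges` — a match is emitted when
#' the absolute ppm error of the observed m/z against the theoretical
#' \[M + zH\]z+ is at most `tol_ppm`. Complete: equivalent to the all-pairs
#' brute-force check.
#'
#' @param peaks data.frame with column `mz`, optional `intensity` and `z`.
#' @param species data.frame from [enumerate_species()] (rows may be pooled
#'   across cores).
#' @param charges integer charges tried for unannotated peaks.
#' @param tol_ppm matching tolerance in ppm (> 0).
#' @return data.frame of matches: peak_mz, intensity, z, core,
#'   n_dehydration, n_methylation, n_dehydrogenation, n_mods, formula,
#'   theoretical_mz, ppm, abs_ppm.
#' @export
match_ms1 <- function(peaks, species, charges = 1:3, tol_ppm = 10) {
  stopifnot(tol_ppm > 0)
  empty <- data.frame(peak_mz = numeric(), intensity = numeric(),
                      z = integer(), core = character(),
                      n_dehydration = integer(), n_methylation = integer(),
                      n_dehydrogenation = integer(), n_mods = integer(),
                      formula = character(), theoretical_mz = numeric(),
                      ppm = numeric(), abs_ppm = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(species) || !nrow(species) || !nrow(peaks)) return(empty)
  if (!"intensity" %in% names(peaks)) peaks$intensity <- 1
  if (!"z" %in% names(peaks)) peaks$z <- NA_integer_
  rows <- list()
  for (p in seq_len(nrow(peaks))) {
    zs <- if (!is.na(peaks$z[p])) peaks$z[p] else charges
    for (z in zs) {
      theo <- mz_from_neutral(species$mass, z)
      ppm <- ppm_error(peaks$mz[p], theo)
      sel <- which(abs(ppm) <= tol_ppm)
      if (!length(sel)) next
      rows[[length(rows) + 1L]] <- data.frame(
        peak_mz = peaks$mz[p], intensity = peaks$intensity[p], z = z,
        core = species$core[sel],
        n_dehydration = species$n_dehydration[sel],
        n_methylation = species$n_methylation[sel],
        n_dehydrogenation = species$n_dehydrogenation[sel],
        n_mods = species$n_mods[sel],
        formula = species$formula[sel],
        theoretical_mz = theo[sel], ppm = ppm[sel], abs_ppm = abs(ppm[sel]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank MS1 matches
#'
#' Lexicographic: fewest total modifications, then smallest absolute ppm
#' error, then lower charge. Stable.
#'
#' @param matches data.frame from [match_ms1()].
#' @return the same rows, ranked, with a `rank` column.
#' @export
rank_matches <- function(matches) {
  if (!nrow(matches)) {
    matches$rank <- integer(0)
    return(matches)
  }
  ord <- order(matches$n_mods, matches$abs_ppm, matches$z)
  out <- matches[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Link precursor candidates to MS1 peaks
#'
#' For every candidate and every leader/core split hypothesis, enumerates
#' modified species, matches them against the peak list and keeps the
#' best-ranked match per split, with full provenance (ORF coordinates,
#' split, modification counts, charge, ppm error).
#'
#' @param candidates data.frame from [filter_precursors()].
#' @param peaks MS1 peak data.frame (columns mz, optional intensity, z).
#' @param space `modspace`.
#' @param tol_ppm MS1 tolerance in ppm.
#' @param min_core,max_core core length bounds for split enumeration.
#' @return data.frame (possibly empty) with one row per (candidate, split)
#'   that has at least one match, plus all ranked matches as attribute
#'   `all_matches`.
#' @export
link_bgc_to_peaks <- function(candidates, peaks, space = modification_space(),
                              tol_ppm = 10, min_core = 5, max_core = 50) {
  empty <- data.frame(candidate = integer(), contig = character(),
                      orf_start = integer(), orf_end = integer(),
                      strand = character(), split = integer(),
                      leader = character(), core = character(),
                      motif_consistent = logical(), peak_mz = numeric(),
                      z = integer(), n_dehydration = integer(),
                      n_methylation = integer(),
                      n_dehydrogenation = integer(), n_mods = integer(),
                      formula = character(), theoretical_mz = numeric(),
                      ppm = numeric(), abs_ppm = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(candidates) || !nrow(peaks)) {
    attr(empty, "all_matches") <- list()
    return(empty)
  }
  links <- list(); all_matches <- list()
  for (i in seq_len(nrow(candidates))) {
    splits <- enumerate_core_splits(candidates$aa[i], min_core, max_core)
    for (s in seq_len(nrow(splits))) {
      sp <- enumerate_species(splits$core[s], space)
      m <- rank_matches(match_ms1(peaks, sp, space$charge_states, tol_ppm))
      if (!nrow(m)) next
      best <- m[1, , drop = FALSE]
      links[[length(links) + 1L]] <- data.frame(
        candidate = i, contig = candidates$contig[i],
        orf_start = candidates$start[i], orf_end = candidates$end[i],
        strand = candidates$strand[i], split = splits$split[s],
        leader = splits$leader[s], core = splits$core[s],
        motif_consistent = splits$motif_consistent[s],
        peak_mz = best$peak_mz, z = best$z,
        n_dehydration = best$n_dehydration,
        n_methylation = best$n_methylation,
        n_dehydrogenation = best$n_dehydrogenation,
        n_mods = best$n_mods, formula = best$formula,
        theoretical_mz = best$theoretical_mz,
        ppm = best$ppm, abs_ppm = best$abs_ppm,
        stringsAsFactors = FALSE)
      all_matches[[paste(i, splits$split[s], sep = ":")]] <- m
    }
  }
  if (!length(links)) {
    attr(empty, "all_matches") <- list()
    return(empty)
  }
  out <- do.call(rbind, links)
  # best links first: fewest modifications, then ppm
  out <- out[order(out$n_mods, out$abs_ppm), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_matches") <- all_matches
  out
}
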