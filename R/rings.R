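# Thioether ring topology: classification, ring-aware b/y fragment
# generation (C-gamma--S rupture pathway), spectrum annotation, topology
# scoring, and reductive-desulfurization simulation (NaBH4/NaBD4).
#
# Ring chemistry bookkeeping, relative to the genetically encoded residues:
# each crosslink consumes one dehydration on its Ser/Thr donor; when a
# fragmentation event cleaves the backbone inside a ring, the C-gamma--S
# bond of the Cys-derived residue breaks so that the sulfur stays on the
# donor side: the Cys-derived residue is observed as Dha (-H2S, nominal
# -34 Da) and the donor-derived residue as donor - H2O + H2S (net +S-O,
# nominal +16 Da).

#' Construct a thioether ring topology
#'
#' A set of (donor, acceptor) crosslinks on a core peptide, 1-based residue
#' positions. Donors must be Ser or Thr (the dehydrated partner), acceptors
#' must be Cys; a residue can participate in at most one link. Link type is
#' Lan for a Ser donor, MeLan for a Thr donor.
#'
#' @param donors,acceptors equal-length integer vectors of 1-based core
#'   positions.
#' @param core core peptide sequence the links live on.
#' @return object of class `ringtop`: data.frame (donor, acceptor, type)
#'   with the core as an attribute.
#' @export
ring_topology <- function(donors, acceptors, core) {
  stopifnot(length(donors) == length(acceptors))
  aa <- strsplit(core, "")[[1]]
  n <- length(aa)
  idx <- c(donors, acceptors)
  if (length(idx)) {
    if (any(idx < 1 | idx > n)) stop("crosslink position outside the core")
    if (anyDuplicated(idx)) {
      stop("invalid topology: residue used by more than one crosslink")
    }
    bad_d <- donors[!aa[donors] %in% c("S", "T")]
    if (length(bad_d)) {
      stop("donor position ", bad_d[1], " is ", aa[bad_d[1]],
           ", must be Ser or Thr")
    }
    bad_a <- acceptors[aa[acceptors] != "C"]
    if (length(bad_a)) {
      stop("acceptor position ", bad_a[1], " is ", aa[bad_a[1]],
           ", must be Cys")
    }
  }
  links <- data.frame(
    donor = as.integer(donors), acceptor = as.integer(acceptors),
    type = ifelse(aa[donors] == "T", "MeLan", "Lan"),
    stringsAsFactors = FALSE)
  if (!length(donors)) {
    links <- data.frame(donor = integer(), acceptor = integer(),
                        type = character(), stringsAsFactors = FALSE)
  }
  structure(links, class = c("ringtop", "data.frame"), core = core)
}

#' @export
print.ringtop <- function(x, ...) {
  core <- attr(x, "core")
  cat("<ringtop> on ", core, "\n", sep = "")
  if (nrow(x)) {
    aa <- strsplit(core, "")[[1]]
    for (i in seq_len(nrow(x))) {
      cat("  ", x$type[i], ": ", aa[x$donor[i]], x$donor[i], " - Cys",
          x$acceptor[i], "\n", sep = "")
    }
    cat("  class: ", classify_topology(x), "\n", sep = "")
  } else cat("  (no crosslinks)\n")
  invisible(x)
}

#' Serialize a topology as a compact string (e.g. "T5-C2,S10-C6")
#' @param rings `ringtop`.
#' @export
format_topology <- function(rings) {
  if (!nrow(rings)) return("(none)")
  aa <- strsplit(attr(rings, "core"), "")[[1]]
  paste(sprintf("%s%d-C%d", aa[rings$donor], rings$donor, rings$acceptor),
        collapse = ",")
}

#' Classify a ring topology as disjoint, nested or interlocking
#'
#' Interval algebra on the (min, max) span of each crosslink:
#' `disjoint` if all spans are pairwise non-overlapping (the simple
#' "bicycle" pattern), `nested` if some span strictly contains another, and
#' `interlocking` (intertwined) if two spans overlap without containment.
#' When both patterns occur, interlocking wins: the topology cannot be drawn
#' without crossing bridges.
#'
#' @param rings `ringtop`.
#' @return character label.
#' @export
classify_topology <- function(rings) {
  if (nrow(rings) < 2) return("disjoint")
  lo <- pmin(rings$donor, rings$acceptor)
  hi <- pmax(rings$donor, rings$acceptor)
  any_nested <- FALSE
  for (i in seq_len(nrow(rings) - 1)) {
    for (j in seq.int(i + 1, nrow(rings))) {
      if (hi[i] < lo[j] || hi[j] < lo[i]) next          # disjoint pair
      if ((lo[i] < lo[j] && hi[j] < hi[i]) ||
          (lo[j] < lo[i] && hi[i] < hi[j])) {
        any_nested <- TRUE                              # strict containment
      } else {
        return("interlocking")
      }
    }
  }
  if (any_nested) "nested" else "disjoint"
}

#' Enumerate all candidate ring topologies for a core
#'
#' All injective pairings of `n_links` Cys positions with `n_links` Ser/Thr
#' positions: count = C(#Cys, n) * C(#Ser+#Thr, n) * n!.
#'
#' @param core core peptide sequence.
#' @param n_links number of crosslinks.
#' @return list of `ringtop` objects (empty list if infeasible; a single
#'   empty topology for `n_links = 0`).
#' @export
enumerate_candidate_topologies <- function(core, n_links) {
  aa <- strsplit(core, "")[[1]]
  cys <- which(aa == "C")
  don <- which(aa %in% c("S", "T"))
  if (n_links == 0) {
    return(list(ring_topology(integer(), integer(), core)))
  }
  if (n_links > length(cys) || n_links > length(don)) return(list())
  cys_sets <- utils::combn(cys, n_links, simplify = FALSE)
  don_sets <- utils::combn(don, n_links, simplify = FALSE)
  perms <- .permutations(n_links)
  out <- list()
  for (cs in cys_sets) {
    for (ds in don_sets) {
      for (p in seq_len(nrow(perms))) {
        out[[length(out) + 1L]] <-
          ring_topology(ds[perms[p, ]], cs, core)
      }
    }
  }
  out
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# ---- fragment generation ----------------------------------------------

.M_H2O <- 18.0105646859
.M_H2S <- 33.9877210538   # shift magnitudes: Cys -> Dha is -H2S
.M_CH2 <- 14.0156500638

# Per-residue monoisotopic masses for the modified species: standard residue
# masses, ring donors dehydrated (-H2O), with optional per-position state
# overrides (used for desulfurization products: Ala/Abu, deuterated forms).
.residue_masses <- function(core, rings, states = NULL) {
  tab <- residue_table()
  aa <- strsplit(core, "")[[1]]
  m <- vapply(aa, function(r) monoisotopic_mass(tab[[r]]), numeric(1),
              USE.NAMES = FALSE)
  if (nrow(rings)) m[rings$donor] <- m[rings$donor] - .M_H2O
  if (!is.null(states)) {
    for (pos in as.integer(names(states))) {
      m[pos] <- monoisotopic_mass(tab[[states[[as.character(pos)]]]])
    }
  }
  m
}

# Core fragment engine. res_m: per-residue neutral masses of the intact
# species; rings: crosslinks that are still closed (eligible for rupture);
# n_methylation: +CH2 units on the N-terminus (carried by b ions and the
# precursor). b and y neutrals are computed independently per side so that
# the complementarity invariant b_i + y_(n-i) = precursor is a real check.
.fragment_table <- function(res_m, rings, core, n_methylation = 0,
                            charges = 1, ring_mode = c("cgs-rupture",
                                                       "suppress")) {
  ring_mode <- match.arg(ring_mode)
  n <- length(res_m)
  aa <- strsplit(core, "")[[1]]
  meth <- n_methylation * .M_CH2
  csum <- cumsum(res_m)
  total <- csum[n] + .M_H2O + meth
  lo <- if (nrow(rings)) pmin(rings$donor, rings$acceptor) else integer()
  hi <- if (nrow(rings)) pmax(rings$donor, rings$acceptor) else integer()
  rows <- list()
  for (i in seq_len(n - 1)) {
    spanned <- which(lo <= i & i < hi)
    if (ring_mode == "suppress" && length(spanned)) next
    b_adj <- 0; y_adj <- 0
    notes <- character()
    for (r in spanned) {
      d <- rings$donor[r]; a <- rings$acceptor[r]
      # sulfur stays with the donor: donor +H2S, acceptor (Cys->Dha) -H2S
      if (d <= i) b_adj <- b_adj + .M_H2S else y_adj <- y_adj + .M_H2S
      if (a <= i) b_adj <- b_adj - .M_H2S else y_adj <- y_adj - .M_H2S
      notes <- c(notes, sprintf("C%d=Dha(-34),%s%d(+16)", a, aa[d], d))
    }
    ring_state <- paste(notes, collapse = ";")
    ruptured <- if (length(spanned))
      paste(sprintf("%d-%d", rings$donor[spanned], rings$acceptor[spanned]),
            collapse = ";") else ""
    b_neutral <- csum[i] + meth + b_adj
    y_neutral <- (csum[n] - csum[i]) + .M_H2O + y_adj
    for (z in charges) {
      rows[[length(rows) + 1L]] <- data.frame(
        series = c("b", "y"), index = c(i, n - i), bond = i, z = z,
        neutral = c(b_neutral, y_neutral),
        mz = c(mz_from_neutral(b_neutral, z),
               mz_from_neutral(y_neutral, z)),
        ruptured = ruptured, ring_state = ring_state,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(series = character(), index = integer(), bond = integer(),
               z = integer(), neutral = numeric(), mz = numeric(),
               ruptured = character(), ring_state = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_residues") <- n
  attr(out, "precursor_neutral") <- total
  out
}

#' Ring-aware theoretical b/y fragments of a modified peptide species
#'
#' b/y ions at every backbone bond. For bonds inside a closed ring interval,
#' ions are emitted only via the C-gamma--S rupture pathway: the link's
#' Cys-derived residue appears as Dha (nominal -34 Da vs Cys) and the
#' Ser/Thr-derived residue carries the sulfur (nominal +16 Da vs the encoded
#' donor). `ring_mode = "suppress"` instead drops all intra-ring cleavages
#' (classical lanthipeptide behaviour). N-terminal methylation (+CH2) rides
#' on b ions; each crosslink consumes one dehydration, so
#' `mods$n_dehydration` must equal the number of rings.
#'
#' @param core core peptide sequence.
#' @param mods `modset` of the species.
#' @param rings `ringtop` on the same core.
#' @param charges integer fragment charges (default 1).
#' @param ring_mode `"cgs-rupture"` (default) or `"suppress"`.
#' @return data.frame of fragment ions (series, index, bond, z, neutral,
#'   mz, ruptured, ring_state) with attributes `n_residues` and
#'   `precursor_neutral`.
#' @export
theoretical_fragments <- function(core, mods, rings, charges = 1,
                                  ring_mode = c("cgs-rupture", "suppress")) {
  stopifnot(inherits(mods, "modset"), inherits(rings, "ringtop"))
  if (!identical(attr(rings, "core"), core)) {
    stop("ring topology was built on a different core sequence")
  }
  if (mods$n_dehydration != nrow(rings)) {
    stop("rings inconsistent with modifications: ", nrow(rings),
         " crosslink(s) require exactly ", nrow(rings), " dehydration(s), ",
         "species has ", mods$n_dehydration)
  }
  if (mods$n_dehydrogenation > 0 || length(mods$extra)) {
    stop("fragment generation supports dehydration + N-terminal ",
         "methylation only")
  }
  res_m <- .residue_masses(core, rings)
  .fragment_table(res_m, rings, core, mods$n_methylation, charges,
                  match.arg(ring_mode))
}

#' Annotate an observed MS/MS spectrum with theoretical fragments
#'
#' Greedy nearest-ppm assignment: each peak receives at most one fragment,
#' the one with the smallest absolute ppm error within `tol_ppm`. Coverage
#' is the fraction of inter-residue bonds supported by at least one
#' annotated b or y ion.
#'
#' @param spectrum a spectrum list (field `peaks`) as from [read_mgf()], or
#'   a peak data.frame with columns mz, intensity.
#' @param fragments data.frame from [theoretical_fragments()].
#' @param tol_ppm annotation tolerance in ppm.
#' @return list with `annotations` (data.frame peak_mz, intensity, series,
#'   index, bond, z, theoretical_mz, ppm, ring_state) and `coverage`.
#' @export
annotate_spectrum <- function(spectrum, fragments, tol_ppm = 10) {
  stopifnot(tol_ppm > 0)
  peaks <- if (is.data.frame(spectrum)) spectrum else spectrum$peaks
  if (is.null(peaks$intensity)) peaks$intensity <- rep(1, nrow(peaks))
  n_res <- attr(fragments, "n_residues")
  ann <- list()
  for (p in seq_len(nrow(peaks))) {
    if (!nrow(fragments)) break
    ppm <- ppm_error(peaks$mz[p], fragments$mz)
    j <- which.min(abs(ppm))
    if (!length(j) || abs(ppm[j]) > tol_ppm) next
    ann[[length(ann) + 1L]] <- data.frame(
      peak = p, peak_mz = peaks$mz[p], intensity = peaks$intensity[p],
      series = fragments$series[j], index = fragments$index[j],
      bond = fragments$bond[j], z = fragments$z[j],
      theoretical_mz = fragments$mz[j], ppm = ppm[j],
      ring_state = fragments$ring_state[j], stringsAsFactors = FALSE)
  }
  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(peak = integer(), peak_mz = numeric(), intensity = numeric(),
               series = character(), index = integer(), bond = integer(),
               z = integer(), theoretical_mz = numeric(), ppm = numeric(),
               ring_state = character(), stringsAsFactors = FALSE)
  rownames(annotations) <- NULL
  coverage <- if (is.null(n_res) || n_res < 2) 0 else
    length(unique(annotations$bond)) / (n_res - 1)
  list(annotations = annotations, coverage = coverage)
}

#' Score candidate ring topologies against an MS/MS spectrum
#'
#' Each candidate's ring-aware fragments are annotated against the spectrum.
#' A discriminating ion is an annotated peak that at least one competing
#' candidate cannot explain. Candidates are ranked by (number of
#' discriminating ions, total annotated intensity, coverage), ties broken by
#' candidate order. If no candidate annotates any peak, or the top
#' candidates tie on all keys, the result is flagged indeterminate.
#'
#' @param spectrum spectrum (list with `peaks` or a peak data.frame).
#' @param core core peptide sequence.
#' @param mods `modset` (dehydration count must equal link count).
#' @param candidates list of `ringtop` objects.
#' @param tol_ppm annotation tolerance in ppm.
#' @param charges fragment charges.
#' @param ring_mode passed to [theoretical_fragments()].
#' @return data.frame ranked best-first: candidate, topology, label,
#'   n_discriminating, annotated_intensity, n_annotated, coverage; with
#'   attributes `topologies` (the candidate list) and `indeterminate`.
#' @export
score_topologies <- function(spectrum, core, mods, candidates,
                             tol_ppm = 10, charges = 1,
                             ring_mode = "cgs-rupture") {
  if (!length(candidates)) stop("empty candidate topology list")
  anns <- lapply(candidates, function(rt) {
    fr <- theoretical_fragments(core, mods, rt, charges, ring_mode)
    annotate_spectrum(spectrum, fr, tol_ppm)
  })
  peak_sets <- lapply(anns, function(a) a$annotations$peak)
  n_disc <- vapply(seq_along(candidates), function(ci) {
    others <- setdiff(seq_along(candidates), ci)
    if (!length(others)) return(0L)
    sum(vapply(peak_sets[[ci]], function(p) {
      any(!vapply(others, function(o) p %in% peak_sets[[o]], logical(1)))
    }, logical(1)))
  }, integer(1))
  scores <- data.frame(
    candidate = seq_along(candidates),
    topology = vapply(candidates, format_topology, character(1)),
    label = vapply(candidates, classify_topology, character(1)),
    n_discriminating = n_disc,
    annotated_intensity = vapply(anns, function(a)
      sum(a$annotations$intensity), numeric(1)),
    n_annotated = vapply(anns, function(a) nrow(a$annotations), integer(1)),
    coverage = vapply(anns, function(a) a$coverage, numeric(1)),
    stringsAsFactors = FALSE)
  ord <- order(-scores$n_discriminating, -scores$annotated_intensity,
               -scores$coverage, scores$candidate)
  scores <- scores[ord, , drop = FALSE]
  rownames(scores) <- NULL
  # indeterminate when the spectrum carries no topology information at all:
  # nothing annotated, or every annotated ion is explained by every
  # candidate (e.g. no ring-region ions). Mass-degenerate candidate pairs
  # (same donor/acceptor sets, swapped pairing) tie and are resolved by
  # serialization order; desulfurization labelling resolves them physically.
  indet <- sum(scores$n_annotated) == 0 ||
    (nrow(scores) > 1 && all(scores$n_discriminating == 0))
  attr(scores, "topologies") <- candidates
  attr(scores, "indeterminate") <- indet
  scores
}

# ---- reductive desulfurization ----------------------------------------

#' Simulate reductive desulfurization of selected crosslinks
#'
#' Ni-boride/NaBH4 (reagent `"H"`) or NaBD4 (reagent `"D"`) removal of the
#' thioether sulfur of the opened links: per opened link the net formula
#' change is -S +2H (reagent H) or -S +H +D (reagent D). The Ser-derived
#' donor becomes Ala (Thr-derived becomes Abu) and the Cys-derived acceptor
#' becomes Ala. With reagent D the single deuterium can end up on either
#' the donor- or the acceptor-derived residue; both placements are
#' enumerated as isomer variants (identical mass, different fragments).
#' Intact links and free Cys are untouched (Met sulfur is never reduced).
#'
#' @param core core peptide sequence.
#' @param mods `modset` of the parent species.
#' @param rings `ringtop`; all crosslinks of the parent.
#' @param open integer indices (rows of `rings`) of the links to open;
#'   default all.
#' @param reagent `"H"` (NaBH4) or `"D"` (NaBD4).
#' @return object of class `desulf_product`: list with core, mods, rings,
#'   open, reagent, formula, mass, and `variants` — a list of per-variant
#'   residue-state maps (position -> residue key: "A", "AlaD", "Abu",
#'   "AbuD") with the deuterium placement recorded.
#' @export
desulfurize <- function(core, mods, rings, open = seq_len(nrow(rings)),
                        reagent = c("H", "D")) {
  reagent <- match.arg(reagent)
  stopifnot(inherits(rings, "ringtop"))
  open <- as.integer(open)
  if (length(open) && (any(open < 1) || any(open > nrow(rings)))) {
    stop("cannot open link(s) ", paste(setdiff(open, seq_len(nrow(rings))),
                                       collapse = ","),
         ": topology has ", nrow(rings), " link(s)")
  }
  aa <- strsplit(core, "")[[1]]
  parent_formula <- apply_modifications(peptide_formula(core), mods)
  s1 <- molform(c(S = 1)); h1 <- molform(c(H = 1)); d1 <- molform(c(D = 1))
  f <- parent_formula
  for (r in open) {
    f <- f - s1 + (if (reagent == "H") h1 + h1 else h1 + d1)
  }
  base_states <- list()
  for (r in open) {
    d <- rings$donor[r]; a <- rings$acceptor[r]
    base_states[[as.character(d)]] <- if (aa[d] == "T") "Abu" else "A"
    base_states[[as.character(a)]] <- "A"
  }
  variants <- list()
  if (reagent == "H" || !length(open)) {
    variants[[1]] <- list(states = base_states, placement = character(0))
  } else {
    # one deuterium per opened link, on the donor- or acceptor-derived side
    sides <- expand.grid(rep(list(c("donor", "acceptor")), length(open)),
                         stringsAsFactors = FALSE)
    for (v in seq_len(nrow(sides))) {
      st <- base_states
      pl <- character(length(open))
      for (k in seq_along(open)) {
        r <- open[k]
        pos <- if (sides[v, k] == "donor") rings$donor[r] else
          rings$acceptor[r]
        st[[as.character(pos)]] <- paste0(
          if (st[[as.character(pos)]] == "Abu") "Abu" else "Ala", "D")
        pl[k] <- sprintf("%s@%d", sides[v, k], pos)
      }
      variants[[length(variants) + 1L]] <- list(states = st, placement = pl)
    }
  }
  structure(list(core = core, mods = mods, rings = rings, open = open,
                 reagent = reagent, formula = f,
                 mass = monoisotopic_mass(f), variants = variants),
            class = "desulf_product")
}

#' @export
print.desulf_product <- function(x, ...) {
  cat("<desulf_product> ", x$core, ", reagent Na B", x$reagent, "4, ",
      length(x$open), "/", nrow(x$rings), " link(s) opened, ",
      format_formula(x$formula), " (", sprintf("%.4f", x$mass), " Da), ",
      length(x$variants), " variant(s)\n", sep = "")
  invisible(x)
}

#' Theoretical b/y fragments of a desulfurization product variant
#'
#' Opened residues are replaced by their reduction products (Ala/Abu,
#' deuterated where the variant places the label); links left intact remain
#' closed and fragment via the usual C-gamma--S rupture pathway.
#'
#' @param product `desulf_product`.
#' @param variant variant index (deuterium placement), default 1.
#' @param charges fragment charges.
#' @param ring_mode passed to the fragment engine.
#' @export
product_fragments <- function(product, variant = 1, charges = 1,
                              ring_mode = "cgs-rupture") {
  stopifnot(inherits(product, "desulf_product"))
  v <- product$variants[[variant]]
  remaining_idx <- setdiff(seq_len(nrow(product$rings)), product$open)
  remaining <- ring_topology(product$rings$donor[remaining_idx],
                             product$rings$acceptor[remaining_idx],
                             product$core)
  res_m <- .residue_masses(product$core, remaining, v$states)
  .fragment_table(res_m, remaining, product$core,
                  product$mods$n_methylation, charges, ring_mode)
}

#' Infer ring topology from partial desulfurization MS/MS spectra
#'
#' For every candidate topology, simulates each single-link-opened
#' NaBH4/NaBD4 product (both deuterium placements), annotates every observed
#' product spectrum, and keeps the best-explaining (link, placement) per
#' spectrum. Candidates are ranked by jointly explained discriminating ions
#' (annotated peaks that some competing candidate cannot explain), then
#' total annotated ions, then intensity. An optional parent (intact species)
#' spectrum contributes via [score_topologies()] on the closed rings.
#'
#' @param product_spectra list of spectra (each a list with `peaks` or a
#'   peak data.frame) of the partial desulfurization products.
#' @param core core peptide sequence.
#' @param mods `modset` of the parent species.
#' @param candidates list of `ringtop`; default all pairings of
#'   `mods$n_dehydration` links via [enumerate_candidate_topologies()].
#' @param reagent `"D"` (default; NaBD4 labelling) or `"H"`.
#' @param tol_ppm annotation tolerance in ppm.
#' @param charges fragment charges.
#' @param parent_spectrum optional spectrum of the intact species.
#' @return list with `topology` (best `ringtop` or NULL), `label`
#'   (classification or "indeterminate"), `indeterminate`, `scores`
#'   (ranked data.frame) and `assignments` (per-spectrum best link/placement
#'   for the winning candidate).
#' @export
infer_topology_from_desulfurization <- function(product_spectra, core, mods,
                                                candidates = NULL,
                                                reagent = "D", tol_ppm = 10,
                                                charges = 1,
                                                parent_spectrum = NULL) {
  if (!length(product_spectra)) {
    stop("at least one partial-product spectrum is required")
  }
  if (is.null(candidates)) {
    candidates <- enumerate_candidate_topologies(core, mods$n_dehydration)
  }
  if (!length(candidates)) stop("empty candidate topology list")
  n_cand <- length(candidates)
  n_spec <- length(product_spectra)

  # best (link, placement) per candidate x spectrum + annotated peak sets
  best <- vector("list", n_cand)
  for (ci in seq_len(n_cand)) {
    rt <- candidates[[ci]]
    per_spec <- vector("list", n_spec)
    for (si in seq_len(n_spec)) {
      bs <- list(n = -1L, intensity = 0, peaks = integer(),
                 link = NA_character_, placement = NA_character_)
      for (l in seq_len(nrow(rt))) {
        prod <- desulfurize(core, mods, rt, open = l, reagent = reagent)
        for (v in seq_along(prod$variants)) {
          fr <- product_fragments(prod, v, charges)
          a <- annotate_spectrum(product_spectra[[si]], fr, tol_ppm)
          n_a <- nrow(a$annotations)
          it <- sum(a$annotations$intensity)
          if (n_a > bs$n || (n_a == bs$n && it > bs$intensity)) {
            bs <- list(n = n_a, intensity = it,
                       peaks = a$annotations$peak,
                       link = sprintf("%d-%d", rt$donor[l], rt$acceptor[l]),
                       placement = paste(prod$variants[[v]]$placement,
                                         collapse = ";"))
          }
        }
      }
      per_spec[[si]] <- bs
    }
    best[[ci]] <- per_spec
  }

  # discriminating ions per candidate, summed over spectra
  n_disc <- integer(n_cand); n_ann <- integer(n_cand); inten <- numeric(n_cand)
  for (ci in seq_len(n_cand)) {
    for (si in seq_len(n_spec)) {
      pk <- best[[ci]][[si]]$peaks
      n_ann[ci] <- n_ann[ci] + length(pk)
      inten[ci] <- inten[ci] + best[[ci]][[si]]$intensity
      others <- setdiff(seq_len(n_cand), ci)
      if (length(others)) {
        n_disc[ci] <- n_disc[ci] + sum(vapply(pk, function(p) {
          any(!vapply(others, function(o)
            p %in% best[[o]][[si]]$peaks, logical(1)))
        }, logical(1)))
      }
    }
  }
  if (!is.null(parent_spectrum)) {
    ps <- score_topologies(parent_spectrum, core, mods, candidates,
                           tol_ppm, charges)
    add <- ps[order(ps$candidate), , drop = FALSE]
    n_disc <- n_disc + add$n_discriminating
    n_ann <- n_ann + add$n_annotated
    inten <- inten + add$annotated_intensity
  }

  scores <- data.frame(
    candidate = seq_len(n_cand),
    topology = vapply(candidates, format_topology, character(1)),
    label = vapply(candidates, classify_topology, character(1)),
    n_discriminating = n_disc, n_annotated = n_ann,
    annotated_intensity = inten, stringsAsFactors = FALSE)
  ord <- order(-scores$n_discriminating, -scores$n_annotated,
               -scores$annotated_intensity, scores$candidate)
  scores <- scores[ord, , drop = FALSE]
  rownames(scores) <- NULL

  if (sum(scores$n_annotated) == 0) {
    return(list(topology = NULL, label = "indeterminate",
                indeterminate = TRUE, scores = scores,
                assignments = NULL))
  }
  win <- scores$candidate[1]
  assignments <- data.frame(
    spectrum = seq_len(n_spec),
    opened_link = vapply(best[[win]], function(b) b$link, character(1)),
    placement = vapply(best[[win]], function(b) b$placement, character(1)),
    n_annotated = vapply(best[[win]], function(b) as.integer(b$n),
                         integer(1)),
    stringsAsFactors = FALSE)
  list(topology = candidates[[win]],
       label = classify_topology(candidates[[win]]),
       indeterminate = FALSE, scores = scores, assignments = assignments)
}
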