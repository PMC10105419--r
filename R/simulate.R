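# Seeded synthetic data: genomes with planted lanM-adjacent precursors and
# decoy ORFs, MS1 peak lists and MS/MS spectra generated from ground-truth
# species with ppm jitter and noise peaks, and the two archalan fixtures.
# All generators take explicit integer seeds and leave the caller's RNG
# state untouched.

.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# fixed reverse-translation table (one stop-free codon per residue)
.CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
            Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
            L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCG",
            S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

.reverse_translate <- function(aa) {
  paste(.CODON[strsplit(aa, "")[[1]]], collapse = "")
}

# gene cassette: in-frame stop guard, start codon, body, stop. The guard
# stop immediately upstream pins the ORF caller's longest-ORF-per-stop rule
# to the planted start.
.gene_cassette <- function(aa) {
  body <- .reverse_translate(substring(aa, 2))  # initiator written as ATG
  paste0("TAA", "ATG", body, "TAA")
}

.random_dna <- function(n, gc) {
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a random core peptide sequence
#'
#' Random residues with a prescribed number of Cys (ring acceptors) and
#' Ser/Thr (ring donors) placed at distinct random positions; the remaining
#' positions avoid C, S and T so the planted counts are exact. Must be
#' called inside a seeded context or given a seed.
#'
#' @param n_aa core length.
#' @param n_cys,n_donors planted Cys and Ser/Thr counts.
#' @param seed optional integer seed.
#' @export
random_core <- function(n_aa, n_cys = 2, n_donors = 2, seed = NULL) {
  gen <- function() {
    stopifnot(n_cys + n_donors <= n_aa)
    others <- c("A", "G", "L", "V", "F", "P", "E", "D", "K", "N", "Q",
                "H", "Y", "W", "I", "M", "R")
    aa <- sample(others, n_aa, replace = TRUE)
    special <- sample(n_aa, n_cys + n_donors)
    aa[special[seq_len(n_cys)]] <- "C"
    aa[special[n_cys + seq_len(n_donors)]] <-
      sample(c("S", "T"), n_donors, replace = TRUE)
    paste(aa, collapse = "")
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

.DEFAULT_LEADER <- "MSEEQLKAYDAEFRELLASA"  # carries Kx(Y/F)(D/E)xx(F/Y)

#' Simulate a genome with planted lanM-adjacent precursors and decoys
#'
#' Builds one contig: uniform-composition background at the requested GC
#' fraction, a central `lanM` marker gene, planted true precursor genes
#' (leader + core, satisfying the precursor filter rule by construction)
#' and decoy ORFs each violating exactly one filter clause: `"length"`
#' (exactly `max_len` residues), `"no_cys"` / `"no_st"` (missing residue
#' class in the C-terminal window), `"far"` (a valid precursor placed
#' outside the mining window). Genes alternate sides and strands around
#' lanM with increasing edge-to-edge distances. Fully deterministic given
#' the seed.
#'
#' @param seed integer seed.
#' @param cores character vector of true core peptides (default one random
#'   core of 12 residues with 2 Cys + 2 Ser/Thr).
#' @param decoys subset of c("length","no_cys","no_st","far").
#' @param contig_length contig size in bp.
#' @param gc background GC fraction (default 0.60, haloarchaeal-like).
#' @param window_bp mining window the `"far"` decoy must fall outside.
#' @param leader leader sequence for planted precursors (synthetic; carries
#'   the conserved leader motif).
#' @param max_len,cterm_window filter parameters the decoys are built
#'   against.
#' @return list with `genome` (a `genome_record`) and `truth` (data.frame:
#'   name, class, start, end, strand, distance, aa, leader, core).
#' @export
simulate_genome <- function(seed = 1, cores = NULL,
                            decoys = c("length", "no_cys", "no_st", "far"),
                            contig_length = 30000, gc = 0.60,
                            window_bp = 6000, leader = .DEFAULT_LEADER,
                            max_len = 100, cterm_window = 20) {
  decoys <- match.arg(decoys, several.ok = TRUE)
  .with_seed(seed, {
    if (is.null(cores)) cores <- random_core(12, 2, 2)

    # amino-acid sequences to plant
    plant_aa <- list()
    for (i in seq_along(cores)) {
      plant_aa[[paste0("true", i)]] <-
        list(class = "true", aa = paste0(leader, cores[i]),
             core = cores[i], far = FALSE)
    }
    if ("length" %in% decoys) {
      # pad to exactly max_len residues; C-terminal window still valid
      pad <- paste(sample(c("A", "G", "L", "V", "E"),
                          max_len - nchar(leader) - 12, replace = TRUE),
                   collapse = "")
      plant_aa$decoy_length <- list(
        class = "decoy_length",
        aa = paste0(leader, pad, random_core(12, 2, 2)),
        core = NA_character_, far = FALSE)
    }
    if ("no_cys" %in% decoys) {
      # 20-aa core so the inspected C-terminal window is core only and the
      # leader cannot re-supply the missing residue class
      plant_aa$decoy_no_cys <- list(
        class = "decoy_no_cys",
        aa = paste0(leader, random_core(cterm_window, 0, 2)),
        core = NA_character_, far = FALSE)
    }
    if ("no_st" %in% decoys) {
      plant_aa$decoy_no_st <- list(
        class = "decoy_no_st",
        aa = paste0(leader, random_core(cterm_window, 2, 0)),
        core = NA_character_, far = FALSE)
    }
    if ("far" %in% decoys) {
      plant_aa$decoy_far <- list(
        class = "decoy_far", aa = paste0(leader, random_core(12, 2, 2)),
        core = NA_character_, far = TRUE)
    }

    # layout: lanM centred; genes alternate sides with growing distances
    lanM_aa <- paste0("M", paste(sample(c("A", "G", "L", "V", "E", "D",
                                          "K", "R", "S", "T", "P"),
                                        298, replace = TRUE),
                                 collapse = ""))
    lanM_cassette <- .gene_cassette(lanM_aa)
    lanM_len <- nchar(lanM_cassette)
    centre <- contig_length %/% 2
    lanM_start <- centre - lanM_len %/% 2   # 0-based, includes guard TAA
    # the annotated lanM feature = the ORF (start codon .. stop codon)
    lanM_feat_start <- lanM_start + 3L
    lanM_feat_end <- lanM_start + lanM_len

    dist_near <- c(200L, 450L, 750L, 1100L, 1500L, 1950L, 2450L, 3000L)
    dist_far <- window_bp + 1000L
    side <- rep(c(1L, -1L), length.out = length(plant_aa))
    near_i <- 0L
    placements <- list()
    for (k in seq_along(plant_aa)) {
      p <- plant_aa[[k]]
      cassette <- .gene_cassette(p$aa)
      clen <- nchar(cassette)
      if (p$far) {
        d <- dist_far
      } else {
        near_i <- near_i + 1L
        if (near_i > length(dist_near)) {
          stop("too many planted genes for the built-in layout")
        }
        d <- dist_near[near_i]
      }
      strand <- if ((k %/% 2) %% 2 == 0) "+" else "-"
      # genomic ORF span: "+" cassette = [guard TAA][ORF]; "-" cassette
      # (written reverse-complemented) = [ORF][guard TAA]
      if (side[k] > 0) {            # downstream: ORF starts at lanM end + d
        orf_start <- lanM_feat_end + d
        cass_start <- if (strand == "+") orf_start - 3L else orf_start
      } else {                       # upstream: ORF ends at lanM start - d
        orf_end <- lanM_feat_start - d
        cass_start <- if (strand == "+") orf_end - clen else
          orf_end - clen + 3L
      }
      if (cass_start < 0 || cass_start + clen > contig_length) {
        stop("contig too short (", contig_length,
             " bp) for the requested genes and window")
      }
      placements[[names(plant_aa)[k]]] <- list(
        info = p, cassette = if (strand == "+") cassette else
          .revcomp(cassette),
        start = cass_start, len = clen, strand = strand, distance = d * side[k])
    }

    contig <- .random_dna(contig_length, gc)
    insert <- function(s, at, frag) {  # at: 0-based
      paste0(substr(s, 1, at), frag, substr(s, at + nchar(frag) + 1,
                                            nchar(s)))
    }
    contig <- insert(contig, lanM_start, lanM_cassette)
    truth_rows <- list()
    for (nm in names(placements)) {
      pl <- placements[[nm]]
      contig <- insert(contig, pl$start, pl$cassette)
      # ORF coordinates (guard TAA excluded, stop codon included)
      if (pl$strand == "+") {
        o_start <- pl$start + 3L; o_end <- pl$start + pl$len
      } else {
        o_start <- pl$start; o_end <- pl$start + pl$len - 3L
      }
      truth_rows[[nm]] <- data.frame(
        name = nm, class = pl$info$class, start = o_start, end = o_end,
        strand = pl$strand, distance = pl$distance, aa = pl$info$aa,
        leader = if (pl$info$class == "true") leader else NA_character_,
        core = pl$info$core, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL

    feats <- data.frame(
      feature_id = "lanM_1", contig = "contig_1",
      start = lanM_feat_start, end = lanM_feat_end, strand = "+",
      type = "lanM", stringsAsFactors = FALSE)
    genome <- genome_record(stats::setNames(contig, "contig_1"), feats)
    list(genome = genome, truth = truth)
  })
}

#' Write a simulated genome to FASTA + GFF3 + truth-table TSV
#'
#' @param sim result of [simulate_genome()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulated_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  gff <- file.path(dir, "genome.gff3")
  tsv <- file.path(dir, "truth.tsv")
  write_genome(sim$genome, fa, gff)
  utils::write.table(sim$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fa, gff, tsv))
}

#' Simulate an MS1 peak list from ground-truth species
#'
#' One peak per species per charge, with multiplicative ppm jitter drawn
#' from Normal(0, sd), plus uniformly distributed noise peaks. Intensities
#' follow a rank-decay model (signal) and uniform (noise).
#'
#' @param masses numeric vector of neutral monoisotopic masses.
#' @param seed integer seed.
#' @param charges charge states emitted per species.
#' @param jitter_ppm_sd mass-accuracy jitter, ppm standard deviation.
#' @param n_noise number of noise peaks.
#' @param noise_range m/z range of noise peaks.
#' @return data.frame (mz, intensity, z, signal); z is NA for noise peaks.
#' @export
simulate_ms1 <- function(masses, seed = 1, charges = 2,
                         jitter_ppm_sd = 0, n_noise = 0,
                         noise_range = c(200, 1600)) {
  .with_seed(seed, {
    grid <- expand.grid(m = masses, z = charges)
    theo <- mz_from_neutral(grid$m, grid$z)
    obs <- theo * (1 + stats::rnorm(length(theo), 0, jitter_ppm_sd) / 1e6)
    sig <- data.frame(
      mz = obs,
      intensity = 1000 / rank(grid$m, ties.method = "first"),
      z = as.integer(grid$z), signal = TRUE)
    if (n_noise > 0) {
      noise <- data.frame(
        mz = stats::runif(n_noise, noise_range[1], noise_range[2]),
        intensity = stats::runif(n_noise, 1, 100),
        z = NA_integer_, signal = FALSE)
      sig <- rbind(sig, noise)
    }
    sig <- sig[order(sig$mz), , drop = FALSE]
    rownames(sig) <- NULL
    sig
  })
}

#' Simulate an MS/MS spectrum from a theoretical fragment table
#'
#' Samples `round(fraction * n)` fragments without replacement, applies
#' multiplicative ppm jitter, and adds uniform noise peaks. With
#' `fraction = 1`, zero jitter and zero noise the peak list equals the
#' theoretical fragment m/z values exactly.
#'
#' @param fragments data.frame from [theoretical_fragments()] or
#'   [product_fragments()].
#' @param seed integer seed.
#' @param fraction fragment sampling fraction in \[0, 1\].
#' @param jitter_ppm_sd ppm jitter standard deviation.
#' @param n_noise number of uniform noise peaks.
#' @param noise_range m/z range for noise peaks.
#' @param pepmass,charge,title optional precursor annotation carried in the
#'   spectrum header.
#' @return spectrum: list(title, pepmass, charge, peaks = data.frame(mz,
#'   intensity)).
#' @export
simulate_ms2 <- function(fragments, seed = 1, fraction = 1,
                         jitter_ppm_sd = 0, n_noise = 0,
                         noise_range = c(100, 1500), pepmass = NA,
                         charge = NA, title = "synthetic") {
  stopifnot(fraction >= 0, fraction <= 1)
  .with_seed(seed, {
    n <- nrow(fragments)
    k <- round(fraction * n)
    idx <- if (k > 0) sort(sample.int(n, k)) else integer()
    mz <- fragments$mz[idx]
    mz <- mz * (1 + stats::rnorm(length(mz), 0, jitter_ppm_sd) / 1e6)
    intensity <- 100 + stats::runif(length(mz), 0, 900)
    if (n_noise > 0) {
      mz <- c(mz, stats::runif(n_noise, noise_range[1], noise_range[2]))
      intensity <- c(intensity, stats::runif(n_noise, 1, 50))
    }
    ord <- order(mz)
    list(title = title, pepmass = pepmass, charge = charge,
         peaks = data.frame(mz = mz[ord], intensity = intensity[ord]))
  })
}

#' In-text fixtures: the two characterized archaeal lanthipeptides
#'
#' `archalan_alpha`: core GCGFTCSPFSSW with two dehydrations and disjoint
#' ("bicycle") rings MeLan Thr5-Cys2 and Lan Ser10-Cys6; observed
#' \[M + 2H\]2+ at m/z 621.7382. `archalan_beta`: core GLPSASMYSFEHCC with
#' two dehydrations plus one N-terminal methylation and intertwined rings
#' Ser4-Cys13 and Ser6-Cys14; observed \[M + 2H\]2+ at m/z 755.3012. The
#' leader sequences are synthetic stand-ins carrying the conserved leader
#' motif (the true leaders are not part of the fixture).
#'
#' @param name `"archalan_alpha"` or `"archalan_beta"`.
#' @return list with name, core, leader (synthetic), mods (`modset`),
#'   rings (`ringtop`), observed_mz, observed_z, formula (character).
#' @export
archalan_fixture <- function(name) {
  fixtures <- list(
    archalan_alpha = function() list(
      name = "archalan_alpha",
      core = "GCGFTCSPFSSW",
      leader = .DEFAULT_LEADER,
      leader_synthetic = TRUE,
      mods = modification_set(n_dehydration = 2),
      rings = ring_topology(donors = c(5, 10), acceptors = c(2, 6),
                            core = "GCGFTCSPFSSW"),
      observed_mz = 621.7382, observed_z = 2L,
      formula = "C57H71N13O15S2"),
    archalan_beta = function() list(
      name = "archalan_beta",
      core = "GLPSASMYSFEHCC",
      leader = .DEFAULT_LEADER,
      leader_synthetic = TRUE,
      mods = modification_set(n_dehydration = 2, n_methylation = 1),
      rings = ring_topology(donors = c(4, 6), acceptors = c(13, 14),
                            core = "GLPSASMYSFEHCC"),
      observed_mz = 755.3012, observed_z = 2L,
      formula = "C66H92N16O19S3")
  )
  if (!name %in% names(fixtures)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(fixtures), collapse = ", "))
  }
  fixtures[[name]]()
}
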