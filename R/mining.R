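# Precursor mining: small-ORF discovery around annotated lanM loci, the
# class II lanthipeptide precursor filters, the conserved leader motif, and
# leader/core split enumeration.

.START_CODONS <- c("ATG", "GTG", "TTG")  # archaeal alternative starts allowed
.STOP_CODONS <- c("TAA", "TAG", "TGA")

# Translate an ORF's coding sequence (without the stop codon). The initiator
# codon is rendered as Met regardless of ATG/GTG/TTG, the biological
# convention for alternative starts.
.translate_orf <- function(cds) {
  n <- nchar(cds)
  if (n < 3) return("")
  st <- seq.int(1, n - 2, by = 3)
  aa <- unname(Biostrings::GENETIC_CODE[substring(cds, st, st + 2)])
  aa[is.na(aa)] <- "X"
  aa[1] <- "M"
  paste(aa, collapse = "")
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Scan one strand of a window sequence for ORFs: per frame, an ORF runs from
# the first start codon after the previous stop to the next in-frame stop
# (longest ORF per stop; stop codon included in the genomic span, excluded
# from the translation).
.scan_strand <- function(winseq, strand) {
  n <- nchar(winseq)
  out <- list()
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3
    if (ncod < 2) next
    starts_at <- frame + 3 * (seq_len(ncod) - 1) + 1  # 1-based in winseq
    codons <- substring(winseq, starts_at, starts_at + 2)
    is_stop <- codons %in% .STOP_CODONS
    is_start <- codons %in% .START_CODONS
    prev_stop <- 0L
    for (j in which(is_stop)) {
      cand <- which(is_start[seq.int(prev_stop + 1L, j)])
      if (length(cand)) {
        i0 <- prev_stop + cand[1]          # codon index of chosen start
        # 0-based half-open coords within window, stop codon included
        w_start <- starts_at[i0] - 1L
        w_end <- starts_at[j] + 2L
        cds <- substring(winseq, starts_at[i0], starts_at[j] - 1L)
        out[[length(out) + 1L]] <- list(
          w_start = w_start, w_end = w_end, frame = frame,
          strand = strand, cds = cds)
      }
      prev_stop <- j
    }
  }
  out
}

#' Find ORFs in a window around a lanM anchor feature
#'
#' Scans all six reading frames within `window_bp` of the anchor's edges.
#' An ORF runs from a start codon (ATG/GTG/TTG) to the next in-frame stop;
#' per stop, the longest ORF (most upstream start) is reported once. ORFs
#' overlapping the anchor's own CDS are excluded. The window is clipped at
#' contig edges with a warning.
#'
#' @param genome `genome_record`.
#' @param anchor_id feature_id of a `lanM`-typed feature in the genome.
#' @param window_bp window size on each side of the anchor (default 6000).
#' @param min_len_aa,max_len_aa length bounds on the translated product.
#' @return data.frame with one row per ORF: contig, start, end (0-based
#'   half-open genomic, stop codon included), strand, frame, aa, length_aa,
#'   distance (signed bp, nearest edge-to-edge; negative = upstream of the
#'   anchor), sorted by |distance| with ties broken by (smaller start,
#'   `+` before `-`).
#' @export
find_orfs <- function(genome, anchor_id, window_bp = 6000,
                      min_len_aa = 20, max_len_aa = Inf) {
  stopifnot(inherits(genome, "genome_record"), min_len_aa >= 1)
  feats <- genome$features
  hit <- feats[feats$feature_id == anchor_id & feats$type == "lanM", ]
  if (nrow(hit) == 0) {
    stop("anchor '", anchor_id, "' is not a lanM feature of this genome")
  }
  anchor <- hit[1, ]
  contig_seq <- genome$seqs[[anchor$contig]]
  clen <- nchar(contig_seq)
  w0 <- anchor$start - window_bp
  w1 <- anchor$end + window_bp
  if (w0 < 0 || w1 > clen) {
    warning("window around '", anchor_id, "' clipped to contig bounds")
    w0 <- max(0L, w0); w1 <- min(clen, w1)
  }
  winseq <- substr(contig_seq, w0 + 1L, w1)
  wlen <- nchar(winseq)

  fw <- .scan_strand(winseq, "+")
  rv <- .scan_strand(.revcomp(winseq), "-")

  rows <- list()
  push <- function(g_start, g_end, strand, frame, cds) {
    aa <- .translate_orf(cds)
    len <- nchar(aa)
    if (len < min_len_aa || len > max_len_aa) return()
    if (grepl("[*X]", aa)) return()
    # exclude overlap with the anchor CDS
    if (g_start < anchor$end && g_end > anchor$start) return()
    dist <- if (g_end <= anchor$start) g_end - anchor$start
            else g_start - anchor$end
    rows[[length(rows) + 1L]] <<- data.frame(
      contig = anchor$contig, start = g_start, end = g_end,
      strand = strand, frame = frame, aa = aa, length_aa = len,
      distance = dist, stringsAsFactors = FALSE)
  }
  for (o in fw) push(w0 + o$w_start, w0 + o$w_end, "+", o$frame, o$cds)
  for (o in rv) {
    # map reverse-strand window coords back to genomic
    g_start <- w0 + (wlen - o$w_end)
    g_end <- w0 + (wlen - o$w_start)
    push(g_start, g_end, "-", o$frame, o$cds)
  }
  if (!length(rows)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), aa = character(),
                      length_aa = integer(), distance = integer(),
                      stringsAsFactors = FALSE))
  }
  orfs <- do.call(rbind, rows)
  ord <- order(abs(orfs$distance), orfs$start,
               match(orfs$strand, c("+", "-")))
  orfs <- orfs[ord, , drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}

#' Select the k ORFs nearest to the anchor
#'
#' Nearest by absolute edge-to-edge distance; ties broken by smaller start,
#' then `+` strand before `-`. Fewer than `k` ORFs are all returned.
#'
#' @param orfs data.frame from [find_orfs()].
#' @param k number of ORFs to keep (default 10).
#' @export
select_adjacent <- function(orfs, k = 10) {
  stopifnot(k >= 0)
  if (!nrow(orfs)) return(orfs)
  ord <- order(abs(orfs$distance), orfs$start,
               match(orfs$strand, c("+", "-")))
  out <- orfs[ord, , drop = FALSE][seq_len(min(k, nrow(orfs))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the class II lanthipeptide precursor filters
#'
#' Keeps ORFs whose translation is strictly shorter than `max_len` amino
#' acids and whose C-terminal `cterm_window` residues contain at least one
#' Cys and at least one Ser or Thr — the residues indispensable for forming
#' thioether crosslinks. Idempotent.
#'
#' @param orfs data.frame from [find_orfs()] / [select_adjacent()].
#' @param max_len length bound, exclusive (default 100).
#' @param cterm_window size of the C-terminal window inspected (default 20).
#' @return the surviving rows with added columns `passes_filters` (TRUE),
#'   `motif_hits` (comma-separated 1-based leader-motif positions, "" if
#'   none).
#' @export
filter_precursors <- function(orfs, max_len = 100, cterm_window = 20) {
  if (!nrow(orfs)) {
    out <- orfs
    out$passes_filters <- logical(0)
    out$motif_hits <- character(0)
    return(out)
  }
  keep <- vapply(seq_len(nrow(orfs)), function(i) {
    aa <- orfs$aa[i]
    len <- nchar(aa)
    if (len >= max_len) return(FALSE)
    tail_aa <- substr(aa, max(1L, len - cterm_window + 1L), len)
    grepl("C", tail_aa, fixed = TRUE) && grepl("[ST]", tail_aa)
  }, logical(1))
  out <- orfs[keep, , drop = FALSE]
  out$passes_filters <- rep(TRUE, nrow(out))
  out$motif_hits <- vapply(out$aa, function(aa) {
    paste(scan_leader_motif(aa)$position, collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  rownames(out) <- NULL
  out
}

#' Scan for the conserved leader motif Kx(Y/F)(D/E)xx(F/Y)
#'
#' The motif shared by archaeal class II lanthipeptide leader regions:
#' Lys, any residue, Tyr/Phe, Asp/Glu, any two residues, Phe/Tyr.
#' All (possibly overlapping) occurrences are reported.
#'
#' @param aa_seq amino-acid string.
#' @return data.frame with columns `position` (1-based start) and `match`
#'   (the 7-residue window).
#' @export
scan_leader_motif <- function(aa_seq) {
  stopifnot(is.character(aa_seq), length(aa_seq) == 1L)
  m <- gregexpr("(?=K.[YF][DE]..[FY])", aa_seq, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(position = integer(), match = character(),
                      stringsAsFactors = FALSE))
  }
  pos <- as.integer(m)
  data.frame(position = pos,
             match = substring(aa_seq, pos, pos + 6L),
             stringsAsFactors = FALSE)
}

#' Enumerate leader/core split hypotheses for a precursor
#'
#' All C-terminal suffixes with length in `[min_core, max_core]` (the leader
#' is never empty, so the core is at most length - 1) that contain at least
#' one Cys and one Ser/Thr. When the leader motif occurs, a split is flagged
#' `motif_consistent` if the motif lies wholly within the leader.
#'
#' @param aa_seq precursor amino-acid string.
#' @param min_core,max_core core length bounds.
#' @return data.frame with columns split (1-based index of the last leader
#'   residue), leader, core, motif_consistent.
#' @export
enumerate_core_splits <- function(aa_seq, min_core = 5, max_core = 50) {
  stopifnot(min_core <= max_core)
  n <- nchar(aa_seq)
  if (min_core > n - 1L) {   # leader is never empty
    return(data.frame(split = integer(), leader = character(),
                      core = character(), motif_consistent = logical(),
                      stringsAsFactors = FALSE))
  }
  hits <- scan_leader_motif(aa_seq)
  core_lens <- seq.int(min_core, min(max_core, n - 1L))
  rows <- lapply(core_lens, function(L) {
    split <- n - L
    core <- substring(aa_seq, split + 1L, n)
    if (!grepl("C", core, fixed = TRUE) || !grepl("[ST]", core)) return(NULL)
    mc <- nrow(hits) > 0 && any(hits$position + 6L <= split)
    data.frame(split = split, leader = substring(aa_seq, 1L, split),
               core = core, motif_consistent = mc, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(split = integer(), leader = character(),
                      core = character(), motif_consistent = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$split), , drop = FALSE]
}

#' Write a precursor-candidate table to TSV
#'
#' @param candidates data.frame from [filter_precursors()].
#' @param path output path.
#' @export
write_candidate_tsv <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
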