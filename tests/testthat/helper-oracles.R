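# Independent brute-force oracles, deliberately written in a different
# style from the package implementation.

# Naive six-frame ORF scan: walk every position of the window on both
# strands; an ORF is a start codon followed by the next in-frame stop.
# Keeps the longest ORF per (strand, stop) like the implementation.
# Returns genomic 0-based half-open coordinates (stop codon included).
oracle_orf_scan <- function(contig, w0, w1, anchor_start, anchor_end,
                            min_len_aa = 20) {
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  win <- substr(contig, w0 + 1, w1)
  L <- nchar(win)
  starts <- c("ATG", "GTG", "TTG"); stops <- c("TAA", "TAG", "TGA")
  scan <- function(s) {
    found <- list()
    for (p in seq_len(nchar(s) - 5)) {
      if (!substr(s, p, p + 2) %in% starts) next
      q <- p + 3
      while (q + 2 <= nchar(s) && !substr(s, q, q + 2) %in% stops) q <- q + 3
      if (q + 2 > nchar(s)) next
      found[[length(found) + 1]] <- c(p - 1, q + 2)  # 0-based half-open
    }
    if (!length(found)) return(NULL)
    m <- do.call(rbind, found)
    # longest per stop = smallest start per end
    do.call(rbind, lapply(split(m[, 1], m[, 2]), function(ss)
      c(min(ss), NA)))[, 1, drop = FALSE] -> tmp
    data.frame(start = tmp[, 1], end = as.numeric(rownames(tmp)))
  }
  out <- list()
  fw <- scan(win)
  if (!is.null(fw)) {
    out[[1]] <- data.frame(start = w0 + fw$start, end = w0 + fw$end,
                           strand = "+")
  }
  bw <- scan(rc(win))
  if (!is.null(bw)) {
    out[[2]] <- data.frame(start = w0 + (L - bw$end),
                           end = w0 + (L - bw$start), strand = "-")
  }
  if (!length(out)) {
    return(data.frame(start = numeric(), end = numeric(),
                      strand = character()))
  }
  res <- do.call(rbind, out)
  len_aa <- (res$end - res$start) / 3 - 1
  res <- res[len_aa >= min_len_aa, , drop = FALSE]
  # drop overlap with anchor
  res[res$end <= anchor_start | res$start >= anchor_end, , drop = FALSE]
}

# All-pairs MS1 matching oracle.
oracle_ms1 <- function(peaks, species, charges, tol_ppm) {
  hits <- list()
  for (p in seq_len(nrow(peaks))) {
    zz <- if (!is.null(peaks$z) && !is.na(peaks$z[p])) peaks$z[p] else charges
    for (z in zz) {
      for (s in seq_len(nrow(species))) {
        theo <- (species$mass[s] + z * 1.007276466) / z
        ppm <- 1e6 * (peaks$mz[p] - theo) / theo
        if (abs(ppm) <= tol_ppm) {
          hits[[length(hits) + 1]] <- data.frame(
            peak = p, z = z, sp = s, ppm = ppm)
        }
      }
    }
  }
  if (!length(hits)) return(data.frame(peak = numeric(), z = numeric(),
                                       sp = numeric(), ppm = numeric()))
  do.call(rbind, hits)
}

# Independent residue monoisotopic masses (textbook values, 5 decimals).
ORACLE_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

# Background sequence with no start codon on either strand (no G at all),
# used to build hand-constructed contigs with fully controlled ORF content.
orf_free_background <- function(n) {
  paste(rep_len(c("T", "T", "A", "A"), n), collapse = "")
}

# splice `frag` into `s` starting at 0-based position `at` (overwrites).
splice_at <- function(s, at, frag) {
  paste0(substr(s, 1, at), frag, substr(s, at + nchar(frag) + 1, nchar(s)))
}
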