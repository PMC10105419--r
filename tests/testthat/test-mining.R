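# lanM-adjacent ORF mining, precursor filters, leader motif, core splits.

make_test_genome <- function(contig) {
  # annotate an arbitrary 300 bp lanM interval at 1000..1300
  genome_record(
    stats::setNames(contig, "c1"),
    data.frame(feature_id = "lanM_1", contig = "c1", start = 2500L,
               end = 2800L, strand = "+", type = "lanM",
               stringsAsFactors = FALSE))
}

test_that("a planted 60-codon ORF 200 bp downstream is recovered exactly", {
  bg <- orf_free_background(6000)
  gene <- paste0("ATG", paste(rep("GCT", 59), collapse = ""), "TAA")
  contig <- splice_at(bg, 3000, gene)  # starts 200 bp after anchor end
  g <- make_test_genome(contig)
  orfs <- find_orfs(g, "lanM_1", window_bp = 2000, min_len_aa = 20)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$start, 3000L)
  expect_equal(orfs$end, 3000L + nchar(gene))
  expect_equal(orfs$strand, "+")
  expect_equal(orfs$distance, 200L)
  expect_equal(orfs$aa, paste0("M", strrep("A", 59)))
})

test_that("a minus-strand planted ORF is recovered with its translation", {
  bg <- orf_free_background(6000)
  gene <- paste0("ATG", paste(rep("GCT", 39), collapse = ""), "TAA")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene)))
  contig <- splice_at(bg, 3500, rc)
  g <- make_test_genome(contig)
  orfs <- find_orfs(g, "lanM_1", window_bp = 2000, min_len_aa = 20)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$strand, "-")
  expect_equal(orfs$aa, paste0("M", strrep("A", 39)))
  expect_equal(orfs$start, 3500L)
})

test_that("windows without start codons yield no ORFs, bad anchors error", {
  g <- make_test_genome(orf_free_background(6000))
  expect_equal(nrow(find_orfs(g, "lanM_1", window_bp = 1500)), 0L)
  expect_error(find_orfs(g, "nope"), "lanM")
  expect_warning(find_orfs(g, "lanM_1", window_bp = 50000), "clipped")
})

test_that("find_orfs agrees with a naive six-frame oracle on a synthetic genome", {
  sim <- simulate_genome(seed = 5, contig_length = 20000, window_bp = 3000)
  g <- sim$genome
  anchor <- g$features[g$features$type == "lanM", ]
  orfs <- find_orfs(g, anchor$feature_id, window_bp = 3000, min_len_aa = 20)
  oracle <- oracle_orf_scan(g$seqs[[1]], anchor$start - 3000,
                            anchor$end + 3000, anchor$start, anchor$end,
                            min_len_aa = 20)
  key <- function(d) sort(paste(d$start, d$end, d$strand))
  expect_equal(key(orfs), key(oracle))
})

test_that("select_adjacent keeps the k nearest with deterministic ties", {
  orfs <- data.frame(
    contig = "c1", start = 1:12 * 100L, end = 1:12 * 100L + 60L,
    strand = rep(c("+", "-"), 6), frame = 0L, aa = strrep("A", 20),
    length_aa = 20L, distance = c(100L, -200L, 300L, -400L, 500L, -600L,
                                  700L, -800L, 900L, -1000L, 1100L, -1200L),
    stringsAsFactors = FALSE)
  top <- select_adjacent(orfs, 10)
  expect_equal(nrow(top), 10L)
  expect_equal(sort(abs(top$distance)), seq(100L, 1000L, by = 100L))
  expect_equal(nrow(select_adjacent(orfs[1:3, ], 10)), 3L)
  # equal distances: smaller start first, then + before -
  ties <- orfs[1:2, ]; ties$distance <- c(500L, -500L)
  ties$start <- c(900L, 100L)
  expect_equal(select_adjacent(ties, 2)$start, c(100L, 900L))
  ties$start <- c(100L, 100L); ties$strand <- c("-", "+")
  expect_equal(select_adjacent(ties, 2)$strand, c("+", "-"))
})

test_that("precursor filters enforce length and C-terminal residue rules", {
  mk <- function(aa) data.frame(
    contig = "c1", start = 0L, end = nchar(aa) * 3L + 3L, strand = "+",
    frame = 0L, aa = aa, length_aa = nchar(aa), distance = 10L,
    stringsAsFactors = FALSE)
  ok99 <- paste0(strrep("A", 91), "AACAASAA")        # 99 aa, C+S in tail
  expect_equal(nrow(filter_precursors(mk(ok99))), 1L)
  too_long <- paste0(strrep("A", 92), "AACAASAA")    # 100 aa, else valid
  expect_equal(nrow(filter_precursors(mk(too_long))), 0L)
  far_cys <- paste0(strrep("A", 24), "C", strrep("S", 25))  # Cys at -26
  expect_equal(nrow(filter_precursors(mk(far_cys))), 0L)
  no_st <- paste0(strrep("A", 30), "CCCAA")
  expect_equal(nrow(filter_precursors(mk(no_st))), 0L)
  # idempotence
  once <- filter_precursors(mk(ok99))
  expect_equal(filter_precursors(once)$aa, once$aa)
})

test_that("leader motif scan finds all overlapping Kx(Y/F)(D/E)xx(F/Y) hits", {
  expect_equal(scan_leader_motif("KAYDAAF")$position, 1L)
  expect_equal(nrow(scan_leader_motif("KAADAAF")), 0L)
  hits <- scan_leader_motif("AKAYDAAFKAFEAAY")
  expect_equal(hits$position, c(2L, 9L))
  expect_equal(hits$match, c("KAYDAAF", "KAFEAAY"))
})

test_that("core splits enumerate suffixes with the residue rule", {
  pre <- "MKAYDAAFELGCGFTCSPFSSW"
  s <- enumerate_core_splits(pre, 12, 12)
  expect_equal(nrow(s), 1L)
  expect_equal(s$core, "GCGFTCSPFSSW")
  expect_equal(s$leader, "MKAYDAAFEL")
  expect_true(s$motif_consistent)
  # full enumeration equals the brute-force suffix rule
  all_s <- enumerate_core_splits(pre, 1, nchar(pre))
  brute <- Filter(function(L) {
    core <- substring(pre, nchar(pre) - L + 1)
    grepl("C", core) && grepl("[ST]", core)
  }, seq_len(nchar(pre) - 1))
  expect_equal(sort(nchar(all_s$core)), sort(unlist(brute)))
  # no-Cys core window excluded
  expect_equal(nrow(enumerate_core_splits("MAAAASSSS", 3, 4)), 0L)
  # min_core beyond the sequence
  expect_equal(nrow(enumerate_core_splits("MAC", 5, 9)), 0L)
})
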