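# Modified-species enumeration and MS1 peak matching.

test_that("species enumeration covers the modification grid and dedups", {
  space <- modification_space(max_dehydrations = 5, allow_methylation = TRUE,
                              max_methylations = 1)
  sp <- enumerate_species("GCGFTCSPFSSW", space)
  expect_equal(nrow(sp), 12L)                       # 6 x 2 count vectors
  expect_equal(nrow(enumerate_species("GCGW", modification_space(0))), 1L)
  # auto bound = Ser + Thr count of the core (S7, S10, S11 + T5)
  expect_equal(dehydration_bound("GCGFTCSPFSSW", modification_space()), 4L)
  auto_sp <- enumerate_species("GCGFTCSPFSSW", modification_space())
  expect_equal(max(auto_sp$n_dehydration), 4L)
  # invariant: formula/mass consistency
  i <- which(auto_sp$n_dehydration == 2)
  expect_equal(auto_sp$formula[i], "C57H71N13O15S2")
})

test_that("growing the space never removes a species", {
  small <- enumerate_species("GCGFTCSPFSSW", modification_space(2))
  big <- enumerate_species("GCGFTCSPFSSW",
                           modification_space(4, allow_methylation = TRUE))
  expect_true(all(small$formula %in% big$formula))
})

test_that("MS1 matching reproduces the archalan worked examples", {
  space <- modification_space(max_dehydrations = 5, allow_methylation = TRUE)
  sp_a <- enumerate_species("GCGFTCSPFSSW", space)
  m <- match_ms1(data.frame(mz = 621.7382, z = 2L), sp_a, tol_ppm = 10)
  best <- rank_matches(m)[1, ]
  expect_equal(best$n_dehydration, 2L)
  expect_equal(best$n_methylation, 0L)
  expect_equal(abs(best$ppm), 1.29, tolerance = 0.1 / 1.29)

  sp_b <- enumerate_species("GLPSASMYSFEHCC", space)
  mb <- rank_matches(match_ms1(data.frame(mz = 755.3012, z = 2L), sp_b,
                               tol_ppm = 10))[1, ]
  expect_equal(mb$n_dehydration, 2L)
  expect_equal(mb$n_methylation, 1L)
  expect_equal(abs(mb$ppm), 0.53, tolerance = 0.1 / 0.53)

  expect_equal(nrow(match_ms1(data.frame(mz = 500.0, z = 2L), sp_a, 10)), 0L)
  expect_equal(nrow(match_ms1(data.frame(mz = 621.7382, z = 2L),
                              sp_a[0, ], 10)), 0L)
})

test_that("matching equals the brute-force all-pairs oracle", {
  set.seed(21)
  for (rep in 1:3) {
    cores <- replicate(4, random_core(sample(8:14, 1), 1, 2,
                                      seed = sample(1e6, 1)))
    species <- do.call(rbind, lapply(cores, function(cc)
      enumerate_species(cc, modification_space(3))))
    # peaks: some derived from species (with small offsets), some random
    derived <- mz_from_neutral(sample(species$mass, 10, replace = TRUE),
                               sample(1:3, 10, replace = TRUE)) *
      (1 + rnorm(10, 0, 4) / 1e6)
    peaks <- data.frame(mz = c(derived, runif(40, 200, 1600)))
    got <- match_ms1(peaks, species, charges = 1:3, tol_ppm = 8)
    want <- oracle_ms1(peaks, species, charges = 1:3, tol_ppm = 8)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(sort(round(got$ppm, 6)), sort(round(want$ppm, 6)))
    }
    # enlarging the tolerance never removes a match
    wider <- match_ms1(peaks, species, charges = 1:3, tol_ppm = 20)
    expect_true(all(paste(got$peak_mz, got$z, got$formula) %in%
                      paste(wider$peak_mz, wider$z, wider$formula)))
  }
})

test_that("peaks with a charge annotation are only tried at that charge", {
  sp <- enumerate_species("GCGFTCSPFSSW", modification_space(2))
  target <- sp[sp$n_dehydration == 2, ]
  pk_z1 <- data.frame(mz = mz_from_neutral(target$mass, 1), z = 1L)
  pk_wrong <- data.frame(mz = mz_from_neutral(target$mass, 1), z = 2L)
  expect_equal(nrow(match_ms1(pk_z1, sp, charges = 1:3, tol_ppm = 5)), 1L)
  expect_equal(nrow(match_ms1(pk_wrong, sp, charges = 1:3, tol_ppm = 5)), 0L)
})

test_that("ranking prefers fewer modifications, then ppm, then charge", {
  m <- data.frame(
    peak_mz = 1, intensity = 1, z = c(2L, 1L, 1L),
    core = "X", n_dehydration = c(4L, 2L, 2L), n_methylation = 0L,
    n_dehydrogenation = 0L, n_mods = c(4L, 2L, 2L), formula = "F",
    theoretical_mz = 1, ppm = c(0.5, 1.3, 1.3), abs_ppm = c(0.5, 1.3, 1.3),
    stringsAsFactors = FALSE)
  r <- rank_matches(m)
  expect_equal(r$n_mods, c(2L, 2L, 4L))
  expect_equal(r$z[1], 1L)           # charge breaks the 2-mod tie
  m2 <- m[2:3, ]; m2$abs_ppm <- c(1.1, 0.4); m2$z <- 1L
  expect_equal(rank_matches(m2)$abs_ppm, c(0.4, 1.1))
  expect_equal(rank_matches(m[2, ])$rank, 1L)
})

test_that("BGC linking ties the planted core to its peak with provenance", {
  sim <- simulate_genome(seed = 9, cores = "GCGFTCSPFSSW", decoys = "no_cys")
  orfs <- find_orfs(sim$genome, "lanM_1")
  cands <- filter_precursors(select_adjacent(orfs, 10))
  peaks <- data.frame(mz = 621.7382, z = 2L)
  links <- link_bgc_to_peaks(cands, peaks, modification_space(),
                             tol_ppm = 10, min_core = 8, max_core = 20)
  expect_gt(nrow(links), 0)
  expect_equal(links$core[1], "GCGFTCSPFSSW")
  expect_equal(links$n_dehydration[1], 2L)
  expect_true(all(c("orf_start", "split", "z", "ppm") %in% names(links)))
  # no candidate within tolerance -> empty link table, not an error
  none <- link_bgc_to_peaks(cands, data.frame(mz = 400.123, z = 2L),
                            modification_space(), 10, 8, 20)
  expect_equal(nrow(none), 0L)
})

test_that("two isobaric cores matching one peak are both reported", {
  cands <- data.frame(
    contig = "c1", start = c(0L, 500L), end = c(120L, 620L),
    strand = "+", frame = 0L,
    aa = c("MKAYDAAFELGCGFTCSPFSSW", "MKAYDAAFELGGCFTCSPFSSW"),
    length_aa = 22L, distance = c(100L, 200L), passes_filters = TRUE,
    motif_hits = "2", stringsAsFactors = FALSE)
  links <- link_bgc_to_peaks(cands, data.frame(mz = 621.7382, z = 2L),
                             modification_space(), 10, 12, 12)
  expect_equal(sort(unique(links$candidate)), c(1L, 2L))
  expect_equal(links$n_dehydration, c(2L, 2L))
})
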