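# lanmine

Genome-to-metabolite discovery of **class II lanthipeptides**, modelled on
the workflow that recently yielded the first characterized archaeal
lanthipeptides (archalans α and β from the haloarchaeon *Halorussus
salinus*). Lanthipeptides are ribosomally synthesized and
post-translationally modified peptides (RiPPs) whose Ser/Thr residues are
dehydrated and then cyclized onto Cys thiols, forming lanthionine (Lan) and
methyllanthionine (MeLan) thioether rings. The class II synthetase gene
*lanM* is the genomic hallmark: the precursor peptide (leader + core) is
encoded by a small open reading frame near it.

`lanmine` is for computational natural-product chemists who want to run —
and stress-test on synthetic data — the complete inference chain:

1. **Precursor mining** — six-frame ORF discovery in a window around
   annotated *lanM* loci; candidate precursors are ORFs shorter than 100
   residues with Cys *and* Ser/Thr within 20 residues of the C-terminus;
   conserved leader-motif `Kx(Y/F)(D/E)xx(F/Y)` scanning; enumeration of
   leader/core split hypotheses.
2. **MS1 linking** — enumeration of modified species per candidate core
   (dehydration −H₂O, methylation +CH₂, dehydrogenation −H₂) and complete
   ppm-tolerance matching of observed high-resolution MS1 peaks to
   theoretical [M + zH]ᶻ⁺ values, ranked by modification parsimony.
3. **Ring topology** — ring-aware b/y fragment generation in which
   cleavages inside a thioether ring proceed only via Cγ–S rupture (the
   Cys-derived residue appears as Dha, nominal −34 Da; the donor-derived
   residue keeps the sulfur, nominal +16 Da), topology classification
   (disjoint "bicycle" / nested / interlocking "intertwined"), and
   simulated reductive desulfurization with NaBH₄/NaBD₄ (per opened link:
   −S +2H, or −S +H +D with a deuterium label) to resolve ring pairings
   that intact-species fragmentation cannot.
4. **Synthetic data** — seeded generators for genomes with planted
   precursors and per-clause decoy ORFs, and for MS1/MS2 spectra with ppm
   jitter and noise peaks, so every stage runs and is tested offline.

The core mass arithmetic is exact monoisotopic formula algebra
(`C, H, N, O, S, D`) with m/z = (M + z·1.007276)/z and
ppm = 10⁶·(obs − theo)/theo.

## Worked example

```r
library(lanmine)

# the characterized archalan alpha core, planted next to a lanM marker
fx  <- archalan_fixture("archalan_alpha")
sim <- simulate_genome(seed = 17, cores = fx$core)
dir <- tempfile(); write_simulated_genome(sim, dir)

genome <- read_genome(file.path(dir, "genome.fasta"),
                      file.path(dir, "genome.gff3"))
cands  <- filter_precursors(select_adjacent(find_orfs(genome, "lanM_1"), 10))

links <- link_bgc_to_peaks(cands, data.frame(mz = 621.7382, z = 2L),
                           modification_space(), tol_ppm = 10,
                           min_core = 8, max_core = 20)
links[1, c("core", "n_dehydration", "formula", "theoretical_mz", "ppm")]
#>           core n_dehydration        formula theoretical_mz       ppm
#> 1 GCGFTCSPFSSW             2 C57H71N13O15S2       621.7390 -1.248897
```

The observed peak at m/z 621.7382 ([M + 2H]²⁺) is explained by the
predicted core `GCGFTCSPFSSW` carrying exactly two dehydrations — the two
thioether rings — with formula C₅₇H₇₁N₁₃O₁₅S₂ at 1.25 ppm. Scoring
candidate ring topologies against a simulated MS/MS spectrum then ranks
the MeLan Thr5–Cys2 / Lan Ser10–Cys6 "bicycle" first:

```r
sp <- simulate_ms2(theoretical_fragments(fx$core, fx$mods, fx$rings),
                   seed = 18, jitter_ppm_sd = 2, n_noise = 5)
sc <- score_topologies(sp, fx$core, fx$mods,
                       enumerate_candidate_topologies(fx$core, 2))
sc[1, c("topology", "label")]
#>       topology    label
#> 1 T5-C2,S10-C6 disjoint
```

For intertwined rings (archalan β), pairing is resolved by simulating
partial NaBD₄ desulfurization products and matching their spectra — see
`infer_topology_from_desulfurization()` and the vignette.

A thin command-line front end with `mine`, `link`, `rings`, `simulate` and
`run-all` subcommands lives at `inst/scripts/lanmine.R`.

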