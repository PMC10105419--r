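---
title: "Mining class II lanthipeptides from genome to metabolite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining class II lanthipeptides from genome to metabolite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lanmine)
```

## The inference problem

Class II lanthipeptides are RiPPs: a small precursor gene near the
synthetase gene *lanM* encodes an N-terminal leader and a C-terminal core;
the synthetase dehydrates core Ser/Thr residues (−H₂O each, to Dha/Dhb) and
cyclizes Cys thiols onto them, installing lanthionine (Lan, from Ser) and
methyllanthionine (MeLan, from Thr) thioether rings. Linking a biosynthetic
gene cluster to a metabolite therefore reduces to three questions this
package answers computationally:

1. *Which small ORF near lanM is the precursor, and where does the core
   start?* (mining + leader/core split enumeration)
2. *Which observed MS1 peak is the matured core?* (modified-species
   enumeration + ppm matching)
3. *Which Ser/Thr–Cys pairing forms the rings?* (ring-aware MS/MS
   annotation, and desulfurization labelling when fragmentation alone
   cannot decide)

## Model and assumptions

**Mass arithmetic.** All masses are exact monoisotopic sums over a fixed
atomic table (C 12, H 1.0078250, N 14.0030740, O 15.9949146, S 31.9720707,
D 2.0141018). Charge is protonation: m/z = (M + z·p)/z with
p = 1.007276 Da. Two conventions are deliberate: deuterium is its own
element symbol (so NaBD₄ products are tracked element-wise), and nominal
masses are rounded monoisotopic masses, used only for the −34/+16
fragmentation bookkeeping.

**Mining filters.** A candidate precursor is an ORF of fewer than 100
residues whose C-terminal 20 residues contain at least one Cys and at least
one Ser/Thr — the residues without which no thioether ring can form. Both
thresholds are configurable (`max_len`, `cterm_window`). ORFs start at
ATG/GTG/TTG (archaea use alternative starts frequently) and the initiator
is translated as Met; per stop codon the longest ORF is reported once. The
mining window defaults to 6 kb each side of *lanM* and the ten nearest ORFs
are kept (`k = 10`), nearest by absolute edge-to-edge distance across both
strands — the adjacency definition is a design choice, as is the 20-residue
minimum ORF length. The leader motif `Kx(Y/F)(D/E)xx(F/Y)` conserved in
archaeal precursor leaders is scanned with overlaps; splits whose motif
lies wholly in the leader are flagged motif-consistent, but the flag does
not gate matching, because the motif is a family feature, not a law.

**MS1 linking.** For each core hypothesis the modification space is the
Cartesian product of dehydration (bounded by the core's Ser+Thr count when
`"auto"`), methylation and dehydrogenation counts. Methylation is off by
default and enabled per locus from a `methyltransferase=true` GFF3
attribute — the genomic justification used when +CH₂ was invoked for a real
cluster. Matching is complete within the tolerance (default 10 ppm,
generous against observed instrument errors near 1 ppm) and ranked
lexicographically by (total modifications, |ppm|, charge): parsimony
first, no probabilistic model, because no training data exists at this
scale. Isobaric count-vectors collapse to one species with full
provenance.

**Ring-aware fragmentation.** b/y ions are generated at every backbone
bond. For a bond inside a closed ring, the only emitted pathway is Cγ–S
rupture: the sulfur stays on the donor side, so the Cys-derived residue
appears as Dha (−H₂S vs Cys, nominal −34 Da) and the donor-derived residue
as donor −H₂O +H₂S (net +S−O = +15.977 Da vs the encoded Ser/Thr, nominal
+16). This matches the observed fragmentation of the characterized archaeal
lanthipeptides; a `ring_mode = "suppress"` flag instead drops intra-ring
cleavages entirely (classical behaviour). b and y neutrals are computed
independently per side, so the complementarity invariant
b\_i + y\_{n−i} = M is a genuine cross-check, tested to 10⁻⁶ Da.

**A structural identifiability fact.** Two topologies over the *same*
donor and acceptor sets but swapped pairings (e.g. {T5–C2, S10–C6} vs
{S10–C2, T5–C6}) produce identical b/y masses under the rupture model: the
±H₂S shift at a bond depends only on which side the donor and acceptor sit,
not on who is paired with whom. `score_topologies()` therefore reports a
winner by its documented deterministic tie-break in that situation and
flags a spectrum `indeterminate` only when no candidate has any
discriminating ion. Pairing is physically resolved by partial reductive
desulfurization: opening one link converts its residues to Ala/Abu
(−S +2H per link, or −S +H +D with NaBD₄, one deuterium per opened link on
either the donor- or acceptor-derived residue — both placements are
enumerated since the mechanism does not fix the site), and the product
spectra differ between pairings. This is exactly why the intertwined
topology of the second archalan required the NaBD₄ route, and
`infer_topology_from_desulfurization()` reproduces that logic: per
candidate topology and product spectrum it selects the best-explaining
(opened link, label placement), then ranks candidates by jointly explained
discriminating ions.

## What the synthetic data emulates — and what it does not

`simulate_genome()` builds one contig: uniform-composition background at a
haloarchaeal-like GC of 0.60, a central *lanM* marker gene, planted
precursors (synthetic leader carrying the conserved motif + core) and
decoys each violating exactly one filter clause (length exactly 100;
no C-terminal Cys; no C-terminal Ser/Thr; a valid precursor outside the
window). Planted genes are pinned by an in-frame stop guard so the ORF
caller recovers their exact coordinates. Background composition is
uniform — no codon-usage realism — so random small ORFs that legitimately
satisfy the filter do occur, as they would in a real genome; tests
therefore assert recovery of planted truth and rule-consistency of every
survivor, not an absence of additional candidates.

`simulate_ms1()`/`simulate_ms2()` draw multiplicative ppm jitter from
Normal(0, sd), add uniform noise peaks, and subsample fragments; with zero
jitter, zero noise and full sampling they reproduce theoretical values
exactly, which anchors the round-trip tests. They do not model isotope
envelopes, retention time, chimeric spectra or realistic intensities, so
passing tests demonstrate correctness of the inference chain under
controlled error, not robustness to every artefact of real LC–MS/MS data.

Default study conditions used by the stochastic tests and the acceptance
script: cores of 10–20 residues with two rings, 5 ppm fragment jitter, 20%
noise peaks, two single-link NaBD₄ product spectra per case, 20 seeded
replicates; genome recovery uses 30 kb contigs with one planted precursor
and all four decoy classes across 5 seeds. These sizes keep the full suite
within minutes on one CPU while leaving every code path exercised.

## Numerical choices and degenerate inputs

* ppm tolerances: MS1 and MS/MS default to 10 ppm; all tolerances must be
  strictly positive.
* Mass agreement in the published characterization is reproduced to within
  ±0.1 ppm rather than exactly, because the original theoretical-m/z
  convention (electron mass, rounding) is not stated; the package's
  convention is fixed and documented above.
* Ties: ORF selection breaks distance ties by (smaller start, then `+`
  strand); match ranking by (mods, |ppm|, z) is stable; topology ties fall
  back to candidate serialization order.
* Fragment generation requires dehydration count = ring count (each ring
  consumes one dehydration); dehydrogenated species and extra deltas are
  matched at MS1 but not fragmented.
* The pipeline skips topology search for species with more than
  `max_rings` (default 3) dehydrations: the candidate space grows as
  C(#C, n)·C(#S+#T, n)·n! and high counts on spurious matches are
  implausible rings, not signal.
* Empty results (no ORFs, no matches, no explicable ions) are successes;
  hard errors are reserved for missing files, absent *lanM* annotations and
  malformed inputs.

## Known limitations

Leader/core splits are enumerated, not predicted — the method deliberately
carries all split hypotheses to the MS1 stage rather than imposing a
cleavage-site model. Only b/y ions are generated (no a-ions, neutral
losses or internal fragments). Met sulfur is never desulfurized.
Stereochemistry (DL vs LL crosslinks) and anything requiring NMR are out of
scope. lanM identification itself is an input annotation: the package
mines around given hallmark loci, it does not detect them by homology.

## A compact end-to-end run

```{r e2e, eval = FALSE}
fx  <- archalan_fixture("archalan_alpha")
sim <- simulate_genome(seed = 17, cores = fx$core)
dir <- tempfile(); write_simulated_genome(sim, dir)
write.table(data.frame(mz = fx$observed_mz, z = fx$observed_z),
            file.path(dir, "peaks.tsv"), sep = "\t", row.names = FALSE)
sp <- simulate_ms2(theoretical_fragments(fx$core, fx$mods, fx$rings),
                   seed = 18, jitter_ppm_sd = 2, n_noise = 5,
                   pepmass = fx$observed_mz, charge = fx$observed_z)
write_mgf(list(sp), file.path(dir, "spectra.mgf"))

report <- run_pipeline(list(
  fasta = file.path(dir, "genome.fasta"),
  gff = file.path(dir, "genome.gff3"),
  ms1_peaks = file.path(dir, "peaks.tsv"),
  ms2_spectra = file.path(dir, "spectra.mgf"),
  min_core = 8, max_core = 20))
report$links[1, c("core", "n_dehydration", "formula", "ppm")]
report$topology[1, c("topology", "label")]
```

The same run is scripted, with every quantity written as JSON, in
`scripts/acceptance.R`.
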