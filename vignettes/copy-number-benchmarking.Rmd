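---
title: "Copy-number benchmarking of proteomics methods: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number benchmarking of proteomics methods: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rulerbench)
```

## The metric

Identification counts reward breadth but say nothing about depth: a method
that finds 5,000 abundant proteins and one that finds 5,000 proteins
reaching three orders of magnitude lower are very different instruments.
`rulerbench` scores a method by joining its identification list onto a
reference table of absolute copies per cell and summarizing the copy-number
distribution of what it caught. The two headline statistics per experiment
are the matched protein count and the mean log10 copies per cell of the
matched proteins; the median is reported alongside, because for strongly
skewed target panels (affinity arrays, for instance) mean and median can
tell different stories, and the package takes no side between them. Deeper
methods show *more* proteins at a *lower* mean log copy number — the two
move in opposite directions, and that anticorrelation is the signature the
visualizations are designed to expose.

Unmatched accessions (proteins absent from the reference) are excluded from
the mean and median rather than imputed; the unmatched fraction is always
reported so that reference-coverage bias stays visible when comparing
methods against references of different depth.

## The proteomic ruler

The ruler converts relative MS signal into absolute copies per cell using
two biological constants: histones are maintained in tight, conserved
proportion to DNA, and the DNA mass of a cell is fixed by its genome:

$$ m_\mathrm{DNA} = \text{genome size (bp)} \times \text{ploidy} \times m_\mathrm{bp}. $$

Equating total histone protein mass with $m_\mathrm{DNA}$ gives, in iBAQ
mode (signal already proportional to molar amount),

$$ c = \frac{m_\mathrm{DNA} N_A}{\sum_{h \in \mathrm{histones}} \mathrm{iBAQ}_h \cdot MW_h},
   \qquad \mathrm{copies}_i = c \cdot \mathrm{iBAQ}_i, $$

and in raw-intensity mode

$$ \mathrm{copies}_i = \frac{I_i}{\sum_h I_h} \cdot \frac{m_\mathrm{DNA} N_A}{MW_i}. $$

Both are invariant to a global rescaling of all signals, which is what makes
the output absolute: the instrument's arbitrary intensity scale cancels.

Defaults (all configurable in `ruler_config()`): $N_A = 6.02214076 \times
10^{23}\,\mathrm{mol}^{-1}$; mean base-pair mass $615.8771 / N_A$ g; genome
size $3.1 \times 10^9$ bp; ploidy 2. The ploidy default assumes a diploid
cell — note that HeLa and many cancer lines are aneuploid, so absolute
accuracy for such lines requires setting ploidy (or an effective genome
size) explicitly. Histones are designated by an explicit accession set
(`default_histones()`, human core + linker histones) rather than gene-name
pattern matching: an explicit list is deterministic and auditable, and can
be replaced wholesale for other organisms.

iBAQ peptide counts use fully tryptic in-silico digestion: cleavage
C-terminal of K or R, blocked when the next residue is proline, zero missed
cleavages, peptide length 7–30 — the common iBAQ convention. Molecular
weights use average (not monoisotopic) residue masses, the appropriate
choice for protein-scale mass bookkeeping. Records with zero signal get
zero copies and are retained by `run_ruler()` but excluded from reference
tables built with `build_reference()`, which require strictly positive
entries.

## Identifier handling

Reference tables are keyed by canonical UniProt accession, so every parser
reduces group identifiers to that form: first `;`-token of a protein group
(the majority/representative protein — alternates in a group are discarded,
not used for fallback matching), `sp|ACC|NAME` and `tr|ACC|NAME` reduced to
`ACC`, isoform suffixes (`-2`) stripped. Distinct raw groups can collapse
to one accession; they then count once (set semantics). MaxQuant rows
flagged `+` for decoy, contaminant, or identified-only-by-site are dropped.
Column names are located case-insensitively with configurable aliases,
since export headers vary across software versions.

## Histograms and the apex

`bin_log_copies()` uses exact equal-width bins over a stated range (default
30 bins over the reference's min–max of log10 copies). This deliberately
deviates from base R's histogram breaks, which treat the requested bin
count as a suggestion and adjust it for round numbers; a benchmarking plot
must have the bin count it claims, and overlays require every histogram to
share edges. Experiments are therefore always binned on the reference's
range, with out-of-range values clamped into the end bins — every protein
is counted, and `sum(counts) == n_total` holds exactly. Bins are half-open
`[lo, hi)` with the last bin closed. Densities are
`counts / (n_total × width)`, so the density integral is exactly 1.

The apex is the midpoint of the modal bin, drawn as a vertical reference
line so a second method's shift toward lower copies is visible at a glance.
Ties break toward the lower-copy bin — the conservative direction for a
sensitivity claim. Every rendered figure writes a companion TSV of bin
edges, counts and densities; re-binning the raw values reproduces the
figure from the TSV exactly, so no figure carries information the data
files do not.

## The synthetic proteome

The generator exists so the entire pipeline — ruler, parsing, mapping,
binning, rendering — runs and is testable offline. It emulates a deep
HeLa-scale reference: 14,179 proteins by default, log10 copies drawn from
a normal with mean 4.2 and SD 1.1 (a unimodal distribution spanning roughly
6–7 decades at ±3σ, matching the shape and scale of deeply fractionated
human cell-line proteomes), molecular weights log-normal with a ~45 kDa
median, and a designated 11-member histone subset. Two histone choices
matter:

* **Conserved stoichiometry.** Histone copies are drawn with a narrow
  0.15-decade spread rather than the bulk proteome's 1.1 decades. Real
  histones exist in tightly conserved ratios; without this, the histone
  mass anchor is dominated by a single protein and one noise draw can move
  every estimate in a simulated experiment.
* **Mass pinning.** After drawing, histone copies are rescaled so histone
  protein mass is exactly a set fraction (default 4%) of total protein
  mass. Exact ruler recovery then requires the ruler's assumed DNA mass to
  equal that histone mass, which is what `sim_ruler_config()` constructs:
  it solves for the genome size that makes `m_DNA` equal the simulated
  histone mass, keeping ploidy and base-pair mass at their defaults. With
  that configuration, zero-noise signals from `generate_quant_records()`
  invert to the reference copies at machine precision in both modes, which
  is the package's strongest self-check of the ruler algebra.

Experiment lists are drawn with a logistic detection model in log10 copies,
$P(\mathrm{detect} \mid x) = 1/(1 + e^{-a(x - t)})$, slope $a = 2$ by
default: the simplest monotone model consistent with the observation that
deeper methods add predominantly lower-copy proteins. Method depth is a
midpoint $t$; nothing about chromatography, spectra, match-between-runs or
labeling is simulated — depth is deliberately abstracted into this one
parameter, so passing tests demonstrate the pipeline's arithmetic and
ordering behavior, not fidelity to any instrument's physics. Simulated
references and experiment lists are written in the same TSV and plain-list
formats the real pipeline reads, so fixtures are indistinguishable from
real inputs. All generators are bit-reproducible for a fixed seed.

## Numerical and degenerate-input choices

* Log base 10 throughout; means of ~4–6 on this scale correspond to real
  cellular copy numbers.
* Reference entries must be strictly positive; `log10_copies` is recomputed
  whenever it is absent or disagrees with `copies_per_cell` beyond 1e-9.
* An experiment with no matched proteins has undefined mean/median; the
  single-experiment API raises a classed error, while batch comparison
  converts it to an NA row plus a warning so one bad file cannot abort a
  multi-method comparison.
* Empty value sets cannot be binned (classed error) and the apex of an
  empty histogram is undefined.
* The ruler requires at least one histone with positive signal; intensity
  mode additionally requires a molecular weight on every record (iBAQ mode
  only on histones).
* CLI reruns with identical inputs produce byte-identical data outputs;
  seeds are explicit arguments, never wall-clock derived.

## Problem sizes used in the test suite

The suite exercises references of 50–5,000 proteins, a full-size 14,179
reference for the self-comparison identity, 1,000-sequence digestion-oracle
sweeps with sequences up to 2,000 residues, and 100-replicate detection
simulations on a 2,000-protein reference — sizes at which every property
under test (standard-error bounds, binomial 3σ windows, ordering
frequencies) has comfortable resolution while the whole suite runs in
seconds.

## Known limitations

* Absolute accuracy inherits the ruler's assumptions: histone:DNA mass
  equivalence, correct ploidy/genome constants, and unbiased histone
  quantification. For aneuploid lines the defaults are a convention, not a
  measurement.
* The reference table defines the universe: proteins absent from it are
  reported but never scored, so cross-method comparisons share the
  reference's blind spots.
* The synthetic generator's unimodality and logistic detection are
  idealizations; a real method's detection curve need not be logistic, and
  real copy-number distributions can carry shoulders the default single
  log-normal lacks.
* No statistical testing between distributions is performed; the outputs
  are descriptive summaries and visualizations.
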