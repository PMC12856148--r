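---
title: "Benchmarking SAAV detection from open-search proteomics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking SAAV detection from open-search proteomics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Translational errors substitute single amino acids in a protein relative to
its coding sequence. Because no nucleic-acid readout exists for them, they
can only be observed as single amino acid variations (SAAVs) in
mass-spectrometry proteomics, typically as unexplained precursor mass shifts
in an open database search. Whether current open-search engines can be
trusted for this task is an empirical question that needs a ground truth
with many known SAAV-bearing peptides per sample.

Patient-derived xenograft (PDX) material provides one: a human tumor grown
in a mouse yields mixed human/mouse proteomes, and orthologous human/mouse
proteins differ at many single residues. A mouse peptide that differs from
its human cognate at exactly one site behaves, to a search engine given only
the human database, exactly like a human peptide carrying a SAAV. `saavbench`
implements the machinery for this benchmark: building the cross-species SAAV
catalog, constructing gold-standard PSM sets from closed searches against
the combined two-species database, interpreting open-search mass shifts as
SAAVs, and scoring candidates at the PSM (spectrum) level — together with a
fully seeded simulator that stands in for the raw data and the search
engines so every component is testable end to end.

## In silico digestion and the cognate-pair catalog

Digestion is tryptic: cleavage after K or R except before P, up to two
missed cleavages, peptide length 6–61 residues, matching common search
defaults. The length filter is applied after enumeration, so missed-cleavage
products face the same bounds. Positions are 1-based throughout. Protein
N-terminal methionine is not specially removed; the digestion parameters
define no N-terminal processing, and adding one would change peptide starts
silently. Peptides are indexed per (species, gene symbol), unioned over
isoforms and deduplicated by sequence, because cognate pairing is gene-keyed
through an ortholog symbol map.

A cognate pair is an equal-length human/mouse peptide pair from an
orthologous gene at Hamming distance exactly 1. Equal length plus
Hamming distance 1 is the operational definition of "cognate peptides with a
SAAV": a substitution cannot change peptide length, and indels are out of
scope. The differing site defines the SAAV in human-to-mouse orientation,
with its monoisotopic mass shift (destination minus origin residue mass).
I and L are kept distinct in the catalog — the sequences are known — while
the mass-based calling side collapses them (below).

Residue masses are stored to six decimal places. Five decimals are enough
for every comparison the package makes except one: rounding each residue to
five decimals before subtracting misrounds the N-to-D shift (0.98402 Da) in
the fifth decimal.

## Biochemical categories

Substitution "conservativeness" uses a fixed five-class partition:
nonpolar/aliphatic {G,A,V,L,I,P,M}, aromatic {F,W,Y}, polar-uncharged
{S,T,C,N,Q}, positive {K,R,H}, negative {D,E}. The scheme was chosen so that
the canonical translational-error substitutions (Val/Ile, Met/Leu nonpolar;
Tyr/Phe aromatic) are within-category; it is configurable because no single
partition is standard. The census default counts distinct peptide pairs
(`pair_instances`); counting unique substitution types is offered as an
alternative because summary fractions in the literature are sometimes
reported either way.

## Assigning SAAVs to open-search mass shifts

A localized open-search PSM carries a base peptide, a mass shift, and a
site. The shift is compared against the theoretical universe of ordered
substitutions — all `from != to` residue pairs, with destinations I and L
collapsed into the ambiguity class `X` (one entry per origin) because the
two are isobaric and indistinguishable by mass. Mass-silent I/L
interchanges (shift 0) are excluded from the universe: a near-zero shift is
not reportable as a variant by any mass-based method.

A PSM is assigned a SAAV when three criteria hold jointly:

1. the candidate substitution's theoretical shift is the nearest to the
   observed shift among all theoretical pairs;
2. that absolute difference is strictly less than 0.1 Da (configurable);
3. the substitution's origin residue equals the base-peptide residue at the
   localized site.

The criteria are applied in exactly this order: a nearer pair with the
wrong origin blocks a farther pair with the right origin
(`origin_mismatch`), rather than falling back — deliberately conservative,
at the cost of discarding some recoverable calls. Chemically identical
elemental changes (e.g. the +CH2 family G→A, S→T, V→X, D→E, N→Q) have
exactly equal shifts; with six-decimal constants their computed values can
differ by ~1e-6 Da, so entries within 1e-4 Da of the minimum are treated as
one tie set. The smallest gap between genuinely different shift families
under the standard masses is >0.02 Da, so this epsilon cannot merge distinct
families. After origin filtering a tie set can hold at most one entry under
the I/L collapse; a residual tie (possible only with a custom mass table) is
rejected as `ambiguous` rather than guessed. Engines that output SAAV calls
directly (rather than raw shifts) bypass the nearest-shift search but are
still validated against criterion 3.

Localization policies mirror engine semantics: the dependent-peptide policy
keeps rows with exactly one localized site of probability strictly greater
than 0.5; the open-search policy requires the localization to resolve to a
single site; the generic policy requires a non-missing site. How a
"confidently assigned" location is encoded varies by engine version, so the
single-site reading is a package decision exposed as a policy argument.

## Gold standards and PSM-level scoring

A gold standard is the per-sample set of (spectrum, mouse peptide) keys a
closed search against the concatenated human+mouse database assigned to a
catalog mouse peptide; matching is exact string equality, since a
sequence-database search disambiguates I/L. The dependent-search variant
further requires the human cognate peptide among the same sample's PSMs,
matching the assumption of dependent-peptide searching. Two tools' gold sets
combine into a mixed gold standard: their intersection (strict truth, used
as the sensitivity denominator) and union (inclusive truth, used for
precision). Spectra the tools assign different peptides simply drop out of
the intersection; no reconciliation is attempted. A chimeric spectrum with
several rows from one tool keeps only its best-scoring row.

A candidate is a true positive when its (sample, spectrum) key is in the
gold standard and its variant peptide equals the gold mouse peptide with
`X` matching I or L at the variant site. Requiring variant-peptide identity
(hence SAAV identity up to I/L), not just spectrum overlap, is the stricter
reading of PSM-level evaluation and is what the simulator's label
bookkeeping validates exactly. Sensitivity is TP over gold; precision TP
over candidates; F1 their harmonic mean (0 when both are 0). Empty
denominators propagate as missing values and are excluded from medians —
never silently reported as 0. Metrics are per sample, summarized by medians;
percentages appear on the 0–100 scale in outputs while fractions are used
internally. Rank-sum (Wilcoxon) utilities compare per-sample metric vectors
between tools.

Per-SAAV stratification computes sensitivity over gold PSMs of each true
substitution type and precision over candidates calling that type; per-type
true-positive counts partition the overall count. The misassignment census
cross-tabulates called versus true SAAVs among false candidates with the
difference of their theoretical shifts — near-zero differences with
differing sites diagnose mislocalization, the characteristic failure of a
closed search given one preset substitution as a variable modification.

## Quality metrics

Retention-time deviation is `|observed - predicted|` in minutes; smaller is
better. The spectral similarity is the standard normalized spectral angle,
`SA = 1 - 2*arccos(<s1, s2>)/pi` on unit-L2-normalized intensity vectors of
matched peaks — 1 for identical normalized spectra, 0 for disjoint ones.
Peaks are matched greedily by nearest m/z within ±0.02 Da, each peak at most
once; unmatched peaks contribute zero to the counterpart. Euclidean
normalization makes the inner product a cosine, as the angle form requires.
The theoretical fragment generator produces singly charged b/y ions with
unit intensities (proton 1.00728, water 18.01056); higher charge states,
neutral losses and isotope envelopes are out of scope, which is adequate for
stick-spectrum comparisons.

## The simulator

The generator replaces PDX raw data and search engines while preserving the
statistical structure the pipeline consumes. Its defaults are the emulated
study conditions and are not tuned per analysis: 200 genes of mean length
300 (SD 60); per-residue substitution rate 0.05 (approximating human/mouse
ortholog divergence); within-category bias 0.575; mouse PSM fraction 0.30;
5000 PSMs per sample over 4 samples; closed-tool overlap 0.672; open-search
detection rate 0.5; mislocalization rate 0.15; wrong-shift rate 0.05;
background spurious-candidate rate 0.05 per human PSM; RT noise SD 0.5 min.
Residues are sampled with K and R enriched to 10% each so tryptic peptides
of in-range length are common even in small proteomes.

Destination residues are drawn within the origin's biochemical category with
probability equal to the bias, otherwise uniformly among residues of other
categories, so the realized within-category fraction is the bias itself.
Injected substitutions are restricted to sites where the variant is
detectable by the benchmark at all: K, R and P are excluded on either side
(they would change tryptic boundaries, so the variant peptide no longer
pairs with its cognate at equal length), H is excluded as an origin (its
only category partners are K and R), and mass-silent I/L interchanges are
excluded. Without this restriction, cleavage-changing substitutions — which
are predominantly cross-category — are selectively lost from the catalog,
and the catalog census overstates the within-category fraction by a few
points relative to the configured bias. Multiple substitutions per peptide
are not prevented; such peptides simply never enter the catalog (the
Hamming-1 filter), mirroring reality.

Open-search corruption is explicit: a detected gold PSM is emitted with the
human cognate as base, the true shift and the true site, then possibly
mislocalized (site moved uniformly to another position) and/or given a mass
error (±0.2–2.0 Da uniform). Background candidates on human-only spectra
draw a random origin-matching substitution, so they pass assignment and
stress precision. Because a mass error of at least 0.2 Da can never select
the true substitution under the 0.1 Da tolerance, and a moved site changes
the variant at two positions relative to the mouse peptide, corrupted rows
are never true positives — which is what makes pipeline precision and
sensitivity equal the generator's label counts exactly, a key invariant the
tests assert.

Retention times come from a linear map on summed Kyte–Doolittle hydropathy
(with I set equal to L so the ambiguity class `X` is well defined); observed
values follow the true peptide plus Gaussian noise, predicted values follow
the called variant peptide. Spectra are the b/y generator's output with
multiplicative intensity jitter on the experimental side. These are
simulation devices to give the quality metrics a detectable signal, not
models of chromatography or fragmentation — passing quality-separation
tests shows the metrics respond to sequence errors in stick spectra, not
that they would perform identically on real data. More generally the
simulator does not emulate chimeric spectra, intensity structure,
FDR-controlled score distributions, or shared peptides between species, so
green tests certify the pipeline's bookkeeping and the calling rule, not
engine behavior on real raw files.

All randomness flows through one explicit seeded generator handle
(`newRng`/`withRng`), so identical configuration and seed reproduce outputs
exactly and the caller's RNG state is never touched.

## Problem sizes and numerical choices

Unit tests run the simulator at 20–150 genes and a few hundred to a few
thousand PSMs per sample; the end-to-end checks use the default 5000 PSMs ×
4 samples, 10,000 randomized triples for assignment-oracle agreement, and 50
random 200-residue proteins for digestion-oracle agreement. Detection-rate
recovery is checked against 95% binomial intervals with the three replicate
seeds pooled per rate (n ≥ 3000), which tests the estimator at a sensible
width without multiplying marginal 95% checks. Mass-shift comparisons use
strict inequalities at the stated tolerances (0.1 Da assignment window,
1e-4 Da tie epsilon, 0.02 Da peak matching); cosine inputs are clamped to
[-1, 1] before `arccos`.

## Known limitations

The catalog treats the ortholog symbol map as ground truth and does not
disambiguate paralogs; multi-residue differences and indels are ignored by
construction; open-search shifts equal to a PTM mass (e.g. D→E versus
methylation) are interpreted as SAAVs whenever the three criteria hold, a
caution that applies equally to real data; and peptide-level (as opposed to
PSM-level) evaluation, FDR re-estimation and quantification are out of
scope.
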