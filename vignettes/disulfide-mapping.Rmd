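---
title: "Mapping disulfide bonds from bottom-up LC-MS/MS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping disulfide bonds from bottom-up LC-MS/MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbondmap)
```

## The problem

Cysteines in a folded protein can be free thiols, oxidized to sulfonic
acid, or joined pairwise by disulfide (S-S) bridges; which of these
states each cysteine occupies is structural information that bottom-up
proteomics can read out directly. The experimental design this package
models is the one used to map disulfide bonds in the mitochondrial
voltage-dependent anion channel (VDAC) isoform family: free thiols are
alkylated with iodoacetamide under mildly acidic pH (so native bridges
neither reshuffle nor reduce), the protein mixture is digested with
trypsin, and the digest is analyzed by high-resolution electrospray
LC-MS/MS. A cysteine that was bridged in the native protein then shows
up either in a *loop-linked* peptide (both bridge ends in one tryptic
peptide, forming a ring), or in a pair of peptides joined by the bridge
(*intra-protein* when both peptides come from one protein, and
*inter-protein* when the bridge crosses two molecules - the signature of
disulfide-mediated oligomerization). A cysteine that was free shows up
carboxyamidomethylated instead, so comparing the intensities of the two
forms of the same peptide estimates how much of each cysteine was
bridged.

The package implements the complete in-silico side of this workflow:
candidate enumeration, precursor matching, fragment annotation,
bond-level reporting, and a synthetic-data generator that makes every
stage testable at desk scale without raw instrument files.

## The mass model

Everything rests on monoisotopic mass arithmetic. A peptide's neutral
mass is the sum of its residue masses plus one water; a protonated ion
at charge $z$ has

$$ m/z = \frac{M + z \cdot 1.007276}{z}, $$

and agreement between an observed and a theoretical value is expressed
as a signed relative error in parts per million,
$(m_\mathrm{obs} - m_\mathrm{theo})/m_\mathrm{theo} \times 10^6$.

A cysteine engaged in a disulfide bridge has lost one hydrogen atom; it
is modeled as a *half-disulfide* state with delta $-1.007825$ Da,
giving the bridge-engaged residue (Cys-S$\cdot$) a mass of
$103.00919 - 1.00783 = 102.0014$ Da and a whole bridge a net
$-2.015650$ Da relative to the two free thiols. Storing the bridge as a
per-residue state, rather than as a special pairwise adduct, keeps the
mass of any assembly a plain sum of chain masses and makes the fragment
bookkeeping below exact by construction. The delta is stored at full
hydrogen-atom precision; search engines conventionally print the
rounded $-1.0078$.

The remaining modification set mirrors a standard alkylation/digestion
search: carboxyamidomethyl cysteine (+57.021464, the fixed state of
reduced cysteines), cysteine trioxidation to sulfonic acid (+47.984744),
methionine oxidation (+15.994915), protein N-terminal acetylation
(+42.010565) and pyroglutamate formation from N-terminal Gln
($-17.026549$) or Glu ($-18.010565$). The three cysteine states plus
the implicit free state are mutually exclusive per position. Residue
masses are 5-decimal monoisotopic values; Ile and Leu are kept as
distinct letters with identical mass, and no average-mass mode exists
anywhere - the workflow is monoisotopic throughout.

```{r}
p <- peptidoform("SCSGVEFSTSGHAYTDTGK")
peptidoform_mass(p)
mz(peptidoform_mass(p), 2)
```

## Digestion

`digest()` applies the classic trypsin rule (cleave C-terminally to K
or R, blocked when the next residue is proline) on the mature chain and
enumerates every peptide with up to `max_missed` internal missed
cleavages (default 3). Initiator methionines are removed by `mature()`
before digestion - several VDAC isoforms lose Met1 post-translationally,
which makes the cysteine encoded at position 2 the mature N-terminal
residue - but all coordinates remain *Met1-based*: they refer to the
full database sequence even when Met1 is absent. Whether cleavage
before proline is blocked is configurable, because search engines
differ; the classic blocking rule is the default since the observed
tryptic peptides are consistent with it.

Trypsin preparations also show a weak chymotryptic-like side activity
at mildly acidic pH. This is modeled as an optional second pass
(`semi_chymo = TRUE`) emitting semi-specific peptides with one tryptic
(or chain-terminal) boundary and one boundary after F/W/Y/L/M. These
peptides are tagged separately and are intended for sequence-coverage
mapping (`coverage()`), not for cross-link candidate generation, which
uses fully tryptic peptides only.

## Candidate enumeration

`enumerate_species()` digests each protein, keeps cysteine-containing
peptides of 5-50 residues (shorter species elute poorly and longer ones
fall outside the survey range at usable charges), expands each into its
modification variants, and assembles:

* one **loop** species per unordered cysteine pair within a peptide;
* one **intra-protein** pair species per unordered pair of distinct,
  *non-overlapping* peptides of one protein and cross-chain cysteine
  pair (two overlapping copies of the same stretch cannot coexist in
  one molecule);
* one **inter-protein** pair species per cross-protein peptide pair and
  cysteine pair.

Exactly one bridge is placed per species; doubly bridged assemblies and
3+-chain species are out of scope, matching what such experiments
resolve in practice. Pairing a peptide with an identical copy of itself
(a homodimer bridge, indistinguishable at MS1 from a loop only by
topology) is behind the `allow_homodimer` flag, off by default.
Non-bridged cysteines default to the carboxyamidomethyl or trioxidized
states; the free thiol is allowed only by configuration, since free
cysteines are alkylated in this protocol. Trioxidized cysteines never
participate in bridges. Acetylation and pyroglutamate formation are not
co-enumerated on one N-terminus (pyroglutamate formation needs a free
alpha-amine). At most 3 variable modifications are allowed per chain;
the fixed carboxyamidomethyl state and the half-disulfide state do not
count against the cap. Duplicate assemblies reachable through different
enumeration paths are removed on a canonical key (sorted chain locants,
modification multiset, bridge pair), so each unordered species is
emitted exactly once.

`mz_grid()` lays each species out over charges 1-5 and keeps ions
inside the survey window m/z 400-1600, the acquisition range the
defaults emulate.

```{r}
fx <- make_fixtures()
sps <- enumerate_species(fx[1:2], enumeration_config(cys_states = "cam"))
length(sps)
candidate_ions(sps[2], enumeration_config())
```

## Matching and fragment annotation

Precursor matching (`match_precursors()`) is ppm-based with a 10 ppm
default tolerance and a 5e3 intensity floor, reflecting
high-resolution survey scans; every qualifying candidate is reported
per observation (sorted by |ppm|), never a single winner, because
disambiguation belongs to the fragment level. Fragment matching
(`annotate_spectrum()`) is dalton-based with a 0.6 Da default, matching
ion-trap MS2 detection.

`generate_fragments()` produces b/y series per chain. A fragment that
retains the bridged cysteine is emitted with the bridge *intact* - the
entire partner chain attached, both engaged cysteines at $-1.007825$ -
so the complementary pair $b_i + y_{n-i}$ reconstructs the species mass
exactly. The disulfide-specific marker ions seen in such spectra
(cleavage at the S-S or S-C bond) are emitted as three variants at the
bridged position: `thiol` (symmetric S-S homolysis back to the
free-thiol mass), `persulfide` (+31.972071, the sulfur transferred) and
`dha` (dehydroalanine, $-33.987721$, the side-chain sulfur stripped).
These offsets are standard persulfide/dehydroalanine chemistry; spectra
in the literature mark such ions without printing their compositions,
so the exact set is an implementation choice and is carried in a
dedicated `variant` column rather than folded into the m/z. For loop
species, cleavages between the linked cysteines are emitted only in
bridge-opened variants - the ring must open before an internal fragment
can separate - while cleavages outside the ring behave normally. Every
ion also gets $-$H2O and $-$NH3 neutral-loss variants. a-ions, immonium
ions and internal double-cleavage ions are not generated; annotated
disulfide spectra in this workflow are read in terms of b/y series,
their losses and the marker ions.

Peak assignment is greedy per peak: nearest theoretical mass within
tolerance, ties broken toward the simpler explanation (plain ion before
neutral loss before bridge-cleavage variant). Per-chain coverage is the
fraction of backbone cleavage sites supported by at least one matched
b or y ion.

## Bond reports and abundance comparison

`summarize_bonds()` groups matches by the unordered protein/Cys pair -
the *bond* - across charge states and peptidoform variants. A bond is
`ms2-confirmed` when an annotated spectrum shows fragments on both
chains (pairs) or at least one bridge-opened fragment (loops);
otherwise it is reported `precursor-only`, the honest status of
identifications for which no usable MS2 was acquired.

`compare_forms()` estimates the bridged fraction of a cysteine by
comparing the apex (maximum) MS1 intensity of the bridged species
against its carboxyamidomethylated counterparts
(`reduced_counterparts()`). Apex rather than integrated area is used
because it is reproducible from centroided peak lists alone; such
comparisons are rough estimates in any case, since a cross-linked pair
and a linear peptide ionize differently. The verbal abundance
categories are operationalized as a step function of the ratio:
$\geq 10$ predominant, $[0.1, 10)$ comparable, $[0.01, 0.1)$ low,
$< 0.01$ trace; the thresholds are configurable and the boundaries are
unit-tested exactly.

## The synthetic data generator

`make_fixtures()` builds three synthetic "mini-isoform" stand-ins for
rat VDAC1/2/3 (accessions suffixed `syn`). Each embeds, at the
published Met1-based locants and between K/R cleavage context residues,
the disulfide-linked tryptic peptides reported for this system, so that
digesting a fixture regenerates exactly those peptides at their
published coordinates; the VDAC3 stand-in carries the full cysteine
census (2, 8, 36, 65, 122, 165, 229) and an initiator Met that
maturation removes. Filler positions use a deterministic ten-residue
cycle free of Cys, Lys, Arg, Pro, Met and aromatics, so all cleavage
and cysteine chemistry is controlled by the planted segments. The
records are synthetic: filler stretches share nothing with the real
SwissProt entries, and every result derived from filler (as opposed to
the planted peptides) is a property of the fixture, not of VDAC
biology. The same records ship as
`inst/extdata/vdac_synthetic.fasta`.

`simulate_dataset()` turns planted species into an MGF-level dataset:
one MS2 block per in-window charge state, precursor m/z perturbed by
Gaussian error at a configurable ppm scale (default 1.0 ppm, typical
of a calibrated Orbitrap survey), fragment peaks perturbed at a Da
scale (default 0.15 Da, ion-trap-like), log-uniform fragment
intensities, Poisson-count uniform noise peaks, and decoy precursors
built from scrambled, cysteine-free fixture digests kept at least
50 ppm away from every avoided m/z. The seed fully determines the
output; serialization is fixed-format, so identical specifications
write byte-identical files. Spectra are centroided and
monoisotopic-only - no isotope envelopes, no chromatographic peak
shapes, no co-isolation - which means passing tests demonstrate the
correctness of the matching and annotation logic, not robustness to
deisotoping errors or chimeric spectra in real data.

## Numerical and design choices

* Printed m/z values in this literature carry 4 decimals and show up to
  ~0.3 mDa of rounding drift between software packages; worked-example
  tests therefore compare at 2 ppm rather than at the last printed
  digit.
* Intervals are half-open internally and inclusive (Met1-based) in all
  outputs; the conversion is applied once at the reporting boundary.
* `match_precursors()` uses a sorted binary-search window; a brute-force
  all-pairs scan serves as its independent oracle in the tests.
* Degenerate inputs (empty sequences, non-canonical residues, charge
  $\leq 0$, conflicting cysteine states, out-of-bounds peptides) are
  rejected with informative errors naming the offending position, never
  silently coerced.
* Fragment charges in the pipeline driver run from 1 to
  min(precursor charge $-$ 1, 3), standard for HCD spectra of
  multiply charged precursors.
* Test problem sizes: property suites use 100-1000 random cases per
  invariant with fixed seeds; the synthetic recovery and calibration
  suites use about 1000 planted ions, enough for a binomial check of
  the closed-form recovery rate at the default tolerances.

## Limitations

The package deliberately excludes probabilistic PSM scoring and
FDR/decoy search machinery (identification confidence here comes from
ppm agreement plus fragment-level support, as in a targeted manual
analysis), isotope-envelope processing, retention-time modeling,
higher-order (3+ chain) assemblies, and non-disulfide cross-link
chemistries. Observed charge states are taken from the peak list or
left unknown - there is no deconvolution. These are the right
boundaries for a desk-scale, fully testable reimplementation of a
targeted disulfide-mapping analysis; they are not claims that such
machinery is unnecessary on real discovery-scale data.
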