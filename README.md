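# ssbondmap

Mapping intra- and intermolecular disulfide bonds from bottom-up
LC-MS/MS data.

`ssbondmap` is for proteomics analysts who want to locate S-S bridges
in proteins — including bridges between molecules, the signature of
disulfide-mediated oligomerization — from standard
alkylation/trypsin-digestion experiments. It was built around the
disulfide mapping of the rat mitochondrial VDAC isoform family
(voltage-dependent anion channels 1-3), whose published cross-linked
peptides serve as the package's worked examples, but the machinery is
generic: any FASTA plus a centroided MGF peak list works.

## What it computes

A cysteine engaged in a bridge is modeled as a *half-disulfide* state,
a −1.007825 Da shift that leaves the bridge-engaged residue (Cys-S·) at
102.0014 Da and a whole bridge at net −2.015650 Da. On top of that mass
model the package:

* digests proteins in silico (classic trypsin rules, missed cleavages,
  optional chymotryptic-like semi-specific pass, Met1-based
  coordinates, coverage mapping);
* enumerates candidate disulfide species — loop-linked peptides,
  intra-protein and inter-protein peptide pairs — with full
  variable-modification combinatorics (carboxyamidomethyl, cysteine
  trioxidation, Met oxidation, N-terminal acetylation, pyroglutamate),
  and lays them out over charges 1-5 in the survey window m/z 400-1600;
* matches candidates to precursor observations at ppm tolerance
  (default 10 ppm, intensity floor 5·10³), with

  ppm = (m/z_obs − m/z_theo) / m/z_theo × 10⁶,

  m/z = (M + z·1.007276)/z;
* annotates MS2 spectra with bridge-aware b/y fragments: intact-bridge
  ions carrying the whole partner chain, disulfide-specific S-S/S-C
  cleavage variants (thiol, persulfide, dehydroalanine), and −H2O/−NH3
  neutral losses, matched at 0.6 Da;
* reports bonds (protein/Cys ↔ protein/Cys, MS2-confirmed vs
  precursor-only) and compares apex intensities of bridged vs
  carboxyamidomethylated forms;
* generates deterministic synthetic datasets (planted species, decoys,
  noise) with ground truth, so the whole pipeline is verifiable without
  instrument data.

## Worked example

The quadruply protonated inter-protein species joining the VDAC3
peptide S35–K53 (Cys36) to the VDAC1 peptide E121–R139 (Cys127):

```r
library(ssbondmap)

pa <- peptidoform("SCSGVEFSTSGHAYTDTGK", "VDAC3", 35,
                  mods = data.frame(position = 2, name = "ssbond_half"))
pb <- peptidoform("EHINLGCDVDFDIAGPSIR", "VDAC1", 121,
                  mods = data.frame(position = 7, name = "ssbond_half"))
sp <- disulfide_species(list(pa, pb), list(chain = c(1L, 2L), pos = c(2L, 7L)))

sp$mass
#> [1] 4000.784

mz_grid(sp, enumeration_config())
#>   charge        mz
#> 1      3 1334.6020
#> 2      4 1001.2034
#> 3      5  801.1641

round(ppm_error(1001.2056, mz(sp$mass, 4)), 2)
#> [1] 2.25
```

The two chain masses (1932.8160 and 2069.9840 Da) minus one bridge give
a 4000.7843 Da assembly; charges 1-2 fall above the survey window, so
the candidate ions are the 3+, 4+ and 5+ species. The last line scores
a hypothetical observation at m/z 1001.2056 against the theoretical 4+
value — a 2.25 ppm error, just outside a 2 ppm acceptance but well
inside the 10 ppm search tolerance.

The full pipeline (digest → enumerate → match → annotate → quantify)
runs from one call or from the shell:

```r
run_pipeline(pipeline_config("proteins.fasta", "spectra.mgf", out_dir = "out"))
```

```sh
Rscript inst/scripts/ssbondmap.R run --fasta proteins.fasta \
    --spectra spectra.mgf --ppm 10 --frag-tol-da 0.6 --out out
```

writing `candidates.tsv`, `matches.tsv`, `bonds.tsv`,
`comparisons.tsv` and a parameter-echoing run log.

Synthetic fixtures: `make_fixtures()` (also shipped as
`inst/extdata/vdac_synthetic.fasta`) builds three *synthetic* VDAC
stand-ins that embed the published disulfide-linked peptides at their
published Met1-based locants; `simulate_dataset()` plants species into
a ground-truthed MGF.

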