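# scaffchron

Time-resolved scaffold diversity and chemical-space mapping for compound
libraries.

Medicinal-chemistry libraries grow fast, but most new molecules reuse a
small set of ring cores. scaffchron is for cheminformaticians and
medicinal chemists who want to separate *numerical* growth from
*structural* growth in a compound collection: it standardizes SMILES
libraries, extracts Bemis–Murcko scaffolds and generic carbon frameworks,
quantifies scaffold diversity over time, measures library growth rates
from origin years, and renders era-sliced 2D maps of the occupied shape
space. A seeded synthetic-library generator makes the whole pipeline
testable without any database download.

## The statistics at the core

With each distinct scaffold treated as a species of proportion
*p<sub>i</sub>* among the *n* scaffolds of a library,

- **Shannon entropy** SE = −Σ *p<sub>i</sub>* log₂ *p<sub>i</sub>*
  measures structural variety in bits;
- **Shannon equitability (evenness)** SEE = SE / log₂ *n* normalizes it to
  [0, 1]: 1 means molecules are spread perfectly evenly over the available
  scaffolds, values near 0 mean a few scaffolds dominate;
- **year-over-year growth** is 100 (C<sub>t</sub> − C<sub>t−1</sub>) /
  C<sub>t−1</sub> on the cumulative or annual first-appearance series,
  with origin year = a compound's earliest citation year.

Scaffolds are computed on the molecular graph as the 2-core plus directly
attached multiply-bonded atoms, which reproduces the reference Murcko
implementations structure-for-structure; maps come from Morgan/ECFP4
fingerprints of generic frameworks via PCA and seeded t-SNE.

## Worked example

```r
library(scaffchron)

lib <- generate_library(synthetic_library_spec(n_molecules = 2000, seed = 7))
std <- standardize_library(lib)                  # desalt + neutralize
sc  <- extract_scaffolds(std$canonical_smiles)   # Bemis-Murcko cores
tab <- scaffold_counts(sc$scaffold_smiles)

shannon_entropy(tab)   # 2.668952  bits of scaffold diversity
equitability(tab)      # 0.8034347 evenness in [0, 1]
top_k_scaffolds(tab, k = 3)
#>             scaffold count percent
#> 1           c1ccccc1   820   41.00
#> 2 c1ccc(cc1)c1ccccc1   365   18.25
#> 3           c1cccnc1   184    9.20

ch <- build_chronicle(data.frame(origin_year = std$origin_year,
                                 scaffold_key = sc$scaffold_smiles),
                      growth_on = "annual", min_base = 50)
ch$mean_growth_pct     # 13.84982  (library simulated at 11.6% annual growth)
```

The entropy/evenness values say the simulated library, drawn from ten
scaffolds with Zipf-skewed frequencies, uses about 2.7 bits of its maximal
log₂ 10 ≈ 3.32 bits of diversity — benzene alone carries 41% of the
molecules. The chronicle recovers the generator's growth rate from the
annual first-appearance counts (at n = 2000 the estimate is still noisy;
it tightens to within a couple of points at n ≥ 20,000).

`run_demo(seed = 7)` runs every stage end-to-end on a simulated library
and writes per-stage CSV/JSON outputs, the effective configuration and a
MANIFEST of checksums; `inst/cli/scaffchron.R` exposes the same stages as
shell subcommands (`simulate`, `standardize`, `scaffold`, `diversity`,
`chronicle`, `embed`, `run`, `demo`).

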