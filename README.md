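# patchsurf

Patch-based comparison and retrieval of protein ligand-binding pockets.

## What it is for

Structural genomics keeps producing protein structures with no annotated
function.  When a structure has a plausible binding pocket, predicting
*which small molecule binds there* is a direct route to a functional
hypothesis — and it works even when no homolog of known function exists,
because binding sites converge where sequences and folds do not.

`patchsurf` represents a pocket as a set of local **surface patches**, one
anchored to each ligand heavy atom.  Each patch carries four channels —
geometric shape, electrostatic potential, hydrophobicity and concaveness
(visibility) — and each channel is encoded as a rotation-invariant **3D
Zernike descriptor**: the function on the patch is expanded in the
Zernike–Canterakis basis Z<sub>nlm</sub> = R<sub>nl</sub>(r)
Y<sub>lm</sub>(θ, φ) on the unit ball,

&nbsp;&nbsp;Ω<sub>nlm</sub> = (3/4π) ∫<sub>|x|≤1</sub> f(x)
Z̄<sub>nlm</sub>(x) dx,
&nbsp;&nbsp;F<sub>nl</sub> = ( Σ<sub>m</sub> |Ω<sub>nlm</sub>|² )<sup>1/2</sup>,

giving 72 invariants per unsigned channel at order n = 15, and 144 for the
signed channels (positive and negative parts encoded separately).  Two
pockets are compared by **optimal one-to-one patch matching** under the
weighted patch distance

&nbsp;&nbsp;pdist(A, B) = Σ<sub>t∈{shape,hyd,ele,conc}</sub>
w<sub>t</sub><sup>B</sup> · ‖d<sub>A,t</sub> − d<sub>B,t</sub>‖₂,

optionally restricted to pairs with pdist ≤ 0.2, where the per-patch
weights w<sup>B</sup> ∝ 1/(avg + 2·std) are learned from the descriptor
dispersion across equivalent patches of same-ligand pockets.  Ranked
retrieval from a pocket database yields a binding-ligand prediction
(reciprocal-rank aggregation over the top k), and retrieval quality is
measured by the enrichment factor
EF<sub>x</sub> = (N<sub>P</sub><sup>x</sup>/N<sub>x</sub>) /
(T<sub>P</sub>/T<sub>DB</sub>).

The package also implements the pocket-database construction filters
(ligands with < 7 heavy atoms dropped; ligands closer than 4.0 Å grouped
into one site; sites closer than 1.4 Å to the protein dropped as covalent;
sites farther than 3.5 Å from every protein heavy atom dropped as
non-interacting) and a deterministic synthetic complex generator so that
the whole pipeline is testable without downloads.

## Worked example

Build a small synthetic database (two ligand families, three pockets
each, 0.3 Å coordinate noise) and search it with a held-out noisy query
from family 1:

```r
library(patchsurf)

spec <- fixture_spec(seed = 42L, family_count = 2L, pockets_per_family = 3L)
bm   <- make_benchmark(spec)
cfg  <- ps_config()                      # order 15, 64^3, threshold 0.2, ...

db <- build_database(bm$database_structures, cfg, ids = bm$db_ids)
db
#> <pocket_database: 6 entries, 2 ligand type(s), order 15>
db$entries[[1]]
#> <pocket F01M01:L01 (ligand L01): 8 patches>

query <- build_pocket(bm$query_structures[["F01Q"]], 1L, cfg,
                      source_id = "F01Q")
res <- search_database(query, db)
head(as.data.frame(res))
#>   rank  pocket_id ligand_code     score
#> 1    1 F01M01:L01         L01 0.4046662
#> 2    2 F02M02:L02         L02 0.4156727
#> 3    3 F01M03:L01         L01 0.4536710
#> 4    4 F01M02:L01         L01 0.4697005
#> 5    5 F02M03:L02         L02 0.5443557
#> 6    6 F02M01:L02         L02 0.5451369

predict_ligand(res, k = 3L)
#>   ligand_code    score
#> 1         L01 1.333333
#> 2         L02 0.500000

correct <- res$pocket_id[res$ligand_code == "L01"]
enrichment_factor(res$pocket_id, correct, x = 50)
#> EF@50% = 1.333 (2/3 correct in top 3 of 6)
```

Reading the output: the noisy family-1 query ranks a family-1 pocket
first (score 0.40; lower = more similar), the reciprocal-rank aggregation
predicts ligand `L01` (score 1.33 vs 0.50), and the enrichment factor at
50% of the database scanned is 1.33 — above the random expectation of 1.
On the full 5-family × 6-pocket benchmark the mean EF@20% is ≈ 4 (see
`tests/testthat/test-acceptance.R`).

A command-line interface with the same pipeline lives at
`inst/cli/patchsurf` (`simulate`, `build-db`, `search`, `predict`,
`evaluate` subcommands).

## Documentation

The methods vignette (`vignettes/pocket-comparison.Rmd`) documents the
model, every tunable parameter with its default and rationale, the
numerical design choices (including why patches are encoded in an
anchor-centered frame with a Gaussian point footprint), what the
synthetic-data generator does and does not emulate, and known
limitations.
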