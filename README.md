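# marinerealms

Statistical delimitation of marine biogeographic realms from point
occurrence records.

Biogeographers ask where one marine biota ends and another begins. Given
millions of georeferenced species records (OBIS/GBIF-style exports), this
package turns them into a map of spatially contiguous **biogeographic
realms** — areas holding a distinct biota with a high share of species
found nowhere else — together with significance tests and per-realm
endemicity statistics. It is aimed at marine macroecologists and anyone
doing beta-diversity regionalization on presence–absence data.

## Method

1. **Cleaning and gridding.** Names that are not complete species names
   (`Calanus sp.`, single words, `cf.`/`aff.` qualifiers, digits) are
   rejected. Records are binned into a global latitude–longitude grid
   (c-squares style; 5° cells by default) and deduplicated: a species is
   either present in a cell or not.
2. **Beta diversity.** Pairwise similarity between cells uses Jaccard's
   coefficient, `S_J = 100·a/(a+b+c)`, with `a` the species shared by the
   two cells and `b`, `c` those unique to either — joint absences never
   count, so poorly sampled elsewhere does not mean similar here.
   Sørensen (`2a/(2a+b+c)`), binary Bray–Curtis and the Simpson turnover
   index β_sim = `min(b,c)/(a+min(b,c))` are available alternatives.
3. **Clustering and tests.** Cells are clustered by group-average
   (UPGMA) linkage. SIMPROF permutation tests (statistic
   π = Σ_k |s₍k₎ − s̄₍k₎| over the ordered similarity profile) decide
   whether a group of cells has real internal structure; ANOSIM
   (rank-based R) tests separation between predefined groups; bootstrap
   resampling of species yields co-clustering support for cell pairs.
4. **Realm delineation.** The dendrogram is cut progressively at 1–6 %
   similarity. Cluster groups are forced to be spatially contiguous
   (non-adjacent fragments of a group are released), and connected groups
   of fewer than four cells surrounded by another group are subsumed into
   it. Each realm is recursively subdivided at the next threshold while
   SIMPROF supports it, giving a nested hierarchy down to the final realm
   map.
5. **Endemicity.** A species is endemic to a realm if it occurs in more
   than one cell and only in that realm; realms are summarised by percent
   endemicity (100·unique/total species), widespread-species rankings and
   per-phylum breakdowns.

A synthetic-data generator plants known contiguous realms (benthic
endemics, cosmopolitan pelagics, gradient species, uneven sampling
effort), so the whole pipeline can be validated against ground truth via
the adjusted Rand index.

## Worked example

```r
library(marinerealms)

sim <- simulate_occurrence_dataset(simulation_config(
  n_realms = 4, endemics_per_realm = 60, cosmopolitan_count = 8,
  gradient_species_count = 4, seed = 3))
m   <- build_presence_matrix(sim$records, grid_spec(10))
fit <- delineate_realms(m, grid_spec(10), seed = 1)
fit
#> Realm hierarchy: 648 cells, 5 realms (4 leaf) at thresholds 1,2,3,4,5,6% (jaccard)

tab <- unique_species_per_realm(m, realm_partition(fit))
as.data.frame(tab)
#>   realm n_cells n_species n_unique pct_endemicity
#> 1     2     171        71       60       84.50704
#> 2     3      74        70       60       85.71429
#> 3     4     228        69       60       86.95652
#> 4     5     175        70       60       85.71429

compare_partitions(realm_partition(fit), sim$truth$cell_realm)$ari
#> [1] 1
```

43,978 simulated records collapse to a 252-species × 648-cell presence
matrix; the fitted hierarchy splits the world into 4 realms at the 5 %
similarity level, each realm holding ~70 species of which 60 are endemic
(≈85 % endemicity — the generator plants 60 endemics per realm), and the
recovered map agrees perfectly with the planted one (adjusted Rand
index 1.0). `plot(fit)` draws the realm map; `run_full_pipeline()` runs
the same stages from a file of records to a directory of CSV / GeoJSON /
Newick artifacts with a reproducibility manifest.

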