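# mitoarch

Analysis of mitochondrial genome architecture in fishes: annotation
accounting, strand-skew composition statistics, codon usage, tRNA gene
rearrangements under the tandem duplication–random loss (TDRL) model, tRNA
base-pair classification, and parsimony mapping of rearrangement characters
onto a phylogeny. The package ships a curated reference set for two Yellow
Sea snailfish mitogenomes (*Liparis chefuensis*, 18,870 bp; *Liparis
tanakae*, 17,485 bp) and a synthetic-genome generator with a full
ground-truth ledger for end-to-end validation.

## Scientific background

Vertebrate mitogenomes are compact circular molecules with 13 protein-coding
genes (PCGs), 22 tRNAs, 2 rRNAs, and a control region. Their architecture
carries signal beyond sequence:

- **Strand skews.** Asymmetric replication leaves compositional fingerprints
  measured as GC-skew = (G − C)/(G + C) and AT-skew = (A − T)/(A + T) per
  region class (PCGs, rRNA, tRNA, control region, whole genome).
- **Codon usage.** Relative synonymous codon usage (RSCU) is a codon's count
  divided by the mean count of its synonymous family under the vertebrate
  mitochondrial genetic code (AGA/AGG are stops, ATA = Met, TGA = Trp);
  incomplete stop codons (T-- / TA--) are completed to TAA by
  polyadenylation, which the coordinate arithmetic must respect.
- **Gene rearrangements.** The WANCY tRNA cluster (Trp-Ala-Asn-Cys-Tyr
  between ND2 and COI) is a rearrangement hotspot. Derived orders such as
  WYANC, WNCYAC, and WNCYAA (with a duplicated tRNA) are explained by TDRL:
  a contiguous block is duplicated in tandem and redundant copies are lost.
  `minimal_scenarios()` finds all most-parsimonious TDRL event histories
  from a source order to an observed order, verified against brute force.
- **Character mapping.** Rearrangement patterns and habitat-depth classes
  are mapped onto a phylogeny with generalized (multifurcation-safe) Fitch
  parsimony plus a tip-permutation test of phylogenetic clustering.
- **tRNA structure.** Base pairs of cloverleaf structures are classified
  into Watson–Crick, G-U wobble, A-C, and other classes.

## Worked example

```r
library(mitoarch)

fx <- liparis_fixtures()
fx$tanakae
#> <mitogenome_record> Liparis_tanakae (PX718960)
#>   length: 17485 bp (circular)
#>   genes: 38 (13 PCG, 23 tRNA, 2 rRNA)
#>   sequence: absent

classify_pattern(extract_cluster(fx$tanakae))
#> [1] "WNCYAA"

ms <- minimal_scenarios("WANCY", extract_cluster(fx$tanakae), max_rounds = 2)
attr(ms, "min_rounds")   # 2
ms[[1]]
#> <tdrl_scenario> WANCY -> WNCYAA in 2 round(s)
#>   round 1: duplicate [2,5], lose {}
#>   round 2: duplicate [6,6], lose {2,8,9,10}

fitch_parsimony(fx$tree, fx$patterns)$steps
#> [1] 3
tip_permutation_test(fx$tree, fx$patterns, n_perm = 999, seed = 42)$p_value
#> [1] 0.001

# synthetic genome with ground truth, re-analysed
sim <- generate_record(generator_spec(seed = 1))
composition_table(sim$record)
#>    Region     T     C     A     G    AT  GC_skew  AT_skew
#> 1    PCGs 32.95 27.02 25.98 14.06 58.92 -0.31543 -0.11828
#> 2    rRNA 23.04 25.02 32.97 18.97 56.01 -0.13742  0.17719
#> 3    tRNA 28.00 20.03 29.97 22.00 57.97  0.04702  0.03409
#> 4 control 31.97 13.97 43.01 11.05 74.98 -0.11706  0.14732
#> 5  genome 30.75 24.87 28.77 15.61 59.52 -0.22864 -0.03330
```

The full pipeline (parse → validate → composition → codon usage → cluster
classification → TDRL search → character mapping) runs via `run_pipeline()`
on a `pipeline_config()` or a YAML file, writing per-species TSV/JSON
outputs plus a manifest with MD5 hashes for reproducibility.

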