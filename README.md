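# onsetQTL

Multi-tissue regulatory genomics of early-onset (EOAD) versus
late-onset (LOAD) Alzheimer's disease.

Most Alzheimer's risk variants are non-coding and act, if at all, by
changing gene expression in particular tissues. `onsetQTL` implements
an offline, fully reproducible pipeline that contrasts the two disease
forms' regulatory architectures:

* **Variant catalogue** — significance filtering at p < 1e-5 (strict),
  per-chromosome distributions, group overlap by rsID,
  most-severe-consequence tabulation over nine classes with a fixed
  severity ranking, gene-recurrence counting (order-insensitive for
  two-gene intergenic annotations), and top-variant ranking.
* **GWAS ↔ eQTL integration** — exact-rsID matching of GWAS variants
  against per-tissue lead *cis*-eQTL tables in the GTEx v8 `egenes`
  column dialect (`gene_name`, `pval_nominal`, `qval`, `slope`,
  `rs_id_dbSNP151_GRCh38p7`), across a panel of twelve brain regions
  plus whole blood, gated at the eGene convention q ≤ 0.05.
* **Slope directionality** — per-gene tissue→slope profiles classified
  as `consistent_positive`, `consistent_negative`, `divergent` or
  `single_tissue`; the slope is the expected change in normalized
  expression per copy of the alternate allele.
* **Expression clustering** — hierarchical clustering of
  log2(TPM + 1) profiles (Euclidean, average linkage, deterministic
  tie-breaks) producing heatmap orderings and merge tables.
* **Network statistics** — edge counts, average degree 2E/N, local
  clustering coefficients 2T/(k(k−1)), a Poisson-null
  interaction-enrichment test, and hypergeometric gene-set
  over-representation with Benjamini–Hochberg FDR.
* **Synthetic data** — a generator that plants known GWAS↔eQTL
  matches, sign-structured slopes, tissue clusters and network modules,
  with *exact* (not expected) group sizes and overlap, so every stage
  is testable without downloads.
* A bundled desk-scale **case-study fixture**
  (`ad_reference_fixture()`) encoding a published EOAD/LOAD comparison;
  unprinted fields are synthesized and itemised in its manifest.

## Worked example

```r
library(onsetQTL)

fx <- ad_reference_fixture()
overlap_summary(fx$gwas_eoad, fx$gwas_load)
#> Variant group overlap
#>   group A: 32 variants ( 26 exclusive )
#>   group B: 255 variants ( 249 exclusive )
#>   shared : 6

rec <- match_variants(dplyr::bind_rows(fx$gwas_eoad, fx$gwas_load),
                      build_match_index(fx$egenes))
prof <- regulatory_profiles(rec[rec$group == "LOAD", ])
prof[, c("gene_name", "n_tissues", "direction_class", "min_slope", "max_slope")]
#>    gene_name n_tissues direction_class     min_slope max_slope
#>  2 APH1B             3 consistent_positive     0.125     0.366
#>  3 APOE              2 divergent              -0.377     0.392
#>  4 CEP63             5 consistent_positive     0.623     1.35
#>  8 HAVCR2            2 divergent              -0.136     0.43
#>  ... (single-tissue genes omitted)

slope_summary(prof)$global_max
#> 1 CEP63     Brain_Cerebellum  1.35

graph_summary(fx$networks$load_graph)
#> Network: 9 nodes, 16 edges
#>   average degree        : 3.556
#>   mean local clustering : 0.5
```

Reading the output: EOAD yields a single eQTL record (*GSE1* in the
frontal cortex BA9) while LOAD's records span eleven genes and nine
tissues; the four genes regulated in two or more tissues split into
directionally consistent ones (*APH1B*, *CEP63* — *CEP63* with the
dataset's strongest activation, slope 1.351 in cerebellum) and
divergent ones (*APOE*, *HAVCR2*), whose effect direction flips with
tissue context. The 9-protein LOAD interaction module has average
degree 32/9 ≈ 3.56.

An end-to-end run over an on-disk bundle:

```r
dir <- tempfile(); fixture_write(dir)            # or write_simulation_bundle()
cfg <- pipeline_config(
  gwas_eoad = file.path(dir, "gwas_eoad.tsv"),
  gwas_load = file.path(dir, "gwas_load.tsv"),
  egenes_dir = file.path(dir, "egenes"),
  out_dir = tempfile(),
  tpm = c(load = file.path(dir, "tpm_load.tsv")),
  edges = c(load = file.path(dir, "ppi_load.tsv"))
)
validate_run_inputs(cfg)   # report-only schema/panel check
run_pipeline(cfg)          # result TSVs + manifest.json
```

A thin command-line wrapper over the same functions lives at
`inst/cli/onsetqtl.R` (`simulate`, `validate`, `run-all` subcommands).

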