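# Packaged fixtures

## table1_rprs57_synthetic_meta.tsv

The 57 rsIDs and their source-GWAS p-values that survive the refined
polygenic-score selection (threshold 0.24, per-SNP refinement at
p < 0.05), as published. Only `snp_id` and `p_value` are real values;
the remaining columns are **synthetic placeholders** generated under a
fixed seed so the file satisfies the full GWAS-summary schema:

- `chrom`, `pos`: arbitrary unique coordinates (chromosomes cycle 1-22);
- `effect_allele`, `other_allele`: random non-strand-ambiguous pairs;
- `beta`: random effect sizes of fasting-insulin-GWAS-like magnitude
  (|beta| in 0.005-0.03), not the real weights, which are not
  redistributable.

Load with `rprs_table1()`.

## demo_config.yaml

Demo pipeline configuration for `run_pipeline(read_pipeline_config(...))`
with a reduced simulated cohort so the demo completes in seconds.
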