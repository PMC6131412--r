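# introscan

Transcriptome scanning of alien chromosome addition lines.

## What problem this solves, and for whom

Wide hybridization puts a chromosome (or chromosome arm) of a donor species
into a host genetic background — an *addition line*. Two things then
routinely go wrong for the people breeding and studying such stocks:
the donor genes are transcribed differently in the foreign background, and
the stocks quietly accumulate structural changes (large deletions) that are
invisible without karyotyping. `introscan` is for researchers who have
gene-level RNA-seq counts for the three genotypes of such a design
(host, donor, addition line) and want, from expression data alone:

1. **Differential transcription (DT) calls** per contrast
   (host vs addition; donor vs addition), with class labels up / down /
   not-DT at a set FDR;
2. **Chromosomal scans** — ratios of DT classes to transcribed genes in
   10 Mbp sliding windows, segmented by exact change-point detection — and
   **deletion calls** from the expression-loss signature;
3. **Homeolog assignment** via synteny-block chaining of protein-similarity
   hits, and **transcriptional compensation** scores for deleted host genes
   with donor homeologs;
4. **GO-term enrichment** of DT gene sets by the Parent-Child-Union test.

A first-class synthetic-data generator emulates the whole design
(3 genotypes × 6 replicates, NB counts, a terminal deletion, a
proximal-up/distal-down donor-arm gradient), so the entire pipeline is
developed and validated against known ground truth.

## The statistics at the core

* Counts: NB GLM with log link, `log(mu) = beta_group + log(eff. lib.
  size)`; 1-df likelihood-ratio test per gene; BH FDR (default 5%); TMM
  normalization (30%/5% double trim, precision-weighted); CPM > 1
  transcribed filter; FPKM for cross-gene comparison.
* Dispersion: Cox-Reid adjusted profile likelihood, common + tagwise with
  shrinkage (prior df 20).
* Windows: R(Down/Trans), R(Up/Trans), R(not-DT/Trans), mean logFC per
  10 Mbp / 1 Mbp sliding window.
* Segmentation: PELT, Gaussian change-in-mean cost, MBIC-style penalty
  `3 log n`; exact (matches exhaustive search on every tested track).
* Deletion evidence: R(Down/Trans) >= 0.9, no up-regulated genes, test
  mean FPKM < 1, >= 10 genes, boundaries refined to gene level.
* Synteny: rank-based DP chaining (E <= 1e-5, block >= 10, gap <= 25),
  strict 1:1 retention; compensation ratio = donor-in-addition FPKM over
  host-in-host FPKM, partial at >= 0.5.
* Enrichment: Parent-Child-Union hypergeometric test, BH-adjusted.

See `vignettes/introscan-methods.Rmd` for assumptions, parameter meanings
and limitations.

## Worked example

```r
library(introscan)
res <- run_all(default_config(seed = 1), outdir = "run1")
res$deletions
```

```
 chrom start_bp   end_bp n_trans n_down n_notdt mean_fpkm_test mean_logfc
    7A    7e+08 7.36e+08      74     74       0              0  -13.54631
```

The simulated world plants a terminal deletion at 700-736 Mbp of the
740 Mbp host chromosome 7A; the caller recovers it exactly (to the Mbp),
spanning 74 transcribed genes, all down-regulated, with test-group FPKM 0 —
the expression signature of physically absent DNA. The donor-arm contrast
summary (written to `run1/summary_donor.tsv`):

```
    category count    pct
 transcribed   899 100.00
      not_DT   751  83.54
          DT   148  16.46
          up    66   7.34
        down    82   9.12
```

reflecting the injected proximal-up/distal-down gradient along the donor
telosome. Compensation of the deleted host genes by their donor homeologs
(`res$homeology$compensation$summary`):

```
n_pairs_in_deletion  n_defined  n_partial  n_high_donor  n_high_partial
                 38         38         20            25              17
```

38 deleted host genes have a retained 1:1 donor homeolog; 20 of them are at
least half as abundantly transcribed in the addition line as the host copy
was in the host — partial transcriptional compensation. All intermediate
tables (DT per gene, window tracks as bedGraph, segments, synteny blocks,
enrichment) are written to the run directory; `report("run1")` renders a
plain-text summary.

A command-line entry point covers the same stages:

```sh
Rscript inst/exec/introscan run --config run.json --seed 1 --outdir run1
```

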