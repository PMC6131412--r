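# Shared fixture builders.  Everything is generated in code at test time;
# sizes are kept small except where a stated scale matters.

# hand-made normalization factors (all 1) for a given count matrix
unit_factors <- function(x) {
  lib <- colSums(x$counts)
  data.frame(sample = colnames(x$counts), lib_size = unname(lib),
             factor = 1, eff_lib_size = unname(lib),
             stringsAsFactors = FALSE)
}

# count_matrix from a bare matrix, groups parsed from column names A_1, B_2..
toy_counts <- function(m) {
  nm <- colnames(m)
  count_matrix(m, data.frame(sample = nm,
                             group = sub("_[0-9]+$", "", nm),
                             replicate = as.integer(sub(".*_", "", nm)),
                             stringsAsFactors = FALSE))
}

# a single host chromosome, no effects: a null world for calibration tests
null_world <- function(n_genes, seed, replicates = 6, dispersion = 0.2) {
  spec <- genome_spec(data.frame(name = "1A", length = 500e6,
                                 genome = "host", n_genes = n_genes))
  ann <- generate_annotation(spec, seed = seed)
  des <- design_spec(replicates = replicates, dispersion = dispersion)
  sim <- generate_counts(ann, des, seed = seed + 1L)
  list(annotation = ann, sim = sim)
}

# host-only world with planted fixed-logFC effects in two regions (~10% of
# genes at |logFC| = 2), used for sensitivity/FDR recovery
planted_world <- function(n_genes, seed, replicates = 6, dispersion = 0.2) {
  spec <- genome_spec(data.frame(name = "1A", length = 500e6,
                                 genome = "host", n_genes = n_genes))
  ann <- generate_annotation(spec, seed = seed)
  des <- design_spec(replicates = replicates, dispersion = dispersion,
                     effect_regions = list(
                       effect_region("1A", 1, 25e6, "fixed_logFC", 2),
                       effect_region("1A", 400e6, 425e6, "fixed_logFC", -2)))
  sim <- generate_counts(ann, des, seed = seed + 1L)
  list(annotation = ann, sim = sim)
}

# run the host-vs-addition contrast of the default synthetic world and call
# deletions on 7A; returns the pieces needed by recovery assertions
run_deletion_recovery <- function(seed) {
  ann <- generate_annotation(addition_line_genome(), seed = seed)
  sim <- generate_counts(ann, addition_line_design(), seed = seed + 1L)
  cm <- subset_counts(sim$counts,
                      genes = ann$gene_id[ann$genome == "host"],
                      groups = c("CS", "CS+7HL"))
  fac <- tmm_factors(cm)
  transcribed <- filter_transcribed(cm, fac, c("CS", "CS+7HL"))
  disp <- estimate_dispersion(cm, fac, genes = transcribed)
  dt <- suppressWarnings(test_dt(cm, fac, disp, "CS", "CS+7HL",
                                 genes = transcribed))
  lengths <- stats::setNames(ann$length, ann$gene_id)
  fk <- fpkm(subset_counts(cm, genes = transcribed), fac, lengths)
  gm <- group_means(fk, cm$samples[cm$samples$group %in% c("CS", "CS+7HL"), ])
  i <- match(dt$gene_id, ann$gene_id)
  dt$chrom <- ann$chrom[i]; dt$start <- ann$start[i]; dt$end <- ann$end[i]
  dt$fpkm_ref <- gm[dt$gene_id, "CS"]
  dt$fpkm_test <- gm[dt$gene_id, "CS+7HL"]
  wm <- window_metrics(dt, "7A", 740e6)
  segs <- pelt_segment(wm, "r_down")
  prof <- classify_segments(segs, dt)
  calls <- call_deletions(prof, dt)
  list(dt = dt, truth = sim$truth, wm = wm, profile = prof, calls = calls)
}
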