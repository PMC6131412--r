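test_that("generate_annotation builds sorted non-overlapping genes", {
  spec <- genome_spec(data.frame(name = "c1", length = 10e6,
                                 genome = "host", n_genes = 10))
  ann <- generate_annotation(spec, seed = 42)
  expect_equal(nrow(ann), 10)
  expect_true(all(diff(ann$start) > 0))
  expect_true(all(ann$start[-1] > ann$end[-nrow(ann)]))
  expect_true(all(ann$start >= 1 & ann$end <= 10e6))

  expect_identical(ann, generate_annotation(spec, seed = 42))

  spec2 <- genome_spec(data.frame(name = c("c1", "c2"),
                                  length = c(100e6, 100e6),
                                  genome = "host", n_genes = 100))
  ann2 <- generate_annotation(spec2, seed = 1)
  expect_equal(nrow(ann2), 200)
  for (ch in c("c1", "c2"))
    expect_true(all(diff(ann2$start[ann2$chrom == ch]) > 0))
})

test_that("spec validation errors name the offending field", {
  base <- data.frame(name = "c1", length = 10e6, genome = "host",
                     n_genes = 10)
  expect_error(genome_spec(transform(base, length = -1)), "length")
  expect_error(genome_spec(transform(base, genome = "alien")), "genome")
  expect_error(genome_spec(transform(base, n_genes = 0)), "n_genes")
  expect_error(design_spec(replicates = 1), "replicates")
  expect_error(design_spec(dispersion = 0), "dispersion")
  des <- design_spec(effect_regions = list(
    effect_region("nope", 1, 100, "deletion")))
  ann <- generate_annotation(genome_spec(base), seed = 1)
  expect_error(generate_counts(ann, des, seed = 1), "unknown chromosome")
})

test_that("deletion regions are structural zeros in the addition group", {
  spec <- genome_spec(data.frame(name = "c1", length = 50e6,
                                 genome = "host", n_genes = 100))
  ann <- generate_annotation(spec, seed = 3)
  des <- design_spec(effect_regions = list(
    effect_region("c1", 20e6, 30e6, "deletion")))
  sim <- generate_counts(ann, des, seed = 3)
  del <- sim$truth$gene_id[sim$truth$in_deletion]
  expect_gt(length(del), 5)
  add_cols <- sim$counts$samples$group == "CS+7HL"
  expect_true(all(sim$counts$counts[del, add_cols] == 0))
  expect_true(all(sim$truth$true_class[sim$truth$in_deletion] == "deleted"))
})

test_that("near-zero dispersion and no effects recover baseline means", {
  spec <- genome_spec(data.frame(name = "c1", length = 100e6,
                                 genome = "host", n_genes = 200))
  ann <- generate_annotation(spec, seed = 5)
  des <- design_spec(replicates = 50, dispersion = 1e-13,
                     library_size_cv = 1e-9)
  sim <- generate_counts(ann, des, seed = 5)
  cs <- sim$counts$samples$group == "CS"
  m <- rowMeans(sim$counts$counts[, cs])
  # Poisson at cv ~ 0: expected mean = libsize * weight share
  mu <- des$library_size_mean * sim$truth$base_weight /
    sum(sim$truth$base_weight)
  se <- sqrt(mu / 50)
  expect_gt(mean(abs(m - mu) <= 3 * se), 0.99)
})

test_that("fixed_logFC regions reproduce the injected fold change", {
  spec <- genome_spec(data.frame(name = "c1", length = 100e6,
                                 genome = "host", n_genes = 300))
  ann <- generate_annotation(spec, seed = 8)
  des <- design_spec(replicates = 20, dispersion = 0.05,
                     baseline_meanlog = log(500), baseline_sdlog = 0.3,
                     effect_regions = list(
                       effect_region("c1", 1, 30e6, "fixed_logFC", 2)))
  sim <- generate_counts(ann, des, seed = 8)
  eff <- sim$truth$true_class == "up"
  expect_true(all(abs(sim$truth$true_logfc[eff] - 2) < 1e-12))
  cs <- sim$counts$samples$group == "CS"
  add <- sim$counts$samples$group == "CS+7HL"
  lr <- log2(rowMeans(sim$counts$counts[, add]) /
             rowMeans(sim$counts$counts[, cs]))
  # composition shifts the whole-library baseline slightly; compare to nulls
  expect_equal(mean(lr[eff]) - mean(lr[!eff]), 2, tolerance = 0.1)
  expect_true(all(abs(lr[eff] - mean(lr[eff])) < 1))
})

test_that("counts follow the NB mean-variance relationship", {
  spec <- genome_spec(data.frame(name = "c1", length = 200e6,
                                 genome = "host", n_genes = 1000))
  ann <- generate_annotation(spec, seed = 11)
  des <- design_spec(replicates = 50, dispersion = 0.3,
                     library_size_cv = 1e-9)
  sim <- generate_counts(ann, des, seed = 11)
  cs <- sim$counts$samples$group == "CS"
  y <- sim$counts$counts[, cs]
  m <- rowMeans(y); v <- apply(y, 1, var)
  keep <- m > 20
  ratio <- v[keep] / (m[keep] + 0.3 * m[keep]^2)
  expect_equal(median(ratio), 1, tolerance = 0.15)
})

test_that("truth table is a complete key-matched companion of the counts", {
  sim <- generate_counts(generate_annotation(addition_line_genome(300, 100,
                                                                  150),
                                             seed = 2),
                         addition_line_design(), seed = 2)
  expect_identical(sim$truth$gene_id, rownames(sim$counts$counts))
  expect_false(anyDuplicated(sim$truth$gene_id) > 0)
})

test_that("homology hit generation honours collinearity and determinism", {
  spec <- genome_spec(data.frame(name = c("a1", "b1"),
                                 length = 50e6,
                                 genome = c("host", "donor"),
                                 n_genes = 30))
  ann <- generate_annotation(spec, seed = 4)
  a <- ann[ann$chrom == "a1", ]; b <- ann[ann$chrom == "b1", ]

  full <- generate_homology_hits(a, b, collinear_fraction = 1, seed = 9,
                                 noise_fraction = 0)
  expect_equal(nrow(full), 30)
  ra <- match(full$qseqid, a$gene_id); rb <- match(full$sseqid, b$gene_id)
  o <- order(ra)
  expect_true(all(diff(rb[o]) > 0))
  expect_true(all(full$evalue < 1e-20))

  expect_identical(full, generate_homology_hits(a, b, 1, seed = 9,
                                                noise_fraction = 0))
  expect_error(generate_homology_hits(a, b, 1.2, seed = 1), "outside")

  none <- generate_homology_hits(a, b, collinear_fraction = 0, seed = 9,
                                 noise_fraction = 0.5)
  ranked <- hit_ranks(filter_hits(none), a, b)
  expect_equal(nrow(chain_collinear_blocks(ranked, min_block = 10)), 0)
})

test_that("generated ontologies are rooted DAGs obeying the true-path rule", {
  og <- generate_ontology(paste0("g", 1:40), n_terms = 12, seed = 6)
  expect_s3_class(og$ontology, "ontology")   # constructor validates acyclicity
  expect_identical(og$ontology$root, "GO:0000001")
  prop <- propagate(og$ontology, og$annotations)
  root_genes <- prop$gene[prop$term == og$ontology$root]
  expect_setequal(root_genes, unique(og$annotations$gene))
  expect_error(generate_ontology(paste0("g", 1:5), n_terms = 2), "n_terms")
  og2 <- generate_ontology(paste0("g", 1:40), n_terms = 12, seed = 6)
  expect_identical(og, og2)
})

test_that("text writers round-trip annotations, counts and hits", {
  spec <- genome_spec(data.frame(name = "c1", length = 20e6,
                                 genome = "host", n_genes = 15))
  ann <- generate_annotation(spec, seed = 7)
  gff <- tempfile(fileext = ".gff3")
  write_annotation_gff3(ann, gff)
  back <- read_annotation_gff3(gff)
  expect_equal(back[, c("gene_id", "chrom", "start", "end")],
               ann[, c("gene_id", "chrom", "start", "end")])

  sim <- generate_counts(ann, design_spec(), seed = 7)
  tsv <- tempfile(fileext = ".tsv")
  write_counts_tsv(sim$counts, tsv)
  cm2 <- read_counts_tsv(tsv, sim$counts$samples)
  expect_identical(cm2$counts, sim$counts$counts)

  obo <- tempfile(fileext = ".obo")
  og <- generate_ontology(paste0("g", 1:10), n_terms = 6, seed = 1)
  write_obo(og$ontology, obo)
  expect_identical(read_obo(obo)$parents, og$ontology$parents)
})
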