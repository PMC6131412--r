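# End-to-end orchestration: simulate (or ingest) -> normalize/filter/test ->
# window metrics and segmentation -> deletion calling -> homeology and
# compensation -> enrichment, with a JSON-configurable run directory and a
# manifest sufficient to replay the run.

#' Default run configuration
#'
#' All thresholds carry the conventional defaults of the analysis: CPM > 1
#' transcribed filter, 5% FDR, 10 Mbp / 1 Mbp windows, MBIC penalty,
#' E-value 1e-5 and block size 10 for synteny, 50% compensation, and the two
#' contrasts of the addition-line design (host vs addition, donor vs
#' addition).
#'
#' @param seed integer seed driving every stochastic stage.
#' @return nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(n_genes_host = 1500, n_genes_host2 = 600,
                    n_genes_donor = 900, replicates = 6,
                    library_size_mean = 1.5e7, library_size_cv = 0.1,
                    dispersion = 0.2,
                    collinear_fraction = 0.8, n_terms = 40),
    groups = list(host = "CS", donor = "B", addition = "CS+7HL"),
    thresholds = list(cpm = 1, fdr = 0.05, window = 10e6, step = 1e6,
                      penalty = "MBIC", evalue = 1e-5, min_block = 10,
                      max_rank_gap = 25, compensation_ratio = 0.5,
                      high_fpkm = 20, enrich_alpha = 0.05,
                      del_r_down = 0.9, del_r_up = 0, del_fpkm = 1)),
    class = "run_config")
}

#' Read a JSON run configuration, filling unset fields with defaults
#' @param path JSON file with any subset of the [default_config()] fields.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  merge_in <- function(base, upd) {
    for (nm in names(upd))
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        merge_in(base[[nm]], upd[[nm]]) else upd[[nm]]
    base
  }
  structure(merge_in(unclass(cfg), user), class = "run_config")
}

.validate_config <- function(cfg) {
  need <- c("seed", "simulate", "groups", "thresholds")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("run_all: config missing field(s): ", paste(miss, collapse = ", "))
  if (!all(c("host", "donor", "addition") %in% names(cfg$groups)))
    stop("run_all: config$groups needs host, donor and addition labels")
  invisible(cfg)
}

# one contrast: normalize, filter, test, annotate with coordinates and FPKM
.run_contrast <- function(cm, annotation, ref, test, genome, th) {
  sub <- subset_counts(cm, genes = annotation$gene_id[annotation$genome ==
                                                      genome],
                       groups = c(ref, test))
  fac <- tmm_factors(sub)
  transcribed <- filter_transcribed(sub, fac, c(ref, test),
                                    threshold = th$cpm)
  disp <- estimate_dispersion(sub, fac, genes = transcribed)
  dt <- test_dt(sub, fac, disp, ref, test, genes = transcribed,
                alpha = th$fdr)
  lengths <- stats::setNames(annotation$length, annotation$gene_id)
  fk <- fpkm(subset_counts(sub, genes = transcribed), fac, lengths)
  gm <- group_means(fk, sub$samples)
  i <- match(dt$gene_id, annotation$gene_id)
  dt$chrom <- annotation$chrom[i]
  dt$start <- annotation$start[i]
  dt$end <- annotation$end[i]
  dt$fpkm_ref <- gm[dt$gene_id, ref]
  dt$fpkm_test <- gm[dt$gene_id, test]
  list(dt = dt, factors = fac, fpkm = fk, fpkm_means = gm,
       transcribed = transcribed, counts = sub)
}

#' Run the full pipeline on synthetic data
#'
#' Stages: simulate -> per-contrast DT (host vs addition on host genes, donor
#' vs addition on donor genes) -> sliding-window metrics and PELT
#' segmentation per chromosome -> deletion calling (host contrast) ->
#' synteny-based 1:1 homeologs and compensation over the called deletion ->
#' Parent-Child-Union enrichment of up/down sets.  All intermediate tables
#' are written to `outdir` together with a manifest.
#'
#' @param config a `run_config` (see [default_config()], [read_config()]).
#' @param outdir run directory (created if needed).
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_all <- function(config = default_config(), outdir = tempfile("run")) {
  .validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  sim <- config$simulate
  seed <- config$seed
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("run_all: stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[introscan] %-12s %6.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  ## simulate
  world <- stage("simulate", {
    genome <- addition_line_genome(sim$n_genes_host, sim$n_genes_host2,
                                   sim$n_genes_donor)
    ann <- generate_annotation(genome, seed = seed)
    design <- addition_line_design(
      groups = unlist(config$groups)[c("host", "donor", "addition")],
      replicates = sim$replicates,
      library_size_mean = sim$library_size_mean,
      library_size_cv = sim$library_size_cv,
      dispersion = sim$dispersion)
    cnt <- generate_counts(ann, design, seed = seed + 1L)
    host7a <- ann[ann$chrom == "7A", ]
    donor <- ann[ann$genome == "donor", ]
    hits <- generate_homology_hits(host7a, donor,
                                   collinear_fraction = sim$collinear_fraction,
                                   seed = seed + 2L)
    onto <- generate_ontology(ann$gene_id, n_terms = sim$n_terms,
                              seed = seed + 3L)
    write_annotation_gff3(ann, file.path(outdir, "genes.gff3"))
    write_counts_tsv(cnt$counts, file.path(outdir, "counts.tsv"))
    write_samples_tsv(cnt$counts$samples, file.path(outdir, "samples.tsv"))
    write_truth_tsv(cnt$truth, file.path(outdir, "truth.tsv"))
    write_hits_blast6(hits, file.path(outdir, "hits.blast6"))
    write_obo(onto$ontology, file.path(outdir, "ontology.obo"))
    write_annotations_tsv(onto$annotations, file.path(outdir,
                                                      "gene2term.tsv"))
    list(annotation = ann, genome = genome, counts = cnt$counts,
         truth = cnt$truth, hits = hits, onto = onto)
  })
  ann <- world$annotation
  g <- config$groups

  ## contrasts
  contrasts <- list(
    host = list(ref = g$host, test = g$addition, genome = "host"),
    donor = list(ref = g$donor, test = g$addition, genome = "donor"))
  dt_res <- lapply(names(contrasts), function(nm) {
    ct <- contrasts[[nm]]
    res <- stage(paste0("dt_", nm),
                 .run_contrast(world$counts, ann, ct$ref, ct$test,
                               ct$genome, th))
    utils::write.table(res$dt, file.path(outdir, paste0("dt_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summarize_contrast(res$dt),
                       file.path(outdir, paste0("summary_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })
  names(dt_res) <- names(contrasts)

  ## windows + segmentation + deletion calls
  scan <- stage("scan", {
    out <- list()
    for (nm in names(contrasts)) {
      genome_sel <- contrasts[[nm]]$genome
      chroms <- world$genome$chromosomes
      chroms <- chroms[chroms$genome == genome_sel, ]
      for (ci in seq_len(nrow(chroms))) {
        chrom <- chroms$name[ci]
        wm <- window_metrics(dt_res[[nm]]$dt, chrom, chroms$length[ci],
                             window = th$window, step = th$step)
        utils::write.table(wm, file.path(outdir, sprintf("windows_%s.tsv",
                                                         chrom)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        segs <- lapply(c("r_notdt", "r_up", "r_down", "mean_logfc"),
                       function(mt) {
          if (sum(!is.na(wm[[mt]])) < 2) return(NULL)
          sg <- pelt_segment(wm, mt, penalty = th$penalty)
          write_bedgraph(wm, mt, file.path(outdir,
                          sprintf("track_%s_%s.bedgraph", chrom, mt)))
          sg
        })
        names(segs) <- c("r_notdt", "r_up", "r_down", "mean_logfc")
        prof <- if (!is.null(segs$r_down))
          classify_segments(segs$r_down, dt_res[[nm]]$dt) else NULL
        out[[chrom]] <- list(wm = wm, segments = segs, profile = prof)
        if (!is.null(prof))
          utils::write.table(prof, file.path(outdir,
                              sprintf("segments_%s.tsv", chrom)),
                             sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    out
  })

  deletions <- stage("deletions", {
    calls <- do.call(rbind, lapply(names(scan), function(chrom) {
      sc <- scan[[chrom]]
      if (is.null(sc$profile)) return(NULL)
      ct <- if (chrom %in% ann$chrom[ann$genome == "host"]) "host" else
        "donor"
      call_deletions(sc$profile, dt_res[[ct]]$dt, th$del_r_down,
                     th$del_r_up, th$del_fpkm)
    }))
    calls <- calls[!is.na(calls$chrom), , drop = FALSE]
    utils::write.table(calls, file.path(outdir, "deletion_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    calls
  })

  ## homeology + compensation
  homeo <- stage("homeology", {
    host7a <- ann[ann$chrom == "7A", ]
    donor <- ann[ann$genome == "donor", ]
    hits <- hit_ranks(filter_hits(world$hits, th$evalue), host7a, donor)
    blocks <- chain_collinear_blocks(hits, th$min_block, th$max_rank_gap)
    pairs <- one_to_one(blocks)
    utils::write.table(blocks, file.path(outdir, "synteny_blocks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pairs, file.path(outdir, "homeolog_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    comp <- NULL
    if (nrow(deletions) > 0 && nrow(pairs) > 0) {
      host_fpkm <- stats::setNames(dt_res$host$dt$fpkm_ref,
                                   dt_res$host$dt$gene_id)
      donor_fpkm <- stats::setNames(dt_res$donor$dt$fpkm_test,
                                    dt_res$donor$dt$gene_id)
      comp <- compensation(pairs, deletions[1, ], host7a, host_fpkm,
                           donor_fpkm, host_side = "qseqid",
                           ratio_threshold = th$compensation_ratio,
                           high_fpkm_threshold = th$high_fpkm)
      utils::write.table(comp$pairs, file.path(outdir, "compensation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(blocks = blocks, pairs = pairs, compensation = comp)
  })

  ## enrichment
  enrich <- stage("enrichment", {
    out <- list()
    for (nm in names(contrasts)) {
      genome_sel <- contrasts[[nm]]$genome
      pop <- intersect(dt_res[[nm]]$transcribed,
                       ann$gene_id[ann$genome == genome_sel])
      for (cls in c("up", "down")) {
        study <- dt_res[[nm]]$dt$gene_id[dt_res[[nm]]$dt$class == cls]
        if (length(study) == 0) next
        res <- parent_child_union_test(study, pop, world$onto$ontology,
                                       world$onto$annotations)
        key <- paste0(nm, "_", cls)
        out[[key]] <- res
        utils::write.table(res, file.path(outdir,
                            sprintf("enrichment_%s.tsv", key)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    out
  })

  ## manifest
  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  tables <- list.files(outdir, pattern = "\\.(tsv|gff3|blast6|obo)$")
  manifest <- list(
    package_version = as.character(utils::packageVersion("introscan")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = lapply(stats::setNames(tables, tables), function(f)
      length(readLines(file.path(outdir, f), warn = FALSE))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(outdir = outdir, world = world, dt = dt_res, scan = scan,
                 deletions = deletions, homeology = homeo,
                 enrichment = enrich))
}

#' Summarize a completed run directory as a plain-text report
#'
#' @param run_dir directory written by [run_all()].
#' @param path output file (default `summary.md` inside the run directory).
#' @return the report lines, invisibly.
#' @export
report <- function(run_dir, path = file.path(run_dir, "summary.md")) {
  lines <- c("# introscan run summary", "")
  for (nm in c("host", "donor")) {
    f <- file.path(run_dir, paste0("summary_", nm, ".tsv"))
    if (!file.exists(f)) {
      lines <- c(lines, sprintf("## Contrast %s: MISSING", nm), "")
      next
    }
    s <- utils::read.delim(f)
    lines <- c(lines, sprintf("## Contrast %s", nm),
               sprintf("- %s: %d (%.2f%%)", s$category, s$count, s$pct), "")
  }
  f <- file.path(run_dir, "deletion_calls.tsv")
  if (file.exists(f)) {
    d <- utils::read.delim(f)
    lines <- c(lines, "## Deletion calls",
               if (nrow(d) == 0) "- none" else
               sprintf("- %s:%.0f-%.0f Mbp (%d transcribed, %d down, mean test FPKM %.2f, mean logFC %.2f)",
                       d$chrom, d$start_bp / 1e6, d$end_bp / 1e6, d$n_trans,
                       d$n_down, d$mean_fpkm_test, d$mean_logfc), "")
  }
  f <- file.path(run_dir, "compensation.tsv")
  lines <- c(lines, "## Compensation",
             if (file.exists(f)) {
               cp <- utils::read.delim(f)
               sprintf("- %d deleted-host pairs, %d partially compensated (>=50%%)",
                       nrow(cp), sum(cp$partial_compensation))
             } else "- absent (no deletion call or no 1:1 pairs)", "")
  writeLines(lines, path)
  invisible(lines)
}

#' Minimal command-line entry point
#'
#' Subcommands:
#' `simulate --seed S --outdir D`;
#' `run --config run.json --outdir D [--seed S]`;
#' `report --rundir D`;
#' `dt --counts c.tsv --annot genes.gff3 --groups REF,TEST [--fdr 0.05]
#' [--cpm 1] [--out dt.tsv]`;
#' `scan --dt dt.tsv --chrom NAME [--length BP] [--window 10000000]
#' [--step 1000000] [--penalty MBIC] [--out prefix]`;
#' `homeo --hits ab.blast6 --annot-a a.gff3 --annot-b b.gff3
#' [--min-block 10] [--evalue 1e-5] [--out prefix]`;
#' `enrich --obo go.obo --ann g2t.tsv --study ids.txt --population ids.txt
#' [--alpha 0.05] [--out enrichment.tsv]`.
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @export
introscan_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i)) args[i[1] + 1] else default
  }
  cmd <- if (length(args)) args[1] else "help"
  seed <- as.integer(opt("--seed", "1"))
  outdir <- opt("--outdir", "introscan_run")
  if (cmd == "simulate") {
    cfg <- default_config(seed)
    ann <- generate_annotation(addition_line_genome(), seed = seed)
    cnt <- generate_counts(ann, addition_line_design(), seed = seed + 1L)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_annotation_gff3(ann, file.path(outdir, "genes.gff3"))
    write_counts_tsv(cnt$counts, file.path(outdir, "counts.tsv"))
    write_samples_tsv(cnt$counts$samples, file.path(outdir, "samples.tsv"))
    write_truth_tsv(cnt$truth, file.path(outdir, "truth.tsv"))
    message("wrote simulation to ", outdir)
  } else if (cmd == "run") {
    cfgf <- opt("--config")
    cfg <- if (is.null(cfgf)) default_config(seed) else read_config(cfgf)
    if (!is.null(opt("--seed"))) cfg$seed <- seed
    run_all(cfg, outdir)
    report(outdir)
    message("run complete: ", outdir)
  } else if (cmd == "report") {
    report(opt("--rundir", outdir))
  } else if (cmd == "dt") {
    ann <- read_annotation_gff3(opt("--annot"))
    sfile <- opt("--samples",
                 file.path(dirname(opt("--counts")), "samples.tsv"))
    samples <- if (file.exists(sfile)) read_samples_tsv(sfile) else NULL
    cm <- read_counts_tsv(opt("--counts"), samples)
    groups <- strsplit(opt("--groups"), ",", fixed = TRUE)[[1]]
    cm <- subset_counts(cm, groups = groups)
    fac <- tmm_factors(cm)
    keep <- filter_transcribed(cm, fac, groups,
                               threshold = as.numeric(opt("--cpm", "1")))
    disp <- estimate_dispersion(cm, fac, genes = keep)
    dt <- test_dt(cm, fac, disp, groups[1], groups[2], genes = keep,
                  alpha = as.numeric(opt("--fdr", "0.05")))
    i <- match(dt$gene_id, ann$gene_id)
    dt$chrom <- ann$chrom[i]; dt$start <- ann$start[i]; dt$end <- ann$end[i]
    lengths <- stats::setNames(ann$length, ann$gene_id)
    gm <- group_means(fpkm(subset_counts(cm, genes = keep), fac, lengths),
                      cm$samples)
    dt$fpkm_ref <- gm[dt$gene_id, groups[1]]
    dt$fpkm_test <- gm[dt$gene_id, groups[2]]
    utils::write.table(dt, opt("--out", "dt.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else if (cmd == "scan") {
    dt <- utils::read.delim(opt("--dt"))
    chrom <- opt("--chrom")
    len <- as.numeric(opt("--length",
                          max(dt$end[dt$chrom == chrom]) + 1e6))
    wm <- window_metrics(dt, chrom, len,
                         window = as.numeric(opt("--window", "1e7")),
                         step = as.numeric(opt("--step", "1e6")))
    pen <- opt("--penalty", "MBIC")
    if (!pen %in% c("MBIC", "BIC")) pen <- as.numeric(pen)
    segs <- pelt_segment(wm, "r_down", penalty = pen)
    prof <- classify_segments(segs, dt)
    calls <- call_deletions(prof, dt)
    pre <- opt("--out", paste0("scan_", chrom))
    utils::write.table(wm, paste0(pre, "_windows.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(prof, paste0(pre, "_segments.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(calls, paste0(pre, "_deletions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else if (cmd == "homeo") {
    a <- read_annotation_gff3(opt("--annot-a"))
    b <- read_annotation_gff3(opt("--annot-b"))
    hits <- read_hits_blast6(opt("--hits"))
    hits <- hit_ranks(filter_hits(hits,
                                  as.numeric(opt("--evalue", "1e-5"))),
                      a, b)
    blocks <- chain_collinear_blocks(hits,
                                     as.numeric(opt("--min-block", "10")))
    pairs <- one_to_one(blocks)
    pre <- opt("--out", "homeo")
    utils::write.table(blocks, paste0(pre, "_blocks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(pairs, paste0(pre, "_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else if (cmd == "enrich") {
    ont <- read_obo(opt("--obo"))
    ann <- read_annotations_tsv(opt("--ann"))
    study <- readLines(opt("--study"))
    pop <- readLines(opt("--population"))
    res <- parent_child_union_test(study, pop, ont, ann)
    res <- enriched_terms(res, as.numeric(opt("--alpha", "0.05")))
    utils::write.table(res, opt("--out", "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    message("usage: introscan <simulate|run|report> [--config f] [--seed s]",
            " [--outdir d]")
  }
  invisible(NULL)
}
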