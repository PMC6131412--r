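# Synthetic-data generator emulating a host/donor/addition-line RNA-seq design:
# multi-chromosome gene annotations, NB-distributed count matrices with injected
# effect regions (deletions, logFC gradients), cross-genome homology hit tables
# and toy ontologies.  Every downstream stage of the pipeline is testable
# against the ground truth recorded here.

#' Describe a set of chromosomes to simulate
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp),
#'   `genome` (`"host"` or `"donor"`), `n_genes`, and optionally
#'   `gene_start`/`gene_end` restricting the gene-bearing region (bp; used to
#'   model a telosome whose genes occupy only part of the pseudomolecule
#'   coordinate system).
#' @return A validated `genome_spec` object.
#' @export
genome_spec <- function(chromosomes) {
  req <- c("name", "length", "genome", "n_genes")
  miss <- setdiff(req, names(chromosomes))
  if (length(miss))
    stop("genome_spec: missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(chromosomes$gene_start)) chromosomes$gene_start <- 1
  if (is.null(chromosomes$gene_end)) chromosomes$gene_end <- chromosomes$length
  chromosomes$gene_start[is.na(chromosomes$gene_start)] <- 1
  chromosomes$gene_end[is.na(chromosomes$gene_end)] <-
    chromosomes$length[is.na(chromosomes$gene_end)]
  if (any(chromosomes$length <= 0))
    stop("genome_spec: field 'length' must be > 0")
  if (any(chromosomes$n_genes < 1))
    stop("genome_spec: field 'n_genes' must be >= 1")
  if (any(!chromosomes$genome %in% c("host", "donor")))
    stop("genome_spec: field 'genome' must be 'host' or 'donor'")
  if (any(chromosomes$gene_start < 1 |
          chromosomes$gene_end > chromosomes$length |
          chromosomes$gene_end <= chromosomes$gene_start))
    stop("genome_spec: field 'gene_start'/'gene_end' outside [1, length]")
  if (anyDuplicated(chromosomes$name))
    stop("genome_spec: field 'name' has duplicates")
  structure(list(chromosomes = chromosomes), class = "genome_spec")
}

#' One injected effect region
#'
#' Effects act on the addition-line group relative to the reference genotype
#' carrying the same genome.
#'
#' @param chrom chromosome name
#' @param start,end region in bp
#' @param kind one of `"deletion"`, `"up_gradient"`, `"down_gradient"`,
#'   `"fixed_logFC"`
#' @param magnitude absolute log2 fold change at the peak of the effect
#'   (ignored for `deletion`). `up_gradient` interpolates +magnitude at
#'   `start` down to 0 at `end`; `down_gradient` interpolates 0 at `start`
#'   down to -magnitude at `end`; `fixed_logFC` applies `magnitude` uniformly.
#' @export
effect_region <- function(chrom, start, end, kind, magnitude = 0) {
  kind <- match.arg(kind, c("deletion", "up_gradient", "down_gradient",
                            "fixed_logFC"))
  if (end <= start) stop("effect_region: end must be > start")
  list(chrom = chrom, start = start, end = end, kind = kind,
       magnitude = magnitude)
}

#' Describe the replicated three-genotype design
#'
#' @param groups named character vector with elements `host`, `donor`,
#'   `addition` giving the genotype labels.
#' @param replicates biological replicates per group (>= 2).
#' @param library_size_mean,library_size_cv mean and coefficient of variation
#'   of per-sample sequencing depth (mapped reads).
#' @param dispersion NB dispersion (squared biological CV), > 0.
#' @param effect_regions list of [effect_region()] objects.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of per-gene
#'   baseline expression weights.
#' @param length_range sampled gene length range in bp (used for FPKM only).
#' @export
design_spec <- function(groups = c(host = "CS", donor = "B",
                                   addition = "CS+7HL"),
                        replicates = 6,
                        library_size_mean = 1.5e7,
                        library_size_cv = 0.1,
                        dispersion = 0.2,
                        effect_regions = list(),
                        baseline_meanlog = log(90),
                        baseline_sdlog = 1.6,
                        length_range = c(500, 5000)) {
  if (!all(c("host", "donor", "addition") %in% names(groups)))
    stop("design_spec: 'groups' needs named elements host, donor, addition")
  if (replicates < 2) stop("design_spec: field 'replicates' must be >= 2")
  if (dispersion <= 0) stop("design_spec: field 'dispersion' must be > 0")
  if (library_size_mean <= 0)
    stop("design_spec: field 'library_size_mean' must be > 0")
  structure(list(groups = groups, replicates = replicates,
                 library_size_mean = library_size_mean,
                 library_size_cv = library_size_cv,
                 dispersion = dispersion,
                 effect_regions = effect_regions,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 length_range = length_range),
            class = "design_spec")
}

#' Default genome emulating a host/donor addition-line karyotype
#'
#' Two host chromosomes and one donor telosome whose genes occupy the
#' 339-656 Mbp coordinate window of the donor pseudomolecule.  The first host
#' chromosome is 740 Mbp so that a terminal 700-736 Mbp deletion can be
#' injected.
#' @param n_genes_host,n_genes_host2,n_genes_donor gene counts per chromosome.
#' @export
addition_line_genome <- function(n_genes_host = 1500, n_genes_host2 = 600,
                                 n_genes_donor = 900) {
  genome_spec(data.frame(
    name = c("7A", "7B", "7H"),
    length = c(740e6, 713e6, 656e6),
    genome = c("host", "host", "donor"),
    n_genes = c(n_genes_host, n_genes_host2, n_genes_donor),
    gene_start = c(1, 1, 339e6),
    gene_end = c(740e6, 713e6, 656e6)))
}

#' Default design: terminal host deletion plus a proximal-up / distal-down
#' regulation gradient along the donor arm
#'
#' The deletion removes 700-736 Mbp of host chromosome 7A in the addition
#' line (structural zeros).  The donor arm carries a gradient: up-regulation
#' strongest at the proximal (centromeric) end, down-regulation strongest at
#' the distal (telomeric) end.
#' @param ... passed on to [design_spec()].
#' @export
addition_line_design <- function(...) {
  design_spec(effect_regions = list(
    effect_region("7A", 700e6, 736e6, "deletion"),
    effect_region("7H", 339e6, 497e6, "up_gradient", magnitude = 0.8),
    effect_region("7H", 497e6, 656e6, "down_gradient", magnitude = 1.2)),
    ...)
}

#' Generate a sorted non-overlapping gene annotation
#'
#' Each chromosome's gene-bearing region is divided into equal slots; one gene
#' is placed uniformly at random inside each slot, which enforces strictly
#' increasing, non-overlapping genes by construction.
#'
#' @param spec a [genome_spec()].
#' @param seed integer seed; identical seeds give identical tables.
#' @param length_range gene length range in bp.
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`, `length`, `genome`
#'   (1-based inclusive coordinates).
#' @export
generate_annotation <- function(spec, seed = 1L, length_range = c(500, 5000)) {
  if (!inherits(spec, "genome_spec")) spec <- genome_spec(spec)
  set.seed(seed)
  out <- lapply(seq_len(nrow(spec$chromosomes)), function(ci) {
    ch <- spec$chromosomes[ci, ]
    n <- ch$n_genes
    span <- ch$gene_end - ch$gene_start + 1
    slot <- floor(span / n)
    if (slot < 50)
      stop("generate_annotation: chromosome ", ch$name,
           " too dense for ", n, " genes")
    len <- pmin(round(stats::runif(n, length_range[1], length_range[2])),
                slot - 2L)
    slot_start <- ch$gene_start + (seq_len(n) - 1) * slot
    start <- slot_start + floor(stats::runif(n) * (slot - len - 1))
    data.frame(gene_id = sprintf("%s_G%05d", ch$name, seq_len(n)),
               chrom = ch$name, start = start, end = start + len - 1,
               length = len, genome = ch$genome,
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, out)
  rownames(ann) <- NULL
  ann
}

# log2 fold change injected at a position by one effect region (0 if outside)
.effect_logfc <- function(eff, pos) {
  inside <- pos >= eff$start & pos <= eff$end
  lfc <- numeric(length(pos))
  frac <- (pos - eff$start) / (eff$end - eff$start)
  lfc[inside] <- switch(eff$kind,
    deletion = NA_real_,               # handled separately
    up_gradient = eff$magnitude * (1 - frac[inside]),
    down_gradient = -eff$magnitude * frac[inside],
    fixed_logFC = eff$magnitude)
  lfc
}

#' Generate NB-distributed counts with injected effects, plus the ground truth
#'
#' Per-gene baseline weights are log-normal; per-sample expected counts are
#' `library size x (weight share within the expressed gene set)`.  Host genes
#' are expressed in the host and addition groups, donor genes in the donor and
#' addition groups (cross-genome read mapping is not modelled).  Effects act
#' multiplicatively on the addition group; deletions are structural zeros
#' (mean exactly 0).
#'
#' @param annotation output of [generate_annotation()].
#' @param design a [design_spec()].
#' @param seed integer seed.
#' @return list with `counts` (a [count_matrix()]) and `truth` (data.frame:
#'   `gene_id`, `genome`, `true_class` in up/down/null/deleted, `true_logfc`
#'   = injected log2 effect, `in_deletion`).
#' @export
generate_counts <- function(annotation, design, seed = 1L) {
  if (!inherits(design, "design_spec")) stop("generate_counts: need design_spec")
  for (eff in design$effect_regions)
    if (!eff$chrom %in% annotation$chrom)
      stop("generate_counts: effect region on unknown chromosome ", eff$chrom)
  set.seed(seed)
  G <- nrow(annotation)
  w <- stats::rlnorm(G, design$baseline_meanlog, design$baseline_sdlog)

  # injected addition-group log2FC per gene; deletions flagged separately
  lfc <- numeric(G)
  deleted <- logical(G)
  pos <- annotation$start
  for (eff in design$effect_regions) {
    on_chr <- annotation$chrom == eff$chrom
    if (eff$kind == "deletion") {
      deleted <- deleted | (on_chr & pos >= eff$start & pos <= eff$end)
    } else {
      v <- .effect_logfc(eff, pos)
      lfc[on_chr] <- lfc[on_chr] + v[on_chr]
    }
  }
  lfc[deleted] <- NA_real_

  groups <- design$groups
  samples <- data.frame(
    sample = paste0(rep(make.names(groups), each = design$replicates), "_",
                    seq_len(design$replicates)),
    group = rep(unname(groups), each = design$replicates),
    replicate = rep(seq_len(design$replicates), 3),
    stringsAsFactors = FALSE)
  S <- nrow(samples)
  sdlog <- sqrt(log(1 + design$library_size_cv^2))
  libsize <- stats::rlnorm(S, log(design$library_size_mean) - sdlog^2 / 2, sdlog)

  is_host <- annotation$genome == "host"
  counts <- matrix(0L, G, S,
                   dimnames = list(annotation$gene_id, samples$sample))
  phi <- design$dispersion
  for (s in seq_len(S)) {
    grp <- samples$group[s]
    role <- names(groups)[match(grp, groups)]
    expressed <- if (role == "host") is_host
                 else if (role == "donor") !is_host
                 else rep(TRUE, G)
    q <- w * expressed
    if (role == "addition") {
      q <- q * 2^ifelse(is.na(lfc), 0, lfc)
      q[deleted] <- 0
    }
    # a group with no expressed genes (e.g. donor group of a host-only
    # simulation) sequences nothing informative: all-zero sample
    mu <- if (sum(q) > 0) libsize[s] * q / sum(q) else numeric(G)
    y <- if (phi < 1e-12) stats::rpois(G, mu)
         else stats::rnbinom(G, size = 1 / phi, mu = mu)
    counts[, s] <- y
  }
  storage.mode(counts) <- "integer"

  truth <- data.frame(
    gene_id = annotation$gene_id, genome = annotation$genome,
    true_class = ifelse(deleted, "deleted",
                  ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "null"))),
    true_logfc = lfc, in_deletion = deleted,
    base_weight = w, stringsAsFactors = FALSE)
  truth$true_logfc[deleted] <- NA_real_

  list(counts = count_matrix(counts, samples), truth = truth)
}

#' Generate a BLAST-tabular homology hit table between two annotations
#'
#' A stated fraction of genes form order-preserving cross-genome pairs with
#' strong E-values; the remainder are random noise pairs whose E-values span
#' both sides of the conventional 1e-5 filter threshold.
#'
#' @param annotation_a,annotation_b gene annotations (query / subject).
#' @param collinear_fraction fraction of `min(nA, nB)` genes forming collinear
#'   pairs, in \[0, 1\].
#' @param seed integer seed.
#' @param noise_fraction number of random noise hits as a fraction of the
#'   collinear pair count (of `min(nA,nB)` when `collinear_fraction` is 0).
#' @return data.frame in 12-column BLAST outfmt-6 layout (`evalue` column 11,
#'   `bitscore` column 12).
#' @export
generate_homology_hits <- function(annotation_a, annotation_b,
                                   collinear_fraction = 0.8, seed = 1L,
                                   noise_fraction = 0.3) {
  if (collinear_fraction < 0 || collinear_fraction > 1)
    stop("generate_homology_hits: collinear_fraction outside [0,1]")
  set.seed(seed)
  a <- annotation_a[order(annotation_a$chrom, annotation_a$start), ]
  b <- annotation_b[order(annotation_b$chrom, annotation_b$start), ]
  nmin <- min(nrow(a), nrow(b))
  k <- round(collinear_fraction * nmin)
  mk_row <- function(q, s, evalue, bit) {
    data.frame(qseqid = q, sseqid = s,
               pident = round(stats::runif(length(q), 70, 99), 2),
               length = round(stats::runif(length(q), 100, 1500)),
               mismatch = round(stats::runif(length(q), 0, 50)),
               gapopen = round(stats::runif(length(q), 0, 5)),
               qstart = 1L, qend = 300L, sstart = 1L, send = 300L,
               evalue = evalue, bitscore = bit, stringsAsFactors = FALSE)
  }
  out <- list()
  if (k > 0) {
    ia <- sort(sample.int(nrow(a), k))
    ib <- sort(sample.int(nrow(b), k))
    out$collinear <- mk_row(a$gene_id[ia], b$gene_id[ib],
                            10^-stats::runif(k, 30, 180),
                            round(stats::runif(k, 500, 2000)))
  }
  n_noise <- round(noise_fraction * max(k, nmin * (collinear_fraction == 0)))
  if (n_noise > 0) {
    qa <- sample(a$gene_id, n_noise, replace = TRUE)
    sb <- sample(b$gene_id, n_noise, replace = TRUE)
    out$noise <- mk_row(qa, sb, 10^-stats::runif(n_noise, 0, 8),
                        round(stats::runif(n_noise, 30, 80)))
  }
  hits <- do.call(rbind, out)
  if (is.null(hits)) hits <- mk_row(character(), character(), numeric(),
                                    numeric())
  hits <- hits[!duplicated(hits[, c("qseqid", "sseqid")]), ]
  rownames(hits) <- NULL
  hits
}

#' Generate a random single-rooted is_a DAG and gene-to-term annotations
#'
#' Term i (i >= 2) draws its parents among earlier terms, which guarantees
#' acyclicity and reachability of the single root.  Direct annotations are
#' uniform over non-root terms.
#'
#' @param genes character vector of gene ids to annotate.
#' @param n_terms number of terms (>= 3), including the root.
#' @param seed integer seed.
#' @param terms_per_gene range of direct annotations per gene.
#' @return list with `ontology` (see [ontology()]) and `annotations`
#'   (data.frame `gene`, `term`; direct, not propagated).
#' @export
generate_ontology <- function(genes, n_terms = 30, seed = 1L,
                              terms_per_gene = c(1, 3)) {
  if (n_terms < 3) stop("generate_ontology: n_terms must be >= 3")
  set.seed(seed)
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  parents <- vector("list", n_terms)
  names(parents) <- terms
  parents[[1]] <- character()
  for (i in 2:n_terms) {
    np <- if (i <= 2) 1L else sample(1:2, 1)
    parents[[i]] <- terms[sample.int(i - 1, min(np, i - 1))]
  }
  ont <- ontology(terms, parents)
  ntg <- sample(terms_per_gene[1]:terms_per_gene[2], length(genes),
                replace = TRUE)
  ann <- data.frame(
    gene = rep(genes, ntg),
    term = unlist(lapply(ntg, function(m) sample(terms[-1], m))),
    stringsAsFactors = FALSE)
  ann <- unique(ann)
  list(ontology = ont, annotations = ann)
}

## ---- plain-text writers -------------------------------------------------

#' Write an annotation as BED (0-based half-open) or GFF3 (1-based inclusive)
#' @param annotation annotation data.frame
#' @param path output file
#' @export
write_annotation_bed <- function(annotation, path) {
  bed <- data.frame(annotation$chrom, annotation$start - 1L, annotation$end,
                    annotation$gene_id, 0L, "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
write_annotation_gff3 <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- sprintf("%s\tintroscan\tgene\t%d\t%d\t.\t+\t.\tID=%s;genome=%s",
                   annotation$chrom, annotation$start, annotation$end,
                   annotation$gene_id, annotation$genome)
  writeLines(lines, con)
  invisible(path)
}

#' Read a gene annotation from a GFF3 file written by this package
#' @param path GFF3 file with `ID=` (and optionally `genome=`) attributes.
#' @export
read_annotation_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  attr9 <- vapply(f, `[`, "", 9L)
  get_attr <- function(key) {
    m <- regmatches(attr9, regexpr(paste0(key, "=[^;]+"), attr9))
    sub(paste0(key, "="), "", m)
  }
  genome <- get_attr("genome")
  if (length(genome) != length(ln)) genome <- rep(NA_character_, length(ln))
  ann <- data.frame(gene_id = get_attr("ID"),
                    chrom = vapply(f, `[`, "", 1L),
                    start = as.integer(vapply(f, `[`, "", 4L)),
                    end = as.integer(vapply(f, `[`, "", 5L)),
                    genome = genome, stringsAsFactors = FALSE)
  ann$length <- ann$end - ann$start + 1L
  ann
}

#' Write/read a count matrix as TSV (gene id column + one column per sample)
#' @param x a [count_matrix()]
#' @param path output file
#' @export
write_counts_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param samples sample metadata data.frame (`sample`, `group`, `replicate`);
#'   if NULL, groups are parsed from column names as `<group>_<replicate>`.
#' @export
read_counts_tsv <- function(path, samples = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  if (is.null(samples)) {
    nm <- colnames(m)
    samples <- data.frame(sample = nm,
                          group = sub("_[0-9]+$", "", nm),
                          replicate = as.integer(sub(".*_", "", nm)),
                          stringsAsFactors = FALSE)
  }
  count_matrix(m, samples)
}

#' Write homology hits as 12-column BLAST tabular
#' @param hits hit data.frame
#' @param path output file
#' @export
write_hits_blast6 <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_blast6
#' @export
read_hits_blast6 <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  hits <- utils::read.delim(path, header = FALSE, col.names = cols,
                            stringsAsFactors = FALSE)
  hits
}

#' Write/read sample metadata as TSV (`sample`, `group`, `replicate`)
#' @param samples sample metadata data.frame
#' @param path output file
#' @export
write_samples_tsv <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples_tsv
#' @export
read_samples_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write the truth table as TSV
#' @param truth truth data.frame from [generate_counts()]
#' @param path output file
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
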