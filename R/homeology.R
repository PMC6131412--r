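# Homeolog assignment from a protein-similarity hit table: E-value filtering,
# gene-rank based collinear chaining into synteny blocks (dynamic
# programming), strict 1:1 retention, DT-class distributions over
# homeolog/nonhomeolog partitions, and cross-genome transcriptional
# compensation scoring over a deleted region.

#' Filter a homology hit table
#'
#' Keeps hits with `evalue <= e_threshold` and removes self-hits.
#'
#' @param hits BLAST-tabular style data.frame (`qseqid`, `sseqid`, `evalue`,
#'   `bitscore` required).
#' @param e_threshold E-value threshold (default 1e-5).
#' @export
filter_hits <- function(hits, e_threshold = 1e-5) {
  hits[hits$evalue <= e_threshold & hits$qseqid != hits$sseqid, ,
       drop = FALSE]
}

#' Attach gene-order ranks from the two annotations
#'
#' Ranks are gene order indices within each chromosome (1 = most proximal by
#' start coordinate); chaining operates on ranks, not bp, so it is invariant
#' to annotation scale.
#'
#' @param hits hit table.
#' @param annotation_a,annotation_b query- and subject-side annotations.
#' @return hits with `q_chrom`, `q_rank`, `s_chrom`, `s_rank` columns; hits
#'   whose genes are absent from the annotations are dropped.
#' @export
hit_ranks <- function(hits, annotation_a, annotation_b) {
  rank_of <- function(ann) {
    ann <- ann[order(ann$chrom, ann$start), ]
    r <- stats::ave(ann$start, ann$chrom, FUN = seq_along)
    data.frame(gene_id = ann$gene_id, chrom = ann$chrom, rank = r,
               stringsAsFactors = FALSE)
  }
  ra <- rank_of(annotation_a); rb <- rank_of(annotation_b)
  ia <- match(hits$qseqid, ra$gene_id)
  ib <- match(hits$sseqid, rb$gene_id)
  keep <- !is.na(ia) & !is.na(ib)
  hits <- hits[keep, , drop = FALSE]
  hits$q_chrom <- ra$chrom[ia[keep]]; hits$q_rank <- ra$rank[ia[keep]]
  hits$s_chrom <- rb$chrom[ib[keep]]; hits$s_rank <- rb$rank[ib[keep]]
  hits
}

# Best chain by dynamic programming over hits of one chromosome pair and one
# orientation.  A chain extends i -> j when query rank strictly increases by
# at most max_gap and subject rank is strictly monotone (direction given by
# `orient`) with gap at most max_gap.  Score = chain size, ties broken by
# total bit score.  Returns indices into `h` of the best chain.
.best_chain <- function(h, orient, max_gap) {
  n <- nrow(h)
  if (n == 0) return(integer(0))
  o <- order(h$q_rank, h$s_rank)
  q <- h$q_rank[o]; s <- h$s_rank[o]; b <- h$bitscore[o]
  len <- rep(1L, n); bit <- b; prev <- rep(0L, n)
  for (i in seq_len(n)) {
    dq <- q[i] - q
    ds <- if (orient == "same") s[i] - s else s - s[i]
    ok <- which(dq > 0 & dq <= max_gap & ds > 0 & ds <= max_gap)
    if (length(ok)) {
      cand_len <- len[ok] + 1L
      cand_bit <- bit[ok] + b[i]
      best <- ok[order(-cand_len, -cand_bit)[1]]
      len[i] <- len[best] + 1L
      bit[i] <- bit[best] + b[i]
      prev[i] <- best
    }
  }
  i <- order(-len, -bit)[1]
  chain <- integer(0)
  while (i > 0) { chain <- c(i, chain); i <- prev[i] }
  o[chain]
}

#' Chain collinear hits into synteny blocks
#'
#' Per chromosome pair and orientation, hits are chained by dynamic
#' programming on gene-order ranks: both ranks must advance strictly and by
#' at most `max_rank_gap`.  Maximal-score chains are extracted greedily
#' without hit reuse; chains smaller than `min_block` are discarded.
#'
#' @param hits filtered hit table with rank columns (see [hit_ranks()]).
#' @param min_block minimum block size in gene pairs (default 10).
#' @param max_rank_gap maximum gene-rank gap within a chain (default 25).
#' @return data.frame of block-supported pairs: `block_id`, `q_chrom`,
#'   `s_chrom`, `orientation`, `qseqid`, `sseqid`, `evalue`, `bitscore`,
#'   `q_rank`, `s_rank`.
#' @export
chain_collinear_blocks <- function(hits, min_block = 10, max_rank_gap = 25) {
  empty <- data.frame(block_id = integer(), q_chrom = character(),
                      s_chrom = character(), orientation = character(),
                      qseqid = character(), sseqid = character(),
                      evalue = numeric(), bitscore = numeric(),
                      q_rank = numeric(), s_rank = numeric())
  if (nrow(hits) == 0) return(empty)
  out <- list(); bid <- 0L
  pairs <- unique(hits[, c("q_chrom", "s_chrom")])
  for (pi in seq_len(nrow(pairs))) {
    h <- hits[hits$q_chrom == pairs$q_chrom[pi] &
              hits$s_chrom == pairs$s_chrom[pi], , drop = FALSE]
    repeat {
      ch_same <- .best_chain(h, "same", max_rank_gap)
      ch_inv <- .best_chain(h, "inverted", max_rank_gap)
      use_same <- length(ch_same) >= length(ch_inv)
      ch <- if (use_same) ch_same else ch_inv
      if (length(ch) < min_block) break
      bid <- bid + 1L
      blk <- h[ch, c("qseqid", "sseqid", "evalue", "bitscore",
                     "q_rank", "s_rank"), drop = FALSE]
      blk <- cbind(block_id = bid, q_chrom = pairs$q_chrom[pi],
                   s_chrom = pairs$s_chrom[pi],
                   orientation = if (use_same) "same" else "inverted",
                   blk)
      out[[length(out) + 1]] <- blk
      h <- h[-ch, , drop = FALSE]
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Strict 1:1 homeolog retention
#'
#' Block-supported pairs are reduced to each query gene's best pair and each
#' subject gene's best pair (bit score, then E-value, then partner id); a
#' pair is retained iff, within the union of both reduced sets, its query and
#' its subject each occur exactly once.  Genes with multiple best partners at
#' identical support are thereby treated as ambiguous and dropped, as are
#' many-to-one (tandem-duplicate style) configurations.
#'
#' @param block_pairs output of [chain_collinear_blocks()].
#' @return data.frame of retained pairs with the same columns.
#' @export
one_to_one <- function(block_pairs) {
  bp <- block_pairs
  if (nrow(bp) == 0) return(bp)
  pair_key <- paste(bp$qseqid, bp$sseqid)
  best_by <- function(key, partner) {
    o <- order(key, -bp$bitscore, bp$evalue, partner)
    b <- bp[o, , drop = FALSE]
    k <- key[o]
    n <- length(k)
    keep <- !duplicated(k)
    # a gene whose best pair ties the runner-up on both bit score and
    # E-value has no unique best partner: treat as ambiguous, drop the gene
    same_next <- c(k[-1] == k[-n], FALSE)
    tie_next <- c(b$bitscore[-1] == b$bitscore[-n] &
                  b$evalue[-1] == b$evalue[-n], FALSE)
    tied_genes <- unique(k[keep & same_next & tie_next])
    paste(b$qseqid, b$sseqid)[keep & !(k %in% tied_genes)]
  }
  rq <- best_by(bp$qseqid, bp$sseqid)
  rs <- best_by(bp$sseqid, bp$qseqid)
  r_union <- bp[pair_key %in% union(rq, rs), , drop = FALSE]
  qcnt <- table(r_union$qseqid); scnt <- table(r_union$sseqid)
  keep <- qcnt[r_union$qseqid] == 1 & scnt[r_union$sseqid] == 1
  res <- r_union[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' DT-class distribution over homeolog / nonhomeolog partitions
#'
#' For each DT class, counts genes in the whole region (`All`), its homeolog
#' subset (genes appearing in `pairs`) and the nonhomeolog remainder, with
#' the homeolog/nonhomeolog percentage split per class.
#'
#' @param records DT table restricted to the region of interest.
#' @param homeolog_genes gene ids that have a retained 1:1 homeolog.
#' @return data.frame: `class`, `n_all`, `n_homeolog`, `n_nonhomeolog`,
#'   `pct_homeolog`, `pct_nonhomeolog`.
#' @export
class_distribution <- function(records, homeolog_genes) {
  is_h <- records$gene_id %in% homeolog_genes
  cls <- c("not_DT", "up", "down")
  out <- lapply(cls, function(cl) {
    n_all <- sum(records$class == cl)
    n_h <- sum(records$class == cl & is_h)
    data.frame(class = cl, n_all = n_all, n_homeolog = n_h,
               n_nonhomeolog = n_all - n_h,
               pct_homeolog = if (n_all) round(n_h / n_all * 100, 2)
                              else NA_real_,
               pct_nonhomeolog = if (n_all)
                 round((n_all - n_h) / n_all * 100, 2) else NA_real_)
  })
  do.call(rbind, out)
}

#' Transcriptional compensation of deleted host genes by donor homeologs
#'
#' For each retained 1:1 pair whose host gene lies in the deleted interval,
#' the compensation ratio is the donor homeolog's mean FPKM in the addition
#' line over the host gene's mean FPKM in the host line.  A pair partially
#' compensates when the ratio reaches `ratio_threshold`; donor genes at or
#' above `high_fpkm_threshold` count as highly transcribed.  Host genes with
#' zero FPKM give an undefined ratio and are excluded from the summary
#' denominator.
#'
#' @param pairs 1:1 pairs; `host_side` names the column holding host gene ids
#'   (`"qseqid"` or `"sseqid"`), the other column holds donor ids.
#' @param deletion list/row with `chrom`, `start_bp`, `end_bp`.
#' @param annotation_host host annotation (for deletion membership by start).
#' @param fpkm_host named vector: host-gene mean FPKM in the host genotype.
#' @param fpkm_donor named vector: donor-gene mean FPKM in the addition line.
#' @param ratio_threshold partial-compensation threshold (default 0.5).
#' @param high_fpkm_threshold "highly transcribed" donor FPKM (default 20).
#' @return list with `pairs` (per-pair table: ids, FPKMs, `ratio`,
#'   `partial_compensation`, `high_donor`) and `summary` (named counts).
#' @export
compensation <- function(pairs, deletion, annotation_host, fpkm_host,
                         fpkm_donor, host_side = "qseqid",
                         ratio_threshold = 0.5, high_fpkm_threshold = 20) {
  donor_side <- if (host_side == "qseqid") "sseqid" else "qseqid"
  host_id <- pairs[[host_side]]; donor_id <- pairs[[donor_side]]
  ann <- annotation_host
  del_genes <- ann$gene_id[ann$chrom == deletion$chrom &
                           ann$start >= deletion$start_bp &
                           ann$start <= deletion$end_bp]
  sel <- host_id %in% del_genes
  host_id <- host_id[sel]; donor_id <- donor_id[sel]
  fh <- unname(fpkm_host[host_id]); fd <- unname(fpkm_donor[donor_id])
  ratio <- ifelse(!is.na(fh) & fh > 0, fd / fh, NA_real_)
  tab <- data.frame(host_gene = host_id, donor_gene = donor_id,
                    fpkm_host = fh, fpkm_donor = fd, ratio = ratio,
                    partial_compensation = !is.na(ratio) &
                      ratio >= ratio_threshold,
                    high_donor = !is.na(fd) & fd >= high_fpkm_threshold,
                    stringsAsFactors = FALSE)
  summary <- c(n_pairs_in_deletion = nrow(tab),
               n_defined = sum(!is.na(tab$ratio)),
               n_partial = sum(tab$partial_compensation),
               n_high_donor = sum(tab$high_donor),
               n_high_partial = sum(tab$high_donor &
                                    tab$partial_compensation))
  list(pairs = tab, summary = summary)
}
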