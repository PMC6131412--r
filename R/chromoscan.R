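# Chromosomal windowing and segmentation: sliding-window DT-class ratios and
# mean logFC along a chromosome, PELT change-point segmentation of those
# tracks (Gaussian change-in-mean cost, exact penalized minimization with
# pruning), per-segment gene-level profiles, and deletion-region calling from
# the expression-loss signature.

#' Sliding-window DT metrics along one chromosome
#'
#' Windows of fixed width at a fixed step starting at 0 bp; the last windows
#' are truncated at the chromosome end rather than dropped, so a terminal
#' event remains visible.  A gene belongs to a window iff its assigned
#' position (start by default, midpoint optionally) lies in
#' `[win_start, win_start + window)`.  Ratio metrics and mean logFC are NA in
#' windows with zero transcribed genes.
#'
#' @param records DT table with columns `chrom`, `start`, (`end`,) `class`,
#'   `logfc` for transcribed genes.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param window,step window width and step in bp (window > 0).
#' @param assign gene-to-window assignment rule: `"start"` or `"midpoint"`.
#' @return data.frame of class `window_metrics`: `chrom`, `win_start`,
#'   `win_end` (0-based half-open), `n_trans`, `n_up`, `n_down`, `n_notdt`,
#'   `r_up`, `r_down`, `r_notdt`, `mean_logfc`, `density` (transcribed genes
#'   per Mbp of window span).
#' @export
window_metrics <- function(records, chrom, chrom_length,
                           window = 10e6, step = 1e6,
                           assign = c("start", "midpoint")) {
  if (window <= 0) stop("window_metrics: window must be > 0")
  assign <- match.arg(assign)
  rec <- records[records$chrom == chrom, , drop = FALSE]
  pos <- if (assign == "start") rec$start
         else floor((rec$start + rec$end) / 2)
  o <- order(pos)
  pos <- pos[o]; rec <- rec[o, , drop = FALSE]

  win_start <- seq(0, chrom_length - 1, by = step)
  win_end <- pmin(win_start + window, chrom_length)
  # rolling counts via cumulative sums at window boundaries
  cum <- function(v) c(0, cumsum(v))
  lo <- findInterval(win_start - 0.5, pos)      # genes with pos < win_start
  hi <- findInterval(win_end - 0.5, pos)        # genes with pos < win_end
  n_of <- function(flag) { cs <- cum(flag); cs[hi + 1] - cs[lo + 1] }
  n_trans <- n_of(rep(1, nrow(rec)))
  n_up <- n_of(rec$class == "up")
  n_down <- n_of(rec$class == "down")
  n_notdt <- n_of(rec$class == "not_DT")
  sum_lfc <- n_of(rec$logfc)
  denom <- ifelse(n_trans > 0, n_trans, NA_real_)
  out <- data.frame(
    chrom = chrom, win_start = win_start, win_end = win_end,
    n_trans = n_trans, n_up = n_up, n_down = n_down, n_notdt = n_notdt,
    r_up = n_up / denom, r_down = n_down / denom, r_notdt = n_notdt / denom,
    mean_logfc = sum_lfc / denom,
    density = n_trans / ((win_end - win_start) / 1e6))
  class(out) <- c("window_metrics", "data.frame")
  out
}

## ---- PELT ---------------------------------------------------------------

# Exact penalized change-in-mean segmentation by the PELT recursion.
# cost(i..j) = (sum of squares - sum^2/n) / sigma2; total objective is
# sum(segment costs) + beta * (number of change points).  Candidate pruning
# uses the standard inequality with K = 0 (valid for this cost).
.pelt_core <- function(x, beta, sigma2, min_seg = 1L) {
  n <- length(x)
  c1 <- c(0, cumsum(x)); c2 <- c(0, cumsum(x^2))
  segcost <- function(i, j) {  # x[i..j], vectorized over i
    len <- j - i + 1
    ((c2[j + 1] - c2[i]) - (c1[j + 1] - c1[i])^2 / len) / sigma2
  }
  F <- c(-beta, rep(Inf, n))
  last <- integer(n)
  cand <- 0L
  for (t in seq_len(n)) {
    ok <- cand <= t - min_seg
    if (!any(ok)) { F[t + 1] <- Inf; last[t] <- 0L; cand <- c(cand, t); next }
    cc <- cand[ok]
    vals <- F[cc + 1] + segcost(cc + 1, t) + beta
    i <- which.min(vals)
    F[t + 1] <- vals[i]
    last[t] <- cc[i]
    keep <- cand[!ok]
    cc <- cc[F[cc + 1] + segcost(cc + 1, t) <= F[t + 1]]
    cand <- c(keep, cc, t)
  }
  cps <- integer(0)
  t <- n
  while (t > 0) { s <- last[t]; if (s > 0) cps <- c(s, cps); t <- s }
  list(changepoints = cps, objective = F[n + 1])
}

# global noise variance from first differences (robust; a mean shift
# contaminates only one difference, so the MAD is insensitive to it)
.track_sigma2 <- function(x) {
  d <- diff(x)
  s2 <- (stats::mad(d) / sqrt(2))^2
  if (!is.finite(s2) || s2 == 0) s2 <- mean(d^2) / 2
  if (!is.finite(s2) || s2 == 0) s2 <- 1
  s2
}

# nearest-non-missing imputation (ties broken toward the left neighbour)
.impute_nearest <- function(v) {
  ok <- which(!is.na(v))
  if (length(ok) == 0) return(v)
  idx <- vapply(seq_along(v), function(i) ok[which.min(abs(ok - i))],
                integer(1))
  v[idx]
}

#' PELT change-point segmentation of a window track
#'
#' Exact minimizer of `sum(segment Gaussian change-in-mean costs) + beta * k`
#' over all segmentations, with PELT candidate pruning.  The noise variance is
#' estimated globally from the first differences of the track (MAD-based).
#' Missing windows (zero transcribed genes) are imputed by the nearest
#' non-missing window for segmentation only; reported per-segment means use
#' the original values.
#'
#' @param wm a [window_metrics()] data.frame (or any data.frame with
#'   `win_start`, `win_end` and the metric column).
#' @param metric column name to segment, e.g. `"r_down"` or `"mean_logfc"`.
#' @param penalty `"MBIC"` (beta = 3 log n), `"BIC"` (beta = 2 log n) or a
#'   manual numeric beta.
#' @param min_seg minimum segment length in windows.
#' @param sigma2 optionally override the noise-variance estimate.
#' @return data.frame of class `segment_set`: `chrom`, `metric`, `seg_start`,
#'   `seg_end` (window indices), `start_bp`, `end_bp`, `mean_value`, with
#'   attributes `changepoints_bp`, `penalty_beta`, `objective`.
#' @export
pelt_segment <- function(wm, metric, penalty = "MBIC", min_seg = 1L,
                         sigma2 = NULL) {
  v <- wm[[metric]]
  if (is.null(v)) stop("pelt_segment: no metric column '", metric, "'")
  if (sum(!is.na(v)) < 2)
    stop("pelt_segment: need >= 2 non-missing windows")
  x <- .impute_nearest(v)
  n <- length(x)
  beta <- if (is.numeric(penalty)) penalty
          else switch(match.arg(penalty, c("MBIC", "BIC")),
                      MBIC = 3 * log(n), BIC = 2 * log(n))
  if (is.null(sigma2)) sigma2 <- .track_sigma2(x)
  fit <- .pelt_core(x, beta, sigma2, min_seg)
  cps <- fit$changepoints
  bounds <- c(0, cps, n)
  seg_start <- bounds[-length(bounds)] + 1
  seg_end <- bounds[-1]
  out <- data.frame(
    chrom = wm$chrom[1], metric = metric,
    seg_start = seg_start, seg_end = seg_end,
    start_bp = wm$win_start[seg_start],
    end_bp = wm$win_end[seg_end],
    mean_value = vapply(seq_along(seg_start), function(i)
      mean(v[seg_start[i]:seg_end[i]], na.rm = TRUE), numeric(1)),
    stringsAsFactors = FALSE)
  attr(out, "changepoints_bp") <- wm$win_start[cps + 1]
  attr(out, "penalty_beta") <- beta
  attr(out, "objective") <- fit$objective
  class(out) <- c("segment_set", "data.frame")
  out
}

#' Gene-level profile of each segment
#'
#' Recomputes class counts, ratios, mean logFC and group-mean FPKM from the
#' genes each segment spans (gene-level, not window-level, so overlapping
#' windows cannot double count).
#'
#' @param segments a [pelt_segment()] result.
#' @param records DT table with `chrom`, `start`, `class`, `logfc`, and
#'   optionally `fpkm_ref`, `fpkm_test` columns.
#' @param assign gene position rule, as in [window_metrics()].
#' @return data.frame: segment bounds plus `n_trans`, `n_up`, `n_down`,
#'   `n_notdt`, `r_up`, `r_down`, `r_notdt`, `mean_logfc`, `mean_fpkm_ref`,
#'   `mean_fpkm_test`.
#' @export
classify_segments <- function(segments, records, assign = c("start",
                                                            "midpoint")) {
  assign <- match.arg(assign)
  rec <- records[records$chrom == segments$chrom[1], , drop = FALSE]
  pos <- if (assign == "start") rec$start
         else floor((rec$start + rec$end) / 2)
  # segments tile gene space at change-point coordinates: a segment's gene
  # range ends where the next one starts (the last extends to the track end)
  nseg <- nrow(segments)
  gene_hi <- c(segments$start_bp[-1], segments$end_bp[nseg])
  segments$gene_lo_bp <- segments$start_bp
  segments$gene_hi_bp <- gene_hi
  prof <- lapply(seq_len(nseg), function(i) {
    inseg <- pos >= segments$start_bp[i] & pos < gene_hi[i]
    r <- rec[inseg, , drop = FALSE]
    n <- nrow(r)
    data.frame(
      n_trans = n,
      n_up = sum(r$class == "up"), n_down = sum(r$class == "down"),
      n_notdt = sum(r$class == "not_DT"),
      r_up = if (n) sum(r$class == "up") / n else NA_real_,
      r_down = if (n) sum(r$class == "down") / n else NA_real_,
      r_notdt = if (n) sum(r$class == "not_DT") / n else NA_real_,
      mean_logfc = if (n) mean(r$logfc) else NA_real_,
      mean_fpkm_ref = if (n && !is.null(r$fpkm_ref)) mean(r$fpkm_ref)
                      else NA_real_,
      mean_fpkm_test = if (n && !is.null(r$fpkm_test)) mean(r$fpkm_test)
                       else NA_real_,
      first_gene_start = if (n) min(r$start) else NA_real_,
      last_gene_end = if (n) max(if (is.null(r$end)) r$start else r$end)
                      else NA_real_)
  })
  cbind(as.data.frame(segments), do.call(rbind, prof))
}

#' Call deletion candidates from segment profiles
#'
#' Because change points are detected on overlapping windows, a segment's
#' boundary in gene space is smeared by up to one window width.  Each
#' segment is therefore refined before evaluation: leading and trailing genes
#' without the deletion signature (class != `"down"`) are trimmed, and the
#' evidence profile recomputed over the trimmed gene set.  A refined segment
#' qualifies iff `r_down >= r_down_min`, `r_up <= r_up_max` and the
#' test-group mean FPKM is below `fpkm_max`; adjacent qualifying segments are
#' merged, and a merged call must span at least `min_genes` transcribed
#' genes.  Reported boundaries span the first to last retained gene, rounded
#' outward to 1 Mbp.
#'
#' @param profiles output of [classify_segments()] (carries the per-segment
#'   gene ranges `gene_lo_bp`/`gene_hi_bp`).
#' @param records the DT table the profiles were computed from (needs
#'   `chrom`, `start`, `end`, `class`, `logfc`, `fpkm_test`).
#' @param r_down_min,r_up_max,fpkm_max evidence thresholds
#'   (defaults 0.9 / 0 / 1).
#' @param min_genes minimum transcribed genes in a merged call (default 10).
#' @return data.frame of calls: `chrom`, `start_bp`, `end_bp`, `n_trans`,
#'   `n_down`, `n_notdt`, `mean_fpkm_test`, `mean_logfc` (empty if none).
#' @export
call_deletions <- function(profiles, records, r_down_min = 0.9,
                           r_up_max = 0, fpkm_max = 1, min_genes = 10) {
  rec <- records[records$chrom == profiles$chrom[1], , drop = FALSE]
  rec <- rec[order(rec$start), , drop = FALSE]
  seg_genes <- function(i) {
    g <- rec[rec$start >= profiles$gene_lo_bp[i] &
             rec$start < profiles$gene_hi_bp[i], , drop = FALSE]
    is_down <- g$class == "down"
    if (!any(is_down)) return(g[0, , drop = FALSE])
    g[min(which(is_down)):max(which(is_down)), , drop = FALSE]
  }
  trimmed <- lapply(seq_len(nrow(profiles)), seg_genes)
  ok <- vapply(trimmed, function(g) {
    n <- nrow(g)
    n > 0 &&
      sum(g$class == "down") / n >= r_down_min &&
      sum(g$class == "up") / n <= r_up_max &&
      mean(g$fpkm_test) < fpkm_max
  }, logical(1))
  empty <- data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), n_trans = integer(),
                      n_down = integer(), n_notdt = integer(),
                      mean_fpkm_test = numeric(), mean_logfc = numeric())
  if (!any(ok)) return(empty)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  calls <- lapply(which(runs$values), function(ri) {
    g <- unique(do.call(rbind, trimmed[starts[ri]:ends[ri]]))
    n <- nrow(g)
    data.frame(
      chrom = g$chrom[1],
      start_bp = floor(min(g$start) / 1e6) * 1e6,
      end_bp = ceiling(max(if (is.null(g$end)) g$start else g$end) / 1e6) *
        1e6,
      n_trans = n, n_down = sum(g$class == "down"),
      n_notdt = sum(g$class == "not_DT"),
      mean_fpkm_test = mean(g$fpkm_test),
      mean_logfc = mean(g$logfc))
  })
  res <- do.call(rbind, calls)
  res[res$n_trans >= min_genes, , drop = FALSE]
}

#' Class ratio over an explicit chromosomal region
#'
#' @param records DT table with `chrom`, `start`, `class`.
#' @param chrom chromosome name.
#' @param start,end region bounds in bp (genes counted by start position,
#'   inclusive of both bounds).
#' @param class DT class to count (`"up"`, `"down"`, `"not_DT"`).
#' @return list with `count_class`, `count_transcribed` and `ratio` (rounded
#'   to 2 decimals; NA when the region holds no transcribed gene).
#' @export
region_ratio <- function(records, chrom, start, end, class) {
  r <- records[records$chrom == chrom & records$start >= start &
               records$start <= end, , drop = FALSE]
  n <- nrow(r)
  k <- sum(r$class == class)
  list(count_class = k, count_transcribed = n,
       ratio = if (n > 0) round(k / n, 2) else NA_real_)
}

#' Write a window track as bedGraph (0-based half-open)
#' @param wm a [window_metrics()] data.frame.
#' @param metric metric column to export.
#' @param path output file.
#' @export
write_bedgraph <- function(wm, metric, path) {
  v <- wm[[metric]]
  keep <- !is.na(v)
  df <- data.frame(wm$chrom[keep], wm$win_start[keep], wm$win_end[keep],
                   v[keep])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s", metric), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
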