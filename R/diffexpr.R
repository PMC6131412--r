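# Differential-transcription core: transcribed-gene filtering (CPM > 1),
# TMM between-sample normalization, NB GLM likelihood-ratio testing with
# Cox-Reid dispersion estimation, BH FDR control and class labelling, and
# CPM/FPKM conversion.  Written as a transparent stand-in for the classic
# count-based DE toolchain; correctness is established against hand-computed
# worked examples and simulation-based parameter recovery, not bit
# compatibility with any particular library.

#' Gene-level count matrix with sample metadata
#'
#' @param counts non-negative integer matrix, genes x samples, with dimnames.
#' @param samples data.frame with columns `sample`, `group`, `replicate`;
#'   rows match `colnames(counts)`.
#' @export
count_matrix <- function(counts, samples) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count_matrix: counts must have gene and sample dimnames")
  if (any(counts < 0)) stop("count_matrix: negative counts")
  if (!all(colnames(counts) == samples$sample))
    stop("count_matrix: samples do not match count columns")
  if (any(is.na(samples$group))) stop("count_matrix: every sample needs a group")
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s n=%d", names(table(x$samples$group)),
                            table(x$samples$group)), collapse = ", ")))
  invisible(x)
}

#' Subset a count matrix by genes and/or samples
#' @param x a [count_matrix()]
#' @param genes gene ids to keep (NULL = all)
#' @param groups group labels whose samples to keep (NULL = all)
#' @export
subset_counts <- function(x, genes = NULL, groups = NULL) {
  keep_s <- if (is.null(groups)) rep(TRUE, ncol(x$counts))
            else x$samples$group %in% groups
  if (!is.null(groups) && !all(groups %in% x$samples$group))
    stop("subset_counts: unknown group label: ",
         paste(setdiff(groups, x$samples$group), collapse = ", "))
  keep_g <- if (is.null(genes)) rep(TRUE, nrow(x$counts))
            else rownames(x$counts) %in% genes
  count_matrix(x$counts[keep_g, keep_s, drop = FALSE],
               x$samples[keep_s, , drop = FALSE])
}

## ---- TMM normalization --------------------------------------------------

# Single-pair TMM factor: trimmed (30% on M, 5% on A), precision-weighted
# mean of log2 expression ratios against the reference column.
.tmm_pair <- function(obs, ref, lib_obs, lib_ref,
                      logratio_trim = 0.3, sum_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(NA_real_)
  o <- obs[keep]; r <- ref[keep]
  m <- log2((o / lib_obs) / (r / lib_ref))
  a <- 0.5 * log2((o / lib_obs) * (r / lib_ref))
  w <- (lib_obs - o) / (lib_obs * o) + (lib_ref - r) / (lib_ref * r)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  sel <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(sel)) return(NA_real_)
  2^(sum(m[sel] / w[sel]) / sum(1 / w[sel]))
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: per-sample scaling factors from precision-weighted
#' means of log2 count ratios against a reference sample, after trimming the
#' most extreme 30% of log-ratios (M) and 5% of absolute intensities (A).
#' Factors are rescaled to geometric mean 1; effective library size =
#' library size x factor.
#'
#' @param x a [count_matrix()].
#' @param ref reference sample (column index or name); by default the sample
#'   whose upper-quartile CPM is closest to the mean across samples.
#' @param logratio_trim,sum_trim trim fractions on M and A.
#' @return data.frame with `sample`, `lib_size`, `factor`, `eff_lib_size`.
#' @export
tmm_factors <- function(x, ref = NULL, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- x$counts
  lib <- colSums(counts)
  if (any(lib == 0)) stop("tmm_factors: sample with zero library size")
  if (is.null(ref)) {
    f75 <- apply(t(counts) / lib, 1, stats::quantile, probs = 0.75)
    ref <- which.min(abs(f75 - mean(f75)))
  } else if (is.character(ref)) ref <- match(ref, colnames(counts))
  f <- vapply(seq_len(ncol(counts)), function(i)
    .tmm_pair(counts[, i], counts[, ref], lib[i], lib[ref],
              logratio_trim, sum_trim), numeric(1))
  if (anyNA(f)) {
    warning("tmm_factors: sample(s) share no co-expressed genes with the ",
            "reference; factor set to 1: ",
            paste(colnames(counts)[is.na(f)], collapse = ", "))
    f[is.na(f)] <- 1
  }
  f <- f / exp(mean(log(f)))
  data.frame(sample = colnames(counts), lib_size = unname(lib),
             factor = f, eff_lib_size = unname(lib) * f,
             stringsAsFactors = FALSE)
}

## ---- CPM / FPKM ---------------------------------------------------------

#' Counts per million (effective-library-size normalized)
#' @param x a [count_matrix()]
#' @param factors output of [tmm_factors()] on the same samples.
#' @return genes x samples matrix of CPM values.
#' @export
cpm <- function(x, factors) {
  eff <- factors$eff_lib_size[match(colnames(x$counts), factors$sample)]
  if (anyNA(eff)) stop("cpm: factors missing for some samples")
  if (any(eff == 0)) stop("cpm: zero effective library size")
  t(t(x$counts) / eff) * 1e6
}

#' Fragments per kilobase per million (length-normalized)
#' @param x a [count_matrix()]
#' @param factors output of [tmm_factors()].
#' @param lengths named vector of gene lengths in bp (> 0).
#' @return genes x samples matrix of FPKM values.
#' @export
fpkm <- function(x, factors, lengths) {
  len <- lengths[rownames(x$counts)]
  if (anyNA(len))
    stop("fpkm: missing length for gene(s): ",
         paste(utils::head(rownames(x$counts)[is.na(len)], 5), collapse = ", "))
  if (any(len <= 0)) stop("fpkm: gene lengths must be > 0")
  cpm(x, factors) * 1e3 / len
}

#' Per-group means of a per-sample expression matrix
#' @param mat genes x samples matrix (CPM or FPKM)
#' @param samples sample metadata matching its columns
#' @return genes x groups matrix of row means
#' @export
group_means <- function(mat, samples) {
  gs <- unique(samples$group)
  out <- vapply(gs, function(g)
    rowMeans(mat[, samples$group == g, drop = FALSE]), numeric(nrow(mat)))
  colnames(out) <- gs
  out
}

#' Transcribed-gene filter: group-mean CPM above threshold in either contrast
#' group
#'
#' @param x a [count_matrix()].
#' @param factors output of [tmm_factors()].
#' @param groups the two contrast group labels.
#' @param threshold CPM threshold (strict `>`), default 1.
#' @return character vector of retained gene ids.
#' @export
filter_transcribed <- function(x, factors, groups, threshold = 1) {
  if (!all(groups %in% x$samples$group))
    stop("filter_transcribed: unknown group label: ",
         paste(setdiff(groups, x$samples$group), collapse = ", "))
  cm <- cpm(x, factors)
  gm <- group_means(cm, x$samples)[, groups, drop = FALSE]
  rownames(x$counts)[apply(gm > threshold, 1, any)]
}

## ---- NB GLM fitting -----------------------------------------------------

# Vectorized single-intercept NB fit with offsets, one row per gene.
# Returns per-gene intercept (log mean at offset 0), log-likelihood and
# Fisher information.  Newton-Raphson on the intercept; beta floored so that
# all-zero genes get an essentially zero mean with finite log-likelihood.
.nb_fit <- function(Y, offset, phi, max_iter = 50L, tol = 1e-10) {
  G <- nrow(Y); S <- ncol(Y)
  phi <- rep_len(phi, G)
  eo <- exp(offset)
  beta <- log((rowSums(Y) + 0.1) / sum(eo))
  beta_min <- log(1e-8) - max(offset)
  allzero <- rowSums(Y) == 0           # boundary MLE: mean -> 0
  beta[allzero] <- beta_min
  conv <- allzero
  for (it in seq_len(max_iter)) {
    mu <- exp(beta) %o% eo
    denom <- 1 + phi * mu
    U <- rowSums((Y - mu) / denom)
    info <- rowSums(mu / denom)
    delta <- U / pmax(info, 1e-12)
    delta <- pmin(pmax(delta, -3), 3)
    delta[allzero] <- 0
    at_floor <- beta + delta <= beta_min
    beta <- pmax(beta + delta, beta_min)
    conv <- conv | abs(delta) < tol | at_floor
    if (all(abs(delta) < tol | allzero | at_floor)) break
  }
  mu <- exp(beta) %o% eo
  size <- 1 / phi
  ll <- rowSums(stats::dnbinom(Y, size = size, mu = pmax(mu, 1e-12),
                               log = TRUE))
  info <- rowSums(mu / (1 + phi * mu))
  list(beta = beta, loglik = ll, info = info, converged = conv)
}

# Group-wise NB fit: independent intercepts per group (factor model with a
# log link separates into per-group fits).  Returns total log-likelihood and
# the Cox-Reid adjustment term 0.5 * sum(log info_g).
.nb_fit_groups <- function(Y, offset, phi, groups) {
  gl <- unique(groups)
  ll <- numeric(nrow(Y)); cr <- numeric(nrow(Y))
  conv <- rep(TRUE, nrow(Y))
  betas <- matrix(NA_real_, nrow(Y), length(gl),
                  dimnames = list(NULL, gl))
  for (g in gl) {
    j <- groups == g
    fit <- .nb_fit(Y[, j, drop = FALSE], offset[j], phi)
    ll <- ll + fit$loglik
    cr <- cr + 0.5 * log(fit$info + 1e-8)
    conv <- conv & fit$converged
    betas[, g] <- fit$beta
  }
  list(loglik = ll, cr = cr, converged = conv, betas = betas)
}

#' Estimate NB dispersion: common (Cox-Reid profile likelihood) and tagwise
#' (shrunk toward common)
#'
#' The common dispersion maximizes the summed Cox-Reid adjusted profile
#' likelihood (APL) across genes with group means profiled out.  Tagwise
#' estimates maximize, on a dispersion grid around the common value, the
#' gene's APL plus `prior_df` times the average APL across genes, which
#' shrinks noisy per-gene estimates toward the common value.  All estimates
#' are floored at 1e-6.
#'
#' @param x a [count_matrix()] (already subset to the contrast samples).
#' @param factors output of [tmm_factors()].
#' @param genes gene ids to use (default all rows).
#' @param prior_df prior degrees of freedom for tagwise shrinkage.
#' @return list with `common`, `tagwise` (named vector), `prior_df`.
#' @export
estimate_dispersion <- function(x, factors, genes = NULL, prior_df = 20) {
  if (!is.null(genes)) x <- subset_counts(x, genes = genes)
  if (max(table(x$samples$group)) < 2)
    stop("estimate_dispersion: no group has >= 2 replicates; ",
         "supply a fixed dispersion to test_dt() instead")
  Y <- x$counts
  eff <- factors$eff_lib_size[match(colnames(Y), factors$sample)]
  offset <- log(eff)
  groups <- x$samples$group
  apl <- function(log_phi)
    with(.nb_fit_groups(Y, offset, exp(log_phi), groups), loglik - cr)
  opt <- stats::optimize(function(lp) sum(apl(lp)),
                         interval = log(c(1e-6, 5)), maximum = TRUE)
  common <- max(exp(opt$maximum), 1e-6)
  grid <- unique(pmin(pmax(common * 2^seq(-8, 8, length.out = 25), 1e-6), 20))
  apl_mat <- vapply(log(grid), apl, numeric(nrow(Y)))
  obj <- apl_mat + prior_df * matrix(colMeans(apl_mat), nrow(Y),
                                     length(grid), byrow = TRUE)
  tagwise <- grid[max.col(obj, ties.method = "first")]
  names(tagwise) <- rownames(Y)
  list(common = common, tagwise = pmax(tagwise, 1e-6), prior_df = prior_df)
}

#' NB GLM likelihood-ratio test of differential transcription
#'
#' Per gene, a negative-binomial log-linear model with offset
#' `log(effective library size)` and a two-level group factor is compared to
#' the intercept-only null by a 1-df likelihood-ratio chi-square test.
#' BH adjustment across tested genes; classes: `up` (q < alpha, logFC > 0),
#' `down` (q < alpha, logFC < 0), else `not_DT`.  The reported logFC is
#' log2(test / reference) of normalized group mean counts with a 0.125
#' pseudo-count per group mean, so fully silenced genes get large finite
#' negative values.
#'
#' @param x a [count_matrix()].
#' @param factors output of [tmm_factors()].
#' @param dispersion result of [estimate_dispersion()], or a numeric
#'   (scalar or per-gene) dispersion.
#' @param group_ref,group_test reference and test group labels (logFC is
#'   test over reference).
#' @param genes gene ids to test (typically from [filter_transcribed()]).
#' @param alpha FDR threshold for class labels.
#' @return data.frame: `gene_id`, `logfc`, `pvalue`, `qvalue`, `class`,
#'   `converged`.
#' @export
test_dt <- function(x, factors, dispersion, group_ref, group_test,
                    genes = NULL, alpha = 0.05) {
  x <- subset_counts(x, genes = genes, groups = c(group_ref, group_test))
  Y <- x$counts
  eff <- factors$eff_lib_size[match(colnames(Y), factors$sample)]
  offset <- log(eff)
  groups <- x$samples$group
  phi <- if (is.list(dispersion)) {
    p <- dispersion$tagwise[rownames(Y)]
    p[is.na(p)] <- dispersion$common
    p
  } else rep_len(dispersion, nrow(Y))
  phi <- pmax(phi, 1e-6)

  full <- .nb_fit_groups(Y, offset, phi, groups)
  null <- .nb_fit(Y, offset, phi)
  stat <- pmax(2 * (full$loglik - null$loglik), 0)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  bad <- !(full$converged & null$converged)
  if (any(bad)) {
    warning("test_dt: ", sum(bad), " gene(s) did not converge; p set to 1: ",
            paste(utils::head(rownames(Y)[bad], 5), collapse = ", "))
    p[bad] <- 1
  }
  q <- bh_adjust(p)

  norm_counts <- t(t(Y) / eff) * exp(mean(log(eff)))
  m_ref <- rowMeans(norm_counts[, groups == group_ref, drop = FALSE])
  m_test <- rowMeans(norm_counts[, groups == group_test, drop = FALSE])
  logfc <- log2((m_test + 0.125) / (m_ref + 0.125))
  class <- ifelse(q < alpha & logfc > 0, "up",
           ifelse(q < alpha & logfc < 0, "down", "not_DT"))
  data.frame(gene_id = rownames(Y), logfc = logfc, pvalue = p, qvalue = q,
             class = class, converged = !bad,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p vector of p-values in \[0, 1\]; NAs are propagated.
#' @return adjusted p-values, input order preserved, monotone in p.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("bh_adjust: p-values outside [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  n <- length(pv)
  if (n > 0) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(n / (n:1) * pv[o]))[ro]
  }
  q
}

## ---- summaries ----------------------------------------------------------

#' Contrast summary from class counts
#'
#' Tabulates transcribed / not-DT / DT / up / down counts with percentages of
#' the transcribed total, rounded to 2 decimals.
#'
#' @param n_transcribed,n_up,n_down class counts (up + down <= transcribed).
#' @return data.frame with `category`, `count`, `pct`.
#' @export
contrast_summary <- function(n_transcribed, n_up, n_down) {
  n_dt <- n_up + n_down
  if (n_dt > n_transcribed)
    stop("contrast_summary: up + down exceeds transcribed")
  cnt <- c(transcribed = n_transcribed, not_DT = n_transcribed - n_dt,
           DT = n_dt, up = n_up, down = n_down)
  data.frame(category = names(cnt), count = unname(cnt),
             pct = round(unname(cnt) / n_transcribed * 100, 2),
             stringsAsFactors = FALSE)
}

#' Contrast summary from a DT result table
#' @param records output of [test_dt()] (transcribed genes of one contrast).
#' @export
summarize_contrast <- function(records) {
  contrast_summary(nrow(records), sum(records$class == "up"),
                   sum(records$class == "down"))
}

#' Genes with FPKM exactly zero in every replicate of a group
#' @param fpkm_mat genes x samples FPKM matrix.
#' @param samples sample metadata matching its columns.
#' @param group group label.
#' @param genes restrict to these gene ids (default all rows).
#' @export
count_silenced <- function(fpkm_mat, samples, group, genes = NULL) {
  j <- samples$group == group
  if (!any(j)) stop("count_silenced: empty group ", group)
  m <- fpkm_mat[, j, drop = FALSE]
  if (!is.null(genes)) m <- m[rownames(m) %in% genes, , drop = FALSE]
  rownames(m)[rowSums(m != 0) == 0]
}

#' Bin group-mean FPKM values into detection classes
#'
#' Half-open bins `[e_i, e_{i+1})`; values below the first edge are labelled
#' `"not detectable"`, the last bin is open-ended.
#'
#' @param values non-negative group-mean FPKM values.
#' @param edges increasing bin edges, default `c(1, 5, 20)` giving bins
#'   `1-5`, `5-20`, `>=20`.
#' @return factor of bin labels (names kept from `values`).
#' @export
expression_bins <- function(values, edges = c(1, 5, 20)) {
  if (is.unsorted(edges, strictly = TRUE))
    stop("expression_bins: edges must be strictly increasing")
  labs <- c("not detectable",
            paste0(edges[-length(edges)], "-", edges[-1]),
            paste0(">=", edges[length(edges)]))
  idx <- findInterval(values, edges) + 1L
  structure(factor(labs[idx], levels = labs), names = names(values))
}
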