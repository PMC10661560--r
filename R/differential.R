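#' Spike-in (RRPM) normalization
#'
#' Reference-adjusted reads per million: per-feature raw counts are scaled
#' by the number of reads mapping to the exogenous spike-in chromatin
#' (added in fixed proportion before immunoprecipitation), so that signal
#' is comparable across libraries even when global occupancy changes.
#'
#' @param counts numeric vector or matrix of raw per-feature counts
#'   (features x samples).
#' @param spikein_total spike-in read total per library (scalar for a
#'   vector, one per column for a matrix).
#' @return densities on the RRPM scale: `counts * 1e6 / spikein_total`.
#' @export
rrpm_normalize <- function(counts, spikein_total) {
  if (any(spikein_total <= 0)) stop("spike-in read total must be > 0")
  if (is.matrix(counts)) {
    if (length(spikein_total) == 1L) {
      spikein_total <- rep(spikein_total, ncol(counts))
    }
    if (length(spikein_total) != ncol(counts)) {
      stop("one spike-in total per sample column required")
    }
    sweep(counts, 2L, spikein_total / 1e6, "/")
  } else {
    counts * 1e6 / spikein_total
  }
}

new_differential_table <- function(ids, wt_mean, mut_mean, M, A, log2FC, p,
                                   fdr, call) {
  data.frame(
    feature_id = ids, wt_mean = wt_mean, mut_mean = mut_mean,
    M = M, A = A, log2FC = log2FC, p = p, fdr = fdr,
    call = call, stringsAsFactors = FALSE
  )
}

.condition_mean <- function(x) {
  if (is.matrix(x)) rowMeans(x) else as.numeric(x)
}

#' Differential ChIP signal under spike-in normalization
#'
#' Replicates are averaged per condition first; a feature is called when
#' `|log2FC| > fc_threshold` and the larger condition mean exceeds
#' `density_threshold` (the abundance gate keeps near-empty features out
#' regardless of their ratio).
#'
#' @param wt,mut RRPM densities for wild type and mutant: vectors or
#'   replicate matrices (features x replicates) with identical, named rows.
#' @param pseudocount added to both means before the log ratio (bounds the
#'   fold change at zero signal).
#' @param fc_threshold log2 fold-change cutoff (default 1).
#' @param density_threshold minimum of `max(wt_mean, mut_mean)` (default 5
#'   RRPM).
#' @return data.frame per feature with means, M/A, log2FC and
#'   `call` in `{"up","down","unchanged"}` (p and fdr are NA on this path;
#'   calling is threshold-only).
#' @export
call_differential_spikein <- function(wt, mut, pseudocount = 1,
                                      fc_threshold = 1,
                                      density_threshold = 5) {
  ids <- if (is.matrix(wt)) rownames(wt) else names(wt)
  ids_mut <- if (is.matrix(mut)) rownames(mut) else names(mut)
  wt_mean <- .condition_mean(wt)
  mut_mean <- .condition_mean(mut)
  if (length(wt_mean) != length(mut_mean) ||
      (!is.null(ids) && !is.null(ids_mut) && !identical(ids, ids_mut))) {
    stop("wild-type and mutant feature sets do not match")
  }
  if (is.null(ids)) ids <- paste0("feature_", seq_along(wt_mean))
  m <- log2(mut_mean + pseudocount) - log2(wt_mean + pseudocount)
  a <- (log2(mut_mean + pseudocount) + log2(wt_mean + pseudocount)) / 2
  passes <- abs(m) > fc_threshold & pmax(wt_mean, mut_mean) > density_threshold
  call <- ifelse(passes & m > 0, "up", ifelse(passes, "down", "unchanged"))
  new_differential_table(ids, wt_mean, mut_mean, m, a, m,
                         NA_real_, NA_real_, call)
}

#' Differential ChIP signal from replicated per-million densities
#'
#' M/A statistics with a z-test whose variance is pooled across features
#' within bins of similar abundance: with duplicate-level replication a
#' per-feature variance is uninformative, so features are grouped into
#' `n_bins` equal-occupancy bins by A and the within-condition variance of
#' log2 densities is pooled per bin. A feature is called when `|M| >
#' m_threshold` and `p < p_threshold`.
#'
#' @param wt,mut matrices of per-million normalized densities, features x
#'   replicates (>= 2 replicates each).
#' @param pseudocount added before logs.
#' @param m_threshold,p_threshold call thresholds (defaults 1, 0.05).
#' @param n_bins number of A-bins for variance pooling (default 20).
#' @return data.frame per feature with means, M, A, p, and call.
#' @export
call_differential_mvalue <- function(wt, mut, pseudocount = 1,
                                     m_threshold = 1, p_threshold = 0.05,
                                     n_bins = 20) {
  if (!is.matrix(wt) || !is.matrix(mut) || ncol(wt) < 2L || ncol(mut) < 2L) {
    stop(">= 2 replicates per condition required; ",
         "use call_differential_spikein() for unreplicated spike-in data")
  }
  if (nrow(wt) != nrow(mut)) stop("feature sets do not match")
  ids <- rownames(wt)
  if (is.null(ids)) ids <- paste0("feature_", seq_len(nrow(wt)))

  lwt <- log2(wt + pseudocount)
  lmut <- log2(mut + pseudocount)
  wt_mean <- rowMeans(wt); mut_mean <- rowMeans(mut)
  m <- log2(mut_mean + pseudocount) - log2(wt_mean + pseudocount)
  a <- (log2(mut_mean + pseudocount) + log2(wt_mean + pseudocount)) / 2

  # per-feature within-condition variance of log2 densities
  v_feat <- (apply(lwt, 1L, stats::var) + apply(lmut, 1L, stats::var)) / 2
  n_bins <- max(1L, min(n_bins, floor(nrow(wt) / 2)))
  bin <- ceiling(rank(a, ties.method = "first") / (nrow(wt) / n_bins))
  bin <- pmin(pmax(bin, 1L), n_bins)
  v_bin <- tapply(v_feat, bin, mean)
  v <- as.numeric(v_bin[as.character(bin)])
  v <- pmax(v, 1e-8)

  z <- m / sqrt(v * (1 / ncol(wt) + 1 / ncol(mut)))
  p <- 2 * stats::pnorm(-abs(z))
  passes <- abs(m) > m_threshold & p < p_threshold
  call <- ifelse(passes & m > 0, "up", ifelse(passes, "down", "unchanged"))
  new_differential_table(ids, wt_mean, mut_mean, m, a, m, p,
                         bh_adjust(p), call)
}

#' Differential expression from replicated count matrices
#'
#' Counts are normalized to counts per million (or per kilobase per
#' million when exon lengths are given), all-zero features are dropped
#' (their ids are reported in the `filtered` attribute), and the log2
#' fold change of condition means is tested with a normal approximation
#' whose variance uses one moment-matched overdispersion factor shared
#' across genes (`var = mu + phi * mu^2`). Calls require `|log2FC| >
#' fc_threshold` and BH FDR < `fdr_threshold`.
#'
#' @param counts integer matrix, genes x samples, with rownames.
#' @param design character/factor of length `ncol(counts)` with exactly
#'   two levels; the first level is treated as the reference (wild type).
#' @param exon_lengths optional per-gene lengths in bp for FPKM-style
#'   normalization.
#' @param pseudocount added to normalized means before logs.
#' @param fc_threshold,fdr_threshold call thresholds (defaults 1, 0.05).
#' @return data.frame per retained gene with means, log2FC, p, fdr, call;
#'   attribute `filtered` lists all-zero gene ids.
#' @export
call_differential_expression <- function(counts, design, exon_lengths = NULL,
                                         pseudocount = 1, fc_threshold = 1,
                                         fdr_threshold = 0.05) {
  if (!is.factor(design)) design <- factor(design, levels = unique(design))
  if (nlevels(design) != 2L) stop("design must have exactly two conditions")
  if (length(design) != ncol(counts)) stop("one condition per sample required")
  if (any(table(design) < 2L)) {
    stop("each condition needs >= 2 replicates")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("gene_", seq_len(nrow(counts)))
  }

  zero <- rowSums(counts) == 0
  filtered <- rownames(counts)[zero]
  counts <- counts[!zero, , drop = FALSE]

  norm <- sweep(counts, 2L, colSums(counts) / 1e6, "/")
  if (!is.null(exon_lengths)) {
    exon_lengths <- exon_lengths[!zero]
    norm <- norm / (exon_lengths / 1e3)
  }

  ref <- levels(design)[1L]
  wt <- norm[, design == ref, drop = FALSE]
  mut <- norm[, design != ref, drop = FALSE]
  wt_mean <- rowMeans(wt); mut_mean <- rowMeans(mut)
  lfc <- log2(mut_mean + pseudocount) - log2(wt_mean + pseudocount)
  a <- (log2(mut_mean + pseudocount) + log2(wt_mean + pseudocount)) / 2

  # moment-matched common overdispersion, var = mu + phi mu^2, pooled over
  # genes (per-gene variances are uninformative at duplicate-level n)
  v_wt <- apply(wt, 1L, stats::var); v_mut <- apply(mut, 1L, stats::var)
  mu_all <- c(wt_mean, mut_mean); v_all <- c(v_wt, v_mut)
  keep <- mu_all > 0
  phi <- sum(v_all[keep] - mu_all[keep]) / sum(mu_all[keep]^2)
  phi <- max(phi, 0)

  # delta-method variance of log2(mean + c) per condition
  vlog <- function(mu, n) {
    (mu + phi * mu^2) / n / ((mu + pseudocount)^2) / log(2)^2
  }
  v <- vlog(wt_mean, ncol(wt)) + vlog(mut_mean, ncol(mut))
  z <- lfc / sqrt(pmax(v, 1e-12))
  p <- 2 * stats::pnorm(-abs(z))
  fdr <- bh_adjust(p)
  passes <- abs(lfc) > fc_threshold & fdr < fdr_threshold
  call <- ifelse(passes & lfc > 0, "up", ifelse(passes, "down", "unchanged"))
  out <- new_differential_table(rownames(counts), wt_mean, mut_mean,
                                lfc, a, lfc, p, fdr, call)
  attr(out, "filtered") <- filtered
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values in the input order (delegates to
#'   `stats::p.adjust(method = "BH")` after validation).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Label genes directly repressed by the factor
#'
#' A gene is a direct target when the repressive mark is called down in
#' the mutant and its expression is called up: the conjunction used to
#' define genes whose repression is attributable to the factor itself.
#'
#' @param mark_diff differential table for the mark (gene-indexed).
#' @param expr_diff differential table for expression (gene-indexed).
#' @return character vector of direct-target gene ids.
#' @export
label_direct_targets <- function(mark_diff, expr_diff) {
  down <- mark_diff$feature_id[mark_diff$call == "down"]
  up <- expr_diff$feature_id[expr_diff$call == "up"]
  sort(intersect(down, up))
}
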