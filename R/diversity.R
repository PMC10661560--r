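.window_id <- function(chrom, start, end) sprintf("%s:%d-%d", chrom, start, end)

#' Classify subgenome regions from pairwise alignments
#'
#' Reciprocal alignment segments strictly longer than `min_len` bp define
#' homologous regions. Each base of a query chromosome is `homo3` when
#' homologous to both other subgenomes, `homo2` when to exactly one, and
#' `specific` otherwise; `homo3` bases that fall inside supplied synteny
#' blocks are additionally flagged homoeologous (`homoeo3`, a subset of
#' homo3 by construction). Coordinates are 0-based half-open.
#'
#' @param segments data.frame with columns `qchrom, qstart, qend, schrom,
#'   sstart, send, aligned, matched, mismatched, reciprocal`.
#' @param chrom_table data.frame `chrom, subgenome, length` covering every
#'   chromosome referenced.
#' @param synteny optional data.frame of blocks with `chrom, start, end`
#'   on query coordinates.
#' @param min_len homologous-region length cutoff in bp; strict
#'   inequality (default 400, i.e. a 400 bp segment does not qualify).
#' @param query_subgenome restrict classification to the chromosomes of
#'   one subgenome (subject chromosomes may still come from the full
#'   table); NULL classifies every chromosome.
#' @return data.frame of disjoint intervals `chrom, start, end, class,
#'   homoeo3` partitioning each classified chromosome.
#' @export
classify_alignment_regions <- function(segments, chrom_table, synteny = NULL,
                                       min_len = 400,
                                       query_subgenome = NULL) {
  need <- c("qchrom", "qstart", "qend", "schrom", "aligned",
            "matched", "mismatched", "reciprocal")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop("segments missing column: ", miss[1L])
  sub_of <- stats::setNames(chrom_table$subgenome, chrom_table$chrom)
  len_of <- stats::setNames(chrom_table$length, chrom_table$chrom)
  if (nrow(segments)) {
    if (any(!segments$qchrom %in% chrom_table$chrom) ||
        any(!segments$schrom %in% chrom_table$chrom)) {
      stop("segment on chromosome absent from chromosome table")
    }
    if (any(segments$qend > len_of[segments$qchrom])) {
      stop("alignment segment extends past chromosome end")
    }
  }
  hom <- segments[segments$reciprocal & segments$aligned > min_len, ,
                  drop = FALSE]
  subgenomes <- unique(chrom_table$subgenome)
  query_chroms <- if (is.null(query_subgenome)) chrom_table$chrom else
    chrom_table$chrom[chrom_table$subgenome == query_subgenome]

  out <- lapply(query_chroms, function(ch) {
    L <- len_of[[ch]]
    own <- sub_of[[ch]]
    others <- setdiff(subgenomes, own)
    segs <- hom[hom$qchrom == ch, , drop = FALSE]
    n_hom <- S4Vectors::Rle(0L, L)
    for (s in others) {
      ss <- segs[sub_of[segs$schrom] == s, , drop = FALSE]
      cov <- IRanges::coverage(
        IRanges::IRanges(ss$qstart + 1L, ss$qend), width = L
      )
      n_hom <- n_hom + S4Vectors::Rle(as.integer(S4Vectors::runValue(cov) > 0),
                                      S4Vectors::runLength(cov))
    }
    synt <- S4Vectors::Rle(0L, L)
    if (!is.null(synteny)) {
      bl <- synteny[synteny$chrom == ch, , drop = FALSE]
      if (nrow(bl)) {
        cov <- IRanges::coverage(
          IRanges::IRanges(bl$start + 1L, bl$end), width = L
        )
        synt <- S4Vectors::Rle(as.integer(S4Vectors::runValue(cov) > 0),
                               S4Vectors::runLength(cov))
      }
    }
    code <- pmin(n_hom, 2L) * 2L + (synt > 0L)
    rl <- S4Vectors::runLength(code)
    rv <- as.integer(S4Vectors::runValue(code))
    ends <- cumsum(rl)
    cls <- c("specific", "specific", "homo2", "homo2", "homo3",
             "homo3")[rv + 1L]
    data.frame(chrom = ch, start = ends - rl, end = ends, class = cls,
               homoeo3 = cls == "homo3" & (rv %% 2L == 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Genome fractions per region class
#'
#' @param regions output of [classify_alignment_regions()].
#' @return named numeric vector of base-pair fractions for `specific`,
#'   `homo2`, `homo3` (these three sum to 1) and `homoeo3` (a subset of
#'   homo3).
#' @export
region_fractions <- function(regions) {
  w <- regions$end - regions$start
  total <- sum(w)
  frac <- vapply(c("specific", "homo2", "homo3"), function(cl) {
    sum(w[regions$class == cl]) / total
  }, numeric(1))
  c(frac, homoeo3 = sum(w[regions$homoeo3]) / total)
}

#' Nucleotide diversity of one window
#'
#' The estimator is the sum over segregating sites of the unbiased
#' per-site heterozygosity `2 p q n/(n-1)` divided by the window length
#' in bp, which equals the average per-bp pairwise difference across
#' haplotypes exactly.
#'
#' @param gt 0/1 haplotype matrix, sites x haplotypes (NA = missing).
#' @param window_length window width in bp.
#' @return pi per bp; NA when fewer than 2 callable haplotypes exist at
#'   every site and the matrix has < 2 haplotype columns.
#' @export
nucleotide_diversity <- function(gt, window_length) {
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L)
  if (ncol(gt) < 2L) return(NA_real_)
  if (nrow(gt) == 0L) return(0)
  n <- rowSums(!is.na(gt))
  p <- rowMeans(gt, na.rm = TRUE)
  ok <- n >= 2L
  if (!any(ok)) return(NA_real_)
  het <- 2 * p[ok] * (1 - p[ok]) * n[ok] / (n[ok] - 1)
  sum(het) / window_length
}

#' Sliding-window nucleotide diversity
#'
#' Non-overlapping windows (step = width) tiling each chromosome; the
#' final partial window is flagged. Windows without segregating sites are
#' monomorphic in the sample and get pi = 0 (a window is missing only
#' when no genotype data exist at all).
#'
#' @param gt 0/1 haplotype matrix, sites x haplotypes.
#' @param pos 0-based site positions, one per row of `gt`.
#' @param chrom chromosome per site.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param width window width in bp (default 100).
#' @return data.frame `window_id, chrom, start, end, pi, n_haplotypes,
#'   partial`.
#' @export
windowed_pi <- function(gt, pos, chrom, chrom_lengths, width = 100) {
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = 1L)
  n_hap <- ncol(gt)
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq.int(0L, max(L - 1L, 0L), by = width)
    ends <- pmin(starts + width, L)
    sel <- which(chrom == ch)
    win <- findInterval(pos[sel], starts)
    het <- numeric(length(sel))
    if (length(sel)) {
      sub <- gt[sel, , drop = FALSE]
      n <- rowSums(!is.na(sub))
      p <- rowMeans(sub, na.rm = TRUE)
      het <- ifelse(n >= 2L, 2 * p * (1 - p) * n / pmax(n - 1, 1), 0)
    }
    pi_sum <- rep(0, length(starts))
    if (length(sel)) {
      agg <- tapply(het, win, sum)
      pi_sum[as.integer(names(agg))] <- agg
    }
    pi <- if (n_hap >= 2L) pi_sum / (ends - starts) else rep(NA_real_,
                                                             length(starts))
    data.frame(
      window_id = .window_id(ch, starts, ends), chrom = ch,
      start = starts, end = ends, pi = pi, n_haplotypes = n_hap,
      partial = (ends - starts) < width, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read phased haplotypes from a VCF
#'
#' @param path VCF file (v4.2, phased biallelic GT).
#' @return list with `gt` (0/1 matrix, sites x haplotypes), `pos`
#'   (0-based), `chrom`.
#' @export
read_haplotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_chr <- vcfR::extract.gt(v, convertNA = FALSE)
  ploidy <- max(lengths(strsplit(gt_chr[!is.na(gt_chr)][1], "[|/]")), 1L)
  split_hap <- function(col) {
    col[is.na(col)] <- paste(rep(".", ploidy), collapse = "|")
    parts <- unlist(strsplit(col, "[|/]"))
    parts[parts == "."] <- NA_character_
    matrix(as.integer(parts), nrow = length(col), byrow = TRUE)
  }
  gt <- do.call(cbind, lapply(seq_len(ncol(gt_chr)), function(j) {
    split_hap(gt_chr[, j])
  }))
  list(gt = gt, pos = as.integer(vcfR::getPOS(v)) - 1L,
       chrom = vcfR::getCHROM(v))
}

#' Captured divergence of windows from homologous alignment segments
#'
#' Pools substitution columns of the homologous segments overlapping each
#' window: `mismatched / (matched + mismatched)`, prorating a segment's
#' columns by the fraction of its query span inside the window. Gap
#' columns are excluded (indels are not counted as differences). Windows
#' with no homologous segment get NA.
#'
#' @param segments homologous alignment segments (same columns as
#'   [classify_alignment_regions()]); only rows with `reciprocal` TRUE and
#'   `aligned > min_len` are used.
#' @param windows data.frame `chrom, start, end` (0-based half-open).
#' @param min_len homologous length cutoff, strict (default 400).
#' @return numeric vector of per-window divergence rates in \[0, 1\].
#' @export
captured_divergence <- function(segments, windows, min_len = 400) {
  hom <- segments[segments$reciprocal & segments$aligned > min_len, ,
                  drop = FALSE]
  mm <- rep(0, nrow(windows)); tot <- rep(0, nrow(windows))
  if (nrow(hom)) {
    win_gr <- GenomicRanges::GRanges(
      windows$chrom, IRanges::IRanges(windows$start + 1L, windows$end)
    )
    seg_gr <- GenomicRanges::GRanges(
      hom$qchrom, IRanges::IRanges(hom$qstart + 1L, hom$qend)
    )
    hits <- GenomicRanges::findOverlaps(win_gr, seg_gr)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(win_gr)[qh], IRanges::ranges(seg_gr)[sh]
    ))
    frac <- ov / (hom$qend[sh] - hom$qstart[sh])
    mm_add <- hom$mismatched[sh] * frac
    tot_add <- (hom$matched[sh] + hom$mismatched[sh]) * frac
    for (i in seq_along(qh)) {
      mm[qh[i]] <- mm[qh[i]] + mm_add[i]
      tot[qh[i]] <- tot[qh[i]] + tot_add[i]
    }
  }
  ifelse(tot > 0, mm / tot, NA_real_)
}

#' Assign diversity quadrants to windows
#'
#' Binarizes captured divergence and population diversity at the supplied
#' thresholds (defaults: per-metric medians over non-missing windows);
#' "high" requires a strict exceedance, so a window sitting exactly at a
#' threshold is "low". The jointly high quadrant is the
#' post-polyploidization further-diversified compartment and carries
#' `region_number = 2`; the other quadrants keep descriptive labels only.
#' The Spearman rank correlation between the two metrics over all
#' complete windows is reported alongside.
#'
#' @param windows data.frame with columns `pi` and `captured_divergence`
#'   (plus identifiers, carried through).
#' @param captured_threshold,pi_threshold numeric cutoffs; NULL = median
#'   of the non-missing values.
#' @return list: `windows` (input plus `captured_level`, `pi_level`,
#'   `quadrant`, `region_number`), `captured_threshold`, `pi_threshold`,
#'   `spearman_rho`, `spearman_p`, `n_complete`.
#' @export
assign_quadrants <- function(windows, captured_threshold = NULL,
                             pi_threshold = NULL) {
  cd <- windows$captured_divergence
  pi <- windows$pi
  if (all(is.na(cd))) stop("all windows are missing captured divergence")
  if (all(is.na(pi))) stop("all windows are missing pi")
  if (is.null(captured_threshold)) {
    captured_threshold <- stats::median(cd, na.rm = TRUE)
  }
  if (is.null(pi_threshold)) pi_threshold <- stats::median(pi, na.rm = TRUE)
  captured_level <- ifelse(is.na(cd), NA,
                           ifelse(cd > captured_threshold, "high", "low"))
  pi_level <- ifelse(is.na(pi), NA, ifelse(pi > pi_threshold, "high", "low"))
  quadrant <- ifelse(is.na(captured_level) | is.na(pi_level), NA,
                     paste(captured_level, pi_level, sep = "/"))
  windows$captured_level <- captured_level
  windows$pi_level <- pi_level
  windows$quadrant <- quadrant
  windows$region_number <- ifelse(!is.na(quadrant) & quadrant == "high/high",
                                 2L, NA_integer_)
  complete <- !is.na(cd) & !is.na(pi)
  ct <- suppressWarnings(
    stats::cor.test(cd[complete], pi[complete], method = "spearman",
                    exact = FALSE)
  )
  list(windows = windows, captured_threshold = captured_threshold,
       pi_threshold = pi_threshold,
       spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
       n_complete = sum(complete))
}

#' Enrichment of feature windows per diversity quadrant
#'
#' For each feature (a factor's bound windows, a mark's windows) and each
#' quadrant, fold enrichment and hypergeometric p against the labeled
#' windows as background, BH-adjusted within each feature.
#'
#' @param feature_windows named list: feature id -> character vector of
#'   window ids (must be labeled windows).
#' @param quadrants result of [assign_quadrants()] (or its `windows`
#'   data.frame, which must carry `window_id` and `quadrant`).
#' @return data.frame `feature_id, quadrant, ...enrichment columns..., q`;
#'   empty quadrants yield NA rows with a warning.
#' @export
quadrant_enrichment <- function(feature_windows, quadrants) {
  win <- if (is.list(quadrants) && !is.data.frame(quadrants)) {
    quadrants$windows
  } else {
    quadrants
  }
  win <- win[!is.na(win$quadrant), , drop = FALSE]
  background <- win$window_id
  quads <- c("low/low", "low/high", "high/low", "high/high")
  rows <- lapply(names(feature_windows), function(f) {
    do.call(rbind, lapply(quads, function(qd) {
      ann <- win$window_id[win$quadrant == qd]
      if (length(ann) == 0L) {
        warning("quadrant ", qd, " is empty")
        return(data.frame(feature_id = f, quadrant = qd, query_size = NA,
                          annotation_size = 0L,
                          background_size = length(background),
                          overlap = NA, fold = NA_real_,
                          log2_fold = NA_real_, p = NA_real_))
      }
      res <- hypergeometric_enrichment(feature_windows[[f]], ann, background)
      cbind(feature_id = f, quadrant = qd, res)
    }))
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (f in unique(out$feature_id)) {
    sel <- out$feature_id == f & !is.na(out$p)
    out$q[sel] <- bh_adjust(out$p[sel])
  }
  rownames(out) <- NULL
  out
}
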