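# deterministic per-component sub-seeds: adding a component never
# perturbs the draws of earlier ones
.sub_seed <- function(seed, k) {
  as.integer((abs(as.double(seed)) * 7919 + k * 104729) %% 2147483629)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a synthetic allopolyploid world with planted ground truth
#'
#' Generates, from one seeded stream, a complete test bed for the
#' buffering-analysis pipeline: homoeolog groups with per-subgenome copy
#' counts, gene models laid out without overlap, a trans-factor binding
#' panel in which the planted factor follows a logistic model with a
#' log-odds preference for non-sc genes, a repressive mark co-localized
#' with the planted factor, ChIP read counts with spike-in libraries for
#' wild-type/mutant and pre/post-infection conditions, expression counts,
#' pairwise subgenome alignment segments whose divergence is elevated
#' around marked targets, a resequenced population whose window mutation
#' rate is coupled to that divergence, and a panel of contrast signatures
#' with one planted infection-matched contrast. The `manifest` element
#' records every planted parameter for recovery tests.
#'
#' @param config a [world_config()].
#' @return object of class `world_bundle`; see the manifest element for
#'   the ground truth.
#' @export
simulate_world <- function(config) {
  validate_world_config(config)
  cf <- config
  S <- length(cf$subgenomes)

  ## --- orthogroups and gene layout -----------------------------------
  og <- .with_seed(.sub_seed(cf$seed, 1L), {
    n <- cf$n_orthogroups
    is_sc <- stats::runif(n) < cf$fraction_sc
    counts <- matrix(1L, n, S)
    idx <- which(!is_sc)
    if (length(idx)) {
      draw <- function(m) {
        matrix(sample(0:3, m * S, replace = TRUE,
                      prob = cf$copy_number_weights), m, S)
      }
      counts[idx, ] <- draw(length(idx))
      repeat {
        bad <- idx[rowSums(counts[idx, , drop = FALSE]) == 0 |
                     rowSums(counts[idx, , drop = FALSE] == 1L) == S]
        if (!length(bad)) break
        counts[bad, ] <- draw(length(bad))
      }
    }
    ids <- sprintf("OG%05d", seq_len(n))
    rownames(counts) <- ids
    colnames(counts) <- cf$subgenomes
    list(ids = ids, counts = counts, is_sc = is_sc)
  })
  classes <- classify_orthogroup(og$counts)
  classes$counts <- apply(og$counts, 1L, paste, collapse = ",")

  genes <- do.call(rbind, lapply(seq_len(S), function(s) {
    cc <- og$counts[, s]
    keep <- cc > 0
    data.frame(
      gene_id = sprintf("%s_%s%d", rep(og$ids[keep], cc[keep]),
                        cf$subgenomes[s],
                        unlist(lapply(cc[keep], seq_len), use.names = FALSE)),
      orthogroup_id = rep(og$ids[keep], cc[keep]),
      subgenome = cf$subgenomes[s], stringsAsFactors = FALSE
    )
  }))
  genes$is_non_sc <- !og$is_sc[match(genes$orthogroup_id, og$ids)]

  pitch <- cf$gene_length_bp + cf$intergenic_bp
  chrom_rows <- list(); k <- 0L
  genes$chrom <- NA_character_; genes$start <- NA_integer_
  for (s in cf$subgenomes) {
    gi <- which(genes$subgenome == s)
    per <- ceiling(length(gi) / cf$chrom_per_subgenome)
    for (cidx in seq_len(cf$chrom_per_subgenome)) {
      on_chrom <- gi[seq_along(gi) > (cidx - 1L) * per &
                       seq_along(gi) <= cidx * per]
      ch <- sprintf("chr%d%s", cidx, s)
      genes$chrom[on_chrom] <- ch
      genes$start[on_chrom] <- cf$intergenic_bp +
        (seq_along(on_chrom) - 1L) * pitch
      k <- k + 1L
      chrom_rows[[k]] <- data.frame(
        chrom = ch, subgenome = s,
        length = cf$intergenic_bp + length(on_chrom) * pitch,
        stringsAsFactors = FALSE
      )
    }
  }
  genes$end <- genes$start + cf$gene_length_bp
  chrom_table <- do.call(rbind, chrom_rows)
  rownames(genes) <- NULL

  ## --- trans-factor binding ------------------------------------------
  factor_ids <- sprintf("TF%03d", seq_len(cf$n_factors))
  planted <- factor_ids[cf$planted_factor_index]
  ng <- nrow(genes)
  binding <- .with_seed(.sub_seed(cf$seed, 2L), {
    A <- matrix(0L, ng, cf$n_factors,
                dimnames = list(genes$gene_id, factor_ids))
    p_planted <- stats::plogis(
      stats::qlogis(cf$baseline_binding_rate) +
        cf$planted_logodds_effect * genes$is_non_sc
    )
    for (j in seq_len(cf$n_factors)) {
      pj <- if (j == cf$planted_factor_index) p_planted else
        rep(cf$baseline_binding_rate, ng)
      A[, j] <- stats::rbinom(ng, 1L, pj)
    }
    A
  })

  ## --- repressive mark and ChIP libraries ----------------------------
  mark <- .with_seed(.sub_seed(cf$seed, 3L), {
    bound <- binding[, planted] == 1L
    mark_target <- bound & stats::runif(ng) < cf$mark_colocalization
    mu_bg <- stats::rlnorm(ng, log(30), 0.5)
    mu_tg <- stats::rlnorm(ng, log(300), 0.3)
    mu_wt <- ifelse(mark_target, mu_tg, mu_bg)
    defense <- mark_target & stats::runif(ng) < cf$fraction_defense
    mu <- data.frame(
      gene_id = genes$gene_id,
      wt = mu_wt,
      mut = mu_wt * ifelse(mark_target, 2^cf$mutant_mark_drop_log2, 1),
      pre = mu_wt,
      post = mu_wt * ifelse(defense, 2^cf$infection_mark_drop_log2, 1),
      stringsAsFactors = FALSE
    )
    conds <- c("wt", "mut", "pre", "post")
    samples <- expand.grid(replicate = seq_len(cf$n_replicates),
                           condition = conds, stringsAsFactors = FALSE)
    samples <- samples[, c("condition", "replicate")]
    samples$sample_id <- sprintf("mark_%s_%d", samples$condition,
                                 samples$replicate)
    samples$spikein_total <- round(cf$spikein_total_reads *
                                     exp(stats::rnorm(nrow(samples), 0, 0.05)))
    samples$focal_total <- round(samples$spikein_total * 100 *
                                   exp(stats::rnorm(nrow(samples), 0, 0.05)))
    counts <- vapply(seq_len(nrow(samples)), function(l) {
      m <- mu[[samples$condition[l]]] * samples$spikein_total[l] / 1e6
      stats::rnbinom(ng, mu = m, size = 1 / cf$nb_dispersion)
    }, numeric(ng))
    dimnames(counts) <- list(genes$gene_id, samples$sample_id)
    list(mark_target = mark_target, defense = defense, mu = mu,
         samples = samples, counts = counts)
  })

  ## --- expression libraries ------------------------------------------
  expr <- .with_seed(.sub_seed(cf$seed, 4L), {
    mu_wt <- stats::rlnorm(ng, log(200), 1)
    mu <- data.frame(
      gene_id = genes$gene_id,
      wt = mu_wt,
      mut = mu_wt * ifelse(mark$mark_target, 2^cf$mutant_expr_gain_log2, 1),
      pre = mu_wt,
      post = mu_wt * ifelse(mark$defense, 2^cf$mutant_expr_gain_log2, 1),
      stringsAsFactors = FALSE
    )
    conds <- c("wt", "mut", "pre", "post")
    samples <- expand.grid(replicate = seq_len(cf$n_replicates),
                           condition = conds, stringsAsFactors = FALSE)
    samples <- samples[, c("condition", "replicate")]
    samples$sample_id <- sprintf("expr_%s_%d", samples$condition,
                                 samples$replicate)
    counts <- vapply(seq_len(nrow(samples)), function(l) {
      stats::rnbinom(ng, mu = mu[[samples$condition[l]]],
                     size = 1 / cf$nb_dispersion)
    }, numeric(ng))
    dimnames(counts) <- list(genes$gene_id, samples$sample_id)
    list(mu = mu, samples = samples, counts = counts)
  })

  ## --- alignment landscape on the focal subgenome --------------------
  focal <- cf$subgenomes[1L]
  others <- cf$subgenomes[-1L]
  land <- .with_seed(.sub_seed(cf$seed, 5L), {
    fch <- chrom_table[chrom_table$subgenome == focal, , drop = FALSE]
    seg_rows <- list(); win_rows <- list(); tile_rows <- list()
    for (r in seq_len(nrow(fch))) {
      ch <- fch$chrom[r]
      cidx <- as.integer(sub("chr(\\d+).*", "\\1", ch))
      partner_len <- vapply(others, function(s) {
        chrom_table$length[chrom_table$chrom == sprintf("chr%d%s", cidx, s)]
      }, numeric(1))
      usable <- min(fch$length[r], partner_len)
      n_tiles <- floor(usable / cf$tile_bp)
      type <- sample(names(cf$region_mix), n_tiles, replace = TRUE,
                     prob = cf$region_mix)
      d <- ifelse(type == "specific", 0, stats::rbeta(n_tiles, 2, 18))
      # divergence is elevated around marked planted targets
      tg <- genes[genes$chrom == ch & mark$mark_target, , drop = FALSE]
      if (nrow(tg)) {
        hit <- unique(unlist(lapply(seq_len(nrow(tg)), function(i) {
          seq.int(floor(tg$start[i] / cf$tile_bp),
                  floor((tg$end[i] - 1L) / cf$tile_bp)) + 1L
        })))
        hit <- hit[hit >= 1L & hit <= n_tiles]
        d[hit] <- pmin(d[hit] * 2, 0.45)
      }
      qstart <- (seq_len(n_tiles) - 1L) * cf$tile_bp
      qend <- qstart + cf$tile_bp
      # one segment per homologous tile x partner subgenome (homo2 tiles
      # align to the first partner only), drawn vectorized
      for (si in seq_along(others)) {
        ti <- if (si == 1L) which(type != "specific") else
          which(type == "homo3")
        if (!length(ti)) next
        mm <- stats::rbinom(length(ti), cf$tile_bp, d[ti])
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          qchrom = ch, qstart = qstart[ti], qend = qend[ti],
          schrom = sprintf("chr%d%s", cidx, others[si]),
          sstart = qstart[ti], send = qend[ti], aligned = cf$tile_bp,
          matched = cf$tile_bp - mm, mismatched = mm, reciprocal = TRUE,
          stringsAsFactors = FALSE
        )
      }
      # decoys exercising the filters: short reciprocal and long
      # non-reciprocal segments over specific tiles (must not count)
      spec <- which(type == "specific")
      if (length(spec) >= 2L) {
        ti <- spec[seq_len(min(4L, length(spec)))]
        short <- seq_along(ti) %% 2L == 0L
        alen <- ifelse(short, 350L, cf$tile_bp)
        mm <- stats::rbinom(length(ti), alen, 0.1)
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          qchrom = ch, qstart = qstart[ti], qend = qstart[ti] + alen,
          schrom = sprintf("chr%d%s", cidx, others[1L]),
          sstart = qstart[ti], send = qstart[ti] + alen, aligned = alen,
          matched = alen - mm, mismatched = mm, reciprocal = !short,
          stringsAsFactors = FALSE
        )
      }
      tile_rows[[length(tile_rows) + 1L]] <- data.frame(
        chrom = ch, start = qstart, end = qend, type = type,
        divergence = d, stringsAsFactors = FALSE
      )
      # per-window truth (windows tile the whole chromosome)
      L <- fch$length[r]
      wstart <- seq.int(0L, L - 1L, by = cf$window_bp)
      wend <- pmin(wstart + cf$window_bp, L)
      tile_of <- floor(wstart / cf$tile_bp) + 1L
      wd <- ifelse(tile_of <= n_tiles, d[tile_of], 0)
      wtype <- ifelse(tile_of <= n_tiles, type[tile_of], "specific")
      win_rows[[length(win_rows) + 1L]] <- data.frame(
        window_id = .window_id(ch, wstart, wend), chrom = ch,
        start = wstart, end = wend, region = wtype, true_divergence = wd,
        theta = cf$base_theta * (1 + cf$divergence_coupling * wd),
        stringsAsFactors = FALSE
      )
    }
    list(segments = do.call(rbind, seg_rows),
         tiles = do.call(rbind, tile_rows),
         windows = do.call(rbind, win_rows))
  })
  synteny <- do.call(rbind, lapply(
    which(chrom_table$subgenome == focal), function(r) {
      data.frame(block_id = paste0("block_", chrom_table$chrom[r]),
                 chrom = chrom_table$chrom[r], start = 0L,
                 end = floor(chrom_table$length[r] * cf$synteny_fraction),
                 stringsAsFactors = FALSE)
    }))

  ## --- population haplotypes -----------------------------------------
  vcf <- .with_seed(.sub_seed(cf$seed, 6L), {
    w <- land$windows
    n_hap <- 2L * cf$n_accessions
    n_sites <- stats::rpois(nrow(w), 3 * w$theta * (w$end - w$start))
    widx <- rep(seq_len(nrow(w)), n_sites)
    pos <- w$start[widx] +
      floor(stats::runif(length(widx)) * (w$end[widx] - w$start[widx]))
    chrom <- w$chrom[widx]
    dup <- duplicated(paste(chrom, pos))
    chrom <- chrom[!dup]; pos <- pos[!dup]
    ord <- order(match(chrom, unique(w$chrom)), pos)
    chrom <- chrom[ord]; pos <- pos[ord]
    p <- stats::runif(length(pos), 0.05, 0.95)
    gt <- matrix(stats::rbinom(length(pos) * n_hap, 1L,
                               rep(p, each = n_hap)),
                 ncol = n_hap, byrow = TRUE)
    if (cf$missingness > 0) {
      gt[stats::runif(length(gt)) < cf$missingness] <- NA_integer_
    }
    list(gt = gt, pos = as.integer(pos), chrom = chrom,
         accessions = sprintf("acc%03d", seq_len(cf$n_accessions)))
  })

  ## --- contrast signatures -------------------------------------------
  contrasts <- .with_seed(.sub_seed(cf$seed, 7L), {
    defense_ids <- genes$gene_id[mark$defense]
    size <- min(max(length(defense_ids), 50L), nrow(genes))
    ids <- sprintf("contrast_%02d", seq_len(cf$n_contrasts))
    planted_contrast <- sample(ids, 1L)
    sets <- lapply(ids, function(id) {
      if (id == planted_contrast) {
        core <- sample(defense_ids, ceiling(0.8 * length(defense_ids)))
        rest <- setdiff(genes$gene_id, defense_ids)
        noise <- sample(rest, min(ceiling(0.1 * size), length(rest)))
        sort(unique(c(core, noise)))
      } else {
        sort(sample(genes$gene_id, size))
      }
    })
    names(sets) <- ids
    list(sets = sets, planted = planted_contrast)
  })

  ## --- peaks ----------------------------------------------------------
  pk <- which(binding == 1L, arr.ind = TRUE)
  binding_peaks <- data.frame(
    chrom = genes$chrom[pk[, 1L]],
    start = genes$start[pk[, 1L]] + floor(cf$gene_length_bp * 0.3),
    end = genes$start[pk[, 1L]] + ceiling(cf$gene_length_bp * 0.7),
    name = factor_ids[pk[, 2L]], stringsAsFactors = FALSE
  )
  binding_peaks <- binding_peaks[order(binding_peaks$name,
                                       binding_peaks$chrom,
                                       binding_peaks$start), ]
  rownames(binding_peaks) <- NULL
  mt <- which(mark$mark_target)
  mark_peaks <- data.frame(
    chrom = genes$chrom[mt],
    start = genes$start[mt] + floor(cf$gene_length_bp * 0.3),
    end = genes$start[mt] + ceiling(cf$gene_length_bp * 0.7),
    name = "H3K27me3", stringsAsFactors = FALSE
  )

  cf_json <- unclass(cf)
  # jsonlite drops names of atomic vectors; store weight vectors as objects
  cf_json$copy_number_weights <- as.list(cf$copy_number_weights)
  cf_json$region_mix <- as.list(cf$region_mix)
  manifest <- list(
    config = cf_json,
    notes = paste("binding-preference and release effect sizes are",
                  "calibration choices of the generator, not estimates"),
    orthogroups = classes,
    planted_factor = planted,
    binding = lapply(stats::setNames(factor_ids, factor_ids), function(f) {
      genes$gene_id[binding[, f] == 1L]
    }),
    mark_targets = genes$gene_id[mark$mark_target],
    defense_genes = genes$gene_id[mark$defense],
    expected_mark = mark$mu,
    expected_expression = expr$mu,
    windows = land$windows,
    planted_contrast = contrasts$planted
  )

  structure(
    list(config = cf, orthogroup_classes = classes,
         orthogroup_counts = og$counts, genes = genes,
         chrom_table = chrom_table, binding = binding,
         factor_ids = factor_ids, planted_factor = planted,
         binding_peaks = binding_peaks, mark_peaks = mark_peaks,
         mark_counts = mark$counts, mark_samples = mark$samples,
         expr_counts = expr$counts, expr_samples = expr$samples,
         alignments = land$segments, tiles = land$tiles,
         synteny = synteny, windows = land$windows, vcf = vcf,
         contrasts = contrasts$sets, manifest = manifest),
    class = "world_bundle"
  )
}
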