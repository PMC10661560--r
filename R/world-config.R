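#' Configuration of a synthetic allopolyploid world
#'
#' Defines the study conditions for the planted-truth simulator: an
#' allopolyploid genome of `n_orthogroups` homoeolog groups over
#' `subgenomes`, a panel of `n_factors` trans-factors of which one (the
#' planted factor) binds non-sc homoeologs with a configurable log-odds
#' preference, a repressive mark co-localizing with that factor, mutant
#' and infection conditions that release the mark, a resequenced
#' population whose per-window mutation rate is coupled to the divergence
#' captured between subgenomes, and negative-binomial read counts.
#' Setting `planted_logodds_effect = 0` (and the release effects to 0)
#' yields a null world for calibration.
#'
#' @param n_orthogroups number of homoeolog groups.
#' @param subgenomes subgenome labels, in slot order.
#' @param chrom_per_subgenome chromosomes per subgenome.
#' @param gene_length_bp,intergenic_bp gene body length and spacing (bp).
#' @param fraction_sc probability that a group is a balanced sc-triad.
#' @param copy_number_weights weights over copy counts 0..3 per subgenome,
#'   conditional on the group being non-sc (draws of all-zero or balanced
#'   1:1:1 are rejected and redrawn).
#' @param n_factors number of trans-factors in the binding panel.
#' @param planted_factor_index which factor carries the planted effect.
#' @param planted_logodds_effect log-odds increment for the planted
#'   factor's binding probability at non-sc genes (0 = null world).
#' @param baseline_binding_rate binding probability of any factor at an
#'   sc gene (and of decoys everywhere).
#' @param mark_colocalization probability that a planted-factor-bound
#'   gene carries the repressive mark.
#' @param mutant_mark_drop_log2 log2 change of mark level at marked
#'   targets in the factor-knockout mutant (negative).
#' @param mutant_expr_gain_log2 log2 change of expression at marked
#'   targets in the mutant (positive).
#' @param fraction_defense fraction of marked targets labeled "defense".
#' @param infection_mark_drop_log2 log2 mark change at defense genes
#'   after infection (negative); defense genes also gain expression by
#'   `mutant_expr_gain_log2` post-infection.
#' @param n_accessions resequenced accessions (phased diploid, so 2x
#'   haplotypes).
#' @param base_theta per-bp population diversity rate at zero divergence.
#' @param divergence_coupling multiplier linking captured divergence d to
#'   the window mutation rate `base_theta * (1 + coupling * d)`.
#' @param nb_dispersion negative-binomial dispersion (var = mu + phi
#'   mu^2).
#' @param spikein_total_reads nominal spike-in reads per ChIP library.
#' @param n_replicates replicates per condition.
#' @param n_contrasts pathogen-response contrast signatures (one planted).
#' @param window_bp diversity window width (100 bp, the analysis
#'   convention).
#' @param tile_bp alignment-tile width for region classes (> 400 bp so
#'   homologous tiles pass the length filter).
#' @param region_mix proportions of specific/homo2/homo3 tiles.
#' @param synteny_fraction leading fraction of each chromosome inside the
#'   synteny block (homoeo3 = homo3 within it).
#' @param missingness per-genotype missing probability (default 0).
#' @param seed integer master seed; all randomness derives from it.
#' @return validated list of class `world_config`.
#' @export
world_config <- function(n_orthogroups = 2000,
                         subgenomes = c("A", "B", "D"),
                         chrom_per_subgenome = 2,
                         gene_length_bp = 1000,
                         intergenic_bp = 500,
                         fraction_sc = 1 / 3,
                         copy_number_weights = c(`0` = 0.25, `1` = 0.40,
                                                 `2` = 0.25, `3` = 0.10),
                         n_factors = 50,
                         planted_factor_index = 1,
                         planted_logodds_effect = 1.5,
                         baseline_binding_rate = 0.15,
                         mark_colocalization = 0.8,
                         mutant_mark_drop_log2 = -2,
                         mutant_expr_gain_log2 = 1.5,
                         fraction_defense = 0.3,
                         infection_mark_drop_log2 = -2,
                         n_accessions = 20,
                         base_theta = 0.002,
                         divergence_coupling = 3,
                         nb_dispersion = 0.05,
                         spikein_total_reads = 1e6,
                         n_replicates = 2,
                         n_contrasts = 12,
                         window_bp = 100,
                         tile_bp = 500,
                         region_mix = c(specific = 0.35, homo2 = 0.15,
                                        homo3 = 0.50),
                         synteny_fraction = 0.32,
                         missingness = 0,
                         seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "world_config"
  validate_world_config(cfg)
  cfg
}

#' @rdname world_config
#' @param config a `world_config` to validate.
#' @export
validate_world_config <- function(config) {
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid configuration field '", field, "': ", why)
  }
  pos_count <- function(x) length(x) == 1L && is.finite(x) && x >= 1 &&
    x == floor(x)
  prop <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
  chk(pos_count(config$n_orthogroups), "n_orthogroups", "positive count")
  chk(length(config$subgenomes) >= 2L &&
        !anyDuplicated(config$subgenomes), "subgenomes",
      ">= 2 distinct labels")
  chk(pos_count(config$chrom_per_subgenome), "chrom_per_subgenome",
      "positive count")
  chk(pos_count(config$gene_length_bp), "gene_length_bp", "positive length")
  chk(pos_count(config$intergenic_bp), "intergenic_bp", "positive length")
  chk(prop(config$fraction_sc), "fraction_sc", "proportion in [0,1]")
  w <- config$copy_number_weights
  chk(length(w) == 4L && all(w >= 0) && sum(w) > 0, "copy_number_weights",
      "4 nonnegative weights over copies 0..3")
  chk(pos_count(config$n_factors), "n_factors", "positive count")
  chk(pos_count(config$planted_factor_index) &&
        config$planted_factor_index <= config$n_factors,
      "planted_factor_index", "must index one of n_factors")
  chk(is.finite(config$planted_logodds_effect), "planted_logodds_effect",
      "finite real")
  chk(prop(config$baseline_binding_rate) &&
        config$baseline_binding_rate > 0 &&
        config$baseline_binding_rate < 1, "baseline_binding_rate",
      "proportion in (0,1)")
  chk(prop(config$mark_colocalization), "mark_colocalization",
      "proportion in [0,1]")
  chk(config$mutant_mark_drop_log2 <= 0, "mutant_mark_drop_log2",
      "non-positive log2 change")
  chk(config$mutant_expr_gain_log2 >= 0, "mutant_expr_gain_log2",
      "non-negative log2 change")
  chk(prop(config$fraction_defense), "fraction_defense",
      "proportion in [0,1]")
  chk(config$infection_mark_drop_log2 <= 0, "infection_mark_drop_log2",
      "non-positive log2 change")
  chk(pos_count(config$n_accessions) && config$n_accessions >= 1,
      "n_accessions", "positive count")
  chk(config$base_theta >= 0, "base_theta", "nonnegative rate")
  chk(config$divergence_coupling >= 0, "divergence_coupling",
      "nonnegative real")
  chk(config$nb_dispersion > 0, "nb_dispersion", "positive real")
  chk(config$spikein_total_reads >= 1, "spikein_total_reads",
      "positive count")
  chk(pos_count(config$n_replicates), "n_replicates", "positive count")
  chk(pos_count(config$n_contrasts), "n_contrasts", "positive count")
  chk(pos_count(config$window_bp), "window_bp", "positive length")
  chk(pos_count(config$tile_bp) && config$tile_bp > 400 &&
        config$tile_bp %% config$window_bp == 0, "tile_bp",
      "> 400 bp and a multiple of window_bp")
  chk(length(config$region_mix) == 3L && all(config$region_mix >= 0) &&
        sum(config$region_mix) > 0, "region_mix",
      "3 nonnegative proportions (specific/homo2/homo3)")
  chk(prop(config$synteny_fraction), "synteny_fraction",
      "proportion in [0,1]")
  chk(prop(config$missingness), "missingness", "proportion in [0,1]")
  chk(length(config$seed) == 1L && is.finite(config$seed) &&
        config$seed == floor(config$seed), "seed", "integer")
  invisible(config)
}
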