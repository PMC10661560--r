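#' Reference species ladder for phylostratigraphic assignment
#'
#' Ordered list of divergence nodes: a gene's phylostratum is the
#' earliest (smallest-index) node whose species set contains a detectable
#' ortholog, so PS1 holds the evolutionarily oldest genes and the last
#' stratum the focal-lineage-restricted ones. The default ladder follows
#' the dicot-to-Triticeae ordering used for hexaploid wheat: PS1
#' Arabidopsis thaliana, PS2 Zea mays, PS3 Oryza sativa, PS4 Brachypodium
#' distachyon, PS5 Hordeum vulgare, PS6 Secale cereale, PS7 Triticum
#' urartu + Aegilops tauschii, PS8 Triticum turgidum, PS9 focal-only.
#'
#' @param nodes named list: stratum name -> character vector of species;
#'   the final stratum is reserved for genes with no ortholog outside the
#'   focal species and must be an empty species set.
#' @return object of class `species_ladder`.
#' @export
species_ladder <- function(nodes = NULL) {
  if (is.null(nodes)) {
    nodes <- list(
      PS1 = "Arabidopsis_thaliana",
      PS2 = "Zea_mays",
      PS3 = "Oryza_sativa",
      PS4 = "Brachypodium_distachyon",
      PS5 = "Hordeum_vulgare",
      PS6 = "Secale_cereale",
      PS7 = c("Triticum_urartu", "Aegilops_tauschii"),
      PS8 = "Triticum_turgidum",
      PS9 = character(0)
    )
  }
  species <- unlist(nodes, use.names = FALSE)
  if (anyDuplicated(species)) {
    stop("species sets of ladder strata must be disjoint: ",
         species[duplicated(species)][1L])
  }
  if (length(nodes[[length(nodes)]]) != 0L) {
    stop("the deepest stratum must be the focal-only node (empty set)")
  }
  structure(list(nodes = nodes, strata = names(nodes)),
            class = "species_ladder")
}

#' Assign genes to phylostrata from ortholog presence
#'
#' @param presence logical matrix genes x species (TRUE = the gene's
#'   orthogroup contains >= 1 gene of that species), or a named logical
#'   vector for a single gene.
#' @param ladder a [species_ladder()].
#' @return data.frame `gene_id, stratum_index, stratum, supporting_species`
#'   (comma-separated species of the assigned node present for the gene).
#'   Genes with no ortholog outside the focal species fall in the deepest
#'   stratum.
#' @export
assign_phylostratum <- function(presence, ladder) {
  if (!is.matrix(presence)) {
    presence <- matrix(presence, nrow = 1L,
                       dimnames = list("gene_1", names(presence)))
  }
  unknown <- setdiff(colnames(presence),
                     unlist(ladder$nodes, use.names = FALSE))
  if (length(unknown)) {
    stop("species absent from ladder: ", unknown[1L])
  }
  k <- length(ladder$strata)
  idx <- rep(k, nrow(presence))
  support <- rep("", nrow(presence))
  for (s in rev(seq_len(k - 1L))) {
    sp <- intersect(ladder$nodes[[s]], colnames(presence))
    if (length(sp) == 0L) next
    hit <- rowSums(presence[, sp, drop = FALSE]) > 0
    support[hit] <- apply(presence[hit, sp, drop = FALSE], 1L, function(z) {
      paste(sp[z], collapse = ",")
    })
    idx[hit] <- s
  }
  ids <- rownames(presence)
  if (is.null(ids)) ids <- paste0("gene_", seq_len(nrow(presence)))
  data.frame(gene_id = ids, stratum_index = idx,
             stratum = ladder$strata[idx],
             supporting_species = support, stringsAsFactors = FALSE)
}

#' Ortholog presence matrix from an orthogroup table
#'
#' A gene counts as present in species S when its orthogroup contains at
#' least one gene of S.
#'
#' @param og an `orthogroups` object parsed with outgroup `species`
#'   columns.
#' @return logical matrix, focal genes x species.
#' @export
presence_from_orthogroups <- function(og) {
  if (length(og$species) == 0L) {
    stop("orthogroup table has no outgroup species columns")
  }
  gt <- orthogroup_gene_table(og)
  og_presence <- vapply(og$members, function(mem) {
    vapply(og$species, function(s) length(mem[[s]]) > 0L, logical(1))
  }, logical(length(og$species)))
  og_presence <- t(og_presence)
  rownames(og_presence) <- og$ids
  out <- og_presence[gt$orthogroup_id, , drop = FALSE]
  rownames(out) <- gt$gene_id
  out
}

#' Per-stratum enrichment of a target gene set
#'
#' For each stratum, tests over-representation of `targets` among the
#' stratum's genes by [hypergeometric_enrichment()] (stratum members as
#' the annotation set) and BH-adjusts across strata. High scores in deep
#' strata indicate expansion of marked targets in recent lineages.
#'
#' @param targets character vector of target gene ids.
#' @param strata assignment data.frame from [assign_phylostratum()].
#' @param background character vector of gene ids; `targets` must be a
#'   subset.
#' @return data.frame, one row per stratum, with enrichment columns and
#'   BH-adjusted `q`.
#' @export
stratum_enrichment <- function(targets, strata, background) {
  if (length(background) == 0L) stop("empty background")
  levels_s <- unique(strata$stratum)
  rows <- lapply(levels_s, function(s) {
    ann <- intersect(strata$gene_id[strata$stratum == s], background)
    res <- hypergeometric_enrichment(targets, ann, background)
    cbind(stratum = s, res)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
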