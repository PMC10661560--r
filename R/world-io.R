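.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.genes_to_granges <- function(genes, chrom_table) {
  seqlens <- stats::setNames(chrom_table$length, chrom_table$chrom)
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
    strand = "+", seqlengths = seqlens
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$orthogroup <- genes$orthogroup_id
  S4Vectors::mcols(gr)$subgenome <- genes$subgenome
  gr
}

.peaks_to_granges <- function(peaks) {
  gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end)
  )
  S4Vectors::mcols(gr)$name <- peaks$name
  gr
}

.write_vcf <- function(vcf, chrom_table, path) {
  n_acc <- length(vcf$accessions)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom_table$chrom,
            chrom_table$length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vcf$accessions), collapse = "\t")
  ), con)
  if (length(vcf$pos)) {
    h1 <- vcf$gt[, seq(1L, 2L * n_acc, by = 2L), drop = FALSE]
    h2 <- vcf$gt[, seq(2L, 2L * n_acc, by = 2L), drop = FALSE]
    fmt <- function(h) ifelse(is.na(h), ".", as.character(h))
    gt_str <- matrix(paste(fmt(h1), fmt(h2), sep = "|"),
                     nrow = nrow(vcf$gt))
    lines <- paste(vcf$chrom, vcf$pos + 1L, ".", "A", "T", ".", "PASS",
                   ".", "GT", apply(gt_str, 1L, paste, collapse = "\t"),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a world bundle to disk in standard formats
#'
#' Emits GFF3 gene models, BED6 binding and mark peaks, per-gene ChIP
#' density and expression count TSVs with sample sheets (including
#' spike-in totals), a phased VCF of the focal-subgenome population, the
#' orthogroup table, pairwise alignment and synteny TSVs, contrast gene
#' sets, a chromosome table and the ground-truth manifest JSON.
#' [read_world()] reproduces the bundle from these files.
#'
#' @param bundle a `world_bundle` from [simulate_world()].
#' @param directory output directory (created if needed).
#' @return (invisibly) the directory.
#' @export
write_world <- function(bundle, directory) {
  if (!inherits(bundle, "world_bundle") || is.null(bundle$genes) ||
      nrow(bundle$genes) == 0L) {
    stop("bundle is empty or not a world_bundle; nothing written")
  }
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", directory)
  }
  p <- function(f) file.path(directory, f)

  .write_tsv(bundle$chrom_table, p("chromosomes.tsv"))
  rtracklayer::export(
    .genes_to_granges(bundle$genes, bundle$chrom_table), p("genes.gff3")
  )
  rtracklayer::export(.peaks_to_granges(bundle$binding_peaks),
                      p("binding_peaks.bed"))
  rtracklayer::export(.peaks_to_granges(bundle$mark_peaks),
                      p("mark_peaks.bed"))

  mk <- data.frame(gene_id = rownames(bundle$mark_counts),
                   bundle$mark_counts, check.names = FALSE)
  .write_tsv(mk, p("mark_density.tsv"))
  .write_tsv(bundle$mark_samples, p("spikein_totals.tsv"))
  ex <- data.frame(gene_id = rownames(bundle$expr_counts),
                   bundle$expr_counts, check.names = FALSE)
  .write_tsv(ex, p("expression_counts.tsv"))
  .write_tsv(bundle$expr_samples, p("expr_samples.tsv"))

  focal_chroms <- bundle$chrom_table[
    bundle$chrom_table$subgenome == bundle$config$subgenomes[1L], ,
    drop = FALSE]
  .write_vcf(bundle$vcf, focal_chroms, p("population.vcf"))

  # orthogroup dialect: comma-space joined ids, empty cell = no copy
  og_tab <- data.frame(Orthogroup = bundle$orthogroup_classes$orthogroup_id,
                       stringsAsFactors = FALSE)
  for (s in bundle$config$subgenomes) {
    sel <- bundle$genes$subgenome == s
    joined <- tapply(bundle$genes$gene_id[sel],
                     bundle$genes$orthogroup_id[sel],
                     function(g) paste(sort(g), collapse = ", "))
    og_tab[[s]] <- unname(joined[og_tab$Orthogroup])
    og_tab[[s]][is.na(og_tab[[s]])] <- ""
  }
  .write_tsv(og_tab, p("orthogroups.tsv"))

  .write_tsv(bundle$alignments, p("alignments.tsv"))
  sy <- bundle$synteny
  partner <- bundle$config$subgenomes[2L]
  sy_out <- data.frame(
    block_id = sy$block_id, chromA = sy$chrom, startA = sy$start,
    endA = sy$end,
    chromB = sub(paste0(bundle$config$subgenomes[1L], "$"), partner,
                 sy$chrom),
    startB = sy$start, endB = sy$end, stringsAsFactors = FALSE
  )
  .write_tsv(sy_out, p("synteny_blocks.tsv"))

  ct <- data.frame(
    set_id = rep(names(bundle$contrasts),
                 vapply(bundle$contrasts, length, integer(1))),
    gene_id = unlist(bundle$contrasts, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  .write_tsv(ct, p("contrasts.tsv"))

  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(directory)
}

#' Read a world bundle back from disk
#'
#' @param directory a directory written by [write_world()].
#' @return a `world_bundle` equal to the one written.
#' @export
read_world <- function(directory) {
  p <- function(f) file.path(directory, f)
  if (!file.exists(p("manifest.json"))) {
    stop("no manifest.json under ", directory)
  }
  manifest <- jsonlite::read_json(p("manifest.json"), simplifyVector = TRUE)
  cf <- manifest$config
  cf$copy_number_weights <- unlist(cf$copy_number_weights)
  cf$region_mix <- unlist(cf$region_mix)
  class(cf) <- "world_config"

  chrom_table <- utils::read.delim(p("chromosomes.tsv"))
  gr <- rtracklayer::import(p("genes.gff3"))
  genes <- data.frame(
    gene_id = S4Vectors::mcols(gr)$ID,
    orthogroup_id = S4Vectors::mcols(gr)$orthogroup,
    subgenome = S4Vectors::mcols(gr)$subgenome,
    stringsAsFactors = FALSE
  )
  genes$chrom <- as.character(GenomicRanges::seqnames(gr))
  genes$start <- GenomicRanges::start(gr) - 1L
  genes$end <- GenomicRanges::end(gr)
  og_classes <- manifest$orthogroups
  genes$is_non_sc <- !og_classes$is_sc_triad[
    match(genes$orthogroup_id, og_classes$orthogroup_id)]
  genes <- genes[, c("gene_id", "orthogroup_id", "subgenome", "is_non_sc",
                     "chrom", "start", "end")]

  read_bed <- function(f) {
    g <- rtracklayer::import(p(f))
    data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
               start = GenomicRanges::start(g) - 1L,
               end = GenomicRanges::end(g),
               name = S4Vectors::mcols(g)$name, stringsAsFactors = FALSE)
  }
  binding_peaks <- read_bed("binding_peaks.bed")
  mark_peaks <- read_bed("mark_peaks.bed")

  read_mat <- function(f) {
    tab <- utils::read.delim(p(f), check.names = FALSE)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- tab[[1L]]
    m
  }
  mark_counts <- read_mat("mark_density.tsv")
  expr_counts <- read_mat("expression_counts.tsv")
  mark_samples <- utils::read.delim(p("spikein_totals.tsv"))
  expr_samples <- utils::read.delim(p("expr_samples.tsv"))

  hap <- read_haplotypes(p("population.vcf"))
  vh <- vcfR::read.vcfR(p("population.vcf"), verbose = FALSE)
  vcf <- list(gt = hap$gt, pos = hap$pos, chrom = hap$chrom,
              accessions = colnames(vh@gt)[-1L])

  og <- parse_orthogroups(p("orthogroups.tsv"), subgenomes = cf$subgenomes)
  counts <- orthogroup_counts(og)

  alignments <- utils::read.delim(p("alignments.tsv"))
  sy <- utils::read.delim(p("synteny_blocks.tsv"))
  synteny <- data.frame(block_id = sy$block_id, chrom = sy$chromA,
                        start = sy$startA, end = sy$endA,
                        stringsAsFactors = FALSE)
  ct <- utils::read.delim(p("contrasts.tsv"))
  contrasts <- split(ct$gene_id, ct$set_id)
  contrasts <- contrasts[unique(ct$set_id)]

  binding_sets <- lapply(manifest$binding, unlist)
  binding <- build_binding_matrix(binding_sets, genes$gene_id)

  structure(
    list(config = cf, orthogroup_classes = og_classes,
         orthogroup_counts = counts, genes = genes,
         chrom_table = chrom_table, binding = binding,
         factor_ids = names(binding_sets),
         planted_factor = manifest$planted_factor,
         binding_peaks = binding_peaks, mark_peaks = mark_peaks,
         mark_counts = mark_counts, mark_samples = mark_samples,
         expr_counts = expr_counts, expr_samples = expr_samples,
         alignments = alignments, tiles = NULL, synteny = synteny,
         windows = manifest$windows, vcf = vcf, contrasts = contrasts,
         manifest = manifest),
    class = "world_bundle"
  )
}
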