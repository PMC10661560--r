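#' Parse an orthogroup table
#'
#' Reads the tab-separated orthogroup dialect: first column `Orthogroup`,
#' one column per subgenome (each subgenome treated as an individual
#' genome) and optionally per outgroup species, cells holding
#' comma-space separated gene ids, empty cell meaning no copy.
#'
#' @param path TSV file path.
#' @param subgenomes character vector of subgenome column labels that must
#'   be present (default `c("A","B","D")`).
#' @param species additional allowed species columns (for
#'   phylostratigraphic presence); any other column is a format error.
#' @return object of class `orthogroups`: list with `ids`, `members`
#'   (per group, a named list label -> character vector of gene ids),
#'   `subgenomes`, `species`.
#' @export
parse_orthogroups <- function(path, subgenomes = c("A", "B", "D"),
                              species = character()) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (!"Orthogroup" %in% names(tab)) stop("missing 'Orthogroup' column")
  cols <- setdiff(names(tab), "Orthogroup")
  unknown <- setdiff(cols, c(subgenomes, species))
  if (length(unknown)) {
    stop("unknown subgenome column: ", unknown[1L])
  }
  missing_sub <- setdiff(subgenomes, cols)
  if (length(missing_sub)) {
    stop("subgenome column absent from file: ", missing_sub[1L])
  }
  split_cell <- function(x) {
    if (is.na(x) || !nzchar(trimws(x))) character(0)
    else trimws(strsplit(x, ",")[[1L]])
  }
  members <- lapply(seq_len(nrow(tab)), function(i) {
    row <- lapply(cols, function(cl) split_cell(tab[[cl]][i]))
    names(row) <- cols
    row
  })
  all_genes <- unlist(lapply(members, function(m) {
    unlist(m[subgenomes], use.names = FALSE)
  }), use.names = FALSE)
  if (anyDuplicated(all_genes)) {
    stop("gene id appears in more than one orthogroup: ",
         all_genes[duplicated(all_genes)][1L])
  }
  structure(
    list(ids = tab$Orthogroup, members = members,
         subgenomes = subgenomes, species = setdiff(cols, subgenomes)),
    class = "orthogroups"
  )
}

#' Per-subgenome copy counts of parsed orthogroups
#'
#' @param og an `orthogroups` object.
#' @return integer matrix, groups x subgenomes, rownames = orthogroup ids.
#' @export
orthogroup_counts <- function(og) {
  m <- vapply(og$members, function(mem) {
    vapply(og$subgenomes, function(s) length(mem[[s]]), integer(1))
  }, integer(length(og$subgenomes)))
  m <- t(m)
  dimnames(m) <- list(og$ids, og$subgenomes)
  m
}

#' Classify per-subgenome copy counts into the homoeolog grammar
#'
#' Each subgenome slot maps 0 -> "0", 1 -> "1", >= 2 -> "N"; slots are
#' joined with colons in subgenome order (A:B:D for hexaploid wheat).
#' The balanced single-copy class "1:1:1" is the sc-triad; everything
#' else is a non-sc homoeolog group. Exact counts are kept by the caller
#' for copy-number trend analyses; the label deliberately collapses
#' multiplicity to "N".
#'
#' @param counts nonnegative integer vector (one group) or matrix
#'   (groups x subgenomes).
#' @return data.frame with `label` and `is_sc_triad`; for a matrix input
#'   also `orthogroup_id` from the rownames.
#' @export
classify_orthogroup <- function(counts) {
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = 1L)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("copy counts must be nonnegative integers")
  }
  if (any(rowSums(counts) == 0)) {
    stop("orthogroup with zero copies in every subgenome")
  }
  sym <- matrix("N", nrow(counts), ncol(counts))
  sym[counts == 0] <- "0"
  sym[counts == 1] <- "1"
  label <- apply(sym, 1L, paste, collapse = ":")
  out <- data.frame(
    label = label,
    is_sc_triad = label == paste(rep("1", ncol(counts)), collapse = ":"),
    stringsAsFactors = FALSE
  )
  if (!is.null(rownames(counts))) {
    out <- cbind(data.frame(orthogroup_id = rownames(counts),
                            stringsAsFactors = FALSE), out)
  }
  out
}

#' Catalog of orthogroup classes
#'
#' Convenience wrapper: counts, class labels and count string per group.
#'
#' @param og an `orthogroups` object.
#' @return data.frame `orthogroup_id, label, is_sc_triad, counts`.
#' @export
classify_orthogroups <- function(og) {
  cn <- orthogroup_counts(og)
  out <- classify_orthogroup(cn)
  out$counts <- apply(cn, 1L, paste, collapse = ",")
  out
}

#' Gene-to-orthogroup lookup table
#'
#' @param og an `orthogroups` object.
#' @return data.frame `gene_id, orthogroup_id, subgenome`.
#' @export
orthogroup_gene_table <- function(og) {
  rows <- lapply(seq_along(og$ids), function(i) {
    mem <- og$members[[i]]
    do.call(rbind, lapply(og$subgenomes, function(s) {
      if (length(mem[[s]]) == 0L) return(NULL)
      data.frame(gene_id = mem[[s]], orthogroup_id = og$ids[i],
                 subgenome = s, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign peak intervals to genes
#'
#' A gene is a target of a factor when any peak overlaps the window
#' `[gene_start - upstream, gene_end + downstream)` on the gene's
#' chromosome. Strand-agnostic: binding over either flank or the body
#' counts. Coordinates are 0-based half-open throughout.
#'
#' @param peaks data.frame with `chrom, start, end` (0-based half-open),
#'   e.g. read from BED.
#' @param genes data.frame with `gene_id, chrom, start, end`.
#' @param upstream,downstream window extension in bp (defaults 2000/500).
#' @return character vector of target gene ids (sorted, unique). Peaks on
#'   chromosomes absent from the gene models are dropped with a warning
#'   stating how many.
#' @export
assign_targets <- function(peaks, genes, upstream = 2000, downstream = 500) {
  if (nrow(peaks) == 0L) return(character(0))
  known <- peaks$chrom %in% unique(genes$chrom)
  if (any(!known)) {
    warning(sum(!known), " peak(s) on chromosomes absent from gene models",
            " were ignored")
    peaks <- peaks[known, , drop = FALSE]
    if (nrow(peaks) == 0L) return(character(0))
  }
  peak_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end)
  )
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$start - upstream, 0L) + 1L,
                     genes$end + downstream)
  )
  hits <- GenomicRanges::findOverlaps(peak_gr, gene_gr)
  sort(unique(genes$gene_id[S4Vectors::subjectHits(hits)]))
}
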