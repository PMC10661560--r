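#' Hypergeometric gene-set enrichment
#'
#' Tests whether a query gene set overlaps an annotation set more than
#' expected under hypergeometric sampling from a stated background. The
#' enrichment score used throughout the package is `log2(fold)` where
#' `fold = (overlap/|query|) / (|annotation|/|background|)`, with the
#' background always carried in the result so it is never implicit.
#'
#' @param query character vector of gene ids (the set of interest).
#' @param annotation character vector of gene ids (the reference set,
#'   e.g. targets of one factor or members of one stratum).
#' @param background character vector of gene ids defining the universe;
#'   both `query` and `annotation` must be subsets of it.
#'
#' @return A one-row data.frame with columns `query_size`,
#'   `annotation_size`, `background_size`, `overlap`, `fold`,
#'   `log2_fold`, `p` (upper-tail hypergeometric `P(X >= overlap)`).
#' @export
hypergeometric_enrichment <- function(query, annotation, background) {
  background <- unique(as.character(background))
  query <- unique(as.character(query))
  annotation <- unique(as.character(annotation))
  if (length(background) == 0L) stop("empty background")
  if (length(query) == 0L) stop("empty query set")
  bad <- setdiff(query, background)
  if (length(bad)) stop("query genes absent from background: ", bad[1L])
  bad <- setdiff(annotation, background)
  if (length(bad)) stop("annotation genes absent from background: ", bad[1L])

  q <- length(query); a <- length(annotation); b <- length(background)
  k <- length(intersect(query, annotation))
  fold <- if (a == 0L) NA_real_ else (k / q) / (a / b)
  # P(X >= k) for X ~ Hypergeometric(white = a, black = b - a, drawn = q)
  p <- stats::phyper(k - 1L, a, b - a, q, lower.tail = FALSE)
  data.frame(
    query_size = q, annotation_size = a, background_size = b,
    overlap = k, fold = fold, log2_fold = log2(fold), p = p
  )
}

#' Match a mutant-induced signature against condition contrasts
#'
#' Ranks a panel of contrast signatures (e.g. resistant-vs-susceptible
#' up-regulated gene sets for different pathogens) by the hypergeometric
#' enrichment of a mutant-induced gene set within each contrast's up-set.
#' Ties in p are broken by descending fold, then by contrast id, so the
#' ranking is a deterministic function of its inputs.
#'
#' @param mutant_up character vector of genes induced in the mutant.
#' @param contrasts named list of character vectors, one up-set per
#'   contrast id; ids must be unique.
#' @param background character vector, the gene universe.
#'
#' @return data.frame ranked by ascending p with columns `contrast_id`,
#'   the [hypergeometric_enrichment()] columns, `q` (BH-adjusted across
#'   contrasts) and `rank`.
#' @export
match_contrasts <- function(mutant_up, contrasts, background) {
  ids <- names(contrasts)
  if (is.null(ids) || any(!nzchar(ids))) stop("contrasts must be a named list")
  if (anyDuplicated(ids)) {
    stop("duplicate contrast ids: ", ids[duplicated(ids)][1L])
  }
  rows <- lapply(ids, function(id) {
    res <- hypergeometric_enrichment(mutant_up, contrasts[[id]], background)
    cbind(contrast_id = id, res)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  ord <- order(out$p, -out$fold, out$contrast_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Descriptive statistics for a phenotype measurement
#'
#' @param values numeric vector of measurements (e.g. hyphal areas).
#' @return data.frame with `n`, `mean`, `median`, `sd` (sample, n-1
#'   denominator), `sem` (= sd/sqrt(n)).
#' @export
summarize_phenotype <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || all(is.na(values))) stop("no measurements supplied")
  values <- values[!is.na(values)]
  n <- length(values)
  s <- stats::sd(values)
  data.frame(
    n = n, mean = mean(values), median = stats::median(values),
    sd = s, sem = s / sqrt(n)
  )
}

#' Standard error of the mean from a sample SD
#'
#' Figure legends typically print integer-rounded SEMs next to the SD and
#' n; this helper reproduces that display. Rounding is half-away-from-zero
#' to match integer display conventions (R's `round` rounds half to even).
#'
#' @param sd sample standard deviation (>= 0).
#' @param n sample size (>= 1).
#' @return list with `sem` (raw) and `sem_rounded` (integer display).
#' @export
standard_error <- function(sd, n) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(sd < 0)) stop("sd must be >= 0")
  sem <- sd / sqrt(n)
  list(sem = sem, sem_rounded = trunc(sem + 0.5 * sign(sem)))
}

#' Consolidate pipeline outputs into a report bundle
#'
#' Writes each completed stage's table as TSV into `dir` plus a JSON
#' index recording which sections are present and the provenance block
#' (configuration, seeds, thresholds). Sections that were not run are
#' simply absent; rerunning with identical inputs reproduces identical
#' files.
#'
#' @param sections named list of data.frames (e.g. `class_catalog`,
#'   `factor_ranking`, `stratum_enrichment`, `quadrant_enrichment`,
#'   `differential_calls`, `direct_targets`, `contrast_ranking`).
#' @param dir output directory, created if needed.
#' @param provenance list of run metadata stored verbatim in the index.
#' @return (invisibly) the path of the JSON index.
#' @export
render_report <- function(sections, dir, provenance = list()) {
  if (!is.list(sections) || length(sections) == 0L) {
    stop("at least one stage output must be present")
  }
  if (is.null(names(sections)) || any(!nzchar(names(sections)))) {
    stop("sections must be named")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(sections)) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(sections[[nm]], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[nm] <- basename(path)
  }
  index <- list(sections = as.list(files), provenance = provenance)
  index_path <- file.path(dir, "report_index.json")
  jsonlite::write_json(index, index_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(index_path)
}
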