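# all-pairs brute-force oracle for window pi
oracle_pi <- function(gt, L) {
  n <- ncol(gt)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(gt[, i] != gt[, j])
    }
  }
  tot / choose(n, 2) / L
}

test_that("window pi equals the all-pairs average difference", {
  # trivial cases first
  expect_equal(nucleotide_diversity(matrix(0L, 3, 4), 100), 0)
  one_site <- matrix(c(0L, 1L), 1, 2)
  expect_equal(nucleotide_diversity(one_site, 100), 0.01)
  # random matrices against the brute-force oracle
  set.seed(41)
  for (i in 1:20) {
    gt <- matrix(rbinom(500, 1, runif(1, 0.1, 0.9)), 10, 50)
    expect_equal(nucleotide_diversity(gt, 100), oracle_pi(gt, 100),
                 tolerance = 1e-12)
  }
})

test_that("pi is invariant to haplotype order and allele relabeling", {
  set.seed(42)
  gt <- matrix(rbinom(300, 1, 0.4), 10, 30)
  base <- nucleotide_diversity(gt, 100)
  expect_equal(nucleotide_diversity(gt[, sample(30)], 100), base)
  expect_equal(nucleotide_diversity(1L - gt, 100), base)
})

test_that("windowed pi tiles chromosomes, flags partial windows and missing data", {
  gt <- matrix(c(0L, 0L, 1L, 1L), 2, 2)  # 2 polymorphic sites, 2 haplotypes
  pw <- windowed_pi(gt, pos = c(5L, 150L), chrom = c("c1", "c1"),
                    chrom_lengths = c(c1 = 250L), width = 100)
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$pi, c(0.01, 0.01, 0))
  expect_true(pw$partial[3])
  expect_equal(pw$end[3] - pw$start[3], 50L)
  # a single haplotype cannot yield pairwise diversity
  pw1 <- windowed_pi(matrix(0L, 1, 1), 5L, "c1", c(c1 = 100L))
  expect_true(is.na(pw1$pi))
})

test_that("captured divergence pools prorated substitution columns", {
  seg <- function(qs, qe, matched, mism, aligned = qe - qs,
                  reciprocal = TRUE) {
    data.frame(qchrom = "c1", qstart = qs, qend = qe, schrom = "c1B",
               sstart = qs, send = qe, aligned = aligned,
               matched = matched, mismatched = mism,
               reciprocal = reciprocal)
  }
  win <- data.frame(chrom = "c1", start = 0L, end = 100L)
  # identical homoeologous sequence
  expect_equal(captured_divergence(seg(0, 500, 500, 0), win), 0)
  # 5 mismatches in 100 aligned columns
  expect_equal(
    captured_divergence(seg(0, 500, 475, 25), win), 0.05
  )
  # window spanning two 50 bp segments: (3 + 1) / (50 + 50)
  segs <- rbind(seg(0, 50, 47, 3, aligned = 500),
                seg(50, 100, 49, 1, aligned = 500))
  expect_equal(captured_divergence(segs, win), 0.04)
  # windows with no homologous coverage are missing, not zero
  far <- data.frame(chrom = "c1", start = 5000L, end = 5100L)
  expect_true(is.na(captured_divergence(seg(0, 500, 500, 0), far)))
})

test_that("only reciprocal alignments strictly longer than 400 bp are homologous", {
  chroms <- data.frame(chrom = c("c1A", "c1B", "c1D"),
                       subgenome = c("A", "B", "D"),
                       length = c(2000L, 2000L, 2000L))
  seg <- function(qe, reciprocal = TRUE, schrom = "c1B") {
    data.frame(qchrom = "c1A", qstart = 0L, qend = qe, schrom = schrom,
               sstart = 0L, send = qe, aligned = qe, matched = qe - 5L,
               mismatched = 5L, reciprocal = reciprocal)
  }
  segs <- rbind(seg(399L), seg(400L), seg(401L))
  reg <- classify_alignment_regions(segs, chroms, query_subgenome = "A")
  homo <- reg[reg$class != "specific", ]
  expect_equal(nrow(homo), 1L)
  expect_equal(homo$end, 401L)
  expect_equal(homo$class, "homo2")
  # a long non-reciprocal alignment still does not count
  reg2 <- classify_alignment_regions(seg(900L, reciprocal = FALSE), chroms,
                                     query_subgenome = "A")
  expect_true(all(reg2$class == "specific"))
  # coverage by both partner subgenomes upgrades to homo3; synteny overlay
  both <- rbind(seg(600L), seg(600L, schrom = "c1D"))
  synt <- data.frame(chrom = "c1A", start = 0L, end = 300L)
  reg3 <- classify_alignment_regions(both, chroms, synteny = synt,
                                     query_subgenome = "A")
  expect_equal(reg3$class[1:2], c("homo3", "homo3"))
  expect_equal(reg3$homoeo3[1:2], c(TRUE, FALSE))
  expect_equal(reg3$end[1], 300L)
  # off-chromosome segments error
  expect_error(
    classify_alignment_regions(seg(3000L), chroms, query_subgenome = "A"),
    "past chromosome end"
  )
})

test_that("region classes partition chromosomes and respect cutoff monotonicity", {
  w <- tiny_world(seed = 44)
  focal <- w$config$subgenomes[1]
  reg <- classify_alignment_regions(w$alignments, w$chrom_table,
                                    synteny = w$synteny,
                                    query_subgenome = focal)
  widths <- tapply(reg$end - reg$start, reg$chrom, sum)
  lens <- stats::setNames(w$chrom_table$length, w$chrom_table$chrom)
  expect_equal(as.numeric(widths), as.numeric(lens[names(widths)]))
  fr <- region_fractions(reg)
  expect_equal(sum(fr[c("specific", "homo2", "homo3")]), 1)
  expect_lte(fr["homoeo3"], fr["homo3"])
  # raising the cutoff never decreases the specific fraction
  fr_strict <- region_fractions(
    classify_alignment_regions(w$alignments, w$chrom_table,
                               min_len = 600, query_subgenome = focal)
  )
  expect_gte(fr_strict["specific"], fr["specific"])
})

test_that("quadrant labels use strict thresholds and report the joint correlation", {
  win <- data.frame(
    window_id = paste0("w", 1:6), chrom = "c1",
    start = seq(0, 500, 100), end = seq(100, 600, 100),
    pi = c(0.1, 0.3, 0.2, 0.05, NA, 0.4),
    captured_divergence = c(0.02, 0.08, 0.05, 0.01, 0.03, NA)
  )
  q <- assign_quadrants(win, captured_threshold = 0.05, pi_threshold = 0.2)
  lab <- q$windows
  # exactly at a threshold is "low"
  expect_equal(lab$captured_level[3], "low")
  expect_equal(lab$pi_level[3], "low")
  expect_equal(lab$quadrant[2], "high/high")
  expect_equal(lab$region_number[2], 2L)
  expect_true(is.na(lab$quadrant[5]) && is.na(lab$quadrant[6]))
  expect_equal(q$n_complete, 4L)
  expect_true(is.finite(q$spearman_rho))
  expect_error(assign_quadrants(transform(win, pi = NA_real_)),
               "missing pi")
})

test_that("a feature covering all windows is unenriched in every quadrant", {
  set.seed(45)
  win <- data.frame(
    window_id = paste0("w", 1:400), chrom = "c1",
    start = 0L, end = 100L,
    pi = runif(400), captured_divergence = runif(400)
  )
  q <- assign_quadrants(win)
  qe <- quadrant_enrichment(list(all = win$window_id), q)
  expect_equal(qe$fold, rep(1, 4))
  expect_equal(qe$p, rep(1, 4))
})

test_that("phased VCF output is read back identically by an independent reader", {
  w <- tiny_world(seed = 46, missingness = 0.05)
  dir <- withr::local_tempdir()
  write_world(w, dir)
  hap <- read_haplotypes(file.path(dir, "population.vcf"))
  expect_identical(hap$gt, w$vcf$gt)
  expect_identical(hap$pos, w$vcf$pos)
  expect_identical(hap$chrom, w$vcf$chrom)
})
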