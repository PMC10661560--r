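test_that("RRPM scaling is linear in counts and inverse in spike-in totals", {
  expect_equal(rrpm_normalize(c(a = 10, b = 20), 1e6), c(a = 10, b = 20))
  expect_equal(rrpm_normalize(500, 2e6), 250)
  x <- matrix(1:6, 2, dimnames = list(c("g1", "g2"), NULL))
  expect_equal(rrpm_normalize(x, c(1e6, 2e6, 4e6)),
               sweep(x, 2, c(1, 2, 4), "/"))
  expect_equal(rrpm_normalize(2 * x, 1e6), 2 * rrpm_normalize(x, 1e6))
  expect_error(rrpm_normalize(x, c(0, 1e6, 1e6)), "> 0")
})

test_that("spike-in differential calls follow the fold-change and abundance gates", {
  wt <- c(g1 = 10, g2 = 4, g3 = 3)
  mut <- c(g1 = 2, g2 = 4, g3 = 0.5)
  d <- call_differential_spikein(wt, mut, pseudocount = 1)
  expect_equal(d$log2FC[1], log2(3 / 11))
  expect_equal(d$call, c("down", "unchanged", "unchanged"))
  # the third gene fails the RRPM > 5 gate regardless of its ratio
  expect_gt(abs(log2(1.5 / 4)), 0)  # ratio is modest anyway
  d2 <- call_differential_spikein(c(g1 = 3), c(g1 = 0.25), pseudocount = 1)
  expect_equal(d2$call, "unchanged")
  expect_error(call_differential_spikein(wt, mut[1:2]), "do not match")
})

test_that("replicate matrices average before the ratio and swap antisymmetrically", {
  wt <- matrix(c(8, 12), 1, 2, dimnames = list("g1", NULL))
  mut <- matrix(c(2, 3), 1, 2, dimnames = list("g1", NULL))
  d <- call_differential_spikein(wt, mut)
  expect_equal(d$M, log2(3.5) - log2(11))
  set.seed(51)
  w2 <- matrix(rexp(40, 0.1), 10, 4,
               dimnames = list(paste0("g", 1:10), NULL))
  m2 <- matrix(rexp(40, 0.1), 10, 4,
               dimnames = list(paste0("g", 1:10), NULL))
  fwd <- call_differential_spikein(w2, m2)
  rev <- call_differential_spikein(m2, w2)
  expect_equal(fwd$M, -rev$M)
  expect_equal(fwd$call == "up", rev$call == "down")
})

test_that("M-value calls require replication and detect planted mark loss", {
  wt <- matrix(c(8, 12), 1, 2, dimnames = list("g1", NULL))
  expect_error(call_differential_mvalue(wt, matrix(2, 1, 1)),
               "spike-in")
  # identical replicate sets give M = 0 and no calls
  set.seed(52)
  x <- matrix(rpois(200, 50), 100, 2,
              dimnames = list(paste0("g", 1:100), NULL))
  d0 <- call_differential_mvalue(x, x)
  expect_equal(d0$M, rep(0, 100))
  expect_true(all(d0$call == "unchanged"))
  # planted mark drop is recovered across three generator seeds
  for (s in 1:3) {
    w <- default_world(s)
    rr <- mark_rrpm(w)
    d <- call_differential_mvalue(rr$wt, rr$mut)
    tg <- d$feature_id %in% w$manifest$mark_targets
    expect_gte(mean(d$call[tg] == "down"), 0.9)
    expect_lte(mean(d$call[!tg] != "unchanged"), 0.05)
  }
})

test_that("expression calls reproduce a hand-constructed instance", {
  # the changed gene is kept small so the 8-fold shift does not move the
  # per-million scaling of the null genes
  base <- c(1000, 1200, 900, 1100, 1050, 20)
  counts <- cbind(
    wt_1 = base, wt_2 = base + c(13, -12, 14, -15, 11, 0),
    mut_1 = base * c(1, 1, 1, 1, 1, 8),
    mut_2 = (base + c(-14, 12, -11, 13, 10, 0)) * c(1, 1, 1, 1, 1, 8)
  )
  rownames(counts) <- paste0("g", 1:6)
  de <- call_differential_expression(counts, c("wt", "wt", "mut", "mut"))
  expect_equal(de$feature_id[de$call == "up"], "g6")
  expect_true(all(de$call[de$feature_id != "g6"] == "unchanged"))
  # identical count columns yield no calls
  same <- cbind(counts[, 1], counts[, 1], counts[, 1], counts[, 1])
  rownames(same) <- paste0("g", 1:6)
  de0 <- call_differential_expression(same, c("a", "a", "b", "b"))
  expect_true(all(de0$call == "unchanged"))
  # all-zero rows are excluded and reported
  withzero <- rbind(counts, g7 = 0)
  de7 <- call_differential_expression(withzero, c("wt", "wt", "mut", "mut"))
  expect_false("g7" %in% de7$feature_id)
  expect_equal(attr(de7, "filtered"), "g7")
  expect_error(
    call_differential_expression(counts[, 1:3], c("wt", "wt", "mut")),
    ">= 2 replicates"
  )
})

test_that("BH adjustment matches the step-up definition and is well-behaved", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # brute-force step-up oracle: q_(i) = min_{j >= i} p_(j) m / j
  oracle_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      j <- i:m
      q[o[i]] <- min(pmin(p[o[j]] * m / j, 1))
    }
    q
  }
  set.seed(54)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    # monotone along sorted p (step-up adjustment is not idempotent)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("direct targets are the conjunction of mark loss and expression gain", {
  mark <- data.frame(
    feature_id = paste0("g", 1:6),
    call = c("down", "down", "down", "unchanged", "up", "unchanged")
  )
  expr <- data.frame(
    feature_id = paste0("g", 1:6),
    call = c("up", "up", "unchanged", "up", "up", "unchanged")
  )
  expect_equal(label_direct_targets(mark, expr), c("g1", "g2"))
  # a sub-threshold mark change is never direct
  mark$call[1] <- "unchanged"   # e.g. M = -0.5
  expect_equal(label_direct_targets(mark, expr), "g2")
})
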