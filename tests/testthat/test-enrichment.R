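test_that("hierarchy roll-up reaches the root and detects cycles", {
  ann <- data.frame(gene_id = c("g1", "g1", "g2", "g3"),
                    domain_id = c("leaf", "mid", "leaf", "orphan"),
                    stringsAsFactors = FALSE)
  hier <- data.frame(child = c("leaf", "mid"), parent = c("mid", "root"),
                     stringsAsFactors = FALSE)
  r <- rollup_to_toplevel(ann, hier)
  expect_setequal(r$domain_id[r$gene_id == "g1"], "root")
  expect_equal(nrow(r[r$gene_id == "g1", ]), 1L)  # duplicates collapse
  expect_equal(r$domain_id[r$gene_id == "g3"], "orphan")  # no parent

  cyc <- data.frame(child = c("x", "y"), parent = c("y", "x"),
                    stringsAsFactors = FALSE)
  expect_error(rollup_to_toplevel(
    data.frame(gene_id = "g", domain_id = "x"), cyc), "cycle")

  # random 3-level forest: result equals an iterative parent-lookup fixpoint
  set.seed(71)
  roots <- sprintf("R%d", 1:4)
  mids <- sprintf("M%d", 1:8)
  leaves <- sprintf("L%d", 1:16)
  hier2 <- rbind(
    data.frame(child = mids, parent = sample(roots, 8, TRUE)),
    data.frame(child = leaves, parent = sample(mids, 16, TRUE)))
  ann2 <- data.frame(gene_id = sample(sprintf("g%d", 1:30), 60, TRUE),
                     domain_id = sample(c(roots, mids, leaves), 60, TRUE),
                     stringsAsFactors = FALSE)
  lookup <- stats::setNames(hier2$parent, hier2$child)
  fix <- ann2$domain_id
  for (k in 1:10) fix <- ifelse(fix %in% names(lookup), lookup[fix], fix)
  expect_identical(rollup_to_toplevel(ann2, hier2),
                   unique(transform(ann2, domain_id = unname(fix))))
})

test_that("rarity filter keeps domains in at least 10 genes", {
  ann <- rbind(
    data.frame(gene_id = sprintf("g%d", 1:9), domain_id = "rare"),
    data.frame(gene_id = sprintf("g%d", 1:10), domain_id = "common"))
  out <- filter_rare_domains(ann)
  expect_setequal(unique(out$domain_id), "common")
  expect_equal(nrow(filter_rare_domains(ann[0, ])), 0L)
  # counting is over distinct genes, not annotation rows
  dup <- data.frame(gene_id = rep(sprintf("g%d", 1:5), 3),
                    domain_id = "dup")
  expect_equal(nrow(filter_rare_domains(dup)), 0L)
})

test_that("log-odds statistic matches hand arithmetic", {
  t1 <- log_odds_test(30, 70, 10, 90)
  expect_equal(t1$log_odds, log(2700 / 700), tolerance = 1e-12)
  expect_equal(round(t1$log_odds, 4), 1.3499)
  # equal proportions give zero log-odds
  t0 <- log_odds_test(20, 80, 10, 40)
  expect_equal(t0$log_odds, 0)
  # label exchange flips the sign
  t2 <- log_odds_test(10, 90, 30, 70)
  expect_equal(t2$log_odds, -t1$log_odds)
  # zero cell: Haldane-Anscombe keeps the estimate finite
  tz <- log_odds_test(0, 10, 5, 5)
  expect_true(is.finite(tz$log_odds))
  expect_equal(tz$log_odds, log((0.5 * 5.5) / (10.5 * 5.5)))
  expect_error(log_odds_test(0, 0, 5, 5), "margin")
})

test_that("Fisher p equals the exhaustive hypergeometric tail sum", {
  enum_p <- function(a, b, c_, d) {
    # enumerate all tables with the same margins; two-sided by the
    # probability-mass rule
    r1 <- a + b; r2 <- c_ + d; k <- a + c_
    xs <- max(0, k - r2):min(r1, k)
    pr <- choose(r1, xs) * choose(r2, k - xs) / choose(r1 + r2, k)
    p_obs <- choose(r1, a) * choose(r2, c_) / choose(r1 + r2, k)
    sum(pr[pr <= p_obs * (1 + 1e-7)])
  }
  set.seed(73)
  for (i in 1:25) {
    a <- sample(0:15, 1); b <- sample(1:15, 1)
    c_ <- sample(0:15, 1); d <- sample(1:15, 1)
    if (a + b == 0 || c_ + d == 0) next
    t <- log_odds_test(a, b, c_, d)
    expect_equal(t$p_value, enum_p(a, b, c_, d), tolerance = 1e-9)
    # invariant under transposing the table
    tt <- stats::fisher.test(t(matrix(c(a, b, c_, d), 2, byrow = TRUE)))
    expect_equal(t$p_value, tt$p.value, tolerance = 1e-9)
  }
})

test_that("step-up FDR adjustment follows the Benjamini-Hochberg rule", {
  expect_equal(bh_correct(0.03), 0.03)
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand-computed staircase: q_i = min over j>=i of p_(j)*m/j
  p <- c(0.005, 0.049, 0.05, 0.2, 0.9)
  m <- length(p)
  hand <- sapply(seq_len(m), function(i)
    min(pmin(1, sort(p)[i:m] * m / (i:m))))
  expect_equal(bh_correct(p), hand[rank(p)])
  # monotone non-decreasing in sorted order
  set.seed(79)
  pr <- runif(50)
  expect_true(all(diff(bh_correct(pr)[order(pr)]) >= -1e-12))
  expect_error(bh_correct(c(0.1, 1.2)), "0, 1")
  expect_error(bh_correct(c(-0.1, 0.5)), "0, 1")
})

test_that("enrichment over a gene universe recovers a planted log-odds", {
  set.seed(83)
  sim <- simulate_domain_annotation(n_genes = 1000L, n_cne_genes = 200L,
                                    lor = 1.5)
  res <- enrich_all(sim$cne_genes, sim$all_genes, sim$annotations,
                    hierarchy = sim$hierarchy)
  tgt <- res[res$domain_id == sim$target_domain, ]
  expect_equal(nrow(tgt), 1L)
  expect_lt(abs(tgt$log_odds - 1.5), 0.6)  # single-run tolerance
  expect_lt(tgt$q_value, 0.05)
  # results are sorted by q then |log-odds|; one domain only: q = p
  expect_true(!is.unsorted(res$q_value))
  one <- enrich_all(sim$cne_genes, sim$all_genes,
                    sim$annotations[sim$annotations$domain_id ==
                                      "homeodomain_like_sub1", ],
                    hierarchy = sim$hierarchy)
  expect_equal(one$q_value, one$p_value)
})
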