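depth_track <- function(depths, genome) {
  g <- dplyr::arrange(genome$genes, chrom, rank)
  tibble::tibble(gene_id = g$gene_id, chrom = g$chrom, rank = g$rank,
                 depth = depths)
}

test_that("TRR calling follows the run, gap and length rules", {
  g <- toy_genome(8)
  # depth 3 everywhere: one TRR covering the chromosome
  t1 <- call_trrs(depth_track(rep(3, 8), g), g, min_copies = 3,
                  min_run = 3, max_gap = 0)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$n_genes, 8L)
  # depth 1 everywhere: nothing
  expect_equal(nrow(call_trrs(depth_track(rep(1, 8), g), g)), 0)
  # 1,1,3,3,3,3,1,1 with max_gap 0: exactly one 4-gene TRR at ranks 2-5
  t3 <- call_trrs(depth_track(c(1, 1, 3, 3, 3, 3, 1, 1), g), g,
                  min_copies = 3, min_run = 3, max_gap = 0)
  expect_equal(nrow(t3), 1)
  expect_equal(c(t3$start_rank, t3$end_rank), c(2L, 5L))
  expect_equal(t3$n_genes, 4L)
  # a single sub-threshold gene inside is tolerated with max_gap 1
  t4 <- call_trrs(depth_track(c(3, 3, 1, 3, 3, 1, 1, 3), g), g,
                  min_copies = 3, min_run = 3, max_gap = 1)
  expect_equal(nrow(t4), 1)
  expect_equal(c(t4$start_rank, t4$end_rank), c(0L, 4L))
  expect_equal(t4$n_qualifying, 4L)
  # runs shorter than min_run are discarded
  t5 <- call_trrs(depth_track(c(3, 3, 1, 1, 1, 1, 1, 1), g), g,
                  min_copies = 3, min_run = 3, max_gap = 1)
  expect_equal(nrow(t5), 0)
})

test_that("TRR calling is idempotent and chromosome-order invariant", {
  g2 <- toy_genome(12, chroms = c("chr1", "chr2"))
  d <- depth_track(c(3, 3, 3, 1, 1, 3, 3, 3, 3, 1, 3, 3), g2)
  a <- call_trrs(d, g2)
  b <- call_trrs(d[sample(nrow(d)), ], g2)
  expect_equal(a, b)
  expect_equal(call_trrs(d, g2), a)
})

test_that("window composition measures unioned genic and repeat bp", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "chr1",
    start = c(1L, 100001L), end = c(200000L, 300000L), strand = "+"
  )
  g <- annotated_genome(
    "sp", genes,
    chromosomes = tibble::tibble(chrom = c("chr1", "chr2"),
                                 length = c(1e6, 1e6)),
    repeats = tibble::tibble(chrom = "chr1", start = 700001L,
                             end = 1000000L, family = "LTR")
  )
  wins <- genome_windows(g, 1e6, 1e6)
  comp <- window_composition(g, wins)
  w1 <- comp[comp$chrom == "chr1", ]
  # overlapping genes counted once: union is 1..300000 = 0.3
  expect_equal(w1$genic_frac, 0.3)
  expect_equal(w1$repeat_frac, 0.3)
  expect_equal(w1$family_bp[[1]][["LTR"]], 3e5)
  # empty window
  w2 <- comp[comp$chrom == "chr2", ]
  expect_equal(c(w2$genic_frac, w2$repeat_frac), c(0, 0))
})

test_that("composition t test matches the pooled-variance formula", {
  r <- composition_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r$t, 3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(round(r$t, 3), 3.674)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 2 * pt(-r$t, 4))
  expect_equal(round(r$p_value, 3), 0.021)
  expect_equal(r$direction, "higher_in_trr")
  # identical groups: t = 0, p = 1
  r0 <- composition_t_test(c(2, 3, 4), c(2, 3, 4))
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 1)
  # zero variance in both groups: degenerate, no p
  rd <- composition_t_test(c(1, 1, 1), c(1, 1, 1))
  expect_true(rd$degenerate)
  expect_true(is.na(rd$p_value))
})

test_that("window-to-TRR assignment uses majority bp overlap", {
  g <- toy_genome(4)
  trrs <- tibble::tibble(chrom = "chr1", start_rank = 0L, end_rank = 1L,
                         start_bp = 1L, end_bp = 1600L,
                         n_genes = 2L, n_qualifying = 2L,
                         gene_ids = list(c("a", "b")))
  wins <- tibble::tibble(chrom = "chr1",
                         start = c(1L, 2001L), end = c(2000L, 4000L),
                         width = 2000L, partial = FALSE,
                         genic_frac = 0.5, repeat_frac = 0.1)
  asg <- assign_windows_to_trrs(wins, trrs)
  expect_equal(asg$in_trr, c(TRUE, FALSE))
})

test_that("hypergeometric enrichment is exact with BH adjustment", {
  bg <- paste0("e", 1:10)
  cats <- tibble::tibble(element_id = bg,
                         category = rep(c("X", "Y"), each = 5))
  # draw of 5 with zero X: depletion p = 1/252
  res <- hypergeom_enrichment(bg[6:10], bg, cats)
  x <- res[res$category == "X", ]
  expect_equal(x$direction, "depleted")
  expect_equal(x$p_value, 1 / 252, tolerance = 1e-12)
  # test set = background: p = 1 everywhere
  all_res <- hypergeom_enrichment(bg, bg, cats)
  expect_true(all(all_res$p_value == 1))
  # subset violation is an error
  expect_error(hypergeom_enrichment(c("zz"), bg, cats), "subset")
  # category absent from background is skipped with a warning
  cats2 <- dplyr::bind_rows(cats,
                            tibble::tibble(element_id = "nope",
                                           category = "Z"))
  expect_warning(hypergeom_enrichment(bg[1:3], bg, cats2), "skipped")
})

test_that("BH adjustment reproduces the step-up hand computation", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  # and flows through the enrichment table
  set.seed(51)
  bg <- paste0("e", 1:40)
  cats <- tibble::tibble(
    element_id = rep(bg, 2),
    category = c(rep(c("a", "b", "c", "d"), each = 10),
                 rep("e", 40)))
  res <- hypergeom_enrichment(bg[1:12], bg, cats)
  expect_equal(res$adjusted_p,
               p.adjust(res$p_value, method = "BH")[
                 order(order(res$p_value))][order(order(res$p_value))],
               tolerance = 1e-12)
  expect_true(all(res$adjusted_p >= res$p_value))
})

test_that("hypergeometric tails equal exhaustive enumeration (N <= 25)", {
  set.seed(52)
  for (i in 1:25) {
    N <- sample(8:25, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    bg <- paste0("e", 1:N)
    cats <- tibble::tibble(element_id = bg,
                           category = c(rep("C", K), rep("o", N - K)))
    test <- sample(bg, n)
    res <- hypergeom_enrichment(test, bg, cats)
    row <- res[res$category == "C", ]
    expect_equal(row$p_enrich,
                 oracle_hyper_tail(row$k_in, K, N, n, upper = TRUE),
                 tolerance = 1e-12)
    expect_equal(row$p_deplete,
                 oracle_hyper_tail(row$k_in, K, N, n, upper = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("Fisher domain tests match enumeration and the m-species rule", {
  counts <- tibble::tibble(
    species = c("s1", "s1", "s2", "s3"),
    domain = c("D1", "D2", "D1", "D1"),
    n11 = c(1, 5, 5, 5), n12 = c(1, 0, 0, 0),
    n21 = c(1, 0, 0, 0), n22 = c(1, 5, 5, 5)
  )
  out <- fisher_domain_enrichment(counts, alpha = 0.05, min_species = 2)
  per <- out$per_species
  expect_equal(per$p_value[per$species == "s1" & per$domain == "D1"], 1)
  p5 <- per$p_value[per$species == "s2"]
  expect_equal(p5, oracle_fisher_two_sided(5, 0, 0, 5), tolerance = 1e-12)
  expect_equal(round(p5, 5), 0.00794)
  # D1 significant in s2 and s3 (2 species) -> in the summary
  expect_true("D1" %in% out$summary$domain)
  expect_equal(out$summary$n_species_significant[
    out$summary$domain == "D1"], 2L)
  # random tables agree with enumeration
  set.seed(53)
  for (i in 1:15) {
    tb <- sample(0:6, 4, replace = TRUE)
    if (sum(tb) == 0) next
    res <- fisher_domain_enrichment(tibble::tibble(
      species = "s", domain = "d", n11 = tb[1], n12 = tb[2],
      n21 = tb[3], n22 = tb[4]))
    expect_equal(res$per_species$p_value,
                 oracle_fisher_two_sided(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-9)
  }
})
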