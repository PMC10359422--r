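test_that("NG86 reproduces the hand-computed synonymous example", {
  a <- strrep("AAA", 100)
  b <- paste0(strrep("AAA", 98), "AAGAAG")
  r <- ng86_pair(a, b)
  expect_equal(r$S, 100 / 3)
  expect_equal(r$Sd, 2)
  expect_equal(r$Nd, 0)
  expect_equal(r$ps, 0.06)
  expect_equal(r$ks, -0.75 * log(1 - 0.08))
  expect_equal(round(r$ks, 4), 0.0625)
  expect_false(r$saturated)
})

test_that("NG86 handles identity, symmetry and degenerate inputs", {
  s <- random_codons(40)
  set.seed(41)
  r0 <- ng86_pair(s, s)
  expect_equal(c(r0$Sd, r0$Nd, r0$ks, r0$ka), c(0, 0, 0, 0))
  a <- random_codons(30)
  b <- random_codons(30)
  expect_equal(ng86_pair(a, b), ng86_pair(b, a))
  expect_error(ng86_pair("ATG", "ATGATG"), "length")
  expect_error(ng86_pair("ATGTAAATG", "ATGATGATG"), "stop")
  # saturation flag on wildly divergent input
  sat <- ng86_pair(strrep("GGG", 50), strrep("CCA", 50))
  expect_true(sat$saturated || sat$ks > 1)
})

test_that("NG86 agrees with the brute-force oracle on random codon pairs", {
  set.seed(42)
  codons <- names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"]
  for (i in 1:60) {
    c1 <- sample(codons, 1)
    c2 <- sample(codons, 1)
    mine <- ng86_pair(c1, c2)
    orc <- oracle_ng86(c1, c2)
    expect_equal(mine$S, orc$S, tolerance = 1e-12)
    expect_equal(mine$Sd, orc$Sd, tolerance = 1e-12)
    expect_equal(mine$Nd, orc$Nd, tolerance = 1e-12)
  }
  # and on a handful of full-length sequence pairs
  for (i in 1:5) {
    a <- random_codons(25)
    b <- random_codons(25)
    mine <- ng86_pair(a, b)
    orc <- oracle_ng86(a, b)
    expect_equal(mine$ks, orc$ks, tolerance = 1e-9)
    expect_equal(mine$ka, orc$ka, tolerance = 1e-9)
  }
})

test_that("codon-aware alignment strips indels before counting", {
  a <- "ATGGCTCCTAAAGGG"
  expect_equal(align_cds(a, a)$a, a)
  b <- "ATGGCTAAAGGG"  # one codon deleted
  al <- align_cds(a, b)
  expect_equal(nchar(al$a), nchar(a) - 3)
  expect_equal(al$a, al$b)
  expect_error(align_cds("", a), "empty")
  # NG86 runs cleanly on the aligned pair
  r <- ng86_pair(al$a, al$b)
  expect_equal(r$ks, 0)
})

test_that("batch Ks matches single-pair results and skips bad CDS", {
  set.seed(43)
  cds_a <- setNames(vapply(1:5, function(i) random_codons(20),
                           character(1)), paste0("a", 1:5))
  cds_b <- setNames(vapply(1:5, function(i) random_codons(20),
                           character(1)), paste0("b", 1:5))
  cds_b["b3"] <- paste0(cds_b["b3"], "AT")  # out of frame
  pairs <- tibble::tibble(gene_a = paste0("a", 1:5),
                          gene_b = paste0("b", 1:5))
  kt <- ks_for_pairs(pairs, cds_a, cds_b)
  expect_equal(nrow(kt), 5)
  expect_true(is.na(kt$ks[3]))
  for (i in c(1, 2, 4, 5)) {
    single <- ng86_pair(cds_a[[i]], cds_b[[i]])
    expect_equal(kt$ks[i], single$ks)
    expect_equal(kt$S[i], single$S)
  }
})

test_that("block Ks summaries take medians over usable anchors", {
  kt <- tibble::tibble(
    block_id = c("b1", "b1", "b1", "b2", "b2", "b2"),
    ks = c(0.5, 0.5, 0.5, 0.4, NA, 0.6),
    ka = c(0.1, 0.1, 0.1, 0.1, NA, 0.2),
    saturated = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  s <- block_ks_summary(kt)
  expect_equal(s$median_ks[s$block_id == "b1"], 0.5)
  # saturated anchor excluded: median of {0.4, 0.6}
  expect_equal(s$median_ks[s$block_id == "b2"], 0.5)
  expect_true(s$low_confidence[s$block_id == "b2"])
  s2 <- block_ks_summary(tibble::tibble(block_id = "b", ks = c(0.1, 0.2, 0.9),
                                        ka = 0.1, saturated = FALSE))
  expect_equal(s2$median_ks, 0.2)
})

test_that("peak fitting is deterministic and recovers planted modes", {
  set.seed(44)
  x <- c(rlnorm(1200, log(0.8), 0.2), rlnorm(800, log(1.6), 0.15))
  m1 <- fit_ks_peaks(x, max_components = 4)
  m2 <- fit_ks_peaks(x, max_components = 4)
  expect_equal(m1$components, m2$components)
  peaks <- m1$components$peak_ks[m1$components$weight > 0.15]
  expect_true(any(abs(peaks - 0.8) < 0.1))
  expect_true(any(abs(peaks - 1.6) < 0.1))
  # near-degenerate data collapses to one component
  m0 <- fit_ks_peaks(rlnorm(300, log(0.5), 0.02), max_components = 3)
  expect_equal(m0$n_components, 1)
  expect_equal(m0$components$peak_ks, 0.5, tolerance = 0.05)
  expect_error(fit_ks_peaks(c(0.5, 0.6)), "at least")
})

test_that("tidy and glance expose peak-model structure", {
  set.seed(45)
  m <- fit_ks_peaks(rlnorm(200, log(0.5), 0.1))
  expect_named(tidy(m), c("mean_log", "sd_log", "weight", "peak_ks"))
  expect_equal(sum(tidy(m)$weight), 1, tolerance = 1e-6)
  g <- glance(m)
  expect_equal(g$n, 200)
})

test_that("event classification applies the sharing and ordering rules", {
  mk_model <- function(peaks, weights = NULL) {
    weights <- weights %||% rep(1 / length(peaks), length(peaks))
    structure(list(
      components = tibble::tibble(mean_log = log(peaks),
                                  sd_log = 0.1, weight = weights,
                                  peak_ks = peaks),
      n_components = length(peaks), n = 1000, bic = 0,
      ks_range = c(0.01, 3)), class = "ks_peak_model")
  }
  tree <- "((A:0.4,B:0.4):0.45,O:0.85):0.75;"
  # shared ingroup paralog peak 0.80, ortholog(A,O) 0.85, outgroup lacks it
  par <- list(A = mk_model(c(0.8, 1.6)), B = mk_model(c(0.8, 1.6)),
              O = mk_model(1.6))
  ort <- list(`A|B` = mk_model(0.4), `A|O` = mk_model(0.85),
              `B|O` = mk_model(0.85))
  ev <- classify_wg_events(par, ort, tree)
  young <- ev[abs(ev$peak_ks - 0.8) < 0.1, ]
  expect_equal(young$branch, "stem:A,B")
  expect_equal(young$order_vs_speciation, "after")
  old <- ev[abs(ev$peak_ks - 1.6) < 0.2, ]
  expect_equal(old$branch, "stem:root")
  expect_equal(old$order_vs_speciation, "before")
  # identical peak sets everywhere: no lineage-specific events
  par_same <- list(A = mk_model(1.6), B = mk_model(1.6),
                   O = mk_model(1.6))
  ev2 <- classify_wg_events(par_same, ort, tree)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$branch, "stem:root")
  # separations below min_peak_sep are indistinguishable
  par3 <- list(A = mk_model(0.84), B = mk_model(0.84), O = mk_model(3))
  ev3 <- classify_wg_events(par3, ort, tree, min_peak_sep = 0.02)
  expect_equal(ev3$order_vs_speciation[
    abs(ev3$peak_ks - 0.84) < 0.05], "indistinguishable")
})

test_that("Ks converts to time under a strict clock", {
  expect_equal(ks_to_time(0.8, 5e-9), 8e7)
  expect_equal(ks_to_time(0, 5e-9), 0)
  expect_equal(ks_to_time(0.8, 1e-8), 4e7)
  expect_error(ks_to_time(NA, 5e-9), "saturated")
  expect_error(ks_to_time(0.5, 0), "positive")
})
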