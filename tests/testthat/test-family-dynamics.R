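fam_table <- function(...) {
  rows <- list(...)
  tibble::tibble(
    family_id = unlist(lapply(rows, function(r) rep(r[[1]], r[[3]]))),
    species = unlist(lapply(rows, function(r) rep(r[[2]], r[[3]]))),
    gene_id = paste0("g", seq_len(sum(vapply(rows, function(r) r[[3]],
                                             numeric(1)))))
  )
}

test_that("family count matrices include zero rows and conserve totals", {
  tab <- fam_table(list("f1", "sp1", 3), list("f1", "sp2", 1),
                   list("f2", "sp2", 2))
  counts <- count_families(tab)
  expect_equal(counts$f1, c(3L, 1L))
  expect_equal(counts$f2, c(0L, 2L))
  # absent species gets a zero row
  counts3 <- count_families(tab, species_subset = c("sp1", "sp2", "sp3"))
  expect_equal(counts3$f1[counts3$species == "sp3"], 0L)
  # totals equal membership rows
  expect_equal(sum(as.matrix(counts[, -1])), nrow(tab))
})

test_that("expansion test matches the Student formula with flags", {
  clade <- paste0("c", 1:3)
  rest <- paste0("r", 1:3)
  tab <- fam_table(
    list("f1", "c1", 4), list("f1", "c2", 5), list("f1", "c3", 6),
    list("f1", "r1", 1), list("f1", "r2", 2), list("f1", "r3", 3),
    list("f2", "c1", 2), list("f2", "c2", 2), list("f2", "c3", 2),
    list("f2", "r1", 2), list("f2", "r2", 2), list("f2", "r3", 2)
  )
  res <- expansion_test(tab, clade, rest)
  f1 <- res[res$family_id == "f1", ]
  expect_equal(round(f1$t, 3), 3.674)
  expect_equal(round(f1$p_value, 3), 0.021)
  expect_false(f1$sig_0.01)
  # equal counts: degenerate (zero pooled variance), not p = 0
  f2 <- res[res$family_id == "f2", ]
  expect_true(f2$degenerate)
  expect_true(is.na(f2$p_value))
  # antisymmetry: swapping groups negates t, keeps p
  swapped <- expansion_test(tab, rest, clade)
  s1 <- swapped[swapped$family_id == "f1", ]
  expect_equal(s1$t, -f1$t)
  expect_equal(s1$p_value, f1$p_value)
  expect_error(expansion_test(tab, "c1", rest), "2 species")
})

test_that("expansion test flags simulated clade-specific expansions", {
  set.seed(71)
  n_fam <- 200
  expanded <- seq_len(40)
  rows <- list()
  for (f in seq_len(n_fam)) {
    base <- sample(1:2, 1)
    # a clade-stem expansion is shared by every clade species, with
    # per-species noise on top (a tenfold duplication-rate burst)
    stem_extra <- if (f %in% expanded) rpois(1, 6) else 0
    for (sp in paste0("clade", 1:4)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        family_id = paste0("f", f), species = sp,
        n = base + stem_extra + rpois(1, 0.3))
    }
    for (sp in paste0("rest", 1:4)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        family_id = paste0("f", f), species = sp,
        n = base + rpois(1, 0.3))
    }
  }
  long <- dplyr::bind_rows(rows)
  tab <- tibble::tibble(
    family_id = rep(long$family_id, long$n),
    species = rep(long$species, long$n),
    gene_id = paste0("g", seq_len(sum(long$n)))
  )
  res <- expansion_test(tab, paste0("clade", 1:4), paste0("rest", 1:4))
  hits <- res$family_id[res$sig_0.01 & res$clade_mean > res$rest_mean]
  recall <- mean(paste0("f", expanded) %in% hits)
  expect_gte(recall, 0.8)
})

test_that("duplication mechanisms partition pairs by distance and blocks", {
  fams <- c("f1", "f1", "f2", sprintf("x%02d", 1:57), "f2")
  g <- toy_genome(61, family = fams)
  # f1 copies adjacent (ranks 0,1) -> tandem; f2 copies 57 apart -> dispersed
  pairs <- tibble::tibble(
    gene_a = g$genes$gene_id[g$genes$family_id == "f1"][1],
    gene_b = g$genes$gene_id[g$genes$family_id == "f1"][2]
  )
  pairs2 <- tibble::tibble(
    gene_a = g$genes$gene_id[g$genes$family_id == "f2"][1],
    gene_b = g$genes$gene_id[g$genes$family_id == "f2"][2]
  )
  blocks <- chain_anchors(find_anchors(g, g))  # no blocks expected
  c1 <- classify_duplication(pairs, g, blocks, max_intervening = 10)
  expect_equal(c1$mechanism, "tandem")
  expect_equal(c1$intervening_genes, 0L)
  c2 <- classify_duplication(pairs2, g, blocks, max_intervening = 10)
  expect_equal(c2$mechanism, "dispersed")
  # mixed-family pairs are rejected
  bad <- tibble::tibble(gene_a = g$genes$gene_id[1],
                        gene_b = g$genes$gene_id[3])
  expect_error(classify_duplication(bad, g, blocks), "share a family")
})

test_that("WGT-derived pairs inside blocks are called segmental", {
  ds <- wgt_fixture(n_genes = 200, seed = 72)
  gT <- ds$genomes$T
  blocks <- chain_anchors(find_anchors(gT, gT))
  pairs <- find_anchors(gT, gT) |>
    dplyr::select(gene_a, gene_b)
  calls <- classify_duplication(pairs, gT, blocks)
  # every pair gets exactly one mechanism
  expect_true(all(calls$mechanism %in%
                    c("tandem", "wgd_segmental", "dispersed")))
  expect_equal(nrow(calls), nrow(pairs))
  # duplicates from the whole-genome event dominate and sit in blocks
  expect_gt(mean(calls$mechanism == "wgd_segmental"), 0.5)
})

test_that("Ka/Ks summary reports purifying fraction and unratioed pairs", {
  kt <- tibble::tibble(
    ks = c(0.5, 0.5, 0, NA, 0.4),
    ka = c(0.1, 0.5, 0, NA, 0.2),
    saturated = c(FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  s <- kaks_selection_summary(kt)
  expect_equal(s$n_ratioed, 3)
  expect_equal(s$n_unratioed, 1)
  expect_equal(s$n_saturated, 1)
  expect_equal(s$frac_purifying, 2 / 3)
  expect_equal(s$mean_ka_ks, mean(c(0.2, 1, 0.5)))
  expect_error(kaks_selection_summary(kt[0, ]), "empty")
})

test_that("simulated purifying selection yields the configured Ka/Ks", {
  set.seed(73)
  anc <- build_ancestor(sim_params(seed = 73, n_ancestral_genes = 200,
                                   n_chromosomes = 1, n_codons = 300))
  g1 <- evolve_cds(anc, 0.5, syn_rate = 0.5, nonsyn_rate = 0.1)
  g2 <- evolve_cds(anc, 0.5, syn_rate = 0.5, nonsyn_rate = 0.1)
  kt <- ks_for_pairs(tibble::tibble(gene_a = names(g1$cds),
                                    gene_b = names(g2$cds)),
                     g1$cds, g2$cds)
  s <- kaks_selection_summary(kt)
  expect_equal(s$frac_purifying, 1)
  expect_lt(abs(s$mean_ka_ks - 0.2), 0.03)
})

test_that("LCN selection is strict, boundary-inclusive and monotone", {
  req <- c("ls", "st", "sm", "gb", "vv")
  oth <- paste0("o", 1:7)
  rows <- list()
  add <- function(fam, sp, n) rows[[length(rows) + 1]] <<-
    list(fam, sp, n)
  for (sp in c(req, oth)) add("good", sp, 1)          # single everywhere
  for (sp in req) add("bound", sp, 1)                  # exactly 5 singles
  for (sp in oth[1:5]) add("bound", sp, 1)
  for (sp in oth[6:7]) add("bound", sp, 2)
  for (sp in setdiff(req, "ls")) add("miss", sp, 1)    # absent in one req
  for (sp in oth) add("miss", sp, 1)
  for (sp in req) add("multi", sp, 2)                  # multi-copy in req
  for (sp in oth) add("multi", sp, 1)
  tab <- do.call(fam_table, rows)
  sel <- select_lcn(tab, req, oth, min_other_single = 5)
  expect_setequal(sel, c("good", "bound"))
  # monotone: relaxing the threshold never removes a selected family
  sel4 <- select_lcn(tab, req, oth, min_other_single = 4)
  expect_true(all(sel %in% sel4))
  sel6 <- select_lcn(tab, req, oth, min_other_single = 6)
  expect_false("bound" %in% sel6)
  expect_error(select_lcn(tab, req, c(req[1], oth)), "disjoint")
})
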