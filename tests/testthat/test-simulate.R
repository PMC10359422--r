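test_that("ancestor is single copy, reproducible, with in-frame CDS", {
  p <- sim_params(seed = 5, n_ancestral_genes = 100, n_chromosomes = 2,
                  n_codons = 20)
  set.seed(p$seed); a1 <- build_ancestor(p)
  set.seed(p$seed); a2 <- build_ancestor(p)
  expect_equal(a1$genes, a2$genes)
  expect_equal(a1$cds, a2$cds)
  expect_equal(nrow(a1$genes), 100)
  expect_equal(dplyr::n_distinct(a1$genes$family_id), 100)
  expect_true(all(nchar(a1$cds) == 60))
  expect_false(any(grepl("TAA|TAG|TGA",
                         substring(a1$cds, seq(1, 58, 3), seq(3, 60, 3)))))
  expect_error(build_ancestor(sim_params(n_ancestral_genes = 1,
                                         n_chromosomes = 3)))
})

test_that("ancestor label frequencies track the configured weights", {
  p <- sim_params(seed = 8, n_ancestral_genes = 3000, n_chromosomes = 2,
                  n_codons = 5)
  set.seed(p$seed)
  a <- build_ancestor(p)
  freq <- table(a$genes$label) / 3000
  for (i in seq_along(p$label_vocab)) {
    w <- p$label_weights[i]
    tol <- 4 * sqrt(w * (1 - w) / 3000)
    expect_lt(abs(freq[[p$label_vocab[i]]] - w), tol)
  }
})

test_that("whole-genome multiplication copies every chromosome and family", {
  set.seed(1)
  a <- build_ancestor(sim_params(n_ancestral_genes = 10,
                                 n_chromosomes = 1, n_codons = 10))
  g3 <- apply_wg_multiplication(a, 3)
  expect_equal(nrow(g3$genes), 30)
  expect_true(all(table(g3$genes$family_id) == 3))
  expect_equal(nrow(g3$chromosomes), 3)
  # order within each copied chromosome preserved exactly
  for (ch in unique(g3$genes$chrom)) {
    sub <- dplyr::arrange(g3$genes[g3$genes$chrom == ch, ], rank)
    expect_equal(sub$family_id, a$genes$family_id[order(a$genes$rank)])
  }
  # composition: x2 then x2 gives family size 4
  g4 <- apply_wg_multiplication(apply_wg_multiplication(a, 2), 2)
  expect_true(all(table(g4$genes$family_id) == 4))
  expect_equal(nrow(event_log(g4)), 2)
})

test_that("fractionation keeps one copy per family and obeys the rate", {
  set.seed(2)
  a <- build_ancestor(sim_params(n_ancestral_genes = 1000,
                                 n_chromosomes = 2, n_codons = 5))
  g3 <- apply_wg_multiplication(a, 3)
  expect_equal(apply_fractionation(g3, 1)$genes |> nrow(), 3000)
  g0 <- apply_fractionation(g3, 0)
  expect_true(all(table(g0$genes$family_id) == 1))
  # with p = 0.5, both extra copies survive independently: P(full) = p^2
  g5 <- apply_fractionation(g3, 0.5)
  frac_full <- mean(table(g5$genes$family_id) == 3)
  expect_lt(abs(frac_full - 0.25), 3 * sqrt(0.25 * 0.75 / 1000))
  # lost genes are logged and account for the size change
  lost <- event_log(g5)$payload[[nrow(event_log(g5))]]$lost_genes
  expect_equal(nrow(g3$genes) - nrow(g5$genes), length(lost))
})

test_that("retention bias multiplies survival for labelled genes", {
  set.seed(3)
  a <- build_ancestor(sim_params(n_ancestral_genes = 2000,
                                 n_chromosomes = 2, n_codons = 5))
  g3 <- apply_wg_multiplication(a, 3)
  g5 <- apply_fractionation(g3, 0.5, retention_bias = c(fattyacid = 1.6))
  full <- names(which(table(g5$genes$family_id) == 3))
  lab <- a$genes |>
    dplyr::mutate(full = family_id %in% full) |>
    dplyr::group_by(label) |>
    dplyr::summarise(p_full = mean(full))
  expect_gt(lab$p_full[lab$label == "fattyacid"],
            lab$p_full[lab$label == "other"])
})

test_that("tandem duplication inserts adjacent same-family copies", {
  set.seed(4)
  a <- build_ancestor(sim_params(n_ancestral_genes = 50,
                                 n_chromosomes = 1, n_codons = 10))
  expect_equal(apply_tandem_duplications(a, 0)$genes, a$genes)
  target <- a$genes$gene_id[a$genes$rank == 10]
  g <- apply_tandem_duplications(a, force_genes = target)
  kid <- g$genes[grepl("\\.t1$", g$genes$gene_id), ]
  expect_equal(nrow(kid), 1)
  expect_equal(kid$rank, 11L)
  expect_equal(kid$family_id, a$genes$family_id[a$genes$rank == 10])
  expect_equal(kid$strand, a$genes$strand[a$genes$rank == 10])
  expect_equal(sum(g$genes$family_id == kid$family_id), 2)
})

test_that("tandem duplication counts follow the Poisson expectation", {
  set.seed(6)
  a <- build_ancestor(sim_params(n_ancestral_genes = 1000,
                                 n_chromosomes = 2, n_codons = 5))
  n_new <- vapply(1:20, function(i) {
    nrow(apply_tandem_duplications(a, 0.01)$genes) - 1000L
  }, integer(1))
  # 20 replicates of Poisson(10): the mean is within 4 sd of 10
  expect_lt(abs(mean(n_new) - 10), 4 * sqrt(10 / 20))
})

test_that("inversion reverses order, flips strands, and is an involution", {
  set.seed(7)
  a <- build_ancestor(sim_params(n_ancestral_genes = 8,
                                 n_chromosomes = 1, n_codons = 10))
  before <- dplyr::arrange(a$genes, rank)
  g <- apply_rearrangement(a, "inversion", "chr1", 2, 5)
  after <- dplyr::arrange(g$genes, rank)
  expect_equal(after$gene_id, before$gene_id[c(1, 2, 6, 5, 4, 3, 7, 8)])
  moved <- before$gene_id[3:6]
  expect_true(all(after$strand[match(moved, after$gene_id)] !=
                    before$strand[match(moved, before$gene_id)]))
  # single-gene inversion: order unchanged, strand flipped
  g1 <- apply_rearrangement(a, "inversion", "chr1", 3, 3)
  expect_equal(dplyr::arrange(g1$genes, rank)$gene_id, before$gene_id)
  expect_equal(sum(g1$genes$strand != before$strand[
    match(g1$genes$gene_id, before$gene_id)]), 1)
  # involution: inverting twice restores order and strands
  g2 <- apply_rearrangement(g, "inversion", "chr1", 2, 5)
  restored <- dplyr::arrange(g2$genes, rank)
  expect_equal(restored$gene_id, before$gene_id)
  expect_equal(restored$strand, before$strand)
  expect_error(apply_rearrangement(a, "inversion", "chr1", 5, 9),
               "chromosome end")
})

test_that("translocation swaps chromosome tails at the breakpoints", {
  set.seed(8)
  a <- build_ancestor(sim_params(n_ancestral_genes = 20,
                                 n_chromosomes = 2, n_codons = 10))
  g <- apply_rearrangement(a, "translocation", "chr1", 6,
                           chrom2 = "chr2", break2 = 4)
  tail1 <- a$genes$gene_id[a$genes$chrom == "chr1" & a$genes$rank >= 6]
  expect_true(all(g$genes$chrom[g$genes$gene_id %in% tail1] == "chr2"))
  expect_equal(nrow(g$genes), 20)
  expect_equal(sort(g$genes$gene_id), sort(a$genes$gene_id))
})

test_that("targeted loss deletes the copy and logs border inversions", {
  set.seed(9)
  a <- build_ancestor(sim_params(n_ancestral_genes = 100,
                                 n_chromosomes = 1, n_codons = 10))
  fam <- a$genes$family_id[a$genes$rank == 50]
  plain <- apply_targeted_loss(a, fam)
  expect_equal(sum(plain$genes$family_id == fam), 0)
  # neighbours keep their relative order
  expect_equal(dplyr::arrange(plain$genes, rank)$gene_id,
               setdiff(dplyr::arrange(a$genes, rank)$gene_id,
                       a$genes$gene_id[a$genes$family_id == fam]))
  withinv <- apply_targeted_loss(a, fam, at_inversion_border = TRUE,
                                 inversion_size = 25,
                                 params = sim_params())
  log <- event_log(withinv)
  loss <- log$payload[[nrow(log)]]
  expect_equal(loss$family_id, fam)
  inv <- loss$inversion
  expect_equal(inv$size, 25)
  # the deleted locus sits on the inversion border
  expect_true(loss$lost_rank %in% c(inv$start_rank, inv$end_rank))
  expect_error(apply_targeted_loss(a, "no_such_family"), "absent")
})

test_that("CDS evolution is null at zero time and Ka-free at zero rate", {
  set.seed(10)
  a <- build_ancestor(sim_params(n_ancestral_genes = 30,
                                 n_chromosomes = 1, n_codons = 50))
  expect_equal(evolve_cds(a, 0)$cds, a$cds)
  g <- evolve_cds(a, 1, syn_rate = 0.3, nonsyn_rate = 0)
  pairs <- tibble::tibble(gene_a = names(a$cds), gene_b = names(g$cds))
  kt <- ks_for_pairs(pairs, a$cds, g$cds)
  expect_true(all(kt$Nd == 0))
  expect_true(all(kt$ka == 0))
  expect_gt(mean(kt$ks), 0.1)
})

test_that("simulated trio with no events yields identical tip gene content", {
  p <- sim_params(seed = 11, n_ancestral_genes = 40, n_chromosomes = 1,
                  n_codons = 10, syn_rate = 0, nonsyn_rate = 0)
  ds <- simulate_dataset("((A:1,B:1):1,O:2):1;", p)
  cont <- lapply(ds$genomes, function(g) {
    dplyr::select(g$genes, core_id, chrom, rank, strand, family_id)
  })
  expect_equal(cont$A, cont$B)
  expect_equal(cont$A, cont$O)
  expect_equal(unname(ds$genomes$A$cds), unname(ds$genomes$O$cds))
})

test_that("a stem triplication multiplies only the descendant tips", {
  p <- sim_params(seed = 12, n_ancestral_genes = 60, n_chromosomes = 1,
                  n_codons = 10, syn_rate = 0, nonsyn_rate = 0)
  ev <- list(list(clade = c("A", "B"), time_frac = 0.5,
                  type = "wg_multiplication", multiplicity = 3))
  ds <- simulate_dataset("((A:1,B:1):1,O:2):1;", p, ev)
  expect_true(all(table(ds$genomes$O$genes$family_id) == 1))
  expect_true(all(table(ds$genomes$A$genes$family_id) == 3))
  expect_equal(ds$truth$A$full_multiplicity, rep(3, 60))
  expect_error(simulate_dataset("(A:1,B:1,O:2);", p), "polytomies")
})

test_that("identical seeds give byte-identical simulator outputs", {
  p <- sim_params(seed = 13, n_ancestral_genes = 50, n_chromosomes = 1,
                  n_codons = 10)
  ev <- list(list(clade = "T", time_frac = 0.3,
                  type = "wg_multiplication", multiplicity = 2),
             list(clade = "T", time_frac = 0.5, type = "fractionation"))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset("(R:0.5,T:0.5):0.1;", p, ev, out_dir = d1)
  simulate_dataset("(R:0.5,T:0.5):0.1;", p, ev, out_dir = d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 info = f)
  }
})

test_that("replaying the event log reproduces each tip's gene count", {
  sc <- trio_scenario(n_ancestral_genes = 80, n_chromosomes = 1,
                      n_codons = 10, seed = 14)
  ds <- simulate_dataset(sc$tree, sc$params, sc$events)
  for (sp in names(ds$genomes)) {
    g <- ds$genomes[[sp]]
    log <- event_log(g)
    n <- 80
    for (i in seq_len(nrow(log))) {
      p <- log$payload[[i]]
      n <- switch(log$event[i],
                  wg_multiplication = n * p$multiplicity,
                  fractionation_loss = n - length(p$lost_genes),
                  tandem_duplication = n + length(p$new_genes),
                  targeted_gene_loss = n - 1,
                  n)
    }
    expect_equal(nrow(g$genes), n, info = sp)
  }
})

test_that("strand flips occur only inside logged inversion intervals", {
  set.seed(15)
  a <- build_ancestor(sim_params(n_ancestral_genes = 60,
                                 n_chromosomes = 1, n_codons = 10))
  g <- apply_rearrangement(a, "micro_inversion", "chr1", 20, 35)
  log <- event_log(g)
  inv_genes <- log$payload[[nrow(log)]]$genes
  flipped <- g$genes$gene_id[g$genes$strand != a$genes$strand[
    match(g$genes$gene_id, a$genes$gene_id)]]
  expect_setequal(flipped, inv_genes)
})
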