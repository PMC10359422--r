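# Gene-family dynamics: count matrices, clade expansion tests,
# duplication-mechanism classification, Ka/Ks selection summaries and
# low-copy-number ortholog selection.

#' Species-by-family count matrix
#'
#' @param table A family membership tibble (`family_id`, `species`,
#'   `gene_id`), e.g. from [load_family_table()].
#' @param species_subset Optional species to keep; species absent from the
#'   table get an all-zero row.
#' @return A wide tibble: one row per species, one column per family,
#'   counts of member genes.
#' @export
count_families <- function(table, species_subset = NULL) {
  table <- as_tibble(table)
  species <- species_subset %||% sort(unique(table$species))
  fams <- sort(unique(table$family_id))
  long <- table |>
    filter(.data$species %in% !!species) |>
    count(.data$species, .data$family_id)
  wide <- long |>
    tidyr::pivot_wider(names_from = "family_id", values_from = "n",
                       values_fill = 0L)
  out <- tibble(species = species) |>
    left_join(wide, by = "species")
  for (f in setdiff(fams, names(out))) out[[f]] <- 0L
  out |>
    mutate(across(-"species", ~ coalesce(.x, 0L))) |>
    select("species", all_of(fams))
}

#' Clade expansion test per family
#'
#' Two-sample two-tailed Student's t test (pooled variance) of per-species
#' gene counts between a clade and the remaining species, per family, with
#' significance flags at the conventional star thresholds (p < 0.01,
#' 0.001, 0.0001). Families with zero pooled variance are reported
#' `degenerate` (not testable) rather than given p = 0.
#'
#' @param table Family membership tibble (`family_id`, `species`,
#'   `gene_id`).
#' @param clade_species,rest_species Species vectors (>= 2 each); species
#'   with no members of a family count 0.
#' @return A tibble per family: group means, `t`, `df`, `p_value`,
#'   `sig_0.01`, `sig_0.001`, `sig_0.0001`, `degenerate`.
#' @export
expansion_test <- function(table, clade_species, rest_species) {
  if (length(clade_species) < 2 || length(rest_species) < 2) {
    abort("need at least 2 species per group")
  }
  counts <- count_families(table,
                           species_subset = c(clade_species, rest_species))
  fams <- setdiff(names(counts), "species")
  in_clade <- counts$species %in% clade_species
  rows <- lapply(fams, function(f) {
    x <- counts[[f]][in_clade]
    y <- counts[[f]][!in_clade]
    degen <- var(x) == 0 && var(y) == 0
    if (degen) {
      t_stat <- NA_real_; df <- NA_real_; p <- NA_real_
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE,
                          alternative = "two.sided")
      t_stat <- unname(tt$statistic)
      df <- unname(tt$parameter)
      p <- tt$p.value
    }
    tibble(family_id = f, clade_mean = mean(x), rest_mean = mean(y),
           t = t_stat, df = df, p_value = p,
           sig_0.01 = !is.na(p) & p < 0.01,
           sig_0.001 = !is.na(p) & p < 0.001,
           sig_0.0001 = !is.na(p) & p < 1e-4,
           degenerate = degen)
  })
  bind_rows(rows)
}

#' Classify the duplication mechanism of same-family gene pairs
#'
#' Same chromosome with at most `max_intervening` genes between the copies
#' is `tandem`; a pair anchored inside an intra-genome synteny block is
#' `wgd_segmental`; anything else is `dispersed`. Every same-family pair
#' receives exactly one mechanism.
#'
#' @param pairs Tibble with `gene_a`, `gene_b` (same genome, same family).
#' @param genome The `annotated_genome` carrying both genes.
#' @param blocks Intra-genome [chain_anchors()] blocks (self-comparison).
#' @param max_intervening Tandem distance D: maximum genes between copies
#'   (default 10).
#' @return `pairs` with `mechanism`, `intervening_genes`, `block_id`.
#' @export
classify_duplication <- function(pairs, genome, blocks,
                                 max_intervening = 10) {
  g <- genome$genes
  fam <- setNames(g$family_id, g$gene_id)
  chrom <- setNames(g$chrom, g$gene_id)
  rank <- setNames(g$rank, g$gene_id)
  pairs <- as_tibble(pairs)
  if (nrow(pairs) > 0 &&
      any(fam[pairs$gene_a] != fam[pairs$gene_b], na.rm = TRUE)) {
    abort("pairs must share a family")
  }
  anchor_keys <- if (nrow(blocks) > 0) {
    blocks |>
      select("block_id", "anchors") |>
      tidyr::unnest("anchors") |>
      mutate(key = paste(pmin(.data$gene_a, .data$gene_b),
                         pmax(.data$gene_a, .data$gene_b))) |>
      select("key", "block_id")
  } else {
    tibble(key = character(), block_id = character())
  }
  pairs |>
    mutate(
      same_chrom = unname(chrom[.data$gene_a] == chrom[.data$gene_b]),
      intervening_genes = unname(ifelse(
        .data$same_chrom,
        abs(rank[.data$gene_a] - rank[.data$gene_b]) - 1L,
        NA_integer_)),
      key = paste(pmin(.data$gene_a, .data$gene_b),
                  pmax(.data$gene_a, .data$gene_b))
    ) |>
    left_join(anchor_keys, by = "key") |>
    mutate(
      mechanism = case_when(
        .data$same_chrom & .data$intervening_genes <= max_intervening ~
          "tandem",
        !is.na(.data$block_id) ~ "wgd_segmental",
        TRUE ~ "dispersed"
      )
    ) |>
    select(-"key", -"same_chrom")
}

#' Selection-pressure summary of duplicate pairs
#'
#' The distribution of Ka/Ks and the fraction under purifying selection
#' (ratio < 1). Pairs with Ks = 0 cannot form a ratio and are reported
#' separately; saturated pairs are excluded.
#'
#' @param ks_table [ks_for_pairs()] output.
#' @return One-row tibble: `n_pairs`, `n_ratioed`, `n_unratioed`,
#'   `n_saturated`, `mean_ka_ks`, `median_ka_ks`, `frac_purifying`.
#' @export
kaks_selection_summary <- function(ks_table) {
  if (nrow(ks_table) == 0) abort("empty Ks table")
  usable <- ks_table |>
    filter(!is.na(.data$ks), !.data$saturated)
  rat <- usable |> filter(.data$ks > 0)
  tibble(
    n_pairs = nrow(ks_table),
    n_ratioed = nrow(rat),
    n_unratioed = nrow(usable) - nrow(rat),
    n_saturated = sum(ks_table$saturated, na.rm = TRUE),
    mean_ka_ks = mean(rat$ka / rat$ks),
    median_ka_ks = median(rat$ka / rat$ks),
    frac_purifying = mean(rat$ka / rat$ks < 1)
  )
}

#' Select low-copy-number (LCN) families
#'
#' Families with exactly one copy in every required species and exactly one
#' copy in at least `min_other_single` of the other species (boundary
#' inclusive) -- the standard filter for phylogenomic marker genes.
#'
#' @param table Family membership tibble.
#' @param required_species Species that must be strictly single copy.
#' @param other_species Disjoint set of additional species.
#' @param min_other_single Minimum number of `other_species` that must be
#'   single copy (default 5).
#' @return Character vector of selected `family_id`s (sorted).
#' @export
select_lcn <- function(table, required_species, other_species,
                       min_other_single = 5) {
  if (length(intersect(required_species, other_species)) > 0) {
    abort("required_species and other_species must be disjoint")
  }
  counts <- count_families(table,
                           species_subset = c(required_species,
                                              other_species))
  fams <- setdiff(names(counts), "species")
  req <- counts$species %in% required_species
  sel <- vapply(fams, function(f) {
    all(counts[[f]][req] == 1) &&
      sum(counts[[f]][!req] == 1) >= min_other_single
  }, logical(1))
  sort(fams[sel])
}
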