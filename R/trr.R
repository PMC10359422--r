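# Triplication-retained regions: calling runs of fully retained genes from
# a syntenic depth track, window-level genomic composition, and
# enrichment/depletion statistics against the genome background.

#' Call triplication-retained regions (TRRs) from a depth track
#'
#' A TRR is a maximal run of consecutive reference genes whose syntenic
#' depth reaches `min_copies`, tolerating at most `max_gap` consecutive
#' sub-threshold genes inside the run; runs with fewer than `min_run`
#' qualifying genes are discarded. Runs always start and end with a
#' qualifying gene. For a best-3 layout `min_copies = 3` calls fully
#' triplicated regions; for a best-6 layout values 4-6 call regions
#' retaining that many copies.
#'
#' @param depth Output of [syntenic_depth()] (columns `gene_id`, `chrom`,
#'   `rank`, `depth`).
#' @param genome The reference `annotated_genome` (for bp bounds).
#' @param min_copies Depth threshold per gene.
#' @param min_run Minimum qualifying genes per region (default 3).
#' @param max_gap Tolerated consecutive sub-threshold genes inside a region
#'   (default 1).
#' @return A tibble of TRR intervals: `chrom`, `start_rank`, `end_rank`,
#'   `start_bp`, `end_bp`, `n_genes`, `n_qualifying`, and a `gene_ids`
#'   list-column.
#' @export
call_trrs <- function(depth, genome, min_copies = 3, min_run = 3,
                      max_gap = 1) {
  coords <- genome$genes |> select("gene_id", "start", "end")
  d <- depth |>
    arrange(.data$chrom, .data$rank) |>
    left_join(coords, by = "gene_id")
  out <- d |>
    group_by(.data$chrom) |>
    group_map(function(g, key) {
      runs <- qualifying_runs(g$depth >= min_copies, min_run, max_gap)
      if (nrow(runs) == 0) return(NULL)
      runs |>
        mutate(chrom = key$chrom,
               start_rank = g$rank[.data$from],
               end_rank = g$rank[.data$to],
               start_bp = g$start[.data$from],
               end_bp = g$end[.data$to],
               n_genes = .data$to - .data$from + 1L,
               gene_ids = map2(.data$from, .data$to,
                               function(a, b) g$gene_id[a:b])) |>
        select("chrom", "start_rank", "end_rank", "start_bp", "end_bp",
               "n_genes", "n_qualifying", "gene_ids")
    }) |>
    bind_rows()
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start_rank = integer(),
                  end_rank = integer(), start_bp = integer(),
                  end_bp = integer(), n_genes = integer(),
                  n_qualifying = integer(), gene_ids = list()))
  }
  arrange(out, .data$chrom, .data$start_rank)
}

# Merge qualifying positions into runs allowing <= max_gap consecutive
# non-qualifying positions inside; returns 1-based from/to indices.
qualifying_runs <- function(q, min_run, max_gap) {
  idx <- which(q)
  if (length(idx) == 0) {
    return(tibble(from = integer(), to = integer(),
                  n_qualifying = integer()))
  }
  gap_ok <- c(TRUE, diff(idx) <= max_gap + 1)
  grp <- cumsum(!gap_ok)
  tibble(idx = idx, grp = grp) |>
    group_by(.data$grp) |>
    summarise(from = min(.data$idx), to = max(.data$idx),
              n_qualifying = n(), .groups = "drop") |>
    filter(.data$n_qualifying >= min_run) |>
    select("from", "to", "n_qualifying")
}

#' Genic and repetitive composition per window
#'
#' For each window, the fraction of bp covered by gene models and by
#' repeats (each track's overlapping intervals are unioned first, so no bp
#' is counted twice within a track), plus per-repeat-family bp.
#'
#' @param genome An `annotated_genome` with repeats loaded.
#' @param windows Output of [genome_windows()].
#' @return `windows` with `genic_bp`, `repeat_bp`, `genic_frac`,
#'   `repeat_frac` and a `family_bp` list-column (named numeric per
#'   window).
#' @export
window_composition <- function(genome, windows) {
  gene_ir <- split(
    IRanges::IRanges(genome$genes$start, genome$genes$end),
    genome$genes$chrom
  )
  rep_ir <- if (nrow(genome$repeats) > 0) {
    split(IRanges::IRanges(genome$repeats$start, genome$repeats$end),
          genome$repeats$chrom)
  } else list()
  rep_fam <- if (nrow(genome$repeats) > 0) {
    split(genome$repeats, genome$repeats$chrom)
  } else list()

  res <- lapply(seq_len(nrow(windows)), function(i) {
    ch <- windows$chrom[i]
    win <- IRanges::IRanges(windows$start[i], windows$end[i])
    gbp <- overlap_bp(gene_ir[[ch]], win)
    rbp <- overlap_bp(rep_ir[[ch]], win)
    fam <- numeric(0)
    rf <- rep_fam[[ch]]
    if (!is.null(rf) && nrow(rf) > 0) {
      per <- vapply(split(rf, rf$family), function(x) {
        overlap_bp(IRanges::IRanges(x$start, x$end), win)
      }, numeric(1))
      fam <- per[per > 0]
    }
    tibble(genic_bp = gbp, repeat_bp = rbp, family_bp = list(fam))
  })
  bind_cols(windows, bind_rows(res)) |>
    mutate(genic_frac = .data$genic_bp / .data$width,
           repeat_frac = .data$repeat_bp / .data$width)
}

overlap_bp <- function(ir, win) {
  if (is.null(ir) || length(ir) == 0) return(0)
  sum(IRanges::width(IRanges::intersect(IRanges::reduce(ir), win)))
}

#' Assign composition windows to TRR vs background by majority overlap
#'
#' @param composition Output of [window_composition()].
#' @param trrs Output of [call_trrs()].
#' @return `composition` with a logical `in_trr` column (TRUE when more
#'   than half of the window overlaps a TRR interval).
#' @export
assign_windows_to_trrs <- function(composition, trrs) {
  trr_ir <- if (nrow(trrs) > 0) {
    split(IRanges::IRanges(trrs$start_bp, trrs$end_bp), trrs$chrom)
  } else list()
  ov <- vapply(seq_len(nrow(composition)), function(i) {
    overlap_bp(trr_ir[[composition$chrom[i]]],
               IRanges::IRanges(composition$start[i],
                                composition$end[i]))
  }, numeric(1))
  mutate(composition, in_trr = ov > .data$width / 2)
}

#' Two-sample Student's t comparison of window composition
#'
#' Pooled-variance two-sample Student's t test (two-tailed) of the genic
#' and repeat fractions between TRR-assigned windows and the remaining
#' genome windows, with the direction of each difference. Welch's
#' correction is available behind `var_equal = FALSE`.
#'
#' @param composition Output of [assign_windows_to_trrs()] (needs
#'   `in_trr`), or any tibble with `in_trr` plus the tested columns.
#' @param tracks Columns to compare (default genic and repeat fractions).
#' @param var_equal Pooled variance (Student, default) or Welch.
#' @return A tibble per track: group means, `t`, `df`, `p_value`,
#'   `direction` (`higher_in_trr` / `lower_in_trr` / `equal`), `degenerate`
#'   (zero pooled variance: no p reported).
#' @export
compare_composition <- function(composition,
                                tracks = c("genic_frac", "repeat_frac"),
                                var_equal = TRUE) {
  bind_rows(lapply(tracks, function(tr) {
    x <- composition[[tr]][composition$in_trr]
    y <- composition[[tr]][!composition$in_trr]
    res <- composition_t_test(x, y, var_equal = var_equal)
    mutate(res, track = tr, .before = 1)
  }))
}

#' Pooled-variance two-sample Student's t test
#'
#' @param x,y Numeric vectors (TRR group first).
#' @param var_equal Pooled variance (default) or Welch.
#' @return One-row tibble: `mean_trr`, `mean_background`, `t`, `df`,
#'   `p_value`, `direction`, `degenerate`, `n_trr`, `n_background`.
#' @export
composition_t_test <- function(x, y, var_equal = TRUE) {
  degenerate <- length(x) < 2 || length(y) < 2 ||
    (stats::var(x) == 0 && stats::var(y) == 0)
  if (degenerate) {
    return(tibble(mean_trr = mean(x), mean_background = mean(y),
                  t = NA_real_, df = NA_real_, p_value = NA_real_,
                  direction = direction_of(mean(x), mean(y)),
                  degenerate = TRUE,
                  n_trr = length(x), n_background = length(y)))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal,
                      alternative = "two.sided")
  tibble(mean_trr = mean(x), mean_background = mean(y),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value,
         direction = direction_of(mean(x), mean(y)),
         degenerate = FALSE,
         n_trr = length(x), n_background = length(y))
}

direction_of <- function(mx, my) {
  if (is.na(mx) || is.na(my) || is.nan(mx) || is.nan(my)) NA_character_
  else if (isTRUE(all.equal(mx, my))) "equal"
  else if (mx > my) "higher_in_trr"
  else "lower_in_trr"
}

#' Hypergeometric enrichment/depletion of categories in a test set
#'
#' For each category, the upper-tail hypergeometric probability of seeing
#' at least the observed members in the test set (enrichment) and the
#' lower-tail probability of seeing at most that many (depletion) are
#' computed exactly; the smaller is reported with its direction.
#' Benjamini-Hochberg adjustment is applied across categories and
#' significance called at `adjusted_p < threshold`.
#'
#' @param test_set Character vector of element ids (must be a subset of
#'   `background`).
#' @param background Character vector of all element ids.
#' @param categories Tibble with columns `element_id`, `category` (an
#'   element may carry several categories). Categories absent from the
#'   background are skipped with a warning.
#' @param threshold Adjusted-p significance threshold (default 0.01).
#' @return A tibble per category: `category`, `k_in`, `n_test`, `K_total`,
#'   `N_total`, `p_enrich`, `p_deplete`, `p_value`, `direction`,
#'   `adjusted_p`, `significant`.
#' @export
hypergeom_enrichment <- function(test_set, background, categories,
                                 threshold = 0.01) {
  if (!all(test_set %in% background)) {
    abort("test_set must be a subset of background")
  }
  categories <- as_tibble(categories)
  skipped <- categories |>
    filter(!.data$element_id %in% background) |>
    distinct(.data$category) |>
    anti_join(categories |>
                filter(.data$element_id %in% background) |>
                distinct(.data$category), by = "category")
  if (nrow(skipped) > 0) {
    warn(paste0("categor(ies) absent from background skipped: ",
                paste(skipped$category, collapse = ", ")))
  }
  categories <- filter(categories, .data$element_id %in% background)
  N <- length(unique(background))
  n <- length(unique(test_set))
  res <- categories |>
    group_by(category = .data$category) |>
    summarise(
      K_total = n_distinct(.data$element_id),
      k_in = n_distinct(intersect(.data$element_id, test_set)),
      .groups = "drop"
    ) |>
    mutate(
      n_test = n, N_total = N,
      p_enrich = phyper(.data$k_in - 1, .data$K_total,
                        N - .data$K_total, n, lower.tail = FALSE),
      p_deplete = phyper(.data$k_in, .data$K_total,
                         N - .data$K_total, n, lower.tail = TRUE),
      direction = ifelse(.data$p_enrich <= .data$p_deplete,
                         "enriched", "depleted"),
      p_value = pmin(.data$p_enrich, .data$p_deplete)
    )
  res |>
    mutate(adjusted_p = p.adjust(.data$p_value, method = "BH"),
           significant = .data$adjusted_p < threshold) |>
    select("category", "k_in", "n_test", "K_total", "N_total",
           "p_enrich", "p_deplete", "p_value", "direction",
           "adjusted_p", "significant") |>
    arrange(.data$p_value)
}

#' Fisher exact tests of functional-domain counts, per species, with a
#' cross-species summary
#'
#' Each domain's 2x2 table (in/out of the test gene set vs with/without
#' the domain) gets a two-sided Fisher exact test per species, BH-adjusted
#' within species. The summary lists domains significant in at least
#' `min_species` species.
#'
#' @param counts Tibble with columns `species`, `domain`, `n11`, `n12`,
#'   `n21`, `n22` (the 2x2 table row-wise: test-set with domain, test-set
#'   without, background-only with, background-only without). All-zero
#'   tables are skipped.
#' @param alpha Per-species adjusted-p significance level (default 0.05).
#' @param min_species Minimum species a domain must be significant in to
#'   enter the summary (default 2).
#' @return A list with `per_species` (tibble of tests) and `summary`
#'   (domains significant in >= `min_species` species, with the count).
#' @export
fisher_domain_enrichment <- function(counts, alpha = 0.05,
                                     min_species = 2) {
  counts <- as_tibble(counts)
  counts <- counts |>
    filter(.data$n11 + .data$n12 + .data$n21 + .data$n22 > 0)
  per <- counts |>
    mutate(p_value = pmap(list(.data$n11, .data$n12, .data$n21,
                               .data$n22), function(a, b, c, d) {
      fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
    }) |> unlist()) |>
    group_by(.data$species) |>
    mutate(adjusted_p = p.adjust(.data$p_value, method = "BH")) |>
    ungroup() |>
    mutate(significant = .data$adjusted_p < alpha,
           direction = ifelse(.data$n11 * .data$n22 >=
                                .data$n12 * .data$n21,
                              "enriched", "depleted"))
  summary <- per |>
    filter(.data$significant) |>
    count(domain = .data$domain, name = "n_species_significant") |>
    filter(.data$n_species_significant >= min_species) |>
    arrange(desc(.data$n_species_significant), .data$domain)
  list(per_species = per, summary = summary)
}
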