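# Collinear synteny: homologous anchor pairs chained into blocks by sparse
# dynamic programming in gene-rank coordinates, then best-k syntenic layouts
# and per-gene syntenic depth against a reference.

#' Find homologous anchor pairs between two genomes
#'
#' In `family` mode, every cross-genome gene pair sharing a `family_id` is
#' an anchor (weight 1). For a self-comparison (same species) pairs are
#' unordered and self-pairs are excluded. In `score` mode a similarity table
#' (`gene_a`, `gene_b`, `weight`) must be supplied. Anchors can be capped at
#' the `top_hits` best-weight partners per gene.
#'
#' @param genome_a,genome_b `annotated_genome`s sharing a family namespace.
#'   Pass the same genome twice for a paralog (self) comparison.
#' @param mode `"family"` or `"score"`.
#' @param top_hits Cap on anchors per gene (by weight, ties broken by gene
#'   id); `Inf` keeps all.
#' @param similarity Similarity table, required in `score` mode.
#' @return A tibble with `gene_a`, `gene_b`, `family_id`, `chrom_a`,
#'   `chrom_b`, `rank_a`, `rank_b`, `strand_a`, `strand_b`, `weight`.
#' @export
find_anchors <- function(genome_a, genome_b, mode = c("family", "score"),
                         top_hits = Inf, similarity = NULL) {
  mode <- match.arg(mode)
  ga <- genome_a$genes |>
    select(gene_a = "gene_id", chrom_a = "chrom", rank_a = "rank",
           strand_a = "strand", family_id = "family_id")
  gb <- genome_b$genes |>
    select(gene_b = "gene_id", chrom_b = "chrom", rank_b = "rank",
           strand_b = "strand", family_id = "family_id")
  if (mode == "family") {
    anchors <- inner_join(ga, gb, by = "family_id",
                          relationship = "many-to-many") |>
      mutate(weight = 1)
  } else {
    if (is.null(similarity)) abort("score mode requires a similarity table")
    anchors <- similarity |>
      as_tibble() |>
      inner_join(select(ga, -"family_id"), by = "gene_a") |>
      inner_join(select(gb, -"family_id"), by = "gene_b") |>
      mutate(family_id = NA_character_)
  }
  self_cmp <- identical(genome_a$species, genome_b$species)
  if (self_cmp) {
    anchors <- anchors |>
      filter(.data$gene_a < .data$gene_b)
  }
  if (is.finite(top_hits)) {
    anchors <- anchors |>
      group_by(.data$gene_a) |>
      arrange(desc(.data$weight), .data$gene_b, .by_group = TRUE) |>
      slice_head(n = top_hits) |>
      group_by(.data$gene_b) |>
      arrange(desc(.data$weight), .data$gene_a, .by_group = TRUE) |>
      slice_head(n = top_hits) |>
      ungroup()
  }
  anchors |>
    select("gene_a", "gene_b", "family_id", "chrom_a", "chrom_b",
           "rank_a", "rank_b", "strand_a", "strand_b", "weight") |>
    arrange(.data$chrom_a, .data$rank_a, .data$chrom_b, .data$rank_b)
}

#' Chain anchors into collinear synteny blocks
#'
#' Sparse dynamic programming over anchors in gene-rank coordinates.
#' A chain's score is the sum of its anchor weights minus
#' `gap_penalty * (skipped ranks in a + skipped ranks in b)`; successive
#' anchors must be strictly increasing in `rank_a` and strictly increasing
#' (orientation `same`) or strictly decreasing (`inverted`) in `rank_b`,
#' with no rank gap larger than `max_gap_genes`. Per chromosome pair, both
#' orientations are chained to optimality; chains are then extracted
#' greedily by score, an anchor joining at most one block, and chains with
#' fewer than `min_block_anchors` anchors are discarded. Ties between
#' equal-scoring chains go to the smaller start rank in a, then b.
#'
#' @param anchors Output of [find_anchors()].
#' @param gap_penalty Score penalty per skipped gene rank (default 0.2).
#' @param max_gap_genes Maximum rank gap between successive anchors
#'   (default 25).
#' @param min_block_anchors Minimum anchors per reported block (default 5).
#' @return A tibble of blocks (`block_id`, `chrom_a`, `chrom_b`,
#'   `orientation`, `score`, `n_anchors`, rank spans) with a nested
#'   `anchors` list-column.
#' @export
chain_anchors <- function(anchors, gap_penalty = 0.2, max_gap_genes = 25,
                          min_block_anchors = 5) {
  anchors <- as_tibble(anchors)
  if (nrow(anchors) == 0) return(empty_blocks())
  pairs <- anchors |> distinct(.data$chrom_a, .data$chrom_b)
  all_chains <- list()
  for (i in seq_len(nrow(pairs))) {
    sub <- anchors |>
      filter(.data$chrom_a == pairs$chrom_a[i],
             .data$chrom_b == pairs$chrom_b[i])
    for (orient in c("same", "inverted")) {
      chains <- extract_chains(sub, orient, gap_penalty, max_gap_genes,
                               min_block_anchors)
      all_chains <- c(all_chains, chains)
    }
  }
  if (length(all_chains) == 0) return(empty_blocks())
  # greedy selection by score; an anchor belongs to at most one block
  ord <- order(-map_dbl(all_chains, "score"),
               map_dbl(all_chains, function(ch) min(ch$anchors$rank_a)),
               map_dbl(all_chains, function(ch) min(ch$anchors$rank_b)))
  used <- character(0)
  blocks <- list()
  for (ch in all_chains[ord]) {
    key <- paste(ch$anchors$gene_a, ch$anchors$gene_b)
    shared <- key %in% used
    if (any(shared)) {
      # anchors claimed by a higher-scoring block are trimmed; the chain
      # survives (re-scored) if enough anchors remain
      ch$anchors <- ch$anchors[!shared, ]
      if (nrow(ch$anchors) < min_block_anchors) next
      ch$score <- rescore_chain(ch$anchors, ch$orientation, gap_penalty)
      key <- key[!shared]
    }
    used <- c(used, key)
    blocks[[length(blocks) + 1]] <- ch
  }
  tibble(
    block_id = paste0("blk", sprintf("%04d", seq_along(blocks))),
    chrom_a = map_chr(blocks, "chrom_a"),
    chrom_b = map_chr(blocks, "chrom_b"),
    orientation = map_chr(blocks, "orientation"),
    score = map_dbl(blocks, "score"),
    n_anchors = map_int(blocks, function(b) nrow(b$anchors)),
    start_rank_a = map_int(blocks, function(b) min(b$anchors$rank_a)),
    end_rank_a = map_int(blocks, function(b) max(b$anchors$rank_a)),
    start_rank_b = map_int(blocks, function(b) min(b$anchors$rank_b)),
    end_rank_b = map_int(blocks, function(b) max(b$anchors$rank_b)),
    anchors = map(blocks, "anchors")
  )
}

# score of a fixed anchor chain: sum of weights minus gap penalties
# between successive anchors (ordered along the reference)
rescore_chain <- function(anchors, orientation, gap_penalty) {
  rb <- if (orientation == "same") anchors$rank_b else -anchors$rank_b
  o <- order(anchors$rank_a, rb)
  ra <- anchors$rank_a[o]
  rb <- rb[o]
  gaps <- if (length(ra) > 1) {
    sum(diff(ra) - 1) + sum(abs(diff(rb)) - 1)
  } else 0
  sum(anchors$weight) - gap_penalty * gaps
}

empty_blocks <- function() {
  tibble(block_id = character(), chrom_a = character(),
         chrom_b = character(), orientation = character(),
         score = numeric(), n_anchors = integer(),
         start_rank_a = integer(), end_rank_a = integer(),
         start_rank_b = integer(), end_rank_b = integer(),
         anchors = list())
}

# Repeatedly run the chaining DP on one chromosome pair and orientation,
# peeling off the best chain until none reaches min_block_anchors.
extract_chains <- function(sub, orient, gap_penalty, max_gap_genes,
                           min_anchors) {
  res <- list()
  remaining <- sub
  repeat {
    if (nrow(remaining) < min_anchors) break
    ch <- best_chain_dp(remaining, orient, gap_penalty, max_gap_genes)
    if (is.null(ch) || nrow(ch$anchors) < min_anchors) break
    res[[length(res) + 1]] <- list(
      chrom_a = remaining$chrom_a[1], chrom_b = remaining$chrom_b[1],
      orientation = orient, score = ch$score, anchors = ch$anchors
    )
    key <- paste(remaining$gene_a, remaining$gene_b) %in%
      paste(ch$anchors$gene_a, ch$anchors$gene_b)
    remaining <- remaining[!key, ]
  }
  res
}

# O(n^2) DP for the maximum-score chain; rank_b is negated for the inverted
# orientation so both passes share one increasing-coordinate formulation.
best_chain_dp <- function(sub, orient, gap_penalty, max_gap_genes) {
  ra <- sub$rank_a
  rb <- if (orient == "same") sub$rank_b else -sub$rank_b
  w <- sub$weight
  o <- order(ra, rb)
  ra <- ra[o]; rb <- rb[o]; w <- w[o]
  n <- length(ra)
  best <- w
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    if (j == 1) next
    i <- seq_len(j - 1)
    ok <- ra[i] < ra[j] & rb[i] < rb[j] &
      (ra[j] - ra[i] - 1) <= max_gap_genes &
      (abs(rb[j] - rb[i]) - 1) <= max_gap_genes
    if (!any(ok)) next
    cand <- which(ok)
    gain <- best[cand] - gap_penalty *
      ((ra[j] - ra[cand] - 1) + (abs(rb[j] - rb[cand]) - 1))
    gi <- which.max(gain)
    if (gain[gi] > 0) {
      best[j] <- w[j] + gain[gi]
      prev[j] <- cand[gi]
    }
  }
  endj <- which(best == max(best))
  # deterministic tie-break: smaller start rank in a, then b
  if (length(endj) > 1) {
    starts <- vapply(endj, function(j) {
      while (!is.na(prev[j])) j <- prev[j]
      ra[j] * 1e9 + (if (orient == "same") rb[j] else -rb[j])
    }, numeric(1))
    endj <- endj[order(starts)]
  }
  j <- endj[1]
  path <- j
  while (!is.na(prev[j])) {
    j <- prev[j]
    path <- c(j, path)
  }
  list(score = best[endj[1]], anchors = sub[o, ][path, ])
}

#' Best-k syntenic layout of a target genome against a reference
#'
#' For each reference gene, the `k` highest-scoring blocks covering its rank
#' define up to `k` target regions; a region is marked present when the
#' block actually anchors that gene (i.e. a homolog exists there).
#'
#' @param blocks Output of [chain_anchors()] computed with the reference as
#'   the `a` side.
#' @param reference The reference `annotated_genome`.
#' @param k Number of target regions per reference segment (3 for a
#'   post-triplication target; 6 when the target experienced a further
#'   duplication).
#' @return A long tibble: `gene_id`, `chrom`, `rank`, `slot` (1..k),
#'   `block_id`, `present`.
#' @export
best_k_layout <- function(blocks, reference, k = 3) {
  if (k < 1) abort("k must be >= 1")
  ref <- reference$genes |> select("gene_id", "chrom", "rank")
  if (nrow(blocks) == 0) {
    return(ref |>
             tidyr::crossing(slot = seq_len(k)) |>
             mutate(block_id = NA_character_, present = FALSE))
  }
  anchored <- blocks |>
    select("block_id", "anchors") |>
    tidyr::unnest("anchors") |>
    select("block_id", gene_id = "gene_a") |>
    distinct() |>
    mutate(anchored = TRUE)
  cover <- ref |>
    left_join(blocks |>
                select("block_id", chrom = "chrom_a", "score",
                       "start_rank_a", "end_rank_a"),
              by = join_by("chrom", between(x$rank, y$start_rank_a,
                                            y$end_rank_a))) |>
    left_join(anchored, by = c("gene_id", "block_id")) |>
    mutate(anchored = coalesce(.data$anchored, FALSE))
  layout <- cover |>
    group_by(.data$gene_id, .data$chrom, .data$rank) |>
    arrange(desc(.data$score), .data$block_id, .by_group = TRUE) |>
    slice_head(n = k) |>
    mutate(slot = seq_len(n())) |>
    ungroup() |>
    filter(!is.na(.data$block_id)) |>
    select("gene_id", "chrom", "rank", "slot", "block_id",
           present = "anchored")
  ref |>
    tidyr::crossing(slot = seq_len(k)) |>
    left_join(layout, by = c("gene_id", "chrom", "rank", "slot")) |>
    mutate(present = coalesce(.data$present, FALSE)) |>
    arrange(.data$chrom, .data$rank, .data$slot)
}

#' Per-gene syntenic depth from a best-k layout
#'
#' @param layout Output of [best_k_layout()].
#' @return A tibble `gene_id`, `chrom`, `rank`, `depth` (number of layout
#'   regions in which a homolog is present).
#' @export
syntenic_depth <- function(layout) {
  layout |>
    group_by(.data$gene_id, .data$chrom, .data$rank) |>
    summarise(depth = sum(.data$present), .groups = "drop") |>
    arrange(.data$chrom, .data$rank)
}
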