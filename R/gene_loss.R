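# Synteny-based tracing of single-gene loss: locate a family's expected
# locus in a target genome through its covering block, detect local
# inversions from anchor order, and classify the loss mechanism.

#' Map a family's reference locus into a target genome
#'
#' Finds the reference copy of the family, the synteny block covering it,
#' and interpolates the expected target rank linearly between the nearest
#' flanking anchors. Presence of a target-side family member inside the
#' block's target span means `retained`; elsewhere in the genome `moved`;
#' nowhere `lost_candidate`. A reference copy outside every block is
#' `unresolved`.
#'
#' @param family_id Family to trace.
#' @param reference,target `annotated_genome`s.
#' @param blocks [chain_anchors()] output with the reference as side a.
#' @return One row per reference copy: `family_id`, `ref_gene`,
#'   `ref_chrom`, `ref_rank`, `block_id`, `target_chrom`,
#'   `expected_rank`, `status`, `target_gene`.
#' @export
map_family_locus <- function(family_id, reference, target, blocks) {
  ref_copies <- reference$genes |> filter(.data$family_id == !!family_id)
  if (nrow(ref_copies) == 0) {
    abort(paste0("family absent from reference: ", family_id))
  }
  tgt_members <- target$genes |> filter(.data$family_id == !!family_id)
  rows <- lapply(seq_len(nrow(ref_copies)), function(i) {
    rg <- ref_copies[i, ]
    base <- tibble(family_id = family_id, ref_gene = rg$gene_id,
                   ref_chrom = rg$chrom, ref_rank = rg$rank)
    cover <- blocks |>
      filter(.data$chrom_a == rg$chrom,
             .data$start_rank_a <= rg$rank,
             .data$end_rank_a >= rg$rank) |>
      arrange(desc(.data$score))
    if (nrow(cover) == 0) {
      return(mutate(base, block_id = NA_character_,
                    target_chrom = NA_character_,
                    expected_rank = NA_real_, expected_lo = NA_real_,
                    expected_hi = NA_real_, status = "unresolved",
                    target_gene = NA_character_))
    }
    blk <- cover[1, ]
    anc <- blk$anchors[[1]] |> arrange(.data$rank_a)
    expected <- interpolate_rank(anc, rg$rank)
    proj <- flank_projections(anc, rg$rank)
    in_block <- tgt_members |>
      filter(.data$chrom == blk$chrom_b,
             .data$rank >= blk$start_rank_b,
             .data$rank <= blk$end_rank_b)
    status <- if (nrow(in_block) > 0) "retained"
      else if (nrow(tgt_members) > 0) "moved"
      else "lost_candidate"
    tgt_gene <- if (nrow(in_block) > 0) in_block$gene_id[1]
      else if (nrow(tgt_members) > 0) tgt_members$gene_id[1]
      else NA_character_
    mutate(base, block_id = blk$block_id, target_chrom = blk$chrom_b,
           expected_rank = expected, expected_lo = proj["lo"],
           expected_hi = proj["hi"], status = status,
           target_gene = tgt_gene)
  })
  bind_rows(rows)
}

# Linear interpolation of the expected target rank at reference rank r,
# between the nearest flanking anchors (extrapolates at block edges).
interpolate_rank <- function(anchors, r) {
  exact <- anchors |> filter(.data$rank_a == r)
  if (nrow(exact) > 0) return(as.numeric(exact$rank_b[1]))
  lo <- anchors |> filter(.data$rank_a < r) |> slice_tail(n = 1)
  hi <- anchors |> filter(.data$rank_a > r) |> slice_head(n = 1)
  if (nrow(lo) == 0) {
    return(hi$rank_b[1] - (hi$rank_a[1] - r))
  }
  if (nrow(hi) == 0) {
    return(lo$rank_b[1] + (r - lo$rank_a[1]))
  }
  frac <- (r - lo$rank_a[1]) / (hi$rank_a[1] - lo$rank_a[1])
  lo$rank_b[1] + frac * (hi$rank_b[1] - lo$rank_b[1])
}

# One-sided projections of the expected locus from each flank: where the
# target copy would sit if local collinearity continued past the nearest
# upstream / downstream anchor. Around a rearrangement breakpoint these
# differ; the lost locus is adjacent to the breakpoint on at least one
# side, so border distances are measured against both.
flank_projections <- function(anchors, r) {
  exact <- anchors |> filter(.data$rank_a == r)
  if (nrow(exact) > 0) {
    v <- as.numeric(exact$rank_b[1])
    return(c(lo = v, hi = v))
  }
  lo <- anchors |> filter(.data$rank_a < r) |> slice_tail(n = 1)
  hi <- anchors |> filter(.data$rank_a > r) |> slice_head(n = 1)
  c(lo = if (nrow(lo)) lo$rank_b[1] + (r - lo$rank_a[1]) else NA_real_,
    hi = if (nrow(hi)) hi$rank_b[1] - (hi$rank_a[1] - r) else NA_real_)
}

#' Detect inverted segments inside a synteny block
#'
#' Orders the block's anchors by reference rank and finds maximal runs
#' whose target ranks move against the block's consensus orientation
#' (strictly decreasing inside a `same` block, strictly increasing inside
#' an `inverted` one). Runs of at least `min_anchors` anchors are reported
#' with their rank intervals, gene counts and whether anchor strands
#' corroborate the flip.
#'
#' @param block One row of [chain_anchors()] output (or a list with
#'   `anchors` and `orientation`).
#' @param min_anchors Minimum anchors per reported segment (default 3,
#'   suppressing single-anchor noise).
#' @return A tibble of segments: `start_rank_a`, `end_rank_a`,
#'   `start_rank_b`, `end_rank_b`, `n_anchors`, `n_genes` (target-rank
#'   span), `strand_corroborated`.
#' @export
detect_inversions <- function(block, min_anchors = 3) {
  anc <- if (is.data.frame(block$anchors)) block$anchors
         else block$anchors[[1]]
  orientation <- if (length(block$orientation) == 1) block$orientation
                 else block$orientation[[1]]
  empty <- tibble(start_rank_a = integer(), end_rank_a = integer(),
                  start_rank_b = integer(), end_rank_b = integer(),
                  n_anchors = integer(), n_genes = integer(),
                  strand_corroborated = logical())
  if (nrow(anc) < 3) return(empty)
  anc <- anc |> arrange(.data$rank_a, .data$rank_b)
  step <- diff(anc$rank_b)
  against <- if (orientation == "same") step < 0 else step > 0
  if (!any(against)) return(empty)
  # maximal runs of consecutive "against" steps
  r <- rle(against)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segs <- tibble(from = starts[r$values], to = ends[r$values] + 1L,
                 len = r$lengths[r$values] + 1L) |>
    filter(.data$len >= min_anchors)
  if (nrow(segs) == 0) return(empty)
  # consensus strand relation outside the candidate segments
  rel <- anc$strand_a == anc$strand_b
  segs |>
    mutate(
      start_rank_a = anc$rank_a[.data$from],
      end_rank_a = anc$rank_a[.data$to],
      start_rank_b = pmin(anc$rank_b[.data$from], anc$rank_b[.data$to]),
      end_rank_b = pmax(anc$rank_b[.data$from], anc$rank_b[.data$to]),
      n_anchors = .data$len,
      n_genes = .data$end_rank_b - .data$start_rank_b + 1L,
      strand_corroborated = map2_lgl(.data$from, .data$to, function(a, b) {
        inside <- rel[a:b]
        outside <- rel[-(a:b)]
        if (length(outside) == 0) return(mean(inside) < 0.5)
        mean(inside != (mean(outside) >= 0.5)) >= 0.5
      })
    ) |>
    select("start_rank_a", "end_rank_a", "start_rank_b", "end_rank_b",
           "n_anchors", "n_genes", "strand_corroborated")
}

#' Classify a candidate gene loss
#'
#' Combines [map_family_locus()] and [detect_inversions()]: a lost
#' candidate whose expected target locus lies within `border_tolerance`
#' genes of a detected inversion breakpoint is classified
#' `lost_at_inversion_border`; a lost candidate far from any rearrangement
#' is `lost`; other statuses pass through from the mapping.
#'
#' @param mapping One row (or tibble) from [map_family_locus()].
#' @param inversions [detect_inversions()] output for the covering block.
#' @param border_tolerance Maximum gene distance from the expected locus to
#'   the nearest inversion breakpoint (default 2).
#' @return `mapping` with `status` upgraded and columns
#'   `nearest_breakpoint_distance`, `n_inversions` added.
#' @export
classify_loss <- function(mapping, inversions, border_tolerance = 2) {
  mapping <- as_tibble(mapping)
  dist_to_breakpoint <- function(lo, hi, mid) {
    cand <- c(lo, hi, mid)
    cand <- cand[!is.na(cand)]
    if (nrow(inversions) == 0 || length(cand) == 0) return(NA_real_)
    bps <- c(inversions$start_rank_b, inversions$end_rank_b)
    min(vapply(cand, function(e) min(abs(bps - e)), numeric(1)))
  }
  if (!"expected_lo" %in% names(mapping)) {
    mapping$expected_lo <- mapping$expected_rank
    mapping$expected_hi <- mapping$expected_rank
  }
  mapping |>
    mutate(
      nearest_breakpoint_distance =
        pmap(list(.data$expected_lo, .data$expected_hi,
                  .data$expected_rank), dist_to_breakpoint) |>
        unlist(),
      n_inversions = nrow(inversions),
      status = case_when(
        .data$status == "lost_candidate" &
          !is.na(.data$nearest_breakpoint_distance) &
          .data$nearest_breakpoint_distance <= border_tolerance ~
          "lost_at_inversion_border",
        .data$status == "lost_candidate" ~ "lost",
        TRUE ~ .data$status
      )
    )
}

#' Trace a family end to end between two genomes
#'
#' Convenience wrapper: anchors, blocks, locus mapping, inversion detection
#' and loss classification in one call.
#'
#' @param family_id Family to trace.
#' @param reference,target `annotated_genome`s.
#' @param blocks Optional precomputed [chain_anchors()] blocks.
#' @param border_tolerance See [classify_loss()].
#' @param ... Passed to [chain_anchors()] when blocks are computed here.
#' @return A classified loss-report tibble (one row per reference copy).
#' @export
trace_family_loss <- function(family_id, reference, target, blocks = NULL,
                              border_tolerance = 2, ...) {
  if (is.null(blocks)) {
    anchors <- find_anchors(reference, target)
    blocks <- chain_anchors(anchors, ...)
  }
  mapping <- map_family_locus(family_id, reference, target, blocks)
  rows <- lapply(seq_len(nrow(mapping)), function(i) {
    bid <- mapping$block_id[i]
    inv <- if (is.na(bid)) {
      tibble(start_rank_b = integer(), end_rank_b = integer())
    } else {
      blk <- blocks[blocks$block_id == bid, ]
      detect_inversions(chrom_pair_pseudo_block(blocks, blk$chrom_a,
                                                blk$chrom_b))
    }
    classify_loss(mapping[i, ], inv, border_tolerance)
  })
  bind_rows(rows)
}

# Pool every block's anchors on one chromosome pair into a pseudo-block
# whose consensus orientation is that of the highest-scoring block there.
# Chaining places a micro-inversion's anchors in their own small inverted
# block next to the main collinear block; pooling restores the local
# order flip so detect_inversions() can see it.
chrom_pair_pseudo_block <- function(blocks, chrom_a, chrom_b) {
  sub <- blocks |>
    filter(.data$chrom_a == !!chrom_a, .data$chrom_b == !!chrom_b) |>
    arrange(desc(.data$score))
  anc <- sub |>
    select("anchors") |>
    tidyr::unnest("anchors") |>
    distinct()
  list(anchors = anc, orientation = sub$orientation[1])
}
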