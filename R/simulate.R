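# Genome-evolution simulator: grows an annotated single-copy ancestor along
# a species tree, applying whole-genome multiplications, biased
# fractionation, tandem duplications, rearrangements, targeted losses and
# code-aware coding-sequence divergence, while logging every event so that
# downstream inference can be scored against ground truth.

#' Simulation parameters
#'
#' Collects the generative parameters of the simulator with documented
#' defaults. Probabilities are in `[0, 1]`; rates are per gene (or per site)
#' per unit branch time on the input tree's scale.
#'
#' @param seed Integer seed; the simulator draws every sample from one
#'   stream seeded here.
#' @param n_ancestral_genes,n_chromosomes Size of the single-copy ancestor.
#' @param n_codons Codons per coding sequence.
#' @param wg_multiplicity Default multiplicity of whole-genome events
#'   (3 = triplication).
#' @param retention_prob Probability that an extra post-polyploidy copy
#'   survives fractionation (one designated copy per family always
#'   survives).
#' @param retention_bias Named multipliers on `retention_prob` per gene
#'   label, emulating functionally biased retention.
#' @param tandem_rate Expected tandem duplications per gene per branch.
#' @param inversion_size_range Gene-count range for micro-inversions
#'   (uniform; default 20-30 genes).
#' @param syn_rate Synonymous substitutions per synonymous site per unit
#'   branch time, per lineage (a duplicate pair separated for time `t`
#'   targets Ks = `2 * syn_rate * t`).
#' @param nonsyn_rate Nonsynonymous substitutions per nonsynonymous site per
#'   unit time (default `0.2 * syn_rate`, i.e. purifying selection).
#' @param gap_mean Baseline intergenic gap in bp.
#' @param repeat_mean_bp Mean repeat bp inserted per intergenic gap.
#' @param repeat_depletion Multiplier on `repeat_mean_bp` inside retained
#'   runs (emulating preferential deletion of LTR retrotransposons there).
#' @param repeat_families,repeat_family_weights Repeat family vocabulary.
#' @param label_vocab,label_weights Functional label vocabulary for genes.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_ancestral_genes = 200L,
                       n_chromosomes = 2L,
                       n_codons = 300L,
                       wg_multiplicity = 3L,
                       retention_prob = 0.5,
                       retention_bias = c(fattyacid = 1),
                       tandem_rate = 0.01,
                       inversion_size_range = c(20L, 30L),
                       syn_rate = 0.5,
                       nonsyn_rate = 0.2 * syn_rate,
                       gap_mean = 2000,
                       repeat_mean_bp = 3000,
                       repeat_depletion = 0.5,
                       repeat_families = c("LTR", "DNA", "LINE"),
                       repeat_family_weights = c(0.7, 0.2, 0.1),
                       label_vocab = c("cellwall", "fattyacid", "other"),
                       label_weights = c(0.15, 0.15, 0.7)) {
  stopifnot(retention_prob >= 0, retention_prob <= 1,
            wg_multiplicity >= 2, all(inversion_size_range >= 2),
            n_ancestral_genes >= n_chromosomes)
  structure(as.list(environment()), class = "sim_params")
}

# ---- event log ------------------------------------------------------------

new_event_log <- function() {
  tibble(event = character(), branch = character(), time = numeric(),
         payload = list())
}

#' Retrieve the ground-truth event log attached to a simulated genome
#'
#' @param genome A simulated `annotated_genome`.
#' @return A tibble of events (`event`, `branch`, `time`, `payload`
#'   list-column).
#' @export
event_log <- function(genome) {
  attr(genome, "event_log") %||% new_event_log()
}

add_event <- function(genome, event, branch, time, payload) {
  log <- event_log(genome)
  log <- bind_rows(log, tibble(event = event, branch = branch,
                               time = time, payload = list(payload)))
  attr(genome, "event_log") <- log
  genome
}

# ---- coordinate layout ----------------------------------------------------

# Recompute bp coordinates from the logical gene order (`ord` column or
# current rank), with a fixed intergenic gap. Gene span = CDS length.
sim_relayout <- function(genome, gap = NULL) {
  gap <- gap %||% attr(genome, "gap_mean") %||% 2000
  g <- genome$genes
  if (!"ord" %in% names(g)) g$ord <- g$rank
  lens <- gene_span_lengths(genome, g$gene_id)
  g <- g |>
    mutate(.len = lens) |>
    arrange(.data$chrom, .data$ord) |>
    group_by(.data$chrom) |>
    mutate(start = as.integer(gap + cumsum(lag(.data$.len, default = 0)) +
                                gap * (seq_len(n()) - 1)),
           end = as.integer(.data$start + .data$.len - 1),
           rank = seq_len(n()) - 1L) |>
    ungroup() |>
    select(-".len", -"ord")
  genome$genes <- g
  genome$chromosomes <- g |>
    group_by(chrom = .data$chrom) |>
    summarise(length = max(.data$end) + gap, .groups = "drop")
  genome
}

gene_span_lengths <- function(genome, gene_ids) {
  if (is.null(genome$cds)) return(rep(1500, length(gene_ids)))
  l <- nchar(genome$cds)[gene_ids]
  ifelse(is.na(l), 1500, unname(l))
}

# ---- ancestor -------------------------------------------------------------

# Amino acids whose codon family is fourfold degenerate at the third
# position; restricting the ancestor to these makes synonymous evolution an
# exact Jukes-Cantor process on third positions.
fourfold_contexts <- c("GC", "GT", "AC", "CC", "GG", "TC")

#' Build the single-copy ancestral genome
#'
#' Every gene founds its own family, receives a random strand, a random
#' functional label and a random in-frame CDS drawn from fourfold-degenerate
#' codon families (no internal stops).
#'
#' @param params A [sim_params()] object. The caller (normally
#'   [simulate_dataset()]) is responsible for seeding the RNG.
#' @return An `annotated_genome` with an empty event log attached.
#' @export
build_ancestor <- function(params) {
  n <- params$n_ancestral_genes
  k <- params$n_chromosomes
  if (n < k) abort("fewer genes than chromosomes")
  ids <- sprintf("anc%05d", seq_len(n))
  # contiguous blocks of near-equal size
  sizes <- diff(floor(seq(0, n, length.out = k + 1)))
  chrom_of <- rep(paste0("chr", seq_len(k)), times = sizes)
  genes <- tibble(
    gene_id = ids,
    chrom = chrom_of,
    start = 0L, end = 0L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    family_id = sprintf("fam%05d", seq_len(n)),
    label = sample(params$label_vocab, n, replace = TRUE,
                   prob = params$label_weights),
    ord = ave(seq_len(n), chrom_of, FUN = seq_along)
  )
  cds <- random_cds(n, params$n_codons)
  names(cds) <- ids
  genome <- annotated_genome("ancestor", select(genes, -"ord"), cds = cds)
  attr(genome, "gap_mean") <- params$gap_mean
  genome <- sim_relayout(genome)
  attr(genome, "event_log") <- new_event_log()
  genome
}

random_cds <- function(n_genes, n_codons) {
  total <- n_genes * n_codons
  ctx <- sample(fourfold_contexts, total, replace = TRUE)
  b3 <- sample(c("T", "C", "A", "G"), total, replace = TRUE)
  codons <- paste0(ctx, b3)
  m <- matrix(codons, nrow = n_codons)
  apply(m, 2, paste0, collapse = "")
}

# ---- whole-genome multiplication ------------------------------------------

#' Apply a whole-genome multiplication (WGD/WGT)
#'
#' Each chromosome is copied `multiplicity - 1` extra times as new
#' chromosomes; copied genes keep their family and order. New gene ids are
#' suffixed with an event-unique tag so provenance stays reconstructible.
#'
#' @param genome An `annotated_genome` from the simulator.
#' @param multiplicity Total copy number after the event (>= 2).
#' @param branch,time Event-log coordinates.
#' @return The multiplied genome with the event logged.
#' @export
apply_wg_multiplication <- function(genome, multiplicity = 3,
                                    branch = "sim", time = 0) {
  stopifnot(multiplicity >= 2)
  n_prev <- nrow(event_log(genome))
  tag <- paste0("w", n_prev + 1)
  base <- genome$genes
  copies <- lapply(2:multiplicity, function(cc) {
    base |>
      mutate(gene_id = paste0(.data$gene_id, ".", tag, "c", cc),
             chrom = paste0(.data$chrom, "_", tag, "c", cc))
  })
  genome$genes <- bind_rows(base, copies)
  if (!is.null(genome$cds)) {
    extra <- lapply(2:multiplicity, function(cc) {
      x <- genome$cds
      names(x) <- paste0(names(x), ".", tag, "c", cc)
      x
    })
    genome$cds <- c(genome$cds, unlist(extra))
  }
  genome$genes$ord <- genome$genes$rank
  genome <- sim_relayout(genome)
  add_event(genome, "wg_multiplication", branch, time,
            list(multiplicity = multiplicity, tag = tag,
                 n_genes_before = nrow(base)))
}

# ---- fractionation --------------------------------------------------------

#' Apply biased fractionation to duplicated families
#'
#' Per family, one randomly designated copy always survives; every other
#' copy survives independently with probability
#' `retention_prob * retention_bias[label]` (capped at 1). Lost genes are
#' logged as `fractionation_loss`.
#'
#' @param genome A simulated `annotated_genome`.
#' @param retention_prob Survival probability for extra copies.
#' @param retention_bias Named per-label multipliers (labels absent from the
#'   vector get multiplier 1).
#' @param branch,time Event-log coordinates.
#' @return The fractionated genome.
#' @export
apply_fractionation <- function(genome, retention_prob,
                                retention_bias = c(other = 1),
                                branch = "sim", time = 0) {
  g <- genome$genes
  bias <- retention_bias[g$label]
  bias[is.na(bias)] <- 1
  p <- pmin(1, retention_prob * unname(bias))
  keep <- rep(TRUE, nrow(g))
  fam_idx <- split(seq_len(nrow(g)), g$family_id)
  for (idx in fam_idx) {
    if (length(idx) < 2) next
    designated <- idx[sample.int(length(idx), 1)]
    others <- setdiff(idx, designated)
    keep[others] <- runif(length(others)) < p[others]
  }
  lost <- g$gene_id[!keep]
  genome$genes <- g[keep, ]
  if (!is.null(genome$cds)) {
    genome$cds <- genome$cds[!names(genome$cds) %in% lost]
  }
  genome$genes$ord <- genome$genes$rank
  genome <- sim_relayout(genome)
  add_event(genome, "fractionation_loss", branch, time,
            list(retention_prob = retention_prob, lost_genes = lost))
}

# ---- tandem duplication ---------------------------------------------------

#' Apply tandem duplications
#'
#' Samples `Poisson(rate * n_genes)` genes (without replacement) and inserts
#' a copy immediately adjacent to each parent: same chromosome, same strand,
#' same family.
#'
#' @param genome A simulated `annotated_genome`.
#' @param rate Expected duplications per gene.
#' @param force_genes Optional character vector of gene ids to duplicate
#'   deterministically instead of sampling.
#' @param branch,time Event-log coordinates.
#' @return The genome with duplicates inserted and the event logged.
#' @export
apply_tandem_duplications <- function(genome, rate = 0.01,
                                      force_genes = NULL,
                                      branch = "sim", time = 0) {
  g <- genome$genes
  if (is.null(force_genes)) {
    n_dup <- rpois(1, rate * nrow(g))
    n_dup <- min(n_dup, nrow(g))
    chosen <- if (n_dup > 0) sample(g$gene_id, n_dup) else character(0)
  } else {
    chosen <- force_genes
  }
  if (length(chosen) == 0) {
    return(add_event(genome, "tandem_duplication", branch, time,
                     list(new_genes = character(0),
                          parent_genes = character(0))))
  }
  parents <- g |> filter(.data$gene_id %in% chosen)
  kids <- parents
  kids$gene_id <- make.unique(paste0(parents$gene_id, ".t1"), sep = "_")
  g$ord <- g$rank
  kids$ord <- parents$rank + 0.5
  genome$genes <- bind_rows(g, kids)
  if (!is.null(genome$cds)) {
    newcds <- genome$cds[parents$gene_id]
    names(newcds) <- kids$gene_id
    genome$cds <- c(genome$cds, newcds)
  }
  genome <- sim_relayout(genome)
  add_event(genome, "tandem_duplication", branch, time,
            list(new_genes = kids$gene_id, parent_genes = parents$gene_id))
}

# ---- rearrangements -------------------------------------------------------

#' Apply an inversion or translocation
#'
#' Inversions reverse gene order and flip every strand inside the rank
#' interval; translocations swap the chromosome tails distal to the two
#' breakpoints. Rank intervals are 0-based gene ranks, inclusive.
#'
#' @param genome A simulated `annotated_genome`.
#' @param kind One of `"inversion"`, `"micro_inversion"`, `"translocation"`.
#' @param chrom Chromosome carrying the interval (first chromosome for
#'   translocations).
#' @param start_rank,end_rank Inverted interval (inversions) or the first
#'   breakpoint (`start_rank`; translocations move ranks `>= start_rank`).
#' @param chrom2,break2 Second chromosome and breakpoint (translocations).
#' @param branch,time Event-log coordinates.
#' @return The rearranged genome.
#' @export
apply_rearrangement <- function(genome, kind = c("inversion",
                                                 "micro_inversion",
                                                 "translocation"),
                                chrom, start_rank, end_rank = NULL,
                                chrom2 = NULL, break2 = NULL,
                                branch = "sim", time = 0) {
  kind <- match.arg(kind)
  g <- genome$genes
  g$ord <- as.numeric(g$rank)
  on_chrom <- g$chrom == chrom
  max_rank <- max(g$rank[on_chrom])
  if (kind %in% c("inversion", "micro_inversion")) {
    if (start_rank < 0 || end_rank > max_rank || start_rank > end_rank) {
      abort("inversion interval crosses a chromosome end")
    }
    inside <- on_chrom & g$rank >= start_rank & g$rank <= end_rank
    g$ord[inside] <- start_rank + end_rank - g$rank[inside]
    g$strand[inside] <- ifelse(g$strand[inside] == "+", "-", "+")
    payload <- list(chrom = chrom, start_rank = start_rank,
                    end_rank = end_rank,
                    genes = g$gene_id[inside][order(g$ord[inside])])
    event <- "inversion"
  } else {
    if (is.null(chrom2) || is.null(break2)) {
      abort("translocation needs chrom2 and break2")
    }
    tail1 <- on_chrom & g$rank >= start_rank
    on2 <- g$chrom == chrom2
    tail2 <- on2 & g$rank >= break2
    g$chrom[tail1] <- chrom2
    g$ord[tail1] <- break2 + (g$ord[tail1] - start_rank)
    g$chrom[tail2] <- chrom
    g$ord[tail2] <- start_rank + (g$ord[tail2] - break2)
    payload <- list(chrom = chrom, break1 = start_rank,
                    chrom2 = chrom2, break2 = break2,
                    n_moved = sum(tail1) + sum(tail2))
    event <- "translocation"
  }
  genome$genes <- g
  genome <- sim_relayout(genome)
  add_event(genome, event, branch, time, payload)
}

# ---- targeted loss --------------------------------------------------------

#' Delete one family's copy, optionally at a micro-inversion border
#'
#' When `at_inversion_border` is set, a micro-inversion whose boundary gene
#' is the target is applied first (size drawn uniformly from
#' `params$inversion_size_range`), and the target is then deleted, leaving
#' the inversion breakpoint adjacent to the vacated locus -- the signature
#' of a single-gene loss caused by a local rearrangement.
#'
#' @param genome A simulated `annotated_genome`.
#' @param family_id Family whose (first) copy is deleted.
#' @param at_inversion_border Apply the bordering micro-inversion first?
#' @param inversion_size Optional fixed inversion size in genes.
#' @param params A [sim_params()] (for the default size range).
#' @param branch,time Event-log coordinates.
#' @return The genome with the loss (and any inversion) logged.
#' @export
apply_targeted_loss <- function(genome, family_id,
                                at_inversion_border = FALSE,
                                inversion_size = NULL,
                                params = sim_params(),
                                branch = "sim", time = 0) {
  g <- genome$genes
  hit <- which(g$family_id == family_id)
  if (length(hit) == 0) abort(paste0("family absent: ", family_id))
  hit <- hit[order(g$chrom[hit], g$rank[hit])][1]
  target_id <- g$gene_id[hit]
  chrom <- g$chrom[hit]
  r <- g$rank[hit]
  max_rank <- max(g$rank[g$chrom == chrom])
  inv_payload <- NULL
  if (at_inversion_border) {
    L <- inversion_size %||%
      sample(seq(params$inversion_size_range[1],
                 params$inversion_size_range[2]), 1)
    # keep the target on the interval border; shrink if the chromosome arm
    # is shorter than the drawn size
    room_right <- max_rank - r
    room_left <- r
    if (room_right >= L - 1) {
      s <- r; e <- r + L - 1
    } else if (room_left >= L - 1) {
      s <- r - L + 1; e <- r
    } else if (room_right >= room_left) {
      s <- r; e <- max_rank
    } else {
      s <- 0; e <- r
    }
    genome <- apply_rearrangement(genome, "micro_inversion", chrom,
                                  s, e, branch = branch, time = time)
    g <- genome$genes
    hit <- which(g$gene_id == target_id)
    inv_payload <- list(start_rank = s, end_rank = e, size = L)
  }
  lost_rank <- g$rank[hit]
  genome$genes <- g[-hit, ]
  if (!is.null(genome$cds)) {
    genome$cds <- genome$cds[names(genome$cds) != target_id]
  }
  genome$genes$ord <- genome$genes$rank
  genome <- sim_relayout(genome)
  add_event(genome, "targeted_gene_loss", branch, time,
            list(family_id = family_id, gene_id = target_id,
                 chrom = chrom, lost_rank = lost_rank,
                 inversion = inv_payload))
}

# ---- coding-sequence evolution --------------------------------------------

#' Evolve coding sequences along a branch
#'
#' Synonymous substitutions arrive per codon as a Poisson process at
#' `syn_rate` per synonymous site and move the third position uniformly
#' within its synonymous codon set (an exact Jukes-Cantor process at
#' fourfold-degenerate codons). Nonsynonymous substitutions hit first and
#' second positions as an independent Jukes-Cantor process at `nonsyn_rate`
#' per site; changes that would create a stop codon are rejected.
#' Substitution counts are logged.
#'
#' @param genome A simulated `annotated_genome` with CDS.
#' @param branch_time Branch duration.
#' @param syn_rate,nonsyn_rate Substitution rates per site per unit time.
#' @param branch,time Event-log coordinates.
#' @return The genome with mutated CDS.
#' @export
evolve_cds <- function(genome, branch_time, syn_rate = 0.5,
                       nonsyn_rate = 0.1, branch = "sim", time = 0) {
  if (is.null(genome$cds)) abort("genome has no CDS")
  if (branch_time <= 0) {
    return(add_event(genome, "cds_evolution", branch, time,
                     list(branch_time = branch_time, n_syn = 0L,
                          n_nonsyn = 0L)))
  }
  lens <- nchar(genome$cds)
  counts <- c(syn = 0, nonsyn = 0)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    m <- vapply(genome$cds[idx],
                function(s) match(strsplit(s, "")[[1]], ng86_bases),
                integer(L))
    dim(m) <- c(L, length(idx))
    out <- mutate_cds_matrix(m, branch_time, syn_rate, nonsyn_rate)
    counts <- counts + out$counts
    seqs <- apply(out$m, 2, function(col)
      paste0(ng86_bases[col], collapse = ""))
    genome$cds[idx] <- seqs
  }
  add_event(genome, "cds_evolution", branch, time,
            list(branch_time = branch_time,
                 n_syn = unname(counts["syn"]),
                 n_nonsyn = unname(counts["nonsyn"])))
}

# After k uniform moves on an s-state complete graph, probability of being
# back at the start: 1/s + (1 - 1/s) * (-1/(s-1))^k.
chain_stay_prob <- function(k, s) {
  1 / s + (1 - 1 / s) * (-1 / (s - 1))^k
}

# Third-position synonymous alternatives per codon index: a 64 x 3 matrix of
# alternative third-base codes (1..4 in TCAG order), NA-padded, plus the
# synonymous-set size s (including the current base).
syn3_tables <- function() {
  if (!is.null(.ng86_cache$syn3)) return(.ng86_cache$syn3)
  aa <- ng86_aa()
  alt <- matrix(NA_integer_, 64, 3)
  scount <- integer(64)
  for (i in seq_len(64)) {
    b3 <- (i - 1) %% 4 + 1
    base_i <- i - b3
    family <- base_i + 1:4
    syn <- which(aa[family] == aa[i] & aa[i] != "*")
    scount[i] <- length(syn)
    others <- setdiff(syn, b3)
    if (length(others) > 0) alt[i, seq_along(others)] <- others
  }
  .ng86_cache$syn3 <- list(alt = alt, s = scount)
  .ng86_cache$syn3
}

mutate_cds_matrix <- function(m, t, rs, rn) {
  L <- nrow(m)
  n_codons <- L %/% 3
  pos3 <- seq(3, L, by = 3)
  pos12 <- setdiff(seq_len(L), pos3)
  n_syn_events <- 0L
  n_nonsyn_events <- 0L

  if (rn > 0) {
    orig12 <- m[pos12, , drop = FALSE]
    k <- matrix(rpois(length(orig12), rn * t), nrow = nrow(orig12))
    hit <- k > 0
    if (any(hit)) {
      stay <- runif(sum(hit)) < chain_stay_prob(k[hit], 4)
      cur <- orig12[hit]
      draw <- ceiling(runif(sum(hit)) * 3)
      alt <- ((cur - 1 + draw) %% 4) + 1
      newb <- ifelse(stay, cur, alt)
      m12 <- orig12
      m12[hit] <- newb
      m[pos12, ] <- m12
      # reject codons that became stops: revert their pos1/2 bases
      ci <- 16L * (m[pos3 - 2, , drop = FALSE] - 1L) +
        4L * (m[pos3 - 1, , drop = FALSE] - 1L) +
        m[pos3, , drop = FALSE]
      stop_idx <- which(ng86_aa()[ci] == "*")
      if (length(stop_idx) > 0) {
        cod <- (stop_idx - 1) %% n_codons + 1
        col <- (stop_idx - 1) %/% n_codons + 1
        for (q in seq_along(stop_idx)) {
          rows <- (cod[q] - 1) * 3 + 1:2
          m[rows, col[q]] <- orig12[(cod[q] - 1) * 2 + 1:2, col[q]]
        }
      }
      n_nonsyn_events <- sum(m[pos12, ] != orig12)
    }
  }

  s3 <- syn3_tables()
  ci <- 16L * (m[pos3 - 2, , drop = FALSE] - 1L) +
    4L * (m[pos3 - 1, , drop = FALSE] - 1L) + m[pos3, , drop = FALSE]
  s <- s3$s[ci]
  dim(s) <- dim(ci)
  rate <- rs * t * pmax(s - 1, 0) / 3
  k <- matrix(rpois(length(ci), rate), nrow = nrow(ci))
  hit <- which(k > 0 & s >= 2)
  if (length(hit) > 0) {
    kk <- k[hit]
    ss <- s[hit]
    stay <- runif(length(hit)) < chain_stay_prob(kk, ss)
    pick <- ceiling(runif(length(hit)) * (ss - 1))
    alt_rows <- s3$alt[cbind(ci[hit], pick)]
    b3_new <- ifelse(stay, (ci[hit] - 1) %% 4 + 1, alt_rows)
    m3 <- m[pos3, , drop = FALSE]
    changed <- b3_new != m3[hit]
    m3[hit] <- b3_new
    m[pos3, ] <- m3
    n_syn_events <- sum(changed)
  }
  list(m = m, counts = c(syn = n_syn_events, nonsyn = n_nonsyn_events))
}
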