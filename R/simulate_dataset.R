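# Tree-level simulation: evolve the ancestor along a species tree, applying
# configured events per branch, and emit per-tip annotated genomes with a
# ground-truth event log and per-family retention truth.

#' Simulate a set of genomes along a species tree
#'
#' Builds the single-copy ancestor, walks the (binary, branch-length) tree
#' from the root and applies the configured events on each branch at their
#' stated positions, evolving coding sequences between events. Events whose
#' `clade` equals the full tip set are applied on the root stem (the tree's
#' `root.edge`). Every random draw comes from one stream seeded with
#' `params$seed`, so identical inputs give identical outputs.
#'
#' @param tree A `phylo` object or newick string with branch lengths (a root
#'   edge carries the pre-speciation stem).
#' @param params A [sim_params()] object.
#' @param events A list of event specifications; each is a list with
#'   `clade` (character vector of descendant tip labels identifying the
#'   branch), `time_frac` (position along the branch in `[0, 1]`), `type`
#'   (one of `wg_multiplication`, `fractionation`, `tandem_duplication`,
#'   `inversion`, `translocation`, `targeted_loss`) and type-specific
#'   arguments (`multiplicity`, `retention_prob`, `rate`, `family_id`,
#'   `at_inversion_border`, `chrom`, `start_rank`, `end_rank`, ...).
#' @param out_dir Optional directory; when given, per-species GFF3 + CDS
#'   FASTA + repeat BED, a combined family TSV, the tree and the truth log
#'   (JSON) are written there.
#' @return A list of class `sim_dataset`: `genomes` (named list of
#'   `annotated_genome`), `truth` (named list of per-family retention
#'   tibbles), `log` (combined event log), `params`, `tree`, and `files`
#'   when `out_dir` was given.
#' @export
simulate_dataset <- function(tree, params = sim_params(), events = list(),
                             out_dir = NULL) {
  tr <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
  if (is.null(tr)) abort("could not parse tree")
  if (!ape::is.rooted(tr) || !ape::is.binary(tr)) {
    abort("tree must be rooted and fully bifurcating (no polytomies)")
  }
  set.seed(params$seed)
  tips <- tr$tip.label
  anc <- build_ancestor(params)

  find_events <- function(clade_tips) {
    evs <- keep(events, function(e) setequal(e$clade, clade_tips))
    evs[order(map_dbl(evs, function(e) e$time_frac %||% 0))]
  }
  branch_name <- function(clade_tips) paste(sort(clade_tips), collapse = ",")

  apply_one <- function(genome, ev, bn, mult) {
    f <- ev$time_frac %||% 0
    switch(
      ev$type,
      wg_multiplication = {
        m <- ev$multiplicity %||% params$wg_multiplicity
        list(genome = apply_wg_multiplication(genome, m, branch = bn,
                                              time = f),
             mult = mult * m)
      },
      fractionation = list(
        genome = apply_fractionation(
          genome, ev$retention_prob %||% params$retention_prob,
          ev$retention_bias %||% params$retention_bias,
          branch = bn, time = f),
        mult = mult),
      tandem_duplication = list(
        genome = apply_tandem_duplications(
          genome, ev$rate %||% params$tandem_rate,
          force_genes = ev$force_genes, branch = bn, time = f),
        mult = mult),
      inversion = list(
        genome = apply_rearrangement(
          genome, "inversion", ev$chrom, ev$start_rank, ev$end_rank,
          branch = bn, time = f),
        mult = mult),
      translocation = list(
        genome = apply_rearrangement(
          genome, "translocation", ev$chrom, ev$start_rank,
          chrom2 = ev$chrom2, break2 = ev$break2, branch = bn, time = f),
        mult = mult),
      targeted_loss = list(
        genome = apply_targeted_loss(
          genome, ev$family_id,
          at_inversion_border = isTRUE(ev$at_inversion_border),
          inversion_size = ev$inversion_size, params = params,
          branch = bn, time = f),
        mult = mult),
      abort(paste0("unknown event type: ", ev$type))
    )
  }

  run_branch <- function(genome, clade_tips, len, mult) {
    bn <- branch_name(clade_tips)
    evs <- find_events(clade_tips)
    prev <- 0
    for (ev in evs) {
      f <- ev$time_frac %||% 0
      dt <- (f - prev) * len
      if (dt > 0) {
        genome <- evolve_cds(genome, dt, params$syn_rate,
                             params$nonsyn_rate, branch = bn, time = prev)
      }
      out <- apply_one(genome, ev, bn, mult)
      genome <- out$genome
      mult <- out$mult
      prev <- f
    }
    if ((1 - prev) * len > 0) {
      genome <- evolve_cds(genome, (1 - prev) * len, params$syn_rate,
                           params$nonsyn_rate, branch = bn, time = prev)
    }
    list(genome = genome, mult = mult)
  }

  tip_states <- list()
  walk_node <- function(node, genome, mult) {
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    for (child in kids) {
      el <- tr$edge.length[which(tr$edge[, 1] == node &
                                   tr$edge[, 2] == child)]
      clade_tips <- if (child <= length(tips)) tips[child] else
        tips[unlist(phangorn_free_descendants(tr, child))]
      out <- run_branch(genome, clade_tips, el, mult)
      if (child <= length(tips)) {
        tip_states[[tips[child]]] <<- out
      } else {
        walk_node(child, out$genome, out$mult)
      }
    }
  }

  root <- length(tips) + 1L
  root_len <- tr$root.edge %||% 0
  state <- run_branch(anc, tips, root_len, 1)
  walk_node(root, state$genome, state$mult)

  # per-tip truth: family copy number vs the full post-polyploidy complement
  truth <- imap(tip_states, function(st, sp) {
    st$genome$genes |>
      count(family_id = .data$family_id, name = "n_copies") |>
      mutate(full_multiplicity = st$mult,
             fully_retained = .data$n_copies >= st$mult)
  })

  # focal species (largest multiplicity) defines which families count as
  # fully retained for repeat-landscape purposes
  mults <- map_dbl(tip_states, "mult")
  focal <- names(which.max(mults))
  retained_fams <- truth[[focal]]$family_id[truth[[focal]]$fully_retained]

  genomes <- imap(tip_states, function(st, sp) {
    g <- st$genome
    g$species <- sp
    g$genes$species <- sp
    old_ids <- g$genes$gene_id
    new_ids <- paste0(sp, "_", old_ids)
    g$genes$core_id <- old_ids
    g$genes$gene_id <- new_ids
    if (!is.null(g$cds)) {
      g$cds <- g$cds[old_ids]
      names(g$cds) <- new_ids
    }
    finalize_repeat_landscape(g, params,
                              g$genes$family_id %in% retained_fams)
  })

  combined_log <- bind_rows(imap(genomes, function(g, sp) {
    mutate(event_log(g), tip = sp)
  }))

  res <- structure(
    list(genomes = genomes, truth = truth, log = combined_log,
         params = params, tree = tr, focal_species = focal),
    class = "sim_dataset"
  )
  if (!is.null(out_dir)) res$files <- write_sim_dataset(res, out_dir)
  res
}

# internal: free (non-phangorn) descendant tips of an internal node
phangorn_free_descendants <- function(tr, node) {
  n_tip <- length(tr$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    cur <- stack[[1]]
    stack <- stack[-1]
    kids <- tr$edge[tr$edge[, 1] == cur, 2]
    out <- c(out, kids[kids <= n_tip])
    stack <- c(stack, kids[kids > n_tip])
  }
  list(out)
}

# Lay out final bp coordinates with a stochastic repeat landscape: each
# intergenic gap gets a baseline spacer plus an exponentially distributed
# repeat tract whose mean is multiplied by `repeat_depletion` inside
# retained runs (>= 3 consecutive fully retained genes, tolerating one
# interloper -- the same run convention the TRR caller defaults to). This
# couples retained runs to shorter, repeat-poor intergenic space (higher
# genic fraction, lower repeat fraction), the landscape the TRR
# composition test probes.
finalize_repeat_landscape <- function(genome, params, retained_flag) {
  g <- genome$genes |> arrange(.data$chrom, .data$rank)
  retained_flag <- retained_flag[order(genome$genes$chrom,
                                       genome$genes$rank)]
  in_run <- unlist(lapply(split(retained_flag, g$chrom), function(fl) {
    runs <- qualifying_runs(fl, min_run = 3, max_gap = 1)
    out <- logical(length(fl))
    for (i in seq_len(nrow(runs))) out[runs$from[i]:runs$to[i]] <- TRUE
    out
  })[unique(g$chrom)], use.names = FALSE)
  lens <- gene_span_lengths(genome, g$gene_id)
  dep <- ifelse(in_run, params$repeat_depletion, 1)
  rep_bp <- round(rexp(nrow(g), rate = 1 / pmax(params$repeat_mean_bp *
                                                  dep, 1)))
  spacer <- round(params$gap_mean * runif(nrow(g), 0.5, 1.5))
  gaps <- spacer + rep_bp
  reps <- vector("list", 0)
  starts <- integer(nrow(g))
  per_chrom <- split(seq_len(nrow(g)), g$chrom)
  for (idx in per_chrom) {
    pos <- params$gap_mean
    for (i in idx) {
      starts[i] <- pos + 1
      pos <- pos + lens[i]
      if (rep_bp[i] >= 50) {
        reps[[length(reps) + 1]] <- tibble(
          chrom = g$chrom[i],
          start = as.integer(pos + spacer[i] %/% 2 + 1),
          end = as.integer(pos + spacer[i] %/% 2 + rep_bp[i]),
          family = sample(params$repeat_families, 1,
                          prob = params$repeat_family_weights)
        )
      }
      pos <- pos + gaps[i]
    }
  }
  g$start <- as.integer(starts)
  g$end <- as.integer(starts + lens - 1)
  g$retained_run <- in_run
  genome$genes <- g
  genome$repeats <- if (length(reps)) bind_rows(reps) else genome$repeats
  genome$chromosomes <- g |>
    group_by(chrom = .data$chrom) |>
    summarise(length = max(.data$end), .groups = "drop") |>
    left_join(
      if (length(reps)) bind_rows(reps) |>
        group_by(chrom = .data$chrom) |>
        summarise(rep_end = max(.data$end), .groups = "drop")
      else tibble(chrom = character(), rep_end = numeric()),
      by = "chrom") |>
    mutate(length = pmax(.data$length, .data$rep_end, na.rm = TRUE) +
             params$gap_mean) |>
    select("chrom", "length")
  genome
}

#' Combined gene-family table of a simulated dataset
#'
#' @param genomes A named list of `annotated_genome`s (or a `sim_dataset`).
#' @return A membership tibble with columns `family_id`, `species`,
#'   `gene_id`.
#' @export
family_table_from_genomes <- function(genomes) {
  if (inherits(genomes, "sim_dataset")) genomes <- genomes$genomes
  bind_rows(lapply(genomes, function(g) {
    select(g$genes, "family_id", "species", "gene_id")
  }))
}

#' Write a simulated dataset to standard formats
#'
#' Per species: GFF3 + CDS FASTA + repeat BED4; plus a combined family TSV,
#' the species tree (newick) and the truth log as JSON.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory.
#' @return A tibble of files written.
#' @export
write_sim_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- bind_rows(imap(dataset$genomes, function(g, sp) {
    write_genome(g, dir, prefix = sp) |> mutate(species = sp)
  }))
  fam_path <- file.path(dir, "families.tsv")
  readr::write_tsv(family_table_from_genomes(dataset), fam_path,
                   progress = FALSE)
  tree_path <- file.path(dir, "tree.nwk")
  ape::write.tree(dataset$tree, file = tree_path)
  truth_path <- file.path(dir, "truth.json")
  truth_json <- list(
    focal_species = dataset$focal_species,
    truth = lapply(dataset$truth, function(t) as.list(t)),
    events = lapply(seq_len(nrow(dataset$log)), function(i) {
      list(event = dataset$log$event[i], branch = dataset$log$branch[i],
           time = dataset$log$time[i], tip = dataset$log$tip[i],
           payload = dataset$log$payload[[i]])
    })
  )
  jsonlite::write_json(truth_json, truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  bind_rows(files,
            tibble(kind = c("families", "tree", "truth"),
                   path = c(fam_path, tree_path, truth_path),
                   species = NA_character_))
}

#' The canonical three-taxon demonstration scenario
#'
#' Two ingroups (`A`, `B`) and one outgroup (`O`). The outgroup carries only
#' an old whole-genome triplication on the root stem (paralog Ks 1.6, the
#' ancient-eudicot-triplication regime); the ingroups share that event plus
#' a younger triplication on their stem at Ks 0.8, shortly after the
#' ingroup/outgroup split (ortholog Ks 0.85). Each triplication is followed
#' by biased fractionation, and the ingroup stem carries a single-gene
#' targeted loss at the border of a 20-30-gene micro-inversion. With the
#' default clock (`syn_rate = 0.5` per site per unit time, so pairwise
#' Ks = 2 x 0.5 x divergence time), branch lengths are in Ks units.
#'
#' @param n_ancestral_genes,n_chromosomes,n_codons Ancestor size.
#' @param seed RNG seed.
#' @param retention_prob Fractionation survival probability.
#' @param retention_bias Per-label retention multipliers (default favours
#'   `fattyacid`-labelled genes 1.6x).
#' @param tandem_rate Tandem duplications per gene on each terminal branch.
#' @param loss_family Family deleted at a micro-inversion border on the
#'   ingroup stem (default: the family founded by the 100th ancestral
#'   gene).
#' @return A list with `tree`, `params`, `events`, ready for
#'   [simulate_dataset()].
#' @export
trio_scenario <- function(n_ancestral_genes = 800, n_chromosomes = 2,
                          n_codons = 500, seed = 1,
                          retention_prob = 0.5,
                          retention_bias = c(fattyacid = 1.6),
                          tandem_rate = 0.02,
                          loss_family = sprintf("fam%05d",
                                                min(100,
                                                    n_ancestral_genes))) {
  params <- sim_params(
    seed = seed, n_ancestral_genes = n_ancestral_genes,
    n_chromosomes = n_chromosomes, n_codons = n_codons,
    retention_prob = retention_prob, retention_bias = retention_bias,
    tandem_rate = tandem_rate, syn_rate = 0.5, nonsyn_rate = 0.1
  )
  tree <- "((A:0.4,B:0.4):0.45,O:0.85):0.75;"
  events <- list(
    # old triplication at the start of the root stem (age 1.6 => Ks 1.6)
    list(clade = c("A", "B", "O"), time_frac = 0, type = "wg_multiplication",
         multiplicity = 3),
    list(clade = c("A", "B", "O"), time_frac = 0.05,
         type = "fractionation"),
    # young shared triplication shortly after the A,B | O split:
    # branch spans ages [0.85, 0.40]; frac 1/9 puts it at age 0.8 => Ks 0.8
    list(clade = c("A", "B"), time_frac = 1 / 9,
         type = "wg_multiplication", multiplicity = 3),
    list(clade = c("A", "B"), time_frac = 0.2, type = "fractionation"),
    # the focal single-gene loss at a micro-inversion border
    list(clade = c("A", "B"), time_frac = 0.5, type = "targeted_loss",
         family_id = loss_family, at_inversion_border = TRUE),
    # background tandem duplication on the terminal branches
    list(clade = "A", time_frac = 0.5, type = "tandem_duplication"),
    list(clade = "B", time_frac = 0.5, type = "tandem_duplication")
  )
  list(tree = tree, params = params, events = events)
}
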