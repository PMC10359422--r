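# End-to-end orchestration of the demonstration workflow: simulate (or
# load) genomes, chain synteny, estimate Ks and classify polyploidy events,
# call TRRs with composition and enrichment statistics, trace the focal
# gene loss, and classify duplication mechanisms -- with a deterministic
# manifest so identical configurations reproduce identical outputs.

#' Default demonstration configuration (simulated three-taxon dataset)
#'
#' @param seed Seed recorded in the config and used for every stage.
#' @param out_dir Output directory.
#' @param n_ancestral_genes,n_codons Scenario size (see [trio_scenario()]).
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
default_demo_config <- function(seed = 1, out_dir = tempfile("paleorun"),
                                n_ancestral_genes = 400, n_codons = 300) {
  list(
    seed = seed,
    out_dir = out_dir,
    scenario = list(n_ancestral_genes = n_ancestral_genes,
                    n_codons = n_codons),
    synteny = list(min_block_anchors = 5, max_gap_genes = 25,
                   gap_penalty = 0.2),
    ks = list(max_components = 4, ks_range = c(0.01, 3), min_values = 50),
    trr = list(reference = "O", target = "A", k = 3, min_copies = 3,
               min_run = 3, max_gap = 1, window_width = 3e4,
               window_step = 3e4, fdr_threshold = 0.01),
    loss = list(border_tolerance = 2),
    families = list(max_intervening = 10)
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> synteny -> Ks -> event classification -> TRR
#' calling -> composition/enrichment -> loss tracing -> family dynamics on
#' a configuration (a list or a YAML file path). Every output file is
#' listed in `manifest.json` together with its MD5 checksum, the full
#' parameter set and the seed, so two runs with identical configuration
#' produce byte-identical manifests. A stage failure halts the pipeline,
#' leaving partial outputs and a `FAILED` marker naming the stage. When the
#' dataset carries no coding sequences the Ks stage (and the stages that
#' need it) are skipped with a logged reason.
#'
#' @param config Configuration list (see [default_demo_config()]) or path
#'   to a YAML file with the same structure.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with `manifest` (the manifest as written),
#'   `results` (in-memory stage results) and `out_dir`.
#' @export
run_pipeline <- function(config = default_demo_config(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) inform(paste0("[paleoretain] ", ...))
  files <- character(0)
  stages <- list()
  results <- list()

  record <- function(stage, status, outputs = character(0),
                     reason = NULL) {
    stages[[stage]] <<- list(status = status,
                             outputs = basename(outputs),
                             reason = reason)
    files <<- c(files, outputs)
  }
  run_stage <- function(stage, fn) {
    say("stage: ", stage)
    tryCatch(fn(), error = function(e) {
      marker <- file.path(out_dir, "FAILED")
      writeLines(paste0("stage ", stage, " failed: ",
                        conditionMessage(e)), marker)
      abort(paste0("pipeline halted at stage '", stage, "': ",
                   conditionMessage(e)))
    })
  }

  # ---- simulate -----------------------------------------------------------
  run_stage("simulate", function() {
    sc_args <- config$scenario %||% list()
    sc_args$seed <- config$seed
    sc <- do.call(trio_scenario, sc_args)
    ds <- simulate_dataset(sc$tree, sc$params, sc$events,
                           out_dir = file.path(out_dir, "data"))
    results$dataset <<- ds
    results$loss_family <<- keep(sc$events, function(e)
      e$type == "targeted_loss")[[1]]$family_id
    record("simulate", "ok", ds$files$path)
  })
  ds <- results$dataset
  gA <- ds$genomes$A; gB <- ds$genomes$B; gO <- ds$genomes$O

  # ---- synteny ------------------------------------------------------------
  run_stage("synteny", function() {
    syn <- config$synteny
    pairs <- list(
      `O|A` = list(gO, gA), `O|B` = list(gO, gB), `A|B` = list(gA, gB),
      `A|A` = list(gA, gA), `B|B` = list(gB, gB), `O|O` = list(gO, gO)
    )
    blocks <- imap(pairs, function(p, nm) {
      anchors <- find_anchors(p[[1]], p[[2]])
      chain_anchors(anchors, gap_penalty = syn$gap_penalty,
                    max_gap_genes = syn$max_gap_genes,
                    min_block_anchors = syn$min_block_anchors)
    })
    results$blocks <<- blocks
    paths <- imap(blocks, function(b, nm) {
      p <- file.path(out_dir, paste0("blocks_", gsub("\\|", "_", nm),
                                     ".tsv"))
      write_blocks_tsv(b, p)
      p
    })
    record("synteny", "ok", unlist(paths))
  })

  # ---- ks -----------------------------------------------------------------
  has_cds <- !is.null(gA$cds) && !is.null(gO$cds)
  if (!has_cds) {
    record("ks", "skipped", reason = "no coding sequences in dataset")
    record("events", "skipped", reason = "requires the Ks stage")
  } else {
    run_stage("ks", function() {
      cds_of <- list(A = gA$cds, B = gB$cds, O = gO$cds)
      ks_tables <- imap(results$blocks, function(b, nm) {
        sp <- strsplit(nm, "|", fixed = TRUE)[[1]]
        anc <- block_anchor_table(b)
        if (nrow(anc) == 0) return(anc)
        ks_for_pairs(anc, cds_of[[sp[1]]], cds_of[[sp[2]]])
      })
      results$ks_tables <<- ks_tables
      paths <- imap(ks_tables, function(k, nm) {
        p <- file.path(out_dir, paste0("ks_", gsub("\\|", "_", nm),
                                       ".tsv"))
        readr::write_tsv(select(k, -any_of("family_id")), p,
                         progress = FALSE)
        p
      })
      kcfg <- config$ks
      fit_one <- function(nm) {
        fit_ks_peaks(ks_tables[[nm]]$ks,
                     max_components = kcfg$max_components,
                     ks_range = kcfg$ks_range,
                     min_values = kcfg$min_values)
      }
      results$paralog_models <<- list(A = fit_one("A|A"),
                                      B = fit_one("B|B"),
                                      O = fit_one("O|O"))
      results$ortholog_models <<- list(`A|B` = fit_one("A|B"),
                                       `A|O` = fit_one("O|A"),
                                       `B|O` = fit_one("O|B"))
      mp <- file.path(out_dir, "ks_peak_models.json")
      jsonlite::write_json(
        list(paralog = lapply(results$paralog_models, tidy),
             ortholog = lapply(results$ortholog_models, tidy)),
        mp, auto_unbox = TRUE, digits = NA, dataframe = "columns")
      record("ks", "ok", c(unlist(paths), mp))
    })

    # ---- event classification --------------------------------------------
    run_stage("events", function() {
      ev <- classify_wg_events(results$paralog_models,
                               results$ortholog_models,
                               ds$tree)
      results$events <<- ev
      p <- file.path(out_dir, "wg_events.tsv")
      readr::write_tsv(ev, p, progress = FALSE)
      record("events", "ok", p)
    })
  }

  # ---- TRR ----------------------------------------------------------------
  run_stage("trr", function() {
    tc <- config$trr
    ref <- ds$genomes[[tc$reference]]
    blocks <- results$blocks[[paste0(tc$reference, "|", tc$target)]]
    layout <- best_k_layout(blocks, ref, k = tc$k)
    depth <- syntenic_depth(layout)
    trrs <- call_trrs(depth, ref, min_copies = tc$min_copies,
                      min_run = tc$min_run, max_gap = tc$max_gap)
    results$layout <<- layout
    results$depth <<- depth
    results$trrs <<- trrs

    wins <- genome_windows(ref, width = tc$window_width,
                           step = tc$window_step)
    comp <- window_composition(ref, wins) |>
      assign_windows_to_trrs(trrs)
    results$composition <<- comp
    comp_test <- compare_composition(comp)
    results$composition_test <<- comp_test

    trr_genes <- unique(unlist(trrs$gene_ids))
    labels <- ref$genes |>
      transmute(element_id = .data$gene_id, category = .data$label)
    enr <- hypergeom_enrichment(trr_genes, ref$genes$gene_id, labels,
                                threshold = tc$fdr_threshold)
    results$label_enrichment <<- enr

    p1 <- file.path(out_dir, "trrs.bed")
    write_trr_bed(trrs, p1)
    p2 <- file.path(out_dir, "trr_composition_test.tsv")
    readr::write_tsv(comp_test, p2, progress = FALSE)
    p3 <- file.path(out_dir, "trr_label_enrichment.tsv")
    readr::write_tsv(enr, p3, progress = FALSE)
    p4 <- file.path(out_dir, "syntenic_depth.tsv")
    readr::write_tsv(depth, p4, progress = FALSE)
    record("trr", "ok", c(p1, p2, p3, p4))
  })

  # ---- loss tracing -------------------------------------------------------
  run_stage("loss", function() {
    tc <- config$trr
    ref <- ds$genomes[[tc$reference]]
    tgt <- ds$genomes[[tc$target]]
    blocks <- results$blocks[[paste0(tc$reference, "|", tc$target)]]
    rep_ <- trace_family_loss(results$loss_family, ref, tgt,
                              blocks = blocks,
                              border_tolerance =
                                config$loss$border_tolerance)
    results$loss_report <<- rep_
    p <- file.path(out_dir, "loss_report.tsv")
    readr::write_tsv(rep_, p, progress = FALSE)
    record("loss", "ok", p)
  })

  # ---- family dynamics ----------------------------------------------------
  run_stage("families", function() {
    fc <- config$families
    self_blocks <- results$blocks$`A|A`
    pairs <- find_anchors(gA, gA) |>
      select("gene_a", "gene_b", "family_id")
    calls <- classify_duplication(pairs, gA, self_blocks,
                                  max_intervening = fc$max_intervening)
    results$duplication_calls <<- calls
    p1 <- file.path(out_dir, "duplication_calls.tsv")
    readr::write_tsv(calls, p1, progress = FALSE)
    outputs <- p1
    if (!is.null(results$ks_tables)) {
      sel <- kaks_selection_summary(results$ks_tables$`A|A`)
      results$selection_summary <<- sel
      p2 <- file.path(out_dir, "selection_summary.tsv")
      readr::write_tsv(sel, p2, progress = FALSE)
      outputs <- c(outputs, p2)
    }
    fam_tab <- family_table_from_genomes(ds)
    lcn <- select_lcn(fam_tab, required_species = "O",
                      other_species = c("A", "B"), min_other_single = 1)
    results$lcn <<- lcn
    p3 <- file.path(out_dir, "lcn_families.txt")
    writeLines(lcn, p3)
    record("families", "ok", c(outputs, p3))
  })

  # ---- manifest -----------------------------------------------------------
  manifest <- list(
    package = "paleoretain",
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    stages = stages,
    files = lapply(sort(files), function(f) {
      list(name = basename(f),
           md5 = unname(tools::md5sum(f)))
    })
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("done: ", mp)
  invisible(list(manifest = manifest, results = results,
                 out_dir = out_dir))
}

# flat anchor table of a block set (one row per anchor with block_id)
block_anchor_table <- function(blocks) {
  if (nrow(blocks) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  block_id = character()))
  }
  blocks |>
    select("block_id", "anchors") |>
    tidyr::unnest("anchors") |>
    select("gene_a", "gene_b", "block_id")
}

#' Write synteny blocks as TSV
#'
#' One row per anchor with its block metadata -- a flat dialect readily
#' convertible to MCScan-style anchor files.
#'
#' @param blocks [chain_anchors()] output.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_blocks_tsv <- function(blocks, path) {
  flat <- if (nrow(blocks) == 0) {
    tibble(block_id = character(), chrom_a = character(),
           chrom_b = character(), orientation = character(),
           score = numeric(), gene_a = character(), gene_b = character())
  } else {
    blocks |>
      select("block_id", "chrom_a", "chrom_b", "orientation", "score",
             "anchors") |>
      tidyr::unnest("anchors", names_sep = ".") |>
      select("block_id", "chrom_a", "chrom_b", "orientation", "score",
             gene_a = "anchors.gene_a", gene_b = "anchors.gene_b")
  }
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' Write TRR intervals as BED (0-based half-open)
#'
#' @param trrs [call_trrs()] output.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_trr_bed <- function(trrs, path) {
  lines <- sprintf("%s\t%d\t%d\tTRR_%03d\t%d", trrs$chrom,
                   as.integer(trrs$start_bp - 1),
                   as.integer(trrs$end_bp),
                   seq_len(nrow(trrs)), trrs$n_qualifying)
  writeLines(lines, path)
  invisible(path)
}
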