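#' Load an annotated genome from GFF3 (and optional CDS FASTA)
#'
#' Reads gene models from a GFF3 file (features of type `gene`, or all
#' features when no `gene` rows are present). The attributes `ID`,
#' `family_id` and `label` are used when available; `family_id` defaults to
#' the gene's own ID (singleton family) and `label` to `"other"`. Chromosome
#' lengths come from `##sequence-region` pragmas when present, otherwise from
#' the furthest annotated gene end.
#'
#' @param gff_path Path to a GFF3 file.
#' @param fasta_path Optional path to a FASTA of coding sequences, one record
#'   per `gene_id` (description after the first whitespace is dropped).
#' @param species Species name; defaults to the GFF3 file name stem.
#' @return An [annotated_genome()].
#' @export
load_genome <- function(gff_path, fasta_path = NULL, species = NULL) {
  if (!file.exists(gff_path)) abort(paste0("no such file: ", gff_path))
  validate_gff3_lines(gff_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  if (is.null(species)) {
    species <- sub("\\.gff3?$", "", basename(gff_path))
  }
  keep <- if ("type" %in% names(S4Vectors::mcols(gr)) &&
              any(gr$type == "gene")) gr[gr$type == "gene"] else gr
  md <- S4Vectors::mcols(keep)
  genes <- tibble(
    gene_id = as.character(md$ID %||% paste0("g", seq_along(keep))),
    chrom = as.character(GenomicRanges::seqnames(keep)),
    start = GenomicRanges::start(keep),
    end = GenomicRanges::end(keep),
    strand = as.character(GenomicRanges::strand(keep))
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  if ("family_id" %in% names(md)) {
    genes$family_id <- as.character(md$family_id)
  }
  if ("label" %in% names(md)) genes$label <- as.character(md$label)

  sl <- GenomeInfoDb::seqlengths(keep)
  chromosomes <- NULL
  if (length(sl) > 0 && !all(is.na(sl))) {
    chromosomes <- tibble(chrom = names(sl), length = as.numeric(sl)) |>
      filter(!is.na(.data$length))
    miss <- setdiff(unique(genes$chrom), chromosomes$chrom)
    if (length(miss) > 0) chromosomes <- NULL
  }
  cds <- NULL
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::readDNAStringSet(fasta_path)
    cds <- as.character(seqs)
    names(cds) <- sub("\\s.*$", "", names(seqs))
  }
  annotated_genome(species, genes, chromosomes = chromosomes, cds = cds)
}

# Minimal structural validation so malformed lines fail with a line number
# (rtracklayer's own errors do not name the offending line).
validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body) == 0) return(invisible(TRUE))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nfield != 9]
  if (length(bad) > 0) {
    abort(paste0("malformed GFF3 line ", bad[1], " in ", path,
                 ": expected 9 tab-separated fields, got ",
                 nfield[body == bad[1]][1]))
  }
  invisible(TRUE)
}

#' Load repeat intervals from BED4
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention. Overlapping or book-ended intervals of the
#' same repeat family on the same chromosome are merged. Records with
#' `end <= start` are rejected with a warning.
#'
#' @param bed_path Path to a BED file whose 4th column is the repeat family.
#' @return A tibble with `chrom`, `start`, `end`, `family`.
#' @export
load_repeats <- function(bed_path) {
  reps <- readr::read_tsv(
    bed_path,
    col_names = c("chrom", "bed_start", "bed_end", "family"),
    col_types = readr::cols(
      chrom = readr::col_character(), bed_start = readr::col_double(),
      bed_end = readr::col_double(), family = readr::col_character()
    ),
    comment = "#", progress = FALSE
  )
  bad <- reps$bed_end <= reps$bed_start
  if (any(bad)) {
    warn(paste0(sum(bad), " BED record(s) with end <= start rejected"))
    reps <- reps[!bad, ]
  }
  reps |>
    mutate(start = as.integer(.data$bed_start + 1),
           end = as.integer(.data$bed_end)) |>
    select("chrom", "start", "end", "family") |>
    merge_repeat_intervals()
}

# merge overlapping/adjacent intervals per (chrom, family)
merge_repeat_intervals <- function(reps) {
  if (nrow(reps) == 0) return(reps)
  reps |>
    group_by(.data$chrom, .data$family) |>
    arrange(.data$start, .data$end, .by_group = TRUE) |>
    mutate(grp = cumsum(.data$start > lag(cummax(as.numeric(.data$end)),
                                          default = -Inf) + 1)) |>
    group_by(.data$chrom, .data$family, .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    select("chrom", "start", "end", "family") |>
    arrange(.data$chrom, .data$start)
}

#' Load a gene-family (orthogroup) membership table
#'
#' @param tsv_path Path to a TSV with columns `family_id`, `species`,
#'   `gene_id` (header required).
#' @return A tibble of memberships. A duplicated `(species, gene_id)` pair
#'   assigned to two different families is an error.
#' @export
load_family_table <- function(tsv_path) {
  tab <- readr::read_tsv(
    tsv_path,
    col_types = readr::cols(
      family_id = readr::col_character(),
      species = readr::col_character(),
      gene_id = readr::col_character()
    ),
    progress = FALSE
  )
  validate_family_table(tab)
}

validate_family_table <- function(tab) {
  tab <- as_tibble(tab)[, c("family_id", "species", "gene_id")]
  conflict <- tab |>
    distinct() |>
    count(.data$species, .data$gene_id) |>
    filter(.data$n > 1)
  if (nrow(conflict) > 0) {
    abort(paste0("gene(s) assigned to conflicting families, e.g. ",
                 conflict$species[1], "/", conflict$gene_id[1]))
  }
  distinct(tab)
}

#' Write a genome back to standard formats
#'
#' Emits the same dialects the loaders read: GFF3 gene models (with
#' `family_id` and `label` attributes and `##sequence-region` pragmas), a
#' CDS FASTA when sequences are present, and a BED4 repeat file when repeats
#' are present.
#'
#' @param genome An `annotated_genome`.
#' @param dir Output directory (created if needed).
#' @param prefix File name stem; defaults to the species name.
#' @return A tibble of the files written (`kind`, `path`).
#' @export
write_genome <- function(genome, dir, prefix = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- prefix %||% genome$species
  out <- list()

  gff <- file.path(dir, paste0(prefix, ".gff3"))
  g <- genome$genes
  header <- c("##gff-version 3",
              sprintf("##sequence-region %s 1 %d",
                      genome$chromosomes$chrom,
                      as.integer(genome$chromosomes$length)))
  body <- sprintf(
    "%s\tpaleoretain\tgene\t%d\t%d\t.\t%s\t.\tID=%s;family_id=%s;label=%s",
    g$chrom, as.integer(g$start), as.integer(g$end), g$strand,
    g$gene_id, g$family_id, g$label
  )
  writeLines(c(header, body), gff)
  out$gff3 <- gff

  if (!is.null(genome$cds)) {
    fa <- file.path(dir, paste0(prefix, ".cds.fa"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(genome$cds), fa, width = 70
    )
    out$fasta <- fa
  }
  if (nrow(genome$repeats) > 0) {
    bed <- file.path(dir, paste0(prefix, ".repeats.bed"))
    r <- genome$repeats
    writeLines(sprintf("%s\t%d\t%d\t%s", r$chrom,
                       as.integer(r$start - 1), as.integer(r$end),
                       r$family), bed)
    out$bed <- bed
  }
  tibble(kind = names(out), path = unlist(out, use.names = FALSE))
}
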