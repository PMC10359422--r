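#' Construct an annotated genome
#'
#' An `annotated_genome` bundles the ordered gene models of one species with
#' its chromosome sizes, optional repeat annotation and optional coding
#' sequences. It is the common input to the synteny, Ks, TRR and gene-loss
#' stages. All coordinates are 1-based inclusive (GFF3 convention); BED input
#' is converted at the boundary by [load_repeats()].
#'
#' Gene order along each chromosome is captured by a 0-based `rank` column,
#' recomputed from `(start, end, gene_id)` so that ties in start position are
#' broken deterministically.
#'
#' @param species Species identifier.
#' @param genes A data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and optionally `family_id`, `label`. Extra columns are kept.
#' @param chromosomes Optional data frame with columns `chrom`, `length`.
#'   When missing, lengths are taken as the furthest gene end per chromosome.
#' @param repeats Optional data frame of repeat intervals with columns
#'   `chrom`, `start`, `end`, `family` (1-based inclusive).
#' @param cds Optional named character vector of coding sequences keyed by
#'   `gene_id`. Sequences whose length is not a multiple of 3 are flagged
#'   (`cds_ok = FALSE`) and excluded from Ks estimation but kept for synteny.
#'
#' @return An object of class `annotated_genome`: a list with elements
#'   `species`, `genes` (tibble with `rank`), `chromosomes`, `repeats`, `cds`.
#' @export
annotated_genome <- function(species, genes, chromosomes = NULL,
                             repeats = NULL, cds = NULL) {
  genes <- as_tibble(genes)
  required <- c("gene_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0("genes is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(genes) > 0) {
    if (any(genes$start > genes$end)) abort("gene start > end")
    if (!all(genes$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
    if (anyDuplicated(genes$gene_id)) abort("duplicated gene_id")
  }
  if (!"species" %in% names(genes)) genes$species <- species
  if (!"family_id" %in% names(genes)) genes$family_id <- genes$gene_id
  if (!"label" %in% names(genes)) genes$label <- "other"
  genes <- assign_ranks(genes)

  if (is.null(chromosomes)) {
    chromosomes <- if (nrow(genes) == 0) {
      tibble(chrom = character(), length = numeric())
    } else {
      genes |>
        group_by(chrom = .data$chrom) |>
        summarise(length = max(.data$end), .groups = "drop")
    }
  } else {
    chromosomes <- as_tibble(chromosomes)
    bad <- setdiff(unique(genes$chrom), chromosomes$chrom)
    if (length(bad) > 0) {
      abort(paste0("gene chromosome(s) absent from chromosome table: ",
                   paste(bad, collapse = ", ")))
    }
    lens <- setNames(chromosomes$length, chromosomes$chrom)
    if (nrow(genes) > 0 && any(genes$end > lens[genes$chrom])) {
      abort("gene interval exceeds chromosome length")
    }
  }
  if (is.null(repeats)) {
    repeats <- tibble(chrom = character(), start = integer(),
                      end = integer(), family = character())
  } else {
    repeats <- as_tibble(repeats)
  }
  cds_ok <- NULL
  if (!is.null(cds)) {
    if (is.null(names(cds))) abort("cds must be named by gene_id")
    cds_ok <- nchar(cds) %% 3 == 0
    if (any(!cds_ok)) {
      warn(paste0(sum(!cds_ok),
                  " CDS length(s) not a multiple of 3; flagged and ",
                  "excluded from Ks estimation"))
    }
  }
  genes$cds_ok <- if (is.null(cds)) NA else
    unname(ifelse(genes$gene_id %in% names(cds),
                  cds_ok[match(genes$gene_id, names(cds))], NA))
  structure(
    list(species = species, genes = genes, chromosomes = chromosomes,
         repeats = repeats, cds = cds),
    class = "annotated_genome"
  )
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome> ", x$species, "\n", sep = "")
  cat("  ", nrow(x$genes), " genes on ", nrow(x$chromosomes),
      " chromosome(s); ", nrow(x$repeats), " repeat interval(s); ",
      if (is.null(x$cds)) "no CDS" else paste0(length(x$cds), " CDS"),
      "\n", sep = "")
  invisible(x)
}

#' Recompute 0-based gene ranks along each chromosome
#'
#' Ranks order genes by `(start, end, gene_id)` within a chromosome, so runs
#' are reproducible even when two gene models share a start coordinate.
#'
#' @param genes A gene tibble (see [annotated_genome()]).
#' @return The tibble with a recomputed integer `rank` column, rows sorted by
#'   chromosome and rank.
#' @export
assign_ranks <- function(genes) {
  genes |>
    arrange(.data$chrom, .data$start, .data$end, .data$gene_id) |>
    group_by(.data$chrom) |>
    mutate(rank = seq_len(n()) - 1L) |>
    ungroup()
}

#' Tidy the gene table of a genome
#'
#' @param x An `annotated_genome`.
#' @param ... Unused.
#' @return The gene tibble.
#' @export
tidy.annotated_genome <- function(x, ...) x$genes

#' One-row summary of a genome
#'
#' @param x An `annotated_genome`.
#' @param ... Unused.
#' @return A one-row tibble with gene, chromosome and repeat counts and the
#'   total assembly span.
#' @export
glance.annotated_genome <- function(x, ...) {
  tibble(
    species = x$species,
    n_genes = nrow(x$genes),
    n_chromosomes = nrow(x$chromosomes),
    n_repeats = nrow(x$repeats),
    total_bp = sum(x$chromosomes$length),
    has_cds = !is.null(x$cds)
  )
}

#' Phred-scaled assembly base-accuracy (QV)
#'
#' The quality value of an assembly from `n_variants` high-confidence
#' mismatch sites (read-vs-assembly SNPs passing the quality and coverage
#' filters) out of `n_covered` assayable positions:
#' \deqn{QV = -10 \log_{10}(n/N).}
#' When no variant is observed the value is a lower bound,
#' \eqn{-10\log_{10}(1/N)}, and `is_lower_bound` is set.
#'
#' The thresholds that define the two counts (variant Phred score, minimum
#' read coverage) are applied upstream when calling variants; they are
#' recorded here so the output is self-describing.
#'
#' @param n_variants Number of high-confidence variant sites (n).
#' @param n_covered Number of positions with sufficient coverage (N).
#' @param phred_min,min_coverage The variant-quality and coverage thresholds
#'   the counts were produced with (metadata only; defaults 30 and 3).
#' @return A one-row tibble with `qv`, `is_lower_bound`, the inputs and the
#'   recorded thresholds.
#' @examples
#' assembly_qv(58, 1e6)  # ~42.37
#' @export
assembly_qv <- function(n_variants, n_covered, phred_min = 30,
                        min_coverage = 3) {
  if (length(n_covered) != 1 || n_covered <= 0) {
    abort("n_covered must be a single positive count")
  }
  if (n_variants < 0 || n_variants > n_covered) {
    abort("need 0 <= n_variants <= n_covered")
  }
  lower <- n_variants == 0
  qv <- -10 * log10(max(n_variants, 1) / n_covered)
  tibble(qv = qv, is_lower_bound = lower,
         n_variants = as.integer(n_variants),
         n_covered = as.double(n_covered),
         phred_min = phred_min, min_coverage = min_coverage)
}

#' Sliding windows over a genome
#'
#' Tiles each chromosome with fixed-width windows advanced by `step`.
#' Windows are generated on the half-open convention `[start0, start0 +
#' width)` and reported 1-based inclusive like all other coordinates in the
#' package. A final partial window is appended (and flagged) when the last
#' full window does not reach the chromosome end.
#'
#' @param genome An `annotated_genome` (or a chromosome tibble with columns
#'   `chrom`, `length`).
#' @param width,step Window width and step in bp.
#' @return A tibble with `chrom`, `start`, `end`, `width`, `partial`.
#' @export
genome_windows <- function(genome, width = 1e6, step = 1e6) {
  if (width <= 0 || step <= 0) abort("width and step must be positive")
  chroms <- if (inherits(genome, "annotated_genome")) genome$chromosomes
            else as_tibble(genome)
  res <- lapply(seq_len(nrow(chroms)), function(i) {
    len <- chroms$length[i]
    starts0 <- seq(0, max(0, len - width), by = step)
    starts0 <- starts0[starts0 + width <= len]
    if (length(starts0) == 0) starts0 <- numeric(0)
    ends0 <- starts0 + width
    covered <- if (length(ends0)) max(ends0) else 0
    partial <- logical(length(starts0))
    if (covered < len) {
      nxt <- if (length(starts0)) max(starts0) + step else 0
      if (nxt < len) {
        starts0 <- c(starts0, nxt)
        ends0 <- c(ends0, len)
        partial <- c(partial, TRUE)
      }
    }
    tibble(chrom = chroms$chrom[i],
           start = as.integer(starts0 + 1), end = as.integer(ends0),
           width = as.integer(ends0 - starts0), partial = partial)
  })
  bind_rows(res)
}
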