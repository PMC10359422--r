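# Small in-code fixtures shared across test files.

# A hand-laid genome: n genes on one or two chromosomes, deterministic
# coordinates, singleton families unless a family map is given.
toy_genome <- function(n = 6, species = "toy", chroms = "chr1",
                       family = NULL, strand = NULL, cds = NULL) {
  chrom <- sort(rep(chroms, length.out = n))
  per <- ave(seq_len(n), chrom, FUN = seq_along)
  genes <- tibble::tibble(
    gene_id = sprintf("%s_g%02d", species, seq_len(n)),
    chrom = chrom,
    start = 1000L * per,
    end = 1000L * per + 500L,
    strand = strand %||% rep("+", n),
    family_id = family %||% sprintf("f%02d", seq_len(n))
  )
  annotated_genome(species, genes, cds = cds)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Random in-frame CDS over the full sense-codon table (may include
# non-fourfold codons; no stops).
random_codons <- function(n_codons) {
  codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste0(sample(codons, n_codons, replace = TRUE), collapse = "")
}

# Large reference-vs-triplicated-target dataset shared by the TRR-recovery
# and composition acceptance checks; built once per session.
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_wgt <- function() {
  if (is.null(.acceptance_cache$wgt)) {
    ds <- wgt_fixture(n_genes = 2000, seed = 11, retention_prob = 0.5,
                      n_codons = 300, n_chromosomes = 2)
    gR <- ds$genomes$R
    blocks <- chain_anchors(find_anchors(gR, ds$genomes$T))
    depth <- syntenic_depth(best_k_layout(blocks, gR, k = 3))
    trrs <- call_trrs(depth, gR, min_copies = 3, min_run = 3,
                      max_gap = 1)
    .acceptance_cache$wgt <- list(ds = ds, gR = gR, blocks = blocks,
                                  depth = depth, trrs = trrs)
  }
  .acceptance_cache$wgt
}

# Reference-vs-triplicated-target dataset used by several tests: a
# single-copy reference R and a target T that triplicated and fractionated.
wgt_fixture <- function(n_genes = 300, seed = 21, retention_prob = 0.5,
                        n_codons = 60, n_chromosomes = 2) {
  params <- sim_params(seed = seed, n_ancestral_genes = n_genes,
                       n_chromosomes = n_chromosomes, n_codons = n_codons,
                       retention_prob = retention_prob,
                       syn_rate = 0.3, nonsyn_rate = 0.05)
  events <- list(
    list(clade = "T", time_frac = 0.1, type = "wg_multiplication",
         multiplicity = 3),
    list(clade = "T", time_frac = 0.2, type = "fractionation")
  )
  simulate_dataset("(R:0.5,T:0.5):0.05;", params, events)
}
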