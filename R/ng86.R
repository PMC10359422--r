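# Nei-Gojobori (1986) counting of synonymous and nonsynonymous sites and
# differences, with Jukes-Cantor multiple-hit correction. Codon-pair
# difference counts are precomputed into 64x64 lookup tables so whole-genome
# batches of pairs reduce to table sums.

.ng86_cache <- new.env(parent = emptyenv())

ng86_bases <- c("T", "C", "A", "G")

ng86_codons <- function() {
  if (is.null(.ng86_cache$codons)) {
    # index = 16*(b1-1) + 4*(b2-1) + b3, bases in TCAG order
    b1 <- rep(ng86_bases, each = 16)
    b2 <- rep(rep(ng86_bases, each = 4), 4)
    b3 <- rep(ng86_bases, 16)
    .ng86_cache$codons <- paste0(b1, b2, b3)
  }
  .ng86_cache$codons
}

ng86_aa <- function() {
  if (is.null(.ng86_cache$aa)) {
    gc <- Biostrings::GENETIC_CODE
    .ng86_cache$aa <- unname(gc[ng86_codons()])
  }
  .ng86_cache$aa
}

codon_index <- function(codon_chars_matrix) {
  # 3 x n matrix of characters -> codon index 1..64
  idx <- match(codon_chars_matrix, ng86_bases)
  dim(idx) <- dim(codon_chars_matrix)
  16L * (idx[1, ] - 1L) + 4L * (idx[2, ] - 1L) + idx[3, ]
}

# Convert a DNA string to codon indices (1..64); NA for codons with
# non-ACGT characters.
seq_to_codons <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1]]
  if (length(v) %% 3 != 0) abort("sequence length not a multiple of 3")
  m <- matrix(v, nrow = 3)
  codon_index(m)
}

# Per-codon synonymous site count: for each position, the fraction of the 3
# possible single-base changes that preserve the amino acid. Changes to stop
# codons count as nonsynonymous. Stop codons themselves get NA.
ng86_site_table <- function() {
  if (!is.null(.ng86_cache$sites)) return(.ng86_cache$sites)
  codons <- ng86_codons()
  aa <- ng86_aa()
  s <- numeric(64)
  for (i in seq_len(64)) {
    if (aa[i] == "*") { s[i] <- NA_real_; next }
    chars <- strsplit(codons[i], "")[[1]]
    syn <- 0
    for (pos in 1:3) {
      for (b in setdiff(ng86_bases, chars[pos])) {
        alt <- chars
        alt[pos] <- b
        j <- codon_index(matrix(alt, nrow = 3))
        if (aa[j] != "*" && aa[j] == aa[i]) syn <- syn + 1
      }
    }
    s[i] <- syn / 3
  }
  .ng86_cache$sites <- s
  s
}

# 64x64 tables of synonymous / nonsynonymous difference counts per codon
# pair, averaging over minimal substitution pathways. Pathways passing
# through a stop codon are excluded unless every pathway does.
ng86_diff_tables <- function() {
  if (!is.null(.ng86_cache$sd)) {
    return(list(sd = .ng86_cache$sd, nd = .ng86_cache$nd))
  }
  codons <- ng86_codons()
  aa <- ng86_aa()
  chars <- strsplit(codons, "")
  sd <- matrix(0, 64, 64)
  nd <- matrix(0, 64, 64)
  perms2 <- list(c(1, 2), c(2, 1))
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  step_type <- function(from_idx, to_idx) {
    # 1 = synonymous, 0 = nonsynonymous; NA if to is a stop
    if (aa[to_idx] == "*") return(NA_real_)
    as.numeric(aa[from_idx] == aa[to_idx])
  }
  for (i in seq_len(64)) {
    if (aa[i] == "*") { sd[i, ] <- NA; nd[i, ] <- NA; next }
    for (j in seq_len(64)) {
      if (aa[j] == "*") { sd[i, j] <- NA; nd[i, j] <- NA; next }
      dpos <- which(chars[[i]] != chars[[j]])
      nd_ <- length(dpos)
      if (nd_ == 0) next
      if (nd_ == 1) {
        st <- as.numeric(aa[i] == aa[j])
        sd[i, j] <- st
        nd[i, j] <- 1 - st
        next
      }
      perms <- if (nd_ == 2) perms2 else perms3
      path_s <- numeric(0)
      path_n <- numeric(0)
      path_ok <- logical(0)
      for (p in perms) {
        cur <- chars[[i]]
        cur_idx <- i
        s_cnt <- 0; n_cnt <- 0; ok <- TRUE
        for (step in p) {
          pos <- dpos[step]
          cur[pos] <- chars[[j]][pos]
          nxt_idx <- codon_index(matrix(cur, nrow = 3))
          if (aa[nxt_idx] == "*") ok <- FALSE
          if (aa[nxt_idx] != "*" && aa[cur_idx] == aa[nxt_idx]) {
            s_cnt <- s_cnt + 1
          } else {
            n_cnt <- n_cnt + 1
          }
          cur_idx <- nxt_idx
        }
        path_s <- c(path_s, s_cnt)
        path_n <- c(path_n, n_cnt)
        path_ok <- c(path_ok, ok)
      }
      use <- if (any(path_ok)) path_ok else rep(TRUE, length(path_ok))
      sd[i, j] <- mean(path_s[use])
      nd[i, j] <- mean(path_n[use])
    }
  }
  .ng86_cache$sd <- sd
  .ng86_cache$nd <- nd
  list(sd = sd, nd = nd)
}

#' Jukes-Cantor distance from a proportion of differences
#'
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)}; `NA` (saturated) when
#' `p >= 3/4`.
#'
#' @param p Proportion of differing sites.
#' @return Corrected distance (substitutions per site).
#' @export
jukes_cantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - (4 / 3) * p))
}

#' Synonymous and nonsynonymous divergence of one aligned codon pair (NG86)
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per Nei-Gojobori
#' (averaged over the two sequences; single-base changes to stop codons
#' count as nonsynonymous) and synonymous/nonsynonymous differences (Sd, Nd;
#' codons differing at 2-3 positions are averaged over minimal substitution
#' pathways, excluding pathways through stop codons). The Jukes-Cantor
#' correction is applied separately to pS and pN; `pS >= 3/4` flags the pair
#' as saturated (`ks = NA`).
#'
#' @param cds_a,cds_b Equal-length, gap-free, in-frame aligned coding
#'   sequences (align first with [align_cds()] if needed). A shared terminal
#'   stop codon is dropped; an internal stop is an error.
#' @return A one-row tibble: `S`, `N`, `Sd`, `Nd`, `ps`, `pn`, `ks`, `ka`,
#'   `ka_ks`, `saturated`.
#' @examples
#' a <- strrep("AAA", 10)
#' b <- paste0(strrep("AAA", 8), "AAGAAG")
#' ng86_pair(a, b)
#' @export
ng86_pair <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) abort("aligned sequences differ in length")
  if (grepl("-", cds_a, fixed = TRUE) || grepl("-", cds_b, fixed = TRUE)) {
    abort("gapped input; remove gap columns first (see align_cds)")
  }
  ca <- seq_to_codons(cds_a)
  cb <- seq_to_codons(cds_b)
  ng86_from_codons(ca, cb)
}

ng86_from_codons <- function(ca, cb) {
  aa <- ng86_aa()
  n_cod <- length(ca)
  # drop shared terminal stop
  if (n_cod > 0 && !is.na(ca[n_cod]) && !is.na(cb[n_cod]) &&
      aa[ca[n_cod]] == "*" && aa[cb[n_cod]] == "*") {
    ca <- ca[-n_cod]; cb <- cb[-n_cod]
  }
  if (any(aa[ca[!is.na(ca)]] == "*") || any(aa[cb[!is.na(cb)]] == "*")) {
    abort("internal stop codon")
  }
  use <- !is.na(ca) & !is.na(cb)
  ca <- ca[use]; cb <- cb[use]
  sites <- ng86_site_table()
  tabs <- ng86_diff_tables()
  S <- (sum(sites[ca]) + sum(sites[cb])) / 2
  N <- 3 * length(ca) - S
  Sd <- sum(tabs$sd[cbind(ca, cb)])
  Nd <- sum(tabs$nd[cbind(ca, cb)])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  ks <- jukes_cantor(ps)
  ka <- jukes_cantor(pn)
  tibble(
    S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
    ks = ks, ka = ka,
    ka_ks = ifelse(!is.na(ks) & ks > 0 & !is.na(ka), ka / ks, NA_real_),
    saturated = ps >= 0.75
  )
}

#' Align two coding sequences codon-wise
#'
#' Translates both sequences, aligns the proteins globally
#' (Needleman-Wunsch via [Biostrings::pairwiseAlignment()]), maps the
#' alignment back to codons and removes gapped codon columns, yielding a
#' gap-free in-frame pair ready for [ng86_pair()].
#'
#' @param cds_a,cds_b Coding nucleotide sequences (lengths multiples of 3).
#' @return A list with elements `a` and `b` (aligned, gap-stripped
#'   sequences of equal length) and `score` (protein alignment score).
#' @export
align_cds <- function(cds_a, cds_b) {
  if (nchar(cds_a) == 0 || nchar(cds_b) == 0) abort("empty sequence")
  if (nchar(cds_a) %% 3 != 0 || nchar(cds_b) %% 3 != 0) {
    abort("CDS length not a multiple of 3")
  }
  if (nchar(cds_a) == nchar(cds_b) && cds_a == cds_b) {
    return(list(a = cds_a, b = cds_b, score = NA_real_))
  }
  pa <- Biostrings::translate(Biostrings::DNAString(cds_a),
                              if.fuzzy.codon = "solve")
  pb <- Biostrings::translate(Biostrings::DNAString(cds_b),
                              if.fuzzy.codon = "solve")
  aln <- Biostrings::pairwiseAlignment(
    pa, pb, type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5
  )
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  cod_a <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  cod_b <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  ia <- 0L; ib <- 0L
  keep_a <- character(0); keep_b <- character(0)
  for (k in seq_along(pat)) {
    ga <- pat[k] == "-"; gb <- sub[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) {
      keep_a <- c(keep_a, cod_a[ia])
      keep_b <- c(keep_b, cod_b[ib])
    }
  }
  list(a = paste0(keep_a, collapse = ""),
       b = paste0(keep_b, collapse = ""),
       score = Biostrings::score(aln))
}

#' Ks/Ka for a table of gene pairs
#'
#' Batch NG86 over many pairs with per-gene codon caching; sequences of
#' unequal length are codon-aligned first. Genes flagged by the loader as
#' having out-of-frame CDS are skipped (`ks = NA`).
#'
#' @param pairs A data frame with columns `gene_a`, `gene_b` (other columns
#'   are carried through).
#' @param cds_a Named character vector of CDS for the `gene_a` side.
#' @param cds_b Named CDS vector for the `gene_b` side; defaults to `cds_a`
#'   (intra-genome comparisons).
#' @return The input tibble with NG86 columns appended.
#' @export
ks_for_pairs <- function(pairs, cds_a, cds_b = cds_a) {
  pairs <- as_tibble(pairs)
  n <- nrow(pairs)
  cols <- list(S = rep(NA_real_, n), N = rep(NA_real_, n),
               Sd = rep(NA_real_, n), Nd = rep(NA_real_, n),
               ps = rep(NA_real_, n), pn = rep(NA_real_, n),
               ks = rep(NA_real_, n), ka = rep(NA_real_, n),
               saturated = rep(NA, n))
  if (n == 0) {
    out <- as_tibble(cols)
    out$ka_ks <- numeric(0)
    return(bind_cols(pairs, out))
  }
  sites <- ng86_site_table()
  tabs <- ng86_diff_tables()
  aa <- ng86_aa()
  # per-gene codon indices and site sums, cached once per side
  prep_side <- function(ids, cds) {
    u <- unique(ids)
    seqs <- cds[u]
    ok <- !vapply(seqs, function(s) is.null(s) || is.na(s) ||
                    nchar(s) %% 3 != 0, logical(1))
    cod <- vector("list", length(u))
    ssum <- rep(NA_real_, length(u))
    for (i in which(ok)) {
      v <- seq_to_codons(seqs[[i]])
      # drop a terminal stop codon; an internal stop disqualifies the gene
      if (length(v) > 0 && !is.na(v[length(v)]) &&
          aa[v[length(v)]] == "*") {
        v <- v[-length(v)]
      }
      if (any(!is.na(v) & aa[v] == "*")) {
        ok[i] <- FALSE
        next
      }
      cod[[i]] <- v
      ssum[i] <- sum(sites[v], na.rm = TRUE)
    }
    list(idx = setNames(seq_along(u), u), cod = cod, ssum = ssum, ok = ok)
  }
  pa <- prep_side(pairs$gene_a, cds_a)
  pb <- prep_side(pairs$gene_b, cds_b)
  ia <- pa$idx[pairs$gene_a]
  ib <- pb$idx[pairs$gene_b]
  for (i in seq_len(n)) {
    if (!pa$ok[ia[i]] || !pb$ok[ib[i]]) next
    va <- pa$cod[[ia[i]]]
    vb <- pb$cod[[ib[i]]]
    if (length(va) != length(vb)) {
      al <- align_cds(cds_a[[pairs$gene_a[i]]], cds_b[[pairs$gene_b[i]]])
      va <- seq_to_codons(al$a)
      vb <- seq_to_codons(al$b)
      S <- (sum(sites[va], na.rm = TRUE) + sum(sites[vb], na.rm = TRUE)) / 2
    } else {
      S <- (pa$ssum[ia[i]] + pb$ssum[ib[i]]) / 2
    }
    use <- !is.na(va) & !is.na(vb)
    ncod <- sum(use)
    N <- 3 * ncod - S
    Sd <- sum(tabs$sd[cbind(va[use], vb[use])])
    Nd <- sum(tabs$nd[cbind(va[use], vb[use])])
    ps <- if (S > 0) Sd / S else 0
    pn <- if (N > 0) Nd / N else 0
    cols$S[i] <- S; cols$N[i] <- N
    cols$Sd[i] <- Sd; cols$Nd[i] <- Nd
    cols$ps[i] <- ps; cols$pn[i] <- pn
    cols$ks[i] <- jukes_cantor(ps)
    cols$ka[i] <- jukes_cantor(pn)
    cols$saturated[i] <- ps >= 0.75
  }
  out <- as_tibble(cols)
  out$ka_ks <- ifelse(!is.na(out$ks) & out$ks > 0 & !is.na(out$ka),
                      out$ka / out$ks, NA_real_)
  bind_cols(pairs, out)
}
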