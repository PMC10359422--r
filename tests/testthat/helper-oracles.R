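# Independent brute-force oracles, deliberately written with different
# machinery than the package implementation (string manipulation and
# explicit enumeration instead of lookup tables and dynamic programming).

# --- NG86 oracle -----------------------------------------------------------

oracle_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

# synonymous site count of one codon by explicit mutation of each position
oracle_codon_sites <- function(codon) {
  aa0 <- oracle_aa(codon)
  syn <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"),
                      substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (oracle_aa(mut) != "*" && oracle_aa(mut) == aa0) syn <- syn + 1
    }
  }
  syn / 3
}

# averaged pathway differences for one codon pair by explicit permutation
oracle_codon_diffs <- function(c1, c2) {
  dpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(dpos) == 0) return(c(sd = 0, nd = 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  paths <- list()
  for (p in perms(dpos)) {
    cur <- c1
    sd <- 0; nd <- 0; through_stop <- FALSE
    for (pos in p) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (oracle_aa(nxt) == "*") through_stop <- TRUE
      if (oracle_aa(nxt) != "*" && oracle_aa(nxt) == oracle_aa(cur)) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    paths[[length(paths) + 1]] <- list(sd = sd, nd = nd,
                                       ok = !through_stop)
  }
  ok <- vapply(paths, function(x) x$ok, logical(1))
  if (!any(ok)) ok <- rep(TRUE, length(ok))
  c(sd = mean(vapply(paths[ok], function(x) x$sd, numeric(1))),
    nd = mean(vapply(paths[ok], function(x) x$nd, numeric(1))))
}

oracle_ng86 <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  S <- (sum(vapply(ca, oracle_codon_sites, numeric(1))) +
          sum(vapply(cb, oracle_codon_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  d <- rowSums(vapply(seq_along(ca), function(i)
    oracle_codon_diffs(ca[i], cb[i]), numeric(2)))
  ps <- if (S > 0) d[["sd"]] / S else 0
  pn <- if (N > 0) d[["nd"]] / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = d[["sd"]], Nd = d[["nd"]],
       ks = jc(ps), ka = jc(pn))
}

# --- chaining oracle -------------------------------------------------------

# maximum chain score over all strictly monotone anchor subsets, both
# orientations, by exhaustive subset enumeration (n <= ~12)
oracle_best_chain_score <- function(ra, rb, w, gap_penalty) {
  n <- length(ra)
  best <- -Inf
  for (mask in seq_len(2^n) - 1) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) == 0) next
    o <- order(ra[idx])
    a <- ra[idx][o]; b <- rb[idx][o]
    if (any(duplicated(a))) next
    up <- all(diff(b) > 0)
    down <- all(diff(b) < 0)
    if (length(idx) > 1 && !up && !down) next
    gaps <- if (length(idx) > 1) {
      sum(diff(a) - 1) + sum(abs(diff(b)) - 1)
    } else 0
    sc <- sum(w[idx]) - gap_penalty * gaps
    if (sc > best) best <- sc
  }
  best
}

# --- exact hypergeometric / Fisher oracles --------------------------------

# upper/lower tail by direct summation of binomial-coefficient ratios
oracle_hyper_tail <- function(k, K, N, n, upper) {
  js <- 0:min(K, n)
  probs <- choose(K, js) * choose(N - K, n - js) / choose(N, n)
  if (upper) sum(probs[js >= k]) else sum(probs[js <= k])
}

# two-sided Fisher p by enumerating all tables with the observed margins
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  as <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- vapply(as, function(x) {
    choose(r1, x) * choose(N - r1, c1 - x) / choose(N, c1)
  }, numeric(1))
  p_obs <- probs[as == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
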