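# Ks distribution summarisation: per-block medians, Gaussian mixtures on
# log-Ks, assignment of paralog peaks to tree branches, and a simple
# molecular-clock conversion to divergence times.

#' Per-block Ks summary
#'
#' Median Ks of the non-saturated anchors of each block; blocks with fewer
#' than `min_usable` usable anchors are flagged low-confidence.
#'
#' @param ks_table Output of [ks_for_pairs()] carrying a `block_id` column
#'   (join the block's anchors with their Ks values).
#' @param min_usable Minimum usable anchors for a confident median
#'   (default 3).
#' @return A tibble: `block_id`, `n_pairs`, `n_usable`, `median_ks`,
#'   `median_ka`, `low_confidence`.
#' @export
block_ks_summary <- function(ks_table, min_usable = 3) {
  ks_table |>
    group_by(.data$block_id) |>
    summarise(
      n_pairs = n(),
      n_usable = sum(!is.na(.data$ks) & !.data$saturated),
      median_ks = median(.data$ks[!is.na(.data$ks) & !.data$saturated]),
      median_ka = median(.data$ka[!is.na(.data$ks) & !.data$saturated]),
      .groups = "drop"
    ) |>
    mutate(low_confidence = .data$n_usable < min_usable)
}

#' Fit a multi-peak model to a Ks distribution
#'
#' Fits Gaussian mixtures to log-Ks inside `ks_range` for 1 to
#' `max_components` components and keeps the model with the best Bayesian
#' information criterion (ties go to fewer components). Initialisation uses
#' a deterministic quantile-spaced subset, so refitting the same data gives
#' the same model.
#'
#' @param ks_values Numeric vector of Ks values (saturated pairs enter as
#'   `NA` and are dropped).
#' @param max_components Largest number of mixture components tried.
#' @param ks_range Ks window retained for fitting; the default
#'   `c(0.01, 3)` suppresses allelic/near-zero noise and saturated tails.
#' @param min_values Minimum retained values required (default 50).
#' @return An object of class `ks_peak_model`: list with `components`
#'   (tibble `mean_log`, `sd_log`, `weight`, `peak_ks`, ordered by mean),
#'   `n_components`, `n`, `bic`, `ks_range`.
#' @export
fit_ks_peaks <- function(ks_values, max_components = 4,
                         ks_range = c(0.01, 3), min_values = 50) {
  x <- ks_values[!is.na(ks_values)]
  x <- x[x >= ks_range[1] & x <= ks_range[2]]
  if (length(x) < min_values) {
    abort(paste0("need at least ", min_values, " usable Ks values inside ",
                 "ks_range; got ", length(x)))
  }
  lx <- sort(log(x))
  init <- NULL
  if (length(lx) > 1500) {
    idx <- unique(round(seq(1, length(lx), length.out = 1500)))
    init <- list(subset = idx)
  }
  fits <- lapply(seq_len(max_components), function(g) {
    suppressWarnings(
      tryCatch(
        mclust::Mclust(lx, G = g, modelNames = "V", verbose = FALSE,
                       initialization = init),
        error = function(e) NULL
      )
    )
  })
  bics <- map_dbl(fits, function(f) if (is.null(f)) -Inf else f$bic)
  if (all(!is.finite(bics))) abort("mixture fitting failed")
  best_g <- which(bics >= max(bics) - 1e-8)[1]  # parsimony on ties
  fit <- fits[[best_g]]
  mu <- as.numeric(fit$parameters$mean)
  sig <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sig) == 1) sig <- rep(sig, length(mu))
  w <- as.numeric(fit$parameters$pro)
  o <- order(mu)
  structure(
    list(
      components = tibble(mean_log = mu[o], sd_log = sig[o],
                          weight = w[o], peak_ks = exp(mu[o])),
      n_components = length(mu),
      n = length(lx),
      bic = fit$bic,
      ks_range = ks_range
    ),
    class = "ks_peak_model"
  )
}

#' @export
print.ks_peak_model <- function(x, ...) {
  cat("<ks_peak_model> ", x$n_components, " component(s) on ", x$n,
      " values\n", sep = "")
  print(x$components)
  invisible(x)
}

#' Tidy the components of a Ks peak model
#'
#' @param x A `ks_peak_model`.
#' @param ... Unused.
#' @return The component tibble (one row per peak).
#' @export
tidy.ks_peak_model <- function(x, ...) x$components

#' One-row summary of a Ks peak model
#'
#' @param x A `ks_peak_model`.
#' @param ... Unused.
#' @return Tibble with `n`, `n_components`, `bic` and the dominant peak.
#' @export
glance.ks_peak_model <- function(x, ...) {
  dom <- x$components$peak_ks[which.max(x$components$weight)]
  tibble(n = x$n, n_components = x$n_components, bic = x$bic,
         dominant_peak_ks = dom)
}

#' Assign paralog Ks peaks to tree branches and order them vs speciations
#'
#' Peaks are matched across species when their positions agree within
#' `match_tol_log` on the log scale. A peak shared by exactly the tips of a
#' clade is assigned to that clade's stem; a peak private to one species to
#' its terminal branch; any other sharing pattern is flagged `unresolved`.
#' The event's order relative to the speciation at the top of its branch is
#' decided by comparing the paralog peak with the relevant ortholog peak
#' (paralog peak smaller by more than `min_peak_sep` means the event
#' happened after the divergence); separations below `min_peak_sep` are
#' reported `indistinguishable`. Multiplicity (duplication vs triplication)
#' is taken from the modal syntenic depth per species when supplied.
#'
#' @param paralog_models Named list (by species) of `ks_peak_model`s fitted
#'   to within-genome anchor-pair Ks.
#' @param ortholog_models Named list of `ks_peak_model`s for species pairs;
#'   names are `"X|Y"` (order-free lookup).
#' @param tree A `phylo` or newick string covering the species.
#' @param depth_by_species Optional named integer vector of modal syntenic
#'   depths, used to annotate event multiplicity.
#' @param match_tol_log Log-scale tolerance for matching peaks across
#'   species (default 0.3, i.e. ~1.35-fold).
#' @param min_peak_sep Minimum Ks separation to call event order
#'   (default 0.02).
#' @param min_weight Mixture components lighter than this are ignored as
#'   noise (default 0.05).
#' @return A tibble: `peak_ks`, `species` (comma-joined), `branch`
#'   (`stem:<clade>` / `terminal:<tip>` / `unresolved`),
#'   `ortholog_peak_ks`, `order_vs_speciation`
#'   (`before`/`after`/`indistinguishable`/`NA`), `multiplicity`.
#' @export
classify_wg_events <- function(paralog_models, ortholog_models, tree,
                               depth_by_species = NULL,
                               match_tol_log = 0.3, min_peak_sep = 0.02,
                               min_weight = 0.05) {
  tr <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
  species <- names(paralog_models)
  peaks <- bind_rows(imap(paralog_models, function(m, sp) {
    m$components |>
      filter(.data$weight >= min_weight) |>
      transmute(species = sp, mean_log = .data$mean_log,
                peak_ks = .data$peak_ks)
  }))
  if (nrow(peaks) == 0) return(empty_event_table())
  # single-linkage grouping of peaks across species on the log scale
  peaks <- peaks |> arrange(.data$mean_log)
  grp <- cumsum(c(TRUE, diff(peaks$mean_log) > match_tol_log))
  peaks$group <- grp

  # The ortholog divergence peak is the youngest substantial component:
  # cross-genome anchor sets also contain homeologous (paralog-derived)
  # matches whose Ks reflects older polyploidy, never younger.
  lookup_ortho <- function(sp1, sp2) {
    nm <- c(paste0(sp1, "|", sp2), paste0(sp2, "|", sp1))
    m <- ortholog_models[[intersect(nm, names(ortholog_models))[1]]]
    if (is.null(m)) return(NA_real_)
    comp <- m$components |> filter(.data$weight >= max(min_weight, 0.15))
    if (nrow(comp) == 0) comp <- m$components
    min(comp$peak_ks)
  }

  events <- peaks |>
    group_by(.data$group) |>
    summarise(peak_ks = exp(mean(.data$mean_log)),
              sharing = list(unique(.data$species)), .groups = "drop")
  rows <- lapply(seq_len(nrow(events)), function(i) {
    share <- events$sharing[[i]]
    pk <- events$peak_ks[i]
    if (setequal(share, species)) {
      branch <- "stem:root"
      inside <- share
      outside <- character(0)
    } else if (length(share) == 1) {
      branch <- paste0("terminal:", share)
      inside <- share
      outside <- setdiff(species, share)
    } else {
      mrca_tips <- tryCatch({
        node <- ape::getMRCA(tr, share)
        tr$tip.label[phangorn_free_descendants(tr, node)[[1]]]
      }, error = function(e) NULL)
      if (!is.null(mrca_tips) && setequal(mrca_tips, share)) {
        branch <- paste0("stem:", paste(sort(share), collapse = ","))
        inside <- share
        outside <- setdiff(species, share)
      } else {
        branch <- "unresolved"
        inside <- share
        outside <- character(0)
      }
    }
    # order vs the speciation at the top of the event's branch: compare
    # with the ortholog peak between a carrier and the nearest non-carrier
    # (for root-stem events, the deepest ortholog peak available)
    ortho <- NA_real_
    if (branch != "unresolved") {
      if (length(outside) > 0) {
        cand <- map_dbl(outside, function(o) lookup_ortho(inside[1], o))
        ortho <- suppressWarnings(min(cand, na.rm = TRUE))
        if (!is.finite(ortho)) ortho <- NA_real_
      } else if (length(species) > 1) {
        cand <- unlist(lapply(seq_along(species), function(a) {
          map_dbl(seq_len(a - 1), function(b)
            lookup_ortho(species[a], species[b]))
        }))
        ortho <- suppressWarnings(max(cand, na.rm = TRUE))
        if (!is.finite(ortho)) ortho <- NA_real_
      }
    }
    ord <- if (is.na(ortho)) NA_character_
    else if (pk < ortho - min_peak_sep) "after"
    else if (pk > ortho + min_peak_sep) "before"
    else "indistinguishable"
    mult <- NA_integer_
    if (!is.null(depth_by_species)) {
      d <- depth_by_species[intersect(inside, names(depth_by_species))]
      if (length(d) > 0) mult <- as.integer(round(median(d)))
    }
    tibble(peak_ks = pk, species = paste(sort(share), collapse = ","),
           branch = branch, ortholog_peak_ks = ortho,
           order_vs_speciation = ord, multiplicity = mult)
  })
  bind_rows(rows) |> arrange(desc(.data$peak_ks))
}

empty_event_table <- function() {
  tibble(peak_ks = numeric(), species = character(), branch = character(),
         ortholog_peak_ks = numeric(), order_vs_speciation = character(),
         multiplicity = integer())
}

#' Convert Ks to divergence time with a strict molecular clock
#'
#' \eqn{T = Ks / (2r)} with `r` synonymous substitutions per synonymous
#' site per year.
#'
#' @param ks Ks value(s); `NA` (saturated) is an error.
#' @param clock_rate Substitution rate `r` (> 0), per site per year.
#' @return Divergence time(s) in years.
#' @examples
#' ks_to_time(0.8, 5e-9)  # 8e7 years
#' @export
ks_to_time <- function(ks, clock_rate) {
  if (any(is.na(ks))) abort("saturated or missing Ks cannot be dated")
  if (clock_rate <= 0) abort("clock_rate must be positive")
  ks / (2 * clock_rate)
}
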