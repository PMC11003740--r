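# Depth-normalised diversity metrics: hypergeometric downsampling, observed
# richness, bias-corrected Chao1, normalised Shannon-Wiener evenness, and
# group-vs-control testing.

#' Downsample a repertoire to a fixed number of molecules
#'
#' Draws `depth` UMI-labelled molecules without replacement from the
#' repertoire's multiset of molecules (multivariate hypergeometric), the
#' standard depth normalisation before computing diversity metrics. The
#' output total is exactly `depth`; clonotypes falling to zero are removed.
#'
#' @param rep A [repertoire()].
#' @param depth Number of molecules to keep (1 <= depth <= total_count).
#' @param seed Optional integer seed.
#' @return A [repertoire()] with `total_count == depth`.
#' @export
downsample <- function(rep, depth, seed = NULL) {
  stopifnot(inherits(rep, "repertoire"))
  if (!is.numeric(depth) || length(depth) != 1 || depth < 1) {
    stop("depth must be a positive integer", call. = FALSE)
  }
  depth <- as.integer(depth)
  if (rep$total_count < depth) {
    stop("repertoire has fewer molecules (", rep$total_count,
         ") than requested depth (", depth, ")", call. = FALSE)
  }
  if (rep$total_count == depth) return(rep)
  run <- function() {
    counts <- rep$clonotypes$count
    picked <- sample.int(rep$total_count, depth) # without replacement
    clone <- findInterval(picked - 0.5, cumsum(counts)) + 1L
    new_counts <- tabulate(clone, nbins = length(counts))
    keep <- new_counts > 0L
    tbl <- rep$clonotypes[keep, , drop = FALSE]
    tbl$count <- new_counts[keep]
    repertoire(tbl, rep$meta)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Observed diversity
#'
#' Number of distinct clonotype records in the repertoire.
#'
#' @param rep A [repertoire()].
#' @return Integer.
#' @export
observed_diversity <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  nrow(rep$clonotypes)
}

#' Bias-corrected Chao1 richness estimator
#'
#' Lower-bound estimate of total clonotype richness from the representation
#' of small clonotypes: `S_obs + n1 (n1 - 1) / (2 (n2 + 1))`, where `n1` and
#' `n2` are the numbers of singleton and doubleton clonotypes. The
#' bias-corrected form is defined even when no doubletons are observed and
#' always satisfies `chao1 >= S_obs`.
#'
#' @param rep A [repertoire()].
#' @return Numeric estimate.
#' @export
chao1 <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  counts <- rep$clonotypes$count
  if (length(counts) == 0) stop("empty repertoire", call. = FALSE)
  s_obs <- length(counts)
  n1 <- sum(counts == 1L)
  n2 <- sum(counts == 2L)
  s_obs + n1 * (n1 - 1) / (2 * (n2 + 1))
}

#' Normalised Shannon-Wiener index
#'
#' Shannon entropy of the clonotype frequency distribution divided by its
#' maximum `log(S_obs)`: 1 for a perfectly even repertoire, approaching 0
#' under extreme clonal expansion. By contract a single-clonotype repertoire
#' returns 0. Invariant to rescaling all counts by a common factor.
#'
#' @param rep A [repertoire()].
#' @return Numeric in \[0, 1\].
#' @export
normalized_shannon <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  p <- rep$clonotypes$freq
  if (length(p) == 0) stop("empty repertoire", call. = FALSE)
  if (length(p) == 1) return(0)
  h <- -sum(p * log(p))
  h / log(length(p))
}

#' Depth-normalised diversity table for a cohort
#'
#' For each sample: samples with fewer than `min_umi` UMIs are excluded;
#' samples with at least `depth` UMIs are downsampled to exactly `depth`
#' molecules; samples between `min_umi` and `depth` are used at full depth.
#' Metrics (observed diversity, Chao1, normalised Shannon-Wiener) are
#' averaged over `n_resamples` independent downsamples.
#'
#' @param x A [cohort()].
#' @param depth Downsampling depth (default 1000 UMIs).
#' @param min_umi Exclusion threshold (default 700 UMIs).
#' @param n_resamples Independent downsample replicates to average (default 1).
#' @param level `"nt"` (clonotypes as extracted) or `"aa"` (apply
#'   [aggregate_aa()] first).
#' @param seed Optional integer seed.
#' @return Tibble with one row per sample: metadata, `depth_used`,
#'   `excluded`, `reason`, `observed`, `chao1`, `shannon_norm`.
#' @export
diversity_table <- function(x, depth = 1000L, min_umi = 700L,
                            n_resamples = 1L, level = c("nt", "aa"),
                            seed = NULL) {
  stopifnot(inherits(x, "cohort"), depth >= 1, min_umi >= 1, n_resamples >= 1)
  level <- match.arg(level)
  run <- function() {
    rows <- lapply(x$repertoires, function(r) {
      base <- tibble::tibble(
        sample_id = r$meta$sample_id, mouse_id = r$meta$mouse_id,
        tissue = r$meta$tissue, subset = r$meta$subset,
        challenge = r$meta$challenge, total_count = r$total_count
      )
      if (r$total_count < min_umi) {
        return(dplyr::mutate(base, depth_used = NA_integer_, excluded = TRUE,
                             reason = sprintf("UMI < %d", min_umi),
                             observed = NA_real_, chao1 = NA_real_,
                             shannon_norm = NA_real_))
      }
      if (level == "aa") r <- aggregate_aa(r)
      d_used <- min(depth, r$total_count)
      mets <- vapply(seq_len(n_resamples), function(i) {
        ds <- if (r$total_count > d_used) downsample(r, d_used) else r
        c(observed_diversity(ds), chao1(ds), normalized_shannon(ds))
      }, numeric(3))
      m <- rowMeans(mets)
      dplyr::mutate(base, depth_used = as.integer(d_used), excluded = FALSE,
                    reason = "", observed = m[1], chao1 = m[2],
                    shannon_norm = m[3])
    })
    dplyr::bind_rows(rows)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Welch t-test of each group against control
#'
#' Two-sample parametric t-test (Welch, unequal variances) of every
#' non-control group against the control group, with the conventional star
#' annotation (* p<0.05, ** p<0.01, *** p<0.001, **** p<0.0001).
#'
#' @param values Numeric vector of per-sample metric values.
#' @param groups Group labels, same length as `values`.
#' @param control Label of the control group (must be non-empty).
#' @return Tibble with columns `group`, `n`, `n_control`, `mean`,
#'   `mean_control`, `p_value`, `stars`. Groups with fewer than 2 usable
#'   samples get `NA` with a warning.
#' @export
group_vs_control_ttest <- function(values, groups, control = "control") {
  stopifnot(length(values) == length(groups))
  ok <- !is.na(values)
  values <- values[ok]
  groups <- as.character(groups[ok])
  ctrl <- values[groups == control]
  if (length(ctrl) == 0) stop("control group is empty", call. = FALSE)
  out <- lapply(setdiff(unique(groups), control), function(g) {
    v <- values[groups == g]
    if (length(v) < 2 || length(ctrl) < 2 ||
        (stats::sd(v) == 0 && stats::sd(ctrl) == 0)) {
      if (length(v) < 2 || length(ctrl) < 2) {
        warning("group '", g, "' vs control: fewer than 2 samples; p = NA",
                call. = FALSE)
        p <- NA_real_
      } else {
        # identical constants in both groups: no evidence of difference
        p <- if (mean(v) == mean(ctrl)) 1 else 0
      }
    } else {
      p <- stats::t.test(v, ctrl, var.equal = FALSE)$p.value
    }
    tibble::tibble(group = g, n = length(v), n_control = length(ctrl),
                   mean = mean(v), mean_control = mean(ctrl),
                   p_value = p, stars = p_stars(p))
  })
  dplyr::bind_rows(out)
}

#' Star annotation for p-values
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: `"****"` (p<0.0001), `"***"` (p<0.001), `"**"`
#'   (p<0.01), `"*"` (p<0.05), `""` otherwise.
#' @export
p_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 1e-4) "****" else if (x < 1e-3) "***"
    else if (x < 1e-2) "**" else if (x < 0.05) "*" else ""
  }, character(1))
}
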