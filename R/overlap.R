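# Pairwise repertoire overlap: F2 metric (clonotype-wise sum of geometric
# mean frequencies) on top-N clonesets, all-vs-all matrices, MDS embeddings
# and dendrograms.

#' Select the top-N clonotypes after random shuffling
#'
#' Rows are shuffled with the seeded RNG and then stably sorted by
#' descending count, so ties among equal counts (e.g. the many count-1 and
#' count-2 clonotypes) are broken at random rather than alphabetically; the
#' first `n` rows are kept and frequencies renormalised within the
#' selection. Repertoires with fewer than `n` clonotypes are returned whole
#' (threshold-based exclusion is the caller's responsibility).
#'
#' @param rep A [repertoire()].
#' @param n Number of clonotypes to keep.
#' @param seed Optional integer seed.
#' @return A [repertoire()] with at most `n` clonotypes and frequencies
#'   summing to 1.
#' @export
top_n_clonotypes <- function(rep, n, seed = NULL) {
  stopifnot(inherits(rep, "repertoire"), n >= 1)
  tbl <- rep$clonotypes
  if (nrow(tbl) <= n) return(repertoire(tbl, rep$meta))
  run <- function() {
    perm <- sample.int(nrow(tbl))
    shuffled <- tbl[perm, , drop = FALSE]
    # stable sort on count only: tie order inherited from the shuffle
    shuffled <- shuffled[order(-shuffled$count, method = "radix"), ,
                         drop = FALSE]
    repertoire(shuffled[seq_len(n), , drop = FALSE], rep$meta)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Clonotype matching key per level: amino-acid level matches on (V gene,
# CDR3 aa); nucleotide level on (V gene, J gene, CDR3 nt). Allele suffixes
# are stripped so segments match at the gene level.
match_key <- function(tbl, match_level) {
  if (match_level == "aa") {
    paste(strip_allele(tbl$v), tbl$cdr3aa, sep = "|")
  } else {
    paste(strip_allele(tbl$v), strip_allele(tbl$j), tbl$cdr3nt, sep = "|")
  }
}

# Frequency per matching key (keys occurring several times are summed).
key_freqs <- function(rep, match_level) {
  key <- match_key(rep$clonotypes, match_level)
  vapply(split(rep$clonotypes$freq, key), sum, numeric(1))
}

#' F2 overlap between two repertoires
#'
#' The frequency-weighted repertoire overlap: the sum over shared clonotype
#' keys of the geometric mean of their frequencies in the two samples,
#' `F2 = sum_i sqrt(p_i q_i)`. It reflects the proportion of shared T cells
#' between the paired repertoires: 1 for identical frequency vectors, 0 for
#' disjoint clonesets. Callers normally reduce both repertoires to their
#' top-N clonotypes first (see [top_n_clonotypes()]), which renormalises
#' frequencies within the selection.
#'
#' @param rep_a,rep_b Non-empty [repertoire()] objects.
#' @param match_level `"aa"` (key: V gene + CDR3 amino acids) or `"nt"`
#'   (key: V gene + J gene + CDR3 nucleotides).
#' @return Numeric in \[0, 1\].
#' @export
f2_overlap <- function(rep_a, rep_b, match_level = c("aa", "nt")) {
  stopifnot(inherits(rep_a, "repertoire"), inherits(rep_b, "repertoire"))
  match_level <- match.arg(match_level)
  if (nrow(rep_a$clonotypes) == 0 || nrow(rep_b$clonotypes) == 0) {
    stop("F2 overlap of an empty repertoire", call. = FALSE)
  }
  pa <- key_freqs(rep_a, match_level)
  pb <- key_freqs(rep_b, match_level)
  shared <- intersect(names(pa), names(pb))
  if (length(shared) == 0) return(0)
  sum(sqrt(pa[shared] * pb[shared]))
}

#' All-vs-all F2 overlap matrix
#'
#' Computes pairwise F2 over a set of samples. At the amino-acid level each
#' repertoire is first collapsed with [aggregate_aa()]. Samples with fewer
#' than `min_clonotypes` clonotypes (at the analysis level) are excluded and
#' listed in the result's `excluded` field. Each eligible sample is reduced
#' to its top-`n` clonotypes (random tie-break, see [top_n_clonotypes()])
#' before the all-vs-all computation.
#'
#' @param samples A [cohort()] or list of [repertoire()] objects.
#' @param n Top-N cloneset size (default 1000).
#' @param match_level `"aa"` or `"nt"`.
#' @param min_clonotypes Exclusion threshold on clonotype count (default 700).
#' @param seed Optional integer seed for the tie-break shuffles.
#' @return An `overlap_matrix`: list with `sample_ids`, `f2` (symmetric
#'   matrix, unit diagonal), `match_level`, `top_n`, `excluded` and `meta`
#'   (sample annotation tibble).
#' @export
pairwise_overlap <- function(samples, n = 1000L, match_level = c("aa", "nt"),
                             min_clonotypes = 700L, seed = NULL) {
  match_level <- match.arg(match_level)
  if (inherits(samples, "cohort")) samples <- samples$repertoires
  stopifnot(all(vapply(samples, inherits, logical(1), "repertoire")))
  run <- function() {
    if (match_level == "aa") samples <- lapply(samples, aggregate_aa)
    sizes <- vapply(samples, function(r) nrow(r$clonotypes), integer(1))
    eligible <- sizes >= min_clonotypes
    excluded <- vapply(samples[!eligible], function(r) r$meta$sample_id,
                       character(1))
    samples <- samples[eligible]
    if (length(samples) < 2) {
      stop("fewer than 2 samples eligible for overlap analysis",
           call. = FALSE)
    }
    tops <- lapply(samples, top_n_clonotypes, n = n)
    kf <- lapply(tops, key_freqs, match_level = match_level)
    ids <- vapply(samples, function(r) r$meta$sample_id, character(1))
    m <- length(ids)
    f2 <- diag(1, m)
    dimnames(f2) <- list(ids, ids)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        shared <- intersect(names(kf[[i]]), names(kf[[j]]))
        val <- if (length(shared) == 0) 0 else
          sum(sqrt(kf[[i]][shared] * kf[[j]][shared]))
        f2[i, j] <- f2[j, i] <- val
      }
    }
    meta <- dplyr::bind_rows(lapply(samples, function(r) {
      tibble::tibble(sample_id = r$meta$sample_id,
                     mouse_id = r$meta$mouse_id, tissue = r$meta$tissue,
                     subset = r$meta$subset, challenge = r$meta$challenge)
    }))
    structure(list(sample_ids = ids, f2 = f2, match_level = match_level,
                   top_n = as.integer(n), excluded = unname(excluded),
                   meta = meta),
              class = "overlap_matrix")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("<overlap_matrix> %d samples, %s level, top-%d (%d excluded)\n",
              length(x$sample_ids), x$match_level, x$top_n,
              length(x$excluded)))
  invisible(x)
}

#' Convert an overlap matrix to a distance matrix
#'
#' The affine transform `d = 1 - F2`: bounded in \[0, 1\], zero for
#' identical repertoires, monotone-decreasing in overlap.
#'
#' @param m An `overlap_matrix` from [pairwise_overlap()], or a plain
#'   symmetric F2 matrix.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
overlap_to_distance <- function(m) {
  f2 <- if (inherits(m, "overlap_matrix")) m$f2 else as.matrix(m)
  d <- 1 - f2
  diag(d) <- 0
  d
}

#' Metric MDS embedding of a repertoire distance matrix
#'
#' Classical (Torgerson) metric multidimensional scaling by default, with
#' Sammon mapping as an iterative alternative. Euclidean distance between
#' embedded points approximates the repertoire distances. Kruskal-type
#' stress `sqrt(sum (dhat - d)^2 / sum d^2)` is reported.
#'
#' @param d Square symmetric non-negative distance matrix.
#' @param dims Embedding dimension (default 2; must be < nrow(d)).
#' @param method `"classical"` or `"sammon"` (requires MASS).
#' @param seed Optional integer seed (used by the Sammon initialisation).
#' @return List with `points` (n x dims matrix), `stress`, `method`.
#' @export
mds_embedding <- function(d, dims = 2L, method = c("classical", "sammon"),
                          seed = NULL) {
  method <- match.arg(method)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8 || any(d < 0)) {
    stop("d must be a square symmetric non-negative distance matrix",
         call. = FALSE)
  }
  if (dims >= nrow(d)) {
    stop("dims must be smaller than the number of samples", call. = FALSE)
  }
  run <- function() {
    if (method == "classical") {
      pts <- stats::cmdscale(stats::as.dist(d), k = dims)
      if (ncol(pts) < dims) { # degenerate configurations
        pts <- cbind(pts, matrix(0, nrow(pts), dims - ncol(pts)))
      }
    } else {
      init <- stats::cmdscale(stats::as.dist(d), k = dims)
      init <- init + matrix(stats::rnorm(length(init), sd = 1e-6),
                            nrow(init))
      pts <- MASS::sammon(stats::as.dist(d), y = init, k = dims,
                          trace = FALSE)$points
    }
    rownames(pts) <- rownames(d)
    dhat <- as.matrix(stats::dist(pts))
    denom <- sum(d^2)
    stress <- if (denom == 0) 0 else sqrt(sum((dhat - d)^2) / denom)
    list(points = pts, stress = stress, method = method)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Hierarchical dendrogram of repertoire distances
#'
#' Agglomerative clustering (average linkage / UPGMA by default) of the
#' repertoire distance matrix, returned as a phylogenetic tree whose branch
#' lengths reflect the distances between repertoires.
#'
#' @param d Square symmetric distance matrix with sample ids as dimnames
#'   (n >= 2).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List with `hclust` (the [stats::hclust()] object), `tree` (an
#'   [ape::as.phylo()] tree) and `newick` (serialised tree string).
#' @export
hierarchical_dendrogram <- function(d, linkage = "average") {
  d <- as.matrix(d)
  if (nrow(d) < 2) stop("need at least 2 samples", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  tree <- ape::as.phylo(hc)
  list(hclust = hc, tree = tree, newick = ape::write.tree(tree))
}
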