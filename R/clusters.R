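# CDR3 sequence-homology clustering: Hamming-1 graph over pooled unique
# amino-acid CDR3s, neighbor-count enrichment against the recombination
# baseline, connected components as motif clusters, per-cluster PWMs and a
# cluster-by-sample frequency matrix.

# All single-mismatch masks of equal-length sequences: for position p each
# sequence is keyed by its string with position p blanked; two sequences
# share a mask key iff they are equal everywhere except (possibly) at p.
position_masks <- function(seqs, p, len) {
  paste0(substr(seqs, 1L, p - 1L), "\r", substr(seqs, p + 1L, len))
}

#' Build the Hamming-1 CDR3 graph
#'
#' Nodes are unique amino-acid CDR3s; edges connect sequences of equal
#' length differing by exactly one substitution. Construction is
#' length-bucketed with per-position mask hashing (two sequences at Hamming
#' distance one share exactly one mask), so it scales near-linearly rather
#' than quadratically in the number of sequences.
#'
#' @param cdr3_set Character vector of amino-acid CDR3s (deduplicated
#'   internally; must be non-empty).
#' @return A `cdr3_graph`: list with `nodes` (character), `edges`
#'   (two-column integer matrix of node indices) and `degree`.
#' @export
build_cdr3_graph <- function(cdr3_set) {
  nodes <- unique(as.character(cdr3_set))
  if (length(nodes) == 0) stop("empty CDR3 set", call. = FALSE)
  lens <- nchar(nodes)
  edge_list <- list()
  for (len in unique(lens)) {
    idx <- which(lens == len)
    if (length(idx) < 2) next
    s <- nodes[idx]
    for (p in seq_len(len)) {
      groups <- split(idx, position_masks(s, p, len))
      groups <- groups[lengths(groups) > 1]
      for (g in groups) {
        edge_list[[length(edge_list) + 1L]] <- t(utils::combn(g, 2L))
      }
    }
  }
  edges <- if (length(edge_list) > 0) {
    do.call(rbind, edge_list)
  } else {
    matrix(integer(0), ncol = 2)
  }
  deg <- tabulate(edges, nbins = length(nodes))
  structure(list(nodes = nodes, edges = edges, degree = deg),
            class = "cdr3_graph")
}

#' @export
print.cdr3_graph <- function(x, ...) {
  cat(sprintf("<cdr3_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Number of baseline sequences at Hamming distance exactly 1 from each
# query sequence (baseline is a multiset; same mask-hash trick, subtracting
# the exact-match occurrences counted once per position).
baseline_neighbor_counts <- function(query, baseline) {
  res <- numeric(length(query))
  qlen <- nchar(query)
  blen <- nchar(baseline)
  for (len in unique(qlen)) {
    qi <- which(qlen == len)
    b <- baseline[blen == len]
    if (length(b) == 0) next
    bu <- unique(b)
    bcount <- tabulate(match(b, bu), nbins = length(bu))
    q <- query[qi]
    nb <- numeric(length(qi))
    for (p in seq_len(len)) {
      bm <- position_masks(b, p, len)
      um <- unique(bm)
      mc <- tabulate(match(bm, um), nbins = length(um))
      mi <- match(position_masks(q, p, len), um)
      hit <- !is.na(mi)
      nb[hit] <- nb[hit] + mc[mi[hit]]
    }
    self <- match(q, bu)
    has_self <- !is.na(self)
    nb[has_self] <- nb[has_self] - len * bcount[self[has_self]]
    res[qi] <- nb
  }
  res
}

#' Neighbor-count enrichment against a recombination baseline
#'
#' For each unique sample CDR3, compares its number of Hamming-1 neighbors
#' within the sample to the number expected by chance under the
#' recombination null: `expected = (neighbors within the baseline pool) x
#' (|sample| / |baseline|)`. Enrichment is assessed with an upper-tail
#' Poisson test at rate `max(expected, 1/|baseline|)`; p-values are
#' multiplicity-corrected and CDR3s with corrected `p < alpha` and at least
#' one observed neighbor are selected.
#'
#' @param sample_cdr3s Character vector of amino-acid CDR3s from the pooled
#'   sample (deduplicated internally).
#' @param baseline_cdr3s Character vector of baseline CDR3s (random
#'   rearrangements; may contain duplicates; must be at least as large as
#'   the sample set).
#' @param alpha Selection threshold on the corrected p-value (default 0.05).
#' @param correction Method for [stats::p.adjust()] (default `"BH"`).
#' @return Tibble with columns `cdr3aa`, `observed_neighbors`,
#'   `expected_neighbors`, `p_value`, `p_adjusted`, `selected`.
#' @export
neighbor_enrichment <- function(sample_cdr3s, baseline_cdr3s,
                                alpha = 0.05, correction = "BH") {
  sample_cdr3s <- unique(as.character(sample_cdr3s))
  baseline_cdr3s <- as.character(baseline_cdr3s)
  if (length(baseline_cdr3s) == 0) stop("empty baseline", call. = FALSE)
  if (length(baseline_cdr3s) < length(sample_cdr3s)) {
    stop("baseline must be at least as large as the sample CDR3 set",
         call. = FALSE)
  }
  graph <- build_cdr3_graph(sample_cdr3s)
  observed <- graph$degree[match(sample_cdr3s, graph$nodes)]
  bl_neighbors <- baseline_neighbor_counts(sample_cdr3s, baseline_cdr3s)
  scale <- length(sample_cdr3s) / length(baseline_cdr3s)
  expected <- bl_neighbors * scale
  lambda <- pmax(expected, 1 / length(baseline_cdr3s))
  p <- stats::ppois(observed - 1L, lambda, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = correction)
  tibble::tibble(
    cdr3aa = sample_cdr3s,
    observed_neighbors = as.integer(observed),
    expected_neighbors = expected,
    p_value = p,
    p_adjusted = padj,
    selected = padj < alpha & observed >= 1L
  )
}

#' Extract motif clusters from selected CDR3s
#'
#' Connected components of the Hamming-1 graph induced on the
#' enrichment-selected CDR3s. Because edges only join equal-length
#' sequences, every cluster is length-homogeneous. Singleton components are
#' discarded (a cluster needs at least two members). Cluster ids are
#' assigned deterministically: descending member count, ties broken by the
#' lexicographically smallest member.
#'
#' @param graph A [build_cdr3_graph()] result over the pooled CDR3 set.
#' @param selected Character vector of selected CDR3s (subset of the
#'   graph's nodes).
#' @return List of `cdr3_cluster` objects (fields `cluster_id`, `members`).
#' @export
extract_clusters <- function(graph, selected) {
  stopifnot(inherits(graph, "cdr3_graph"))
  selected <- unique(as.character(selected))
  if (!all(selected %in% graph$nodes)) {
    stop("selected CDR3s must be nodes of the graph", call. = FALSE)
  }
  if (length(selected) == 0) return(list())
  keep <- graph$nodes[graph$edges[, 1]] %in% selected &
    graph$nodes[graph$edges[, 2]] %in% selected
  edges <- graph$edges[keep, , drop = FALSE]
  if (nrow(edges) == 0) return(list())
  g <- igraph::graph_from_edgelist(
    cbind(graph$nodes[edges[, 1]], graph$nodes[edges[, 2]]),
    directed = FALSE
  )
  comp <- igraph::components(g)
  members_by_comp <- split(igraph::V(g)$name, comp$membership)
  members_by_comp <- members_by_comp[lengths(members_by_comp) >= 2]
  if (length(members_by_comp) == 0) return(list())
  smallest <- vapply(members_by_comp, function(m) sort(m, method = "radix")[1],
                     character(1))
  ord <- order(-lengths(members_by_comp), smallest, method = "radix")
  members_by_comp <- members_by_comp[ord]
  lapply(seq_along(members_by_comp), function(i) {
    structure(list(cluster_id = i,
                   members = sort(members_by_comp[[i]], method = "radix")),
              class = "cdr3_cluster")
  })
}

#' @export
print.cdr3_cluster <- function(x, ...) {
  cat(sprintf("<cdr3_cluster> #%d: %d members (len %d)\n", x$cluster_id,
              length(x$members), nchar(x$members[1])))
  invisible(x)
}

#' Cluster-by-sample frequency matrix
#'
#' Each entry is the total frequency, within one sample, of clonotypes
#' whose amino-acid CDR3 belongs to the cluster. Rows (clusters) and
#' columns (samples) are ordered by average-linkage hierarchical clustering
#' of Euclidean distances on `log10(freq + 1e-5)`.
#'
#' @param clusters List of `cdr3_cluster` objects from [extract_clusters()].
#' @param x A [cohort()].
#' @param reorder Reorder rows/columns by hierarchical clustering (default
#'   TRUE).
#' @return Matrix (clusters x samples) with `row_hclust` / `col_hclust`
#'   attributes when reordered.
#' @export
cluster_frequency_matrix <- function(clusters, x, reorder = TRUE) {
  stopifnot(inherits(x, "cohort"))
  ids <- vapply(x$repertoires, function(r) r$meta$sample_id, character(1))
  m <- matrix(0, nrow = length(clusters), ncol = length(ids),
              dimnames = list(paste0("C", vapply(clusters, `[[`, integer(1),
                                                 "cluster_id")), ids))
  for (j in seq_along(x$repertoires)) {
    tbl <- x$repertoires[[j]]$clonotypes
    for (i in seq_along(clusters)) {
      m[i, j] <- sum(tbl$freq[tbl$cdr3aa %in% clusters[[i]]$members])
    }
  }
  if (reorder && nrow(m) >= 2 && ncol(m) >= 2) {
    lm <- log10(m + 1e-5)
    rh <- stats::hclust(stats::dist(lm), method = "average")
    ch <- stats::hclust(stats::dist(t(lm)), method = "average")
    m <- m[rh$order, ch$order, drop = FALSE]
    attr(m, "row_hclust") <- rh
    attr(m, "col_hclust") <- ch
  }
  m
}

#' Position weight matrix and consensus of a motif cluster
#'
#' Per-position residue proportions over the cluster's member sequences,
#' weighted by each member's pooled clonotype frequency across the cohort
#' (members absent from the cohort contribute equal weight). Rows are the
#' 20 amino acids, columns are CDR3 positions and sum to 1, the layout
#' consumed by standard sequence-logo renderers. The consensus is the
#' argmax residue per position.
#'
#' @param cluster A `cdr3_cluster`.
#' @param x Optional [cohort()] supplying the frequency weights.
#' @return List with `pwm` (20 x L matrix), `consensus` (string) and
#'   `weights` (named member weights).
#' @export
cluster_pwm <- function(cluster, x = NULL) {
  stopifnot(inherits(cluster, "cdr3_cluster"))
  members <- cluster$members
  len <- nchar(members[1])
  stopifnot(all(nchar(members) == len))
  w <- rep(1, length(members))
  if (!is.null(x)) {
    stopifnot(inherits(x, "cohort"))
    w <- vapply(members, function(s) {
      sum(vapply(x$repertoires, function(r) {
        sum(r$clonotypes$freq[r$clonotypes$cdr3aa == s])
      }, numeric(1)))
    }, numeric(1))
    if (sum(w) == 0) w <- rep(1, length(members))
  }
  w <- w / sum(w)
  pwm <- matrix(0, nrow = length(AA_ALPHABET), ncol = len,
                dimnames = list(AA_ALPHABET, seq_len(len)))
  for (i in seq_along(members)) {
    res <- strsplit(members[i], "")[[1]]
    for (p in seq_len(len)) {
      pwm[res[p], p] <- pwm[res[p], p] + w[i]
    }
  }
  consensus <- paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
  list(pwm = pwm, consensus = consensus,
       weights = stats::setNames(w, members))
}

#' Run the full motif-clustering stage on a cohort
#'
#' Pools all unique amino-acid CDR3s across the cohort, scores neighbor
#' enrichment against a recombination baseline (generated from `model` at
#' `baseline_factor` times the pooled unique count when `baseline` is not
#' supplied), and extracts motif clusters.
#'
#' @param x A [cohort()].
#' @param baseline Optional character vector of baseline CDR3s.
#' @param model Recombination model used when `baseline` is `NULL`.
#' @param baseline_factor Baseline size as a multiple of the pooled unique
#'   CDR3 count (default 10).
#' @param alpha,correction Passed to [neighbor_enrichment()].
#' @param seed Optional integer seed (baseline generation).
#' @return List with `enrichment` (tibble), `clusters` (list) and `graph`.
#' @export
find_motif_clusters <- function(x, baseline = NULL,
                                model = default_recombination_model(),
                                baseline_factor = 10, alpha = 0.05,
                                correction = "BH", seed = NULL) {
  stopifnot(inherits(x, "cohort"))
  pooled <- unique(unlist(lapply(x$repertoires,
                                 function(r) r$clonotypes$cdr3aa),
                          use.names = FALSE))
  if (is.null(baseline)) {
    baseline <- generate_baseline(model,
                                  ceiling(baseline_factor * length(pooled)),
                                  seed = seed)$cdr3aa
  }
  enr <- neighbor_enrichment(pooled, baseline, alpha = alpha,
                             correction = correction)
  graph <- build_cdr3_graph(pooled)
  clusters <- extract_clusters(graph, enr$cdr3aa[enr$selected])
  list(enrichment = enr, clusters = clusters, graph = graph)
}
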