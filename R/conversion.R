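# Matched-pair analysis of clonal sharing between eCD4 and eTreg subsets
# (nucleotide-level F2 on top-100 clonesets) and invariant NKT tracking.

#' Nucleotide-level F2 between a mouse's eCD4 and eTreg samples
#'
#' Both repertoires are reduced to their top-`top_n` clonotypes (random
#' tie-break, frequencies renormalised) and overlapped at the nucleotide
#' level (key: V gene + J gene + CDR3 nt). Shared nucleotide rearrangements
#' between the two subsets of one animal are the repertoire signature of
#' clonal conversion. Samples with fewer than `min_clonotypes` clonotypes
#' are ineligible: the function returns `NA` with attribute
#' `eligible = FALSE` (and a warning on direct calls).
#'
#' @param ecd4,etreg [repertoire()] objects from the same mouse and tissue.
#' @param top_n Cloneset size (default 100).
#' @param min_clonotypes Eligibility threshold (default 100).
#' @param seed Optional integer seed for the tie-break shuffles.
#' @param warn Emit a warning when a sample is ineligible (default TRUE).
#' @return Numeric F2 in \[0, 1\], or `NA` when ineligible; attribute
#'   `eligible`.
#' @export
conversion_f2 <- function(ecd4, etreg, top_n = 100L, min_clonotypes = 100L,
                          seed = NULL, warn = TRUE) {
  stopifnot(inherits(ecd4, "repertoire"), inherits(etreg, "repertoire"))
  if (ecd4$meta$mouse_id != etreg$meta$mouse_id ||
      ecd4$meta$tissue != etreg$meta$tissue) {
    stop("conversion F2 requires samples from the same mouse and tissue",
         call. = FALSE)
  }
  if (nrow(ecd4$clonotypes) < min_clonotypes ||
      nrow(etreg$clonotypes) < min_clonotypes) {
    if (warn) {
      warning("sample with < ", min_clonotypes,
              " clonotypes: pair ineligible for conversion analysis",
              call. = FALSE)
    }
    return(structure(NA_real_, eligible = FALSE))
  }
  run <- function() {
    a <- top_n_clonotypes(ecd4, top_n)
    b <- top_n_clonotypes(etreg, top_n)
    f2_overlap(a, b, match_level = "nt")
  }
  val <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(val, eligible = TRUE)
}

#' Conversion table and group comparison for a cohort
#'
#' Computes the matched-pair nucleotide F2 for every (mouse, tissue) with
#' both subsets present, then tests each challenge group against control
#' separately per tissue (so the challenge-site and spleen contrasts are
#' reported side by side). Mice missing one subset are skipped with a
#' warning.
#'
#' @param x A [cohort()] containing matched eCD4/eTreg pairs.
#' @param top_n,min_clonotypes See [conversion_f2()].
#' @param control Control challenge label.
#' @param seed Optional integer seed.
#' @return List with `records` (tibble: mouse_id, tissue, challenge, f2_nt,
#'   eligible) and `tests` (tibble of per-tissue Welch t-tests vs control).
#' @export
conversion_table <- function(x, top_n = 100L, min_clonotypes = 100L,
                             control = "control", seed = NULL) {
  stopifnot(inherits(x, "cohort"))
  meta <- cohort_summary(x)
  pairs <- unique(meta[, c("mouse_id", "tissue", "challenge")])
  run <- function() {
    rows <- list()
    for (i in seq_len(nrow(pairs))) {
      sel <- meta$mouse_id == pairs$mouse_id[i] &
        meta$tissue == pairs$tissue[i]
      ids <- meta$sample_id[sel]
      subs <- meta$subset[sel]
      if (!all(c("eCD4", "eTreg") %in% subs)) {
        warning("mouse ", pairs$mouse_id[i], " (", pairs$tissue[i],
                "): missing subset, pair skipped", call. = FALSE)
        next
      }
      ecd4 <- x$repertoires[[ids[subs == "eCD4"][1]]]
      etreg <- x$repertoires[[ids[subs == "eTreg"][1]]]
      val <- conversion_f2(ecd4, etreg, top_n = top_n,
                           min_clonotypes = min_clonotypes, warn = FALSE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        mouse_id = pairs$mouse_id[i], tissue = pairs$tissue[i],
        challenge = pairs$challenge[i], f2_nt = as.numeric(val),
        eligible = attr(val, "eligible")
      )
    }
    if (length(rows) == 0) stop("no matched subset pairs in cohort",
                                call. = FALSE)
    records <- dplyr::bind_rows(rows)
    tests <- list()
    for (tis in unique(records$tissue)) {
      rt <- records[records$tissue == tis & records$eligible, ]
      if (!control %in% rt$challenge || length(unique(rt$challenge)) < 2) next
      tt <- group_vs_control_ttest(rt$f2_nt, rt$challenge, control = control)
      tt$tissue <- tis
      tests[[length(tests) + 1L]] <- tt
    }
    list(records = records,
         tests = if (length(tests) > 0) dplyr::bind_rows(tests) else
           tibble::tibble())
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Invariant NKT fraction of a repertoire
#'
#' Summed frequency of clonotypes matching the canonical invariant NKT
#' receptor — TRAV11 V gene, CVVGDRGSALGRLHF amino-acid CDR3 and TRAJ18 J
#' gene — over any nucleotide variant. Invariant under [aggregate_aa()] and
#' under splitting the clonotype into nucleotide variants.
#'
#' @param rep A [repertoire()].
#' @return Numeric fraction in \[0, 1\].
#' @export
inkt_fraction <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  def <- inkt_definition()
  tbl <- rep$clonotypes
  hit <- strip_allele(tbl$v) == def$v &
    strip_allele(tbl$j) == def$j &
    tbl$cdr3aa == def$cdr3aa
  sum(tbl$freq[hit])
}

#' iNKT fractions across a cohort
#'
#' @param x A [cohort()].
#' @return Tibble with sample annotation and `inkt_fraction`.
#' @export
inkt_table <- function(x) {
  stopifnot(inherits(x, "cohort"))
  meta <- cohort_summary(x)
  meta$inkt_fraction <- unname(vapply(x$repertoires, inkt_fraction,
                                      numeric(1)))
  meta
}

#' Per-sample share of a motif cluster, split by subset
#'
#' Annotated per-sample frequency of one CDR3 cluster, enabling the
#' comparison of a shared motif's representation in eTreg vs eCD4
#' repertoires across tissues and challenges.
#'
#' @param cluster A `cdr3_cluster` from [extract_clusters()].
#' @param x A [cohort()].
#' @return Tibble: sample_id, mouse_id, tissue, subset, challenge,
#'   `frequency`.
#' @export
cluster_share_in_subsets <- function(cluster, x) {
  stopifnot(inherits(cluster, "cdr3_cluster"), inherits(x, "cohort"))
  meta <- cohort_summary(x)
  meta$frequency <- unname(vapply(x$repertoires, function(r) {
    sum(r$clonotypes$freq[r$clonotypes$cdr3aa %in% cluster$members])
  }, numeric(1)))
  meta[, c("sample_id", "mouse_id", "tissue", "subset", "challenge",
           "frequency")]
}
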