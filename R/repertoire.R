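# Domain types: sample metadata, repertoire (clonotype table + metadata), cohort.

#' Controlled vocabularies for sample annotation
#'
#' Tissue, subset and challenge labels used throughout the package. The seven
#' tissues are the lung, the skin, three lymph node stations (lung-draining
#' mediastinal MLN, axillary AXLN, intraglandular IGLN), the spleen and the
#' thymus. Subsets are effector regulatory (eTreg, FoxP3+) and conventional
#' effector (eCD4) CD4+ T cells.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
TISSUES <- c("lung", "skin", "MLN", "AXLN", "IGLN", "spleen", "thymus")

#' @rdname vocabularies
#' @export
SUBSETS <- c("eTreg", "eCD4")

#' @rdname vocabularies
#' @export
CHALLENGES <- c("control", "influenza", "nippo", "bleomycin", "LLC", "PYMT", "B16")

#' Create sample metadata
#'
#' @param sample_id Unique sample identifier.
#' @param mouse_id Animal identifier.
#' @param tissue One of [TISSUES].
#' @param subset One of [SUBSETS].
#' @param challenge One of [CHALLENGES].
#' @return A `sample_meta` object.
#' @export
sample_meta <- function(sample_id, mouse_id, tissue, subset, challenge) {
  tissue <- match.arg(tissue, TISSUES)
  subset <- match.arg(subset, SUBSETS)
  challenge <- match.arg(challenge, CHALLENGES)
  structure(
    list(
      sample_id = as.character(sample_id),
      mouse_id = as.character(mouse_id),
      tissue = tissue,
      subset = subset,
      challenge = challenge
    ),
    class = "sample_meta"
  )
}

#' @export
print.sample_meta <- function(x, ...) {
  cat(sprintf(
    "<sample_meta> %s: mouse %s, %s %s, challenge %s\n",
    x$sample_id, x$mouse_id, x$tissue, x$subset, x$challenge
  ))
  invisible(x)
}

# Strip allele suffixes so segments are matched at the gene level
# ("TRAV11*01" -> "TRAV11").
strip_allele <- function(x) sub("\\*.*$", "", x)

# Deterministic clonotype ordering: descending count, then C-locale
# lexicographic CDR3 nt (aa as fallback where nt is absent).
order_clonotypes <- function(tbl) {
  nt <- tbl$cdr3nt
  nt[is.na(nt)] <- ""
  tbl[order(-tbl$count, nt, tbl$cdr3aa, method = "radix"), , drop = FALSE]
}

#' Construct a repertoire
#'
#' A repertoire is one sample's clonotype table plus its metadata. Counts are
#' UMI-labelled cDNA molecule counts; frequencies are always recomputed as
#' `count / total_count`. Clonotypes are stored sorted by descending count
#' with lexicographic CDR3 tie-break so that identical inputs serialise
#' byte-identically.
#'
#' @param clonotypes Data frame with columns `count`, `cdr3nt`, `cdr3aa`,
#'   `v`, `j` and optionally `d`. Counts must be >= 1; amino-acid CDR3s must
#'   be stop-free and, where the nucleotide CDR3 is present, in frame
#'   (`nchar(cdr3nt) == 3 * nchar(cdr3aa)`).
#' @param meta A [sample_meta()] object.
#' @return A `repertoire` object: list with elements `meta`, `clonotypes`
#'   (tibble with recomputed `freq`) and `total_count`.
#' @export
repertoire <- function(clonotypes, meta) {
  stopifnot(inherits(meta, "sample_meta"))
  tbl <- tibble::as_tibble(clonotypes)
  required <- c("count", "cdr3nt", "cdr3aa", "v", "j")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop("clonotype table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"d" %in% names(tbl)) tbl$d <- ""
  tbl$d[is.na(tbl$d)] <- ""
  tbl$count <- as.integer(tbl$count)
  if (nrow(tbl) > 0) {
    if (anyNA(tbl$count) || any(tbl$count < 1)) {
      stop("clonotype counts must be integers >= 1", call. = FALSE)
    }
    if (any(grepl("[*_]", tbl$cdr3aa))) {
      stop("amino-acid CDR3s must be stop-free (no '*' or '_')", call. = FALSE)
    }
    has_nt <- !is.na(tbl$cdr3nt) & nzchar(tbl$cdr3nt)
    bad_frame <- has_nt & nchar(tbl$cdr3nt) != 3L * nchar(tbl$cdr3aa)
    if (any(bad_frame)) {
      stop("out-of-frame clonotype(s): nchar(cdr3nt) != 3 * nchar(cdr3aa)",
           call. = FALSE)
    }
  }
  tbl <- tbl[, c("count", "cdr3nt", "cdr3aa", "v", "d", "j")]
  tbl <- order_clonotypes(tbl)
  total <- sum(tbl$count)
  tbl$freq <- if (total > 0) tbl$count / total else numeric(0)
  tbl <- tbl[, c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j")]
  structure(
    list(meta = meta, clonotypes = tbl, total_count = as.integer(total)),
    class = "repertoire"
  )
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf(
    "<repertoire> %s (%s, %s, %s): %d clonotypes, %d UMIs\n",
    x$meta$sample_id, x$meta$tissue, x$meta$subset, x$meta$challenge,
    nrow(x$clonotypes), x$total_count
  ))
  invisible(x)
}

#' Collapse a repertoire to amino-acid clonotypes
#'
#' Groups clonotypes by (V gene, amino-acid CDR3) — the clonotype definition
#' used for amino-acid-level overlap analyses — summing counts over
#' nucleotide variants. Segment names are matched at the gene level (allele
#' suffixes stripped). The nucleotide CDR3 and J segment of the largest
#' member are retained as representatives. Total count is conserved exactly
#' and the operation is idempotent.
#'
#' @param rep A [repertoire()].
#' @return A [repertoire()] with one row per (V gene, CDR3 aa) pair.
#' @export
aggregate_aa <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  tbl <- rep$clonotypes
  if (nrow(tbl) == 0) return(rep)
  tbl <- order_clonotypes(tbl) # largest member first within each group
  tbl$v <- strip_allele(tbl$v)
  agg <- dplyr::summarise(
    dplyr::group_by(tbl, .data$v, .data$cdr3aa),
    cdr3nt = .data$cdr3nt[1],
    d = .data$d[1],
    j = .data$j[1],
    count = sum(.data$count),
    .groups = "drop"
  )
  repertoire(agg, rep$meta)
}

#' Construct a cohort
#'
#' A cohort is a set of repertoires plus the study design (which mice belong
#' to which challenge). The (mouse, tissue, subset) triple must be unique.
#'
#' @param repertoires List of [repertoire()] objects.
#' @param design Optional named list mapping challenge to mouse ids; derived
#'   from the repertoires when `NULL`.
#' @return A `cohort` object.
#' @export
cohort <- function(repertoires, design = NULL) {
  stopifnot(length(repertoires) > 0,
            all(vapply(repertoires, inherits, logical(1), "repertoire")))
  meta <- cohort_metadata_(repertoires)
  key <- paste(meta$mouse_id, meta$tissue, meta$subset)
  if (anyDuplicated(key)) {
    stop("duplicate (mouse, tissue, subset) combination in cohort", call. = FALSE)
  }
  if (is.null(design)) {
    design <- lapply(split(meta$mouse_id, meta$challenge), unique)
  } else {
    for (i in seq_len(nrow(meta))) {
      ch <- meta$challenge[i]
      if (!ch %in% names(design) || !meta$mouse_id[i] %in% design[[ch]]) {
        stop("repertoire ", meta$sample_id[i],
             " inconsistent with cohort design", call. = FALSE)
      }
    }
  }
  names(repertoires) <- meta$sample_id
  structure(list(repertoires = repertoires, design = design), class = "cohort")
}

cohort_metadata_ <- function(repertoires) {
  dplyr::bind_rows(lapply(repertoires, function(r) {
    tibble::tibble(
      sample_id = r$meta$sample_id, mouse_id = r$meta$mouse_id,
      tissue = r$meta$tissue, subset = r$meta$subset,
      challenge = r$meta$challenge,
      total_count = r$total_count, n_clonotypes = nrow(r$clonotypes)
    )
  }))
}

#' Summarise cohort samples
#'
#' @param x A [cohort()].
#' @return Tibble with one row per sample (metadata, UMI total, clonotype
#'   count).
#' @export
cohort_summary <- function(x) {
  stopifnot(inherits(x, "cohort"))
  cohort_metadata_(x$repertoires)
}

#' @export
print.cohort <- function(x, ...) {
  meta <- cohort_summary(x)
  cat(sprintf(
    "<cohort> %d samples, %d mice, %d challenges, %d tissues\n",
    nrow(meta), length(unique(meta$mouse_id)),
    length(unique(meta$challenge)), length(unique(meta$tissue))
  ))
  invisible(x)
}

#' Subset a cohort by sample annotation
#'
#' @param x A [cohort()].
#' @param tissues,subsets,challenges Optional label vectors to keep.
#' @return A [cohort()] with the matching repertoires.
#' @export
cohort_subset <- function(x, tissues = NULL, subsets = NULL, challenges = NULL) {
  stopifnot(inherits(x, "cohort"))
  keep <- vapply(x$repertoires, function(r) {
    (is.null(tissues) || r$meta$tissue %in% tissues) &&
      (is.null(subsets) || r$meta$subset %in% subsets) &&
      (is.null(challenges) || r$meta$challenge %in% challenges)
  }, logical(1))
  if (!any(keep)) stop("no repertoires match the requested subset", call. = FALSE)
  cohort(x$repertoires[keep])
}
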