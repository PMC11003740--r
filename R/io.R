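# Clonotype-table and manifest I/O. The tabular dialect follows the common
# repertoire-table convention: tab-separated, header row, columns
# count / freq / cdr3nt / cdr3aa / v / d / j.

#' Default clonotype-table column mapping
#'
#' Maps the internal field names to the column headers of the tabular
#' clonotype format. Override individual entries to read tables from tools
#' using different headers.
#'
#' @return Named character vector.
#' @export
default_columns <- function() {
  c(count = "count", freq = "freq", cdr3nt = "cdr3nt", cdr3aa = "cdr3aa",
    v = "v", d = "d", j = "j")
}

#' Read a clonotype table
#'
#' Reads a tab-separated clonotype table, validates the in-frame invariant,
#' and returns a [repertoire()] sorted by descending count with frequencies
#' recomputed from counts. Rows violating the invariants (count < 1, stop
#' symbol `*`/`_` in the amino-acid CDR3, nucleotide CDR3 length not equal to
#' three times the amino-acid length) are dropped with a warning; the number
#' of dropped rows is returned in the `"dropped"` attribute.
#'
#' @param path Path to the TSV file.
#' @param meta A [sample_meta()] object.
#' @param columns Column mapping, see [default_columns()]. `count`, `cdr3nt`,
#'   `cdr3aa`, `v` and `j` are mandatory in the file; `freq` and `d` are
#'   optional.
#' @return A [repertoire()] with attribute `dropped` (integer).
#' @export
read_clonotype_table <- function(path, meta, columns = default_columns()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  mandatory <- c("count", "cdr3nt", "cdr3aa", "v", "j")
  for (field in mandatory) {
    if (!columns[[field]] %in% names(raw)) {
      stop("clonotype table ", path, " lacks mandatory column '",
           columns[[field]], "' (field ", field, ")", call. = FALSE)
    }
  }
  if (nrow(raw) == 0) stop("empty clonotype table: ", path, call. = FALSE)
  tbl <- tibble::tibble(
    count = suppressWarnings(as.integer(raw[[columns[["count"]]]])),
    cdr3nt = raw[[columns[["cdr3nt"]]]],
    cdr3aa = raw[[columns[["cdr3aa"]]]],
    v = raw[[columns[["v"]]]],
    d = if (columns[["d"]] %in% names(raw)) raw[[columns[["d"]]]] else "",
    j = raw[[columns[["j"]]]]
  )
  tbl$d[is.na(tbl$d) | tbl$d == "."] <- ""
  has_nt <- !is.na(tbl$cdr3nt) & nzchar(tbl$cdr3nt)
  ok <- !is.na(tbl$count) & tbl$count >= 1L &
    !is.na(tbl$cdr3aa) & nzchar(tbl$cdr3aa) &
    !grepl("[*_]", tbl$cdr3aa) &
    (!has_nt | nchar(tbl$cdr3nt) == 3L * nchar(tbl$cdr3aa)) &
    (!has_nt | !grepl("[^ACGT]", tbl$cdr3nt))
  dropped <- sum(!ok)
  if (dropped > 0) {
    warning("dropped ", dropped, " invalid clonotype row(s) from ", path,
            call. = FALSE)
  }
  tbl <- tbl[ok, , drop = FALSE]
  if (nrow(tbl) == 0) {
    stop("no valid clonotype rows in ", path, call. = FALSE)
  }
  out <- repertoire(tbl, meta)
  attr(out, "dropped") <- as.integer(dropped)
  out
}

#' Write a clonotype table
#'
#' Serialises a repertoire as a TSV in the default dialect. Rows are written
#' in descending count order with lexicographic CDR3 tie-break, so a
#' read-back reproduces the repertoire exactly. Refuses to write an empty
#' repertoire.
#'
#' @param rep A [repertoire()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(rep, path) {
  stopifnot(inherits(rep, "repertoire"))
  if (nrow(rep$clonotypes) == 0) {
    stop("refusing to write an empty repertoire", call. = FALSE)
  }
  readr::write_tsv(rep$clonotypes, path, progress = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' @param path TSV with columns `sample_id`, `path`, `mouse_id`, `tissue`,
#'   `subset`, `challenge`.
#' @return Tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  man <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("sample_id", "path", "mouse_id", "tissue", "subset", "challenge")
  missing_cols <- setdiff(needed, names(man))
  if (length(missing_cols) > 0) {
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  man
}

#' Read a cohort from a manifest
#'
#' @param manifest Path to a manifest TSV or a tibble as returned by
#'   [read_manifest()].
#' @param base_dir Directory relative to which sample paths are resolved;
#'   defaults to the manifest's directory when `manifest` is a path.
#' @return A [cohort()].
#' @export
read_cohort <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  if (is.null(base_dir)) base_dir <- "."
  reps <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, p)
    if (!file.exists(p)) {
      stop("sample ", manifest$sample_id[i], ": file not found: ",
           manifest$path[i], call. = FALSE)
    }
    meta <- sample_meta(manifest$sample_id[i], manifest$mouse_id[i],
                        manifest$tissue[i], manifest$subset[i],
                        manifest$challenge[i])
    reps[[i]] <- read_clonotype_table(p, meta)
  }
  cohort(reps)
}

#' Write a cohort to disk
#'
#' Writes one clonotype TSV per sample plus a manifest TSV.
#'
#' @param x A [cohort()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- cohort_summary(x)
  files <- paste0(meta$sample_id, ".tsv")
  for (i in seq_along(x$repertoires)) {
    write_clonotype_table(x$repertoires[[i]], file.path(dir, files[i]))
  }
  man <- tibble::tibble(
    sample_id = meta$sample_id, path = files, mouse_id = meta$mouse_id,
    tissue = meta$tissue, subset = meta$subset, challenge = meta$challenge
  )
  manifest_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(man, manifest_path, progress = FALSE)
  invisible(manifest_path)
}
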