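# Clonotype table reading/writing and repertoire transforms.

write_fixture_tsv <- function(df, path = withr::local_tempfile(
                                fileext = ".tsv",
                                .local_envir = parent.frame())) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

test_that("reading a clonotype table recomputes frequencies from counts", {
  path <- write_fixture_tsv(tibble::tibble(
    count = c(10, 5, 1), freq = c(0.9, 0.05, 0.05),
    cdr3nt = nt_of(make_aa(0:2)), cdr3aa = make_aa(0:2),
    v = "TRAV1", d = "", j = "TRAJ1"
  ))
  rep <- read_clonotype_table(path, sample_meta("s", "m", "lung", "eTreg",
                                                "control"))
  expect_equal(rep$total_count, 16L)
  expect_equal(rep$clonotypes$freq, c(0.625, 0.3125, 0.0625))
  expect_equal(attr(rep, "dropped"), 0L)
})

test_that("rows violating the in-frame invariant are dropped and counted", {
  aa <- make_aa(0:2)
  aa[2] <- "CASS_F" # stop symbol
  path <- write_fixture_tsv(tibble::tibble(
    count = c(5, 4, 3), cdr3nt = nt_of(make_aa(0:2)), cdr3aa = aa,
    v = "TRAV1", d = "", j = "TRAJ1"
  ))
  expect_warning(
    rep <- read_clonotype_table(path, sample_meta("s", "m", "lung", "eTreg",
                                                  "control")),
    "dropped 1"
  )
  expect_equal(attr(rep, "dropped"), 1L)
  expect_equal(nrow(rep$clonotypes), 2L)

  # frame violation: nt length not 3x aa length
  path2 <- write_fixture_tsv(tibble::tibble(
    count = 2, cdr3nt = "TGTGC", cdr3aa = "CA", v = "TRAV1", d = "",
    j = "TRAJ1"
  ))
  expect_warning(
    expect_error(read_clonotype_table(path2, sample_meta("s", "m", "lung",
                                                         "eTreg", "control")),
                 "no valid"),
    "dropped"
  )
})

test_that("missing mandatory columns and empty tables are format errors", {
  path <- write_fixture_tsv(tibble::tibble(
    cdr3nt = "TGTGCTTTT", cdr3aa = "CAF", v = "TRAV1", j = "TRAJ1"
  ))
  expect_error(
    read_clonotype_table(path, sample_meta("s", "m", "lung", "eTreg",
                                           "control")),
    "count"
  )
  empty <- write_fixture_tsv(tibble::tibble(
    count = integer(0), cdr3nt = character(0), cdr3aa = character(0),
    v = character(0), j = character(0)
  ))
  expect_error(
    read_clonotype_table(empty, sample_meta("s", "m", "lung", "eTreg",
                                            "control")),
    "empty"
  )
})

test_that("write/read round-trips randomly generated repertoires", {
  dir <- withr::local_tempdir()
  for (seed in 1:5) {
    rep <- random_rep(40, seed)
    path <- file.path(dir, sprintf("r%d.tsv", seed))
    write_clonotype_table(rep, path)
    back <- read_clonotype_table(path, rep$meta)
    attr(back, "dropped") <- NULL
    expect_equal(back, rep)
  }
})

test_that("writing refuses empty repertoires and keeps single rows intact", {
  empty <- make_rep(integer(0), cdr3aa = character(0), v = character(0),
                    j = character(0), cdr3nt = character(0))
  expect_error(write_clonotype_table(empty, tempfile()), "empty")

  one <- make_rep(7L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clonotype_table(one, path)
  lines <- readLines(path)
  expect_length(lines, 2L) # header + 1 row
})

test_that("aggregate_aa sums nucleotide variants of the same (V, CDR3aa)", {
  aa <- c("CAASF", "CAASF", "CADGF")
  rep <- make_rep(c(3, 2, 4), cdr3aa = aa,
                  cdr3nt = c("TGTGCTGCTTCTTTT", "TGCGCAGCATCATTC",
                             nt_of("CADGF")),
                  v = c("TRAV11", "TRAV11*01", "TRAV2"),
                  j = c("TRAJ1", "TRAJ2", "TRAJ1"))
  agg <- aggregate_aa(rep)
  expect_equal(nrow(agg$clonotypes), 2L)
  merged <- agg$clonotypes[agg$clonotypes$cdr3aa == "CAASF", ]
  expect_equal(merged$count, 5L)
  expect_equal(merged$v, "TRAV11") # allele suffix stripped
  expect_equal(agg$total_count, rep$total_count)
})

test_that("aggregate_aa keeps identical CDR3aa under different V genes apart", {
  rep <- make_rep(c(3, 2), cdr3aa = c("CAASF", "CAASF"),
                  cdr3nt = rep(nt_of("CAASF"), 2),
                  v = c("TRAV11", "TRAV12"), j = c("TRAJ1", "TRAJ1"))
  agg <- aggregate_aa(rep)
  expect_equal(nrow(agg$clonotypes), 2L)
})

test_that("aggregate_aa is idempotent, conserves totals, reduces diversity", {
  for (seed in 1:4) {
    rep <- random_rep(60, seed)
    agg <- aggregate_aa(rep)
    expect_equal(agg$total_count, rep$total_count)
    expect_lte(observed_diversity(agg), observed_diversity(rep))
    expect_equal(aggregate_aa(agg)$clonotypes$count, agg$clonotypes$count)
  }
  distinct <- make_rep(c(5, 3), cdr3aa = make_aa(0:1))
  expect_equal(aggregate_aa(distinct)$clonotypes$count,
               distinct$clonotypes$count)
})

test_that("cohorts round-trip through manifest and per-sample files", {
  reps <- list(
    random_rep(30, 1, sample_id = "a", mouse_id = "m1", subset = "eTreg"),
    random_rep(30, 2, sample_id = "b", mouse_id = "m1", subset = "eCD4"),
    random_rep(30, 3, sample_id = "c", mouse_id = "m2", subset = "eTreg")
  )
  coh <- cohort(reps)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(coh, dir)
  back <- read_cohort(manifest)
  for (id in names(coh$repertoires)) {
    got <- back$repertoires[[id]]
    attr(got, "dropped") <- NULL
    expect_equal(got, coh$repertoires[[id]])
  }
  # missing file is reported with the sample name
  man <- read_manifest(manifest)
  man$path[2] <- "nonexistent.tsv"
  bad <- file.path(dir, "bad_manifest.tsv")
  readr::write_tsv(man, bad, progress = FALSE)
  expect_error(read_cohort(bad), "sample b")
})

test_that("duplicate (mouse, tissue, subset) combinations are rejected", {
  reps <- list(
    random_rep(10, 1, sample_id = "a", mouse_id = "m1"),
    random_rep(10, 2, sample_id = "b", mouse_id = "m1")
  )
  expect_error(cohort(reps), "duplicate")
})
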