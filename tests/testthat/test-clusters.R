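# CDR3 homology graph, neighbor enrichment, cluster extraction, PWMs.

test_that("the Hamming-1 graph connects single substitutions only", {
  g <- build_cdr3_graph(c("CASSL", "CASSF"))
  expect_equal(nrow(g$edges), 1L)
  g2 <- build_cdr3_graph(c("CASSL", "CASS")) # length differs: no edge
  expect_equal(nrow(g2$edges), 0L)
  g3 <- build_cdr3_graph(c("CASSL", "CASSL", "CAXXL"))
  expect_length(g3$nodes, 2L) # deduplicated, no self-edges
  expect_equal(nrow(g3$edges), 0L)
  expect_error(build_cdr3_graph(character(0)), "empty")
})

test_that("graph construction equals the all-pairs oracle on random CDR3s", {
  seqs <- withr::with_seed(55, unique(make_aa(sample.int(5000, 400) - 1L,
                                              len = 3)))
  g <- build_cdr3_graph(seqs)
  oracle <- hamming1_oracle_edges(g$nodes)
  expect_gt(nrow(oracle), 0) # fixture dense enough to be informative
  expect_identical(edge_key_set(g$nodes, g$edges),
                   edge_key_set(g$nodes, oracle))
  expect_equal(g$degree, tabulate(oracle, nbins = length(g$nodes)))
})

test_that("neighbor enrichment needs neighbors and a large enough baseline", {
  baseline <- make_aa(0:199, len = 4)
  enr <- neighbor_enrichment(c("CWWWWF", "CYYYYF"), baseline)
  expect_false(any(enr$selected)) # observed 0 neighbors: never selected
  expect_true(all(enr$p_value >= 0 & enr$p_value <= 1))
  expect_true(all(enr$expected_neighbors >= 0))
  expect_error(neighbor_enrichment(make_aa(0:49), make_aa(0:9)),
               "at least as large")
  expect_error(neighbor_enrichment("CAF", character(0)), "empty")
})

test_that("a planted one-mismatch cluster is detected against the baseline", {
  model <- default_recombination_model()
  baseline <- generate_baseline(model, 20000, seed = 61)$cdr3aa
  sample_bg <- unique(generate_baseline(model, 2000, seed = 62)$cdr3aa)
  planted <- c("CAQQQQQQKLF",
               vapply(1:10, function(i) {
                 s <- strsplit("CAQQQQQQKLF", "")[[1]]
                 s[4] <- AA20[i]
                 paste(s, collapse = "")
               }, character(1)))
  planted <- unique(planted)
  enr <- neighbor_enrichment(c(sample_bg, planted), baseline)
  hit <- enr$selected[match(planted, enr$cdr3aa)]
  expect_gte(mean(hit), 0.9) # nearly all planted members selected
})

test_that("clusters are the connected components of selected CDR3s", {
  g <- build_cdr3_graph(c("CAAAF", "CAABF", "CAABW", "CXXXF", "CYYYF",
                          "CAAAAAF"))
  expect_length(extract_clusters(g, character(0)), 0L)
  cl <- extract_clusters(g, c("CAAAF", "CAABF", "CAABW"))
  expect_length(cl, 1L) # chain A-B-C is one component
  expect_setequal(cl[[1]]$members, c("CAAAF", "CAABF", "CAABW"))
  # singleton components are discarded
  cl2 <- extract_clusters(g, c("CAAAF", "CAABF", "CXXXF"))
  expect_length(cl2, 1L)
  expect_setequal(cl2[[1]]$members, c("CAAAF", "CAABF"))
  expect_error(extract_clusters(g, "CZZZF"), "nodes of the graph")
})

test_that("clusters of different lengths are never merged and ids are deterministic", {
  seqs <- c("CAAAF", "CAABF", "CAAAAAF", "CAABAAF", "CAACAAF")
  g <- build_cdr3_graph(seqs)
  cl <- extract_clusters(g, seqs)
  expect_length(cl, 2L)
  lens <- lapply(cl, function(x) unique(nchar(x$members)))
  expect_true(all(lengths(lens) == 1L)) # length-homogeneous
  # id 1 goes to the larger cluster
  expect_equal(length(cl[[1]]$members), 3L)
  expect_equal(cl[[1]]$cluster_id, 1L)
  cl_again <- extract_clusters(g, rev(seqs))
  expect_identical(lapply(cl, `[[`, "members"),
                   lapply(cl_again, `[[`, "members"))
})

test_that("the cluster frequency matrix aggregates member frequencies per sample", {
  motif <- motif_spec("CAVSNTGNYKYVF",
                      alternatives = list(`4` = c("G", "T"), `8` = c("A", "D")),
                      target = "challenge", target_label = "LLC",
                      total_frequency = 0.10)
  d <- cohort_design(
    challenges = c("control", "LLC"), mice_per_challenge = 4L,
    tissues = "lung", subsets = "eTreg",
    depth_meanlog = c(eTreg = log(400), eCD4 = log(400)), min_depth = 200L,
    motifs = list(motif), seed = 71
  )
  coh <- generate_cohort(d)
  g <- build_cdr3_graph(unique(unlist(lapply(coh$repertoires,
                                             function(r) r$clonotypes$cdr3aa))))
  cl <- extract_clusters(g, motif$members[motif$members %in% g$nodes])
  expect_length(cl, 1L)
  m <- cluster_frequency_matrix(cl, coh, reorder = FALSE)
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(colSums(m) <= 1 + 1e-9))
  meta <- cohort_summary(coh)
  in_llc <- m[1, meta$sample_id[meta$challenge == "LLC"]]
  in_ctrl <- m[1, meta$sample_id[meta$challenge == "control"]]
  expect_equal(unname(in_ctrl), rep(0, 4)) # absent samples score 0
  tt <- stats::t.test(in_llc, mu = 0)
  expect_lt(tt$p.value, 0.01)
})

test_that("cluster PWMs are column-normalised frequency profiles", {
  cl1 <- structure(list(cluster_id = 1L, members = c("CAAAF", "CAAAF")),
                   class = "cdr3_cluster")
  pw1 <- cluster_pwm(cl1)
  expect_true(all(pw1$pwm %in% c(0, 1))) # one-hot
  expect_equal(unname(colSums(pw1$pwm)), rep(1, 5))
  expect_equal(pw1$consensus, "CAAAF")

  cl2 <- structure(list(cluster_id = 2L, members = c("CAASF", "CAADF")),
                   class = "cdr3_cluster")
  pw2 <- cluster_pwm(cl2)
  expect_equal(pw2$pwm["S", 4], 0.5)
  expect_equal(pw2$pwm["D", 4], 0.5)
  expect_equal(unname(colSums(pw2$pwm)), rep(1, 5), tolerance = 1e-9)
})

test_that("find_motif_clusters recovers a planted motif end to end", {
  motif <- motif_spec("CAVSNTGNYKYVF",
                      alternatives = list(`4` = c("G", "T", "N", "L"),
                                          `8` = c("A", "D", "R", "K")),
                      target = "challenge", target_label = "LLC",
                      total_frequency = 0.08)
  d <- cohort_design(
    challenges = c("control", "LLC"), mice_per_challenge = 4L,
    tissues = "lung", subsets = "eTreg",
    depth_meanlog = c(eTreg = log(500), eCD4 = log(500)), min_depth = 250L,
    motifs = list(motif), seed = 81
  )
  coh <- generate_cohort(d)
  mc <- find_motif_clusters(coh, seed = 82)
  jac <- vapply(mc$clusters, function(cl) {
    length(intersect(cl$members, motif$members)) /
      length(union(cl$members, motif$members))
  }, numeric(1))
  expect_gte(max(jac), 0.7)
})
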