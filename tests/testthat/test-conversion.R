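# eCD4/eTreg matched-pair conversion analysis and iNKT tracking.

paired_cohort <- function(conv_fraction, seed, tissues = c("lung", "spleen"),
                          challenges = c("control", "LLC", "influenza")) {
  conv <- if (conv_fraction > 0) {
    list(conversion_spec("LLC", "lung", conv_fraction))
  } else {
    list()
  }
  generate_cohort(cohort_design(
    challenges = challenges, mice_per_challenge = 4L,
    tissues = tissues, subsets = SUBSETS,
    depth_meanlog = c(eTreg = log(450), eCD4 = log(550)), min_depth = 250L,
    conversions = conv, seed = seed
  ))
}

test_that("conversion F2 validates pairing and eligibility", {
  a <- make_rep(rep(2L, 120), sample_id = "a", mouse_id = "m1",
                subset = "eCD4")
  b_other <- make_rep(rep(2L, 120), sample_id = "b", mouse_id = "m2",
                      subset = "eTreg")
  expect_error(conversion_f2(a, b_other), "same mouse")
  small <- make_rep(rep(2L, 80), sample_id = "c", mouse_id = "m1",
                    subset = "eTreg")
  expect_warning(val <- conversion_f2(a, small), "ineligible")
  expect_true(is.na(val))
  expect_false(attr(val, "eligible"))
})

test_that("planted shared clonotypes give a large matched-pair F2", {
  coh <- paired_cohort(0.3, seed = 91)
  vals <- vapply(paste0("LLC_m", 1:4), function(m) {
    as.numeric(conversion_f2(coh$repertoires[[paste0(m, "_lung_eCD4")]],
                             coh$repertoires[[paste0(m, "_lung_eTreg")]],
                             min_clonotypes = 50, seed = 1))
  }, numeric(1))
  expect_true(all(vals >= 0.2))
  # symmetric in its arguments
  v1 <- conversion_f2(coh$repertoires[["LLC_m1_lung_eCD4"]],
                      coh$repertoires[["LLC_m1_lung_eTreg"]],
                      min_clonotypes = 50, seed = 2)
  v2 <- conversion_f2(coh$repertoires[["LLC_m1_lung_eTreg"]],
                      coh$repertoires[["LLC_m1_lung_eCD4"]],
                      min_clonotypes = 50, seed = 2)
  expect_equal(as.numeric(v1), as.numeric(v2), tolerance = 1e-12)
})

test_that("without planted conversion matched pairs look like re-paired mice", {
  coh <- paired_cohort(0, seed = 92, tissues = "lung",
                       challenges = c("control", "LLC"))
  ids <- paste0(rep(c("control_m", "LLC_m"), each = 4), rep(1:4, 2))
  top <- function(id, sub) {
    top_n_clonotypes(coh$repertoires[[paste0(id, "_lung_", sub)]], 100,
                     seed = 3)
  }
  matched <- vapply(ids, function(m) {
    f2_overlap(top(m, "eCD4"), top(m, "eTreg"), "nt")
  }, numeric(1))
  crosses <- c()
  for (i in seq_along(ids)) {
    for (k in seq_along(ids)) {
      if (i != k) {
        crosses <- c(crosses,
                     f2_overlap(top(ids[i], "eCD4"), top(ids[k], "eTreg"),
                                "nt"))
      }
    }
  }
  null95 <- stats::quantile(crosses, 0.95)
  expect_lte(mean(matched > null95 + 1e-12), 0.25)
})

test_that("conversion_table reports pairs and site-specific significance", {
  coh <- paired_cohort(0.3, seed = 93)
  res <- conversion_table(coh, top_n = 100, min_clonotypes = 50)
  expect_equal(nrow(res$records), 3 * 4 * 2) # (mouse, tissue) pairs
  elig <- res$records$f2_nt[res$records$eligible]
  expect_true(all(elig >= 0 & elig <= 1))
  expect_true(all(is.na(res$records$f2_nt[!res$records$eligible])))
  lung <- res$tests[res$tests$tissue == "lung", ]
  expect_lt(lung$p_value[lung$group == "LLC"], 0.05)
  spleen <- res$tests[res$tests$tissue == "spleen", ]
  if ("LLC" %in% spleen$group) {
    expect_gt(spleen$p_value[spleen$group == "LLC"], 0.05)
  }
  # a mouse missing one subset is skipped with a warning
  partial <- cohort(coh$repertoires[names(coh$repertoires) !=
                                      "LLC_m1_lung_eTreg"])
  expect_warning(conversion_table(partial, top_n = 100,
                                  min_clonotypes = 50),
                 "missing subset")
})

test_that("inkt_fraction counts exactly the canonical receptor", {
  def <- inkt_definition()
  none <- make_rep(c(5L, 5L))
  expect_equal(inkt_fraction(none), 0)
  full <- make_rep(10L, cdr3aa = def$cdr3aa, v = def$v, j = def$j,
                   cdr3nt = nt_of(def$cdr3aa))
  expect_equal(inkt_fraction(full), 1)
  wrong_v <- make_rep(10L, cdr3aa = def$cdr3aa, v = "TRAV12", j = def$j,
                      cdr3nt = nt_of(def$cdr3aa))
  expect_equal(inkt_fraction(wrong_v), 0)
})

test_that("inkt_fraction is invariant to nt-variant splitting and aa aggregation", {
  def <- inkt_definition()
  nt1 <- nt_of(def$cdr3aa)
  nt2 <- sub("TGT", "TGC", nt1) # synonymous Cys codon
  split_rep <- make_rep(c(6L, 4L, 10L),
                        cdr3aa = c(def$cdr3aa, def$cdr3aa, "CAAAAF"),
                        v = c(def$v, paste0(def$v, "*01"), "TRAV2"),
                        j = c(def$j, def$j, "TRAJ2"),
                        cdr3nt = c(nt1, nt2, nt_of("CAAAAF")))
  expect_equal(inkt_fraction(split_rep), 0.5)
  expect_equal(inkt_fraction(aggregate_aa(split_rep)), 0.5)
})

test_that("cluster shares split by subset localise a planted shared motif", {
  motif <- motif_spec("CAVRDSNYQLIW",
                      alternatives = list(`5` = c("G", "T")),
                      target = "challenge", target_label = "LLC",
                      subset_scope = "both", total_frequency = 0.08,
                      tissues = "lung")
  coh <- generate_cohort(cohort_design(
    challenges = c("control", "LLC"), mice_per_challenge = 3L,
    tissues = c("lung", "spleen"), subsets = SUBSETS,
    depth_meanlog = c(eTreg = log(400), eCD4 = log(400)), min_depth = 250L,
    motifs = list(motif), seed = 95
  ))
  cl <- structure(list(cluster_id = 1L, members = motif$members),
                  class = "cdr3_cluster")
  share <- cluster_share_in_subsets(cl, coh)
  expect_true(all(share$frequency >= 0 & share$frequency <= 1))
  at_site <- share[share$challenge == "LLC" & share$tissue == "lung", ]
  expect_true(all(at_site$frequency > 0.02)) # both subsets carry it at site
  systemic <- share[share$tissue == "spleen", ]
  expect_true(all(systemic$frequency < 0.01))
})
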