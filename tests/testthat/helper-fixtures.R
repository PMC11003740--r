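# Shared fixtures: deterministic repertoires built in code.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Deterministic distinct amino-acid CDR3s: base-20 encoding of an index,
# framed by the conserved C...F.
make_aa <- function(i, len = 6) {
  vapply(i, function(x) {
    res <- character(len)
    for (p in seq_len(len)) {
      res[p] <- AA20[(x %% 20L) + 1L]
      x <- x %/% 20L
    }
    paste0("C", paste(res, collapse = ""), "F")
  }, character(1))
}

# First-choice-codon back-translation (deterministic).
nt_of <- function(aa) {
  vapply(strsplit(aa, ""), function(rs) {
    paste(vapply(rs, function(r) tcrep:::CODON_TABLE[[r]][1], character(1)),
          collapse = "")
  }, character(1))
}

make_rep <- function(counts, cdr3aa = NULL, v = NULL, j = NULL,
                     cdr3nt = NULL, sample_id = "s1", mouse_id = "m1",
                     tissue = "lung", subset = "eTreg",
                     challenge = "control") {
  n <- length(counts)
  if (is.null(cdr3aa)) cdr3aa <- make_aa(seq_len(n) - 1L)
  if (is.null(v)) v <- rep("TRAV1", n)
  if (is.null(j)) j <- rep("TRAJ1", n)
  if (is.null(cdr3nt)) cdr3nt <- nt_of(cdr3aa)
  repertoire(
    tibble::tibble(count = counts, cdr3nt = cdr3nt, cdr3aa = cdr3aa,
                   v = v, d = "", j = j),
    sample_meta(sample_id, mouse_id, tissue, subset, challenge)
  )
}

# Random repertoire with n distinct clonotypes and skewed counts.
random_rep <- function(n, seed, ...) {
  withr::with_seed(seed, {
    counts <- sample(1:50, n, replace = TRUE)
    aa <- make_aa(sample.int(1e6, n) - 1L, len = sample(5:8, 1))
    make_rep(counts, cdr3aa = aa,
             v = sample(paste0("TRAV", 1:6), n, replace = TRUE),
             j = sample(paste0("TRAJ", 1:6), n, replace = TRUE), ...)
  })
}

# A single-V / single-J zero-indel model whose only product is
# TGTGCT + GGCACT = "CAGT".
deterministic_model <- function() {
  recombination_model(
    v_segments = c(TRAV1 = "TGTGCT"),
    j_segments = c(TRAJ1 = "GGCACT"),
    deletion_probs = 1,
    insertion_length_probs = 1
  )
}

# Brute-force F2 oracle: explicit aggregation over unique keys, then the
# stated sum of geometric mean frequencies.
f2_oracle <- function(rep_a, rep_b, match_level) {
  keys <- function(r) {
    tbl <- r$clonotypes
    if (match_level == "aa") {
      paste(sub("\\*.*$", "", tbl$v), tbl$cdr3aa, sep = "|")
    } else {
      paste(sub("\\*.*$", "", tbl$v), sub("\\*.*$", "", tbl$j), tbl$cdr3nt,
            sep = "|")
    }
  }
  ka <- keys(rep_a); kb <- keys(rep_b)
  total <- 0
  for (k in unique(ka)) {
    pa <- sum(rep_a$clonotypes$freq[ka == k])
    pb <- sum(rep_b$clonotypes$freq[kb == k])
    if (pb > 0) total <- total + sqrt(pa * pb)
  }
  total
}

# O(n^2) Hamming-1 oracle over a set of sequences.
hamming1_oracle_edges <- function(seqs) {
  n <- length(seqs)
  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (nchar(seqs[i]) != nchar(seqs[j])) next
      a <- strsplit(seqs[i], "")[[1]]
      b <- strsplit(seqs[j], "")[[1]]
      if (sum(a != b) == 1L) edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  if (length(edges) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, edges)
}

# Canonical edge-set representation for comparing graphs.
edge_key_set <- function(nodes, edges) {
  if (nrow(edges) == 0) return(character(0))
  a <- nodes[edges[, 1]]; b <- nodes[edges[, 2]]
  sort(paste(pmin(a, b), pmax(a, b)))
}
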