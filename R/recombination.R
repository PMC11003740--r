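# V(D)J recombination null model: random TCR-alpha rearrangements used as
# the baseline for CDR3 neighbor enrichment and as background clonotypes in
# synthetic cohorts.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Synonymous codon table (standard genetic code, coding strand).
CODON_TABLE <- list(
  A = c("GCT", "GCC", "GCA", "GCG"),
  C = c("TGT", "TGC"),
  D = c("GAT", "GAC"),
  E = c("GAA", "GAG"),
  F = c("TTT", "TTC"),
  G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"),
  K = c("AAA", "AAG"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  M = "ATG",
  N = c("AAT", "AAC"),
  P = c("CCT", "CCC", "CCA", "CCG"),
  Q = c("CAA", "CAG"),
  R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"),
  V = c("GTT", "GTC", "GTA", "GTG"),
  W = "TGG",
  Y = c("TAT", "TAC")
)

# Back-translate an amino-acid string, drawing synonymous codons with the
# current RNG. Vectorised over sequences.
back_translate <- function(aa) {
  vapply(aa, function(s) {
    res <- strsplit(s, "")[[1]]
    paste(vapply(res, function(r) {
      cods <- CODON_TABLE[[r]]
      if (is.null(cods)) stop("cannot back-translate residue '", r, "'",
                              call. = FALSE)
      cods[sample.int(length(cods), 1L)]
    }, character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Translate in-frame nucleotide CDR3s to amino acids ('*' marks stops).
translate_nt <- function(nt) {
  if (length(nt) == 0) return(character(0))
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nt),
    no.init.codon = TRUE, if.fuzzy.codon = "X"
  ))
}

#' Construct a V(D)J recombination model
#'
#' The model generates nucleotide CDR3s as: germline 3' tail of a V segment
#' (starting at the conserved Cys codon), trimmed at its 3' end; a random
#' N-region insertion; and the germline 5' head of a J segment (ending at
#' the conserved Phe codon), trimmed at its 5' end. TCR-alpha has no D
#' segment. Trimming never removes the conserved terminal codons.
#'
#' @param v_segments Named character vector: V gene name -> germline 3' tail
#'   (nucleotides, starting `TGT`).
#' @param j_segments Named character vector: J gene name -> germline 5' head.
#' @param v_usage,j_usage Segment usage probabilities (default uniform).
#' @param deletion_probs Probability vector over 0..k nucleotides trimmed
#'   from each junction side.
#' @param insertion_length_probs Probability vector over N-region lengths
#'   0..(length-1).
#' @param insertion_base_freq Probability vector over A/C/G/T for inserted
#'   bases.
#' @return A `recombination_model` object.
#' @export
recombination_model <- function(v_segments, j_segments,
                                v_usage = NULL, j_usage = NULL,
                                deletion_probs = c(0.30, 0.25, 0.18, 0.12,
                                                   0.08, 0.05, 0.02),
                                insertion_length_probs = rep(1 / 12, 12),
                                insertion_base_freq = c(A = 0.22, C = 0.28,
                                                        G = 0.28, T = 0.22)) {
  stopifnot(length(v_segments) >= 1, length(j_segments) >= 1,
            !is.null(names(v_segments)), !is.null(names(j_segments)))
  if (is.null(v_usage)) v_usage <- rep(1 / length(v_segments), length(v_segments))
  if (is.null(j_usage)) j_usage <- rep(1 / length(j_segments), length(j_segments))
  for (p in list(v_usage, j_usage, deletion_probs, insertion_length_probs,
                 insertion_base_freq)) {
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      stop("probability vectors must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  stopifnot(length(v_usage) == length(v_segments),
            length(j_usage) == length(j_segments),
            all(nchar(v_segments) >= 3), all(nchar(j_segments) >= 3))
  structure(
    list(v_segments = v_segments, j_segments = j_segments,
         v_usage = v_usage, j_usage = j_usage,
         deletion_probs = deletion_probs,
         insertion_length_probs = insertion_length_probs,
         insertion_base_freq = insertion_base_freq),
    class = "recombination_model"
  )
}

#' Default mouse-style recombination model
#'
#' A packaged synthetic stand-in for the mouse TRA locus: 24 TRAV and 22
#' TRAJ segments with deterministic germline tails/heads built from a fixed
#' codon pool. Segment names follow the TRAV1..24 / TRAJ1..22 convention,
#' so the literal TRAV11 and TRAJ18 genes used by the invariant NKT
#' clonotype exist. V tails start with the conserved Cys codon `TGT`; J
#' heads end with the conserved Phe codon `TTT`. The default insertion
#' length distribution is uniform on 0..11 nucleotides, so all residues
#' modulo 3 are equally likely and one third of raw rearrangements are in
#' frame in expectation.
#'
#' @return A [recombination_model()].
#' @export
default_recombination_model <- function() {
  pool <- c("GCT", "GGA", "AGT", "GAA", "ACC", "CTG",
            "GTG", "GAT", "AGA", "AAC", "TCC", "CAG")
  v_tail <- vapply(1:24, function(i) {
    k <- 1L + (i %% 4L) # 1..4 codons after the Cys codon
    idx <- ((i + seq_len(k) * 3L) %% 12L) + 1L
    paste0("TGT", paste(pool[idx], collapse = ""))
  }, character(1))
  names(v_tail) <- paste0("TRAV", 1:24)
  j_head <- vapply(1:22, function(i) {
    k <- 2L + (i %% 3L) # 2..4 codons before the Phe codon
    idx <- ((2L * i + seq_len(k) * 5L) %% 12L) + 1L
    paste0(paste(pool[idx], collapse = ""), "TTT")
  }, character(1))
  names(j_head) <- paste0("TRAJ", 1:22)
  recombination_model(v_tail, j_head)
}

#' Draw raw rearrangement candidates (pre-selection)
#'
#' Generates `n` rearrangements without the in-frame / stop-free rejection
#' step, for diagnostics and calibration. The returned tibble flags which
#' candidates are in frame and which are productive (in frame and stop-free).
#'
#' @param model A [recombination_model()].
#' @param n Number of candidates.
#' @return Tibble with columns `v`, `j`, `cdr3nt`, `inframe`, `productive`,
#'   `cdr3aa` (`NA` for non-productive candidates).
#' @export
rearrangement_candidates <- function(model, n) {
  stopifnot(inherits(model, "recombination_model"), n >= 1)
  vs <- model$v_segments
  js <- model$j_segments
  vi <- sample.int(length(vs), n, replace = TRUE, prob = model$v_usage)
  ji <- sample.int(length(js), n, replace = TRUE, prob = model$j_usage)
  ndel <- length(model$deletion_probs)
  dv <- sample.int(ndel, n, replace = TRUE, prob = model$deletion_probs) - 1L
  dj <- sample.int(ndel, n, replace = TRUE, prob = model$deletion_probs) - 1L
  nins <- length(model$insertion_length_probs)
  il <- sample.int(nins, n, replace = TRUE,
                   prob = model$insertion_length_probs) - 1L
  vtail <- unname(vs[vi])
  jhead <- unname(js[ji])
  dv <- pmin(dv, nchar(vtail) - 3L) # keep the conserved Cys codon
  dj <- pmin(dj, nchar(jhead) - 3L) # keep the conserved Phe codon
  vpart <- substr(vtail, 1L, nchar(vtail) - dv)
  jpart <- substring(jhead, dj + 1L)
  ins <- character(n)
  total_ins <- sum(il)
  if (total_ins > 0) {
    bases <- sample(c("A", "C", "G", "T"), total_ins, replace = TRUE,
                    prob = model$insertion_base_freq)
    grp <- rep.int(seq_len(n), il)
    pieces <- vapply(split(bases, grp), paste, character(1), collapse = "")
    ins[as.integer(names(pieces))] <- pieces
  }
  nt <- paste0(vpart, ins, jpart)
  inframe <- nchar(nt) %% 3L == 0L
  aa <- rep(NA_character_, n)
  if (any(inframe)) aa[inframe] <- translate_nt(nt[inframe])
  productive <- inframe & !is.na(aa) & !grepl("*", aa, fixed = TRUE)
  aa[!productive] <- NA_character_
  tibble::tibble(v = names(vs)[vi], j = names(js)[ji], cdr3nt = nt,
                 inframe = inframe, productive = productive, cdr3aa = aa)
}

#' Sample one productive rearrangement
#'
#' Rejection-samples raw rearrangements until one is in frame and stop-free.
#'
#' @param model A [recombination_model()].
#' @param seed Optional integer seed (uses the current RNG state when `NULL`).
#' @return One-row tibble with columns `cdr3nt`, `cdr3aa`, `v`, `d`, `j`.
#' @export
sample_rearrangement <- function(model, seed = NULL) {
  run <- function() generate_baseline(model, 1L)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a baseline of random rearrangements
#'
#' Draws `n` independent productive rearrangements (duplicates allowed),
#' emulating a pool of random TCR-alpha V(D)J recombination products. This
#' is the null model against which CDR3 neighbor counts are calibrated in
#' [neighbor_enrichment()].
#'
#' @param model A [recombination_model()].
#' @param n Number of rearrangements (>= 1).
#' @param seed Optional integer seed.
#' @return Tibble with columns `cdr3nt`, `cdr3aa`, `v`, `d`, `j`.
#' @export
generate_baseline <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "recombination_model"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  run <- function() {
    out <- vector("list", 0L)
    have <- 0L
    rejected <- 0L
    batch <- max(16L, ceiling(n * 3.6))
    while (have < n) {
      cand <- rearrangement_candidates(model, batch)
      keep <- cand[cand$productive, , drop = FALSE]
      if (nrow(keep) > 0) {
        out[[length(out) + 1L]] <- keep
        have <- have + nrow(keep)
        rejected <- 0L
      } else {
        rejected <- rejected + batch
        if (rejected >= 1e6) {
          stop("degenerate recombination model: 1e6 consecutive rejections",
               call. = FALSE)
        }
        batch <- min(batch * 4L, 500000L) # fail fast on degenerate models
        next
      }
      batch <- max(16L, ceiling((n - have) * 3.6))
    }
    res <- dplyr::bind_rows(out)[seq_len(n), ]
    tibble::tibble(cdr3nt = res$cdr3nt, cdr3aa = res$cdr3aa,
                   v = res$v, d = "", j = res$j)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
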