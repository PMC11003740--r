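# Synthetic cohort generator: full study-design cohorts with planted
# convergent challenge motifs, tissue-resident motifs, subset-shared
# (conversion) clonotypes and an invariant NKT spike, on top of background
# clonotypes drawn from the recombination null with power-law clone sizes.

#' The invariant NKT TCR-alpha clonotype
#'
#' The canonical semi-invariant NKT receptor used throughout:
#' TRAV11 - CVVGDRGSALGRLHF - TRAJ18.
#'
#' @return List with fields `v`, `cdr3aa`, `j`.
#' @export
inkt_definition <- function() {
  list(v = "TRAV11", cdr3aa = "CVVGDRGSALGRLHF", j = "TRAJ18")
}

# One fixed nucleotide realisation of the iNKT clonotype (back-translation
# with first-choice codons); additional nt variants are generated on demand.
inkt_canonical_nt <- function() {
  paste(vapply(strsplit(inkt_definition()$cdr3aa, "")[[1]],
               function(r) CODON_TABLE[[r]][1], character(1)), collapse = "")
}

#' Specify a planted CDR3 motif
#'
#' A motif is a consensus amino-acid CDR3 plus per-position alternative
#' residues. Its realised member set is the consensus and every
#' single-substitution variant listed in `alternatives`, so all members lie
#' within Hamming distance one of the consensus and members sharing a
#' variable position form a clique in the Hamming-1 graph. Each mouse
#' realises the members with independent synonymous-codon back-translations,
#' modelling convergent recombination (shared amino-acid motif, distinct
#' nucleotide rearrangements).
#'
#' @param consensus_aa Consensus CDR3 (start `C`, end `F` by convention).
#' @param alternatives Named list: position (as character or integer) ->
#'   alternative residues at that position.
#' @param target `"challenge"` (motif follows an antigenic challenge) or
#'   `"tissue"` (motif marks tissue residence irrespective of challenge).
#' @param target_label The challenge or tissue label the motif follows.
#' @param subset_scope `"both"`, `"eTreg"` or `"eCD4"`.
#' @param total_frequency Fraction of a matching sample occupied by the
#'   motif's clonotypes (<= 0.5).
#' @param tissues For challenge motifs: tissues in which the motif appears
#'   (default all tissues of the design).
#' @param v,j Segment names carried by the motif's clonotypes.
#' @return A `motif_spec` object.
#' @export
motif_spec <- function(consensus_aa, alternatives = list(),
                       target = c("challenge", "tissue"), target_label,
                       subset_scope = c("both", "eTreg", "eCD4"),
                       total_frequency = 0.03, tissues = NULL,
                       v = "TRAV5", j = "TRAJ7") {
  target <- match.arg(target)
  subset_scope <- match.arg(subset_scope)
  stopifnot(is.character(consensus_aa), nchar(consensus_aa) >= 5,
            total_frequency > 0, total_frequency <= 0.5)
  res <- strsplit(consensus_aa, "")[[1]]
  pos <- as.integer(names(alternatives))
  if (length(alternatives) > 0 &&
      (anyNA(pos) || any(pos < 1) || any(pos > length(res)))) {
    stop("variable positions must lie within the consensus", call. = FALSE)
  }
  members <- consensus_aa
  for (k in seq_along(alternatives)) {
    p <- pos[k]
    for (r in setdiff(alternatives[[k]], res[p])) {
      variant <- res
      variant[p] <- r
      members <- c(members, paste(variant, collapse = ""))
    }
  }
  structure(
    list(consensus_aa = consensus_aa, alternatives = alternatives,
         members = unique(members), target = target,
         target_label = target_label, subset_scope = subset_scope,
         total_frequency = total_frequency, tissues = tissues, v = v, j = j),
    class = "motif_spec"
  )
}

#' Specify planted eCD4/eTreg-shared clonotypes (conversion)
#'
#' At the designated (challenge, tissue), both subsets of each mouse receive
#' identical (V, J, nucleotide CDR3) clonotypes totalling `fraction` of each
#' sample — the repertoire signature of clonal conversion between subsets.
#'
#' @param challenge,tissue Where sharing is planted.
#' @param fraction Total sample fraction occupied by shared clonotypes.
#' @param n_clonotypes Number of distinct shared clonotypes per mouse.
#' @return A `conversion_spec` object.
#' @export
conversion_spec <- function(challenge, tissue, fraction, n_clonotypes = 20L) {
  stopifnot(fraction >= 0, fraction <= 1, n_clonotypes >= 1)
  structure(list(challenge = challenge, tissue = tissue,
                 fraction = fraction, n_clonotypes = as.integer(n_clonotypes)),
            class = "conversion_spec")
}

#' Specify an invariant NKT spike
#'
#' @param challenge,tissue,subset Sample stratum receiving the spike.
#' @param frequency Expected fraction of the sample occupied by the iNKT
#'   clonotype (realised with binomial sampling noise).
#' @return An `inkt_spec` object.
#' @export
inkt_spec <- function(challenge, tissue, subset, frequency) {
  stopifnot(frequency >= 0, frequency <= 0.5)
  structure(list(challenge = challenge, tissue = tissue, subset = subset,
                 frequency = frequency), class = "inkt_spec")
}

#' Define a synthetic cohort design
#'
#' Encodes the study layout: challenge groups of 3-7 mice, a tissue panel,
#' the two effector subsets, per-sample sequencing depths (log-normal,
#' defaults matching eTreg ~1.4e3 and eCD4 ~3.7e3 UMIs per sample), a
#' power-law clone-size distribution for background clonotypes, and the
#' planted structure (motifs, conversion, iNKT).
#'
#' @param challenges Challenge labels (subset of [CHALLENGES]).
#' @param mice_per_challenge Integer in 3..7, recycled over challenges.
#' @param tissues Subset of [TISSUES].
#' @param subsets Subset of [SUBSETS].
#' @param depth_meanlog Named numeric (`eTreg`, `eCD4`): log-normal meanlog
#'   of per-sample UMI totals.
#' @param depth_sdlog Log-normal sdlog of per-sample depth.
#' @param min_depth Lower clip on per-sample depth.
#' @param clone_exponent Power-law exponent of background clone sizes.
#' @param motifs List of [motif_spec()].
#' @param conversions List of [conversion_spec()].
#' @param inkt `NULL`, an [inkt_spec()], or a list of them.
#' @param model A [recombination_model()]; default
#'   [default_recombination_model()].
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the design including this seed.
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(challenges = CHALLENGES,
                          mice_per_challenge = 4L,
                          tissues = c("lung", "MLN", "spleen"),
                          subsets = SUBSETS,
                          depth_meanlog = c(eTreg = log(1360), eCD4 = log(3740)),
                          depth_sdlog = 0.35,
                          min_depth = 200L,
                          clone_exponent = 2,
                          motifs = list(),
                          conversions = list(),
                          inkt = NULL,
                          model = default_recombination_model(),
                          seed = 1L) {
  challenges <- match.arg(challenges, CHALLENGES, several.ok = TRUE)
  tissues <- match.arg(tissues, TISSUES, several.ok = TRUE)
  subsets <- match.arg(subsets, SUBSETS, several.ok = TRUE)
  mice_per_challenge <- rep_len(as.integer(mice_per_challenge),
                                length(challenges))
  if (any(mice_per_challenge < 3L | mice_per_challenge > 7L)) {
    stop("mice_per_challenge must lie in 3..7", call. = FALSE)
  }
  if (inherits(inkt, "inkt_spec")) inkt <- list(inkt)
  stopifnot(all(vapply(motifs, inherits, logical(1), "motif_spec")),
            all(vapply(conversions, inherits, logical(1), "conversion_spec")),
            is.null(inkt) || all(vapply(inkt, inherits, logical(1), "inkt_spec")),
            inherits(model, "recombination_model"))
  structure(
    list(challenges = challenges, mice_per_challenge = mice_per_challenge,
         tissues = tissues, subsets = subsets,
         depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
         min_depth = as.integer(min_depth), clone_exponent = clone_exponent,
         motifs = motifs, conversions = conversions,
         inkt = if (is.null(inkt)) list() else inkt,
         model = model, seed = as.integer(seed)),
    class = "cohort_design"
  )
}

# Split `total` into `m` integer parts proportional to weights w (largest
# remainder); zero parts dropped by the caller.
apportion_counts <- function(total, w) {
  if (total <= 0) return(integer(length(w)))
  raw <- total * w / sum(w)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Background clone sizes: discrete power law P(k) ~ k^-expo on 1..kmax,
# drawn until the running total reaches `total` (last clone trimmed).
power_law_sizes <- function(total, expo, kmax) {
  if (total <= 0) return(integer(0))
  kmax <- max(2L, min(as.integer(kmax), 10000L))
  probs <- (1:kmax)^(-expo)
  probs <- probs / sum(probs)
  mean_size <- sum((1:kmax) * probs)
  sizes <- integer(0)
  while (sum(sizes) < total) {
    need <- total - sum(sizes)
    batch <- sample.int(kmax, max(16L, ceiling(need / mean_size * 1.3)),
                        replace = TRUE, prob = probs)
    sizes <- c(sizes, batch)
  }
  cum <- cumsum(sizes)
  n_keep <- which(cum >= total)[1]
  sizes <- sizes[seq_len(n_keep)]
  sizes[n_keep] <- sizes[n_keep] - (cum[n_keep] - total)
  sizes[sizes > 0]
}

motif_matches_sample <- function(m, challenge, tissue, subset, design) {
  scope_ok <- m$subset_scope == "both" || m$subset_scope == subset
  if (!scope_ok) return(FALSE)
  if (m$target == "challenge") {
    m$target_label == challenge &&
      (is.null(m$tissues) || tissue %in% m$tissues)
  } else {
    m$target_label == tissue
  }
}

#' Generate a synthetic cohort
#'
#' Builds one repertoire per (mouse, tissue, subset) cell of the design.
#' Background clonotypes are random rearrangements from the design's
#' recombination model with power-law UMI counts. Planted structure:
#' challenge motifs are injected into matching samples using per-mouse
#' nucleotide back-translations of the same amino-acid members (convergent
#' recombination); tissue-resident motifs are injected into the designated
#' tissue across all challenges; conversion specs inject identical
#' (V, J, nucleotide CDR3) clonotypes into both subsets of the same mouse at
#' the designated (challenge, tissue) only; iNKT specs inject the literal
#' TRAV11-CVVGDRGSALGRLHF-TRAJ18 clonotype with binomial sampling noise.
#' Identical design (including seed) yields a byte-identical cohort.
#'
#' @param design A [cohort_design()].
#' @return A [cohort()].
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  withr::with_seed(design$seed, generate_cohort_(design))
}

generate_cohort_ <- function(design) {
  mice <- list()
  for (i in seq_along(design$challenges)) {
    ch <- design$challenges[i]
    mice[[ch]] <- paste0(ch, "_m", seq_len(design$mice_per_challenge[i]))
  }
  all_mice <- unlist(mice, use.names = FALSE)

  # Nucleotide realisations of each motif per (mouse, subset): stable across
  # that animal's tissues, distinct across mice and subsets with high
  # probability. Only conversion specs plant identical rearrangements in
  # both subsets — a clonal expansion is one cell lineage, so amino-acid
  # convergence between animals or subsets must not look like nucleotide
  # identity.
  motif_nt <- list()
  for (mid in all_mice) {
    for (sub in design$subsets) {
      motif_nt[[paste(mid, sub)]] <- lapply(design$motifs, function(m) {
        back_translate(m$members)
      })
    }
  }
  # Per-mouse conversion clonotypes (identical in both subsets of a mouse).
  conv_clones <- list()
  for (mid in all_mice) {
    conv_clones[[mid]] <- lapply(design$conversions, function(cv) {
      generate_baseline(design$model, cv$n_clonotypes)
    })
  }

  reps <- list()
  for (ch in design$challenges) {
    for (mid in mice[[ch]]) {
      for (tis in design$tissues) {
        for (sub in design$subsets) {
          meanlog <- design$depth_meanlog[[sub]]
          depth <- max(design$min_depth,
                       round(stats::rlnorm(1, meanlog, design$depth_sdlog)))

          parts <- list()
          planted_freq <- 0

          for (k in seq_along(design$motifs)) {
            m <- design$motifs[[k]]
            if (!motif_matches_sample(m, ch, tis, sub, design)) next
            planted_freq <- planted_freq + m$total_frequency
            total <- round(m$total_frequency * depth)
            w <- 1 / seq_along(m$members) # consensus dominates
            cnt <- apportion_counts(total, w)
            keep <- cnt > 0
            if (any(keep)) {
              parts[[length(parts) + 1L]] <- tibble::tibble(
                count = cnt[keep],
                cdr3nt = motif_nt[[paste(mid, sub)]][[k]][keep],
                cdr3aa = m$members[keep], v = m$v, d = "", j = m$j
              )
            }
          }

          for (k in seq_along(design$conversions)) {
            cv <- design$conversions[[k]]
            if (cv$challenge != ch || cv$tissue != tis) next
            planted_freq <- planted_freq + cv$fraction
            total <- round(cv$fraction * depth)
            cl <- conv_clones[[mid]][[k]]
            cnt <- apportion_counts(total, 1 / seq_len(nrow(cl)))
            keep <- cnt > 0
            if (any(keep)) {
              parts[[length(parts) + 1L]] <- tibble::tibble(
                count = cnt[keep], cdr3nt = cl$cdr3nt[keep],
                cdr3aa = cl$cdr3aa[keep], v = cl$v[keep], d = "",
                j = cl$j[keep]
              )
            }
          }

          for (sp in design$inkt) {
            if (sp$challenge != ch || sp$tissue != tis || sp$subset != sub) next
            planted_freq <- planted_freq + sp$frequency
            cnt <- stats::rbinom(1, depth, sp$frequency)
            if (cnt > 0) {
              def <- inkt_definition()
              parts[[length(parts) + 1L]] <- tibble::tibble(
                count = cnt, cdr3nt = inkt_canonical_nt(),
                cdr3aa = def$cdr3aa, v = def$v, d = "", j = def$j
              )
            }
          }

          if (planted_freq > 0.9) {
            stop("planted motif frequencies exceed 0.9 of sample ",
                 paste(mid, tis, sub), call. = FALSE)
          }
          planted_total <- sum(vapply(parts, function(p) sum(p$count),
                                      numeric(1)))
          bg_total <- depth - planted_total
          if (bg_total > 0) {
            sizes <- power_law_sizes(bg_total, design$clone_exponent, depth)
            bg <- generate_baseline(design$model, length(sizes))
            parts[[length(parts) + 1L]] <- tibble::tibble(
              count = sizes, cdr3nt = bg$cdr3nt, cdr3aa = bg$cdr3aa,
              v = bg$v, d = "", j = bg$j
            )
          }

          tbl <- dplyr::bind_rows(parts)
          tbl <- dplyr::summarise(
            dplyr::group_by(tbl, .data$cdr3nt, .data$cdr3aa, .data$v,
                            .data$d, .data$j),
            count = sum(.data$count), .groups = "drop"
          )
          sid <- paste(mid, tis, sub, sep = "_")
          meta <- sample_meta(sid, mid, tis, sub, ch)
          reps[[sid]] <- repertoire(tbl, meta)
        }
      }
    }
  }
  cohort(reps, design = mice)
}
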