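# Codon-space OSC-formation likelihoods: the probability that the codon
# junction of an ordered amino-acid pair contains an out-of-frame stop,
# and the two position-level summaries over an alignment (frequency-
# weighted over all pairs, and averaged over observed per-sequence pairs).
#
# Junction windows: exactly the two out-of-frame triplets fully contained
# in the 6-nt codon pair c1c2 — offset +1 (c1[2] c1[3] c2[1]) and offset
# +2 (c1[3] c2[1] c2[2]). Windows extending into neighboring codons are
# excluded: the analysis concerns isolated position pairs. This choice
# changes the numbers and is deliberate.

#' Codon usage model
#'
#' Per-amino-acid codon weights. The default is uniform within each amino
#' acid (the instrument for codon-bias-independent statements); organism
#' usage can be supplied as a table.
#'
#' @param weights Optional data.frame `codon`, `weight` (`amino_acid`
#'   column ignored; identity comes from the codon table). Missing sense
#'   codons get weight 0; weights are renormalized per amino acid.
#' @param codon_table_id NCBI translation table (default 11).
#' @return Object of class `codon_usage`: `weights` named over the 61
#'   sense codons (per-amino-acid sums = 1), `by_aa` list of codon sets.
#' @export
codon_usage <- function(weights = NULL, codon_table_id = 11L) {
  gc <- genetic_code(codon_table_id)
  sense <- names(gc)[gc != "*"]
  by_aa <- split(sense, gc[sense])
  w <- stats::setNames(rep(NA_real_, length(sense)), sense)
  if (is.null(weights)) {
    for (codons in by_aa) w[codons] <- 1 / length(codons)
  } else {
    stopifnot(is.data.frame(weights),
              all(c("codon", "weight") %in% names(weights)))
    cod <- toupper(gsub("U", "T", weights$codon))
    bad <- setdiff(cod, sense)
    if (length(bad)) stop("unknown/stop codons in usage table: ",
                          paste(bad, collapse = ", "))
    w[] <- 0
    w[cod] <- weights$weight
    for (codons in by_aa) {
      s <- sum(w[codons])
      if (s <= 0) stop("zero total usage weight for amino acid ",
                       gc[codons[1L]])
      w[codons] <- w[codons] / s
    }
  }
  structure(list(weights = w, by_aa = by_aa,
                 codon_table_id = as.integer(codon_table_id)),
            class = "codon_usage")
}

junction_windows <- function(c1, c2) {
  c(paste0(substr(c1, 2L, 3L), substr(c2, 1L, 1L)),
    paste0(substr(c1, 3L, 3L), substr(c2, 1L, 2L)))
}

#' Probability that an amino-acid pair's codon junction contains an OSC
#'
#' Sums `usage(c1) * usage(c2)` over codon pairs whose junction contains
#' at least one stop triplet in the two fully-contained out-of-frame
#' windows (probability of the union; `frame_breakdown` exposes the
#' per-frame parts, which can double-count pairs with stops in both).
#'
#' @param aa1,aa2 One-letter amino acids (ordered: aa1 precedes aa2).
#' @param usage `codon_usage` (default uniform).
#' @return List (class `junction_likelihood`): `aa_pair`, `probability`,
#'   `frame_breakdown` (named over `"+1"`, `"+2"`).
#' @examples
#' pair_osc_probability("K", "K")$probability  # 0: lysine codons lack T
#' pair_osc_probability("L", "K")$probability  # 5/6
#' @export
pair_osc_probability <- function(aa1, aa2, usage = codon_usage()) {
  stopifnot(inherits(usage, "codon_usage"))
  for (a in c(aa1, aa2)) {
    if (!a %in% names(usage$by_aa)) stop("unknown amino acid: ", a)
  }
  c1s <- usage$by_aa[[aa1]]
  c2s <- usage$by_aa[[aa2]]
  p_union <- 0; p1 <- 0; p2 <- 0
  for (c1 in c1s) {
    for (c2 in c2s) {
      w <- usage$weights[[c1]] * usage$weights[[c2]]
      win <- junction_windows(c1, c2)
      s1 <- win[1L] %in% STOP_TRIPLETS
      s2 <- win[2L] %in% STOP_TRIPLETS
      if (s1) p1 <- p1 + w
      if (s2) p2 <- p2 + w
      if (s1 || s2) p_union <- p_union + w
    }
  }
  structure(list(aa_pair = c(aa1, aa2), probability = p_union,
                 frame_breakdown = c("+1" = p1, "+2" = p2)),
            class = "junction_likelihood")
}

#' @export
print.junction_likelihood <- function(x, ...) {
  cat("<junction_likelihood> (", x$aa_pair[1L], ",", x$aa_pair[2L],
      "): P(OSC) = ", format(x$probability, digits = 4),
      " [+1: ", format(x$frame_breakdown[["+1"]], digits = 4),
      ", +2: ", format(x$frame_breakdown[["+2"]], digits = 4), "]\n",
      sep = "")
  invisible(x)
}

profile_aa_freqs <- function(profile) {
  f <- if (is.list(profile)) profile$frequencies else profile
  if (sum(f) <= 0) stop("all-gap column: no residue frequencies")
  f / sum(f)
}

#' Frequency-weighted positional OSC likelihood
#'
#' First summary method: over two adjacent alignment positions, sums
#' `freq_i(a) * freq_j(b) * P(OSC | a, b)` across all amino-acid pairs.
#' Gaps are excluded and frequencies renormalized.
#'
#' @param profile_i,profile_j Column profiles ([profile_at()]) of the two
#'   adjacent positions (i precedes j in the reference frame).
#' @param usage `codon_usage`.
#' @return Probability in `[0, 1]`.
#' @export
positional_likelihood_weighted <- function(profile_i, profile_j,
                                           usage = codon_usage()) {
  fi <- profile_aa_freqs(profile_i)
  fj <- profile_aa_freqs(profile_j)
  ai <- names(fi)[fi > 0]
  aj <- names(fj)[fj > 0]
  total <- 0
  for (a in ai) {
    for (b in aj) {
      total <- total + fi[[a]] * fj[[b]] *
        pair_osc_probability(a, b, usage)$probability
    }
  }
  total
}

#' Observed per-sequence positional OSC likelihood
#'
#' Second summary method: for each alignment row, takes the residues at
#' the two columns and computes the pair OSC probability; rows gapped at
#' either column are excluded (non-occurring pairs contribute nothing).
#'
#' @param aln `protein_alignment`.
#' @param col_i,col_j 1-based alignment columns (i precedes j).
#' @param usage `codon_usage`.
#' @return List: `mean` (over included rows), `per_sequence` data.frame
#'   (`seq_id`, `aa_i`, `aa_j`, `probability`), `n_included`.
#' @export
positional_likelihood_observed <- function(aln, col_i, col_j,
                                           usage = codon_usage()) {
  stopifnot(inherits(aln, "protein_alignment"))
  nc <- ncol(aln$mat)
  if (col_i < 1L || col_j > nc) stop("columns outside alignment (1-", nc, ")")
  ri <- aln$mat[, col_i]
  rj <- aln$mat[, col_j]
  ok <- !(ri %in% GAP_CHARS) & !(rj %in% GAP_CHARS) &
    ri %in% AA20 & rj %in% AA20
  if (!any(ok)) stop("all rows gapped at columns ", col_i, "/", col_j)
  key <- paste(ri[ok], rj[ok])
  probs_by_pair <- vapply(unique(key), function(k) {
    ab <- strsplit(k, " ")[[1L]]
    pair_osc_probability(ab[1L], ab[2L], usage)$probability
  }, 0)
  per_seq <- data.frame(seq_id = aln$ids[ok], aa_i = ri[ok], aa_j = rj[ok],
                        probability = unname(probs_by_pair[key]),
                        stringsAsFactors = FALSE)
  list(mean = mean(per_seq$probability), per_sequence = per_seq,
       n_included = sum(ok))
}

#' Positional nucleotide pattern of an amino-acid pair
#'
#' Tags amino acids whose *every* codon matches a positional nucleotide
#' pattern (per-position consensus base, `N` where codons vary). The
#' classic OSC-prone configuration is a middle-T first amino acid (NTN:
#' L, I, M, V, F) followed by lysine (AAN): the junction then reads
#' T-A-A or yields TGA/TAG variants.
#'
#' @param aa1,aa2 One-letter amino acids.
#' @param usage `codon_usage` (codon sets only; weights unused).
#' @return List: `pattern1`, `pattern2` (3-character patterns), `tag`
#'   (`"pattern1|pattern2"`), `ntn_aan` (`TRUE` when aa1 matches N-T-N
#'   and aa2 matches A-A-N).
#' @export
classify_pair_pattern <- function(aa1, aa2, usage = codon_usage()) {
  pat <- function(aa) {
    codons <- usage$by_aa[[aa]]
    if (is.null(codons)) stop("unknown amino acid: ", aa)
    paste(vapply(1:3, function(i) {
      b <- unique(substr(codons, i, i))
      if (length(b) == 1L) b else "N"
    }, ""), collapse = "")
  }
  p1 <- pat(aa1)
  p2 <- pat(aa2)
  list(pattern1 = p1, pattern2 = p2, tag = paste(p1, p2, sep = "|"),
       ntn_aan = substr(p1, 2L, 2L) == "T" && substr(p2, 1L, 2L) == "AA")
}
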