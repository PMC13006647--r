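# Seeded synthetic-data generators for every input the pipeline consumes:
# clean ORFs with controlled GC and homopolymer content, synonymous
# +OSC/-OSC construct pairs, engineered +1 frameshifts, revertant pools
# drawn from a known indel spectrum with gain-of-function filtering,
# Luria-Delbruck parallel-culture counts, stationary-phase revertant
# series, and toy protein alignments with planted conservation and
# loop-length structure.
#
# Every generator is a pure function of its arguments (seed included):
# RNG state is isolated per call via withr::with_seed, so adding one
# generator call never perturbs another at the same seed.

#' Generate a random coding sequence
#'
#' Starts with ATG, ends with a single in-frame stop, has no internal
#' in-frame stop, and hits a GC target within +/- 0.05 (codons are drawn
#' with exponentially tilted weights whose tilt is solved so the expected
#' per-nucleotide GC equals the target, then rejection-checked).
#'
#' @param n_codons Total codons including start and stop (>= 3).
#' @param gc_target Target GC fraction. Default 0.435 (B. subtilis-like).
#' @param seed Integer seed.
#' @param forbid_homopolymers_over Maximal allowed homopolymer run length
#'   (`NULL` = unconstrained).
#' @param stop_codon Terminal stop triplet (default `"TAA"`).
#' @param max_tries Whole-sequence retry budget before a generation error.
#' @return A `coding_sequence` (id `synth_<seed>`).
#' @export
gen_coding_sequence <- function(n_codons, gc_target = 0.435, seed = 1L,
                                forbid_homopolymers_over = NULL,
                                stop_codon = "TAA", max_tries = 200L) {
  stopifnot(n_codons >= 3L, gc_target > 0, gc_target < 1,
            stop_codon %in% STOP_TRIPLETS)
  gc_code <- genetic_code(11L)
  sense <- names(gc_code)[gc_code != "*"]
  gc_cnt <- vapply(strsplit(sense, ""), function(b) sum(b %in% c("G", "C")), 0L)
  # solve the exponential tilt so mean per-nt GC of internal codons
  # compensates the fixed start/stop codons
  n_internal <- n_codons - 2L
  fixed_gc <- sum(strsplit(paste0("ATG", stop_codon), "")[[1]] %in% c("G", "C"))
  target_internal <- (gc_target * 3 * n_codons - fixed_gc) / (3 * n_internal)
  target_internal <- min(max(target_internal, 0.02), 0.98)
  mean_gc <- function(lambda) {
    w <- exp(lambda * gc_cnt)
    sum(w * gc_cnt) / sum(w) / 3
  }
  lambda <- stats::uniroot(function(l) mean_gc(l) - target_internal,
                           c(-30, 30))$root
  w <- exp(lambda * gc_cnt)
  w <- w / sum(w)
  max_run <- if (is.null(forbid_homopolymers_over)) Inf
             else as.integer(forbid_homopolymers_over)
  if (max_run < 1L) stop("forbid_homopolymers_over must be >= 1")

  result <- withr::with_seed(seed, {
    found <- NULL
    for (try in seq_len(max_tries)) {
      codons <- character(n_codons)
      codons[1L] <- "ATG"
      codons[n_codons] <- stop_codon
      ok <- TRUE
      for (i in 2L:(n_codons - 1L)) {
        placed <- FALSE
        for (attempt in 1:100) {
          cand <- sample(sense, 1L, prob = w)
          if (is.finite(max_run)) {
            ctx <- paste0(paste(codons[max(1L, i - 2L):(i - 1L)],
                                collapse = ""), cand)
            if (max(rle(strsplit(ctx, "")[[1L]])$lengths) > max_run) next
          }
          codons[i] <- cand
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (!ok) next
      nt <- paste(codons, collapse = "")
      if (is.finite(max_run) &&
          max(rle(strsplit(nt, "")[[1L]])$lengths) > max_run) next
      if (abs(gc_content(nt) - gc_target) <= 0.05) {
        found <- nt
        break
      }
    }
    found
  })
  if (is.null(result)) {
    stop("gen_coding_sequence: constraints unsatisfiable after ", max_tries,
         " tries (gc_target = ", gc_target, ", max homopolymer = ",
         max_run, ")")
  }
  coding_sequence(paste0("synth_", seed), result)
}

# enumerate synonymous options of a codon (sense codons, same amino acid)
synonymous_codons <- function(codon, gc_code = genetic_code(11L)) {
  aa <- gc_code[[codon]]
  names(gc_code)[gc_code == aa & gc_code != "*"]
}

junction_has_stop <- function(c1, c2) {
  any(junction_windows(c1, c2) %in% STOP_TRIPLETS)
}

#' Remove OSCs from a codon region by synonymous recoding
#'
#' Finds, by dynamic programming over codon junctions, a synonymous
#' recoding of the region with zero out-of-frame stop triplets in any
#' window overlapping the region's codons (including junctions with the
#' fixed flanking codons), minimizing the number of changed codons, then
#' the number of changed nucleotides (remaining ties broken toward the
#' alphabetically smallest codon). Every out-of-frame triplet spans a
#' codon junction, so junction-wise checking is exhaustive.
#'
#' @param cds `coding_sequence` (length a multiple of 3, in-frame stop at
#'   the end permitted).
#' @param region `c(start_codon, end_codon)` 1-based codon range to
#'   recode.
#' @return Object of class `construct_pair`: `plus_osc` and `minus_osc`
#'   (`osc_construct`s with `frameshift_offset = 0`), and
#'   `osc_positions_removed` (0-based nt offsets of the OSCs present in
#'   the original region). Infeasible regions (e.g. an ATG AAA junction,
#'   whose TGA cannot be recoded away) raise an error listing the stuck
#'   junctions.
#' @export
remove_oscs_synonymously <- function(cds, region) {
  stopifnot(inherits(cds, "coding_sequence"), length(region) == 2L)
  codons <- split_codons(cds$nt)
  n <- length(codons)
  r1 <- as.integer(region[1L]); r2 <- as.integer(region[2L])
  if (r1 < 1L || r2 > n || r1 > r2) stop("region outside sequence")
  gc_code <- genetic_code(cds$codon_table_id)
  if (any(gc_code[codons[r1:r2]] == "*")) {
    stop("region contains an in-frame stop codon; recode sense codons only")
  }
  opts <- lapply(r1:r2, function(i) sort(synonymous_codons(codons[i], gc_code)))
  nt_diff <- function(a, b) sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  cost_of <- function(i, cand) {
    orig <- codons[r1 + i - 1L]
    c(changed = as.numeric(cand != orig), ntd = nt_diff(cand, orig))
  }
  better <- function(a, b) {  # TRUE if cost a < cost b
    if (a[1L] != b[1L]) return(a[1L] < b[1L])
    a[2L] < b[2L]
  }
  left_fixed <- if (r1 > 1L) codons[r1 - 1L] else NULL
  right_fixed <- if (r2 < n) codons[r2 + 1L] else NULL

  # DP states: per candidate codon at position i, best (cost, path)
  states <- list()
  for (cand in opts[[1L]]) {
    if (!is.null(left_fixed) && junction_has_stop(left_fixed, cand)) next
    states[[cand]] <- list(cost = cost_of(1L, cand), path = cand)
  }
  k <- r2 - r1 + 1L
  if (k > 1L) {
    for (i in 2L:k) {
      nxt <- list()
      for (cand in opts[[i]]) {
        step <- cost_of(i, cand)
        for (prev in names(states)) {
          if (junction_has_stop(prev, cand)) next
          tot <- states[[prev]]$cost + step
          if (is.null(nxt[[cand]]) || better(tot, nxt[[cand]]$cost)) {
            nxt[[cand]] <- list(cost = tot,
                                path = c(states[[prev]]$path, cand))
          }
        }
      }
      states <- nxt
      if (length(states) == 0L) break
    }
  }
  if (!is.null(right_fixed)) {
    states <- Filter(function(s) {
      !junction_has_stop(s$path[length(s$path)], right_fixed)
    }, states)
  }
  if (length(states) == 0L) {
    stuck <- character(0)
    ext <- seq(max(1L, r1 - 1L), min(n, r2 + 1L))
    for (i in ext[-length(ext)]) {
      o1 <- if (i >= r1 && i <= r2) opts[[i - r1 + 1L]] else codons[i]
      o2 <- if (i + 1L >= r1 && i + 1L <= r2) opts[[i + 1L - r1 + 1L]] else codons[i + 1L]
      if (all(outer(o1, o2, Vectorize(junction_has_stop)))) {
        stuck <- c(stuck, paste0("codons ", i, "-", i + 1L, " (",
                                 codons[i], "|", codons[i + 1L], ")"))
      }
    }
    stop("no synonymous recoding removes all OSCs in region ", r1, "-", r2,
         if (length(stuck)) paste0("; irreducible junction(s): ",
                                   paste(stuck, collapse = ", ")) else "")
  }
  best <- NULL
  for (s in states) if (is.null(best) || better(s$cost, best$cost)) best <- s
  new_codons <- codons
  new_codons[r1:r2] <- best$path
  minus_nt <- paste(new_codons, collapse = "")
  minus <- coding_sequence(paste0(cds$id, "_minusOSC"), minus_nt,
                           codon_table_id = cds$codon_table_id)
  # OSCs present in the original region (windows overlapping its nt span)
  all_oscs <- scan_oscs(cds)
  span0 <- c(3L * (r1 - 1L), 3L * r2)  # 0-based half-open
  removed <- all_oscs$nt_offset[all_oscs$nt_offset + 3L > span0[1L] &
                                  all_oscs$nt_offset < span0[2L]]
  leftover <- scan_oscs(minus)
  leftover <- leftover[leftover$nt_offset + 3L > span0[1L] &
                         leftover$nt_offset < span0[2L], ]
  if (nrow(leftover)) stop("internal error: OSC left in recoded region")
  plus <- coding_sequence(paste0(cds$id, "_plusOSC"), cds$nt,
                          codon_table_id = cds$codon_table_id)
  structure(list(plus_osc = construct(plus),
                 minus_osc = construct(minus),
                 region = c(r1, r2),
                 osc_positions_removed = removed),
            class = "construct_pair")
}

#' @export
print.construct_pair <- function(x, ...) {
  cat("<construct_pair> ", x$plus_osc$cds$id, " / ", x$minus_osc$cds$id,
      ": ", length(x$osc_positions_removed), " OSC(s) removed from codons ",
      x$region[1L], "-", x$region[2L], "\n", sep = "")
  invisible(x)
}

#' Introduce an engineered +1 frameshift
#'
#' Inserts a single base immediately after the given codon, producing a
#' `frameshift_offset = +1` construct (the selection-system "off" state:
#' inserted downstream of a Gln codon followed by A-A, the very next
#' in-frame codon becomes an ochre TAA).
#'
#' @param x `coding_sequence` or `osc_construct` with
#'   `frameshift_offset = 0`.
#' @param codon_index 1-based codon after which to insert.
#' @param base Inserted base (default `"T"`).
#' @param loop Optional loop bounds forwarded to [construct()].
#' @return An `osc_construct` with `frameshift_offset = 1`.
#' @export
introduce_frameshift <- function(x, codon_index, base = "T", loop = NULL) {
  cds <- as_cds(x)
  if (inherits(x, "osc_construct") && x$frameshift_offset != 0L) {
    stop("construct already carries a frameshift")
  }
  pep <- translate_cds(cds)
  if (!pep$terminated) stop("sequence has no in-frame stop")
  n_cod <- nt_length(cds) %/% 3L
  codon_index <- as.integer(codon_index)
  if (codon_index < 1L || codon_index >= pep$stop_codon_index) {
    stop("codon_index must lie before the natural stop (codon ",
         pep$stop_codon_index, ")")
  }
  mutant <- apply_indel(cds, indel_event("insertion", 3L * codon_index, base,
                                         label = paste0("+1", base)))
  mutant$id <- paste0(cds$id, "_fs", codon_index)
  construct(mutant, frameshift_offset = 1L,
            natural_stop_codon_index = pep$stop_codon_index, loop = loop)
}

#' Generate a revertant mutant pool from a known indel spectrum
#'
#' Draws events by weight from a spectrum and applies them to the
#' construct. With `selectable_only = TRUE` only gain-of-function
#' (frame-restoring, [classify_outcome()] `functional_restored`) events
#' are drawn — each spectrum entry is classified once and sampling is
#' restricted to the selectable entries with renormalized weights, which
#' is exactly the conditional spectrum that per-draw rejection sampling
#' converges to (events are deterministic given the construct).
#'
#' @param cons `osc_construct`.
#' @param spectrum data.frame `kind`, `position`, `payload`, `weight`
#'   (non-negative, normalizable), optional `label`.
#' @param n_mutants Pool size (0 gives an empty pool).
#' @param seed Integer seed.
#' @param selectable_only Restrict to gain-of-function events?
#' @return List of length `n_mutants`; each element has `event`
#'   (`indel_event`) and `mutant` (`coding_sequence`).
#' @export
gen_mutant_pool <- function(cons, spectrum, n_mutants, seed = 1L,
                            selectable_only = FALSE) {
  stopifnot(inherits(cons, "osc_construct"), is.data.frame(spectrum),
            all(c("kind", "position", "payload", "weight") %in%
                  names(spectrum)))
  if (any(spectrum$weight < 0) || sum(spectrum$weight) <= 0) {
    stop("spectrum weights must be non-negative and normalizable")
  }
  events <- lapply(seq_len(nrow(spectrum)), function(i) {
    lab <- if ("label" %in% names(spectrum)) spectrum$label[i] else NA
    indel_event(spectrum$kind[i], spectrum$position[i], spectrum$payload[i],
                label = if (is.na(lab) || !nzchar(lab)) NULL else lab)
  })
  mutants <- lapply(events, function(e) apply_indel(cons, e))
  weights <- spectrum$weight
  if (selectable_only) {
    sel <- vapply(mutants, function(m) {
      classify_outcome(cons, m)$classification == "functional_restored"
    }, logical(1L))
    if (!any(sel & weights > 0)) {
      stop("spectrum has zero selectable mass on construct '",
           cons$cds$id, "'")
    }
    weights[!sel] <- 0
  }
  if (n_mutants == 0L) return(list())
  idx <- withr::with_seed(seed, {
    sample.int(length(events), n_mutants, replace = TRUE,
               prob = weights / sum(weights))
  })
  lapply(idx, function(i) list(event = events[[i]], mutant = mutants[[i]]))
}

#' Simulate a Luria-Delbruck fluctuation experiment
#'
#' Mutations arise during growth from `n0` to `n_final` cells as a
#' Poisson process with total expectation `m_true` per culture (one
#' opportunity per division); each mutation founds a clone that doubles
#' thereafter. Two growth models:
#'
#' * `"asynchronous"` (default) — the continuous limit: a mutation occurs
#'   at a division drawn uniformly over the `n_final - n0` divisions
#'   (population size `N ~ Uniform(n0, n_final)` at that moment) and its
#'   clone reaches `floor(n_final / N)` cells. This reproduces the
#'   classical clone-size law `P(size >= s) = 1/s` that the Lea-Coulson
#'   median calibration (the 1.24 constant) assumes, and the median
#'   estimator recovers `m_true` essentially unbiasedly on it.
#' * `"discrete"` — synchronized doubling generations with mutation at
#'   division; a clone founded in generation k reaches `2^(G-k)`.
#'   Clone-size quantization under-produces mutants relative to the
#'   continuous model and biases the median estimator ~15% low; retained
#'   for comparison with generation-by-generation brute-force simulators.
#'
#' @param m_true Expected mutations per culture (> 0; 0 allowed and gives
#'   all-zero counts).
#' @param n0 Initial cells per culture (>= 1).
#' @param n_final Cells per culture at plating (> n0; the discrete model
#'   rounds it to the nearest `n0 * 2^G`).
#' @param n_cultures Number of parallel cultures.
#' @param seed Integer seed.
#' @param model `"asynchronous"` or `"discrete"` (see above).
#' @return A `fluctuation_dataset` ([fluctuation_dataset()]) with
#'   `n_final` set to the realized final population.
#' @export
gen_luria_delbruck <- function(m_true, n0, n_final, n_cultures, seed = 1L,
                               model = c("asynchronous", "discrete")) {
  stopifnot(n0 >= 1, n_final > n0, n_cultures >= 1L, m_true >= 0)
  model <- match.arg(model)
  if (model == "asynchronous") {
    counts <- withr::with_seed(seed, {
      vapply(seq_len(n_cultures), function(i) {
        k <- stats::rpois(1L, m_true)
        if (k == 0L) return(0)
        N <- stats::runif(k, n0, n_final)
        sum(floor(n_final / N))
      }, 0)
    })
    return(fluctuation_dataset(counts, n_final = n_final))
  }
  G <- max(1L, round(log2(n_final / n0)))
  nf <- n0 * 2^G
  # divisions in generation k: n0 * 2^(k-1); clone founded at k reaches 2^(G-k)
  divs <- n0 * 2^(0:(G - 1L))
  mu_div <- m_true / sum(divs)
  counts <- withr::with_seed(seed, {
    vapply(seq_len(n_cultures), function(i) {
      new_mut <- stats::rpois(G, mu_div * divs)
      sum(new_mut * 2^(G - seq_len(G)))
    }, 0)
  })
  fluctuation_dataset(counts, n_final = nf)
}

#' Simulate a stationary-phase mutagenesis time series
#'
#' Daily new revertant counts drawn as Poisson around a constant daily
#' mean — the instrument for planted fold-change recovery, not a
#' mechanistic SPM model.
#'
#' @param strain_id Label.
#' @param n_days Number of scored days.
#' @param daily_mean Mean new revertants per day.
#' @param cfu_plated Initial CFU plated.
#' @param seed Integer seed.
#' @return An `spm_series`.
#' @export
gen_spm_series <- function(strain_id, n_days, daily_mean, cfu_plated,
                           seed = 1L) {
  counts <- withr::with_seed(seed, stats::rpois(n_days, daily_mean))
  spm_series(strain_id, seq_len(n_days), counts, cfu_plated)
}

#' Generate a toy protein alignment with planted structure
#'
#' Plants (a) a consensus residue at each conserved column with a stated
#' identity fraction, (b) per-taxon loop-length distributions realized as
#' gaps inside an anchor-delimited loop span (both anchor columns always
#' occupied), and (c) uniform residues elsewhere. A gap-free reference
#' row (`"ref"`) is prepended when `include_reference = TRUE`.
#'
#' @param taxa List of taxon configs: each `list(label =, n =, loop_dist =)`
#'   where `loop_dist` is a named numeric vector mapping loop length to
#'   probability (lengths between 2 and the loop span width).
#' @param n_columns Alignment width.
#' @param conserved_columns Integer columns to plant conservation at.
#' @param conserved_identity Planted consensus fraction (default 0.6).
#' @param loop `c(start_column, end_column)` of the loop span.
#' @param seed Integer seed.
#' @param include_reference Prepend the gap-free reference row?
#' @return List: `alignment` (`protein_alignment`, taxon map attached),
#'   `taxon_map` (data.frame `seq_id`, `domain`, `phylum`), `consensus`
#'   (planted consensus residues by column), `loop`
#'   (`start_column`/`end_column` list).
#' @export
gen_alignment <- function(taxa, n_columns, conserved_columns = integer(0),
                          conserved_identity = 0.6, loop = NULL, seed = 1L,
                          include_reference = TRUE) {
  stopifnot(n_columns >= 1L)
  if (!is.null(loop)) {
    stopifnot(length(loop) == 2L, loop[1L] >= 1L, loop[2L] <= n_columns,
              loop[1L] < loop[2L])
    span <- loop[2L] - loop[1L] + 1L
    for (tx in taxa) {
      lens <- as.integer(names(tx$loop_dist))
      if (any(lens > span) || any(lens < 2L)) {
        stop("taxon '", tx$label, "': loop lengths must be in [2, ",
             span, "]")
      }
    }
  }
  withr::with_seed(seed, {
    consensus <- sample(AA20, n_columns, replace = TRUE)
    rows <- character(0)
    map <- data.frame(seq_id = character(0), domain = character(0),
                      phylum = character(0), stringsAsFactors = FALSE)
    make_row <- function(loop_len) {
      res <- sample(AA20, n_columns, replace = TRUE)
      for (j in conserved_columns) {
        res[j] <- if (stats::runif(1) < conserved_identity) consensus[j]
                  else sample(setdiff(AA20, consensus[j]), 1L)
      }
      if (!is.null(loop) && !is.na(loop_len)) {
        cols <- loop[1L]:loop[2L]
        keep <- c(loop[1L], loop[2L])
        interior <- setdiff(cols, keep)
        if (loop_len > 2L) {
          keep <- c(keep, sample(interior, loop_len - 2L))
        }
        res[setdiff(cols, keep)] <- "-"
      }
      paste(res, collapse = "")
    }
    if (include_reference) {
      rows["ref"] <- make_row(if (is.null(loop)) NA else
        loop[2L] - loop[1L] + 1L)
      map <- rbind(map, data.frame(seq_id = "ref", domain = "d_Bacteria",
                                   phylum = "reference",
                                   stringsAsFactors = FALSE))
    }
    for (tx in taxa) {
      lens <- as.integer(names(tx$loop_dist))
      p <- tx$loop_dist / sum(tx$loop_dist)
      for (i in seq_len(tx$n)) {
        id <- paste0(tx$label, "_", i)
        ll <- if (is.null(loop)) NA else sample(lens, 1L, prob = p)
        rows[id] <- make_row(ll)
        map <- rbind(map, data.frame(
          seq_id = id,
          domain = if (!is.null(tx$domain)) tx$domain else "d_Bacteria",
          phylum = tx$label, stringsAsFactors = FALSE))
      }
    }
    list(alignment = protein_alignment(rows, taxon_map = map),
         taxon_map = map, consensus = consensus,
         loop = if (is.null(loop)) NULL else
           list(start_column = loop[1L], end_column = loop[2L]))
  })
}

#' The shipped toy +OSC/-OSC construct pair
#'
#' A 13-codon ORF mirroring the experimental design: two out-of-frame
#' stops directly upstream of a "loop" (a frame +2 TGA at the codon 3|4
#' junction and a frame +1 TGA at the CTG|AAA codon 5|6 junction), a Gln
#' codon at position 7 followed by A-A so that the engineered +1T
#' insertion after codon 7 places an in-frame ochre TAA at codon 8, and
#' synonymous recoding (AAT->AAC, CTG->CTC) removing both OSCs in the
#' minus variant. Revertant indel events for this pair ship in
#' `system.file("extdata", "toy_events.tsv", package = "oscindel")`; 4 of
#' those 11 events are forbidden in the +OSC host (36.4%).
#'
#' @return List: `pair` (`construct_pair` of the unshifted ORFs),
#'   `plus_osc`, `minus_osc` (`osc_construct`s carrying the +1T after
#'   codon 7), `frameshift_codon` (7).
#' @export
toy_construct_pair <- function() {
  wt <- coding_sequence(
    "toy",
    paste0("ATG", "GCA", "AAT", "GAA", "CTG", "AAA", "CAA",
           "AAC", "GGC", "CTT", "GAA", "CAT", "TAA"))
  pair <- remove_oscs_synonymously(wt, region = c(3L, 6L))
  list(pair = pair,
       plus_osc = introduce_frameshift(pair$plus_osc$cds, 7L, "T",
                                       loop = c(5L, 10L)),
       minus_osc = introduce_frameshift(pair$minus_osc$cds, 7L, "T",
                                        loop = c(5L, 10L)),
       frameshift_codon = 7L)
}

#' Check a user-supplied reference CDS against the designed construct
#'
#' Convenience verification for a downloaded coding sequence (e.g. the
#' B. subtilis 168 argF CDS, which this package never bundles): scans
#' forward frames +1/+2 for OSCs, translates, and reports where the first
#' in-frame stop lands after a +1 single-base insertion downstream of a
#' given codon.
#'
#' @param x A `coding_sequence`, or a FASTA path (first record is used).
#' @param insertion_after_codon Codon index after which to insert
#'   (default 37, the Gln-37 design).
#' @param base Inserted base (default `"T"`).
#' @return List: `id`, `n_oscs` (forward +1/+2), `by_stop_class`,
#'   `protein_length` (residues before the natural stop),
#'   `first_stop_codon_after_insertion`, `first_stop_class`.
#' @export
verify_reference_cds <- function(x, insertion_after_codon = 37L,
                                 base = "T") {
  cds <- if (is.character(x)) read_fasta(x)[[1L]] else as_cds(x)
  oscs <- scan_oscs(cds)
  pep <- translate_cds(cds)
  shifted <- introduce_frameshift(cds, insertion_after_codon, base)
  out <- classify_outcome(shifted, shifted$cds)
  fs <- out$first_stop_codon_index
  list(id = cds$id,
       n_oscs = nrow(oscs),
       by_stop_class = count_by_stop_class(oscs),
       protein_length = nchar(pep$aa),
       first_stop_codon_after_insertion = fs,
       first_stop_class = if (!is.na(fs)) {
         stop_class(substr(shifted$cds$nt, 3L * fs - 2L, 3L * fs))
       } else NA_character_)
}
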