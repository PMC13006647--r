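# Indel engine: apply insertion/deletion events to engineered frameshift
# constructs, translate, classify gain-of-function outcomes, transplant
# events between synonymous +OSC/-OSC homologs (sequence reconstruction
# analysis), and summarize mutant spectra.
#
# Model: a construct is an ORF that may already carry an engineered net
# reading-frame shift (e.g. the +1T insertion downstream of a glutamine
# codon that switches the selection system off). A revertant indel is
# "gain-of-function" (frame-restoring) when the combined shift returns to
# 0 mod 3 AND translation from codon 1 reaches the construct's natural
# stop codon exactly, with no earlier stop. Reading through the natural
# stop is frame_disrupted, not functional.

#' Engineered construct
#'
#' @param cds `coding_sequence` of the construct as built (including any
#'   engineered frameshift insertion).
#' @param frameshift_offset Net reading-frame shift already engineered
#'   (0, 1 or 2). All engineered shift-causing edits are assumed upstream
#'   of the natural stop codon.
#' @param natural_stop_codon_index 1-based codon index of the natural stop
#'   in the *original* (unshifted) ORF numbering. Defaults, for
#'   `frameshift_offset = 0`, to the first in-frame stop of `cds`.
#' @param loop Optional `c(start, end)` 1-based codon bounds of the
#'   protein loop on the wild-type protein.
#' @return Object of class `osc_construct`.
#' @export
construct <- function(cds, frameshift_offset = 0L,
                      natural_stop_codon_index = NULL, loop = NULL) {
  stopifnot(inherits(cds, "coding_sequence"))
  frameshift_offset <- as.integer(frameshift_offset)
  if (!frameshift_offset %in% 0:2) {
    stop("frameshift_offset must be 0, 1 or 2")
  }
  if (is.null(natural_stop_codon_index)) {
    if (frameshift_offset != 0L) {
      stop("natural_stop_codon_index is required for a shifted construct")
    }
    pep <- translate_cds(cds)
    if (!pep$terminated) stop("construct '", cds$id, "' has no in-frame stop")
    natural_stop_codon_index <- pep$stop_codon_index
  }
  natural_stop_codon_index <- as.integer(natural_stop_codon_index)
  # the natural stop triplet sits at 0-based offset
  # 3*(index-1) + frameshift_offset in construct coordinates
  s0 <- 3L * (natural_stop_codon_index - 1L) + frameshift_offset
  if (s0 + 3L > nt_length(cds) ||
      !substr(cds$nt, s0 + 1L, s0 + 3L) %in% STOP_TRIPLETS) {
    stop("construct '", cds$id, "': no stop triplet at expected natural ",
         "stop position (codon ", natural_stop_codon_index, ", offset ",
         frameshift_offset, ")")
  }
  if (!is.null(loop)) {
    stopifnot(length(loop) == 2L, loop[1] <= loop[2],
              loop[2] <= natural_stop_codon_index)
  }
  structure(list(cds = cds, frameshift_offset = frameshift_offset,
                 natural_stop_codon_index = natural_stop_codon_index,
                 loop = loop),
            class = "osc_construct")
}

#' @export
print.osc_construct <- function(x, ...) {
  cat("<osc_construct> ", x$cds$id, ": ", nt_length(x$cds),
      " nt, engineered shift +", x$frameshift_offset,
      ", natural stop at codon ", x$natural_stop_codon_index, "\n", sep = "")
  invisible(x)
}

#' Describe an insertion or deletion event
#'
#' @param kind `"insertion"` or `"deletion"`.
#' @param position 1-based nucleotide position. Insertions are inserted
#'   immediately *after* this position (0 = before the first base);
#'   deletions start (first deleted base) *at* this position.
#' @param payload Inserted nucleotide string (insertions) or deleted
#'   length >= 1 (deletions).
#' @param label Optional display label, e.g. `"+2 GA"`, `"-1A"`; defaults
#'   to that style.
#' @return Object of class `indel_event`.
#' @export
indel_event <- function(kind = c("insertion", "deletion"), position, payload,
                        label = NULL) {
  kind <- match.arg(kind)
  position <- as.integer(position)
  if (kind == "insertion") {
    stopifnot(is.character(payload), nchar(payload) >= 1L)
    payload <- toupper(payload)
    if (grepl("[^ACGT]", payload)) stop("insertion payload must be ACGT")
    if (position < 0L) stop("insertion position must be >= 0")
    if (is.null(label)) label <- paste0("+", nchar(payload), payload)
  } else {
    payload <- as.integer(payload)
    if (payload < 1L) stop("deletion length must be >= 1")
    if (position < 1L) stop("deletion position must be >= 1")
    if (is.null(label)) label <- paste0("-", payload)
  }
  structure(list(kind = kind, position = position, payload = payload,
                 label = label),
            class = "indel_event")
}

#' Net length change of an event
#' @param event An `indel_event`.
#' @return Signed integer (+inserted length / -deleted length).
#' @export
net_delta <- function(event) {
  if (event$kind == "insertion") nchar(event$payload) else -event$payload
}

as_cds <- function(x) {
  if (inherits(x, "osc_construct")) x$cds
  else if (inherits(x, "coding_sequence")) x
  else stop("expected a coding_sequence or osc_construct")
}

#' Apply an indel event to a sequence
#'
#' @param x A `coding_sequence` or `osc_construct`.
#' @param event An `indel_event`.
#' @return The mutated `coding_sequence` (id suffixed with the event
#'   label). Length bookkeeping: |out| = |in| + inserted length, or
#'   |in| - deleted length; bases outside the edit are unchanged.
#' @examples
#' cds <- coding_sequence("toy", "ATGCAAAAT")
#' apply_indel(cds, indel_event("insertion", 6, "T"))$nt  # "ATGCAATAAT"
#' @export
apply_indel <- function(x, event) {
  cds <- as_cds(x)
  stopifnot(inherits(event, "indel_event"))
  n <- nt_length(cds)
  if (event$kind == "insertion") {
    if (event$position > n) stop("insertion position ", event$position,
                                 " beyond sequence end (", n, ")")
    nt <- paste0(substr(cds$nt, 1L, event$position), event$payload,
                 substring(cds$nt, event$position + 1L))
  } else {
    last <- event$position + event$payload - 1L
    if (last > n) stop("deletion runs past sequence end: positions ",
                       event$position, "-", last, " on ", n, " nt")
    nt <- paste0(substr(cds$nt, 1L, event$position - 1L),
                 substring(cds$nt, last + 1L))
  }
  coding_sequence(paste0(cds$id, "|", gsub(" ", "", event$label)), nt,
                  codon_table_id = cds$codon_table_id)
}

#' Left-align an indel event within repeat context
#'
#' Events inside repeat runs admit several equivalent placements (the
#' classic ambiguous di-adenine deletion). Following variant-call
#' practice, events are shifted to the leftmost placement that yields the
#' same mutant sequence, before deduplication and spectrum tallying.
#'
#' @param x Host `coding_sequence` or `osc_construct` the event applies to.
#' @param event An `indel_event`.
#' @return The left-aligned `indel_event` (label preserved).
#' @export
left_align_indel <- function(x, event) {
  cds <- as_cds(x)
  s <- strsplit(cds$nt, "")[[1L]]
  p <- event$position
  if (event$kind == "deletion") {
    L <- event$payload
    while (p > 1L && s[p - 1L] == s[p + L - 1L]) p <- p - 1L
    out <- indel_event("deletion", p, L, label = event$label)
  } else {
    v <- strsplit(event$payload, "")[[1L]]
    L <- length(v)
    while (p >= 1L && s[p] == v[L]) {
      v <- c(s[p], v[-L])
      p <- p - 1L
    }
    out <- indel_event("insertion", p, paste(v, collapse = ""),
                       label = event$label)
  }
  out
}

#' Classify the translational outcome of a mutant
#'
#' Translates the mutant in frame 0 from codon 1 and classifies it
#' against the construct's natural stop:
#' * `functional_restored` — net frame shift 0 and translation terminates
#'   exactly at the construct's natural stop, no earlier stop;
#' * `premature_stop` — a stop codon is read before the natural stop
#'   position;
#' * `frame_disrupted` — anything else (shifted frame surviving to or past
#'   the natural stop; read-through with no stop at all gives an absent
#'   stop index).
#'
#' The mutant is assumed derived from the construct by edits upstream of
#' the natural stop codon (the loop mutagenesis setting), so the natural
#' stop's position in mutant coordinates follows from the length change.
#'
#' @param cons An `osc_construct`.
#' @param mutant The mutated `coding_sequence` (any length >= 3).
#' @return List (class `translation_outcome`): `classification`,
#'   `peptide` (translated to the first stop), `first_stop_codon_index`
#'   (or `NA`), `net_frame_shift` (0/1/2), `loop_delta_aa` (signed codons
#'   gained in the loop when functional, else `NA`; assumes the engineered
#'   shift and the event both fall in the loop region).
#' @export
classify_outcome <- function(cons, mutant) {
  stopifnot(inherits(cons, "osc_construct"))
  mutant <- as_cds(mutant)
  delta <- nt_length(mutant) - nt_length(cons$cds)
  net_shift <- (cons$frameshift_offset + delta) %% 3L
  # 0-based nt start of the natural stop triplet in mutant coordinates
  stop_nt0 <- 3L * (cons$natural_stop_codon_index - 1L) +
    cons$frameshift_offset + delta

  n_codons <- nt_length(mutant) %/% 3L
  codons <- substring(mutant$nt, 3L * seq_len(n_codons) - 2L,
                      3L * seq_len(n_codons))
  gc <- genetic_code(mutant$codon_table_id)
  aa <- gc[codons]
  stop_idx <- which(aa == "*")
  fs <- if (length(stop_idx)) unname(stop_idx[1L]) else NA_integer_
  aa_str <- if (is.na(fs)) paste(aa[aa != "*"], collapse = "") else
    paste(aa[seq_len(fs - 1L)], collapse = "")
  pep <- structure(list(id = mutant$id, aa = aa_str,
                        terminated = !is.na(fs), stop_codon_index = fs),
                   class = "peptide")

  expected_idx <- if (net_shift == 0L) stop_nt0 %/% 3L + 1L else NA_integer_
  classification <-
    if (net_shift == 0L && !is.na(fs) && fs == expected_idx) {
      "functional_restored"
    } else if (!is.na(fs) && 3L * (fs - 1L) < stop_nt0) {
      "premature_stop"
    } else {
      "frame_disrupted"
    }
  loop_delta <- if (classification == "functional_restored") {
    (cons$frameshift_offset + delta) %/% 3L
  } else NA_integer_
  structure(list(classification = classification, peptide = pep,
                 first_stop_codon_index = fs,
                 net_frame_shift = net_shift,
                 loop_delta_aa = loop_delta),
            class = "translation_outcome")
}

#' @export
print.translation_outcome <- function(x, ...) {
  cat("<translation_outcome> ", x$classification,
      " (net shift ", x$net_frame_shift,
      if (!is.na(x$first_stop_codon_index))
        paste0(", first stop at codon ", x$first_stop_codon_index) else "",
      ")\n", sep = "")
  invisible(x)
}

#' Reconstruct an indel event in a homologous host construct
#'
#' Sequence reconstruction analysis: an event observed in one strain is
#' transplanted into the synonymous homolog at the same 1-based
#' coordinate and its translational outcome classified. Valid because the
#' +OSC/-OSC pair differ only by synonymous substitutions, so coordinates
#' correspond one-to-one.
#'
#' @param event An `indel_event`.
#' @param source `osc_construct` in which the event was observed.
#' @param host `osc_construct` to transplant into (same length).
#' @return List (class `reconstruction_result`): `event`,
#'   `source_construct_id`, `host_construct_id`, `outcome`, `permitted`
#'   (`TRUE` iff the outcome is `functional_restored`).
#' @export
reconstruct_in_host <- function(event, source, host) {
  stopifnot(inherits(source, "osc_construct"), inherits(host, "osc_construct"))
  if (nt_length(source$cds) != nt_length(host$cds)) {
    stop("source and host constructs differ in length (",
         nt_length(source$cds), " vs ", nt_length(host$cds),
         "); no site map available")
  }
  mutant <- apply_indel(host, event)
  outcome <- classify_outcome(host, mutant)
  structure(list(event = event,
                 source_construct_id = source$cds$id,
                 host_construct_id = host$cds$id,
                 outcome = outcome,
                 permitted = outcome$classification == "functional_restored"),
            class = "reconstruction_result")
}

#' Fraction of events forbidden in a host construct
#'
#' @param events Nonempty list of `indel_event`.
#' @param source,host `osc_construct` pair (see [reconstruct_in_host()]).
#' @return Fraction in `[0, 1]` of events not permitted
#'   (non-frame-restoring or truncated) in the host.
#' @export
fraction_forbidden <- function(events, source, host) {
  if (length(events) == 0L) stop("fraction_forbidden: empty event list")
  permitted <- vapply(events, function(e) {
    reconstruct_in_host(e, source, host)$permitted
  }, logical(1L))
  mean(!permitted)
}

#' Summarize per-strain indel spectra
#'
#' Per strain: % insertions vs deletions among sequenced mutants, and %
#' occurrence of each (site, event label) among that strain's total
#' (denominator: per-strain total sequenced mutants). Events are
#' left-aligned before tallying when host constructs are supplied.
#' Across two strains, indel *sites* are compared: unique to each,
#' shared.
#'
#' @param events data.frame with columns `strain_id`, `kind`
#'   (insertion/deletion), `position` (1-based), `payload` (string for
#'   insertions, length for deletions), optional `label`.
#' @param constructs Optional named list of `osc_construct` by strain id;
#'   when given, events are left-aligned against their strain's construct.
#' @param compare Character vector of 2 strain ids to compare (default:
#'   the two strains present, if exactly two).
#' @return List with `per_strain` (each: `entries` data.frame
#'   site/label/count/pct_occurrence, `n_total`, `pct_insertions`,
#'   `pct_deletions`) and `comparison` (`unique_a`, `unique_b`, `shared`
#'   site vectors) or `NULL`.
#' @export
summarize_spectrum <- function(events, constructs = NULL, compare = NULL) {
  stopifnot(is.data.frame(events),
            all(c("strain_id", "kind", "position", "payload") %in%
                  names(events)))
  if (!"label" %in% names(events)) events$label <- NA_character_
  evs <- lapply(seq_len(nrow(events)), function(i) {
    lab <- events$label[i]
    e <- indel_event(events$kind[i], events$position[i], events$payload[i],
                     label = if (is.na(lab) || !nzchar(lab)) NULL else lab)
    sid <- events$strain_id[i]
    if (!is.null(constructs)) {
      if (is.null(constructs[[sid]])) {
        stop("no construct supplied for strain '", sid, "'")
      }
      e <- left_align_indel(constructs[[sid]], e)
    }
    list(strain_id = sid, event = e)
  })
  strains <- unique(vapply(evs, `[[`, "", "strain_id"))
  per_strain <- list()
  for (sid in strains) {
    es <- Filter(function(x) x$strain_id == sid, evs)
    n <- length(es)
    kinds <- vapply(es, function(x) x$event$kind, "")
    site <- vapply(es, function(x) x$event$position, 0L)
    lab <- vapply(es, function(x) x$event$label, "")
    key <- paste(site, lab, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    entries <- data.frame(
      site = as.integer(vapply(parts, `[`, "", 1L)),
      label = vapply(parts, `[`, "", 2L),
      count = as.integer(tab),
      stringsAsFactors = FALSE
    )
    entries <- entries[order(entries$site, entries$label), , drop = FALSE]
    entries$pct_occurrence <- 100 * entries$count / n
    rownames(entries) <- NULL
    per_strain[[sid]] <- list(
      entries = entries, n_total = n,
      pct_insertions = 100 * mean(kinds == "insertion"),
      pct_deletions = 100 * mean(kinds == "deletion"),
      sites = sort(unique(site))
    )
  }
  comparison <- NULL
  if (is.null(compare) && length(strains) == 2L) compare <- strains
  if (!is.null(compare)) {
    if (!all(compare %in% strains)) {
      stop("unknown strain id(s) in comparison request: ",
           paste(setdiff(compare, strains), collapse = ", "))
    }
    a <- per_strain[[compare[1L]]]$sites
    b <- per_strain[[compare[2L]]]$sites
    comparison <- list(strain_a = compare[1L], strain_b = compare[2L],
                       unique_a = setdiff(a, b), unique_b = setdiff(b, a),
                       shared = intersect(a, b))
  }
  list(per_strain = per_strain, comparison = comparison)
}

#' Read an indel event table (TSV)
#'
#' Columns: `strain_id`, `kind`, `position` (1-based), `payload`,
#' optional `label`.
#' @param path TSV path.
#' @return data.frame suitable for [summarize_spectrum()].
#' @export
read_events_tsv <- function(path) {
  df <- read_table_tsv(path)
  need <- c("strain_id", "kind", "position", "payload")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("event table '", path, "' missing column(s): ",
                         paste(miss, collapse = ", "))
  df$position <- as.integer(df$position)
  df
}
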