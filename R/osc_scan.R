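# Detection and classification of out-of-frame stop codons (OSCs):
# TAA/TAG/TGA triplets starting at a nucleotide offset not divisible by 3,
# i.e. "hidden" stops that become active only after a frameshift.
# Plus sequence-composition confound checks (GC content, homopolymers).

#' Scan a coding sequence for out-of-frame stop codons
#'
#' Reports every triplet fully inside the sequence whose 0-based start
#' offset modulo 3 is in `frames` and whose content is one of TAA, TAG,
#' TGA. Forward strand only; no wrap or partial windows. OSCs overlapping
#' the natural stop codon region are counted like any other triplet.
#' Output is sorted by offset, then frame.
#'
#' @param cds A `coding_sequence` (length >= 3). Windows containing
#'   ambiguous characters (possible when the sequence was read with
#'   `strict = FALSE`) are skipped.
#' @param frames Frames to scan, a subset of `c(1, 2)` (+1 and +2).
#' @return data.frame with one row per OSC: `nt_offset` (0-based start of
#'   the triplet), `frame` (1 or 2), `triplet`, `stop_class`
#'   (ochre/amber/opal), `codon_start`, `codon_end` (1-based in-frame
#'   codon indices the triplet overlaps).
#' @examples
#' scan_oscs(coding_sequence("lk", "CTGAAA"))
#' @export
scan_oscs <- function(cds, frames = c(1L, 2L)) {
  stopifnot(inherits(cds, "coding_sequence"))
  frames <- unique(as.integer(frames))
  if (length(frames) == 0L) stop("scan_oscs: empty frame set")
  if (!all(frames %in% c(1L, 2L))) {
    stop("scan_oscs: frames must be a subset of {1, 2}")
  }
  n <- nt_length(cds)
  starts <- seq_len(n - 2L)            # 1-based triplet starts
  offs <- starts - 1L                  # 0-based
  frame <- offs %% 3L
  keep <- frame %in% frames
  starts <- starts[keep]
  offs <- offs[keep]
  frame <- frame[keep]
  trip <- substring(cds$nt, starts, starts + 2L)
  hit <- trip %in% STOP_TRIPLETS
  starts <- starts[hit]; offs <- offs[hit]; frame <- frame[hit]; trip <- trip[hit]
  ord <- order(offs, frame)
  data.frame(
    nt_offset = offs[ord],
    frame = frame[ord],
    triplet = trip[ord],
    stop_class = if (length(ord)) stop_class(trip[ord]) else character(0),
    codon_start = offs[ord] %/% 3L + 1L,
    codon_end = (offs[ord] + 2L) %/% 3L + 1L,
    stringsAsFactors = FALSE
  )
}

#' Tally OSCs by stop class
#' @param oscs data.frame from [scan_oscs()].
#' @return Named integer vector `c(ochre=, amber=, opal=)`; sums to
#'   `nrow(oscs)`.
#' @export
count_by_stop_class <- function(oscs) {
  out <- c(ochre = 0L, amber = 0L, opal = 0L)
  if (nrow(oscs)) {
    tab <- table(factor(oscs$stop_class, levels = names(out)))
    out[] <- as.integer(tab)
  }
  out
}

#' GC content of a sequence
#' @param cds A `coding_sequence` or plain nucleotide string.
#' @return Fraction of G+C in `[0, 1]`.
#' @export
gc_content <- function(cds) {
  nt <- if (inherits(cds, "coding_sequence")) cds$nt else toupper(cds)
  if (nchar(nt) == 0L) stop("gc_content: empty sequence")
  counts <- table(strsplit(nt, "")[[1L]])
  sum(counts[names(counts) %in% c("G", "C")]) / nchar(nt)
}

#' Find maximal homopolymer runs
#'
#' @param cds A `coding_sequence` or nucleotide string.
#' @param min_run Minimum run length to report (>= 2).
#' @return data.frame `base`, `start` (1-based), `length`; maximal runs
#'   only, sorted by start.
#' @export
find_homopolymers <- function(cds, min_run = 2L) {
  if (min_run < 2L) stop("find_homopolymers: min_run must be >= 2")
  nt <- if (inherits(cds, "coding_sequence")) cds$nt else toupper(cds)
  r <- rle(strsplit(nt, "")[[1L]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_run
  data.frame(base = r$values[keep], start = starts[keep],
             length = r$lengths[keep], stringsAsFactors = FALSE)
}
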