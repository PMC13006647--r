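# Protein multiple-alignment profiling: per-column residue frequencies,
# conservation under the strict >50%-of-sequences rule, information
# content in bits (WebLogo convention), gap-aware residue<->column
# coordinate mapping, OSC overlay, and anchor-delimited loop lengths
# stratified by taxon.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
GAP_CHARS <- c("-", ".")

#' Protein multiple alignment
#'
#' @param rows Named character vector (names = sequence ids) of aligned
#'   one-letter amino-acid strings with `-` (or `.`) as gap. All rows must
#'   have equal length; at least one row.
#' @param taxon_map Optional data.frame `seq_id`, `domain`, `phylum`.
#' @return Object of class `protein_alignment` with fields `ids`, `mat`
#'   (character matrix rows x columns), `taxon_map`.
#' @export
protein_alignment <- function(rows, taxon_map = NULL) {
  stopifnot(is.character(rows), length(rows) >= 1L, !is.null(names(rows)))
  if (anyDuplicated(names(rows))) stop("duplicate sequence ids in alignment")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows have unequal lengths: ",
         paste(range(widths), collapse = "-"))
  }
  if (widths[1L] == 0L) stop("zero-width alignment")
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  rownames(mat) <- names(rows)
  if (!is.null(taxon_map)) {
    stopifnot(is.data.frame(taxon_map), "seq_id" %in% names(taxon_map))
  }
  structure(list(ids = names(rows), mat = mat, taxon_map = taxon_map),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("<protein_alignment> ", nrow(x$mat), " sequences x ", ncol(x$mat),
      " columns\n", sep = "")
  invisible(x)
}

#' Read a protein multiple alignment
#'
#' @param path Aligned FASTA or Clustal file.
#' @param format `"fasta"` or `"clustal"`.
#' @param taxon_map_path Optional TSV (`seq_id`, `domain`, `phylum`).
#' @return `protein_alignment`.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"),
                           taxon_map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    rows <- as.character(set)
    names(rows) <- vapply(strsplit(names(set), "[ \t]+"), `[`, "", 1L)
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    rows <- as.character(aln)
  }
  tm <- if (!is.null(taxon_map_path)) read_table_tsv(taxon_map_path) else NULL
  protein_alignment(rows, taxon_map = tm)
}

#' Per-column conservation profiles
#'
#' For each column: residue frequencies among non-gap rows, gap fraction,
#' consensus (argmax; ties broken to the lexicographically smallest and
#' flagged), conservation under the strict majority rule, and
#' information content in bits.
#'
#' Conservation rule: a column is conserved when the consensus residue is
#' shared by strictly more than `threshold` of *sequences*. With
#' `gaps_in_denominator = TRUE` (default) the denominator is all rows, so
#' a gap counts against conservation; set `FALSE` to count non-gap rows
#' only.
#'
#' @param aln `protein_alignment`.
#' @param threshold Conservation threshold on the consensus fraction
#'   (strict inequality). Default 0.5.
#' @param gaps_in_denominator Count gapped rows in the denominator?
#' @param small_sample_correction Subtract the WebLogo small-sample
#'   correction from bits? Default `FALSE`.
#' @return Object of class `column_profiles`: `summary` data.frame
#'   (`column`, `consensus`, `consensus_fraction`, `conserved`,
#'   `gap_fraction`, `bits`, `tie`), `freqs` (20 x ncol matrix of non-gap
#'   frequencies), `n_rows`.
#' @export
column_profiles <- function(aln, threshold = 0.5,
                            gaps_in_denominator = TRUE,
                            small_sample_correction = FALSE) {
  stopifnot(inherits(aln, "protein_alignment"))
  mat <- aln$mat
  n <- nrow(mat)
  nc <- ncol(mat)
  freqs <- matrix(0, nrow = length(AA20), ncol = nc,
                  dimnames = list(AA20, NULL))
  summary <- data.frame(column = seq_len(nc), consensus = NA_character_,
                        consensus_fraction = NA_real_, conserved = FALSE,
                        gap_fraction = 0, bits = NA_real_, tie = FALSE,
                        stringsAsFactors = FALSE)
  for (j in seq_len(nc)) {
    col <- mat[, j]
    is_gap <- col %in% GAP_CHARS
    summary$gap_fraction[j] <- mean(is_gap)
    res <- col[!is_gap]
    if (length(res) == 0L) next  # all-gap column: no consensus, bits NA
    counts <- table(factor(res, levels = AA20))
    freqs[, j] <- as.numeric(counts) / length(res)
    top <- max(counts)
    cands <- names(counts)[counts == top]
    summary$tie[j] <- length(cands) > 1L
    summary$consensus[j] <- sort(cands)[1L]
    denom <- if (gaps_in_denominator) n else length(res)
    summary$consensus_fraction[j] <- top / denom
    summary$conserved[j] <- summary$consensus_fraction[j] > threshold
  }
  out <- structure(list(summary = summary, freqs = freqs, n_rows = n),
                   class = "column_profiles")
  for (j in seq_len(nc)) {
    out$summary$bits[j] <- if (summary$gap_fraction[j] < 1) {
      information_bits(profile_at(out, j), n_sequences = n,
                       small_sample_correction = small_sample_correction)
    } else NA_real_
  }
  out
}

#' @export
print.column_profiles <- function(x, ...) {
  cat("<column_profiles> ", ncol(x$freqs), " columns over ", x$n_rows,
      " sequences; ", sum(x$summary$conserved), " conserved\n", sep = "")
  invisible(x)
}

#' Extract one column profile
#'
#' @param profiles `column_profiles`.
#' @param column 1-based column index.
#' @return List: `column_index`, `frequencies` (named over the 20 amino
#'   acids, non-gap-normalized), `gap_fraction`, `consensus`,
#'   `consensus_fraction`, `bits`.
#' @export
profile_at <- function(profiles, column) {
  stopifnot(inherits(profiles, "column_profiles"))
  if (column < 1L || column > ncol(profiles$freqs)) {
    stop("column ", column, " outside alignment (1-", ncol(profiles$freqs), ")")
  }
  s <- profiles$summary[column, ]
  list(column_index = column,
       frequencies = profiles$freqs[, column],
       gap_fraction = s$gap_fraction,
       consensus = s$consensus,
       consensus_fraction = s$consensus_fraction,
       bits = s$bits)
}

#' Information content of a column in bits
#'
#' `bits = log2(20) - H(frequencies) [- e_n]`, floored at 0, with `H` the
#' Shannon entropy in bits over the 20 amino acids and `e_n = 19 /
#' (2 ln(2) n)` the WebLogo small-sample correction (off by default; at
#' n = 100 it shifts bits by ~0.14).
#'
#' @param profile A profile list from [profile_at()] (or any list with a
#'   `frequencies` element), or a bare named frequency vector.
#' @param n_sequences Number of sequences (used by the correction).
#' @param small_sample_correction Apply `e_n`? Default `FALSE`.
#' @return Bits in `[0, log2(20)]`.
#' @export
information_bits <- function(profile, n_sequences = NULL,
                             small_sample_correction = FALSE) {
  f <- if (is.list(profile)) profile$frequencies else profile
  f <- f[f > 0]
  h <- -sum(f * log2(f))
  bits <- log2(20) - h
  if (small_sample_correction) {
    if (is.null(n_sequences) || n_sequences < 1L) {
      stop("n_sequences required for the small-sample correction")
    }
    bits <- bits - 19 / (2 * log(2) * n_sequences)
  }
  max(bits, 0)
}

#' Map a reference residue index to its alignment column
#'
#' @param aln `protein_alignment`.
#' @param seq_id Row id.
#' @param residue_index 1-based residue (non-gap character) index.
#' @return 1-based alignment column holding that residue.
#' @export
map_residue_to_column <- function(aln, seq_id, residue_index) {
  row <- alignment_row(aln, seq_id)
  non_gap <- which(!row %in% GAP_CHARS)
  if (residue_index < 1L || residue_index > length(non_gap)) {
    stop("residue index ", residue_index, " beyond sequence '", seq_id,
         "' (", length(non_gap), " residues)")
  }
  non_gap[residue_index]
}

#' Map an alignment column to a reference residue index
#'
#' Inverse of [map_residue_to_column()].
#' @param aln `protein_alignment`.
#' @param seq_id Row id.
#' @param column 1-based alignment column; must hold a residue (not a
#'   gap) in that row.
#' @return 1-based residue index.
#' @export
map_column_to_residue <- function(aln, seq_id, column) {
  row <- alignment_row(aln, seq_id)
  if (column < 1L || column > length(row)) {
    stop("column ", column, " outside alignment (1-", length(row), ")")
  }
  if (row[column] %in% GAP_CHARS) {
    stop("column ", column, " is a gap in '", seq_id, "'")
  }
  sum(!row[seq_len(column)] %in% GAP_CHARS)
}

alignment_row <- function(aln, seq_id) {
  stopifnot(inherits(aln, "protein_alignment"))
  i <- match(seq_id, aln$ids)
  if (is.na(i)) stop("sequence '", seq_id, "' not in alignment")
  aln$mat[i, ]
}

#' Anchor-delimited loop region
#'
#' Defines a loop span by two anchor residues of a reference row and maps
#' them to alignment columns. Both anchors are counted inside the loop
#' (inclusive on both ends), so anchors at reference residues 36 and 47
#' delimit a 12-residue reference loop.
#'
#' @param aln `protein_alignment`.
#' @param reference_id Reference row id.
#' @param start_anchor,end_anchor 1-based reference residue indices.
#' @return List (class `loop_region`): `reference_id`, `start_anchor`,
#'   `end_anchor`, `start_column`, `end_column`, `inclusive = TRUE`.
#' @export
loop_region <- function(aln, reference_id, start_anchor, end_anchor) {
  stopifnot(start_anchor <= end_anchor)
  sc <- map_residue_to_column(aln, reference_id, start_anchor)
  ec <- map_residue_to_column(aln, reference_id, end_anchor)
  structure(list(reference_id = reference_id,
                 start_anchor = start_anchor, end_anchor = end_anchor,
                 start_column = sc, end_column = ec, inclusive = TRUE),
            class = "loop_region")
}

#' Per-sequence loop lengths
#'
#' For each row, counts the non-gap residues in the loop's column span,
#' inclusive of both anchor columns.
#'
#' @param aln `protein_alignment`.
#' @param loop `loop_region` (or list with `start_column`, `end_column`).
#' @return Named integer vector of lengths, one per row.
#' @export
loop_lengths <- function(aln, loop) {
  stopifnot(inherits(aln, "protein_alignment"))
  sc <- loop$start_column; ec <- loop$end_column
  if (sc < 1L || ec > ncol(aln$mat) || sc > ec) {
    stop("loop columns ", sc, "-", ec, " outside alignment (1-",
         ncol(aln$mat), ")")
  }
  apply(aln$mat[, sc:ec, drop = FALSE], 1L,
        function(r) sum(!r %in% GAP_CHARS))
}

#' Loop-length distribution by taxon
#'
#' @param lengths Named integer vector from [loop_lengths()].
#' @param taxon_map data.frame `seq_id` plus a grouping column (`phylum`
#'   by default, falling back to `domain`); ids missing from the map are
#'   grouped as `"unassigned"`.
#' @param group Column of `taxon_map` to stratify by.
#' @return List of two data.frames: `counts` (`taxon`, `loop_length`,
#'   `count`) and `percentages` (`taxon`, `loop_length`, `pct` — summing
#'   to 100 within each taxon).
#' @export
loop_length_by_taxon <- function(lengths, taxon_map, group = "phylum") {
  stopifnot(!is.null(names(lengths)))
  if (is.null(taxon_map)) {
    taxon <- rep("unassigned", length(lengths))
  } else {
    if (!group %in% names(taxon_map)) group <- "domain"
    taxon <- taxon_map[[group]][match(names(lengths), taxon_map$seq_id)]
    taxon[is.na(taxon)] <- "unassigned"
  }
  tab <- as.data.frame(table(taxon = taxon, loop_length = lengths),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  counts <- data.frame(taxon = tab$taxon,
                       loop_length = as.integer(tab$loop_length),
                       count = tab$Freq, stringsAsFactors = FALSE)
  counts <- counts[order(counts$taxon, counts$loop_length), , drop = FALSE]
  rownames(counts) <- NULL
  totals <- tapply(counts$count, counts$taxon, sum)
  percentages <- counts
  percentages$pct <- 100 * counts$count / as.numeric(totals[counts$taxon])
  percentages$count <- NULL
  list(counts = counts, percentages = percentages)
}

#' Overlay OSCs on alignment conservation
#'
#' Maps each OSC's overlapped in-frame codons (reference-protein residue
#' indices) to alignment columns and flags whether the OSC falls on a
#' conserved position. An OSC is counted as "on a conserved codon" when
#' ANY of its overlapped codons' columns is conserved (any-overlap rule;
#' boundary-spanning triplets overlap two codons).
#'
#' @param profiles `column_profiles` of the alignment.
#' @param oscs data.frame from [scan_oscs()] on the reference coding
#'   sequence.
#' @param reference_id Alignment row id of the reference protein.
#' @param aln `protein_alignment`.
#' @return data.frame, one row per OSC: scan columns plus `col_start`,
#'   `col_end` (alignment columns of the overlapped codons), `conserved`.
#'   Attribute `n_conserved` holds the summary count. OSCs overlapping
#'   codons beyond the reference protein (e.g. the natural stop) get `NA`
#'   columns and `conserved = FALSE`.
#' @export
overlay_oscs <- function(profiles, oscs, reference_id, aln) {
  stopifnot(inherits(profiles, "column_profiles"),
            inherits(aln, "protein_alignment"))
  row <- alignment_row(aln, reference_id)
  n_res <- sum(!row %in% GAP_CHARS)
  out <- oscs
  out$col_start <- rep(NA_integer_, nrow(out))
  out$col_end <- rep(NA_integer_, nrow(out))
  out$conserved <- rep(FALSE, nrow(out))
  for (i in seq_len(nrow(oscs))) {
    codons <- seq(oscs$codon_start[i], oscs$codon_end[i])
    codons <- codons[codons <= n_res]
    if (length(codons) == 0L) next
    cols <- vapply(codons, function(k) {
      map_residue_to_column(aln, reference_id, k)
    }, 0L)
    out$col_start[i] <- min(cols)
    out$col_end[i] <- max(cols)
    out$conserved[i] <- any(profiles$summary$conserved[cols])
  }
  attr(out, "n_conserved") <- sum(out$conserved)
  out
}
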