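# Core sequence data model: coding sequences, translation under the
# bacterial/plastid code (NCBI transl_table 11), and FASTA/TSV I/O.
#
# Coordinate convention: internal coordinates are 0-based half-open;
# everything written to or read from disk is 1-based inclusive. The
# conversion happens at the I/O boundary only.

STOP_TRIPLETS <- c("TAA", "TAG", "TGA")

#' Genetic code table
#'
#' Returns the codon -> amino acid map for an NCBI translation table,
#' with stops encoded as `"*"`.
#'
#' @param codon_table_id Integer NCBI translation table identifier.
#'   Default 11 (bacterial/archaeal/plant plastid), the code used
#'   throughout this package. Start-codon special-casing is deliberately
#'   not applied: ATG/GTG/TTG are translated by table, because the
#'   downstream frameshift logic is frame arithmetic, not gene calling.
#' @return Named character vector of length 64.
#' @export
genetic_code <- function(codon_table_id = 11L) {
  Biostrings::getGeneticCode(as.character(codon_table_id))
}

#' Coding sequence object
#'
#' A nucleotide ORF with a codon-table identity. The substrate for OSC
#' scanning and in-silico mutagenesis.
#'
#' @param id Sequence identifier (non-empty string).
#' @param nt Nucleotide string. Lowercase input is uppercased. With
#'   `strict = TRUE` (default) any character outside A/C/G/T is rejected
#'   with the offending id and position; with `strict = FALSE` ambiguous
#'   characters are kept (scanning then skips windows containing them).
#' @param codon_table_id NCBI translation table (default 11).
#' @param description Optional free-text description.
#' @param strict Reject non-ACGT characters? Default `TRUE`.
#' @return An object of class `coding_sequence`.
#' @examples
#' cds <- coding_sequence("toy", "ATGAAATAA")
#' translate_cds(cds)
#' @export
coding_sequence <- function(id, nt, codon_table_id = 11L, description = "",
                            strict = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(nt), length(nt) == 1L)
  nt <- toupper(nt)
  if (nchar(nt) < 3L) {
    stop("coding_sequence '", id, "': length ", nchar(nt), " < 3")
  }
  bad <- gregexpr("[^ACGT]", nt)[[1L]]
  if (bad[1L] != -1L) {
    if (strict) {
      stop("coding_sequence '", id, "': non-ACGT character '",
           substr(nt, bad[1L], bad[1L]), "' at position ", bad[1L])
    }
    if (gregexpr("[^ACGTNRYSWKMBDHV]", nt)[[1L]][1L] != -1L) {
      stop("coding_sequence '", id, "': non-nucleotide characters present")
    }
  }
  structure(
    list(id = id, nt = nt, codon_table_id = as.integer(codon_table_id),
         description = description),
    class = "coding_sequence"
  )
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("<coding_sequence> ", x$id, ": ", nchar(x$nt), " nt (table ",
      x$codon_table_id, ")\n", sep = "")
  invisible(x)
}

#' Number of nucleotides in a coding sequence
#' @param cds A `coding_sequence`.
#' @return Integer length.
#' @export
nt_length <- function(cds) nchar(cds$nt)

#' Split a nucleotide string into frame-0 codons
#' @param nt Nucleotide string, length a multiple of 3.
#' @return Character vector of triplets.
#' @export
split_codons <- function(nt) {
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  substring(nt, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Classify a stop triplet
#'
#' @param triplet One of TAA, TAG, TGA.
#' @return `"ochre"` (TAA), `"amber"` (TAG) or `"opal"` (TGA).
#' @export
stop_class <- function(triplet) {
  out <- c(TAA = "ochre", TAG = "amber", TGA = "opal")[toupper(triplet)]
  if (anyNA(out)) stop("not a stop triplet: ", paste(triplet[is.na(out)], collapse = ", "))
  unname(out)
}

#' Translate a coding sequence
#'
#' Translation in frame 0 from position 1 under the sequence's codon
#' table. Stops at the first stop codon unless `through_stop = TRUE`.
#'
#' @param cds A `coding_sequence` whose length is a multiple of 3.
#' @param through_stop Keep translating past stop codons? Stops are then
#'   reported at the first stop but `aa` covers all non-stop codons up to
#'   the end (stop codons themselves contribute no residue).
#' @return A `peptide`: list with `id`, `aa` (one-letter string, no stop
#'   symbol), `terminated` (logical), `stop_codon_index` (1-based codon
#'   index of the first stop, or `NA_integer_`).
#' @examples
#' translate_cds(coding_sequence("x", "ATGAAATAA"))
#' @export
translate_cds <- function(cds, through_stop = FALSE) {
  stopifnot(inherits(cds, "coding_sequence"))
  if (nt_length(cds) %% 3L != 0L) {
    stop("translate: length of '", cds$id, "' (", nt_length(cds),
         ") is not a multiple of 3")
  }
  if (grepl("[^ACGT]", cds$nt)) {
    stop("translate: '", cds$id, "' contains ambiguous characters")
  }
  gc <- genetic_code(cds$codon_table_id)
  codons <- split_codons(cds$nt)
  aa <- gc[codons]
  stop_idx <- which(aa == "*")
  first_stop <- if (length(stop_idx)) unname(stop_idx[1L]) else NA_integer_
  keep <- if (!is.na(first_stop) && !through_stop) {
    seq_len(first_stop - 1L)
  } else {
    which(aa != "*")
  }
  structure(
    list(id = cds$id,
         aa = paste(aa[keep], collapse = ""),
         terminated = !is.na(first_stop),
         stop_codon_index = first_stop),
    class = "peptide"
  )
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", x$id, ": ", nchar(x$aa), " aa",
      if (x$terminated) paste0(", stop at codon ", x$stop_codon_index)
      else ", no stop", "\n", sep = "")
  invisible(x)
}

#' Read coding sequences from a FASTA file
#'
#' Order-preserving; ids (first whitespace-delimited token of the header)
#' must be unique within the file; sequences are uppercased.
#'
#' @param path FASTA file.
#' @param strict Reject records containing non-ACGT characters (default
#'   `TRUE`); the error names the record and position.
#' @return List of `coding_sequence` (empty list for an empty file).
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) return(list())
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA ids in '", path, "': ",
                        paste(unique(dup), collapse = ", "))
  desc <- sub("^[^ \t]+[ \t]*", "", headers)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- coding_sequence(ids[i], as.character(set[[i]]),
                                description = desc[i], strict = strict)
  }
  out
}

#' Write coding sequences to FASTA
#' @param seqs List of `coding_sequence`.
#' @param path Output file.
#' @param width Line wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    header <- if (nzchar(s$description)) paste(s$id, s$description) else s$id
    writeLines(paste0(">", header), con)
    n <- nchar(s$nt)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s$nt, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Write tabular records as TSV
#'
#' Header row, stable column order, UTF-8, '.' decimal separator.
#' Numeric columns are serialized with `digits` significant digits;
#' `digits = NA` writes full double precision (round-trip exact).
#'
#' @param records A data.frame.
#' @param path Output path.
#' @param digits Significant digits for numeric columns (default `NA` =
#'   full precision, 17 significant digits).
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path, digits = NA) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      d <- if (is.na(digits)) 17L else as.integer(digits)
      out[[j]] <- formatC(out[[j]], digits = d, format = "g")
    }
  }
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("cannot write table to '", path, "': ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' Read a TSV written by [write_table()]
#' @param path Input path.
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("table file not found: ", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
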