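# Independent brute-force oracles used to pin expected values. Each is
# deliberately written down a different path from the implementation it
# checks (explicit enumeration, Biostrings translation, direct formulas).

STOPS <- c("TAA", "TAG", "TGA")

# brute-force OSC enumeration: every offset, membership test, then filter
oracle_scan <- function(nt, frames = c(1L, 2L)) {
  n <- nchar(nt)
  hits <- data.frame(nt_offset = integer(0), triplet = character(0))
  for (o in 0:(n - 3L)) {
    tri <- substr(nt, o + 1L, o + 3L)
    if (tri %in% STOPS && (o %% 3L) %in% frames) {
      hits <- rbind(hits, data.frame(nt_offset = o, triplet = tri,
                                     stringsAsFactors = FALSE))
    }
  }
  hits
}

# random ACGT sequence
random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# full-translation outcome oracle via Biostrings: classify a mutant
# against a construct description without using the package's engine
oracle_classify <- function(cons, mutant_nt) {
  n <- nchar(mutant_nt)
  trimmed <- substr(mutant_nt, 1L, 3L * (n %/% 3L))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(trimmed),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE))
  fs <- regexpr("*", aa, fixed = TRUE)[1L]
  fs <- if (fs == -1L) NA_integer_ else fs
  delta <- n - nchar(cons$cds$nt)
  net <- (cons$frameshift_offset + delta) %% 3L
  stop_nt0 <- 3L * (cons$natural_stop_codon_index - 1L) +
    cons$frameshift_offset + delta
  if (net == 0L && !is.na(fs) && fs == stop_nt0 %/% 3L + 1L) {
    "functional_restored"
  } else if (!is.na(fs) && 3L * (fs - 1L) < stop_nt0) {
    "premature_stop"
  } else {
    "frame_disrupted"
  }
}

# exhaustive codon-pair enumeration for junction OSC probability
oracle_pair_prob <- function(aa1, aa2) {
  gc <- Biostrings::getGeneticCode("11")
  c1s <- names(gc)[gc == aa1 & gc != "*"]
  c2s <- names(gc)[gc == aa2 & gc != "*"]
  hit <- 0L
  for (c1 in c1s) for (c2 in c2s) {
    six <- paste0(c1, c2)
    if (substr(six, 2, 4) %in% STOPS || substr(six, 3, 5) %in% STOPS) {
      hit <- hit + 1L
    }
  }
  hit / (length(c1s) * length(c2s))
}

# generation-by-generation Luria-Delbruck simulator, per-division binomial
oracle_ld_discrete <- function(m_true, G, n_cultures, seed) {
  mu <- m_true / (2^G - 1)
  withr::with_seed(seed, vapply(seq_len(n_cultures), function(i) {
    wt <- 1; mut <- 0
    for (k in seq_len(G)) {
      nm <- stats::rbinom(1L, wt, mu)
      wt <- 2L * wt - nm
      mut <- 2 * mut + nm
    }
    mut
  }, 0))
}

# load the shipped toy pair and event list once per test file
toy_world <- function() {
  toy <- toy_construct_pair()
  ev <- read_events_tsv(system.file("extdata", "toy_events.tsv",
                                    package = "oscindel"))
  toy$events <- lapply(seq_len(nrow(ev)), function(i) {
    indel_event(ev$kind[i], ev$position[i], ev$payload[i],
                label = ev$label[i])
  })
  toy$events_df <- ev
  toy
}

# all amino acids of the standard code
AA_ALL <- sort(unique(Biostrings::getGeneticCode("11")[
  Biostrings::getGeneticCode("11") != "*"]))
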