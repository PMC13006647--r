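test_that("apply_indel edits exactly the stated bases", {
  cds <- coding_sequence("toy", "ATGCAAAAT")
  ins <- apply_indel(cds, indel_event("insertion", 6, "T"))
  expect_equal(ins$nt, "ATGCAATAAT")

  del <- apply_indel(cds, indel_event("deletion", 2, 4))
  expect_equal(del$nt, paste0(substr(cds$nt, 1, 1), substring(cds$nt, 6)))
  expect_equal(nchar(del$nt), 5L)

  # event then its exact inverse restores the original
  back <- apply_indel(ins, indel_event("deletion", 7, 1))
  expect_equal(back$nt, cds$nt)

  expect_error(apply_indel(cds, indel_event("deletion", 8, 4)),
               "past sequence end")
  expect_error(apply_indel(cds, indel_event("insertion", 15, "A")),
               "beyond sequence end")
})

test_that("left alignment normalizes repeat-run placements", {
  cds <- coding_sequence("run", "CAAATGGG")
  # deleting any single A of the tri-A run normalizes to position 2
  for (p in 2:4) {
    e <- left_align_indel(cds, indel_event("deletion", p, 1))
    expect_equal(e$position, 2L)
    expect_equal(apply_indel(cds, e)$nt,
                 apply_indel(cds, indel_event("deletion", p, 1))$nt)
  }
  # inserting A anywhere in/after the run normalizes to just after the C
  for (p in 1:4) {
    e <- left_align_indel(cds, indel_event("insertion", p, "A"))
    expect_equal(e$position, 1L)
    expect_equal(apply_indel(cds, e)$nt,
                 apply_indel(cds, indel_event("insertion", p, "A"))$nt)
  }
  # left-normalization never changes the mutant, hence never the outcome
  toy <- toy_world()
  for (e in toy$events) {
    ne <- left_align_indel(toy$minus_osc, e)
    expect_equal(apply_indel(toy$minus_osc, ne)$nt,
                 apply_indel(toy$minus_osc, e)$nt)
    expect_equal(
      classify_outcome(toy$minus_osc,
                       apply_indel(toy$minus_osc, ne))$classification,
      classify_outcome(toy$minus_osc,
                       apply_indel(toy$minus_osc, e))$classification)
  }
})

test_that("classification follows the gain-of-function contract", {
  toy <- toy_world()
  minus <- toy$minus_osc
  plus <- toy$plus_osc

  # the fresh +1-shifted constructs are premature_stop (ochre at codon 8)
  for (cons in list(minus, plus)) {
    out <- classify_outcome(cons, cons$cds)
    expect_equal(out$classification, "premature_stop")
    expect_equal(out$first_stop_codon_index, 8L)
    expect_equal(out$net_frame_shift, 1L)
  }

  # -1 deletion downstream of the OSCs restores frame: functional, delta 0
  e <- indel_event("deletion", 20, 1)
  out <- classify_outcome(minus, apply_indel(minus, e))
  expect_equal(out$classification, "functional_restored")
  expect_equal(out$loop_delta_aa, 0L)
  expect_equal(out$net_frame_shift, 0L)

  # +2 insertion upstream of the latent CTG AAA TGA shifts it in frame
  e <- indel_event("insertion", 6, "GA")
  out <- classify_outcome(plus, apply_indel(plus, e))
  expect_equal(out$classification, "premature_stop")
  expect_equal(out$first_stop_codon_index, 6L)
  expect_equal(substr(apply_indel(plus, e)$nt, 16, 18), "TGA")

  # +1 insertion into an unshifted construct before an A-A forms an ochre
  wt <- construct(toy$pair$plus_osc$cds)
  mut <- apply_indel(wt, indel_event("insertion", 21, "T"))
  out <- classify_outcome(wt, mut)
  expect_equal(out$classification, "premature_stop")
  fs <- out$first_stop_codon_index
  expect_equal(stop_class(substr(mut$nt, 3 * fs - 2, 3 * fs)), "ochre")

  # net frame shift arithmetic holds for every toy event
  for (e in toy$events) {
    out <- classify_outcome(minus, apply_indel(minus, e))
    expect_equal(out$net_frame_shift,
                 (minus$frameshift_offset + net_delta(e)) %% 3L)
  }
})

test_that("engine classification equals the full-translation oracle", {
  toy <- toy_world()
  for (cons in list(toy$minus_osc, toy$plus_osc)) {
    n <- nchar(cons$cds$nt)
    # exhaustive single-base insertions at every position
    for (p in 0:(n - 1)) {
      for (b in c("A", "C", "G", "T")) {
        mut <- apply_indel(cons, indel_event("insertion", p, b))
        expect_equal(classify_outcome(cons, mut)$classification,
                     oracle_classify(cons, mut$nt))
      }
    }
    # exhaustive single-base deletions
    for (p in 1:n) {
      mut <- apply_indel(cons, indel_event("deletion", p, 1))
      expect_equal(classify_outcome(cons, mut)$classification,
                   oracle_classify(cons, mut$nt))
    }
  }
})

test_that("reconstruction permits and forbids per the OSC mechanism", {
  toy <- toy_world()
  # identity host: reconstructed mutant equals the observed mutant
  e <- toy$events[[1L]]
  r <- reconstruct_in_host(e, toy$minus_osc, toy$minus_osc)
  expect_equal(apply_indel(toy$minus_osc, e)$nt,
               apply_indel(toy$minus_osc, r$event)$nt)
  expect_true(r$permitted)

  # all 11 shipped events are permitted in their source (-OSC) strain
  perm_minus <- vapply(toy$events, function(e) {
    reconstruct_in_host(e, toy$minus_osc, toy$minus_osc)$permitted
  }, logical(1))
  expect_true(all(perm_minus))

  # exactly the 4 events upstream of the frame +1 OSC are forbidden in +OSC
  perm_plus <- vapply(toy$events, function(e) {
    reconstruct_in_host(e, toy$minus_osc, toy$plus_osc)$permitted
  }, logical(1))
  upstream <- vapply(toy$events, function(e) {
    if (e$kind == "insertion") e$position <= 13 else e$position <= 13
  }, logical(1))
  expect_equal(!perm_plus, upstream)
  expect_equal(sum(!perm_plus), 4L)

  # the forbidden ones fail specifically by premature stop in the host
  for (e in toy$events[!perm_plus]) {
    out <- reconstruct_in_host(e, toy$minus_osc, toy$plus_osc)$outcome
    expect_equal(out$classification, "premature_stop")
  }

  expect_error(reconstruct_in_host(e, toy$minus_osc,
                                   construct(coding_sequence("short",
                                                             "ATGTAA"))),
               "differ in length")
})

test_that("fraction_forbidden reproduces 4/11 and matches brute force", {
  toy <- toy_world()
  frac <- fraction_forbidden(toy$events, toy$minus_osc, toy$plus_osc)
  expect_equal(frac, 4 / 11, tolerance = 1e-12)
  expect_equal(round(100 * frac, 1), 36.4)

  # brute-force reimplementation over exhaustive single-base insertions
  n <- nchar(toy$minus_osc$cds$nt)
  events <- list()
  for (p in 0:(n - 1)) for (b in c("A", "T")) {
    events[[length(events) + 1L]] <- indel_event("insertion", p, b)
  }
  brute <- mean(vapply(events, function(e) {
    oracle_classify(toy$plus_osc,
                    apply_indel(toy$plus_osc, e)$nt) != "functional_restored"
  }, logical(1)))
  expect_equal(fraction_forbidden(events, toy$minus_osc, toy$plus_osc), brute)

  expect_error(fraction_forbidden(list(), toy$minus_osc, toy$plus_osc),
               "empty")
  # events upstream of any latent OSC with net shift 0 are never forbidden:
  # a 0-shift construct pair with a frame-neutral +3 insertion
  wt <- construct(toy$pair$minus_osc$cds)
  e3 <- indel_event("insertion", 6, "GCT")
  expect_equal(fraction_forbidden(list(e3), wt, wt), 0)
})

test_that("permitted events of -OSC are a strict superset of +OSC", {
  toy <- toy_world()
  n <- nchar(toy$minus_osc$cds$nt)
  events <- list()
  for (p in 0:(n - 1)) {
    for (b in c("A", "C", "G", "T")) {
      events[[length(events) + 1L]] <- indel_event("insertion", p, b)
    }
    for (b2 in c("GA", "CT", "AA", "TC")) {
      events[[length(events) + 1L]] <- indel_event("insertion", p, b2)
    }
  }
  perm <- function(host) vapply(events, function(e) {
    reconstruct_in_host(e, toy$minus_osc, host)$permitted
  }, logical(1))
  pm <- perm(toy$minus_osc)
  pp <- perm(toy$plus_osc)
  expect_true(all(pm[pp]))      # permitted in +OSC => permitted in -OSC
  expect_gt(sum(pm), sum(pp))   # strictly more permitted in -OSC
})

test_that("spectrum summaries tally percentages and compare sites", {
  df <- data.frame(
    strain_id = c(rep("A", 10), rep("B", 3)),
    kind = c(rep("insertion", 4), rep("deletion", 6),
             "deletion", "deletion", "insertion"),
    position = c(3, 3, 7, 7, 7, 7, 3, 3, 3, 3, 7, 9, 11),
    payload = c("G", "G", "TC", "TC", 1, 1, 1, 1, 1, 1, 1, 1, "A"),
    stringsAsFactors = FALSE)
  sp <- summarize_spectrum(df)
  a <- sp$per_strain[["A"]]
  expect_equal(a$pct_insertions, 40)
  expect_equal(a$pct_deletions, 60)
  expect_equal(a$n_total, 10L)
  expect_equal(sum(a$entries$count), 10L)
  expect_equal(sum(a$entries$pct_occurrence), 100)
  expect_equal(sp$comparison$unique_a, 3)
  expect_equal(sp$comparison$unique_b, c(9, 11))
  expect_equal(sp$comparison$shared, 7)
  expect_error(summarize_spectrum(df, compare = c("A", "Z")),
               "unknown strain")

  # % occurrence arithmetic: 2 of 21 -> 9.5%
  df21 <- data.frame(strain_id = "S", kind = "deletion",
                     position = c(rep(5, 2), 6:24), payload = 1,
                     stringsAsFactors = FALSE)
  s <- summarize_spectrum(df21)$per_strain[["S"]]
  expect_equal(round(s$entries$pct_occurrence[s$entries$site == 5], 1), 9.5)

  # left-alignment merges ambiguous di-adenine placements when constructs
  # are supplied
  toy <- toy_world()
  amb <- data.frame(strain_id = "minusOSC", kind = "deletion",
                    position = c(16, 17, 18), payload = 1,
                    label = "-1A", stringsAsFactors = FALSE)
  merged <- summarize_spectrum(amb, constructs = list(minusOSC = toy$minus_osc))
  expect_equal(nrow(merged$per_strain$minusOSC$entries), 1L)
  expect_equal(merged$per_strain$minusOSC$entries$count, 3L)
})
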