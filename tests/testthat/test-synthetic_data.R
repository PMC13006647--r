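test_that("generated ORFs honor their constraints and seeds", {
  a <- gen_coding_sequence(50, seed = 1)
  b <- gen_coding_sequence(50, seed = 1)
  expect_identical(a$nt, b$nt)           # determinism
  expect_false(identical(a$nt, gen_coding_sequence(50, seed = 2)$nt))

  pep <- translate_cds(a)
  expect_true(pep$terminated)
  expect_equal(pep$stop_codon_index, 50L)  # single terminal stop
  expect_equal(nchar(pep$aa), 49L)

  gc40 <- gen_coding_sequence(80, gc_target = 0.40, seed = 3)
  expect_lte(abs(gc_content(gc40) - 0.40), 0.05)

  nohomo <- gen_coding_sequence(60, seed = 4, forbid_homopolymers_over = 3)
  expect_equal(nrow(find_homopolymers(nohomo, min_run = 4L)), 0L)

  # the TAA stop's A-A run can never satisfy a max-run of 1
  expect_error(gen_coding_sequence(10, seed = 5,
                                   forbid_homopolymers_over = 1,
                                   stop_codon = "TAA", max_tries = 5),
               "unsatisfiable")
})

test_that("synonymous OSC removal preserves protein, removes OSCs minimally", {
  toy <- toy_world()
  pair <- toy$pair
  plus <- pair$plus_osc$cds
  minus <- pair$minus_osc$cds

  # identical protein, identical length
  expect_equal(translate_cds(minus)$aa, translate_cds(plus)$aa)
  expect_equal(nchar(minus$nt), nchar(plus$nt))

  # zero OSCs in the recoded region of the minus variant
  span0 <- c(3 * (pair$region[1] - 1), 3 * pair$region[2])
  left <- scan_oscs(minus)
  left <- left[left$nt_offset + 3 > span0[1] & left$nt_offset < span0[2], ]
  expect_equal(nrow(left), 0L)
  expect_equal(length(pair$osc_positions_removed), 2L)

  # differences only at synonymous positions (codon-wise same amino acid)
  pc <- split_codons(plus$nt)
  mc <- split_codons(minus$nt)
  gc <- genetic_code()
  diff_at <- which(pc != mc)
  expect_true(length(diff_at) > 0)
  expect_equal(gc[pc[diff_at]], gc[mc[diff_at]], ignore_attr = TRUE)
  # minimality on this toy: the two stuck junctions force exactly 2 changes
  expect_equal(length(diff_at), 2L)

  # region with no OSCs -> identity pair
  clean <- coding_sequence("clean", "ATGGCAGCAGCATAA")
  idpair <- remove_oscs_synonymously(clean, c(2, 4))
  expect_equal(idpair$minus_osc$cds$nt, clean$nt)
  expect_equal(length(idpair$osc_positions_removed), 0L)

  # infeasible: ATG AAA junction TGA cannot be recoded away (M is fixed)
  stuck <- coding_sequence("stuck", "ATGATGAAATAA")
  expect_error(remove_oscs_synonymously(stuck, c(2, 3)),
               "irreducible junction")
})

test_that("scan contrast property: +OSC region nonempty, -OSC empty", {
  # over seeded ORFs, whenever a region contains removable OSCs the pair
  # shows the +/- contrast while translating identically
  found <- 0L
  for (seed in 1:30) {
    cds <- gen_coding_sequence(30, seed = 400 + seed)
    region <- c(5L, 12L)
    span0 <- c(3 * (region[1] - 1), 3 * region[2])
    oscs <- scan_oscs(cds)
    in_region <- oscs[oscs$nt_offset + 3 > span0[1] &
                        oscs$nt_offset < span0[2], ]
    if (nrow(in_region) == 0L) next
    pair <- tryCatch(remove_oscs_synonymously(cds, region),
                     error = function(e) NULL)
    if (is.null(pair)) next  # genuinely irreducible junction in this draw
    found <- found + 1L
    minus_oscs <- scan_oscs(pair$minus_osc$cds)
    minus_in <- minus_oscs[minus_oscs$nt_offset + 3 > span0[1] &
                             minus_oscs$nt_offset < span0[2], ]
    expect_equal(nrow(minus_in), 0L)
    expect_equal(translate_cds(pair$minus_osc$cds)$aa,
                 translate_cds(pair$plus_osc$cds)$aa)
  }
  expect_gte(found, 3L)  # the contrast was actually exercised
})

test_that("introduce_frameshift creates the +1TAA off state and inverts", {
  toy <- toy_world()
  wt <- toy$pair$plus_osc$cds
  fs <- introduce_frameshift(wt, 7)
  expect_equal(fs$frameshift_offset, 1L)
  expect_equal(nchar(fs$cds$nt), nchar(wt$nt) + 1L)
  # the very next in-frame codon is an ochre stop
  out <- classify_outcome(fs, fs$cds)
  expect_equal(out$classification, "premature_stop")
  expect_equal(out$first_stop_codon_index, 8L)
  expect_equal(substr(fs$cds$nt, 22, 24), "TAA")
  # inserting then deleting the same base restores the original
  back <- apply_indel(fs$cds, indel_event("deletion", 22, 1))
  expect_equal(back$nt, wt$nt)
  expect_error(introduce_frameshift(wt, 13), "before the natural stop")
})

test_that("mutant pools follow the planted spectrum and selection filter", {
  toy <- toy_world()
  ev <- toy$events_df
  spectrum <- data.frame(kind = ev$kind, position = ev$position,
                         payload = ev$payload, label = ev$label,
                         weight = 1, stringsAsFactors = FALSE)
  expect_length(gen_mutant_pool(toy$minus_osc, spectrum, 0, seed = 1), 0L)

  # two-event spectrum at 50/50: empirical split within binomial 99% bounds
  sp2 <- spectrum[1:2, ]
  sp2$weight <- c(0.5, 0.5)
  pool <- gen_mutant_pool(toy$minus_osc, sp2, 1000, seed = 6)
  frac <- mean(vapply(pool, function(x) x$event$label == sp2$label[1],
                      logical(1)))
  expect_lt(abs(frac - 0.5), 2.576 * sqrt(0.25 / 1000))

  # determinism
  pool2 <- gen_mutant_pool(toy$minus_osc, sp2, 1000, seed = 6)
  expect_identical(vapply(pool, function(x) x$mutant$nt, ""),
                   vapply(pool2, function(x) x$mutant$nt, ""))

  # selectable_only on the +OSC construct excludes the four events that
  # shift its OSC in frame
  pool_sel <- gen_mutant_pool(toy$plus_osc, spectrum, 400, seed = 7,
                              selectable_only = TRUE)
  labels <- unique(vapply(pool_sel, function(x) x$event$label, ""))
  forbidden <- ev$label[vapply(toy$events, function(e) {
    !reconstruct_in_host(e, toy$minus_osc, toy$plus_osc)$permitted
  }, logical(1))]
  expect_length(intersect(labels, forbidden), 0L)
  # and every drawn mutant is functional in its construct
  for (x in pool_sel[1:20]) {
    expect_equal(classify_outcome(toy$plus_osc, x$mutant)$classification,
                 "functional_restored")
  }

  # zero selectable mass errors out
  bad <- spectrum[1, ]
  expect_error(gen_mutant_pool(toy$plus_osc, bad, 10, seed = 1,
                               selectable_only = TRUE),
               "zero selectable mass")
})

test_that("Luria-Delbruck simulations behave like the model class", {
  # m -> 0 limit: all counts zero
  z <- gen_luria_delbruck(1e-9, 100, 1e6, 30, seed = 2)
  expect_true(all(z$mutant_counts == 0))

  # jackpot inflation: mean of counts exceeds m_true
  ds <- gen_luria_delbruck(2, 100, 1e6, 500, seed = 3)
  expect_gt(mean(ds$mutant_counts), 2)

  # determinism
  expect_identical(ds$mutant_counts,
                   gen_luria_delbruck(2, 100, 1e6, 500, seed = 3)$mutant_counts)

  # discrete model matches the generation-by-generation brute-force
  # simulator in distribution (chi-square on binned counts, fixed seeds)
  a <- gen_luria_delbruck(2, 1, 64, 2000, seed = 7,
                          model = "discrete")$mutant_counts
  b <- oracle_ld_discrete(2, G = 6, n_cultures = 2000, seed = 8)
  br <- c(-0.5, 0.5, 1.5, 2.5, 4.5, 8.5, 16.5, Inf)
  tab <- rbind(table(cut(a, br)), table(cut(b, br)))
  p <- suppressWarnings(stats::chisq.test(tab))$p.value
  expect_gt(p, 0.001)
})

test_that("generated alignments recover their planted structure", {
  taxa <- list(
    list(label = "Bacillota", n = 100,
         loop_dist = c(`11` = 0.8, `16` = 0.2)),
    list(label = "Pseudomonadota", n = 100, domain = "d_Bacteria",
         loop_dist = c(`16` = 0.5, `21` = 0.5)))
  gen <- gen_alignment(taxa, n_columns = 40, conserved_columns = c(3, 5),
                       conserved_identity = 0.6, loop = c(10, 33), seed = 11)
  aln <- gen$alignment

  # byte-identical regeneration
  gen2 <- gen_alignment(taxa, n_columns = 40, conserved_columns = c(3, 5),
                        conserved_identity = 0.6, loop = c(10, 33), seed = 11)
  expect_identical(aln$mat, gen2$alignment$mat)

  # planted identity recovered within sampling bounds (n = 201 rows)
  prof <- column_profiles(aln)
  n <- nrow(aln$mat)
  for (j in c(3, 5)) {
    expect_equal(profile_at(prof, j)$consensus, gen$consensus[j])
    expect_lt(abs(profile_at(prof, j)$consensus_fraction - 0.6),
              3 * sqrt(0.6 * 0.4 / n) + 1 / n)
  }

  # planted loop-length distributions recovered within multinomial bounds
  loop <- list(start_column = 10, end_column = 33)
  ll <- loop_lengths(aln, loop)
  out <- loop_length_by_taxon(ll, gen$taxon_map)
  for (tx in taxa) {
    pc <- out$percentages[out$percentages$taxon == tx$label, ]
    for (len in names(tx$loop_dist)) {
      planted <- 100 * tx$loop_dist[[len]]
      got <- pc$pct[pc$loop_length == as.integer(len)]
      expect_lt(abs(got - planted),
                100 * 3 * sqrt(tx$loop_dist[[len]] *
                                 (1 - tx$loop_dist[[len]]) / tx$n))
    }
    # only the planted lengths occur
    expect_setequal(pc$loop_length, as.integer(names(tx$loop_dist)))
  }

  # loop length larger than the span errors
  expect_error(gen_alignment(list(list(label = "x", n = 2,
                                       loop_dist = c(`30` = 1))),
                             n_columns = 40, loop = c(10, 20), seed = 1),
               "loop lengths")
})

test_that("the synthetic 319-codon reference stand-in verifies end to end", {
  # a synthetic stand-in for a downloadable reference CDS: 320 codons
  # (319 residues + stop), Gln codon CAA at 37 followed by A-A so the
  # engineered +1T lands an ochre at codon 38
  base <- gen_coding_sequence(320, gc_target = 0.435, seed = 2026)
  codons <- split_codons(base$nt)
  codons[37] <- "CAA"
  codons[38] <- "AAC"
  synth <- coding_sequence("synthetic_argF_standin",
                           paste(codons, collapse = ""))
  expect_equal(translate_cds(synth)$stop_codon_index, 320L)
  chk <- verify_reference_cds(synth, insertion_after_codon = 37)
  expect_equal(chk$protein_length, 319L)
  expect_equal(chk$first_stop_codon_after_insertion, 38L)
  expect_equal(chk$first_stop_class, "ochre")
  expect_equal(chk$n_oscs, nrow(scan_oscs(synth)))
  expect_equal(sum(chk$by_stop_class), chk$n_oscs)
})
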