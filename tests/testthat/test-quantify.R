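# Reference loading, read assignment, frequency normalization, detection
# and star annotation.

test_that("reference loading derives loop intervals and validates input", {
  hp <- tibble::tibble(
    hairpin_id = "h1",
    sequence = paste(rep("ACGT", 20), collapse = ""))  # 80 nt
  ann <- tibble::tibble(hairpin_id = "h1",
                        mature_id = c("m5", "m3"), arm = c("5p", "3p"),
                        start = c(6L, 50L), end = c(28L, 72L))
  ref <- mirna_reference(hp, ann)
  expect_equal(ref$loops$start, 28)
  expect_equal(ref$loops$end, 50)

  expect_error(
    mirna_reference(hp, dplyr::mutate(ann, hairpin_id = "nope")),
    "unknown hairpin")
  expect_error(
    mirna_reference(hp, dplyr::mutate(ann, end = c(28L, 99L))),
    "out-of-bounds")
  expect_error(
    mirna_reference(dplyr::mutate(hp, sequence = sub("A", "N", sequence)),
                    ann),
    "non-ACGTU")
})

test_that("U-containing FASTA round-trips through load_reference", {
  fa <- tempfile(fileext = ".fa")
  tsv <- tempfile(fileext = ".tsv")
  rna <- "GGGGGUUUUACGUACGUACGUACGUACCCCCGGGGGUUGCAGGCAGUUGCAGGCAGUUAAAAA"
  writeLines(c(">h1 some description", rna), fa)
  readr::write_tsv(tibble::tibble(hairpin_id = "h1", mature_id = "m5",
                                  arm = "5p", start = 8L, end = 28L), tsv)
  ref <- load_reference(fa, tsv)
  expect_false(grepl("U", ref$hairpins$sequence))
  expect_identical(ref$matures$sequence,
                   gsub("U", "T", toupper(substr(rna, 9, 28))))
})

test_that("reads are assigned, offset and NTA-annotated as constructed", {
  ref <- toy_reference()
  m5a <- ref$matures$sequence[ref$matures$mature_id == "mirA-5p"]
  loop_a <- substr(ref$hairpins$sequence[1], 28, 44)  # the hpA loop
  reads <- list(
    s1 = c(rep(m5a, 5),                                  # exact mature
           rep(substr(m5a, 2, 22), 3),                   # 5' trim
           rep(loop_a, 2),                               # loop read
           paste0(m5a, "AA"),                            # NTA candidate
           "ACGTACGTACGTAC"))                            # 14 nt, discarded
  th <- threshold_config()

  cnt <- quantify_reads(reads, ref, th, nta = FALSE)
  exact <- cnt[cnt$sequence == m5a, ]
  expect_equal(exact$region, "mature5p")
  expect_equal(exact$off5, 0L)
  expect_equal(exact$off3, 0L)
  expect_equal(exact$s1, 5L)
  trim <- cnt[cnt$sequence == substr(m5a, 2, 22), ]
  expect_equal(trim$off5, 1L)
  expect_equal(trim$off3, 0L)
  lp <- cnt[cnt$region == "loop", ]
  expect_equal(lp$sequence, loop_a)
  expect_equal(attr(cnt, "discarded")[["s1"]], 1)
  expect_false(paste0(m5a, "AA") %in% cnt$sequence)

  # the NTA pass picks up the mature + "AA" read with its suffix recorded
  cnt2 <- quantify_reads(reads, ref, th, nta = TRUE)
  nta_row <- cnt2[cnt2$sequence == paste0(m5a, "AA"), ]
  expect_equal(nrow(nta_row), 1)
  expect_equal(nta_row$nta, "AA")
  expect_equal(nta_row$region, "mature5p")
})

test_that("quantification equals the exhaustive position-scan oracle", {
  cfg <- sim_config(n_hairpins = 12, depth = 3000, seed = 17)
  sr <- generate_reference(cfg)
  sim <- simulate_timecourse(sr)
  cnt <- quantify_reads(sim$counts, sr$reference)

  oracle <- oracle_assign_reads(
    sim$counts$sequence, sr$reference$hairpins, sr$reference$matures,
    sr$reference$loops)
  # unique matures here, so no multimapping: one row per assigned sequence
  got <- cnt[order(cnt$sequence), c("sequence", "hairpin_id", "region",
                                    "mature_id")]
  want <- oracle[order(oracle$sequence), ]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$sequence, want$sequence)
  expect_equal(got$region, want$region)
  expect_equal(got$hairpin_id, want$hairpin_id)
  expect_equal(got$mature_id[got$region != "loop"],
               want$mature_id[want$region != "loop"])
})

test_that("read order and duplicated input rows never change counts", {
  cfg <- sim_config(n_hairpins = 8, depth = 2000, seed = 23)
  sr <- generate_reference(cfg)
  sim <- simulate_timecourse(sr)
  cnt1 <- quantify_reads(sim$counts, sr$reference)
  shuffled <- sim$counts[sample.int(nrow(sim$counts)), ]
  cnt2 <- quantify_reads(shuffled, sr$reference)
  o1 <- cnt1[order(cnt1$sequence), ]
  o2 <- cnt2[order(cnt2$sequence), ]
  expect_equal(o1$sequence, o2$sequence)
  for (s in sim$samples$sample_id) expect_equal(o1[[s]], o2[[s]])
})

test_that("a read shared by two hairpins counts once per mature group", {
  # two hairpins share an identical 3p mature sequence
  m5a <- "ACGTACGTACGTACGTACGTAC"
  shared <- "TTGCAGGCAGTTGCAGGCAGTT"
  m5b <- "GGATCCGGATCCGGATCCGGAT"
  hp <- tibble::tibble(
    hairpin_id = c("h1", "h2"),
    sequence = c(paste0("GGGGG", m5a, "CCCCCGGGGGCCCCCGG", shared, "GGGGG"),
                 paste0("TTTTT", m5b, "AAAAATTTTTAAAAATT", shared, "TTTTT")))
  ann <- tibble::tibble(
    hairpin_id = c("h1", "h1", "h2", "h2"),
    mature_id = c("m1-5p", "m1-3p", "m2-5p", "m2-3p"),
    arm = rep(c("5p", "3p"), 2),
    start = c(5L, 44L, 5L, 44L), end = c(27L, 66L, 27L, 66L))
  ref <- mirna_reference(hp, ann)
  expect_equal(length(unique(ref$matures$group_id)), 3)

  reads <- list(s1 = c(rep(shared, 10), rep(m5a, 4)))
  cnt <- quantify_reads(reads, ref)
  sh <- cnt[cnt$sequence == shared, ]
  expect_equal(nrow(sh), 1)            # one row for the one sequence group
  expect_false(sh$multimapped)         # same group: not ambiguous
  samples <- tibble::tibble(sample_id = "s1", time_h = 0, replicate = 1)
  fr <- compute_frequencies(cnt, samples)
  # totals count the shared read once: 14 mature reads in total
  expect_equal(unname(fr$totals[["s1"]]), 14)
  expect_equal(sort(fr$isoform$s1), sort(c(10 / 14, 4 / 14)))
})

test_that("frequencies sum to one, scale-invariantly, and detection filters", {
  cfg <- sim_config(n_hairpins = 10, depth = 5000, seed = 29)
  sr <- generate_reference(cfg)
  sim <- simulate_timecourse(sr)
  cnt <- quantify_reads(sim$counts, sr$reference)
  fr <- compute_frequencies(cnt, sim$samples)
  sums <- colSums(fr$isoform[sim$samples$sample_id])
  expect_equal(unname(sums), rep(1, nrow(sim$samples)))

  # scaling all counts of a sample leaves frequencies unchanged
  cnt2 <- cnt
  cnt2[[sim$samples$sample_id[1]]] <- 7L * cnt2[[sim$samples$sample_id[1]]]
  fr2 <- compute_frequencies(cnt2, sim$samples)
  expect_equal(fr2$isoform[[sim$samples$sample_id[1]]],
               fr$isoform[[sim$samples$sample_id[1]]])

  # detection threshold boundary: mean 0-h frequency 4e-6 is not detected
  samples <- toy_samples(times = 0, reps = 1)
  big <- toy_reference()
  m5a <- big$matures$sequence[1]
  m3a <- big$matures$sequence[2]
  counts <- tibble::tibble(sequence = c(m5a, m3a),
                           t0_r1 = c(4L, 999996L))
  frb <- compute_frequencies(quantify_reads(counts, big), samples)
  expect_false(frb$isoform$detected[frb$isoform$sequence == m5a])
  expect_true(frb$isoform$detected[frb$isoform$sequence == m3a])

  # zero mature reads in a sample is a named error
  counts0 <- tibble::tibble(sequence = m5a, t0_r1 = 0L)
  expect_error(compute_frequencies(quantify_reads(counts0, big), samples),
               "t0_r1")
})

test_that("star annotation follows 0-h abundance with the documented ties", {
  ref <- toy_reference()
  samples <- toy_samples(times = 0, reps = 2)
  seqs <- ref$matures$sequence
  names(seqs) <- ref$matures$mature_id
  # hpA: 3p 10x more abundant than 5p (the miR-222-like configuration);
  # hpB: exactly equal arms -> tie
  counts <- tibble::tibble(
    sequence = unname(seqs[c("mirA-5p", "mirA-3p", "mirB-5p", "mirB-3p")]),
    t0_r1 = c(100L, 1000L, 500L, 500L),
    t0_r2 = c(100L, 1000L, 500L, 500L))
  fr <- compute_frequencies(quantify_reads(counts, ref), samples)
  star <- annotate_star(fr, ref)
  get <- function(id, col) star[[col]][star$mature_id == id]
  expect_equal(get("mirA-3p", "strand_role"), "non_star")
  expect_equal(get("mirA-5p", "strand_role"), "star")
  expect_false(get("mirA-5p", "ambiguous"))
  expect_equal(get("mirB-5p", "strand_role"), "non_star")
  expect_equal(get("mirB-3p", "strand_role"), "star")
  expect_true(get("mirB-3p", "ambiguous"))

  # single-arm hairpin is non-star
  hp1 <- ref$hairpins[1, ]
  ann1 <- ref$matures[ref$matures$hairpin_id == "hpA" &
                        ref$matures$arm == "5p",
                      c("hairpin_id", "mature_id", "arm", "start", "end")]
  ref1 <- mirna_reference(hp1, ann1)
  counts1 <- tibble::tibble(sequence = unname(seqs["mirA-5p"]), t0_r1 = 10L)
  fr1 <- compute_frequencies(quantify_reads(counts1, ref1),
                             toy_samples(times = 0, reps = 1))
  star1 <- annotate_star(fr1, ref1)
  expect_equal(star1$strand_role, "non_star")
})

test_that("per-occurrence read FASTA round-trips to the same counts", {
  cfg <- sim_config(n_hairpins = 6, depth = 800, seed = 43)
  sr <- generate_reference(cfg)
  sim <- simulate_timecourse(sr)
  dir <- tempfile("reads")
  paths <- write_reads_fasta(sim, dir)
  reads <- lapply(paths, function(p)
    as.character(Biostrings::readBStringSet(p)))
  cnt_fa <- quantify_reads(reads, sr$reference)
  cnt_tbl <- quantify_reads(sim$counts, sr$reference)
  a <- cnt_fa[order(cnt_fa$sequence), ]
  b <- cnt_tbl[order(cnt_tbl$sequence), ]
  # sequences drawn with zero counts in every sample have no FASTA records
  b <- b[rowSums(b[sim$samples$sample_id]) > 0, ]
  expect_equal(a$sequence, b$sequence)
  for (s in sim$samples$sample_id) expect_equal(a[[s]], b[[s]])
})

test_that("planted strand roles are recovered on synthetic data", {
  cfg <- sim_config(n_hairpins = 60, depth = 1e5, seed = 37)
  sr <- generate_reference(cfg)
  sim <- simulate_timecourse(sr)
  fr <- compute_frequencies(quantify_reads(sim$counts, sr$reference),
                            sim$samples)
  star <- annotate_star(fr, sr$reference)
  j <- dplyr::inner_join(star,
                         sr$truth_mature[, c("mature_id", "strand_role")],
                         by = "mature_id", suffix = c("_called", "_true"))
  # generator plants >= 4:1 ratios, so every role should be recovered
  expect_equal(mean(j$strand_role_called == j$strand_role_true), 1)
})
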