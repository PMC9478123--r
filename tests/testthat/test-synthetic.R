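test_that("sim_spec validates fractions, plans and distributions", {
  expect_error(sim_spec(seed = 1, trace_edit_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_spec(seed = 1, trace_noise_sd = -0.1), "non-negative")
  expect_error(sim_spec(seed = 1, pileup_plan = data.frame(
    pos = 1, freq = 1, coverage = 100, class = "TC")), "SNP regime")
  expect_error(sim_spec(seed = 1, pileup_plan = data.frame(
    pos = 1, freq = 0.5, coverage = 100, class = "AC")), "\\{AG,TC,CT,GA\\}")
  bad_dist <- list(P1 = matrix(0.5, nrow = 20, ncol = 35,
                               dimnames = list(pprkp:::AA20, NULL)))
  expect_error(sim_spec(seed = 1, motif_column_dists = bad_dist),
               "validation error")
})

test_that("generators are bit-identical under a repeated seed", {
  sp <- function() sim_spec(seed = 71, n_proteins = 20,
                            transcript_lengths = rep(150L, 3),
                            planted_sites = data.frame(transcript = 1, offset = 50,
                                                       mismatches = 1),
                            pileup_plan = data.frame(pos = 100, freq = 0.2,
                                                     coverage = 200, class = "TC"),
                            n_background = 20)
  ref <- "GCUAGCUAGCUAGCAU"
  expect_identical(gen_motif_library(sp()), gen_motif_library(sp()))
  expect_identical(gen_transcriptome(sp(), ref), gen_transcriptome(sp(), ref))
  t1 <- gen_trace(sp(), "ACGTACGTACGTACGTGCATGCATGCATGCA", 16)
  t2 <- gen_trace(sp(), "ACGTACGTACGTACGTGCATGCATGCATGCA", 16)
  expect_identical(t1, t2)
  expect_identical(gen_pileups(sp()), gen_pileups(sp()))
  # and different seeds differ
  sp2 <- sim_spec(seed = 72, n_proteins = 20)
  expect_false(identical(gen_motif_library(sp2)$motifs,
                         gen_motif_library(sp())$motifs))
})

test_that("degenerate column distributions make every motif the consensus", {
  lens <- c(P1 = 35L, L1 = 35L, S1 = 31L, P2 = 35L, L2 = 35L, S2 = 31L,
            E1 = 34L, E2 = 31L)
  dists <- lapply(lens, function(len) {
    d <- matrix(0, nrow = 20, ncol = len, dimnames = list(pprkp:::AA20, NULL))
    d["K", ] <- 1
    d
  })
  lib <- gen_motif_library(sim_spec(seed = 73, n_proteins = 5,
                                    motif_column_dists = dists))
  for (t in names(lens)) {
    expect_equal(unique(lib$motifs$sequence[lib$motifs$motif_type == t]),
                 strrep("K", lens[[t]]))
    expect_equal(lib$consensus[[t]], strrep("K", lens[[t]]))
  }
})

test_that("the planted consensus is recovered from a 0.6-plurality library", {
  lib <- gen_motif_library(sim_spec(seed = 74, n_proteins = 200))
  cons <- vapply(split(lib$motifs$sequence, lib$motifs$motif_type),
                 function(s) consensus(s)$consensus, "")
  expect_identical(cons[names(lib$consensus)], lib$consensus)
  # every emitted motif has the declared length
  lens <- c(P1 = 35L, L1 = 35L, S1 = 31L, P2 = 35L, L2 = 35L, S2 = 31L,
            E1 = 34L, E2 = 31L)
  expect_true(all(nchar(lib$motifs$sequence) ==
                    lens[lib$motifs$motif_type]))
  # DYW domains all carry the signature
  expect_true(all(vapply(lib$dyw$sequence, function(s)
    !is.null(detect_deaminase_signature(s)), TRUE)))
})

test_that("transcriptome planting is exact and its manifest exhaustive", {
  ref <- "GCUAGCUAGCUAGCAU"
  plant <- data.frame(transcript = c(1, 1, 2), offset = c(20, 80, 40),
                      mismatches = c(0, 2, 3))
  sp <- sim_spec(seed = 75, transcript_lengths = rep(150L, 3),
                 planted_sites = plant)
  txm <- gen_transcriptome(sp, ref)
  expect_equal(nrow(txm$manifest), 3L)
  expect_setequal(txm$manifest$mismatches, c(0, 2, 3))
  for (r in seq_len(nrow(txm$manifest))) {
    w <- substr(txm$transcripts[[txm$manifest$transcript[r]]],
                txm$manifest$offset[r] + 1, txm$manifest$offset[r] + 16)
    expect_equal(sum(strsplit(w, "")[[1]] != strsplit(ref, "")[[1]]),
                 txm$manifest$mismatches[r])
    expect_equal(substr(w, 16, 16), "U")  # edited base never mutated
  }
  # each planted feature appears exactly once
  expect_false(anyDuplicated(txm$manifest[c("transcript", "offset")]) > 0)
})

test_that("transcriptome generation rejects impossible plants", {
  ref <- "GCUAGCUAGCUAGCAU"
  expect_error(gen_transcriptome(
    sim_spec(seed = 76, transcript_lengths = 100L,
             planted_sites = data.frame(transcript = 1, offset = 95,
                                        mismatches = 0)), ref),
    "offset out of range")
  expect_error(gen_transcriptome(
    sim_spec(seed = 76, transcript_lengths = 100L,
             planted_sites = data.frame(transcript = 1, offset = 10,
                                        mismatches = 17)), ref),
    "exceeds site length")
  expect_error(gen_transcriptome(
    sim_spec(seed = 76, transcript_lengths = 100L,
             planted_sites = data.frame(transcript = 2, offset = 10,
                                        mismatches = 0)), ref),
    "out of range")
})

test_that("pileup generation plants binomial edits over an error-only floor", {
  plan <- data.frame(pos = c(10, 20), freq = c(0.3, 0.0), coverage = 1000,
                     class = c("TC", "GA"))
  sp <- sim_spec(seed = 77, pileup_plan = plan, n_background = 10)
  piles <- gen_pileups(sp)
  expect_equal(nrow(piles$treated), 12L)
  expect_equal(piles$treated$pos, piles$control$pos)
  t10 <- piles$treated[piles$treated$pos == 10, ]
  expect_equal(t10$ref, "T")
  expect_gt(t10$nC / (t10$nC + t10$nT), 0.25)
  expect_lt(t10$nC / (t10$nC + t10$nT), 0.35)
  c10 <- piles$control[piles$control$pos == 10, ]
  expect_lt(c10$nC / (c10$nC + c10$nT), 0.01)
  expect_equal(piles$truth$true_freq, plan$freq)
  # coverage is conserved through the error channel
  expect_equal(rowSums(piles$treated[c("nA", "nC", "nG", "nT")]),
               rep(1000, 12), ignore_attr = TRUE)
})

test_that("generated artifacts round-trip through the pipeline readers", {
  ref <- "GCUAGCUAGCUAGCAU"
  sp <- sim_spec(seed = 78, n_proteins = 5, transcript_lengths = rep(120L, 2),
                 planted_sites = data.frame(transcript = 1, offset = 30,
                                            mismatches = 0),
                 pileup_plan = data.frame(pos = 50, freq = 0.2, coverage = 100,
                                          class = "TC"),
                 n_background = 5)
  dir <- withr::local_tempdir()
  lib <- gen_motif_library(sp)
  write_motif_table(lib$motifs, file.path(dir, "motifs.tsv"))
  expect_identical(read_motif_table(file.path(dir, "motifs.tsv")), lib$motifs)
  txm <- gen_transcriptome(sp, ref)
  write_fasta_seqs(txm$transcripts, file.path(dir, "tx.fasta"))
  expect_identical(read_fasta_seqs(file.path(dir, "tx.fasta")), txm$transcripts)
  piles <- gen_pileups(sp)
  write_pileup(piles$treated, file.path(dir, "t.tsv"))
  back <- load_pileup(file.path(dir, "t.tsv"))
  expect_equal(back, piles$treated, tolerance = 1e-12)
})
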