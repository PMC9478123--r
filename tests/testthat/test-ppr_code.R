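test_that("code tables validate and normalise weights", {
  df <- data.frame(motif_type = "P1", aa5 = "N", aa_last = "D",
                   wA = 1, wC = 1, wG = 1, wU = 1)
  ct <- code_table(df)
  expect_equal(as.numeric(ct[1, c("wA", "wC", "wG", "wU")]), rep(0.25, 4))
  df$wA <- -1
  expect_error(code_table(df), "non-negative")
  dup <- rbind(data.frame(motif_type = "P1", aa5 = "N", aa_last = "D",
                          wA = 1, wC = 0, wG = 0, wU = 0),
               data.frame(motif_type = "P1", aa5 = "N", aa_last = "D",
                          wA = 0, wC = 1, wG = 0, wU = 0))
  expect_error(code_table(dup), "duplicate")
  # the shipped canonical table loads and reaches all four nucleotides for
  # the canonical-code motif types
  canon <- default_code_table()
  for (t in c("P1", "L1", "S1", "P2")) {
    w <- as.matrix(canon[canon$motif_type == t, c("wA", "wC", "wG", "wU")])
    expect_setequal(colnames(w)[apply(w, 1, which.max)][!duplicated(colnames(w)[apply(w, 1, which.max)])],
                    c("wA", "wC", "wG", "wU"))
  }
})

test_that("binding motifs map bijectively onto positions -15..-3", {
  pr <- make_designer()
  pos <- motif_binding_positions(pr)
  expect_identical(unname(pos), -15:-3)
  expect_equal(unname(pos["P1.1"]), -15)  # first P1
  expect_equal(unname(pos["S1.2"]), -10)  # second S1
  expect_equal(unname(pos["L1.3"]), -8)   # third L1
  expect_equal(unname(pos[c("L2.1", "S2.1", "E1.1")]), c(-5, -4, -3))
  expect_error(motif_binding_positions(c("S1", "P1", "L1")), "non-canonical")
})

test_that("target sites validate the window and the edited base", {
  expect_error(target_site(strrep("A", 25), "U2C"), "26 nt")
  expect_error(target_site(paste0(strrep("A", 20), "G", strrep("A", 5)), "U2C"),
               "requires U")
  s <- target_site(paste0(strrep("a", 20), "t", strrep("g", 5)), "U2C")
  expect_equal(site_base(s, 0), "U")   # DNA transcribed on read
  expect_equal(site_base(s, -20), "A")
  expect_equal(site_base(s, 5), "G")
  expect_error(site_base(s, -21), "outside")
})

test_that("retarget/predict round trip reproduces the target under a bijective code", {
  pr <- make_designer()
  code <- bijective_code()
  set.seed(101)
  for (i in 1:25) {
    window <- random_rna_string(13)
    site <- make_site(window, seed = i)
    rt <- retarget(pr, site, code, overrides_for(site))
    model <- predict_binding(rt, code)
    expect_equal(binding_consensus(model), window)
    # everything but the recognition residues is untouched
    expect_equal(nchar(rt$sequence), nchar(pr$sequence))
    expect_identical(rt$dyw$sequence, pr$dyw$sequence)
  }
})

test_that("retarget errors when the code cannot reach a required nucleotide", {
  pr <- make_designer()
  code <- bijective_code()
  crippled <- code_table(as.data.frame(code)[!(code$motif_type == "P1" &
                                                 code$aa_last == "D" &
                                                 code$aa5 == "N"), ])
  window <- paste0("U", random_rna_string(12))  # -15 needs U from a P1 motif
  site <- make_site(window, seed = 3)
  expect_error(retarget(pr, site, crippled, overrides_for(site)),
               "achieves nucleotide U")
  expect_error(retarget(pr, site, code, list(L2 = c("N", "S"))),
               "overrides")
})

test_that("retargeted pairs equal an exhaustive argmax oracle under random codes", {
  pr <- make_designer()
  set.seed(33)
  for (rep in 1:20) {
    entries <- do.call(rbind, lapply(c("P1", "L1", "S1", "P2"), function(t) {
      pairs <- expand.grid(aa5 = c("N", "S", "T"), aa_last = c("D", "N", "S"),
                           stringsAsFactors = FALSE)
      w <- matrix(stats::runif(nrow(pairs) * 4), ncol = 4)
      data.frame(motif_type = t, pairs, wA = w[, 1], wC = w[, 2],
                 wG = w[, 3], wU = w[, 4])
    }))
    code <- code_table(entries)
    window <- random_rna_string(13)
    site <- make_site(window, seed = rep)
    ov <- list(L2 = c("Q", "Q"), S2 = c("Q", "Q"), E1 = c("Q", "Q"))
    res <- try(retarget(pr, site, code, ov), silent = TRUE)
    posmap <- motif_binding_positions(pr)
    # oracle: exhaustive admissibility + argmax search per canonical motif
    oracle <- lapply(1:10, function(k) {
      type <- pr$motifs$motif_type[k]
      nt <- site_base(site, unname(posmap[k]))
      rows <- as.data.frame(code)[code$motif_type == type, ]
      w <- as.matrix(rows[c("wA", "wC", "wG", "wU")])
      colnames(w) <- c("A", "C", "G", "U")
      ok <- which(w[, nt] >= apply(w, 1, max) - 1e-12)
      if (!length(ok)) return(NULL)
      best <- ok[which.max(w[ok, nt])]
      c(rows$aa5[best], rows$aa_last[best])
    })
    if (any(vapply(oracle, is.null, TRUE))) {
      expect_s3_class(res, "try-error")
      next
    }
    expect_false(inherits(res, "try-error"))
    rr <- recognition_residues(res)
    for (k in 1:10) {
      expect_equal(unname(c(rr$aa5[k], rr$aa_last[k])), unname(oracle[[k]]),
                   info = paste("rep", rep, "motif", k))
    }
  }
})

test_that("binding prediction normalises weights and flags unknown pairs", {
  pr <- make_designer()
  code <- bijective_code()
  site <- make_site(random_rna_string(13), seed = 9)
  rt <- retarget(pr, site, code, overrides_for(site))
  model <- predict_binding(rt, code)
  expect_equal(colSums(model$weights), rep(1, 13), ignore_attr = TRUE)
  expect_false(any(model$unknown))
  # unknown pair -> uniform, flagged, not fatal
  model2 <- predict_binding(pr, code)  # unretargeted residues are random
  expect_true(any(model2$unknown))
  expect_equal(model2$weights[, which(model2$unknown)[1]],
               c(A = 0.25, C = 0.25, G = 0.25, U = 0.25))
  # a specific entry lookup: L1 with pair (P, D)
  pd <- code_table(rbind(as.data.frame(code), data.frame(
    motif_type = "L1", aa5 = "P", aa_last = "D",
    wA = 0.1, wC = 0.1, wG = 0.7, wU = 0.1, provenance = "synthetic")))
  rt2 <- rt
  rt2$motifs$sequence[2] <- local({
    s <- rt2$motifs$sequence[2]
    substr(s, 5, 5) <- "P"; substr(s, nchar(s), nchar(s)) <- "D"; s
  })
  m3 <- predict_binding(rt2, pd)
  expect_equal(unname(m3$weights[, 2]), c(0.1, 0.1, 0.7, 0.1))
})

test_that("mismatch counting is an exact Hamming count with tie tolerance", {
  pr <- make_designer()
  code <- bijective_code()
  window <- "GCUAGCUAGCUAG"
  site <- make_site(window, seed = 2)
  model <- predict_binding(retarget(pr, site, code, overrides_for(site)), code)
  expect_equal(mismatch_count(model, window)$count, 0L)
  # window starts GCU; AAA changes G->A, C->A, U->A: 3 mismatches at -15..-13
  w3 <- paste0("AAA", substr(window, 4, 13))
  got <- mismatch_count(model, w3)
  expect_equal(got$count, 3L)
  expect_equal(got$positions, c(-15L, -14L, -13L))
  expect_error(mismatch_count(model, "ACGU"), "13 nt")
  set.seed(4)
  for (i in 1:100) {
    w <- random_rna_string(13)
    expect_equal(mismatch_count(model, w)$count,
                 sum(strsplit(w, "")[[1]] != strsplit(window, "")[[1]]))
  }
  # argmax ties count as matches
  tied <- code_table(rbind(as.data.frame(code), data.frame(
    motif_type = "P1", aa5 = "Y", aa_last = "Y",
    wA = 0.5, wC = 0.5, wG = 0, wU = 0, provenance = "synthetic")))
  rt <- retarget(pr, site, code, overrides_for(site))
  rt$motifs$sequence[1] <- local({
    s <- rt$motifs$sequence[1]
    substr(s, 5, 5) <- "Y"; substr(s, nchar(s), nchar(s)) <- "Y"; s
  })
  mt <- predict_binding(rt, tied)
  for (b in c("A", "C")) {
    w <- paste0(b, substr(window, 2, 13))
    expect_equal(mismatch_count(mt, w)$count, 0L)
  }
  wg <- paste0("G", substr(window, 2, 13))
  expect_equal(mismatch_count(mt, wg)$count, 1L)
  expect_equal(mismatch_count(mt, wg)$positions, -15L)
})
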