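write_pileup_file <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  pprkp::write_pileup(df, path)
  path
}

mk_site <- function(pos, ref, nA = 0, nC = 0, nG = 0, nT = 0, qual = 35,
                    chrom = "tx1") {
  data.frame(chrom = chrom, pos = pos, strand = "+", ref = ref,
             nA = nA, nC = nC, nG = nG, nT = nT, mean_qual = qual,
             stringsAsFactors = FALSE)
}

test_that("pileup loading applies the quality floor and rejects malformed rows", {
  df <- rbind(mk_site(1, "T", nT = 100), mk_site(2, "T", nT = 100, qual = 19))
  path <- write_pileup_file(df)
  expect_message(got <- load_pileup(path), "mean_qual < 20")
  expect_equal(got$pos, 1)
  # empty file (header only) loads as an empty table
  empty <- write_pileup_file(df[0, ])
  expect_equal(nrow(load_pileup(empty)), 0L)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("chrom","pos","strand","ref","nA","nC","nG","nT","mean_qual"),
                     collapse = "\t"),
               "tx1\toops\t+\tT\t0\t0\t0\t10\t35"), bad)
  expect_error(load_pileup(bad), "malformed")
})

test_that("candidate gating follows coverage, class, frequency and SNP rules", {
  pile <- rbind(
    mk_site(1, "T", nT = 5, nC = 5),            # coverage 10: excluded (strictly > 10)
    mk_site(2, "T", nT = 6, nC = 5),            # coverage 11: candidate
    mk_site(3, "T", nT = 96, nC = 4),           # freq 0.04 < 0.05: excluded
    mk_site(4, "A", nC = 30, nA = 70),          # A->C transversion: excluded
    mk_site(5, "T", nC = 100),                  # freq 1: SNP-like, excluded
    mk_site(6, "G", nA = 20, nG = 80),          # GA class: candidate
    mk_site(7, "C", nT = 10, nC = 90)           # CT class: candidate
  )
  cand <- candidate_sites(pile)
  expect_equal(cand$pos, c(2, 6, 7))
  expect_equal(cand$class, c("TC", "GA", "CT"))
  expect_equal(cand$freq, c(5 / 11, 0.2, 0.1))
  # variant-count reading of the gate
  cand_v <- candidate_sites(pile, min_cov = 10, count_mode = "variant")
  expect_equal(cand_v$pos, c(6, 7))
})

test_that("fisher_exact_p matches naive enumeration on all small tables", {
  for (m in 0:12) for (n in 0:12) for (a in 0:m) for (cc in 0:n) {
    p <- fisher_exact_p(a, m - a, cc, n - cc)
    q <- oracle_fisher_p(a, m - a, cc, n - cc)
    if (abs(p - q) > 1e-12) {
      expect_equal(p, q, tolerance = 1e-12,
                   info = sprintf("table %d/%d vs %d/%d", a, m - a, cc, n - cc))
    }
  }
  succeed()
})

test_that("fisher_exact_p agrees with stats::fisher.test on random tables", {
  set.seed(61)
  for (i in 1:300) {
    a <- sample(0:60, 1); b <- sample(0:60, 1)
    cc <- sample(0:60, 1); d <- sample(0:60, 1)
    p <- fisher_exact_p(a, b, cc, d)
    q <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
    expect_equal(p, min(q, 1), tolerance = 1e-12,
                 info = sprintf("%d %d %d %d", a, b, cc, d))
  }
  # documented examples
  expect_equal(fisher_exact_p(10, 90, 0, 100),
               stats::fisher.test(matrix(c(10, 90, 0, 100), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
  expect_equal(fisher_exact_p(5, 95, 5, 95), 1)       # identical tables
  expect_equal(fisher_exact_p(0, 100, 0, 100), 1)     # no variant anywhere
})

test_that("fisher_vs_control joins by coordinate and flags missing controls", {
  cand <- candidate_sites(rbind(mk_site(2, "T", nT = 60, nC = 40),
                                mk_site(9, "T", nT = 60, nC = 40)))
  control <- mk_site(2, "T", nT = 99, nC = 1)
  got <- fisher_vs_control(cand, control)
  expect_equal(got$c_var, c(1, 0))
  expect_equal(got$p[1], fisher_exact_p(40, 60, 1, 99))
  expect_equal(got$p[2], fisher_exact_p(40, 60, 0, 0))
  strict <- fisher_vs_control(cand, control, min_control_cov = 10)
  expect_false(strict$untestable[1])
  expect_true(strict$untestable[2])
  expect_true(is.na(strict$p[2]))
})

test_that("BH correction reproduces the step-up by hand", {
  expect_equal(bh_correct(0.01), 0.01)
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_correct(rep(1, 5)), rep(1, 5))
  expect_error(bh_correct(c(0.1, 1.2)), "\\[0, 1\\]")
  # hand-computed step-up on an uneven vector
  p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  hand <- rev(cummin(rev(p * 5 / seq_along(p))))
  expect_equal(bh_correct(p), pmin(1, hand))
})

test_that("control-significant and SNP positions are subtracted with reasons", {
  calls <- rbind(mk_site(5, "T", nT = 70, nC = 30),
                 mk_site(6, "T", nT = 70, nC = 30),
                 mk_site(7, "T", nT = 70, nC = 30))
  res <- subtract_control_and_snps(
    calls,
    control_significant = data.frame(chrom = "tx1", pos = 5),
    snp_positions = data.frame(chrom = "tx1", pos = c(5, 6)))
  expect_equal(res$calls$pos, 7)
  expect_equal(res$removed$reason[res$removed$pos == 5], "control")
  expect_equal(res$removed$reason[res$removed$pos == 6], "snp")
  untouched <- subtract_control_and_snps(
    calls, data.frame(chrom = "tx1", pos = 99),
    data.frame(chrom = "tx2", pos = 5))
  expect_equal(nrow(untouched$calls), 3L)
})

test_that("the caller recovers planted sites and ignores background", {
  plan <- data.frame(pos = c(1000, 2000, 3000), freq = c(0.05, 0.1, 0.3),
                     coverage = 1000, class = c("TC", "AG", "CT"))
  sp <- sim_spec(seed = 62, pileup_plan = plan)
  piles <- gen_pileups(sp)
  res <- call_editing_sites(piles$treated, piles$control)
  gated <- candidate_sites(piles$treated)
  planted_gated <- gated[gated$pos %in% plan$pos, ]
  expect_true(all(planted_gated$pos %in% res$calls$pos))
  expect_true(all(res$calls$pos %in% plan$pos))  # no background calls
  # planted frequency ~0.3 recovered within a binomial interval
  f3 <- res$calls$freq[res$calls$pos == 3000]
  expect_gt(f3, 0.25); expect_lt(f3, 0.35)
  # empty plan: nothing is ever called
  sp0 <- sim_spec(seed = 63, pileup_plan = NULL, n_background = 50)
  piles0 <- gen_pileups(sp0)
  res0 <- call_editing_sites(piles0$treated, piles0$control)
  expect_equal(nrow(res0$calls), 0L)
})

test_that("calls are invariant to pileup row order", {
  plan <- data.frame(pos = c(500, 1500), freq = c(0.2, 0.4),
                     coverage = 500, class = "TC")
  piles <- gen_pileups(sim_spec(seed = 64, pileup_plan = plan, n_background = 30))
  a <- call_editing_sites(piles$treated, piles$control)
  shuffle <- function(df) df[sample(nrow(df)), ]
  set.seed(1)
  b <- call_editing_sites(shuffle(piles$treated), shuffle(piles$control))
  expect_identical(a$calls, b$calls)
  expect_identical(a$candidates, b$candidates)
})
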