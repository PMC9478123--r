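## editcall: RNA-editing site calling from treated/control pileups.
## Filters: mean base quality >= 20 at load, coverage strictly above 10,
## transition classes {AG, TC, CT, GA}, frequency >= 0.05 and < 1; statistics:
## two-sided Fisher exact test vs the control, Benjamini-Hochberg correction,
## then subtraction of control-significant and known-SNP positions.

#' Load a pileup table
#'
#' TSV with columns `chrom`, `pos` (1-based), `strand`, `ref`, `nA`, `nC`,
#' `nG`, `nT`, `mean_qual`. Rows with mean base quality below `min_qual` are
#' dropped (with a message).
#'
#' @param path TSV file.
#' @param min_qual Mean base-quality floor (default 20).
#' @return data.frame of pileup sites.
#' @export
load_pileup <- function(path, min_qual = 20) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(pileup_cols, names(df))
  if (length(missing)) stop("pileup ", path, " lacks columns: ",
                            paste(missing, collapse = ", "))
  df <- df[pileup_cols]
  num <- c("pos", "nA", "nC", "nG", "nT", "mean_qual")
  for (col in num) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) stop("malformed pileup rows (column ", col, ") at lines: ",
                          paste(bad + 1L, collapse = ", "))
    df[[col]] <- as.numeric(df[[col]])
  }
  if (any(df[c("nA", "nC", "nG", "nT")] < 0)) stop("negative counts in pileup")
  drop <- df$mean_qual < min_qual
  if (any(drop)) {
    message("dropping ", sum(drop), " pileup sites with mean_qual < ", min_qual)
    df <- df[!drop, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Candidate editing sites from a pileup
#'
#' A site is a candidate iff its read support passes the count gate, the
#' dominant non-reference base forms an allowed transition class with the
#' reference (ties broken towards A < C < G < T), the editing frequency
#' `variant / (variant + ref)` is at least `min_freq`, and the frequency is
#' strictly below 1 (all-variant sites are homozygous SNP-like changes, not
#' editing).
#'
#' Two readings of the read-count gate are provided: `count_mode = "coverage"`
#' (default) requires total coverage strictly above `min_cov`;
#' `count_mode = "variant"` requires at least `min_cov` variant reads.
#'
#' @param pileup data.frame from [load_pileup()].
#' @param min_cov Count threshold (default 10).
#' @param min_freq Minimum editing frequency (default 0.05).
#' @param classes Allowed `ref`-`variant` transition classes
#'   (default `c("AG","TC","CT","GA")`).
#' @param count_mode `"coverage"` or `"variant"`, see above.
#' @return data.frame of candidates: pileup columns plus `variant`, `class`,
#'   `n_ref`, `n_var`, `coverage`, `freq`.
#' @export
candidate_sites <- function(pileup, min_cov = 10L, min_freq = 0.05,
                            classes = c("AG", "TC", "CT", "GA"),
                            count_mode = c("coverage", "variant")) {
  count_mode <- match.arg(count_mode)
  counts <- as.matrix(pileup[c("nA", "nC", "nG", "nT")])
  colnames(counts) <- DNA4
  coverage <- rowSums(counts)
  ref <- toupper(pileup$ref)
  n_ref <- counts[cbind(seq_len(nrow(counts)), match(ref, DNA4))]
  nonref <- counts
  nonref[cbind(seq_len(nrow(counts)), match(ref, DNA4))] <- -1L
  variant <- DNA4[max.col(nonref, ties.method = "first")]
  n_var <- nonref[cbind(seq_len(nrow(nonref)), match(variant, DNA4))]
  n_var[n_var < 0] <- 0
  freq <- ifelse(n_var + n_ref > 0, n_var / (n_var + n_ref), 0)
  cls <- paste0(ref, variant)
  count_ok <- if (count_mode == "coverage") coverage > min_cov else n_var >= min_cov
  keep <- count_ok & cls %in% classes & freq >= min_freq & freq < 1
  out <- pileup[keep, , drop = FALSE]
  out$variant <- variant[keep]
  out$class <- cls[keep]
  out$n_ref <- n_ref[keep]
  out$n_var <- n_var[keep]
  out$coverage <- coverage[keep]
  out$freq <- freq[keep]
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher exact p-value for 2x2 variant/reference tables
#'
#' Exact hypergeometric computation, vectorised over tables: the two-sided
#' p-value sums the probabilities of all tables (at fixed margins) whose
#' probability does not exceed the observed table's, with the customary
#' `1 + 1e-7` relative tie buffer (the same definition as
#' [stats::fisher.test()]). Tables sharing margins are grouped so that large
#' batches are cheap.
#'
#' @param v1,r1 Variant and reference counts in the treated sample.
#' @param v2,r2 Variant and reference counts in the control sample.
#' @return Numeric vector of p-values.
#' @export
fisher_exact_p <- function(v1, r1, v2, r2) {
  n <- max(length(v1), length(r1), length(v2), length(r2))
  v1 <- rep_len(as.numeric(v1), n); r1 <- rep_len(as.numeric(r1), n)
  v2 <- rep_len(as.numeric(v2), n); r2 <- rep_len(as.numeric(r2), n)
  if (any(c(v1, r1, v2, r2) < 0)) stop("counts must be non-negative")
  m <- v1 + r1          # treated margin
  nn <- v2 + r2         # control margin
  k <- v1 + v2          # variant margin
  p <- numeric(n)
  key <- paste(m, nn, k)
  for (grp in split(seq_len(n), key)) {
    mi <- m[grp[1L]]; ni <- nn[grp[1L]]; ki <- k[grp[1L]]
    lo <- max(0, ki - ni); hi <- min(ki, mi)
    support <- lo:hi
    d <- stats::dhyper(support, mi, ni, ki)
    ds <- sort(d)
    cs <- cumsum(ds)
    thr <- d[v1[grp] - lo + 1L] * (1 + 1e-7)
    p[grp] <- pmin(1, cs[findInterval(thr, ds)])
  }
  p
}

#' Fisher exact test of candidates against a control pileup
#'
#' Joins candidates to the control by `(chrom, pos)` and computes the
#' two-sided Fisher exact p-value on the 2x2 table
#' `[treated variant, treated ref; control variant, control ref]`, the control
#' variant being the candidate's variant base. Candidates without a control
#' row are assigned zero control counts when `min_control_cov <= 0`, otherwise
#' flagged untestable (`p = NA`). A candidate with identical treated and
#' control composition yields p = 1; a site with no variant reads in either
#' sample yields p = 1 (no enrichment). Note the test is two-sided, so a
#' variant-depleted treated sample can also reach small p; such sites never
#' pass the candidate frequency gate.
#'
#' @param candidates data.frame from [candidate_sites()].
#' @param control Control pileup data.frame ([load_pileup()] output).
#' @param min_control_cov Control coverage floor for assuming zero counts at
#'   coordinates absent from the control (default 0: absent rows count as
#'   zero-coverage controls).
#' @return `candidates` with added columns `c_var`, `c_ref`, `p`, `untestable`.
#' @export
fisher_vs_control <- function(candidates, control, min_control_cov = 0L) {
  if (!nrow(candidates)) {
    candidates$c_var <- numeric(0); candidates$c_ref <- numeric(0)
    candidates$p <- numeric(0); candidates$untestable <- logical(0)
    return(candidates)
  }
  key_t <- paste(candidates$chrom, candidates$pos)
  key_c <- paste(control$chrom, control$pos)
  idx <- match(key_t, key_c)
  ccounts <- as.matrix(control[c("nA", "nC", "nG", "nT")])
  colnames(ccounts) <- DNA4
  c_var <- c_ref <- numeric(nrow(candidates))
  untestable <- logical(nrow(candidates))
  present <- !is.na(idx)
  c_var[present] <- ccounts[cbind(idx[present], match(candidates$variant[present], DNA4))]
  c_ref[present] <- ccounts[cbind(idx[present], match(toupper(candidates$ref[present]), DNA4))]
  if (min_control_cov > 0L) untestable[!present] <- TRUE
  p <- rep(NA_real_, nrow(candidates))
  testable <- !untestable
  p[testable] <- fisher_exact_p(candidates$n_var[testable], candidates$n_ref[testable],
                                c_var[testable], c_ref[testable])
  candidates$c_var <- c_var
  candidates$c_ref <- c_ref
  candidates$p <- p
  candidates$untestable <- untestable
  candidates
}

#' Benjamini-Hochberg correction
#'
#' Step-up adjusted q-values; significance is customarily declared at
#' q < 0.05.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
bh_correct <- function(pvals) {
  stopifnot(length(pvals) >= 1L)
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

#' Remove control-significant and known-SNP positions from calls
#'
#' Positions significant in the empty-vector control are artifacts or SNPs;
#' positions in the SNP database are SNPs. Both are removed with a recorded
#' reason (control checked first).
#'
#' @param calls data.frame of calls with `chrom`, `pos`.
#' @param control_significant data.frame (`chrom`, `pos`) of sites significant
#'   in the control sample, or NULL.
#' @param snp_positions data.frame (`chrom`, `pos`) of known SNPs (e.g. from
#'   [read_snp_positions()]), or NULL.
#' @return List with `calls` (kept) and `removed` (with `reason` in
#'   `{"control", "snp"}`).
#' @export
subtract_control_and_snps <- function(calls, control_significant = NULL,
                                      snp_positions = NULL) {
  key <- paste(calls$chrom, calls$pos)
  reason <- rep(NA_character_, nrow(calls))
  if (!is.null(control_significant) && nrow(control_significant)) {
    reason[key %in% paste(control_significant$chrom, control_significant$pos)] <- "control"
  }
  if (!is.null(snp_positions) && nrow(snp_positions)) {
    hit <- key %in% paste(snp_positions$chrom, snp_positions$pos)
    reason[is.na(reason) & hit] <- "snp"
  }
  removed <- calls[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  kept <- calls[is.na(reason), , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(calls = kept, removed = removed)
}

#' Call RNA-editing sites from treated and control pileups
#'
#' End-to-end caller: candidate filtering on the treated pileup, Fisher exact
#' test against the control, Benjamini-Hochberg correction, significance at
#' `q < alpha`, then subtraction of control-significant and SNP positions.
#' Output row order is canonical (chrom, pos), independent of input order.
#'
#' @param treated,control Pileup data.frames ([load_pileup()] output).
#' @param snp_positions Optional data.frame (`chrom`, `pos`) of known SNPs.
#' @param control_significant Optional data.frame (`chrom`, `pos`) of sites
#'   significant in the empty-vector control.
#' @param alpha Significance level on q (default 0.05).
#' @inheritParams candidate_sites
#' @param min_control_cov See [fisher_vs_control()].
#' @return List with `calls` (significant, filtered calls with `q`),
#'   `removed` (calls dropped by control/SNP subtraction), `candidates`
#'   (all tested candidates with `p` and `q`).
#' @export
call_editing_sites <- function(treated, control, snp_positions = NULL,
                               control_significant = NULL,
                               min_cov = 10L, min_freq = 0.05,
                               classes = c("AG", "TC", "CT", "GA"),
                               count_mode = c("coverage", "variant"),
                               alpha = 0.05, min_control_cov = 0L) {
  count_mode <- match.arg(count_mode)
  cand <- candidate_sites(treated, min_cov = min_cov, min_freq = min_freq,
                          classes = classes, count_mode = count_mode)
  cand <- cand[order(cand$chrom, cand$pos), , drop = FALSE]
  rownames(cand) <- NULL
  cand <- fisher_vs_control(cand, control, min_control_cov = min_control_cov)
  cand$q <- if (nrow(cand)) bh_correct(cand$p) else numeric(0)
  sig <- cand[!is.na(cand$q) & cand$q < alpha, , drop = FALSE]
  sub <- subtract_control_and_snps(sig, control_significant, snp_positions)
  list(calls = sub$calls, removed = sub$removed, candidates = cand)
}

#' Write editing calls as TSV
#' @param calls data.frame of calls.
#' @param path Output TSV.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
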