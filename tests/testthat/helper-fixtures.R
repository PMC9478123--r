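## Shared fixtures, built in code.

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

## bijective synthetic code: one residue pair per nucleotide per motif type
## (TN -> A, NS -> C, TD -> G, ND -> U, one-hot weights)
bijective_code <- function(types = c("P1", "L1", "S1", "P2", "L2", "S2", "E1")) {
  code_table(do.call(rbind, lapply(types, function(t) data.frame(
    motif_type = t,
    aa5 = c("T", "N", "T", "N"),
    aa_last = c("N", "S", "D", "D"),
    wA = c(1, 0, 0, 0), wC = c(0, 1, 0, 0),
    wG = c(0, 0, 1, 0), wU = c(0, 0, 0, 1),
    provenance = "synthetic_bijective", stringsAsFactors = FALSE))))
}

## residue pair of the bijective code preferring a given nucleotide
bijective_pair <- function(nt) {
  switch(nt, A = c("T", "N"), C = c("N", "S"), G = c("T", "D"), U = c("N", "D"))
}

## a designer protein assembled from a generated motif library
make_designer <- function(seed = 5L, name = "KPtest") {
  lib <- gen_motif_library(sim_spec(seed = seed, n_proteins = 3L))
  m <- lib$motifs[lib$motifs$protein_id == "prot0001", ]
  assemble_designer(
    pls = m[m$ordinal <= 9, c("motif_type", "sequence")],
    cterm = m[m$ordinal > 9, c("motif_type", "sequence")],
    dyw = lib$dyw$sequence[1L],
    name = name
  )
}

## a 26-nt target site whose binding window (-15..-3) is `window13`
make_site <- function(window13, direction = "U2C", seed = 1L) {
  set.seed(seed)
  edit <- if (direction == "U2C") "U" else "C"
  target_site(paste0(
    paste(sample(RNA_BASES, 5, replace = TRUE), collapse = ""),
    window13,
    paste(sample(RNA_BASES, 2, replace = TRUE), collapse = ""),
    edit,
    paste(sample(RNA_BASES, 5, replace = TRUE), collapse = "")
  ), direction)
}

## L2/S2/E1 overrides that encode the site's bases at -5, -4, -3 under the
## bijective code (makes the retarget -> predict round trip exact at all 13)
overrides_for <- function(site) {
  list(L2 = bijective_pair(site_base(site, -5)),
       S2 = bijective_pair(site_base(site, -4)),
       E1 = bijective_pair(site_base(site, -3)))
}

## binding model with a one-hot preference for the 13-nt window of `ref16`
## (reference site spanning positions -15..0), built through the public API
model_for_reference <- function(ref16, scaffold = NULL) {
  stopifnot(nchar(ref16) >= 13L)
  if (is.null(scaffold)) scaffold <- make_designer()
  window13 <- substr(chartr("T", "U", toupper(ref16)), 1, 13)
  site <- make_site(window13)
  code <- bijective_code()
  rt <- retarget(scaffold, site, code, overrides_for(site))
  predict_binding(rt, code)
}

random_rna_string <- function(n) {
  paste(sample(RNA_BASES, n, replace = TRUE), collapse = "")
}

## brute-force sliding-window scan oracle: enumerate every window, count
## Hamming mismatches against the model's argmax base sets, require the edit
## base 3 nt downstream of the window
oracle_scan <- function(transcripts, model, max_mm, require_edit_base = "U") {
  allowed <- argmax_bases(model)
  rows <- list()
  for (id in names(transcripts)) {
    s <- chartr("T", "U", toupper(transcripts[[id]]))
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    if (n < 16) next
    for (start in seq_len(n - 15)) {
      mm <- 0L
      for (k in 1:13) {
        if (!chars[start + k - 1] %in% allowed[[k]]) mm <- mm + 1L
      }
      if (mm <= max_mm &&
          (is.na(require_edit_base) || chars[start + 15] == require_edit_base)) {
        rows[[length(rows) + 1L]] <- data.frame(
          transcript = id, offset = start - 1L, mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript = character(), offset = integer(),
               mismatches = integer())
  out <- out[order(out$transcript, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## exact two-sided Fisher p by explicit enumeration with lchoose (independent
## of dhyper); per-table, used on small/random batches
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  pr <- exp(logp)
  obs <- pr[a - lo + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}
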