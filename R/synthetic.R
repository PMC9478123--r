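## synthetic_data: seeded generators for every pipeline input, with
## ground-truth manifests. Each generator re-seeds R's RNG from the spec's
## single integer seed at entry, so every generator is independently
## reproducible from the same SimSpec.

#' Simulation specification
#'
#' Bundles the parameters and the single RNG seed for all synthetic-data
#' generators. Defaults are the package's reference study conditions: 200
#' proteins with a per-column plurality residue probability of 0.6; 20
#' transcripts of 500 nt; a planted trace editing fraction of 0.30 with
#' multiplicative channel noise sd 0.05; pileups at coverage 1000 with
#' per-base sequencing error 0.001 and planted editing frequencies 0.05, 0.1
#' and 0.3 among the four transition classes.
#'
#' @param seed Integer seed; one documented RNG stream per generator.
#' @param n_proteins Number of proteins in the motif library.
#' @param plurality_prob Probability of the planted plurality residue per
#'   motif column (remaining mass spread uniformly over the other residues).
#' @param motif_lengths Named integer vector of motif lengths per type.
#' @param motif_column_dists Optional list motif_type -> 20 x length matrix of
#'   per-column residue probabilities (rows named by [AA20] residues, columns
#'   summing to 1). When NULL, distributions are drawn from `plurality_prob`.
#' @param transcript_lengths Integer vector of transcript lengths (nt).
#' @param planted_sites Optional data.frame `transcript` (index), `offset`
#'   (1-based start of the planted site), `mismatches` (count vs the reference
#'   site).
#' @param trace_edit_fraction Planted %C/(%C+%T) fraction at the edit position,
#'   in `[0, 1]`.
#' @param trace_noise_sd Non-negative sd of the multiplicative (log-normal)
#'   per-channel peak-area noise.
#' @param trace_baseline Baseline area fraction of dark channels
#'   (default 0.01).
#' @param pileup_plan Optional data.frame `pos`, `freq` (in `[0, 1)`),
#'   `coverage`, `class` (one of AG, TC, CT, GA), optional `chrom`.
#' @param error_rate Per-base sequencing error rate, uniform over the three
#'   non-template bases.
#' @param n_background Unedited background positions added to the pileups.
#' @param background_coverage Coverage at background positions.
#' @param genome_length Coordinate space for background positions.
#' @return A validated list of class `sim_spec`.
#' @export
sim_spec <- function(seed,
                     n_proteins = 200L,
                     plurality_prob = 0.6,
                     motif_lengths = c(P1 = 35L, L1 = 35L, S1 = 31L, P2 = 35L,
                                       L2 = 35L, S2 = 31L, E1 = 34L, E2 = 31L),
                     motif_column_dists = NULL,
                     transcript_lengths = rep(500L, 20L),
                     planted_sites = NULL,
                     trace_edit_fraction = 0.30,
                     trace_noise_sd = 0.05,
                     trace_baseline = 0.01,
                     pileup_plan = NULL,
                     error_rate = 0.001,
                     n_background = 200L,
                     background_coverage = 1000L,
                     genome_length = 100000L) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  seed <- as.integer(seed)
  if (trace_edit_fraction < 0 || trace_edit_fraction > 1) {
    stop("trace_edit_fraction must lie in [0, 1]")
  }
  if (trace_noise_sd < 0) stop("trace_noise_sd must be non-negative")
  if (plurality_prob <= 0 || plurality_prob > 1) {
    stop("plurality_prob must lie in (0, 1]")
  }
  if (!is.null(motif_column_dists)) {
    for (t in names(motif_column_dists)) {
      d <- motif_column_dists[[t]]
      if (any(d < 0) || any(abs(colSums(d) - 1) > 1e-8)) {
        stop("validation error: column distributions for ", t,
             " are not normalised probability vectors")
      }
    }
  }
  if (!is.null(pileup_plan)) {
    stopifnot(all(c("pos", "freq", "coverage", "class") %in% names(pileup_plan)))
    if (any(pileup_plan$freq >= 1)) {
      stop("planted frequency 1 is the SNP regime, not editing; ",
           "plan frequencies must lie in [0, 1)")
    }
    if (any(pileup_plan$freq < 0)) stop("plan frequencies must lie in [0, 1)")
    if (any(pileup_plan$coverage < 0)) stop("coverage must be >= 0")
    bad <- setdiff(unique(pileup_plan$class), c("AG", "TC", "CT", "GA"))
    if (length(bad)) stop("substitution classes outside {AG,TC,CT,GA}: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(
    seed = seed, n_proteins = as.integer(n_proteins),
    plurality_prob = plurality_prob, motif_lengths = motif_lengths,
    motif_column_dists = motif_column_dists,
    transcript_lengths = as.integer(transcript_lengths),
    planted_sites = planted_sites,
    trace_edit_fraction = trace_edit_fraction,
    trace_noise_sd = trace_noise_sd, trace_baseline = trace_baseline,
    pileup_plan = pileup_plan, error_rate = error_rate,
    n_background = as.integer(n_background),
    background_coverage = as.integer(background_coverage),
    genome_length = as.integer(genome_length)
  ), class = "sim_spec")
}

## per-type column distributions: plurality_prob on a randomly drawn consensus
## residue, the remainder uniform over the other 19
draw_column_dists <- function(spec) {
  lapply(spec$motif_lengths, function(len) {
    cons <- sample(AA20, len, replace = TRUE)
    d <- matrix((1 - spec$plurality_prob) / (length(AA20) - 1L),
                nrow = length(AA20), ncol = len, dimnames = list(AA20, NULL))
    d[cbind(match(cons, AA20), seq_len(len))] <- spec$plurality_prob
    d
  })
}

#' Generate a motif library with a planted consensus
#'
#' Emits, per protein, a canonical (P1L1S1)x3-P2L2S2-E1E2 motif array whose
#' motif sequences are drawn column-wise from per-type residue distributions,
#' plus a DYW domain carrying the deaminase signature. The true consensus per
#' motif type is the per-column argmax of the generating distribution.
#'
#' @param spec A [sim_spec()].
#' @return List with `motifs` (motif table data.frame), `consensus` (named
#'   character, true consensus per motif type), `dyw` (data.frame
#'   `protein_id`, `sequence`, `unannotated_upstream`) and `column_dists`.
#' @export
gen_motif_library <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  dists <- spec$motif_column_dists
  if (is.null(dists)) {
    dists <- draw_column_dists(spec)
  } else {
    for (t in names(dists)) {
      if (any(abs(colSums(dists[[t]]) - 1) > 1e-8)) {
        stop("validation error: column distributions for ", t, " not normalised")
      }
    }
  }
  types <- designer_motif_order
  missing <- setdiff(unique(types), names(dists))
  if (length(missing)) stop("no column distributions for motif types: ",
                            paste(missing, collapse = ", "))
  true_consensus <- vapply(dists, function(d)
    paste(rownames(d)[apply(d, 2L, which.max)], collapse = ""), "")
  n <- spec$n_proteins
  ## draw all instances of each array slot at once, column-wise
  slot_seqs <- lapply(types, function(t) {
    d <- dists[[t]]
    cols <- vapply(seq_len(ncol(d)), function(j)
      sample(rownames(d), n, replace = TRUE, prob = d[, j]), character(n))
    if (n == 1L) cols <- matrix(cols, nrow = 1L)
    apply(cols, 1L, paste, collapse = "")
  })
  protein_id <- sprintf("prot%04d", seq_len(n))
  rows <- lapply(seq_along(types), function(k) data.frame(
    protein_id = protein_id, ordinal = k, motif_type = types[k],
    sequence = slot_seqs[[k]], stringsAsFactors = FALSE))
  motifs <- do.call(rbind, rows)
  motifs <- motifs[order(motifs$protein_id, motifs$ordinal), ]
  lens <- nchar(motifs$sequence)
  ends <- stats::ave(lens, motifs$protein_id, FUN = cumsum)
  motifs$start <- as.integer(ends - lens + 1L)
  motifs$end <- as.integer(ends)
  motifs <- motifs[motif_table_cols]
  rownames(motifs) <- NULL
  ## DYW domains with a planted HxE(x)CxxC signature, 136 aa
  dyw_seq <- vapply(seq_len(n), function(i) {
    body <- sample(setdiff(AA20, c("H", "C")), 136L, replace = TRUE)
    body[40:42] <- c("H", "A", "E")
    body[c(73, 76)] <- "C"
    paste(body, collapse = "")
  }, "")
  dyw <- data.frame(protein_id = protein_id, sequence = dyw_seq,
                    unannotated_upstream = 0L, stringsAsFactors = FALSE)
  list(motifs = motifs, consensus = true_consensus, dyw = dyw,
       column_dists = dists)
}

random_rna <- function(n) paste(sample(RNA4, n, replace = TRUE), collapse = "")

## mismatch counts of every 13-nt window of s against ref13, plus the base at
## site position 0 (window start + 15); used for background scrubbing and as
## the planting post-condition check
window_mismatches <- function(s, ref13) {
  n <- nchar(s)
  if (n < 16L) return(data.frame(start = integer(), mm = integer(),
                                 edit_base = character()))
  starts <- seq_len(n - 15L)
  ref <- seq_chars(ref13)
  mm <- integer(length(starts))
  for (k in seq_len(13L)) {
    mm <- mm + (substring(s, starts + k - 1L, starts + k - 1L) != ref[k])
  }
  data.frame(start = starts, mm = mm,
             edit_base = substring(s, starts + 15L, starts + 15L),
             stringsAsFactors = FALSE)
}

#' Generate a transcriptome with planted binding sites
#'
#' Transcripts are uniform random RNA of the specified lengths. Each planted
#' site is a copy of `reference_site` altered at exactly the requested number
#' of positions (chosen within the 13-nt binding window; the edited base is
#' never touched). When sites are planted, the random background is scrubbed
#' of incidental near-matches (within `protect_mm` mismatches and carrying the
#' edit base), so the returned manifest is the complete hit set at
#' `max_mm <= protect_mm`; without planted sites the background is left as
#' drawn.
#'
#' @param spec A [sim_spec()] (fields `transcript_lengths`, `planted_sites`).
#' @param reference_site The reference binding site: a 16-nt RNA string
#'   spanning site positions -15..0 (last base = edited base), or any
#'   sequence of length >= 1 when scanning semantics are not needed.
#' @param protect_mm Background scrub radius (default 4).
#' @return List with `transcripts` (named character), `manifest` (data.frame
#'   `transcript`, `offset` 0-based, `mismatches`, `site`) and
#'   `reference_site`.
#' @export
gen_transcriptome <- function(spec, reference_site, protect_mm = 4L) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  ref <- as_rna(reference_site)
  L <- nchar(ref)
  stopifnot(L >= 1L)
  lens <- spec$transcript_lengths
  ids <- sprintf("tx%03d", seq_along(lens))
  plant <- spec$planted_sites
  scrub <- !is.null(plant) && nrow(plant) > 0L && L == 16L
  if (!is.null(plant) && nrow(plant)) {
    stopifnot(all(c("transcript", "offset", "mismatches") %in% names(plant)))
    if (any(plant$mismatches > L)) stop("mismatch count exceeds site length")
    if (any(plant$mismatches < 0)) stop("negative mismatch count")
    if (any(plant$transcript < 1L | plant$transcript > length(lens))) {
      stop("planted transcript index out of range")
    }
    if (any(plant$offset < 1L | plant$offset + L - 1L > lens[plant$transcript])) {
      stop("planted offset out of range for its transcript")
    }
    for (tx in unique(plant$transcript)) {
      off <- sort(plant$offset[plant$transcript == tx])
      if (length(off) > 1L && any(diff(off) < L + 15L)) {
        stop("planted sites too close together on transcript ", tx)
      }
    }
  }
  mutable <- seq_len(min(13L, L))
  transcripts <- character(length(lens))
  manifest <- list()
  for (i in seq_along(lens)) {
    rows <- if (!is.null(plant) && nrow(plant)) {
      plant[plant$transcript == i, , drop = FALSE]
    } else NULL
    for (try in seq_len(100L)) {
      s <- random_rna(lens[i])
      ## plant the requested sites
      planted_here <- list()
      ok <- TRUE
      if (!is.null(rows) && nrow(rows)) {
        for (r in seq_len(nrow(rows))) {
          site <- seq_chars(ref)
          mm <- rows$mismatches[r]
          if (mm > 0L) {
            at <- sample(mutable, mm)
            for (p in at) site[p] <- sample(setdiff(RNA4, site[p]), 1L)
          }
          site <- paste(site, collapse = "")
          substr(s, rows$offset[r], rows$offset[r] + L - 1L) <- site
          planted_here[[r]] <- data.frame(
            transcript = ids[i], offset = rows$offset[r] - 1L,
            mismatches = mm, site = site, stringsAsFactors = FALSE)
        }
      }
      if (scrub) {
        wm <- window_mismatches(s, substr(ref, 1L, 13L))
        hits <- wm$start[wm$mm <= protect_mm & wm$edit_base == substr(ref, 16L, 16L)]
        extra <- setdiff(hits, rows$offset)
        ok <- length(extra) == 0L
      }
      if (ok) break
    }
    if (!ok) stop("could not scrub background near-matches on transcript ", ids[i])
    transcripts[i] <- s
    manifest <- c(manifest, planted_here)
  }
  names(transcripts) <- ids
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(transcript = character(), offset = integer(),
               mismatches = integer(), site = character())
  ## post-condition: each planted locus differs from the reference at exactly
  ## the requested number of positions
  if (nrow(manifest)) {
    got <- mapply(function(tx, off) {
      w <- substr(transcripts[[tx]], off + 1L, off + L)
      sum(seq_chars(w) != seq_chars(ref))
    }, manifest$transcript, manifest$offset)
    stopifnot(identical(as.integer(got), as.integer(manifest$mismatches)))
  }
  list(transcripts = transcripts, manifest = manifest, reference_site = ref)
}

#' Generate a Sanger trace with a planted editing fraction
#'
#' Peak-area-level trace model: at every position the called channel carries
#' the signal and the dark channels a small baseline fraction; at the edit
#' position the C and T channels split the signal so that the edited-base
#' channel receives `trace_edit_fraction` of the C+T signal (C for U-to-C at a
#' T position, T for C-to-U at a C position). Every channel area is multiplied
#' by independent log-normal noise `exp(N(0, trace_noise_sd))`.
#'
#' @param spec A [sim_spec()] (`trace_edit_fraction`, `trace_noise_sd`,
#'   `trace_baseline`).
#' @param context Nucleotide sequence of the read (RNA or DNA; stored as DNA
#'   base calls).
#' @param edit_position 1-based position of the editing site in `context`;
#'   must index a T (U-to-C) or C (C-to-U).
#' @return A `sanger_trace` with attribute `truth` (list `edit_index`,
#'   `fraction`, `direction`).
#' @export
gen_trace <- function(spec, context, edit_position) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  ctx <- seq_chars(as_dna(context))
  n <- length(ctx)
  stopifnot(edit_position >= 1L, edit_position <= n)
  base <- ctx[edit_position]
  if (!base %in% c("T", "C")) {
    stop("edit position must index a T (U-to-C) or C (C-to-U), found ", base)
  }
  direction <- if (base == "T") "U2C" else "C2U"
  f <- spec$trace_edit_fraction
  b <- spec$trace_baseline
  scale <- 1000
  frac <- matrix(b, nrow = n, ncol = 4L, dimnames = list(NULL, DNA4))
  frac[cbind(seq_len(n), match(ctx, DNA4))] <- 1 - 3 * b
  signal <- 1 - 2 * b
  edited_channel <- if (direction == "U2C") "C" else "T"
  other_channel <- if (direction == "U2C") "T" else "C"
  frac[edit_position, ] <- b
  frac[edit_position, edited_channel] <- f * signal
  frac[edit_position, other_channel] <- (1 - f) * signal
  noise <- matrix(exp(stats::rnorm(n * 4L, 0, spec$trace_noise_sd)),
                  nrow = n, ncol = 4L)
  areas <- frac * scale * noise
  calls <- DNA4[max.col(areas, ties.method = "first")]
  df <- data.frame(position = seq_len(n), base_call = calls,
                   area_A = areas[, "A"], area_C = areas[, "C"],
                   area_G = areas[, "G"], area_T = areas[, "T"],
                   stringsAsFactors = FALSE)
  tr <- sanger_trace(df, sample_id = sprintf("sim_seed%d", spec$seed))
  attr(tr, "truth") <- list(edit_index = as.integer(edit_position),
                            fraction = f, direction = direction)
  tr
}

## apply per-base sequencing error to a vector of true base counts: each read
## keeps its base with prob 1 - e, otherwise becomes one of the three other
## bases uniformly
apply_seq_error <- function(true_counts, error_rate) {
  out <- stats::setNames(numeric(4L), DNA4)
  for (bse in DNA4) {
    c0 <- true_counts[[bse]]
    if (is.na(c0) || c0 <= 0) next
    probs <- rep(error_rate / 3, 4L)
    probs[match(bse, DNA4)] <- 1 - error_rate
    out <- out + drop(stats::rmultinom(1L, c0, probs))
  }
  out
}

#' Generate treated and control pileups with planted editing
#'
#' At each planted position the treated sample draws the number of edited
#' reads from a binomial at the planned frequency; every read is then subject
#' to a uniform per-base sequencing error over the three non-template bases.
#' The control sample carries reference reads plus errors only, as do the
#' background positions added to both samples.
#'
#' @param spec A [sim_spec()] (fields `pileup_plan`, `error_rate`,
#'   `n_background`, `background_coverage`, `genome_length`).
#' @return List with `treated` and `control` pileup data.frames and `truth`
#'   (data.frame `chrom`, `pos`, `ref`, `variant`, `class`, `true_freq`,
#'   `obs_freq` - the realised variant frequency in the treated pileup).
#' @export
gen_pileups <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  plan <- spec$pileup_plan
  if (is.null(plan)) {
    plan <- data.frame(pos = integer(), freq = numeric(),
                       coverage = integer(), class = character())
  }
  if (is.null(plan$chrom)) plan$chrom <- rep("tx1", nrow(plan))
  e <- spec$error_rate
  n_bg <- spec$n_background
  bg_pos <- if (n_bg > 0L) {
    sample(setdiff(seq_len(spec$genome_length), plan$pos), n_bg)
  } else integer(0)
  bg_ref <- sample(DNA4, n_bg, replace = TRUE)
  mk_row <- function(chrom, pos, ref, counts) {
    data.frame(chrom = chrom, pos = pos, strand = "+", ref = ref,
               nA = counts[["A"]], nC = counts[["C"]],
               nG = counts[["G"]], nT = counts[["T"]],
               mean_qual = round(stats::runif(1L, 30, 40), 1L),
               stringsAsFactors = FALSE)
  }
  treated <- list(); control <- list(); truth <- list()
  for (r in seq_len(nrow(plan))) {
    ref <- substr(plan$class[r], 1L, 1L)
    var <- substr(plan$class[r], 2L, 2L)
    cov <- plan$coverage[r]
    n_edit <- stats::rbinom(1L, cov, plan$freq[r])
    true_t <- stats::setNames(numeric(4L), DNA4)
    true_t[ref] <- cov - n_edit
    true_t[var] <- true_t[var] + n_edit
    obs_t <- apply_seq_error(true_t, e)
    true_c <- stats::setNames(numeric(4L), DNA4)
    true_c[ref] <- cov
    obs_c <- apply_seq_error(true_c, e)
    treated[[r]] <- mk_row(plan$chrom[r], plan$pos[r], ref, obs_t)
    control[[r]] <- mk_row(plan$chrom[r], plan$pos[r], ref, obs_c)
    truth[[r]] <- data.frame(
      chrom = plan$chrom[r], pos = plan$pos[r], ref = ref, variant = var,
      class = plan$class[r], true_freq = plan$freq[r],
      obs_freq = obs_t[[var]] / (obs_t[[var]] + obs_t[[ref]]),
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_bg)) {
    true_b <- stats::setNames(numeric(4L), DNA4)
    true_b[bg_ref[j]] <- spec$background_coverage
    treated[[nrow(plan) + j]] <- mk_row("tx1", bg_pos[j], bg_ref[j],
                                        apply_seq_error(true_b, e))
    control[[nrow(plan) + j]] <- mk_row("tx1", bg_pos[j], bg_ref[j],
                                        apply_seq_error(true_b, e))
  }
  bind <- function(x) {
    df <- if (length(x)) do.call(rbind, x) else
      utils::read.table(text = "", col.names = pileup_cols)
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               variant = character(), class = character(),
               true_freq = numeric(), obs_freq = numeric())
  rownames(truth) <- NULL
  list(treated = bind(treated), control = bind(control), truth = truth)
}
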