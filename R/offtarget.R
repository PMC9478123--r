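## offtarget: mismatch-tolerant transcriptome scanning, position frequency
## matrices (sequence logos) and neighbouring-nucleotide preference tables.

#' Scan transcripts for near-matches to a binding site
#'
#' Slides a 13-nt window (site positions -15..-3) over the sense strand of
#' every transcript. A window is reported when the base three nucleotides
#' downstream of its end (site position 0) equals `require_edit_base` and the
#' mismatch count against the binding model's preferred bases is at most
#' `max_mm`. Windows whose position-0 base would fall beyond the transcript
#' end are excluded; no window spans record boundaries.
#'
#' The comparison is a mismatch count against the model's argmax bases (the
#' on-target site under a programmed model), not a weighted PWM score.
#'
#' @param transcripts Named character vector of transcript sequences (RNA or
#'   DNA; transcribed on read), or a FASTA path.
#' @param model A `binding_model` from [predict_binding()].
#' @param max_mm Maximum mismatches (default 3, i.e. "fewer than four").
#' @param require_edit_base Base required at site position 0 (default `"U"`;
#'   `NA` disables the check).
#' @return data.frame with columns `transcript`, `offset` (0-based start of
#'   the half-open window), `mismatches`, `mismatch_positions`
#'   (comma-separated site coordinates), `window` (13 nt), `edit_base`.
#' @export
scan_transcripts <- function(transcripts, model, max_mm = 3L,
                             require_edit_base = "U") {
  stopifnot(inherits(model, "binding_model"), max_mm >= 0L)
  if (is.character(transcripts) && length(transcripts) == 1L &&
      is.null(names(transcripts)) && file.exists(transcripts)) {
    transcripts <- read_fasta_seqs(transcripts, alphabet = "rna")
  }
  if (!length(transcripts)) {
    return(data.frame(transcript = character(), offset = integer(),
                      mismatches = integer(), mismatch_positions = character(),
                      window = character(), edit_base = character()))
  }
  stopifnot(!is.null(names(transcripts)))
  allowed <- argmax_bases(model)
  out <- lapply(names(transcripts), function(id) {
    s <- as_rna(transcripts[[id]])
    n <- nchar(s)
    if (n < 16L) return(NULL)
    starts <- seq_len(n - 15L)  # 1-based window starts with room for position 0
    mism <- integer(length(starts))
    mmpos <- matrix(FALSE, nrow = length(starts), ncol = 13L)
    for (k in seq_len(13L)) {
      b <- substring(s, starts + k - 1L, starts + k - 1L)
      bad <- !(b %in% allowed[[k]])
      mmpos[, k] <- bad
      mism <- mism + bad
    }
    edit <- substring(s, starts + 15L, starts + 15L)
    keep <- mism <= max_mm
    if (!is.na(require_edit_base)) keep <- keep & edit == as_rna(require_edit_base)
    if (!any(keep)) return(NULL)
    idx <- which(keep)
    data.frame(
      transcript = id,
      offset = starts[idx] - 1L,
      mismatches = mism[idx],
      mismatch_positions = vapply(idx, function(i)
        paste(model$positions[mmpos[i, ]], collapse = ","), ""),
      window = substring(s, starts[idx], starts[idx] + 12L),
      edit_base = edit[idx],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(transcript = character(), offset = integer(),
                      mismatches = integer(), mismatch_positions = character(),
                      window = character(), edit_base = character())
  }
  ## canonical order, independent of input transcript order
  out <- out[order(out$transcript, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Position frequency matrix from aligned site contexts
#'
#' Empirical per-column nucleotide frequencies over a set of equally long
#' windows aligned on the edited base, the numeric content of a sequence logo.
#'
#' @param contexts Character vector of aligned windows (RNA or DNA).
#' @param positions Integer positions labelling the columns; default -16..+5
#'   style centring with position 0 at column `zero_col`.
#' @param zero_col Column index of the edited base used to derive default
#'   positions (default 17, i.e. a -16..+5 window for 22-nt contexts).
#' @return A 4 x width matrix (rows A, C, G, U; columns sum to 1) of class
#'   `frequency_matrix`, with attributes `positions` and `n_sites`.
#' @export
build_logo <- function(contexts, positions = NULL, zero_col = 17L) {
  stopifnot(length(contexts) >= 1L)
  contexts <- as_rna(contexts)
  w <- unique(nchar(contexts))
  if (length(w) != 1L) {
    stop("ragged contexts: widths ", paste(w, collapse = ", "))
  }
  if (is.null(positions)) positions <- seq_len(w) - zero_col
  stopifnot(length(positions) == w)
  mat <- matrix(unlist(strsplit(contexts, "", fixed = TRUE)),
                nrow = length(contexts), ncol = w, byrow = TRUE)
  freq <- vapply(seq_len(w), function(j) {
    tab <- tabulate(factor(mat[, j], levels = RNA4), nbins = 4L)
    tab / sum(tab)
  }, numeric(4L))
  dimnames(freq) <- list(RNA4, positions)
  structure(freq, positions = as.integer(positions),
            n_sites = length(contexts), class = "frequency_matrix")
}

#' Write a frequency matrix as TSV
#' @param fm A `frequency_matrix`.
#' @param path Output TSV (columns: position, A, C, G, U).
#' @export
write_frequency_matrix <- function(fm, path) {
  df <- data.frame(position = attr(fm, "positions"), t(unclass(fm)))
  names(df) <- c("position", RNA4)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compact letter display from pairwise adjusted p-values
#'
#' Assigns letters to groups so that two groups share a letter iff their
#' pairwise adjusted p-value is >= `alpha` (insert-and-absorb algorithm with
#' deterministic group order: letters are assigned to letter-classes sorted by
#' their first member in input order).
#'
#' @param pmat Symmetric numeric matrix of pairwise adjusted p-values with
#'   group names on both dimnames (diagonal ignored).
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letter strings per group.
#' @export
compact_letter_display <- function(pmat, alpha = 0.05) {
  groups <- rownames(pmat)
  stopifnot(!is.null(groups), identical(groups, colnames(pmat)))
  cols <- list(groups)  # start: all groups share one letter
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i) next
      if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
      gi <- groups[i]; gj <- groups[j]
      new_cols <- list()
      for (col in cols) {
        if (gi %in% col && gj %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, gi)), list(setdiff(col, gj)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      ## absorb: drop columns that are subsets of another column
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[a] && keep[b] &&
              all(new_cols[[a]] %in% new_cols[[b]]) &&
              !(all(new_cols[[b]] %in% new_cols[[a]]) && a < b)) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- unique(new_cols[keep])
      cols <- cols[vapply(cols, length, 0L) > 0L]
    }
  }
  ord <- order(vapply(cols, function(col) min(match(col, groups)), 0L))
  cols <- cols[ord]
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (k in seq_along(cols)) {
    for (g in cols[[k]]) {
      letters_out[g] <- paste0(letters_out[g], letters[k])
    }
  }
  letters_out
}

#' Nucleotide preference around the editing site
#'
#' For each position, runs a one-way ANOVA of editing efficiency across the
#' nucleotide groups followed by Tukey's HSD pairwise comparisons at `alpha`,
#' converted to a compact letter display (groups sharing a letter are not
#' significantly different). Groups with fewer than `min_replicates`
#' measurements are excluded with a warning. When the within-group variance is
#' (numerically) zero the pairwise p-value degenerates to 0 for groups with
#' different means and 1 otherwise.
#'
#' @param measurements data.frame with columns `position`, `nucleotide`,
#'   `replicate`, `efficiency`.
#' @param alpha Significance level (default 0.05).
#' @param min_replicates Minimum replicates per group (default 2).
#' @return data.frame of class `preference_table`: `position`, `nucleotide`,
#'   `mean`, `sd`, `n`, `letters`, plus a `values` attribute holding the
#'   per-replicate measurements.
#' @export
neighbor_preference <- function(measurements, alpha = 0.05, min_replicates = 2L) {
  need <- c("position", "nucleotide", "replicate", "efficiency")
  missing <- setdiff(need, names(measurements))
  if (length(missing)) stop("measurements lack columns: ", paste(missing, collapse = ", "))
  out <- list()
  for (pos in sort(unique(measurements$position))) {
    d <- measurements[measurements$position == pos, , drop = FALSE]
    counts <- table(d$nucleotide)
    small <- names(counts)[counts < min_replicates]
    if (length(small)) {
      warning("position ", pos, ": excluding groups with < ", min_replicates,
              " replicates: ", paste(small, collapse = ", "))
      d <- d[!d$nucleotide %in% small, , drop = FALSE]
    }
    if (!nrow(d)) next
    groups <- sort(unique(d$nucleotide))
    means <- vapply(groups, function(g) mean(d$efficiency[d$nucleotide == g]), 0)
    sds <- vapply(groups, function(g) stats::sd(d$efficiency[d$nucleotide == g]), 0)
    ns <- vapply(groups, function(g) sum(d$nucleotide == g), 0L)
    if (length(groups) >= 2L) {
      pmat <- tukey_pairwise_p(d$efficiency, d$nucleotide)
      letts <- compact_letter_display(pmat, alpha = alpha)
    } else {
      letts <- stats::setNames("a", groups)
    }
    out[[length(out) + 1L]] <- data.frame(
      position = pos, nucleotide = groups, mean = unname(means),
      sd = unname(sds), n = unname(ns), letters = unname(letts[groups]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(position = integer(), nucleotide = character(),
                      mean = numeric(), sd = numeric(), n = integer(),
                      letters = character())
  }
  rownames(res) <- NULL
  attr(res, "values") <- measurements
  class(res) <- c("preference_table", "data.frame")
  res
}

## Tukey HSD adjusted p-values as a symmetric matrix; degenerates gracefully
## when the residual variance is numerically zero.
tukey_pairwise_p <- function(y, g) {
  g <- factor(g)
  groups <- levels(g)
  k <- length(groups)
  pmat <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  fit <- stats::aov(y ~ g)
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  means <- tapply(y, g, mean)
  scale_y <- max(abs(y), 1)
  if (!is.finite(mse) || mse < (1e-10 * scale_y)^2) {
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      p <- if (abs(means[a] - means[b]) <= 1e-9 * scale_y) 1 else 0
      pmat[a, b] <- pmat[b, a] <- p
    }
    return(pmat)
  }
  tk <- stats::TukeyHSD(fit)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (r in seq_len(nrow(tk))) {
    a <- pairs[[r]][1L]; b <- pairs[[r]][2L]
    pmat[a, b] <- pmat[b, a] <- tk[r, "p adj"]
  }
  pmat
}
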