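## chromatogram_quant: editing-efficiency quantification from four-channel
## Sanger peak areas, EditR-style: percent areas, empirical noise zeroing at
## p < 0.01, and the %C/(%C+%T) editing ratio.

#' Construct a Sanger trace object
#'
#' @param df data.frame with columns `position`, `base_call`, `area_A`,
#'   `area_C`, `area_G`, `area_T` (one row per called position).
#' @param sample_id Sample label.
#' @return data.frame of class `sanger_trace` with a `sample_id` attribute.
#' @export
sanger_trace <- function(df, sample_id = "sample") {
  missing <- setdiff(trace_cols, names(df))
  if (length(missing)) stop("trace lacks columns: ", paste(missing, collapse = ", "))
  areas <- as.matrix(df[c("area_A", "area_C", "area_G", "area_T")])
  if (any(areas < 0)) stop("peak areas must be non-negative")
  if (any(rowSums(areas) <= 0)) stop("every position needs at least one positive area")
  if (any(!df$base_call %in% c(DNA4, "N"))) {
    stop("base calls must be A/C/G/T/N")
  }
  df <- df[trace_cols]
  attr(df, "sample_id") <- sample_id
  class(df) <- c("sanger_trace", "data.frame")
  df
}

#' Percent peak areas per position
#'
#' Each channel's area divided by the position's total area, times 100.
#'
#' @param trace A `sanger_trace`.
#' @return Numeric matrix (positions x channels A, C, G, T), rows summing
#'   to 100.
#' @export
percent_areas <- function(trace) {
  areas <- as.matrix(as.data.frame(trace)[c("area_A", "area_C", "area_G", "area_T")])
  colnames(areas) <- DNA4
  100 * areas / rowSums(areas)
}

#' Locate the editing site within a trace
#'
#' Anchors the edit position of an amplicon inside the trace's base calls with
#' an exact-match search over a >= 15-nt anchor centred on the edit; if no
#' exact match exists, a single mismatch is tolerated (one base-call error).
#' More than one match at the accepted tolerance is an ambiguity error.
#'
#' @param trace A `sanger_trace`.
#' @param amplicon Nucleotide string containing the editing site (RNA or DNA).
#' @param edit_offset 1-based position of the edited base within `amplicon`.
#' @param anchor_width Anchor length (default 15).
#' @return 1-based trace row index aligned to the edited base.
#' @export
locate_edit_position <- function(trace, amplicon, edit_offset, anchor_width = 15L) {
  stopifnot(anchor_width >= 15L)
  amplicon <- as_dna(amplicon)
  n_amp <- nchar(amplicon)
  stopifnot(edit_offset >= 1L, edit_offset <= n_amp)
  half <- (anchor_width - 1L) %/% 2L
  a_start <- min(max(1L, edit_offset - half), n_amp - anchor_width + 1L)
  if (a_start < 1L) stop("amplicon too short for a ", anchor_width, "-nt anchor")
  anchor <- seq_chars(substr(amplicon, a_start, a_start + anchor_width - 1L))
  calls <- as.data.frame(trace)$base_call
  n <- length(calls)
  if (n < anchor_width) stop("trace shorter than the anchor")
  starts <- seq_len(n - anchor_width + 1L)
  mm <- integer(length(starts))
  for (k in seq_len(anchor_width)) {
    mm <- mm + (calls[starts + k - 1L] != anchor[k])
  }
  hits <- starts[mm == 0L]
  if (!length(hits)) hits <- starts[mm == 1L]
  if (!length(hits)) stop("anchor not found in trace (within 1 mismatch)")
  if (length(hits) > 1L) stop("ambiguous anchor: ", length(hits), " matches")
  hits + (edit_offset - a_start)
}

#' Percent areas with empirical noise zeroing
#'
#' Computes the four percent areas at a trace position and zeroes every
#' channel whose percent area is not significantly above the background noise:
#' for each channel, the background is the empirical distribution of that
#' channel's percent areas over the flanking window restricted to positions
#' where the channel is not the called base, trimmed of its largest `trim`
#' fraction; the channel is zeroed when the one-sided empirical p-value
#' `mean(background >= observed)` is `>= p_cutoff`. Channels with fewer than
#' `min_background` per-channel background values fall back to the pooled
#' non-call background of all channels. Surviving percents are not
#' renormalised.
#'
#' @param trace A `sanger_trace`.
#' @param index 1-based trace row of the editing site.
#' @param flank Flanking positions required (and used) on each side
#'   (default 10).
#' @param p_cutoff Zeroing cutoff (default 0.01).
#' @param trim Fraction of largest background values trimmed (default 0.05).
#' @param min_background Minimum per-channel background size before the pooled
#'   fallback (default 5).
#' @return A list of class `editing_measurement`: `sample_id`, `index`,
#'   `position`, `base_call`, `pct_raw`, `pct` (after zeroing), `p_values`,
#'   `zeroed`, `flags`, and `ratio`/`direction` slots (NA until
#'   [editing_ratio()]).
#' @export
percent_areas_with_noise_zeroing <- function(trace, index, flank = 10L,
                                             p_cutoff = 0.01, trim = 0.05,
                                             min_background = 5L) {
  df <- as.data.frame(trace)
  n <- nrow(df)
  stopifnot(index >= 1L, index <= n)
  if (index - flank < 1L || index + flank > n) {
    stop("insufficient flank: need ", flank, " positions on each side of ", index)
  }
  pct <- percent_areas(trace)
  win <- setdiff((index - flank):(index + flank), index)
  calls <- df$base_call[win]
  obs <- pct[index, ]
  pvals <- stats::setNames(numeric(4L), DNA4)
  flags <- character(0)
  trim_bg <- function(bg) {
    drop <- floor(length(bg) * trim)
    if (drop > 0L) bg <- sort(bg)[seq_len(length(bg) - drop)]
    bg
  }
  pooled <- unlist(lapply(DNA4, function(ch) pct[win, ch][calls != ch]))
  pooled <- trim_bg(pooled)
  for (ch in DNA4) {
    bg <- pct[win, ch][calls != ch]
    if (length(bg) < min_background) {
      bg <- pooled
      flags <- c(flags, paste0("pooled_background_", ch))
    } else {
      bg <- trim_bg(bg)
    }
    pvals[ch] <- mean(bg >= obs[ch])
  }
  zeroed <- pvals >= p_cutoff
  out <- obs
  out[zeroed] <- 0
  if (all(zeroed)) flags <- c(flags, "all_channels_zeroed")
  structure(list(
    sample_id = attr(trace, "sample_id"),
    index = index,
    position = df$position[index],
    base_call = df$base_call[index],
    pct_raw = obs,
    pct = out,
    p_values = pvals,
    zeroed = zeroed,
    flags = flags,
    direction = NA_character_,
    ratio = NA_real_
  ), class = "editing_measurement")
}

#' Editing ratio from a measurement
#'
#' U-to-C ratio: `pctC / (pctC + pctT)` after zeroing; C-to-U:
#' `pctT / (pctC + pctT)`. Undefined (NA, with flag) when both channels were
#' zeroed.
#'
#' @param measurement An `editing_measurement`.
#' @param direction `"U2C"` or `"C2U"`.
#' @return The numeric ratio in `[0, 1]`, or `NA` when undefined. The updated
#'   measurement is attached as attribute `measurement`.
#' @export
editing_ratio <- function(measurement, direction = c("U2C", "C2U")) {
  stopifnot(inherits(measurement, "editing_measurement"))
  direction <- match.arg(direction)
  den <- measurement$pct[["C"]] + measurement$pct[["T"]]
  if (den <= 0) {
    measurement$flags <- union(measurement$flags, "ratio_undefined")
    measurement$direction <- direction
    measurement$ratio <- NA_real_
  } else {
    r <- measurement$pct[["C"]] / den
    measurement$ratio <- if (direction == "U2C") r else 1 - r
    measurement$direction <- direction
  }
  structure(measurement$ratio, measurement = measurement)
}

#' Quantify editing at a known site in a trace
#'
#' Convenience wrapper: noise-zeroed percent areas at `index`, then the
#' editing ratio.
#'
#' @inheritParams percent_areas_with_noise_zeroing
#' @inheritParams editing_ratio
#' @return An `editing_measurement` with `ratio` and `direction` filled in.
#' @export
quantify_editing <- function(trace, index, direction = c("U2C", "C2U"),
                             flank = 10L, p_cutoff = 0.01, trim = 0.05) {
  direction <- match.arg(direction)
  m <- percent_areas_with_noise_zeroing(trace, index, flank = flank,
                                        p_cutoff = p_cutoff, trim = trim)
  r <- editing_ratio(m, direction)
  attr(r, "measurement")
}

#' Summarise replicate editing measurements
#'
#' Arithmetic mean and sample standard deviation (n - 1) with the per-replicate
#' values preserved. A single replicate reports sd 0 with the
#' `single_replicate` flag.
#'
#' @param measurements Numeric vector of ratios, or a list of
#'   `editing_measurement`s.
#' @return List with `mean`, `sd`, `n`, `values`, `flags`.
#' @export
summarize_replicates <- function(measurements) {
  if (is.list(measurements) && all(vapply(measurements, inherits, TRUE,
                                          "editing_measurement"))) {
    values <- vapply(measurements, function(m) m$ratio, numeric(1))
  } else {
    values <- as.numeric(measurements)
  }
  stopifnot(length(values) >= 1L)
  flags <- character(0)
  if (anyNA(values)) flags <- c(flags, "na_replicates_dropped")
  vals <- values[!is.na(values)]
  if (!length(vals)) {
    return(list(mean = NA_real_, sd = NA_real_, n = 0L, values = values,
                flags = c(flags, "no_defined_replicates")))
  }
  s <- if (length(vals) == 1L) {
    flags <- c(flags, "single_replicate")
    0
  } else {
    stats::sd(vals)
  }
  list(mean = mean(vals), sd = s, n = length(vals), values = values,
       flags = flags)
}
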