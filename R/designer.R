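## designer: plurality consensus motifs and assembly of designer DYW:KP
## proteins, including active-site mutants.

#' Plurality-0 consensus of an aligned set of sequences
#'
#' Emits, per column, the most frequent residue regardless of its absolute
#' count (plurality value 0). Ties are broken deterministically towards the
#' lexicographically smallest residue and flagged. Gap characters (`-`) are
#' counted but can never win a column: a gap-majority column emits the most
#' frequent non-gap residue and is flagged in `gap_majority` (columns of only
#' gaps emit `-`).
#'
#' @param seqs Character vector of equal-length aligned sequences.
#' @param gap Gap character (default `-`).
#' @return A list of class `ppr_consensus`: `consensus` (string), `counts`
#'   (residue x column matrix, columns summing to `length(seqs)`), `tie`
#'   (logical per column, `TRUE` where >= 2 eligible residues share the
#'   maximum) and `gap_majority` (logical per column).
#' @export
#' @examples
#' consensus(c("AAC", "AAG", "AAC"))$consensus
consensus <- function(seqs, gap = "-") {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("ragged input: sequence lengths ", paste(unique(lens), collapse = ", "))
  }
  width <- lens[1L]
  mat <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE)),
                nrow = length(seqs), ncol = width, byrow = TRUE)
  residues <- sort(unique(as.vector(mat)))
  counts <- vapply(seq_len(width), function(j)
    tabulate(factor(mat[, j], levels = residues), nbins = length(residues)),
    integer(length(residues)))
  if (!is.matrix(counts)) counts <- matrix(counts, ncol = width)
  rownames(counts) <- residues
  non_gap <- setdiff(residues, gap)
  cons <- character(width)
  tie <- logical(width)
  gap_majority <- logical(width)
  for (j in seq_len(width)) {
    cj <- counts[, j]
    gap_n <- if (gap %in% residues) cj[gap] else 0L
    eligible <- cj[non_gap]
    if (!length(eligible) || all(eligible == 0L)) {
      cons[j] <- gap
      gap_majority[j] <- TRUE
      next
    }
    m <- max(eligible)
    winners <- sort(names(eligible)[eligible == m])
    cons[j] <- winners[1L]
    tie[j] <- length(winners) > 1L
    gap_majority[j] <- gap_n > m
  }
  structure(list(consensus = paste(cons, collapse = ""),
                 counts = counts, tie = tie, gap_majority = gap_majority),
            class = "ppr_consensus")
}

#' @export
print.ppr_consensus <- function(x, ...) {
  cat("plurality-0 consensus (", ncol(x$counts), " columns, ",
      sum(x$counts[, 1]), " sequences)\n", sep = "")
  cat(x$consensus, "\n")
  if (any(x$tie)) cat("ties at columns:", which(x$tie), "\n")
  invisible(x)
}

designer_motif_order <- c(rep(c("P1", "L1", "S1"), 3), "P2", "L2", "S2", "E1", "E2")

#' Assemble a designer PPR-DYW:KP protein
#'
#' Concatenates, in scaffold order, three P1L1S1 triplets, the C-terminal
#' P2-L2-S2-E1-E2 motifs and a DYW domain, keeping a residue-level boundary
#' map. P1/L1/S1 motif lengths must satisfy the length policy; the C-terminal
#' motif and domain lengths are free (designer DYW:KP domains of 133 or 136
#' residues are both valid). The DYW deaminase-signature positions are located
#' at assembly time and frozen on the object, so catalytic mutants remain
#' addressable after mutation.
#'
#' @param pls Character vector of 9 motif sequences in P1,L1,S1 x3 order, or a
#'   data.frame with columns `motif_type`, `sequence`.
#' @param cterm Character vector of 5 motif sequences in P2,L2,S2,E1,E2 order,
#'   or a data.frame as above.
#' @param dyw DYW domain sequence (string) or a [dyw_domain()].
#' @param name Protein name.
#' @param length_policy Required P1/L1/S1 lengths, see
#'   [default_length_policy()].
#' @return A list of class `designer_protein`: `name`, `motifs` (data.frame
#'   `motif_type`, `sequence`, `start`, `end`), `dyw` (list with `sequence`,
#'   `start`, `end`, `signature`), `mutation` (`"none"`) and `sequence`.
#' @export
assemble_designer <- function(pls, cterm, dyw, name = "designer",
                              length_policy = default_length_policy()) {
  get_seqs <- function(x, expected_types) {
    if (is.data.frame(x)) {
      if (!identical(as.character(x$motif_type), expected_types)) {
        stop("motif order must be exactly ", paste(expected_types, collapse = "-"),
             ", got ", paste(x$motif_type, collapse = "-"))
      }
      as.character(x$sequence)
    } else {
      if (length(x) != length(expected_types)) {
        stop("expected ", length(expected_types), " motifs (",
             paste(expected_types, collapse = "-"), "), got ", length(x))
      }
      as.character(x)
    }
  }
  pls_seqs <- get_seqs(pls, designer_motif_order[1:9])
  ct_seqs <- get_seqs(cterm, designer_motif_order[10:14])
  seqs <- toupper(c(pls_seqs, ct_seqs))
  types <- designer_motif_order
  for (k in 1:9) {
    want <- unname(length_policy[types[k]])
    if (!is.na(want) && nchar(seqs[k]) != want) {
      stop("motif ", k, " (", types[k], ") has length ", nchar(seqs[k]),
           ", policy requires ", want)
    }
  }
  if (inherits(dyw, "dyw_domain")) {
    dyw_seq <- dyw$sequence
    sig <- dyw$signature
  } else {
    dyw_seq <- toupper(dyw)
    sig <- detect_deaminase_signature(dyw_seq)
  }
  ends <- cumsum(nchar(seqs))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  motifs <- data.frame(motif_type = types, sequence = seqs,
                       start = starts, end = ends, stringsAsFactors = FALSE)
  dyw_start <- ends[length(ends)] + 1L
  structure(list(
    name = name,
    motifs = motifs,
    dyw = list(sequence = dyw_seq,
               start = dyw_start,
               end = dyw_start + nchar(dyw_seq) - 1L,
               signature = sig),
    mutation = "none",
    sequence = paste0(paste(seqs, collapse = ""), dyw_seq)
  ), class = "designer_protein")
}

#' @export
print.designer_protein <- function(x, ...) {
  cat("designer PPR-DYW:KP protein '", x$name, "' (", nchar(x$sequence),
      " aa, mutation: ", x$mutation, ")\n", sep = "")
  cat("  motifs:", paste(x$motifs$motif_type, collapse = "-"),
      "+ DYW(", nchar(x$dyw$sequence), " aa)\n")
  invisible(x)
}

#' Decompose a designer protein into its motif list
#'
#' Inverse of [assemble_designer()]: returns the ordered motif sequences and
#' the DYW domain exactly as assembled.
#'
#' @param protein A `designer_protein`.
#' @return List with `motifs` (data.frame) and `dyw` (sequence string).
#' @export
decompose_designer <- function(protein) {
  stopifnot(inherits(protein, "designer_protein"))
  list(motifs = protein$motifs, dyw = protein$dyw$sequence)
}

#' Apply a catalytic active-site mutation to a designer protein
#'
#' Operates on the frozen deaminase-signature coordinates of the DYW domain:
#'
#' * `HAA` - the signature glutamate (HAE -> HAA) is replaced by alanine;
#' * `AxxA` - both signature cysteines (CxxC -> AxxA) are replaced by alanine;
#' * `HSE` - the residue between the signature H and E is replaced by serine
#'   (HAE -> HSE); a warning is issued when that residue is not alanine.
#'
#' All other residues are unchanged; the mutation tag is updated. Applying the
#' same variant twice is a no-op relative to applying it once.
#'
#' @param protein A `designer_protein` whose DYW signature was detected.
#' @param variant One of `"HAA"`, `"AxxA"`, `"HSE"`.
#' @return The mutated `designer_protein`.
#' @export
apply_catalytic_mutant <- function(protein, variant = c("HAA", "AxxA", "HSE")) {
  stopifnot(inherits(protein, "designer_protein"))
  variant <- match.arg(variant)
  sig <- protein$dyw$signature
  if (is.null(sig)) {
    stop("no deaminase signature recorded for the DYW domain of ", protein$name)
  }
  chars <- seq_chars(protein$dyw$sequence)
  if (variant == "HAA") {
    chars[sig[["posE"]]] <- "A"
  } else if (variant == "AxxA") {
    chars[c(sig[["posC1"]], sig[["posC2"]])] <- "A"
  } else {
    mid <- sig[["posH"]] + 1L
    if (chars[mid] != "A" && chars[mid] != "S") {
      warning("residue between signature H and E is '", chars[mid],
              "', not A; substituting S anyway")
    }
    chars[mid] <- "S"
  }
  protein$dyw$sequence <- paste(chars, collapse = "")
  protein$mutation <- variant
  protein$sequence <- paste0(paste(protein$motifs$sequence, collapse = ""),
                             protein$dyw$sequence)
  protein
}

#' Recognition residues of each motif
#'
#' The two target-specifying amino acids per PPR motif under the
#' "position 5 and last residue" convention.
#'
#' @param protein A `designer_protein`.
#' @param pos5 Index of the first recognition residue within a motif
#'   (default 5).
#' @return data.frame `motif` (1-based index), `motif_type`, `aa5`, `aa_last`.
#' @export
recognition_residues <- function(protein, pos5 = 5L) {
  stopifnot(inherits(protein, "designer_protein"))
  data.frame(
    motif = seq_len(nrow(protein$motifs)),
    motif_type = protein$motifs$motif_type,
    aa5 = substr(protein$motifs$sequence, pos5, pos5),
    aa_last = substr(protein$motifs$sequence,
                     nchar(protein$motifs$sequence),
                     nchar(protein$motifs$sequence)),
    stringsAsFactors = FALSE
  )
}
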