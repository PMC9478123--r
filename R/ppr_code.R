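## ppr_code: residue-pair -> nucleotide code, scaffold retargeting and
## binding prediction over target positions -15..-3.

#' Construct a PPR code table
#'
#' Maps `(motif_type, aa5, aa_last)` residue pairs to nucleotide preference
#' weights over {A, C, G, U}. Weights must be non-negative with a positive row
#' sum; they are normalised to sum 1 per entry.
#'
#' @param entries data.frame with columns `motif_type`, `aa5`, `aa_last`,
#'   `wA`, `wC`, `wG`, `wU` and optionally `provenance`.
#' @return The normalised data.frame with class `ppr_code_table`.
#' @export
code_table <- function(entries) {
  need <- c("motif_type", "aa5", "aa_last", "wA", "wC", "wG", "wU")
  missing <- setdiff(need, names(entries))
  if (length(missing)) stop("code table lacks columns: ", paste(missing, collapse = ", "))
  if (!"provenance" %in% names(entries)) entries$provenance <- "unspecified"
  w <- as.matrix(entries[c("wA", "wC", "wG", "wU")])
  if (any(w < 0)) stop("code weights must be non-negative")
  s <- rowSums(w)
  if (any(s <= 0)) stop("each code entry needs a positive weight sum")
  entries[c("wA", "wC", "wG", "wU")] <- w / s
  key <- paste(entries$motif_type, entries$aa5, entries$aa_last)
  if (anyDuplicated(key)) {
    stop("duplicate code entries: ", paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  class(entries) <- c("ppr_code_table", "data.frame")
  entries
}

#' Canonical PPR code table
#'
#' The default code shipped with the package, read from
#' `inst/extdata/code_table_canonical.tsv`. It seeds the classic residue-pair
#' preferences of the P- and S-family code (e.g. TD -> G, TN -> A, ND -> U,
#' NS -> C) for the P1, L1, S1 and P2 motif types and is labelled
#' literature-derived: it is an editable starting point, not a fitted model.
#' Analyses that need exact inversion should use synthetic bijective tables.
#'
#' @return A `ppr_code_table`.
#' @export
default_code_table <- function() {
  read_code_table(system.file("extdata", "code_table_canonical.tsv",
                              package = "pprkp", mustWork = TRUE))
}

code_lookup <- function(code, motif_type, aa5, aa_last) {
  hit <- code$motif_type == motif_type & code$aa5 == aa5 & code$aa_last == aa_last
  if (!any(hit)) return(NULL)
  w <- as.numeric(code[which(hit)[1L], c("wA", "wC", "wG", "wU")])
  names(w) <- RNA4
  w
}

#' Construct a target editing site
#'
#' A window of 26 nucleotides spanning positions -20..+5 around the edited
#' base (position 0). For U-to-C sites the base at 0 must be U; for C-to-U
#' sites, C. DNA input is transcribed on read.
#'
#' @param sequence 26-nt string (positions -20..+5).
#' @param direction `"U2C"` or `"C2U"`.
#' @return A list of class `target_site`: `sequence`, `positions` (-20..5),
#'   `direction`.
#' @export
target_site <- function(sequence, direction = c("U2C", "C2U")) {
  direction <- match.arg(direction)
  sequence <- as_rna(sequence)
  if (nchar(sequence) != 26L) {
    stop("target site must span positions -20..+5 (26 nt), got ",
         nchar(sequence), " nt")
  }
  bad <- setdiff(unique(seq_chars(sequence)), RNA4)
  if (length(bad)) stop("non-RNA characters in target site: ", paste(bad, collapse = ", "))
  base0 <- substr(sequence, 21L, 21L)
  want <- if (direction == "U2C") "U" else "C"
  if (base0 != want) {
    stop("base at position 0 is ", base0, " but direction ", direction,
         " requires ", want)
  }
  structure(list(sequence = sequence, positions = -20:5, direction = direction),
            class = "target_site")
}

#' Base of a target site at given positions
#' @param site A `target_site`.
#' @param pos Integer positions relative to the edited base (0).
#' @return Character vector of bases.
#' @export
site_base <- function(site, pos) {
  idx <- match(pos, site$positions)
  if (anyNA(idx)) stop("positions outside the site window: ",
                       paste(pos[is.na(idx)], collapse = ", "))
  substring(site$sequence, idx, idx)
}

#' Map binding motifs to target positions
#'
#' The 13 recognition motifs (P1L1S1 x3, P2, L2, S2, E1) bind one nucleotide
#' each; motif k (1-based) binds target position k - 16, so the first P1 binds
#' -15, the second S1 binds -10, the third L1 binds -8, L2/S2/E1 bind
#' -5/-4/-3, and the edited base sits at 0, three nucleotides downstream of
#' E1. E2 and the DYW domain are unmapped.
#'
#' @param protein A `designer_protein`, or a character vector of motif types.
#' @return Named integer vector of length 13 (names like `"P1.1"`, positions
#'   -15..-3).
#' @export
motif_binding_positions <- function(protein) {
  types <- if (inherits(protein, "designer_protein")) {
    protein$motifs$motif_type
  } else {
    as.character(protein)
  }
  if (length(types) < 13L || !identical(types[1:13], BINDING_MOTIF_ORDER)) {
    stop("non-canonical motif array [", paste(types, collapse = "-"),
         "]; need ", paste(BINDING_MOTIF_ORDER, collapse = "-"),
         " before any E2/DYW")
  }
  pos <- seq_len(13L) - 16L
  reps <- stats::ave(seq_along(types[1:13]), types[1:13], FUN = seq_along)
  names(pos) <- paste(types[1:13], reps, sep = ".")
  pos
}

#' Retarget a designer scaffold to an RNA site
#'
#' For each canonical-code motif (the three P1, three L1, three S1 and the P2),
#' the code entry of that motif type whose weight vector is maximised at the
#' site's nucleotide at the motif's position is selected, and the motif's
#' recognition residues (position 5 and last residue) are set to that entry's
#' pair. The L2, S2 and E1 motifs follow a non-canonical code that is not
#' modelled: their residue pairs must be supplied verbatim via `overrides`
#' (donor-protein residues are configuration, not computed). All
#' non-recognition residues are unchanged.
#'
#' Entry selection is deterministic: among entries achieving the maximal
#' weight at the required nucleotide, the first in table order wins, and an
#' entry is only acceptable when the required nucleotide attains the entry's
#' row maximum (ties allowed).
#'
#' @param scaffold A `designer_protein`.
#' @param site A [target_site()].
#' @param code A [code_table()].
#' @param overrides Named list with elements `L2`, `S2`, `E1`, each a
#'   2-character vector `c(aa5, aa_last)`.
#' @param pos5 Recognition-residue convention, see [recognition_residues()].
#' @return The retargeted `designer_protein`.
#' @export
retarget <- function(scaffold, site, code, overrides, pos5 = 5L) {
  stopifnot(inherits(scaffold, "designer_protein"),
            inherits(site, "target_site"),
            inherits(code, "ppr_code_table"))
  need_over <- c("L2", "S2", "E1")
  if (missing(overrides) || !all(need_over %in% names(overrides))) {
    stop("residue-pair overrides are required for motifs: ",
         paste(setdiff(need_over, names(if (missing(overrides)) list() else overrides)),
               collapse = ", "))
  }
  posmap <- motif_binding_positions(scaffold)
  motifs <- scaffold$motifs
  set_pair <- function(seq, aa5, aa_last) {
    substr(seq, pos5, pos5) <- aa5
    substr(seq, nchar(seq), nchar(seq)) <- aa_last
    seq
  }
  for (k in seq_len(13L)) {
    type <- motifs$motif_type[k]
    if (type %in% need_over) {
      pair <- overrides[[type]]
      stopifnot(length(pair) == 2L)
      motifs$sequence[k] <- set_pair(motifs$sequence[k], pair[1L], pair[2L])
      next
    }
    nt <- site_base(site, unname(posmap[k]))
    rows <- code[code$motif_type == type, , drop = FALSE]
    if (!nrow(rows)) stop("no code entries for motif type ", type)
    w <- as.matrix(rows[c("wA", "wC", "wG", "wU")])
    colnames(w) <- RNA4
    ok <- w[, nt] >= apply(w, 1L, max) - 1e-12
    if (!any(ok)) {
      stop("no code entry for motif ", k, " (", type,
           ") achieves nucleotide ", nt)
    }
    cand <- which(ok)
    best <- cand[which.max(w[cand, nt])]
    motifs$sequence[k] <- set_pair(motifs$sequence[k],
                                   rows$aa5[best], rows$aa_last[best])
  }
  scaffold$motifs <- motifs
  scaffold$sequence <- paste0(paste(motifs$sequence, collapse = ""),
                              scaffold$dyw$sequence)
  scaffold
}

#' Predict the binding preference of a designer protein
#'
#' Looks up the code entry for each of the 13 recognition motifs' residue
#' pairs. Unknown pairs yield the uniform vector over {A, C, G, U} and are
#' flagged, not fatal.
#'
#' @param protein A `designer_protein`.
#' @param code A [code_table()].
#' @param pos5 Recognition-residue convention.
#' @return A list of class `binding_model`: `positions` (-15..-3), `weights`
#'   (4 x 13 matrix, rows A/C/G/U, columns summing to 1), `motif_type`,
#'   `pairs` (character "aa5 aa_last"), `unknown` (logical per motif).
#' @export
predict_binding <- function(protein, code, pos5 = 5L) {
  stopifnot(inherits(code, "ppr_code_table"))
  posmap <- motif_binding_positions(protein)
  rr <- recognition_residues(protein, pos5 = pos5)[seq_len(13L), ]
  weights <- matrix(NA_real_, nrow = 4L, ncol = 13L,
                    dimnames = list(RNA4, names(posmap)))
  unknown <- logical(13L)
  for (k in seq_len(13L)) {
    w <- code_lookup(code, rr$motif_type[k], rr$aa5[k], rr$aa_last[k])
    if (is.null(w)) {
      w <- stats::setNames(rep(0.25, 4L), RNA4)
      unknown[k] <- TRUE
    }
    weights[, k] <- w
  }
  structure(list(positions = unname(posmap), weights = weights,
                 motif_type = rr$motif_type, pairs = paste(rr$aa5, rr$aa_last),
                 unknown = unknown),
            class = "binding_model")
}

#' Preferred (argmax) bases of a binding model
#'
#' @param model A `binding_model`.
#' @return List of length 13; element k is the character vector of bases tied
#'   for the maximal weight at position k (singletons in the common case).
#' @export
argmax_bases <- function(model) {
  stopifnot(inherits(model, "binding_model"))
  lapply(seq_len(ncol(model$weights)), function(k) {
    w <- model$weights[, k]
    names(w)[w >= max(w) - 1e-12]
  })
}

#' Consensus binding sequence of a model
#'
#' @param model A `binding_model`.
#' @return 13-nt string of argmax bases (ties resolved alphabetically).
#' @export
binding_consensus <- function(model) {
  paste(vapply(argmax_bases(model), function(b) sort(b)[1L], ""), collapse = "")
}

#' Mismatches between a binding model and a 13-nt window
#'
#' A position matches when the window base is among the model's argmax base
#' set at that position (argmax ties count as matches).
#'
#' @param model A `binding_model`.
#' @param window 13-nt string (positions -15..-3; DNA transcribed on read).
#' @return List with `count` and `positions` (site coordinates of the
#'   mismatches, within -15..-3).
#' @export
mismatch_count <- function(model, window) {
  window <- as_rna(window)
  if (nchar(window) != 13L) {
    stop("window must be 13 nt, got ", nchar(window))
  }
  bases <- seq_chars(window)
  am <- argmax_bases(model)
  mm <- !mapply(function(b, allowed) b %in% allowed, bases, am)
  list(count = sum(mm), positions = model$positions[mm])
}
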