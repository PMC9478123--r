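## motif_catalog: classification and filtering of PPR motif annotations and
## DYW deaminase domains.

#' Detect the HxE(x)CxxC deaminase signature
#'
#' Scans an amino-acid sequence for the cytidine deaminase active-site
#' signature of DYW domains: an H followed two residues later by E, then a
#' downstream CxxC zinc-binding pair. The leftmost occurrence is returned:
#' the smallest H position, and for that H the smallest admissible first C.
#'
#' @param seq Amino-acid string over the 20-letter alphabet (X allowed).
#' @param max_span Maximum residue distance from the signature H to the first
#'   C (default 80); bounds the variable-length spacer written `HxE(x)nCxxC`.
#' @return Named integer vector `c(posH, posE, posC1, posC2)` (1-based), or
#'   `NULL` when the signature is absent.
#' @export
#' @examples
#' detect_deaminase_signature("MRHAEGGGGCSSCK")  # c(3, 5, 10, 13)
detect_deaminase_signature <- function(seq, max_span = 80L) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  chars <- seq_chars(toupper(seq))
  bad <- setdiff(unique(chars), c(AA20, "X"))
  if (length(bad)) {
    stop("illegal characters in sequence: ", paste(bad, collapse = ", "))
  }
  n <- length(chars)
  h_pos <- which(chars == "H")
  h_pos <- h_pos[h_pos + 2L <= n & chars[h_pos + 2L] == "E"]
  c_pos <- which(chars == "C")
  c_pos <- c_pos[c_pos + 3L <= n & chars[c_pos + 3L] == "C"]
  for (h in h_pos) {
    ok <- c_pos[c_pos > h + 2L & c_pos - h <= max_span]
    if (length(ok)) {
      c1 <- ok[1L]
      return(c(posH = h, posE = h + 2L, posC1 = c1, posC2 = c1 + 3L))
    }
  }
  NULL
}

#' Construct a DYW domain record
#'
#' @param sequence Amino-acid string of the domain.
#' @param unannotated_upstream Number of residues between the last annotated
#'   PPR motif and the domain start, as supplied by the annotation table.
#' @param protein_id Optional source protein identifier.
#' @param max_span Passed to [detect_deaminase_signature()].
#' @return A list of class `dyw_domain` with `sequence`, `length`,
#'   `signature` (positions or NULL), `unannotated_upstream`,
#'   `terminal_triplet` and `protein_id`.
#' @export
dyw_domain <- function(sequence, unannotated_upstream = 0L, protein_id = NA_character_,
                       max_span = 80L) {
  stopifnot(nzchar(sequence), unannotated_upstream >= 0)
  n <- nchar(sequence)
  structure(list(
    protein_id = protein_id,
    sequence = toupper(sequence),
    length = n,
    signature = detect_deaminase_signature(sequence, max_span = max_span),
    unannotated_upstream = as.integer(unannotated_upstream),
    terminal_triplet = substr(toupper(sequence), n - 2L, n)
  ), class = "dyw_domain")
}

#' Filter DYW domains by deaminase signature, upstream gap and length
#'
#' A domain is retained iff (in this order of reporting) it carries the
#' HxE(x)CxxC deaminase signature, has at most `max_unannotated` unannotated
#' residues upstream, and is at least `min_length` residues long (domains of
#' 115 aa or shorter are removed under the default). Each rejected domain is
#' annotated with the first failed rule.
#'
#' @param domains data.frame with columns `protein_id`, `sequence`,
#'   `unannotated_upstream`, or a list of [dyw_domain()] objects.
#' @param max_unannotated Maximum tolerated upstream gap (default 34).
#' @param min_length Minimum domain length (default 116).
#' @param max_span Signature span bound, see [detect_deaminase_signature()].
#' @return List with `retained` and `rejected` data.frames; `rejected` carries
#'   a `reason` column in `{"signature", "upstream", "length"}`.
#' @export
filter_dyw_domains <- function(domains, max_unannotated = 34L, min_length = 116L,
                               max_span = 80L) {
  if (is.data.frame(domains)) {
    df <- domains
  } else {
    df <- do.call(rbind, lapply(domains, function(d) data.frame(
      protein_id = d$protein_id, sequence = d$sequence,
      unannotated_upstream = d$unannotated_upstream)))
    if (is.null(df)) df <- data.frame(protein_id = character(),
                                      sequence = character(),
                                      unannotated_upstream = integer())
  }
  if (!nrow(df)) {
    empty <- cbind(df, length = integer(0))
    return(list(retained = empty, rejected = cbind(empty, reason = character(0))))
  }
  df$length <- nchar(df$sequence)
  has_sig <- vapply(df$sequence, function(s)
    !is.null(detect_deaminase_signature(s, max_span = max_span)), logical(1),
    USE.NAMES = FALSE)
  reason <- rep(NA_character_, nrow(df))
  reason[!has_sig] <- "signature"
  reason[is.na(reason) & df$unannotated_upstream > max_unannotated] <- "upstream"
  reason[is.na(reason) & df$length < min_length] <- "length"
  keep <- is.na(reason)
  rejected <- df[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  rownames(rejected) <- NULL
  retained <- df[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, rejected = rejected)
}

#' Classify P1L1S1 triplets by their position in a PPR array
#'
#' Every run of three consecutive motifs typed exactly P1, L1, S1 is located
#' and given a (possibly empty, possibly multiple) set of positional labels:
#'
#' * `N-term` - it is the protein's first motif triplet and the protein starts
#'   with a P1 motif;
#' * `Central` - at least three PPR motifs precede it and a P1L1S1 triplet
#'   immediately follows;
#' * `C-term` - a P2L2S2 triplet immediately follows.
#'
#' Labels depend only on motif types and positions, never on sequence content.
#'
#' @param motif_types Character vector of motif types in array order, or a
#'   motif table data.frame for a single protein (column `motif_type`, ordered
#'   by `ordinal`).
#' @return data.frame with columns `triplet` (index among P1L1S1 triplets),
#'   `first_ordinal` (ordinal of the triplet's P1) and `labels`
#'   (comma-separated subset of `N-term,Central,C-term`, possibly "").
#' @export
classify_triplets <- function(motif_types) {
  if (is.data.frame(motif_types)) {
    motif_types <- motif_types$motif_type[order(motif_types$ordinal)]
  }
  n <- length(motif_types)
  starts <- which(
    motif_types[seq_len(max(0L, n - 2L))] == "P1" &
    motif_types[seq_len(max(0L, n - 2L)) + 1L] == "L1" &
    motif_types[seq_len(max(0L, n - 2L)) + 2L] == "S1"
  )
  labs <- lapply(starts, function(i) {
    l <- character(0)
    if (i == 1L && motif_types[1L] == "P1") l <- c(l, "N-term")
    followed_by <- function(types) {
      i + 5L <= n && identical(motif_types[(i + 3L):(i + 5L)], types)
    }
    if (i - 1L >= 3L && followed_by(c("P1", "L1", "S1"))) l <- c(l, "Central")
    if (followed_by(c("P2", "L2", "S2"))) l <- c(l, "C-term")
    l
  })
  data.frame(
    triplet = seq_along(starts),
    first_ordinal = as.integer(starts),
    labels = vapply(labs, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Select motifs matching a per-type length policy
#'
#' Retains only motifs whose sequence length equals the policy value for their
#' type (default: 35 aa for P1 and L1, 31 aa for S1).
#'
#' @param motifs Motif table data.frame (columns `motif_type`, `sequence`).
#' @param policy Named integer vector motif_type -> required length.
#' @param missing_type What to do with motifs whose type has no policy entry:
#'   `"drop"` (default, with a warning) or `"error"`.
#' @return The retained subset of `motifs`.
#' @export
select_by_length <- function(motifs, policy = default_length_policy(),
                             missing_type = c("drop", "error")) {
  missing_type <- match.arg(missing_type)
  unknown <- setdiff(unique(motifs$motif_type), names(policy))
  if (length(unknown)) {
    if (missing_type == "error") {
      stop("no length policy for motif types: ", paste(unknown, collapse = ", "))
    }
    warning("dropping motifs with types absent from the length policy: ",
            paste(unknown, collapse = ", "))
  }
  keep <- motifs$motif_type %in% names(policy) &
    nchar(motifs$sequence) == unname(policy[motifs$motif_type])
  keep[is.na(keep)] <- FALSE
  out <- motifs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
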