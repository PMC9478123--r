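## Readers and writers for the plain-text interchange formats used by the
## pipeline: FASTA (via Biostrings), motif tables, trace TSV, pileup TSV,
## code tables, BED/VCF position lists.

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @param alphabet `"rna"` (T transcribed to U on read), `"dna"` or `"aa"`.
#' @return Named uppercase character vector of sequences.
#' @export
read_fasta_seqs <- function(path, alphabet = c("rna", "dna", "aa")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  x <- toupper(as.character(set))
  names(x) <- sub("\\s.*$", "", names(set))
  if (alphabet == "rna") x <- chartr("T", "U", x)
  x
}

#' Write sequences to FASTA
#'
#' @param x Named character vector of sequences.
#' @param path Output file.
#' @export
write_fasta_seqs <- function(x, path) {
  stopifnot(is.character(x), !is.null(names(x)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), path, width = 70L)
  invisible(path)
}

motif_table_cols <- c("protein_id", "ordinal", "motif_type", "start", "end", "sequence")

#' Read a PPR motif annotation table
#'
#' Tab-separated with columns `protein_id`, `ordinal` (1-based position of the
#' motif within the protein's array), `motif_type` (P1, L1, S1, P2, L2, S2, E1,
#' E2 or SS), `start`, `end` (residue coordinates in the source protein, NA
#' allowed) and `sequence` (amino acids).
#'
#' @param path TSV file.
#' @return data.frame with the columns above; motif ordinals are checked to be
#'   strictly increasing and contiguous within each protein.
#' @export
read_motif_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(motif_table_cols, names(df))
  if (length(missing)) {
    stop("motif table ", path, " lacks columns: ", paste(missing, collapse = ", "))
  }
  df <- df[motif_table_cols]
  validate_motif_table(df)
  df
}

validate_motif_table <- function(df) {
  bad <- setdiff(unique(df$motif_type), MOTIF_TYPES)
  if (length(bad)) stop("unknown motif types: ", paste(bad, collapse = ", "))
  for (pid in unique(df$protein_id)) {
    ords <- df$ordinal[df$protein_id == pid]
    if (!identical(as.integer(ords), seq_along(ords))) {
      stop("motif ordinals for protein ", pid, " are not contiguous from 1")
    }
  }
  invisible(df)
}

#' Write a PPR motif annotation table
#' @param df data.frame as produced by [read_motif_table()].
#' @param path Output TSV.
#' @export
write_motif_table <- function(df, path) {
  utils::write.table(df[motif_table_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

trace_cols <- c("position", "base_call", "area_A", "area_C", "area_G", "area_T")

#' Read a Sanger trace in the TSV peak-area dialect
#'
#' The dialect carries, per called position, the base call and the four channel
#' peak areas: columns `position`, `base_call`, `area_A`, `area_C`, `area_G`,
#' `area_T`. This is the normative trace input of the package; AB1 files must
#' be converted to this dialect upstream (e.g. with a base-caller export),
#' as binary AB1 parsing is not implemented.
#'
#' @param path TSV file.
#' @param dialect `"tsv"`; `"ab1"` raises an informative error.
#' @param sample_id Optional sample label (default: file base name).
#' @return A `sanger_trace` object (see [sanger_trace()]).
#' @export
read_trace <- function(path, dialect = c("tsv", "ab1"), sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "ab1") {
    stop("AB1 parsing is not implemented; export called peak areas to the ",
         "TSV trace dialect (position, base_call, area_A, area_C, area_G, ",
         "area_T) and read with dialect = \"tsv\"")
  }
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stop("failed to parse trace ", path, ": ",
                                          conditionMessage(e)))
  missing <- setdiff(trace_cols, names(df))
  if (length(missing)) {
    stop("trace ", path, " lacks columns: ", paste(missing, collapse = ", "))
  }
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  sanger_trace(df[trace_cols], sample_id = sample_id)
}

#' Write a Sanger trace in the TSV peak-area dialect
#' @param trace A `sanger_trace`.
#' @param path Output TSV.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(as.data.frame(unclass(trace))[trace_cols], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pileup_cols <- c("chrom", "pos", "strand", "ref", "nA", "nC", "nG", "nT", "mean_qual")

#' Write a pileup table
#' @param df Pileup data.frame (`chrom`, `pos` 1-based, `strand`, `ref`, `nA`,
#'   `nC`, `nG`, `nT`, `mean_qual`).
#' @param path Output TSV.
#' @export
write_pileup <- function(df, path) {
  utils::write.table(df[pileup_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read SNP positions from BED or VCF
#'
#' Only positions are used. BED intervals are expanded to 1-based positions;
#' VCF rows contribute their POS field.
#'
#' @param path `.bed` or `.vcf` file (format inferred from the extension unless
#'   `format` is given).
#' @param format `"bed"` or `"vcf"`.
#' @return data.frame with columns `chrom`, `pos` (1-based).
#' @export
read_snp_positions <- function(path, format = c("auto", "bed", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "bed"
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(data.frame(chrom = character(), pos = integer()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "bed") {
    out <- do.call(rbind, lapply(parts, function(p) {
      start <- as.integer(p[2]); end <- as.integer(p[3])
      data.frame(chrom = p[1], pos = seq.int(start + 1L, end))
    }))
  } else {
    out <- data.frame(chrom = vapply(parts, `[`, "", 1),
                      pos = as.integer(vapply(parts, `[`, "", 2)))
  }
  rownames(out) <- NULL
  out
}

#' Write off-target hits as BED
#'
#' Transcript-relative, 0-based half-open windows; the name field carries the
#' mismatch count.
#'
#' @param hits data.frame from [scan_transcripts()].
#' @param path Output BED file.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$transcript,
                    start = hits$offset,
                    end = hits$offset + nchar(hits$window),
                    name = paste0("mm", hits$mismatches))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

code_table_cols <- c("motif_type", "aa5", "aa_last", "wA", "wC", "wG", "wU", "provenance")

#' Read a PPR code table
#'
#' TSV with columns `motif_type`, `aa5`, `aa_last`, `wA`, `wC`, `wG`, `wU`,
#' `provenance`. Weights are normalised per row on read.
#'
#' @param path TSV file.
#' @return A `ppr_code_table` (see [code_table()]).
#' @export
read_code_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(code_table_cols, names(df))
  if (length(missing)) {
    stop("code table ", path, " lacks columns: ", paste(missing, collapse = ", "))
  }
  code_table(df)
}

#' Write a PPR code table
#' @param code A `ppr_code_table`.
#' @param path Output TSV.
#' @export
write_code_table <- function(code, path) {
  utils::write.table(as.data.frame(code)[code_table_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## shared helpers -----------------------------------------------------------

## split a sequence string into a character vector of single residues/bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## uppercase + transcribe to the internal RNA alphabet
as_rna <- function(x) chartr("T", "U", toupper(x))

## uppercase + reverse-transcribe to DNA (for base-call matching)
as_dna <- function(x) chartr("U", "T", toupper(x))
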