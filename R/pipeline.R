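## pipeline_cli: config-driven orchestration of the pipeline stages with
## provenance manifests. The command-line wrapper lives in
## inst/scripts/pprkp.R; run_pipeline() is the programmatic surface.

#' Write a designer protein as FASTA plus a JSON sidecar
#'
#' The sidecar records motif boundaries, the DYW domain with its frozen
#' signature positions, recognition residues and the mutation tag.
#'
#' @param protein A `designer_protein`.
#' @param fasta,json Output paths (either may be NULL to skip).
#' @return Invisibly, the JSON path.
#' @export
write_designer <- function(protein, fasta = NULL, json = NULL) {
  stopifnot(inherits(protein, "designer_protein"))
  if (!is.null(fasta)) {
    write_fasta_seqs(stats::setNames(protein$sequence, protein$name), fasta)
  }
  if (!is.null(json)) {
    payload <- list(
      name = protein$name,
      motifs = protein$motifs,
      dyw = list(sequence = protein$dyw$sequence, start = protein$dyw$start,
                 end = protein$dyw$end,
                 signature = as.list(protein$dyw$signature)),
      recognition = recognition_residues(protein),
      mutation = protein$mutation
    )
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(json)
}

#' Read a designer protein from its JSON sidecar
#' @param json Path written by [write_designer()].
#' @return A `designer_protein`.
#' @export
read_designer <- function(json) {
  x <- jsonlite::read_json(json, simplifyVector = TRUE)
  sig <- unlist(x$dyw$signature)
  structure(list(
    name = x$name,
    motifs = as.data.frame(x$motifs, stringsAsFactors = FALSE),
    dyw = list(sequence = x$dyw$sequence, start = x$dyw$start,
               end = x$dyw$end,
               signature = if (length(sig)) sig else NULL),
    mutation = x$mutation,
    sequence = paste0(paste(x$motifs$sequence, collapse = ""), x$dyw$sequence)
  ), class = "designer_protein")
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      config <- yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  if (is.null(config$subcommand)) stop("config lacks a 'subcommand'")
  known <- c("simulate", "catalog", "design", "retarget", "scan",
             "quantify", "call", "preference")
  if (!config$subcommand %in% known) {
    stop("unknown subcommand '", config$subcommand, "'; expected one of: ",
         paste(known, collapse = ", "))
  }
  if (is.null(config$out_dir)) stop("config lacks an 'out_dir'")
  if (is.null(config$params)) config$params <- list()
  if (is.null(config$inputs)) config$inputs <- list()
  config
}

param <- function(config, name, default = NULL) {
  v <- config$params[[name]]
  if (is.null(v)) default else v
}

need_input <- function(config, name) {
  path <- config$inputs[[name]]
  if (is.null(path)) stop("missing input '", name, "' for subcommand ",
                          config$subcommand)
  if (!file.exists(path)) stop("input '", name, "' not found: ", path)
  path
}

write_provenance <- function(config, artifacts) {
  digests <- lapply(config$inputs, function(p)
    list(path = p, md5 = unname(tools::md5sum(p))))
  manifest <- list(
    subcommand = config$subcommand,
    params = config$params,
    inputs = digests,
    artifacts = artifacts,
    package_version = as.character(utils::packageVersion("pprkp")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run a pipeline stage from a configuration
#'
#' Subcommands: `simulate` (all synthetic generators), `catalog` (motif
#' length selection, triplet classification, DYW filtering), `design`
#' (consensus motifs and scaffold assembly), `retarget` (PPR-code
#' reprogramming), `scan` (off-target scan and logo), `quantify` (trace
#' quantification and replicate summary), `call` (editing-site calling),
#' `preference` (neighbouring-nucleotide ANOVA/Tukey table). Every run writes
#' its artifacts plus a `provenance.json` (parameters, input digests, package
#' version) into `out_dir`.
#'
#' @param config A list, or a path to a YAML/JSON file, with elements
#'   `subcommand`, `out_dir`, `params` (stage parameters; defaults follow the
#'   package's reference study conditions) and `inputs` (named paths).
#' @return Invisibly, a named list of the written artifact paths.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(config$subcommand,
    simulate = stage_simulate(config),
    catalog = stage_catalog(config),
    design = stage_design(config),
    retarget = stage_retarget(config),
    scan = stage_scan(config),
    quantify = stage_quantify(config),
    call = stage_call(config),
    preference = stage_preference(config)
  )
  out$provenance <- write_provenance(config, out)
  invisible(out)
}

ofile <- function(config, name) file.path(config$out_dir, name)

stage_simulate <- function(config) {
  seed <- param(config, "seed", 1L)
  plant <- param(config, "planted_sites")
  if (!is.null(plant)) plant <- as.data.frame(plant)
  plan <- param(config, "pileup_plan")
  if (is.null(plan)) {
    plan <- data.frame(pos = c(1000L, 2000L, 3000L),
                       freq = c(0.05, 0.1, 0.3),
                       coverage = 1000L, class = "TC")
  } else {
    plan <- as.data.frame(plan)
  }
  spec <- sim_spec(
    seed = seed,
    n_proteins = param(config, "n_proteins", 200L),
    plurality_prob = param(config, "plurality_prob", 0.6),
    transcript_lengths = param(config, "transcript_lengths", rep(500L, 20L)),
    planted_sites = plant,
    trace_edit_fraction = param(config, "trace_edit_fraction", 0.30),
    trace_noise_sd = param(config, "trace_noise_sd", 0.05),
    pileup_plan = plan,
    error_rate = param(config, "error_rate", 0.001),
    n_background = param(config, "n_background", 200L)
  )
  lib <- gen_motif_library(spec)
  write_motif_table(lib$motifs, ofile(config, "motifs.tsv"))
  utils::write.table(lib$dyw, ofile(config, "dyw.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(lib$consensus), ofile(config, "consensus_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  ref <- param(config, "reference_site", {
    set.seed(seed)  # deterministic default reference site
    paste0(random_rna(15L), "U")
  })
  txm <- gen_transcriptome(spec, ref)
  write_fasta_seqs(txm$transcripts, ofile(config, "transcripts.fasta"))
  jsonlite::write_json(txm$manifest, ofile(config, "transcript_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ctx <- param(config, "trace_context", {
    set.seed(seed)  # deterministic default amplicon context
    paste0(random_rna(15L), "U", random_rna(15L))
  })
  trace <- gen_trace(spec, ctx, param(config, "trace_edit_position", 16L))
  write_trace(trace, ofile(config, "trace.tsv"))
  jsonlite::write_json(attr(trace, "truth"), ofile(config, "trace_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  piles <- gen_pileups(spec)
  write_pileup(piles$treated, ofile(config, "treated_pileup.tsv"))
  write_pileup(piles$control, ofile(config, "control_pileup.tsv"))
  utils::write.table(piles$truth, ofile(config, "pileup_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(motifs = ofile(config, "motifs.tsv"),
       dyw = ofile(config, "dyw.tsv"),
       consensus_truth = ofile(config, "consensus_truth.json"),
       transcripts = ofile(config, "transcripts.fasta"),
       transcript_manifest = ofile(config, "transcript_manifest.json"),
       trace = ofile(config, "trace.tsv"),
       trace_truth = ofile(config, "trace_truth.json"),
       treated_pileup = ofile(config, "treated_pileup.tsv"),
       control_pileup = ofile(config, "control_pileup.tsv"),
       pileup_truth = ofile(config, "pileup_truth.tsv"))
}

stage_catalog <- function(config) {
  motifs <- read_motif_table(need_input(config, "motif_table"))
  policy <- unlist(param(config, "length_policy",
                         as.list(default_length_policy())))
  selected <- suppressWarnings(select_by_length(motifs, policy = policy))
  write_motif_table(selected, ofile(config, "motifs_selected.tsv"))
  trip <- do.call(rbind, lapply(split(motifs, motifs$protein_id), function(d) {
    out <- classify_triplets(d)
    if (nrow(out)) cbind(protein_id = d$protein_id[1L], out) else NULL
  }))
  rownames(trip) <- NULL
  utils::write.table(trip, ofile(config, "triplet_classes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  arts <- list(motifs_selected = ofile(config, "motifs_selected.tsv"),
               triplet_classes = ofile(config, "triplet_classes.tsv"))
  if (!is.null(config$inputs$dyw_table)) {
    dyw <- utils::read.delim(need_input(config, "dyw_table"),
                             stringsAsFactors = FALSE)
    res <- filter_dyw_domains(dyw,
                              max_unannotated = param(config, "max_unannotated", 34L),
                              min_length = param(config, "min_length", 116L),
                              max_span = param(config, "max_span", 80L))
    utils::write.table(res$retained, ofile(config, "dyw_retained.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$rejected, ofile(config, "dyw_rejections.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    arts$dyw_retained <- ofile(config, "dyw_retained.tsv")
    arts$dyw_rejections <- ofile(config, "dyw_rejections.tsv")
  }
  arts
}

stage_design <- function(config) {
  motifs <- read_motif_table(need_input(config, "motif_table"))
  dyw_seqs <- read_fasta_seqs(need_input(config, "dyw_fasta"), alphabet = "aa")
  cons <- lapply(split(motifs$sequence, motifs$motif_type), consensus)
  type_cons <- vapply(cons, `[[`, "", "consensus")
  need <- unique(designer_motif_order)
  missing <- setdiff(need, names(type_cons))
  if (length(missing)) stop("no motifs of type: ", paste(missing, collapse = ", "))
  dyw_seq <- if (length(dyw_seqs) > 1L) consensus(unname(dyw_seqs))$consensus
             else unname(dyw_seqs[[1L]])
  protein <- assemble_designer(
    pls = type_cons[designer_motif_order[1:9]],
    cterm = type_cons[designer_motif_order[10:14]],
    dyw = dyw_seq,
    name = param(config, "name", "designerKP"),
    length_policy = unlist(param(config, "length_policy",
                                 as.list(default_length_policy())))
  )
  write_designer(protein, fasta = ofile(config, "designer.fasta"),
                 json = ofile(config, "designer.json"))
  list(designer_fasta = ofile(config, "designer.fasta"),
       designer_json = ofile(config, "designer.json"))
}

stage_retarget <- function(config) {
  protein <- read_designer(need_input(config, "designer_json"))
  code <- if (!is.null(config$inputs$code_table)) {
    read_code_table(need_input(config, "code_table"))
  } else {
    default_code_table()
  }
  overrides <- param(config, "overrides")
  if (is.null(overrides) ||
      !all(c("L2", "S2", "E1") %in% names(overrides))) {
    stop("retarget requires residue-pair overrides for L2, S2 and E1")
  }
  overrides <- lapply(overrides, function(p) unlist(p))
  site <- target_site(param(config, "target_sequence",
                            stop("retarget requires params$target_sequence")),
                      direction = param(config, "direction", "U2C"))
  out <- retarget(protein, site, code, overrides)
  write_designer(out, fasta = ofile(config, "retargeted.fasta"),
                 json = ofile(config, "retargeted.json"))
  model <- predict_binding(out, code)
  jsonlite::write_json(
    list(positions = model$positions, weights = as.data.frame(t(model$weights)),
         motif_type = model$motif_type, pairs = model$pairs,
         unknown = model$unknown, consensus = binding_consensus(model)),
    ofile(config, "binding_model.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  list(retargeted_fasta = ofile(config, "retargeted.fasta"),
       retargeted_json = ofile(config, "retargeted.json"),
       binding_model = ofile(config, "binding_model.json"))
}

stage_scan <- function(config) {
  protein <- read_designer(need_input(config, "designer_json"))
  code <- if (!is.null(config$inputs$code_table)) {
    read_code_table(need_input(config, "code_table"))
  } else {
    default_code_table()
  }
  transcripts <- read_fasta_seqs(need_input(config, "transcripts"), "rna")
  model <- predict_binding(protein, code)
  hits <- scan_transcripts(transcripts, model,
                           max_mm = param(config, "max_mm", 3L),
                           require_edit_base = param(config, "require_edit_base", "U"))
  utils::write.table(hits, ofile(config, "hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_hits_bed(hits, ofile(config, "hits.bed"))
  arts <- list(hits = ofile(config, "hits.tsv"), hits_bed = ofile(config, "hits.bed"))
  ## logo over -16..+5 contexts of the hits that fit inside their transcript
  ctx <- mapply(function(tx, off) {
    s <- transcripts[[tx]]
    start <- off + 1L - 1L  # window starts at -15; logo starts at -16
    if (start >= 1L && start + 21L <= nchar(s)) substr(s, start, start + 21L)
    else NA_character_
  }, hits$transcript, hits$offset)
  ctx <- ctx[!is.na(ctx)]
  if (length(ctx)) {
    fm <- build_logo(ctx)
    write_frequency_matrix(fm, ofile(config, "logo.tsv"))
    arts$logo <- ofile(config, "logo.tsv")
  }
  arts
}

stage_quantify <- function(config) {
  paths <- config$inputs$traces
  if (is.null(paths)) paths <- need_input(config, "trace")
  paths <- unlist(paths)
  direction <- param(config, "direction", "U2C")
  rows <- list()
  ratios <- numeric(0)
  for (p in paths) {
    tr <- read_trace(p)
    idx <- param(config, "edit_index")
    if (is.null(idx)) {
      idx <- locate_edit_position(tr, param(config, "amplicon"),
                                  param(config, "edit_offset"))
    }
    m <- quantify_editing(tr, idx, direction = direction,
                          flank = param(config, "flank", 10L),
                          p_cutoff = param(config, "p_cutoff", 0.01))
    rows[[length(rows) + 1L]] <- data.frame(
      sample = m$sample_id, position = m$position,
      pctA = m$pct[["A"]], pctC = m$pct[["C"]],
      pctG = m$pct[["G"]], pctT = m$pct[["T"]],
      ratio = m$ratio, direction = direction,
      flags = paste(m$flags, collapse = ";"), stringsAsFactors = FALSE)
    ratios <- c(ratios, m$ratio)
  }
  meas <- do.call(rbind, rows)
  utils::write.table(meas, ofile(config, "measurements.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  s <- summarize_replicates(ratios)
  utils::write.table(
    data.frame(mean = s$mean, sd = s$sd, n = s$n,
               values = paste(signif(s$values, 6), collapse = ","),
               flags = paste(s$flags, collapse = ";")),
    ofile(config, "replicate_summary.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  list(measurements = ofile(config, "measurements.tsv"),
       replicate_summary = ofile(config, "replicate_summary.tsv"))
}

stage_call <- function(config) {
  treated <- load_pileup(need_input(config, "treated"),
                         min_qual = param(config, "min_qual", 20))
  control <- load_pileup(need_input(config, "control"),
                         min_qual = param(config, "min_qual", 20))
  snps <- if (!is.null(config$inputs$snp)) {
    read_snp_positions(need_input(config, "snp"))
  } else NULL
  ctl_sig <- if (!is.null(config$inputs$control_significant)) {
    utils::read.delim(need_input(config, "control_significant"),
                      stringsAsFactors = FALSE)
  } else NULL
  res <- call_editing_sites(
    treated, control, snp_positions = snps, control_significant = ctl_sig,
    min_cov = param(config, "min_cov", 10L),
    min_freq = param(config, "min_freq", 0.05),
    count_mode = param(config, "count_mode", "coverage"),
    alpha = param(config, "alpha", 0.05))
  write_calls(res$calls, ofile(config, "calls.tsv"))
  write_calls(res$removed, ofile(config, "calls_removed.tsv"))
  write_calls(res$candidates, ofile(config, "candidates.tsv"))
  message("editcall: ", nrow(res$candidates), " candidates, ",
          nrow(res$calls), " significant calls, ",
          nrow(res$removed), " removed (control/SNP)")
  list(calls = ofile(config, "calls.tsv"),
       calls_removed = ofile(config, "calls_removed.tsv"),
       candidates = ofile(config, "candidates.tsv"))
}

stage_preference <- function(config) {
  meas <- utils::read.delim(need_input(config, "measurements"),
                            stringsAsFactors = FALSE)
  pref <- neighbor_preference(meas, alpha = param(config, "alpha", 0.05))
  utils::write.table(as.data.frame(pref), ofile(config, "preference.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(preference = ofile(config, "preference.tsv"))
}
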