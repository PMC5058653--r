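# End-to-end pipeline: ensembles in (files or synthetic specs), fluctuation
# profiles, clustering, lysine reactivity, cross-RMSd comparison and mimetic
# window selection out, with full provenance. Identical config + seed
# reproduces every numeric field exactly.

#' Pipeline configuration
#'
#' All tunable parameters of the analysis chain with their standard
#' defaults: 150-frame ensembles, fragment 1-38, 5-residue core window,
#' clustering cutoff 2.0 A, probe radius 1.4 A with 960 sphere points, and
#' a 2-4 A band for the cross-RMSd range statistic.
#'
#' @param protein_pdb,fragment_pdb optional multi-model PDB paths; when
#'   absent the synthetic samplers generate the ensembles.
#' @param sequence protein sequence used by the synthetic samplers (default:
#'   the packaged human Fhit sequence).
#' @param fragment_range N-terminal fragment range (default 1-38).
#' @param n_frames frames per synthetic ensemble (default 150).
#' @param amplitude per-axis Gaussian amplitude in A (default 0.3).
#' @param loop_range elevated-flexibility loop (default 108-127).
#' @param loop_multiplier loop amplitude multiplier (default 3).
#' @param planted_window fragment window whose dynamics match the protein's
#'   (default 8-12).
#' @param outside_scale fragment amplitude multiplier outside the planted
#'   window (default 3).
#' @param window_len mimetic core window length (default 5).
#' @param max_extension hydrophilic extension per side (default 1).
#' @param cluster_cutoff average-linkage cutoff in A (default 2.0).
#' @param probe_radius SASA probe radius in A (default 1.4).
#' @param n_sphere_points SASA sphere points (default 960).
#' @param range_lo,range_hi cross-RMSd band in A (defaults 2 and 4).
#' @param charge_table optional path to a residue charge TSV.
#' @param output_dir optional directory for written artifacts.
#' @param seed integer seed driving every source of randomness.
#' @return object of class `PipelineConfig` (a named list).
#' @export
pipeline_config <- function(protein_pdb = NULL, fragment_pdb = NULL,
                            sequence = fhit_sequence(),
                            fragment_range = residue_range(1, 38),
                            n_frames = 150L, amplitude = 0.3,
                            loop_range = residue_range(108, 127),
                            loop_multiplier = 3,
                            planted_window = residue_range(8, 12),
                            outside_scale = 3,
                            window_len = 5L, max_extension = 1L,
                            cluster_cutoff = 2.0, probe_radius = 1.4,
                            n_sphere_points = 960L,
                            range_lo = 2.0, range_hi = 4.0,
                            charge_table = NULL, output_dir = NULL,
                            seed = 1L) {
  cfg <- list(protein_pdb = protein_pdb, fragment_pdb = fragment_pdb,
              sequence = sequence,
              fragment_range = .as_residue_range(fragment_range),
              n_frames = as.integer(n_frames), amplitude = amplitude,
              loop_range = if (!is.null(loop_range))
                .as_residue_range(loop_range),
              loop_multiplier = loop_multiplier,
              planted_window = .as_residue_range(planted_window),
              outside_scale = outside_scale,
              window_len = as.integer(window_len),
              max_extension = as.integer(max_extension),
              cluster_cutoff = cluster_cutoff, probe_radius = probe_radius,
              n_sphere_points = as.integer(n_sphere_points),
              range_lo = range_lo, range_hi = range_hi,
              charge_table = charge_table, output_dir = output_dir,
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from a key-value file
#'
#' Plain-text format, one `key = value` per line; `#` starts a comment.
#' Keys match the arguments of [pipeline_config()], with ranges written as
#' `start-end` (e.g. `loop_range = 108-127`). Unknown keys are an error.
#'
#' @param path path to the config file.
#' @param ... overrides applied after the file (e.g. `seed`, `output_dir`).
#' @return a `PipelineConfig`.
#' @export
read_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  range_keys <- c("fragment_range", "loop_range", "planted_window")
  char_keys <- c("protein_pdb", "fragment_pdb", "sequence", "charge_table",
                 "output_dir")
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: '", ln, "'",
                              call. = FALSE)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    if (!key %in% names(formals(pipeline_config)))
      stop("unknown config key: '", key, "'", call. = FALSE)
    args[[key]] <-
      if (key %in% range_keys) {
        parts <- as.integer(strsplit(val, "-", fixed = TRUE)[[1L]])
        residue_range(parts[1L], parts[2L])
      } else if (key %in% char_keys) val
      else as.numeric(val)
  }
  args <- utils::modifyList(args, list(...))
  do.call(pipeline_config, args)
}

.log_stage <- function(log, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  log$lines <- c(log$lines, line)
  message(line)
  log
}

#' Run the full ensemble-mimicry pipeline
#'
#' Stages, in order: (1) load or generate the protein and fragment
#' ensembles; (2) align both and compute fluctuation profiles; (3) cluster
#' the protein ensemble (average linkage) and pick medoid representatives;
#' (4) trajectory-averaged lysine exposure and reactivity ranking; (5)
#' fragment-vs-protein cross-RMSd matrix and fraction-in-range statistic;
#' (6) mimetic window selection, hydrophilic extension, Tat fusion and
#' scrambled control. When `output_dir` is set, TSV tables, FASTA peptides
#' and a log are written there.
#'
#' @param config a [pipeline_config()].
#' @return object of class `PipelineReport`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  log <- list(lines = character(0))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # stage 1: ensembles
  log <- .log_stage(log, "stage 1: ensembles (n_frames=%d, seed=%d)",
                    config$n_frames, config$seed)
  if (!is.null(config$protein_pdb)) {
    protein <- stage("load", read_pdb_models(config$protein_pdb))
    fragment <- stage("load", read_pdb_models(config$fragment_pdb))
  } else {
    pspec <- ensemble_spec(config$sequence, n_frames = config$n_frames,
                           sampler = "gaussian",
                           amplitude = config$amplitude,
                           loop_range = config$loop_range,
                           loop_multiplier = config$loop_multiplier,
                           seed = config$seed)
    mspec <- mimicry_spec(config$fragment_range, config$planted_window,
                          outside_scale = config$outside_scale,
                          seed = config$seed + 1000L)
    pair <- stage("generate", sample_fragment_pair(pspec, mspec))
    protein <- pair$protein; fragment <- pair$fragment
  }

  # stage 2: fluctuation profiles
  log <- .log_stage(log, "stage 2: residue fluctuation analysis")
  rfa_protein <- stage("rfa", residue_fluctuation(protein))
  rfa_fragment <- stage("rfa", residue_fluctuation(fragment))

  # stage 3: protein clustering
  log <- .log_stage(log, "stage 3: clustering (cutoff %.2f A)",
                    config$cluster_cutoff)
  pw <- stage("cluster", pairwise_rmsd_matrix(protein, fit = "backbone"))
  clustering <- stage("cluster",
                      average_linkage_cluster(pw, config$cluster_cutoff))

  # stage 4: lysine reactivity
  log <- .log_stage(log, "stage 4: lysine ASASA (probe %.2f A, %d points)",
                    config$probe_radius, config$n_sphere_points)
  asasa <- stage("sasa", lysine_asasa(protein,
                                      probe_radius = config$probe_radius,
                                      n_points = config$n_sphere_points))
  charges <- if (!is.null(config$charge_table))
    stage("charges", load_charge_table(config$charge_table))
  reactivity <- if (nrow(asasa))
    stage("rank", rank_lysines(asasa, charges)) else NULL

  # stage 5: cross-RMSd matrix
  log <- .log_stage(log, "stage 5: cross-RMSd matrix")
  frag_res <- unique(fragment$topology$residue_number)
  mapping <- residue_mapping(frag_res, .range_seq(config$fragment_range))
  cross <- stage("cross", cross_rmsd_matrix(fragment, protein, mapping))
  frac <- fraction_in_range(cross, config$range_lo, config$range_hi)
  log <- .log_stage(log, "  %d x %d = %d values, fraction in [%g, %g] A: %.3f",
                    nrow(cross$values), ncol(cross$values),
                    length(cross$values), config$range_lo, config$range_hi,
                    frac)

  # stage 6: mimetic window
  log <- .log_stage(log, "stage 6: mimetic window selection (len %d)",
                    config$window_len)
  frag_seq <- substr(config$sequence, config$fragment_range$start,
                     config$fragment_range$end)
  mim <- stage("window",
               mimicry_report(rfa_fragment, rfa_protein, mapping, frag_seq,
                              window_len = config$window_len,
                              max_extension = config$max_extension,
                              seed = config$seed + 2000L))
  log <- .log_stage(log, "  core %s (%s), extended %s (%s)",
                    format(mim$core), mim$core_peptide,
                    format(mim$extended), mim$extended_peptide)

  report <- structure(list(
    rfa_protein = rfa_protein, rfa_fragment = rfa_fragment,
    clustering = clustering, lys_asasa = asasa, reactivity = reactivity,
    cross_matrix = cross, fraction_in_range = frac, mimicry = mim,
    protein = protein, fragment = fragment,
    provenance = list(config = config, seed = config$seed,
                      version = as.character(utils::packageVersion("ensemblemimic"))),
    log = log$lines
  ), class = "PipelineReport")

  if (!is.null(config$output_dir)) .write_report(report, config$output_dir)
  report
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(report$rfa_protein, file.path(dir, "rfa_protein.tsv"))
  .write_tsv(report$rfa_fragment, file.path(dir, "rfa_fragment.tsv"))
  cl <- report$clustering
  .write_tsv(data.frame(frame = seq_along(cl$assignment),
                        cluster = cl$assignment),
             file.path(dir, "clusters.tsv"))
  .write_tsv(data.frame(cluster = as.integer(names(cl$representatives)),
                        representative_frame = unname(cl$representatives)),
             file.path(dir, "representatives.tsv"))
  if (!is.null(report$reactivity))
    .write_tsv(report$reactivity, file.path(dir, "lys_reactivity.tsv"))
  m <- report$cross_matrix$values
  utils::write.table(m, file.path(dir, "cross_rmsd.tsv"), sep = "\t",
                     quote = FALSE,
                     row.names = paste0("frag_", seq_len(nrow(m))),
                     col.names = paste0("prot_", seq_len(ncol(m))))
  mim <- report$mimicry
  fasta <- c(paste0(">core_", format(mim$core)), mim$core_peptide,
             paste0(">extended_", format(mim$extended)), mim$extended_peptide,
             ">tat_construct", mim$tat_construct,
             ">scrambled_control", mim$scrambled)
  writeLines(fasta, file.path(dir, "peptides.fasta"))
  write_pdb_models(report$protein, file.path(dir, "protein.pdb"))
  write_pdb_models(report$fragment, file.path(dir, "fragment.pdb"))
  writeLines(report$log, file.path(dir, "pipeline.log"))
  invisible(dir)
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("PipelineReport (seed ", x$provenance$seed, ")\n", sep = "")
  cat("  protein : ", n_frames(x$protein), " frames, ",
      length(unique(x$protein$topology$residue_number)), " residues\n",
      sep = "")
  cat("  fragment: ", n_frames(x$fragment), " frames, ",
      length(unique(x$fragment$topology$residue_number)), " residues\n",
      sep = "")
  cat("  clusters: ", max(x$clustering$assignment), " (cutoff ",
      x$clustering$cutoff, " A)\n", sep = "")
  cat("  cross-RMSd: ", nrow(x$cross_matrix$values), " x ",
      ncol(x$cross_matrix$values), " values; fraction in band: ",
      round(x$fraction_in_range, 3), "\n", sep = "")
  if (!is.null(x$reactivity))
    cat("  top-ranked Lys: ", x$reactivity$residue_number[1L], "\n", sep = "")
  print(x$mimicry)
  invisible(x)
}

#' @export
summary.PipelineReport <- function(object, ...) {
  x <- object
  cat("Fluctuation (protein): mean ", round(mean(x$rfa_protein$rmsf), 3),
      " A, max ", round(max(x$rfa_protein$rmsf), 3), " A at residue ",
      x$rfa_protein$residue_number[which.max(x$rfa_protein$rmsf)], "\n",
      sep = "")
  cat("Fluctuation (fragment): mean ", round(mean(x$rfa_fragment$rmsf), 3),
      " A\n", sep = "")
  print(x)
  invisible(x)
}
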