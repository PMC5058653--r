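# Mimetic window selection: compare fragment and protein fluctuation
# profiles over a residue mapping, pick the contiguous window of closest
# dynamic similarity, extend it with hydrophilic flanks, and build the
# cell-penetrating Tat fusion plus a scrambled control.

#' Residue correspondence between a fragment and a protein
#'
#' Ordered 1:1 pairs of residue numbers; both sides must be strictly
#' increasing. For an N-terminal fragment the mapping is positional identity.
#'
#' @param fragment,protein integer vectors of equal length.
#' @return object of class `ResidueMapping` with a `pairs` data.frame.
#' @export
residue_mapping <- function(fragment, protein = fragment) {
  fragment <- as.integer(fragment); protein <- as.integer(protein)
  if (length(fragment) != length(protein))
    stop("mapping sides must have equal length", call. = FALSE)
  if (!length(fragment)) stop("empty mapping", call. = FALSE)
  if (any(diff(fragment) <= 0) || any(diff(protein) <= 0))
    stop("mapping residue numbers must be strictly increasing", call. = FALSE)
  structure(list(pairs = data.frame(fragment = fragment, protein = protein)),
            class = "ResidueMapping")
}

#' @export
print.ResidueMapping <- function(x, ...) {
  cat("ResidueMapping: ", nrow(x$pairs), " residues (fragment ",
      x$pairs$fragment[1L], "-", x$pairs$fragment[nrow(x$pairs)],
      " -> protein ", x$pairs$protein[1L], "-",
      x$pairs$protein[nrow(x$pairs)], ")\n", sep = "")
  invisible(x)
}

#' Per-residue fluctuation difference between fragment and protein
#'
#' `|RMSF_frag(i) - RMSF_prot(map(i))|` for every mapped residue, in mapping
#' order: the dissimilarity profile the mimetic window is selected on.
#'
#' @param frag,prot `FluctuationProfile` objects (see
#'   [residue_fluctuation()]).
#' @param mapping a [residue_mapping()]; both profiles must cover all mapped
#'   residues.
#' @return data.frame with columns `residue_number` (fragment numbering) and
#'   `delta` (A).
#' @export
rfa_difference_profile <- function(frag, prot, mapping) {
  fi <- match(mapping$pairs$fragment, frag$residue_number)
  pi_ <- match(mapping$pairs$protein, prot$residue_number)
  if (anyNA(fi) || anyNA(pi_))
    stop("mapping refers to residues absent from a fluctuation profile",
         call. = FALSE)
  data.frame(residue_number = mapping$pairs$fragment,
             delta = abs(frag$rmsf[fi] - prot$rmsf[pi_]))
}

#' Select the minimal mimetic window
#'
#' Scans every contiguous window of `window_len` residues in the difference
#' profile and returns the one minimising the mean `|delta|`; ties go to the
#' smallest start position. The window covers contiguous residue numbers
#' only.
#'
#' @param diff data.frame from [rfa_difference_profile()] (columns
#'   `residue_number`, `delta`).
#' @param window_len window length in residues (default 5).
#' @return list with `range` (a `ResidueRange` in fragment numbering) and
#'   `score` (mean `|delta|` in A).
#' @export
select_mimetic_window <- function(diff, window_len = 5L) {
  window_len <- as.integer(window_len)
  if (window_len < 1L) stop("window_len must be >= 1", call. = FALSE)
  n <- nrow(diff)
  if (window_len > n)
    stop("window_len exceeds the number of mapped residues", call. = FALSE)
  best <- NULL
  for (s in seq_len(n - window_len + 1L)) {
    idx <- s:(s + window_len - 1L)
    resn <- diff$residue_number[idx]
    if (any(diff(resn) != 1L)) next  # non-contiguous stretch
    score <- mean(diff$delta[idx])
    if (is.null(best) || score < best$score - 1e-15)
      best <- list(range = residue_range(resn[1L], resn[window_len]),
                   score = score)
  }
  if (is.null(best))
    stop("no contiguous window of length ", window_len, " in the profile",
         call. = FALSE)
  best
}

#' Extend a core window with hydrophilic flanking residues
#'
#' On each side independently, up to `max_extension` flanking residues are
#' included as long as their Kyte-Doolittle hydropathy is negative
#' (hydrophilic); extension stops at the first hydrophobic flank or the
#' chain end. Improves water solubility of the designed peptide without
#' touching the core.
#'
#' @param core a `ResidueRange` (positions within `sequence`).
#' @param sequence one-letter sequence the positions refer to.
#' @param max_extension maximum residues added per side (default 1).
#' @return the extended `ResidueRange` (always containing the core).
#' @export
extend_window_hydrophilic <- function(core, sequence, max_extension = 1L) {
  core <- .as_residue_range(core)
  aa <- .validate_peptide(sequence, "sequence")
  n <- length(aa)
  if (core$start < 1L || core$end > n)
    stop("core window outside the sequence", call. = FALSE)
  start <- core$start
  for (k in seq_len(max_extension)) {
    cand <- core$start - k
    if (cand < 1L || hydropathy(aa[cand]) >= 0) break
    start <- cand
  }
  end <- core$end
  for (k in seq_len(max_extension)) {
    cand <- core$end + k
    if (cand > n || hydropathy(aa[cand]) >= 0) break
    end <- cand
  }
  residue_range(start, end)
}

#' Fuse a peptide downstream of the Tat cell-penetrating sequence
#'
#' Returns `YGRKKRRQRRR` (HIV-1 Tat 47-58) + `G` linker + peptide.
#'
#' @param peptide one-letter peptide string.
#' @return the Tat-G-peptide construct string.
#' @export
build_tat_construct <- function(peptide) {
  .validate_peptide(peptide)
  paste0(.TAT_SEQUENCE, "G", peptide)
}

#' Scrambled control peptide
#'
#' Seeded Fisher-Yates permutation of the residues, redrawn until it differs
#' from the input; the residue composition is preserved exactly.
#'
#' @param peptide one-letter peptide string, length >= 2 with at least two
#'   distinct residues.
#' @param seed integer seed (same seed, same scramble).
#' @return the scrambled peptide string.
#' @export
scramble_peptide <- function(peptide, seed) {
  aa <- .validate_peptide(peptide)
  if (length(aa) < 2L || length(unique(aa)) < 2L)
    stop("peptide cannot be scrambled: fewer than two distinct residues",
         call. = FALSE)
  .with_seed(seed, {
    repeat {
      perm <- aa[sample.int(length(aa))]
      if (!identical(perm, aa)) break
    }
    paste(perm, collapse = "")
  })
}

#' Full mimicry report for a fragment/protein pair of fluctuation profiles
#'
#' Runs the window-selection chain in one call: difference profile, minimal
#' window, hydrophilic extension, peptide strings, Tat fusion and scrambled
#' control.
#'
#' @param frag,prot `FluctuationProfile` objects.
#' @param mapping a [residue_mapping()].
#' @param sequence one-letter fragment sequence (positions = fragment
#'   residue numbers).
#' @param window_len core window length (default 5).
#' @param max_extension hydrophilic extension per side (default 1).
#' @param seed seed for the scrambled control.
#' @return object of class `MimicryReport`.
#' @export
mimicry_report <- function(frag, prot, mapping, sequence, window_len = 5L,
                           max_extension = 1L, seed = 1L) {
  diff <- rfa_difference_profile(frag, prot, mapping)
  sel <- select_mimetic_window(diff, window_len)
  ext <- extend_window_hydrophilic(sel$range, sequence, max_extension)
  core_pep <- substr(sequence, sel$range$start, sel$range$end)
  ext_pep <- substr(sequence, ext$start, ext$end)
  structure(list(
    diff_profile = diff,
    core = sel$range, core_score = sel$score,
    extended = ext,
    core_peptide = core_pep,
    extended_peptide = ext_pep,
    tat_construct = build_tat_construct(ext_pep),
    scrambled = scramble_peptide(ext_pep, seed),
    window_len = as.integer(window_len),
    seed = as.integer(seed)
  ), class = "MimicryReport")
}

#' @export
print.MimicryReport <- function(x, ...) {
  cat("MimicryReport\n")
  cat("  core window      : ", format(x$core), " (", x$core_peptide,
      "), mean |dRMSF| = ", signif(x$core_score, 3), " A\n", sep = "")
  cat("  extended window  : ", format(x$extended), " (", x$extended_peptide,
      ")\n", sep = "")
  cat("  Tat construct    : ", x$tat_construct, "\n", sep = "")
  cat("  scrambled control: ", x$scrambled, "\n", sep = "")
  invisible(x)
}
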