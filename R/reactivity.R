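# Lysine cross-linker reactivity ranking. NHS-ester cross-linkers react
# with the primary amine of lysine sidechains; adduct propensity is scored
# from (a) trajectory-averaged sidechain exposure (ASASA) and (b) optional
# amine partial charges from an external quantum-chemistry computation
# (consumed, never computed here). A more negative charge is read as greater
# electron availability on the amine, i.e. higher nucleophilicity.

#' Load a residue partial-charge table
#'
#' Plain-text TSV with header `residue_number<TAB>charge`; one row per
#' residue.
#'
#' @param path path to the TSV file.
#' @return named numeric vector: residue number -> charge. Empty (with a
#'   warning) for a header-only file.
#' @export
load_charge_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty charge table: ", path, call. = FALSE)
    return(stats::setNames(numeric(0), character(0)))
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || trimws(header[1L]) != "residue_number" ||
      trimws(header[2L]) != "charge")
    stop("charge table must have header 'residue_number<TAB>charge': ", path,
         call. = FALSE)
  if (length(lines) == 1L) {
    warning("charge table has no data rows: ", path, call. = FALSE)
    return(stats::setNames(numeric(0), character(0)))
  }
  res <- numeric(0)
  for (ln in 2:length(lines)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L)
      stop("malformed charge-table row at line ", ln, " of ", path,
           call. = FALSE)
    num <- suppressWarnings(as.integer(trimws(f[1L])))
    # tolerate a unicode minus sign in hand-edited tables
    val <- suppressWarnings(as.numeric(gsub("−", "-", trimws(f[2L]))))
    if (is.na(val) || is.na(num))
      stop("malformed charge-table row at line ", ln, " of ", path,
           call. = FALSE)
    if (as.character(num) %in% names(res))
      stop("duplicate residue number ", num, " at line ", ln, " of ", path,
           call. = FALSE)
    res[as.character(num)] <- val
  }
  res
}

#' Rank lysines by predicted cross-linker adduct propensity
#'
#' Combines two descriptors over the lysine set: an exposure score (min-max
#' normalised ASASA) and, when charges are supplied, a nucleophilicity score
#' (min-max normalised negated charge, so more negative charge scores
#' higher). The combined score is the weighted mean of the available
#' descriptors (default equal weights); with a single lysine both
#' normalisations degenerate to 1. Ranks are by descending combined score,
#' ties to the lower residue number.
#'
#' @param asasa named numeric vector (residue number -> mean sidechain SASA
#'   in A^2) or the data.frame returned by [lysine_asasa()].
#' @param charges optional named numeric vector (residue number -> partial
#'   charge) covering every lysine in `asasa`.
#' @param exposure_weight weight of the exposure descriptor when charges are
#'   present (default 0.5).
#' @return a `LysReactivityTable` data.frame with columns `residue_number`,
#'   `asasa`, `amine_charge`, `exposure_score`, `nucleophilicity_score`,
#'   `combined_score`, `rank`, ordered by rank.
#' @export
rank_lysines <- function(asasa, charges = NULL, exposure_weight = 0.5) {
  if (is.data.frame(asasa))
    asasa <- stats::setNames(asasa$asasa, asasa$residue_number)
  if (!length(asasa)) stop("empty ASASA table", call. = FALSE)
  resno <- as.integer(names(asasa))
  if (anyNA(resno)) stop("ASASA values must be named by residue number",
                         call. = FALSE)
  minmax <- function(x) {
    rng <- range(x)
    if (length(x) == 1L || rng[1L] == rng[2L]) return(rep(1, length(x)))
    (x - rng[1L]) / (rng[2L] - rng[1L])
  }
  exposure <- minmax(unname(asasa))
  if (!is.null(charges)) {
    ch <- charges[as.character(resno)]
    if (anyNA(ch))
      stop("charges missing for lysine(s): ",
           paste(resno[is.na(ch)], collapse = ", "), call. = FALSE)
    nucleo <- minmax(-unname(ch))
    combined <- exposure_weight * exposure + (1 - exposure_weight) * nucleo
  } else {
    ch <- rep(NA_real_, length(resno))
    nucleo <- rep(NA_real_, length(resno))
    combined <- exposure
  }
  ord <- order(-combined, resno)
  out <- data.frame(residue_number = resno, asasa = unname(asasa),
                    amine_charge = unname(ch), exposure_score = exposure,
                    nucleophilicity_score = nucleo,
                    combined_score = combined)[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("LysReactivityTable", "data.frame")
  out
}
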