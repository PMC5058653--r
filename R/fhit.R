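# The human Fhit (fragile histidine triad) sequence packaged as plain-text
# FASTA. Fhit's N-terminal 38 residues carry the annexin-A4 binding region;
# the QHLIKPS heptapeptide sits at positions 7-13 and the fragment's
# lysines at 11, 18 and 29.

#' Human Fhit protein sequence
#'
#' Returns the 147-residue human Fhit sequence (UniProt P49789) shipped with
#' the package, optionally restricted to a residue range.
#'
#' @param region optional [residue_range()] (or length-2 vector) to extract,
#'   e.g. `c(1, 38)` for the N-terminal fragment.
#' @return one-letter amino-acid string.
#' @export
fhit_sequence <- function(region = NULL) {
  path <- system.file("extdata", "fhit_P49789.fasta",
                      package = "ensemblemimic", mustWork = TRUE)
  lines <- readLines(path, warn = FALSE)
  seq <- paste(lines[!startsWith(lines, ">")], collapse = "")
  if (!is.null(region)) {
    region <- .as_residue_range(region)
    seq <- substr(seq, region$start, region$end)
  }
  seq
}

#' Lysine positions in a sequence
#'
#' @param sequence one-letter amino-acid string.
#' @return integer positions of K residues (possibly empty).
#' @export
lysine_positions <- function(sequence) {
  which(strsplit(sequence, "")[[1]] == "K")
}
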