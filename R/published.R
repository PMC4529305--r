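# published summary values for the PtK2 (rat kangaroo) transcriptome
# resource, used as worked-arithmetic inputs and consistency anchors

#' Published transcriptome-wide statistics for the PtK2 resource
#'
#' The printed transcriptome-wide statistics of the rat kangaroo
#' (*Potorous tridactylus*) PtK2 transcriptome resource this package
#' re-implements the computations of. These are inputs for worked
#' arithmetic (partition identities, per-Unigene isoform means), not
#' values the package claims to reproduce from raw data.
#'
#' @return named numeric vector.
#' @export
ptk2_published_stats <- function() {
  c(total_raw_reads = 679303792,
    total_clean_reads = 678793914,
    total_nucleotides = 99012349450,
    q20_pct = 98.4,
    gc_pct = 49.9,
    mean_transcript_length = 1197,
    n50 = 3405,
    total_transcripts = 347323,
    transcripts_without_orf = 272033,
    transcripts_with_orf = 75290,
    total_unigenes = 252022,
    unigenes_without_orf = 231943,
    unigenes_with_orf = 20079,
    coding_clusters = 7846,
    coding_singletons = 12233,
    ribosomal_with_orf_of_75 = 65,
    ribosomal_with_transcripts_of_75 = 75,
    ceg_complete_of_248 = 239,
    ceg_partial_of_248 = 248)
}

#' Published binucleation counts from the PRC1 knockdown validation
#'
#' Cell counts scored 48 h after treating PtK2 cells with either carrier
#' alone (mock control) or the validated anti-PRC1 siRNA. Binucleation is
#' the scored phenotype of cytokinesis failure after PRC1 depletion.
#'
#' @return data.frame: condition, binucleated, total.
#' @export
ptk2_binucleation_counts <- function() {
  data.frame(condition = c("control", "siRNA"),
             binucleated = c(2L, 53L),
             total = c(278L, 256L))
}

#' The validated anti-PRC1 siRNA sequence
#'
#' Sense-strand sequence (5'->3') of the siRNA that produced the largest
#' binucleation increase in PtK2 cells; its length equals the design
#' default `k = 19`.
#'
#' @return a character string.
#' @export
prc1_sirna <- function() "GGACTGAGGTTGTCAAGAA"

#' Binucleation percentage from scored counts
#'
#' @param binucleated,total cell counts.
#' @param digits decimal places reported (1, matching the published
#'   precision).
#' @return percentage.
#' @export
binucleation_pct <- function(binucleated, total, digits = 1) {
  round(100 * binucleated / total, digits)
}
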