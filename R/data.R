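# Bundled example data: a qRT-PCR validation experiment of candidate
# (novel) and traditional housekeeping genes measured across five breast
# cell lines (MCF-7, MDA-MB-231, MDA-MB-468, T47D, MCF10A), and the
# RNA-seq screen summary of both panels over eight breast cell lines.

#' Paths to the bundled example data files
#'
#' @param file File name within the package's `extdata` directory; when
#'   omitted, lists the available files.
#' @return A path (or a character vector of file names).
#' @export
hkg_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "hkgselect")))
  }
  path <- system.file("extdata", file, package = "hkgselect")
  if (!nzchar(path)) abort(sprintf("No bundled file named %s.", file))
  path
}

#' Bundled qPCR C_T plate of ten reference genes in five breast cell lines
#'
#' Threshold cycles for a five-gene novel reference panel (CCSER2, UBXN4,
#' SYMPK, TMEM11, ANKRD17) and a five-gene traditional panel (GAPDH, B2M,
#' ACTB, TUBA1A, 18S) measured across five breast cell lines. The default
#' plate reports two decimals for all ten genes; `precise = TRUE` returns
#' the five-decimal measurements available for the novel panel only.
#'
#' @param precise Return the 5-gene, five-decimal novel-panel plate.
#' @return A C_T tibble (`gene_id` + five sample columns).
#' @export
example_ct_plate <- function(precise = FALSE) {
  file <- if (precise) "ct_plate_nhkg_precise.tsv" else "ct_plate_cell_lines.tsv"
  read_ct_matrix(hkg_example(file))
}

#' Bundled RNA-seq screen summary of both reference-gene panels
#'
#' Per-gene normalized mean expression and CV% over eight breast cell
#' lines for the ten novel housekeeping-gene candidates and the nine
#' traditional housekeeping genes, with the panel label.
#'
#' @return Tibble: `gene_id`, `panel` ("nhkg"/"thkg"), `mean`,
#'   `cv_percent`.
#' @export
example_panel_stats <- function() {
  x <- readr::read_tsv(hkg_example("cell_line_panel_stats.tsv"),
                       show_col_types = FALSE, progress = FALSE)
  tibble(gene_id = as.character(x$gene_id), panel = x$panel,
         mean = x$mean, cv_percent = x$cv_percent)
}

#' Reference-gene panels and the breast-cancer TF list
#'
#' The gene panels used throughout the examples: the ten screen candidates
#' (`nhkg_screen`), the nine traditional genes they are compared against
#' (`thkg_screen`), the five-gene qPCR validation panels (`nhkg_qpcr`,
#' `thkg_qpcr`), and the breast-cancer transcription-factor panel (`tfs`)
#' used by the co-regulation filter.
#'
#' @return Named list of character vectors.
#' @export
hkg_panels <- function() {
  list(
    nhkg_screen = c("UBXN4", "DHX9", "TMEM11", "LARP1", "STX5",
                    "ANKRD17", "SYMPK", "TAF2", "CCSER2", "MZT2B"),
    thkg_screen = c("PUM1", "RPL13A", "PGK1", "GUSB", "ACTB",
                    "DIMT1", "TUBA1A", "GAPDH", "B2M"),
    nhkg_qpcr = c("CCSER2", "UBXN4", "SYMPK", "TMEM11", "ANKRD17"),
    thkg_qpcr = c("GAPDH", "B2M", "ACTB", "TUBA1A", "18S"),
    tfs = c("AP1", "NFKB", "GATA3", "FOXA1", "ER", "Elk1", "STAT3",
            "STAT5", "HIF", "NOTCH", "SP1", "TP53", "MYC")
  )
}
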