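# Diagnostic figures for the pre-processing stage.

#' Plot dataset summary figures
#'
#' Draws a histogram of protein lengths and pie charts of the phylum and
#' genus composition of the filtered dataset (wedges ordered by count,
#' descending; records of unknown taxonomy appear as an "unknown" wedge).
#' Plotting failures (e.g. no graphics device available) are downgraded to
#' warnings so the pipeline continues.
#'
#' @param records Filtered protein records (lengths for the histogram).
#' @param summary A `dataset_summary` (taxon counts for the pie charts).
#' @param out_dir Output directory for PNG files.
#' @return Character vector of files actually written, invisibly.
#' @export
plot_summaries <- function(records, summary, out_dir) {
  written <- character(0)
  draw <- function(fname, expr) {
    path <- file.path(out_dir, fname)
    ok <- tryCatch({
      grDevices::png(path, width = 800, height = 600)
      on.exit(grDevices::dev.off(), add = TRUE)
      expr()
      TRUE
    }, error = function(e) {
      warning("could not draw ", fname, ": ", conditionMessage(e))
      FALSE
    })
    if (ok) written <<- c(written, path)
  }
  draw("protein_length_histogram.png", function() {
    graphics::hist(records$length, breaks = 30, col = "grey70",
                   main = "Protein length distribution",
                   xlab = "Length (AA residues)")
  })
  pie_of <- function(counts, n_unknown, title) {
    if (n_unknown > 0) {
      counts <- c(counts, unknown = n_unknown)
    }
    if (length(counts) == 0) stop("no categories to draw")
    graphics::pie(counts, labels = paste0(names(counts), " (", counts, ")"),
                  main = title)
  }
  draw("phylum_composition.png", function() {
    pie_of(summary$counts_by_phylum,
           summary$n_after - sum(summary$counts_by_phylum),
           "Proteins per phylum")
  })
  draw("genus_composition.png", function() {
    pie_of(summary$counts_by_genus, summary$n_unknown_taxonomy,
           "Proteins per genus")
  })
  invisible(written)
}
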