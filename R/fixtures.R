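fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "mycodiff", mustWork = FALSE)
  if (!nzchar(p)) stop("fixture not found: ", file)
  p
}

read_fixture <- function(file) {
  utils::read.delim(fixture_path(file), stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Published per-gene abundance tables and primer list
#'
#' Returns the printed per-gene log2 abundance triplets (MII24/MI16,
#' MII48/MI16, MII72/MI16) shipped as plain-text fixtures: the
#' well-characterized genes with the greatest MI/MII differences
#' (\code{known}), the 53 strongly regulated genes of unknown function
#' conserved across the genus (\code{top_unknown}), the putative
#' secondary-metabolite clusters (\code{secondary}), and the qPCR primer
#' pairs (\code{primers}: 12 primers targeting 6 genes).
#'
#' @return Named list of data.frames: \code{primers}, \code{known},
#'   \code{top_unknown}, \code{secondary}.
#' @export
load_paper_tables <- function() {
  list(primers = read_fixture("table1_primers.tsv"),
       known = read_fixture("table2_known_genes.tsv"),
       top_unknown = read_fixture("table3_top_unknown_genes.tsv"),
       secondary = read_fixture("table4_secondary_clusters.tsv"))
}
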