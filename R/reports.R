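#' Write a region report TSV
#'
#' One row per region with the full [region_set()] schema (plus the
#' `coregulated` column when present, as in ground-truth sets from
#' [simulate_genome()]). Readable back with [read_region_table()].
#'
#' @param regions A [region_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_region_table <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  df <- as.data.frame(regions)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a region report TSV
#'
#' @param path Path written by [write_region_table()].
#' @return A [region_set()].
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) stop("region table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = NA, check.names = FALSE)
  if (nrow(df) == 0L) {
    out <- empty_region_set()
    if ("coregulated" %in% names(df)) out$coregulated <- logical(0)
    return(out)
  }
  df$span_start <- as.integer(df$span_start)
  df$span_end <- as.integer(df$span_end)
  df$n_members <- as.integer(df$n_members)
  df$n_distinct_families <- as.integer(df$n_distinct_families)
  df$strict_cluster <- as.logical(df$strict_cluster)
  df$dominant_family <- as.character(df$dominant_family)
  if ("coregulated" %in% names(df)) df$coregulated <- as.logical(df$coregulated)
  region_set(df)
}

#' Export regions as BED intervals
#'
#' BED uses 0-based half-open coordinates, so `span_start` is shifted down
#' by one on output. Columns: chrom, start, end, region_id, member count,
#' strand placeholder `"."`.
#'
#' @param regions A [region_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_region_bed <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  bed <- data.frame(
    chrom = regions$chrom,
    start = regions$span_start - 1L,
    end = regions$span_end,
    name = regions$region_id,
    score = regions$n_members,
    strand = rep(".", nrow(regions)),
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a survey summary TSV
#'
#' One survey-table-shaped row: label, cluster count, one tandem column per
#' family, tandem sum, total.
#'
#' @param summary A `survey_summary` from [summarize_survey()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_survey_table <- function(summary, path) {
  stopifnot(inherits(summary, "survey_summary"))
  utils::write.table(as.data.frame(summary), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
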