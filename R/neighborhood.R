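#' Construct a region set
#'
#' A region set is the package's representation of detected (or planted)
#' neighborhoods: a data frame with one row per region and columns
#' `region_id`, `chrom`, `span_start`, `span_end` (1-based inclusive, min
#' start / max end over members), `n_members`, `n_distinct_families`,
#' `category` (`multi_family_cluster` or `single_family_tandem`),
#' `strict_cluster` (logical: at least three distinct families, the classical
#' biosynthetic-cluster definition), `dominant_family` (for tandems; `NA`
#' otherwise), `member_ids` and `member_families` (comma-joined, in
#' increasing-start order). Ground-truth region sets from [simulate_genome()]
#' carry an extra logical `coregulated` column.
#'
#' @param df Data frame with the columns above.
#' @return The data frame with class `region_set` prepended.
#' @keywords internal
#' @export
region_set <- function(df) {
  need <- c("region_id", "chrom", "span_start", "span_end", "n_members",
            "n_distinct_families", "category", "strict_cluster",
            "dominant_family", "member_ids", "member_families")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("region set missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$region_id)) stop("duplicate region_id in region set")
  rownames(df) <- NULL
  class(df) <- c("region_set", "data.frame")
  df
}

empty_region_set <- function() {
  region_set(data.frame(
    region_id = character(0), chrom = character(0),
    span_start = integer(0), span_end = integer(0),
    n_members = integer(0), n_distinct_families = integer(0),
    category = character(0), strict_cluster = logical(0),
    dominant_family = character(0), member_ids = character(0),
    member_families = character(0), stringsAsFactors = FALSE
  ))
}

# Member gene IDs of one region row, as a character vector.
region_members <- function(regions, i = seq_len(nrow(regions))) {
  strsplit(regions$member_ids[i], ",", fixed = TRUE)
}

#' @export
print.region_set <- function(x, ...) {
  cat("Region set:", nrow(x), "regions (",
      sum(x$category == "multi_family_cluster"), "multi-family clusters,",
      sum(x$category == "single_family_tandem"), "single-family tandems )\n")
  if (nrow(x)) {
    show <- x[, c("region_id", "chrom", "span_start", "span_end", "n_members",
                  "category", "dominant_family")]
    print(utils::head(as.data.frame(show), 10L))
    if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more regions\n")
  }
  invisible(x)
}

#' Detect neighborhoods of proximal family genes
#'
#' Scans each chromosome left to right and chains family-labelled genes into
#' maximal runs. Two consecutive family genes join one chain iff the number
#' of unassigned genes between them is at most `max_intervening` AND the gap
#' (bases strictly between the end of the earlier and the start of the later
#' gene; overlapping genes count as 0) is at most `max_gap_bp`. Maximal
#' chains with at least `min_genes` members are emitted, so every family
#' gene belongs to at most one region and no region can be extended by an
#' adjacent family gene without violating a constraint.
#'
#' Input gene order is irrelevant (genes are sorted by chromosome, start,
#' end, gene_id first) and strand is never consulted: characterized plant
#' clusters mix gene orientations.
#'
#' @param genes A gene table ([gene_table()] / [read_gff3()]).
#' @param catalog A [family_catalog()]. Catalog genes absent from the
#'   annotation trigger a warning and are ignored.
#' @param max_intervening Maximum number of unassigned genes tolerated
#'   between two consecutive chained family genes (default 3).
#' @param max_gap_bp Maximum base-pair gap between consecutive chained family
#'   genes (default 50000, the scale of known plant cluster spans).
#' @param min_genes Minimum region size (default 3, the classical
#'   at-least-three-genes region definition).
#' @param min_distinct_families Passed to [classify_regions()] (default 2).
#' @return A classified [region_set()], ordered by (chrom, span_start), with
#'   region IDs `R001`, `R002`, ...
#' @export
detect_neighborhoods <- function(genes, catalog,
                                 max_intervening = 3L,
                                 max_gap_bp = 50000L,
                                 min_genes = 3L,
                                 min_distinct_families = 2L) {
  validate_gene_table(genes)
  stopifnot(inherits(catalog, "family_catalog"),
            max_intervening >= 0L, max_gap_bp > 0L, min_genes >= 2L)
  missing_ids <- setdiff(names(catalog$assignments), genes$gene_id)
  if (length(missing_ids)) {
    warning(length(missing_ids),
            " catalog gene(s) absent from the annotation were ignored (e.g. '",
            missing_ids[1L], "')")
  }
  if (nrow(genes) == 0L) return(empty_region_set())
  g <- sort_gene_table(genes)
  fam <- family_of(catalog, g$gene_id)

  chains <- list()
  for (chrom in unique(g$chrom)) {
    idx <- which(g$chrom == chrom)
    fidx <- idx[!is.na(fam[idx])]
    if (length(fidx) == 0L) next
    cur <- fidx[1L]
    for (k in seq_along(fidx)[-1L]) {
      prev <- fidx[k - 1L]
      this <- fidx[k]
      intervening <- this - prev - 1L  # genes between two consecutive family genes are all unassigned
      gap <- gene_gap_bp(g$end[prev], g$start[this])
      if (intervening <= max_intervening && gap <= max_gap_bp) {
        cur <- c(cur, this)
      } else {
        chains[[length(chains) + 1L]] <- cur
        cur <- this
      }
    }
    chains[[length(chains) + 1L]] <- cur
  }
  chains <- Filter(function(ch) length(ch) >= min_genes, chains)
  if (length(chains) == 0L) return(empty_region_set())

  rows <- lapply(chains, function(ch) {
    data.frame(
      chrom = g$chrom[ch[1L]],
      span_start = min(g$start[ch]),
      span_end = max(g$end[ch]),
      n_members = length(ch),
      n_distinct_families = length(unique(fam[ch])),
      category = NA_character_,
      strict_cluster = NA,
      dominant_family = NA_character_,
      member_ids = paste(g$gene_id[ch], collapse = ","),
      member_families = paste(fam[ch], collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$span_start, df$span_end), , drop = FALSE]
  df <- cbind(region_id = sprintf("R%03d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  classify_regions(region_set(df),
                   min_distinct_families = min_distinct_families,
                   families = catalog$families)
}

#' Classify regions as multi-family clusters or single-family tandems
#'
#' A region is a `multi_family_cluster` when it contains at least
#' `min_distinct_families` distinct families, otherwise a
#' `single_family_tandem` with `dominant_family` set to its most frequent
#' member family (ties broken by the canonical family order). The
#' `strict_cluster` flag additionally records whether the region meets the
#' classical biosynthetic-cluster bar of at least three distinct enzyme
#' classes; with the default five-family catalog the two-family bar is used
#' for the survey category because non-signature classes (acyltransferases
#' and the like) are invisible to the family universe.
#'
#' @param regions A [region_set()].
#' @param min_distinct_families Distinct-family threshold for the
#'   cluster category (default 2; must be >= 2).
#' @param families Canonical family order for tie-breaking.
#' @return The region set with `category`, `strict_cluster`,
#'   `dominant_family` and `n_distinct_families` (re)computed.
#' @export
classify_regions <- function(regions, min_distinct_families = 2L,
                             families = metabolic_families()) {
  stopifnot(inherits(regions, "region_set"), min_distinct_families >= 2L)
  if (nrow(regions) == 0L) return(regions)
  memfam <- strsplit(regions$member_families, ",", fixed = TRUE)
  n_distinct <- vapply(memfam, function(f) length(unique(f)), integer(1))
  regions$n_distinct_families <- n_distinct
  regions$strict_cluster <- n_distinct >= 3L
  is_cluster <- n_distinct >= min_distinct_families
  regions$category <- ifelse(is_cluster, "multi_family_cluster", "single_family_tandem")
  regions$dominant_family <- NA_character_
  for (i in which(!is_cluster)) {
    f <- memfam[[i]]
    lev <- c(families, sort(setdiff(unique(f), families)))
    tab <- table(factor(f, levels = lev))
    regions$dominant_family[i] <- names(tab)[which.max(tab)]
  }
  regions
}

#' Summarize a survey of detected regions
#'
#' Aggregates a classified region set into per-genome counts in the shape of
#' a published genomic-survey table: the number of multi-family cluster
#' candidates, the number of single-family tandem regions per family, and
#' their total. The additivity invariant
#' `n_total_regions == n_cluster_regions + sum(n_tandem_by_family)` holds by
#' construction.
#'
#' @param regions A classified [region_set()].
#' @param label Species or run name for the summary row.
#' @param families Family universe for the tandem columns; families observed
#'   as dominant but absent from this set are appended.
#' @return An object of class `survey_summary`: a list with `label`,
#'   `n_cluster_regions`, `n_tandem_by_family` (named integer vector) and
#'   `n_total_regions`.
#' @export
summarize_survey <- function(regions, label = "run", families = metabolic_families()) {
  stopifnot(inherits(regions, "region_set"))
  if (nrow(regions) && anyNA(regions$category)) {
    stop("regions must be classified before summarizing (see classify_regions)")
  }
  tand <- regions[regions$category == "single_family_tandem", , drop = FALSE]
  fams <- c(families, sort(setdiff(unique(tand$dominant_family), families)))
  n_tandem <- table(factor(tand$dominant_family, levels = fams))
  n_tandem <- stats::setNames(as.integer(n_tandem), fams)
  n_cluster <- sum(regions$category == "multi_family_cluster")
  structure(
    list(
      label = label,
      n_cluster_regions = as.integer(n_cluster),
      n_tandem_by_family = n_tandem,
      n_total_regions = as.integer(n_cluster + sum(n_tandem))
    ),
    class = "survey_summary"
  )
}

#' @export
print.survey_summary <- function(x, ...) {
  cat("Genomic survey:", x$label, "\n")
  cat("  multi-family cluster candidates:", x$n_cluster_regions, "\n")
  cat("  single-family tandem regions:   ",
      paste(sprintf("%s=%d", names(x$n_tandem_by_family), x$n_tandem_by_family),
            collapse = ", "),
      "(sum", sum(x$n_tandem_by_family), ")\n")
  cat("  total regions:", x$n_total_regions, "\n")
  invisible(x)
}

#' @export
as.data.frame.survey_summary <- function(x, ...) {
  out <- data.frame(label = x$label, n_cluster_regions = x$n_cluster_regions,
                    stringsAsFactors = FALSE)
  for (f in names(x$n_tandem_by_family)) {
    out[[paste0("tandem_", f)]] <- x$n_tandem_by_family[[f]]
  }
  out$n_tandem_total <- sum(x$n_tandem_by_family)
  out$n_total_regions <- x$n_total_regions
  out
}

#' Build a survey summary from per-category region counts
#'
#' Constructs a region set with the stated composition — `n_cluster`
#' placeholder multi-family clusters plus the given number of single-family
#' tandem regions per family — and summarizes it with [summarize_survey()].
#' Useful for checking the additivity of externally reported survey tables
#' against the package's own accounting.
#'
#' @param n_cluster Number of multi-family cluster regions.
#' @param n_tandem_by_family Named integer vector: single-family tandem
#'   region count per family.
#' @inheritParams summarize_survey
#' @return A `survey_summary`.
#' @export
#' @examples
#' survey_from_counts(39, c(P450 = 28, `2ODD` = 16, TPS = 6, PKS = 5, UGT = 15),
#'                    label = "A. thaliana")
survey_from_counts <- function(n_cluster, n_tandem_by_family, label = "run",
                               families = metabolic_families()) {
  stopifnot(n_cluster >= 0, all(n_tandem_by_family >= 0),
            !is.null(names(n_tandem_by_family)))
  fam_universe <- unique(c(families, names(n_tandem_by_family)))
  comp <- c(rep(list(c("P450", "TPS", "UGT")), n_cluster),
            unlist(lapply(names(n_tandem_by_family), function(f) {
              rep(list(rep(f, 3)), n_tandem_by_family[[f]])
            }), recursive = FALSE))
  if (length(comp) == 0L) {
    return(summarize_survey(empty_region_set(), label = label,
                            families = fam_universe))
  }
  rows <- lapply(seq_along(comp), function(i) {
    fams <- comp[[i]]
    data.frame(
      region_id = sprintf("S%04d", i), chrom = "chr1",
      span_start = i * 10000L, span_end = i * 10000L + 5000L,
      n_members = length(fams), n_distinct_families = NA_integer_,
      category = NA_character_, strict_cluster = NA,
      dominant_family = NA_character_,
      member_ids = paste(sprintf("S%04dg%d", i, seq_along(fams)), collapse = ","),
      member_families = paste(fams, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  regions <- classify_regions(region_set(do.call(rbind, rows)),
                              families = fam_universe)
  summarize_survey(regions, label = label, families = fam_universe)
}

#' Match detected regions against ground truth
#'
#' A detected region matches a truth region when the Jaccard index of their
#' member gene-ID sets is at least `min_jaccard`; pairs are matched greedily
#' one-to-one in descending Jaccard order (ties broken by detected then
#' truth position, for determinism). Precision is the fraction of detected
#' regions matched, recall the fraction of truth regions matched; empty sets
#' give the vacuous value 1.
#'
#' @param detected,truth [region_set()] objects.
#' @param min_jaccard Minimum member-set Jaccard index for a match
#'   (default 0.5, in (0, 1]).
#' @return A list of class `region_match` with `precision`, `recall`,
#'   `n_matched`, and a `pairs` data frame (detected_id, truth_id, jaccard).
#' @export
match_regions <- function(detected, truth, min_jaccard = 0.5) {
  stopifnot(inherits(detected, "region_set"), inherits(truth, "region_set"),
            min_jaccard > 0, min_jaccard <= 1)
  nd <- nrow(detected)
  nt <- nrow(truth)
  pairs <- data.frame(detected_id = character(0), truth_id = character(0),
                      jaccard = numeric(0), stringsAsFactors = FALSE)
  if (nd > 0L && nt > 0L) {
    dm <- region_members(detected)
    tm <- region_members(truth)
    cand <- expand.grid(d = seq_len(nd), t = seq_len(nt))
    cand$jaccard <- mapply(function(d, t) {
      a <- dm[[d]]; b <- tm[[t]]
      length(intersect(a, b)) / length(union(a, b))
    }, cand$d, cand$t)
    cand <- cand[cand$jaccard >= min_jaccard, , drop = FALSE]
    cand <- cand[order(-cand$jaccard, cand$d, cand$t), , drop = FALSE]
    used_d <- logical(nd); used_t <- logical(nt)
    for (i in seq_len(nrow(cand))) {
      d <- cand$d[i]; t <- cand$t[i]
      if (!used_d[d] && !used_t[t]) {
        used_d[d] <- TRUE; used_t[t] <- TRUE
        pairs <- rbind(pairs, data.frame(
          detected_id = detected$region_id[d], truth_id = truth$region_id[t],
          jaccard = cand$jaccard[i], stringsAsFactors = FALSE
        ))
      }
    }
  }
  structure(
    list(
      precision = if (nd == 0L) 1 else nrow(pairs) / nd,
      recall = if (nt == 0L) 1 else nrow(pairs) / nt,
      n_matched = nrow(pairs),
      pairs = pairs
    ),
    class = "region_match"
  )
}

#' @export
print.region_match <- function(x, ...) {
  cat(sprintf("Region matching: precision %.3f, recall %.3f (%d matched)\n",
              x$precision, x$recall, x$n_matched))
  invisible(x)
}
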