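#' Construct a gene table
#'
#' The package's representation of an annotation is a plain data frame with
#' one row per gene: `gene_id`, `chrom`, `start`, `end` (base pairs, 1-based
#' inclusive, as in GFF3), `strand` (`+`, `-` or `.`) and a free-text
#' `product` description (possibly empty). This constructor validates the
#' invariants; most users will get a gene table from [read_gff3()] or
#' [simulate_genome()] instead.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chrom Character vector of chromosome (sequence) names. Treated as
#'   opaque strings; no natural-sort assumptions.
#' @param start,end Integer vectors, 1-based inclusive, `1 <= start <= end`.
#' @param strand Character vector over `+`, `-`, `.` (default `.`). Strand is
#'   carried through all outputs but never used by the detector: known plant
#'   clusters mix gene orientations.
#' @param product Character vector of product descriptions (default empty).
#' @return A `data.frame` with the six columns above.
#' @export
#' @examples
#' gene_table("g1", "chr1", 100, 900, "+", "terpene synthase 21")
gene_table <- function(gene_id, chrom, start, end, strand = ".", product = "") {
  n <- length(gene_id)
  g <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    product = rep_len(as.character(product), n),
    stringsAsFactors = FALSE
  )
  validate_gene_table(g)
  g
}

validate_gene_table <- function(g) {
  stopifnot(is.data.frame(g))
  need <- c("gene_id", "chrom", "start", "end", "strand", "product")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("gene table is missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(g$start) || anyNA(g$end)) stop("gene coordinates must not be NA")
  if (any(g$start < 1L)) stop("gene start coordinates must be >= 1")
  if (any(g$end < g$start)) {
    bad <- g$gene_id[g$end < g$start][1L]
    stop("gene '", bad, "' has end < start")
  }
  if (!all(g$strand %in% c("+", "-", "."))) stop("strand must be one of '+', '-', '.'")
  if (anyDuplicated(g$gene_id)) {
    dup <- g$gene_id[duplicated(g$gene_id)][1L]
    stop("duplicate gene_id '", dup, "' in annotation")
  }
  invisible(g)
}

# Deterministic genomic sort: (chrom, start, end, gene_id).
sort_gene_table <- function(g) {
  g[order(g$chrom, g$start, g$end, g$gene_id), , drop = FALSE]
}

#' Read gene models from a GFF3 annotation
#'
#' Parses a GFF3 file (via \pkg{rtracklayer}) and returns one gene-table row
#' per feature of type `feature_type` (default `"gene"`); mRNA, CDS and other
#' feature rows are ignored because the survey counts genes, not transcripts.
#' Comment and directive lines are skipped. Coordinates are kept 1-based
#' inclusive exactly as in the file. Every selected feature must carry an
#' `ID=` attribute, unique within the file; the free-text `product` attribute
#' is carried along when present.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type (column 3) to extract; default `"gene"`.
#' @return A gene table ([gene_table()]) in file order.
#' @seealso [write_gff3()] for the lossless inverse.
#' @export
read_gff3 <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  prescan_gff3(path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) == 0L) {
    return(gene_table(character(0), character(0), integer(0), integer(0)))
  }
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(ids == "")) {
    stop("GFF3 feature of type '", feature_type, "' without an ID attribute")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate ID '", ids[duplicated(ids)][1L], "' in GFF3 file ", path)
  }
  product <- if ("product" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$product)
  } else {
    rep("", length(gr))
  }
  product[is.na(product)] <- ""
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  gene_table(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = strand,
    product = product
  )
}

# Line-numbered syntax checks the downstream GRanges import cannot report:
# wrong column count and end < start, each named by file line.
prescan_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 9L) {
      stop("malformed GFF3 line ", i, " in ", path, ": expected 9 tab-separated columns, found ",
           length(fields))
    }
    s <- suppressWarnings(as.integer(fields[[4L]]))
    e <- suppressWarnings(as.integer(fields[[5L]]))
    if (is.na(s) || is.na(e)) {
      stop("malformed GFF3 line ", i, " in ", path, ": non-numeric coordinates")
    }
    if (e < s) {
      stop("malformed GFF3 line ", i, " in ", path, ": end (", e, ") < start (", s, ")")
    }
  }
  invisible(TRUE)
}

#' Write gene models to a GFF3 file
#'
#' Emits a `##gff-version 3` annotation readable by [read_gff3()] with a
#' lossless round-trip of gene_id, chrom, start, end, strand and product.
#'
#' @param genes A gene table ([gene_table()]).
#' @param path Output path.
#' @param source Value for the GFF3 source column (default `"clusterscout"`).
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(genes, path, source = "clusterscout") {
  validate_gene_table(genes)
  if (nrow(genes) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  strand <- genes$strand
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = strand
  )
  gr$source <- source
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  prod <- genes$product
  prod[prod == ""] <- NA_character_
  gr$product <- prod
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Construct a family catalog
#'
#' A family catalog assigns gene IDs to signature enzyme families. Every
#' assigned label must belong to the recognized family set and each gene has
#' at most one label; genes absent from the catalog are "unassigned" and act
#' only as intervening genes during detection.
#'
#' @param assignments Named character vector: names are gene IDs, values are
#'   family labels.
#' @param families Recognized family labels, in canonical order; defaults to
#'   the five-family universe [metabolic_families()].
#' @return An object of class `family_catalog`.
#' @export
#' @examples
#' family_catalog(c(g1 = "P450", g2 = "TPS"))
family_catalog <- function(assignments = character(0), families = metabolic_families()) {
  assignments <- unlist(assignments)
  if (length(assignments) && is.null(names(assignments))) {
    stop("assignments must be a named character vector (gene_id -> family)")
  }
  assignments <- vapply(assignments, as.character, character(1))
  if (anyDuplicated(names(assignments))) {
    ids <- names(assignments)
    for (id in unique(ids[duplicated(ids)])) {
      labs <- unique(assignments[ids == id])
      if (length(labs) > 1L) {
        stop("gene '", id, "' assigned to conflicting families: ",
             paste(labs, collapse = ", "))
      }
    }
    assignments <- assignments[!duplicated(ids)]
  }
  unknown <- setdiff(unique(assignments), families)
  if (length(unknown)) {
    stop("unknown family label(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(families, collapse = ", "))
  }
  structure(
    list(assignments = assignments, families = families),
    class = "family_catalog"
  )
}

#' @export
print.family_catalog <- function(x, ...) {
  cat("Family catalog:", length(x$assignments), "genes over",
      length(x$families), "families\n")
  tab <- table(factor(x$assignments, levels = x$families))
  print(tab)
  invisible(x)
}

#' @export
length.family_catalog <- function(x) length(x$assignments)

# Family label per gene id, NA_character_ for unassigned genes.
family_of <- function(catalog, gene_ids) {
  out <- unname(catalog$assignments[gene_ids])
  names(out) <- gene_ids
  out
}

#' Read a gene-family assignment table
#'
#' Reads a two-column tab-separated file (`gene_id`, family label), with an
#' optional header line (recognized when the first field is `gene_id`,
#' `gene` or `id`, case-insensitively). Duplicate rows with conflicting
#' labels, and labels outside `families`, are errors.
#'
#' @param path Path to the TSV file.
#' @inheritParams family_catalog
#' @return A [family_catalog()].
#' @export
read_family_table <- function(path, families = metabolic_families()) {
  if (!file.exists(path)) stop("family table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[lines != ""]
  if (length(lines) == 0L) return(family_catalog(character(0), families))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("malformed family-table line ", bad[1L], " in ", path,
         ": expected 2 tab-separated columns")
  }
  first <- tolower(parts[[1L]][[1L]])
  if (first %in% c("gene_id", "gene", "id")) parts <- parts[-1L]
  if (length(parts) == 0L) return(family_catalog(character(0), families))
  ids <- vapply(parts, `[[`, character(1), 1L)
  labs <- vapply(parts, `[[`, character(1), 2L)
  family_catalog(stats::setNames(labs, ids), families = families)
}

#' Write a gene-family assignment table
#'
#' @param catalog A [family_catalog()].
#' @param path Output path; two-column TSV with a `gene_id`/`family` header.
#' @return Invisibly, `path`.
#' @export
write_family_table <- function(catalog, path) {
  stopifnot(inherits(catalog, "family_catalog"))
  df <- data.frame(
    gene_id = names(catalog$assignments),
    family = unname(catalog$assignments),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default keyword rules for family assignment
#'
#' Maps case-insensitive substrings of annotation product descriptions to the
#' five signature families. The first matching rule, in rule order, wins.
#' These heuristics are transparent and overridable; a curated family table
#' always beats them (see [run_survey()]).
#'
#' @return Named character vector: names are keywords, values are family labels.
#' @export
default_keyword_rules <- function() {
  c(
    "cytochrome P450" = "P450",
    "2-oxoglutarate" = "2ODD",
    "dioxygenase" = "2ODD",
    "terpene synthase" = "TPS",
    "polyketide synthase" = "PKS",
    "chalcone synthase" = "PKS",
    "UDP-glycosyltransferase" = "UGT",
    "UDP-glucosyltransferase" = "UGT"
  )
}

#' Assign gene families by keyword search on product descriptions
#'
#' Case-insensitive fixed-substring search of each rule keyword against each
#' gene's `product` text; the first matching rule in rule order wins. Genes
#' with no match stay unassigned (not an error). The assignment is
#' deterministic and independent of gene order.
#'
#' @param genes A gene table.
#' @param rules Named character vector keyword -> family label; default
#'   [default_keyword_rules()].
#' @inheritParams family_catalog
#' @return A [family_catalog()] covering the matched genes only.
#' @export
assign_families_by_keyword <- function(genes, rules = default_keyword_rules(),
                                       families = metabolic_families()) {
  validate_gene_table(genes)
  if (length(rules) == 0L) stop("keyword rules must be non-empty")
  unknown <- setdiff(unique(unname(rules)), families)
  if (length(unknown)) {
    stop("keyword rules map to unknown families: ", paste(unknown, collapse = ", "))
  }
  prod <- tolower(genes$product)
  assigned <- rep(NA_character_, nrow(genes))
  for (k in seq_along(rules)) {
    hit <- is.na(assigned) & grepl(tolower(names(rules)[k]), prod, fixed = TRUE)
    assigned[hit] <- unname(rules[[k]])
  }
  keep <- !is.na(assigned)
  family_catalog(stats::setNames(assigned[keep], genes$gene_id[keep]),
                 families = families)
}

#' Read a gene-by-sample expression matrix
#'
#' Tab-separated text: first column gene IDs, first row sample IDs, numeric
#' body. IDs are preserved in file order. With `strict = TRUE` (default)
#' negative values are rejected, matching the non-negativity expected of raw
#' abundance data.
#'
#' @param path Path to the TSV file.
#' @param strict Reject negative values? Default `TRUE`.
#' @return Numeric matrix, genes in rows, samples in columns, with dimnames.
#' @export
read_expression_matrix <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("expression matrix not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[lines != ""]
  if (length(lines) < 2L) stop("expression matrix ", path, " has no data rows")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1L]]
  samples <- header[-1L]
  ncol_expect <- length(header)
  body <- parts[-1L]
  bad <- which(lengths(body) != ncol_expect)
  if (length(bad)) {
    stop("ragged expression matrix ", path, ": line ", bad[1L] + 1L, " has ",
         lengths(body)[bad[1L]], " fields, expected ", ncol_expect)
  }
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ID '", gene_ids[duplicated(gene_ids)][1L],
         "' in expression matrix")
  }
  cells <- t(vapply(body, function(p) p[-1L], character(length(samples))))
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric value '", cells[idx[1L], idx[2L]], "' at gene '",
         gene_ids[idx[1L]], "', sample '", samples[idx[2L]], "'")
  }
  if (strict && any(vals < 0)) {
    idx <- which(vals < 0, arr.ind = TRUE)[1L, ]
    stop("negative value at gene '", gene_ids[idx[1L]], "', sample '",
         samples[idx[2L]], "' (strict mode expects non-negative raw values)")
  }
  dimnames(vals) <- list(gene_ids, samples)
  vals
}

#' Write a gene-by-sample expression matrix
#'
#' @param mat Numeric matrix with gene IDs as rownames and sample IDs as
#'   colnames.
#' @param path Output path (TSV).
#' @param digits Significant digits written (default 8).
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(mat, path, digits = 8) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1L, function(row) {
    paste(formatC(row, digits = digits, format = "g"), collapse = "\t")
  })
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}
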