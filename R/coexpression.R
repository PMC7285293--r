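#' Preprocess a raw expression matrix for correlation analysis
#'
#' Applies the standard log transform `log2(value + pseudo_count)` and drops
#' genes that cannot support a meaningful correlation: genes expressed
#' (raw value > 0) in fewer than `min_expressed_samples` samples, and genes
#' with zero variance after transformation (dropped with a warning).
#'
#' @param mat Numeric matrix, genes in rows, samples in columns, non-negative
#'   raw values.
#' @param min_expressed_samples Minimum number of samples with a positive raw
#'   value (default 3).
#' @param pseudo_count Added before the log (default 1).
#' @return Transformed numeric matrix over the surviving genes.
#' @export
preprocess_expression <- function(mat, min_expressed_samples = 3L, pseudo_count = 1) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (anyNA(mat)) stop("expression matrix contains missing values")
  if (any(mat < 0)) stop("raw expression values must be non-negative")
  if (ncol(mat) < 3L) stop("fewer than 3 samples: correlation is meaningless")
  keep <- rowSums(mat > 0) >= min_expressed_samples
  mat <- mat[keep, , drop = FALSE]
  lg <- log2(mat + pseudo_count)
  vars <- apply(lg, 1L, stats::var)
  zero <- vars == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene(s) dropped: ",
            paste(utils::head(rownames(lg)[zero], 5L), collapse = ", "))
    lg <- lg[!zero, , drop = FALSE]
  }
  lg
}

#' Pearson correlation matrix over genes
#'
#' Standard product-moment correlation of each gene pair across samples.
#' Expects a preprocessed matrix ([preprocess_expression()]): at least 3
#' samples and no zero-variance genes.
#'
#' @param mat Numeric matrix, genes in rows, samples in columns.
#' @return Symmetric correlation matrix with unit diagonal and gene IDs as
#'   dimnames.
#' @export
pcc_matrix <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (ncol(mat) < 3L) stop("need at least 3 samples for correlation")
  if (any(apply(mat, 1L, stats::var) == 0)) {
    stop("zero-variance gene reached pcc_matrix: preprocessing contract violated")
  }
  stats::cor(t(mat))
}

#' Mutual-rank matrix from a correlation matrix
#'
#' The ATTED-II co-expression score. For each gene i, its partners j != i are
#' ranked by descending correlation (best partner has rank 1; ties receive
#' the average of the tied rank positions), and the mutual rank is the
#' geometric mean of the two reciprocal rank positions:
#' `mr(i, j) = sqrt(rank_i(j) * rank_j(i))`. Lower values mean stronger
#' co-expression; off-diagonal values lie in `[1, n - 1]`. The diagonal is a
#' 0 sentinel (self-rank is undefined).
#'
#' @param pcc Symmetric correlation matrix (from [pcc_matrix()]), n >= 3.
#' @return Symmetric mutual-rank matrix with the same dimnames.
#' @export
mutual_rank <- function(pcc) {
  stopifnot(is.matrix(pcc), nrow(pcc) == ncol(pcc))
  n <- nrow(pcc)
  if (n < 3L) stop("mutual rank needs at least 3 genes")
  rk <- matrix(0, n, n, dimnames = dimnames(pcc))
  for (i in seq_len(n)) {
    rk[i, -i] <- rank(-pcc[i, -i], ties.method = "average")
  }
  mr <- sqrt(rk * t(rk))
  diag(mr) <- 0
  mr
}

#' Build a thresholded co-expression network
#'
#' Nodes are all genes; an undirected edge (i, j) is included iff
#' `mr(i, j) <= mr_max` and, when `pcc_min` is enabled,
#' `pcc(i, j) >= pcc_min`. Either rule may be disabled by passing `NULL`,
#' but not both. Edges carry `pcc` and `mr` attributes.
#'
#' @param pcc Correlation matrix ([pcc_matrix()]).
#' @param mr Mutual-rank matrix ([mutual_rank()]) over the same genes.
#' @param mr_max Mutual-rank cutoff (default 30, the usual ATTED-II scale), or
#'   `NULL` to disable.
#' @param pcc_min Minimum correlation, in (0, 1], or `NULL` (default) to
#'   disable.
#' @return An object of class `coexpression_network`: a list with `graph`
#'   (an \pkg{igraph} graph), `mr_max` and `pcc_min`.
#' @export
build_network <- function(pcc, mr, mr_max = 30, pcc_min = NULL) {
  stopifnot(is.matrix(pcc), is.matrix(mr), all(dim(pcc) == dim(mr)),
            identical(rownames(pcc), rownames(mr)))
  if (is.null(mr_max) && is.null(pcc_min)) {
    stop("at least one threshold rule (mr_max or pcc_min) must be enabled")
  }
  if (!is.null(mr_max) && mr_max < 0) stop("mr_max must be non-negative")
  if (!is.null(pcc_min) && (pcc_min <= 0 || pcc_min > 1)) {
    stop("pcc_min must lie in (0, 1]")
  }
  ids <- rownames(pcc)
  n <- nrow(pcc)
  keep <- upper.tri(pcc)
  if (!is.null(mr_max)) keep <- keep & (mr <= mr_max)
  if (!is.null(pcc_min)) keep <- keep & (pcc >= pcc_min)
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(
    gene_a = ids[idx[, 1L]],
    gene_b = ids[idx[, 2L]],
    pcc = pcc[idx],
    mr = mr[idx],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  structure(list(graph = g, mr_max = mr_max, pcc_min = pcc_min),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("Co-expression network:", igraph::vcount(x$graph), "genes,",
      igraph::ecount(x$graph), "edges\n")
  cat("  thresholds: mr <=", if (is.null(x$mr_max)) "(disabled)" else x$mr_max,
      "; pcc >=", if (is.null(x$pcc_min)) "(disabled)" else x$pcc_min, "\n")
  invisible(x)
}

#' @export
plot.coexpression_network <- function(x, ...) {
  g <- x$graph
  deg <- igraph::degree(g)
  g <- igraph::induced_subgraph(g, which(deg > 0))
  if (igraph::vcount(g) == 0L) {
    warning("network has no edges; nothing to plot")
    return(invisible(x))
  }
  w <- igraph::E(g)$mr
  igraph::plot.igraph(g, edge.width = 2 / sqrt(pmax(w, 1)),
                      vertex.size = 6, vertex.label.cex = 0.7, ...)
  invisible(x)
}

#' Extract co-expressed candidate regions
#'
#' The screen that turns a genomic candidate list into co-regulated
#' neighboring-gene clusters. For each region, members present as network
#' nodes are located in the connected components of the network; the report
#' records how many members fall inside the single best component, the mean
#' mutual rank over within-region edges (0 sentinel when the region has no
#' internal edge) and whether the region qualifies
#' (`n_members_in_largest_component >= min_coexpressed_members`). Region
#' members absent from the network are simply counted as not in the network.
#'
#' @param network A [build_network()] result.
#' @param regions A [region_set()].
#' @param min_coexpressed_members Minimum number of region members that must
#'   share one network component (default 3).
#' @return A data frame of class `coexpression_report`, sorted by
#'   (qualifies descending, mean_mr_within ascending), with columns
#'   `region_id`, `n_members`, `n_members_in_network`,
#'   `n_members_in_largest_component`, `mean_mr_within`, `qualifies`.
#' @export
extract_coexpressed_regions <- function(network, regions,
                                        min_coexpressed_members = 3L) {
  stopifnot(inherits(network, "coexpression_network"),
            inherits(regions, "region_set"),
            min_coexpressed_members >= 2L)
  g <- network$graph
  comp <- igraph::components(g)$membership
  nodes <- names(comp)
  members <- region_members(regions)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    mem <- members[[i]]
    in_net <- mem[mem %in% nodes]
    n_largest <- if (length(in_net)) max(table(comp[in_net])) else 0L
    mean_mr <- 0
    if (length(in_net) >= 2L) {
      sub <- igraph::induced_subgraph(g, in_net)
      if (igraph::ecount(sub) > 0L) mean_mr <- mean(igraph::E(sub)$mr)
    }
    data.frame(
      region_id = regions$region_id[i],
      n_members = regions$n_members[i],
      n_members_in_network = length(in_net),
      n_members_in_largest_component = as.integer(n_largest),
      mean_mr_within = mean_mr,
      qualifies = n_largest >= min_coexpressed_members,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    region_id = character(0), n_members = integer(0),
    n_members_in_network = integer(0),
    n_members_in_largest_component = integer(0),
    mean_mr_within = numeric(0), qualifies = logical(0),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$qualifies, out$mean_mr_within, out$region_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("coexpression_report", "data.frame")
  out
}

#' Write network edges as a TSV
#'
#' Columns `gene_a`, `gene_b`, `pcc`, `mutual_rank`, sorted by gene pair;
#' byte-identical across reruns on identical inputs.
#'
#' @param network A [build_network()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network_edges <- function(network, path) {
  stopifnot(inherits(network, "coexpression_network"))
  e <- igraph::as_data_frame(network$graph, what = "edges")
  df <- data.frame(
    gene_a = pmin(e$from, e$to),
    gene_b = pmax(e$from, e$to),
    pcc = formatC(e$pcc, digits = 8, format = "g"),
    mutual_rank = formatC(e$mr, digits = 8, format = "g"),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the network as GraphML
#'
#' @param network A [build_network()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network_graphml <- function(network, path) {
  stopifnot(inherits(network, "coexpression_network"))
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' Write a co-expression report TSV
#'
#' @param report A `coexpression_report` from [extract_coexpressed_regions()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_coexpression_report <- function(report, path) {
  stopifnot(inherits(report, "coexpression_report"))
  df <- as.data.frame(report)
  df$mean_mr_within <- formatC(df$mean_mr_within, digits = 8, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
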