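#' Specify a planted region for the synthetic genome
#'
#' Describes one region to plant: its category, the family label of each
#' member gene in genomic order (length = member count, at least 3), the gap
#' between consecutive members, and whether the members share a latent
#' co-regulation factor in the companion expression simulation.
#'
#' @param category `"multi_family_cluster"` (at least 2 distinct labels) or
#'   `"single_family_tandem"` (all labels identical).
#' @param families Character vector of member family labels, in order.
#' @param intra_gap_bp Gap between consecutive member genes (default 2000).
#' @param coregulated Should the members load on one latent expression
#'   factor? Default `FALSE`.
#' @return A list of class `planted_region_spec`.
#' @export
#' @examples
#' planted_region_spec("multi_family_cluster", c("TPS", "P450", "P450", "UGT"),
#'                     coregulated = TRUE)
planted_region_spec <- function(category = c("multi_family_cluster", "single_family_tandem"),
                                families, intra_gap_bp = 2000L,
                                coregulated = FALSE) {
  category <- match.arg(category)
  stopifnot(length(families) >= 3L, intra_gap_bp >= 0L)
  nd <- length(unique(families))
  if (category == "single_family_tandem" && nd != 1L) {
    stop("single_family_tandem requires identical member families")
  }
  if (category == "multi_family_cluster" && nd < 2L) {
    stop("multi_family_cluster requires at least 2 distinct member families")
  }
  structure(list(category = category, families = as.character(families),
                 intra_gap_bp = as.integer(intra_gap_bp),
                 coregulated = isTRUE(coregulated)),
            class = "planted_region_spec")
}

#' Default planted regions
#'
#' Five archetypal regions mirroring the signatures the scan targets: a
#' thalianol-like terpene cluster (TPS + three P450s, co-regulated), a
#' steroidal-alkaloid-like cluster (P450 + 2ODD + UGT, co-regulated), a
#' mixed four-family cluster without co-regulation, and two single-family
#' tandem arrays (UGT x4 and P450 x3).
#'
#' @return List of five [planted_region_spec()] objects.
#' @export
default_planted_regions <- function() {
  list(
    planted_region_spec("multi_family_cluster", c("TPS", "P450", "P450", "P450"),
                        coregulated = TRUE),
    planted_region_spec("multi_family_cluster", c("P450", "2ODD", "UGT"),
                        coregulated = TRUE),
    planted_region_spec("multi_family_cluster", c("PKS", "P450", "UGT", "2ODD"),
                        coregulated = FALSE),
    planted_region_spec("single_family_tandem", rep("UGT", 4L)),
    planted_region_spec("single_family_tandem", rep("P450", 3L))
  )
}

#' Specify a synthetic genome
#'
#' Study conditions for the genome generator: chromosomes carrying the
#' planted regions of `planted` among `n_background_genes` background genes,
#' of which a fraction `background_family_rate` receive a random family
#' label. Placement honours a recoverability contract: no background family
#' gene lies within `isolation_bp` of a planted region or of another
#' labelled background gene, so at default detector settings the planted
#' regions are exactly the detectable ones.
#'
#' @param n_chromosomes Number of chromosomes (default 5).
#' @param chrom_length Chromosome length in bp (default 3e7).
#' @param n_background_genes Background genes across the genome (default 200).
#' @param background_family_rate Fraction of background genes given a random
#'   family label (default 0.1).
#' @param planted List of [planted_region_spec()]; default
#'   [default_planted_regions()].
#' @param min_intergenic Minimum spacing between background genes
#'   (default 500 bp).
#' @param isolation_bp Isolation radius enforcing the recoverability
#'   contract (default 60000, above the detector's default 50 kb gap).
#' @param seed RNG seed (default 1).
#' @return A list of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(n_chromosomes = 5L, chrom_length = 3e7,
                                  n_background_genes = 200L,
                                  background_family_rate = 0.1,
                                  planted = default_planted_regions(),
                                  min_intergenic = 500L,
                                  isolation_bp = 60000L, seed = 1L) {
  stopifnot(n_chromosomes >= 1L, chrom_length > 0, n_background_genes >= 0L,
            background_family_rate >= 0, background_family_rate <= 1,
            min_intergenic >= 0L, isolation_bp > 0L)
  for (p in planted) stopifnot(inherits(p, "planted_region_spec"))
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.numeric(chrom_length),
    n_background_genes = as.integer(n_background_genes),
    background_family_rate = background_family_rate,
    planted = planted,
    min_intergenic = as.integer(min_intergenic),
    isolation_bp = as.integer(isolation_bp),
    seed = as.integer(seed)
  ), class = "synthetic_genome_spec")
}

# Product strings matching default_keyword_rules(), one pool per family.
family_product <- function(family, i) {
  switch(family,
    P450 = sprintf("cytochrome P450, family %d, subfamily A", 70L + i %% 30L),
    `2ODD` = "2-oxoglutarate and Fe(II)-dependent dioxygenase superfamily protein",
    TPS = sprintf("terpene synthase %d", 1L + i %% 30L),
    PKS = "polyketide synthase, chalcone synthase-like",
    UGT = sprintf("UDP-glycosyltransferase 7%dB%d", 1L + i %% 9L, 1L + i %% 6L),
    stop("no product template for family ", family)
  )
}

# Neutral products guaranteed not to match any default keyword rule.
neutral_products <- function() {
  c("hypothetical protein", "protein kinase superfamily protein",
    "pentatricopeptide repeat-containing protein", "F-box family protein",
    "RNA-binding protein", "major facilitator superfamily transporter",
    "zinc finger protein", "unknown protein")
}

#' Simulate a genome with planted clusters and tandem arrays
#'
#' Places the planted regions of `spec` at evenly spaced anchors (round-robin
#' across chromosomes), then scatters background genes uniformly outside an
#' isolation zone around each planted span, with at least `min_intergenic`
#' spacing. A fraction of background genes receive a random family label,
#' but labels are kept only when the gene is more than `isolation_bp` from
#' every other labelled background gene, so background genes can never form
#' a detectable chain and the planted regions are exactly the ground truth.
#' Product strings are generated to match [default_keyword_rules()], so
#' keyword assignment reproduces the returned catalog. Deterministic for a
#' fixed seed.
#'
#' @param spec A [synthetic_genome_spec()].
#' @return A list with `genes` (gene table, sorted by position), `catalog`
#'   (a [family_catalog()]) and `truth` (a classified [region_set()] with a
#'   logical `coregulated` column).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  with_seed(spec$seed, {
    planted <- spec$planted
    n_plant <- length(planted)
    chrom_names <- sprintf("chr%d", seq_len(spec$n_chromosomes))
    chrom_of <- if (n_plant) ((seq_len(n_plant) - 1L) %% spec$n_chromosomes) + 1L else integer(0)

    rows <- list()     # per-gene records
    planted_members <- vector("list", n_plant)
    exclusion <- lapply(seq_len(spec$n_chromosomes), function(i) NULL)
    gene_counter <- 0L

    for (ci in seq_len(spec$n_chromosomes)) {
      rids <- which(chrom_of == ci)
      m <- length(rids)
      if (m == 0L) next
      anchors <- round(spec$chrom_length * seq_len(m) / (m + 1L))
      for (j in seq_along(rids)) {
        p <- planted[[rids[j]]]
        k <- length(p$families)
        lens <- sample(1000:3000, k, replace = TRUE)
        starts <- integer(k); ends <- integer(k)
        starts[1L] <- anchors[j]
        ends[1L] <- starts[1L] + lens[1L] - 1L
        for (q in seq_len(k)[-1L]) {
          starts[q] <- ends[q - 1L] + p$intra_gap_bp + 1L
          ends[q] <- starts[q] + lens[q] - 1L
        }
        if (ends[k] + spec$isolation_bp > spec$chrom_length) {
          stop("planted region ", rids[j], " does not fit on ", chrom_names[ci],
               ": increase chrom_length or reduce planted regions")
        }
        keys <- character(k)
        for (q in seq_len(k)) {
          gene_counter <- gene_counter + 1L
          keys[q] <- sprintf("P%04d", gene_counter)
          rows[[length(rows) + 1L]] <- list(
            key = keys[q], chrom = chrom_names[ci],
            start = starts[q], end = ends[q],
            strand = sample(c("+", "-"), 1L),
            family = p$families[q],
            product = family_product(p$families[q], gene_counter)
          )
        }
        planted_members[[rids[j]]] <- keys
        exclusion[[ci]] <- rbind(exclusion[[ci]],
                                 c(starts[1L] - spec$isolation_bp,
                                   ends[k] + spec$isolation_bp))
      }
      # adjacent planted regions on one chromosome must not chain together
      if (m > 1L && any(diff(anchors) < 2L * spec$isolation_bp)) {
        stop("planted regions too dense on ", chrom_names[ci],
             ": anchors closer than twice isolation_bp")
      }
    }

    # background genes: uniform placement outside exclusion zones
    n_bg <- spec$n_background_genes
    if (n_bg > 0L) {
      bg_chrom <- sample.int(spec$n_chromosomes, n_bg, replace = TRUE)
      placed <- lapply(seq_len(spec$n_chromosomes), function(i) NULL)
      bg_keys <- character(n_bg)
      for (b in seq_len(n_bg)) {
        ci <- bg_chrom[b]
        len <- sample(1000:3000, 1L)
        ok <- FALSE
        for (attempt in 1:200) {
          s <- sample.int(max(1L, floor(spec$chrom_length - len - 1L)), 1L)
          e <- s + len - 1L
          ex <- exclusion[[ci]]
          if (!is.null(ex) && any(s <= ex[, 2L] & e >= ex[, 1L])) next
          pl <- placed[[ci]]
          if (!is.null(pl) &&
              any(s <= pl[, 2L] + spec$min_intergenic &
                  e >= pl[, 1L] - spec$min_intergenic)) next
          ok <- TRUE
          break
        }
        if (!ok) stop("could not place background gene ", b,
                      ": genome too crowded for spec")
        placed[[ci]] <- rbind(placed[[ci]], c(s, e))
        gene_counter <- gene_counter + 1L
        key <- sprintf("B%04d", gene_counter)
        bg_keys[b] <- key
        rows[[length(rows) + 1L]] <- list(
          key = key, chrom = chrom_names[ci], start = s, end = e,
          strand = sample(c("+", "-"), 1L),
          family = NA_character_,
          product = sample(neutral_products(), 1L)
        )
      }
      # label a fraction of background genes, keeping mutual isolation
      want_label <- stats::runif(n_bg) < spec$background_family_rate
      df_idx <- (length(rows) - n_bg + 1L):length(rows)
      lab_pos <- lapply(seq_len(spec$n_chromosomes), function(i) NULL)
      for (b in seq_len(n_bg)) {
        fam <- sample(metabolic_families(), 1L)  # draw always, for RNG-stream stability
        if (!want_label[b]) next
        r <- rows[[df_idx[b]]]
        ci <- bg_chrom[b]
        lp <- lab_pos[[ci]]
        if (!is.null(lp) &&
            any(r$start <= lp[, 2L] + spec$isolation_bp &
                r$end >= lp[, 1L] - spec$isolation_bp)) next
        lab_pos[[ci]] <- rbind(lp, c(r$start, r$end))
        r$family <- fam
        r$product <- family_product(fam, b)
        rows[[df_idx[b]]] <- r
      }
    }

    if (length(rows) == 0L) {
      truth <- empty_region_set()
      truth$coregulated <- logical(0)
      return(list(genes = gene_table(character(0), character(0), integer(0), integer(0)),
                  catalog = family_catalog(), truth = truth))
    }

    df <- do.call(rbind, lapply(rows, function(r) {
      data.frame(key = r$key, chrom = r$chrom, start = r$start, end = r$end,
                 strand = r$strand, family = r$family, product = r$product,
                 stringsAsFactors = FALSE)
    }))
    df <- df[order(df$chrom, df$start, df$end, df$key), , drop = FALSE]
    df$gene_id <- sprintf("SYNG%05d", seq_len(nrow(df)))
    id_of <- stats::setNames(df$gene_id, df$key)

    genes <- gene_table(df$gene_id, df$chrom, df$start, df$end, df$strand,
                        df$product)
    assigned <- !is.na(df$family)
    catalog <- family_catalog(stats::setNames(df$family[assigned],
                                              df$gene_id[assigned]))

    truth_rows <- lapply(seq_len(n_plant), function(ri) {
      ids <- unname(id_of[planted_members[[ri]]])
      sub <- df[match(ids, df$gene_id), , drop = FALSE]
      ord <- order(sub$start)
      sub <- sub[ord, , drop = FALSE]
      data.frame(
        region_id = sprintf("T%03d", ri),
        chrom = sub$chrom[1L],
        span_start = min(sub$start), span_end = max(sub$end),
        n_members = nrow(sub),
        n_distinct_families = length(unique(sub$family)),
        category = NA_character_, strict_cluster = NA,
        dominant_family = NA_character_,
        member_ids = paste(sub$gene_id, collapse = ","),
        member_families = paste(sub$family, collapse = ","),
        coregulated = planted[[ri]]$coregulated,
        stringsAsFactors = FALSE
      )
    })
    truth <- if (n_plant) region_set(do.call(rbind, truth_rows)) else {
      t0 <- empty_region_set(); t0$coregulated <- logical(0); t0
    }
    if (n_plant) {
      coreg <- truth$coregulated
      truth <- classify_regions(truth)
      truth$coregulated <- coreg
    }
    list(genes = genes, catalog = catalog, truth = truth)
  })
}

#' Specify a synthetic expression experiment
#'
#' Study conditions for the expression generator: a one-factor linear latent
#' model on the log2 scale. Each gene has a baseline drawn from
#' `Normal(baseline_mean, baseline_sd^2)`; for every co-regulated planted
#' region one latent factor `f_s ~ Normal(0, 1)` is drawn per sample and
#' member genes take `baseline + module_loading * f_s + noise`, while all
#' other genes take `baseline + noise`, `noise ~ Normal(0, noise_sd^2)`.
#' The expected within-module correlation is the classical one-factor value
#' `b^2 / (b^2 + sigma^2)`, i.e. 0.5 at the defaults `b = 1`, `sigma = 1`.
#'
#' @param n_samples Number of samples (default 100, at least 3).
#' @param module_loading Factor loading `b` of co-regulated module genes
#'   (default 1).
#' @param noise_sd Residual standard deviation `sigma` (default 1).
#' @param baseline_mean,baseline_sd Per-gene log2-scale baseline distribution
#'   (defaults 5 and 1).
#' @param seed RNG seed (default 1).
#' @return A list of class `synthetic_expression_spec`.
#' @export
synthetic_expression_spec <- function(n_samples = 100L, module_loading = 1,
                                      noise_sd = 1, baseline_mean = 5,
                                      baseline_sd = 1, seed = 1L) {
  stopifnot(n_samples >= 3L, noise_sd >= 0, baseline_sd >= 0)
  structure(list(
    n_samples = as.integer(n_samples), module_loading = module_loading,
    noise_sd = noise_sd, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, seed = as.integer(seed)
  ), class = "synthetic_expression_spec")
}

#' Simulate an expression matrix with planted co-regulation
#'
#' Applies the latent-factor model of [synthetic_expression_spec()] to the
#' genes of a synthetic genome: members of every truth region flagged
#' `coregulated` share one latent factor per sample. The log2-scale values
#' are exported on the raw scale as `pmax(2^value - 1, 0)`, so
#' [preprocess_expression()] with the default pseudo-count of 1 inverts the
#' transform exactly wherever no clipping occurred. Deterministic for a
#' fixed seed.
#'
#' @param spec A [synthetic_expression_spec()].
#' @param genes Gene table (rows become matrix rows, in order).
#' @param truth Ground-truth [region_set()] with a `coregulated` column.
#' @return Non-negative numeric matrix, genes by samples.
#' @export
simulate_expression <- function(spec, genes, truth) {
  stopifnot(inherits(spec, "synthetic_expression_spec"))
  validate_gene_table(genes)
  stopifnot(inherits(truth, "region_set"))
  coreg <- if ("coregulated" %in% names(truth)) truth$coregulated else
    rep(FALSE, nrow(truth))
  with_seed(spec$seed, {
    n_g <- nrow(genes)
    n_s <- spec$n_samples
    baseline <- stats::rnorm(n_g, spec$baseline_mean, spec$baseline_sd)
    v <- matrix(baseline, n_g, n_s) +
      matrix(stats::rnorm(n_g * n_s, 0, spec$noise_sd), n_g, n_s)
    for (i in which(coreg)) {
      mem <- region_members(truth, i)[[1L]]
      ridx <- match(mem, genes$gene_id)
      ridx <- ridx[!is.na(ridx)]
      if (length(ridx) == 0L) next
      f <- stats::rnorm(n_s)
      v[ridx, ] <- v[ridx, ] + spec$module_loading * rep(f, each = length(ridx))
    }
    raw <- pmax(2^v - 1, 0)
    dimnames(raw) <- list(genes$gene_id, sprintf("S%03d", seq_len(n_s)))
    raw
  })
}

#' Write ground-truth regions
#'
#' Same TSV schema as [write_region_table()] (including the `coregulated`
#' column), so truth round-trips through [read_region_table()] and matches
#' itself under [match_regions()].
#'
#' @param truth Ground-truth [region_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  write_region_table(truth, path)
}
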