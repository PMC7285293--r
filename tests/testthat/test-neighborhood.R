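# Toy annotation mirroring the thalianol-cluster composition: an unassigned
# acyltransferase followed by four signature-family genes within gap range.
thalianol_fixture <- function() {
  gff <- system.file("extdata", "thalianol_toy.gff3", package = "clusterscout")
  fam <- system.file("extdata", "thalianol_toy_families.tsv", package = "clusterscout")
  list(genes = read_gff3(gff), catalog = read_family_table(fam))
}

test_that("thalianol-style toy annotation yields one 4-member multi-family cluster", {
  fx <- thalianol_fixture()
  r <- detect_neighborhoods(fx$genes, fx$catalog)
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_members, 4L)
  expect_equal(r$category, "multi_family_cluster")
  expect_false(r$strict_cluster)  # P450 x3 + TPS: only two distinct families
  expect_equal(sort(strsplit(r$member_families, ",")[[1]]),
               sort(c("P450", "P450", "P450", "TPS")))
  expect_equal(strsplit(r$member_ids, ",")[[1]],
               c("THAH", "THAS", "THAD", "CYP705A12"))  # increasing start order
  expect_equal(r$span_start, 105000L)
  expect_equal(r$span_end, 123000L)
})

test_that("runs below min_genes are not emitted", {
  g <- gene_table(c("a", "b"), "chr1", c(1000, 5000), c(2000, 6000))
  cat_ <- family_catalog(c(a = "P450", b = "P450"))
  expect_equal(nrow(detect_neighborhoods(g, cat_, min_genes = 3L)), 0L)
})

test_that("chaining honours max_intervening and max_gap_bp separately", {
  # four family genes; an oversized gap between 2nd and 3rd splits the chain
  g <- gene_table(sprintf("f%d", 1:4), "chr1",
                  c(1e3, 10e3, 200e3, 210e3), c(2e3, 11e3, 201e3, 211e3))
  cat_ <- family_catalog(stats::setNames(rep("UGT", 4), g$gene_id))
  r <- detect_neighborhoods(g, cat_, max_gap_bp = 50000L, min_genes = 2L)
  expect_equal(nrow(r), 2L)
  expect_equal(sort(r$member_ids), c("f1,f2", "f3,f4"))

  # too many intervening unassigned genes also split, even at zero bp gap
  ga <- gene_table(c("f1", sprintf("u%d", 1:4), "f2", "f3"), "chr1",
                   seq(1000, by = 3000, length.out = 7),
                   seq(1000, by = 3000, length.out = 7) + 2000)
  cat2 <- family_catalog(c(f1 = "TPS", f2 = "TPS", f3 = "TPS"))
  r2 <- detect_neighborhoods(ga, cat2, max_intervening = 3L, min_genes = 2L)
  expect_equal(r2$member_ids, "f2,f3")
  r3 <- detect_neighborhoods(ga, cat2, max_intervening = 4L, min_genes = 2L)
  expect_equal(r3$member_ids, "f1,f2,f3")
})

test_that("detector equals the brute-force chain-enumeration oracle on random genomes", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(40:200, 1)
    rg <- random_genome(n, n_chrom = sample(1:4, 1),
                        chrom_len = sample(c(5e5, 1e6, 3e6), 1),
                        family_rate = stats::runif(1, 0.2, 0.7))
    for (params in list(list(mi = 3L, gap = 50000L, mg = 3L),
                        list(mi = 1L, gap = 20000L, mg = 3L),
                        list(mi = 5L, gap = 100000L, mg = 4L))) {
      got <- detect_neighborhoods(rg$genes, rg$catalog,
                                  max_intervening = params$mi,
                                  max_gap_bp = params$gap,
                                  min_genes = params$mg)
      want <- chain_oracle(rg$genes, rg$catalog,
                           max_intervening = params$mi,
                           max_gap_bp = params$gap,
                           min_genes = params$mg)
      expect_identical(member_sets(got), want)
    }
  }
})

test_that("detection is invariant to gene order and strand flips, and regions partition genes", {
  set.seed(33)
  rg <- random_genome(150)
  r1 <- detect_neighborhoods(rg$genes, rg$catalog)
  shuf <- rg$genes[sample(nrow(rg$genes)), ]
  r2 <- detect_neighborhoods(shuf, rg$catalog)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  flip <- rg$genes
  flip$strand <- chartr("+-", "-+", flip$strand)
  r3 <- detect_neighborhoods(flip, rg$catalog)
  expect_equal(member_sets(r1), member_sets(r3))

  members <- unlist(region_members(r1))
  expect_false(anyDuplicated(members) > 0)  # disjoint across regions
  expect_true(all(members %in% names(rg$catalog$assignments)))
  expect_lte(length(members), length(rg$catalog))
})

test_that("emitted regions are maximal: no adjacent family gene can extend them", {
  set.seed(55)
  rg <- random_genome(180, family_rate = 0.5)
  mi <- 3L; gap <- 50000L
  r <- detect_neighborhoods(rg$genes, rg$catalog, max_intervening = mi,
                            max_gap_bp = gap)
  g <- rg$genes[order(rg$genes$chrom, rg$genes$start, rg$genes$end, rg$genes$gene_id), ]
  fam <- unname(rg$catalog$assignments[g$gene_id])
  for (i in seq_len(nrow(r))) {
    mem <- region_members(r, i)[[1]]
    pos <- match(mem, g$gene_id)
    chrom_idx <- which(g$chrom == r$chrom[i])
    fidx <- chrom_idx[!is.na(fam[chrom_idx])]
    k_first <- match(pos[1], fidx)
    k_last <- match(pos[length(pos)], fidx)
    link_ok <- function(i1, i2) {
      (i2 - i1 - 1L) <= mi && max(0L, g$start[i2] - g$end[i1] - 1L) <= gap
    }
    if (k_first > 1L) expect_false(link_ok(fidx[k_first - 1L], fidx[k_first]))
    if (k_last < length(fidx)) expect_false(link_ok(fidx[k_last], fidx[k_last + 1L]))
  }
})

test_that("catalog genes absent from the annotation warn and are ignored", {
  g <- gene_table(c("a", "b", "c"), "chr1", c(1, 5, 9) * 1000, c(2, 6, 10) * 1000)
  cat_ <- family_catalog(c(a = "P450", b = "P450", c = "P450", ghost = "TPS"))
  expect_warning(r <- detect_neighborhoods(g, cat_), "absent from the annotation")
  expect_equal(r$n_members, 3L)
  expect_warning(r0 <- detect_neighborhoods(g[0, ], cat_), "absent")
  expect_equal(nrow(r0), 0L)
})

test_that("classification separates clusters from tandems and flags strict clusters", {
  mk <- function(fams) {
    region_set(data.frame(
      region_id = "r1", chrom = "chr1", span_start = 1L, span_end = 10L,
      n_members = length(fams), n_distinct_families = NA_integer_,
      category = NA_character_, strict_cluster = NA,
      dominant_family = NA_character_,
      member_ids = paste(sprintf("g%d", seq_along(fams)), collapse = ","),
      member_families = paste(fams, collapse = ","), stringsAsFactors = FALSE
    ))
  }
  r1 <- classify_regions(mk(c("P450", "TPS", "P450", "P450")))
  expect_equal(r1$category, "multi_family_cluster")
  expect_false(r1$strict_cluster)

  r2 <- classify_regions(mk(rep("UGT", 4)))
  expect_equal(r2$category, "single_family_tandem")
  expect_equal(r2$dominant_family, "UGT")

  r3 <- classify_regions(mk(c("P450", "2ODD", "UGT")))
  expect_equal(r3$category, "multi_family_cluster")
  expect_true(r3$strict_cluster)

  # stricter bar demotes a 2-family region; dominant is the most frequent family
  r4 <- classify_regions(mk(c("P450", "TPS", "P450")), min_distinct_families = 3L)
  expect_equal(r4$category, "single_family_tandem")
  expect_equal(r4$dominant_family, "P450")
})

test_that("survey summaries satisfy the additivity invariant on published-style counts", {
  mk_regions <- function(n_cluster, tandems) {
    rows <- list()
    i <- 0
    add <- function(fams) {
      i <<- i + 1
      data.frame(region_id = sprintf("r%03d", i), chrom = "chr1",
                 span_start = i * 1000L, span_end = i * 1000L + 500L,
                 n_members = length(fams), n_distinct_families = NA_integer_,
                 category = NA_character_, strict_cluster = NA,
                 dominant_family = NA_character_,
                 member_ids = paste(sprintf("r%dg%d", i, seq_along(fams)), collapse = ","),
                 member_families = paste(fams, collapse = ","),
                 stringsAsFactors = FALSE)
    }
    for (k in seq_len(n_cluster)) rows[[length(rows) + 1]] <- add(c("P450", "TPS", "UGT"))
    for (f in names(tandems)) {
      for (k in seq_len(tandems[[f]])) rows[[length(rows) + 1]] <- add(rep(f, 3))
    }
    classify_regions(region_set(do.call(rbind, rows)))
  }

  # four genome-survey rows: tandem sums and totals must be additive
  surveys <- list(
    list(label = "A. thaliana", cluster = 39,
         tandems = c(P450 = 28, `2ODD` = 16, TPS = 6, PKS = 5, UGT = 15),
         tandem_total = 70, total = 109),
    list(label = "O. sativa", cluster = 34,
         tandems = c(P450 = 57, `2ODD` = 15, TPS = 10, PKS = 10, UGT = 37),
         tandem_total = 129, total = 163),
    list(label = "S. lycopersicum", cluster = 50,
         tandems = c(P450 = 30, `2ODD` = 24, TPS = 8, PKS = 9, UGT = 30),
         tandem_total = 101, total = 151),
    list(label = "L. japonicus", cluster = 18,
         tandems = c(P450 = 29, `2ODD` = 7, TPS = 5, PKS = 4, UGT = 7),
         tandem_total = 52, total = 70)
  )
  for (s in surveys) {
    regions <- mk_regions(s$cluster, as.list(s$tandems))
    sm <- summarize_survey(regions, label = s$label)
    expect_equal(sm$n_cluster_regions, s$cluster)
    expect_equal(sm$n_tandem_by_family[names(s$tandems)], s$tandems)
    expect_equal(sum(sm$n_tandem_by_family), s$tandem_total)
    expect_equal(sm$n_total_regions, s$total)
    expect_equal(sm$n_total_regions,
                 sm$n_cluster_regions + sum(sm$n_tandem_by_family))
  }

  no_regions <- detect_neighborhoods(
    gene_table(character(0), character(0), integer(0), integer(0)),
    family_catalog())
  empty <- summarize_survey(no_regions)
  expect_equal(empty$n_total_regions, 0L)
  expect_equal(sum(empty$n_tandem_by_family), 0L)
})

test_that("region matching computes precision and recall by greedy Jaccard", {
  set.seed(77)
  rg <- random_genome(150)
  det <- detect_neighborhoods(rg$genes, rg$catalog)
  m <- match_regions(det, det)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)

  none <- detect_neighborhoods(rg$genes, family_catalog())
  m2 <- match_regions(none, det)
  if (nrow(det)) {
    expect_equal(m2$precision, 1)  # vacuous
    expect_equal(m2$recall, 0)
  }
  expect_equal(match_regions(none, none)$precision, 1)
  expect_equal(match_regions(none, none)$recall, 1)

  # hand-enumerated merge case: one detected region covering two truth regions
  mk <- function(id, ids) {
    region_set(data.frame(region_id = id, chrom = "chr1", span_start = 1L,
                          span_end = 2L, n_members = length(ids),
                          n_distinct_families = 1L, category = "single_family_tandem",
                          strict_cluster = FALSE, dominant_family = "UGT",
                          member_ids = paste(ids, collapse = ","),
                          member_families = paste(rep("UGT", length(ids)), collapse = ","),
                          stringsAsFactors = FALSE))
  }
  truth <- region_set(rbind(mk("t1", c("a", "b", "c")), mk("t2", c("d", "e", "f"))))
  det1 <- mk("d1", c("a", "b", "c", "d", "e", "f"))
  # Jaccard(d1, t1) = 3/6 = 0.5 -> d1 matches one truth region only
  m3 <- match_regions(det1, truth, min_jaccard = 0.5)
  expect_equal(m3$n_matched, 1L)
  expect_equal(m3$precision, 1)
  expect_equal(m3$recall, 0.5)
})
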