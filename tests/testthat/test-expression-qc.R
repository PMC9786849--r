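test_that("TPM reproduces the worked example and its identities", {
  counts <- tibble::tibble(gene = c("g1", "g2"), s1 = c(10, 20))
  out <- tpm(counts, c(g1 = 1000, g2 = 2000))
  expect_equal(out$s1, c(5e5, 5e5))
  one <- tpm(tibble::tibble(gene = "g1", s1 = 7), c(g1 = 500))
  expect_equal(one$s1, 1e6)
  # columns always sum to 1e6 on random input
  set.seed(19)
  big <- tibble::tibble(gene = paste0("g", 1:200))
  for (s in paste0("s", 1:6)) big[[s]] <- rpois(200, 50)
  lens <- setNames(sample(200:3000, 200), big$gene)
  norm <- tpm(big, lens)
  for (s in paste0("s", 1:6)) {
    expect_equal(sum(norm[[s]]), 1e6, tolerance = 1e-6)
  }
  bad <- tibble::tibble(gene = c("g1", "g2"), ok = c(1, 2), dead = c(0, 0))
  expect_error(tpm(bad, c(g1 = 100, g2 = 100)), "dead")
  expect_error(tpm(counts, c(g1 = 1000)), "g2")
})

# a synthetic three-stage, two-genotype experiment with 2 replicates each
make_expr <- function(n_genes = 300, shift_sample = NULL, seed = 1) {
  set.seed(seed)
  meta <- tidyr::expand_grid(stage = c("tetrad", "microspore", "young_pollen"),
                             genotype = c("wt", "mut"),
                             replicate = 1:2) |>
    dplyr::mutate(sample = paste(stage, genotype, replicate, sep = "_"))
  base <- matrix(rpois(n_genes * nrow(meta), 60), nrow = n_genes)
  # group-specific signal so same-group replicates cluster together
  for (i in seq_len(nrow(meta))) {
    grp_seed <- as.integer(factor(paste(meta$stage, meta$genotype)))[i]
    idx <- ((grp_seed - 1) * 30 + 1):(grp_seed * 30)
    base[idx, i] <- base[idx, i] + 400
  }
  if (!is.null(shift_sample)) {
    j <- which(meta$sample == shift_sample)
    base[, j] <- rpois(n_genes, 60) + sample(c(0, 500), n_genes, TRUE)
  }
  tbl <- tibble::as_tibble(base, .name_repair = ~meta$sample)
  tbl <- dplyr::bind_cols(tibble::tibble(gene = paste0("g", 1:n_genes)), tbl)
  lens <- setNames(rep(1000, n_genes), paste0("g", 1:n_genes))
  list(tpm = tpm(tbl, lens), meta = meta)
}

test_that("a planted outlier replicate is flagged; clean replicates are not", {
  clean <- make_expr(seed = 2)
  qc <- replicate_consistency(clean$tpm, clean$meta, top_k = 200)
  expect_false(any(qc$flags$flagged))
  expect_length(qc$top_genes, 200)
  shifted <- make_expr(shift_sample = "microspore_mut_2", seed = 2)
  qc2 <- replicate_consistency(shifted$tpm, shifted$meta, top_k = 200)
  expect_true(qc2$flags$flagged[qc2$flags$sample == "microspore_mut_2"])
  # brute-force check: the flagged sample's nearest neighbour by direct
  # Euclidean distance on the Z-matrix is outside its group
  z <- qc2$zscores
  d <- as.matrix(dist(t(z)))["microspore_mut_2", ]
  nn <- names(sort(d[names(d) != "microspore_mut_2"]))[1]
  expect_false(startsWith(nn, "microspore_mut"))
})

test_that("top-k selection uses cumulative expression with id tie-breaks", {
  tbl <- tibble::tibble(gene = c("b", "a", "c", "d"),
                        s1 = c(10, 10, 500, 1),
                        s2 = c(10, 10, 500, 1))
  meta <- tibble::tibble(sample = c("s1", "s2"), stage = "t",
                         genotype = "wt", replicate = 1:2)
  qc <- replicate_consistency(tbl, meta, top_k = 3)
  expect_equal(sort(qc$top_genes), c("a", "b", "c"))
  expect_warning(replicate_consistency(tbl, meta, top_k = 10), "all genes")
})

test_that("sample clustering matches a hand-computed complete-linkage merge", {
  # two tight sample pairs in z-space: the merge order is unambiguous
  tbl <- tibble::tibble(gene = paste0("g", 1:3),
                        a = c(0, 0, 1), b = c(1, 1, 0),
                        c = c(10, 10, 11), d = c(11, 11, 10))
  meta <- tibble::tibble(sample = c("a", "b", "c", "d"),
                         stage = c("t", "t", "m", "m"), genotype = "wt",
                         replicate = c(1, 2, 1, 2))
  qc <- replicate_consistency(tbl, meta, top_k = 3)
  merges <- qc$sample_tree$merge
  labs <- qc$sample_tree$labels
  # brute-force: on the z-matrix the two smallest pairwise distances are
  # (a,b) and (c,d), so complete linkage must merge those pairs first
  d <- as.matrix(dist(t(qc$zscores)))
  d[upper.tri(d, diag = TRUE)] <- Inf
  ranks <- order(d)[1:2]
  pairs <- sort(vapply(ranks, function(i) {
    rc <- arrayInd(i, dim(d))
    paste(sort(rownames(d)[rc]), collapse = ",")
  }, character(1)))
  expect_equal(pairs, c("a,b", "c,d"))
  first_pairs <- lapply(1:2, function(i) sort(labs[-merges[i, ]]))
  expect_setequal(lapply(first_pairs, paste, collapse = ","),
                  list("a,b", "c,d"))
  expect_false(any(qc$flags$flagged))
})

test_that("permuting sample columns does not change the flags", {
  shifted <- make_expr(shift_sample = "tetrad_wt_1", seed = 5)
  qc1 <- replicate_consistency(shifted$tpm, shifted$meta, top_k = 150)
  perm <- c("gene", sample(shifted$meta$sample))
  qc2 <- replicate_consistency(shifted$tpm[, perm], shifted$meta,
                               top_k = 150)
  f1 <- dplyr::arrange(qc1$flags, sample)
  f2 <- dplyr::arrange(qc2$flags, sample)
  expect_equal(f1$flagged, f2$flagged)
})

test_that("dendrograms export as readable Newick", {
  clean <- make_expr(seed = 3)
  qc <- replicate_consistency(clean$tpm, clean$meta, top_k = 50)
  f <- withr::local_tempfile(fileext = ".nwk")
  export_dendrogram(qc$sample_tree, f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, clean$meta$sample)
})

test_that("the Venn partition matches brute-force set arithmetic", {
  de <- tibble::tibble(stage = c("t", "m", "m", "y"),
                       gene = c("b", "b", "c", "b"))
  ov <- stage_overlap(de)
  expect_equal(ov$regions$genes[[which(ov$regions$region == "all_three")]],
               "b")
  disjoint <- tibble::tibble(stage = c("t", "m", "y"),
                             gene = c("x", "y", "z"))
  ov2 <- stage_overlap(disjoint)
  expect_equal(ov2$regions$n[ov2$regions$region == "all_three"], 0L)
  expect_equal(sum(ov2$regions$n), 3L)
  set.seed(44)
  for (case in 1:220) {
    pool <- paste0("g", 1:30)
    lists <- lapply(1:3, function(i) sample(pool, sample(0:20, 1)))
    de_r <- dplyr::bind_rows(purrr::map2(
      c("s1", "s2", "s3"), lists,
      ~tibble::tibble(stage = .x, gene = .y)))
    de_r <- dplyr::bind_rows(de_r,
                             tibble::tibble(stage = c("s1", "s2", "s3"),
                                            gene = "anchor"))
    ov_r <- stage_overlap(de_r)
    a <- unique(c(lists[[1]], "anchor"))
    b <- unique(c(lists[[2]], "anchor"))
    c3 <- unique(c(lists[[3]], "anchor"))
    # brute force: triple intersection and union totals
    expect_equal(sort(ov_r$regions$genes[[
      which(ov_r$regions$region == "all_three")]]),
      sort(intersect(intersect(a, b), c3)))
    expect_equal(sum(ov_r$regions$n), length(union(union(a, b), c3)))
    only_a <- setdiff(a, union(b, c3))
    expect_equal(ov_r$regions$n[ov_r$regions$region == "s1_only"],
                 length(only_a))
  }
  expect_error(stage_overlap(tibble::tibble(stage = c("t", "t"),
                                            gene = c("a", "a"))),
               "once|three")
})

test_that("direction consistency is tabulated for the shared genes", {
  de <- tibble::tibble(
    stage = rep(c("t", "m", "y"), each = 2),
    gene = rep(c("up3", "mix"), 3),
    direction = c("up", "up", "up", "down", "up", "up"))
  td <- stage_overlap(de)$triple_direction
  expect_true(td$consistent[td$gene == "up3"])
  expect_false(td$consistent[td$gene == "mix"])
})

test_that("delta-delta-Ct folds follow the defining arithmetic", {
  expect_equal(ddct(20, 20, 20, 20), 1)
  expect_equal(ddct(19, 20, 20, 20), 2)   # delta-delta-Ct = -1
  expect_equal(ddct(20, 18, 24, 18), 16)  # 2 - 6 = -4 -> 2^4
  expect_equal(ddct(c(20, 19), c(20, 20), 20, 20), c(1, 2))
  expect_error(ddct(Inf, 20, 20, 20), "finite")
})
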