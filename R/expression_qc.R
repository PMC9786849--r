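#' TPM normalization
#'
#' Transcripts-per-million: per sample, each gene's count is divided by its
#' effective length, and the resulting rates are scaled to sum to one
#' million, so columns are comparable across samples.
#'
#' @param counts Counts tibble with a `gene` column and one numeric column
#'   per sample (non-negative read counts).
#' @param lengths Effective gene lengths (bp): a named numeric vector or a
#'   data frame with columns `gene` and `length`; must cover every gene.
#'
#' @return A tibble of the same shape with counts replaced by TPM values;
#'   every sample column sums to 1e6.
#' @export
#' @examples
#' counts <- tibble::tibble(gene = c("g1", "g2"), s1 = c(10, 20))
#' tpm(counts, c(g1 = 1000, g2 = 2000))
tpm <- function(counts, lengths) {
  stopifnot("gene" %in% names(counts))
  if (is.data.frame(lengths)) {
    lengths <- stats::setNames(lengths$length, lengths$gene)
  }
  missing <- setdiff(counts$gene, names(lengths))
  if (length(missing) > 0) {
    stop("no length for gene(s): ", paste(utils::head(missing, 5),
                                          collapse = ", "))
  }
  len <- unname(lengths[counts$gene])
  if (any(len <= 0)) stop("gene lengths must be positive")
  sample_cols <- setdiff(names(counts), "gene")
  out <- counts
  for (s in sample_cols) {
    if (any(counts[[s]] < 0)) stop("negative counts in sample '", s, "'")
    rate <- counts[[s]] / len
    tot <- sum(rate)
    if (tot == 0) stop("sample '", s, "' has all-zero counts")
    out[[s]] <- 1e6 * rate / tot
  }
  out
}

#' Replicate-consistency screening by biclustering
#'
#' Selects the `top_k` genes with the highest cumulative expression across
#' all samples (ties broken by gene id), converts them to per-gene Z-scores
#' across samples, and biclusters genes and samples with complete-linkage
#' hierarchical clustering on Euclidean distances. A replicate is flagged
#' as inconsistent when its nearest neighbour in the sample tree (smallest
#' cophenetic distance) is not a replicate of the same
#' (stage, genotype) group — an operational version of the visual exclusion
#' of replicates that cluster away from their group.
#'
#' @param tpm_tbl TPM tibble (`gene` column plus sample columns), e.g. from
#'   [tpm()].
#' @param metadata Tibble with columns `sample`, `stage`, `genotype`
#'   (and optionally `replicate`); one row per sample column.
#' @param top_k Number of top cumulative-expression genes to retain
#'   (default 5000; capped at the gene count with a warning).
#'
#' @return A `replicate_qc` list: `sample_tree` and `gene_tree` (`hclust`),
#'   `flags` tibble (`sample`, `group`, `nearest`, `nearest_group`,
#'   `flagged`), `top_genes` (character), `zscores` (matrix).
#' @export
replicate_consistency <- function(tpm_tbl, metadata, top_k = 5000) {
  stopifnot("gene" %in% names(tpm_tbl),
            all(c("sample", "stage", "genotype") %in% names(metadata)))
  sample_cols <- setdiff(names(tpm_tbl), "gene")
  if (!setequal(sample_cols, metadata$sample)) {
    stop("metadata samples do not match the TPM table's sample columns")
  }
  grp <- paste(metadata$stage, metadata$genotype, sep = ".")
  names(grp) <- metadata$sample
  if (any(table(grp) < 2)) {
    stop("every (stage, genotype) group needs at least 2 replicates")
  }
  mat <- as.matrix(tpm_tbl[, sample_cols])
  rownames(mat) <- tpm_tbl$gene
  if (top_k > nrow(mat)) {
    warning("top_k (", top_k, ") exceeds gene count (", nrow(mat),
            "); using all genes")
    top_k <- nrow(mat)
  }
  cum <- rowSums(mat)
  keep <- order(-cum, rownames(mat))[seq_len(top_k)]
  sub <- mat[keep, , drop = FALSE]
  z <- t(apply(sub, 1, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  colnames(z) <- sample_cols
  sample_tree <- stats::hclust(stats::dist(t(z)), method = "complete")
  gene_tree <- stats::hclust(stats::dist(z), method = "complete")
  coph <- as.matrix(stats::cophenetic(sample_tree))
  flags <- purrr::map_dfr(sample_cols, function(s) {
    others <- setdiff(sample_cols, s)
    d <- stats::setNames(coph[s, others], others)
    nearest <- names(d)[d == min(d)]
    same <- grp[nearest] == grp[[s]]
    tibble::tibble(sample = s, group = grp[[s]],
                   nearest = nearest[1],
                   nearest_group = grp[[nearest[1]]],
                   flagged = !any(same))
  })
  structure(list(sample_tree = sample_tree, gene_tree = gene_tree,
                 flags = flags, top_genes = rownames(sub), zscores = z),
            class = "replicate_qc")
}

#' @export
print.replicate_qc <- function(x, ...) {
  cat("<replicate_qc> ", length(x$top_genes), " genes x ",
      nrow(x$flags), " samples\n", sep = "")
  bad <- x$flags$sample[x$flags$flagged]
  if (length(bad) == 0) cat("  all replicates cluster with their group\n")
  else cat("  flagged replicate(s): ", paste(bad, collapse = ", "), "\n",
           sep = "")
  invisible(x)
}

#' Export a dendrogram in Newick format
#'
#' @param tree An `hclust` object (e.g. from [replicate_consistency()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_dendrogram <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Three-stage overlap (Venn partition) of DE gene lists
#'
#' Partitions three per-stage differentially-expressed gene lists into the
#' seven Venn regions and tabulates direction consistency for the genes
#' shared by all three stages.
#'
#' @param de Tibble with columns `stage`, `gene` and optionally
#'   `direction` (`"up"`/`"down"`); exactly three distinct stages, each
#'   gene at most once per stage.
#'
#' @return A list: `regions` (tibble `region`, `n`, `genes` list-column;
#'   region names like `"tetrad_only"`, `"tetrad&microspore"`,
#'   `"all_three"`), and `triple_direction` (tibble with each shared
#'   gene's per-stage direction and a `consistent` flag; `NULL` when `de`
#'   has no direction column).
#' @export
#' @examples
#' de <- tibble::tibble(stage = c("t", "m", "m", "y"),
#'                      gene = c("b", "b", "c", "b"))
#' stage_overlap(de)$regions
stage_overlap <- function(de) {
  stopifnot(all(c("stage", "gene") %in% names(de)))
  stages <- unique(de$stage)
  if (length(stages) != 3) stop("exactly three stages are required, got ",
                                length(stages))
  if (any(duplicated(de[, c("stage", "gene")]))) {
    stop("a gene appears more than once within a stage list")
  }
  sets <- purrr::map(stages, ~unique(de$gene[de$stage == .x]))
  names(sets) <- stages
  membership <- purrr::map(sets, ~unique(unlist(sets)) %in% .x)
  univ <- unique(unlist(sets))
  combos <- expand.grid(a = c(FALSE, TRUE), b = c(FALSE, TRUE),
                        c = c(FALSE, TRUE))[-1, ]
  region_name <- function(inset) {
    if (all(inset)) return("all_three")
    on <- stages[inset]
    if (length(on) == 1) paste0(on, "_only") else paste(on, collapse = "&")
  }
  regions <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    inset <- unlist(combos[i, ])
    in_region <- Reduce(`&`, purrr::map2(membership, inset,
                                         ~if (.y) .x else !.x))
    tibble::tibble(region = region_name(inset),
                   n = sum(in_region),
                   genes = list(univ[in_region]))
  })
  triple <- regions$genes[[which(regions$region == "all_three")]]
  triple_direction <- NULL
  if ("direction" %in% names(de) && length(triple) > 0) {
    triple_direction <- de |>
      dplyr::filter(.data$gene %in% triple) |>
      tidyr::pivot_wider(names_from = "stage", values_from = "direction") |>
      dplyr::rowwise() |>
      dplyr::mutate(consistent = length(unique(
        dplyr::c_across(dplyr::all_of(stages)))) == 1) |>
      dplyr::ungroup()
  }
  list(regions = regions, triple_direction = triple_direction)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Computes qPCR relative expression as
#' `2^-((Ct_target,test - Ct_ref,test) - (Ct_target,calibrator -
#' Ct_ref,calibrator))`, i.e. the fold change of the target gene in the
#' test sample relative to a calibrator sample, normalized to a reference
#' (housekeeping) gene.
#'
#' @param ct_target_test,ct_ref_test Target- and reference-gene Ct in the
#'   test sample.
#' @param ct_target_calibrator,ct_ref_calibrator Same for the calibrator.
#'
#' @return Relative expression fold (vectorized).
#' @export
#' @examples
#' ddct(20, 18, 24, 18)  # delta-delta-Ct = -4 -> fold 16
ddct <- function(ct_target_test, ct_ref_test,
                 ct_target_calibrator, ct_ref_calibrator) {
  vals <- c(ct_target_test, ct_ref_test,
            ct_target_calibrator, ct_ref_calibrator)
  if (any(!is.finite(vals))) stop("Ct values must be finite")
  dd <- (ct_target_test - ct_ref_test) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-dd)
}
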