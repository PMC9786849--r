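#' Call a pooled genotype state from an allele frequency
#'
#' Maps a pool's alternative-allele frequency onto a diploid-style genotype
#' vocabulary for pooled data: below `het_low` is `hom_ref` (0/0), within
#' `[het_low, het_high]` is `het` (0/1), above `het_high` is `hom_alt`
#' (1/1); depth below `min_depth` gives `no_call`. For a recessive causal
#' site the wild-type pool (a 2:1 mixture of heterozygotes and homozygous
#' reference plants) has expected ALT frequency 1/3 and the mutant pool 1,
#' so the default thresholds separate those with margin.
#'
#' @param af Alternative-allele frequency (vectorized).
#' @param depth Total allele depth (vectorized).
#' @param het_low,het_high Frequency bounds of the heterozygous band.
#' @param min_depth Minimum depth for a call.
#'
#' @return Character vector in `c("hom_ref", "het", "hom_alt", "no_call")`.
#' @export
#' @examples
#' call_pool_state(c(0, 1/3, 1), depth = 40)
call_pool_state <- function(af, depth, het_low = 0.15, het_high = 0.85,
                            min_depth = 10) {
  if (het_low >= het_high) {
    stop("het_low (", het_low, ") must be below het_high (", het_high, ")")
  }
  out <- dplyr::case_when(
    depth < min_depth ~ "no_call",
    af < het_low ~ "hom_ref",
    af <= het_high ~ "het",
    TRUE ~ "hom_alt"
  )
  out
}

# Normalize a known catalog to (chrom, pos, ref, alt). Accepts a VCF path,
# a TSV path, or a data frame with those four columns.
read_known_catalog <- function(catalog) {
  if (is.data.frame(catalog)) {
    df <- tibble::as_tibble(catalog)
    names(df)[1:4] <- c("chrom", "pos", "ref", "alt")
  } else if (is.character(catalog) && length(catalog) == 1) {
    if (grepl("\\.vcf(\\.gz)?$", catalog)) {
      vcf <- vcfR::read.vcfR(catalog, verbose = FALSE)
      fix <- vcfR::getFIX(vcf)
      df <- tibble::tibble(chrom = fix[, "CHROM"],
                           pos = as.integer(fix[, "POS"]),
                           ref = fix[, "REF"], alt = fix[, "ALT"])
    } else {
      df <- readr::read_tsv(catalog, show_col_types = FALSE,
                            col_names = c("chrom", "pos", "ref", "alt"))
      # tolerate a header row
      if (suppressWarnings(is.na(as.integer(df$pos[1])))) df <- df[-1, ]
      df$pos <- as.integer(df$pos)
    }
  } else {
    stop("catalog must be a data frame or a VCF/TSV path")
  }
  dplyr::mutate(df, pos = as.integer(.data$pos))
}

#' Apply the two-criteria candidate filter
#'
#' Annotates every variant (typically those inside a candidate region) with
#' pooled genotype calls and applies the causal-candidate criteria:
#' (i) the alternative allele must be heterozygous (0/1) in the wild-type
#' pool and homozygous (1/1) in the mutant pool, and (ii) the alternative
#' allele must be novel — absent from the known-variant catalog. Linked
#' background markers whose ALT is the wild-parent allele fail criterion (i)
#' in the mutant pool by design: mutant-pool plants are homozygous for the
#' reference-background haplotype there.
#'
#' @param variants Pooled-variant tibble (see [read_pooled_vcf()]).
#' @param known_catalog Optional catalog (data frame or VCF/TSV path with
#'   chrom, pos, ref, alt); matching requires all four fields equal. When
#'   `NULL`, the `in_known_catalog` column of `variants` is used.
#' @param het_low,het_high,min_depth Passed to [call_pool_state()].
#'
#' @return A tibble sorted passing-first then by position, adding `af_wt`,
#'   `af_mut`, `wt_call`, `mut_call`, `novel`, `passes` and `fail_reasons`
#'   (semicolon-separated; empty for passing variants).
#' @export
filter_candidates <- function(variants, known_catalog = NULL,
                              het_low = 0.15, het_high = 0.85,
                              min_depth = 10) {
  if (nrow(variants) == 0) {
    return(dplyr::mutate(variants, af_wt = numeric(0), af_mut = numeric(0),
                         wt_call = character(0), mut_call = character(0),
                         novel = logical(0), passes = logical(0),
                         fail_reasons = character(0)))
  }
  out <- variants
  out$af_wt <- allele_frequency(variants, "wt")
  out$af_mut <- allele_frequency(variants, "mut")
  out$wt_call <- call_pool_state(out$af_wt, variants$wt_ref + variants$wt_alt,
                                 het_low, het_high, min_depth)
  out$mut_call <- call_pool_state(out$af_mut,
                                  variants$mut_ref + variants$mut_alt,
                                  het_low, het_high, min_depth)
  if (!is.null(known_catalog)) {
    cat_df <- read_known_catalog(known_catalog)
    key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
    out$novel <- !(key(out) %in% key(cat_df))
  } else if ("in_known_catalog" %in% names(out)) {
    out$novel <- !out$in_known_catalog
  } else {
    stop("no known catalog given and variants lack an in_known_catalog column")
  }
  out$fail_reasons <- purrr::pmap_chr(
    list(out$wt_call, out$mut_call, out$novel),
    function(w, m, nv) {
      r <- character(0)
      if (w != "het") r <- c(r, "wt_pool_not_het")
      if (m != "hom_alt") r <- c(r, "mut_pool_not_hom_alt")
      if (!nv) r <- c(r, "previously_reported")
      paste(r, collapse = ";")
    }
  )
  out$passes <- out$fail_reasons == ""
  dplyr::arrange(out, dplyr::desc(.data$passes), .data$chrom, .data$pos)
}

#' Write a candidate-variant report
#'
#' One TSV row per variant with calls, flags and fail reasons, followed by a
#' commented summary block (`#` lines) counting passing variants and each
#' fail reason.
#'
#' @param candidates A [filter_candidates()] result.
#' @param path Output TSV path.
#'
#' @return A tibble of summary counts (`reason`, `n`), invisibly.
#' @export
report_candidates <- function(candidates, path) {
  readr::write_tsv(tibble::as_tibble(candidates), path)
  reasons <- unlist(strsplit(candidates$fail_reasons[
    candidates$fail_reasons != ""], ";"))
  summary <- tibble::tibble(reason = c("passing", names(table(reasons))),
                            n = c(sum(candidates$passes),
                                  as.integer(table(reasons))))
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(c("#", "# summary",
               sprintf("# %s\t%d", summary$reason, summary$n)), con)
  invisible(summary)
}
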