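#' Read pooled variants from a VCF
#'
#' Parses a VCF with two pooled samples carrying `AD` allelic depths, keeping
#' biallelic SNVs where both pools reach a minimum total allele depth.
#' Multiallelic records and records where either pool's total depth falls
#' below `min_depth` are dropped; the boundary is inclusive (depth exactly
#' `min_depth` is retained). Drop reasons are counted and attached as the
#' `"drop_counts"` attribute and reported via a message.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param wt_sample,mut_sample Sample-column names of the wild-type and
#'   mutant pools.
#' @param min_depth Minimum total allele depth per pool (inclusive).
#'
#' @return A tibble of pooled variants: `chrom`, `pos`, `ref`, `alt`,
#'   `wt_ref`, `wt_alt`, `mut_ref`, `mut_alt`, `in_known_catalog`.
#' @export
read_pooled_vcf <- function(path, wt_sample = "wt_pool",
                            mut_sample = "mut_pool", min_depth = 10) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  for (s in c(wt_sample, mut_sample)) {
    if (!s %in% samples) {
      stop("sample '", s, "' not found in VCF (has: ",
           paste(samples, collapse = ", "), ")")
    }
  }
  fix <- tibble::as_tibble(vcfR::getFIX(vcf, getINFO = TRUE))
  empty <- tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), wt_ref = integer(), wt_alt = integer(),
    mut_ref = integer(), mut_alt = integer(), in_known_catalog = logical()
  )
  if (nrow(fix) == 0) {
    attr(empty, "drop_counts") <- c(multiallelic = 0L, low_depth = 0L)
    return(empty)
  }
  fmt <- vcf@gt[, "FORMAT"]
  if (!all(grepl("(^|:)AD(:|$)", fmt))) {
    bad <- which(!grepl("(^|:)AD(:|$)", fmt))[1]
    stop("record ", fix$CHROM[bad], ":", fix$POS[bad],
         " has no AD field in FORMAT")
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  parse_ad <- function(x) {
    parts <- stringr::str_split_fixed(x, ",", 2)
    cbind(suppressWarnings(as.integer(parts[, 1])),
          suppressWarnings(as.integer(parts[, 2])))
  }
  wt <- parse_ad(ad[, wt_sample])
  mut <- parse_ad(ad[, mut_sample])
  out <- tibble::tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    wt_ref = wt[, 1], wt_alt = wt[, 2],
    mut_ref = mut[, 1], mut_alt = mut[, 2],
    in_known_catalog = grepl("(^|;)KNOWN(;|$|=)", fix$INFO %||% ".")
  )
  multi <- grepl(",", out$alt) | is.na(out$alt) | is.na(out$wt_alt) |
    is.na(out$mut_alt)
  low <- !multi & ((out$wt_ref + out$wt_alt) < min_depth |
                     (out$mut_ref + out$mut_alt) < min_depth)
  drop_counts <- c(multiallelic = sum(multi), low_depth = sum(low))
  message("read_pooled_vcf: kept ", sum(!multi & !low), " of ", nrow(out),
          " records (dropped ", sum(multi), " multiallelic, ",
          sum(low), " below depth ", min_depth, ")")
  out <- out[!multi & !low, ]
  attr(out, "drop_counts") <- drop_counts
  out
}

#' Per-pool allele frequency ratio
#'
#' The mapping statistic: non-reference allele read count divided by total
#' allele read count for the named pool, per variant.
#'
#' @param variants Pooled-variant tibble (see [read_pooled_vcf()]).
#' @param pool `"wt"` or `"mut"`.
#'
#' @return Numeric vector of frequencies in [0, 1], one per row.
#' @export
#' @examples
#' v <- tibble::tibble(wt_ref = 10, wt_alt = 10, mut_ref = 25, mut_alt = 0)
#' allele_frequency(v, "wt")   # 0.5
#' allele_frequency(v, "mut")  # 0
allele_frequency <- function(variants, pool = c("wt", "mut")) {
  pool <- match.arg(pool)
  ref <- variants[[paste0(pool, "_ref")]]
  alt <- variants[[paste0(pool, "_alt")]]
  total <- ref + alt
  if (any(total == 0)) {
    stop("zero total depth in ", pool,
         " pool at row(s) ", paste(utils::head(which(total == 0), 5),
                                   collapse = ", "),
         "; apply the depth filter first")
  }
  alt / total
}

#' Sliding-window allele-frequency profile per chromosome
#'
#' Windows are defined in variant-rank space: within each chromosome,
#' variants are ranked by position and windows of `window_size` variants
#' advance by `step` variants. Each full window reports the unweighted mean
#' of the per-variant allele-frequency ratios for each pool; base-pair
#' bounds are taken from the first and last member variants. Trailing
#' variants that cannot fill a final full window are covered by the last
#' full window only; a chromosome with fewer variants than `window_size`
#' yields a single window flagged `partial`.
#'
#' @param variants Pooled-variant tibble sorted by (chrom, pos).
#' @param window_size,step Window and step sizes in number of variants
#'   (defaults 1000 and 100).
#'
#' @return A `window_profile` tibble: `chrom`, `window`, `start_rank`,
#'   `end_rank`, `start_bp`, `end_bp`, `mean_af_wt`, `mean_af_mut`,
#'   `n_variants`, `partial`.
#' @export
window_profile <- function(variants, window_size = 1000, step = 100) {
  stopifnot(window_size >= step, step >= 1)
  o <- order(variants$chrom, variants$pos)
  if (!identical(o, seq_len(nrow(variants)))) {
    stop("variants must be sorted by chromosome then position")
  }
  af_wt <- allele_frequency(variants, "wt")
  af_mut <- allele_frequency(variants, "mut")
  one_chrom <- function(rows) {
    n <- length(rows)
    if (n < window_size) {
      starts <- 1L
      ends <- n
      partial <- TRUE
    } else {
      starts <- seq.int(1L, n - window_size + 1L, by = step)
      ends <- starts + window_size - 1L
      partial <- FALSE
    }
    tibble::tibble(
      window = seq_along(starts),
      start_rank = starts, end_rank = ends,
      start_bp = variants$pos[rows[starts]],
      end_bp = variants$pos[rows[ends]],
      mean_af_wt = vapply(seq_along(starts), function(i)
        mean(af_wt[rows[starts[i]:ends[i]]]), numeric(1)),
      mean_af_mut = vapply(seq_along(starts), function(i)
        mean(af_mut[rows[starts[i]:ends[i]]]), numeric(1)),
      n_variants = ends - starts + 1L,
      partial = partial
    )
  }
  out <- tibble::tibble(chrom = variants$chrom, row = seq_len(nrow(variants))) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(one_chrom(.data$row))
  attr(out, "window_size") <- window_size
  attr(out, "step") <- step
  class(out) <- c("window_profile", class(out))
  out
}

#' Detect candidate regions from window profiles
#'
#' Flags windows where the mutant-pool mean allele frequency is at most
#' `mut_af_max` and the wild-type-minus-mutant difference is at least
#' `delta_min`, then merges flagged windows that overlap or abut in rank
#' space into candidate regions. Under the recessive bulk-segregant design
#' the causal region shows mutant-pool frequencies near 0 (all mutant-pool
#' plants homozygous for the reference-background haplotype) against a
#' wild-type pool near 2/3, so the defaults separate those expectations with
#' margin; they are heuristics, not reconstructions of any published cutoff.
#'
#' @param profile A [window_profile()] tibble.
#' @param mut_af_max Maximum mutant-pool window mean allele frequency.
#' @param delta_min Minimum (wt - mut) window mean difference.
#'
#' @return A tibble of regions ranked by `mean_delta` descending (ties:
#'   larger `n_windows`, then chromosome name): `chrom`, `start_bp`,
#'   `end_bp`, `n_windows`, `min_mut_af`, `mean_delta`, `start_rank`,
#'   `end_rank`. Empty tibble when no window passes.
#' @export
detect_candidate_region <- function(profile, mut_af_max = 0.2,
                                    delta_min = 0.25) {
  flagged <- profile |>
    dplyr::mutate(delta = .data$mean_af_wt - .data$mean_af_mut) |>
    dplyr::filter(.data$mean_af_mut <= mut_af_max, .data$delta >= delta_min)
  empty <- tibble::tibble(
    chrom = character(), start_bp = integer(), end_bp = integer(),
    n_windows = integer(), min_mut_af = numeric(), mean_delta = numeric(),
    start_rank = integer(), end_rank = integer()
  )
  if (nrow(flagged) == 0) return(empty)
  flagged |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start_rank, .by_group = TRUE) |>
    dplyr::mutate(
      new_region = .data$start_rank > dplyr::lag(.data$end_rank,
                                                 default = -1L) + 1L,
      region_id = cumsum(.data$new_region)
    ) |>
    dplyr::group_by(.data$chrom, .data$region_id) |>
    dplyr::summarise(
      start_bp = min(.data$start_bp), end_bp = max(.data$end_bp),
      n_windows = dplyr::n(),
      min_mut_af = min(.data$mean_af_mut),
      mean_delta = mean(.data$delta),
      start_rank = min(.data$start_rank), end_rank = max(.data$end_rank),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_delta),
                   dplyr::desc(.data$n_windows), .data$chrom) |>
    dplyr::select(-"region_id")
}

#' Export a window profile as a plot-ready table (and optional figure)
#'
#' Writes one TSV row per window and, when `plot_path` is given, a
#' per-chromosome line plot of both pools' mean allele frequencies.
#'
#' @param profile A [window_profile()] tibble.
#' @param tsv_path Output TSV path.
#' @param plot_path Optional figure path (extension decides the device,
#'   e.g. `.png` or `.svg`).
#' @param ... Passed to [ggplot2::ggsave()].
#'
#' @return The profile, invisibly.
#' @export
export_profile <- function(profile, tsv_path, plot_path = NULL, ...) {
  stopifnot(nrow(profile) > 0)
  readr::write_tsv(tibble::as_tibble(profile), tsv_path)
  if (!is.null(plot_path)) {
    ggplot2::ggsave(plot_path, autoplot.window_profile(profile),
                    width = 9, height = 6, ...)
  }
  invisible(profile)
}

#' Plot a window allele-frequency profile
#'
#' One panel per chromosome; the wild-type pool in blue and the mutant pool
#' in red, mirroring the usual bulk-segregant mapping figure. The causal
#' region appears as a dip of the mutant-pool line toward 0 with the
#' wild-type line near 2/3.
#'
#' @param object A [window_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot window_profile
#' @export
autoplot.window_profile <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("mean_af_wt", "mean_af_mut"),
                        names_to = "pool", values_to = "mean_af") |>
    dplyr::mutate(pool = ifelse(.data$pool == "mean_af_wt",
                                "wild-type pool", "mutant pool"))
  mid_bp <- (long$start_bp + long$end_bp) / 2
  ggplot2::ggplot(long, ggplot2::aes(x = mid_bp / 1e6, y = .data$mean_af,
                                     colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom) +
    ggplot2::scale_colour_manual(values = c("wild-type pool" = "#2166ac",
                                            "mutant pool" = "#b2182b")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "window midpoint (Mb)",
                  y = "mean allele frequency", colour = NULL) +
    ggplot2::theme_minimal()
}
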