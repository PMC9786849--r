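#' Define a marker genome for cross simulation
#'
#' Builds the marker landscape used by [simulate_f2()] and
#' [sample_pooled_reads()]: a set of chromosomes with physical and genetic
#' lengths, evenly spaced biallelic marker positions, and a "known catalog"
#' flag marking the subset of markers that stand in for previously reported
#' variants (background polymorphisms between the two parental genomes are
#' mostly present in public variant lists; an induced point mutation is not).
#'
#' The default is a desk-scale, tomato-shaped genome: 12 chromosomes of 5 Mb
#' and 100 cM each with 2,000 markers per chromosome, enough for the default
#' 1000/100 sliding-window parameters to yield 11 full windows per chromosome.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_bp Physical length of each chromosome (bp).
#' @param chrom_length_cM Genetic length of each chromosome (centimorgan).
#' @param markers_per_chrom Number of evenly spaced biallelic markers per
#'   chromosome.
#' @param known_frac Fraction of markers flagged as previously reported
#'   (deterministic stripe: every `round(1/(1 - known_frac))`-th marker is
#'   left novel).
#'
#' @return A `genome_map` object: a list with tibbles `chromosomes`
#'   (`chrom`, `length_bp`, `length_cM`) and `markers`
#'   (`chrom`, `pos`, `ref`, `alt`, `known`).
#' @export
#' @examples
#' g <- genome_map(n_chrom = 2, markers_per_chrom = 50)
#' g$chromosomes
genome_map <- function(n_chrom = 12,
                       chrom_length_bp = 5e6,
                       chrom_length_cM = 100,
                       markers_per_chrom = 2000,
                       known_frac = 0.9) {
  stopifnot(n_chrom >= 1, chrom_length_bp > 0, chrom_length_cM > 0,
            markers_per_chrom >= 2, known_frac >= 0, known_frac < 1)
  chroms <- sprintf("chr%02d", seq_len(n_chrom))
  chromosomes <- tibble::tibble(
    chrom = chroms,
    length_bp = rep(chrom_length_bp, n_chrom),
    length_cM = rep(chrom_length_cM, n_chrom)
  )
  spacing <- floor(chrom_length_bp / (markers_per_chrom + 1))
  pos <- spacing * seq_len(markers_per_chrom)
  bases <- c("A", "C", "G", "T")
  ref <- bases[(seq_len(markers_per_chrom) - 1L) %% 4L + 1L]
  alt <- bases[seq_len(markers_per_chrom) %% 4L + 1L]
  # deterministic novelty stripe: every k-th marker is novel
  if (known_frac > 0) {
    k <- max(2L, round(1 / (1 - known_frac)))
    known <- (seq_len(markers_per_chrom) %% k) != 0L
  } else {
    known <- rep(FALSE, markers_per_chrom)
  }
  markers <- tidyr::expand_grid(chrom = chroms,
                                idx = seq_len(markers_per_chrom)) |>
    dplyr::mutate(pos = pos[.data$idx],
                  ref = ref[.data$idx],
                  alt = alt[.data$idx],
                  known = known[.data$idx]) |>
    dplyr::select("chrom", "pos", "ref", "alt", "known")
  structure(list(chromosomes = chromosomes, markers = markers),
            class = "genome_map")
}

#' Configure an F2 bulk-segregant cross simulation
#'
#' Holds the parameters of the simulated cross: population and pool sizes,
#' the location of the recessive causal mutation, the pooled sequencing depth
#' model and the global RNG seed. Defaults mirror the mapping study design:
#' 117 F2 plants, pools of 25 phenotypically wild-type and 16 mutant plants,
#' the causal mutation mid-chromosome-4, Poisson depth of mean 40 per pool
#' and a per-read miscall probability of 0.001.
#'
#' @param n_f2 Number of F2 plants.
#' @param n_wt_pool,n_mut_pool Pool sizes drawn from the wild-type- and
#'   mutant-phenotype classes.
#' @param causal_chrom,causal_pos Location of the causal SNP; must be one of
#'   the marker positions of the genome it is used with. `causal_pos = NULL`
#'   picks the marker closest to the middle of `causal_chrom` at simulation
#'   time.
#' @param mean_depth Expected pooled read depth per marker and pool (Poisson).
#' @param base_error Per-read allele miscall probability, in [0, 0.5).
#' @param seed Integer seed governing all sampling.
#'
#' @return A `cross_config` object (a named list).
#' @export
cross_config <- function(n_f2 = 117,
                         n_wt_pool = 25,
                         n_mut_pool = 16,
                         causal_chrom = "chr04",
                         causal_pos = NULL,
                         mean_depth = 40,
                         base_error = 0.001,
                         seed = 1L) {
  stopifnot(n_f2 >= 1, n_wt_pool >= 1, n_mut_pool >= 1,
            n_wt_pool + n_mut_pool <= n_f2,
            mean_depth > 0, base_error >= 0, base_error < 0.5)
  structure(list(n_f2 = as.integer(n_f2),
                 n_wt_pool = as.integer(n_wt_pool),
                 n_mut_pool = as.integer(n_mut_pool),
                 causal_chrom = causal_chrom,
                 causal_pos = causal_pos,
                 mean_depth = mean_depth,
                 base_error = base_error,
                 seed = as.integer(seed)),
            class = "cross_config")
}

# Resolve causal position: NULL -> marker nearest mid-chromosome.
resolve_causal <- function(genome, config) {
  mk <- genome$markers[genome$markers$chrom == config$causal_chrom, ]
  if (nrow(mk) == 0) {
    stop("causal_chrom '", config$causal_chrom, "' is not in the genome map")
  }
  if (is.null(config$causal_pos)) {
    len <- genome$chromosomes$length_bp[
      genome$chromosomes$chrom == config$causal_chrom]
    return(mk$pos[which.min(abs(mk$pos - len / 2))])
  }
  if (!config$causal_pos %in% mk$pos) {
    stop("causal_pos ", config$causal_pos,
         " is not a marker position on ", config$causal_chrom)
  }
  config$causal_pos
}

# Simulate one batch of gametes for one chromosome.
# Returns a markers x n_gametes 0/1 matrix of parental origin
# (1 = non-reference / S. pimpinellifolium haplotype).
# Haldane model: crossover count ~ Poisson(length_cM / 100), positions
# uniform in genetic distance, no interference; markers mapped to genetic
# position linearly along the chromosome.
sim_gametes <- function(marker_pos, length_bp, length_cM, n_gametes) {
  g_mark <- length_cM * marker_pos / length_bp
  n_x <- stats::rpois(n_gametes, length_cM / 100)
  start <- stats::rbinom(n_gametes, 1L, 0.5)
  out <- matrix(0L, nrow = length(marker_pos), ncol = n_gametes)
  for (j in seq_len(n_gametes)) {
    if (n_x[j] == 0L) {
      out[, j] <- start[j]
    } else {
      xpos <- sort(stats::runif(n_x[j], 0, length_cM))
      crossings <- findInterval(g_mark, xpos)
      out[, j] <- (start[j] + crossings) %% 2L
    }
  }
  out
}

#' Simulate an F2 mapping population
#'
#' Self-fertilizes the F1 of a cross between a reference-background mutant
#' parent and a fully diverged wild parent: every F2 plant receives two
#' independently recombined F1 gametes (Haldane map, no interference).
#' Phenotypes follow a fully penetrant monogenic recessive model: a plant is
#' mutant iff both haplotypes at the causal site come from the mutant
#' (reference-background) parent. Pools are drawn without replacement from
#' the phenotype classes.
#'
#' Haplotype origin is coded 0 = reference (mutant-parent) haplotype,
#' 1 = non-reference (wild-parent) haplotype. Note the allele coding used
#' downstream: at background markers the VCF ALT allele is the wild-parent
#' allele (origin 1), while at the causal site the ALT allele is the induced
#' mutation, carried on the reference-background haplotype (origin 0).
#'
#' @param genome A [genome_map()].
#' @param config A [cross_config()]; `config$seed` seeds all sampling.
#'   Stream order: chromosomes in map order, one gamete batch per chromosome,
#'   then pool membership draws.
#'
#' @return A `cross_sim_truth` object: list with `hap1`/`hap2` (marker x
#'   plant 0/1 origin matrices), `phenotype` (character vector,
#'   `"wt"`/`"mutant"`), `pools` tibble (`plant`, `pool`), `causal_chrom`,
#'   `causal_pos`, plus the `genome` and `config` used.
#' @export
#' @examples
#' g <- genome_map(n_chrom = 1, markers_per_chrom = 20)
#' cfg <- cross_config(n_f2 = 40, n_wt_pool = 10, n_mut_pool = 5,
#'                     causal_chrom = "chr01", seed = 7)
#' truth <- simulate_f2(g, cfg)
#' table(truth$phenotype)
simulate_f2 <- function(genome, config) {
  stopifnot(inherits(genome, "genome_map"), inherits(config, "cross_config"))
  causal_pos <- resolve_causal(genome, config)
  set.seed(config$seed)
  mk <- genome$markers
  n_mark <- nrow(mk)
  n <- config$n_f2
  hap1 <- matrix(0L, n_mark, n)
  hap2 <- matrix(0L, n_mark, n)
  for (ci in seq_len(nrow(genome$chromosomes))) {
    ch <- genome$chromosomes[ci, ]
    rows <- which(mk$chrom == ch$chrom)
    gam <- sim_gametes(mk$pos[rows], ch$length_bp, ch$length_cM, 2L * n)
    hap1[rows, ] <- gam[, seq_len(n), drop = FALSE]
    hap2[rows, ] <- gam[, n + seq_len(n), drop = FALSE]
  }
  causal_row <- which(mk$chrom == config$causal_chrom & mk$pos == causal_pos)
  # recessive: mutant iff both haplotypes are reference-parent origin (0)
  phenotype <- ifelse(hap1[causal_row, ] == 0L & hap2[causal_row, ] == 0L,
                      "mutant", "wt")
  for (cls in c("wt", "mutant")) {
    want <- if (cls == "wt") config$n_wt_pool else config$n_mut_pool
    have <- sum(phenotype == cls)
    if (have < want) {
      stop("phenotype class '", cls, "' has only ", have,
           " plants; cannot draw a pool of ", want)
    }
  }
  wt_members <- sample(which(phenotype == "wt"), config$n_wt_pool)
  mut_members <- sample(which(phenotype == "mutant"), config$n_mut_pool)
  pools <- tibble::tibble(
    plant = c(wt_members, mut_members),
    pool = rep(c("wt", "mut"), c(config$n_wt_pool, config$n_mut_pool))
  )
  structure(list(hap1 = hap1, hap2 = hap2,
                 phenotype = phenotype, pools = pools,
                 causal_chrom = config$causal_chrom, causal_pos = causal_pos,
                 genome = genome, config = config),
            class = "cross_sim_truth")
}

#' @export
print.cross_sim_truth <- function(x, ...) {
  cat("<cross_sim_truth>\n")
  cat("  F2 plants:", length(x$phenotype),
      sprintf("(%d wt / %d mutant)", sum(x$phenotype == "wt"),
              sum(x$phenotype == "mutant")), "\n")
  cat("  markers:", nrow(x$hap1), "  causal:",
      paste0(x$causal_chrom, ":", x$causal_pos), "\n")
  cat("  pools:", sum(x$pools$pool == "wt"), "wt /",
      sum(x$pools$pool == "mut"), "mut\n")
  invisible(x)
}

# ALT-allele dosage matrix for the truth's markers x plants.
# Background markers: ALT = wild-parent allele (origin 1).
# Causal site: ALT = induced mutation on the reference-background
# haplotype (origin 0).
alt_dosage <- function(truth) {
  mk <- truth$genome$markers
  dos <- truth$hap1 + truth$hap2
  causal_row <- which(mk$chrom == truth$causal_chrom &
                        mk$pos == truth$causal_pos)
  dos[causal_row, ] <- 2L - dos[causal_row, ]
  dos
}

#' Sample pooled sequencing read counts from a simulated cross
#'
#' Emulates pooled short-read sequencing of the two phenotype bulks: for
#' every marker and pool, depth is Poisson(`mean_depth`) and each read is
#' drawn from a uniformly chosen pool haplotype and miscalled with
#' probability `base_error`. The causal site is emitted with the induced
#' mutant allele as ALT (a G-to-A transition) and is never in the known
#' catalog; background markers carry the wild-parent allele as ALT and
#' inherit the genome map's catalog flag.
#'
#' @param truth A [simulate_f2()] result.
#' @param genome The [genome_map()] the truth was simulated on (defaults to
#'   the one stored in `truth`).
#' @param config The [cross_config()] (defaults to the one stored in
#'   `truth`). Sampling is seeded with `config$seed + 1` so read noise is
#'   reproducible yet independent of the meiosis stream.
#'
#' @return A tibble of pooled variants sorted by (chrom, pos):
#'   `chrom`, `pos`, `ref`, `alt`, `wt_ref`, `wt_alt`, `mut_ref`, `mut_alt`,
#'   `in_known_catalog`.
#' @export
sample_pooled_reads <- function(truth, genome = truth$genome,
                                config = truth$config) {
  stopifnot(inherits(truth, "cross_sim_truth"))
  mk <- genome$markers
  dos <- alt_dosage(truth)
  set.seed(config$seed + 1L)
  n_mark <- nrow(mk)
  counts <- list()
  for (pool in c("wt", "mut")) {
    plants <- truth$pools$plant[truth$pools$pool == pool]
    f <- rowSums(dos[, plants, drop = FALSE]) / (2 * length(plants))
    p_alt <- f * (1 - config$base_error) + (1 - f) * config$base_error
    depth <- stats::rpois(n_mark, config$mean_depth)
    alt_n <- stats::rbinom(n_mark, depth, p_alt)
    counts[[pool]] <- list(ref = depth - alt_n, alt = alt_n)
  }
  causal_row <- which(mk$chrom == truth$causal_chrom &
                        mk$pos == truth$causal_pos)
  ref <- mk$ref
  alt <- mk$alt
  ref[causal_row] <- "G"
  alt[causal_row] <- "A"
  known <- mk$known
  known[causal_row] <- FALSE
  tibble::tibble(
    chrom = mk$chrom, pos = mk$pos, ref = ref, alt = alt,
    wt_ref = counts$wt$ref, wt_alt = counts$wt$alt,
    mut_ref = counts$mut$ref, mut_alt = counts$mut$alt,
    in_known_catalog = known
  ) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Write simulated pooled variants as VCF (with optional truth sidecar)
#'
#' Emits a plain-text VCF 4.2 file with two sample columns (`wt_pool`,
#' `mut_pool`) carrying `AD` (ref,alt) and `DP` per sample, and a `KNOWN`
#' INFO flag for catalog membership. Output is byte-deterministic for a
#' given variant table. An optional truth sidecar TSV records each plant's
#' pool, phenotype and causal-site genotype.
#'
#' @param variants Pooled-variant tibble from [sample_pooled_reads()],
#'   sorted by (chrom, pos).
#' @param path Output VCF path.
#' @param genome Optional [genome_map()] for `##contig` header lines.
#' @param truth Optional [simulate_f2()] truth; written to `truth_path`.
#' @param truth_path Sidecar TSV path (default: `path` with `.truth.tsv`).
#'
#' @return `path`, invisibly.
#' @export
write_sim_vcf <- function(variants, path, genome = NULL,
                          truth = NULL,
                          truth_path = paste0(path, ".truth.tsv")) {
  if (nrow(variants) > 0) {
    o <- order(variants$chrom, variants$pos)
    if (!identical(o, seq_len(nrow(variants)))) {
      stop("variants must be sorted by chromosome then position")
    }
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=poolmapr",
    if (!is.null(genome)) {
      sprintf("##contig=<ID=%s,length=%d>",
              genome$chromosomes$chrom,
              as.integer(genome$chromosomes$length_bp))
    },
    "##INFO=<ID=KNOWN,Number=0,Type=Flag,Description=\"Previously reported variant\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "wt_pool", "mut_pool", sep = "\t")
  )
  body <- character(0)
  if (nrow(variants) > 0) {
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tAD:DP\t%d,%d:%d\t%d,%d:%d",
      variants$chrom, as.integer(variants$pos), variants$ref, variants$alt,
      ifelse(variants$in_known_catalog, "KNOWN", "."),
      variants$wt_ref, variants$wt_alt, variants$wt_ref + variants$wt_alt,
      variants$mut_ref, variants$mut_alt, variants$mut_ref + variants$mut_alt
    )
  }
  writeLines(c(hdr, body), path)
  if (!is.null(truth)) {
    mk <- truth$genome$markers
    causal_row <- which(mk$chrom == truth$causal_chrom &
                          mk$pos == truth$causal_pos)
    dos <- 2L - (truth$hap1[causal_row, ] + truth$hap2[causal_row, ])
    pool <- rep("none", length(truth$phenotype))
    pool[truth$pools$plant] <- truth$pools$pool
    sidecar <- tibble::tibble(
      plant = seq_along(truth$phenotype),
      pool = pool,
      phenotype = truth$phenotype,
      causal_genotype = c("0/0", "0/1", "1/1")[dos + 1L]
    )
    readr::write_tsv(sidecar, truth_path)
  }
  invisible(path)
}
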