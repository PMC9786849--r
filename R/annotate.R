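#' Build a gene model for variant-effect prediction
#'
#' Couples a spliced coding sequence with its genomic exon structure so that
#' genomic SNV coordinates can be projected into the CDS and translated.
#' The CDS length must be divisible by 3; a missing ATG start or canonical
#' stop only warns (partial models are common in draft annotation).
#'
#' @param gene_id Gene identifier.
#' @param cds Spliced coding sequence, 5' to 3' (character or
#'   [Biostrings::DNAString]).
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame of CDS exon intervals in genomic coordinates
#'   (`start`, `end`, 1-based inclusive), non-overlapping; any order is
#'   accepted and sorted genomically.
#'
#' @return A `gene_model` object.
#' @export
gene_model <- function(gene_id, cds, strand = c("+", "-"), exons) {
  strand <- match.arg(strand)
  cds <- toupper(as.character(cds))
  if (!grepl("^[ACGT]+$", cds)) stop("CDS must be over the A/C/G/T alphabet")
  if (nchar(cds) %% 3 != 0) {
    stop("CDS length (", nchar(cds), ") is not divisible by 3")
  }
  exons <- tibble::as_tibble(exons)[, c("start", "end")]
  exons <- dplyr::arrange(exons, .data$start)
  if (any(exons$end < exons$start)) stop("exon with end < start")
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("exon intervals overlap")
  }
  if (sum(exons$end - exons$start + 1) != nchar(cds)) {
    stop("exon intervals cover ", sum(exons$end - exons$start + 1),
         " bp but the CDS is ", nchar(cds), " bp")
  }
  if (substr(cds, 1, 3) != "ATG") warning("CDS does not start with ATG")
  last <- substr(cds, nchar(cds) - 2, nchar(cds))
  if (!last %in% c("TAA", "TAG", "TGA")) {
    warning("CDS does not end with a stop codon")
  }
  structure(list(gene_id = gene_id, cds = cds, strand = strand,
                 exons = exons),
            class = "gene_model")
}

#' Project a genomic position onto the CDS
#'
#' Returns the 1-based CDS offset of a genomic position, strand-aware: on
#' the minus strand the CDS starts at the 3'-most genomic exon base and
#' counts downward. Positions outside the exons return `NA` (noncoding).
#'
#' @param model A [gene_model()].
#' @param chrom_pos Genomic position (1-based), vectorized.
#'
#' @return Integer vector of CDS positions, `NA` where noncoding.
#' @export
project_to_cds <- function(model, chrom_pos) {
  stopifnot(inherits(model, "gene_model"), all(chrom_pos >= 1))
  ex <- model$exons
  widths <- ex$end - ex$start + 1L
  before <- cumsum(c(0L, widths))[seq_len(nrow(ex))]
  vapply(chrom_pos, function(p) {
    i <- which(p >= ex$start & p <= ex$end)
    if (length(i) == 0) return(NA_integer_)
    plus_off <- as.integer(before[i] + (p - ex$start[i]) + 1)
    if (model$strand == "+") plus_off
    else as.integer(nchar(model$cds) - plus_off + 1)
  }, integer(1))
}

#' Predict the coding consequence of an SNV
#'
#' Substitutes a single base in the coding sequence and reports the affected
#' codon and amino-acid change under the standard nuclear genetic code.
#' Input bases are given on the forward genomic strand (VCF convention) and
#' complemented internally for minus-strand genes. The supplied reference
#' base must match the CDS at the target position.
#'
#' @param model A [gene_model()].
#' @param cds_pos 1-based CDS position (e.g. from [project_to_cds()]).
#' @param ref_base,alt_base Reference and alternative bases on the forward
#'   genomic strand.
#'
#' @return A one-row tibble: `gene_id`, `cds_pos`, `codon_index`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `effect_class` (one of
#'   `synonymous`, `missense`, `stop_gain`, `stop_loss`, `start_loss`).
#' @export
#' @examples
#' m <- gene_model("toy", "ATGCGGTAA", "+",
#'                 data.frame(start = 101, end = 109))
#' predict_effect(m, 5, "G", "A")  # CGG -> CAG, Arg -> Gln missense
predict_effect <- function(model, cds_pos, ref_base, alt_base) {
  stopifnot(inherits(model, "gene_model"),
            length(cds_pos) == 1, cds_pos >= 1,
            cds_pos <= nchar(model$cds))
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  if (!ref_base %in% c("A", "C", "G", "T") ||
      !alt_base %in% c("A", "C", "G", "T")) {
    stop("bases must be one of A, C, G, T")
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (model$strand == "-") {
    ref_base <- comp[[ref_base]]
    alt_base <- comp[[alt_base]]
  }
  have <- substr(model$cds, cds_pos, cds_pos)
  if (have != ref_base) {
    stop("reference mismatch at CDS position ", cds_pos, ": CDS has '",
         have, "' but variant says '", ref_base, "'")
  }
  codon_index <- ceiling(cds_pos / 3)
  codon_start <- 3 * (codon_index - 1) + 1
  ref_codon <- substr(model$cds, codon_start, codon_start + 2)
  within <- cds_pos - codon_start + 1
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_base
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  effect_class <- if (ref_aa == alt_aa) {
    "synonymous"
  } else if (alt_aa == "*") {
    "stop_gain"
  } else if (ref_aa == "*") {
    "stop_loss"
  } else if (codon_index == 1 && ref_codon == "ATG") {
    "start_loss"
  } else {
    "missense"
  }
  tibble::tibble(gene_id = model$gene_id, cds_pos = as.integer(cds_pos),
                 codon_index = as.integer(codon_index),
                 ref_codon = ref_codon, alt_codon = alt_codon,
                 ref_aa = ref_aa, alt_aa = alt_aa,
                 effect_class = effect_class)
}
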