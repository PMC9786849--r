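#' Restriction enzyme definitions
#'
#' A small editable catalog ships with the package at
#' `system.file("extdata", "enzymes.tsv", package = "poolmapr")`
#' (columns: name, site, cut_offset). `restriction_enzymes()` loads it;
#' `enzyme()` builds a definition directly, e.g. ClaI cuts AT/CGAT
#' (recognition `ATCGAT`, top-strand cut offset 2).
#'
#' Only top-strand scanning is performed; the modeled enzymes have
#' palindromic recognition sites, so no reverse-strand pass is needed.
#' IUPAC ambiguity codes are allowed in recognition sequences.
#'
#' @param name Enzyme name.
#' @param site Recognition sequence (IUPAC allowed), length >= 4.
#' @param cut_offset Top-strand cut position after this many bases of the
#'   recognition site (0 .. site length).
#'
#' @return An `enzyme` object (named list).
#' @export
#' @examples
#' enzyme("ClaI", "ATCGAT", 2)
#' restriction_enzymes()
enzyme <- function(name, site, cut_offset) {
  site <- toupper(site)
  if (nchar(site) < 4) stop("recognition sequence must be >= 4 bases")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", site)) {
    stop("recognition sequence must be IUPAC nucleotide codes")
  }
  if (cut_offset < 0 || cut_offset > nchar(site)) {
    stop("cut_offset must be between 0 and the recognition length")
  }
  structure(list(name = name, site = site,
                 cut_offset = as.integer(cut_offset)),
            class = "enzyme")
}

#' @rdname enzyme
#' @export
restriction_enzymes <- function() {
  path <- system.file("extdata", "enzymes.tsv", package = "poolmapr")
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stats::setNames(
    purrr::pmap(tab, function(name, site, cut_offset)
      enzyme(name, site, cut_offset)),
    tab$name
  )
}

iupac_class <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGT]")

#' Scan a sequence for restriction recognition sites
#'
#' Finds every top-strand match of the enzyme's recognition pattern
#' (IUPAC-aware, case-insensitive), overlapping matches included.
#'
#' @param sequence DNA sequence (character).
#' @param enz An [enzyme()].
#'
#' @return Integer vector of 1-based match start positions (empty when
#'   there is no match or the sequence is empty).
#' @export
#' @examples
#' scan_sites("tctagactcgagACTTCC", enzyme("XbaI", "TCTAGA", 1))
scan_sites <- function(sequence, enz) {
  stopifnot(inherits(enz, "enzyme"))
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0) return(integer(0))
  pat <- paste0("(?=", paste(iupac_class[strsplit(enz$site, "")[[1]]],
                             collapse = ""), ")")
  m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Digest an amplicon in silico
#'
#' Cuts a linear amplicon at every recognition site: the cut falls after
#' base `match_start - 1 + cut_offset`; fragments are the resulting
#' left-to-right intervals, so fragment lengths always sum to the amplicon
#' length and `n_fragments = n_cuts + 1`.
#'
#' @param amplicon DNA sequence (character).
#' @param enz An [enzyme()].
#'
#' @return A `digest_result` list: `amplicon_length`, `cut_positions`
#'   (1-based, cut after that base) and `fragment_lengths`.
#' @export
#' @examples
#' claI <- enzyme("ClaI", "ATCGAT", 2)
#' digest(paste0(strrep("C", 70), "ATCGAT", strrep("C", 20)), claI)
digest <- function(amplicon, enz) {
  amplicon <- toupper(as.character(amplicon))
  len <- nchar(amplicon)
  starts <- scan_sites(amplicon, enz)
  cuts <- starts - 1L + enz$cut_offset
  cuts <- sort(unique(cuts[cuts > 0 & cuts < len]))
  structure(list(amplicon_length = len,
                 cut_positions = cuts,
                 fragment_lengths = diff(c(0L, cuts, len))),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat("<digest_result> ", x$amplicon_length, " bp; ",
      length(x$cut_positions), " cut(s); fragments: ",
      paste(x$fragment_lengths, collapse = " + "), "\n", sep = "")
  invisible(x)
}

# smallest distance from any distinguishing fragment of one digest to the
# nearest fragment of the other digest
min_distinguishing_diff <- function(a, b) {
  only_a <- vecsets_diff(a, b)
  only_b <- vecsets_diff(b, a)
  d <- c(
    vapply(only_a, function(f) min(abs(f - b)), numeric(1)),
    vapply(only_b, function(f) min(abs(f - a)), numeric(1))
  )
  min(d)
}

# multiset difference a \ b
vecsets_diff <- function(a, b) {
  for (x in b) {
    i <- match(x, a)
    if (!is.na(i)) a <- a[-i]
  }
  a
}

#' Evaluate a CAPS/dCAPS marker candidate
#'
#' Digests the two allelic amplicons and decides whether the assay can
#' distinguish them on a gel: the marker is usable iff the fragment-length
#' multisets differ and the smallest distinguishing fragment-size
#' difference is at least `min_diff_bp` (default 10 bp, roughly the
#' resolution of a 2% agarose gel).
#'
#' @param wt_amplicon,mut_amplicon Equal-length allelic amplicon sequences
#'   differing at one or more bases.
#' @param enz An [enzyme()].
#' @param min_diff_bp Minimum resolvable fragment-size difference (bp).
#'
#' @return A `marker_verdict` list: `usable`, `min_distinguishing_diff`
#'   (NA when digests are identical), `wt_digest`, `mut_digest`, `enzyme`,
#'   `min_diff_bp`.
#' @export
evaluate_marker <- function(wt_amplicon, mut_amplicon, enz,
                            min_diff_bp = 10) {
  wt_amplicon <- toupper(as.character(wt_amplicon))
  mut_amplicon <- toupper(as.character(mut_amplicon))
  if (nchar(wt_amplicon) != nchar(mut_amplicon)) {
    stop("allelic amplicons must have equal length")
  }
  if (wt_amplicon == mut_amplicon) {
    stop("amplicons are identical; no marker to evaluate")
  }
  wt_d <- digest(wt_amplicon, enz)
  mut_d <- digest(mut_amplicon, enz)
  same <- identical(sort(wt_d$fragment_lengths),
                    sort(mut_d$fragment_lengths))
  mdd <- if (same) NA_real_ else
    min_distinguishing_diff(wt_d$fragment_lengths, mut_d$fragment_lengths)
  structure(list(usable = !same && mdd >= min_diff_bp,
                 min_distinguishing_diff = mdd,
                 wt_digest = wt_d, mut_digest = mut_d,
                 enzyme = enz$name, min_diff_bp = min_diff_bp),
            class = "marker_verdict")
}

#' @export
print.marker_verdict <- function(x, ...) {
  cat("<marker_verdict> enzyme ", x$enzyme, ": ",
      if (x$usable) "usable" else "not usable", "\n", sep = "")
  cat("  wt fragments: ", paste(x$wt_digest$fragment_lengths,
                                collapse = " + "), "\n", sep = "")
  cat("  mut fragments: ", paste(x$mut_digest$fragment_lengths,
                                 collapse = " + "), "\n", sep = "")
  if (!is.na(x$min_distinguishing_diff)) {
    cat("  smallest distinguishing difference: ",
        x$min_distinguishing_diff, " bp (threshold ", x$min_diff_bp,
        ")\n", sep = "")
  }
  invisible(x)
}

#' The worked dCAPS amplicon pair
#'
#' A synthetic 96 bp amplicon pair reproducing the published assay
#' arithmetic: the wild-type allele carries one ClaI site (ATCGAT) placed
#' so the cut falls after base 72, yielding 72 + 24 bp fragments, while the
#' mutant allele carries the causal G-to-A substitution that ablates the
#' site and stays uncut at 96 bp. The flanking sequence is synthetic — the
#' study's amplicon sequence is not published — so only the fragment
#' arithmetic is reproduced.
#'
#' @return Named list with `wt` and `mut` 96-character sequences.
#' @export
dcaps_fixture_amplicons <- function() {
  # ClaI cut offset 2: cut after base (start - 1) + 2 = 72 -> site at 71..76
  bases <- c("A", "C", "G", "T")
  flank <- paste(bases[(seq_len(96) %% 4) + 1], collapse = "")
  wt <- flank
  substr(wt, 71, 76) <- "ATCGAT"
  mut <- wt
  substr(mut, 74, 74) <- "A"  # the G>A ablates the recognition site
  list(wt = wt, mut = mut)
}
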