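# Shared fixtures built in code at test time.

# small cross: 1 chromosome, quick to simulate
small_genome <- function(markers = 40, known_frac = 0.9) {
  genome_map(n_chrom = 1, chrom_length_bp = 1e6, chrom_length_cM = 100,
             markers_per_chrom = markers, known_frac = known_frac)
}

small_config <- function(seed = 1, ...) {
  cross_config(n_f2 = 60, n_wt_pool = 12, n_mut_pool = 8,
               causal_chrom = "chr01", seed = seed, ...)
}

# a pooled-variant tibble with hand-set counts
make_variants <- function(n, chrom = "chr01", seed = 1) {
  set.seed(seed)
  tibble::tibble(
    chrom = chrom,
    pos = sort(sample.int(1e6, n)),
    ref = "A", alt = "G",
    wt_ref = rpois(n, 20), wt_alt = rpois(n, 20),
    mut_ref = rpois(n, 20), mut_alt = rpois(n, 20),
    in_known_catalog = FALSE
  )
}

# naive brute-force restriction-site matcher (independent of scan_sites)
iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

brute_scan <- function(sequence, site) {
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  site_chars <- strsplit(toupper(site), "")[[1]]
  m <- length(site_chars)
  hits <- integer(0)
  if (length(seq_chars) < m) return(hits)
  for (i in seq_len(length(seq_chars) - m + 1)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!seq_chars[i + j - 1] %in% iupac_sets[[site_chars[j]]]) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
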