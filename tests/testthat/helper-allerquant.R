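# shared fixtures and independent oracles for the test suite

synthetic_construct <- function() {
  read_construct(
    system.file("extdata", "construct_34-216_synthetic.fasta",
                package = "allerquant"),
    numbering_offset = 34
  )
}

# minimal fragment row for matching tests, bypassing sequence bookkeeping
fake_fragment <- function(mass_na, n_count, enrichment = 1,
                          start = 1L, end = 2L, sequence = "GG") {
  tibble::tibble(
    start = as.integer(start), end = as.integer(end),
    full_start = as.integer(start), full_end = as.integer(end),
    sequence = sequence, n_count = as.integer(n_count),
    mass_na = mass_na,
    mass_15n = mass_na + enrichment * n_count * 0.9970349
  )
}

# brute-force substring enumeration oracle, independent of the prefix-sum
# implementation: explicit nested loops, per-peptide residue summation
brute_force_fragments <- function(sequence, min_len, max_len,
                                  mz_min = -Inf, mz_max = Inf) {
  codes <- strsplit(sequence, "")[[1]]
  n <- length(codes)
  res <- allerquant:::AA_MONO
  water <- allerquant:::WATER_MONO
  proton <- allerquant:::PROTON
  out <- list()
  for (len in min_len:max_len) {
    if (len > n) next
    for (s in 1:(n - len + 1)) {
      e <- s + len - 1
      m <- sum(vapply(codes[s:e], function(a) res[[a]], numeric(1))) +
        water + proton
      if (m >= mz_min && m <= mz_max) {
        out[[length(out) + 1]] <- c(start = s, end = e, mass = m)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), mass = numeric()))
  }
  as.data.frame(do.call(rbind, out))
}
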