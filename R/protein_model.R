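#' Protein construct with a residue-numbering offset
#'
#' Expression constructs are often truncations of the full protein; the Bla g 1
#' construct studied here spans residues 34-216 of the full sequence, so
#' construct residue 1 corresponds to full-protein residue 34. A
#' `protein_construct` records the one-letter sequence together with that
#' offset so fragment intervals can be reported in either coordinate system.
#'
#' @param sequence One-letter amino-acid string (canonical 20 codes only).
#' @param id Identifier for the construct.
#' @param numbering_offset Full-protein position of construct residue 1
#'   (integer >= 1).
#'
#' @return An object of class `protein_construct` with fields `id`,
#'   `sequence` and `numbering_offset`.
#' @examples
#' protein_construct("GGAKAR", id = "demo", numbering_offset = 34)
#' @export
protein_construct <- function(sequence, id = "construct", numbering_offset = 1L) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("`sequence` must be a single non-empty string", call. = FALSE)
  }
  numbering_offset <- as.integer(numbering_offset)
  if (is.na(numbering_offset) || numbering_offset < 1L) {
    stop("`numbering_offset` must be an integer >= 1", call. = FALSE)
  }
  sequence <- toupper(sequence)
  .check_canonical(sequence)
  structure(
    list(id = as.character(id), sequence = sequence,
         numbering_offset = numbering_offset),
    class = "protein_construct"
  )
}

#' @export
print.protein_construct <- function(x, ...) {
  n <- nchar(x$sequence)
  cat(sprintf(
    "<protein_construct> %s: %d residues (full-protein numbering %d-%d)\n",
    x$id, n, x$numbering_offset, x$numbering_offset + n - 1L
  ))
  invisible(x)
}

#' @export
length.protein_construct <- function(x) nchar(x$sequence)

.check_canonical <- function(sequence) {
  codes <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!codes %in% CANONICAL_AA)
  if (length(bad) > 0L) {
    stop(sprintf(
      "non-canonical residue '%s' at position %d (ambiguity codes B/Z/X/U/O are rejected)",
      codes[bad[1]], bad[1]
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Parse a single-record FASTA into a protein construct
#'
#' Accepts the text of a FASTA file containing exactly one record. Whitespace
#' inside the sequence lines is ignored; ambiguity codes are rejected with the
#' offending position named.
#'
#' @param fasta_text FASTA-formatted text (single record).
#' @param numbering_offset Full-protein position of construct residue 1.
#' @return A [protein_construct()].
#' @examples
#' parse_sequence(">p\nGG AK\nAR", numbering_offset = 34)
#' @seealso [read_construct()] to read from a file.
#' @export
parse_sequence <- function(fasta_text, numbering_offset = 1L) {
  stopifnot(is.character(fasta_text), length(fasta_text) == 1L)
  lines <- strsplit(fasta_text, "\r?\n")[[1]]
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(headers) == 0L) {
    stop("not FASTA: no '>' header line found", call. = FALSE)
  }
  if (length(headers) > 1L) {
    stop("expected exactly one FASTA record, found ", length(headers),
         call. = FALSE)
  }
  if (headers[1] != 1L) {
    stop("not FASTA: sequence text precedes the '>' header", call. = FALSE)
  }
  id <- sub("^>\\s*", "", lines[1])
  id <- strsplit(id, "\\s+")[[1]][1]
  seq <- gsub("\\s", "", paste(lines[-1], collapse = ""))
  if (!nzchar(seq)) stop("empty FASTA record", call. = FALSE)
  protein_construct(seq, id = id, numbering_offset = numbering_offset)
}

#' Read a protein construct from a FASTA file
#'
#' @param path Path to a FASTA file with exactly one record.
#' @inheritParams parse_sequence
#' @return A [protein_construct()].
#' @export
read_construct <- function(path, numbering_offset = 1L) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) != 1L) {
    stop("expected exactly one FASTA record in ", path, ", found ",
         length(set), call. = FALSE)
  }
  id <- strsplit(names(set)[1], "\\s+")[[1]][1]
  protein_construct(as.character(set[[1]]), id = id,
                    numbering_offset = numbering_offset)
}

#' Count nitrogen atoms in a peptide
#'
#' Uniform metabolic 15N labeling shifts a peptide mass by one neutron-mass
#' difference per nitrogen atom, so the nitrogen count is what determines the
#' spacing of a natural-abundance/15N isotope pair. Each residue contributes
#' one backbone amide nitrogen; Lys adds 1 side-chain N, Arg 3, His 2, and
#' Asn/Gln/Trp 1 each.
#'
#' @param peptide Character vector of peptide sequences (canonical codes).
#' @return Integer vector of total nitrogen atoms.
#' @examples
#' nitrogen_count(c("GG", "AKA", "R"))  # 2, 4, 4
#' @export
nitrogen_count <- function(peptide) {
  vapply(peptide, function(p) {
    .check_canonical(toupper(p))
    codes <- strsplit(toupper(p), "", fixed = TRUE)[[1]]
    sum(AA_NITROGEN[codes])
  }, integer(1), USE.NAMES = FALSE)
}

#' Digestion and mass-computation settings
#'
#' Collects the parameters that control in-silico fragment enumeration and
#' peptide mass computation. Defaults reflect reflector-MALDI peptide analysis
#' of an unspecific endosomal digest: fragment lengths 5-40 residues, the
#' m/z 800-4000 acquisition window, monoisotopic masses, singly protonated
#' ions, and full (enrichment 1) uniform 15N labeling for the heavy channel.
#'
#' @param min_length,max_length Fragment length bounds in residues.
#' @param mz_min,mz_max Acquisition window bounds in Da for the
#'   natural-abundance [M+H]+ mass.
#' @param specificity `"unspecific"` enumerates every contiguous substring;
#'   `"user_rules"` additionally requires both cleavage sites flanking a
#'   fragment to satisfy `user_rules`.
#' @param user_rules For `specificity = "user_rules"`: a list with element
#'   `cleave_after`, a character vector of residues after which cleavage is
#'   allowed (the P1 position). Protein termini always count as valid sites.
#' @param enrichment 15N isotopic enrichment fraction in (0, 1].
#' @param mass_type `"monoisotopic"` or `"average"` residue masses.
#' @param charge_adduct Mass added for the charge carrier; default is one
#'   proton (1.007276 Da) for [M+H]+.
#' @return An object of class `digest_config`.
#' @export
digest_config <- function(min_length = 5L, max_length = 40L,
                          mz_min = 800, mz_max = 4000,
                          specificity = c("unspecific", "user_rules"),
                          user_rules = NULL,
                          enrichment = 1.0,
                          mass_type = c("monoisotopic", "average"),
                          charge_adduct = PROTON) {
  specificity <- match.arg(specificity)
  mass_type <- match.arg(mass_type)
  min_length <- as.integer(min_length); max_length <- as.integer(max_length)
  if (!(min_length > 0L && min_length <= max_length)) {
    stop("need 0 < min_length <= max_length", call. = FALSE)
  }
  if (!(mz_min < mz_max)) stop("need mz_min < mz_max", call. = FALSE)
  if (!(enrichment > 0 && enrichment <= 1)) {
    stop("enrichment must lie in (0, 1]", call. = FALSE)
  }
  if (specificity == "user_rules") {
    if (is.null(user_rules$cleave_after)) {
      stop("specificity = 'user_rules' requires user_rules$cleave_after",
           call. = FALSE)
    }
    if (!all(user_rules$cleave_after %in% CANONICAL_AA)) {
      stop("user_rules$cleave_after must use canonical residue codes",
           call. = FALSE)
    }
  }
  structure(
    list(min_length = min_length, max_length = max_length,
         mz_min = mz_min, mz_max = mz_max,
         specificity = specificity, user_rules = user_rules,
         enrichment = enrichment, mass_type = mass_type,
         charge_adduct = charge_adduct),
    class = "digest_config"
  )
}

.residue_masses <- function(mass_type) {
  if (mass_type == "average") AA_AVG else AA_MONO
}

.water_mass <- function(mass_type) {
  if (mass_type == "average") WATER_AVG else WATER_MONO
}

#' Peptide mass under natural abundance or uniform 15N labeling
#'
#' Computes the charged peptide mass as the sum of residue masses plus one
#' water plus the charge adduct. For `label = "n15"` the mass is shifted by
#' `enrichment * n_count * 0.9970349` Da, the centroid displacement of a
#' uniformly enriched peptide (isotopologue envelopes are not modeled; peak
#' lists are assumed centroided).
#'
#' @param peptide Character vector of peptide sequences.
#' @param config A [digest_config()].
#' @param label `"na"` (natural abundance) or `"n15"` (uniform 15N).
#' @return Numeric vector of masses in Da.
#' @examples
#' peptide_mass("GG")                       # 133.0608 ([M+H]+)
#' peptide_mass("LAVIPWAIV", label = "n15") # 15N partner of the 981.6 ion
#' @export
peptide_mass <- function(peptide, config = digest_config(),
                         label = c("na", "n15")) {
  label <- match.arg(label)
  stopifnot(inherits(config, "digest_config"))
  res <- .residue_masses(config$mass_type)
  base <- vapply(peptide, function(p) {
    p <- toupper(p)
    .check_canonical(p)
    codes <- strsplit(p, "", fixed = TRUE)[[1]]
    sum(res[codes])
  }, numeric(1), USE.NAMES = FALSE)
  m <- base + .water_mass(config$mass_type) + config$charge_adduct
  if (label == "n15") {
    m <- m + config$enrichment * nitrogen_count(peptide) * N15_SHIFT
  }
  m
}

#' Enumerate candidate digestion fragments of a construct
#'
#' Builds the candidate space against which observed MALDI peaks are assigned.
#' With `specificity = "unspecific"` every contiguous substring with length in
#' `[min_length, max_length]` and natural-abundance [M+H]+ inside
#' `[mz_min, mz_max]` is returned; with `"user_rules"` both flanking cleavage
#' sites must additionally satisfy the rules (termini always qualify). Each
#' fragment carries its nitrogen count and both label masses.
#'
#' @param construct A [protein_construct()].
#' @param config A [digest_config()].
#' @return A tibble with columns `start`, `end` (construct-relative, 1-based
#'   inclusive), `full_start`, `full_end` (full-protein numbering),
#'   `sequence`, `n_count`, `mass_na`, `mass_15n`, sorted by (start, end).
#' @export
enumerate_fragments <- function(construct, config = digest_config()) {
  stopifnot(inherits(construct, "protein_construct"),
            inherits(config, "digest_config"))
  seq <- construct$sequence
  n <- nchar(seq)
  codes <- strsplit(seq, "", fixed = TRUE)[[1]]
  res <- .residue_masses(config$mass_type)
  # prefix sums give O(1) interval masses / nitrogen counts and make
  # concatenation additivity exact by construction
  cum_mass <- c(0, cumsum(unname(res[codes])))
  cum_n <- c(0L, cumsum(unname(AA_NITROGEN[codes])))

  lens <- seq.int(config$min_length, min(config$max_length, n))
  if (length(lens) == 0L || lens[1] > n) return(.empty_fragment_table())
  starts <- unlist(lapply(lens, function(L) seq_len(n - L + 1L)), use.names = FALSE)
  ends <- unlist(lapply(lens, function(L) seq_len(n - L + 1L) + L - 1L), use.names = FALSE)

  if (config$specificity == "user_rules") {
    p1 <- config$user_rules$cleave_after
    ok_start <- starts == 1L | codes[pmax(starts - 1L, 1L)] %in% p1
    ok_end <- ends == n | codes[ends] %in% p1
    keep <- ok_start & ok_end
    starts <- starts[keep]; ends <- ends[keep]
  }
  if (length(starts) == 0L) return(.empty_fragment_table())

  water_adduct <- .water_mass(config$mass_type) + config$charge_adduct
  mass_na <- cum_mass[ends + 1L] - cum_mass[starts] + water_adduct
  n_count <- cum_n[ends + 1L] - cum_n[starts]
  keep <- mass_na >= config$mz_min & mass_na <= config$mz_max
  starts <- starts[keep]; ends <- ends[keep]
  mass_na <- mass_na[keep]; n_count <- n_count[keep]
  if (length(starts) == 0L) return(.empty_fragment_table())

  ord <- order(starts, ends)
  starts <- starts[ord]; ends <- ends[ord]
  mass_na <- mass_na[ord]; n_count <- n_count[ord]
  off <- construct$numbering_offset
  tibble::tibble(
    start = starts,
    end = ends,
    full_start = starts + off - 1L,
    full_end = ends + off - 1L,
    sequence = substring(seq, starts, ends),
    n_count = as.integer(n_count),
    mass_na = mass_na,
    mass_15n = mass_na + config$enrichment * n_count * N15_SHIFT
  )
}

.empty_fragment_table <- function() {
  tibble::tibble(
    start = integer(), end = integer(),
    full_start = integer(), full_end = integer(),
    sequence = character(), n_count = integer(),
    mass_na = numeric(), mass_15n = numeric()
  )
}

#' Write a fragment table to TSV
#'
#' @param fragments Output of [enumerate_fragments()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fragment_table <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
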