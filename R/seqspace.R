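DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over plain character k-mers.  Only the
#' unambiguous alphabet A/C/G/T is supported; anything else is an error.
#'
#' @param x Character vector of DNA strings (upper case A/C/G/T).
#' @return Character vector of the same length with each element reverse
#'   complemented.
#' @examples
#' revcomp(c("ACGT", "AAA"))
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("non-ACGT character in sequence(s): ",
         paste(utils::head(x[bad], 3L), collapse = ", "))
  }
  stringi::stri_reverse(chartr("ACGT", "TGCA", x))
}

#' Complement single bases
#' @param x Character vector of single bases.
#' @return Complemented bases.
#' @export
complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

#' Canonical form of a k-mer
#'
#' The canonical representative of the strand-equivalence class
#' \{k-mer, reverse complement\} is the lexicographically smaller of the
#' two.  Canonicalization is idempotent and strand-invariant:
#' `canonical_kmer(x) == canonical_kmer(revcomp(x))`.
#'
#' @param x Character vector of k-mers.
#' @return Character vector of canonical k-mers.
#' @export
canonical_kmer <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

#' Enumerate all k-mers of width k
#'
#' Returns the full 4^k k-mer space in lexicographic order.  Intended for
#' small k (the exhaustive phase); memory grows as 4^k.
#'
#' @param k Integer width, 1..13.
#' @return Character vector of 4^k k-mers, lexicographically sorted.
#' @export
enumerate_kmers <- function(k) {
  k <- check_k(k, max_k = 13L)
  grids <- rep(list(DNA_BASES), k)
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  m <- do.call(expand.grid, c(rev(grids), stringsAsFactors = FALSE))
  do.call(paste0, rev(m))
}

check_k <- function(k, min_k = 1L, max_k = 19L) {
  if (length(k) != 1L || is.na(k) || k != as.integer(k)) {
    stop("k must be a single integer")
  }
  k <- as.integer(k)
  if (k < min_k || k > max_k) {
    stop("k must be between ", min_k, " and ", max_k, ", got ", k)
  }
  k
}

#' Size of the k-mer sequence space
#'
#' Closed-form size of the raw k-mer space (4^k) and of its
#' reverse-complement-canonical quotient: 4^k / 2 for odd k, and
#' (4^k + 4^(k/2)) / 2 for even k, where the correction term counts the
#' reverse-complement palindromes that are their own class.
#'
#' @param k Integer width, 1..19.
#' @return A tibble with columns `k`, `raw` (4^k) and `canonical`.
#' @examples
#' kmer_space_size(19)   # raw = 274,877,906,944
#' @export
kmer_space_size <- function(k) {
  k <- check_k(k)
  raw <- 4^k
  canonical <- if (k %% 2L == 1L) raw / 2 else (raw + 4^(k / 2)) / 2
  tibble::tibble(k = k, raw = raw, canonical = canonical)
}

#' Enumerate canonical k-mers
#'
#' One representative (lexicographic minimum of k-mer and reverse
#' complement) per strand-equivalence class, in lexicographic order.
#' For odd k there are 4^k/2 classes; for even k, (4^k + 4^(k/2))/2
#' because palindromic k-mers form singleton classes.
#'
#' @param k Integer width, 1..13 (exhaustive enumeration).
#' @return Character vector of canonical k-mers.
#' @examples
#' enumerate_canonical_kmers(2)  # 10 classes
#' @export
enumerate_canonical_kmers <- function(k) {
  k <- check_k(k, max_k = 13L)
  all_kmers <- enumerate_kmers(k)
  sort(unique(canonical_kmer(all_kmers)))
}

# ---- 96-class trinucleotide mutation catalog --------------------------------

SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96-class trinucleotide mutation catalog
#'
#' All strand-collapsed single-base substitution classes in their
#' trinucleotide context, in COSMIC order: substitution class major
#' (C>A, C>G, C>T, T>A, T>C, T>G), then 5' base (A, C, G, T), then
#' 3' base (A, C, G, T).  Labels follow the `A[C>A]A` convention.
#'
#' @return A tibble with 96 rows and columns `class` (label),
#'   `five_prime`, `ref`, `alt`, `three_prime`, `ref_trinucleotide`.
#' @examples
#' mutation_catalog()
#' @export
mutation_catalog <- function() {
  grid <- expand.grid(
    three_prime = DNA_BASES,
    five_prime = DNA_BASES,
    substitution = SUBSTITUTIONS,
    stringsAsFactors = FALSE
  )[, 3:1]
  ref <- substr(grid$substitution, 1L, 1L)
  alt <- substr(grid$substitution, 3L, 3L)
  tibble::tibble(
    class = paste0(grid$five_prime, "[", grid$substitution, "]",
                   grid$three_prime),
    five_prime = grid$five_prime,
    ref = ref,
    alt = alt,
    three_prime = grid$three_prime,
    ref_trinucleotide = paste0(grid$five_prime, ref, grid$three_prime)
  )
}

#' The 32 pyrimidine-centered reference trinucleotides
#'
#' @return Character vector of the 32 trinucleotides with C or T center,
#'   ordered as they first appear in the mutation catalog.
#' @export
reference_trinucleotides <- function() {
  unique(mutation_catalog()$ref_trinucleotide)
}

#' Collapse trinucleotides to the pyrimidine-centered strand
#'
#' Trinucleotides whose center base is a purine (A/G) are replaced by
#' their reverse complement, so each strand-equivalence class is
#' represented by its C- or T-centered member (COSMIC convention).
#'
#' @param trinuc Character vector of trinucleotides.
#' @return Character vector of pyrimidine-centered trinucleotides.
#' @export
pyrimidine_collapse <- function(trinuc) {
  stopifnot(all(nchar(trinuc) == 3L))
  center <- substr(trinuc, 2L, 2L)
  flip <- center %in% c("A", "G")
  out <- trinuc
  out[flip] <- revcomp(trinuc[flip])
  out
}

#' Classify a single-base substitution in trinucleotide context
#'
#' Maps (reference trinucleotide, alternative center base) to one of the
#' 96 strand-collapsed mutation classes.  Purine-centered inputs are
#' collapsed to the pyrimidine strand first, so
#' `classify_mutation(revcomp(t), complement_base(a))` equals
#' `classify_mutation(t, a)`.
#'
#' @param trinuc Character vector of reference trinucleotides.
#' @param alt Character vector of alternative center bases (same length).
#' @return Character vector of class labels such as `"A[C>A]A"`.
#' @examples
#' classify_mutation("ACA", "A")  # "A[C>A]A"
#' classify_mutation("TGT", "T")  # same class, opposite strand
#' @export
classify_mutation <- function(trinuc, alt) {
  stopifnot(length(trinuc) == length(alt), all(nchar(trinuc) == 3L),
            all(nchar(alt) == 1L))
  ref_center <- substr(trinuc, 2L, 2L)
  if (any(ref_center == alt)) {
    stop("alt base equals the reference center base")
  }
  flip <- ref_center %in% c("A", "G")
  trinuc[flip] <- revcomp(trinuc[flip])
  alt[flip] <- complement_base(alt[flip])
  paste0(substr(trinuc, 1L, 1L), "[", substr(trinuc, 2L, 2L), ">", alt, "]",
         substr(trinuc, 3L, 3L))
}

# ---- genome k-mer counting --------------------------------------------------

read_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  stats::setNames(toupper(as.character(seqs)), names(seqs))
}

# windows of width k over one contig; returns character vector (possibly
# containing ambiguity codes, filtered by caller)
contig_windows <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

#' Count canonical k-mer occurrences in a genome
#'
#' Slides a width-k window over the forward strand of every contig and
#' counts each window once under its canonical (lexicographic-minimum)
#' representative.  Windows containing any non-A/C/G/T character are
#' skipped entirely.
#'
#' @param fasta Path to a FASTA file, or a named character vector of
#'   contig sequences.
#' @param k Integer window width.
#' @return A tibble with columns `kmer` (canonical) and `count`, sorted
#'   by `kmer`; attribute `k` records the width.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">toy", "ACGTACGT"), fa)
#' count_genome_kmers(fa, 3)
#' @export
count_genome_kmers <- function(fasta, k) {
  k <- check_k(k)
  contigs <- if (is.character(fasta) && length(fasta) == 1L &&
                 file.exists(fasta)) {
    read_genome(fasta)
  } else {
    toupper(fasta)
  }
  if (length(contigs) == 0L || all(nchar(contigs) == 0L)) {
    warning("empty genome: returning empty k-mer table")
    out <- tibble::tibble(kmer = character(0), count = integer(0))
    attr(out, "k") <- k
    return(out)
  }
  wins <- unlist(lapply(contigs, contig_windows, k = k), use.names = FALSE)
  wins <- wins[grepl("^[ACGT]+$", wins)]
  if (length(wins) == 0L) {
    warning("no unambiguous windows of width ", k)
    out <- tibble::tibble(kmer = character(0), count = integer(0))
    attr(out, "k") <- k
    return(out)
  }
  tab <- table(canonical_kmer(wins))
  out <- tibble::tibble(kmer = names(tab), count = as.integer(tab)) |>
    dplyr::arrange(.data$kmer)
  attr(out, "k") <- k
  out
}

#' Count genome trinucleotides on the pyrimidine-collapsed strand
#'
#' Counts every unambiguous 3-base window once, keyed by its
#' pyrimidine-centered representative.  This is the reference
#' trinucleotide abundance used to normalize alteration event counts
#' (each genomic trinucleotide is tested w-2 times per width-w motif).
#'
#' @param fasta Path to a FASTA file, or a named character vector of
#'   contig sequences.
#' @return A tibble with all 32 pyrimidine-centered trinucleotides
#'   (`trinucleotide`) and their `count` (0 for absent ones), in catalog
#'   order.
#' @export
count_genome_trinucleotides <- function(fasta) {
  contigs <- if (is.character(fasta) && length(fasta) == 1L &&
                 file.exists(fasta)) {
    read_genome(fasta)
  } else {
    toupper(fasta)
  }
  keys <- reference_trinucleotides()
  counts <- stats::setNames(integer(32L), keys)
  wins <- unlist(lapply(contigs, contig_windows, k = 3L), use.names = FALSE)
  wins <- wins[grepl("^[ACGT]+$", wins)]
  if (length(wins) > 0L) {
    tab <- table(pyrimidine_collapse(wins))
    counts[names(tab)] <- as.integer(tab)
  }
  tibble::tibble(trinucleotide = keys, count = unname(counts))
}
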