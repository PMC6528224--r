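# Shared fixtures, all built in code.

# a near-consensus PWM: `p_major` mass on the consensus base per column
sharp_pwm <- function(consensus, id = "SHARP", depth = 97L) {
  w <- nchar(consensus)
  m <- matrix(1L, nrow = 4L, ncol = w,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T")),
          seq_len(w))] <- depth
  pwm_from_counts(stats::setNames(list(m), id))[[1]]
}

# round count matrices through the JASPAR text format (the public path)
pwm_from_counts <- function(counts, pseudocount = 1) {
  pfm <- withr::local_tempfile(fileext = ".pfm",
                               .local_envir = parent.frame())
  write_jaspar(counts, pfm)
  read_jaspar(pfm, pseudocount = pseudocount)
}

uniform_pwm <- function(width = 6L, id = "UNI") {
  m <- matrix(25L, nrow = 4L, ncol = width,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm_from_counts(stats::setNames(list(m), id))[[1]]
}

# independent reverse complement via Biostrings (oracle)
bio_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# brute-force per-genomic-position alteration counting: slide every
# width-w window, mutate every interior position to every alternative
# base, classify by strand-collapsed trinucleotide, and tally binding
# state changes.  Independent of the k-mer-space counting path.
naive_phi_counts <- function(pwm, contigs, threshold_p = 0.001) {
  w <- pwm$width
  dist <- score_pvalue_distribution(pwm)
  bind <- function(seqs) binding_pvalue(dist, seqs) <= threshold_p
  cat96 <- mutation_catalog()$class
  disrupt <- stats::setNames(integer(96L), cat96)
  create <- stats::setNames(integer(96L), cat96)
  for (seq in contigs) {
    n <- nchar(seq)
    if (n < w) next
    wins <- substring(seq, 1:(n - w + 1L), w:n)
    wins <- wins[grepl("^[ACGT]+$", wins)]
    ref_binding <- bind(wins)
    for (p in 2:(w - 1L)) {
      ref_base <- substr(wins, p, p)
      tri <- substr(wins, p - 1L, p + 1L)
      for (alt in c("A", "C", "G", "T")) {
        sel <- ref_base != alt
        if (!any(sel)) next
        mut <- wins[sel]
        substr(mut, p, p) <- alt
        mut_binding <- bind(mut)
        cls <- classify_mutation(tri[sel], rep(alt, sum(sel)))
        d <- ref_binding[sel] & !mut_binding
        c_ <- !ref_binding[sel] & mut_binding
        if (any(d)) {
          t_ <- table(cls[d])
          disrupt[names(t_)] <- disrupt[names(t_)] + as.integer(t_)
        }
        if (any(c_)) {
          t_ <- table(cls[c_])
          create[names(t_)] <- create[names(t_)] + as.integer(t_)
        }
      }
    }
  }
  list(create = create, disrupt = disrupt)
}
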