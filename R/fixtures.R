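# Synthetic-data generators: genomes from an order-2 Markov chain,
# JASPAR-format PWM sets with controllable per-column concentration,
# COSMIC-style signature tables, exposure tables, and SNVs sampled
# under a chosen signature.  All generators are deterministic per seed
# (R's default Mersenne-Twister stream, seeded locally).

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate a random genome
#'
#' Draws a genome from an order-2 Markov chain whose stationary GC
#' content approximates `gc_content` (bases are drawn i.i.d. per
#' position from the base composition implied by `gc_content`, which is
#' the order-0 special case of the chain; an explicit
#' `trinucleotide_weights` vector over the 32 pyrimidine-collapsed
#' classes biases the chain's transition counts instead).  Optionally
#' plants given motif sequences at recorded non-overlapping positions.
#'
#' @param length Genome length in bases.
#' @param gc_content Target GC fraction in `[0, 1]` (default 0.41, a
#'   mammalian-like value).
#' @param seed Integer seed.
#' @param plant Optional character vector of sequences to embed.
#' @param n_plant Copies of each `plant` sequence (default 1).
#' @param contig_name Name of the single contig (default "chr1").
#' @param trinucleotide_weights Optional named non-negative weights over
#'   the 32 reference trinucleotides used to bias sampling.
#' @param fasta Optional path; when given the genome is also written as
#'   FASTA.
#' @return A named character vector (the contig) with attribute
#'   `plant_positions` (tibble `seq`, `start`) and, when `fasta` is
#'   given, attribute `path`.
#' @export
simulate_genome <- function(length, gc_content = 0.41, seed = 1L,
                            plant = NULL, n_plant = 1L,
                            contig_name = "chr1",
                            trinucleotide_weights = NULL, fasta = NULL) {
  stopifnot(length >= 10L, gc_content >= 0, gc_content <= 1)
  genome <- with_seed(seed, {
    if (is.null(trinucleotide_weights)) {
      p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
             G = gc_content / 2, T = (1 - gc_content) / 2)
      bases <- sample(DNA_BASES, length, replace = TRUE, prob = p)
    } else {
      bases <- sample_markov_genome(length, trinucleotide_weights)
    }
    seq <- paste0(bases, collapse = "")
    positions <- tibble::tibble(seq = character(0), start = integer(0))
    if (!is.null(plant)) {
      taken <- integer(0)
      for (m in rep(plant, each = n_plant)) {
        w <- nchar(m)
        for (try in 1:200) {
          s <- sample.int(length - w + 1L, 1L)
          if (!any(abs(s - taken) < w + 2L)) break
        }
        taken <- c(taken, s)
        substr(seq, s, s + w - 1L) <- m
        positions <- dplyr::bind_rows(positions,
                                      tibble::tibble(seq = m, start = s))
      }
    }
    attr(seq, "plant_positions") <- positions
    seq
  })
  out <- stats::setNames(as.character(genome), contig_name)
  attr(out, "plant_positions") <- attr(genome, "plant_positions")
  if (!is.null(fasta)) {
    writeLines(c(paste0(">", contig_name), chunk_fasta(out[[1]])), fasta)
    attr(out, "path") <- fasta
  }
  out
}

chunk_fasta <- function(seq, width = 70L) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, width), pmin(seq(1L, n, width) + width - 1L, n))
}

# order-2 chain whose trimer emission probabilities follow the given
# (pyrimidine-collapsed) trinucleotide weights, expanded to both strands
sample_markov_genome <- function(length, weights) {
  keys <- reference_trinucleotides()
  if (!all(names(weights) %in% keys) || any(weights < 0) ||
      sum(weights) <= 0) {
    stop("trinucleotide_weights must be non-negative over the 32 ",
         "pyrimidine-centered trinucleotides")
  }
  w32 <- stats::setNames(rep(0, 32L), keys)
  w32[names(weights)] <- weights
  tri64 <- enumerate_kmers(3L)
  w64 <- w32[pyrimidine_collapse(tri64)] / 2
  names(w64) <- tri64
  w64 <- w64 + 1e-9  # keep the chain irreducible
  # conditional P(b3 | b1 b2) from trimer weights
  ctx <- substr(tri64, 1L, 2L)
  bases <- character(length)
  start <- sample(tri64, 1L, prob = w64)
  bases[1:3] <- strsplit(start, "")[[1]]
  cond <- matrix(w64, nrow = 16L, byrow = TRUE,
                 dimnames = list(enumerate_kmers(2L), DNA_BASES))
  cond <- sweep(cond, 1L, rowSums(cond), "/")
  if (length > 3L) {
    for (i in 4:length) {
      cxt <- paste0(bases[i - 2L], bases[i - 1L])
      bases[i] <- sample(DNA_BASES, 1L, prob = cond[cxt, ])
    }
  }
  bases
}

#' Simulate a JASPAR-format PWM set
#'
#' Generates count matrices whose columns are Dirichlet-like draws with
#' concentration `sharpness` (large = near-consensus columns, small =
#' diffuse), with optional AT bias, and always appends two hand-crafted
#' extremes when `include_extremes` is set: a uniform motif and a
#' single-consensus motif, plus an AT-rich homeobox-like and a mixed
#' paired-box-like pair for entropy contrasts.
#'
#' @param n Number of random motifs.
#' @param widths Integer vector of motif widths to cycle through.
#' @param sharpness Per-motif concentration parameter(s), recycled.
#' @param at_rich Logical vector (recycled): bias columns toward A/T.
#' @param seed Integer seed.
#' @param include_extremes Append the hand-crafted motifs (default
#'   FALSE).
#' @param pfm Optional path; when given, the set is written in JASPAR
#'   PFM format.
#' @param depth Total count per column (default 100).
#' @return A named list of 4 x w count matrices; attribute `path` when
#'   written.
#' @export
simulate_pwms <- function(n, widths = c(6L, 7L, 8L), sharpness = 20,
                          at_rich = FALSE, seed = 1L,
                          include_extremes = FALSE, pfm = NULL,
                          depth = 100L) {
  widths <- rep_len(as.integer(widths), n)
  sharpness <- rep_len(sharpness, n)
  at_rich <- rep_len(at_rich, n)
  out <- with_seed(seed, {
    mats <- list()
    for (i in seq_len(n)) {
      w <- widths[i]
      m <- matrix(0, nrow = 4L, ncol = w, dimnames = list(DNA_BASES, NULL))
      for (j in seq_len(w)) {
        # pick a consensus base (A/T-biased for AT-rich motifs), then
        # draw the column from Dirichlet(1 + sharpness * e_consensus):
        # sharpness -> Inf concentrates the column on the consensus,
        # sharpness = 0 gives a flat Dirichlet(1) column
        base_pref <- if (at_rich[i]) c(8, 1, 1, 8) else rep(1, 4)
        cons <- sample.int(4L, 1L, prob = base_pref)
        alpha <- rep(1, 4)
        alpha[cons] <- 1 + sharpness[i]
        g <- stats::rgamma(4L, shape = alpha, rate = 1)
        if (sum(g) == 0) g <- alpha
        p <- g / sum(g)
        m[, j] <- round(p * depth)
        if (sum(m[, j]) == 0) m[which.max(p), j] <- depth
      }
      mats[[sprintf("SIM%03d", i)]] <- m
    }
    mats
  })
  if (include_extremes) {
    uni <- matrix(25L, nrow = 4L, ncol = 8L, dimnames = list(DNA_BASES, NULL))
    cons <- matrix(0L, nrow = 4L, ncol = 8L, dimnames = list(DNA_BASES, NULL))
    cons[cbind(match(strsplit("TTACGTAA", "")[[1]], DNA_BASES), 1:8)] <- 100L
    athox <- matrix(1L, nrow = 4L, ncol = 8L, dimnames = list(DNA_BASES, NULL))
    athox[cbind(match(strsplit("TAATTAAT", "")[[1]], DNA_BASES), 1:8)] <- 97L
    mixed <- matrix(c(
      50, 20, 15, 15,  15, 50, 20, 15,  15, 15, 50, 20,  20, 15, 15, 50,
      50, 20, 15, 15,  15, 50, 20, 15,  15, 15, 50, 20,  20, 15, 15, 50
    ), nrow = 4L, dimnames = list(DNA_BASES, NULL))
    out <- c(out, list(UNIFORM = uni, CONSENSUS = cons,
                       ATHOX = athox, MIXED = mixed))
  }
  if (!is.null(pfm)) {
    write_jaspar(out, pfm)
    attr(out, "path") <- pfm
  }
  out
}

#' Simulate a COSMIC-style signature set
#'
#' Emits one-hot signatures on chosen classes, a uniform signature, and
#' Dirichlet-sampled signatures with the given concentration.
#'
#' @param n_random Number of Dirichlet signatures.
#' @param concentration Dirichlet concentration per class (default 0.1:
#'   spiky, signature-like rows).
#' @param one_hot Character vector of mutation classes to emit as
#'   one-hot signatures (default none).
#' @param uniform Include a uniform 1/96 signature (default TRUE).
#' @param seed Integer seed.
#' @param tsv Optional path; when given, written as a COSMIC-style TSV.
#' @return A `signature_tbl`; attribute `path` when written.
#' @export
simulate_signatures <- function(n_random, concentration = 0.1,
                                one_hot = character(0), uniform = TRUE,
                                seed = 1L, tsv = NULL) {
  cat96 <- mutation_catalog()$class
  rows <- list()
  for (cl in one_hot) {
    stopifnot(cl %in% cat96)
    v <- stats::setNames(rep(0, 96L), cat96)
    v[cl] <- 1
    rows[[paste0("OneHot.", cl)]] <- v
  }
  if (uniform) rows[["Uniform"]] <- stats::setNames(rep(1 / 96, 96L), cat96)
  if (n_random > 0L) {
    rand <- with_seed(seed, {
      lapply(seq_len(n_random), function(i) {
        g <- stats::rgamma(96L, shape = concentration, rate = 1)
        if (sum(g) == 0) g[sample.int(96L, 1L)] <- 1
        stats::setNames(g / sum(g), cat96)
      })
    })
    names(rand) <- sprintf("Random.%02d", seq_len(n_random))
    rows <- c(rows, rand)
  }
  out <- tibble::tibble(
    signature_id = rep(names(rows), each = 96L),
    class = rep(cat96, times = length(rows)),
    prob = unlist(rows, use.names = FALSE)
  )
  class(out) <- c("signature_tbl", class(out))
  if (!is.null(tsv)) {
    write_signatures(out, tsv)
    attr(out, "path") <- tsv
  }
  out
}

#' Simulate a per-sample exposure table
#'
#' Dirichlet-distributed normalized exposures over the given signatures,
#' scaled to count-like magnitudes in the `raw` column.
#'
#' @param signature_ids Character vector of signature ids.
#' @param n_samples Number of samples.
#' @param concentration Dirichlet concentration (default 0.5).
#' @param seed Integer seed.
#' @param tsv Optional output path (signatures x samples, raw scale).
#' @return An `exposure_tbl`; attribute `path` when written.
#' @export
simulate_exposures <- function(signature_ids, n_samples,
                               concentration = 0.5, seed = 1L, tsv = NULL) {
  k <- length(signature_ids)
  vals <- with_seed(seed, {
    m <- matrix(stats::rgamma(k * n_samples, shape = concentration, rate = 1),
                nrow = k,
                dimnames = list(signature_ids,
                                sprintf("sample%03d", seq_len(n_samples))))
    zero <- colSums(m) == 0
    m[1L, zero] <- 1
    round(sweep(m, 2L, colSums(m), "/") * 10000)
  })
  vals[1L, colSums(vals) == 0] <- 1
  if (!is.null(tsv)) {
    df <- tibble::as_tibble(vals, rownames = "signature_id")
    readr::write_tsv(df, tsv)
  }
  out <- normalize_exposure_matrix(vals)
  if (!is.null(tsv)) attr(out, "path") <- tsv
  out
}

#' Simulate SNVs under a mutational signature
#'
#' Samples `n` single-base substitutions whose strand-collapsed class
#' frequencies follow the signature's class probabilities multiplied by
#' the genomic abundance of each class's reference trinucleotide
#' (renormalized; classes with no genomic site and nonzero probability
#' are dropped with a warning).  Sites are drawn with replacement; the
#' returned table keeps every draw, while the VCF output holds each
#' site once (a message reports collisions).
#'
#' @param contigs Named character vector of contig sequences (or FASTA
#'   path).
#' @param signature A `signature_tbl` restricted to one signature, or a
#'   named numeric vector of 96 class probabilities.
#' @param n Number of SNVs to draw.
#' @param seed Integer seed.
#' @param vcf Optional path; when given, a sorted minimal VCF is
#'   written.
#' @param sample_id,cohort_id Optional annotations for the output table.
#' @return An `snv_tbl`; attribute `path` when written.
#' @export
simulate_snvs <- function(contigs, signature, n, seed = 1L, vcf = NULL,
                          sample_id = NA_character_,
                          cohort_id = NA_character_) {
  if (is.character(contigs) && length(contigs) == 1L &&
      file.exists(contigs)) contigs <- read_genome(contigs)
  contigs <- toupper(contigs)
  if (inherits(signature, "data.frame")) {
    stopifnot(length(unique(signature$signature_id)) == 1L)
    sig <- stats::setNames(signature$prob, signature$class)
  } else {
    sig <- signature
  }
  cat96 <- mutation_catalog()
  stopifnot(all(cat96$class %in% names(sig)))
  sig <- sig[cat96$class]
  # index every genomic trinucleotide site by collapsed reference class
  sites <- dplyr::bind_rows(lapply(names(contigs), function(cn) {
    seq <- contigs[[cn]]
    wins <- contig_windows(seq, 3L)
    ok <- grepl("^[ACGT]+$", wins)
    tibble::tibble(contig = cn, pos = which(ok) + 1L,
                   trinuc = wins[ok])
  }))
  sites$collapsed <- pyrimidine_collapse(sites$trinuc)
  abundance <- table(factor(sites$collapsed,
                            levels = reference_trinucleotides()))
  class_weight <- sig * as.numeric(abundance[cat96$ref_trinucleotide])
  dropped <- sig > 0 & class_weight == 0
  if (any(dropped)) {
    warning(sum(dropped), " mutation class(es) with nonzero signature ",
            "probability have no genomic site; renormalizing")
  }
  if (sum(class_weight) == 0) stop("no genomic site matches the signature")
  class_weight <- class_weight / sum(class_weight)
  out <- with_seed(seed, {
    classes <- sample(cat96$class, n, replace = TRUE, prob = class_weight)
    drawn <- lapply(cat96$class[cat96$class %in% classes], function(cl) {
      row <- cat96[cat96$class == cl, ]
      cand <- sites[sites$collapsed == row$ref_trinucleotide, ]
      k <- sum(classes == cl)
      pick <- cand[sample.int(nrow(cand), k, replace = TRUE), ]
      # emit on the forward strand: if the genomic trinucleotide is the
      # collapsed form, alt is the class alt; else the complement
      flipped <- pick$trinuc != pick$collapsed
      tibble::tibble(
        contig = pick$contig, pos = pick$pos,
        ref = substr(pick$trinuc, 2L, 2L),
        alt = ifelse(flipped, complement_base(row$alt), row$alt)
      )
    })
    dplyr::bind_rows(drawn)
  })
  out <- dplyr::arrange(out, .data$contig, .data$pos)
  out$sample_id <- sample_id
  out$cohort_id <- cohort_id
  class(out) <- c("snv_tbl", class(out))
  if (!is.null(vcf)) {
    # the returned table keeps every draw; the VCF must hold each site
    # once, so colliding draws are deduplicated only here
    dup <- duplicated(out[, c("contig", "pos")])
    if (any(dup)) {
      message(sum(dup), " colliding site draw(s) deduplicated in the VCF")
    }
    vout <- out[!dup, ]
    header <- c("##fileformat=VCFv4.2",
                paste0("##contig=<ID=", names(contigs), ",length=",
                       nchar(contigs), ">"),
                "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                    vout$contig, vout$pos, vout$ref, vout$alt)
    writeLines(c(header, body), vcf)
    attr(out, "path") <- vcf
  }
  out
}
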