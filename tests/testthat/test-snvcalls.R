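test_that("VCF and TSV SNV input load identically, skipping non-SNVs", {
  genome <- simulate_genome(5000, seed = 51)
  sig <- simulate_signatures(1, seed = 52, uniform = FALSE)
  sig1 <- sig[sig$signature_id == "Random.01", ]
  vcf <- withr::local_tempfile(fileext = ".vcf")
  snvs <- suppressMessages(simulate_snvs(genome, sig1, 50, seed = 53,
                                         vcf = vcf))
  # the VCF holds each drawn site once
  uniq <- snvs[!duplicated(snvs[, c("contig", "pos")]), ]
  back <- read_snvs(vcf)
  expect_equal(back[, c("contig", "pos", "ref", "alt")],
               uniq[, c("contig", "pos", "ref", "alt")],
               ignore_attr = TRUE)
  # indels and multiallelic records are skipped with a count
  lines <- readLines(vcf)
  extra <- c("chr1\t10\t.\tA\tAT\t.\t.\t.", "chr1\t12\t.\tC\tA,G\t.\t.\t.")
  writeLines(c(lines, extra), vcf)
  expect_message(back2 <- read_snvs(vcf), "2 non-SNV")
  expect_identical(nrow(back2), nrow(back))
  expect_identical(attr(back2, "n_skipped"), 2L)
  # TSV fallback
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(chrom = back$contig, pos = back$pos,
                                  ref = back$ref, alt = back$alt,
                                  sample_id = "s1"), tsv)
  back3 <- read_snvs(tsv)
  expect_equal(back3[, c("contig", "pos", "ref", "alt")],
               back[, c("contig", "pos", "ref", "alt")],
               ignore_attr = TRUE)
  expect_identical(unique(back3$sample_id), "s1")
})

test_that("the Markov background learns local composition", {
  # homopolymer: P(A | AA) ~ 1
  bg <- markov_background(strrep("A", 300))
  expect_gt(bg$p2["AA", "A"], 0.98)
  # pseudocount keeps unseen contexts near-uniform
  expect_equal(unname(bg$p2["CG", ]), rep(0.25, 4), tolerance = 1e-9)
  # alternating ACAC...: P(C | .A) ~ 1 and P(A | .C) ~ 1 where seen
  bg2 <- markov_background(strrep("AC", 150))
  expect_gt(bg2$p2["CA", "C"], 0.95)
  expect_gt(bg2$p2["AC", "A"], 0.95)
  # all 16 conditional distributions sum to 1
  expect_equal(unname(rowSums(bg2$p2)), rep(1, 16))
  expect_equal(unname(rowSums(bg2$p1)), rep(1, 4))
  expect_equal(sum(bg2$p0), 1)
  # strand symmetry of the estimate
  s <- simulate_genome(400, seed = 55)[[1]]
  bg3 <- markov_background(s)
  bg4 <- markov_background(revcomp(s))
  expect_equal(bg3$p2, bg4$p2)
  # ambiguity codes split the sequence; no n-gram spans them
  bg5 <- markov_background("AAANAAA")
  expect_identical(bg5$n_bases, 6L)
})

test_that("background falls back to genome scale at contig edges", {
  contigs <- simulate_genome(2000, seed = 56)
  expect_warning(build_background(contigs, "chr1", 5, window = 20),
                 "falling back")
  bg <- build_background(contigs, "chr1", 1000, window = 500)
  expect_s3_class(bg, "markov_background")
})

test_that("Markov-background DP matches exhaustive enumeration", {
  genome <- simulate_genome(1500, seed = 57)
  bg <- markov_background(substr(genome[[1]], 1, 1001))
  for (consensus in c("TACGT", "TTACG")) {
    pwm <- sharp_pwm(consensus)
    dist <- markov_pvalue_distribution(pwm, bg)
    w <- pwm$width
    seqs <- enumerate_kmers(w)
    # exact sequence probability under the background chain
    chars <- strsplit(seqs, "")
    probs <- vapply(chars, function(b) {
      p <- bg$p0[b[1]] * bg$p1[b[1], b[2]]
      for (j in 3:w) p <- p * bg$p2[paste0(b[j - 2], b[j - 1]), b[j]]
      p
    }, numeric(1))
    expect_equal(sum(probs), 1, tolerance = 1e-12)
    # integer grid scores recomputed independently from the grid tables
    g <- dist$grid
    int_scores <- vapply(chars, function(b) {
      s <- g$inc1[b[1]] + g$inc2[b[1], b[2]]
      for (j in 3:w) s <- s + g$inc3[[j]][paste0(b[j - 2], b[j - 1]), b[j]]
      s
    }, numeric(1))
    probe <- unique(round(seq(min(int_scores), max(int_scores),
                              length.out = 30)))
    oracle <- vapply(probe, function(s) sum(probs[int_scores >= s]),
                     numeric(1))
    dp <- dist$tail_prob[probe - dist$int_lo + 1L]
    expect_equal(dp, oracle, tolerance = 1e-10)
    # p-value lookup agrees for arbitrary sequences
    pick <- seqs[c(1, 57, 512, 1000)]
    expect_equal(markov_pvalue(dist, pick),
                 vapply(pick, function(q) {
                   sum(probs[int_scores >= int_scores[match(q, seqs)]])
                 }, numeric(1), USE.NAMES = FALSE),
                 tolerance = 1e-10)
  }
})

planted_fixture <- function(seed = 61, n_plant = 6) {
  # sparse planting: the +/-500 bp background window around a site then
  # holds at most a copy or two, keeping the local Markov model close
  # to genomic composition
  consensus <- "TTACGTAA"
  genome <- simulate_genome(8000, seed = seed, plant = consensus,
                            n_plant = n_plant)
  list(genome = genome, pwm = sharp_pwm(consensus, id = "CONS"),
       positions = attr(genome, "plant_positions"))
}

test_that("an SNV breaking a planted site is called as disruption", {
  fx <- planted_fixture()
  # mutate the C inside the planted ACG context (consensus offset 3)
  pos <- fx$positions$start[1] + 3L
  snv <- tibble::tibble(contig = "chr1", pos = pos, ref = "C", alt = "T",
                        sample_id = "s1", cohort_id = "co1")
  calls <- call_snvs(fx$genome, snv, list(CONS = fx$pwm))
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$event, "disrupt")
  expect_lte(calls$p_ref, 1e-4)
  expect_gt(calls$p_alt, 1e-4)
  expect_gte(calls$p_alt / calls$p_ref, 10)
  # a wrong reference allele is an error naming the position
  bad <- snv
  bad$ref <- "G"
  expect_error(call_snvs(fx$genome, bad, list(CONS = fx$pwm)),
               "reference allele mismatch")
})

test_that("an SNV with no p-value change yields no call", {
  # uniform PWM: every sequence has the same score, nothing can change state
  fx <- planted_fixture()
  uni <- uniform_pwm(8)
  snv <- tibble::tibble(contig = "chr1", pos = fx$positions$start[1] + 3L,
                        ref = "C", alt = "T",
                        sample_id = NA_character_, cohort_id = NA_character_)
  calls <- call_snvs(fx$genome, snv, list(UNI = uni))
  expect_identical(nrow(calls), 0L)
})

test_that("calls are invariant under reverse-complementing the input", {
  fx <- planted_fixture(seed = 62)
  pos <- fx$positions$start[1] + 3L
  snv <- tibble::tibble(contig = "chr1", pos = pos, ref = "C", alt = "T",
                        sample_id = NA_character_, cohort_id = NA_character_)
  calls <- call_snvs(fx$genome, snv, list(CONS = fx$pwm))
  L <- nchar(fx$genome[[1]])
  rc_genome <- stats::setNames(revcomp(fx$genome[[1]]), "chr1")
  rc_snv <- tibble::tibble(contig = "chr1", pos = L - pos + 1L,
                           ref = "G", alt = "A",
                           sample_id = NA_character_,
                           cohort_id = NA_character_)
  rc_calls <- call_snvs(rc_genome, rc_snv, list(CONS = fx$pwm))
  expect_identical(nrow(calls), nrow(rc_calls))
  expect_identical(calls$event, rc_calls$event)
  expect_equal(calls$p_ref, rc_calls$p_ref, tolerance = 1e-9)
  expect_equal(calls$p_alt, rc_calls$p_alt, tolerance = 1e-9)
})

test_that("the dual criterion is stricter than either criterion alone", {
  fx <- planted_fixture(seed = 63, n_plant = 10)
  sig <- simulate_signatures(0, one_hot = "A[C>T]G", uniform = FALSE)
  snvs <- suppressMessages(simulate_snvs(fx$genome, sig, 120, seed = 64))
  strict <- call_snvs(fx$genome, snvs, list(CONS = fx$pwm),
                      binding_p = 1e-4, fold = 10)
  no_fold <- call_snvs(fx$genome, snvs, list(CONS = fx$pwm),
                       binding_p = 1e-4, fold = 1)
  # relaxing the fold requirement never removes calls
  key <- function(x) paste(x$pos, x$motif_id, x$event)
  expect_true(all(key(strict) %in% key(no_fold)))
  # both conditions are required: every call satisfies the threshold
  # crossing AND the fold change
  expect_true(all(pmax(strict$p_ref, strict$p_alt) /
                    pmin(strict$p_ref, strict$p_alt) >= 10))
  expect_true(all(pmin(strict$p_ref, strict$p_alt) <= 1e-4 &
                    pmax(strict$p_ref, strict$p_alt) > 1e-4))
  # tightening the binding threshold can only drop calls, except for
  # boundary cases where the alternative allele itself was binding at
  # the looser threshold
  tighter <- call_snvs(fx$genome, snvs, list(CONS = fx$pwm),
                       binding_p = 1e-5, fold = 10)
  new_calls <- tighter[!key(tighter) %in% key(strict), ]
  expect_true(all(pmax(new_calls$p_ref, new_calls$p_alt) <= 1e-4))
})

test_that("cohort normalization and log-ratios aggregate counts correctly", {
  calls <- tibble::tibble(
    contig = "chr1", pos = 1:9, ref = "C", alt = "T",
    sample_id = rep(c("s1", "s2", "s3"), each = 3),
    cohort_id = rep(c("co1", "co2"), c(6, 3)),
    motif_id = "M",
    event = c("create", "create", "disrupt",
              "create", "create", "create",
              "disrupt", "disrupt", "create"),
    p_ref = 1e-5, p_alt = 1e-2,
    best_window_offset = 0L, orientation = "+"
  )
  totals <- tibble::tibble(cohort_id = c("co1", "co2"),
                           total = c(1000L, 500L))
  out <- cohort_normalize(calls, totals)
  expect_equal(out$probability[out$cohort_id == "co1" &
                                 out$event == "create"], 5 / 1000)
  expect_equal(out$probability[out$cohort_id == "co2" &
                                 out$event == "disrupt"], 2 / 500)
  # proportional cohorts have equal probabilities
  twice <- dplyr::mutate(calls, cohort_id = paste0(cohort_id, "x"))
  both <- dplyr::bind_rows(calls, twice)
  tot2 <- tibble::tibble(cohort_id = c("co1", "co2", "co1x", "co2x"),
                         total = c(1000L, 500L, 1000L, 500L))
  out2 <- cohort_normalize(both, tot2)
  a <- out2[out2$cohort_id == "co1", ]
  b <- out2[out2$cohort_id == "co1x", ]
  expect_equal(a$probability, b$probability)
  expect_error(cohort_normalize(calls,
                                tibble::tibble(cohort_id = "co1",
                                               total = 0L)),
               "positive")

  # log-ratios: equal counts give 0, 20/10 gives log 2
  lr <- observed_log_ratio(calls)
  expect_equal(lr$n_create, 6L)
  expect_equal(lr$n_disrupt, 3L)
  expect_equal(lr$log_ratio, log(2))
  groups <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                           group = c("g1", "g1", "g2"))
  lr2 <- observed_log_ratio(calls, groups)
  expect_equal(lr2$log_ratio[lr2$group == "g1"], log(5 / 1))
  # zero counts get a pseudocount with a message
  expect_message(
    lr3 <- observed_log_ratio(calls[calls$event == "create", ]),
    "pseudocount")
  expect_equal(lr3$log_ratio, log(7 / 1))
})
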