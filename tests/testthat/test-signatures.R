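make_phi_fixture <- function(seed = 4) {
  genome <- simulate_genome(4000, seed = seed)
  pwms <- list(M1 = sharp_pwm("TTACGT", id = "M1"),
               M2 = sharp_pwm("AACGTT", id = "M2"))
  build_phi(pwms, genome)
}

test_that("signature TSVs load in both dialects, any row order", {
  sig <- simulate_signatures(3, one_hot = "A[C>A]A", seed = 8)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_signatures(sig, tsv)
  back <- read_signatures(tsv)
  expect_equal(
    dplyr::arrange(tibble::as_tibble(back), signature_id, class),
    dplyr::arrange(tibble::as_tibble(sig), signature_id, class)
  )
  # one-hot row: a single 1
  oh <- back[back$signature_id == "OneHot.A[C>A]A", ]
  expect_equal(sum(oh$prob), 1)
  expect_equal(max(oh$prob), 1)

  # shuffled row order loads to the same matrix
  wide <- readr::read_tsv(tsv, show_col_types = FALSE)
  set.seed(1)
  readr::write_tsv(wide[sample(96), ], tsv)
  expect_equal(
    dplyr::arrange(tibble::as_tibble(read_signatures(tsv)),
                   signature_id, class),
    dplyr::arrange(tibble::as_tibble(back), signature_id, class)
  )

  # substitution-type + trinucleotide column dialect
  cat96 <- mutation_catalog()
  two <- tibble::tibble(
    `Substitution Type` = paste0(cat96$ref, ">", cat96$alt),
    Trinucleotide = cat96$ref_trinucleotide,
    S1 = rep(1 / 96, 96)
  )
  readr::write_tsv(two, tsv)
  expect_equal(read_signatures(tsv)$prob, rep(1 / 96, 96))

  # a full 30-column COSMIC-shaped table loads 30 signatures
  thirty <- simulate_signatures(30, seed = 30, uniform = FALSE, tsv = tsv)
  expect_length(unique(read_signatures(tsv)$signature_id), 30L)
})

test_that("defective signature tables are rejected", {
  cat96 <- mutation_catalog()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bad <- tibble::tibble(class = cat96$class[-1], S1 = rep(1 / 95, 95))
  readr::write_tsv(bad, tsv)
  expect_error(read_signatures(tsv), "lacks mutation class")
  bad2 <- tibble::tibble(class = cat96$class, S1 = rep(1 / 90, 96))
  readr::write_tsv(bad2, tsv)
  expect_error(read_signatures(tsv), "deviate")
  bad3 <- tibble::tibble(class = cat96$class,
                         S1 = c(-0.01, rep(1.01 / 95, 95)))
  readr::write_tsv(bad3, tsv)
  expect_error(read_signatures(tsv), "negative")
})

test_that("projection reproduces Phi under delta and uniform signatures", {
  phi <- make_phi_fixture()
  sig <- simulate_signatures(0, one_hot = "A[C>T]G", uniform = TRUE)
  stf <- project_signatures(phi, sig)
  for (ev in c("create", "disrupt")) {
    for (m in c("M1", "M2")) {
      row <- phi[phi$motif_id == m & phi$event == ev, ]
      # one-hot signature picks out the Phi entry for its class
      expect_equal(
        stf$prob[stf$signature_id == "OneHot.A[C>T]G" &
                   stf$motif_id == m & stf$event == ev],
        row$prob[row$class == "A[C>T]G"]
      )
      # uniform signature gives the mean of the Phi row
      expect_equal(
        stf$prob[stf$signature_id == "Uniform" &
                   stf$motif_id == m & stf$event == ev],
        mean(row$prob)
      )
    }
  }
})

test_that("projection matches the element-wise sum oracle", {
  phi <- make_phi_fixture()
  sig <- simulate_signatures(4, seed = 3, uniform = FALSE)
  stf <- project_signatures(phi, sig)
  cat96 <- mutation_catalog()$class
  for (i in seq_len(nrow(stf))) {
    row <- stf[i, ]
    phirow <- phi[phi$motif_id == row$motif_id & phi$event == row$event, ]
    sigrow <- sig[sig$signature_id == row$signature_id, ]
    oracle <- sum(phirow$prob[match(cat96, phirow$class)] *
                    sigrow$prob[match(cat96, sigrow$class)])
    expect_equal(row$prob, oracle, tolerance = 1e-12)
  }
})

test_that("S_TF and Psi entries obey the convexity bounds", {
  phi <- make_phi_fixture()
  set.seed(99)
  sig <- simulate_signatures(100, seed = 99, uniform = FALSE)
  stf <- project_signatures(phi, sig)
  ex <- simulate_exposures(unique(sig$signature_id), 20, seed = 100)
  psi <- predict_patients(stf, ex)
  for (ev in c("create", "disrupt")) {
    for (m in unique(phi$motif_id)) {
      rng <- range(phi$prob[phi$motif_id == m & phi$event == ev])
      s <- stf$prob[stf$motif_id == m & stf$event == ev]
      p <- psi$prob[psi$motif_id == m & psi$event == ev]
      expect_true(all(s >= rng[1] - 1e-12 & s <= rng[2] + 1e-12))
      expect_true(all(p >= rng[1] - 1e-12 & p <= rng[2] + 1e-12))
    }
  }
})

test_that("signature mapping maximizes Pearson correlation", {
  sig <- simulate_signatures(5, seed = 12, uniform = FALSE)
  # a matrix maps to itself identically
  self_map <- map_signature_sets(sig, sig)
  expect_identical(self_map$source_id, self_map$target_id)
  expect_equal(self_map$correlation, rep(1, 5))

  # a 0.9 target + 0.1 uniform blend maps to its target
  cat96 <- mutation_catalog()$class
  target_a <- sig[sig$signature_id == "Random.01", ]
  blend <- tibble::tibble(
    signature_id = "Blend", class = cat96,
    prob = 0.9 * target_a$prob[match(cat96, target_a$class)] + 0.1 / 96
  )
  class(blend) <- class(sig)
  m <- map_signature_sets(blend, sig)
  expect_identical(m$target_id, "Random.01")

  # many-to-one mapping is allowed
  two <- dplyr::bind_rows(
    dplyr::mutate(blend, signature_id = "BlendA"),
    dplyr::mutate(blend, signature_id = "BlendB"))
  class(two) <- class(sig)
  m2 <- map_signature_sets(two, sig)
  expect_identical(m2$target_id, c("Random.01", "Random.01"))

  # constant vectors are an error naming the signature
  const <- tibble::tibble(signature_id = "Flat", class = cat96,
                          prob = rep(1 / 96, 96))
  class(const) <- class(sig)
  expect_error(map_signature_sets(const, sig), "Flat")
})

test_that("exposure collapse sums groups and renormalizes columns", {
  ex <- simulate_exposures(c("P1", "P2", "P3"), 4, seed = 5)
  mapping <- tibble::tibble(source_id = c("P1", "P2", "P3"),
                            target_id = c("C1", "C1", "C2"))
  out <- collapse_exposures(ex, mapping)
  sums <- tapply(out$exposure, out$sample_id, sum)
  expect_equal(as.numeric(sums), rep(1, 4))
  # additivity on the raw scale
  s1 <- ex$raw[ex$signature_id == "P1" & ex$sample_id == "sample001"] +
    ex$raw[ex$signature_id == "P2" & ex$sample_id == "sample001"]
  expect_equal(out$raw[out$signature_id == "C1" &
                         out$sample_id == "sample001"], s1)
  # identity mapping leaves normalized exposures unchanged
  idm <- tibble::tibble(source_id = c("P1", "P2", "P3"),
                        target_id = c("P1", "P2", "P3"))
  same <- collapse_exposures(ex, idm)
  merged <- dplyr::inner_join(tibble::as_tibble(ex), tibble::as_tibble(same),
                              by = c("signature_id", "sample_id"))
  expect_equal(merged$exposure.x, merged$exposure.y)
  # unmapped ids are an error
  expect_error(collapse_exposures(ex, mapping[1:2, ]), "P3")
})

test_that("patient prediction is an exposure-weighted combination", {
  phi <- make_phi_fixture()
  sig <- simulate_signatures(3, seed = 21, uniform = FALSE)
  stf <- project_signatures(phi, sig)
  ids <- unique(sig$signature_id)
  # one-hot exposure picks out the signature's S_TF column
  raw <- matrix(0, nrow = 3, ncol = 2,
                dimnames = list(ids, c("s1", "s2")))
  raw["Random.02", "s1"] <- 7
  raw["Random.03", "s2"] <- 3
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::as_tibble(raw, rownames = "signature_id"), tsv)
  ex <- read_exposures(tsv)
  expect_equal(ex$exposure[ex$signature_id == "Random.02" &
                             ex$sample_id == "s1"], 1)
  psi <- predict_patients(stf, ex)
  for (ev in c("create", "disrupt")) {
    expect_equal(
      psi$prob[psi$sample_id == "s1" & psi$event == ev],
      stf$prob[stf$signature_id == "Random.02" & stf$event == ev]
    )
  }
  # loop oracle on a random exposure matrix, plus scale invariance
  ex2 <- simulate_exposures(ids, 3, seed = 33)
  psi2 <- predict_patients(stf, ex2)
  for (i in seq_len(nrow(psi2))) {
    row <- psi2[i, ]
    stf_col <- stf[stf$motif_id == row$motif_id & stf$event == row$event, ]
    e_col <- ex2[ex2$sample_id == row$sample_id, ]
    oracle <- sum(stf_col$prob[match(ids, stf_col$signature_id)] *
                    e_col$exposure[match(ids, e_col$signature_id)])
    expect_equal(row$prob, oracle, tolerance = 1e-12)
  }
  ex2_scaled <- ex2
  ex2_scaled$raw <- ex2$raw * 2
  psi3 <- predict_patients(stf, ex2_scaled)  # exposure column unchanged
  expect_equal(psi3$prob, psi2$prob)
})

test_that("projection and prediction associate", {
  phi <- make_phi_fixture()
  sig <- simulate_signatures(5, seed = 41, uniform = FALSE)
  stf <- project_signatures(phi, sig)
  ex <- simulate_exposures(unique(sig$signature_id), 6, seed = 42)
  psi <- predict_patients(stf, ex)
  # (S_M Phi^T)^T E == Phi^T (S_M^T E)
  cat96 <- mutation_catalog()$class
  ids <- unique(sig$signature_id)
  samples <- unique(ex$sample_id)
  sm <- matrix(sig$prob[order(match(sig$signature_id, ids),
                              match(sig$class, cat96))],
               nrow = length(ids), byrow = TRUE,
               dimnames = list(ids, cat96))
  emat <- matrix(0, nrow = length(ids), ncol = length(samples),
                 dimnames = list(ids, samples))
  emat[cbind(match(ex$signature_id, ids),
             match(ex$sample_id, samples))] <- ex$exposure
  for (ev in c("create", "disrupt")) {
    sub <- phi[phi$event == ev, ]
    motifs <- unique(sub$motif_id)
    pm <- matrix(0, nrow = length(motifs), ncol = 96,
                 dimnames = list(motifs, cat96))
    pm[cbind(match(sub$motif_id, motifs), match(sub$class, cat96))] <-
      sub$prob
    lhs <- t(sm %*% t(pm)) %*% emat
    rhs <- pm %*% (t(sm) %*% emat)
    expect_equal(lhs, rhs, tolerance = 1e-12)
    got <- psi[psi$event == ev, ]
    gmat <- matrix(0, nrow = length(motifs), ncol = length(samples),
                   dimnames = list(motifs, samples))
    gmat[cbind(match(got$motif_id, motifs),
               match(got$sample_id, samples))] <- got$prob
    expect_equal(gmat, lhs, tolerance = 1e-12)
  }
})
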