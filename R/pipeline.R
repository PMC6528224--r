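# End-to-end workflow: genome counting -> k-mer partition -> Phi ->
# S_TF -> Psi, plus SNV calling, driven by a single config (YAML file
# or list) with a manifest recording inputs, hashes and every
# parameter.

#' Default pipeline configuration
#'
#' @return A list of defaults: `threshold_p` (enumeration binding
#'   threshold, 0.001), `binding_p_snv` (SNV pipeline threshold, 1e-4),
#'   `fold` (10), `max_exhaustive_k` (13), `pseudocount` (1),
#'   `background` ("uniform"), `window` (500), `n_bins` (4000),
#'   `seed` (1).
#' @export
default_config <- function() {
  list(
    fasta = NULL, pfm = NULL, signatures = NULL, exposures = NULL,
    vcf = NULL, out_dir = ".",
    threshold_p = 0.001, binding_p_snv = 1e-4, fold = 10,
    max_exhaustive_k = 13L, pseudocount = 1,
    background = "uniform", window = 500L, n_bins = 4000L, seed = 1L
  )
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  stopifnot(cfg$threshold_p > 0, cfg$threshold_p < 1,
            cfg$binding_p_snv > 0, cfg$binding_p_snv < 1, cfg$fold >= 1)
  cfg
}

genome_background <- function(contigs) {
  tab <- table(factor(strsplit(paste(contigs, collapse = ""), "")[[1]],
                      levels = DNA_BASES))
  p <- as.numeric(tab) + 1
  p / sum(p)
}

#' Run the motif alteration signature pipeline
#'
#' Executes, in dependency order and as far as the configured inputs
#' allow: Phi construction (`fasta` + `pfm`), signature projection
#' (`+ signatures`), patient prediction (`+ exposures`), and SNV
#' alteration calling (`+ vcf`).  Each stage's table is written as TSV
#' under `out_dir` and a JSON manifest records the inputs, their MD5
#' hashes, the full configuration and the package version.  The run is
#' deterministic for a fixed config; inputs are never modified.
#'
#' @param config A YAML path or a list overriding [default_config()];
#'   stages run only when their inputs are present.
#' @return The manifest, invisibly, as a list; its `outputs` element
#'   names the files written.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  if (is.null(cfg$fasta) || is.null(cfg$pfm)) {
    stop("config must provide at least 'fasta' and 'pfm'")
  }
  contigs <- stage("genome", read_genome(cfg$fasta))
  bg <- if (identical(cfg$background, "genome")) {
    genome_background(contigs)
  } else {
    rep(0.25, 4)
  }
  pwms <- stage("pwm", read_jaspar(cfg$pfm, pseudocount = cfg$pseudocount,
                                   background = bg))
  phi <- stage("phi", build_phi(pwms, contigs, threshold_p = cfg$threshold_p,
                                max_exhaustive_k = cfg$max_exhaustive_k,
                                n_bins = cfg$n_bins))
  outputs$phi <- file.path(cfg$out_dir, "phi.tsv")
  write_phi(phi, outputs$phi)
  if (!is.null(cfg$signatures)) {
    sm <- stage("signatures", read_signatures(cfg$signatures))
    stf <- stage("project", project_signatures(phi, sm))
    outputs$stf <- file.path(cfg$out_dir, "stf.tsv")
    readr::write_tsv(tibble::as_tibble(stf), outputs$stf)
    if (!is.null(cfg$exposures)) {
      ex <- stage("exposures", read_exposures(cfg$exposures))
      psi <- stage("predict", predict_patients(stf, ex))
      outputs$psi <- file.path(cfg$out_dir, "psi.tsv")
      readr::write_tsv(tibble::as_tibble(psi), outputs$psi)
    }
  }
  if (!is.null(cfg$vcf)) {
    snvs <- stage("snv", read_snvs(cfg$vcf))
    calls <- stage("call", call_snvs(contigs, snvs, pwms,
                                     binding_p = cfg$binding_p_snv,
                                     fold = cfg$fold, window = cfg$window))
    outputs$calls <- file.path(cfg$out_dir, "calls.tsv")
    write_calls(calls, outputs$calls)
  }
  inputs <- Filter(Negate(is.null),
                   cfg[c("fasta", "pfm", "signatures", "exposures", "vcf")])
  manifest <- list(
    package = "sigmotif",
    version = as.character(utils::packageVersion("sigmotif")),
    config = cfg[setdiff(names(cfg),
                         c("fasta", "pfm", "signatures", "exposures",
                           "vcf", "out_dir"))],
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
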