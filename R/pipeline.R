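# Orchestration: one validated config drives simulate -> select-oligos ->
# noref -> design -> detect -> report, with per-stage counts logged and
# the effective config echoed into the output directory.

sao_defaults <- function() {
  list(
    seed = 42L,
    # simulate
    n_chrom = 3L, chrom_len = 100000L, repeat_fraction = 0.2,
    repeat_unit = 500L, gc = 0.5,
    snp_rate = 0.005, indel_rate = 0.0005, indel_len_geom_p = 0.3,
    max_indel = 15L,
    depth = 10, read_len = 150L, paired = TRUE,
    insert_mean = 400, insert_sd = 40, error_rate = 0.002,
    wild_chroms = c(1L, 3L),
    # oligo selection
    oligo_len = 45L, step = 25L, kmer = 17L,
    max_mean_count = 1.5, max_single_count = 4,
    min_identity = 0.80, dtm_min = 10, Na_mM = 50, oligo_nM = 250,
    # noref
    flank = 100L, min_cov = 3L, min_af = 0.7, seed_len_assign = 15L,
    band = 25L, min_score_frac = 0.3, reach = 200L,
    # marker design
    max_gap = 500L, use_snps = FALSE, max_candidates = 12L,
    primer_min_len = 18L, primer_max_len = 25L,
    primer_tm_min = 52, primer_tm_max = 60,
    primer_gc_min = 0.35, primer_gc_max = 0.65, max_run = 4L,
    max_total_mm = 2L, max_3prime_mm = 0L, three_prime_window = 5L,
    max_product = 2000L, min_len_diff_frac = 0.02, min_len_diff_bp = 10,
    # optional real inputs (paths); when NULL the simulator supplies them
    genome_path = NULL, reads_path = NULL, target_genome_path = NULL,
    sample_paths = NULL)
}

#' Build a validated pipeline configuration
#'
#' Returns the full default configuration with the supplied overrides
#' applied; unknown keys are rejected.  All defaults are the pipeline's
#' study conditions (45/25 tiling, 80\% homology, dTm >= 10 C, 100-nt
#' flanks, min_cov 3 / min_af 0.7, <500-nt oligo gaps, 52-60 C primers).
#'
#' @param ... name = value overrides of the defaults.
#' @return a list of class `sao_config`.
#' @export
sao_config <- function(...) {
  cfg <- sao_defaults()
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == ""))) {
    stop("sao_config: all arguments must be named")
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("sao_config: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "sao_config")
}

#' @export
print.sao_config <- function(x, ...) {
  cat("<sao_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(" ", k, "=", if (is.null(v)) "NULL" else paste(v, collapse = ","),
        "\n")
  }
  invisible(x)
}

# restrict the configured introgression set to chromosomes that exist
resolve_wild_chroms <- function(wild_chroms, wild) {
  if (is.numeric(wild_chroms)) {
    keep <- wild_chroms[wild_chroms >= 1 & wild_chroms <= length(wild)]
  } else {
    keep <- intersect(wild_chroms, names(wild))
  }
  if (length(keep) < length(wild_chroms)) {
    warning("wild_chroms clipped to the ", length(wild),
            " simulated chromosomes")
  }
  keep
}

log_stage <- function(log_path, stage, ..., verbose = TRUE) {
  kv <- list(...)
  line <- paste0("stage=", stage,
                 if (length(kv) > 0) paste0(" ", paste(names(kv), unlist(kv),
                                                       sep = "=",
                                                       collapse = " ")))
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
  sao_msg(verbose, "[", stage, "] ",
          paste(names(kv), unlist(kv), sep = "=", collapse = " "))
}

#' Run the full SAO workflow
#'
#' Executes simulate (unless genome/read paths are configured) ->
#' select-oligos -> noref -> design -> detect -> report, writing every
#' stage artifact plus a provenance copy of the effective config
#' (`config.yaml`) and a machine-parseable `run.log` into `out_dir`.
#' Stage outputs are pure functions of (inputs, config): a rerun with the
#' same config yields byte-identical tables.
#'
#' @param config an [sao_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose log per-stage counts to the console?
#' @return (invisibly) a list with every stage result: `genome`, `wild`,
#'   `truth`, `reads`, `oligos`, `noref`, `markers`, `detect`, `report`.
#' @export
sao_run_all <- function(config = sao_config(), out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "sao_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(config)
  yaml::write_yaml(cfg[!vapply(cfg, is.null, TRUE)],
                   file.path(out_dir, "config.yaml"))
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)  # truncate
  cc <- config

  # --- inputs: simulate or load -------------------------------------------
  truth <- NULL; repeats <- NULL; wild <- NULL
  if (is.null(cc$genome_path)) {
    simref <- make_reference(cc$n_chrom, cc$chrom_len, cc$repeat_fraction,
                             cc$repeat_unit, cc$gc, seed = cc$seed)
    genome <- simref$genome
    repeats <- simref$repeats
    div <- diverge_genome(genome, cc$snp_rate, cc$indel_rate,
                          cc$indel_len_geom_p, cc$max_indel,
                          seed = cc$seed + 1L)
    wild <- div$genome
    truth <- div$truth
    reads <- simulate_reads(wild, cc$depth, cc$read_len, cc$paired,
                            cc$insert_mean, cc$insert_sd, cc$error_rate,
                            seed = cc$seed + 2L)
    write_fasta(genome, file.path(out_dir, "ref.fa"))
    write_fasta(wild, file.path(out_dir, "wild.fa"))
    write_variants_vcf(truth, file.path(out_dir, "truth.vcf"))
    write_bed(tibble(chrom = repeats$chrom, start = repeats$start,
                     end = repeats$end,
                     name = paste0("family", repeats$family),
                     score = round(100 * repeats$identity),
                     strand = "+"),
              file.path(out_dir, "repeats.bed"))
    if (cc$paired) {
      write_fastq(reads[reads$mate == 1L, ],
                  file.path(out_dir, "reads_1.fq.gz"))
      write_fastq(reads[reads$mate == 2L, ],
                  file.path(out_dir, "reads_2.fq.gz"))
    } else {
      write_fastq(reads, file.path(out_dir, "reads.fq.gz"))
    }
    log_stage(log_path, "simulate", n_chrom = length(genome),
              genome_bp = sum(nchar(genome)), n_truth_variants = nrow(truth),
              n_reads = nrow(reads), verbose = verbose)
  } else {
    genome <- read_fasta(cc$genome_path, verbose = verbose)
    if (is.null(cc$reads_path)) stop("reads_path required with genome_path")
    reads <- do.call(rbind, lapply(cc$reads_path, read_fastq,
                                   verbose = verbose))
    if (!is.null(cc$target_genome_path)) {
      wild <- read_fasta(cc$target_genome_path, verbose = verbose)
    }
    log_stage(log_path, "load", n_chrom = length(genome),
              n_reads = nrow(reads), verbose = verbose)
  }

  # --- oligo selection -----------------------------------------------------
  oligos <- select_specific_oligos(
    genome, cc$oligo_len, cc$step, cc$kmer, cc$max_mean_count,
    cc$max_single_count, cc$min_identity, cc$dtm_min, cc$Na_mM, cc$oligo_nM,
    out = file.path(out_dir, "sao"), verbose = FALSE)
  retained <- oligos[oligos$status == "RETAINED", ]
  log_stage(log_path, "select_oligos", n_tiled = nrow(oligos),
            n_retained = nrow(retained), verbose = verbose)
  if (nrow(retained) == 0) stop("select_oligos: no oligos retained")

  # --- noref ---------------------------------------------------------------
  nr <- noref_pipeline(genome, retained, reads, cc$flank, cc$min_cov,
                       cc$min_af, cc$seed_len_assign, cc$band,
                       cc$min_score_frac, cc$reach,
                       out = file.path(out_dir, "sao"), verbose = FALSE)
  log_stage(log_path, "noref", n_windows = nr$stats$n_windows,
            n_complete = nr$stats$n_complete,
            n_snp = sum(nr$variants$vclass == "SNP"),
            n_indel = sum(nr$variants$vclass != "SNP"), verbose = verbose)

  # --- marker design -------------------------------------------------------
  markers <- design_markers(
    nr$target_oligos, nr$variants, genome, target_genome = wild,
    max_gap = cc$max_gap, use_snps = cc$use_snps,
    max_candidates = cc$max_candidates,
    min_len = cc$primer_min_len, max_len = cc$primer_max_len,
    tm_range = c(cc$primer_tm_min, cc$primer_tm_max),
    gc_range = c(cc$primer_gc_min, cc$primer_gc_max), max_run = cc$max_run,
    max_total_mm = cc$max_total_mm, max_3prime_mm = cc$max_3prime_mm,
    three_prime_window = cc$three_prime_window,
    max_product = cc$max_product,
    min_len_diff_frac = cc$min_len_diff_frac,
    min_len_diff_bp = cc$min_len_diff_bp,
    Na_mM = cc$Na_mM, oligo_nM = cc$oligo_nM,
    out = file.path(out_dir, "sao"), verbose = FALSE)
  tt <- table(markers$type)
  log_stage(log_path, "design", n_markers = nrow(markers),
            n_type_I = sum(markers$type == "I"),
            n_type_II = sum(markers$type == "II"),
            n_type_III = sum(markers$type == "III"),
            n_type_IV = sum(markers$type == "IV"), verbose = verbose)

  # --- detection -----------------------------------------------------------
  detect <- NULL
  samples <- list()
  if (!is.null(wild) && is.null(cc$genome_path)) {
    hybrid <- make_hybrid(genome, wild, resolve_wild_chroms(cc$wild_chroms,
                                                            wild))
    write_fasta(hybrid, file.path(out_dir, "hybrid.fa"))
    samples <- list(hybrid = hybrid, reference_only = genome)
  } else if (!is.null(cc$sample_paths)) {
    samples <- lapply(cc$sample_paths, read_fasta, verbose = FALSE)
    if (is.null(names(samples))) {
      names(samples) <- tools::file_path_sans_ext(basename(unlist(cc$sample_paths)))
    }
  }
  if (length(samples) > 0 && nrow(markers) > 0) {
    detect <- detect_alien(markers, samples, cc$max_total_mm,
                           cc$max_3prime_mm, cc$three_prime_window,
                           cc$max_product)
    write_tsv_file(detect, file.path(out_dir, "sao.detect.tsv"))
    log_stage(log_path, "detect",
              n_present = sum(detect$status == "PRESENT"),
              n_absent = sum(detect$status == "ABSENT"),
              n_untestable = sum(detect$status == "UNTESTABLE"),
              verbose = verbose)
  }

  # --- report --------------------------------------------------------------
  report <- sao_report(markers, nr$variants)
  write_tsv_file(report, file.path(out_dir, "sao.summary.tsv"))
  log_stage(log_path, "report",
            n_specific = report$n_specific[report$chrom == "TOTAL"],
            rate = report$polymorphism_rate_label[report$chrom == "TOTAL"],
            verbose = verbose)

  invisible(list(genome = genome, wild = wild, truth = truth,
                 repeats = repeats, reads = reads, oligos = oligos,
                 noref = nr, markers = markers, detect = detect,
                 report = report, config = config, out_dir = out_dir))
}
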