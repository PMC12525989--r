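# seqio: file formats and shared sequence/coordinate utilities.
#
# Internal coordinates are 0-based half-open everywhere; every text output
# (BED is the exception by definition of the format) is 1-based inclusive.

#' Read a genome from FASTA
#'
#' Reads one record per chromosome.  Sequences are uppercased and any
#' character outside \{A,C,G,T,N\} is replaced by N (a count is reported).
#' Duplicate record ids and empty sequences are hard errors.
#'
#' @param path path to a FASTA file (plain or gzip).
#' @param verbose report substitution counts?
#' @return a named character vector of chromosome sequences, in file order.
#' @export
read_fasta <- function(path, verbose = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(x))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stop("duplicate id ", dup[1])
  seqs <- normalize_dna(as.character(x))
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for record ", ids[nchar(seqs) == 0][1])
  }
  nsub <- attr(seqs, "n_substituted")
  if (nsub > 0) {
    sao_msg(verbose, "read_fasta: ", nsub,
            " non-ACGTN character(s) replaced by N")
  }
  attr(seqs, "n_substituted") <- NULL
  setNames(as.character(seqs), ids)
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(genome, path, width = 70) {
  x <- Biostrings::DNAStringSet(genome)
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read short reads from FASTQ
#'
#' Parses 4-line FASTQ records (gzip input is detected by magic bytes, not
#' by file extension).  Qualities are parsed for validation but not kept:
#' downstream consensus building uses read counts only.  Reads shorter than
#' `min_len` are skipped and counted.
#'
#' @param path FASTQ file, plain or gzip.
#' @param min_len minimum read length kept (default 30).
#' @param verbose report skip counts?
#' @return tibble with columns `id`, `seq`, `mate` (1, 2 or NA, parsed from
#'   a trailing `/1` or `/2` in the id); attribute `n_skipped` holds the
#'   number of too-short reads dropped.
#' @export
read_fastq <- function(path, min_len = 30, verbose = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  magic <- readBin(path, "raw", n = 2)
  is_gz <- length(magic) == 2 && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
  con <- if (is_gz) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0) {
    warning("empty FASTQ file: ", path)
    out <- tibble(id = character(), seq = character(), mate = integer())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  if (length(lines) %% 4 != 0) {
    stop("truncated FASTQ record at line ",
         (length(lines) %/% 4) * 4 + 1, " of ", path)
  }
  i <- seq(1, length(lines), by = 4)
  hdr <- lines[i]; seqs <- lines[i + 1]; plus <- lines[i + 2]; qual <- lines[i + 3]
  bad_hdr <- !startsWith(hdr, "@")
  if (any(bad_hdr)) stop("malformed FASTQ header at line ", i[bad_hdr][1])
  bad_plus <- !startsWith(plus, "+")
  if (any(bad_plus)) stop("malformed FASTQ separator at line ", i[bad_plus][1] + 2)
  bad_len <- nchar(seqs) != nchar(qual)
  if (any(bad_len)) {
    stop("sequence/quality length mismatch at line ", i[bad_len][1] + 1,
         " (record ", sub("^@", "", hdr[bad_len][1]), ")")
  }
  ids <- sub("\\s.*$", "", sub("^@", "", hdr))
  mate <- ifelse(grepl("/1$", ids), 1L, ifelse(grepl("/2$", ids), 2L, NA_integer_))
  seqs <- normalize_dna(seqs)
  nsub <- attr(seqs, "n_substituted")
  if (nsub > 0) sao_msg(verbose, "read_fastq: ", nsub, " base(s) replaced by N")
  keep <- nchar(seqs) >= min_len
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    sao_msg(verbose, "read_fastq: skipped ", n_skipped,
            " read(s) shorter than ", min_len, " nt")
  }
  out <- tibble(id = ids[keep], seq = as.character(seqs[keep]), mate = mate[keep])
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write reads to FASTQ
#'
#' Constant qualities ('I') are written; the pipeline never consumes
#' qualities.  A `.gz` suffix selects gzip output.
#'
#' @param reads tibble with `id` and `seq` columns.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  qual <- vapply(nchar(reads$seq), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  writeLines(lines, con)
  invisible(path)
}

#' Write intervals to 6-column BED
#'
#' @param df data frame with columns `chrom`, `start` (0-based), `end`,
#'   `name`, `score`, `strand`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end", "name", "score", "strand") %in%
                  names(df)))
  write.table(df[, c("chrom", "start", "end", "name", "score", "strand")],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# plain TSV with header, no quoting (deterministic byte output)
write_tsv_file <- function(df, path) {
  df <- as.data.frame(df)
  listcols <- vapply(df, is.list, logical(1))
  df <- df[, !listcols, drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_file <- function(path) {
  as_tibble(read.table(path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE, comment.char = ""))
}

#' Write a variant catalog as minimal VCF
#'
#' Eight fixed columns, 1-based positions, left-normalized anchored alleles.
#' No date line is written so identical catalogs are byte-identical.
#'
#' @param variants tibble with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `vclass`, and optionally `depth`, `af`.
#' @param path output path.
#' @export
write_variants_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=saomark",
           paste0("##INFO=<ID=DP,Number=1,Type=Integer,Description=",
                  "\"Supporting read depth\">"),
           paste0("##INFO=<ID=AF,Number=1,Type=Float,Description=",
                  "\"Supporting allele fraction\">"),
           paste0("##INFO=<ID=TYPE,Number=1,Type=String,Description=",
                  "\"SNP, INS or DEL\">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  depth <- if ("depth" %in% names(variants)) variants$depth else
    rep(NA_integer_, nrow(variants))
  af <- if ("af" %in% names(variants)) variants$af else
    rep(NA_real_, nrow(variants))
  info <- paste0("DP=", ifelse(is.na(depth), ".", depth),
                 ";AF=", ifelse(is.na(af), ".", sprintf("%.3f", af)),
                 ";TYPE=", variants$vclass)
  body <- if (nrow(variants) == 0) character(0) else {
    paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
          ".", "PASS", info, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal VCF variant catalog
#'
#' Inverse of [write_variants_vcf()] (and compatible with any
#' 8-column site-only VCF).
#'
#' @param path VCF path.
#' @return tibble with `chrom`, `pos`, `ref`, `alt`, `vclass`, `depth`, `af`.
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), vclass = character(),
                  depth = integer(), af = numeric()))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  info <- get(8)
  grab <- function(key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
    val <- rep(NA_character_, length(info))
    val[grepl(paste0(key, "="), info)] <- sub(paste0(key, "="), "", m)
    val
  }
  ref <- get(4); alt <- get(5)
  vclass <- grab("TYPE")
  infer <- ifelse(nchar(ref) == nchar(alt), "SNP",
                  ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
  vclass <- ifelse(is.na(vclass) | vclass == ".", infer, vclass)
  tibble(chrom = get(1), pos = as.integer(get(2)), ref = ref, alt = alt,
         vclass = vclass,
         depth = suppressWarnings(as.integer(grab("DP"))),
         af = suppressWarnings(as.numeric(grab("AF"))))
}
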