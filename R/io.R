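#' Read and write reference FASTA
#'
#' Thin wrappers around Biostrings. Sequences are handled package-wide as a
#' named character vector; files are written 60 columns wide.
#'
#' @param x named character vector of sequences.
#' @param path file path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path, width = 60)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")

#' Write a variant set as VCF v4.2
#'
#' Emits FORMAT `GT:GC` for RAD-source sets (GC being the RAD genotype
#' confidence) and `GT:GQ` for RNA-source sets. Site annotations present in
#' the `info` slot (QD, FS, MQ, MQRankSum, ReadPosRankSum, SOR) are written
#' to INFO. NULLed calls become `./.` with a missing confidence.
#'
#' @param vs a [variant_set()].
#' @param path output path.
#' @export
write_vcf <- function(vs, path) {
  stopifnot(inherits(vs, "variant_set"))
  conf_id <- if (vs$source == "RAD") "GC" else "GQ"
  ann <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=snpforge",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (conf_id == "GC")
      '##FORMAT=<ID=GC,Number=1,Type=Float,Description="Genotype confidence (GT_CONF)">'
    else
      '##FORMAT=<ID=GQ,Number=1,Type=Float,Description="Genotype quality">',
    if (!is.null(vs$info))
      sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="%s">',
              intersect(ann, names(vs$info)), intersect(ann, names(vs$info)))
  )
  ctgs <- unique(vs$variants$contig)
  hdr <- c(hdr, sprintf("##contig=<ID=%s>", ctgs),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(vs$calls)), collapse = "\t"))
  v <- vs$variants
  info_str <- rep(".", nrow(v))
  if (!is.null(vs$info)) {
    cols <- intersect(ann, names(vs$info))
    info_str <- apply(vs$info[, cols, drop = FALSE], 1, function(r) {
      ok <- !is.na(r)
      if (!any(ok)) "." else
        paste(sprintf("%s=%s", cols[ok], format(r[ok], trim = TRUE)),
              collapse = ";")
    })
  }
  gt <- matrix(gt_code[vs$calls], nrow(v))
  gt[is.na(gt)] <- "./."
  cf <- matrix(ifelse(is.na(vs$conf), ".",
                      formatC(vs$conf, format = "f", digits = 2)), nrow(v))
  samp <- matrix(paste(gt, cf, sep = ":"), nrow(v))
  body <- paste(v$contig, v$pos, v$variant_id, v$ref, v$alt, ".", ".",
                info_str, paste0("GT:", conf_id),
                apply(samp, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a discovery VCF into a variant set
#'
#' Parsing is delegated to `VariantAnnotation::readVcf`; the result is
#' mapped losslessly onto the [variant_set()] container. Genotype
#' confidence is taken from the `GC` FORMAT field for RAD data and `GQ`
#' for RNA data. Multiallelic rows are split into one biallelic record per
#' alternate allele with a warning.
#'
#' @param path VCF v4.2 path.
#' @param source "RAD" or "RNA".
#' @return a [variant_set()].
#' @export
read_vcf <- function(path, source = c("RAD", "RNA")) {
  source <- match.arg(source)
  v <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (any(lengths(VariantAnnotation::alt(v)) > 1)) {
    warning("multiallelic sites split into biallelic records")
    v <- VariantAnnotation::expand(v)
  }
  rr <- SummarizedExperiment::rowRanges(v)
  ref <- as.character(rr$REF)
  alt <- VariantAnnotation::alt(v)
  if (methods::is(alt, "DNAStringSetList") ||
      methods::is(alt, "CharacterList"))
    alt <- unlist(alt)   # guaranteed one ALT per row after expand()
  alt <- as.character(alt)
  vars <- data.frame(
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref, alt = alt,
    type = ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP", "InDel"),
    stringsAsFactors = FALSE)
  gt <- VariantAnnotation::geno(v)$GT
  calls <- matrix(NA_character_, nrow(gt), ncol(gt),
                  dimnames = dimnames(gt))
  calls[gt %in% c("0/0", "0|0")] <- "hom_ref"
  calls[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- "het"
  calls[gt %in% c("1/1", "1|1")] <- "hom_alt"
  conf_id <- if (source == "RAD") "GC" else "GQ"
  gen <- VariantAnnotation::geno(v)
  conf <- if (conf_id %in% names(gen)) {
    m <- gen[[conf_id]]
    storage.mode(m) <- "double"
    m
  } else {
    matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  }
  ann <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR")
  inf <- VariantAnnotation::info(v)
  cols <- intersect(ann, names(inf))
  info <- if (length(cols)) {
    as.data.frame(lapply(setNames(cols, cols), function(cc)
      as.numeric(unlist(inf[[cc]]))))
  } else NULL
  variant_set(vars, calls, conf, source = source, info = info)
}

#' Read and write mask interval BED files
#'
#' Masks are carried internally as a 1-based closed-interval data.frame
#' with columns `contig`, `start`, `end`, `type`; on disk they are standard
#' 0-based half-open BED with the type in the name field. Conversion is
#' delegated to rtracklayer/GenomicRanges.
#'
#' @param mask data.frame contig/start/end/type (1-based closed).
#' @param path BED path.
#' @return `read_mask_bed` returns the data.frame form.
#' @export
write_mask_bed <- function(mask, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = mask$contig,
    ranges = IRanges::IRanges(start = mask$start, end = mask$end),
    name = mask$type)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_mask_bed
#' @export
read_mask_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             type = gr$name %||% rep("lcr", length(gr)),
             stringsAsFactors = FALSE)
}

#' Read an array call matrix with sample metadata
#'
#' The calls table is CSV with sample ids in the first column and one
#' column per SNP; entries are `AA`/`AB`/`BB`/`NoCall` or the numeric
#' encoding `0`/`1`/`2`/`-1`. Metadata is joined on `sample_id` and must
#' cover every sample in the calls table.
#'
#' @param calls_path CSV of calls.
#' @param meta_path CSV with `sample_id` plus population/region/
#'   duplicate_of/dqc columns.
#' @return a [genotype_matrix()].
#' @export
read_calls <- function(calls_path, meta_path) {
  raw <- read.csv(calls_path, check.names = FALSE,
                  stringsAsFactors = FALSE)
  ids <- raw[[1]]
  m <- as.matrix(raw[, -1, drop = FALSE])
  out <- matrix(NA_integer_, nrow(m), ncol(m),
                dimnames = list(ids, colnames(m)))
  map <- c(AA = 0L, AB = 1L, BB = 2L, NoCall = NA_integer_,
           "0" = 0L, "1" = 1L, "2" = 2L, "-1" = NA_integer_)
  chr <- trimws(as.character(m))
  bad <- !(chr %in% names(map)) & !is.na(chr)
  if (any(bad)) {
    ij <- which(bad, arr.ind = FALSE)[1]
    rr <- (ij - 1) %% nrow(m) + 1
    cc <- (ij - 1) %/% nrow(m) + 1
    stop(sprintf("unknown genotype token '%s' at sample %s, SNP %s",
                 chr[ij], ids[rr], colnames(m)[cc]), call. = FALSE)
  }
  out[] <- map[chr]
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  if (!all(ids %in% meta$sample_id))
    stop("samples in calls missing from metadata: ",
         paste(head(setdiff(ids, meta$sample_id)), collapse = ", "),
         call. = FALSE)
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (!is.null(meta$duplicate_of))
    meta$duplicate_of[meta$duplicate_of %in% c("", "NA")] <- NA
  genotype_matrix(out, meta)
}

#' @rdname read_calls
#' @param gm a [genotype_matrix()] to write.
#' @export
write_calls <- function(gm, calls_path, meta_path) {
  lab <- c("AA", "AB", "BB")
  m <- matrix(ifelse(is.na(gm$calls), "NoCall", lab[gm$calls + 1L]),
              nrow(gm$calls), dimnames = dimnames(gm$calls))
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, calls_path, row.names = FALSE)
  write.csv(gm$samples, meta_path, row.names = FALSE)
  invisible(calls_path)
}
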