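# Readers/writers for the standard formats the pipeline consumes:
# FASTA transcripts (Biostrings), SNPs as minimal VCF 4.x (vcfR) or
# 4-column TSV, binding sites as BED (rtracklayer). All coordinates are
# converted to 1-based inclusive at this boundary.

#' Read / write transcript sequences as FASTA
#'
#' Sequences are normalised to uppercase RNA (T -> U) on read. Duplicate
#' record IDs and empty files are errors. IDs are the first whitespace
#' token of each header.
#'
#' @param path FASTA file path.
#' @return Named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  seqs <- vapply(as.character(set), norm_rna, character(1),
                 USE.NAMES = FALSE)
  setNames(seqs, ids)
}

#' @param seqs Named character vector of sequences.
#' @param width Line-wrap width.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read SNPs from minimal VCF or 4-column TSV
#'
#' VCF (`*.vcf`, `*.vcf.gz`): `CHROM` is the transcript ID and `POS` the
#' 1-based transcript coordinate. Multi-allelic records are split into
#' biallelic SNVs; records whose REF or an ALT is not a single nucleotide
#' are skipped and counted. TSV: columns
#' `transcript_id`, `pos` (1-based), `ref`, `alt` (header optional).
#' Alleles are normalised to RNA (T -> U).
#'
#' @param path Input path; format chosen by extension.
#' @return Data.frame with columns `transcript_id`, `pos` (integer,
#'   1-based), `ref`, `alt`; attribute `n_skipped_non_snv`.
#' @export
read_snps <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
    read_snps_vcf(path)
  else read_snps_tsv(path)
}

read_snps_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  out <- vector("list", nrow(fix))
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix[i, "REF"])
    alts <- strsplit(toupper(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]
    if (nchar(ref) != 1L || !ref %in% c("A", "C", "G", "T", "U")) {
      skipped <- skipped + length(alts)
      next
    }
    ok <- nchar(alts) == 1L & alts %in% c("A", "C", "G", "T", "U")
    skipped <- skipped + sum(!ok)
    alts <- alts[ok]
    if (!length(alts)) next
    out[[i]] <- data.frame(
      transcript_id = unname(fix[i, "CHROM"]),
      pos = as.integer(fix[i, "POS"]),
      ref = unname(chartr("T", "U", ref)),
      alt = unname(chartr("T", "U", alts)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(transcript_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0))
  rownames(res) <- NULL
  attr(res, "n_skipped_non_snv") <- skipped
  res
}

read_snps_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty SNP TSV: ", path, call. = FALSE)
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  has_header <- suppressWarnings(is.na(as.numeric(first[2])))
  body <- if (has_header) lines[-1] else lines
  out <- vector("list", length(body))
  skipped <- 0L
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L || is.na(suppressWarnings(as.integer(f[2]))))
      stop("malformed SNP TSV line ", i + has_header, ": ", body[i],
           call. = FALSE)
    ref <- chartr("T", "U", toupper(f[3]))
    alt <- chartr("T", "U", toupper(f[4]))
    if (nchar(ref) != 1L || nchar(alt) != 1L ||
        !all(c(ref, alt) %in% BASES)) {
      skipped <- skipped + 1L
      next
    }
    out[[i]] <- data.frame(transcript_id = f[1], pos = as.integer(f[2]),
                           ref = ref, alt = alt, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(transcript_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0))
  rownames(res) <- NULL
  attr(res, "n_skipped_non_snv") <- skipped
  res
}

#' Write SNPs as minimal VCF 4.2
#'
#' `CHROM` is the transcript ID, `POS` the 1-based coordinate; alleles
#' are written as DNA (U -> T) per VCF convention.
#'
#' @param snps Data.frame with `transcript_id`, `pos`, `ref`, `alt`.
#' @param path Output path.
#' @export
write_snps_vcf <- function(snps, path) {
  stopifnot(all(c("transcript_id", "pos", "ref", "alt") %in% names(snps)))
  header <- c("##fileformat=VCFv4.2",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                  snps$transcript_id, as.integer(snps$pos),
                  chartr("U", "T", snps$ref), chartr("U", "T", snps$alt))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write binding sites as BED
#'
#' BED intervals (0-based half-open) are converted to 1-based inclusive
#' on read and back on write. Coordinates are transcript coordinates;
#' only the first three columns are used.
#'
#' @param path BED file path.
#' @return Data.frame with `transcript_id`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_sites <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e)
                   stop("invalid BED file ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  if (any(IRanges::width(gr) < 1L))
    stop("BED interval with start >= end in ", path, call. = FALSE)
  if (any(GenomicRanges::start(gr) < 1L))
    stop("negative BED start in ", path, call. = FALSE)
  data.frame(transcript_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' @param sites Data.frame with `transcript_id`, `start`, `end`
#'   (1-based inclusive).
#' @rdname read_sites
#' @export
write_sites <- function(sites, path) {
  stopifnot(all(c("transcript_id", "start", "end") %in% names(sites)))
  gr <- GenomicRanges::GRanges(
    sites$transcript_id,
    IRanges::IRanges(start = sites$start, end = sites$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
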