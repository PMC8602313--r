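#' Read and write per-site pileup tables
#'
#' The pileup TSV is the alignment-free input format of the caller: one row
#' per read overlapping a candidate site, with columns `chrom`, `pos`
#' (1-based), `ref`, `alt`, `sample` (`"cell"` or `"bulk"`), `allele`
#' (`"REF"`, `"ALT"`, `"OTHER"`) and `base_qual` (PHRED). The same tibble
#' shape is produced by [extract_pileup()] and [simulate_dataset()].
#'
#' @param path File path.
#' @param pileup A pileup tibble.
#' @return `read_pileup_tsv()` returns the pileup tibble;
#'   `write_pileup_tsv()` returns `path` invisibly.
#' @export
read_pileup_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    ref = readr::col_character(),
    alt = readr::col_character(),
    sample = readr::col_character(),
    allele = readr::col_character(),
    base_qual = readr::col_double()
  ))
  bad <- setdiff(unique(out$sample), c("cell", "bulk"))
  if (length(bad) > 0) {
    stop("unknown sample label(s) in pileup: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @rdname read_pileup_tsv
#' @export
write_pileup_tsv <- function(pileup, path) {
  readr::write_tsv(pileup, path)
  invisible(path)
}

#' Read candidate sites from a VCF or TSV
#'
#' Candidate sites direct the caller to positions of interest (typically
#' alternative-allele candidates seen in the bulk). A `.vcf` file is parsed
#' minimally (CHROM, POS, REF, ALT); multiallelic records are split into one
#' biallelic candidate per alternative allele and non-SNV alleles are
#' dropped. Any other extension is read as a TSV with columns `chrom`,
#' `pos`, `ref`, `alt`.
#'
#' @param path File path.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
read_candidates <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
    if (length(ln) == 0) {
      return(tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character()))
    }
    f <- strsplit(ln, "\t", fixed = TRUE)
    out <- tibble::tibble(
      chrom = vapply(f, `[[`, "", 1L),
      pos = as.integer(vapply(f, `[[`, "", 2L)),
      ref = vapply(f, `[[`, "", 4L),
      alt = vapply(f, `[[`, "", 5L)
    )
    out <- tidyr::separate_rows(out, "alt", sep = ",")
  } else {
    out <- readr::read_tsv(path, col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character()
    ))
  }
  out <- out[nchar(out$ref) == 1 & nchar(out$alt) == 1 &
               out$alt %in% c("A", "C", "G", "T") & out$alt != out$ref, ]
  tibble::as_tibble(out)
}

#' Extract per-read pileups from alignment files
#'
#' Builds the read-level pileup at each candidate site from a single-cell
#' and a bulk alignment file (BAM, indexed). Each read overlapping a site is
#' classified as `REF`, `ALT`, or `OTHER` (any other base, a deletion, or a
#' reference skip spanning the site). Duplicate, unmapped and secondary
#' alignments are excluded; reads below `min_mapq` and base calls below
#' `min_baseq` are dropped. Positions are 1-based in all interfaces.
#'
#' @param sc_bam,bulk_bam Paths to indexed BAM files for the single cell and
#'   the bulk sample.
#' @param sites Candidate sites: a data frame with columns `chrom`, `pos`,
#'   `ref`, `alt` (see [read_candidates()]).
#' @param min_mapq Minimum mapping quality (default 0 = off).
#' @param min_baseq Minimum base quality (default 3).
#' @return A pileup tibble (see [read_pileup_tsv()]).
#' @export
extract_pileup <- function(sc_bam, bulk_bam, sites, min_mapq = 0,
                           min_baseq = 3) {
  for (pkg in c("Rsamtools", "GenomicRanges")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("package `", pkg, "` is required for BAM extraction",
           call. = FALSE)
    }
  }
  res <- list(
    .extract_one_bam(sc_bam, sites, "cell", min_mapq, min_baseq),
    .extract_one_bam(bulk_bam, sites, "bulk", min_mapq, min_baseq)
  )
  dplyr::bind_rows(res)
}

.extract_one_bam <- function(bam, sites, sample_label, min_mapq,
                             min_baseq) {
  if (!file.exists(bam)) stop("alignment file not found: ", bam,
                              call. = FALSE)
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, sites$pos))
  param <- Rsamtools::ScanBamParam(
    which = gr,
    what = c("pos", "cigar", "seq", "qual", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isDuplicate = FALSE,
                                  isSecondaryAlignment = FALSE)
  )
  chunks <- tryCatch(Rsamtools::scanBam(bam, param = param),
                     error = function(e) {
      stop("failed reading ", bam, ": ", conditionMessage(e), call. = FALSE)
    })
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    ch <- chunks[[i]]
    if (length(ch$pos) == 0) next
    keep <- is.na(ch$mapq) | ch$mapq >= min_mapq
    if (min_mapq > 0) keep <- !is.na(ch$mapq) & ch$mapq >= min_mapq
    alleles <- character(0)
    quals <- numeric(0)
    for (j in which(keep)) {
      hit <- .base_at(ch$pos[j], ch$cigar[j],
                      as.character(ch$seq[j]), as.character(ch$qual[j]),
                      sites$pos[i])
      if (is.null(hit)) next
      if (!is.na(hit$base) && hit$qual < min_baseq) next
      allele <- if (is.na(hit$base)) "OTHER"
        else if (hit$base == sites$ref[i]) "REF"
        else if (hit$base == sites$alt[i]) "ALT"
        else "OTHER"
      alleles <- c(alleles, allele)
      quals <- c(quals, hit$qual)
    }
    if (length(alleles) == 0) next
    out[[i]] <- tibble::tibble(
      chrom = sites$chrom[i], pos = sites$pos[i],
      ref = sites$ref[i], alt = sites$alt[i],
      sample = sample_label, allele = alleles, base_qual = quals
    )
  }
  dplyr::bind_rows(out)
}

# Walk a CIGAR string to find the read base and quality at a 1-based
# reference position; returns NULL if the read does not span the position,
# base = NA for a deletion or reference skip at the position.
.base_at <- function(aln_start, cigar, seq, qual, target) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  refc <- aln_start
  qryc <- 1L
  for (op in ops) {
    len <- as.integer(substr(op, 1, nchar(op) - 1))
    type <- substr(op, nchar(op), nchar(op))
    if (type %in% c("M", "=", "X")) {
      if (target >= refc && target < refc + len) {
        qpos <- qryc + (target - refc)
        return(list(base = substr(seq, qpos, qpos),
                    qual = utf8ToInt(substr(qual, qpos, qpos)) - 33))
      }
      refc <- refc + len
      qryc <- qryc + len
    } else if (type %in% c("D", "N")) {
      if (target >= refc && target < refc + len) {
        return(list(base = NA_character_, qual = NA_real_))
      }
      refc <- refc + len
    } else if (type %in% c("I", "S")) {
      qryc <- qryc + len
    } # H, P consume nothing
  }
  NULL
}
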