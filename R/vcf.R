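#' PHRED-scale probabilities
#'
#' Event posteriors are written to VCF on the PHRED scale,
#' \eqn{-10 \log_{10} p}, capped at 10000 so that zero probabilities stay
#' representable. Below the cap the round trip back to linear scale is
#' accurate to well under `1e-4`.
#'
#' @param p Probability vector.
#' @param phred PHRED-scaled vector.
#' @param cap Cap applied on the PHRED scale.
#' @return Numeric vector.
#' @examples
#' prob_to_phred(0.5)
#' phred_to_prob(prob_to_phred(0.25))
#' @export
prob_to_phred <- function(p, cap = 10000) {
  pmin(-10 * log10(p), cap)
}

#' @rdname prob_to_phred
#' @export
phred_to_prob <- function(phred) {
  10^(-phred / 10)
}

.prob_fields <- c(
  PROB_HOM_REF = "p_hom_ref", PROB_ERR_ALT = "p_err_alt",
  PROB_ADO_TO_ALT = "p_ado_to_alt", PROB_HET = "p_het",
  PROB_ADO_TO_REF = "p_ado_to_ref", PROB_ERR_REF = "p_err_ref",
  PROB_HOM_ALT = "p_hom_alt", PROB_ALT_PRESENCE = "p_alt_presence"
)

#' Write calls to VCF
#'
#' Emits a VCF 4.2 file with one biallelic record per called site. The
#' seven event posteriors and the alt-presence compound are stored as
#' PHRED-scaled INFO fields (`PROB_HOM_REF`, `PROB_ERR_ALT`,
#' `PROB_ADO_TO_ALT`, `PROB_HET`, `PROB_ADO_TO_REF`, `PROB_ERR_REF`,
#' `PROB_HOM_ALT`, `PROB_ALT_PRESENCE`); read depths and alternative counts
#' of both samples go to `SC_DP`/`SC_ALT`/`BULK_DP`/`BULK_ALT`, imputed
#' sites carry the `IMPUTED` flag, and the cell's genotype call is written
#' as the `GT` of the single sample column (with `DP`).
#'
#' Records must be sorted by contig and position; contig order follows the
#' order of first appearance in `calls`.
#'
#' @param calls A calls tibble from [call_sites()].
#' @param path Output file path.
#' @param sample_name Name for the single-cell sample column.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, sample_name = "CELL") {
  chrom_f <- factor(calls$chrom, levels = unique(calls$chrom))
  if (!identical(order(chrom_f, calls$pos), seq_len(nrow(calls)))) {
    stop("`calls` must be sorted by contig and position", call. = FALSE)
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mdavar",
    sprintf("##contig=<ID=%s>", unique(calls$chrom)),
    sprintf(paste0("##INFO=<ID=%s,Number=1,Type=Float,Description=",
                   "\"PHRED-scaled posterior probability of the %s ",
                   "single-cell event\">"),
            names(.prob_fields)[1:7],
            sub("^p_", "", unname(.prob_fields)[1:7])),
    paste0("##INFO=<ID=PROB_ALT_PRESENCE,Number=1,Type=Float,Description=",
           "\"PHRED-scaled posterior probability that the alternative ",
           "allele is present in the cell\">"),
    "##INFO=<ID=SC_DP,Number=1,Type=Integer,Description=\"Single-cell read depth (REF+ALT)\">",
    "##INFO=<ID=SC_ALT,Number=1,Type=Integer,Description=\"Single-cell ALT read count\">",
    "##INFO=<ID=BULK_DP,Number=1,Type=Integer,Description=\"Bulk read depth (REF+ALT)\">",
    "##INFO=<ID=BULK_ALT,Number=1,Type=Integer,Description=\"Bulk ALT read count\">",
    "##INFO=<ID=IMPUTED,Number=0,Type=Flag,Description=\"Genotype imputed from the bulk (zero single-cell coverage)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t")
  )
  fmt_p <- function(p) sprintf("%.6f", prob_to_phred(p))
  info <- vapply(seq_len(nrow(calls)), function(i) {
    if (is.na(calls$p_hom_ref[i])) return(".")
    parts <- sprintf("%s=%s", names(.prob_fields),
                     fmt_p(unlist(calls[i, unname(.prob_fields)])))
    parts <- c(parts,
               sprintf("SC_DP=%d", calls$l[i]),
               sprintf("SC_ALT=%d", calls$k[i]),
               sprintf("BULK_DP=%d", calls$n[i]),
               sprintf("BULK_ALT=%d", calls$m_obs[i]))
    if (isTRUE(calls$imputed[i])) parts <- c(parts, "IMPUTED")
    paste(parts, collapse = ";")
  }, character(1))
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")
  gt <- ifelse(is.na(calls$genotype), "./.", gt_code[calls$genotype])
  body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                ".", info, "GT:DP", paste0(gt, ":", calls$l), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a calls VCF back into a calls tibble
#'
#' Parses a VCF written by [write_calls()], reconstructing linear-scale
#' event posteriors from the PHRED-scaled INFO fields and re-deriving the
#' genotype call and compound posteriors with [genotype_call()], so that a
#' write/read round trip yields identical downstream FDR selections.
#'
#' @param path VCF file path.
#' @return A calls tibble (see [call_sites()]).
#' @export
read_calls <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  get_info <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
    vapply(m, function(x) if (length(x) == 2) as.numeric(x[2]) else NA_real_,
           numeric(1))
  }
  info <- vapply(f, `[[`, "", 8L)
  out <- tibble::tibble(
    chrom = vapply(f, `[[`, "", 1L),
    pos = as.integer(vapply(f, `[[`, "", 2L)),
    ref = vapply(f, `[[`, "", 4L),
    alt = vapply(f, `[[`, "", 5L),
    l = as.integer(get_info(info, "SC_DP")),
    k = as.integer(get_info(info, "SC_ALT")),
    n = as.integer(get_info(info, "BULK_DP")),
    m_obs = as.integer(get_info(info, "BULK_ALT"))
  )
  for (fld in names(.prob_fields)[1:7]) {
    out[[.prob_fields[[fld]]]] <- phred_to_prob(get_info(info, fld))
  }
  out$imputed <- ifelse(info == ".", NA, grepl("(?:^|;)IMPUTED(?:;|$)", info))
  genotype_call(out)
}
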