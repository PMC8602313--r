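# Alignment fixtures are generated programmatically: a small SAM is written
# as text and converted to an indexed BAM with Rsamtools at test time.

# one aligned read; pos is 1-based leftmost; qual is a single PHRED value
sam_read <- function(name, pos, seq, flag = 0, cigar = NULL, mapq = 60,
                     qual = 40) {
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  paste(name, flag, "chr1", pos, mapq, cigar, "*", 0, 0, seq,
        strrep(rawToChar(as.raw(qual + 33)), nchar(seq)), sep = "\t")
}

write_test_bam <- function(reads, dir, prefix) {
  sam <- file.path(dir, paste0(prefix, ".sam"))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               "@SQ\tSN:chr1\tLN:100",
               reads), sam)
  Rsamtools::asBam(sam, file.path(dir, prefix), overwrite = TRUE,
                   indexDestination = TRUE)
}

# reads spanning chr1:50 (offset 5 into a 10 bp read starting at 46);
# REF allele A, ALT allele T at the site
read_at_50 <- function(name, base, ...) {
  sam_read(name, 46, paste0("CCCC", base, "GGGGG"), ...)
}

cli_path <- function() {
  p <- system.file("exec", "mdavar", package = "mdavar")
  if (p == "") p <- file.path(find.package("mdavar"), "exec", "mdavar")
  p
}

run_cli <- function(...) {
  env <- paste0("R_LIBS=", paste(.libPaths(),
                                 collapse = .Platform$path.sep))
  out <- suppressWarnings(
    system2("Rscript", c(cli_path(), ...), stdout = TRUE, stderr = TRUE,
            env = env)
  )
  status <- attr(out, "status")
  list(output = out, status = if (is.null(status)) 0L else status)
}
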