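# Shared fixture builders; everything is generated in code at test time.

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

make_track <- function(scores, id = "P1", predictor = "vsl2b") {
  disorder_track(id, predictor, scores)
}

random_track <- function(n, id = "P1", predictor = "vsl2b") {
  disorder_track(id, predictor, runif(n))
}

# A small proteome with random canonical sequences.
random_group <- function(n = 5L, len = 40L, name = "grp") {
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "D", "E", "G", "K", "L", "P", "R", "S"),
                 len, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- sprintf("P%03d", seq_len(n))
  proteome_group(name, seqs)
}
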