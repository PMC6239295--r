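# Emit a HMMER3-style domtblout table from a DomainHit data.frame (23
# whitespace-separated fields; only the fields the parser consumes carry
# real values). Used to test parse/write round-tripping.
write_domtblout <- function(hits, path = NULL) {
  fmt_e <- function(x) formatC(x, format = "e", digits = 2)
  body <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    full_e <- if ("full_seq_e_value" %in% names(hits))
      h$full_seq_e_value else h$e_value
    paste(h$target_id, "-", 600, h$profile_id, "-", 80,
          fmt_e(full_e), 100.0, 1.0,
          1, 1, fmt_e(h$e_value), fmt_e(h$e_value),
          h$bit_score, 1.0, 1, 80, h$start, h$end, h$start, h$end,
          0.98, "synthetic", sep = " ")
  }, character(1))
  lines <- c("# target name accession tlen query name ...",
             "#------------------- ----------",
             body)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(path))
  }
  lines
}

# Random protein of length n under uniform residues.
random_protein <- function(n) {
  paste(sample(tpsminer:::AA20, n, replace = TRUE), collapse = "")
}
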