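# Test-only writer of minimal FCS 3.0 list-mode files (float32 data, little
# endian), used to exercise the reader round-trip without shipping binary
# fixtures.
write_test_fcs <- function(data, channel_names, path, version = "FCS3.0") {
  n_tot <- nrow(data)
  n_par <- ncol(data)
  kw <- c("$MODE", "L", "$DATATYPE", "F", "$BYTEORD", "1,2,3,4",
          "$PAR", n_par, "$TOT", n_tot)
  for (i in seq_len(n_par))
    kw <- c(kw, sprintf("$P%dN", i), channel_names[i],
            sprintf("$P%dB", i), 32L, sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), 262144L)
  text_seg <- paste0("|", paste(kw, collapse = "|"), "|")
  text_beg <- 58L
  text_end <- text_beg + nchar(text_seg) - 1L
  data_beg <- text_end + 1L
  data_end <- data_beg + 4L * n_par * n_tot - 1L
  header <- sprintf("%-6s    %8d%8d%8d%8d%8d%8d", version,
                    text_beg, text_end, data_beg, data_end, 0L, 0L)
  stopifnot(nchar(header) == 58L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text_seg, con, eos = NULL)
  writeBin(as.numeric(t(data)), con, size = 4L, endian = "little")
  invisible(path)
}
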