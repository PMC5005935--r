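# Minimal list-mode FCS 3.0/3.1 reader. Only what modern instruments emit for
# list-mode data is supported: $MODE L, $DATATYPE F/D/I, a single data
# segment, common byte orders. Anything else is rejected with a clear message.

read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (nchar(header) < 58L) stop("'", path, "' is too short to be an FCS file")
  version <- trimws(substr(header, 1L, 6L))
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version '", version,
         "' in '", path, "' (only FCS 3.0/3.1 are read)")
  off <- function(a, b) {
    v <- suppressWarnings(as.integer(trimws(substr(header, a, b))))
    if (is.na(v)) stop("malformed FCS header offsets in '", path,
                       "' (bytes ", a - 1L, "-", b - 1L, ")")
    v
  }
  text_beg <- off(11L, 18L); text_end <- off(19L, 26L)
  data_beg <- off(27L, 34L); data_end <- off(35L, 42L)

  seek(con, text_beg)
  txt <- readChar(con, text_end - text_beg + 1L, useBytes = TRUE)
  delim <- substr(txt, 1L, 1L)
  parts <- strsplit(substring(txt, 2L), delim, fixed = TRUE)[[1L]]
  if (length(parts) < 2L) stop("empty FCS TEXT segment in '", path, "'")
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2L, length(parts), 2L)],
                        trimws(parts[seq(1L, length(parts), 2L)]))
  need <- function(key) {
    if (is.na(kw[key]) || is.null(kw[key]))
      stop("FCS keyword ", key, " missing in '", path, "'")
    kw[[key]]
  }
  if (toupper(trimws(need("$MODE"))) != "L")
    stop("only list-mode ($MODE L) FCS data are supported")
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  dtype <- toupper(trimws(need("$DATATYPE")))
  byteord <- trimws(need("$BYTEORD"))
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little"
            else if (byteord %in% c("4,3,2,1", "2,1")) "big"
            else stop("unsupported $BYTEORD '", byteord, "'")
  bits <- vapply(seq_len(n_par), function(i)
    as.integer(need(sprintf("$P%dB", i))), integer(1L))
  ch <- vapply(seq_len(n_par), function(i)
    need(sprintf("$P%dN", i)), character(1L))

  if (data_beg == 0L && !is.na(kw["$BEGINDATA"])) {
    data_beg <- as.integer(kw[["$BEGINDATA"]])
    data_end <- as.integer(kw[["$ENDDATA"]])
  }
  seek(con, data_beg)
  n_values <- n_par * n_tot
  if (dtype %in% c("F", "D")) {
    size <- if (dtype == "F") 4L else 8L
    if (any(bits != size * 8L))
      stop("$PnB inconsistent with $DATATYPE ", dtype)
    raw_v <- readBin(con, "double", n = n_values, size = size,
                     endian = endian)
  } else if (dtype == "I") {
    if (length(unique(bits)) != 1L || !bits[1L] %in% c(16L, 32L))
      stop("integer FCS data are read only for uniform 16/32-bit $PnB")
    raw_v <- readBin(con, "integer", n = n_values, size = bits[1L] / 8L,
                     signed = bits[1L] > 16L, endian = endian)
  } else {
    stop("unsupported $DATATYPE '", dtype, "' (ASCII data not read)")
  }
  if (length(raw_v) < n_values)
    stop("FCS data segment of '", path, "' truncated: expected ",
         n_values, " values, got ", length(raw_v))
  data <- matrix(raw_v, nrow = n_tot, ncol = n_par, byrow = TRUE)
  list(data = data, channel_names = ch, keywords = kw)
}
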