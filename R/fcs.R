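# Minimal FCS 3.1 support: primary TEXT + DATA segments, list-mode,
# $DATATYPE F (single-precision float). Spillover/compensation keywords and
# ANALYSIS segments are ignored. This covers files written by this package
# and plain float list-mode exports; integer ($DATATYPE I) files are not
# supported.

FCS_DELIM <- "/"

write_events_fcs <- function(table, path) {
  ev <- table$events
  n <- nrow(ev)
  p <- ncol(ev)
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "############", "$ENDDATA" = "############",
    "$NEXTDATA" = "0",
    "$MODE" = "L", "$DATATYPE" = "F", "$BYTEORD" = "1,2,3,4",
    "$PAR" = as.character(p), "$TOT" = as.character(n)
  )
  for (i in seq_len(p)) {
    rng <- max(1, ceiling(max(ev[, i], 0, na.rm = TRUE)))
    kw[sprintf("$P%dN", i)] <- table$channels$marker[i]
    if (!is.na(table$channels$detector[i])) {
      kw[sprintf("$P%dS", i)] <- table$channels$detector[i]
    }
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- as.character(rng)
  }
  kw["SAMPLEID"] <- as.character(table$sample_id)
  kw["SCALESTATE"] <- table$scale_state
  if (table$scale_state == "transformed") {
    kw["TRANSFORMKIND"] <- table$transform$kind
    kw["TRANSFORMCOFACTOR"] <- format(table$transform$cofactor, digits = 17)
  }
  if (any(grepl(FCS_DELIM, c(names(kw), kw), fixed = TRUE))) {
    stop("keyword values may not contain the TEXT delimiter", call. = FALSE)
  }
  text <- paste0(FCS_DELIM,
                 paste0(names(kw), FCS_DELIM, kw, collapse = FCS_DELIM),
                 FCS_DELIM)
  text_begin <- 256L
  text_end <- text_begin + nchar(text) - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * n * p - 1L
  text <- sub("############", sprintf("%012d", data_begin), text, fixed = TRUE)
  text <- sub("############", sprintf("%012d", data_end), text, fixed = TRUE)

  hdr_off <- function(x) if (x <= 99999999) sprintf("%8d", x) else sprintf("%8d", 0)
  header <- paste0("FCS3.1    ",
                   hdr_off(text_begin), hdr_off(text_end),
                   hdr_off(data_begin), hdr_off(data_end),
                   hdr_off(0), hdr_off(0))
  pad <- strrep(" ", text_begin - nchar(header))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(header, pad, text), con, eos = NULL)
  if (n * p > 0) {
    writeBin(as.vector(t(ev)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

read_events_fcs <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = sz)
  magic <- rawToChar(raw[1:6])
  if (!magic %in% c("FCS3.0", "FCS3.1")) {
    stop(sprintf("format error: not an FCS 3.x file: %s", path), call. = FALSE)
  }
  off <- function(i) {
    s <- trimws(rawToChar(raw[(10 + 8 * (i - 1) + 1):(10 + 8 * i)]))
    if (s == "") 0L else as.integer(s)
  }
  text_begin <- off(1); text_end <- off(2)
  data_begin <- off(3); data_end <- off(4)
  text <- rawToChar(raw[(text_begin + 1):(text_end + 1)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substr(text, 2, nchar(text)), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 != 0) parts <- parts[seq_len(length(parts) - 1)]
  keys <- parts[seq(1, length(parts), 2)]
  vals <- parts[seq(2, length(parts), 2)]
  kw <- stats::setNames(vals, toupper(trimws(keys)))

  if (toupper(kw[["$DATATYPE"]]) != "F") {
    stop("format error: only $DATATYPE F is supported", call. = FALSE)
  }
  byteord <- kw[["$BYTEORD"]]
  endian <- if (byteord %in% c("1,2,3,4")) "little" else "big"
  p <- as.integer(kw[["$PAR"]])
  n <- as.integer(kw[["$TOT"]])
  if (data_begin == 0) data_begin <- as.integer(kw[["$BEGINDATA"]])
  mk <- vapply(seq_len(p), function(i) kw[[sprintf("$P%dN", i)]], character(1))
  det <- vapply(seq_len(p), function(i) {
    k <- sprintf("$P%dS", i)
    if (k %in% names(kw)) kw[[k]] else NA_character_
  }, character(1))

  vals <- if (n * p > 0) {
    readBin(raw[(data_begin + 1):length(raw)], "double", n = n * p,
            size = 4L, endian = endian)
  } else numeric(0)
  ev <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)

  scale_state <- if (identical(kw[["SCALESTATE"]], "transformed"))
    "transformed" else "raw"
  tr <- NULL
  if (scale_state == "transformed") {
    tr <- transform_spec(kw[["TRANSFORMKIND"]],
                         as.numeric(kw[["TRANSFORMCOFACTOR"]]))
  }
  event_table(ev, markers = mk, detectors = det,
              sample_id = if ("SAMPLEID" %in% names(kw)) kw[["SAMPLEID"]]
                          else sub("\\.[^.]*$", "", basename(path)),
              scale_state = scale_state, transform = tr)
}
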