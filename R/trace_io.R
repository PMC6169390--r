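#' Read a chromatogram trace from file
#'
#' Dispatches on content: files beginning with the `ABIF` magic bytes are
#' parsed as binary ABIF (`.ab1`) traces ([read_abif()]); anything else is
#' parsed as the package's plain-text trace dialect ([read_trace_text()]).
#'
#' @param path Path to an `.ab1` file or a plain-text trace.
#' @return A [trace_data()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) == 4L && rawToChar(magic) == "ABIF") {
    read_abif(path)
  } else {
    read_trace_text(path)
  }
}

# ---------------------------------------------------------------------------
# Plain-text trace dialect:
#   lines starting with '#' are comments;
#   a '[channels]' section with a header line 'A<TAB>C<TAB>G<TAB>T' followed
#   by one tab-separated intensity row per scan point;
#   a '[peaks]' section with one 'position<TAB>base' line per called base.

#' Read the plain-text trace dialect
#'
#' @param path Path to a text trace written by [write_trace_text()] (or by
#'   any tool emitting the same layout; see Details in [read_trace()]).
#' @return A [trace_data()].
#' @export
read_trace_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines, which = "right")
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  ich <- match("[channels]", lines)
  ipk <- match("[peaks]", lines)
  if (is.na(ich) || is.na(ipk) || ipk <= ich) {
    stop("malformed trace file: need a [channels] then a [peaks] section",
         call. = FALSE)
  }
  head_line <- strsplit(lines[ich + 1L], "\t", fixed = TRUE)[[1]]
  if (!identical(head_line, c("A", "C", "G", "T"))) {
    stop("malformed trace file: channel header must be A C G T",
         call. = FALSE)
  }
  ch_lines <- lines[seq(ich + 2L, ipk - 1L)]
  ch <- do.call(rbind, lapply(strsplit(ch_lines, "\t", fixed = TRUE),
                              as.numeric))
  if (is.null(ch) || ncol(ch) != 4L || anyNA(ch)) {
    stop("malformed trace file: bad channel rows", call. = FALSE)
  }
  colnames(ch) <- c("A", "C", "G", "T")
  pk_lines <- lines[seq(ipk + 1L, length(lines))]
  if (length(pk_lines) < 1L) {
    stop("malformed trace file: missing peak index", call. = FALSE)
  }
  parts <- strsplit(pk_lines, "\t", fixed = TRUE)
  pos <- as.integer(vapply(parts, `[`, character(1), 1L))
  base <- vapply(parts, `[`, character(1), 2L)
  if (anyNA(pos) || anyNA(base)) {
    stop("malformed trace file: bad peak rows", call. = FALSE)
  }
  trace_data(ch, peak_positions = pos, called_bases = base)
}

#' Write a trace in the plain-text dialect
#'
#' @param trace A [trace_data()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_text <- function(trace, path) {
  stopifnot(inherits(trace, "trace_data"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# chromatogram trace, text dialect v1",
               "[channels]",
               paste(c("A", "C", "G", "T"), collapse = "\t")), con)
  ch <- trace$channels
  rows <- apply(matrix(sprintf("%.12g", ch), nrow = nrow(ch)), 1L,
                paste, collapse = "\t")
  writeLines(rows, con)
  writeLines("[peaks]", con)
  writeLines(paste(trace$peak_positions, trace$called_bases, sep = "\t"),
             con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# ABIF binary format (Applied Biosystems .ab1). Big-endian; a 128-byte header
# holds the magic, version and the root directory entry; each 28-byte
# directory entry is name(4) number(i4) elemtype(i2) elemsize(i2)
# numelements(i4) datasize(i4) dataoffset(i4) datahandle(i4); data of four
# bytes or fewer is stored inside the dataoffset field itself.

abif_int <- function(raw, off, size) {
  # off: 0-based byte offset into `raw`
  readBin(raw[(off + 1L):(off + size)], "integer", n = 1L, size = size,
          endian = "big", signed = TRUE)
}

#' Read an ABIF (.ab1) chromatogram
#'
#' Minimal ABIF parser extracting what allele quantification needs: the four
#' processed intensity channels (`DATA` tags 9-12, mapped to bases via the
#' `FWO_` filter-wheel-order tag), the called-peak scan positions (`PLOC`,
#' converted from the format's 0-based indices to 1-based), and the base
#' calls (`PBAS`).
#'
#' @param path Path to an `.ab1` file.
#' @return A [trace_data()].
#' @export
read_abif <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 128L || rawToChar(raw[1:4]) != "ABIF") {
    stop("not an ABIF file: ", path, call. = FALSE)
  }
  read_entry <- function(off) {
    list(name = rawToChar(raw[(off + 1L):(off + 4L)]),
         number = abif_int(raw, off + 4L, 4L),
         elemtype = abif_int(raw, off + 8L, 2L),
         elemsize = abif_int(raw, off + 10L, 2L),
         numelements = abif_int(raw, off + 12L, 4L),
         datasize = abif_int(raw, off + 16L, 4L),
         dataoffset = abif_int(raw, off + 20L, 4L),
         raw_offset = off)
  }
  root <- read_entry(6L)
  if (root$name != "tdir") stop("malformed ABIF directory", call. = FALSE)
  entries <- lapply(seq_len(root$numelements) - 1L,
                    function(i) read_entry(root$dataoffset + 28L * i))
  entry_data <- function(e) {
    if (e$datasize <= 4L) {
      # inline: the four bytes of the dataoffset field
      raw[(e$raw_offset + 21L):(e$raw_offset + 20L + e$datasize)]
    } else {
      raw[(e$dataoffset + 1L):(e$dataoffset + e$datasize)]
    }
  }
  find <- function(name, numbers) {
    for (num in numbers) {
      for (e in entries) {
        if (e$name == name && e$number == num) return(e)
      }
    }
    NULL
  }
  as_shorts <- function(e) {
    readBin(entry_data(e), "integer", n = e$numelements, size = 2L,
            endian = "big", signed = TRUE)
  }
  fwo <- find("FWO_", 1L)
  order <- if (is.null(fwo)) c("G", "A", "T", "C") else
    strsplit(rawToChar(entry_data(fwo)), "")[[1]]
  if (!setequal(order, c("A", "C", "G", "T"))) {
    stop("bad FWO_ channel order in ABIF file", call. = FALSE)
  }
  ch <- list()
  for (i in 1:4) {
    e <- find("DATA", 8L + i)
    if (is.null(e)) stop("missing DATA tag ", 8L + i, call. = FALSE)
    ch[[order[i]]] <- as_shorts(e)
  }
  len <- unique(vapply(ch, length, integer(1)))
  if (length(len) != 1L) {
    stop("ABIF channels have unequal lengths", call. = FALSE)
  }
  channels <- cbind(A = ch$A, C = ch$C, G = ch$G, T = ch$T)
  channels[channels < 0] <- 0
  ploc <- find("PLOC", c(2L, 1L))
  if (is.null(ploc)) stop("missing PLOC peak index in ABIF file",
                          call. = FALSE)
  positions <- as_shorts(ploc) + 1L
  pbas <- find("PBAS", c(2L, 1L))
  calls <- if (is.null(pbas)) rep(NA_character_, length(positions)) else
    strsplit(rawToChar(entry_data(pbas)), "")[[1]]
  trace_data(channels, peak_positions = positions, called_bases = calls)
}

#' Write a minimal ABIF (.ab1) chromatogram
#'
#' Writes the channels, peak index and base calls of a [trace_data()] as a
#' minimal ABIF file readable by [read_abif()] (tags `DATA` 9-12, `FWO_`,
#' `PLOC` 2, `PBAS` 2). Intensities are rounded and clipped to the int16
#' range of the format. Intended for generating test fixtures and small
#' synthetic traces; real sequencer files carry many more tags.
#'
#' @param trace A [trace_data()].
#' @param path Output path (conventionally `.ab1`).
#' @return `path`, invisibly.
#' @export
write_abif <- function(trace, path) {
  stopifnot(inherits(trace, "trace_data"))
  order <- c("A", "C", "G", "T")
  to_short <- function(x) as.integer(pmin(pmax(round(x), 0), 32767))
  blocks <- list()
  entries <- list()
  offset <- 128L  # data section starts after the fixed-size header
  add <- function(name, number, elemtype, elemsize, values, raw_data) {
    n <- length(values)
    size <- as.integer(n * elemsize)
    if (size <= 4L) {
      pad <- as.raw(rep(0L, 4L - size))
      entries[[length(entries) + 1L]] <<- list(
        name = name, number = number, elemtype = elemtype,
        elemsize = elemsize, n = n, size = size,
        offset_raw = c(raw_data, pad), offset = NA_integer_)
    } else {
      entries[[length(entries) + 1L]] <<- list(
        name = name, number = number, elemtype = elemtype,
        elemsize = elemsize, n = n, size = size,
        offset_raw = NULL, offset = offset)
      blocks[[length(blocks) + 1L]] <<- raw_data
      offset <<- offset + size
    }
  }
  short_raw <- function(x) writeBin(to_short(x), raw(), size = 2L,
                                    endian = "big")
  for (i in 1:4) {
    v <- trace$channels[, order[i]]
    add("DATA", 8L + i, 4L, 2L, v, short_raw(v))
  }
  add("FWO_", 1L, 2L, 1L, 1:4, charToRaw(paste(order, collapse = "")))
  add("PLOC", 2L, 4L, 2L, trace$peak_positions,
      short_raw(trace$peak_positions - 1L))
  calls <- paste(trace$called_bases, collapse = "")
  add("PBAS", 2L, 2L, 1L, seq_len(nchar(calls)), charToRaw(calls))

  dir_offset <- offset
  entry_raw <- function(name, number, elemtype, elemsize, n, size,
                        data_offset_raw) {
    c(charToRaw(name),
      writeBin(as.integer(number), raw(), size = 4L, endian = "big"),
      writeBin(as.integer(elemtype), raw(), size = 2L, endian = "big"),
      writeBin(as.integer(elemsize), raw(), size = 2L, endian = "big"),
      writeBin(as.integer(n), raw(), size = 4L, endian = "big"),
      writeBin(as.integer(size), raw(), size = 4L, endian = "big"),
      data_offset_raw,
      writeBin(0L, raw(), size = 4L, endian = "big"))
  }
  dir_raw <- unlist(lapply(entries, function(e) {
    off_raw <- if (!is.null(e$offset_raw)) e$offset_raw else
      writeBin(as.integer(e$offset), raw(), size = 4L, endian = "big")
    entry_raw(e$name, e$number, e$elemtype, e$elemsize, e$n, e$size, off_raw)
  }))
  header <- c(
    charToRaw("ABIF"),
    writeBin(101L, raw(), size = 2L, endian = "big"),
    entry_raw("tdir", 1L, 1023L, 28L, length(entries),
              28L * length(entries),
              writeBin(as.integer(dir_offset), raw(), size = 4L,
                       endian = "big"))
  )
  header <- c(header, as.raw(rep(0L, 128L - length(header))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  for (b in blocks) writeBin(b, con)
  writeBin(dir_raw, con)
  invisible(path)
}
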