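# Little-endian raw-buffer primitives for the container format.
# Writers accumulate raw chunks in a list (concatenated once at the end);
# the reader walks a raw vector with a cursor kept in an environment.

new_wbuf <- function() {
  e <- new.env(parent = emptyenv())
  e$chunks <- vector("list", 64L)
  e$i <- 0L
  e
}

wbuf_put <- function(buf, raw) {
  buf$i <- buf$i + 1L
  if (buf$i > length(buf$chunks)) buf$chunks <- c(buf$chunks, vector("list", length(buf$chunks)))
  buf$chunks[[buf$i]] <- raw
  invisible(buf)
}

wbuf_raw <- function(buf) {
  out <- unlist(buf$chunks[seq_len(buf$i)], use.names = FALSE)
  if (is.null(out)) raw(0) else out
}

w_u8  <- function(x) writeBin(as.integer(x), raw(), size = 1L, endian = "little")
w_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
w_i32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
w_i16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
w_f32 <- function(x) writeBin(as.numeric(x), raw(), size = 4L, endian = "little")
w_f64 <- function(x) writeBin(as.numeric(x), raw(), size = 8L, endian = "little")
w_str <- function(s) {
  b <- charToRaw(enc2utf8(as.character(s)))
  c(w_u16(length(b)), b)
}

new_rcur <- function(raw) {
  e <- new.env(parent = emptyenv())
  e$raw <- raw
  e$pos <- 0L   # bytes consumed
  e$decoded_payload_bytes <- 0
  e
}

rcur_left <- function(cur) length(cur$raw) - cur$pos

rcur_take <- function(cur, n) {
  if (rcur_left(cur) < n) stop("short read: stream truncated", call. = FALSE)
  out <- cur$raw[(cur$pos + 1L):(cur$pos + n)]
  cur$pos <- cur$pos + as.integer(n)
  out
}

rcur_skip <- function(cur, n) {
  if (rcur_left(cur) < n) stop("short read: stream truncated", call. = FALSE)
  cur$pos <- cur$pos + as.integer(n)
  invisible(cur)
}

r_u8  <- function(cur) readBin(rcur_take(cur, 1L), "integer", size = 1L, signed = FALSE, endian = "little")
r_u16 <- function(cur) readBin(rcur_take(cur, 2L), "integer", size = 2L, signed = FALSE, endian = "little")
r_i32 <- function(cur, n = 1L) readBin(rcur_take(cur, 4L * n), "integer", size = 4L, n = n, endian = "little")
r_i16 <- function(cur, n = 1L) readBin(rcur_take(cur, 2L * n), "integer", size = 2L, n = n, endian = "little")
r_f32 <- function(cur, n = 1L) readBin(rcur_take(cur, 4L * n), "double", size = 4L, n = n, endian = "little")
r_f64 <- function(cur, n = 1L) readBin(rcur_take(cur, 8L * n), "double", size = 8L, n = n, endian = "little")
r_str <- function(cur) {
  n <- r_u16(cur)
  if (n == 0L) return("")
  rawToChar(rcur_take(cur, n))
}

# Read an entire (possibly gzip-compressed) file tolerantly: a truncated
# compressed stream yields the decompressed prefix plus truncated = TRUE
# instead of an error, so partial packet recovery is possible upstream.
read_stream_raw <- function(path, compressed = TRUE) {
  con <- if (compressed) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  chunks <- list()
  truncated <- FALSE
  repeat {
    chunk <- tryCatch(readBin(con, "raw", n = 1048576L),
                      error = function(e) { truncated <<- TRUE; raw(0) },
                      warning = function(w) { truncated <<- TRUE; raw(0) })
    if (length(chunk) == 0L) break
    chunks[[length(chunks) + 1L]] <- chunk
  }
  list(raw = unlist(chunks, use.names = FALSE), truncated = truncated)
}
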