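# internal helpers

NM_PER_ANGSTROM <- 0.1
ANGSTROM_PER_NM <- 10

# FNV-1a 32-bit hash of a character scalar; used to stamp outputs with a
# config fingerprint without an external digest dependency
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; keep h a double to stay in 2^32
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    # 32-bit modular multiply split in 16-bit halves (doubles stay exact)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %%
      4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# parse "a-b" / "a" tokens into an integer vector
parseRanges <- function(tokens) {
  out <- integer(0)
  for (tok in tokens) {
    if (grepl("^[0-9]+-[0-9]+$", tok)) {
      ab <- as.integer(strsplit(tok, "-", fixed = TRUE)[[1]])
      if (ab[2] < ab[1]) stop("empty residue range: ", tok)
      out <- c(out, ab[1]:ab[2])
    } else if (grepl("^[0-9]+$", tok)) {
      out <- c(out, as.integer(tok))
    } else {
      stop("cannot parse residue token: '", tok, "'")
    }
  }
  out
}

writeTSVWithMeta <- function(df, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
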