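# deterministic per-replicate child seed; stays below 2^31 - 1
childSeed <- function(seed, r) {
  as.integer((as.double(seed) %% 2147483629 * 48271 + r * 9973) %% 2147483629)
}

writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
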