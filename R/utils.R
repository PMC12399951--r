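#' @importFrom rlang .data %||%
NULL

pkg_version <- function() {
  as.character(utils::packageVersion("tootree"))
}

# every TSV the package writes starts with commented provenance lines;
# the readers skip them
write_tsv_provenance <- function(df, path, seed = NULL, config_hash = NULL) {
  header <- c(
    sprintf("# tootree %s", pkg_version()),
    sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    if (!is.null(seed)) sprintf("# seed: %s", seed),
    if (!is.null(config_hash)) sprintf("# config_hash: %s", config_hash))
  writeLines(header, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_tsv_quiet <- function(path, col_types = NULL) {
  readr::read_tsv(path, comment = "#", col_types = col_types,
                  progress = FALSE, show_col_types = FALSE)
}

# stable short hash for provenance headers (no digest dependency):
# fold the serialized object through a 32-bit FNV-1a
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2)[-seq_len(14)])
  hash <- 2166136261
  for (b in bytes) {
    hash <- bitwXor(as.integer(hash %% 2^31), b)
    hash <- (hash * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(hash %% 2^31))
}
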